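test_that("ensembles are reproducible and seed-sensitive", {
  net <- constitutive_net()
  e1 <- simulate_ensemble(net, N = 200, t_grid = seq(0, 5, 1), seed = 7)
  e2 <- simulate_ensemble(net, N = 200, t_grid = seq(0, 5, 1), seed = 7)
  e3 <- simulate_ensemble(net, N = 200, t_grid = seq(0, 5, 1), seed = 8)
  expect_identical(e1$counts, e2$counts)
  expect_false(identical(e1$counts, e3$counts))
  # trajectory streams are independent of ensemble size: the first
  # trajectories of a larger ensemble reproduce the smaller one
  e4 <- simulate_ensemble(net, N = 300, t_grid = seq(0, 5, 1), seed = 7)
  expect_identical(e4$counts[, , 1:200], e1$counts)
})

test_that("geometric burst sampler has the right law", {
  expect_true(all(sample_geometric_burst(1000, 0, seed = 1) == 0))
  k <- sample_geometric_burst(1e6, 0.5, seed = 2)
  se <- sd(k) / sqrt(length(k))
  expect_lt(abs(mean(k) - 1), 3 * se)             # B = p/(1-p) = 1
  k2 <- sample_geometric_burst(1e6, 0.75, seed = 3)
  expect_lt(abs(mean(k2) - 3), 3 * sd(k2) / sqrt(length(k2)))
  # full distribution: P(k = n) = p^n (1 - p)
  emp <- tabulate(k + 1L, 8) / length(k)
  expect_lt(max(abs(emp - 0.5^(1:8))), 5e-3)
  expect_error(sample_geometric_burst(10, 1.2), "p")
})

test_that("constitutive bursty mean matches rho*B/d within Monte Carlo error", {
  net <- constitutive_net()  # rho = 2, B = 3, d = 1 -> mean 6
  ens <- simulate_ensemble(net, N = 10000, t_grid = c(0, 12), seed = 5)
  n_end <- ens$counts["P1", 2, ]
  se <- sd(n_end) / sqrt(length(n_end))
  expect_lt(abs(mean(n_end) - 6), 3 * se)
})

test_that("telegraph ensembles converge to the FSP distribution", {
  tel <- telegraph_net()
  d_fsp <- fsp_steady(telegraph_params(1, 1, 0, 10, 1, 0.5))
  ens <- simulate_ensemble(tel, N = 1e5, t_grid = c(0, 6, 12), seed = 3,
                           species = c("G1*", "P1"))
  d_emp <- empirical_distribution(ens, "P1", 12)
  expect_lt(hellinger(d_emp, d_fsp), 0.02)
  # HD decreases roughly like N^(-1/2)
  hds <- vapply(c(1000, 4000, 16000), function(N) {
    e <- simulate_ensemble(tel, N = N, t_grid = c(0, 12), seed = 11)
    hellinger(empirical_distribution(e, "P1", 12), d_fsp)
  }, 0)
  expect_true(all(diff(hds) < 0))
  expect_lt(hds[3], hds[1] / 2)
})

test_that("empirical distributions are normalized histograms", {
  net <- constitutive_net()
  ens <- simulate_ensemble(net, N = 1, t_grid = c(0, 3), seed = 2)
  d <- empirical_distribution(ens, "P1", 3)
  expect_equal(sum(d$p), 1)
  expect_equal(sum(d$p == 1), 1)     # a single trajectory is a point mass
  expect_error(empirical_distribution(ens, "X", 3), "unknown species")
  expect_error(empirical_distribution(ens, "P1", 2.5), "grid")
})

test_that("gene-state indicators stay consistent along trajectories", {
  net <- autoreg_h1()
  ens <- simulate_ensemble(net, N = 50, t_grid = seq(0, 10, 2), seed = 13)
  expect_true(all(ens$counts["G1", , ] + ens$counts["G1*", , ] == 1))
  expect_true(all(ens$counts >= 0))
})

test_that("sample conditional moments are the empirical factorial moments", {
  net <- autoreg_h1()
  ens <- simulate_ensemble(net, N = 2000, t_grid = c(0, 8), seed = 17)
  scm <- sample_conditional_moments(ens, 1, 8, order = 2)
  expect_equal(sum(scm$g), 1)
  s <- ens$counts["G1*", 2, ]; n <- ens$counts["P1", 2, ]
  expect_equal(scm$mu[1, 1], mean(n * (s == 0)))
  expect_equal(scm$mu[2, 2], mean(n * (n - 1) * (s == 1)))
  # all trajectories in one state with equal counts: falling factorials
  ens1 <- simulate_ensemble(constitutive_net(rho = 0), N = 10,
                            t_grid = c(0, 1), seed = 1,
                            init = c(P1 = 3))
  scm1 <- sample_conditional_moments(ens1, 1, 0, order = 2)
  expect_equal(scm1$g, c(1, 0))
  expect_equal(scm1$mu[1, 1], 3)
  expect_equal(scm1$mu[2, 1], 6)     # 3 * 2
  expect_true(scm1$missing_state[2])
})

test_that("ensemble moments track the moment-equation solution", {
  tel <- telegraph_net()
  ms <- derive_moment_system(tel, K = 2)
  out <- integrate_moments(ms, t_grid = c(0, 3))
  y <- out[2, -1]
  ens <- simulate_ensemble(tel, N = 20000, t_grid = c(0, 3), seed = 23)
  scm <- sample_conditional_moments(ens, 1, 3, order = 1)
  mu11_ode <- y[holimap:::moment_pos(ms, 1L, 1L)]
  n <- ens$counts["P1", 2, ]; s <- ens$counts["G1*", 2, ]
  se <- sd(n * (s == 1)) / sqrt(length(n))
  expect_lt(abs(scm$mu[1, 2] - mu11_ode), 3 * se)
})

test_that("Michaelis-Menten propensities follow the stated rate law", {
  rs <- build_fixture("phosphorylation")
  x <- stats::setNames(c(1, 0, 10, 5, 2), rs$species)
  a <- propensities(rs, x)
  mm1 <- which(vapply(rs$reactions, function(r)
    r$kind == "mm" && r$mm_sub == match("P", rs$species), TRUE))[1]
  V <- rs$reactions[[mm1]]$rate; K <- rs$reactions[[mm1]]$mm_K
  expect_equal(a[1, mm1], V * 10 / (K + 10))
})
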