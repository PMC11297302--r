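test_that("conditional-mean (LMA) rates follow the defining formula", {
  net <- autoreg_h1()
  st <- example_moment_state(net)
  par <- lma_params(st, net)
  expect_equal(par$s_on, 0.1 * 2 / 0.5)   # sigma_b mu_{1,0} / g_0 = 0.4
  expect_equal(par$s_off, 1)              # unbinding rate unchanged

  # zero conditional mean gives zero switch-on rate
  st0 <- moment_state(net, 2)
  st0 <- moment_entry(st0, 0L, 0L, 1)
  expect_equal(lma_params(st0, net)$s_on, 0)

  # h = 2: conditional falling-factorial mean; Poisson(4) oracle
  net2 <- build_autoreg(sigma_b = 0.1, sigma_u = 1, rho_b = 50, rho_u = 1,
                        d = 1, h = 2, p = 0.5)
  lam <- 4
  st2 <- moment_state(net2, 2)
  st2 <- moment_entry(st2, 0L, 0L, 1)
  st2 <- moment_entry(st2, 0L, 1L, lam)       # Poisson factorial moments
  st2 <- moment_entry(st2, 0L, 2L, lam^2)     # are powers of lambda
  expect_equal(lma_params(st2, net2)$s_on, 0.1 * lam^2)
})

test_that("two-parameter matching solves the documented 2x2 system", {
  net <- autoreg_h1()
  par <- hm2_params(example_moment_state(net), net)
  # independent linear solve of
  #   su~ g1 - sb~ g0 = su g1 - sb mu10 ; su~ mu11 - sb~ mu10 = su mu11 - sb mu20
  A <- rbind(c(0.5, -0.5), c(4, -2))
  b <- c(1 * 0.5 - 0.1 * 2, 1 * 4 - 0.1 * 6)
  x <- solve(A, b)
  expect_equal(par$s_off, x[1], tolerance = 1e-10)   # 1.1
  expect_equal(par$s_on, x[2], tolerance = 1e-10)    # 0.5
})

test_that("matching is the identity for unregulated genes", {
  tel <- telegraph_net(s_on = 0.7, s_off = 1.3)
  ms <- derive_moment_system(tel, K = 2)
  y <- steady_state_moments(ms)
  st <- moment_state(tel, 2)
  st$y <- as.vector(y)
  for (fn in list(hm2_params, hm4_params)) {
    par <- fn(st, tel)
    expect_equal(par$s_on, 0.7, tolerance = 1e-7)
    expect_equal(par$s_off, 1.3, tolerance = 1e-7)
    expect_equal(par$rho0, 0, tolerance = 1e-7)
    expect_equal(par$rho1, 10, tolerance = 1e-6)
  }
})

test_that("degenerate matching falls back with a recorded warning", {
  net <- autoreg_h1()
  # equal conditional means make the switching system singular
  st <- moment_state(net, 2)
  st <- moment_entry(st, 0L, 0L, 0.5)
  st <- moment_entry(st, 1L, 0L, 0.5)
  st <- moment_entry(st, 0L, 1L, 2)
  st <- moment_entry(st, 1L, 1L, 2)
  st <- moment_entry(st, 0L, 2L, 6)
  par <- hm2_params(st, net, negative = "clamp")
  expect_true(any(grepl("singular|conditional-mean", attr(par, "notes"))))
})

test_that("matching residuals vanish at a converged fit", {
  net <- autoreg_h1()
  fit <- holimap(net, method = "hm2", mode = "steady", negative = "clamp")
  res <- residuals(fit)
  expect_lt(max(abs(res)), 1e-6)
  fit4 <- holimap(net, method = "hm4", mode = "steady", negative = "clamp")
  expect_lt(max(abs(residuals(fit4))), 1e-6)
})

test_that("4-HM self-consistency: refitting the converged moments returns
          the same parameters", {
  net <- autoreg_h1()
  fit <- holimap(net, method = "hm4", mode = "steady", negative = "clamp")
  cl <- fit$closure
  par2 <- holimap:::match_core(cl, fit$moments, negative = "clamp")
  expect_equal(unname(par2[1, 1:4]),
               unname(unlist(fit$params[1, c("s_on", "s_off",
                                             "rho0", "rho1")])),
               tolerance = 1e-8)
})

test_that("negative effective rates raise unless clamping is requested", {
  # large binding/unbinding rates push the 4-HM matching negative
  tog <- build_fixture("toggle")
  ms <- derive_moment_system(tog, K = 3)
  # moments of the true (bimodal) stationary state, from a long ensemble
  ens <- simulate_ensemble(tog, N = 400, t_grid = c(0, 30), seed = 4)
  cnt <- ens$counts[, 2, ]
  st <- moment_state(tog, 3)
  for (i in seq_along(st$idx$keys)) {
    s <- st$idx$s[i]; m <- st$idx$m[i, ]
    ind <- (cnt["G1*", ] == bitwAnd(s, 1L)) &
      (cnt["G2*", ] == bitwAnd(bitwShiftR(s, 1L), 1L))
    st$y[i] <- mean(ff(cnt["P1", ], m[1]) * ff(cnt["P2", ], m[2]) * ind)
  }
  expect_error(hm4_params(st, tog, negative = "error"), "negative")
  par <- hm4_params(st, tog, negative = "clamp")
  expect_true(all(par$s_on >= 0))
  expect_true(any(grepl("clamped", attr(par, "notes"))))
})

test_that("hybrid matching agrees with the closure rows on exact moments", {
  # feed the same conditional moments through both implementations
  net <- autoreg_h1()
  rs <- compile_reactions(net)
  ens <- simulate_ensemble(net, N = 3000, t_grid = c(0, 4, 8), seed = 9)
  cnt <- ens$counts[, 3, ]
  st <- moment_state(net, 2)
  for (i in seq_along(st$idx$keys)) {
    s <- st$idx$s[i]; m <- st$idx$m[i, ]
    st$y[i] <- mean(ff(cnt["P1", ], m[1]) * (cnt["G1*", ] == s))
  }
  par_rows <- hm2_params(st, net, negative = "clamp")
  stats <- holimap:::sample_match_stats(net, cnt, 1)
  par_stats <- holimap:::stats_to_params(stats, net$genes[1, ], "hm2")
  expect_equal(par_rows$s_on, unname(par_stats["s_on"]), tolerance = 1e-8)
  expect_equal(par_rows$s_off, unname(par_stats["s_off"]), tolerance = 1e-8)
})

test_that("3-parameter mapping folds nonlinear losses into decay", {
  rs <- build_fixture("mrna_degradation_control", alpha = 0)
  # no enzymatic channel: effective decay equals the spontaneous rate
  counts <- matrix(0, 50, length(rs$species),
                   dimnames = list(NULL, rs$species))
  counts[, "G"] <- 1; counts[, "E"] <- 1
  counts[, "M"] <- rpois(50, 10)
  p0 <- hm3_params(counts, rs)
  expect_equal(p0$d, 1)

  # independent M and E*: d~ = d + alpha E[nM nE*]/E[nM] = 1 + 0.2*40/10
  rs2 <- build_fixture("mrna_degradation_control", alpha = 0.2)
  n <- 40000
  set.seed(31)
  counts <- matrix(0, n, length(rs2$species),
                   dimnames = list(NULL, rs2$species))
  counts[, "G"] <- 1
  counts[, "M"] <- rpois(n, 10)
  estar <- rbinom(n, 1, 0.4) * 10    # E[n_E*] = 4, independent of M
  counts[, "E*"] <- estar; counts[, "E"] <- 1 - (estar > 0)
  p1 <- hm3_params(counts, rs2)
  expect_equal(p1$d, 1 + 0.2 * mean(counts[, "M"] * estar) /
                 mean(counts[, "M"]), tolerance = 1e-10)
  expect_equal(p1$d, 1.8, tolerance = 0.05)
})
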