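test_that("steady FSP matches closed-form laws", {
  # constitutive bursty gene: negative binomial, pointwise
  d <- fsp_steady(telegraph_params(0, 0, 2, 0, 1, p = 0.75))
  nb <- dnbinom(seq_along(d$p) - 1, size = 2, prob = 0.25)
  expect_lt(max(abs(d$p - nb)), 1e-6)
  expect_equal(dist_mean(d), 6, tolerance = 1e-5)
  expect_equal(dist_var(d) / dist_mean(d), 4, tolerance = 1e-5)  # 1 + B

  # telegraph: mean B(rho_u g0 + rho_b g1)/d
  d2 <- fsp_steady(telegraph_params(1, 1, 0, 10, 1, p = 0.5))
  expect_equal(dist_mean(d2), 5, tolerance = 1e-6)

  # equal synthesis rates: switching becomes irrelevant
  d3 <- fsp_steady(telegraph_params(0.3, 7, 2, 2, 1, p = 0.75))
  d4 <- fsp_steady(telegraph_params(0, 0, 2, 0, 1, p = 0.75))
  k <- min(length(d3$p), length(d4$p))
  expect_lt(max(abs(d3$p[1:k] - d4$p[1:k])), 1e-8)

  expect_error(fsp_steady(telegraph_params(1, 1, 5, 5, 0, p = 0)),
               "no stationary distribution")
})

test_that("transient FSP converges to the stationary solution", {
  d_ss <- fsp_steady(telegraph_params(1, 1, 0, 10, 1, p = 0.5))
  traj <- data.frame(time = c(0, 60), s_on = 1, s_off = 1, rho0 = 0,
                     rho1 = 10, d = 1)
  tr <- fsp_transient(traj, p = 0.5, t_grid = c(0, 60))
  expect_lt(hellinger(tr[[2]], d_ss), 1e-4)
  expect_lt(tr[[2]]$eps, 1e-6)
  # zero-rate system returns the initial distribution unchanged
  z <- fsp_transient(data.frame(time = c(0, 5), s_on = 0, s_off = 0,
                                rho0 = 0, rho1 = 0, d = 0),
                     p = 0, t_grid = c(0, 5))
  expect_equal(z[[2]]$p[1], 1, tolerance = 1e-10)
})

test_that("truncation choice follows the mean + safety * sd rule", {
  expect_equal(choose_truncation(5, 3), 64L)          # floor applies
  expect_equal(choose_truncation(100, 20), 300L)
  expect_equal(choose_truncation(100, 20, safety = 5), 200L)
  # adversarial heavy-tailed bursts: adaptive growth still bounds the tail
  d <- fsp_steady(telegraph_params(0, 0, 0.5, 0, 1, p = 0.98), tol = 1e-8)
  expect_lt(d$eps, 1e-8)
  expect_equal(dist_mean(d), 0.5 * 49, tolerance = 1e-3)
})

test_that("nonlinear FSP agrees with the linear solver on linear input", {
  tel <- telegraph_net()
  dn <- fsp_nonlinear(tel)$P1
  dl <- fsp_steady(telegraph_params(1, 1, 0, 10, 1, 0.5))
  k <- min(length(dn$p), length(dl$p))
  expect_lt(max(abs(dn$p[1:k] - dl$p[1:k])), 1e-10)
})

test_that("nonlinear FSP resolves slow-switching bimodality", {
  net <- build_autoreg(sigma_b = 0.01, sigma_u = 0.2, rho_b = 50,
                       rho_u = 1, d = 1, h = 1, p = 0.5)
  d <- fsp_nonlinear(net)$P1
  expect_gte(count_modes(d), 2)
})

test_that("state-space guard refuses oversized truncations", {
  tog <- build_fixture("toggle")
  expect_error(fsp_nonlinear(tog, caps = c(P1 = 900, P2 = 900),
                             max_states = 1e5), "SSA")
})

test_that("telegraph bimodality needs both switching rates below decay", {
  # sigma_off >= d: no bimodal steady state anywhere on the scan
  grid <- expand.grid(on = 10^seq(-2, 1, length.out = 5),
                      off = 10^seq(0, 1.5, length.out = 4))
  modes_fast <- mapply(function(on, off)
    count_modes(fsp_steady(telegraph_params(on, off, 0, 50, 1, 0.5))),
    grid$on, grid$off)
  expect_true(all(modes_fast == 1))
  # both rates below d: bimodality appears
  d_slow <- fsp_steady(telegraph_params(0.1, 0.1, 0, 50, 1, 0.5))
  expect_gte(count_modes(d_slow), 2)
})
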