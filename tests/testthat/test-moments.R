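test_that("generated moment equations reproduce the autoregulation system", {
  net <- autoreg_h1()
  ms <- derive_moment_system(net, K = 2)
  # d g_0/dt = sigma_u g_1 - sigma_b mu_{1,0}, term by term
  row <- ms$A[holimap:::moment_pos(ms, 0L, 0L), ]
  keys <- c(ms$idx$keys, ms$closure_keys)
  nz <- which(row != 0)
  expect_setequal(keys[nz], c("1|0", "0|1"))
  expect_equal(row[ms$idx$pos[["1|0"]]], 1)      # +sigma_u on g_1
  expect_equal(row[ms$idx$pos[["0|1"]]], -0.1)   # -sigma_b on mu_{1,0}
  # closure status: order-3 moments are referenced, flagged not silently cut
  expect_false(ms$closed)
  expect_true(all(grepl("3$", ms$closure_keys)))
})

test_that("equation counts follow L = 1 + 2h (LMA order) and 3 + 2h", {
  for (h in 1:3) {
    net <- build_autoreg(sigma_b = 1e-3, sigma_u = 1, rho_b = 50,
                         rho_u = 1, d = 1, h = h, p = 0.5)
    expect_equal(attr(derive_moment_system(net, K = h, check = FALSE), "L"),
                 1 + 2 * h)
    expect_equal(attr(derive_moment_system(net, K = h + 1), "L"), 3 + 2 * h)
  }
  expect_error(derive_moment_system(autoreg_h1(), K = 1), "K >= h \\+ 1")
})

test_that("zero-rate networks give identically zero right-hand sides", {
  dead <- gene_network(data.frame(alpha0 = 0, alpha1 = 0, rho0 = 0,
                                  rho1 = 0, d = 0, p = 0))
  ms <- derive_moment_system(dead, K = 2)
  expect_equal(Matrix::norm(ms$A, "M"), 0)
  expect_true(ms$closed)
})

test_that("moment equations agree with the brute-force CME generator", {
  # linear telegraph: machine-precision agreement
  tel <- telegraph_net()
  dev_tel <- rhs_oracle_check(derive_moment_system(tel, K = 2),
                              compile_reactions(tel), n_max = 200,
                              n_vectors = 3, seed = 1)
  expect_lt(dev_tel, 1e-8)
  # nonlinear autoregulation, random probability vectors
  net <- autoreg_h1()
  dev <- rhs_oracle_check(derive_moment_system(net, K = 2),
                          compile_reactions(net), n_max = 200,
                          n_vectors = 3, seed = 2)
  expect_lt(dev, 1e-6)
  # multi-gene with cooperative binding
  tog <- build_fixture("toggle")
  dev_tog <- rhs_oracle_check(derive_moment_system(tog, K = 3),
                              compile_reactions(tog), n_max = 25,
                              n_vectors = 2, seed = 3)
  expect_lt(dev_tog, 1e-6)
  # zero-rate network: exactly zero deviation
  dead <- gene_network(data.frame(alpha0 = 0, alpha1 = 0, rho0 = 0,
                                  rho1 = 0, d = 0, p = 0))
  expect_equal(rhs_oracle_check(derive_moment_system(dead, K = 2),
                                compile_reactions(dead), n_max = 30,
                                n_vectors = 1), 0)
})

test_that("probability mass is conserved at the coefficient level", {
  for (net in list(autoreg_h1(), build_fixture("toggle"),
                   build_random_network(3L, 5L))) {
    K <- max(c(net$edges$h, 1)) + 1
    ms <- derive_moment_system(net, K = K)
    g_rows <- which(rowSums(ms$idx$m) == 0)
    expect_equal(max(abs(Matrix::colSums(ms$A[g_rows, , drop = FALSE]))), 0)
  }
})

test_that("closed moment systems integrate to known steady values", {
  # telegraph: steady mean B(rho_u g_0 + rho_b g_1)/d = 5 at symmetric rates
  tel <- telegraph_net()
  ms <- derive_moment_system(tel, K = 2)
  expect_true(ms$closed)
  out <- integrate_moments(ms, t_grid = c(0, 200))
  y <- out[2, -1]
  g1 <- unname(y[holimap:::moment_pos(ms, 1L, 0L)])
  mean_p <- unname(y[holimap:::moment_pos(ms, 0L, 1L)] +
    y[holimap:::moment_pos(ms, 1L, 1L)])
  expect_equal(g1, 0.5, tolerance = 1e-6)
  expect_equal(mean_p, 5, tolerance = 1e-6)

  # constitutive bursty gene: mean rho*B/d = 6, Fano 1 + B = 4
  con <- constitutive_net()
  msc <- derive_moment_system(con, K = 2)
  ys <- steady_state_moments(msc)
  m1 <- unname(ys[holimap:::moment_pos(msc, 0L, 1L)])
  m2 <- unname(ys[holimap:::moment_pos(msc, 0L, 2L)])
  expect_equal(m1, 6, tolerance = 1e-6)
  expect_equal((m2 + m1 - m1^2) / m1, 4, tolerance = 1e-6)
  expect_lt(attr(ys, "residual"), 1e-8)

  # zero synthesis, zero initial moments: trajectory identically zero
  dead <- gene_network(data.frame(alpha0 = 1, alpha1 = 1, rho0 = 0,
                                  rho1 = 0, d = 1, p = 0))
  msd <- derive_moment_system(dead, K = 2)
  out0 <- integrate_moments(msd, t_grid = c(0, 5, 10))
  mu_cols <- 1 + which(rowSums(msd$idx$m) > 0)
  expect_equal(max(abs(out0[, mu_cols])), 0, tolerance = 1e-12)

  # unclosed systems refuse to integrate
  expect_error(integrate_moments(derive_moment_system(autoreg_h1(), K = 2),
                                 t_grid = c(0, 1)), "not closed")
})

test_that("FSP and moment integration agree on linear networks", {
  tel <- telegraph_net()
  ms <- derive_moment_system(tel, K = 2)
  y <- steady_state_moments(ms)
  mean_ode <- unname(y[holimap:::moment_pos(ms, 0L, 1L)] +
    y[holimap:::moment_pos(ms, 1L, 1L)])
  d <- fsp_steady(telegraph_params(1, 1, 0, 10, 1, 0.5))
  expect_equal(dist_mean(d), mean_ode, tolerance = 1e-4)
  m2 <- unname(y[holimap:::moment_pos(ms, 0L, 2L)] +
    y[holimap:::moment_pos(ms, 1L, 2L)])
  expect_equal(dist_var(d), m2 + mean_ode - mean_ode^2, tolerance = 1e-4)
})
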