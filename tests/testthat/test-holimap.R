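test_that("the fit object supports the standard modelling interface", {
  net <- autoreg_h1()
  fit <- holimap(net, method = "hm2", mode = "steady", negative = "clamp")
  expect_s3_class(fit, "holimap")
  expect_output(print(fit), "HM2")
  expect_output(print(summary(fit)), "means")
  par <- coef(fit)
  expect_true(all(c("s_on", "s_off", "rho0", "rho1", "d") %in% names(par)))
  d <- predict(fit, gene = 1)
  expect_s3_class(d, "count_dist")
  expect_equal(sum(d$p), 1, tolerance = 1e-8)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  ens <- simulate(fit, nsim = 20, seed = 3)
  expect_s3_class(ens, "trajectory_ensemble")
  expect_equal(ens$N, 20L)
})

test_that("auto method selection follows the steady/transient rule", {
  net <- autoreg_h1()
  fit_s <- holimap(net, mode = "steady", negative = "clamp")
  expect_equal(fit_s$method, "hm4")
  fit_t <- holimap(net, mode = "transient", t_grid = c(0, 1, 2),
                   negative = "clamp")
  expect_equal(fit_t$method, "hm2")
  expect_error(holimap(net, mode = "transient"), "t_grid")
})

test_that("a linear network is mapped onto itself", {
  tel <- telegraph_net()
  fit <- holimap(tel, method = "hm2", mode = "steady")
  expect_equal(fit$params$s_on, 1, tolerance = 1e-6)
  expect_equal(fit$params$s_off, 1, tolerance = 1e-6)
  truth <- fsp_nonlinear(tel)$P1
  expect_lt(hellinger(truth, fit$dists$P1), 1e-5)
})

test_that("approximation quality improves from LMA to the Holimaps", {
  net <- autoreg_h1()   # positive feedback, sigma_u >= d
  truth <- fsp_nonlinear(net)$P1
  hd <- vapply(c("lma", "hm2", "hm4"), function(m)
    hellinger(truth, holimap(net, method = m, mode = "steady",
                             negative = "clamp")$dists$P1), 0)
  expect_lt(hd[["hm4"]], hd[["hm2"]] + 1e-6)
  expect_lt(hd[["hm2"]], hd[["lma"]])
})

test_that("slow-switching bimodality is captured by the mappings", {
  net <- build_autoreg(sigma_b = 0.01, sigma_u = 0.2, rho_b = 50,
                       rho_u = 1, d = 1, h = 1, p = 0.5)
  truth <- fsp_nonlinear(net)$P1
  expect_gte(count_modes(truth), 2)
  for (m in c("hm2", "hm4")) {
    fit <- holimap(net, method = m, mode = "steady", negative = "clamp")
    expect_lt(hellinger(truth, fit$dists$P1), 0.05)
    expect_equal(count_modes(fit$dists$P1), count_modes(truth))
  }
})

test_that("transient fits track the nonlinear distribution over time", {
  # negative feedback: the conditional-moment mapping is most accurate here
  net <- build_autoreg(sigma_b = 0.02, sigma_u = 1, rho_b = 1, rho_u = 50,
                       d = 1, h = 1, p = 0.5)
  tg <- seq(0, 6, 0.5)
  truth <- fsp_nonlinear(net, mode = "transient", t_grid = tg)
  fit <- holimap(net, method = "hm2", mode = "transient", t_grid = tg,
                 negative = "clamp")
  hds <- vapply(seq_along(tg)[-1], function(i)
    hellinger(truth[[i]]$P1, fit$dists$P1[[i]]), 0)
  expect_lt(max(hds), 0.1)   # visually accurate throughout
  # effective parameters are recorded per output time
  expect_equal(nrow(fit$params), length(tg))
  expect_true(all(fit$params$s_on >= 0))
})

test_that("time-dependent rates reproduce the time evolution seen by the SSA", {
  net <- build_autoreg(sigma_b = 0.02, sigma_u = 1, rho_b = 1, rho_u = 50,
                       d = 1, h = 1, p = 0.5)
  tg <- seq(0, 6, 0.5)
  fit <- holimap(net, method = "hm2", mode = "transient", t_grid = tg,
                 negative = "clamp")
  ens <- simulate_ensemble(net, N = 20000, t_grid = tg, seed = 19,
                           species = "P1")
  for (i in c(5, 13)) {
    de <- empirical_distribution(ens, "P1", tg[i])
    expect_lt(hellinger(de, fit$dists$P1[[i]]), 0.08)
  }
})

test_that("oversized joint moment spaces are refused with advice", {
  big <- build_random_network(13L, seed = 2L)
  expect_error(holimap(big, method = "hm2", mode = "steady"), "hybrid")
})

test_that("results serialize deterministically and round-trip", {
  net <- autoreg_h1()
  fit <- holimap(net, method = "hm2", mode = "steady", negative = "clamp")
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- write_results(fit, d1)
  f2 <- write_results(fit, d2)
  expect_identical(readLines(f1["distributions"]),
                   readLines(f2["distributions"]))
  tab <- read.delim(f1["distributions"])
  p_back <- tab$probability[tab$species == "P1"]
  expect_equal(p_back, fit$dists$P1$p, tolerance = 1e-15)
  man <- yaml::read_yaml(f1["manifest"])
  expect_equal(man$method, "hm2")
  # a stochastic-stage fit records its seed in the manifest
  hy <- holimap(net, method = "hm2", mode = "steady", engine = "ssa",
                n_traj = 300, seed = 42, t_grid = seq(0, 8, 1),
                negative = "clamp")
  man2 <- yaml::read_yaml(write_results(hy, tempfile())["manifest"])
  expect_equal(man2$seed, 42)
})
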