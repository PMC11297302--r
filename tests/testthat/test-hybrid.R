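test_that("hybrid output matches direct FSP when the mapping is the identity", {
  tel <- telegraph_net()
  tg <- seq(0, 8, 0.5)
  hy <- holimap(tel, method = "hm2", mode = "transient", t_grid = tg,
                engine = "ssa", n_traj = 2000, seed = 5)
  direct <- fsp_nonlinear(tel, mode = "transient", t_grid = tg)
  hds <- vapply(seq_along(tg)[-1], function(i)
    hellinger(hy$dists$P1[[i]], direct[[i]]$P1), 0)
  expect_lt(mean(hds), 0.01)   # only Monte-Carlo parameter noise remains
})

test_that("hybrid runs are reproducible and smooth", {
  rep3 <- build_fixture("repressilator")
  tg <- seq(0, 6, 0.5)
  h1 <- holimap(rep3, method = "hm2", mode = "transient", t_grid = tg,
                engine = "ssa", n_traj = 500, seed = 3, negative = "clamp")
  h2 <- holimap(rep3, method = "hm2", mode = "transient", t_grid = tg,
                engine = "ssa", n_traj = 500, seed = 3, negative = "clamp")
  expect_equal(h1$dists$P1[[7]]$p, h2$dists$P1[[7]]$p)
  # independent seeds: hybrid outputs differ far less than raw histograms
  h3 <- holimap(rep3, method = "hm2", mode = "transient", t_grid = tg,
                engine = "ssa", n_traj = 500, seed = 4, negative = "clamp")
  tv <- function(p, q) {
    k <- max(length(p), length(q))
    sum(abs(c(p, numeric(k - length(p))) - c(q, numeric(k - length(q))))) / 2
  }
  i <- length(tg)
  e3 <- simulate_ensemble(rep3, N = 500, t_grid = tg, seed = 3,
                          species = "P1")
  e4 <- simulate_ensemble(rep3, N = 500, t_grid = tg, seed = 4,
                          species = "P1")
  tv_hybrid <- tv(h1$dists$P1[[i]]$p, h3$dists$P1[[i]]$p)
  tv_raw <- tv(empirical_distribution(e3, "P1", tg[i])$p,
               empirical_distribution(e4, "P1", tg[i])$p)
  expect_lt(tv_hybrid, tv_raw / 2)
})

test_that("sample-size sufficiency follows the N vs 3N criterion", {
  rep3 <- build_fixture("repressilator")
  tg <- seq(0, 6, 1)
  # degenerate self-comparison: identical runs, zero distance
  sc0 <- sufficiency_check(rep3, N = 300, t_grid = tg, seed = 2,
                           N2 = 300, seed2 = 2)
  expect_equal(sc0$hd, 0)
  expect_true(sc0$pass)
  # a tiny ensemble on a high-noise model fails the criterion
  sc_small <- sufficiency_check(rep3, N = 10, t_grid = tg, seed = 2)
  expect_false(sc_small$pass)
})

test_that("3-parameter hybrid reproduces post-regulation dynamics", {
  rs <- build_fixture("sequestration")
  tg <- seq(0, 8, 0.5)
  hy <- holimap(rs, method = "hm3", mode = "transient", t_grid = tg,
                engine = "ssa", n_traj = 2000, seed = 11,
                negative = "clamp")
  expect_named(hy$dists, "P1")
  # effective decay exceeds the intrinsic rate (sequestration losses)
  late <- hy$params[hy$params$time >= 4, "d"]
  expect_true(all(late > attr(rs, "holimap3")$d))
  # distributions match a large-ensemble reference within a few percent
  ref <- simulate_ensemble(rs, N = 20000, t_grid = tg, seed = 99,
                           species = "P1")
  hds <- vapply(c(9, 17), function(i)
    hellinger(empirical_distribution(ref, "P1", tg[i]), hy$dists$P1[[i]]), 0)
  expect_lt(mean(hds), 0.1)
  # SSA-mean cross-check of the mapped model's mean
  i <- 17
  n <- ref$counts["P1", i, ]
  expect_lt(abs(dist_mean(hy$dists$P1[[i]]) - mean(n)),
            max(3 * sd(n) / sqrt(length(n)), 0.05 * mean(n)))
})

test_that("hm3 requires the simulation engine and motif metadata", {
  rs <- build_fixture("sequestration")
  expect_error(holimap(rs, method = "hm3", mode = "steady"), "ssa")
  bare <- reaction_system("X", list(rxn(1, stoich = c(X = 1)),
                                    rxn(1, orders = c(X = 1),
                                        stoich = c(X = -1))))
  expect_error(holimap(bare, method = "hm3", mode = "steady",
                       engine = "ssa", t_grid = 0:5), "metadata")
})

test_that("all post-regulation fixtures run through the hybrid pipeline", {
  tg <- seq(0, 5, 0.5)
  for (name in c("phosphorylation", "mrna_degradation_control",
                 "mirna_mrna")) {
    rs <- build_fixture(name)
    hy <- holimap(rs, method = "hm3", mode = "transient", t_grid = tg,
                  engine = "ssa", n_traj = 800, seed = 7,
                  negative = "clamp")
    sp <- attr(rs, "holimap3")$track
    expect_named(hy$dists, sp)
    last <- hy$dists[[sp]][[length(tg)]]
    expect_equal(sum(last$p), 1, tolerance = 1e-6)
    ref <- simulate_ensemble(rs, N = 8000, t_grid = tg, seed = 55,
                             species = sp)
    hd <- hellinger(empirical_distribution(ref, sp, tg[length(tg)]), last)
    expect_lt(hd, 0.15)
  }
})
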