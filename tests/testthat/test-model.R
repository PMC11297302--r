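test_that("autoregulation constructor validates and stores parameters", {
  net <- autoreg_h1()
  expect_s3_class(net, "gene_network")
  expect_equal(net$M, 1L)
  expect_equal(burst_size(net$genes$p), 1)        # p = 0.5 -> B = 1
  expect_equal(net$edges$type, "bind")

  # B and p parameterizations are interchangeable
  netB <- build_autoreg(sigma_b = 0.1, sigma_u = 1, rho_b = 50, rho_u = 1,
                        d = 1, h = 1, B = 3)
  expect_equal(netB$genes$p, 0.75)

  expect_error(build_autoreg(sigma_b = -1, sigma_u = 1, rho_b = 1,
                             rho_u = 1, d = 1), "sigma_b")
  expect_error(build_autoreg(sigma_b = 1, sigma_u = 1, rho_b = 1,
                             rho_u = 1, d = 1, h = 0), "h")
  expect_error(build_autoreg(sigma_b = 1, sigma_u = 1, rho_b = 1,
                             rho_u = 1, d = 1, p = 1), "p")
})

test_that("p = 0 is the non-bursty degenerate case (one molecule/event)", {
  net <- build_autoreg(sigma_b = 0.1, sigma_u = 1, rho_b = 50, rho_u = 1,
                       d = 1, h = 1, p = 0)
  rs <- compile_reactions(net)
  synth <- Filter(function(r) r$stoich["P1"] > 0 &&
                    all(r$stoich[c("G1", "G1*")] == 0), rs$reactions)
  expect_length(synth, 2L)
  for (r in synth) {
    expect_true(is.na(r$burst))
    expect_equal(unname(r$stoich["P1"]), 1)
  }
})

test_that("removing feedback removes the bimolecular channel", {
  net <- build_autoreg(sigma_b = 0, sigma_u = 0, rho_b = 50, rho_u = 1,
                       d = 1, h = 1, p = 0.5)
  rs <- compile_reactions(net)
  orders <- vapply(rs$reactions, function(r) sum(r$orders), 0)
  expect_true(all(orders <= 1))
})

test_that("compiled autoregulation has the hand-enumerated channel set", {
  # bind, unbind, synthesis in each gene state, decay
  rs <- compile_reactions(autoreg_h1())
  expect_length(rs$reactions, 5L)
  expect_setequal(rs$species, c("G1", "G1*", "P1"))
  # a network with all rates zero compiles to no active channels
  dead <- gene_network(data.frame(alpha0 = 0, alpha1 = 0, rho0 = 0,
                                  rho1 = 0, d = 0, p = 0))
  expect_length(compile_reactions(dead)$reactions, 0L)
})

test_that("binding uses the falling-factorial (combinatorial) propensity", {
  net <- build_autoreg(sigma_b = 2, sigma_u = 1, rho_b = 5, rho_u = 1,
                       d = 1, h = 3, p = 0)
  rs <- compile_reactions(net)
  bind_idx <- which(vapply(rs$reactions, function(r)
    r$orders["P1"] == 3, TRUE))
  x <- c("G1" = 1, "G1*" = 0, "P1" = 5)
  a <- propensities(rs, x[rs$species])
  expect_equal(a[1, bind_idx], 2 * 5 * 4 * 3)
  # below the cooperativity the propensity vanishes
  x2 <- c("G1" = 1, "G1*" = 0, "P1" = 2)
  expect_equal(propensities(rs, x2[rs$species])[1, bind_idx], 0)
})

test_that("propensities are non-negative on random count vectors", {
  set.seed(42)
  for (name in c("two_node", "toggle", "repressilator", "sequestration",
                 "mirna_mrna")) {
    x <- build_fixture(name)
    rs <- if (inherits(x, "reaction_system")) x else compile_reactions(x)
    ns <- length(rs$species)
    counts <- matrix(rpois(200 * ns, 5), 200, ns)
    # put switch pairs into valid 0/1 configurations
    for (pr in rs$pairs) {
      b <- rbinom(200, 1, 0.5)
      counts[, pr[1]] <- 1 - b
      counts[, pr[2]] <- b
    }
    expect_true(all(propensities(rs, counts) >= 0), label = name)
  }
})

test_that("random networks have the documented connectivity law", {
  # per-pair connection probability 2/M; mean directed edge count 2M
  M <- 5L
  n_edges <- vapply(1:400, function(s)
    nrow(build_random_network(M, s)$edges), 0)
  # edge count ~ Binomial(M^2, 2/M): chi-squared goodness of fit on counts
  expect_equal(mean(n_edges), 2 * M, tolerance = 0.08)
  pbin <- dbinom(0:25, M^2, 2 / M)
  obs <- tabulate(pmin(n_edges, 25) + 1L, nbins = 26L)
  keep <- pbin * length(n_edges) >= 5
  chi2 <- sum((obs[keep] - length(n_edges) * pbin[keep])^2 /
                (length(n_edges) * pbin[keep]))
  expect_lt(chi2, qchisq(0.999, sum(keep) - 1))

  net <- build_random_network(10L, seed = 3L)
  expect_true(all(net$genes$rho1 == 81))
  expect_true(all(net$genes$rho0 == 5.4))
  expect_true(all(net$genes$alpha0 == 0.5))
  expect_true(all(net$edges$rate == 0.01))
  expect_true(all(net$edges$type %in% c("act", "rep")))
  # pure function of (M, seed)
  expect_identical(build_random_network(10L, 7L)$edges,
                   build_random_network(10L, 7L)$edges)
  expect_error(build_random_network(0, 1), "M")
})

test_that("fixtures are the documented motifs", {
  expect_error(build_fixture("nope"), "valid names")
  tog <- build_fixture("toggle", h = c(2, 2))
  expect_true(all(tog$edges$h == 2))
  expect_true(all(tog$genes$rho0 > tog$genes$rho1))  # binding represses
  expect_true(all(tog$genes$p == 0))                 # non-bursty motif
  rep3 <- build_fixture("repressilator")
  expect_true(all(rep3$edges$h == 3))
  rep1 <- build_fixture("repressilator", h = c(1, 1, 1))
  expect_s3_class(rep1, "gene_network")
  mm <- build_fixture("mirna_mrna")
  expect_s3_class(mm, "reaction_system")
  expect_true(all(c("C1", "C2", "M", "R") %in% mm$species))
})

test_that("network config files round-trip exactly", {
  path <- tempfile(fileext = ".yaml")
  for (net in list(autoreg_h1(), build_fixture("toggle"),
                   build_random_network(6L, 11L))) {
    write_network_config(net, path)
    back <- read_network_config(path)
    expect_equal(back$genes, net$genes)
    expect_equal(back$edges$rate, net$edges$rate)
    expect_equal(back$edges$type, net$edges$type)
  }
  # schema violations are rejected with a location
  cfg <- yaml::read_yaml(path)
  cfg$genes[[1]]$bogus <- 1
  writeLines(yaml::as.yaml(cfg), path)
  expect_error(read_network_config(path), "genes\\[1\\]")
  cfg$genes[[1]]$bogus <- NULL
  cfg$schema <- 99
  writeLines(yaml::as.yaml(cfg), path)
  expect_error(read_network_config(path), "schema")
})

test_that("invalid edges are rejected", {
  genes <- data.frame(alpha0 = 0, alpha1 = 0, rho0 = 1, rho1 = 2,
                      d = 1, p = 0)[c(1, 1), ]
  expect_error(gene_network(genes, data.frame(
    from = 1, to = 2, h = 0, type = "act", rate = 1, unbind = 0)), "h")
  expect_error(gene_network(genes, data.frame(
    from = 1, to = 3, h = 1, type = "act", rate = 1, unbind = 0)), "index")
  # an 'act' edge cannot also carry an unbinding rate
  expect_error(gene_network(genes, data.frame(
    from = 1, to = 2, h = 1, type = "act", rate = 1, unbind = 2)), "unbind")
})

test_that("printed rate arithmetic helpers are correct", {
  expect_equal(decay_rate(46, 27.5), 6.7e-4, tolerance = 0.01)
  expect_equal(decay_rate(46, 27.5, unit = "per_hour") / 60,
               decay_rate(46, 27.5))
  expect_error(decay_rate(0, 1), "positive")
})
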