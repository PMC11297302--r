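# Hybrid method: estimate the matching moments from a modest ensemble of
# exact trajectories, convert them to effective linear-network parameters
# per output time, and solve the linear network by FSP.  This is the
# practical route for networks too large for the self-consistent moment
# closure (whose size grows exponentially with the number of genes).

# per-gene matching statistics at one recorded time, computed directly as
# sample averages of the switching-channel fluxes.  The second matching
# equation tracks the regulator mean conditioned on the target's state,
# sum_i E[n_i ; s_j], summed over the regulators i of gene j.
sample_match_stats <- function(network, counts, j) {
  genes <- network$genes; ed <- network$edges
  gsp <- function(k) paste0("G", k, "*"); psp <- function(k) paste0("P", k)
  s <- counts[gsp(j), ]
  n <- counts[psp(j), ]
  nreg <- n   # bound-state moments of the gene's own protein
  g0 <- mean(s == 0); g1 <- mean(s == 1)
  m10 <- mean(nreg * (s == 0)); m11 <- mean(nreg * (s == 1))
  self_reg <- TRUE
  onf <- genes$alpha0[j] * g0; offf <- genes$alpha1[j] * g1
  onB <- genes$alpha0[j] * m10; offB <- genes$alpha1[j] * m11
  for (e in seq_len(nrow(ed))) {
    if (ed$to[e] != j) next
    h <- ed$h[e]; i <- ed$from[e]
    ffi <- ff(counts[psp(i), ], h)
    if (ed$type[e] %in% c("bind", "act")) {
      onf <- onf + ed$rate[e] * mean(ffi * (s == 0))
      onB <- onB + ed$rate[e] *
        mean(ffi * (nreg - h * (i == j)) * (s == 0))
    }
    if (ed$type[e] == "bind") {
      offf <- offf + ed$unbind[e] * g1
      offB <- offB + ed$unbind[e] * m11
    }
    if (ed$type[e] == "rep") {
      offf <- offf + ed$rate[e] * mean(ffi * (s == 1))
      offB <- offB + ed$rate[e] * mean(ffi * nreg * (s == 1))
    }
  }
  out <- list(g0 = g0, g1 = g1, m10 = m10, m11 = m11,
              onf = onf, offf = offf, onB = onB, offB = offB,
              self_reg = self_reg)
  # protein-flux statistics for the four-parameter matching
  m1 <- mean(n); m2 <- mean(ff(n, 2))
  cons1 <- rel1 <- cons2 <- rel2 <- 0
  for (e in seq_len(nrow(ed))) {
    if (ed$from[e] != j) next
    h <- ed$h[e]; k <- ed$to[e]
    sk <- counts[gsp(k), ]
    ffh <- ff(n, h); ffh1 <- ff(n, h + 1)
    if (ed$type[e] %in% c("bind", "act")) {
      ind <- sk == 0
      cons1 <- cons1 + h * ed$rate[e] * mean(ffh * ind)
      cons2 <- cons2 + ed$rate[e] *
        mean((2 * h * ffh1 + h * (h - 1) * ffh) * ind)
    }
    if (ed$type[e] == "rep") {
      ind <- sk == 1
      cons1 <- cons1 + h * ed$rate[e] * mean(ffh * ind)
      cons2 <- cons2 + ed$rate[e] *
        mean((2 * h * ffh1 + h * (h - 1) * ffh) * ind)
    }
    if (ed$type[e] == "bind") {
      rel1 <- rel1 + h * ed$unbind[e] * mean(sk == 1)
      rel2 <- rel2 + ed$unbind[e] * mean((2 * h * n + h * (h - 1)) * (sk == 1))
    }
  }
  c(out, list(m1 = m1, m2 = m2, cons1 = cons1, rel1 = rel1,
              cons2 = cons2, rel2 = rel2))
}

# matching statistics of gene j evaluated exactly on a truncated-CME
# probability vector (the infinite-ensemble limit of sample_match_stats)
fsp_match_stats <- function(network, space, pvec, j) {
  genes <- network$genes; ed <- network$edges
  gsp <- function(k) paste0("G", k, "*"); psp <- function(k) paste0("P", k)
  E <- function(orders = NULL, state = NULL) {
    pat <- if (is.null(state)) NULL else
      stats::setNames(list(state), gsp(j))
    cme_expect(space, pvec, orders = orders, pattern = pat)
  }
  ordv <- function(...) {
    v <- list(...)
    stats::setNames(lapply(v[seq(2, length(v), 2)], identity),
                    unlist(v[seq(1, length(v), 2)]))
  }
  g0 <- E(state = 0); g1 <- E(state = 1)
  m10 <- E(ordv(psp(j), 1), 0); m11 <- E(ordv(psp(j), 1), 1)
  onf <- genes$alpha0[j] * g0; offf <- genes$alpha1[j] * g1
  onB <- genes$alpha0[j] * m10; offB <- genes$alpha1[j] * m11
  for (e in seq_len(nrow(ed))) {
    if (ed$to[e] != j) next
    h <- ed$h[e]; i <- ed$from[e]
    if (ed$type[e] %in% c("bind", "act")) {
      onf <- onf + ed$rate[e] * E(ordv(psp(i), h), 0)
      onB <- onB + ed$rate[e] *
        (if (i == j) E(ordv(psp(j), h + 1), 0)
         else E(ordv(psp(i), h, psp(j), 1), 0))
    }
    if (ed$type[e] == "bind") {
      offf <- offf + ed$unbind[e] * g1
      offB <- offB + ed$unbind[e] * m11
    }
    if (ed$type[e] == "rep") {
      offf <- offf + ed$rate[e] * E(ordv(psp(i), h), 1)
      # n (n)_h = (n)_{h+1} + h (n)_h for the self-regulating case
      offB <- offB + ed$rate[e] *
        (if (i == j) E(ordv(psp(j), h + 1), 1) + h * E(ordv(psp(j), h), 1)
         else E(ordv(psp(i), h, psp(j), 1), 1))
    }
  }
  m1 <- E(ordv(psp(j), 1)); m2 <- E(ordv(psp(j), 2))
  cons1 <- rel1 <- cons2 <- rel2 <- 0
  for (e in seq_len(nrow(ed))) {
    if (ed$from[e] != j) next
    h <- ed$h[e]; k <- ed$to[e]
    st_req <- if (ed$type[e] == "rep") 1 else 0
    patk <- stats::setNames(list(st_req), gsp(k))
    ffh <- cme_expect(space, pvec,
                      orders = stats::setNames(list(h), psp(j)),
                      pattern = patk)
    ffh1 <- cme_expect(space, pvec,
                       orders = stats::setNames(list(h + 1), psp(j)),
                       pattern = patk)
    if (ed$type[e] %in% c("bind", "act", "rep")) {
      cons1 <- cons1 + h * ed$rate[e] * ffh
      cons2 <- cons2 + ed$rate[e] * (2 * h * ffh1 + h * (h - 1) * ffh)
    }
    if (ed$type[e] == "bind") {
      g1k <- cme_expect(space, pvec, pattern = stats::setNames(list(1),
                                                              gsp(k)))
      n1k <- cme_expect(space, pvec,
                        orders = stats::setNames(list(1), psp(j)),
                        pattern = stats::setNames(list(1), gsp(k)))
      rel1 <- rel1 + h * ed$unbind[e] * g1k
      rel2 <- rel2 + ed$unbind[e] * (2 * h * n1k + h * (h - 1) * g1k)
    }
  }
  list(g0 = g0, g1 = g1, m10 = m10, m11 = m11,
       onf = onf, offf = offf, onB = onB, offB = offB,
       m1 = m1, m2 = m2, cons1 = cons1, rel1 = rel1,
       cons2 = cons2, rel2 = rel2, self_reg = TRUE)
}

# effective telegraph parameters of one gene from matching statistics;
# returns NULL when the switching system is singular
stats_to_params <- function(st, genes_row, method, note = function(...) NULL) {
  rho0 <- genes_row$rho0; rho1 <- genes_row$rho1
  b1 <- if (genes_row$p == 0) 1 else genes_row$p / (1 - genes_row$p)
  b2 <- if (genes_row$p == 0) 0 else 2 * b1^2
  corr <- 0
  if (method == "hm4") {
    a11 <- b1 * st$g0; a12 <- b1 * st$g1
    a21 <- b1 * st$m10 + b2 * st$g0 / 2
    a22 <- b1 * st$m11 + b2 * st$g1 / 2
    rhs1 <- rho0 * a11 + rho1 * a12 - st$cons1 + st$rel1
    rhs2 <- rho0 * a21 + rho1 * a22 - st$cons2 / 2 + st$rel2 / 2
    dt <- a11 * a22 - a12 * a21
    if (abs(dt) > 1e-12 * max(abs(c(a11, a12, a21, a22)), 1)^2) {
      r0 <- (a22 * rhs1 - a12 * rhs2) / dt
      r1 <- (a11 * rhs2 - a21 * rhs1) / dt
      # the synthesis correction enters the switching match only when the
      # gene's own protein is among its regulators
      if (isTRUE(st$self_reg)) corr <- (rho1 - r1) * b1 * st$g1
      rho0 <- r0; rho1 <- r1
    } else {
      note("singular synthesis matching; keeping original synthesis rates")
    }
  }
  a11 <- st$g0; a12 <- -st$g1
  a21 <- st$m10; a22 <- -st$m11
  dt <- a11 * a22 - a12 * a21
  if (abs(dt) <= 1e-12 * max(abs(c(a11, a12, a21, a22)), 1)^2) return(NULL)
  rhs1 <- st$onf - st$offf
  rhs2 <- st$onB - st$offB + corr
  s_on <- (a22 * rhs1 - a12 * rhs2) / dt
  s_off <- (a11 * rhs2 - a21 * rhs1) / dt
  if (max(abs(c(s_on, s_off))) > 1e8) return(NULL)
  c(s_on = s_on, s_off = s_off, rho0 = rho0, rho1 = rho1)
}

# hybrid pipeline shared by holimap(engine = "ssa")
hybrid_solve <- function(network, method, mode, t_grid, N = 2000, seed = NULL,
                         negative = "error", fsp_tol = 1e-8, call = NULL,
                         reference_grid = NULL) {
  if (is.null(seed)) seed <- 1L
  if (method == "hm3")
    return(hybrid_solve_hm3(network, mode, t_grid, N, seed, negative,
                            fsp_tol, call))
  stopifnot(inherits(network, "gene_network"))
  M <- network$M
  if (is.null(t_grid))
    t_grid <- seq(0, 30 / min(network$genes$d), length.out = 61)
  t_sim <- as.numeric(Sys.time())
  rec <- c(paste0("G", 1:M, "*"), paste0("P", 1:M))
  ens <- simulate_ensemble(network, N = N, t_grid = t_grid, seed = seed,
                           species = rec)
  t_sim <- as.numeric(Sys.time()) - t_sim
  notes <- character(0)
  note <- function(...) notes <<- c(notes, paste0(...))
  nt <- length(t_grid)
  stats <- lapply(seq_len(nt), function(it)
    lapply(1:M, function(j)
      sample_match_stats(network, ens$counts[, it, ], j)))
  t_fsp <- as.numeric(Sys.time())
  if (mode == "steady") {
    # time-average the matching statistics over the stationary tail
    window <- which(t_grid >= stats::quantile(t_grid, 0.8))
    par <- do.call(rbind, lapply(1:M, function(j) {
      avg <- Reduce(function(a, b) Map(`+`, a, b),
                    lapply(window, function(it) stats[[it]][[j]]))
      avg <- lapply(avg, function(v) v / length(window))
      pp <- stats_to_params(avg, network$genes[j, ], method, note)
      if (is.null(pp)) {
        note("singular matching for gene ", j,
             " at steady state; conditional-mean fallback")
        pp <- c(s_on = unname(avg$onf / max(avg$g0, 1e-12)),
                s_off = unname(avg$offf / max(avg$g1, 1e-12)),
                rho0 = network$genes$rho0[j], rho1 = network$genes$rho1[j])
      }
      data.frame(gene = j, s_on = pp[1], s_off = pp[2], rho0 = pp[3],
                 rho1 = pp[4], d = network$genes$d[j], p = network$genes$p[j])
    }))
    par <- clamp_params(par, negative, note)
    dists <- lapply(1:M, function(j)
      fsp_steady(telegraph_params(par$s_on[j], par$s_off[j], par$rho0[j],
                                  par$rho1[j], par$d[j], par$p[j]),
                 tol = fsp_tol))
  } else {
    par <- do.call(rbind, lapply(1:M, function(j) {
      last <- NULL
      rows <- lapply(seq_len(nt), function(it) {
        pp <- stats_to_params(stats[[it]][[j]], network$genes[j, ],
                              method, note)
        if (is.null(pp)) {
          st <- stats[[it]][[j]]
          pp <- if (!is.null(last)) {
            note("singular matching for gene ", j, " at t = ", t_grid[it],
                 "; carrying forward previous parameters")
            last
          } else {
            note("singular matching for gene ", j, " at t = ", t_grid[it],
                 "; conditional-mean fallback")
            c(s_on = unname((st$onf) / max(st$g0, 1e-12)),
              s_off = unname(st$offf / max(st$g1, 1e-12)),
              rho0 = network$genes$rho0[j], rho1 = network$genes$rho1[j])
          }
        }
        last <<- pp
        data.frame(time = t_grid[it], gene = j, s_on = pp[1], s_off = pp[2],
                   rho0 = pp[3], rho1 = pp[4],
                   d = network$genes$d[j], p = network$genes$p[j])
      })
      do.call(rbind, rows)
    }))
    par <- clamp_params(par, negative, note)
    dists <- lapply(1:M, function(j) {
      pj <- par[par$gene == j, ]
      ds <- fsp_transient(pj[c("time", "s_on", "s_off", "rho0", "rho1", "d")],
                          p = network$genes$p[j], t_grid = t_grid,
                          tol = max(fsp_tol, 1e-6))
      for (i in seq_along(ds)) ds[[i]]$species <- paste0("P", j)
      ds
    })
  }
  t_fsp <- as.numeric(Sys.time()) - t_fsp
  names(dists) <- paste0("P", 1:M)
  if (t_sim > 1 && t_fsp > 0.1 * (t_sim + t_fsp))
    message(sprintf(
      "hybrid stage timing: simulation %.1fs, linear solves %.1fs", t_sim,
      t_fsp))
  structure(list(call = call, network = network, method = method,
                 mode = mode, engine = "ssa", t_grid = t_grid, params = par,
                 dists = dists, moments = NULL, notes = notes,
                 closure = NULL, ensemble_seed = seed, N = N,
                 timing = c(simulate = t_sim, solve = t_fsp)),
            class = "holimap")
}

clamp_params <- function(par, negative, note) {
  for (nm in c("s_on", "s_off", "rho0", "rho1")) {
    v <- par[[nm]]
    v[v < 0 & v > -1e-8 * max(abs(v), 1)] <- 0
    if (any(v < 0)) {
      if (negative == "error")
        stop("hybrid matching produced a negative effective ", nm,
             "; rerun with negative = 'clamp'")
      note("negative effective ", nm, " clamped to zero")
      v <- pmax(v, 0)
    }
    par[[nm]] <- v
  }
  par
}

# 3-parameter mapping for post-translational / post-transcriptional motifs:
# gene switching matched as in the 2-HM, every nonlinear loss channel of
# the tracked species folded into an effective first-order decay rate
hybrid_solve_hm3 <- function(rs, mode, t_grid, N, seed, negative, fsp_tol,
                             call) {
  stopifnot(inherits(rs, "reaction_system"))
  meta <- attr(rs, "holimap3")
  if (is.null(meta))
    stop("this reaction system does not describe a supported ",
         "post-regulation motif (no tracked-species metadata)")
  if (is.null(t_grid)) t_grid <- seq(0, 30 / meta$d, length.out = 61)
  ens <- simulate_ensemble(rs, N = N, t_grid = t_grid, seed = seed)
  notes <- character(0)
  note <- function(...) notes <<- c(notes, paste0(...))
  nt <- length(t_grid)
  rows <- vector("list", nt)
  last <- NULL
  for (it in seq_len(nt)) {
    pp <- hm3_params(t(ens$counts[, it, ]), rs, last = last, note = note)
    last <- pp
    rows[[it]] <- cbind(time = t_grid[it], gene = 1L, pp)
  }
  par <- clamp_params(do.call(rbind, rows), negative, note)
  if (mode == "steady") {
    window <- which(t_grid >= stats::quantile(t_grid, 0.8))
    avg <- colMeans(par[window, c("s_on", "s_off", "d")])
    d1 <- fsp_steady(telegraph_params(avg["s_on"], avg["s_off"],
                                      meta$rho0, meta$rho1,
                                      avg["d"], meta$p), tol = fsp_tol)
    d1$species <- meta$track
    dists <- list(d1)
  } else {
    ds <- fsp_transient(par[c("time", "s_on", "s_off", "rho0", "rho1", "d")],
                        p = meta$p, t_grid = t_grid, tol = max(fsp_tol, 1e-6))
    for (i in seq_along(ds)) ds[[i]]$species <- meta$track
    dists <- list(ds)
  }
  names(dists) <- meta$track
  structure(list(call = call, network = rs, method = "hm3", mode = mode,
                 engine = "ssa", t_grid = t_grid, params = par,
                 dists = dists, moments = NULL, notes = notes,
                 closure = NULL, ensemble_seed = seed, N = N),
            class = "holimap")
}

#' Three-parameter mapping for post-regulation reaction systems
#'
#' Maps a post-translational or post-transcriptional motif onto a linear
#' telegraph model for its tracked species: the gene-switching channels
#' are matched as in the two-parameter mapping, and every nonlinear loss
#' channel of the tracked species (bimolecular binding, enzymatic or
#' Michaelis-Menten degradation) is folded into an effective first-order
#' decay rate chosen so the linear model's mean loss flux equals the
#' nonlinear network's expected loss rate:
#' \eqn{\tilde d = d + E[\mathrm{loss\ propensity}] / E[n]}.
#'
#' @param counts matrix of sampled states, one row per observation and
#'   one column per species of \code{rs} (e.g. an ensemble slice).
#' @param rs a supported motif \code{\link{reaction_system}} (see
#'   \code{\link{build_fixture}}).
#' @param last parameters carried forward if the switching match is
#'   singular at this sample (internal).
#' @param note callback receiving fallback records.
#' @return one-row data frame with \code{s_on, s_off, rho0, rho1, d, p};
#'   \code{d} is the effective decay rate of the tracked species.
#' @export
hm3_params <- function(counts, rs, last = NULL, note = function(...) NULL) {
  meta <- attr(rs, "holimap3")
  if (is.null(meta))
    stop("this reaction system does not describe a supported ",
         "post-regulation motif (no tracked-species metadata)")
  kx <- match(meta$track, rs$species)
  k_act <- match(meta$gene_pair[2], rs$species)
  flips <- vapply(rs$reactions, function(r) r$stoich[k_act] != 0, TRUE)
  flip_dir <- vapply(rs$reactions, function(r) r$stoich[k_act], 0)
  is_lin_decay <- vapply(seq_along(rs$reactions), function(i) {
    r <- rs$reactions[[i]]
    r$kind == "massaction" && r$stoich[kx] == -1 && !flips[i] &&
      sum(r$orders) == 1 && r$orders[kx] == 1
  }, TRUE)
  loss <- vapply(seq_along(rs$reactions), function(i) {
    r <- rs$reactions[[i]]
    r$stoich[kx] < 0 && !is_lin_decay[i] && !flips[i]
  }, TRUE)
  # telegraph synthesis channels sense only the gene state; any other
  # channel producing the tracked species (complex dissociation and the
  # like) is a nonlinear gain that offsets the mapped loss flux
  gpair <- match(meta$gene_pair, rs$species)
  is_synth <- vapply(seq_along(rs$reactions), function(i) {
    r <- rs$reactions[[i]]
    makes <- r$stoich[kx] > 0 || identical(r$burst, kx)
    makes && all(which(r$orders > 0) %in% gpair) && !flips[i]
  }, TRUE)
  gain <- vapply(seq_along(rs$reactions), function(i) {
    r <- rs$reactions[[i]]
    r$stoich[kx] > 0 && !is_synth[i] && !flips[i]
  }, TRUE)
  d_lin <- sum(vapply(which(is_lin_decay), function(i)
    rs$reactions[[i]]$rate, 0))
  # regulator species sensed by the switching channels
  reg_sp <- sort(unique(unlist(lapply(which(flips), function(i) {
    o <- which(rs$reactions[[i]]$orders > 0)
    setdiff(o, match(meta$gene_pair, rs$species))
  }))))
  if (!length(reg_sp)) reg_sp <- kx
  a <- propensities(rs, counts)
  s <- counts[, k_act]
  n <- counts[, kx]
  nreg <- rowSums(counts[, reg_sp, drop = FALSE])
  g0 <- mean(s == 0); g1 <- mean(s == 1)
  onf <- offf <- onB <- offB <- 0
  for (i in which(flips)) {
    post <- nreg + sum(rs$reactions[[i]]$stoich[reg_sp])
    if (flip_dir[i] > 0) {  # activation: fires in state 0
      onf <- onf + mean(a[, i])
      onB <- onB + mean(a[, i] * post)
    } else {
      offf <- offf + mean(a[, i])
      offB <- offB + mean(a[, i] * nreg)
    }
  }
  st <- list(g0 = g0, g1 = g1,
             m10 = mean(nreg * (s == 0)), m11 = mean(nreg * (s == 1)),
             onf = onf, offf = offf, onB = onB, offB = offB)
  pp <- stats_to_params(st, data.frame(rho0 = meta$rho0, rho1 = meta$rho1,
                                       p = meta$p), "hm2", note)
  if (is.null(pp)) {
    pp <- if (!is.null(last))
      c(s_on = last$s_on, s_off = last$s_off,
        rho0 = meta$rho0, rho1 = meta$rho1)
    else
      c(s_on = onf / max(g0, 1e-12), s_off = offf / max(g1, 1e-12),
        rho0 = meta$rho0, rho1 = meta$rho1)
    note("singular gene matching in the 3-parameter mapping")
  }
  mean_n <- mean(n)
  if (mean_n <= 1e-9) {
    d_eff <- d_lin
    if (any(loss)) note("tracked species absent; effective decay kept ",
                        "at its linear part")
  } else {
    loss_flux <- sum(vapply(which(loss), function(i)
      mean(a[, i]) * (-rs$reactions[[i]]$stoich[kx]), 0))
    gain_flux <- sum(vapply(which(gain), function(i)
      mean(a[, i]) * rs$reactions[[i]]$stoich[kx], 0))
    d_eff <- d_lin + (loss_flux - gain_flux) / mean_n
    if (d_eff < 0) {
      note("net nonlinear gain exceeds all losses; effective decay ",
           "clamped at zero")
      d_eff <- 0
    }
  }
  data.frame(s_on = unname(pp[["s_on"]]), s_off = unname(pp[["s_off"]]),
             rho0 = meta$rho0, rho1 = meta$rho1, d = d_eff, p = meta$p)
}

#' Is the hybrid ensemble size sufficient?
#'
#' Runs the hybrid pipeline with \code{N} and with \code{3N} trajectories
#' and compares the resulting (smooth) distributions; if their Hellinger
#' distance averaged over all output times and tracked species is below
#' 0.02, enlarging the sample would not substantially change the hybrid
#' result, so \code{N} is deemed sufficient.
#'
#' @param network a \code{\link{gene_network}} or a post-regulation
#'   \code{\link{reaction_system}}.
#' @param N base ensemble size.
#' @param t_grid recording times.
#' @param seed integer seed (the \code{3N} run uses \code{seed + 1}).
#' @param method mapping used by the hybrid pipeline.
#' @param N2,seed2 size and seed of the comparison run (defaults
#'   \code{3N} and \code{seed + 1}).
#' @return list with the time-averaged \code{hd} per species and overall,
#'   and logical \code{pass}.
#' @export
sufficiency_check <- function(network, N, t_grid, seed = 1, method = "hm2",
                              N2 = 3L * N, seed2 = seed + 1L) {
  run <- function(n, s)
    hybrid_solve(network, method = method, mode = "transient",
                 t_grid = t_grid, N = n, seed = s, negative = "clamp")
  f1 <- run(N, seed)
  f3 <- run(N2, seed2)
  species <- names(f1$dists)
  hds <- vapply(species, function(sp)
    mean(vapply(seq_along(t_grid), function(i)
      hellinger(f1$dists[[sp]][[i]], f3$dists[[sp]][[i]]), 0)), 0)
  hd <- mean(hds)
  list(hd = hd, per_species = hds, pass = hd < 0.02)
}
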