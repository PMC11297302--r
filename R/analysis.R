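# Accuracy metrics, distribution-shape diagnostics and deterministic
# (mean-field) classification.

as_prob <- function(x, tol = 1e-6) {
  p <- if (inherits(x, "count_dist")) x$p else as.numeric(x)
  if (any(p < -tol)) stop("negative probabilities")
  s <- sum(p)
  if (abs(s - 1) > tol) stop("distribution is not normalized (sum = ",
                             format(s), ")")
  pmax(p, 0) / s
}

#' Hellinger distance between two count distributions
#'
#' \eqn{HD(p, q) = \sqrt{1 - \sum_n \sqrt{p_n q_n}}}, bounded in [0, 1]
#' (the Bhattacharyya-coefficient convention; the alternative
#' \eqn{L_2/\sqrt{2}} normalization is deliberately not used). Supports of
#' different lengths are zero-padded. Distances well below 0.1 correspond
#' to visually indistinguishable distributions.
#'
#' @param p,q probability vectors or \code{\link{count_dist}} objects.
#' @param tol normalization tolerance.
#' @return Hellinger distance in [0, 1].
#' @export
hellinger <- function(p, q, tol = 1e-6) {
  p <- as_prob(p, tol); q <- as_prob(q, tol)
  n <- max(length(p), length(q))
  p <- c(p, numeric(n - length(p)))
  q <- c(q, numeric(n - length(q)))
  bc <- sum(sqrt(p * q))
  sqrt(max(1 - bc, 0))
}

#' Fano factor of a count distribution
#'
#' Variance divided by the mean: 1 for a Poisson distribution, \eqn{1 + B}
#' for constitutive synthesis in geometric bursts of mean size \eqn{B}.
#'
#' @param dist probability vector or \code{\link{count_dist}}.
#' @return variance/mean.
#' @export
fano <- function(dist) {
  p <- as_prob(dist)
  n <- seq_along(p) - 1
  m <- sum(n * p)
  if (m <= 0) stop("Fano factor undefined: zero mean")
  (sum(n^2 * p) - m^2) / m
}

#' Count the modes of a distribution
#'
#' A mode is a local maximum (a plateau of equal values counts once, the
#' boundary \code{n = 0} may be a mode) whose prominence — height above
#' the higher of the two flanking minima — exceeds \code{min_prominence}.
#' The default prominence suppresses truncation-level ripple without
#' hiding genuinely shallow modes.
#'
#' @param dist probability vector or \code{\link{count_dist}}.
#' @param min_prominence minimal prominence of a counted mode.
#' @return integer number of modes.
#' @export
count_modes <- function(dist, min_prominence = 1e-4) {
  p <- as_prob(dist)
  # collapse plateaus
  r <- rle(p)
  v <- r$values
  k <- length(v)
  if (k == 1) return(1L)
  is_peak <- logical(k)
  for (i in seq_len(k)) {
    left <- if (i == 1) -Inf else v[i - 1]
    right <- if (i == k) -Inf else v[i + 1]
    is_peak[i] <- v[i] > left && v[i] > right
  }
  n_modes <- 0L
  for (i in which(is_peak)) {
    # flanking minima: lowest value reachable on each side without
    # climbing above the peak itself
    lmin <- flank_min(v, i, -1L)
    rmin <- flank_min(v, i, +1L)
    if (v[i] - max(lmin, rmin) > min_prominence) n_modes <- n_modes + 1L
  }
  max(n_modes, 1L)
}

flank_min <- function(v, i, step) {
  j <- i + step
  cur <- v[i]
  best <- Inf
  while (j >= 1 && j <= length(v)) {
    if (v[j] > cur) break  # climbed above the peak: stop
    best <- min(best, v[j])
    j <- j + step
  }
  # a boundary peak has no flanking minimum on that side
  if (is.infinite(best)) -Inf else best
}

#' Steady-state accuracy and bimodality sweep
#'
#' Sweeps a two-parameter family of networks, computes the ground-truth
#' steady-state distribution by direct FSP of the nonlinear system, solves
#' each requested approximation, and records the Hellinger distance and
#' mode count at every grid point.
#'
#' @param factory function \code{(a, b) -> gene_network} building the
#'   network at grid point \code{(a, b)}.
#' @param grid_a,grid_b parameter grids.
#' @param solvers subset of \code{c("lma", "hm2", "hm4")}.
#' @param species protein whose distribution is scored.
#' @param min_prominence mode-detection prominence.
#' @param max_fail_frac error if more than this fraction of points fails.
#' @param engine moment source for the approximations: \code{"ode"}
#'   (self-consistent closure), \code{"ssa"} (hybrid: moments sampled
#'   from an ensemble) or \code{"moments"} (exact conditional moments of
#'   the nonlinear FSP solution, the infinite-ensemble limit of the
#'   hybrid; recommended in multistable regimes, where the
#'   self-consistent closure may settle on a spurious branch).
#' @param n_traj,seed,t_grid hybrid-engine settings.
#' @return list with the truth bimodality mask, per-solver HD and
#'   bimodality-mask matrices, per-solver \code{max_hd}, and failure
#'   bookkeeping.
#' @export
sweep_bimodal_region <- function(factory, grid_a, grid_b,
                                 solvers = c("lma", "hm2", "hm4"),
                                 species = "P1", min_prominence = 1e-4,
                                 max_fail_frac = 0.1,
                                 engine = c("ode", "ssa", "moments"),
                                 n_traj = 2000, seed = 1, t_grid = NULL) {
  engine <- match.arg(engine)
  na <- length(grid_a); nb <- length(grid_b)
  shape <- function() matrix(NA_real_, na, nb,
                             dimnames = list(signif(grid_a, 4),
                                             signif(grid_b, 4)))
  truth_modes <- shape()
  hd <- lapply(solvers, function(s) shape()); names(hd) <- solvers
  modes <- lapply(solvers, function(s) shape()); names(modes) <- solvers
  failures <- 0L
  gene_idx <- as.integer(sub("^P", "", species))
  for (ia in seq_len(na)) for (ib in seq_len(nb)) {
    net <- factory(grid_a[ia], grid_b[ib])
    truth_all <- tryCatch(fsp_nonlinear(net, species = species,
                                        keep_joint = engine == "moments"),
                          error = function(e) NULL)
    if (is.null(truth_all)) { failures <- failures + 1L; next }
    truth <- truth_all[[species]]
    truth_modes[ia, ib] <- count_modes(truth, min_prominence)
    for (s in solvers) {
      d <- NULL
      if (engine == "moments") {
        joint <- attr(truth_all, "joint")
        st <- fsp_match_stats(net, joint$space, joint$p, gene_idx)
        g <- net$genes[gene_idx, ]
        lma_par <- c(s_on = st$onf / max(st$g0, 1e-12),
                     s_off = st$offf / max(st$g1, 1e-12),
                     rho0 = g$rho0, rho1 = g$rho1)
        par <- switch(s, lma = lma_par, stats_to_params(st, g, s))
        if (!is.null(par) && any(par < 0)) par <- NULL
        if (is.null(par)) {
          par <- if (s == "hm4") {
            p2 <- stats_to_params(st, g, "hm2")
            if (!is.null(p2) && all(p2 >= 0)) p2 else lma_par
          } else lma_par
        }
        d <- tryCatch(fsp_steady(telegraph_params(
          par[["s_on"]], par[["s_off"]], par[["rho0"]], par[["rho1"]],
          g$d, g$p)), error = function(e) NULL)
      } else {
        fit <- tryCatch(
          if (s != "lma" && engine == "ssa")
            holimap(net, method = s, mode = "steady", engine = "ssa",
                    n_traj = n_traj, seed = seed, t_grid = t_grid,
                    negative = "clamp")
          else
            holimap(net, method = s, mode = "steady", negative = "clamp"),
          error = function(e) NULL)
        if (!is.null(fit)) d <- fit$dists[[species]]
      }
      if (is.null(d)) { failures <- failures + 1L; next }
      hd[[s]][ia, ib] <- hellinger(truth, d)
      modes[[s]][ia, ib] <- count_modes(d, min_prominence)
    }
  }
  n_cells <- na * nb * (1 + length(solvers))
  if (failures > max_fail_frac * n_cells)
    stop("sweep failed at ", failures, " of ", n_cells, " evaluations")
  list(grid_a = grid_a, grid_b = grid_b,
       truth_bimodal = truth_modes >= 2,
       hd = hd, bimodal = lapply(modes, function(m) m >= 2),
       max_hd = vapply(hd, function(m) max(m, na.rm = TRUE), 0),
       failures = failures)
}

#' Accuracy of the mappings across autoregulation parameter space
#'
#' For each cooperativity \code{h}, sweeps a log-spaced grid over the
#' unbinding rate and the (count-scaled) binding rate of a positive
#' autoregulatory loop, computes the exact steady-state protein
#' distribution by direct FSP of the nonlinear model, and records the
#' Hellinger distance of each requested mapping at every grid point.
#' The binding-rate grid is scaled by \eqn{\langle n\rangle^h} (with
#' \eqn{\langle n\rangle = B\rho_b/d} the high-state protein scale) so
#' that the effective switching flux spans the same decades for every
#' cooperativity.
#'
#' @param h_values cooperativities to sweep.
#' @param n_grid grid resolution per axis.
#' @param rho_b,rho_u,d,p autoregulation parameters (positive feedback:
#'   \code{rho_b >> rho_u}; the basal rate is kept away from zero so the
#'   cooperative binding propensity is active in both gene states).
#' @param decades log10 range (relative to \code{d}) of the unbinding
#'   axis.
#' @param flux_decades log10 range of the scaled binding-flux axis.
#' @param flux_scale reference molecule number at which the binding-flux
#'   axis is normalized: \code{sigma_b = flux * d / (flux_scale)_h}
#'   (falling factorial), so the same axis spans comparable switching
#'   fluxes for every cooperativity.
#' @param methods mappings to score.
#' @return list with per-\code{h} HD arrays and the \code{max_hd} matrix
#'   (methods x cooperativities).
#' @export
autoreg_accuracy_sweep <- function(h_values = 1:4, n_grid = 15,
                                   rho_b = 50, rho_u = 5, d = 1, p = 0.5,
                                   decades = c(-1.5, 1.5),
                                   flux_decades = c(-1.5, 1.5),
                                   flux_scale = 10,
                                   methods = c("lma", "hm2", "hm4")) {
  B <- burst_size(p)
  n_c <- B * rho_b / d
  N <- choose_truncation(n_c, sqrt(n_c * (1 + B)), safety = 8)
  grid <- 10^seq(decades[1], decades[2], length.out = n_grid)
  fgrid <- 10^seq(flux_decades[1], flux_decades[2], length.out = n_grid)
  fallbacks <- 0L
  max_hd <- matrix(NA_real_, length(methods), length(h_values),
                   dimnames = list(methods, paste0("h", h_values)))
  detail <- list()
  for (hi in seq_along(h_values)) {
    h <- h_values[hi]
    unit <- function(sb, su, r0, r1, dd)
      cme_generator(compile_reactions(build_autoreg(
        sigma_b = sb, sigma_u = su, rho_b = r1, rho_u = r0, d = dd,
        h = h, p = p)), c(P1 = N))
    Qb <- unit(1, 0, 0, 0, 0)$Q
    gen_u <- unit(0, 1, 0, 0, 0)
    Qu <- gen_u$Q
    Qfix <- unit(0, 0, rho_u, rho_b, d)$Q
    space <- gen_u$space
    hd <- array(NA_real_, c(n_grid, n_grid, length(methods)),
                dimnames = list(NULL, NULL, methods))
    for (ia in seq_len(n_grid)) for (ib in seq_len(n_grid)) {
      su <- grid[ia] * d
      sb <- fgrid[ib] * d / ff(flux_scale, h)
      pv <- steady_solve(Qfix + sb * Qb + su * Qu)
      pn <- cme_marginal(space, pv, "P1")
      truth <- count_dist(pn / sum(pn), species = "P1")
      net <- build_autoreg(sigma_b = sb, sigma_u = su, rho_b = rho_b,
                           rho_u = rho_u, d = d, h = h, p = p)
      # each mapping is evaluated at the exact conditional moments of the
      # nonlinear network (the infinite-ensemble limit of the hybrid
      # pipeline), so the sweep scores the mapping itself rather than the
      # self-consistency iteration
      st <- fsp_match_stats(net, space, pv, 1L)
      lma_par <- c(s_on = st$onf / max(st$g0, 1e-12),
                   s_off = st$offf / max(st$g1, 1e-12),
                   rho0 = rho_u, rho1 = rho_b)
      hm2_par <- stats_to_params(st, net$genes[1, ], "hm2")
      if (is.null(hm2_par) || any(hm2_par < 0)) hm2_par <- NULL
      for (m in methods) {
        par <- switch(m, lma = lma_par,
                      hm2 = hm2_par,
                      hm4 = stats_to_params(st, net$genes[1, ], "hm4"))
        if (!is.null(par) && any(par < 0)) par <- NULL
        if (is.null(par)) {
          # degenerate matching degrades gracefully: the 4-HM drops the
          # synthesis match (2-HM), the 2-HM drops to conditional-mean
          par <- if (m == "hm4" && !is.null(hm2_par)) hm2_par else lma_par
          fallbacks <- fallbacks + 1L
        }
        dfit <- tryCatch(
          fsp_steady(telegraph_params(par[["s_on"]], par[["s_off"]],
                                      par[["rho0"]], par[["rho1"]], d, p)),
          error = function(e) NULL)
        if (!is.null(dfit)) hd[ia, ib, m] <- hellinger(truth, dfit)
      }
    }
    for (m in methods) max_hd[m, hi] <- max(hd[, , m], na.rm = TRUE)
    detail[[paste0("h", h)]] <- hd
  }
  list(max_hd = max_hd, hd = detail, grid = grid, flux_grid = fgrid,
       N = N, fallbacks = fallbacks)
}

#' Deterministic rate equations of a gene network
#'
#' Mean-field ODEs for the active-state probabilities and mean protein
#' numbers, with the mean burst size folded into the synthesis flux and
#' cooperative binding entering as \eqn{x^h}.
#'
#' @param network a \code{\link{gene_network}}.
#' @return function \code{(t, state, parms)} in \code{deSolve} form; the
#'   state is \code{c(gstar_1..M, x_1..M)}.
#' @export
rate_equations <- function(network) {
  g <- network$genes
  M <- network$M
  b1 <- ifelse(g$p == 0, 1, g$p / (1 - g$p))
  ed <- network$edges
  function(t, state, parms = NULL) {
    gs <- state[1:M]
    x <- pmax(state[M + 1:M], 0)
    on <- g$alpha0 + numeric(M)
    off <- g$alpha1 + numeric(M)
    dx <- b1 * (g$rho0 * (1 - gs) + g$rho1 * gs) - g$d * x
    for (k in seq_len(nrow(ed))) {
      i <- ed$from[k]; j <- ed$to[k]; h <- ed$h[k]
      xh <- x[i]^h
      if (ed$type[k] %in% c("bind", "act")) {
        on[j] <- on[j] + ed$rate[k] * xh
        dx[i] <- dx[i] - h * ed$rate[k] * xh * (1 - gs[j])
      }
      if (ed$type[k] == "bind") {
        off[j] <- off[j] + ed$unbind[k]
        dx[i] <- dx[i] + h * ed$unbind[k] * gs[j]
      }
      if (ed$type[k] == "rep") {
        off[j] <- off[j] + ed$rate[k] * xh
        dx[i] <- dx[i] - h * ed$rate[k] * xh * gs[j]
      }
    }
    dgs <- on * (1 - gs) - off * gs
    list(c(dgs, dx))
  }
}

#' Classify the deterministic dynamics of a network
#'
#' Enumerates fixed points of the rate equations by multi-start Newton
#' iteration (numerical Jacobians), classifies their stability by Jacobian
#' eigenvalues, and detects sustained limit-cycle oscillations by long-time
#' integration.
#'
#' @param network a \code{\link{gene_network}}.
#' @param n_starts number of Newton starts.
#' @return list with \code{class} (\code{"monostable"}, \code{"bistable"},
#'   \code{"oscillatory"} or \code{"unclassified"}), the fixed-point matrix
#'   \code{fixed_points}, and their \code{stable} flags.
#' @export
classify_determinism <- function(network, n_starts = 60) {
  M <- network$M
  f <- rate_equations(network)
  fvec <- function(x) unlist(f(0, x))
  scales <- rate_equation_scales(network)
  # deterministic multi-start pattern over gene states and protein scales
  fracs <- c(0.01, 0.1, 0.3, 0.6, 1, 1.5)
  starts <- list()
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(20240801)
  for (i in seq_len(n_starts)) {
    gs <- stats::runif(M)
    x <- scales * sample(fracs, M, replace = TRUE) * stats::runif(M, 0.5, 1.5)
    starts[[i]] <- c(gs, x)
  }
  fps <- list(); stable <- logical(0)
  for (s0 in starts) {
    sol <- tryCatch(pracma::newtonsys(fvec, s0, maxiter = 80),
                    error = function(e) NULL)
    if (is.null(sol) || max(abs(fvec(sol$zero))) > 1e-6) next
    z <- sol$zero
    if (any(z[1:M] < -1e-6 | z[1:M] > 1 + 1e-6) || any(z[M + 1:M] < -1e-6))
      next
    if (length(fps) && any(vapply(fps, function(w)
      max(abs(w - z) / pmax(abs(w), 1)) < 1e-4, TRUE))) next
    J <- pracma::jacobian(fvec, z)
    fps[[length(fps) + 1L]] <- z
    stable <- c(stable, all(Re(eigen(J, only.values = TRUE)$values) < 0))
  }
  n_stable <- sum(stable)
  osc <- FALSE
  if (n_stable == 0) {
    # probe for a sustained limit cycle from an asymmetric state (a
    # symmetric start can sit on an invariant manifold of cyclic motifs)
    t_end <- 400 / min(network$genes$d)
    tr <- deSolve::ode(y = c(rep(0.2, M),
                             scales * seq(1, 0.1, length.out = M)),
                       times = seq(0, t_end, length.out = 2001), func = f,
                       parms = NULL, method = "lsoda")
    x1 <- tr[, 1 + M + 1]
    late <- x1[tr[, 1] > 0.75 * t_end]
    mid <- x1[tr[, 1] > 0.5 * t_end & tr[, 1] <= 0.75 * t_end]
    osc <- (max(late) - min(late)) > 0.05 * max(scales[1], 1) &&
      (max(late) - min(late)) > 0.8 * (max(mid) - min(mid))
  }
  cls <- if (osc) "oscillatory"
  else if (n_stable >= 2) "bistable"
  else if (n_stable == 1) "monostable"
  else "unclassified"
  list(class = cls,
       fixed_points = if (length(fps)) do.call(rbind, fps) else
         matrix(numeric(0), 0, 2 * M),
       stable = stable)
}
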