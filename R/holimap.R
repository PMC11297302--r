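#' Fit a linear-network approximation to a stochastic gene network
#'
#' Maps a nonlinear gene regulatory network onto an effective linear
#' network by conditional moment-matching and solves the linear network's
#' chemical master equation by finite state projection, yielding smooth
#' protein-number distributions for every gene. Methods:
#' \describe{
#'   \item{\code{"lma"}}{linear-mapping approximation: the binding rate is
#'     replaced by its conditional mean-field value.}
#'   \item{\code{"hm2"}}{two-parameter Holimap: both switching rates are
#'     matched (recommended for time-dependent solutions).}
#'   \item{\code{"hm4"}}{four-parameter Holimap: switching and synthesis
#'     rates are matched (recommended at steady state; may produce
#'     negative effective rates in extreme regimes, see \code{negative}).}
#'   \item{\code{"hm3"}}{three-parameter Holimap for post-translational /
#'     post-transcriptional reaction systems: switching rates plus an
#'     effective first-order degradation rate replacing bimolecular or
#'     enzymatic loss channels. Requires \code{engine = "ssa"}.}
#' }
#' With \code{engine = "ode"} the closed moment equations are integrated
#' self-consistently (the matching relations are evaluated inside the
#' right-hand side); with \code{engine = "ssa"} the moments are estimated
#' from a modest ensemble of exact stochastic simulations (the hybrid
#' method), which is the practical route for large networks.
#'
#' @param network a \code{\link{gene_network}}, or a
#'   \code{\link{reaction_system}} for \code{method = "hm3"}.
#' @param method \code{"auto"} (4-HM at steady state, 2-HM for dynamics),
#'   \code{"lma"}, \code{"hm2"}, \code{"hm3"} or \code{"hm4"}.
#' @param mode \code{"steady"} or \code{"transient"}.
#' @param t_grid output times (required for transient mode).
#' @param engine \code{"ode"} (self-consistent moment closure) or
#'   \code{"ssa"} (hybrid: sample moments from simulated trajectories).
#' @param n_traj ensemble size for \code{engine = "ssa"}.
#' @param seed RNG seed for \code{engine = "ssa"}.
#' @param negative policy when matching yields negative effective rates:
#'   \code{"error"} (default) or \code{"clamp"} (truncate at zero with a
#'   recorded warning).
#' @param init optional initial moment vector (ODE engine); default: all
#'   genes inactive, no protein.
#' @param fsp_tol truncation tolerance of the linear-network FSP solves.
#' @param steady_tol residual tolerance of the steady-state moment solve.
#' @param ... reserved.
#' @return an object of class \code{holimap} with components
#'   \code{params} (effective-rate trajectory or steady values),
#'   \code{dists} (per-gene \code{\link{count_dist}}, per time point in
#'   transient mode), \code{moments}, and \code{notes} (structured records
#'   of fallbacks and clamps). Supports \code{print}, \code{summary},
#'   \code{coef}, \code{residuals}, \code{predict}, \code{plot} and
#'   \code{simulate}.
#' @examples
#' \donttest{
#' net <- build_autoreg(sigma_b = 0.1, sigma_u = 1, rho_b = 50, rho_u = 1,
#'                      d = 1, h = 1, p = 0.5)
#' fit <- holimap(net, method = "hm4", mode = "steady")
#' coef(fit)
#' }
#' @export
holimap <- function(network, method = c("auto", "lma", "hm2", "hm3", "hm4"),
                    mode = c("steady", "transient"), t_grid = NULL,
                    engine = c("ode", "ssa"), n_traj = 2000, seed = NULL,
                    negative = c("error", "clamp"), init = NULL,
                    fsp_tol = 1e-8, steady_tol = 1e-8, ...) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  negative <- match.arg(negative)
  cal <- match.call()
  if (method == "auto")
    method <- if (mode == "steady") "hm4" else "hm2"
  if (inherits(network, "reaction_system") || method == "hm3") {
    if (method %in% c("auto", "hm3")) method <- "hm3" else
      stop("reaction-system input requires method = 'hm3'")
    if (engine != "ssa")
      stop("the 3-parameter mapping estimates moments from simulation; ",
           "use engine = 'ssa'")
  }
  if (mode == "transient" && is.null(t_grid))
    stop("transient mode needs a t_grid")
  if (engine == "ssa")
    return(hybrid_solve(network, method = method, mode = mode,
                        t_grid = t_grid, N = n_traj, seed = seed,
                        negative = negative, fsp_tol = fsp_tol, call = cal))

  cl <- holimap_closure(network, method)
  notes <- character(0)
  note <- function(...) notes <<- c(notes, paste0(...))
  if (is.null(init)) init <- init_moments(cl$ms_nl)
  rhs <- function(t, y, parms) list(closure_rhs(cl, y, negative = negative,
                                                note = note)$dy)
  if (mode == "steady") {
    y <- steady_closure(cl, init, negative, note, steady_tol)
    par <- match_params(cl, y, negative = negative, note = note)
    dists <- lapply(seq_len(network$M), function(j) {
      dj <- fsp_steady(telegraph_params(par$s_on[j], par$s_off[j],
                                        par$rho0[j], par$rho1[j],
                                        par$d[j], par$p[j]), tol = fsp_tol)
      dj$species <- paste0("P", j)
      dj
    })
    names(dists) <- paste0("P", seq_len(network$M))
    moments <- y
  } else {
    sol <- integrate_closure_grid(rhs, init, t_grid)
    par_list <- lapply(seq_along(t_grid), function(i) {
      p <- match_params(cl, sol[i, -1], negative = negative, note = note)
      cbind(time = t_grid[i], p)
    })
    par <- do.call(rbind, par_list)
    dists <- lapply(seq_len(network$M), function(j) {
      pj <- par[par$gene == j, ]
      traj <- data.frame(time = pj$time, s_on = pj$s_on, s_off = pj$s_off,
                         rho0 = pj$rho0, rho1 = pj$rho1, d = pj$d)
      ds <- fsp_transient(traj, p = network$genes$p[j], t_grid = t_grid,
                          tol = max(fsp_tol, 1e-6))
      for (i in seq_along(ds)) ds[[i]]$species <- paste0("P", j)
      ds
    })
    names(dists) <- paste0("P", seq_len(network$M))
    moments <- sol
  }
  structure(list(call = cal, network = network, method = method, mode = mode,
                 engine = "ode", t_grid = t_grid, params = par,
                 dists = dists, moments = moments, notes = notes,
                 closure = cl),
            class = "holimap")
}

# integrate the closed moment system over a grid; the matched right-hand
# side is only piecewise smooth (fallback switches), which lsoda's stiff
# mode occasionally refuses — fall back to an explicit embedded pair
integrate_closure_grid <- function(rhs, init, t_grid) {
  run <- function(method, rtol, atol)
    tryCatch(suppressWarnings(
      deSolve::ode(y = init, times = t_grid, func = rhs, parms = NULL,
                   method = method, rtol = rtol, atol = atol,
                   maxsteps = 50000)),
      error = function(e) NULL)
  ok <- function(sol) !is.null(sol) && nrow(sol) == length(t_grid) &&
    !anyNA(sol)
  sol <- run("lsoda", 1e-8, 1e-10)
  if (!ok(sol)) sol <- run("ode45", 1e-6, 1e-8)
  if (!ok(sol)) {
    reached <- if (is.null(sol)) min(t_grid) else max(sol[, 1], na.rm = TRUE)
    stop("moment closure integration failed near t = ", reached)
  }
  sol
}

# steady moments of the mapped linear network at fixed effective rates:
# the closed system is linear, so the fixed point is a single dense solve
# with the redundant gene-state equation replaced by normalization
steady_linear_moments <- function(cl, theta) {
  A <- cl$A_fix
  for (j in seq_len(cl$network$M)) {
    A <- A + theta[j, 1] * cl$A_on[[j]] + theta[j, 2] * cl$A_off[[j]]
    if (cl$method == "hm4")
      A <- A + theta[j, 3] * cl$A_r0[[j]] + theta[j, 4] * cl$A_r1[[j]]
  }
  A <- as.matrix(A)
  g_rows <- which(rowSums(cl$idx$m) == 0)
  A[g_rows[1], ] <- 0
  A[g_rows[1], g_rows] <- 1
  b <- numeric(nrow(A)); b[g_rows[1]] <- 1
  solve(A, b)
}

# steady state of the matched closure.  The closure can have several
# self-consistent fixed points (it inherits the multistability of the
# underlying network), so the primary route integrates the closure ODE
# from the physically prepared initial state (genes inactive, no protein)
# and polishes the end point by Newton; a damped self-consistent iteration
# on the effective parameters and horizon doubling serve as fallbacks.
steady_closure <- function(cl, init, negative, note, tol) {
  t_end <- 50 / min(cl$network$genes$d)
  if (cl$method == "hm4") {
    # the 4-HM closure ODE is unstable far from its fixed point; polish
    # the 2-HM steady state instead (the two share the same moment basis)
    y2 <- tryCatch(
      steady_closure(holimap_closure(cl$network, "hm2"), init, negative,
                     function(...) NULL, tol),
      error = function(e) NULL)
    if (!is.null(y2)) {
      y <- steady_closure_polish(cl, y2, negative, note, tol)
      if (!is.null(y)) return(y)
    }
    return(steady_closure_picard(cl, init, negative, note, tol,
                                 ode_fallback = FALSE))
  }
  rhs <- function(t, z, p)
    list(closure_rhs(cl, z, negative = "clamp", note = note)$dy)
  y <- init
  horizon <- t_end
  for (k in 0:1) {
    sol <- tryCatch(integrate_closure_grid(rhs, y, c(0, horizon)),
                    error = function(e) NULL)
    if (is.null(sol)) break
    y_end <- pmax(sol[nrow(sol), -1], 0)
    y_pol <- steady_closure_polish(cl, y_end, negative, note, tol)
    if (!is.null(y_pol)) {
      # accept only if refinement stays near the integrated end point
      # (a large jump means Newton crossed into a different basin)
      drift <- max(abs(y_pol - y_end) / pmax(abs(y_end), 1))
      if (drift < 0.2) return(y_pol)
    }
    y <- y_end
    horizon <- 2 * horizon
  }
  steady_closure_picard(cl, init, negative, note, tol)
}

steady_closure_picard <- function(cl, init, negative, note, tol,
                                  ode_fallback = TRUE) {
  theta <- try(match_core(cl, init, negative = "clamp"), silent = TRUE)
  if (!inherits(theta, "try-error")) {
    omega <- 0.5
    delta_prev <- Inf
    y <- init
    for (it in 1:400) {
      y_new <- try(steady_linear_moments(cl, theta), silent = TRUE)
      if (inherits(y_new, "try-error")) break
      theta_new <- try(match_core(cl, y_new, negative = "clamp"),
                       silent = TRUE)
      if (inherits(theta_new, "try-error")) break
      delta <- max(abs(theta_new[, 1:4] - theta[, 1:4]) /
                     pmax(abs(theta[, 1:4]), 1))
      theta <- (1 - omega) * theta + omega * theta_new
      y <- y_new
      if (delta > delta_prev) omega <- max(omega / 2, 0.05)
      delta_prev <- delta
      if (delta < 1e-12) break
    }
    if (!inherits(y, "try-error")) {
      y <- steady_closure_polish(cl, y, negative, note, tol)
      if (!is.null(y)) return(y)
    }
  }
  if (!ode_fallback)
    stop("the 4-parameter closure did not reach a self-consistent steady ",
         "state (its matching can turn negative when binding/unbinding ",
         "rates are large); use method = 'hm2' or engine = 'ssa'")
  steady_closure_ode(cl, init, negative, note, tol)
}

steady_closure_polish <- function(cl, y, negative, note, tol) {
  g_rows <- which(rowSums(cl$idx$m) == 0)
  f_mod <- function(z) {
    r <- closure_rhs(cl, z, negative = negative, note = note)$dy
    r[g_rows[1]] <- sum(z[g_rows]) - 1
    r
  }
  y <- newton_refine(f_mod, y, tol)
  ok <- max(abs(f_mod(y))) < max(tol, 1e-9 * max(abs(y))) &&
    all(y[g_rows] > -1e-8) && abs(sum(y[g_rows]) - 1) < 1e-6
  if (ok) y else NULL
}

newton_refine <- function(f_mod, y, tol) {
  L <- length(y)
  for (it in 1:25) {
    r <- f_mod(y)
    if (max(abs(r)) < tol) break
    J <- matrix(0, L, L)
    for (i in seq_len(L)) {
      hstep <- 1e-7 * max(abs(y[i]), 1)
      yp <- y; yp[i] <- yp[i] + hstep
      J[, i] <- (f_mod(yp) - r) / hstep
    }
    dy <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(dy)) break
    lam <- 1
    repeat {
      y_new <- y + lam * dy
      if (max(abs(f_mod(y_new))) < max(abs(r)) || lam < 1e-4) break
      lam <- lam / 2
    }
    if (max(abs(y_new - y)) == 0) break
    y <- y_new
  }
  y
}

steady_closure_ode <- function(cl, init, negative, note, tol) {
  g_rows <- which(rowSums(cl$idx$m) == 0)
  norm_row <- g_rows[1]
  f_mod <- function(z) {
    r <- closure_rhs(cl, z, negative = negative, note = note)$dy
    r[norm_row] <- sum(z[g_rows]) - 1
    r
  }
  t_end <- 50 / min(cl$network$genes$d)
  y <- init
  res <- Inf
  for (k in 0:4) {
    sol <- deSolve::ode(y = y, times = c(0, t_end * 2^k),
                        func = function(t, z, p)
                          list(closure_rhs(cl, z, negative = negative,
                                           note = note)$dy),
                        parms = NULL, method = "lsoda",
                        rtol = 1e-6, atol = 1e-8, maxsteps = 20000)
    y <- newton_refine(f_mod, pmax(sol[nrow(sol), -1], 0), tol)
    res <- max(abs(f_mod(y)))
    if (res < max(tol, 1e-9 * max(abs(y)))) return(y)
  }
  stop("moment closure did not reach steady state (residual ",
       format(res), ")")
}

#' @export
print.holimap <- function(x, ...) {
  cat(sprintf("Holimap fit (%s, %s mode, %s engine)\n",
              toupper(x$method), x$mode, x$engine))
  M <- if (inherits(x$network, "gene_network")) x$network$M else 1L
  cat(sprintf("  genes: %d; distributions for: %s\n", M,
              paste(names(x$dists), collapse = ", ")))
  if (x$mode == "steady") {
    cat("  effective parameters:\n")
    print(x$params, row.names = FALSE)
  } else {
    cat(sprintf("  %d output times in [%g, %g]\n", length(x$t_grid),
                min(x$t_grid), max(x$t_grid)))
  }
  if (length(x$notes))
    cat("  notes:", length(x$notes), "matching fallback/clamp record(s)\n")
  invisible(x)
}

#' @export
summary.holimap <- function(object, ...) {
  means <- vapply(object$dists, function(d) {
    if (inherits(d, "count_dist")) dist_mean(d) else dist_mean(d[[length(d)]])
  }, 0)
  structure(list(fit = object, means = means,
                 notes = unique(object$notes)), class = "summary.holimap")
}

#' @export
print.summary.holimap <- function(x, ...) {
  print(x$fit)
  lab <- if (x$fit$mode == "steady") "steady-state" else "final-time"
  cat(sprintf("  %s means: %s\n", lab,
              paste(sprintf("%s = %.3f", names(x$means), x$means),
                    collapse = ", ")))
  if (length(x$notes)) cat("  ", paste(x$notes, collapse = "\n   "), "\n")
  invisible(x)
}

#' @export
coef.holimap <- function(object, ...) object$params

#' Matching residuals of a Holimap fit
#'
#' Re-evaluates the moment-matching equations at the fitted moments and
#' effective parameters; residuals are zero (to solver tolerance) except
#' where a singular-system fallback or a clamp was applied.
#'
#' @param object a \code{\link{holimap}} fit (ODE engine).
#' @param ... unused.
#' @return matrix of residuals, one row per gene.
#' @export
residuals.holimap <- function(object, ...) {
  if (is.null(object$closure))
    stop("matching residuals are only recorded for the ODE engine")
  cl <- object$closure
  y <- if (object$mode == "steady") object$moments else
    object$moments[nrow(object$moments), -1]
  par <- if (object$mode == "steady") object$params else
    object$params[object$params$time == max(object$params$time), ]
  M <- cl$network$M
  out <- matrix(0, M, 2, dimnames = list(paste0("gene", 1:M),
                                         c("state_eq", "bound_mean_eq")))
  if (cl$method == "lma") return(out)
  dot <- function(r) sum(r * y)
  for (j in 1:M) {
    r <- cl$rows[[j]]
    lin_g0 <- dot(r$fix_g0) + par$s_on[j] * dot(r$on_g0) +
      par$s_off[j] * dot(r$off_g0)
    lin_1b <- dot(r$fix_1b) + par$s_on[j] * dot(r$on_1b) +
      par$s_off[j] * dot(r$off_1b)
    if (cl$method == "hm4") {
      lin_g0 <- lin_g0 + par$rho0[j] * dot(r$r0_g0) + par$rho1[j] * dot(r$r1_g0)
      lin_1b <- lin_1b + par$rho0[j] * dot(r$r0_1b) + par$rho1[j] * dot(r$r1_1b)
    }
    out[j, ] <- c(dot(r$nl_g0) - lin_g0, dot(r$nl_1b) - lin_1b)
  }
  out
}

#' Predicted count distribution of a fitted gene
#'
#' @param object a \code{\link{holimap}} fit.
#' @param gene gene index (or species name for 3-HM fits).
#' @param time requested time (nearest stored output time is returned);
#'   ignored for steady-state fits.
#' @param ... unused.
#' @return a \code{\link{count_dist}}.
#' @export
predict.holimap <- function(object, gene = 1, time = NULL, ...) {
  d <- if (is.character(gene)) object$dists[[gene]] else object$dists[[gene]]
  if (inherits(d, "count_dist")) return(d)
  if (is.null(time)) return(d[[length(d)]])
  d[[which.min(abs(object$t_grid - time))]]
}

#' @export
plot.holimap <- function(x, gene = 1, time = NULL, ...) {
  d <- predict.holimap(x, gene = gene, time = time)
  graphics::plot(seq_along(d$p) - 1, d$p, type = "h",
                 xlab = "molecule number", ylab = "probability",
                 main = sprintf("%s (%s)", d$species, toupper(x$method)), ...)
  invisible(x)
}

#' Simulate exact trajectories of the fitted nonlinear network
#'
#' @param object a \code{\link{holimap}} fit.
#' @param nsim number of stochastic simulation trajectories.
#' @param seed RNG seed.
#' @param t_grid recording times (defaults to the fit's grid, or
#'   \code{0..10/min(d)} for steady-state fits).
#' @param ... passed to \code{\link{simulate_ensemble}}.
#' @return a \code{trajectory_ensemble}.
#' @export
simulate.holimap <- function(object, nsim = 1000, seed = 1, t_grid = NULL, ...) {
  rs <- if (inherits(object$network, "reaction_system")) object$network
        else compile_reactions(object$network)
  if (is.null(t_grid)) {
    t_grid <- if (!is.null(object$t_grid)) object$t_grid else {
      d_min <- if (inherits(object$network, "gene_network"))
        min(object$network$genes$d) else 1
      seq(0, 10 / d_min, length.out = 51)
    }
  }
  simulate_ensemble(rs, N = nsim, t_grid = t_grid, seed = seed, ...)
}
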