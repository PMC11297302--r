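# Exact stochastic simulation (SSA) front end.  The event loop is compiled
# code; each trajectory uses an independent RNG stream derived from
# (seed, trajectory index), so ensembles are bitwise reproducible.

#' Simulate an ensemble of exact trajectories
#'
#' Direct-method stochastic simulation of a reaction system. Bursty
#' synthesis channels draw geometric jump sizes
#' \eqn{P(k = n) = p^n (1 - p)}; the state is recorded by holding it
#' constant between reaction events (exact for jump processes).
#'
#' @param x a \code{\link{reaction_system}} or \code{\link{gene_network}}
#'   (compiled automatically).
#' @param N number of trajectories.
#' @param t_grid increasing recording times (must start at or after 0).
#' @param seed integer seed; the same \code{(seed, N, t_grid)} always
#'   reproduces the same ensemble.
#' @param species character vector of species to record (default: all,
#'   use a subset to save memory in large ensembles).
#' @param init named initial counts (default: all genes inactive, all
#'   other species at zero).
#' @return a \code{trajectory_ensemble}: list with the count array
#'   \code{counts} (species x time x trajectory), \code{species},
#'   \code{t_grid}, \code{N} and \code{seed}.
#' @export
simulate_ensemble <- function(x, N, t_grid, seed, species = NULL,
                              init = NULL) {
  rs <- if (inherits(x, "gene_network")) compile_reactions(x) else x
  stopifnot(inherits(rs, "reaction_system"))
  N <- check_count(N, "N")
  seed <- check_count(seed, "seed", min = 0L)
  if (is.unsorted(t_grid, strictly = TRUE) || any(t_grid < 0))
    stop("t_grid must be strictly increasing and non-negative")
  ns <- length(rs$species)
  if (is.null(species)) species <- rs$species
  rec <- match(species, rs$species)
  if (anyNA(rec)) stop("unknown species: ",
                       paste(species[is.na(rec)], collapse = ", "))
  x0 <- integer(ns)
  for (pr in rs$pairs) x0[pr[1]] <- 1L   # switches start inactive
  if (!is.null(init)) {
    ii <- match(names(init), rs$species)
    if (anyNA(ii)) stop("unknown species in init")
    x0[ii] <- as.integer(init)
  }
  nr <- length(rs$reactions)
  stoich <- matrix(0L, ns, nr)
  orders <- matrix(0L, ns, nr)
  rate <- numeric(nr); kind <- integer(nr)
  mm_sub <- rep(-1L, nr); mm_K <- numeric(nr)
  burst_sp <- rep(-1L, nr); burst_p <- numeric(nr)
  for (r in seq_len(nr)) {
    rc <- rs$reactions[[r]]
    stoich[, r] <- as.integer(rc$stoich)
    orders[, r] <- as.integer(rc$orders)
    rate[r] <- rc$rate
    if (rc$kind == "mm") { kind[r] <- 1L; mm_sub[r] <- rc$mm_sub - 1L
                           mm_K[r] <- rc$mm_K }
    if (!is.na(rc$burst)) { burst_sp[r] <- rc$burst - 1L; burst_p[r] <- rc$p }
  }
  counts <- .ssa_run(stoich, rate, orders, kind, mm_sub, mm_K,
                     burst_sp, burst_p, x0, t_grid, N, seed, rec - 1L)
  dimnames(counts) <- list(species, NULL, NULL)
  structure(list(counts = counts, species = species, t_grid = t_grid,
                 N = N, seed = seed, system = rs),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf(
    "Trajectory ensemble: %d trajectories, %d species, %d times in [%g, %g]\n",
    x$N, length(x$species), length(x$t_grid), min(x$t_grid), max(x$t_grid)))
  invisible(x)
}

#' Draw geometric burst sizes
#'
#' Samples from \eqn{P(k = n) = p^n (1 - p)}, \eqn{n = 0, 1, 2, \ldots}
#' (mean \eqn{p/(1-p)}); \code{p = 0} always returns 0.
#'
#' @param n number of draws.
#' @param p burst parameter in [0, 1).
#' @param seed integer seed.
#' @return integer vector of burst sizes.
#' @export
sample_geometric_burst <- function(n, p, seed = 1) {
  check_prob(p, "p")
  .sample_geometric(as.integer(n), p, as.integer(seed))
}

#' Empirical count distribution at a recorded time
#'
#' @param ens a \code{trajectory_ensemble}.
#' @param species recorded species name.
#' @param t a time in the recording grid.
#' @return a \code{\link{count_dist}} (normalized histogram; support is the
#'   observed maximum plus one).
#' @export
empirical_distribution <- function(ens, species, t) {
  it <- match(t, ens$t_grid)
  if (is.na(it)) stop("t is not in the recording grid")
  k <- match(species, ens$species)
  if (is.na(k)) stop("unknown species: ", species)
  n <- ens$counts[k, it, ]
  p <- tabulate(n + 1L, nbins = max(n) + 1L) / length(n)
  count_dist(p, species = species, time = t)
}

#' Sample conditional moments of a gene from an ensemble
#'
#' Empirical analogue of the conditional factorial moments: gene-state
#' frequencies \code{g} and falling-factorial averages of the gene's
#' protein count restricted to each gene state.
#'
#' @param ens a \code{trajectory_ensemble} recorded from a compiled
#'   \code{\link{gene_network}} (species \code{Gj*} and \code{Pj} present).
#' @param gene gene index.
#' @param t a recorded time.
#' @param order maximal factorial-moment order.
#' @return list with \code{g} (state frequencies, unbound first) and
#'   \code{mu} (matrix \code{order x 2} of conditional factorial moments;
#'   row \code{m}, column \code{i+1} holds \eqn{\mu_{m,i}}), plus
#'   \code{missing_state} flagging a state never visited at \code{t}.
#' @export
sample_conditional_moments <- function(ens, gene, t, order = 2) {
  it <- match(t, ens$t_grid)
  if (is.na(it)) stop("t is not in the recording grid")
  gsp <- paste0("G", gene, "*"); psp <- paste0("P", gene)
  kg <- match(gsp, ens$species); kp <- match(psp, ens$species)
  if (is.na(kg) || is.na(kp))
    stop("ensemble does not record ", gsp, " and ", psp)
  s <- ens$counts[kg, it, ]
  n <- ens$counts[kp, it, ]
  g <- c(mean(s == 0), mean(s == 1))
  mu <- matrix(0, max(order, 0), 2)
  for (m in seq_len(max(order, 0)))
    for (i in 0:1)
      mu[m, i + 1] <- mean(ff(n, m) * (s == i))
  list(g = g, mu = mu, missing_state = g == 0)
}
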