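#' Generic reaction system
#'
#' A \code{reaction_system} is a species/reaction representation of a
#' stochastic kinetic model, consumed by the stochastic simulation
#' algorithm (\code{\link{simulate_ensemble}}) and by the truncated
#' chemical-master-equation generator (\code{\link{cme_generator}}).
#'
#' Propensities are products of falling factorials of species counts
#' (\code{orders}), so an \eqn{h}-th order binding channel has the
#' combinatorial form \eqn{\sigma\, n(n-1)\cdots(n-h+1)}. Two propensity
#' kinds are supported: \code{"massaction"} and \code{"mm"}
#' (Michaelis-Menten, \eqn{V n_S/(K + n_S)} times any additional
#' mass-action factors). A reaction may produce a geometric burst of a
#' species (parameter \code{p}; the jump size is drawn from
#' \eqn{P(k=n) = p^n(1-p)}) in addition to its fixed stoichiometry.
#'
#' Species that form conserved two-state switches (gene states, enzyme
#' activity states) are recorded in \code{pairs}; the members of a pair
#' have counts summing to one.
#'
#' @param species character vector of species names.
#' @param reactions list of reactions created with \code{\link{rxn}}.
#' @param pairs list of length-2 integer vectors (or character pairs)
#'   naming conserved two-state switches, inactive member first.
#' @return an object of class \code{reaction_system}.
#' @export
reaction_system <- function(species, reactions, pairs = list()) {
  stopifnot(is.character(species), !anyDuplicated(species))
  ns <- length(species)
  pairs <- lapply(pairs, function(p) {
    if (is.character(p)) p <- match(p, species)
    stopifnot(length(p) == 2L, !anyNA(p))
    as.integer(p)
  })
  reactions <- lapply(reactions, function(r) {
    expand <- function(v) {
      out <- numeric(ns); names(out) <- species
      if (length(v)) {
        if (is.null(names(v))) stop("stoich/orders must be named by species")
        bad <- setdiff(names(v), species)
        if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
        out[names(v)] <- v
      }
      out
    }
    r$stoich <- expand(r$stoich)
    r$orders <- expand(r$orders)
    if (r$rate < 0) stop("reaction rate must be non-negative")
    if (!r$kind %in% c("massaction", "mm")) stop("unknown propensity kind")
    if (r$kind == "mm") {
      r$mm_sub <- match(r$mm_sub, species)
      if (is.na(r$mm_sub)) stop("Michaelis-Menten substrate not a species")
    }
    if (!is.null(r$burst) && !is.na(r$burst)) {
      r$burst <- match(r$burst, species)
      if (is.na(r$burst)) stop("burst species not a species")
      check_prob(r$p, "p")
      if (r$p == 0) {  # degenerate burst: exactly one molecule per event
        r$stoich[r$burst] <- r$stoich[r$burst] + 1
        r$burst <- NA_integer_
      }
    } else r$burst <- NA_integer_
    r
  })
  structure(list(species = species, reactions = reactions, pairs = pairs),
            class = "reaction_system")
}

#' Define a reaction channel
#'
#' @param rate rate constant.
#' @param orders named vector of falling-factorial orders of the propensity
#'   (e.g. \code{c(G = 1, P = 2)} for \eqn{\sigma\, g\, n(n-1)}).
#' @param stoich named vector of fixed count changes on firing.
#' @param kind \code{"massaction"} or \code{"mm"}.
#' @param mm_sub,mm_K Michaelis-Menten substrate name and constant.
#' @param burst species receiving a geometric burst on firing (or NULL).
#' @param p geometric burst parameter.
#' @param label optional channel label used in error messages.
#' @return a list describing one reaction channel.
#' @export
rxn <- function(rate, orders = NULL, stoich = NULL, kind = "massaction",
                mm_sub = NULL, mm_K = NULL, burst = NULL, p = 0,
                label = NULL) {
  list(rate = rate, orders = orders, stoich = stoich, kind = kind,
       mm_sub = mm_sub, mm_K = mm_K, burst = burst, p = p,
       label = label)
}

#' @export
print.reaction_system <- function(x, ...) {
  cat(sprintf("Reaction system: %d species, %d reactions, %d switch pair(s)\n",
              length(x$species), length(x$reactions), length(x$pairs)))
  cat("Species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate propensities
#'
#' @param rs a \code{\link{reaction_system}}.
#' @param x count matrix (states in rows, one column per species) or a
#'   single count vector.
#' @return matrix of propensities (states in rows, reactions in columns).
#' @export
propensities <- function(rs, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(rs$species)) stop("state dimension mismatch")
  a <- matrix(0, nrow(x), length(rs$reactions))
  for (r in seq_along(rs$reactions)) {
    rc <- rs$reactions[[r]]
    v <- rep(rc$rate, nrow(x))
    for (k in which(rc$orders > 0)) v <- v * ff(x[, k], rc$orders[k])
    if (rc$kind == "mm") {
      s <- x[, rc$mm_sub]
      v <- v * s / (rc$mm_K + s)
    }
    a[, r] <- v
  }
  if (any(a < 0)) stop("negative propensity encountered")
  a
}

#' Compile a gene network into a reaction system
#'
#' Expands a \code{\link{gene_network}} into explicit reaction channels:
#' spontaneous switching, regulation (cooperative binding with
#' falling-factorial propensity), bursty synthesis in each gene state, and
#' first-order decay. Channels with zero rate are omitted. Species are
#' ordered as \code{G1, G1*, ..., GM, GM*, P1, ..., PM}; for gene \eqn{j}
#' the pair \code{Gj} (inactive) / \code{Gj*} (active) forms a conserved
#' switch.
#'
#' @param network a \code{\link{gene_network}}.
#' @return a \code{\link{reaction_system}}.
#' @export
compile_reactions <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  M <- network$M
  G0 <- paste0("G", 1:M)
  G1 <- paste0("G", 1:M, "*")
  P <- paste0("P", 1:M)
  species <- c(rbind(G0, G1), P)
  rx <- list()
  add <- function(r) rx[[length(rx) + 1L]] <<- r
  for (j in 1:M) {
    g <- network$genes[j, ]
    if (g$alpha0 > 0)
      add(rxn(g$alpha0, orders = stats::setNames(1, G0[j]),
              stoich = stats::setNames(c(-1, 1), c(G0[j], G1[j])),
              label = sprintf("gene %d spontaneous activation", j)))
    if (g$alpha1 > 0)
      add(rxn(g$alpha1, orders = stats::setNames(1, G1[j]),
              stoich = stats::setNames(c(1, -1), c(G0[j], G1[j])),
              label = sprintf("gene %d spontaneous inactivation", j)))
    for (state in 0:1) {
      rho <- if (state == 0) g$rho0 else g$rho1
      gs <- if (state == 0) G0[j] else G1[j]
      if (rho > 0) {
        if (g$p > 0)
          add(rxn(rho, orders = stats::setNames(1, gs), burst = P[j], p = g$p,
                  label = sprintf("gene %d synthesis (state %d)", j, state)))
        else
          add(rxn(rho, orders = stats::setNames(1, gs),
                  stoich = stats::setNames(1, P[j]),
                  label = sprintf("gene %d synthesis (state %d)", j, state)))
      }
    }
    if (g$d > 0)
      add(rxn(g$d, orders = stats::setNames(1, P[j]),
              stoich = stats::setNames(-1, P[j]),
              label = sprintf("protein %d decay", j)))
  }
  ed <- network$edges
  for (e in seq_len(nrow(ed))) {
    i <- ed$from[e]; j <- ed$to[e]; h <- ed$h[e]
    if (ed$type[e] %in% c("bind", "act") && ed$rate[e] > 0)
      add(rxn(ed$rate[e], orders = stats::setNames(c(1, h), c(G0[j], P[i])),
              stoich = stats::setNames(c(-1, 1, -h), c(G0[j], G1[j], P[i])),
              label = sprintf("binding of %d P%d to gene %d", h, i, j)))
    if (ed$type[e] == "bind" && ed$unbind[e] > 0)
      add(rxn(ed$unbind[e], orders = stats::setNames(1, G1[j]),
              stoich = stats::setNames(c(1, -1, h), c(G0[j], G1[j], P[i])),
              label = sprintf("unbinding of %d P%d from gene %d", h, i, j)))
    if (ed$type[e] == "rep" && ed$rate[e] > 0)
      add(rxn(ed$rate[e], orders = stats::setNames(c(1, h), c(G1[j], P[i])),
              stoich = stats::setNames(c(1, -1, -h), c(G0[j], G1[j], P[i])),
              label = sprintf("repressive binding of %d P%d to gene %d", h, i, j)))
  }
  rs <- reaction_system(species, rx,
                        pairs = lapply(1:M, function(j) c(G0[j], G1[j])))
  attr(rs, "network") <- network
  rs
}
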