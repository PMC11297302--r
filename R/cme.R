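# Truncated chemical-master-equation machinery.
#
# A state space is the product of one binary digit per conserved switch pair
# and one bounded count digit per remaining species.  The generator Q acts on
# probability vectors as dp/dt = Q p; probability flowing beyond the
# truncation is lost (finite state projection), so 1 - sum(p) bounds the
# truncation error.

#' Enumerate a truncated state space
#'
#' @param rs a \code{\link{reaction_system}}.
#' @param caps named integer vector of count caps for every species that is
#'   not a member of a switch pair.
#' @return a list describing the state space: digit dimensions, strides,
#'   and the \code{n_states x n_species} count matrix.
#' @export
cme_space <- function(rs, caps) {
  ns <- length(rs$species)
  pair_members <- unlist(rs$pairs)
  count_sp <- setdiff(seq_len(ns), pair_members)
  if (!all(rs$species[count_sp] %in% names(caps)))
    stop("caps must name every non-switch species")
  caps <- caps[rs$species[count_sp]]
  dims <- c(rep(2L, length(rs$pairs)), as.integer(caps) + 1L)
  n <- prod(dims)
  if (n > 5e6) stop("truncated state space too large (", n, " states)")
  strides <- cumprod(c(1L, dims[-length(dims)]))
  idx0 <- 0:(n - 1)
  digits <- matrix(0L, n, length(dims))
  for (k in seq_along(dims))
    digits[, k] <- (idx0 %/% strides[k]) %% dims[k]
  counts <- matrix(0, n, ns, dimnames = list(NULL, rs$species))
  for (q in seq_along(rs$pairs)) {
    pr <- rs$pairs[[q]]
    counts[, pr[1]] <- 1 - digits[, q]
    counts[, pr[2]] <- digits[, q]
  }
  for (k in seq_along(count_sp))
    counts[, count_sp[k]] <- digits[, length(rs$pairs) + k]
  list(rs = rs, dims = dims, strides = strides, n = n,
       digits = digits, counts = counts,
       pair_digit = seq_along(rs$pairs), count_sp = count_sp)
}

# digit-space jump vector of a reaction (NULL if it leaves the digits fixed)
reaction_digit_delta <- function(space, stoich) {
  rs <- space$rs
  delta <- integer(length(space$dims))
  for (q in seq_along(rs$pairs)) {
    pr <- rs$pairs[[q]]
    if (stoich[pr[1]] != -stoich[pr[2]])
      stop("switch pair stoichiometry must be conservative")
    delta[q] <- stoich[pr[2]]
  }
  for (k in seq_along(space$count_sp))
    delta[length(rs$pairs) + k] <- stoich[space$count_sp[k]]
  delta
}

#' Build the truncated CME generator
#'
#' @param rs a \code{\link{reaction_system}}.
#' @param caps named count caps (see \code{\link{cme_space}}).
#' @param burst_tol geometric burst jumps are truncated where the remaining
#'   tail probability falls below this value.
#' @return list with the sparse generator \code{Q} (\code{dgCMatrix},
#'   \code{dp/dt = Q p}) and the \code{space} description.
#' @export
cme_generator <- function(rs, caps, burst_tol = 1e-12) {
  space <- cme_space(rs, caps)
  n <- space$n
  a <- propensities(rs, space$counts)
  ii <- jj <- xx <- list()
  slot <- 0
  push <- function(i, j, x) {
    slot <<- slot + 1
    ii[[slot]] <<- i; jj[[slot]] <<- j; xx[[slot]] <<- x
  }
  diag_a <- rowSums(a)
  for (r in seq_along(rs$reactions)) {
    rc <- rs$reactions[[r]]
    ar <- a[, r]
    src <- which(ar > 0)
    if (!length(src)) next
    delta <- reaction_digit_delta(space, rc$stoich)
    jumps <- if (!is.na(rc$burst)) {
      bdig <- length(rs$pairs) + which(space$count_sp == rc$burst)
      p <- rc$p
      kmax <- max(1L, ceiling(log(burst_tol) / log(max(p, 1e-16))))
      kmax <- min(kmax, space$dims[bdig] - 1L)
      lapply(0:kmax, function(k) {
        d2 <- delta; d2[bdig] <- d2[bdig] + k
        list(delta = d2, w = p^k * (1 - p))
      })
    } else list(list(delta = delta, w = 1))
    for (jmp in jumps) {
      d <- jmp$delta
      if (all(d == 0)) { push(src, src, ar[src] * jmp$w); next }
      tgt_dig <- space$digits[src, , drop = FALSE]
      ok <- rep(TRUE, length(src))
      for (k in which(d != 0)) {
        v <- tgt_dig[, k] + d[k]
        ok <- ok & v >= 0 & v <= space$dims[k] - 1L
        tgt_dig[, k] <- v
      }
      if (!any(ok)) next
      s2 <- src[ok]
      tj <- 1 + as.vector((tgt_dig[ok, , drop = FALSE] %*% space$strides))
      push(tj, s2, ar[s2] * jmp$w)
    }
  }
  push(seq_len(n), seq_len(n), -diag_a)
  Q <- Matrix::sparseMatrix(i = unlist(ii[seq_len(slot)]),
                            j = unlist(jj[seq_len(slot)]),
                            x = unlist(xx[seq_len(slot)]),
                            dims = c(n, n))
  list(Q = Q, space = space)
}

# marginal distribution of one species from a joint probability vector
cme_marginal <- function(space, p, species) {
  k <- match(species, space$rs$species)
  if (is.na(k)) stop("unknown species: ", species)
  nvals <- space$counts[, k]
  as.vector(rowsum(p, group = nvals)[as.character(0:max(nvals)), , drop = TRUE])
}

# E[ prod_k (n_k)_{m_k} * 1{pattern} ] functionals evaluated on a joint
# probability vector; `orders` named, `pattern` named 0/1 over pair species.
cme_expect <- function(space, p, orders = NULL, pattern = NULL) {
  w <- rep(1, space$n)
  if (!is.null(orders))
    for (nm in names(orders))
      w <- w * ff(space$counts[, nm], orders[[nm]])
  if (!is.null(pattern))
    for (nm in names(pattern))
      w <- w * (space$counts[, nm] == pattern[[nm]])
  sum(w * p)
}
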