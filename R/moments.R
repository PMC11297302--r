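# Conditional factorial-moment calculus.
#
# For a network of M two-state genes define, for every joint gene-state
# vector s in {0,1}^M and every protein multi-order m,
#     mu_{m,s} = E[ prod_j (n_j)_{m_j} ; S = s ],
# the factorial moment of protein numbers restricted to joint state s
# (mu_{0,s} = g_s is the state probability).  Every reaction channel
# contributes linearly to d/dt mu_{m,s}; the contributions follow from two
# falling-factorial identities:
#     (n)_a (n)_q     = sum_t C(a,t) C(q,t) t! (n)_{a+q-t}
#     (n+delta)_m     = sum_t C(m,t) (delta)_t (n)_{m-t}      (Vandermonde)
# with (delta)_t replaced by the burst-size factorial moments E[(k)_t] for
# geometric-burst synthesis.  The resulting system is linear in the moments;
# for networks whose propensities are all first order it closes at every
# order, while cooperative binding couples order m to order m + h.

mi_key <- function(s, m) paste(s, paste(m, collapse = "."), sep = "|")

# all multi-indices m over M species with total order <= K
multi_orders <- function(M, K) {
  grid <- do.call(expand.grid, rep(list(0:K), M))
  grid <- as.matrix(grid[rowSums(grid) <= K, , drop = FALSE])
  dimnames(grid) <- NULL
  grid[order(rowSums(grid), apply(grid, 1, paste, collapse = ".")), ,
       drop = FALSE]
}

# index table over (joint gene state, protein multi-order)
moment_index <- function(M, K) {
  mm <- multi_orders(M, K)
  s <- rep(0:(2^M - 1), each = nrow(mm))
  m <- mm[rep(seq_len(nrow(mm)), times = 2^M), , drop = FALSE]
  ord <- order(rowSums(m), s)
  s <- s[ord]; m <- m[ord, , drop = FALSE]
  keys <- vapply(seq_along(s), function(i) mi_key(s[i], m[i, ]), "")
  list(s = s, m = m, keys = keys, pos = stats::setNames(seq_along(keys), keys),
       M = M, K = K)
}

# elementary reaction channels of a gene network, in moment-calculus form
moment_channels <- function(network) {
  M <- network$M
  ch <- list()
  add <- function(c, a = integer(M), req = NULL, flip = 0L,
                  delta = numeric(M), burst = 0L, p = 0) {
    if (c > 0)
      ch[[length(ch) + 1L]] <<- list(c = c, a = a, req = req, flip = flip,
                                     delta = delta, burst = burst, p = p)
  }
  e <- function(j, v) { x <- numeric(M); x[j] <- v; x }
  for (j in seq_len(M)) {
    g <- network$genes[j, ]
    add(g$alpha0, req = c(j, 0), flip = j)
    add(g$alpha1, req = c(j, 1), flip = j)
    add(g$rho0, req = c(j, 0), burst = j, p = g$p)
    add(g$rho1, req = c(j, 1), burst = j, p = g$p)
    add(g$d, a = e(j, 1), delta = e(j, -1))
  }
  ed <- network$edges
  for (k in seq_len(nrow(ed))) {
    i <- ed$from[k]; j <- ed$to[k]; h <- ed$h[k]
    if (ed$type[k] %in% c("bind", "act"))
      add(ed$rate[k], a = e(i, h), req = c(j, 0), flip = j, delta = e(i, -h))
    if (ed$type[k] == "bind")
      add(ed$unbind[k], req = c(j, 1), flip = j, delta = e(i, h))
    if (ed$type[k] == "rep")
      add(ed$rate[k], a = e(i, h), req = c(j, 1), flip = j, delta = e(i, -h))
  }
  ch
}

# coefficients of (n)_a (n)_q in the falling-factorial basis
ffprod_coef <- function(a, q) {
  out <- numeric(a + q + 1)
  for (t in 0:min(a, q))
    out[a + q - t + 1] <- out[a + q - t + 1] +
      choose(a, t) * choose(q, t) * factorial(t)
  out
}

# coefficients of (n)_a E[(n + jump)_q] where jump is a fixed integer delta
# or a burst with factorial moments bfm[t+1] = E[(k)_t]
ffjump_coef <- function(a, q, delta = 0, bfm = NULL) {
  out <- numeric(a + q + 1)
  for (t in 0:q) {
    w <- if (!is.null(bfm)) bfm[t + 1] else prod(delta - seq_len(t) + 1)
    if (w == 0) next
    base <- ffprod_coef(a, q - t)
    out[seq_along(base)] <- out[seq_along(base)] + choose(q, t) * w * base
  }
  out
}

bit <- function(s, j) bitwAnd(bitwShiftR(s, j - 1L), 1L)

# contribution of one channel to d/dt mu_{m,s}: a list of (key, coef) terms
channel_terms <- function(ch, m, s, M, K) {
  terms <- list()
  emit <- function(sgn, s_at) {
    # multi-species expansion of (n)_a times the jumped falling factorials
    polys <- vector("list", M)
    for (k in seq_len(M)) {
      if (sgn < 0) {
        polys[[k]] <- ffprod_coef(ch$a[k], m[k])
      } else {
        bfm <- if (ch$burst == k) burst_factorial_moments(ch$p, m[k]) else NULL
        polys[[k]] <- ffjump_coef(ch$a[k], m[k],
                                  delta = ch$delta[k], bfm = bfm)
      }
    }
    combos <- list(list(m = integer(0), c = 1))
    for (k in seq_len(M)) {
      pk <- polys[[k]]
      nz <- which(pk != 0)
      combos <- unlist(lapply(combos, function(cb) {
        lapply(nz, function(r)
          list(m = c(cb$m, r - 1L), c = cb$c * pk[r]))
      }), recursive = FALSE)
    }
    for (cb in combos)
      terms[[length(terms) + 1L]] <<- list(key = mi_key(s_at, cb$m),
                                           coef = sgn * ch$c * cb$c,
                                           order = sum(cb$m))
  }
  req_ok <- function(sv) is.null(ch$req) || bit(sv, ch$req[1]) == ch$req[2]
  if (ch$flip > 0L) {
    s_pre <- bitwXor(s, bitwShiftL(1L, ch$flip - 1L))
    if (req_ok(s_pre)) emit(+1, s_pre)   # arrival from the flipped state
    if (req_ok(s)) emit(-1, s)           # departure
  } else {
    if (req_ok(s)) { emit(+1, s); emit(-1, s) }
  }
  terms
}

#' Conditional moment equations of a gene network
#'
#' Generates the time-evolution equations of the gene-state probabilities
#' and conditional factorial moments of protein numbers (conditioned on the
#' joint gene-state vector), up to total protein order \code{K}, directly
#' from the chemical master equation. The right-hand side is linear in the
#' moments; entries referencing moments of order above \code{K} are kept in
#' separate closure columns and flag the system as unclosed.
#'
#' @param network a \code{\link{gene_network}}.
#' @param K total moment order cap. The moment-matching construction
#'   requires \code{K >= h + 1} for the largest cooperativity \code{h};
#'   pass \code{check = FALSE} to build lower-order systems (as used by the
#'   conditional-mean linear-mapping approximation).
#' @param check enforce the \code{K >= h_max + 1} requirement.
#' @return an object of class \code{moment_system}: index tables, the
#'   sparse right-hand-side matrix \code{A} (\code{d mu/dt = A [mu; mu_closure]}),
#'   and closure information. The attribute \code{L} counts the independent
#'   equations (the joint-state normalization removes one).
#' @export
derive_moment_system <- function(network, K, check = TRUE) {
  stopifnot(inherits(network, "gene_network"))
  h_max <- if (nrow(network$edges)) max(network$edges$h) else 0L
  if (check && K < h_max + 1)
    stop(sprintf("K = %d too small: moment matching requires K >= h + 1 = %d",
                 K, h_max + 1))
  if (network$M > 12)
    stop("joint conditional moments scale exponentially in the number of ",
         "genes; networks with M > 12 should use the hybrid method")
  idx <- moment_index(network$M, K)
  channels <- moment_channels(network)
  L <- length(idx$keys)
  closure <- character(0)
  ii <- jj <- integer(0); xx <- numeric(0)
  acc_i <- list(); acc_j <- list(); acc_x <- list(); na <- 0
  for (row in seq_len(L)) {
    m <- idx$m[row, ]; s <- idx$s[row]
    for (ch in channels) {
      for (tm in channel_terms(ch, m, s, network$M, K)) {
        if (tm$coef == 0) next
        col <- idx$pos[tm$key]
        if (is.na(col)) {
          pos_c <- match(tm$key, closure)
          if (is.na(pos_c)) { closure <- c(closure, tm$key); pos_c <- length(closure) }
          col <- L + pos_c
        }
        na <- na + 1
        acc_i[[na]] <- row; acc_j[[na]] <- col; acc_x[[na]] <- tm$coef
      }
    }
  }
  A <- Matrix::sparseMatrix(i = c(unlist(acc_i), integer(0)),
                            j = c(unlist(acc_j), integer(0)),
                            x = c(unlist(acc_x), numeric(0)),
                            dims = c(L, L + length(closure)))
  A <- Matrix::drop0(A)
  # arrival/departure contributions above order K may cancel exactly (e.g.
  # first-order decay); keep only closure moments actually referenced
  if (length(closure)) {
    used <- which(Matrix::colSums(A[, L + seq_along(closure), drop = FALSE] != 0) > 0)
    A <- A[, c(seq_len(L), L + used), drop = FALSE]
    closure <- closure[used]
  }
  structure(list(network = network, K = K, idx = idx, A = A,
                 closure_keys = closure, closed = length(closure) == 0),
            class = "moment_system", L = L - 1L)
}

#' @export
print.moment_system <- function(x, ...) {
  cat(sprintf(
    "Conditional moment system: %d equations (order cap K = %d), %s\n",
    length(x$idx$keys), x$K,
    if (x$closed) "closed" else
      sprintf("unclosed (%d higher-order moments referenced)",
              length(x$closure_keys))))
  invisible(x)
}

# position of moment (s, m) in the state vector of a moment system
moment_pos <- function(ms, s, m) {
  p <- ms$idx$pos[mi_key(s, m)]
  if (is.na(p)) stop("moment not tracked: s = ", s, ", m = ",
                     paste(m, collapse = ","))
  unname(p)
}

# default initial condition: all genes inactive, no protein
init_moments <- function(ms) {
  y <- numeric(length(ms$idx$keys))
  y[moment_pos(ms, 0L, integer(ms$network$M))] <- 1
  y
}

#' Integrate a closed moment system
#'
#' @param ms a closed \code{\link{derive_moment_system}} result.
#' @param init initial moment vector (defaults to all genes inactive, zero
#'   protein).
#' @param t_grid increasing vector of output times.
#' @param rtol,atol integrator tolerances (stiff-capable \code{lsoda}).
#' @return matrix of moment trajectories, one row per time (first column
#'   \code{time}), with the moment system attached as an attribute.
#' @export
integrate_moments <- function(ms, init = NULL, t_grid, rtol = 1e-8,
                              atol = 1e-10) {
  stopifnot(inherits(ms, "moment_system"))
  if (!ms$closed)
    stop("moment system is not closed (references order > K); ",
         "use a mapping method to close it")
  if (is.null(init)) init <- init_moments(ms)
  A <- ms$A
  out <- deSolve::ode(y = init, times = t_grid,
                      func = function(t, y, parms) list(as.vector(A %*% y)),
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (anyNA(out))
    stop("moment integration failed (NaN) near t = ",
         max(out[stats::complete.cases(out), "time"]))
  attr(out, "moment_system") <- ms
  out
}

#' Steady state of a closed moment system
#'
#' Integrates to \code{t = 50/min(d)} and accepts the end point when the
#' right-hand-side infinity norm falls below \code{tol}, doubling the
#' horizon (up to \code{max_doublings}) otherwise.
#'
#' @param ms a closed \code{\link{derive_moment_system}} result.
#' @param init optional initial moment vector.
#' @param tol residual tolerance on the right-hand side.
#' @param max_doublings horizon doublings before giving up.
#' @return steady moment vector with attribute \code{residual}.
#' @export
steady_state_moments <- function(ms, init = NULL, tol = 1e-8,
                                 max_doublings = 8) {
  if (is.null(init)) init <- init_moments(ms)
  t_end <- 50 / min(ms$network$genes$d)
  y <- init
  for (k in 0:max_doublings) {
    out <- integrate_moments(ms, y, c(0, t_end))
    y <- out[nrow(out), -1]
    res <- max(abs(ms$A %*% y))
    if (res < tol) {
      attr(y, "residual") <- res
      return(y)
    }
  }
  stop("steady state not reached: residual ", format(res))
}

#' Check generated moment equations against a brute-force CME generator
#'
#' Builds the truncated master-equation generator of the compiled reaction
#' system and verifies, on random probability vectors supported away from
#' the truncation boundary, that the generated moment right-hand sides
#' agree with the moments of \eqn{Q p}.
#'
#' @param ms a \code{\link{derive_moment_system}} result.
#' @param rs the matching compiled \code{\link{reaction_system}}.
#' @param n_max protein count cap of the brute-force generator.
#' @param n_vectors number of random probability vectors.
#' @param seed RNG seed for the random vectors.
#' @return maximum absolute deviation over all equations and vectors.
#' @export
rhs_oracle_check <- function(ms, rs, n_max = 200, n_vectors = 5, seed = 1) {
  network <- ms$network
  M <- network$M
  prot <- paste0("P", 1:M)
  gen <- cme_generator(rs, stats::setNames(rep(n_max, M), prot),
                       burst_tol = 1e-15)
  space <- gen$space
  interior <- rowSums(space$counts[, prot, drop = FALSE] > n_max / 2) == 0
  all_keys <- c(ms$idx$keys, ms$closure_keys)
  parse_key <- function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    list(s = as.integer(parts[1]),
         m = as.integer(strsplit(parts[2], ".", fixed = TRUE)[[1]]))
  }
  km <- lapply(all_keys, parse_key)
  moments_of <- function(p) {
    vapply(km, function(e) {
      pat <- as.list(vapply(1:M, function(j) bit(e$s, j), 0L))
      names(pat) <- paste0("G", 1:M, "*")
      ords <- as.list(e$m); names(ords) <- prot
      cme_expect(space, p, orders = ords[e$m > 0], pattern = pat)
    }, 0)
  }
  worst <- 0
  set.seed(seed)
  for (v in seq_len(n_vectors)) {
    p <- numeric(space$n)
    p[interior] <- stats::runif(sum(interior))
    p <- p / sum(p)
    y <- moments_of(p)
    lhs <- as.vector(ms$A %*% y)
    rhs <- moments_of(as.vector(gen$Q %*% p))[seq_len(length(ms$idx$keys))]
    worst <- max(worst, max(abs(lhs - rhs)))
  }
  worst
}
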