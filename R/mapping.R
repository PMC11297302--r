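# Conditional moment-matching: the mapping from a nonlinear gene network to
# an effective linear one.
#
# For every regulated gene the nonlinear gene-state switching reactions are
# replaced by first-order switches G <-> G* whose rates are fixed by
# requiring selected moment equations of the two networks to coincide:
#   LMA : one rate (switch-on), the conditional-mean approximation
#   2-HM: two rates, matching d/dt g_0 and d/dt mu_{1,1}
#   4-HM: four rates (switching + synthesis), additionally matching the
#         summed first- and second-order moment equations
# Because the synthesis/decay channels of the two networks are represented
# by identical linear operators, full-right-hand-side matching reduces
# algebraically to the classical matching relations; the implementation
# matches full right-hand sides, which generalizes uniformly to multiple
# genes, multiple regulators and cooperativities h >= 2.

#' Conditional moment state
#'
#' Container for gene-state probabilities \code{g_s} and conditional
#' factorial moments \code{mu_{m,s}} of a network with \code{M} genes,
#' indexed by joint gene state \code{s} (bit \code{j} = state of gene
#' \code{j}) and protein multi-order \code{m}. Unspecified entries are zero.
#'
#' @param network a \code{\link{gene_network}} (or gene count \code{M}).
#' @param K total moment order cap.
#' @param values optional named vector; names are \code{"s|m1.m2..."} keys
#'   as produced by the moment indexing (see examples in the tests).
#' @return an object of class \code{moment_state}.
#' @export
moment_state <- function(network, K, values = NULL) {
  M <- if (inherits(network, "gene_network")) network$M else as.integer(network)
  idx <- moment_index(M, K)
  y <- numeric(length(idx$keys))
  if (!is.null(values)) {
    pos <- idx$pos[names(values)]
    if (anyNA(pos)) stop("unknown moment keys: ",
                         paste(names(values)[is.na(pos)], collapse = ", "))
    y[pos] <- values
  }
  structure(list(M = M, K = K, idx = idx, y = y), class = "moment_state")
}

#' Set or read one entry of a moment state
#' @param st a \code{\link{moment_state}}.
#' @param s joint gene state (integer, bit \code{j} = gene \code{j}).
#' @param m protein multi-order (vector of length M).
#' @param value if supplied, the entry is set and the state returned.
#' @export
moment_entry <- function(st, s, m, value = NULL) {
  p <- st$idx$pos[mi_key(s, m)]
  if (is.na(p)) stop("moment outside the tracked set")
  if (is.null(value)) return(st$y[p])
  st$y[p] <- value
  st
}

# positions of (m, s) combinations in a moment index
idx_positions <- function(idx, m_target, j = NULL, bitval = NULL) {
  hit <- apply(idx$m, 1, function(r) all(r == m_target))
  if (!is.null(j)) hit <- hit & (bit(idx$s, j) == bitval)
  which(hit)
}

unit_m <- function(M, j, v = 1L) { m <- integer(M); m[j] <- v; m }

# sparse row: w' A restricted to the tracked columns, asserting that the
# functional does not touch closure moments
functional_row <- function(A, w_pos, L, label) {
  r <- Matrix::colSums(A[w_pos, , drop = FALSE])
  if (length(r) > L) {
    tailmax <- max(abs(r[(L + 1):length(r)]))
    scale <- max(abs(r), 1)
    if (tailmax > 1e-9 * scale)
      stop("internal error: matching functional '", label,
           "' references closure moments")
    r <- r[seq_len(L)]
  }
  r
}

# component gene tables with a single nonzero rate
blank_genes <- function(network) {
  g <- network$genes
  g$alpha0 <- 0; g$alpha1 <- 0; g$rho0 <- 0; g$rho1 <- 0; g$d <- 0
  g
}

#' Holimap closure operator
#'
#' Precomputes everything needed to close the moment equations of a
#' network by moment-matching: the nonlinear moment system, the component
#' operators of the mapped linear network (one per effective rate), and the
#' matching functionals. Used internally by \code{\link{holimap}} and by
#' the parameter extractors \code{\link{lma_params}},
#' \code{\link{hm2_params}} and \code{\link{hm4_params}}.
#'
#' @param network a \code{\link{gene_network}}.
#' @param method \code{"lma"}, \code{"hm2"} or \code{"hm4"}.
#' @return an object of class \code{holimap_closure}.
#' @export
holimap_closure <- function(network, method = c("hm2", "hm4", "lma")) {
  method <- match.arg(method)
  M <- network$M
  h_max <- if (nrow(network$edges)) max(network$edges$h) else 1L
  K <- if (method == "lma") max(h_max, 1L) else max(h_max + 1L, 2L)
  ms_nl <- derive_moment_system(network, K, check = FALSE)
  L <- length(ms_nl$idx$keys)
  idx <- ms_nl$idx

  L_probe <- length(ms_nl$idx$keys)
  densify <- function(A) if (L_probe <= 400) as.matrix(A) else A
  sub_system <- function(genes) {
    densify(derive_moment_system(gene_network(genes, NULL), K, check = FALSE)$A)
  }
  fix_genes <- network$genes
  fix_genes$alpha0 <- 0; fix_genes$alpha1 <- 0
  if (method == "hm4") { fix_genes$rho0 <- 0; fix_genes$rho1 <- 0 }
  A_fix <- sub_system(fix_genes)
  A_on <- A_off <- A_r0 <- A_r1 <- vector("list", M)
  for (j in 1:M) {
    g <- blank_genes(network); g$alpha0[j] <- 1
    A_on[[j]] <- sub_system(g)
    g <- blank_genes(network); g$alpha1[j] <- 1
    A_off[[j]] <- sub_system(g)
    if (method == "hm4") {
      g <- blank_genes(network); g$rho0[j] <- 1; g$p[j] <- network$genes$p[j]
      A_r0[[j]] <- sub_system(g)
      g <- blank_genes(network); g$rho1[j] <- 1; g$p[j] <- network$genes$p[j]
      A_r1[[j]] <- sub_system(g)
    }
  }

  # matching functionals per gene j: d/dt of the unbound-state probability
  # g^(j)_0 and of the gene's own bound-state protein mean E[n_j ; s_j = 1]
  # (for autoregulation the protein is simultaneously the regulator, which
  # recovers the single-gene construction exactly); the 4-HM additionally
  # matches E[n_j] and E[(n_j)_2].  Conditioning the *regulator* on the
  # target state instead degenerates: the mapped linear network decouples
  # the genes, so those cross moments factorize and the matching matrix
  # becomes singular.
  regs <- lapply(1:M, function(j) {
    r <- unique(network$edges$from[network$edges$to == j])
    if (length(r)) sort(r) else j
  })
  w_g0 <- lapply(1:M, function(j) idx_positions(idx, integer(M), j, 0L))
  w_g1 <- lapply(1:M, function(j) idx_positions(idx, integer(M), j, 1L))
  w_m11 <- lapply(1:M, function(j) idx_positions(idx, unit_m(M, j), j, 1L))
  w_m1 <- lapply(1:M, function(j) idx_positions(idx, unit_m(M, j)))
  w_m2 <- lapply(1:M, function(j) idx_positions(idx, unit_m(M, j, 2L)))
  rows <- vector("list", M)
  for (j in if (method == "lma") integer(0) else 1:M) {
    mk <- function(A, w, lab) functional_row(A, w, L, lab)
    rows[[j]] <- list(
      nl_g0 = mk(ms_nl$A, w_g0[[j]], "g0"),
      nl_1b = mk(ms_nl$A, w_m11[[j]], "mu11"),
      fix_g0 = mk(A_fix, w_g0[[j]], "g0/fix"),
      fix_1b = mk(A_fix, w_m11[[j]], "mu11/fix"),
      on_g0 = mk(A_on[[j]], w_g0[[j]], "g0/on"),
      on_1b = mk(A_on[[j]], w_m11[[j]], "mu11/on"),
      off_g0 = mk(A_off[[j]], w_g0[[j]], "g0/off"),
      off_1b = mk(A_off[[j]], w_m11[[j]], "mu11/off"))
    if (method == "hm4")
      rows[[j]] <- c(rows[[j]], list(
        nl_m1 = mk(ms_nl$A, w_m1[[j]], "m1"),
        nl_m2 = mk(ms_nl$A, w_m2[[j]], "m2"),
        fix_m1 = mk(A_fix, w_m1[[j]], "m1/fix"),
        fix_m2 = mk(A_fix, w_m2[[j]], "m2/fix"),
        r0_m1 = mk(A_r0[[j]], w_m1[[j]], "m1/r0"),
        r0_m2 = mk(A_r0[[j]], w_m2[[j]], "m2/r0"),
        r1_m1 = mk(A_r1[[j]], w_m1[[j]], "m1/r1"),
        r1_m2 = mk(A_r1[[j]], w_m2[[j]], "m2/r1"),
        r0_g0 = mk(A_r0[[j]], w_g0[[j]], "g0/r0"),
        r0_1b = mk(A_r0[[j]], w_m11[[j]], "mu11/r0"),
        r1_g0 = mk(A_r1[[j]], w_g0[[j]], "g0/r1"),
        r1_1b = mk(A_r1[[j]], w_m11[[j]], "mu11/r1")))
  }

  # directional switching fluxes for the conditional-mean (LMA) rates
  flux_rows <- lapply(1:M, function(j) {
    on <- off <- numeric(L)
    on[w_g0[[j]]] <- on[w_g0[[j]]] + network$genes$alpha0[j]
    off[w_g1[[j]]] <- off[w_g1[[j]]] + network$genes$alpha1[j]
    ed <- network$edges
    for (k in seq_len(nrow(ed))) {
      if (ed$to[k] != j) next
      hk <- ed$h[k]; ik <- ed$from[k]
      if (ed$type[k] %in% c("bind", "act")) {
        pos <- idx_positions(idx, unit_m(M, ik, hk), j, 0L)
        on[pos] <- on[pos] + ed$rate[k]
      }
      if (ed$type[k] == "bind")
        off[w_g1[[j]]] <- off[w_g1[[j]]] + ed$unbind[k]
      if (ed$type[k] == "rep") {
        pos <- idx_positions(idx, unit_m(M, ik, hk), j, 1L)
        off[pos] <- off[pos] + ed$rate[k]
      }
    }
    list(on = on, off = off, g0 = w_g0[[j]], g1 = w_g1[[j]])
  })

  scale_rates <- c(network$genes$alpha0, network$genes$alpha1,
                   network$genes$d, network$edges$unbind,
                   network$edges$rate * rate_equation_scales(network)[
                     network$edges$from]^network$edges$h)
  structure(list(network = network, method = method, K = K, idx = idx,
                 ms_nl = ms_nl, L = L,
                 A_fix = A_fix, A_on = A_on, A_off = A_off,
                 A_r0 = A_r0, A_r1 = A_r1,
                 rows = rows, flux_rows = flux_rows, regulators = regs,
                 rate_cap = 1e3 * max(scale_rates, 1)),
            class = "holimap_closure")
}

# conditional-mean (LMA) rates by directional flux matching; safe at
# degenerate states (vanishing state probability -> spontaneous rate only)
lma_rates <- function(cl, y, j, strict = FALSE) {
  fr <- cl$flux_rows[[j]]
  g0 <- sum(y[fr$g0]); g1 <- sum(y[fr$g1])
  if (strict && g0 <= 1e-12)
    stop("unbound-state probability vanishes for gene ", j)
  s_on <- if (g0 > 1e-12) sum(fr$on * y) / g0 else cl$network$genes$alpha0[j]
  s_off <- if (g1 > 1e-12) sum(fr$off * y) / g1 else {
    ed <- cl$network$edges
    cl$network$genes$alpha1[j] +
      sum(ed$unbind[ed$to == j & ed$type == "bind"])
  }
  c(s_on = max(s_on, 0), s_off = max(s_off, 0))
}

# ridge-regularized 2x2 solve: indistinguishable from the exact solution
# for well-conditioned matching systems, but continuous and bounded as the
# system degenerates (a hard fallback would put jumps into the closure ODE)
solve2_ridge <- function(a11, a12, a21, a22, b1, b2) {
  s <- max(abs(c(a11, a12, a21, a22)))
  if (s == 0) return(NULL)
  lam <- (1e-9 * s)^2
  m11 <- a11 * a11 + a21 * a21 + lam
  m12 <- a11 * a12 + a21 * a22
  m22 <- a12 * a12 + a22 * a22 + lam
  r1 <- a11 * b1 + a21 * b2
  r2 <- a12 * b1 + a22 * b2
  dt <- m11 * m22 - m12 * m12
  if (dt <= 0) return(NULL)
  c((m22 * r1 - m12 * r2) / dt, (m11 * r2 - m12 * r1) / dt)
}

# solve the per-gene matching equations; returns an M x 6 matrix with
# columns s_on, s_off, rho0, rho1, d, p (hot path: no data frames)
match_core <- function(cl, y, negative = "error",
                       note = function(...) NULL) {
  net <- cl$network
  M <- net$M
  out <- cbind(s_on = rep(NA_real_, M), s_off = NA_real_,
               rho0 = net$genes$rho0, rho1 = net$genes$rho1,
               d = net$genes$d, p = net$genes$p)
  for (j in 1:M) {
    r <- cl$rows[[j]]
    if (cl$method == "lma") {
      sr <- lma_rates(cl, y, j)
      out[j, 1:2] <- sr
      next
    }
    fr <- cl$flux_rows[[j]]
    if (min(sum(y[fr$g0]), sum(y[fr$g1])) < 1e-4) {
      # one gene state is essentially unpopulated: the matching system
      # carries no information there; use the conditional-mean rates
      out[j, 1:2] <- lma_rates(cl, y, j)
      next
    }
    rhs_g0 <- sum(r$nl_g0 * y) - sum(r$fix_g0 * y)
    rhs_1b <- sum(r$nl_1b * y) - sum(r$fix_1b * y)
    if (cl$method == "hm4") {
      rho <- solve2_ridge(sum(r$r0_m1 * y), sum(r$r1_m1 * y),
                          sum(r$r0_m2 * y), sum(r$r1_m2 * y),
                          sum(r$nl_m1 * y) - sum(r$fix_m1 * y),
                          sum(r$nl_m2 * y) - sum(r$fix_m2 * y))
      if (is.null(rho) || max(abs(rho)) > cl$rate_cap) {
        rho <- c(net$genes$rho0[j], net$genes$rho1[j])
        note("singular synthesis matching for gene ", j,
             "; keeping original synthesis rates")
      }
      out[j, 3:4] <- rho
      rhs_g0 <- rhs_g0 - rho[1] * sum(r$r0_g0 * y) - rho[2] * sum(r$r1_g0 * y)
      rhs_1b <- rhs_1b - rho[1] * sum(r$r0_1b * y) - rho[2] * sum(r$r1_1b * y)
    }
    sw <- solve2_ridge(sum(r$on_g0 * y), sum(r$off_g0 * y),
                       sum(r$on_1b * y), sum(r$off_1b * y),
                       rhs_g0, rhs_1b)
    # a negative switching rate is a matching breakdown: clamping it at
    # zero would freeze the linear gene in one state and lock the closure
    # onto a spurious branch, so fall back to the conditional-mean rates
    if (!is.null(sw) && max(abs(sw)) <= cl$rate_cap &&
        min(sw) > -1e-8 * max(abs(sw), 1)) {
      out[j, 1] <- max(sw[1], 0); out[j, 2] <- max(sw[2], 0)
    } else {
      out[j, 1:2] <- lma_rates(cl, y, j)
      note("singular or negative switching matching for gene ", j,
           "; falling back to conditional-mean rates")
    }
  }
  # roundoff-level negatives are zeroed silently; larger ones follow policy
  for (cix in 1:4) {
    v <- out[, cix]
    v[v < 0 & v > -1e-8 * max(abs(v), 1)] <- 0
    if (any(v < 0)) {
      if (negative == "error")
        stop("moment matching produced a negative effective rate (",
             colnames(out)[cix], " = ", format(min(v)),
             "); rerun with negative = 'clamp' to truncate at zero")
      note("negative effective ", colnames(out)[cix], " clamped to zero")
      v <- pmax(v, 0)
    }
    out[, cix] <- v
  }
  out
}

match_params <- function(cl, y, negative = c("error", "clamp"),
                         note = function(...) NULL) {
  negative <- match.arg(negative)
  m <- match_core(cl, y, negative = negative, note = note)
  cbind(data.frame(gene = seq_len(nrow(m))), as.data.frame(m))
}

# right-hand side of the closed (matched) moment system
closure_rhs <- function(cl, y, negative = "clamp", note = function(...) NULL) {
  par <- match_core(cl, y, negative = negative, note = note)
  dy <- cl$A_fix %*% y
  for (j in seq_len(cl$network$M)) {
    dy <- dy + par[j, 1] * (cl$A_on[[j]] %*% y) +
      par[j, 2] * (cl$A_off[[j]] %*% y)
    if (cl$method == "hm4")
      dy <- dy + par[j, 3] * (cl$A_r0[[j]] %*% y) +
        par[j, 4] * (cl$A_r1[[j]] %*% y)
  }
  list(dy = as.vector(dy), par = par)
}

#' Effective parameters of the linear-mapping approximation
#'
#' The switch-on rate of each regulated gene is the binding rate times the
#' conditional \eqn{h}-th falling-factorial mean of the regulator in the
#' target's unbound state (plus any spontaneous switching); the switch-off
#' rate is matched analogously for repressive channels.
#'
#' @param moments a \code{\link{moment_state}}.
#' @param network a \code{\link{gene_network}}.
#' @return data frame of per-gene effective telegraph parameters.
#' @export
lma_params <- function(moments, network) {
  cl <- holimap_closure(network, "lma")
  y <- project_state(moments, cl)
  out <- match_params(cl, y)
  for (j in seq_len(network$M)) lma_rates(cl, y, j, strict = TRUE)
  out
}

#' Effective parameters of the two-parameter Holimap
#'
#' Solves, per regulated gene, the 2x2 linear system equating the
#' zeroth-order and bound-state first-order conditional moment equations of
#' the nonlinear and mapped linear networks.
#'
#' @inheritParams lma_params
#' @param negative policy for negative solutions (\code{"error"} or
#'   \code{"clamp"}).
#' @return data frame of per-gene effective telegraph parameters.
#' @export
hm2_params <- function(moments, network, negative = "error") {
  cl <- holimap_closure(network, "hm2")
  notes <- character(0)
  note <- function(...) notes <<- c(notes, paste0(...))
  out <- match_params(cl, project_state(moments, cl), negative = negative,
                      note = note)
  attr(out, "notes") <- notes
  out
}

#' Effective parameters of the four-parameter Holimap
#'
#' As \code{\link{hm2_params}}, but additionally replaces the two synthesis
#' rates, fixed by matching the summed first- and second-order moment
#' equations; the switching match then carries the synthesis correction
#' term.
#'
#' @inheritParams hm2_params
#' @return data frame of per-gene effective telegraph parameters.
#' @export
hm4_params <- function(moments, network, negative = "error") {
  cl <- holimap_closure(network, "hm4")
  notes <- character(0)
  note <- function(...) notes <<- c(notes, paste0(...))
  out <- match_params(cl, project_state(moments, cl), negative = negative,
                      note = note)
  attr(out, "notes") <- notes
  out
}

# interior initial state for steady solves: gene states equidistributed,
# proteins at their mean-field scale with Poisson-like factorial moments;
# keeps the matching systems away from their degenerate corners
init_moments_interior <- function(cl) {
  net <- cl$network
  M <- net$M
  x <- rate_equation_scales(net)
  idx <- cl$idx
  g <- 2^(-M)
  vapply(seq_along(idx$keys), function(i)
    g * prod(x^idx$m[i, ]), 0)
}

# embed a moment_state into the index of a closure (orders above the
# state's cap are zero; orders below must be present)
project_state <- function(moments, cl) {
  stopifnot(inherits(moments, "moment_state"))
  if (moments$M != cl$network$M)
    stop("moment state and network disagree on the number of genes")
  y <- numeric(cl$L)
  pos <- cl$idx$pos[moments$idx$keys]
  ok <- !is.na(pos)
  y[pos[ok]] <- moments$y[ok]
  y
}
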