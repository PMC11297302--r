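#' Gene regulatory network objects
#'
#' A \code{gene_network} describes a transcriptional network of \eqn{M}
#' two-state genes. Gene \eqn{j} switches between an inactive state
#' \eqn{G_j} (state 0) and an active state \eqn{G_j^*} (state 1), produces
#' protein \eqn{P_j} with rate \code{rho0} (state 0) or \code{rho1} (state 1)
#' in geometric bursts with parameter \code{p} (\code{p = 0}: one molecule
#' per event), and the protein decays with rate \code{d}. Spontaneous
#' switching occurs with rates \code{alpha0} (\eqn{G_j \to G_j^*}) and
#' \code{alpha1} (\eqn{G_j^* \to G_j}).
#'
#' Regulation edges come in three kinds, distinguished by the \code{type}
#' column of \code{edges}:
#' \describe{
#'   \item{\code{"bind"}}{reversible cooperative binding
#'     \eqn{G_j + h P_i \rightleftharpoons G_j^*}: binding (rate
#'     \code{rate}, combinatorial propensity \eqn{\sigma_b (n_i)_h})
#'     sequesters \eqn{h} regulator molecules, unbinding (rate
#'     \code{unbind}) releases them. Activation versus repression is
#'     encoded in the synthesis rates of the target gene.}
#'   \item{\code{"act"}}{activation \eqn{G_j + h P_i \to G_j^*} with rate
#'     \code{rate}; the regulator molecules are consumed.}
#'   \item{\code{"rep"}}{repression \eqn{G_j^* + h P_i \to G_j} with rate
#'     \code{rate}; the regulator molecules are consumed.}
#' }
#'
#' @param genes data frame with one row per gene and columns
#'   \code{alpha0, alpha1, rho0, rho1, d, p}.
#' @param edges data frame with columns \code{from} (regulator), \code{to}
#'   (target), \code{h} (cooperativity), \code{type}, \code{rate},
#'   \code{unbind}; may have zero rows.
#' @param allow_inverted allow \code{rho1 <= rho0} for \code{"act"}/\code{"rep"}
#'   edges (by convention the active state is the more productive one).
#' @return an object of class \code{gene_network}.
#' @seealso \code{\link{build_autoreg}}, \code{\link{build_fixture}},
#'   \code{\link{build_random_network}}, \code{\link{compile_reactions}}
#' @export
gene_network <- function(genes, edges = NULL, allow_inverted = TRUE) {
  genes <- as.data.frame(genes)
  need <- c("alpha0", "alpha1", "rho0", "rho1", "d", "p")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("genes is missing columns: ", paste(miss, collapse = ", "))
  genes <- genes[need]
  M <- nrow(genes)
  if (M < 1) stop("network must contain at least one gene")
  for (nm in c("alpha0", "alpha1", "rho0", "rho1", "d")) {
    if (any(genes[[nm]] < 0 | is.na(genes[[nm]])))
      stop(sprintf("gene field '%s' must be non-negative", nm))
  }
  check_prob(genes$p, "p")
  if (is.null(edges)) {
    edges <- data.frame(from = integer(), to = integer(), h = integer(),
                        type = character(), rate = numeric(), unbind = numeric())
  }
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    if (!all(c("from", "to", "h", "type", "rate") %in% names(edges)))
      stop("edges needs columns from, to, h, type, rate")
    if (is.null(edges$unbind)) edges$unbind <- 0
    if (any(edges$from < 1 | edges$from > M | edges$to < 1 | edges$to > M))
      stop("edge references a gene index outside 1..M")
    if (any(edges$h < 1 | edges$h != round(edges$h)))
      stop("'h' (cooperativity) must be a positive integer")
    if (!all(edges$type %in% c("bind", "act", "rep")))
      stop("edge type must be one of 'bind', 'act', 'rep'")
    if (any(edges$rate < 0) || any(edges$unbind < 0))
      stop("edge rates must be non-negative")
    if (any(edges$type != "bind" & edges$unbind > 0))
      stop("only 'bind' edges carry an unbinding rate")
    reg <- unique(edges$to[edges$type %in% c("act", "rep")])
    if (!allow_inverted && length(reg) &&
        any(genes$rho1[reg] <= genes$rho0[reg]))
      stop("rho1 > rho0 expected for regulated genes (active state more productive)")
  }
  structure(list(genes = genes, edges = edges, M = M), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("Gene regulatory network: %d gene(s), %d regulation edge(s)\n",
              x$M, nrow(x$edges)))
  cat("Genes:\n"); print(x$genes)
  if (nrow(x$edges)) { cat("Edges:\n"); print(x$edges) }
  invisible(x)
}

#' Autoregulatory feedback loop
#'
#' One gene whose own protein binds cooperatively to its promoter:
#' \eqn{G + hP \rightleftharpoons G^*} with binding rate \code{sigma_b} and
#' unbinding rate \code{sigma_u}, bursty synthesis with burst frequencies
#' \code{rho_u} (unbound) and \code{rho_b} (bound), degradation \code{d}.
#' Positive feedback when \code{rho_b > rho_u}, negative when
#' \code{rho_b < rho_u}.
#'
#' @param sigma_b,sigma_u binding/unbinding rates.
#' @param rho_b,rho_u burst frequencies in the bound/unbound state.
#' @param d protein decay rate.
#' @param h cooperativity (number of protein copies bound per event).
#' @param p geometric burst parameter; \code{p = 0} for non-bursty synthesis.
#'   Alternatively supply the mean burst size \code{B} (then \code{p = B/(1+B)}).
#' @param B optional mean burst size used instead of \code{p}.
#' @return a \code{\link{gene_network}} with a single gene.
#' @examples
#' net <- build_autoreg(sigma_b = 0.1, sigma_u = 1, rho_b = 50, rho_u = 1,
#'                      d = 1, h = 1, p = 0.5)
#' @export
build_autoreg <- function(sigma_b, sigma_u, rho_b, rho_u, d, h = 1L, p = 0.5,
                          B = NULL) {
  check_rate(sigma_b, "sigma_b"); check_rate(sigma_u, "sigma_u")
  check_rate(rho_b, "rho_b"); check_rate(rho_u, "rho_u"); check_rate(d, "d")
  h <- check_count(h, "h")
  if (!is.null(B)) p <- burst_param(B)
  check_prob(p, "p")
  genes <- data.frame(alpha0 = 0, alpha1 = 0, rho0 = rho_u, rho1 = rho_b,
                      d = d, p = p)
  edges <- if (sigma_b > 0 || sigma_u > 0) {
    data.frame(from = 1L, to = 1L, h = h, type = "bind",
               rate = sigma_b, unbind = sigma_u)
  } else NULL
  gene_network(genes, edges)
}

# shared builder for the 2- and 3-node cyclic motifs (protein P_i binds the
# next gene in the cycle); non-bursty by default
cyclic_motif <- function(rho_u, rho_b, d, sigma_b, sigma_u, h) {
  M <- length(rho_u)
  genes <- data.frame(alpha0 = 0, alpha1 = 0, rho0 = rho_u, rho1 = rho_b,
                      d = d, p = 0)
  edges <- data.frame(from = 1:M, to = c(2:M, 1L), h = h, type = "bind",
                      rate = sigma_b, unbind = sigma_u)
  gene_network(genes, edges)
}

#' Random gene regulatory network
#'
#' Generates a random \code{M}-gene network in which every ordered pair of
#' genes (self-pairs included, so autoregulation is allowed) is independently
#' connected with probability \code{2/M}, giving on average \eqn{2M} directed
#' edges. A present edge is activating or repressing with probability 1/2
#' each. Rates follow the reference parameterization: \code{d = 1},
#' \code{h = 1}, \code{rho1 = 81}, \code{rho0 = 5.4},
#' \code{alpha0 = alpha1 = 0.5}, regulation rate \code{sigma = 0.01}.
#' Generation is a pure function of \code{(M, seed)}.
#'
#' @param M number of genes.
#' @param seed integer seed.
#' @return a \code{\link{gene_network}}.
#' @export
build_random_network <- function(M, seed) {
  M <- check_count(M, "M")
  seed <- check_count(seed, "seed", min = 0L)
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    pairs <- expand.grid(from = 1:M, to = 1:M)
    on <- stats::runif(nrow(pairs)) < 2 / M
    sgn <- stats::runif(nrow(pairs)) < 0.5
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    list(pairs = pairs[on, , drop = FALSE], act = sgn[on])
  })
  genes <- data.frame(alpha0 = 0.5, alpha1 = 0.5, rho0 = 5.4, rho1 = 81,
                      d = 1, p = 0)[rep(1, M), ]
  rownames(genes) <- NULL
  edges <- if (nrow(rng$pairs)) {
    data.frame(from = rng$pairs$from, to = rng$pairs$to, h = 1L,
               type = ifelse(rng$act, "act", "rep"), rate = 0.01, unbind = 0)
  } else NULL
  gene_network(genes, edges)
}

#' Named network fixtures
#'
#' Constructs the benchmark motifs used throughout the package. The
#' transcriptional motifs return a \code{\link{gene_network}}; the
#' post-translational/post-transcriptional motifs
#' (\code{"sequestration"}, \code{"phosphorylation"},
#' \code{"mrna_degradation_control"}, \code{"mirna_mrna"}) return a
#' \code{\link{reaction_system}} directly. Two- and three-node motifs are
#' non-bursty. Default rate values for the post-regulation motifs are
#' package choices documented in the methods vignette.
#'
#' @param name one of \code{"two_node"}, \code{"toggle"},
#'   \code{"repressilator"}, \code{"goodwin"}, \code{"sequestration"},
#'   \code{"phosphorylation"}, \code{"mrna_degradation_control"},
#'   \code{"mirna_mrna"}.
#' @param ... overrides of the motif's default parameters (see the
#'   individual builders' code for the accepted names).
#' @return a \code{gene_network} or \code{reaction_system}.
#' @examples
#' build_fixture("toggle", h = c(2, 2))
#' @export
build_fixture <- function(name, ...) {
  fixtures <- c("two_node", "toggle", "repressilator", "goodwin",
                "sequestration", "phosphorylation",
                "mrna_degradation_control", "mirna_mrna")
  if (!is.character(name) || length(name) != 1L || !(name %in% fixtures))
    stop("unknown fixture; valid names: ", paste(fixtures, collapse = ", "))
  switch(name,
    two_node = fixture_two_node(...),
    toggle = fixture_toggle(...),
    repressilator = fixture_repressilator(...),
    goodwin = fixture_goodwin(...),
    sequestration = fixture_sequestration(...),
    phosphorylation = fixture_phosphorylation(...),
    mrna_degradation_control = fixture_mrna_degradation(...),
    mirna_mrna = fixture_mirna_mrna(...))
}

# Two-node negative feedback loop, non-cooperative by default: binding of
# P1 (rare, weak) activates G2, whose short active episodes release large
# amounts of the repressor P2; P2 in turn binds G1 strongly and shuts it
# off.  With fast promoter switching (sigma_u >> d) this motif exhibits
# bimodality in P1 that neither ultrasensitive positive feedback nor slow
# promoter switching explains (type III).  sigma_b[1] is the binding rate
# of P1 to G2, sigma_b[2] that of P2 to G1.
fixture_two_node <- function(h = c(1L, 1L),
                             rho_u = c(30, 0.05), rho_b = c(0, 400),
                             d = c(1, 1),
                             sigma_b = c(0.003, 30), sigma_u = c(20, 20)) {
  cyclic_motif(rho_u, rho_b, d, sigma_b, sigma_u, as.integer(h))
}

# Toggle switch: mutual repression with cooperative binding; positive
# feedback loop with ultrasensitivity, capable of deterministic bistability.
fixture_toggle <- function(h = c(2L, 2L),
                           rho_u = c(20, 20), rho_b = c(0.4, 0.4),
                           d = c(1, 1),
                           sigma_b = c(0.8, 0.8), sigma_u = c(20, 20)) {
  cyclic_motif(rho_u, rho_b, d, sigma_b, sigma_u, as.integer(h))
}

# Repressilator: three genes repressing cyclically; cooperativity 3 puts the
# deterministic rate equations in the oscillatory regime.
fixture_repressilator <- function(h = c(3L, 3L, 3L),
                                  rho_u = c(60, 60, 60), rho_b = c(0, 0, 0),
                                  d = c(1, 1, 1),
                                  sigma_b = rep(0.3 / 30^3, 3),
                                  sigma_u = c(0.3, 0.3, 0.3)) {
  cyclic_motif(rho_u, rho_b, d, sigma_b, sigma_u, as.integer(h))
}

# Goodwin-type loop: two activations and one repression around the cycle.
fixture_goodwin <- function(h = c(3L, 3L, 3L),
                            rho_u = c(5, 5, 50), rho_b = c(50, 50, 0),
                            d = c(1, 1, 1),
                            sigma_b = c(1e-3, 1e-3, 1e-3),
                            sigma_u = c(1, 1, 1)) {
  cyclic_motif(rho_u, rho_b, d, sigma_b, sigma_u, as.integer(h))
}
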