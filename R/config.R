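# Network configuration files and result serialization.
#
# Configurations are YAML with an explicit schema version; all floating
# point values survive a write/read round trip exactly (17 significant
# digits).

CONFIG_SCHEMA <- 1L

#' Write a gene network to a configuration file
#'
#' @param network a \code{\link{gene_network}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_network_config <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  num <- function(x) as.numeric(x)  # yaml keeps doubles; precision below
  cfg <- list(
    schema = CONFIG_SCHEMA,
    kind = "gene_network",
    genes = lapply(seq_len(network$M), function(j) {
      g <- network$genes[j, ]
      list(alpha0 = num(g$alpha0), alpha1 = num(g$alpha1),
           rho0 = num(g$rho0), rho1 = num(g$rho1),
           d = num(g$d), p = num(g$p))
    }),
    edges = lapply(seq_len(nrow(network$edges)), function(e) {
      ed <- network$edges[e, ]
      list(from = as.integer(ed$from), to = as.integer(ed$to),
           h = as.integer(ed$h), type = ed$type,
           rate = num(ed$rate), unbind = num(ed$unbind))
    }))
  writeLines(yaml::as.yaml(cfg, precision = 17), path)
  invisible(path)
}

#' Read a network configuration file
#'
#' Validates the schema version and field set; unknown keys and invalid
#' combinations (e.g. cooperativity below one, or an edge carrying both an
#' activating and a repressing rate) are rejected with the offending
#' location.
#'
#' @param path configuration file path.
#' @return a \code{\link{gene_network}}.
#' @export
read_network_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema)) stop("missing schema version")
  if (cfg$schema != CONFIG_SCHEMA)
    stop("config schema version ", cfg$schema, " not supported (expected ",
         CONFIG_SCHEMA, ")")
  if (!identical(cfg$kind, "gene_network"))
    stop("unsupported config kind: ", cfg$kind)
  extra <- setdiff(names(cfg), c("schema", "kind", "genes", "edges"))
  if (length(extra)) stop("unknown top-level keys: ",
                          paste(extra, collapse = ", "))
  gene_fields <- c("alpha0", "alpha1", "rho0", "rho1", "d", "p")
  genes <- do.call(rbind, lapply(seq_along(cfg$genes), function(j) {
    g <- cfg$genes[[j]]
    bad <- setdiff(names(g), gene_fields)
    if (length(bad)) stop("genes[", j, "]: unknown keys ",
                          paste(bad, collapse = ", "))
    miss <- setdiff(gene_fields, names(g))
    if (length(miss)) stop("genes[", j, "]: missing ",
                           paste(miss, collapse = ", "))
    as.data.frame(g)
  }))
  edge_fields <- c("from", "to", "h", "type", "rate", "unbind")
  edges <- if (length(cfg$edges)) {
    do.call(rbind, lapply(seq_along(cfg$edges), function(e) {
      ed <- cfg$edges[[e]]
      bad <- setdiff(names(ed), edge_fields)
      if (length(bad)) stop("edges[", e, "]: unknown keys ",
                            paste(bad, collapse = ", "))
      as.data.frame(ed)
    }))
  } else NULL
  gene_network(genes, edges)
}

#' Write distributions, parameters and a run manifest
#'
#' Serializes fitted distributions and effective-parameter trajectories as
#' delimited text plus a YAML manifest recording the method, seeds,
#' tolerances and package version. Identical inputs produce byte-identical
#' files.
#'
#' @param fit a \code{\link{holimap}} fit.
#' @param out_dir output directory (created if missing).
#' @return named character vector of the files written.
#' @export
write_results <- function(fit, out_dir) {
  stopifnot(inherits(fit, "holimap"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  dist_rows <- list()
  for (sp in names(fit$dists)) {
    d <- fit$dists[[sp]]
    dl <- if (inherits(d, "count_dist")) list(d) else d
    for (dd in dl) {
      dist_rows[[length(dist_rows) + 1L]] <- data.frame(
        time = if (is.na(dd$time)) "steady" else fmt(dd$time),
        species = sp, n = seq_along(dd$p) - 1L, probability = fmt(dd$p))
    }
  }
  dist_file <- file.path(out_dir, "distributions.tsv")
  utils::write.table(do.call(rbind, dist_rows), dist_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  par <- fit$params
  for (nm in c("s_on", "s_off", "rho0", "rho1", "d", "p"))
    if (nm %in% names(par)) par[[nm]] <- fmt(par[[nm]])
  par_file <- file.path(out_dir, "parameters.tsv")
  utils::write.table(par, par_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(
    package = "holimap",
    version = as.character(utils::packageVersion("holimap")),
    method = fit$method, mode = fit$mode, engine = fit$engine,
    seed = if (!is.null(fit$ensemble_seed)) fit$ensemble_seed else NA,
    n_trajectories = if (!is.null(fit$N)) fit$N else NA,
    notes = if (length(fit$notes)) fit$notes else list())
  man_file <- file.path(out_dir, "manifest.yaml")
  writeLines(yaml::as.yaml(manifest, precision = 17), man_file)
  invisible(c(distributions = dist_file, parameters = par_file,
              manifest = man_file))
}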