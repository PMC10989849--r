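#' Assign assembly processes to network edges
#'
#' For each edge, the joint abundance distance of the taxon pair is
#' Mantel-tested against the geographic and the environmental distance
#' matrices. An edge is "explained" by a factor when the Mantel r is
#' positive (distance-decay direction) and its permutation p is below
#' `alpha`. The 2x2 significance pattern yields four mutually exclusive
#' classes: geographic only = `dispersal_limitation`; environmental only =
#' `environmental_selection`; both = `overlap`; neither = `biotic`
#' (a putative biotic association).
#'
#' @param net an `association_network`.
#' @param table the `abundance_table` (relative abundance; counts are
#'   converted with a notice).
#' @param geo_d,env_d `dist` objects over the table's samples (see
#'   [geo_distance()], [env_distance()]).
#' @param alpha per-link significance level, default 0.05 (no multiplicity
#'   correction by default; set `fdr = TRUE` for Benjamini-Hochberg across
#'   edges, applied per factor).
#' @param n_perm Mantel permutations per test, default 999.
#' @param seed integer; each edge's two tests draw from a deterministic
#'   per-edge stream derived from it.
#' @param pair_metric metric for [pair_abundance_distance()], default
#'   Bray-Curtis.
#' @param method Mantel correlation method, default `"spearman"`.
#' @param fdr logical, default FALSE.
#' @return An object of class `process_assignment`: data.frame with one
#'   row per edge (`taxon_a`, `taxon_b`, `weight`, `r_geo`, `p_geo`,
#'   `r_env`, `p_env`, `process`) plus attributes `alpha`, `n_perm`.
#' @export
assign_processes <- function(net, table, geo_d, env_d, alpha = 0.05,
                             n_perm = 999, seed = 1L,
                             pair_metric = c("braycurtis", "euclidean"),
                             method = c("spearman", "pearson"),
                             fdr = FALSE) {
  stopifnot(inherits(net, "association_network"),
            inherits(table, "abundance_table"))
  pair_metric <- match.arg(pair_metric)
  method <- match.arg(method)
  if (!table$is_relative && pair_metric == "braycurtis") {
    message("converting counts to relative abundance for link tests")
    table <- to_relative(table)
  }
  edges <- net$edges
  out <- data.frame(taxon_a = edges$taxon_a, taxon_b = edges$taxon_b,
                    weight = edges$weight, r_geo = numeric(nrow(edges)),
                    p_geo = numeric(nrow(edges)),
                    r_env = numeric(nrow(edges)),
                    p_env = numeric(nrow(edges)),
                    process = character(nrow(edges)),
                    stringsAsFactors = FALSE)
  if (nrow(edges)) {
    labels <- attr(geo_d, "Labels")
    if (!is.null(labels) && !identical(labels, sample_ids(table)))
      stop("geographic distance labels do not match the abundance table")
    for (k in seq_len(nrow(edges))) {
      dp <- pair_abundance_distance(table, edges$taxon_a[k],
                                    edges$taxon_b[k], metric = pair_metric)
      tg <- suppressWarnings(
        mantel_test(dp, geo_d, method = method, n_perm = n_perm,
                    seed = seed + 2L * k))
      te <- suppressWarnings(
        mantel_test(dp, env_d, method = method, n_perm = n_perm,
                    seed = seed + 2L * k + 1L))
      out$r_geo[k] <- tg$r; out$p_geo[k] <- tg$p_value
      out$r_env[k] <- te$r; out$p_env[k] <- te$p_value
    }
    p_geo <- if (fdr) fdr_adjust(out$p_geo) else out$p_geo
    p_env <- if (fdr) fdr_adjust(out$p_env) else out$p_env
    sig_geo <- p_geo < alpha & out$r_geo > 0
    sig_env <- p_env < alpha & out$r_env > 0
    out$process <- ifelse(sig_geo & sig_env, "overlap",
                   ifelse(sig_geo, "dispersal_limitation",
                   ifelse(sig_env, "environmental_selection", "biotic")))
  }
  structure(out, alpha = alpha, n_perm = n_perm, fdr = fdr,
            class = c("process_assignment", "data.frame"))
}

#' Fractions of edges per assembly process
#'
#' @param assignment a `process_assignment`.
#' @return named numeric vector over
#'   `c("biotic", "environmental_selection", "dispersal_limitation",
#'   "overlap")`, summing to 1.
#' @export
process_fractions <- function(assignment) {
  if (nrow(assignment) == 0L) stop("empty assignment: no edges to summarise")
  classes <- c("biotic", "environmental_selection", "dispersal_limitation",
               "overlap")
  counts <- table(factor(assignment$process, levels = classes))
  f <- as.vector(counts) / nrow(assignment)
  names(f) <- classes
  f
}

#' Restrict a network to its putative biotic edges
#'
#' Convenience: drops every edge whose assigned process is not `biotic`,
#' returning the filtered network that the quantification stage consumes.
#'
#' @param net an `association_network`.
#' @param assignment the matching `process_assignment`.
#' @return An [association_network()] on the same taxa.
#' @export
biotic_network <- function(net, assignment) {
  keep <- assignment$process == "biotic"
  key_net <- paste(net$edges$taxon_a, net$edges$taxon_b)
  key_asg <- paste(assignment$taxon_a, assignment$taxon_b)[keep]
  association_network(net$taxa,
                      net$edges[key_net %in% key_asg, , drop = FALSE],
                      method = c(net$method, list(filtered = "biotic")))
}

#' Write a process assignment as TSV plus a JSON fraction summary
#'
#' @param assignment a `process_assignment`.
#' @param path TSV path; fractions go to `<path>.fractions.json`.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  utils::write.table(as.data.frame(assignment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(process_fractions(assignment)),
                       paste0(path, ".fractions.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
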