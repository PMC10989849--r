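#' Run the full association-quantification pipeline
#'
#' Chains the whole workflow on in-memory inputs and writes every
#' intermediate as deterministic plain text: taxon filtering, correlation
#' network inference (or an imported network), per-edge link tests and
#' process assignment, biotic filtering, connectedness and per-sample
#' community strengths. File outputs under `out_dir`:
#' `network.tsv` (+ `.meta.json`), `assignment.tsv`
#' (+ `.fractions.json`), `biotic_network.tsv` (+ `.meta.json`),
#' `connectedness.tsv`, `strength.tsv`.
#'
#' @param table an `abundance_table` (counts or relative).
#' @param geo data.frame with `longitude`/`latitude` (and optionally
#'   `elevation`), rownames = sample ids.
#' @param env data.frame of numeric environmental variables, rownames =
#'   sample ids.
#' @param out_dir output directory (created if needed).
#' @param network optional pre-built `association_network` (e.g. from
#'   [import_network()]); when given, the filtering and inference stages
#'   are skipped.
#' @param min_occurrence_frac,min_relabund taxon filter thresholds
#'   (see [filter_taxa()]); set both to 0 to skip filtering.
#' @param cor_method correlation method for inference, default
#'   `"spearman"`.
#' @param r_min,q_max network gates, defaults 0.6 and 0.05.
#' @param use_rmt choose `r_min` by [rmt_threshold()] when the scan
#'   succeeds, default FALSE.
#' @param env_vars environmental variables to use; default = result of
#'   [screen_env_covariance()] on all columns.
#' @param alpha,n_perm,seed link-test parameters (see
#'   [assign_processes()]).
#' @param include_elevation passed to [geo_distance()].
#' @return list with `network`, `assignment`, `fractions`,
#'   `biotic_network`, `profile`, `strength`, invisibly.
#' @export
run_pipeline <- function(table, geo, env, out_dir,
                         network = NULL, min_occurrence_frac = 0.25,
                         min_relabund = 1e-5,
                         cor_method = "spearman", r_min = 0.6,
                         q_max = 0.05, use_rmt = FALSE,
                         env_vars = NULL, alpha = 0.05, n_perm = 999,
                         seed = 1L, include_elevation = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(network)) {
    filtered <- if (min_occurrence_frac > 0 || min_relabund > 0)
      filter_taxa(table, min_occurrence_frac, min_relabund) else table
    cm <- correlation_matrix(filtered, method = cor_method)
    if (use_rmt) {
      scan <- rmt_threshold(cm$R)
      if (scan$found) r_min <- scan$chosen
    }
    network <- threshold_network(cm, r_min = r_min, q_max = q_max)
  } else {
    filtered <- table
  }
  write_network(network, file.path(out_dir, "network.tsv"))

  geo <- geo[sample_ids(filtered), , drop = FALSE]
  env <- env[sample_ids(filtered), , drop = FALSE]
  if (is.null(env_vars)) env_vars <- screen_env_covariance(env)
  geo_d <- geo_distance(geo, include_elevation = include_elevation)
  env_d <- env_distance(env, variables = env_vars)

  assignment <- assign_processes(network, filtered, geo_d, env_d,
                                 alpha = alpha, n_perm = n_perm,
                                 seed = seed)
  fractions <- if (nrow(assignment)) process_fractions(assignment) else NULL
  if (nrow(assignment))
    write_assignment(assignment, file.path(out_dir, "assignment.tsv"))

  bnet <- biotic_network(network, assignment)
  write_network(bnet, file.path(out_dir, "biotic_network.tsv"))

  profile <- connectedness(bnet, taxon_ids(filtered), table = filtered)
  strength <- community_strength(filtered, profile)
  write_connectedness(profile, file.path(out_dir, "connectedness.tsv"))
  write_strength(strength, file.path(out_dir, "strength.tsv"))

  invisible(list(network = network, assignment = assignment,
                 fractions = fractions, biotic_network = bnet,
                 profile = profile, strength = strength))
}
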