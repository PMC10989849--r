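#' Specification of a synthetic community with planted assembly structure
#'
#' Describes a simulated survey: samples scattered uniformly over a
#' geographic window, one environmental gradient, and taxa of four kinds
#' -- pairs jointly tracking the environmental gradient, pairs tracking a
#' smooth spatial field, pairs coupled through a latent bivariate-normal
#' copula independent of space and environment (the planted "biotic"
#' associations, positive or negative), and independent log-normal noise
#' taxa. Defaults follow the recovery scenario the test-suite exercises:
#' 60 samples, 100 noise taxa, 20 pairs of each planted class, strong
#' effects (slope 2 on a unit-variance gradient, residual sigma 0.3,
#' copula correlation 0.9).
#'
#' @param n_samples number of samples, default 60.
#' @param n_noise_taxa independent noise taxa, default 100.
#' @param n_env_pairs,n_space_pairs planted environmentally / spatially
#'   driven pairs, default 20 each.
#' @param n_biotic_pos_pairs,n_biotic_neg_pairs planted biotic pairs with
#'   positive / negative copula correlation, defaults 15 and 5.
#' @param env_effect,space_effect slope of the log-abundance response to
#'   the (unit-variance) gradient / spatial field, default 2.
#' @param biotic_rho magnitude of the latent copula correlation in (0,1),
#'   default 0.9; the pair type sets its sign.
#' @param noise_sigma residual log-abundance s.d. of planted taxa,
#'   default 0.3.
#' @param base_abundance_logmean,base_abundance_logsd log-normal baseline
#'   per taxon, defaults -3 and 1 (a realistic rank-abundance curve).
#' @param sparsity_quantile fraction of each taxon's lowest values zeroed
#'   to emulate amplicon zero inflation, default 0.3.
#' @param env_space_cor correlation between the environmental gradient
#'   and the spatial field, default 0 (keeps the planted classes
#'   identifiable); raise it to generate overlap-class edges.
#' @param seed integer RNG seed, default 1.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 60, n_noise_taxa = 100,
                           n_env_pairs = 20, n_space_pairs = 20,
                           n_biotic_pos_pairs = 15,
                           n_biotic_neg_pairs = 5, env_effect = 2,
                           space_effect = 2, biotic_rho = 0.9,
                           noise_sigma = 0.3,
                           base_abundance_logmean = -3,
                           base_abundance_logsd = 1,
                           sparsity_quantile = 0.3, env_space_cor = 0,
                           seed = 1L) {
  spec <- list(n_samples = n_samples, n_noise_taxa = n_noise_taxa,
               n_env_pairs = n_env_pairs, n_space_pairs = n_space_pairs,
               n_biotic_pos_pairs = n_biotic_pos_pairs,
               n_biotic_neg_pairs = n_biotic_neg_pairs,
               env_effect = env_effect, space_effect = space_effect,
               biotic_rho = biotic_rho, noise_sigma = noise_sigma,
               base_abundance_logmean = base_abundance_logmean,
               base_abundance_logsd = base_abundance_logsd,
               sparsity_quantile = sparsity_quantile,
               env_space_cor = env_space_cor, seed = as.integer(seed))
  counts <- unlist(spec[c("n_samples", "n_noise_taxa", "n_env_pairs",
                          "n_space_pairs", "n_biotic_pos_pairs",
                          "n_biotic_neg_pairs")])
  if (any(counts < 0)) stop("counts must be >= 0")
  if (spec$n_samples < 4) stop("need at least 4 samples")
  if (abs(biotic_rho) >= 1) stop("biotic_rho must lie in (-1, 1)")
  if (noise_sigma <= 0) stop("noise_sigma must be > 0")
  if (sparsity_quantile < 0 || sparsity_quantile >= 1)
    stop("sparsity_quantile must lie in [0, 1)")
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic community with ground truth
#'
#' Draws coordinates, environmental gradient, and log-abundances per
#' [synthetic_spec()]; exponentiates, zeroes each taxon's lowest
#' `sparsity_quantile` of values, renormalises rows to relative
#' abundance, and reports the planted pairs. Deterministic given the
#' spec's seed.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `table` (relative `abundance_table`), `geo`
#'   (data.frame: longitude, latitude, elevation), `env` (data.frame:
#'   `env1` = the driving gradient, `env2` = an inert variable),
#'   `truth` (data.frame: taxon_a, taxon_b, class, sign).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  samples <- sprintf("S%03d", seq_len(n))

  # ~50 km box; haversine distances on it are near-planar
  lon <- stats::runif(n, 100, 100.5)
  lat <- stats::runif(n, 30, 30.5)
  elevation <- stats::runif(n, 3000, 3500)
  geo <- data.frame(longitude = lon, latitude = lat,
                    elevation = elevation, row.names = samples)

  # smooth spatial field: linear in rotated standardised coordinates
  g_raw <- scale(lon)[, 1] * cos(pi / 6) + scale(lat)[, 1] * sin(pi / 6)
  G <- as.vector(scale(g_raw))
  e_latent <- stats::rnorm(n)
  E <- spec$env_space_cor * G +
    sqrt(1 - spec$env_space_cor^2) * e_latent
  E <- as.vector(scale(E + stats::rnorm(n, sd = 0.1)))
  env <- data.frame(env1 = E, env2 = stats::rnorm(n),
                    row.names = samples)

  n_pairs <- spec$n_env_pairs + spec$n_space_pairs +
    spec$n_biotic_pos_pairs + spec$n_biotic_neg_pairs
  n_taxa <- spec$n_noise_taxa + 2L * n_pairs
  taxa <- sprintf("T%04d", seq_len(n_taxa))
  base <- stats::rnorm(n_taxa, spec$base_abundance_logmean,
                       spec$base_abundance_logsd)
  logA <- matrix(0, n, n_taxa, dimnames = list(samples, taxa))

  truth <- data.frame(taxon_a = character(), taxon_b = character(),
                      class = character(), sign = integer(),
                      stringsAsFactors = FALSE)
  idx <- 0L
  plant_pair <- function(class, sign, draw) {
    a <- taxa[idx + 1L]; b <- taxa[idx + 2L]
    logA[, idx + 1L] <<- base[idx + 1L] + draw[[1L]]
    logA[, idx + 2L] <<- base[idx + 2L] + draw[[2L]]
    truth <<- rbind(truth, data.frame(taxon_a = a, taxon_b = b,
                                      class = class, sign = sign,
                                      stringsAsFactors = FALSE))
    idx <<- idx + 2L
  }
  for (k in seq_len(spec$n_env_pairs))
    plant_pair("environmental_selection", 1L, list(
      spec$env_effect * E + stats::rnorm(n, sd = spec$noise_sigma),
      spec$env_effect * E + stats::rnorm(n, sd = spec$noise_sigma)))
  for (k in seq_len(spec$n_space_pairs))
    plant_pair("dispersal_limitation", 1L, list(
      spec$space_effect * G + stats::rnorm(n, sd = spec$noise_sigma),
      spec$space_effect * G + stats::rnorm(n, sd = spec$noise_sigma)))
  rho_pairs <- c(rep(spec$biotic_rho, spec$n_biotic_pos_pairs),
                 rep(-spec$biotic_rho, spec$n_biotic_neg_pairs))
  for (rho in rho_pairs) {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    amp <- spec$env_effect   # planted signals on a common scale
    plant_pair("biotic", if (rho > 0) 1L else -1L,
               list(amp * z1 + stats::rnorm(n, sd = spec$noise_sigma),
                    amp * z2 + stats::rnorm(n, sd = spec$noise_sigma)))
  }
  if (spec$n_noise_taxa > 0)
    logA[, idx + seq_len(spec$n_noise_taxa)] <-
      rep(base[idx + seq_len(spec$n_noise_taxa)], each = n) +
      stats::rnorm(n * spec$n_noise_taxa)

  A <- exp(logA)
  if (spec$sparsity_quantile > 0) {
    for (j in seq_len(n_taxa)) {
      cut <- stats::quantile(A[, j], spec$sparsity_quantile)
      A[A[, j] <= cut, j] <- 0
    }
  }
  keep_rows <- rowSums(A) > 0
  A <- A[keep_rows, , drop = FALSE]
  tab <- to_relative(abundance_table(A, is_relative = FALSE))
  list(table = tab, geo = geo[keep_rows, , drop = FALSE],
       env = env[keep_rows, , drop = FALSE], truth = truth)
}

#' Write a synthetic bundle as a TSV fixture directory
#'
#' Emits `abundance.tsv` (samples as rows), `geo.tsv`, `env.tsv` and
#' `ground_truth.tsv` in the package's standard formats.
#'
#' @param bundle result of [generate_community()].
#' @param directory output directory.
#' @param overwrite allow writing into an existing directory, default
#'   FALSE.
#' @return the directory, invisibly.
#' @export
write_fixture <- function(bundle, directory, overwrite = FALSE) {
  if (dir.exists(directory) && !overwrite)
    stop("directory exists (use overwrite = TRUE): ", directory)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_abundance(bundle$table, file.path(directory, "abundance.tsv"))
  write_metadata(bundle$geo, file.path(directory, "geo.tsv"))
  write_metadata(bundle$env, file.path(directory, "env.tsv"))
  utils::write.table(bundle$truth, file.path(directory, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(directory)
}

#' Read a fixture directory back into a bundle
#'
#' @param directory directory written by [write_fixture()].
#' @return list with `table`, `geo`, `env`, `truth`.
#' @export
read_fixture <- function(directory) {
  list(table = read_abundance(file.path(directory, "abundance.tsv"),
                              orientation = "samples_as_rows",
                              is_relative = TRUE),
       geo = read_metadata(file.path(directory, "geo.tsv"),
                           required = c("longitude", "latitude")),
       env = read_metadata(file.path(directory, "env.tsv")),
       truth = utils::read.table(file.path(directory, "ground_truth.tsv"),
                                 header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
}
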