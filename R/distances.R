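#' Geographic distance matrix between samples
#'
#' Great-circle (haversine, Earth radius 6371 km) or planar Euclidean
#' distance from a geographic table with `longitude`/`latitude` columns in
#' decimal degrees. With `include_elevation`, the elevation difference
#' (converted from metres to km) is combined with the horizontal distance
#' as a Euclidean norm.
#'
#' @param geo data.frame with rownames = sample ids and columns
#'   `longitude`, `latitude` and optionally `elevation` (metres).
#' @param mode `"haversine"` (default, km) or `"euclidean"` (planar, in
#'   coordinate units).
#' @param include_elevation logical, default FALSE.
#' @return A `dist` object labelled by sample id (km for haversine).
#' @export
geo_distance <- function(geo, mode = c("haversine", "euclidean"),
                         include_elevation = FALSE) {
  mode <- match.arg(mode)
  validate_geo(geo)
  if (include_elevation && !"elevation" %in% names(geo))
    stop("include_elevation = TRUE but no 'elevation' column")
  n <- nrow(geo)
  if (mode == "haversine") {
    lat <- geo$latitude * pi / 180
    lon <- geo$longitude * pi / 180
    h <- outer(seq_len(n), seq_len(n), function(i, j) {
      dlat <- lat[i] - lat[j]
      dlon <- lon[i] - lon[j]
      a <- sin(dlat / 2)^2 + cos(lat[i]) * cos(lat[j]) * sin(dlon / 2)^2
      2 * 6371 * asin(pmin(sqrt(a), 1))
    })
  } else {
    h <- as.matrix(stats::dist(geo[, c("longitude", "latitude")]))
  }
  if (include_elevation) {
    dz <- outer(geo$elevation, geo$elevation, "-") / 1000  # m -> km
    h <- sqrt(h^2 + dz^2)
  }
  dimnames(h) <- list(rownames(geo), rownames(geo))
  stats::as.dist(h)
}

#' Environmental distance matrix between samples
#'
#' Euclidean distance on the selected environmental variables, by default
#' after z-score standardisation (so the result is invariant to affine
#' rescaling of any input variable).
#'
#' @param env data.frame with rownames = sample ids, numeric columns.
#' @param variables character vector of column names; default all columns.
#' @param standardize logical, default TRUE.
#' @return A `dist` object labelled by sample id.
#' @export
env_distance <- function(env, variables = colnames(env),
                         standardize = TRUE) {
  missing <- setdiff(variables, colnames(env))
  if (length(missing))
    stop("unknown environmental variable(s): ",
         paste(missing, collapse = ", "))
  x <- as.matrix(env[, variables, drop = FALSE])
  if (!is.numeric(x)) stop("environmental variables must be numeric")
  if (anyNA(x)) stop("missing values among selected environmental variables")
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance variable(s) cannot be standardised: ",
           paste(variables[sds == 0], collapse = ", "))
    x <- scale(x)
  }
  rownames(x) <- rownames(env)
  stats::dist(x)
}

#' Greedy covariance screen of environmental variables
#'
#' When several variables are folded into one environmental dissimilarity
#' matrix, strongly covarying variables should not all enter. Variables
#' are scanned in the caller-given priority order; one is retained iff its
#' absolute Spearman correlation with every previously retained variable
#' is strictly below `rho_max`.
#'
#' @param env data.frame of numeric variables (columns in priority order).
#' @param rho_max Spearman magnitude cut-off, default 0.5.
#' @return character vector of retained variable names.
#' @export
screen_env_covariance <- function(env, rho_max = 0.5) {
  vars <- colnames(env)
  if (length(vars) == 0L) stop("no environmental variables")
  kept <- vars[1L]
  for (v in vars[-1L]) {
    rho <- abs(suppressWarnings(
      stats::cor(env[[v]], env[, kept, drop = FALSE],
                 method = "spearman")))
    rho[is.na(rho)] <- 1    # constant variable: treat as redundant
    if (all(rho < rho_max)) kept <- c(kept, v)
  }
  kept
}

#' Sample-sample distance from one taxon pair's abundances
#'
#' The per-edge link tests ask whether the joint abundance profile of a
#' significantly associated taxon pair tracks space or environment. This
#' builds the sample x sample distance matrix from the two-column
#' submatrix of the pair's abundances: Bray-Curtis (default, on relative
#' abundances) or Euclidean. A Bray-Curtis pair of samples in which both
#' taxa are absent from both samples is defined as 0.
#'
#' @param table an `abundance_table`.
#' @param taxon_i,taxon_j taxon identifiers.
#' @param metric `"braycurtis"` (default) or `"euclidean"`.
#' @return A `dist` object over the table's samples.
#' @export
pair_abundance_distance <- function(table, taxon_i, taxon_j,
                                    metric = c("braycurtis", "euclidean")) {
  stopifnot(inherits(table, "abundance_table"))
  metric <- match.arg(metric)
  missing <- setdiff(c(taxon_i, taxon_j), taxon_ids(table))
  if (length(missing))
    stop("taxon not found: ", paste(missing, collapse = ", "))
  sub <- table$values[, c(taxon_i, taxon_j), drop = FALSE]
  if (metric == "euclidean") return(stats::dist(sub))
  tot <- outer(rowSums(sub), rowSums(sub), "+")
  num <- as.matrix(stats::dist(sub, method = "manhattan"))
  d <- ifelse(tot > 0, num / tot, 0)
  dimnames(d) <- list(rownames(sub), rownames(sub))
  stats::as.dist(d)
}
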