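#' Construct a sample x taxon abundance table
#'
#' The central container of the package: a non-negative numeric matrix with
#' samples as rows and taxa as columns. Counts and relative abundances share
#' the container; `is_relative` records which one is stored.
#'
#' @param values numeric matrix, samples as rows, taxa as columns; rownames
#'   and colnames are the sample and taxon identifiers.
#' @param is_relative logical; if `TRUE` every row must sum to 1 (within
#'   1e-9) and all-zero rows are forbidden.
#' @return An object of class `abundance_table` with elements `values`
#'   (the matrix) and `is_relative`.
#' @export
abundance_table <- function(values, is_relative = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance_table requires sample (row) and taxon (column) names")
  if (anyNA(values)) stop("abundance_table forbids missing values")
  if (any(values < 0)) stop("abundance_table forbids negative values")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample identifier: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate taxon identifier: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (isTRUE(is_relative)) {
    rs <- rowSums(values)
    if (any(rs == 0))
      stop("relative abundance table has all-zero row(s): ",
           paste(rownames(values)[rs == 0], collapse = ", "))
    if (any(abs(rs - 1) > 1e-9))
      stop("relative abundance rows must sum to 1 (max deviation ",
           format(max(abs(rs - 1))), ")")
  }
  structure(list(values = values, is_relative = isTRUE(is_relative)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_relative) "relative abundance" else "counts"))
  invisible(x)
}

#' Sample identifiers of an abundance table
#' @param table an `abundance_table`
#' @return character vector of sample ids, in table order
#' @export
sample_ids <- function(table) rownames(table$values)

#' Taxon identifiers of an abundance table
#' @param table an `abundance_table`
#' @return character vector of taxon ids, in table order
#' @export
taxon_ids <- function(table) colnames(table$values)

#' Read a delimited abundance table
#'
#' Reads a TSV/CSV whose first column holds identifiers and whose header
#' holds the identifiers of the other axis. The orientation is never
#' guessed: the caller states whether taxa are rows or samples are rows.
#' The returned table is always in the canonical samples x taxa
#' orientation.
#'
#' @param path file path.
#' @param orientation `"taxa_as_rows"` (the common OTU-table dialect) or
#'   `"samples_as_rows"`.
#' @param delimiter field delimiter, default tab.
#' @param is_relative passed through to [abundance_table()].
#' @return An [abundance_table()].
#' @export
read_abundance <- function(path, orientation = c("taxa_as_rows",
                                                 "samples_as_rows"),
                           delimiter = "\t", is_relative = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate identifier in first column of ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell in %s at row '%s', column '%s'",
                 path, ids[bad[1L]], colnames(body)[bad[2L]]))
  }
  dimnames(num) <- list(ids, colnames(body))
  if (orientation == "taxa_as_rows") num <- t(num)
  abundance_table(num, is_relative = is_relative)
}

#' Write an abundance table as TSV
#'
#' Emits samples as rows with a leading `sample_id` column; integer-valued
#' tables are written without decimals so that write/read round-trips are
#' exact.
#'
#' @param table an `abundance_table`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  int_like <- all(v == round(v)) && max(v) < .Machine$integer.max
  df <- data.frame(sample_id = rownames(v), check.names = FALSE,
                   stringsAsFactors = FALSE)
  body <- as.data.frame(if (int_like) matrix(as.integer(v), nrow(v),
                                             dimnames = dimnames(v))
                        else v, check.names = FALSE)
  df <- cbind(df, body)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundance
#'
#' Divides each sample row by its sum. Idempotent on already-relative
#' tables.
#'
#' @param table an `abundance_table`
#' @return An `abundance_table` with `is_relative = TRUE`.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  rs <- rowSums(table$values)
  if (any(rs == 0))
    stop("cannot normalise sample(s) with zero total abundance: ",
         paste(rownames(table$values)[rs == 0], collapse = ", "))
  abundance_table(table$values / rs, is_relative = TRUE)
}

#' Filter taxa by occurrence and mean relative abundance
#'
#' Standard pre-network filtering: a taxon is kept iff it is present
#' (abundance > 0) in strictly more than `min_occurrence_frac` of samples
#' AND its relative abundance, summarised across samples by `abund_stat`,
#' is at least `min_relabund`. The defaults implement the common
#' ">25% occurrence, >= 0.001% relative abundance" rule. Surviving taxa
#' keep their original (unnormalised) values.
#'
#' @param table an `abundance_table`
#' @param min_occurrence_frac occurrence fraction threshold (strict `>`),
#'   default 0.25.
#' @param min_relabund relative-abundance threshold (`>=`), default 1e-5
#'   (i.e. 0.001%).
#' @param abund_stat how relative abundance is summarised across samples
#'   before comparison: `"mean"` (default) or `"max"`.
#' @return An `abundance_table` restricted to the surviving taxa.
#' @export
filter_taxa <- function(table, min_occurrence_frac = 0.25,
                        min_relabund = 1e-5,
                        abund_stat = c("mean", "max")) {
  stopifnot(inherits(table, "abundance_table"))
  abund_stat <- match.arg(abund_stat)
  v <- table$values
  occ <- colMeans(v > 0)
  rel <- if (table$is_relative) v else to_relative(table)$values
  stat <- switch(abund_stat, mean = colMeans(rel),
                 max = apply(rel, 2L, max))
  keep <- occ > min_occurrence_frac & stat >= min_relabund
  if (!any(keep))
    stop("no taxa survive filtering; relax min_occurrence_frac (",
         min_occurrence_frac, ") or min_relabund (", min_relabund, ")")
  abundance_table(v[, keep, drop = FALSE], is_relative = table$is_relative)
}

#' Read a per-sample metadata table
#'
#' Reads a TSV with a `sample_id` column plus named variable columns and
#' returns a data frame with sample ids as row names. Shared by the
#' geographic and environmental table readers.
#'
#' @param path file path
#' @param required character vector of column names that must be present
#' @return data.frame with rownames = sample ids.
#' @export
read_metadata <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("metadata table ", path, " lacks a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in ", path)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("metadata table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  rownames(df) <- df$sample_id
  df$sample_id <- NULL
  df
}

#' Write a per-sample metadata table as TSV
#' @param df data.frame with rownames = sample ids
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_metadata <- function(df, path) {
  out <- cbind(data.frame(sample_id = rownames(df),
                          stringsAsFactors = FALSE), df)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Validate a geographic table against its invariants.
validate_geo <- function(geo, samples = NULL) {
  for (col in c("longitude", "latitude"))
    if (!col %in% names(geo)) stop("geographic table lacks '", col, "'")
  if (any(geo$latitude < -90 | geo$latitude > 90))
    stop("latitude out of [-90, 90]")
  if (any(geo$longitude < -180 | geo$longitude > 180))
    stop("longitude out of [-180, 180]")
  if (!is.null(samples) && !all(rownames(geo) %in% samples))
    stop("geographic table contains samples absent from the abundance table")
  invisible(geo)
}
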