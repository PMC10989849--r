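RANK_NAMES <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")

#' Construct a taxonomy table
#'
#' Maps taxon identifiers to rank strings in the fixed order
#' domain...species; missing ranks are stored as empty strings. Purely a
#' carrier: no stage of the pipeline consumes taxonomy, but subnetworks
#' and profiles are commonly summarised against it downstream.
#'
#' @param df data.frame with rownames = taxon ids and any subset of the
#'   columns domain/phylum/class/order/family/genus/species (others are
#'   rejected).
#' @return data.frame of class `taxonomy_table` with all seven rank
#'   columns in canonical order.
#' @export
taxonomy_table <- function(df) {
  if (is.null(rownames(df)) || anyDuplicated(rownames(df)))
    stop("taxonomy requires unique taxon identifiers as rownames")
  unknown <- setdiff(colnames(df), RANK_NAMES)
  if (length(unknown))
    stop("unknown rank column(s): ", paste(unknown, collapse = ", "))
  out <- data.frame(row.names = rownames(df))
  for (r in RANK_NAMES)
    out[[r]] <- if (r %in% colnames(df)) as.character(df[[r]]) else ""
  out[is.na(out)] <- ""
  structure(out, class = c("taxonomy_table", "data.frame"))
}

#' Read a taxonomy table from TSV
#'
#' Expects a `taxon_id` column plus rank columns named among
#' domain/phylum/class/order/family/genus/species.
#'
#' @param path file path.
#' @return A [taxonomy_table()].
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  if (!"taxon_id" %in% names(df))
    stop("taxonomy table ", path, " lacks a 'taxon_id' column")
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon_id in ", path)
  rownames(df) <- df$taxon_id
  df$taxon_id <- NULL
  taxonomy_table(df)
}
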