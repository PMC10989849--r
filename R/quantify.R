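#' Per-taxon zero counts
#'
#' Number of samples in which each taxon is absent (abundance exactly 0).
#'
#' @param table an `abundance_table`.
#' @return named integer vector over taxa.
#' @export
zero_counts <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  colSums(table$values == 0)
}

#' Per-taxon positive and negative connectedness
#'
#' For each taxon, the mean weight of its positive edges and the mean
#' weight of its negative edges in the (typically biotic-filtered)
#' network; a taxon with no edges of a sign gets 0. By default the mean
#' runs over the taxon's incident links only; `denominator = "all_taxa"`
#' divides by `length(taxa) - 1` instead, the cohesion-style variant.
#'
#' @param net an `association_network`.
#' @param taxa ordered taxon list the profile should cover (typically
#'   `taxon_ids(table)`); every network node must be in it.
#' @param table optional `abundance_table` used to attach per-taxon zero
#'   counts.
#' @param denominator `"links"` (default) or `"all_taxa"`.
#' @return data.frame (class `connectedness_profile`) with rownames =
#'   taxa and columns `pos_connectedness`, `neg_connectedness`,
#'   `n_pos_links`, `n_neg_links`, `n_zeros`.
#' @export
connectedness <- function(net, taxa, table = NULL,
                          denominator = c("links", "all_taxa")) {
  stopifnot(inherits(net, "association_network"))
  denominator <- match.arg(denominator)
  taxa <- as.character(taxa)
  bad <- setdiff(net$taxa, taxa)
  if (length(bad))
    stop("network taxa absent from the requested taxon list: ",
         paste(bad, collapse = ", "))
  pos_sum <- neg_sum <- stats::setNames(numeric(length(taxa)), taxa)
  n_pos <- n_neg <- stats::setNames(integer(length(taxa)), taxa)
  e <- net$edges
  for (side in c("taxon_a", "taxon_b")) {
    id <- e[[side]]
    pos <- e$weight > 0
    pt <- tapply(e$weight[pos], id[pos], sum)
    nt <- tapply(e$weight[!pos], id[!pos], sum)
    pc <- tapply(pos, id, sum)
    nc <- tapply(!pos, id, sum)
    pos_sum[names(pt)] <- pos_sum[names(pt)] + pt
    neg_sum[names(nt)] <- neg_sum[names(nt)] + nt
    n_pos[names(pc)] <- n_pos[names(pc)] + as.integer(pc)
    n_neg[names(nc)] <- n_neg[names(nc)] + as.integer(nc)
  }
  if (denominator == "links") {
    pos_conn <- ifelse(n_pos > 0, pos_sum / n_pos, 0)
    neg_conn <- ifelse(n_neg > 0, neg_sum / n_neg, 0)
  } else {
    pos_conn <- pos_sum / max(length(taxa) - 1L, 1L)
    neg_conn <- neg_sum / max(length(taxa) - 1L, 1L)
  }
  n_zeros <- if (is.null(table)) rep(NA_integer_, length(taxa))
             else zero_counts(table)[taxa]
  structure(data.frame(pos_connectedness = pos_conn,
                       neg_connectedness = neg_conn,
                       n_pos_links = n_pos, n_neg_links = n_neg,
                       n_zeros = n_zeros, row.names = taxa),
            class = c("connectedness_profile", "data.frame"))
}

#' Community-level positive and negative association strengths
#'
#' The community-level metric: per-sample sums of relative abundance
#' weighted by taxon connectedness, i.e. the matrix products
#' `A %*% pos_connectedness` and `A %*% neg_connectedness` where `A` is
#' the relative abundance matrix. A count table is converted to relative
#' abundance with a notice.
#'
#' @param table an `abundance_table`.
#' @param profile a `connectedness_profile` covering all table taxa.
#' @return data.frame (class `community_strength`) with rownames =
#'   samples and columns `positive_strength` (>= 0) and
#'   `negative_strength` (<= 0).
#' @export
community_strength <- function(table, profile) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(profile, "connectedness_profile"))
  if (!table$is_relative) {
    message("converting counts to relative abundance for quantification")
    table <- to_relative(table)
  }
  taxa <- taxon_ids(table)
  missing <- setdiff(taxa, rownames(profile))
  if (length(missing))
    stop("connectedness profile lacks taxa: ",
         paste(missing, collapse = ", "))
  A <- table$values
  pos <- drop(A %*% profile[taxa, "pos_connectedness"])
  neg <- drop(A %*% profile[taxa, "neg_connectedness"])
  structure(data.frame(positive_strength = pos, negative_strength = neg,
                       row.names = rownames(A)),
            class = c("community_strength", "data.frame"))
}

#' Write a connectedness profile as TSV
#' @param profile a `connectedness_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_connectedness <- function(profile, path) {
  out <- cbind(data.frame(taxon_id = rownames(profile),
                          stringsAsFactors = FALSE),
               as.data.frame(profile))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write community strengths as TSV
#' @param strength a `community_strength`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_strength <- function(strength, path) {
  out <- cbind(data.frame(sample_id = rownames(strength),
                          stringsAsFactors = FALSE),
               as.data.frame(strength))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
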