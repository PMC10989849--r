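#' Construct a signed association network
#'
#' An undirected signed weighted graph over taxa. Each edge is an unordered
#' taxon pair with a weight (association strength, signed), a p-value and a
#' q-value. Pairs are canonicalised (`taxon_a < taxon_b`) and sorted
#' lexicographically so that writers produce reproducible diffs.
#'
#' @param taxa character vector of node identifiers.
#' @param edges data.frame with columns `taxon_a`, `taxon_b`, `weight`,
#'   `p_value`, `q_value` (the last two optional, defaulting to 0 = treated
#'   as pre-validated).
#' @param method named list of metadata (method name, thresholds,
#'   n_samples, ...).
#' @return An object of class `association_network`.
#' @export
association_network <- function(taxa, edges, method = list()) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("duplicate taxon in node list")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(taxon_a = character(), taxon_b = character(),
                        weight = numeric(), p_value = numeric(),
                        q_value = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    for (col in c("taxon_a", "taxon_b", "weight"))
      if (!col %in% names(edges)) stop("edge list lacks column '", col, "'")
    if (!"p_value" %in% names(edges)) edges$p_value <- 0
    if (!"q_value" %in% names(edges)) edges$q_value <- 0
    edges <- edges[, c("taxon_a", "taxon_b", "weight", "p_value",
                       "q_value")]
    edges$taxon_a <- as.character(edges$taxon_a)
    edges$taxon_b <- as.character(edges$taxon_b)
    if (any(edges$taxon_a == edges$taxon_b))
      stop("self-loop edge(s): ",
           paste(unique(edges$taxon_a[edges$taxon_a == edges$taxon_b]),
                 collapse = ", "))
    if (any(edges$weight == 0))
      stop("zero-weight edge(s) are not allowed")
    swap <- edges$taxon_a > edges$taxon_b
    tmp <- edges$taxon_a[swap]
    edges$taxon_a[swap] <- edges$taxon_b[swap]
    edges$taxon_b[swap] <- tmp
    key <- paste(edges$taxon_a, edges$taxon_b, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate edge(s): ",
           paste(gsub("\r", " -- ", unique(key[duplicated(key)])),
                 collapse = ", "))
    bad <- setdiff(c(edges$taxon_a, edges$taxon_b), taxa)
    if (length(bad))
      stop("edge node(s) absent from taxa: ", paste(bad, collapse = ", "))
    edges <- edges[order(edges$taxon_a, edges$taxon_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(taxa = taxa, edges = edges, method = method),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  w <- x$edges$weight
  cat(sprintf("association_network: %d taxa, %d edges (%d positive, %d negative)\n",
              length(x$taxa), nrow(x$edges), sum(w > 0), sum(w < 0)))
  if (length(x$method$method))
    cat("  method:", x$method$method, "\n")
  invisible(x)
}

#' Taxon-taxon correlation matrix with p-values
#'
#' Pearson or Spearman correlations between all taxon pairs, with two-sided
#' p-values from the t-distribution transform `t = r * sqrt(n-2) /
#' sqrt(1-r^2)` on n-2 degrees of freedom (the classic co-expression
#' network recipe). Spearman ties receive average ranks. Zero-variance taxa
#' get r = 0, p = 1 with a warning rather than NaN.
#'
#' @param table an `abundance_table` with at least 4 samples and 2 taxa.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `R` (taxon x taxon correlations, unit diagonal),
#'   `P` (matching two-sided p-values, 0 on the diagonal), `n_samples`,
#'   `method`.
#' @export
correlation_matrix <- function(table, method = c("pearson", "spearman")) {
  stopifnot(inherits(table, "abundance_table"))
  method <- match.arg(method)
  v <- table$values
  n <- nrow(v)
  if (n < 4L) stop("need >= 4 samples for correlation inference")
  if (ncol(v) < 2L) stop("need >= 2 taxa")
  constant <- apply(v, 2L, function(x) all(x == x[1L]))
  if (any(constant))
    warning("zero-variance taxa reported as r = 0, p = 1: ",
            paste(colnames(v)[constant], collapse = ", "))
  x <- if (method == "spearman") apply(v, 2L, rank) else v
  R <- suppressWarnings(stats::cor(x))
  R[is.na(R)] <- 0
  diag(R) <- 1
  P <- correlation_pvalue(R, n)
  P[constant, ] <- 1
  P[, constant] <- 1
  diag(P) <- 0
  list(R = R, P = P, n_samples = n, method = method)
}

# Two-sided p-value of a correlation via the t transform, n-2 df.
correlation_pvalue <- function(r, n) {
  r2 <- pmin(abs(r), 1)
  tval <- r2 * sqrt(n - 2) / sqrt(pmax(1 - r2^2, 0))
  p <- 2 * stats::pt(tval, df = n - 2, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  pmin(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value collection; thin
#' wrapper over [stats::p.adjust()] kept as the package's single
#' multiplicity-control point.
#'
#' @param p numeric vector (or matrix) of p-values in (0, 1].
#' @param method only `"bh"`.
#' @return q-values with the same shape as `p`.
#' @export
fdr_adjust <- function(p, method = "bh") {
  method <- match.arg(tolower(method), "bh")
  if (length(p) == 0L) return(p)
  if (any(p <= 0 | p > 1, na.rm = TRUE) && !all(p >= 0 & p <= 1))
    stop("p-values must lie in (0, 1]")
  q <- stats::p.adjust(as.vector(p), method = "BH")
  if (is.matrix(p)) q <- matrix(q, nrow(p), ncol(p), dimnames = dimnames(p))
  q
}

#' Threshold a correlation matrix into an association network
#'
#' Retains edge (i, j) iff `|R_ij| > r_min` AND `q_ij < q_max`; the edge
#' weight is the signed correlation. If `Q` is missing it is computed from
#' the upper triangle of `P` by Benjamini-Hochberg.
#'
#' @param cm result of [correlation_matrix()], or a list with elements
#'   `R`, `P` (and optionally `n_samples`, `method`).
#' @param r_min correlation magnitude gate (strict `>`), default 0.6.
#' @param q_max q-value gate (strict `<`), default 0.05.
#' @param Q optional precomputed q-value matrix aligned with `R`.
#' @return An [association_network()] over all taxa of `R`.
#' @export
threshold_network <- function(cm, r_min = 0.6, q_max = 0.05, Q = NULL) {
  R <- cm$R; P <- cm$P
  stopifnot(is.matrix(R), identical(dim(R), dim(P)))
  taxa <- colnames(R)
  ut <- upper.tri(R)
  if (is.null(Q)) {
    Q <- R * 0
    Q[ut] <- fdr_adjust(P[ut])
    Q <- Q + t(Q)
  }
  keep <- ut & abs(R) > r_min & Q < q_max
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(taxon_a = taxa[idx[, 1L]], taxon_b = taxa[idx[, 2L]],
                      weight = R[keep], p_value = P[keep],
                      q_value = Q[keep], stringsAsFactors = FALSE)
  association_network(taxa, edges,
                      method = list(method = cm$method %||% "correlation",
                                    r_min = r_min, q_max = q_max,
                                    n_samples = cm$n_samples %||% NA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Import an externally inferred network from an edge list
#'
#' Accepts the signed edge lists produced by covariance-based inference
#' tools: a TSV with columns `taxon_a`, `taxon_b`, `weight` and optional
#' `p_value`/`q_value` (missing values default to 0 = pre-validated).
#' All network invariants (no self-loops, no duplicates, nonzero weights)
#' are enforced.
#'
#' @param path edge-list TSV path.
#' @param taxa optional node list; defaults to the taxa seen in the edges.
#' @return An [association_network()].
#' @export
import_network <- function(path, taxa = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(taxa)) taxa <- sort(unique(c(df$taxon_a, df$taxon_b)))
  association_network(taxa, df, method = list(method = "imported",
                                              source = path))
}

#' Write an association network as an edge-list TSV plus JSON sidecar
#'
#' @param net an `association_network`
#' @param path edge-list output path; the method metadata is written next
#'   to it as `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "association_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- net$method
  meta$n_taxa <- length(net$taxa)
  meta$n_edges <- nrow(net$edges)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Extract the habitat subnetwork induced by a sample subset
#'
#' Restricts the network to taxa with nonzero total abundance within the
#' selected samples (the composition of that habitat); edge weights are
#' unchanged.
#'
#' @param net an `association_network`
#' @param table the `abundance_table` the network was built from.
#' @param samples character vector, subset of the table's samples.
#' @return An [association_network()] on the occurring taxa.
#' @export
extract_subnetwork <- function(net, table, samples) {
  stopifnot(inherits(net, "association_network"),
            inherits(table, "abundance_table"))
  if (length(samples) == 0L) stop("empty sample subset")
  missing <- setdiff(samples, sample_ids(table))
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  sub <- table$values[samples, , drop = FALSE]
  present <- colnames(sub)[colSums(sub) > 0]
  keep_taxa <- intersect(net$taxa, present)
  e <- net$edges
  e <- e[e$taxon_a %in% keep_taxa & e$taxon_b %in% keep_taxa, ,
         drop = FALSE]
  association_network(keep_taxa, e, method = c(net$method,
                                               list(subset = length(samples))))
}
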