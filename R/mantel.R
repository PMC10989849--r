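#' Mantel test between two distance matrices
#'
#' Correlates the upper-triangle entries of two labelled distance
#' matrices and assesses significance by permuting the labels of the
#' second matrix. The p-value is one-sided (large positive r = distance
#' decay) and includes the identity permutation:
#' `p = (1 + #{perm : r_perm >= r_obs}) / (1 + n_perm)`, so p > 0 always.
#' When the full permutation group is no larger than the requested number
#' of random permutations (`factorial(n) - 1 <= n_perm`), all `n!`
#' relabelings are enumerated instead and `p = #{r_perm >= r_obs} / n!`
#' (the identity is one of them); the result is flagged `exact`.
#'
#' @param d1,d2 `dist` objects (or symmetric matrices) with identical
#'   labels in identical order; n >= 3.
#' @param method `"pearson"` (default) or `"spearman"` (average ranks).
#' @param n_perm number of random permutations, default 999.
#' @param seed integer seed for the permutation stream.
#' @return list with `r`, `p_value`, `n_perm` (permutations actually
#'   used, excluding the identity for the sampled case), `exact`
#'   (logical), `method`.
#' @export
mantel_test <- function(d1, d2, method = c("pearson", "spearman"),
                        n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  if (!identical(dim(m1), dim(m2))) stop("distance matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("distance matrices have mismatched labels")
  n <- nrow(m1)
  if (n < 3L) stop("need at least 3 samples for a Mantel test")
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  if (method == "spearman") {
    v1 <- rank(v1)
    # embed triangle ranks back into a symmetric matrix: relabeling
    # permutes the triangle multiset, so permuted ranks can be looked up
    r2 <- m2 * 0
    r2[ut] <- rank(m2[ut])
    m2 <- r2 + t(r2)
  }
  v2 <- m2[ut]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("zero variance in a distance upper triangle; r undefined")
    return(list(r = 0, p_value = 1, n_perm = 0L, exact = FALSE,
                method = method))
  }
  r_obs <- stats::cor(v1, v2)

  exact <- n <= 170 && factorial(n) - 1 <= n_perm
  if (exact) {
    perms <- all_permutations(n)           # includes the identity
    nperm_used <- nrow(perms)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    perms <- t(replicate(n_perm, sample.int(n)))
    nperm_used <- n_perm
  }
  r_perm <- mantel_perm_cors(v1, m2, perms, ut)
  if (exact) {
    p <- sum(r_perm >= r_obs - 1e-12) / nperm_used
  } else {
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + nperm_used)
  }
  list(r = r_obs, p_value = p, n_perm = nperm_used, exact = exact,
       method = method)
}

# Correlations of v1 with the upper triangle of m2 under each row
# permutation in `perms` (one permutation per row). Vectorised: the
# permuted triangles are gathered into one matrix and correlated in a
# single crossproduct.
mantel_perm_cors <- function(v1, m2, perms, ut) {
  n <- nrow(m2)
  ij <- which(ut, arr.ind = TRUE)
  i <- ij[, 1L]; j <- ij[, 2L]
  V2 <- vapply(seq_len(nrow(perms)), function(k) {
    p <- perms[k, ]
    m2[cbind(p[i], p[j])]
  }, numeric(length(i)))
  drop(stats::cor(v1, V2))
}

# All n! permutations of 1..n, one per row (iterative Heap-free build).
all_permutations <- function(n) {
  out <- matrix(1L, 1L, 1L)
  for (k in 2L:n) {
    nr <- nrow(out)
    grown <- matrix(0L, nr * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1L) * nr + seq_len(nr)
      grown[rows, pos] <- k
      grown[rows, -pos] <- out
    }
    out <- grown
  }
  out
}
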