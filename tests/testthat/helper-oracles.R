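# Independent oracles: deliberately naive implementations kept separate
# from the package's code paths.

# Benjamini-Hochberg step-up by direct definition:
# q_i = min_{j : p_j >= p_i over the sorted order, j >= rank(i)} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(cands))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Two-sided correlation p-value, closed form.
oracle_cor_p <- function(r, n) {
  tval <- abs(r) * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(tval, df = n - 2, lower.tail = FALSE)
}

# Brute-force Mantel over ALL label permutations of d2 (n <= 6): r and
# the exact one-sided p. Permutations generated recursively, matrices
# permuted whole, triangles correlated with cor().
oracle_mantel_exact <- function(d1, d2, method = "pearson") {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  n <- nrow(m1)
  perms <- oracle_perms(n)
  ut <- upper.tri(m1)
  corf <- function(a, b) cor(a, b, method = method)
  v1 <- m1[ut]
  r_obs <- corf(v1, m2[ut])
  rs <- vapply(perms, function(p) {
    mp <- m2[p, p]
    corf(v1, mp[ut])
  }, numeric(1))
  list(r = r_obs, p = sum(rs >= r_obs - 1e-12) / length(perms))
}

oracle_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- oracle_perms(n - 1L)
  out <- list()
  for (p in sub)
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# Triple-loop community strength: for each sample and taxon, average the
# taxon's positive/negative edge weights by scanning the edge list, then
# accumulate abundance-weighted sums.
oracle_strength <- function(rel_values, edges) {
  taxa <- colnames(rel_values)
  pos_c <- neg_c <- setNames(numeric(length(taxa)), taxa)
  for (tx in taxa) {
    pw <- nw <- c()
    for (k in seq_len(nrow(edges))) {
      if (edges$taxon_a[k] == tx || edges$taxon_b[k] == tx) {
        w <- edges$weight[k]
        if (w > 0) pw <- c(pw, w) else nw <- c(nw, w)
      }
    }
    pos_c[tx] <- if (length(pw)) mean(pw) else 0
    neg_c[tx] <- if (length(nw)) mean(nw) else 0
  }
  pos_s <- neg_s <- setNames(numeric(nrow(rel_values)),
                             rownames(rel_values))
  for (s in rownames(rel_values))
    for (tx in taxa) {
      pos_s[s] <- pos_s[s] + rel_values[s, tx] * pos_c[tx]
      neg_s[s] <- neg_s[s] + rel_values[s, tx] * neg_c[tx]
    }
  list(pos_connectedness = pos_c, neg_connectedness = neg_c,
       positive_strength = pos_s, negative_strength = neg_s)
}

# Small labelled abundance fixture with reproducible values.
make_table <- function(n_samples = 10, n_taxa = 15, seed = 42,
                       relative = FALSE) {
  set.seed(seed)
  v <- matrix(rpois(n_samples * n_taxa, lambda = 8) + 0, n_samples,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("t%02d", seq_len(n_taxa))))
  v[1, 1] <- v[1, 1] + 1  # guard against an all-zero first cell pattern
  tab <- abundance_table(v)
  if (relative) to_relative(tab) else tab
}

# Random dist object with labels.
make_dist <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * 3), n)
  rownames(x) <- sprintf("s%02d", seq_len(n))
  dist(x)
}
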