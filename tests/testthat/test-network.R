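test_that("correlation_matrix matches its contracts and the t oracle", {
  set.seed(7)
  v <- matrix(rexp(10 * 4), 10,
              dimnames = list(sprintf("s%d", 1:10), c("a", "b", "c", "d")))
  v[, "b"] <- v[, "a"]            # identical vectors
  v[, "c"] <- max(v[, "a"]) - v[, "a"]  # negation (affine)
  cm <- correlation_matrix(abundance_table(v), method = "pearson")
  expect_equal(cm$R["a", "b"], 1)
  expect_equal(cm$R["a", "c"], -1)
  expect_equal(diag(cm$R), rep(1, 4), ignore_attr = TRUE)
  expect_equal(diag(cm$P), rep(0, 4), ignore_attr = TRUE)

  # closed-form oracle on a random table
  tab <- make_table(n_samples = 30, n_taxa = 8, seed = 11)
  cm2 <- correlation_matrix(tab, method = "pearson")
  for (pair in list(c(1, 2), c(3, 7), c(4, 8))) {
    r <- cm2$R[pair[1], pair[2]]
    expect_equal(cm2$P[pair[1], pair[2]], oracle_cor_p(r, 30),
                 tolerance = 1e-10)
  }
  # spec spot value: r = 0.6, n = 30
  expect_equal(bioticnet:::correlation_pvalue(0.6, 30),
               2 * pt(0.6 * sqrt(28) / sqrt(1 - 0.36), 28,
                      lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("zero-variance taxa yield r = 0, p = 1 with a warning", {
  v <- cbind(a = c(1, 2, 3, 4, 5), b = rep(2, 5), c = c(5, 1, 4, 2, 3))
  rownames(v) <- sprintf("s%d", 1:5)
  expect_warning(cm <- correlation_matrix(abundance_table(v)), "b")
  expect_equal(cm$R["a", "b"], 0)
  expect_equal(cm$P["a", "b"], 1)
  expect_false(anyNA(cm$R))
})

test_that("fdr_adjust equals the brute-force step-up oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_identical(fdr_adjust(numeric()), numeric())
  set.seed(3)
  for (m in c(1, 7, 40)) {
    p <- runif(m)
    expect_equal(fdr_adjust(p), oracle_bh(p), tolerance = 1e-14)
  }
  p <- runif(25)
  expect_true(all(fdr_adjust(p) >= p))
  expect_true(all(diff(fdr_adjust(sort(p))) >= -1e-15))
})

test_that("threshold_network gates on |r| and q and keeps sign", {
  taxa <- c("a", "b", "c")
  R <- diag(3); dimnames(R) <- list(taxa, taxa)
  R["a", "b"] <- R["b", "a"] <- 0.7
  R["a", "c"] <- R["c", "a"] <- -0.8
  R["b", "c"] <- R["c", "b"] <- 0.9
  P <- 1 - diag(3); dimnames(P) <- dimnames(R)
  Q <- matrix(c(0, 0.001, 0.01, 0.001, 0, 0.2, 0.01, 0.2, 0), 3,
              dimnames = dimnames(R))
  net <- threshold_network(list(R = R, P = P), r_min = 0.6, q_max = 0.05,
                           Q = Q)
  expect_identical(nrow(net$edges), 2L)          # b-c fails the q gate
  expect_equal(net$edges$weight[net$edges$taxon_b == "b"], 0.7)
  expect_equal(net$edges$weight[net$edges$taxon_b == "c"], -0.8)

  # monotonicity: tightening either gate never adds edges
  tab <- make_table(n_samples = 20, n_taxa = 12, seed = 5)
  cm <- correlation_matrix(tab)
  base <- nrow(threshold_network(cm, r_min = 0.3, q_max = 0.2)$edges)
  for (r_min in c(0.4, 0.5, 0.7))
    expect_lte(nrow(threshold_network(cm, r_min = r_min,
                                      q_max = 0.2)$edges), base)
  for (q_max in c(0.1, 0.05, 0.01))
    expect_lte(nrow(threshold_network(cm, r_min = 0.3,
                                      q_max = q_max)$edges), base)
})

test_that("association_network enforces invariants", {
  e <- data.frame(taxon_a = c("b", "a"), taxon_b = c("a", "c"),
                  weight = c(0.5, -0.3))
  net <- association_network(c("a", "b", "c"), e)
  expect_identical(net$edges$taxon_a, c("a", "a"))  # canonicalised, sorted
  expect_error(association_network("a", data.frame(
    taxon_a = "a", taxon_b = "a", weight = 1)), "self-loop")
  expect_error(association_network(c("a", "b"), data.frame(
    taxon_a = c("a", "b"), taxon_b = c("b", "a"), weight = c(1, 1))),
    "duplicate")
  expect_error(association_network(c("a", "b"), data.frame(
    taxon_a = "a", taxon_b = "b", weight = 0)), "zero-weight")
})

test_that("networks import from and export to edge-list TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_a\ttaxon_b\tweight",
               "t1\tt2\t0.8", "t2\tt3\t-0.5", "t1\tt4\t0.6"), path)
  net <- import_network(path)
  expect_identical(nrow(net$edges), 3L)
  expect_equal(net$edges$p_value, rep(0, 3))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, out)
  back <- import_network(out)
  expect_equal(back$edges[, 1:3], net$edges[, 1:3])
  expect_true(file.exists(paste0(out, ".meta.json")))

  writeLines(c("taxon_a\ttaxon_b\tweight", "t1\tt1\t0.8"), path)
  expect_error(import_network(path), "self-loop")
})

test_that("extract_subnetwork induces the occurring-taxon subgraph", {
  v <- rbind(s1 = c(a = 1, b = 2, c = 0),
             s2 = c(a = 3, b = 0, c = 0),
             s3 = c(a = 0, b = 0, c = 5))
  tab <- abundance_table(v)
  net <- association_network(c("a", "b", "c"), data.frame(
    taxon_a = c("a", "b"), taxon_b = c("b", "c"), weight = c(0.7, -0.6)))
  sub <- extract_subnetwork(net, tab, c("s1", "s2"))
  expect_setequal(sub$taxa, c("a", "b"))
  expect_identical(nrow(sub$edges), 1L)
  expect_equal(sub$edges$weight, 0.7)

  all_s <- extract_subnetwork(net, tab, rownames(v))
  expect_equal(all_s$edges, net$edges)
  expect_error(extract_subnetwork(net, tab, character()), "empty")
})
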