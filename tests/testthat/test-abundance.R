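test_that("read_abundance honours orientation and round-trips exactly", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tsA\tsB", "t1\t1\t4", "t2\t2\t5", "t3\t3\t6"), tsv)
  tab <- read_abundance(tsv, orientation = "taxa_as_rows")
  expect_identical(sample_ids(tab), c("sA", "sB"))
  expect_identical(taxon_ids(tab), c("t1", "t2", "t3"))
  expect_equal(tab$values["sA", ], c(t1 = 1, t2 = 2, t3 = 3))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(tab, out)
  back <- read_abundance(out, orientation = "samples_as_rows")
  expect_identical(back$values, tab$values)
})

test_that("read_abundance rejects duplicates and non-numeric cells", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tsA\tsB", "t1\t1\t2", "t1\t3\t4"), tsv)
  expect_error(read_abundance(tsv, "taxa_as_rows"), "duplicate")

  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tsA\tsB", "t1\t1\toops"), tsv2)
  expect_error(read_abundance(tsv2, "taxa_as_rows"),
               "non-numeric cell.*row 't1', column 'sB'")
})

test_that("to_relative normalises, is idempotent, rejects zero rows", {
  v <- matrix(c(2, 3, 5, 1, 1, 2), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  rel <- to_relative(abundance_table(v))
  expect_equal(rel$values["s1", ], c(a = 0.2, b = 0.3, c = 0.5))
  expect_true(rel$is_relative)
  again <- to_relative(rel)
  expect_equal(again$values, rel$values, tolerance = 1e-12)

  v0 <- rbind(v, s3 = c(0, 0, 0))
  expect_error(to_relative(abundance_table(v0)), "s3")
})

test_that("filter_taxa applies both occurrence and abundance gates", {
  # 8 samples; each row totals 1e6 via the filler taxon D.
  n <- 8
  A <- c(rep(160000, 3), rep(0, 5))        # 3/8 occ, mean rel 0.06 -> keep
  B <- c(1000, rep(0, 7))                  # 1/8 occ -> drop
  C <- rep(5, n)                           # mean rel 5e-6 < 1e-5 -> drop
  v <- cbind(A = A, B = B, C = C)
  v <- cbind(v, D = 1e6 - rowSums(v))      # 8/8 occ, dominant -> keep
  rownames(v) <- sprintf("s%d", 1:n)
  tab <- abundance_table(v)
  kept <- filter_taxa(tab)
  expect_setequal(taxon_ids(kept), c("A", "D"))
  expect_identical(sample_ids(kept), sample_ids(tab))
  # surviving values are the original counts, not renormalised
  expect_identical(kept$values[, "A"], v[, "A"])

  # idempotence
  twice <- filter_taxa(kept)
  expect_identical(twice$values, kept$values)

  # zero thresholds are the identity when no all-zero taxa exist
  tab2 <- make_table()
  expect_identical(filter_taxa(tab2, 0, 0)$values, tab2$values)

  expect_error(filter_taxa(tab, 1, 0.5), "no taxa survive")
})

test_that("abundance_table enforces its invariants", {
  v <- matrix(1:4, 2, dimnames = list(c("s1", "s2"), c("t1", "t2")))
  expect_silent(abundance_table(v))
  v_neg <- v; v_neg[1] <- -1
  expect_error(abundance_table(v_neg), "negative")
  v_rel <- matrix(c(0.6, 0.5, 0.4, 0.5), 2,
                  dimnames = list(c("s1", "s2"), c("t1", "t2")))
  expect_error(abundance_table(v_rel * 1.2, is_relative = TRUE), "sum to 1")
  expect_silent(abundance_table(v_rel, is_relative = TRUE))
})

test_that("metadata tables round-trip and validate", {
  df <- data.frame(longitude = c(10, 20), latitude = c(1, 2),
                   row.names = c("s1", "s2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(df, path)
  back <- read_metadata(path, required = c("longitude", "latitude"))
  expect_equal(back, df)
  expect_error(read_metadata(path, required = "elevation"), "elevation")
  expect_error(bioticnet:::validate_geo(
    data.frame(longitude = 0, latitude = 91, row.names = "s1")),
    "latitude")
})

test_that("taxonomy tables carry fixed-order ranks", {
  df <- data.frame(phylum = c("Proteobacteria", "Acidobacteriota"),
                   genus = c("Pseudomonas", NA),
                   row.names = c("t1", "t2"))
  tx <- taxonomy_table(df)
  expect_identical(colnames(tx),
                   c("domain", "phylum", "class", "order", "family",
                     "genus", "species"))
  expect_identical(tx["t2", "genus"], "")
  expect_error(taxonomy_table(data.frame(kingdom = "x", row.names = "t1")),
               "unknown rank")

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tphylum\tgenus",
               "t1\tProteobacteria\tPseudomonas",
               "t2\tAcidobacteriota\t"), path)
  back <- read_taxonomy(path)
  expect_identical(back$phylum, tx$phylum)
  writeLines(c("taxon_id\tphylum", "t1\tA", "t1\tB"), path)
  expect_error(read_taxonomy(path), "duplicate")
})
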