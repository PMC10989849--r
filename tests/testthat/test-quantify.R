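worked_net <- function() {
  association_network(c("t1", "t2", "t3"), data.frame(
    taxon_a = c("t1", "t1"), taxon_b = c("t2", "t3"),
    weight = c(0.6, -0.4)))
}

test_that("zero_counts counts absences and conserves totals", {
  v <- rbind(s1 = c(a = 0, b = 1), s2 = c(a = 0, b = 2),
             s3 = c(a = 1, b = 3), s4 = c(a = 0, b = 4))
  tab <- abundance_table(v)
  z <- zero_counts(tab)
  expect_equal(z, c(a = 3, b = 0))
  expect_equal(sum(z), sum(v == 0))
})

test_that("connectedness reproduces the worked 3-taxon example", {
  prof <- connectedness(worked_net(), c("t1", "t2", "t3"))
  expect_equal(prof["t1", "pos_connectedness"], 0.6)
  expect_equal(prof["t1", "neg_connectedness"], -0.4)
  expect_equal(prof["t2", "pos_connectedness"], 0.6)
  expect_equal(prof["t2", "neg_connectedness"], 0)
  expect_equal(prof["t3", "pos_connectedness"], 0)
  expect_equal(prof["t3", "neg_connectedness"], -0.4)
  expect_equal(prof$n_pos_links, c(1L, 1L, 0L))
  expect_equal(prof$n_neg_links, c(1L, 0L, 1L))

  # mean over a taxon's own positive links
  net2 <- association_network(c("a", "b", "c"), data.frame(
    taxon_a = c("a", "a"), taxon_b = c("b", "c"), weight = c(0.8, 0.4)))
  expect_equal(connectedness(net2, c("a", "b", "c"))["a",
                                                     "pos_connectedness"],
               0.6)

  # edgeless network: all zero
  empty <- association_network(c("a", "b"), NULL)
  expect_true(all(connectedness(empty, c("a", "b"))[, 1:2] == 0))
})

test_that("community_strength reproduces the worked example", {
  v <- matrix(c(0.5, 0.3, 0.2), 1,
              dimnames = list("s1", c("t1", "t2", "t3")))
  tab <- abundance_table(v, is_relative = TRUE)
  st <- community_strength(tab, connectedness(worked_net(),
                                              c("t1", "t2", "t3")))
  expect_equal(st["s1", "positive_strength"], 0.48)
  expect_equal(st["s1", "negative_strength"], -0.28)
})

test_that("quantification matches the triple-loop oracle on random fixtures", {
  set.seed(77)
  tab <- to_relative(make_table(10, 15, seed = 77))
  taxa <- taxon_ids(tab)
  pairs <- t(combn(taxa, 2))
  pick <- sample(nrow(pairs), 25)
  edges <- data.frame(taxon_a = pairs[pick, 1], taxon_b = pairs[pick, 2],
                      weight = round(runif(25, -1, 1), 3))
  edges <- edges[edges$weight != 0, ]
  net <- association_network(taxa, edges)
  prof <- connectedness(net, taxa, table = tab)
  st <- community_strength(tab, prof)
  or <- oracle_strength(tab$values, net$edges)
  expect_equal(prof$pos_connectedness, unname(or$pos_connectedness[taxa]),
               tolerance = 1e-12)
  expect_equal(prof$neg_connectedness, unname(or$neg_connectedness[taxa]),
               tolerance = 1e-12)
  expect_equal(st$positive_strength,
               unname(or$positive_strength[sample_ids(tab)]),
               tolerance = 1e-12)
  expect_equal(st$negative_strength,
               unname(or$negative_strength[sample_ids(tab)]),
               tolerance = 1e-12)

  # convexity bound: strengths bounded by the extreme connectedness
  expect_true(all(st$positive_strength <=
                    max(prof$pos_connectedness) + 1e-12))
  expect_true(all(st$negative_strength >=
                    min(prof$neg_connectedness) - 1e-12))
  # sign invariants
  expect_true(all(st$positive_strength >= 0))
  expect_true(all(st$negative_strength <= 0))
})

test_that("community_strength is linear in the connectedness profile", {
  tab <- to_relative(make_table(6, 5, seed = 5))
  taxa <- taxon_ids(tab)
  netA <- association_network(taxa, data.frame(
    taxon_a = "t01", taxon_b = "t02", weight = 0.5))
  netB <- association_network(taxa, data.frame(
    taxon_a = "t03", taxon_b = "t04", weight = -0.7))
  pA <- connectedness(netA, taxa)
  pB <- connectedness(netB, taxa)
  pSum <- pA
  pSum$pos_connectedness <- pA$pos_connectedness + pB$pos_connectedness
  pSum$neg_connectedness <- pA$neg_connectedness + pB$neg_connectedness
  sA <- community_strength(tab, pA)
  sB <- community_strength(tab, pB)
  sSum <- community_strength(tab, pSum)
  expect_equal(sSum$positive_strength,
               sA$positive_strength + sB$positive_strength,
               tolerance = 1e-12)
  expect_equal(sSum$negative_strength,
               sA$negative_strength + sB$negative_strength,
               tolerance = 1e-12)
})

test_that("relative-abundance invariance: rescaling a sample's counts", {
  tab <- make_table(5, 6, seed = 9)
  v2 <- tab$values
  v2["s01", ] <- v2["s01", ] * 2
  taxa <- taxon_ids(tab)
  net <- association_network(taxa, data.frame(
    taxon_a = c("t01", "t02"), taxon_b = c("t03", "t04"),
    weight = c(0.9, -0.6)))
  prof <- connectedness(net, taxa)
  s1 <- suppressMessages(community_strength(tab, prof))
  s2 <- suppressMessages(community_strength(abundance_table(v2), prof))
  expect_equal(s1["s01", ], s2["s01", ], tolerance = 1e-12)
})
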