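test_that("stability overlap curves follow the counting definition", {
  t1 <- feature_table(matrix(c(100L, 5L), 1,
                             dimnames = list("r1", c("AAAA", "CCCC"))))
  t2 <- feature_table(matrix(3L, 1, dimnames = list("r2", "AAAA")))
  cv <- stability_overlap(t1, t2, thresholds = c(1, 10))
  expect_equal(cv$overlap_12, c(0.5, 1.0))
  expect_equal(cv$overlap_21, c(1.0, NaN))

  same <- stability_overlap(t1, feature_table(
    matrix(c(7L, 2L), 1, dimnames = list("x", c("AAAA", "CCCC")))),
    thresholds = c(1, 5, 101))
  expect_equal(same$overlap_12, c(1, 1, NaN))  # no feature reaches 101

  disj <- stability_overlap(t1, feature_table(
    matrix(4L, 1, dimnames = list("y", "GGGG"))), thresholds = 1)
  expect_equal(disj$overlap_12, 0)
})

test_that("unweighted UniFrac reproduces the hand-worked tree", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  tab <- feature_table(matrix(c(1L, 1L, 0L, 0L,
                                0L, 0L, 1L, 1L,
                                1L, 0L, 1L, 0L),
                              nrow = 3, byrow = TRUE,
                              dimnames = list(c("S1", "S2", "S3"),
                                              c("a", "b", "c", "d"))))
  d <- unweighted_unifrac(tab, tree)
  expect_equal(d["S1", "S2"], 1.0)   # disjoint clades share no branches
  expect_equal(d["S1", "S3"], 0.6)   # unique: b, c, (c,d) stem = 3 of 5
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d, t(d))

  ident <- unweighted_unifrac(tab[c(1, 1), , drop = FALSE], tree)
  expect_equal(max(abs(ident)), 0)

  expect_error(
    unweighted_unifrac(feature_table(
      matrix(1L, 1, dimnames = list("S1", "zz"))), tree),
    "zz")
})

test_that("UniFrac matches brute-force branch sets on random instances", {
  for (seed in 1:10) {
    inst <- random_unifrac_instance(seed)
    got <- unweighted_unifrac(inst$table, inst$tree)
    want <- oracle_unifrac(inst$table, inst$tree)
    expect_equal(got, want, tolerance = 1e-12, info = paste("seed", seed))
    # triangle inequality on all triples
    n <- nrow(got)
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      expect_lte(got[i, j], got[i, k] + got[k, j] + 1e-12)
    }
  }
})

test_that("UPGMA on Hamming distances builds the expected dendrogram", {
  # d(A,B) = 2, d(A,C) = d(B,C) = 4 -> ((A,B),C), AB height 1
  A <- "AAAAAA"
  B <- "AAAATT"
  C <- "GGGATA"
  expect_equal(oracle_hamming(A, B), 2)
  expect_equal(oracle_hamming(A, C), 4)
  expect_equal(oracle_hamming(B, C), 4)
  tr <- hamming_upgma(c(A, B, C))
  expect_true(ape::is.ultrametric(tr))
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp[A, B], 2)
  expect_equal(cp[A, C], 4)

  two <- hamming_upgma(c("AAAA", "AATT"))
  expect_equal(unname(ape::cophenetic.phylo(two)["AAAA", "AATT"]), 2)
  expect_equal(ape::node.depth.edgelength(two)[1], 1)  # leaf depth = d/2

  # three equidistant sequences: deterministic first merge by tie-break
  eq <- c("AAAA", "TTTT", "GGGG")
  t1 <- hamming_upgma(eq)
  t2 <- hamming_upgma(rev(eq))
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("Newick files round-trip and malformed input names the offset", {
  f <- withr::local_tempfile(lines = "((a:1,b:1):1,c:2);")
  tr <- read_newick(f)
  expect_identical(sort(tr$tip.label), c("a", "b", "c"))
  f2 <- withr::local_tempfile()
  write_newick(tr, f2)
  tr2 <- read_newick(f2)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  expect_equal(tr2$edge.length, tr$edge.length, tolerance = 1e-10)

  # unlabeled internal nodes accepted
  ok <- withr::local_tempfile(lines = "((a:1,b:2):0.5,(c:1,d:1):2);")
  expect_s3_class(read_newick(ok), "phylo")

  bad <- withr::local_tempfile(lines = "((a:1,b:1):1,c:2));")
  expect_error(read_newick(bad), "character")
})
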