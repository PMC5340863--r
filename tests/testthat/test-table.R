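res_of <- function(id, seqs, counts) {
  subotu:::new_denoise_result(data.frame(sequence = seqs,
                                         count = as.integer(counts)),
                              character(0), id)
}

rand_table <- function(seed, n_samp = 3, n_feat = 6, L = 12) {
  withr::with_seed(seed, {
    feats <- replicate(n_feat, rand_seq(L))
    while (anyDuplicated(feats)) feats <- replicate(n_feat, rand_seq(L))
    m <- matrix(rbinom(n_samp * n_feat, 30, 0.4), n_samp,
                dimnames = list(paste0("s", seed, "_", 1:n_samp), feats))
    feature_table(m)
  })
}

test_that("tables assemble from per-sample results keyed by sequence", {
  A <- strrep("ACGT", 5)
  B <- strrep("TTGA", 5)
  t1 <- build_table(list(res_of("s1", A, 5), res_of("s2", A, 7)))
  expect_identical(dim(unclass(t1)), c(2L, 1L))
  expect_identical(unname(unclass(t1)[, A]), c(5L, 7L))

  t2 <- build_table(list(res_of("s1", A, 5), res_of("s2", B, 7)))
  expect_identical(dim(unclass(t2)), c(2L, 2L))
  expect_identical(sum(unclass(t2) == 0L), 2L)

  t3 <- build_table(list(res_of("s1", A, 5),
                         res_of("s2", character(0), integer(0))))
  expect_identical(unname(unclass(t3)["s2", ]), 0L)

  expect_error(build_table(list(res_of("s1", A, 5), res_of("s1", B, 2))),
               "duplicate")
})

test_that("the minimum-count filter is strictly 'fewer than'", {
  m <- matrix(c(9L, 10L, 11L), nrow = 1,
              dimnames = list("s1", c("AAAA", "CCCC", "GGGG")))
  t <- feature_table(m)
  expect_identical(colnames(filter_min_count(t, 10)), c("CCCC", "GGGG"))
  expect_identical(unclass(filter_min_count(t, 0)), unclass(t))
  expect_identical(ncol(filter_min_count(t, 100)), 0L)
})

test_that("merging matches features by exact sequence across runs", {
  A <- strrep("ACGT", 3)
  B <- strrep("TTGA", 3)
  r1 <- build_table(list(res_of("r1s1", A, 5)))
  r2 <- build_table(list(res_of("r2s1", A, 9)))
  m <- merge_tables(list(r1, r2))
  expect_identical(ncol(m), 1L)
  expect_identical(unname(unclass(m)[, A]), c(5L, 9L))

  r3 <- build_table(list(res_of("r3s1", B, 4)))
  blk <- merge_tables(list(r1, r3))
  expect_identical(sum(unclass(blk) == 0L), 2L)

  expect_error(merge_tables(list(r1, build_table(list(res_of("r1s1", B, 1))))),
               "overlapping")
})

test_that("trim-to-common truncates features and sums collapsed prefixes", {
  long1 <- paste0(strrep("A", 10), "CCGG")   # 14 nt
  long2 <- paste0(strrep("A", 10), "TTAA")   # same 10-nt prefix
  short <- strrep("A", 10)
  r150 <- build_table(list(res_of("x1", c(long1, long2), c(5, 7))))
  r125 <- build_table(list(res_of("y1", short, 9)))
  m <- merge_tables(list(r150, r125), trim_to_common = TRUE)
  expect_identical(colnames(m), short)
  expect_identical(unname(unclass(m)[, short]), c(12L, 9L))
})

test_that("merging on exact ids is associative and order-independent", {
  a <- rand_table(1)
  b <- rand_table(2)
  c <- rand_table(3)
  m1 <- merge_tables(list(a, merge_tables(list(b, c))))
  m2 <- merge_tables(list(merge_tables(list(a, b)), c))
  m3 <- merge_tables(list(c, a, b))
  norm <- function(t) {
    m <- unclass(t)
    m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  }
  expect_identical(norm(m1), norm(m2))
  expect_identical(norm(m1), norm(m3))
})

test_that("merge-then-filter equals filter-after-merge at equal thresholds", {
  a <- rand_table(4)
  b <- rand_table(5)
  direct <- filter_min_count(merge_tables(list(a, b)), 25)
  twice <- filter_min_count(filter_min_count(merge_tables(list(a, b)), 25), 25)
  expect_identical(unclass(direct), unclass(twice))
})

test_that("rarefaction subsamples exactly to depth, deterministically", {
  m <- matrix(c(3000L, 1999L, 2L, 4998L, 0L, 1L,
                2500L, 2500L, 1000L),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"),
                              c("AAAA", "CCCC", "GGGG")))
  t <- feature_table(m)
  r <- rarefy_table(t, 5000, seed = 9)
  expect_identical(rownames(unclass(r)), c("a", "c"))  # b is below depth
  expect_true(all(rowSums(unclass(r)) == 5000L))
  expect_true(all(colnames(r) %in% colnames(t)))
  r2 <- rarefy_table(t, 5000, seed = 9)
  expect_identical(unclass(r), unclass(r2))
  expect_false(identical(unclass(r),
                         unclass(rarefy_table(t, 5000, seed = 10))))

  # depth equal to a sample's total leaves it unchanged
  one <- feature_table(m["a", , drop = FALSE])
  expect_identical(unclass(rarefy_table(one, sum(m["a", ]), seed = 1)),
                   unclass(one)[, unclass(one)[1, ] > 0, drop = FALSE])
})

test_that("BIOM and TSV round-trips preserve the table", {
  t <- rand_table(6)
  fb <- withr::local_tempfile(fileext = ".biom")
  write_table(t, fb, "biom")
  expect_identical(norm_tab(read_table_file(fb, "biom")), norm_tab(t))

  ft <- withr::local_tempfile(fileext = ".tsv")
  write_table(t, ft, "tsv")
  expect_identical(norm_tab(read_table_file(ft, "tsv")), norm_tab(t))
  # orientation: features as rows -> one header line plus one line per feature
  expect_length(readLines(ft), ncol(t) + 1L)
})
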