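test_that("error profiles validate probabilities and monotonicity", {
  p <- error_profile(c(1, 0.06, 0.02, 0.01))
  expect_length(p, 4L)
  expect_error(error_profile(c(1, 0.02, 0.06)), "non-increasing")
  expect_warning(p2 <- error_profile(c(0.5, 0.06)), "overridden")
  expect_equal(unclass(p2)[1], 1)
  expect_error(error_profile(c(1, -0.1)), "probabilities")
})

test_that("error profiles load from one- and two-column text files", {
  f <- withr::local_tempfile(lines = "1 0.06 0.02 0.01")
  p <- load_error_profile(f)
  expect_equal(as.numeric(p), c(1, 0.06, 0.02, 0.01))

  f2 <- withr::local_tempfile(lines = c("0 1", "2 0.02", "1 0.06"))
  expect_equal(as.numeric(load_error_profile(f2)), c(1, 0.06, 0.02))

  f3 <- withr::local_tempfile(lines = "1 0.06 0.2")  # E[2] > E[1]
  expect_error(load_error_profile(f3), "non-increasing")
  expect_error(load_error_profile("/no/such/profile.txt"), "profile")

  shipped <- system.file("extdata", "error_profile_default.txt",
                         package = "subotu")
  expect_equal(as.numeric(load_error_profile(shipped)),
               as.numeric(default_error_profile()))
})

test_that("mod factor is the error-free read probability", {
  expect_equal(mod_factor(denoise_params(mean_error = 0, read_length = 150)),
               1)
  expect_equal(mod_factor(denoise_params(read_length = 150)),
               0.995^150)
  expect_equal(mod_factor(denoise_params(read_length = 100)),
               0.995^100, tolerance = 1e-12)
  expect_equal(round(mod_factor(denoise_params(read_length = 100)), 5),
               0.60577)
})

test_that("predicted errors scale residuals by E[h]/M and clamp past H", {
  prof <- error_profile(c(1, 0.06, 0.02))
  par <- denoise_params(read_length = 100)
  v <- predicted_errors(100, prof, par, max_h = 5)
  expect_equal(v[2], 100 * 0.06 / 0.995^100, tolerance = 1e-12)
  expect_equal(round(v[2], 3), 9.905)
  expect_equal(v[4], v[3])  # h = 3 clamps to H = 2
  expect_equal(v[6], v[3])
  expect_error(predicted_errors(0, prof, par, 3))
})

test_that("the greedy core reproduces the worked two-sequence cases", {
  prof <- error_profile(c(1, 0.06))
  par <- denoise_params(read_length = 100)
  A <- strrep("A", 100)
  B <- paste0(strrep("A", 99), "C")  # h = 1 from A

  ws <- center_star_msa(data.frame(sequence = c(A, B), count = c(100L, 4L)))
  res <- deblur_sample(ws, prof, par)
  expect_identical(res$retained$sequence, A)
  expect_identical(res$retained$count, 100L)
  expect_identical(res$removed, B)

  ws2 <- center_star_msa(data.frame(sequence = c(A, B), count = c(100L, 50L)))
  res2 <- deblur_sample(ws2, prof, par)
  expect_identical(res2$retained$count[res2$retained$sequence == B], 40L)

  single <- deblur_sample(center_star_msa(
    data.frame(sequence = "ACGTACGT", count = 50L)), prof,
    denoise_params(read_length = 8))
  expect_identical(single$retained$count, 50L)
})

test_that("a zero error profile reproduces the input exactly", {
  for (seed in 1:5) {
    inst <- random_deblur_instance(seed)
    ws <- center_star_msa(inst$derep)
    res <- deblur_sample(ws, error_profile(c(1, 0, 0)),
                         denoise_params(read_length = inst$read_length))
    expect_setequal(res$retained$sequence, inst$derep$sequence)
    expect_identical(
      res$retained$count[match(inst$derep$sequence, res$retained$sequence)],
      inst$derep$count)
  }
})

test_that("subtraction-only: outputs never exceed inputs", {
  for (seed in 1:10) {
    inst <- random_deblur_instance(seed)
    ws <- center_star_msa(inst$derep)
    res <- deblur_sample(ws, error_profile(inst$profile),
                         denoise_params(inst$mean_error, inst$indel_prob,
                                        inst$indel_max, inst$read_length))
    m <- match(res$retained$sequence, inst$derep$sequence)
    expect_true(all(res$retained$count <= inst$derep$count[m]))
    expect_lte(sum(res$retained$count), sum(inst$derep$count))
  }
})

test_that("raising an upper bound deepens the subtraction where no cascade intervenes", {
  # predicted errors are monotone in the profile at every distance
  par <- denoise_params(read_length = 30)
  lo <- error_profile(c(1, 0.02, 0.01))
  hi <- error_profile(c(1, 0.06, 0.03))
  expect_true(all(predicted_errors(50, hi, par, 6)[-1] >=
                    predicted_errors(50, lo, par, 6)[-1]))

  # on a two-sequence workspace (no removed-source feedback) the
  # neighbour's retained count is non-increasing in E[1]
  A <- strrep("A", 30)
  B <- paste0(strrep("A", 29), "T")
  ws <- center_star_msa(data.frame(sequence = c(A, B), count = c(100L, 60L)))
  counts_b <- vapply(c(0.01, 0.05, 0.1, 0.2), function(e1) {
    res <- deblur_sample(ws, error_profile(c(1, e1)), par)
    out <- res$retained$count[res$retained$sequence == B]
    if (length(out) == 0L) 0L else out
  }, integer(1))
  expect_true(all(diff(counts_b) <= 0L))
})

test_that("the greedy core matches the brute-force oracle bit for bit", {
  for (seed in 1:40) {
    inst <- random_deblur_instance(seed)
    ws <- center_star_msa(inst$derep)
    res <- deblur_sample(ws, error_profile(inst$profile),
                         denoise_params(inst$mean_error, inst$indel_prob,
                                        inst$indel_max, inst$read_length))
    exp <- oracle_deblur(ws$gapped, ws$counts, inst$profile,
                         inst$mean_error, inst$indel_prob,
                         inst$indel_max, inst$read_length)
    o <- order(res$retained$sequence)
    expect_identical(res$retained$sequence[o], exp$sequences,
                     info = paste("seed", seed))
    expect_identical(res$retained$count[o], exp$counts,
                     info = paste("seed", seed))
  }
})

test_that("well-separated simulated communities are recovered exactly", {
  for (seed in 1:3) {
    tc <- make_truth_community(12, 60, min_hamming = 10, seed = seed)
    sr <- simulate_reads(tc, 4000, sub_rate = 0.001, seed = seed + 50)
    res <- denoise_one_sample(sr, pipeline_config(trim_length = 60))
    sc <- score_against_truth(res, tc)
    expect_equal(sc$recall, 1)
    expect_equal(sc$precision, 1)
  }
})
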