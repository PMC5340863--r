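# Programmatic fixtures: everything is generated in code at test time.

rand_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                              collapse = "")

mutate_seq <- function(s, nmut) {
  v <- strsplit(s, "")[[1]]
  for (p in sample(length(v), nmut)) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}

# A cluster-structured random instance: a few founder sequences plus close
# mutants, with random counts, returned as an aligned workspace plus a
# random valid error profile and parameters. Used to exercise the greedy
# core against the brute-force oracle.
random_deblur_instance <- function(seed, max_seqs = 30L, L = 30L) {
  withr::with_seed(seed, {
    n_founders <- sample(2:5, 1)
    seqs <- character(0)
    founders <- replicate(n_founders, rand_seq(L))
    seqs <- founders
    while (length(seqs) < max_seqs) {
      cand <- mutate_seq(sample(founders, 1), sample(1:4, 1))
      seqs <- c(seqs, cand)
    }
    seqs <- unique(seqs)[seq_len(min(max_seqs, length(unique(seqs))))]
    counts <- sample(2:200, length(seqs), replace = TRUE)
    H <- sample(3:8, 1)
    prof_tail <- sort(runif(H, 0, 0.08), decreasing = TRUE)
    list(
      derep = data.frame(sequence = seqs, count = counts),
      profile = c(1, prof_tail),
      mean_error = runif(1, 0.001, 0.01),
      indel_prob = runif(1, 0.005, 0.05),
      indel_max = sample(0:4, 1),
      read_length = L
    )
  })
}

write_temp_fasta <- function(seqs, names = paste0("r", seq_along(seqs)),
                             ext = ".fasta") {
  f <- withr::local_tempfile(fileext = ext,
                             .local_envir = parent.frame())
  writeLines(rbind(paste0(">", names), seqs), f)
  f
}

write_temp_fastq <- function(seqs, quals = NULL,
                             names = paste0("r", seq_along(seqs))) {
  f <- withr::local_tempfile(fileext = ".fastq",
                             .local_envir = parent.frame())
  if (is.null(quals)) quals <- vapply(nchar(seqs), strrep, x = "I", "")
  writeLines(rbind(paste0("@", names), seqs, "+", quals), f)
  f
}

norm_tab <- function(t) {
  m <- unclass(t)
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

# A random rooted tree over the given feature sequences plus a random
# presence table, for UniFrac oracle checks.
random_unifrac_instance <- function(seed, n_feats = 8L, n_samps = 4L) {
  withr::with_seed(seed, {
    feats <- replicate(n_feats, rand_seq(12))
    while (anyDuplicated(feats)) feats <- replicate(n_feats, rand_seq(12))
    tree <- ape::rtree(n_feats, tip.label = feats)
    m <- matrix(rbinom(n_samps * n_feats, 3, 0.45),
                nrow = n_samps,
                dimnames = list(paste0("s", seq_len(n_samps)), feats))
    # ensure every sample observes at least one feature
    for (i in seq_len(n_samps)) {
      if (sum(m[i, ]) == 0L) m[i, sample(n_feats, 1)] <- 1L
    }
    list(table = feature_table(m), tree = tree)
  })
}
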