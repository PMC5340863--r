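# Simulation apparatus: ground-truth communities with a controlled
# similarity radius, an error-prone read simulator, and scoring of denoised
# output against the truth.

#' Simulate a ground-truth community
#'
#' Draws `k` unique sequences of the given length whose pairwise Hamming
#' distances are all at least `min_hamming`. To make `min_hamming` behave as
#' a similarity *radius* (communities genuinely containing close pairs, not
#' merely permitting them), half of the sequences after the first are
#' derived from a randomly chosen earlier sequence by substituting exactly
#' `min_hamming` positions; the rest are drawn uniformly at random. Every
#' candidate is rejected unless it keeps all pairwise distances at or above
#' `min_hamming`. Relative abundances are uniform or lognormal
#' (`meanlog = 0`, `sdlog = 1`), normalised to sum to 1.
#'
#' @param k Number of sequences.
#' @param length Sequence length.
#' @param min_hamming Minimum pairwise Hamming distance (the similarity
#'   radius).
#' @param abundance_model `"uniform"` or `"lognormal"`.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling attempts per sequence before
#'   declaring the constraint infeasible.
#' @return An object of class `truth_community`: a list with `sequences`,
#'   `rel_abundances` and `similarity_radius` (the realised minimum
#'   pairwise distance).
#' @export
make_truth_community <- function(k, length, min_hamming = 1L,
                                 abundance_model = c("lognormal", "uniform"),
                                 seed = 1L, max_tries = 1000L) {
  abundance_model <- match.arg(abundance_model)
  stopifnot(k >= 1, length >= 1, min_hamming >= 0, min_hamming <= length)
  with_seed(seed, {
    seqs <- character(k)
    seqs[1L] <- paste(sample(DNA_BASES, length, replace = TRUE),
                      collapse = "")
    i <- 2L
    while (i <= k) {
      derive <- min_hamming >= 1L && (i %% 2L == 0L)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- if (derive) {
          mutate_at_distance(seqs[sample.int(i - 1L, 1L)], min_hamming)
        } else {
          paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
        }
        d <- vapply(seqs[seq_len(i - 1L)], hamming_distance, integer(1),
                    b = cand, USE.NAMES = FALSE)
        if (all(d >= max(min_hamming, 1L))) {
          seqs[i] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not satisfy min_hamming = ", min_hamming,
             " for k = ", k, ", length = ", length)
      }
      i <- i + 1L
    }
    ab <- switch(abundance_model,
                 uniform = rep(1, k),
                 lognormal = rlnorm(k, meanlog = 0, sdlog = 1))
    radius <- if (k >= 2L) {
      min(vapply(utils::combn(k, 2L, simplify = FALSE),
                 function(p) hamming_distance(seqs[p[1L]], seqs[p[2L]]),
                 integer(1)))
    } else NA_integer_
    structure(list(sequences = seqs, rel_abundances = ab / sum(ab),
                   similarity_radius = radius),
              class = "truth_community")
  })
}

hamming_distance <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(av) == length(bv))
  sum(av != bv)
}

mutate_at_distance <- function(seq, d) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample.int(length(v), d)
  for (p in pos) {
    v[p] <- sample(setdiff(DNA_BASES, v[p]), 1L)
  }
  paste(v, collapse = "")
}

#' Simulate error-prone amplicon reads from a truth community
#'
#' A minimal Illumina-like error model: each read's source sequence is drawn
#' from the community's relative abundances; every position is substituted
#' independently with probability `sub_rate` (uniform over the three
#' alternative bases); insertions and deletions occur per nucleotide at
#' `ins_rate` and `del_rate`. Reads are emitted at their natural length
#' (trimming is a downstream stage). Deterministic for a given seed.
#'
#' @param truth A [make_truth_community()] object.
#' @param n_reads Number of reads.
#' @param sub_rate Per-nucleotide substitution probability (default 0.001,
#'   i.e. the 0.1% error rate typical of Illumina 16S data).
#' @param ins_rate,del_rate Per-nucleotide indel probabilities (default
#'   5e-05 each).
#' @param seed Integer seed.
#' @param sample_id Sample id for the returned reads.
#' @return A [sample_reads()] object with attribute `sources` giving each
#'   read's truth-sequence index.
#' @export
simulate_reads <- function(truth, n_reads, sub_rate = 0.001,
                           ins_rate = 5e-05, del_rate = 5e-05,
                           seed = 1L, sample_id = "sim") {
  stopifnot(n_reads >= 1, sub_rate >= 0, sub_rate < 1,
            ins_rate >= 0, ins_rate < 1, del_rate >= 0, del_rate < 1)
  k <- length(truth$sequences)
  L <- nchar(truth$sequences[1L])
  with_seed(seed, {
    src <- sample.int(k, n_reads, replace = TRUE,
                      prob = truth$rel_abundances)
    cm <- seq_char_matrix(truth$sequences)[src, , drop = FALSE]
    # substitutions, vectorised over the whole read matrix
    mask <- matrix(runif(n_reads * L) < sub_rate, n_reads, L)
    nsub <- sum(mask)
    if (nsub > 0L) {
      cur <- match(cm[mask], DNA_BASES)
      alt <- matrix(c(2L, 1L, 1L, 1L, 3L, 3L, 2L, 2L, 4L, 4L, 4L, 3L),
                    nrow = 4L)  # alt[base, 1:3]: the three other bases
      cm[mask] <- DNA_BASES[alt[cbind(cur, sample.int(3L, nsub,
                                                      replace = TRUE))]]
    }
    reads <- collapse_rows(cm)
    # indels are rare: handle only the affected reads
    n_ins <- rbinom(n_reads, L, ins_rate)
    n_del <- rbinom(n_reads, L, del_rate)
    touched <- which(n_ins > 0L | n_del > 0L)
    for (i in touched) {
      v <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
      if (n_del[i] > 0L) {
        v <- v[-sample.int(length(v), min(n_del[i], length(v) - 1L))]
      }
      for (j in seq_len(n_ins[i])) {
        at <- sample.int(length(v) + 1L, 1L)
        v <- append(v, sample(DNA_BASES, 1L), after = at - 1L)
      }
      reads[i] <- paste(v, collapse = "")
    }
    out <- sample_reads(sample_id, reads)
    attr(out, "sources") <- src
    out
  })
}

#' Score a denoised result against the simulation ground truth
#'
#' @param result A `denoise_result`.
#' @param truth A `truth_community`; its sequences are truncated to the
#'   retained read length (and deduplicated) before comparison, so the
#'   truth is expressed in the same coordinates the denoiser saw.
#' @return A list with `recall`, `precision`, `observed_ratio`
#'   (retained/truth feature counts), `empty` (TRUE when nothing was
#'   retained; precision is then reported as 0), and `truth_abundance`, a
#'   data frame of per-truth-sequence retained counts.
#' @export
score_against_truth <- function(result, truth) {
  retained <- result$retained$sequence
  L <- if (length(retained) > 0L) nchar(retained[1L]) else
    nchar(truth$sequences[1L])
  truth_set <- unique(substr(truth$sequences, 1L, L))
  hit <- intersect(retained, truth_set)
  empty <- length(retained) == 0L
  list(
    recall = length(hit) / length(truth_set),
    precision = if (empty) 0 else length(hit) / length(retained),
    observed_ratio = length(retained) / length(truth_set),
    empty = empty,
    truth_abundance = data.frame(
      sequence = truth_set,
      count = result$retained$count[match(truth_set, retained)]
    )
  )
}
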