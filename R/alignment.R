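# Per-sample alignment: global pairwise alignment plus a center-star MSA
# used only to detect the rare indels between same-length amplicon reads.

#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Deterministic global alignment with linear gap costs. The defaults
#' (match +1, mismatch -1.5, gap -3) deliberately discourage gaps between
#' reads that are trimmed to identical length, where true indels are rare.
#' Traceback ties are resolved by preferring the diagonal move, then the
#' vertical (gap in `b`), then the horizontal (gap in `a`), so results are
#' reproducible across platforms.
#'
#' @param a,b Gap-free nucleotide strings.
#' @param match,mismatch,gap Alignment scores; `gap` is the per-column gap
#'   penalty (no affine extension).
#' @return A list with elements `a` and `b` (equal-length gapped strings)
#'   and `score` (the optimal alignment score).
#' @export
#' @examples
#' pairwise_align("ACGTA", "ACTA")
pairwise_align <- function(a, b, match = 1, mismatch = -1.5, gap = -3) {
  stopifnot(nzchar(a), nzchar(b), !grepl("-", a), !grepl("-", b))
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av)
  m <- length(bv)
  H <- matrix(0, n + 1L, m + 1L)
  H[1L, ] <- gap * (0:m)
  H[, 1L] <- gap * (0:n)
  jj <- seq_len(m)
  # row recurrence: the horizontal (left) dependency is absorbed into a
  # running maximum, making each row fully vectorised:
  #   H[i,j] = gap*j + max_{k<=j} (cand[k] - gap*k)
  for (i in seq_len(n)) {
    s <- ifelse(bv == av[i], match, mismatch)
    cand <- pmax(H[i, jj] + s, H[i, jj + 1L] + gap)   # diag, up
    c0 <- c(H[i + 1L, 1L], cand)
    H[i + 1L, ] <- gap * (0:m) + cummax(c0 - gap * (0:m))
  }
  # traceback with fixed tie preference: diagonal > up > left
  ga <- character(0)
  gb <- character(0)
  i <- n
  j <- m
  while (i > 0L || j > 0L) {
    h <- H[i + 1L, j + 1L]
    if (i > 0L && j > 0L &&
        h == H[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      ga <- c(av[i], ga); gb <- c(bv[j], gb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && h == H[i, j + 1L] + gap) {
      ga <- c(av[i], ga); gb <- c("-", gb); i <- i - 1L
    } else {
      ga <- c("-", ga); gb <- c(bv[j], gb); j <- j - 1L
    }
  }
  list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""),
       score = H[n + 1L, m + 1L])
}

#' Substitution and indel counts between two aligned sequences
#'
#' Scans two equal-length gapped strings column by column: a column with two
#' differing bases is a substitution; a column where exactly one member is a
#' gap is an indel position (a run of g one-sided gap columns counts as g);
#' columns with two gaps contribute nothing.
#'
#' @param ga,gb Equal-length strings over `{A,C,G,T,N,-}`.
#' @return A list with integer elements `substitutions` and
#'   `indel_positions`.
#' @export
pair_distance <- function(ga, gb) {
  if (nchar(ga) != nchar(gb)) {
    stop("aligned sequences must have equal gapped lengths")
  }
  ca <- strsplit(ga, "", fixed = TRUE)[[1L]]
  cb <- strsplit(gb, "", fixed = TRUE)[[1L]]
  gap_a <- ca == "-"
  gap_b <- cb == "-"
  list(substitutions = sum(ca != cb & !gap_a & !gap_b),
       indel_positions = sum(xor(gap_a, gap_b)))
}

#' Center-star multiple sequence alignment of dereplicated reads
#'
#' Aligns every sequence pairwise to the most abundant one (the "center";
#' count ties broken lexicographically) and merges the pairwise alignments
#' under the "once a gap, always a gap" rule: the merged alignment inserts,
#' between consecutive center residues, as many gap columns as the widest
#' insertion observed there in any pairwise alignment. Inserted residues are
#' left-justified within their block. This is adequate for same-length
#' amplicon reads, where indels are rare and alignment exists only to make
#' them countable.
#'
#' A gapped alignment to the center is accepted only when its residual
#' substitutions plus indel columns amount to at most half the ungapped
#' Hamming distance of the pair; otherwise the identity (column-for-column)
#' alignment is kept. A genuine frame shift passes this test by a wide
#' margin, while the opportunistic gaps an optimal aligner finds between
#' highly divergent same-length sequences never halve the apparent
#' divergence. Without this rule, distantly related sequences would be
#' aligned inconsistently to the center, and true one-substitution
#' neighbours could inherit spurious indel columns in the merged alignment.
#'
#' @param derep Data frame with columns `sequence` and `count`, as returned
#'   by [dereplicate()] (equal ungapped lengths; already sorted by count
#'   descending, sequence ascending — re-sorted defensively here).
#' @param match,mismatch,gap Scores passed to [pairwise_align()].
#' @return An object of class `aligned_workspace`: a list with parallel
#'   elements `gapped` (strings over `{A,C,G,T,N,-}`, equal lengths),
#'   `sequences` (the originals), `counts` and `residuals` (initialised to
#'   `counts`), plus `sample_id` (`NA` unless set by the caller).
#' @export
center_star_msa <- function(derep, match = 1, mismatch = -1.5, gap = -3) {
  stopifnot(nrow(derep) >= 1L)
  if (length(unique(nchar(derep$sequence))) != 1L) {
    stop("dereplicated sequences must have equal ungapped lengths")
  }
  ord <- order(-derep$count, derep$sequence, method = "radix")
  seqs <- derep$sequence[ord]
  counts <- as.integer(derep$count[ord])
  k <- length(seqs)
  center <- seqs[1L]
  n <- nchar(center)

  if (k == 1L) {
    return(new_workspace(seqs, seqs, counts))
  }

  # per-sequence alignment to the center, decomposed against center slots:
  # slot p (0..n) holds residues inserted before center residue p+1.
  aln <- vector("list", k - 1L)
  ins_width <- integer(n + 1L)
  center_chars <- strsplit(center, "", fixed = TRUE)[[1L]]
  for (idx in 2:k) {
    s_chars <- strsplit(seqs[idx], "", fixed = TRUE)[[1L]]
    subs_identity <- sum(center_chars != s_chars)
    use_gapped <- FALSE
    if (subs_identity >= 4L) {
      pa <- pairwise_align(center, seqs[idx], match, mismatch, gap)
      d <- pair_distance(pa$a, pa$b)
      use_gapped <- 2L * (d$substitutions + d$indel_positions) <=
        subs_identity
    }
    if (!use_gapped) {
      pa <- list(a = center, b = seqs[idx])
    }
    cc <- strsplit(pa$a, "", fixed = TRUE)[[1L]]
    cs <- strsplit(pa$b, "", fixed = TRUE)[[1L]]
    slots <- vector("list", n + 1L)
    for (p in 0:n) slots[[p + 1L]] <- character(0)
    matched <- character(n)
    p <- 0L
    for (col in seq_along(cc)) {
      if (cc[col] == "-") {
        slots[[p + 1L]] <- c(slots[[p + 1L]], cs[col])
      } else {
        p <- p + 1L
        matched[p] <- cs[col]
      }
    }
    aln[[idx - 1L]] <- list(slots = slots, matched = matched)
    ins_width <- pmax(ins_width, lengths(slots))
  }

  assemble <- function(slots, matched) {
    parts <- character(2L * n + 1L)
    for (p in 0:n) {
      blk <- slots[[p + 1L]]
      parts[2L * p + 1L] <- paste0(
        paste(blk, collapse = ""),
        strrep("-", ins_width[p + 1L] - length(blk)))
      if (p < n) parts[2L * p + 2L] <- matched[p + 1L]
    }
    paste(parts, collapse = "")
  }

  center_slots <- lapply(seq_len(n + 1L), function(p) character(0))
  gapped <- c(assemble(center_slots, strsplit(center, "", fixed = TRUE)[[1L]]),
              vapply(aln, function(x) assemble(x$slots, x$matched),
                     character(1)))
  new_workspace(gapped, seqs, counts)
}

new_workspace <- function(gapped, sequences, counts, sample_id = NA_character_) {
  stopifnot(length(unique(nchar(gapped))) <= 1L,
            identical(ungap(gapped), sequences))
  structure(list(gapped = gapped, sequences = sequences,
                 counts = counts, residuals = as.numeric(counts),
                 sample_id = sample_id),
            class = "aligned_workspace")
}

#' @export
print.aligned_workspace <- function(x, ...) {
  cat(sprintf("<aligned_workspace> %d sequences, gapped length %d\n",
              length(x$gapped),
              if (length(x$gapped)) nchar(x$gapped[1L]) else 0L))
  invisible(x)
}

#' Import an externally computed multiple sequence alignment
#'
#' Builds an `aligned_workspace` from an aligned FASTA (for parity
#' experiments with external aligners) together with the counts of the
#' ungapped sequences.
#'
#' @param path Aligned FASTA; records may contain `-` gap characters.
#' @param counts Integer vector parallel to the records.
#' @return An `aligned_workspace`.
#' @export
read_aligned_fasta <- function(path, counts) {
  ss <- Biostrings::readBStringSet(path)
  gapped <- toupper(unname(as.character(ss)))
  if (length(gapped) != length(counts)) {
    stop("counts must be parallel to the alignment records")
  }
  new_workspace(gapped, ungap(gapped), as.integer(counts))
}
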