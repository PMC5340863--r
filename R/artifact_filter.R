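# Reference-based artifact depletion via k-mer containment: keep matches to
# known 16S (positive mode) or remove matches to known artifacts such as
# PhiX (negative mode). A deterministic containment screen is used instead
# of an external aligner so the pipeline is self-contained.

#' Build a reference k-mer screen
#'
#' Indexes every k-mer of every reference sequence, on both strands. A query
#' "matches" the screen when at least `min_fraction` of its (forward)
#' k-mers occur in the index; indexing both strands makes the verdict
#' strand-symmetric.
#'
#' @param refs Path to a reference FASTA, or a character vector of reference
#'   sequences.
#' @param k K-mer size (default 16).
#' @param mode `"positive"` (keep matches) or `"negative"` (remove matches).
#' @param min_fraction Fraction of a query's k-mers that must be indexed to
#'   call a match (default 0.5).
#' @return An object of class `reference_screen`.
#' @export
build_screen <- function(refs, k = 16L, mode = c("positive", "negative"),
                         min_fraction = 0.5) {
  mode <- match.arg(mode)
  stopifnot(min_fraction > 0, min_fraction <= 1, k >= 1)
  if (is.character(refs) && length(refs) == 1L && file.exists(refs)) {
    refs <- as.character(Biostrings::readDNAStringSet(refs))
  }
  refs <- toupper(unname(refs))
  if (length(refs) == 0L) stop("reference set is empty")
  if (all(nchar(refs) < k)) {
    stop("k = ", k, " exceeds the length of every reference sequence")
  }
  both <- c(refs, reverse_complement(refs))
  kmers <- unique(unlist(lapply(both, seq_kmers, k = k), use.names = FALSE))
  structure(list(kmers = kmers, k = as.integer(k), mode = mode,
                 min_fraction = min_fraction),
            class = "reference_screen")
}

seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(x, starts, starts + k - 1L)
}

#' Screen dereplicated sequences against a reference
#'
#' Partitions sequences into kept and removed according to the screen's
#' mode; counts are untouched. Queries shorter than `k` have no k-mers and
#' never match.
#'
#' @param seqs Data frame with columns `sequence` and `count`
#'   (gap-free sequences).
#' @param screen A [build_screen()] object.
#' @return A list with data-frame elements `kept` and `removed` that
#'   partition the input rows (input order preserved).
#' @export
screen_sequences <- function(seqs, screen) {
  if (nrow(seqs) == 0L) return(list(kept = seqs, removed = seqs))
  frac <- vapply(seqs$sequence, function(s) {
    km <- seq_kmers(s, screen$k)
    if (length(km) == 0L) return(0)
    mean(km %in% screen$kmers)
  }, numeric(1), USE.NAMES = FALSE)
  matches <- frac >= screen$min_fraction
  keep <- if (screen$mode == "positive") matches else !matches
  list(kept = seqs[keep, , drop = FALSE],
       removed = seqs[!keep, , drop = FALSE])
}
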