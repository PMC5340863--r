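# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Round half away from zero (not banker's rounding): output counts use the
# convention that 0.5 rounds up to 1.
round_half_up <- function(x) floor(x + 0.5)

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# A NULL seed means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), force(code))
  }
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split sequences into a character matrix, one row per sequence. All
# sequences must have equal length.
seq_char_matrix <- function(seqs) {
  if (length(seqs) == 0L) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  n <- unique(nchar(seqs))
  if (length(n) != 1L) {
    stop("sequences must all have the same length")
  }
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = n, byrow = TRUE)
}

collapse_rows <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

check_dna <- function(reads, what = "read") {
  bad <- grep("[^ACGTN]", reads)
  if (length(bad) > 0L) {
    stop(sprintf("%s %d contains characters outside {A,C,G,T,N}",
                 what, bad[1L]))
  }
  invisible(reads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
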