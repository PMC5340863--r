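#' Per-sample read container
#'
#' Holds the raw reads for one sample: the unit the denoiser operates on
#' independently. Reads are stored uppercase over the alphabet A, C, G, T, N;
#' per-read phred strings are carried along when the input was FASTQ but are
#' never consulted by the algorithm (quality filtering is assumed to have
#' happened upstream).
#'
#' @param sample_id Single string identifying the sample.
#' @param reads Character vector of nucleotide strings (case-insensitive).
#' @param qualities Optional character vector of phred+33 strings, parallel
#'   to `reads`.
#' @return An object of class `sample_reads`: a list with elements
#'   `sample_id`, `reads` and `qualities`.
#' @export
#' @examples
#' sample_reads("s1", c("ACGT", "acgtn"))
sample_reads <- function(sample_id, reads, qualities = NULL) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  reads <- toupper(as.character(reads))
  if (any(!nzchar(reads))) stop("empty read in sample ", sample_id)
  check_dna(reads)
  if (!is.null(qualities) && length(qualities) != length(reads)) {
    stop("qualities must be parallel to reads")
  }
  structure(list(sample_id = sample_id, reads = reads,
                 qualities = qualities),
            class = "sample_reads")
}

#' @export
print.sample_reads <- function(x, ...) {
  cat(sprintf("<sample_reads> sample '%s': %d reads\n",
              x$sample_id, length(x$reads)))
  invisible(x)
}

FASTA_EXT <- "\\.(fa|fasta|fna)(\\.gz)?$"
FASTQ_EXT <- "\\.(fq|fastq)(\\.gz)?$"

sample_id_from_path <- function(path) {
  sub("\\.(fa|fasta|fna|fq|fastq)(\\.gz)?$", "", basename(path),
      ignore.case = TRUE)
}

read_one_sample_file <- function(path) {
  id <- sample_id_from_path(path)
  is_fastq <- grepl(FASTQ_EXT, path, ignore.case = TRUE)
  parsed <- tryCatch({
    if (is_fastq) {
      ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                         with.qualities = TRUE)
      list(reads = as.character(ss),
           qualities = as.character(S4Vectors::mcols(ss)$qualities))
    } else {
      ss <- Biostrings::readDNAStringSet(path, format = "fasta")
      list(reads = as.character(ss), qualities = NULL)
    }
  }, error = function(e) {
    stop(sprintf("malformed record in '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (length(parsed$reads) == 0L) {
    warning(sprintf("empty sequence file: '%s'", path), call. = FALSE)
    return(structure(list(sample_id = id, reads = character(0),
                          qualities = NULL),
                     class = "sample_reads"))
  }
  sample_reads(id, unname(parsed$reads), unname(parsed$qualities))
}

#' Read demultiplexed per-sample sequence files
#'
#' Reads one FASTA/FASTQ file, or a directory of per-sample files, into a
#' list of [sample_reads()] objects. In directory mode each file becomes one
#' sample whose id is the file name without its sequence extension.
#' Recognised extensions: `.fa`, `.fasta`, `.fna`, `.fq`, `.fastq`,
#' optionally gzip-compressed. Lowercase bases are uppercased; `N` bases
#' are preserved.
#'
#' @param path Path to a sequence file or a directory of per-sample files.
#' @return A list of `sample_reads`, one per sample, in lexicographic
#'   sample-id order for directory input.
#' @export
read_sample_files <- function(path) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    files <- files[grepl(paste0(FASTA_EXT, "|", FASTQ_EXT), files,
                         ignore.case = TRUE)]
    if (length(files) == 0L) {
      stop("no FASTA/FASTQ files found in directory: ", path)
    }
    files <- files[order(sample_id_from_path(files))]
    out <- lapply(files, read_one_sample_file)
    ids <- vapply(out, `[[`, character(1), "sample_id")
    if (anyDuplicated(ids)) {
      stop("duplicate sample ids in directory: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    out
  } else {
    list(read_one_sample_file(path))
  }
}

#' Write a sample's reads to FASTA or FASTQ
#'
#' @param sample A [sample_reads()] object.
#' @param path Output path; `.gz` suffix enables compression.
#' @param format `"fasta"` or `"fastq"`. FASTQ output uses the carried
#'   qualities, or a constant `I` (phred 40) when none are present.
#' @return `path`, invisibly.
#' @export
write_sample_file <- function(sample, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  ss <- Biostrings::DNAStringSet(sample$reads)
  names(ss) <- sprintf("%s_%d", sample$sample_id, seq_along(sample$reads))
  if (format == "fasta") {
    Biostrings::writeXStringSet(ss, path, format = "fasta",
                                compress = grepl("\\.gz$", path))
  } else {
    qual <- sample$qualities %||%
      vapply(nchar(sample$reads), function(n) strrep("I", n), character(1))
    Biostrings::writeXStringSet(ss, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qual),
                                compress = grepl("\\.gz$", path))
  }
  invisible(path)
}

#' Trim reads to a fixed length
#'
#' Keeps the first `length` bases of each read; reads shorter than `length`
#' are discarded. The number of discarded reads is attached as attribute
#' `n_discarded`.
#'
#' @param sample A [sample_reads()] object.
#' @param length Positive integer trim length.
#' @return A `sample_reads` with every read exactly `length` bases long.
#' @export
trim_reads <- function(sample, length) {
  stopifnot(length >= 1)
  keep <- nchar(sample$reads) >= length
  out <- sample_reads(
    sample$sample_id,
    substr(sample$reads[keep], 1L, length),
    if (!is.null(sample$qualities)) substr(sample$qualities[keep], 1L, length)
  )
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Dereplicate a sample with singleton removal
#'
#' Collapses identical reads into (sequence, count) pairs, removes
#' singletons (count 1), and sorts by count descending with ties broken by
#' sequence lexicographic ascending — the fixed processing order the greedy
#' denoiser relies on. Run after [trim_reads()]: all reads must have equal
#' length.
#'
#' @param sample A [sample_reads()] object with equal-length reads.
#' @return A data frame with columns `sequence` (character) and `count`
#'   (integer, all >= 2). The number of removed singletons is attached as
#'   attribute `n_singletons`.
#' @export
dereplicate <- function(sample) {
  if (length(sample$reads) == 0L) {
    out <- data.frame(sequence = character(0), count = integer(0))
    attr(out, "n_singletons") <- 0L
    return(out)
  }
  if (length(unique(nchar(sample$reads))) != 1L) {
    stop("reads must all have the same length; run trim_reads() first")
  }
  tab <- table(sample$reads)
  counts <- as.integer(tab)
  seqs <- names(tab)
  keep <- counts >= 2L
  n_singletons <- sum(!keep)
  seqs <- seqs[keep]
  counts <- counts[keep]
  # radix sort is stable and locale-independent
  ord <- order(-counts, seqs, method = "radix")
  out <- data.frame(sequence = seqs[ord], count = counts[ord])
  attr(out, "n_singletons") <- n_singletons
  out
}
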