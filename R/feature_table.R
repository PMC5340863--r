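# Exact-sequence feature tables: samples x features integer counts, where
# the feature id IS the sub-OTU sequence. Using the literal sequence as the
# id means the same sequence observed in any run receives the same id, so
# tables from different runs merge without any centroid bookkeeping.

#' Exact-sequence feature table
#'
#' @param counts Non-negative integer matrix, samples as rows (rownames =
#'   sample ids), features as columns (colnames = uppercase sub-OTU
#'   sequences).
#' @return An object of class `feature_table` (the validated matrix).
#' @export
feature_table <- function(counts) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts)))) {
    stop("counts must carry sample ids as rownames and sequences as colnames")
  }
  dimnames(counts) <- list(rownames(counts) %||% character(0),
                           colnames(counts) %||% character(0))
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate feature ids")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("feature_table", "matrix", "array"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features, %d total counts\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

as_plain_matrix <- function(t) {
  unclass(t)[, , drop = FALSE]
}

#' Assemble per-sample denoised results into a feature table
#'
#' @param results List of `denoise_result` objects. Sample ids are taken
#'   from each result's `sample_id` (or the list names); they must be
#'   unique. A sample with an empty result contributes a row of zeros.
#' @return A `feature_table` over the union of retained sequences (features
#'   in lexicographic order, samples in input order).
#' @export
build_table <- function(results) {
  ids <- vapply(seq_along(results), function(i) {
    id <- results[[i]]$sample_id
    if (is.null(id) || is.na(id)) id <- names(results)[i]
    if (is.null(id) || !nzchar(id)) {
      stop("result ", i, " has no sample id")
    }
    id
  }, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  feats <- sort(unique(unlist(lapply(results,
                                     function(r) r$retained$sequence))))
  m <- matrix(0L, nrow = length(ids), ncol = length(feats),
              dimnames = list(ids, feats))
  for (i in seq_along(results)) {
    ret <- results[[i]]$retained
    if (nrow(ret) > 0L) m[i, ret$sequence] <- as.integer(ret$count)
  }
  feature_table(m)
}

drop_zero_features <- function(t) {
  m <- as_plain_matrix(t)
  keep <- colSums(m) > 0L
  feature_table(m[, keep, drop = FALSE])
}

#' Drop low-abundance features
#'
#' Removes features whose total count across samples is strictly below
#' `min_total` (so `min_total = 10` drops observations with fewer than 10
#' counts).
#'
#' @param t A `feature_table`.
#' @param min_total Non-negative integer threshold.
#' @return A filtered `feature_table`.
#' @export
filter_min_count <- function(t, min_total) {
  stopifnot(min_total >= 0)
  m <- as_plain_matrix(t)
  feature_table(m[, colSums(m) >= min_total, drop = FALSE])
}

#' Merge feature tables across sequencing runs
#'
#' Features are matched by exact sequence identity, so a sequence observed
#' in several runs collapses into one column. Sample ids must be disjoint
#' across tables. With `trim_to_common = TRUE`, every feature sequence is
#' first truncated to the shortest feature length across all tables and
#' counts of now-identical sequences are summed per sample — for merging
#' runs trimmed to different lengths.
#'
#' @param tables List of `feature_table` objects.
#' @param trim_to_common Logical (default `FALSE`).
#' @return The merged `feature_table` (samples in input order, features
#'   lexicographic).
#' @export
merge_tables <- function(tables, trim_to_common = FALSE) {
  stopifnot(length(tables) >= 1L)
  ids <- unlist(lapply(tables, rownames))
  if (anyDuplicated(ids)) {
    stop("overlapping sample ids across tables: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mats <- lapply(tables, as_plain_matrix)
  if (trim_to_common) {
    lmin <- min(unlist(lapply(mats, function(m) nchar(colnames(m)))))
    mats <- lapply(mats, function(m) {
      trimmed <- substr(colnames(m), 1L, lmin)
      grouped <- t(rowsum(t(m), group = trimmed))
      colnames(grouped) <- sort(unique(trimmed))
      grouped
    })
  }
  feats <- sort(unique(unlist(lapply(mats, colnames))))
  out <- matrix(0L, nrow = length(ids), ncol = length(feats),
                dimnames = list(ids, feats))
  for (m in mats) {
    out[rownames(m), colnames(m)] <- m
  }
  feature_table(out)
}

#' Rarefy a feature table
#'
#' Subsamples each sample's counts without replacement (multivariate
#' hypergeometric) to exactly `depth` reads. Samples with fewer than
#' `depth` total reads are dropped, as are features left with zero counts
#' everywhere. Deterministic for a given `seed`.
#'
#' @param t A `feature_table`.
#' @param depth Positive integer target depth.
#' @param seed Integer seed.
#' @return A rarefied `feature_table`.
#' @export
rarefy_table <- function(t, depth, seed = 1L) {
  stopifnot(depth >= 1)
  m <- as_plain_matrix(t)
  keep <- rowSums(m) >= depth
  m <- m[keep, , drop = FALSE]
  with_seed(seed, {
    for (i in seq_len(nrow(m))) {
      pool <- rep.int(seq_len(ncol(m)), m[i, ])
      hit <- sample(pool, depth, replace = FALSE)
      m[i, ] <- tabulate(hit, nbins = ncol(m))
    }
  })
  drop_zero_features(feature_table(m))
}

#' Write a feature table to BIOM 1.0 JSON or TSV
#'
#' TSV output is oriented features-as-rows: the header row holds the sample
#' ids and each subsequent row is `sequence` followed by its counts.
#'
#' @param t A `feature_table`.
#' @param path Output path.
#' @param format `"biom"` (BIOM 1.0 JSON, sparse) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(t, path, format = c("biom", "tsv")) {
  format <- match.arg(format)
  m <- as_plain_matrix(t)
  if (format == "biom") {
    b <- biomformat::make_biom(t(m))
    b$date <- "1970-01-01T00:00:00"  # fixed stamp: identical runs give identical bytes
    biomformat::write_biom(b, path)
  } else {
    df <- data.frame(feature_id = colnames(m), t(m), check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a feature table written by [write_table()]
#'
#' @param path Input path.
#' @param format `"biom"` or `"tsv"`.
#' @return A `feature_table`.
#' @export
read_table_file <- function(path, format = c("biom", "tsv")) {
  format <- match.arg(format)
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    feature_table(t(m))
  } else {
    df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                     colClasses = "character")
    feats <- df[[1L]]
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- feats
    feature_table(t(m))
  }
}
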