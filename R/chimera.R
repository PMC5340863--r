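# De novo detection of PCR chimeras among denoised sequences, using an
# explicit two-parent single-crossover model: a query is flagged when the
# prefix of one sufficiently more abundant sequence concatenated with the
# suffix of another reconstructs it (almost) exactly, while neither parent
# alone explains it.

#' Chimera-detection parameters
#'
#' @param abundance_skew Minimum parent/query count ratio for a sequence to
#'   be an eligible parent (default 2.0; chimeras arise late in PCR, so
#'   parents should be clearly more abundant than their chimeras).
#' @param min_parent_diffs Minimum differences between the query and each
#'   single parent within the segment contributed by the *other* parent
#'   (default 3); prevents flagging near-copies of one real sequence.
#' @param max_model_diffs Maximum differences allowed between the query and
#'   the best two-parent model (default 0: the crossover must reconstruct
#'   the query exactly).
#' @return An object of class `chimera_params`.
#' @export
chimera_params <- function(abundance_skew = 2.0, min_parent_diffs = 3L,
                           max_model_diffs = 0L) {
  stopifnot(abundance_skew >= 1, min_parent_diffs >= 0, max_model_diffs >= 0)
  structure(list(abundance_skew = abundance_skew,
                 min_parent_diffs = as.integer(min_parent_diffs),
                 max_model_diffs = as.integer(max_model_diffs)),
            class = "chimera_params")
}

#' Detect de novo two-parent chimeras
#'
#' Queries are processed from least to most abundant. For a query with
#' count `c`, candidate parents are the not-yet-flagged sequences with
#' count `>= abundance_skew * c`. The query is flagged as a chimera when
#' some ordered parent pair (P1, P2) and crossover column `x` yield a model
#' `P1[1..x] + P2[(x+1)..L]` within `max_model_diffs` of the query, while
#' P1 differs from the query by at least `min_parent_diffs` in the suffix
#' (P2's segment) and P2 by at least `min_parent_diffs` in the prefix
#' (P1's segment). The first qualifying combination in (P1 abundance
#' descending, P2 abundance descending, leftmost x) order is reported.
#' Flagged sequences are excluded from the parent pool for later queries.
#'
#' @param result A [deblur_sample()] result; all retained sequences must
#'   have equal length.
#' @param params A [chimera_params()] object.
#' @return A data frame with one row per retained sequence, columns
#'   `sequence`, `count`, `is_chimera`, `parent1`, `parent2`, `crossover`
#'   (NA unless flagged), in the input's row order.
#' @export
detect_chimeras <- function(result, params = chimera_params()) {
  ret <- result$retained
  n <- nrow(ret)
  verdicts <- data.frame(sequence = ret$sequence, count = ret$count,
                         is_chimera = logical(n),
                         parent1 = NA_character_, parent2 = NA_character_,
                         crossover = NA_integer_)
  if (n < 3L) return(verdicts)
  if (length(unique(nchar(ret$sequence))) != 1L) {
    stop("chimera detection requires equal-length sequences")
  }
  L <- nchar(ret$sequence[1L])
  cm <- seq_char_matrix(ret$sequence)

  query_order <- order(ret$count, ret$sequence, method = "radix")
  pool_order <- order(-ret$count, ret$sequence, method = "radix")

  for (q in query_order) {
    parents <- pool_order[!verdicts$is_chimera[pool_order] &
                          ret$count[pool_order] >=
                            params$abundance_skew * ret$count[q]]
    parents <- parents[parents != q]
    if (length(parents) < 2L) next
    hit <- find_crossover(cm, q, parents, L, params)
    if (!is.null(hit)) {
      verdicts$is_chimera[q] <- TRUE
      verdicts$parent1[q] <- ret$sequence[hit$p1]
      verdicts$parent2[q] <- ret$sequence[hit$p2]
      verdicts$crossover[q] <- hit$x
    }
  }
  verdicts
}

# First qualifying (P1, P2, x); mismatch prefix sums make the scan over the
# crossover column O(L) per parent pair.
find_crossover <- function(cm, q, parents, L, params) {
  qrow <- cm[q, ]
  mism <- lapply(parents, function(p) cumsum(cm[p, ] != qrow))
  xs <- seq_len(L - 1L)
  for (a in seq_along(parents)) {
    m1 <- mism[[a]]
    for (b in seq_along(parents)) {
      if (b == a) next
      m2 <- mism[[b]]
      model_diffs <- m1[xs] + (m2[L] - m2[xs])
      ok <- model_diffs <= params$max_model_diffs &
        (m1[L] - m1[xs]) >= params$min_parent_diffs &
        m2[xs] >= params$min_parent_diffs
      if (any(ok)) {
        return(list(p1 = parents[a], p2 = parents[b], x = which(ok)[1L]))
      }
    }
  }
  NULL
}

#' Remove flagged chimeras from a denoised result
#'
#' @param result A `denoise_result`.
#' @param verdicts Output of [detect_chimeras()] on the same result.
#' @return A `denoise_result` without the flagged sequences; retained
#'   counts are unchanged and flagged sequences are appended to `removed`.
#' @export
remove_chimeras <- function(result, verdicts) {
  stopifnot(identical(verdicts$sequence, result$retained$sequence))
  flag <- verdicts$is_chimera
  new_denoise_result(result$retained[!flag, , drop = FALSE],
                     c(result$removed, verdicts$sequence[flag]),
                     result$sample_id)
}
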