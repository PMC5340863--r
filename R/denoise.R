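# The greedy denoising core: abundance-ordered subtraction of predicted
# error-derived reads, driven by an upper-bound per-Hamming-distance error
# profile.

#' Upper-bound error profile
#'
#' The profile is a vector `E[h]`, `h = 0..H`, bounding the expected number
#' of reads a true sequence spawns at Hamming distance `h`, expressed as a
#' fraction of its (error-free-scaled) abundance. `E[0] = 1` by convention
#' (the self term is never applied) and `E[h]` must be non-increasing for
#' `h >= 1`. Distances beyond `H` reuse `E[H]`.
#'
#' @param upper_bounds Numeric vector of probabilities for `h = 0, 1, ...`;
#'   a leading value other than 1 is overridden to 1 with a warning.
#' @return An object of class `error_profile` (numeric vector; element `i`
#'   is `E[i-1]`).
#' @export
#' @examples
#' error_profile(c(1, 0.06, 0.02, 0.01))
error_profile <- function(upper_bounds) {
  e <- as.numeric(upper_bounds)
  if (length(e) < 1L) stop("error profile needs at least E[0]")
  if (any(!is.finite(e)) || any(e < 0) || any(e[-1L] > 1)) {
    stop("error profile values must be probabilities in [0, 1]")
  }
  if (e[1L] != 1) {
    warning("E[0] overridden to 1 (the self term is never applied)")
    e[1L] <- 1
  }
  if (length(e) > 2L && any(diff(e[-1L]) > 0)) {
    stop("error profile must be non-increasing for h >= 1")
  }
  structure(e, class = "error_profile")
}

#' Shipped default error profile
#'
#' A conservative upper-bound profile for 12 Hamming-distance bins,
#' modelled on the distribution used by per-sample greedy denoisers for
#' Illumina 16S data: `E[1..12] = 0.06, 0.02, 0.02, 0.01, 0.005, 0.005,
#' 0.005, 0.001, 0.001, 0.001, 0.0005, 0.0005`. Intended as a configuration
#' default; platform-specific profiles can be supplied through
#' [load_error_profile()].
#'
#' @return An `error_profile` with `H = 12`.
#' @export
default_error_profile <- function() {
  error_profile(c(1, 0.06, 0.02, 0.02, 0.01, 0.005, 0.005, 0.005,
                  0.001, 0.001, 0.001, 0.0005, 0.0005))
}

#' Load an error profile from a text file
#'
#' Accepts a whitespace-delimited one-column file of values for
#' `h = 0, 1, ...`, or a two-column `h value` file (any `h` order;
#' must form `0..H` once each).
#'
#' @param path Path to the profile file.
#' @return An `error_profile`.
#' @export
load_error_profile <- function(path) {
  if (!file.exists(path)) stop("no such error-profile file: ", path)
  tab <- read.table(path, header = FALSE)
  m <- suppressWarnings(apply(as.matrix(tab), 2L, as.numeric))
  if (anyNA(m)) stop("non-numeric value in error-profile file: ", path)
  if (ncol(tab) == 2L && nrow(tab) >= 2L) {
    h <- as.integer(m[, 1L])
    if (!setequal(h, seq_along(h) - 1L) || anyDuplicated(h)) {
      stop("two-column profile must list each h = 0..H exactly once")
    }
    vals <- m[order(h), 2L]
  } else {
    vals <- as.numeric(t(m))  # values for h = 0, 1, ... in reading order
  }
  error_profile(vals)
}

#' Denoising parameters
#'
#' @param mean_error Mean per-nucleotide read error rate used for
#'   normalisation (default 0.005, i.e. 0.5%).
#' @param indel_prob Maximal probability for indels (default 0.01): the
#'   factor applied to a neighbour's predicted error count when the aligned
#'   pair contains 1 or more indel positions.
#' @param indel_max Neighbours with more than this many indel positions are
#'   not subtracted from at all (default 3).
#' @param read_length Ungapped (trimmed) read length `L`.
#' @return An object of class `denoise_params`.
#' @export
denoise_params <- function(mean_error = 0.005, indel_prob = 0.01,
                           indel_max = 3L, read_length) {
  stopifnot(mean_error >= 0, mean_error <= 1,
            indel_prob >= 0, indel_prob <= 1,
            indel_max >= 0, read_length >= 1)
  structure(list(mean_error = mean_error, indel_prob = indel_prob,
                 indel_max = as.integer(indel_max),
                 read_length = as.integer(read_length)),
            class = "denoise_params")
}

#' Error-free read probability (the normalisation "mod factor")
#'
#' `M = (1 - mean_error)^L` is the probability that a read of length `L`
#' contains no errors. An observed abundance divided by `M` estimates the
#' number of reads the true sequence presented to the sequencer, which is
#' the quantity the profile's upper bounds apply to.
#'
#' @param params A [denoise_params()] object.
#' @return A number in (0, 1].
#' @export
mod_factor <- function(params) {
  (1 - params$mean_error)^params$read_length
}

#' Predicted error-derived reads per Hamming distance
#'
#' For a sequence with current residual abundance `r`, the number of reads
#' it is predicted to spawn at Hamming distance `h` is
#' `r * E[min(h, H)] / M`, where `M` is [mod_factor()]. Distances beyond the
#' profile's last bin reuse the last bound.
#'
#' @param residual Positive current residual abundance of the source.
#' @param profile An [error_profile()].
#' @param params A [denoise_params()].
#' @param max_h Largest distance to tabulate.
#' @return Numeric vector `v` with `v[h + 1] = num_err[h]`, `h = 0..max_h`.
#' @export
predicted_errors <- function(residual, profile, params, max_h) {
  stopifnot(residual > 0)
  h <- 0:max_h
  e <- unclass(profile)[pmin(h, length(profile) - 1L) + 1L]
  residual * e / mod_factor(params)
}

#' Greedy per-sample denoising
#'
#' The core algorithm. Sequences are visited once, in fixed order of
#' descending observed count (ties broken by sequence, lexicographically).
#' Each still-valid source projects its predicted error-derived reads onto
#' every neighbour according to their aligned substitution distance `h` and
#' indel positions `g`: neighbours with `g > indel_max` are skipped;
#' neighbours with `1 <= g <= indel_max` receive the `h`-distance prediction
#' multiplied once by `indel_prob`. The prediction scales with the source's
#' *current* residual, so a partially explained sequence projects
#' proportionally fewer errors. Any sequence whose residual drops to zero or
#' below is removed immediately and never acts as a source. Finally,
#' residuals are rounded half-up; sequences rounding to zero are dropped.
#'
#' @param ws An `aligned_workspace` from [center_star_msa()] with residuals
#'   equal to counts.
#' @param profile An [error_profile()].
#' @param params A [denoise_params()]; `read_length` should equal the
#'   ungapped read length.
#' @return An object of class `denoise_result`: a list with `retained`
#'   (data frame of `sequence`, `count`, sorted count descending, sequence
#'   ascending), `removed` (character vector of zeroed-out sequences) and
#'   `sample_id`.
#' @export
deblur_sample <- function(ws, profile, params) {
  k <- length(ws$gapped)
  if (k == 0L) {
    return(new_denoise_result(data.frame(sequence = character(0),
                                         count = integer(0)),
                              character(0), ws$sample_id))
  }
  stopifnot(identical(ws$residuals, as.numeric(ws$counts)))
  e <- unclass(profile)
  H <- length(e) - 1L
  M <- mod_factor(params)

  cm <- seq_char_matrix(ws$gapped)
  is_gap <- cm == "-"
  r <- as.numeric(ws$counts)
  removed <- rep(FALSE, k)
  ord <- order(-ws$counts, ws$sequences, method = "radix")

  for (i in ord) {
    if (removed[i] || r[i] <= 0) next
    if (k == 1L) break
    mi <- cm[i, ]
    gi <- is_gap[i, ]
    neq <- t(t(cm) != mi)
    both_base <- t(t(!is_gap) & !gi)
    subs <- rowSums(neq & both_base)
    indels <- rowSums(t(xor(t(is_gap), gi)))
    pen <- r[i] * e[pmin(subs, H) + 1L] / M
    pen[indels >= 1L] <- pen[indels >= 1L] * params$indel_prob
    pen[indels > params$indel_max] <- 0
    pen[i] <- 0
    r <- r - pen
    removed <- removed | (r <= 0)
  }

  rounded <- round_half_up(r)
  keep <- !removed & rounded >= 1
  ret_ord <- order(-rounded[keep], ws$sequences[keep], method = "radix")
  retained <- data.frame(sequence = ws$sequences[keep][ret_ord],
                         count = as.integer(rounded[keep][ret_ord]))
  new_denoise_result(retained, ws$sequences[!keep], ws$sample_id)
}

new_denoise_result <- function(retained, removed, sample_id = NA_character_) {
  structure(list(retained = retained, removed = removed,
                 sample_id = sample_id),
            class = "denoise_result")
}

#' @export
print.denoise_result <- function(x, ...) {
  cat(sprintf("<denoise_result> sample '%s': %d retained, %d removed\n",
              x$sample_id, nrow(x$retained), length(x$removed)))
  invisible(x)
}
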