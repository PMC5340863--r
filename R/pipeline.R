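# End-to-end orchestration. Every sample is processed completely
# independently — trim, dereplicate (singletons removed), artifact screen,
# align, denoise, chimera check — before results are combined into one
# exact-sequence feature table. Independence is what makes the output of a
# sample invariant to which other samples happen to share the batch.

#' Pipeline configuration
#'
#' Bundles every tunable of [run_pipeline()]. Defaults: 150 nt trim, 0.5%
#' mean read error, indel probability 0.01 (capped at 3 indel positions),
#' minimum 10 total counts per feature.
#'
#' @param trim_length Trim length in nt (default 150).
#' @param mean_error Mean per-nucleotide error rate (default 0.005).
#' @param indel_prob Maximal indel probability (default 0.01).
#' @param indel_max Maximum indel positions subtracted across (default 3).
#' @param error_profile An [error_profile()] (default
#'   [default_error_profile()]).
#' @param pos_ref,neg_ref Optional reference FASTA paths or sequence
#'   vectors for positive / negative artifact screening (negative applied
#'   first).
#' @param screen_k,screen_min_fraction K-mer screen parameters (see
#'   [build_screen()]).
#' @param min_reads Features with fewer total counts are dropped from the
#'   final table (default 10).
#' @param rarefy_depth Optional rarefaction depth.
#' @param chimera_check Run de novo chimera removal (default TRUE).
#' @param chimera A [chimera_params()] object.
#' @param seed Integer seed (used by rarefaction).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(trim_length = 150L, mean_error = 0.005,
                            indel_prob = 0.01, indel_max = 3L,
                            error_profile = default_error_profile(),
                            pos_ref = NULL, neg_ref = NULL,
                            screen_k = 16L, screen_min_fraction = 0.5,
                            min_reads = 10L, rarefy_depth = NULL,
                            chimera_check = TRUE,
                            chimera = chimera_params(), seed = 1L) {
  structure(list(trim_length = as.integer(trim_length),
                 mean_error = mean_error, indel_prob = indel_prob,
                 indel_max = as.integer(indel_max),
                 error_profile = error_profile,
                 pos_ref = pos_ref, neg_ref = neg_ref,
                 screen_k = as.integer(screen_k),
                 screen_min_fraction = screen_min_fraction,
                 min_reads = as.integer(min_reads),
                 rarefy_depth = rarefy_depth,
                 chimera_check = isTRUE(chimera_check),
                 chimera = chimera, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Denoise one sample end to end
#'
#' The per-sample stages in order: trim to `trim_length` (short reads
#' discarded), dereplicate with singleton removal, drop sequences containing
#' `N` (the Hamming error model is defined over unambiguous bases), negative
#' then positive artifact screen, center-star alignment, greedy error
#' subtraction, de novo chimera removal. A stage-count record is attached as
#' attribute `stages`.
#'
#' @param sample A [sample_reads()] object.
#' @param config A [pipeline_config()].
#' @return A `denoise_result` with attribute `stages` (named integer vector
#'   of read/sequence counts surviving each stage).
#' @export
denoise_one_sample <- function(sample, config = pipeline_config()) {
  stages <- c(input_reads = length(sample$reads))
  trimmed <- trim_reads(sample, config$trim_length)
  stages["trimmed_reads"] <- length(trimmed$reads)
  derep <- dereplicate(trimmed)
  stages["derep_seqs"] <- nrow(derep)
  derep <- derep[!grepl("N", derep$sequence, fixed = TRUE), , drop = FALSE]
  stages["no_ambiguous"] <- nrow(derep)
  if (!is.null(config$neg_ref)) {
    scr <- build_screen(config$neg_ref, k = config$screen_k,
                        mode = "negative",
                        min_fraction = config$screen_min_fraction)
    derep <- screen_sequences(derep, scr)$kept
  }
  if (!is.null(config$pos_ref)) {
    scr <- build_screen(config$pos_ref, k = config$screen_k,
                        mode = "positive",
                        min_fraction = config$screen_min_fraction)
    derep <- screen_sequences(derep, scr)$kept
  }
  stages["post_screen"] <- nrow(derep)

  if (nrow(derep) == 0L) {
    res <- new_denoise_result(data.frame(sequence = character(0),
                                         count = integer(0)),
                              character(0), sample$sample_id)
    stages["denoised"] <- 0L
    stages["post_chimera"] <- 0L
    attr(res, "stages") <- stages
    return(res)
  }

  ws <- center_star_msa(derep)
  ws$sample_id <- sample$sample_id
  params <- denoise_params(mean_error = config$mean_error,
                           indel_prob = config$indel_prob,
                           indel_max = config$indel_max,
                           read_length = config$trim_length)
  res <- deblur_sample(ws, config$error_profile, params)
  stages["denoised"] <- nrow(res$retained)
  if (config$chimera_check) {
    res <- remove_chimeras(res, detect_chimeras(res, config$chimera))
  }
  stages["post_chimera"] <- nrow(res$retained)
  attr(res, "stages") <- stages
  res
}

#' Run the full pipeline over one or many samples
#'
#' Applies [denoise_one_sample()] to every sample, combines the results
#' into an exact-sequence feature table, drops features with fewer than
#' `min_reads` total counts, optionally rarefies, and (when `out_dir` is
#' given) writes `table.biom`, `table.tsv` and a JSON run manifest holding
#' all parameters and per-sample stage counts. A sample whose processing
#' fails is skipped with a warning; the remaining samples proceed.
#'
#' @param input A path (file or directory, see [read_sample_files()]) or a
#'   list of [sample_reads()] objects.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return A list with `table` (the final `feature_table`), `results`
#'   (per-sample `denoise_result`s), `stages` (data frame of per-sample
#'   stage counts) and `failed` (named character vector of error messages).
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL) {
  samples <- if (is.character(input)) read_sample_files(input) else input
  stopifnot(length(samples) >= 1L)

  results <- list()
  failed <- character(0)
  for (s in samples) {
    res <- tryCatch(denoise_one_sample(s, config), error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("sample '%s' failed: %s", s$sample_id,
                      conditionMessage(res)), call. = FALSE)
      failed[s$sample_id] <- conditionMessage(res)
    } else {
      results[[s$sample_id]] <- res
    }
  }
  if (length(results) == 0L) stop("every sample failed")
  # merge deterministically in sample-name order
  results <- results[order(names(results), method = "radix")]

  tab <- build_table(results)
  tab <- filter_min_count(tab, config$min_reads)
  tab <- drop_zero_features(tab)
  if (!is.null(config$rarefy_depth)) {
    tab <- rarefy_table(tab, config$rarefy_depth, seed = config$seed)
  }

  stage_df <- do.call(rbind, lapply(results, function(r) {
    as.data.frame(as.list(attr(r, "stages")))
  }))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(tab, file.path(out_dir, "table.biom"), "biom")
    write_table(tab, file.path(out_dir, "table.tsv"), "tsv")
    manifest <- list(
      parameters = list(
        trim_length = config$trim_length, mean_error = config$mean_error,
        indel_prob = config$indel_prob, indel_max = config$indel_max,
        error_profile = as.numeric(config$error_profile),
        min_reads = config$min_reads,
        rarefy_depth = config$rarefy_depth,
        chimera_check = config$chimera_check, seed = config$seed),
      samples = cbind(sample_id = rownames(stage_df), stage_df),
      failed = as.list(failed))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(table = tab, results = results, stages = stage_df, failed = failed)
}
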