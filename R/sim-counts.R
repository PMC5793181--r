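#' Simulate ground-truth expression and realized read counts
#'
#' Each feature gets a log2-normal baseline expression. Features listed in
#' the configuration's spike table have their expectation multiplied by
#' `2^log2_fold_change` in samples of the named subtype only. Optional
#' per-sample biological noise (log2-normal, `sample_noise_log2_sd`) is
#' applied on top. Realized counts are multinomial over features within each
#' sample, totalling exactly `reads_per_sample`.
#'
#' @param config an [srna_sim_config()].
#' @param features feature data.frame from [build_reference()].
#' @return list of class `srna_truth`: `expected` and `counts` (feature x
#'   sample matrices), `design` (the sample sheet).
#' @export
simulate_counts <- function(config, features) {
  validate_sim_config(config)
  if (nrow(features) == 0L) stop("no features to simulate counts for")
  st <- config$spike_table
  if (!is.null(st) && nrow(st) > 0L) {
    missing <- setdiff(st$feature_id, features$feature_id)
    if (length(missing)) {
      stop("spike_table names unknown feature(s): ",
           paste(missing, collapse = ", "))
    }
  }
  set.seed(stage_seed(config$seed, "counts"))

  fids <- features$feature_id
  samples <- config$design$sample_id
  subtypes <- config$design$subtype

  baseline <- 2^stats::rnorm(length(fids), config$baseline_log2_mean,
                             config$baseline_log2_sd)
  expected <- matrix(baseline, nrow = length(fids), ncol = length(samples),
                     dimnames = list(fids, samples))
  if (!is.null(st) && nrow(st) > 0L) {
    for (k in seq_len(nrow(st))) {
      cols <- subtypes == st$subtype[k]
      expected[st$feature_id[k], cols] <-
        expected[st$feature_id[k], cols] * 2^st$log2_fold_change[k]
    }
  }
  if (config$sample_noise_log2_sd > 0) {
    noise <- matrix(
      2^stats::rnorm(length(expected), 0, config$sample_noise_log2_sd),
      nrow = nrow(expected)
    )
    expected <- expected * noise
  }

  counts <- vapply(seq_along(samples), function(j) {
    as.integer(stats::rmultinom(1L, config$reads_per_sample,
                                expected[, j] / sum(expected[, j])))
  }, integer(length(fids)))
  dimnames(counts) <- dimnames(expected)

  out <- list(expected = expected, counts = counts, design = config$design)
  class(out) <- "srna_truth"
  out
}

#' @export
print.srna_truth <- function(x, ...) {
  cat("srna_truth: ", nrow(x$counts), " features x ", ncol(x$counts),
      " samples, ", sum(x$counts), " reads total\n", sep = "")
  invisible(x)
}
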