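#' sRNA categories quantified by the pipeline
#'
#' The seven small non-coding RNA categories handled throughout the package,
#' in annotation priority order (highest first).
#'
#' @export
SRNA_CATEGORIES <- c("miRNA", "tRNA", "snoRNA", "snRNA", "yRNA", "7SK", "7SL")

#' Tumor subtype labels accepted in sample metadata
#' @export
TNBC_SUBTYPES <- c("BL1", "BL2", "M", "LAR")

# Canonical anticodon per amino acid used when labelling simulated tRNA loci.
# One representative anticodon per amino acid keeps family ids unambiguous.
ANTICODON_TABLE <- c(
  Ala = "AGC", Arg = "ACG", Asn = "GTT", Asp = "GTC", Cys = "GCA",
  Gln = "TTG", Glu = "CTC", Gly = "GCC", His = "GTG", Ile = "AAT",
  Leu = "CAA", Lys = "CTT", Met = "CAT", Phe = "GAA", Pro = "AGG",
  Ser = "AGA", Thr = "AGT", Trp = "CCA", Tyr = "GTA", Val = "CAC"
)

# Sampling weights for anticodon families: Val/Gly/Lys/Glu/His dominate the
# cellular tRNA pool, so simulated loci are concentrated in those families.
ANTICODON_WEIGHTS <- local({
  w <- setNames(rep(0.05 / 15, 20), names(ANTICODON_TABLE))
  w[c("Val", "Gly", "Lys", "Glu", "His")] <- c(0.30, 0.25, 0.15, 0.15, 0.10)
  w
})

#' Default sample design: 26 cell lines over the four TNBC subtypes
#'
#' @return data.frame with columns `sample_id` and `subtype`.
#' @export
default_design <- function() {
  subtype <- rep(c("BL1", "BL2", "M", "LAR"), times = c(7, 5, 7, 7))
  data.frame(
    sample_id = sprintf("%s_%02d", subtype, unlist(lapply(c(7, 5, 7, 7), seq_len))),
    subtype = subtype,
    stringsAsFactors = FALSE
  )
}

#' Build a validated simulation configuration
#'
#' All downstream synthetic-data operations consume this object. Defaults
#' describe a desk-scale study: 26 samples over four subtypes, a two-
#' chromosome 50-kb-per-chromosome genome carrying non-overlapping loci of
#' the seven sRNA categories, 3' adapter ligation, per-base substitution
#' errors, 5' isomiR offsets, non-templated 3' additions, and 5'-half-biased
#' tRNA fragments.
#'
#' @param seed integer master seed; all randomness in the generator derives
#'   from it.
#' @param n_chromosomes,chromosome_length genome dimensions (nt).
#' @param features_per_category named integer vector over a subset of
#'   [SRNA_CATEGORIES].
#' @param category_length_ranges named list of `c(min, max)` feature lengths
#'   (nt). miRNA must stay within 19-25 nt and tRNA within 73-94 nt, the
#'   biological length ranges of mature miRNAs and parent tRNAs.
#' @param design data.frame with `sample_id`, `subtype` columns.
#' @param baseline_log2_mean,baseline_log2_sd log2-normal feature baseline
#'   expression parameters.
#' @param sample_noise_log2_sd per-sample biological noise (sd on log2 scale)
#'   applied on top of the feature baseline; 0 leaves multinomial sampling as
#'   the only source of count variation.
#' @param spike_table data.frame(feature_id, subtype, log2_fold_change) of
#'   subtype-restricted differential spikes (may have zero rows).
#' @param reads_per_sample sequencing depth per sample.
#' @param read_length raw read length (nt).
#' @param adapter_sequence 3' adapter ligated to every insert (Illumina
#'   TruSeq small RNA 3' adapter by default).
#' @param error_rate per-base substitution error probability.
#' @param isomir_offset_probs named probabilities over 5' offsets "0","1","2"
#'   applied to miRNA-derived reads; must sum to 1.
#' @param nta_probs named probabilities over "0".."3" non-templated 3'
#'   additions; must sum to 1.
#' @param trna_half_bias probability that a tRNA-derived read is a 5'-half
#'   fragment rather than a full-length (read-length-clipped) molecule.
#' @param mixed_strands place features on both strands (default `FALSE`:
#'   plus strand only, which isolates strand-handling in tests).
#' @param quality_char constant Phred+33 quality character for FASTQ output.
#'
#' @return object of class `srna_sim_config` (a validated list).
#' @export
srna_sim_config <- function(seed = 1L,
                            n_chromosomes = 2L,
                            chromosome_length = 50000L,
                            features_per_category = c(
                              miRNA = 30L, tRNA = 20L, snoRNA = 10L,
                              snRNA = 10L, yRNA = 8L, `7SK` = 4L, `7SL` = 4L
                            ),
                            category_length_ranges = list(
                              miRNA = c(19L, 25L), tRNA = c(73L, 94L),
                              snoRNA = c(60L, 150L), snRNA = c(100L, 190L),
                              yRNA = c(83L, 112L), `7SK` = c(330L, 332L),
                              `7SL` = c(299L, 301L)
                            ),
                            design = default_design(),
                            baseline_log2_mean = 6,
                            baseline_log2_sd = 1.5,
                            sample_noise_log2_sd = 0.25,
                            spike_table = NULL,
                            reads_per_sample = 200000L,
                            read_length = 50L,
                            adapter_sequence = "TGGAATTCTCGGGTGCCAAGG",
                            error_rate = 0.001,
                            isomir_offset_probs = c(`0` = 0.8, `1` = 0.15, `2` = 0.05),
                            nta_probs = c(`0` = 0.7, `1` = 0.2, `2` = 0.08, `3` = 0.02),
                            trna_half_bias = 0.8,
                            mixed_strands = FALSE,
                            quality_char = "I") {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    features_per_category = features_per_category,
    category_length_ranges = category_length_ranges,
    design = design,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    sample_noise_log2_sd = sample_noise_log2_sd,
    spike_table = spike_table,
    reads_per_sample = as.integer(reads_per_sample),
    read_length = as.integer(read_length),
    adapter_sequence = adapter_sequence,
    error_rate = error_rate,
    isomir_offset_probs = isomir_offset_probs,
    nta_probs = nta_probs,
    trna_half_bias = trna_half_bias,
    mixed_strands = isTRUE(mixed_strands),
    quality_char = quality_char
  )
  class(cfg) <- "srna_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L)
  fpc <- cfg$features_per_category
  if (is.null(names(fpc)) || !all(names(fpc) %in% SRNA_CATEGORIES)) {
    stop("features_per_category names must be a subset of: ",
         paste(SRNA_CATEGORIES, collapse = ", "))
  }
  if (any(fpc < 0)) stop("features_per_category must be non-negative")
  for (cat in names(fpc)[fpc > 0]) {
    rng <- cfg$category_length_ranges[[cat]]
    if (is.null(rng) || length(rng) != 2L || rng[1] > rng[2] || rng[1] < 1) {
      stop("invalid length range for category ", cat)
    }
  }
  mr <- cfg$category_length_ranges[["miRNA"]]
  if (!is.null(mr) && (mr[1] < 19 || mr[2] > 25)) {
    stop("miRNA length range must lie within [19, 25] nt")
  }
  tr <- cfg$category_length_ranges[["tRNA"]]
  if (!is.null(tr) && (tr[1] < 73 || tr[2] > 94)) {
    stop("tRNA length range must lie within [73, 94] nt")
  }
  d <- cfg$design
  if (!is.data.frame(d) || !all(c("sample_id", "subtype") %in% names(d)) ||
      nrow(d) == 0L) {
    stop("design must be a non-empty data.frame with sample_id and subtype")
  }
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in design")
  if (!all(d$subtype %in% TNBC_SUBTYPES)) {
    stop("design subtypes must be among: ", paste(TNBC_SUBTYPES, collapse = ", "))
  }
  if (!grepl("^[ACGT]+$", cfg$adapter_sequence)) {
    stop("adapter_sequence must be a non-empty string over A/C/G/T")
  }
  check_prob <- function(p, what) {
    if (any(p < 0) || any(p > 1)) stop(what, " probabilities must be in [0,1]")
  }
  check_prob(cfg$error_rate, "error_rate")
  check_prob(cfg$trna_half_bias, "trna_half_bias")
  check_prob_map <- function(p, keys, what) {
    if (!setequal(names(p), keys) || abs(sum(p) - 1) > 1e-9) {
      stop(what, " must be named over {", paste(keys, collapse = ","),
           "} and sum to 1")
    }
    check_prob(p, what)
  }
  check_prob_map(cfg$isomir_offset_probs, c("0", "1", "2"), "isomir_offset_probs")
  check_prob_map(cfg$nta_probs, c("0", "1", "2", "3"), "nta_probs")
  if (!is.null(cfg$spike_table)) {
    st <- cfg$spike_table
    if (!is.data.frame(st) ||
        !all(c("feature_id", "subtype", "log2_fold_change") %in% names(st))) {
      stop("spike_table needs columns feature_id, subtype, log2_fold_change")
    }
    bad <- setdiff(st$subtype, TNBC_SUBTYPES)
    if (length(bad)) stop("spike_table has unknown subtype(s): ",
                          paste(bad, collapse = ", "))
  }
  if (cfg$reads_per_sample < 1L) stop("reads_per_sample must be >= 1")
  if (cfg$read_length < 16L) stop("read_length must be >= 16")
  invisible(cfg)
}

#' @export
print.srna_sim_config <- function(x, ...) {
  cat("srna_sim_config\n")
  cat("  genome: ", x$n_chromosomes, " chromosome(s) x ",
      x$chromosome_length, " nt\n", sep = "")
  cat("  features:", paste(names(x$features_per_category),
                           x$features_per_category, sep = "=", collapse = " "), "\n")
  cat("  samples: ", nrow(x$design), " (",
      paste(names(table(x$design$subtype)), table(x$design$subtype),
            sep = ":", collapse = " "), ")\n", sep = "")
  cat("  reads/sample: ", x$reads_per_sample, ", read length ",
      x$read_length, " nt, error rate ", x$error_rate, "\n", sep = "")
  cat("  spikes:", if (is.null(x$spike_table)) 0L else nrow(x$spike_table), "\n")
  invisible(x)
}

# Derive a deterministic sub-seed for a named generator stage so that stages
# draw from independent streams under one master seed (kept below 2^31).
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000000L) * 1013L + h %% 100000L
}
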