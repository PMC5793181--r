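#' Synthesize adapter-ligated sequencing reads from ground-truth counts
#'
#' Every realized count in `truth` becomes one read. A read is built as
#' insert + non-templated 3' additions + 3' adapter, truncated to the read
#' length, then subjected to per-base substitution errors:
#'
#' * miRNA inserts start at a 5' offset of 0/+1/+2 (per
#'   `isomir_offset_probs`) into the mature sequence and run to its 3' end;
#' * tRNA inserts are 5'-half fragments spanning feature positions
#'   `1 .. L/2 +- 5` with probability `trna_half_bias`, otherwise the
#'   full-length molecule (clipped by the read length);
#' * all other categories contribute their full sequence (clipped).
#'
#' Each read gets a provenance record (source feature, 5' offset, fragment
#' span, NTA length, number of injected errors), which downstream recovery
#' tests compare against.
#'
#' @param truth an `srna_truth` from [simulate_counts()].
#' @param reference an `srna_reference` from [build_reference()].
#' @param config the same [srna_sim_config()] used to build the inputs.
#' @return list of class `srna_readset`: `reads` (named list, per-sample
#'   character vectors), `provenance` (data.frame), `config`.
#' @export
synthesize_reads <- function(truth, reference, config) {
  validate_sim_config(config)
  feats <- reference$features
  fseqs <- feature_sequences(reference)
  stopifnot(identical(rownames(truth$counts), feats$feature_id))

  samples <- colnames(truth$counts)
  reads_out <- vector("list", length(samples))
  names(reads_out) <- samples
  prov_out <- vector("list", length(samples))

  off_lv <- as.integer(names(config$isomir_offset_probs))
  nta_lv <- as.integer(names(config$nta_probs))
  bases <- c("A", "C", "G", "T")

  for (s in seq_along(samples)) {
    # independent streams for read construction and error injection, so the
    # same seed yields identical pre-error reads at any error rate
    set.seed(stage_seed(config$seed, paste0("reads_", s)))
    cnt <- truth$counts[, s]
    n <- sum(cnt)
    if (n == 0L) {
      reads_out[[s]] <- character(0)
      prov_out[[s]] <- NULL
      next
    }
    src <- rep.int(seq_len(nrow(feats)), cnt)
    cat_r <- feats$category[src]
    L <- nchar(fseqs)[src]

    offset <- integer(n)
    is_mir <- cat_r == "miRNA"
    if (any(is_mir)) {
      offset[is_mir] <- sample(off_lv, sum(is_mir), replace = TRUE,
                               prob = config$isomir_offset_probs)
    }
    frag_start <- offset + 1L
    frag_end <- L
    is_trna <- cat_r == "tRNA"
    if (any(is_trna)) {
      half <- stats::runif(sum(is_trna)) < config$trna_half_bias
      half_len <- L[is_trna] %/% 2L +
        sample(-5:5, sum(is_trna), replace = TRUE)
      frag_end[is_trna] <- ifelse(half, pmin(half_len, L[is_trna]), L[is_trna])
    }
    insert <- substring(fseqs[src], frag_start, frag_end)

    nta_len <- sample(nta_lv, n, replace = TRUE, prob = config$nta_probs)
    nta_str <- character(n)
    for (k in nta_lv[nta_lv > 0L]) {
      idx <- which(nta_len == k)
      if (!length(idx)) next
      m <- matrix(sample(bases, length(idx) * k, replace = TRUE), ncol = k)
      nta_str[idx] <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    }

    read <- substr(paste0(insert, nta_str, config$adapter_sequence),
                   1L, config$read_length)

    n_err <- integer(n)
    if (config$error_rate > 0) {
      set.seed(stage_seed(config$seed, paste0("readerr_", s)))
      n_err <- stats::rbinom(n, nchar(read), config$error_rate)
      for (i in which(n_err > 0L)) {
        pos <- sample.int(nchar(read[i]), n_err[i])
        for (p in pos) {
          cur <- substr(read[i], p, p)
          substr(read[i], p, p) <- sample(setdiff(bases, cur), 1L)
        }
      }
    }

    read_id <- sprintf("%s_read%07d", samples[s], seq_len(n))
    reads_out[[s]] <- setNames(read, read_id)
    prov_out[[s]] <- data.frame(
      read_id = read_id, sample_id = samples[s],
      feature_id = feats$feature_id[src], category = cat_r,
      offset_5p = offset, frag_start = frag_start, frag_end = frag_end,
      nta_len = nta_len, n_errors = n_err,
      stringsAsFactors = FALSE
    )
  }

  out <- list(reads = reads_out,
              provenance = do.call(rbind, prov_out),
              config = config)
  rownames(out$provenance) <- NULL
  class(out) <- "srna_readset"
  out
}

#' @export
print.srna_readset <- function(x, ...) {
  cat("srna_readset: ", length(x$reads), " sample(s), ",
      nrow(x$provenance), " reads\n", sep = "")
  invisible(x)
}

#' Write one sample's reads as FASTQ (Phred+33, constant quality)
#'
#' @param reads named character vector of read sequences.
#' @param path output FASTQ path.
#' @param quality_char constant quality character.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  seqs <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::BStringSet(strrep(quality_char, nchar(reads)))
  names(quals) <- names(seqs)
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file's sequences (qualities are not used by the pipeline)
#'
#' @param path FASTQ path (gzip transparent).
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}
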