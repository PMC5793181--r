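#' Trim the 3' adapter from read sequences
#'
#' Scans every start position in each read for an adapter match: the full
#' adapter internally, or an adapter prefix of at least `min_overlap` bases
#' running off the read's 3' end. A position qualifies when its mismatch
#' fraction over the overlap is `<= max_error_rate`; the read is cut at the
#' leftmost qualifying position. Reads with no qualifying match are returned
#' unchanged.
#'
#' @param reads character vector of read sequences (A/C/G/T/N).
#' @param adapter adapter sequence (A/C/G/T).
#' @param min_overlap minimum adapter bases required at the read's 3' end
#'   for a partial match (>= 3).
#' @param max_error_rate maximum mismatch fraction over the overlap.
#' @return character vector of trimmed sequences (possibly zero-length
#'   strings when the adapter starts at position 1).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L,
                         max_error_rate = 0.1) {
  stopifnot(nchar(adapter) > 0L, min_overlap >= 3L)
  n <- length(reads)
  if (n == 0L) return(character(0))
  len <- nchar(reads)
  maxlen <- max(len)
  alen <- nchar(adapter)
  achr <- strsplit(adapter, "")[[1]]

  # reads as a character matrix (rows = reads), NA beyond each read's end
  padded <- vapply(reads, function(r) {
    c(strsplit(r, "")[[1]], rep(NA_character_, maxlen - nchar(r)))
  }, character(maxlen), USE.NAMES = FALSE)
  padded <- t(padded)  # n x maxlen

  cut_at <- rep(NA_integer_, n)
  for (p in seq_len(maxlen)) {
    overlap <- pmin(alen, len - p + 1L)
    active <- is.na(cut_at) & overlap >= pmin(alen, min_overlap) & overlap >= 1L
    if (!any(active)) next
    jmax <- min(alen, maxlen - p + 1L)
    mm <- integer(n)
    for (j in seq_len(jmax)) {
      col <- padded[, p + j - 1L]
      mm <- mm + (j <= overlap & !is.na(col) & col != achr[j])
    }
    hit <- active & (mm / overlap) <= max_error_rate
    cut_at[hit] <- p
  }
  out <- reads
  idx <- !is.na(cut_at)
  out[idx] <- substr(reads[idx], 1L, cut_at[idx] - 1L)
  out
}

#' Discard reads shorter than a minimum length
#'
#' Reads shorter than `min_length` nucleotides (default 16) are dropped;
#' reads of exactly `min_length` are retained. Input order is preserved.
#'
#' @param reads character vector of (trimmed) read sequences.
#' @param min_length minimum retained length.
#' @return list with `retained` (character vector) and `n_discarded`.
#' @export
filter_by_length <- function(reads, min_length = 16L) {
  keep <- nchar(reads) >= min_length
  list(retained = reads[keep], n_discarded = sum(!keep))
}

#' Collapse reads into non-redundant tags with copy numbers
#'
#' @param reads character vector of usable (trimmed, length-filtered) reads.
#' @param sample_id sample label attached to every tag.
#' @return data.frame(sequence, copies, sample_id), one row per distinct
#'   sequence; `sum(copies)` equals `length(reads)`.
#' @export
collapse_tags <- function(reads, sample_id) {
  if (length(reads) == 0L) {
    return(data.frame(sequence = character(0), copies = integer(0),
                      sample_id = character(0), stringsAsFactors = FALSE))
  }
  tab <- table(reads)
  data.frame(sequence = names(tab), copies = as.integer(tab),
             sample_id = sample_id, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Summarize a preprocessed sample
#'
#' @param raw_reads raw read sequences.
#' @param trimmed_reads the same reads after adapter trimming.
#' @param min_length length filter applied to the trimmed reads.
#' @param sample_id sample label.
#' @return list of class `srna_preprocess_stats`: `stats` (n_raw,
#'   n_adapter_trimmed, n_too_short_discarded, n_usable, n_unique_tags),
#'   `length_hist` (table over usable read lengths) and `base_composition`
#'   (per-position base fractions over usable reads).
#' @export
qc_summary <- function(raw_reads, trimmed_reads, min_length = 16L,
                       sample_id = "sample") {
  stopifnot(length(raw_reads) == length(trimmed_reads))
  flt <- filter_by_length(trimmed_reads, min_length)
  usable <- flt$retained
  stats <- list(
    sample_id = sample_id,
    n_raw = length(raw_reads),
    n_adapter_trimmed = sum(nchar(trimmed_reads) < nchar(raw_reads)),
    n_too_short_discarded = flt$n_discarded,
    n_usable = length(usable),
    n_unique_tags = length(unique(usable))
  )
  length_hist <- if (length(usable)) table(nchar(usable)) else table(integer(0))
  base_composition <- if (length(usable)) {
    maxlen <- max(nchar(usable))
    comp <- matrix(0, nrow = 5, ncol = maxlen,
                   dimnames = list(c("A", "C", "G", "T", "N"), NULL))
    for (p in seq_len(maxlen)) {
      ch <- substr(usable, p, p)
      tab <- table(factor(ch[nchar(usable) >= p],
                          levels = c("A", "C", "G", "T", "N")))
      tot <- sum(tab)
      if (tot > 0) comp[, p] <- as.numeric(tab) / tot
    }
    comp
  } else NULL
  out <- list(stats = stats, length_hist = length_hist,
              base_composition = base_composition)
  class(out) <- "srna_preprocess_stats"
  out
}

#' @export
print.srna_preprocess_stats <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "%s: raw %d | adapter-trimmed %d | <16 nt discarded %d | usable %d | unique tags %d\n",
    s$sample_id, s$n_raw, s$n_adapter_trimmed, s$n_too_short_discarded,
    s$n_usable, s$n_unique_tags))
  invisible(x)
}

#' Preprocess one sample: trim, length-filter, collapse
#'
#' Orchestrates [trim_adapter()], [filter_by_length()], [collapse_tags()] and
#' [qc_summary()]. Trimming is computed once per distinct raw sequence and
#' expanded back by multiplicity, which leaves results identical to per-read
#' trimming (the trimmer is a pure function of the sequence) while keeping
#' deep samples fast.
#'
#' @param reads raw read sequences for one sample.
#' @param sample_id sample label.
#' @param adapter 3' adapter sequence.
#' @param min_overlap,max_error_rate see [trim_adapter()].
#' @param min_length see [filter_by_length()].
#' @param require_adapter drop reads in which no adapter was detected
#'   (default `FALSE`: such reads are kept, since long inserts legitimately
#'   fill the whole read). When `TRUE`, dropped reads are tallied in
#'   `n_no_adapter_discarded` and the funnel becomes
#'   `n_raw = n_usable + n_too_short_discarded + n_no_adapter_discarded`.
#' @return list of class `srna_tagset`: `tags` (data.frame sequence, copies,
#'   sample_id) and `qc` (an `srna_preprocess_stats`).
#' @export
preprocess_reads <- function(reads, sample_id, adapter,
                             min_overlap = 5L, max_error_rate = 0.1,
                             min_length = 16L, require_adapter = FALSE) {
  uniq <- collapse_tags(reads, sample_id)
  trimmed_u <- trim_adapter(uniq$sequence, adapter, min_overlap, max_error_rate)
  has_adapter <- nchar(trimmed_u) < nchar(uniq$sequence)
  no_adapter_dropped <- if (require_adapter) !has_adapter else
    rep(FALSE, length(trimmed_u))
  keep <- nchar(trimmed_u) >= min_length & !no_adapter_dropped
  if (any(keep)) {
    cp <- tapply(uniq$copies[keep], trimmed_u[keep], sum)
    tags <- data.frame(sequence = names(cp), copies = as.integer(cp),
                       sample_id = sample_id, stringsAsFactors = FALSE)
  } else {
    tags <- data.frame(sequence = character(0), copies = integer(0),
                       sample_id = character(0), stringsAsFactors = FALSE)
  }
  tags <- tags[order(tags$sequence), , drop = FALSE]
  rownames(tags) <- NULL

  stats <- list(
    sample_id = sample_id,
    n_raw = length(reads),
    n_adapter_trimmed = sum(uniq$copies[has_adapter]),
    n_too_short_discarded = sum(uniq$copies[!keep & !no_adapter_dropped]),
    n_no_adapter_discarded = sum(uniq$copies[no_adapter_dropped]),
    n_usable = sum(uniq$copies[keep]),
    n_unique_tags = nrow(tags)
  )
  # length histogram / composition over usable reads, weighted by copies
  usable_len <- rep.int(nchar(tags$sequence), tags$copies)
  qc <- list(
    stats = stats,
    length_hist = if (length(usable_len)) table(usable_len) else table(integer(0)),
    base_composition = NULL
  )
  class(qc) <- "srna_preprocess_stats"
  out <- list(tags = tags, qc = qc)
  class(out) <- "srna_tagset"
  out
}

#' Write collapsed tags as FASTA with `tag{i}_x{copies}` headers
#'
#' @param tags tag data.frame (sequence, copies, sample_id).
#' @param path output FASTA path.
#' @export
write_tags_fasta <- function(tags, path) {
  seqs <- Biostrings::DNAStringSet(tags$sequence)
  names(seqs) <- sprintf("tag%d_x%d", seq_len(nrow(tags)), tags$copies)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read collapsed tags from a `tag{i}_x{copies}` FASTA
#'
#' @param path FASTA path.
#' @param sample_id sample label for the returned tags.
#' @return tag data.frame (sequence, copies, sample_id).
#' @export
read_tags_fasta <- function(path, sample_id) {
  x <- Biostrings::readDNAStringSet(path)
  copies <- as.integer(sub(".*_x(\\d+)$", "\\1", names(x)))
  data.frame(sequence = as.character(x), copies = copies,
             sample_id = sample_id, stringsAsFactors = FALSE,
             row.names = NULL)
}
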