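#' Assign aligned tags to annotated sRNA features
#'
#' Each alignment hit is matched to same-strand features whose interval
#' overlaps at least `overlap_fraction` of the aligned span. Among all of a
#' tag's candidate (hit, feature) pairs, only the highest-priority category
#' survives (miRNA > tRNA > snoRNA > snRNA > yRNA > 7SK > 7SL); the tag's
#' unit weight is then split equally across the surviving distinct features.
#' Mapped tags with no surviving candidate get a single `unannotated`
#' assignment with weight 1.
#'
#' The 5' offset is strand-aware: on plus-strand features it is
#' `hit_start - feature_start`; on minus-strand features it is measured from
#' the feature's biological 5' end, `feature_end - hit_end`. miRNA
#' assignments at offsets +1/+2 are isomiR calls; offset 0 is canonical;
#' any other offset keeps contributing to the locus but carries class
#' `not_applicable`.
#'
#' @param hits alignment data.frame from [align_tags()].
#' @param features feature data.frame (see [build_reference()]).
#' @param overlap_fraction minimum overlap as a fraction of the aligned span.
#' @param strict_5p_offsets when `TRUE`, miRNA candidates at 5' offsets other
#'   than 0/+1/+2 are dropped before category selection (such tags may fall
#'   through to lower-priority categories or `unannotated`); the default
#'   `FALSE` keeps them as locus evidence with class `not_applicable`.
#' @return data.frame with one row per (tag, feature) assignment: `sequence`,
#'   `feature_id`, `category`, `anticodon`, `offset_5p`, `nta_length`,
#'   `aligned_length`, `mismatches`, `isomir_class`, `weight`.
#' @export
assign_tags <- function(hits, features, overlap_fraction = 0.8,
                        strict_5p_offsets = FALSE) {
  validate_features(features)
  if (nrow(hits) == 0L) {
    return(empty_assignments())
  }
  hit_gr <- GenomicRanges::GRanges(
    seqnames = hits$chrom,
    ranges = IRanges::IRanges(start = hits$start,
                              width = hits$aligned_length),
    strand = hits$strand
  )
  feat_gr <- features_to_granges(features)
  GenomeInfoDb::seqlevels(hit_gr) <- union(GenomeInfoDb::seqlevels(hit_gr),
                                           GenomeInfoDb::seqlevels(feat_gr))
  GenomeInfoDb::seqlevels(feat_gr) <- GenomeInfoDb::seqlevels(hit_gr)
  ov <- GenomicRanges::findOverlaps(hit_gr, feat_gr, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  if (length(qh)) {
    ow <- GenomicRanges::width(GenomicRanges::pintersect(
      hit_gr[qh], feat_gr[sh]
    ))
    keep <- ow >= overlap_fraction * hits$aligned_length[qh]
    qh <- qh[keep]; sh <- sh[keep]
  }

  cand <- data.frame(
    sequence = hits$sequence[qh],
    hit_row = qh,
    feature_id = features$feature_id[sh],
    category = features$category[sh],
    anticodon = features$anticodon[sh],
    nta_length = hits$nta_length[qh],
    aligned_length = hits$aligned_length[qh],
    mismatches = hits$mismatches[qh],
    stringsAsFactors = FALSE
  )
  # strand-aware 5' offset
  fs <- features$start[sh]; fe <- features$end[sh]
  hs <- hits$start[qh]; he <- hits$start[qh] + hits$aligned_length[qh] - 1L
  plus <- features$strand[sh] == "+"
  cand$offset_5p <- ifelse(plus, hs - fs, fe - he)
  if (strict_5p_offsets) {
    cand <- cand[!(cand$category == "miRNA" &
                     !cand$offset_5p %in% 0:2), , drop = FALSE]
  }

  out <- vector("list", 0L)
  seqs <- unique(hits$sequence)
  cand_split <- split(cand, cand$sequence)
  prio <- stats::setNames(seq_along(SRNA_CATEGORIES), SRNA_CATEGORIES)
  rows <- lapply(seqs, function(sq) {
    cc <- cand_split[[sq]]
    if (is.null(cc) || nrow(cc) == 0L) {
      return(data.frame(
        sequence = sq, feature_id = "unannotated", category = "unannotated",
        anticodon = NA_character_, offset_5p = NA_integer_,
        nta_length = hits$nta_length[match(sq, hits$sequence)],
        aligned_length = hits$aligned_length[match(sq, hits$sequence)],
        mismatches = hits$mismatches[match(sq, hits$sequence)],
        isomir_class = "not_applicable", weight = 1,
        stringsAsFactors = FALSE
      ))
    }
    best <- min(prio[cc$category])
    cc <- cc[prio[cc$category] == best, , drop = FALSE]
    # one row per distinct feature; if several hits touch the same feature,
    # keep the one with fewest mismatches, then smallest 5' offset
    cc <- cc[order(cc$feature_id, cc$mismatches, abs(cc$offset_5p)), ,
             drop = FALSE]
    cc <- cc[!duplicated(cc$feature_id), , drop = FALSE]
    cc$isomir_class <- vapply(seq_len(nrow(cc)), function(r) {
      if (cc$category[r] == "miRNA") call_isomir(cc$offset_5p[r]) else
        "not_applicable"
    }, character(1))
    cc$weight <- 1 / nrow(cc)
    cc[, c("sequence", "feature_id", "category", "anticodon", "offset_5p",
           "nta_length", "aligned_length", "mismatches", "isomir_class",
           "weight")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_assignments <- function() {
  data.frame(sequence = character(0), feature_id = character(0),
             category = character(0), anticodon = character(0),
             offset_5p = integer(0), nta_length = integer(0),
             aligned_length = integer(0), mismatches = integer(0),
             isomir_class = character(0), weight = numeric(0),
             stringsAsFactors = FALSE)
}

#' Classify a miRNA 5' offset as canonical / isomiR
#'
#' Offset 0 is the canonical 5' start; offsets +1 and +2 are the two isomiR
#' classes; any other offset is `not_applicable` (the read still counts as
#' locus evidence).
#'
#' @param offset_5p integer 5' offset relative to the annotated miRNA start
#'   (strand-aware, biological 5' end).
#' @param category assignment category; must be `"miRNA"`.
#' @return one of `"canonical"`, `"isomiR_plus1"`, `"isomiR_plus2"`,
#'   `"not_applicable"`.
#' @export
call_isomir <- function(offset_5p, category = "miRNA") {
  if (!identical(category, "miRNA")) {
    stop("isomiR classes are only defined for miRNA assignments")
  }
  if (is.na(offset_5p)) return("not_applicable")
  if (offset_5p == 0L) "canonical"
  else if (offset_5p == 1L) "isomiR_plus1"
  else if (offset_5p == 2L) "isomiR_plus2"
  else "not_applicable"
}

#' Build per-category count matrices from assignments
#'
#' The count of feature f in sample s is the sum over that sample's tags of
#' `copies x weight`. miRNA-locus evidence is split by isomiR class: reads
#' at offsets +1/+2 populate a separate `isomiR` matrix (rows
#' `feature:+1` / `feature:+2`), so that miRNA and isomiR act as distinct
#' species in downstream summaries; canonical and other-offset reads stay on
#' the miRNA rows. Per-sample unannotated totals are carried alongside, so
#' that `sum(all matrices) + unannotated = mapped copies` holds exactly.
#'
#' @param assignments data.frame from [assign_tags()].
#' @param tags tag data.frame (sequence, copies, sample_id), any number of
#'   samples.
#' @param features feature data.frame (fixes each matrix's row universe).
#' @param sample_ids optional explicit column order; defaults to the samples
#'   present in `tags`.
#' @return list of class `srna_quant`: `matrices` (named list of feature x
#'   sample matrices per category, plus `isomiR`), `unannotated` (per-sample
#'   totals), `mapped` (per-sample mapped copies).
#' @export
quantify <- function(assignments, tags, features, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- unique(tags$sample_id)
  if (!all(tags$sample_id %in% sample_ids)) {
    stop("tags contain sample ids absent from sample_ids")
  }
  m <- merge(tags, assignments, by = "sequence")
  m$value <- m$copies * m$weight

  # row label: isomiR reads go to "feature:+k" rows of the isomiR matrix
  iso <- m$category == "miRNA" & m$isomir_class %in% c("isomiR_plus1",
                                                       "isomiR_plus2")
  m$species <- m$category
  m$row_id <- m$feature_id
  m$species[iso] <- "isomiR"
  m$row_id[iso] <- paste0(m$feature_id[iso], ":+",
                          ifelse(m$isomir_class[iso] == "isomiR_plus1", 1, 2))

  cats <- intersect(c(SRNA_CATEGORIES, "isomiR"),
                    unique(c(m$species, features$category)))
  mats <- lapply(cats, function(cat) {
    rows <- if (cat == "isomiR") {
      sort(unique(m$row_id[m$species == "isomiR"]))
    } else {
      features$feature_id[features$category == cat]
    }
    mm <- matrix(0, nrow = length(rows), ncol = length(sample_ids),
                 dimnames = list(rows, sample_ids))
    sel <- m$species == cat & m$row_id %in% rows
    if (any(sel)) {
      agg <- tapply(m$value[sel], list(m$row_id[sel], m$sample_id[sel]), sum)
      mm[rownames(agg), colnames(agg)] <-
        ifelse(is.na(agg), 0, agg)
    }
    mm
  })
  names(mats) <- cats

  unann <- setNames(numeric(length(sample_ids)), sample_ids)
  sel <- m$category == "unannotated"
  if (any(sel)) {
    u <- tapply(m$value[sel], m$sample_id[sel], sum)
    unann[names(u)] <- u
  }
  mapped <- setNames(numeric(length(sample_ids)), sample_ids)
  mt <- tapply(m$copies * m$weight, m$sample_id, sum)
  mapped[names(mt)] <- mt

  out <- list(matrices = mats, unannotated = unann, mapped = mapped,
              sample_ids = sample_ids)
  class(out) <- "srna_quant"
  out
}

#' @export
print.srna_quant <- function(x, ...) {
  cat("srna_quant: ", length(x$matrices), " species matrices over ",
      length(x$sample_ids), " sample(s)\n", sep = "")
  for (cat_ in names(x$matrices)) {
    cat(sprintf("  %-8s %d features, %.0f copies\n", cat_,
                nrow(x$matrices[[cat_]]), sum(x$matrices[[cat_]])))
  }
  cat(sprintf("  unannotated copies: %.0f\n", sum(x$unannotated)))
  invisible(x)
}

#' Features detected per sample at incremental count thresholds
#'
#' @param matrix feature x sample count matrix.
#' @param thresholds strictly increasing positive thresholds.
#' @param metadata optional data.frame(sample_id, subtype); when given,
#'   per-subtype means are appended.
#' @return data.frame with columns `sample_id`, `threshold`, `n_detected`
#'   (and, with metadata, an attached `by_subtype` attribute of per-subtype
#'   mean detections).
#' @export
detection_curve <- function(matrix, thresholds = c(1, 5, 10, 15, 20),
                            metadata = NULL) {
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0)) {
    stop("thresholds must be strictly increasing and positive")
  }
  out <- do.call(rbind, lapply(colnames(matrix), function(s) {
    data.frame(sample_id = s, threshold = thresholds,
               n_detected = vapply(thresholds,
                                   function(t) sum(matrix[, s] >= t),
                                   numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(metadata)) {
    m <- merge(out, metadata[, c("sample_id", "subtype")], by = "sample_id")
    bs <- stats::aggregate(n_detected ~ subtype + threshold, data = m,
                           FUN = mean)
    attr(out, "by_subtype") <- bs
  }
  out
}

#' Rank features by median count across samples
#'
#' The per-feature median over samples (mean of the central pair for even
#' sample counts), sorted descending with ties broken lexicographically by
#' feature id.
#'
#' @param matrix feature x sample count matrix (>= 1 sample).
#' @return data.frame(feature_id, median_count), sorted.
#' @export
median_expression_profile <- function(matrix) {
  if (ncol(matrix) < 1L) stop("at least one sample required")
  med <- apply(matrix, 1, stats::median)
  out <- data.frame(feature_id = rownames(matrix), median_count = med,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$median_count, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
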