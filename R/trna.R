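#' Aggregate tRNA counts by anticodon family
#'
#' Sums locus-level tRNA counts into anticodon families (amino acid +
#' anticodon, e.g. `Val_CAC`) and converts them to per-sample fractions of
#' all tRNA counts.
#'
#' @param trna_matrix tRNA feature x sample count matrix.
#' @param features feature data.frame; every matrix row must be a tRNA
#'   feature with an anticodon label.
#' @return list of class `srna_anticodon_profile`: `counts` and `fractions`
#'   (family x sample matrices).
#' @export
aggregate_anticodon <- function(trna_matrix, features) {
  idx <- match(rownames(trna_matrix), features$feature_id)
  if (anyNA(idx)) stop("matrix rows missing from the feature table")
  if (any(features$category[idx] != "tRNA")) {
    stop("all matrix rows must be tRNA features")
  }
  anticodon <- features$anticodon[idx]
  if (anyNA(anticodon)) stop("tRNA feature without anticodon label")
  counts <- rowsum(trna_matrix, group = anticodon)
  totals <- colSums(counts)
  fractions <- sweep(counts, 2, ifelse(totals > 0, totals, 1), "/")
  out <- list(counts = counts, fractions = fractions)
  class(out) <- "srna_anticodon_profile"
  out
}

#' @export
print.srna_anticodon_profile <- function(x, ...) {
  cat("srna_anticodon_profile: ", nrow(x$counts), " families x ",
      ncol(x$counts), " samples\n", sep = "")
  avg <- sort(rowMeans(x$fractions), decreasing = TRUE)
  top <- utils::head(avg, 5)
  cat("  top families (mean fraction):",
      paste(sprintf("%s=%.3f", names(top), top), collapse = " "), "\n")
  invisible(x)
}

#' Positional read coverage over tRNA features
#'
#' Each tRNA-assigned tag adds `copies x weight` depth to feature positions
#' `offset_5p+1 .. offset_5p+aligned_length` (1-based, biological 5'->3'),
#' clipped to the feature. Per-locus profiles are pooled into their
#' anticodon family over 100 percentile-of-length bins so families of
#' different lengths are comparable; the 5'-half fraction (share of total
#' depth in the first half of the feature) is computed from the unbinned
#' depth. Reads whose offset falls outside `[-2, L)` are skipped and
#' tallied.
#'
#' @param assignments assignment data.frame restricted by the function to
#'   category tRNA.
#' @param tags tag data.frame (sequence, copies, sample_id).
#' @param features feature data.frame.
#' @param n_bins number of percentile bins for the pooled profile.
#' @return list of class `srna_coverage_profile`: `binned` (family x bin
#'   depth matrix), `five_prime_half_fraction` (named per family),
#'   `pooled_half_fraction` (over all families), `total_depth` (per family),
#'   `n_excluded` (reads skipped for out-of-range offsets).
#' @export
positional_coverage <- function(assignments, tags, features, n_bins = 100L) {
  a <- assignments[assignments$category == "tRNA", , drop = FALSE]
  cp <- tapply(tags$copies, tags$sequence, sum)  # copies pooled over samples
  a$copies <- as.numeric(cp[a$sequence])
  a <- a[!is.na(a$copies), , drop = FALSE]

  fl <- setNames(features$end - features$start + 1L, features$feature_id)
  fam <- setNames(features$anticodon, features$feature_id)
  families <- sort(unique(fam[!is.na(fam)]))

  n_excluded <- 0
  if (nrow(a)) {
    # accumulate per-locus depth vectors
    locus_depth <- list()
    for (r in seq_len(nrow(a))) {
      fid <- a$feature_id[r]
      L <- fl[[fid]]
      off <- a$offset_5p[r]
      if (is.na(off) || off < -2L || off >= L) {
        n_excluded <- n_excluded + a$copies[r] * a$weight[r]
        next
      }
      from <- max(off + 1L, 1L)
      to <- min(off + a$aligned_length[r], L)
      if (to < from) next
      if (is.null(locus_depth[[fid]])) locus_depth[[fid]] <- numeric(L)
      locus_depth[[fid]][from:to] <- locus_depth[[fid]][from:to] +
        a$copies[r] * a$weight[r]
    }
  } else locus_depth <- list()

  binned <- matrix(0, nrow = length(families), ncol = n_bins,
                   dimnames = list(families, NULL))
  half_num <- setNames(numeric(length(families)), families)
  half_den <- setNames(numeric(length(families)), families)
  for (fid in names(locus_depth)) {
    d <- locus_depth[[fid]]
    L <- length(d)
    f <- fam[[fid]]
    pos0 <- seq_len(L) - 1L
    bin <- pmin(n_bins, floor(pos0 / L * n_bins) + 1L)
    add <- rowsum(d, bin)
    binned[f, as.integer(rownames(add))] <-
      binned[f, as.integer(rownames(add))] + add[, 1]
    half_num[f] <- half_num[f] + sum(d[pos0 < L / 2])
    half_den[f] <- half_den[f] + sum(d)
  }
  five <- ifelse(half_den > 0, half_num / half_den, NA_real_)
  pooled <- if (sum(half_den) > 0) sum(half_num) / sum(half_den) else NA_real_
  out <- list(binned = binned,
              five_prime_half_fraction = five,
              pooled_half_fraction = pooled,
              total_depth = half_den,
              n_excluded = n_excluded)
  class(out) <- "srna_coverage_profile"
  out
}

#' @export
print.srna_coverage_profile <- function(x, ...) {
  cat("srna_coverage_profile: ", nrow(x$binned), " families, pooled 5'-half ",
      "fraction ", sprintf("%.3f", x$pooled_half_fraction), "\n", sep = "")
  invisible(x)
}

#' One-vs-rest differential test of anticodon-family fractions
#'
#' Compares each family's per-sample fraction of total tRNA counts between
#' one subtype and all other samples: effect = difference of group mean
#' fractions, p from a two-sided Wilcoxon rank-sum test, FDR by
#' Benjamini-Hochberg.
#'
#' @param profile an `srna_anticodon_profile` from [aggregate_anticodon()].
#' @param metadata data.frame(sample_id, subtype).
#' @param subtype the subtype compared against all others.
#' @param alpha FDR significance level.
#' @param on compare family `"fractions"` (default; total-tRNA-content
#'   differences cancel) or raw family `"counts"`.
#' @return data.frame(family, mean_in, mean_out, effect, p_value, fdr,
#'   significant), ordered by p.
#' @export
anticodon_differential <- function(profile, metadata, subtype, alpha = 0.05,
                                   on = c("fractions", "counts")) {
  fr <- profile[[match.arg(on)]]
  md <- metadata[match(colnames(fr), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stop("metadata missing for some samples")
  grp <- md$subtype == subtype
  if (sum(grp) < 2L || sum(!grp) < 2L) {
    stop("insufficient replication: need >= 2 samples per group")
  }
  res <- do.call(rbind, lapply(rownames(fr), function(f) {
    xi <- fr[f, grp]; xo <- fr[f, !grp]
    p <- if (all(xi == xi[1]) && all(xo == xo[1]) && xi[1] == xo[1]) 1 else
      suppressWarnings(stats::wilcox.test(xi, xo, exact = FALSE)$p.value)
    data.frame(family = f, mean_in = mean(xi), mean_out = mean(xo),
               effect = mean(xi) - mean(xo), p_value = p,
               stringsAsFactors = FALSE)
  }))
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$fdr < alpha
  res <- res[order(res$p_value, res$family), , drop = FALSE]
  rownames(res) <- NULL
  res
}
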