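#' Counts-per-million normalization
#'
#' @param matrix feature x sample count matrix with positive column sums.
#' @param log2 return `log2(CPM + 1)` instead of raw CPM.
#' @return normalized matrix of the same shape.
#' @export
normalize_cpm <- function(matrix, log2 = FALSE) {
  libsize <- colSums(matrix)
  if (any(libsize <= 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(matrix)[libsize <= 0], collapse = ", "))
  }
  cpm <- sweep(matrix, 2, libsize, "/") * 1e6
  if (log2) log2(cpm + 1) else cpm
}

#' Rank-aggregation differential expression test between two groups
#'
#' For every feature, three criteria are computed on `log2(CPM + 1)` values:
#' a two-sided Wilcoxon rank-sum p-value, a two-sided Welch t-test p-value,
#' and the log2 fold change of group mean CPM (with pseudocount 1). Features
#' are ranked by each criterion (ascending p, descending |lfc|) and the
#' aggregate rank is the sum of the three ranks — a rank-aggregation scheme
#' that combines evidence from several test statistics rather than trusting
#' any single one. FDR is Benjamini-Hochberg over the rank-sum p-values.
#' A feature is significant when `fdr < alpha` and `|lfc| >= lfc_min`.
#'
#' Extra per-feature p-value columns (e.g. from external count-model tests)
#' can be supplied via `extra_pvalues`; each adds one rank to the aggregate.
#'
#' @param matrix raw count matrix (features x samples).
#' @param metadata data.frame(sample_id, subtype) covering every column.
#' @param group_a subtype defining group A.
#' @param group_b subtype defining group B, or `"others"` for all remaining
#'   samples (one-vs-rest).
#' @param alpha FDR threshold.
#' @param lfc_min minimum |log2 fold change| for significance.
#' @param categories optional named vector feature_id -> sRNA category,
#'   carried into the result.
#' @param extra_pvalues optional data.frame of additional per-feature
#'   p-value columns (rownames = feature ids).
#' @return data.frame of class `srna_de_result`, sorted by aggregate rank
#'   (ties by feature id): feature_id, category, comparison,
#'   log2_fold_change, p_value (rank-sum), p_welch, fdr, aggregate_rank,
#'   significant.
#' @export
de_test <- function(matrix, metadata, group_a, group_b = "others",
                    alpha = 0.05, lfc_min = 1.0, categories = NULL,
                    extra_pvalues = NULL) {
  md <- metadata[match(colnames(matrix), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stop("metadata missing for some samples")
  in_a <- md$subtype == group_a
  in_b <- if (identical(group_b, "others")) !in_a else md$subtype == group_b
  if (sum(in_a) < 2L || sum(in_b) < 2L) {
    stop("insufficient replication: need >= 2 samples per group")
  }
  cpm <- normalize_cpm(matrix)
  lcpm <- log2(cpm + 1)

  n_feat <- nrow(matrix)
  p_rs <- p_t <- lfc <- numeric(n_feat)
  for (i in seq_len(n_feat)) {
    xa <- lcpm[i, in_a]; xb <- lcpm[i, in_b]
    if (length(unique(c(xa, xb))) == 1L) {
      p_rs[i] <- 1; p_t[i] <- 1
    } else {
      p_rs[i] <- suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
      p_t[i] <- if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
        if (xa[1] == xb[1]) 1 else 0
      } else {
        suppressWarnings(stats::t.test(xa, xb, var.equal = FALSE)$p.value)
      }
    }
    lfc[i] <- log2((mean(cpm[i, in_a]) + 1) / (mean(cpm[i, in_b]) + 1))
  }

  rank_cols <- cbind(rank(p_rs, ties.method = "min"),
                     rank(p_t, ties.method = "min"),
                     rank(-abs(lfc), ties.method = "min"))
  if (!is.null(extra_pvalues)) {
    ep <- as.matrix(extra_pvalues[rownames(matrix), , drop = FALSE])
    for (j in seq_len(ncol(ep))) {
      rank_cols <- cbind(rank_cols, rank(ep[, j], ties.method = "min"))
    }
  }
  agg <- as.integer(rowSums(rank_cols))
  fdr <- stats::p.adjust(p_rs, method = "BH")

  comparison <- paste(group_a, "vs",
                      if (identical(group_b, "others")) "others" else group_b)
  out <- data.frame(
    feature_id = rownames(matrix),
    category = if (is.null(categories)) NA_character_ else
      as.character(categories[rownames(matrix)]),
    comparison = comparison,
    log2_fold_change = lfc,
    p_value = p_rs,
    p_welch = p_t,
    fdr = fdr,
    aggregate_rank = agg,
    significant = fdr < alpha & abs(lfc) >= lfc_min,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$aggregate_rank, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("srna_de_result", "data.frame")
  out
}

#' @export
print.srna_de_result <- function(x, ...) {
  cat(sprintf("srna_de_result: %s | %d features | %d significant\n",
              x$comparison[1], nrow(x), sum(x$significant)))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  invisible(x)
}

#' Run all six pairwise subtype comparisons
#'
#' @param matrix,metadata,categories,... passed to [de_test()].
#' @return named list of `srna_de_result`, one per unordered subtype pair.
#' @export
pairwise_de <- function(matrix, metadata, categories = NULL, ...) {
  subtypes <- intersect(TNBC_SUBTYPES, unique(metadata$subtype))
  pairs <- utils::combn(subtypes, 2, simplify = FALSE)
  res <- lapply(pairs, function(p) {
    de_test(matrix, metadata, p[1], p[2], categories = categories, ...)
  })
  names(res) <- vapply(pairs, function(p) paste(p[1], "vs", p[2]), "")
  res
}

#' Summarize pairwise results as a comparisons x species count table
#'
#' Counts significant features per sRNA species for each of the six pairwise
#' subtype comparisons, with row and column totals.
#'
#' @param results named list of 6 pairwise `srna_de_result` objects whose
#'   `category` column is populated.
#' @param species column order (default: the eight quantified species).
#' @return matrix of counts with a `Total` row and column.
#' @export
pairwise_summary <- function(results,
                             species = c("miRNA", "isomiR", "tRNA", "snRNA",
                                         "snoRNA", "yRNA", "7SK", "7SL")) {
  if (length(results) != 6L) {
    stop("expected results for all 6 subtype pairs, got ", length(results))
  }
  tab <- t(vapply(results, function(r) {
    sig <- r[r$significant, , drop = FALSE]
    vapply(species, function(sp) sum(sig$category == sp, na.rm = TRUE),
           numeric(1))
  }, numeric(length(species))))
  tab <- cbind(tab, Total = rowSums(tab))
  rbind(tab, Total = colSums(tab))
}

#' Subtype-exclusive feature sets from one-vs-rest comparisons
#'
#' A feature is exclusive to subtype S when it is significant in "S vs
#' others" and in no other subtype's one-vs-rest comparison; the resulting
#' sets are pairwise disjoint by construction.
#'
#' @param ovr_results named list (subtype -> `srna_de_result`) of one-vs-rest
#'   results for every subtype present.
#' @return list of class `srna_exclusive_sets`: `sets` (subtype -> feature
#'   ids) and `species_table` (subtype x species counts) when categories are
#'   available.
#' @export
exclusive_sets <- function(ovr_results) {
  sig <- lapply(ovr_results, function(r) r$feature_id[r$significant])
  subtypes <- names(ovr_results)
  sets <- lapply(setNames(nm = subtypes), function(s) {
    others <- unlist(sig[setdiff(subtypes, s)], use.names = FALSE)
    setdiff(sig[[s]], others)
  })
  species_table <- NULL
  cats <- ovr_results[[1]]$category
  if (!all(is.na(cats))) {
    cat_of <- setNames(ovr_results[[1]]$category, ovr_results[[1]]$feature_id)
    species <- c("miRNA", "isomiR", "tRNA", "snRNA", "snoRNA", "yRNA",
                 "7SK", "7SL")
    species_table <- t(vapply(sets, function(f) {
      vapply(species, function(sp) sum(cat_of[f] == sp, na.rm = TRUE),
             numeric(1))
    }, numeric(length(species))))
    species_table <- cbind(species_table, Total = rowSums(species_table))
  }
  out <- list(sets = sets, species_table = species_table)
  class(out) <- "srna_exclusive_sets"
  out
}

#' @export
print.srna_exclusive_sets <- function(x, ...) {
  cat("srna_exclusive_sets:",
      paste(sprintf("%s=%d", names(x$sets), lengths(x$sets)),
            collapse = " "), "\n")
  invisible(x)
}
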