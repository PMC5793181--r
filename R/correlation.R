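#' Spearman rank correlation with small-sample permutation p-values
#'
#' rho is the Pearson correlation of mid-ranks (average ranks on ties). The
#' two-sided p-value uses the t approximation with n-2 degrees of freedom
#' for n >= 10; for n < 10 it is computed by permutation of one vector's
#' ranks — full enumeration when `n! <= 10000` (n <= 7), otherwise 10,000
#' sampled permutations (n = 8, 9 fall back to sampling when enumeration
#' exceeds the cap; with the default cap only n = 8 enumerates at 40320 >
#' 10000, so n = 8 and 9 sample).
#'
#' @param x,y equal-length numeric vectors (n >= 4), neither constant.
#' @return list(rho, p_value, n).
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (n >= 10L) {
    spearman_p_t(rho, n)
  } else {
    spearman_p_perm(rx, ry, rho)
  }
  list(rho = rho, p_value = p, n = n)
}

spearman_p_t <- function(rho, n) {
  r <- pmin(1 - 1e-15, pmax(-1 + 1e-15, rho))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

spearman_p_perm <- function(rx, ry, rho_obs, max_perm = 10000L) {
  n <- length(rx)
  eps <- 1e-12
  if (factorial(n) <= max_perm) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    mean(abs(rhos) >= abs(rho_obs) - eps)
  } else {
    # deterministic sampled permutations; global RNG state is untouched
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(20180129L)
    rhos <- replicate(max_perm, stats::cor(rx, ry[sample.int(n)]))
    (sum(abs(rhos) >= abs(rho_obs) - eps) + 1) / (max_perm + 1)
  }
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Correlate every sRNA row against every mRNA row
#'
#' Rows are transformed to `log2(CPM + 1)` on the shared samples and ranked;
#' the full rho matrix is one ranked-Pearson cross-correlation. All-constant
#' rows (e.g. all-zero counts) are dropped and audited. Benjamini-Hochberg
#' q-values are computed over all pairs within each sRNA category.
#'
#' @param srna,mrna count (or expression) matrices with sample columns.
#' @param min_samples minimum shared samples required.
#' @param categories optional named vector sRNA id -> category (q-values are
#'   adjusted within category); default treats all sRNAs as one category.
#' @param already_normalized set `TRUE` when inputs are expression values
#'   that should be ranked as-is rather than CPM-transformed.
#' @return data.frame of class `srna_correlations`: srna_id, mrna_id,
#'   category, rho, p_value, q_value, n_samples, sign; attribute `dropped`
#'   lists constant rows that were skipped.
#' @export
correlate_matrices <- function(srna, mrna, min_samples = 8L,
                               categories = NULL,
                               already_normalized = FALSE) {
  shared <- intersect(colnames(srna), colnames(mrna))
  if (length(shared) < min_samples) {
    stop("only ", length(shared), " shared samples; need >= ", min_samples)
  }
  a <- srna[, shared, drop = FALSE]
  b <- mrna[, shared, drop = FALSE]
  if (!already_normalized) {
    a <- normalize_cpm(a, log2 = TRUE)
    b <- normalize_cpm(b, log2 = TRUE)
  }
  const_a <- apply(a, 1, function(v) stats::sd(v) == 0)
  const_b <- apply(b, 1, function(v) stats::sd(v) == 0)
  dropped <- c(rownames(a)[const_a], rownames(b)[const_b])
  a <- a[!const_a, , drop = FALSE]
  b <- b[!const_b, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) stop("no non-constant rows to correlate")

  n <- length(shared)
  ra <- t(apply(a, 1, rank))
  rb <- t(apply(b, 1, rank))
  rho <- stats::cor(t(ra), t(rb))  # srna x mrna

  p <- if (n >= 10L) {
    spearman_p_t(rho, n)
  } else {
    matrix(mapply(function(i, j) {
      spearman_p_perm(ra[i, ], rb[j, ], rho[i, j])
    }, row(rho), col(rho)), nrow = nrow(rho))
  }

  out <- data.frame(
    srna_id = rep(rownames(a), times = ncol(rho)),
    mrna_id = rep(colnames(rho), each = nrow(rho)),
    category = NA_character_,
    rho = as.vector(rho),
    p_value = as.vector(p),
    n_samples = n,
    stringsAsFactors = FALSE
  )
  out$category <- if (is.null(categories)) "sRNA" else
    as.character(categories[out$srna_id])
  out$q_value <- stats::ave(out$p_value, out$category,
                            FUN = function(p) stats::p.adjust(p, "BH"))
  out$sign <- ifelse(out$rho > 0, "positive",
                     ifelse(out$rho < 0, "negative", "zero"))
  out <- out[, c("srna_id", "mrna_id", "category", "rho", "p_value",
                 "q_value", "n_samples", "sign")]
  attr(out, "dropped") <- dropped
  class(out) <- c("srna_correlations", "data.frame")
  out
}

#' Directional bias of correlations by |rho| bin
#'
#' Bins records into `[0, 0.1), ..., [0.9, 1.0]` on |rho| and reports, per
#' bin, the number of positive and negative correlations and the positive
#' fraction. Records with rho exactly 0 are excluded from both counts.
#'
#' @param records an `srna_correlations` data.frame (or any data.frame with
#'   `rho`).
#' @param bin_width bin width on |rho|.
#' @return data.frame(bin_lo, bin_hi, n_positive, n_negative,
#'   fraction_positive).
#' @export
direction_bias <- function(records, bin_width = 0.1) {
  if (nrow(records) == 0L) stop("no correlation records")
  r <- records$rho[records$rho != 0]
  n_bins <- as.integer(round(1 / bin_width))
  edges <- (0:n_bins) / n_bins
  # epsilon guards the left-closed bin edges against floating-point droop
  bin <- pmin(n_bins, floor(abs(r) / bin_width + 1e-9) + 1L)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(bk) {
    sel <- bin == bk
    npos <- sum(sel & r > 0)
    nneg <- sum(sel & r < 0)
    data.frame(bin_lo = edges[bk], bin_hi = edges[bk + 1L],
               n_positive = npos, n_negative = nneg,
               fraction_positive = if (npos + nneg > 0)
                 npos / (npos + nneg) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Per-gene counts of correlated miRNAs, split by gene class
#'
#' For every gene in the tumor-suppressor / oncogene list, counts the
#' distinct sRNAs whose correlation passes `|rho| >= rho_min` and
#' `q <= q_max`, partitioned by correlation sign.
#'
#' @param records an `srna_correlations` data.frame.
#' @param gene_classes data.frame(gene_id, class) with class in
#'   `tumor_suppressor` / `oncogene`.
#' @param rho_min,q_max thresholds.
#' @return data.frame(gene_id, class, n_negative_mirnas, n_positive_mirnas,
#'   in_records).
#' @export
gene_class_counts <- function(records, gene_classes, rho_min = 0.5,
                              q_max = 0.05) {
  stopifnot(all(c("gene_id", "class") %in% names(gene_classes)))
  if (anyDuplicated(gene_classes$gene_id)) {
    stop("each gene may appear once in the class list")
  }
  pass <- records[abs(records$rho) >= rho_min & records$q_value <= q_max, ,
                  drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(gene_classes)), function(i) {
    g <- gene_classes$gene_id[i]
    pg <- pass[pass$mrna_id == g, , drop = FALSE]
    data.frame(
      gene_id = g, class = gene_classes$class[i],
      n_negative_mirnas = length(unique(pg$srna_id[pg$rho < 0])),
      n_positive_mirnas = length(unique(pg$srna_id[pg$rho > 0])),
      in_records = g %in% records$mrna_id,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Subtype-resolved miRNA-target table
#'
#' Pairs subtype-differential miRNAs with class-listed genes they correlate
#' negatively with (passing the same thresholds as [gene_class_counts()]):
#' miRNAs UP in "S vs others" paired with negatively correlated genes give
#' relation `decreased_target_of_increased_miRNA`; miRNAs DOWN give
#' `increased_target_of_decreased_miRNA`.
#'
#' @param ovr_results named list (subtype -> `srna_de_result`) of one-vs-rest
#'   results.
#' @param records an `srna_correlations` data.frame.
#' @param gene_classes data.frame(gene_id, class).
#' @param rho_min,q_max correlation thresholds.
#' @return data.frame(subtype, gene_class, gene_id, srna_id, rho, q_value,
#'   log2_fold_change, relation).
#' @export
subtype_target_table <- function(ovr_results, records, gene_classes,
                                 rho_min = 0.5, q_max = 0.05) {
  pass <- records[abs(records$rho) >= rho_min & records$q_value <= q_max &
                    records$rho < 0, , drop = FALSE]
  pass <- pass[pass$mrna_id %in% gene_classes$gene_id, , drop = FALSE]
  cls <- setNames(gene_classes$class, gene_classes$gene_id)
  rows <- lapply(names(ovr_results), function(s) {
    r <- ovr_results[[s]]
    sig <- r[r$significant, , drop = FALSE]
    if (nrow(sig) == 0L) return(NULL)
    m <- merge(sig, pass, by.x = "feature_id", by.y = "srna_id")
    if (nrow(m) == 0L) return(NULL)
    data.frame(
      subtype = s,
      gene_class = as.character(cls[m$mrna_id]),
      gene_id = m$mrna_id,
      srna_id = m$feature_id,
      rho = m$rho,
      q_value = m$q_value,
      log2_fold_change = m$log2_fold_change,
      relation = ifelse(m$log2_fold_change > 0,
                        "decreased_target_of_increased_miRNA",
                        "increased_target_of_decreased_miRNA"),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(subtype = character(0), gene_class = character(0),
               gene_id = character(0), srna_id = character(0),
               rho = numeric(0), q_value = numeric(0),
               log2_fold_change = numeric(0), relation = character(0),
               stringsAsFactors = FALSE)
  }
  out <- out[order(out$subtype, out$gene_id, out$srna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a correlation network as edge-list and node-attribute tables
#'
#' @param records an `srna_correlations` data.frame (already thresholded by
#'   the caller, or pass `rho_min` / `q_max`).
#' @param gene_classes optional data.frame(gene_id, class) for node classes.
#' @param edge_path,node_path output TSV paths.
#' @param rho_min,q_max optional thresholds applied before export.
#' @return invisibly, list(edges, nodes) as written.
#' @export
export_network <- function(records, gene_classes = NULL,
                           edge_path, node_path,
                           rho_min = 0.5, q_max = 0.05) {
  pass <- records[abs(records$rho) >= rho_min & records$q_value <= q_max, ,
                  drop = FALSE]
  edges <- data.frame(
    source = pass$srna_id, target = pass$mrna_id,
    rho = pass$rho, sign = pass$sign, q_value = pass$q_value,
    stringsAsFactors = FALSE
  )
  edges <- edges[order(-abs(edges$rho), edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  cls <- if (is.null(gene_classes)) character(0) else
    setNames(gene_classes$class, gene_classes$gene_id)
  src <- unique(edges$source)
  tgt <- unique(edges$target)
  nodes <- rbind(
    data.frame(id = src, type = rep("miRNA", length(src)),
               class = rep(NA_character_, length(src)),
               stringsAsFactors = FALSE),
    data.frame(id = tgt, type = rep("gene", length(tgt)),
               class = ifelse(tgt %in% names(cls), cls[tgt], NA_character_),
               stringsAsFactors = FALSE)
  )
  nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  write_tsv(edges, edge_path)
  write_tsv(nodes, node_path)
  invisible(list(edges = edges, nodes = nodes))
}
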