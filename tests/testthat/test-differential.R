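# Direct count-matrix generator for DE tests: log-normal baselines,
# subtype-restricted fold-change spikes, multinomial sampling to fixed depth.
de_counts <- function(seed, n_feat = 200L, n_a = 7L, n_b = 7L,
                      spiked = character(0), lfc = 3,
                      reads = 200000L) {
  set.seed(seed)
  fids <- sprintf("f%03d", seq_len(n_feat))
  base <- 2^rnorm(n_feat, 6, 1.5)
  design <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n_a + n_b)),
    subtype = rep(c("BL1", "LAR"), c(n_a, n_b)),
    stringsAsFactors = FALSE
  )
  expected <- matrix(base, n_feat, n_a + n_b,
                     dimnames = list(fids, design$sample_id))
  expected[spiked, design$subtype == "BL1"] <-
    expected[spiked, design$subtype == "BL1"] * 2^lfc
  counts <- vapply(seq_len(ncol(expected)), function(j) {
    as.numeric(rmultinom(1, reads, expected[, j] / sum(expected[, j])))
  }, numeric(n_feat))
  dimnames(counts) <- dimnames(expected)
  list(counts = counts, design = design, spiked = spiked)
}

test_that("CPM normalization is exact, scale-invariant and zero-safe", {
  m <- matrix(c(1, 3), ncol = 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(normalize_cpm(m)[, 1]), c(250000, 750000))
  set.seed(2)
  r <- matrix(rpois(50, 20) + 1, nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:5)))
  expect_equal(normalize_cpm(r), normalize_cpm(r * 10))
  expect_true(all(abs(colSums(normalize_cpm(r)) - 1e6) < 1e-6))
  r0 <- r; r0[, 2] <- 0
  expect_error(normalize_cpm(r0), "s2")
})

test_that("constant features are never significant and get p = 1", {
  fx <- de_counts(5, n_feat = 20L)
  fx$counts[1, ] <- 50
  res <- de_test(fx$counts, fx$design, "BL1", "LAR")
  # equal CPM across samples requires equal library sizes too; use the
  # all-equal log-CPM row directly
  flat <- matrix(7, nrow = 2, ncol = 14,
                 dimnames = list(c("x", "y"), fx$design$sample_id))
  res2 <- de_test(flat, fx$design, "BL1", "LAR")
  expect_true(all(res2$p_value == 1))
  expect_false(any(res2$significant))
  expect_error(de_test(fx$counts[, c(1, 8:14)], fx$design, "BL1", "LAR"),
               "insufficient replication")
})

test_that("8-fold spikes are recovered with correct sign across seeds", {
  hits <- vapply(1:50, function(s) {
    fx <- de_counts(100 + s, n_feat = 200L,
                    spiked = sprintf("f%03d", 1:20), lfc = 3)
    res <- de_test(fx$counts, fx$design, "BL1", "LAR")
    sp <- res[res$feature_id %in% fx$spiked, ]
    all(sp$significant & sp$log2_fold_change > 0)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("type-I error under permuted labels stays near alpha", {
  # raw rank-sum p at alpha = 0.05; fraction of FDR-significant calls is
  # checked against the spec's alpha + 2*SE bound as well
  rates <- vapply(1:20, function(s) {
    fx <- de_counts(300 + s, n_feat = 200L)
    set.seed(9000 + s)
    fx$design$subtype <- sample(fx$design$subtype)
    res <- de_test(fx$counts, fx$design, "BL1", "LAR")
    c(mean(res$p_value < 0.05), mean(res$significant))
  }, numeric(2))
  expect_gt(mean(rates[1, ]), 0.02)
  expect_lt(mean(rates[1, ]), 0.08)
  se <- sd(rates[2, ]) / sqrt(ncol(rates))
  expect_lte(mean(rates[2, ]), 0.05 + 2 * se + 1e-6)
})

test_that("stronger spikes never worsen rank or fold change in expectation", {
  # hold the null background fixed per seed and scale only the spiked
  # feature's group-A counts; the spiked feature is low-abundance so the
  # scaling leaves library sizes (and hence every other feature's CPM)
  # essentially untouched, isolating the monotonicity property
  stats <- vapply(1:20, function(s) {
    fx <- de_counts(500 + s, n_feat = 100L)
    set.seed(50000 + s)
    fx$counts["f001", ] <- rpois(ncol(fx$counts), 150)
    in_a <- fx$design$subtype == "BL1"
    c2 <- fx$counts; c2["f001", in_a] <- c2["f001", in_a] * 4
    c3 <- fx$counts; c3["f001", in_a] <- c3["f001", in_a] * 8
    r2 <- de_test(c2, fx$design, "BL1", "LAR")
    r3 <- de_test(c3, fx$design, "BL1", "LAR")
    c(lfc2 = r2$log2_fold_change[r2$feature_id == "f001"],
      lfc3 = r3$log2_fold_change[r3$feature_id == "f001"],
      rank2 = r2$aggregate_rank[r2$feature_id == "f001"],
      rank3 = r3$aggregate_rank[r3$feature_id == "f001"])
  }, numeric(4))
  expect_true(all(stats["lfc3", ] >= stats["lfc2", ]))
  expect_lte(mean(stats["rank3", ]), mean(stats["rank2", ]))
})

test_that("results are invariant to sample column order", {
  fx <- de_counts(7, n_feat = 50L, spiked = "f010", lfc = 3)
  r1 <- de_test(fx$counts, fx$design, "BL1", "LAR")
  perm <- sample(ncol(fx$counts))
  r2 <- de_test(fx$counts[, perm], fx$design, "BL1", "LAR")
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("external p-value columns extend the rank aggregation", {
  fx <- de_counts(8, n_feat = 30L)
  extra <- data.frame(p_ext = runif(30), row.names = rownames(fx$counts))
  r0 <- de_test(fx$counts, fx$design, "BL1", "LAR")
  r1 <- de_test(fx$counts, fx$design, "BL1", "LAR", extra_pvalues = extra)
  expect_gt(sum(r1$aggregate_rank), sum(r0$aggregate_rank))
})

test_that("pairwise summary mirrors hand counts with exact marginals", {
  mk_res <- function(comparison, sig_cats) {
    n <- 10L
    cats <- c(sig_cats, rep("miRNA", n - length(sig_cats)))
    structure(data.frame(
      feature_id = paste0(comparison, "_f", seq_len(n)),
      category = cats, comparison = comparison,
      log2_fold_change = 2, p_value = 0.001, p_welch = 0.001, fdr = 0.01,
      aggregate_rank = seq_len(n),
      significant = c(rep(TRUE, length(sig_cats)), rep(FALSE, n - length(sig_cats))),
      stringsAsFactors = FALSE
    ), class = c("srna_de_result", "data.frame"))
  }
  pairs <- c("BL1 vs BL2", "BL1 vs M", "BL1 vs LAR", "BL2 vs M",
             "BL2 vs LAR", "M vs LAR")
  res <- list(
    mk_res(pairs[1], c("miRNA", "miRNA", "tRNA")),
    mk_res(pairs[2], c("snRNA")),
    mk_res(pairs[3], character(0)),
    mk_res(pairs[4], c("yRNA", "isomiR")),
    mk_res(pairs[5], c("7SK")),
    mk_res(pairs[6], c("miRNA"))
  )
  names(res) <- pairs
  tab <- pairwise_summary(res)
  expect_equal(unname(tab["BL1 vs BL2", "miRNA"]), 2)
  expect_equal(unname(tab["BL1 vs BL2", "Total"]), 3)
  expect_equal(unname(tab["BL1 vs LAR", "Total"]), 0)
  expect_equal(unname(tab["Total", "Total"]), 8)
  expect_equal(unname(tab["Total", ]),
               unname(colSums(tab[setdiff(rownames(tab), "Total"), ])))
  expect_error(pairwise_summary(res[1:5]), "6 subtype pairs")

  none <- lapply(res, function(r) { r$significant <- FALSE; r })
  expect_true(all(pairwise_summary(none) == 0))
})

test_that("exclusive sets follow the one-vs-rest definition and stay disjoint", {
  mk_ovr <- function(subtype, sig_ids) {
    ids <- paste0("f", 1:12)
    structure(data.frame(
      feature_id = ids, category = "miRNA",
      comparison = paste(subtype, "vs others"),
      log2_fold_change = 2, p_value = 0.01, p_welch = 0.01, fdr = 0.02,
      aggregate_rank = seq_along(ids), significant = ids %in% sig_ids,
      stringsAsFactors = FALSE
    ), class = c("srna_de_result", "data.frame"))
  }
  ovr <- list(BL1 = mk_ovr("BL1", c("f1", "f2")),
              BL2 = mk_ovr("BL2", c("f2", "f3")),
              M = mk_ovr("M", character(0)),
              LAR = mk_ovr("LAR", "f9"))
  ex <- exclusive_sets(ovr)
  expect_equal(ex$sets$BL1, "f1")      # f2 shared with BL2: excluded
  expect_equal(ex$sets$BL2, "f3")
  expect_equal(ex$sets$M, character(0))
  expect_equal(ex$sets$LAR, "f9")
  for (a in names(ex$sets)) {
    for (b in setdiff(names(ex$sets), a)) {
      expect_length(intersect(ex$sets[[a]], ex$sets[[b]]), 0)
    }
  }
})

test_that("spiked subtype signatures are recovered as exclusive sets", {
  # 3-fold spikes: the subtype's own one-vs-rest contrast clears the
  # |lfc| >= 1 gate (log2 3 ~ 1.58) while the cross-contrast induced in
  # other subtypes' comparisons (~0.8) does not; at much larger folds
  # one-vs-rest exclusivity intrinsically empties the sets because every
  # other comparison flags the marker with opposite sign
  sizes <- vapply(1:10, function(s) {
    set.seed(700 + s)
    n_feat <- 400L
    fids <- sprintf("f%03d", seq_len(n_feat))
    design <- data.frame(
      sample_id = sprintf("s%02d", 1:26),
      subtype = rep(c("BL1", "BL2", "M", "LAR"), c(7, 5, 7, 7)),
      stringsAsFactors = FALSE
    )
    base <- 2^rnorm(n_feat, 6, 1.5)
    expected <- matrix(base, n_feat, 26, dimnames = list(fids, design$sample_id))
    lar_spike <- sprintf("f%03d", 1:10)
    m_spike <- sprintf("f%03d", 11:15)
    expected[lar_spike, design$subtype == "LAR"] <-
      expected[lar_spike, design$subtype == "LAR"] * 3
    expected[m_spike, design$subtype == "M"] <-
      expected[m_spike, design$subtype == "M"] * 3
    counts <- vapply(1:26, function(j) {
      as.numeric(rmultinom(1, 200000, expected[, j] / sum(expected[, j])))
    }, numeric(n_feat))
    dimnames(counts) <- dimnames(expected)
    ovr <- lapply(setNames(nm = c("BL1", "BL2", "M", "LAR")), function(st) {
      de_test(counts, design, st, "others")
    })
    ex <- exclusive_sets(ovr)
    for (a in names(ex$sets)) {
      for (b in setdiff(names(ex$sets), a)) {
        expect_length(intersect(ex$sets[[a]], ex$sets[[b]]), 0)
      }
    }
    c(lar = length(ex$sets$LAR), m = length(ex$sets$M))
  }, numeric(2))
  expect_true(all(abs(sizes["lar", ] - 10) <= 2))
  expect_true(all(abs(sizes["m", ] - 5) <= 2))
})
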