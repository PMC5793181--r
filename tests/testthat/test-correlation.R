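test_that("spearman matches the explicit mid-rank Pearson oracle, with ties", {
  set.seed(14)
  for (i in 1:100) {
    x <- rnorm(12)
    y <- rnorm(12)
    if (i %% 3 == 0) {           # inject ties
      x[sample(12, 3)] <- x[1]
      y[sample(12, 2)] <- y[2]
    }
    sp <- spearman_cor(x, y)
    expect_equal(sp$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
    expect_equal(sp$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("monotone transforms leave rho unchanged; negation flips it", {
  set.seed(15)
  for (i in 1:100) {
    x <- rnorm(20)
    y <- rnorm(20)
    r <- spearman_cor(x, y)$rho
    expect_identical(spearman_cor(exp(x), y)$rho, r)
    expect_identical(spearman_cor(x, 3 * y + 7)$rho, r)
    expect_identical(spearman_cor(log(exp(x)), exp(y))$rho,
                     spearman_cor(x, y)$rho)
    expect_equal(spearman_cor(x, -y)$rho, -r, tolerance = 1e-12)
  }
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10)^3)$rho, -1)
  expect_error(spearman_cor(rep(1, 10), rnorm(10)), "constant")
})

test_that("small-sample p-values come from the permutation distribution", {
  set.seed(16)
  x <- rnorm(7)
  y <- rnorm(7)
  sp <- spearman_cor(x, y)
  # enumeration oracle over all 7! = 5040 orderings
  perms <- srnapipe:::permutations_of(7)
  rhos <- apply(perms, 1, function(p) cor(rank(x), rank(y)[p]))
  expect_equal(sp$p_value, mean(abs(rhos) >= abs(sp$rho) - 1e-12))
  # t-approximation branch for n >= 10 agrees with cor.test at moderate rho
  x2 <- rnorm(30); y2 <- 0.5 * x2 + rnorm(30)
  sp2 <- spearman_cor(x2, y2)
  ct <- suppressWarnings(cor.test(x2, y2, method = "spearman"))
  expect_equal(sp2$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_lt(abs(log10(sp2$p_value) - log10(ct$p.value)), 0.5)
})

test_that("matrix correlation recovers designated copula structure", {
  pair_tab <- data.frame(srna_id = c("miR-sim-1", "miR-sim-2"),
                         mrna_id = c("gene-1", "gene-2"),
                         target_rho = c(0.8, -0.8),
                         stringsAsFactors = FALSE)
  # signs must be recovered in every seed; the rho estimate is unbiased, so
  # its mean over seeds stays within the 0.15 band (individual draws at
  # n = 26 have sampling sd ~ 0.08 and may stray further)
  rhos <- vapply(1:20, function(s) {
    sim <- simulate_paired_expression(10, 10, 26, pair_tab, seed = 600 + s)
    rec <- correlate_matrices(sim$srna, sim$mrna, already_normalized = TRUE)
    r1 <- rec[rec$srna_id == "miR-sim-1" & rec$mrna_id == "gene-1", ]
    r2 <- rec[rec$srna_id == "miR-sim-2" & rec$mrna_id == "gene-2", ]
    expect_equal(r1$sign, "positive")
    expect_equal(r2$sign, "negative")
    c(pos = r1$rho, neg = r2$rho)
  }, numeric(2))
  expect_lt(abs(mean(rhos["pos", ]) - 0.8), 0.15)
  expect_lt(abs(mean(rhos["neg", ]) + 0.8), 0.15)
  expect_lt(mean(abs(c(rhos["pos", ] - 0.8, rhos["neg", ] + 0.8))), 0.15)
})

test_that("identical vectors give rho 1; independent matrices stay null", {
  m <- matrix(c(1, 5, 2, 9, 4, 7, 3, 8, 6, 10), nrow = 1,
              dimnames = list("a", paste0("s", 1:10)))
  m2 <- m
  rownames(m2) <- "b"
  rec <- correlate_matrices(m, m2, min_samples = 8,
                            already_normalized = TRUE)
  expect_equal(rec$rho, 1)

  sim <- simulate_paired_expression(50, 50, 26, NULL, seed = 888)
  rec2 <- correlate_matrices(sim$srna, sim$mrna, already_normalized = TRUE)
  expect_lt(abs(mean(rec2$rho)), 4 * sd(rec2$rho) / sqrt(nrow(rec2)))
  # constant rows are dropped and audited
  sim$srna[1, ] <- 5
  rec3 <- correlate_matrices(sim$srna, sim$mrna, already_normalized = TRUE)
  expect_true("miR-sim-1" %in% attr(rec3, "dropped"))
  expect_false("miR-sim-1" %in% rec3$srna_id)
  expect_error(correlate_matrices(sim$srna[, 1:5], sim$mrna[, 1:5]),
               "shared samples")
})

test_that("direction bias bins by |rho| and excludes zero-rho records", {
  rec <- data.frame(rho = c(0.5, 0.6, -0.5, 0, 0.65))
  bp <- direction_bias(rec)
  b56 <- bp[bp$bin_lo == 0.5, ]
  expect_equal(b56$n_positive, 1)
  expect_equal(b56$n_negative, 1)
  expect_equal(b56$fraction_positive, 0.5)
  b67 <- bp[bp$bin_lo == 0.6, ]
  expect_equal(b67$n_positive, 2)
  expect_equal(b67$fraction_positive, 1.0)
  expect_equal(sum(bp$n_positive + bp$n_negative), 4)  # zero excluded

  neg <- data.frame(rho = -runif(50, 0.05, 0.95))
  bpn <- direction_bias(neg)
  occ <- bpn[bpn$n_negative > 0, ]
  expect_true(all(occ$fraction_positive == 0))
})

test_that("a 70%-positive strong-pair mixture shows the expected bias profile", {
  pair_tab <- data.frame(
    srna_id = paste0("miR-sim-", 1:500),
    mrna_id = paste0("gene-", 1:500),
    target_rho = rep(c(0.8, -0.8), c(350, 150)),
    stringsAsFactors = FALSE
  )
  pooled <- do.call(rbind, lapply(1:20, function(s) {
    sim <- simulate_paired_expression(500, 500, 26, pair_tab, seed = 700 + s)
    ra <- t(apply(sim$srna, 1, rank))
    rb <- t(apply(sim$mrna, 1, rank))
    rho <- vapply(1:500, function(i) cor(ra[i, ], rb[i, ]), numeric(1))
    data.frame(rho = rho)
  }))
  bp <- direction_bias(pooled)
  strong <- bp[bp$bin_lo >= 0.6 & (bp$n_positive + bp$n_negative) > 0, ]
  frac <- sum(strong$n_positive) / sum(strong$n_positive + strong$n_negative)
  expect_lt(abs(frac - 0.7), 0.05)
})

test_that("gene-class counts apply thresholds by brute-force comparison", {
  rec <- data.frame(
    srna_id = c("m1", "m2", "m3", "m4", "m5"),
    mrna_id = c("G", "G", "G", "G", "H"),
    rho = c(-0.7, -0.6, 0.8, -0.3, 0.9),
    q_value = c(0.01, 0.01, 0.01, 0.01, 0.2),
    stringsAsFactors = FALSE
  )
  classes <- data.frame(gene_id = c("G", "H", "Z"),
                        class = c("tumor_suppressor", "oncogene",
                                  "oncogene"),
                        stringsAsFactors = FALSE)
  gc <- gene_class_counts(rec, classes, rho_min = 0.5, q_max = 0.05)
  expect_equal(gc$n_negative_mirnas[gc$gene_id == "G"], 2L)
  expect_equal(gc$n_positive_mirnas[gc$gene_id == "G"], 1L)
  expect_equal(gc$n_positive_mirnas[gc$gene_id == "H"], 0L)  # q too high
  expect_false(gc$in_records[gc$gene_id == "Z"])
  expect_true(all(gene_class_counts(rec, classes,
                                    rho_min = 1.01)$n_negative_mirnas == 0))

  set.seed(18)
  big <- data.frame(
    srna_id = sample(paste0("m", 1:30), 400, TRUE),
    mrna_id = sample(c("G", "H"), 400, TRUE),
    rho = runif(400, -1, 1),
    q_value = runif(400, 0, 0.2),
    stringsAsFactors = FALSE
  )
  big <- big[!duplicated(big[, c("srna_id", "mrna_id")]), ]
  gc2 <- gene_class_counts(big, classes)
  for (g in c("G", "H")) {
    sel <- big$mrna_id == g & abs(big$rho) >= 0.5 & big$q_value <= 0.05
    expect_equal(gc2$n_negative_mirnas[gc2$gene_id == g],
                 length(unique(big$srna_id[sel & big$rho < 0])))
    expect_equal(gc2$n_positive_mirnas[gc2$gene_id == g],
                 length(unique(big$srna_id[sel & big$rho > 0])))
  }
})

test_that("subtype target table pairs up-miRNAs with anti-correlated genes", {
  ovr <- list(LAR = structure(data.frame(
    feature_id = c("miR-X", "miR-Y"), category = "miRNA",
    comparison = "LAR vs others",
    log2_fold_change = c(2.5, -2.5), p_value = 1e-4, p_welch = 1e-4,
    fdr = 0.01, aggregate_rank = 1:2, significant = TRUE,
    stringsAsFactors = FALSE
  ), class = c("srna_de_result", "data.frame")),
  M = structure(data.frame(
    feature_id = "miR-Z", category = "miRNA", comparison = "M vs others",
    log2_fold_change = 2, p_value = 1e-4, p_welch = 1e-4, fdr = 0.01,
    aggregate_rank = 1L, significant = FALSE, stringsAsFactors = FALSE
  ), class = c("srna_de_result", "data.frame")))
  rec <- data.frame(
    srna_id = c("miR-X", "miR-Y", "miR-Z"),
    mrna_id = c("GATA3", "GATA3", "VHL"),
    rho = c(-0.7, -0.8, -0.9),
    q_value = c(0.01, 0.01, 0.01),
    sign = "negative",
    stringsAsFactors = FALSE
  )
  classes <- data.frame(gene_id = c("GATA3", "VHL"),
                        class = "tumor_suppressor", stringsAsFactors = FALSE)
  tab <- subtype_target_table(ovr, rec, classes)
  expect_equal(nrow(tab), 2L)  # miR-Z not significant: no M rows
  xr <- tab[tab$srna_id == "miR-X", ]
  expect_equal(xr$subtype, "LAR")
  expect_equal(xr$gene_id, "GATA3")
  expect_equal(xr$relation, "decreased_target_of_increased_miRNA")
  yr <- tab[tab$srna_id == "miR-Y", ]
  expect_equal(yr$relation, "increased_target_of_decreased_miRNA")
  expect_false("M" %in% tab$subtype)
})

test_that("network export is deterministic with complete node sets", {
  rec <- data.frame(
    srna_id = c("m1", "m2", "m3"), mrna_id = c("G", "H", "G"),
    rho = c(-0.9, 0.6, 0.7), q_value = c(0.001, 0.01, 0.01),
    sign = c("negative", "positive", "positive"),
    stringsAsFactors = FALSE
  )
  classes <- data.frame(gene_id = c("G", "H"),
                        class = c("tumor_suppressor", "oncogene"),
                        stringsAsFactors = FALSE)
  d <- withr::local_tempdir()
  out <- export_network(rec, classes, file.path(d, "e1.tsv"),
                        file.path(d, "n1.tsv"))
  expect_equal(nrow(out$edges), 3L)
  expect_equal(out$edges$source[1], "m1")  # sorted by |rho| descending
  expect_setequal(out$nodes$id, c("m1", "m2", "m3", "G", "H"))
  export_network(rec, classes, file.path(d, "e2.tsv"), file.path(d, "n2.tsv"))
  expect_identical(readLines(file.path(d, "e1.tsv")),
                   readLines(file.path(d, "e2.tsv")))
  expect_identical(readLines(file.path(d, "n1.tsv")),
                   readLines(file.path(d, "n2.tsv")))

  empty <- rec[0, ]
  out0 <- export_network(empty, classes, file.path(d, "e0.tsv"),
                         file.path(d, "n0.tsv"))
  expect_equal(nrow(out0$edges), 0L)
  expect_equal(length(readLines(file.path(d, "e0.tsv"))), 1L)  # header only
})
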