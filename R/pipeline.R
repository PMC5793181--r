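#' Run the full synthetic-data pipeline end to end
#'
#' Executes, in order: simulate (reference + counts + reads), preprocess
#' (trim / length-filter / collapse per sample), quantify (align, annotate,
#' count, detection curves, median profiles), trna (anticodon fractions,
#' positional coverage), de (pairwise and one-vs-rest differential tests,
#' exclusive sets) and — when a paired mRNA matrix is supplied — correlate
#' (sRNA-mRNA Spearman records, direction bias, gene-class counts, network
#' export). Every stage writes its outputs under `outdir` and the run ends
#' with a manifest of output files and md5 checksums plus explicit
#' conservation checks (read-count funnel and count-matrix totals).
#'
#' @param config an [srna_sim_config()]; all randomness derives from its
#'   seed, so two runs with the same config produce byte-identical outputs.
#' @param outdir output directory (created if needed).
#' @param force overwrite an existing non-empty `outdir`.
#' @param mrna_matrix optional gene x sample expression matrix sharing
#'   sample ids with the design (enables the correlate stage).
#' @param gene_classes optional data.frame(gene_id, class).
#' @param min_overlap,max_error_rate adapter-trimming parameters.
#' @param overlap_fraction feature-assignment overlap threshold.
#' @param alpha,lfc_min differential-test thresholds.
#' @param rho_min,q_max correlation network thresholds.
#' @return list of class `srna_run_report`: `stages` (status data.frame),
#'   `manifest` (file + md5), `checks` (named logicals), and the in-memory
#'   stage outputs (`reference`, `truth`, `tags`, `quant`, `de`, ...).
#' @export
run_pipeline <- function(config, outdir, force = FALSE,
                         mrna_matrix = NULL, gene_classes = NULL,
                         min_overlap = 5L, max_error_rate = 0.1,
                         overlap_fraction = 0.8,
                         alpha = 0.05, lfc_min = 1.0,
                         rho_min = 0.5, q_max = 0.05) {
  validate_sim_config(config)
  if (dir.exists(outdir) && length(list.files(outdir)) && !force) {
    stop("output directory exists and is non-empty; use force = TRUE")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  checks <- list()
  path <- function(...) file.path(outdir, ...)

  ## --- simulate -----------------------------------------------------------
  ref <- build_reference(config)
  truth <- simulate_counts(config, ref$features)
  readset <- synthesize_reads(truth, ref, config)
  write_reference(ref, path("genome.fa"), path("features.gff3"))
  dir.create(path("fastq"), showWarnings = FALSE)
  for (s in names(readset$reads)) {
    write_fastq(readset$reads[[s]], path("fastq", paste0(s, ".fastq")),
                config$quality_char)
  }
  write_matrix_tsv(truth$counts, path("truth_counts.tsv"))
  write_tsv(readset$provenance, path("truth_provenance.tsv"))
  write_tsv(config$design, path("metadata.tsv"))
  stages <- c(stages, "simulate")

  ## --- preprocess ---------------------------------------------------------
  tag_list <- list()
  stat_rows <- list()
  for (s in names(readset$reads)) {
    pp <- preprocess_reads(readset$reads[[s]], s, config$adapter_sequence,
                           min_overlap, max_error_rate)
    tag_list[[s]] <- pp$tags
    stat_rows[[s]] <- as.data.frame(pp$qc$stats, stringsAsFactors = FALSE)
  }
  tags <- do.call(rbind, tag_list)
  rownames(tags) <- NULL
  pstats <- do.call(rbind, stat_rows)
  rownames(pstats) <- NULL
  write_tsv(pstats, path("preprocess_stats.tsv"))
  dir.create(path("tags"), showWarnings = FALSE)
  for (s in names(tag_list)) {
    write_tags_fasta(tag_list[[s]], path("tags", paste0(s, ".fa")))
  }
  checks$preprocess_conservation <- all(
    pstats$n_raw == pstats$n_usable + pstats$n_too_short_discarded +
      pstats$n_no_adapter_discarded
  ) && all(vapply(names(tag_list), function(s) {
    sum(tag_list[[s]]$copies) == pstats$n_usable[pstats$sample_id == s]
  }, logical(1)))
  stages <- c(stages, "preprocess")

  ## --- quantify -----------------------------------------------------------
  gidx <- genome_index(ref$genome)
  useq <- sort(unique(tags$sequence))
  hits <- align_tags(useq, gidx)
  assignments <- assign_tags(hits, ref$features, overlap_fraction)
  quant <- quantify(assignments, tags, ref$features,
                    sample_ids = config$design$sample_id)
  dir.create(path("counts"), showWarnings = FALSE)
  for (cat_ in names(quant$matrices)) {
    write_matrix_tsv(quant$matrices[[cat_]],
                     path("counts", paste0(gsub("7", "RN7", cat_), ".tsv")))
  }
  write_tsv(assignments, path("assignment_audit.tsv"))
  curves <- lapply(quant$matrices, detection_curve, metadata = config$design)
  write_tsv(do.call(rbind, Map(function(cat_, d) {
    cbind(species = cat_, d)
  }, names(curves), curves)), path("detection_curves.tsv"))
  medians <- do.call(rbind, Map(function(cat_, m) {
    cbind(species = cat_, median_expression_profile(m))
  }, names(quant$matrices), quant$matrices))
  write_tsv(medians, path("median_expression.tsv"))
  total_counted <- Reduce(`+`, lapply(quant$matrices, colSums)) +
    quant$unannotated
  checks$quantify_conservation <-
    isTRUE(all.equal(unname(total_counted), unname(quant$mapped),
                     tolerance = 1e-9))
  stages <- c(stages, "quantify")

  ## --- trna ---------------------------------------------------------------
  trna_de <- NULL
  if (!is.null(quant$matrices$tRNA) && nrow(quant$matrices$tRNA)) {
    acp <- aggregate_anticodon(quant$matrices$tRNA, ref$features)
    cov <- positional_coverage(assignments, tags, ref$features)
    write_matrix_tsv(acp$fractions, path("trna_anticodon_fractions.tsv"))
    write_matrix_tsv(cov$binned, path("trna_coverage_bins.tsv"))
    write_tsv(data.frame(family = names(cov$five_prime_half_fraction),
                         five_prime_half_fraction =
                           unname(cov$five_prime_half_fraction),
                         stringsAsFactors = FALSE),
              path("trna_half_fractions.tsv"))
    trna_de <- lapply(setNames(nm = intersect(TNBC_SUBTYPES,
                                              unique(config$design$subtype))),
                      function(s) {
                        anticodon_differential(acp, config$design, s, alpha)
                      })
    write_tsv(do.call(rbind, Map(function(s, d) cbind(subtype = s, d),
                                 names(trna_de), trna_de)),
              path("trna_anticodon_differential.tsv"))
    stages <- c(stages, "trna")
  } else {
    acp <- NULL; cov <- NULL
  }

  ## --- de -----------------------------------------------------------------
  all_counts <- do.call(rbind, quant$matrices)
  cat_of <- setNames(
    rep(names(quant$matrices), vapply(quant$matrices, nrow, 1L)),
    unlist(lapply(quant$matrices, rownames), use.names = FALSE)
  )
  rownames(all_counts) <- names(cat_of)
  pw <- pairwise_de(all_counts, config$design, categories = cat_of,
                    alpha = alpha, lfc_min = lfc_min)
  # the comparisons x species table requires the full four-subtype design
  pw_tab <- if (length(pw) == 6L) pairwise_summary(pw) else NULL
  ovr <- lapply(setNames(nm = intersect(TNBC_SUBTYPES,
                                        unique(config$design$subtype))),
                function(s) {
                  de_test(all_counts, config$design, s, "others",
                          alpha = alpha, lfc_min = lfc_min,
                          categories = cat_of)
                })
  excl <- exclusive_sets(ovr)
  dir.create(path("de"), showWarnings = FALSE)
  for (nm in names(pw)) {
    write_tsv(as.data.frame(pw[[nm]]),
              path("de", paste0(gsub(" ", "_", nm), ".tsv")))
  }
  for (nm in names(ovr)) {
    write_tsv(as.data.frame(ovr[[nm]]),
              path("de", paste0(nm, "_vs_others.tsv")))
  }
  if (!is.null(pw_tab)) {
    write_matrix_tsv(pw_tab, path("de", "pairwise_summary.tsv"))
  }
  if (!is.null(excl$species_table)) {
    write_matrix_tsv(excl$species_table, path("de", "exclusive_summary.tsv"))
  }
  write_tsv(data.frame(
    subtype = rep(names(excl$sets), lengths(excl$sets)),
    feature_id = unlist(excl$sets, use.names = FALSE),
    stringsAsFactors = FALSE
  ), path("de", "exclusive_features.tsv"))
  stages <- c(stages, "de")

  ## --- correlate ----------------------------------------------------------
  cor_records <- NULL
  if (!is.null(mrna_matrix)) {
    srna_mat <- quant$matrices$miRNA
    cor_records <- correlate_matrices(srna_mat, mrna_matrix,
                                      categories = setNames(
                                        rep("miRNA", nrow(srna_mat)),
                                        rownames(srna_mat)))
    write_tsv(as.data.frame(cor_records), path("correlations.tsv"))
    write_tsv(direction_bias(cor_records), path("correlation_bias.tsv"))
    if (!is.null(gene_classes)) {
      write_tsv(gene_class_counts(cor_records, gene_classes,
                                  rho_min, q_max),
                path("gene_class_counts.tsv"))
      write_tsv(subtype_target_table(ovr, cor_records, gene_classes,
                                     rho_min, q_max),
                path("subtype_targets.tsv"))
      export_network(cor_records, gene_classes,
                     path("network_edges.tsv"), path("network_nodes.tsv"),
                     rho_min, q_max)
    }
    stages <- c(stages, "correlate")
  }

  ## --- manifest -----------------------------------------------------------
  files <- sort(list.files(outdir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, path("manifest.tsv"))

  if (!all(unlist(checks))) {
    stop("conservation check failed: ",
         paste(names(checks)[!unlist(checks)], collapse = ", "))
  }
  report <- list(
    stages = data.frame(stage = stages, status = "ok",
                        stringsAsFactors = FALSE),
    manifest = manifest,
    checks = checks,
    outdir = outdir,
    reference = ref, truth = truth, tags = tags, quant = quant,
    anticodon = acp, coverage = cov, trna_de = trna_de,
    pairwise = pw, pairwise_table = pw_tab, one_vs_rest = ovr,
    exclusive = excl, correlations = cor_records
  )
  class(report) <- "srna_run_report"
  report
}

#' @export
print.srna_run_report <- function(x, ...) {
  cat("srna_run_report:", x$outdir, "\n")
  cat("  stages:", paste(x$stages$stage, collapse = " -> "), "\n")
  cat("  checks:", paste(sprintf("%s=%s", names(x$checks),
                                 unlist(x$checks)), collapse = " "), "\n")
  cat("  outputs:", nrow(x$manifest), "files\n")
  invisible(x)
}
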