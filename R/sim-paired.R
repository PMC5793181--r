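#' Simulate paired sRNA/mRNA expression with controlled Spearman structure
#'
#' Gaussian-copula generator: designated (sRNA, mRNA) pairs share a latent
#' bivariate normal with Pearson correlation `r = 2*sin(pi*rho_s/6)` — the
#' exact inverse of the Spearman-Pearson relation for bivariate Gaussians —
#' so the population Spearman correlation of the pair equals `target_rho`.
#' Latents are mapped through a strictly monotone log-normal transform to
#' positive, expression-like values (rank structure, and hence Spearman
#' correlation, is preserved exactly). Non-designated row pairs are
#' independent.
#'
#' @param n_srna,n_mrna,n_samples matrix dimensions.
#' @param pair_table data.frame(srna_id, mrna_id, target_rho); each id may
#'   appear in at most one pair; `target_rho` in `[-1, 1]`. May be `NULL`.
#' @param seed integer seed.
#' @param srna_prefix,mrna_prefix row-name prefixes.
#' @return list of class `srna_paired_sim`: `srna`, `mrna` (row x sample
#'   matrices), `truth` (pair table with the latent Pearson r used).
#' @export
simulate_paired_expression <- function(n_srna, n_mrna, n_samples,
                                       pair_table = NULL, seed = 1L,
                                       srna_prefix = "miR-sim-",
                                       mrna_prefix = "gene-") {
  srna_ids <- paste0(srna_prefix, seq_len(n_srna))
  mrna_ids <- paste0(mrna_prefix, seq_len(n_mrna))
  if (!is.null(pair_table) && nrow(pair_table) > 0L) {
    stopifnot(all(c("srna_id", "mrna_id", "target_rho") %in% names(pair_table)))
    if (any(abs(pair_table$target_rho) > 1)) {
      stop("target_rho must lie in [-1, 1]")
    }
    if (anyDuplicated(pair_table$srna_id) || anyDuplicated(pair_table$mrna_id)) {
      stop("each id may appear in at most one designated pair")
    }
    bad <- c(setdiff(pair_table$srna_id, srna_ids),
             setdiff(pair_table$mrna_id, mrna_ids))
    if (length(bad)) stop("pair_table names unknown id(s): ",
                          paste(bad, collapse = ", "))
  }
  set.seed(stage_seed(seed, "paired"))

  z_srna <- matrix(stats::rnorm(n_srna * n_samples), nrow = n_srna,
                   dimnames = list(srna_ids, sprintf("S%02d", seq_len(n_samples))))
  z_mrna <- matrix(stats::rnorm(n_mrna * n_samples), nrow = n_mrna,
                   dimnames = list(mrna_ids, colnames(z_srna)))

  truth <- data.frame(srna_id = character(0), mrna_id = character(0),
                      target_rho = numeric(0), latent_r = numeric(0),
                      stringsAsFactors = FALSE)
  if (!is.null(pair_table) && nrow(pair_table) > 0L) {
    r <- 2 * sin(pi * pair_table$target_rho / 6)
    for (k in seq_len(nrow(pair_table))) {
      zi <- z_srna[pair_table$srna_id[k], ]
      eps <- z_mrna[pair_table$mrna_id[k], ]
      z_mrna[pair_table$mrna_id[k], ] <- r[k] * zi + sqrt(1 - r[k]^2) * eps
    }
    truth <- data.frame(pair_table[, c("srna_id", "mrna_id", "target_rho")],
                        latent_r = r, stringsAsFactors = FALSE)
  }

  # strictly monotone map to positive expression-like values
  out <- list(
    srna = exp(log(500) + 1.2 * z_srna),
    mrna = exp(log(2000) + 1.2 * z_mrna),
    truth = truth
  )
  class(out) <- "srna_paired_sim"
  out
}
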