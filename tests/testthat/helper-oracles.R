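# Independent brute-force oracles used to validate the optimized
# implementations. These deliberately share no code with the package
# internals: character-by-character scans, full-position alignment sweeps,
# and explicit mid-rank formulas.

# --- adapter trimming: scan every start position, char by char ------------
oracle_trim <- function(read, adapter, min_overlap = 5L, max_error_rate = 0.1) {
  L <- nchar(read)
  A <- nchar(adapter)
  for (p in seq_len(L)) {
    overlap <- min(A, L - p + 1L)
    if (overlap < min(A, min_overlap)) next
    mm <- 0L
    for (j in seq_len(overlap)) {
      if (substr(read, p + j - 1L, p + j - 1L) != substr(adapter, j, j)) {
        mm <- mm + 1L
      }
    }
    if (mm / overlap <= max_error_rate) return(substr(read, 1L, p - 1L))
  }
  read
}

# --- alignment: exhaustive scan over positions, strands, trim lengths -----
# Returns a data.frame(chrom, start, strand, mismatches, nta_length,
# aligned_length) of the best tier (fewest mismatches, then smallest k),
# matching align_tags()'s contract, or a 0-row frame.
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

oracle_align_one <- function(tag, genome_chars, max_mismatch = 1L,
                             max_nta = 3L, min_len = 16L) {
  gint <- lapply(genome_chars, utf8ToInt)
  rows <- list()
  n <- nchar(tag)
  for (k in 0:max_nta) {
    alen <- n - k
    if (alen < min_len) break
    for (strand in c("+", "-")) {
      q <- substr(tag, 1L, alen)
      if (strand == "-") q <- oracle_revcomp(q)
      qi <- utf8ToInt(q)
      for (ci in seq_along(gint)) {
        g <- gint[[ci]]
        npos <- length(g) - alen + 1L
        if (npos < 1L) next
        mm <- integer(npos)
        for (j in seq_len(alen)) {
          mm <- mm + (g[j:(j + npos - 1L)] != qi[j])
        }
        hit <- which(mm <= max_mismatch)
        if (length(hit)) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = names(genome_chars)[ci], start = hit, strand = strand,
            mismatches = mm[hit], nta_length = k, aligned_length = alen,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0),
                      nta_length = integer(0), aligned_length = integer(0),
                      stringsAsFactors = FALSE))
  }
  all_hits <- do.call(rbind, rows)
  best_mm <- min(all_hits$mismatches)
  all_hits <- all_hits[all_hits$mismatches == best_mm, , drop = FALSE]
  best_k <- min(all_hits$nta_length)
  all_hits <- all_hits[all_hits$nta_length == best_k, , drop = FALSE]
  all_hits[order(all_hits$strand, all_hits$chrom, all_hits$start), ,
           drop = FALSE]
}

# --- Spearman rho via explicit mid-ranks and Pearson sums -----------------
oracle_midrank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

oracle_spearman_rho <- function(x, y) {
  rx <- oracle_midrank(x)
  ry <- oracle_midrank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# --- fixtures -------------------------------------------------------------
tiny_design <- function(n_per = 2L) {
  subtype <- rep(c("BL1", "LAR"), each = n_per)
  data.frame(sample_id = paste0(tolower(subtype), seq_len(2 * n_per)),
             subtype = subtype, stringsAsFactors = FALSE)
}

tiny_config <- function(seed = 1L, reads_per_sample = 2000L, ...) {
  srna_sim_config(
    seed = seed,
    reads_per_sample = reads_per_sample,
    features_per_category = c(miRNA = 8L, tRNA = 5L, snoRNA = 3L,
                              snRNA = 3L, yRNA = 2L, `7SK` = 1L, `7SL` = 1L),
    design = tiny_design(),
    ...
  )
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
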