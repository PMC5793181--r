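# Seed-and-verify short-tag aligner.
#
# Alignment contract: a tag maps to the genome full-length (substitutions
# only, at most `max_mismatch` of them) after trimming k = 0..max_nta bases
# from its 3' end, k being the putative non-templated addition (NTA) length.
# The reported tier minimizes mismatches first, then the trim length k, so a
# read carrying a genuine NTA is recognized as such (trimmed, 0 mismatches)
# rather than absorbed as an untrimmed mismatch.
# With <=1 mismatch, one half of the trimmed tag must
# match exactly, so exact 8-mer seeds taken from both ends of the trimmed
# tag enumerate every candidate placement (pigeonhole); candidates are then
# verified base-by-base.

SEED_K <- 8L
CHROM_ENC <- 16777216L  # positions encoded as (chrom_idx-1)*2^24 + pos

#' Build a seed index over a reference genome
#'
#' Hashes every 8-mer of the (+ strand) genome to its positions. Minus-strand
#' alignment reverse-complements the query, so one strand of index suffices.
#' Chromosomes longer than 16.7 Mb are not supported (position encoding).
#'
#' @param genome a named [Biostrings::DNAStringSet] or named character
#'   vector of chromosome sequences.
#' @return object of class `srna_genome_index`.
#' @export
genome_index <- function(genome) {
  seqs <- if (is.character(genome)) genome else {
    setNames(as.character(genome), names(genome))
  }
  if (is.null(names(seqs))) stop("genome sequences must be named")
  if (any(nchar(seqs) >= CHROM_ENC)) stop("chromosome too long for the index")
  kmers <- character(0)
  encs <- integer(0)
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[[i]])
    if (n < SEED_K) next
    starts <- seq_len(n - SEED_K + 1L)
    kmers <- c(kmers, substring(seqs[[i]], starts, starts + SEED_K - 1L))
    encs <- c(encs, (i - 1L) * CHROM_ENC + starts)
  }
  idx <- list2env(split(encs, kmers), hash = TRUE,
                  size = max(2L, length(unique(kmers))))
  out <- list(
    chrom_names = names(seqs),
    chrom_len = nchar(seqs),
    chrom_int = lapply(seqs, utf8ToInt),
    seeds = idx
  )
  class(out) <- "srna_genome_index"
  out
}

#' @export
print.srna_genome_index <- function(x, ...) {
  cat("srna_genome_index: ", length(x$chrom_names), " chromosome(s), ",
      sum(x$chrom_len), " nt\n", sep = "")
  invisible(x)
}

#' Align collapsed tags to the genome with NTA-aware one-mismatch matching
#'
#' For each tag and each NTA trim length k = 0..`max_nta`, the tag minus its
#' last k bases is aligned full-length on both strands, allowing at most
#' `max_mismatch` substitutions (counted over the aligned portion only; `N`
#' never matches). All hits of the best tier are returned, where the tier
#' first minimizes the mismatch count and then the trim length k — so a read
#' whose 3' extension is absent from the genome is reported as an NTA hit
#' with 0 mismatches rather than an untrimmed hit with 1. The aligned length
#' must stay >= `min_aligned_length`.
#'
#' @param sequences character vector of distinct tag sequences (>= 16 nt).
#' @param index an [genome_index()] object.
#' @param max_mismatch maximum substitutions over the aligned portion.
#' @param max_nta maximum 3' bases treated as non-templated additions.
#' @param min_aligned_length minimum aligned length after NTA trimming.
#' @return data.frame with one row per hit: `sequence`, `chrom`, `start`
#'   (1-based leftmost), `strand`, `mismatches`, `nta_length`,
#'   `aligned_length`. Tags with no hit at any k contribute no rows.
#' @export
align_tags <- function(sequences, index, max_mismatch = 1L, max_nta = 3L,
                       min_aligned_length = 16L) {
  stopifnot(inherits(index, "srna_genome_index"))
  if (any(nchar(sequences) < min_aligned_length)) {
    stop("all tags must be at least ", min_aligned_length, " nt")
  }
  n_tag <- length(sequences)
  if (n_tag == 0L) {
    return(empty_hits())
  }
  lens <- nchar(sequences)

  # trimmed queries and their reverse complements, precomputed per k
  subs <- vector("list", max_nta + 1L)
  rcs <- vector("list", max_nta + 1L)
  for (k in 0:max_nta) {
    s <- substr(sequences, 1L, lens - k)
    subs[[k + 1L]] <- s
    rcs[[k + 1L]] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(s))
    )
  }

  env <- index$seeds
  res <- vector("list", n_tag)
  for (i in seq_len(n_tag)) {
    hit_rows <- NULL
    best_mm <- max_mismatch + 1L
    for (k in 0:max_nta) {
      alen <- lens[i] - k
      if (alen < min_aligned_length) break
      hits <- rbind(
        verify_candidates(subs[[k + 1L]][i], "+", index, env, max_mismatch),
        verify_candidates(rcs[[k + 1L]][i], "-", index, env, max_mismatch)
      )
      if (!is.null(hits) && nrow(hits)) {
        mm_k <- min(hits$mismatches)
        if (mm_k < best_mm) {
          best_mm <- mm_k
          hits <- hits[hits$mismatches == mm_k, , drop = FALSE]
          hits$nta_length <- k
          hits$aligned_length <- alen
          hit_rows <- hits
        }
      }
      if (best_mm == 0L) break  # no later (larger-k) tier can improve
    }
    if (!is.null(hit_rows)) {
      hit_rows$sequence <- sequences[i]
      res[[i]] <- hit_rows
    }
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty_hits())
  out <- do.call(rbind, res)
  out <- out[, c("sequence", "chrom", "start", "strand", "mismatches",
                 "nta_length", "aligned_length")]
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(sequence = character(0), chrom = character(0),
             start = integer(0), strand = character(0),
             mismatches = integer(0), nta_length = integer(0),
             aligned_length = integer(0), stringsAsFactors = FALSE)
}

# Verify all seed candidates of one query string on one strand.
# Returns data.frame(chrom, start, strand, mismatches) or NULL.
verify_candidates <- function(query, strand, index, env, max_mismatch) {
  alen <- nchar(query)
  s1 <- substr(query, 1L, SEED_K)
  s2 <- substr(query, alen - SEED_K + 1L, alen)
  c1 <- env[[s1]]
  c2 <- env[[s2]]
  cand <- c(c1, if (!is.null(c2)) c2 - (alen - SEED_K))
  if (is.null(cand) || !length(cand)) return(NULL)
  cand <- unique(cand)
  qint <- utf8ToInt(query)
  keep_chrom <- integer(0)
  keep_pos <- integer(0)
  keep_mm <- integer(0)
  for (enc in cand) {
    ci <- enc %/% CHROM_ENC + 1L
    pos <- enc %% CHROM_ENC
    if (ci < 1L || ci > length(index$chrom_len)) next
    if (pos < 1L || pos + alen - 1L > index$chrom_len[ci]) next
    mm <- sum(qint != index$chrom_int[[ci]][pos:(pos + alen - 1L)])
    if (mm <= max_mismatch) {
      keep_chrom <- c(keep_chrom, ci)
      keep_pos <- c(keep_pos, pos)
      keep_mm <- c(keep_mm, mm)
    }
  }
  if (!length(keep_pos)) return(NULL)
  ord <- order(keep_chrom, keep_pos)
  data.frame(chrom = index$chrom_names[keep_chrom[ord]],
             start = keep_pos[ord], strand = strand,
             mismatches = keep_mm[ord], stringsAsFactors = FALSE)
}
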