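#' Generate a random reference genome with non-overlapping sRNA annotations
#'
#' Draws a uniform-random A/C/G/T genome and places the requested number of
#' features of each category at non-overlapping coordinates. tRNA loci get an
#' anticodon family label (amino acid + anticodon, e.g. `"Val_CAC"`) drawn
#' from a fixed 20-family alphabet weighted toward the families that dominate
#' real tRNA pools (Val, Gly, Lys, Glu, His).
#'
#' Coordinates are 1-based inclusive throughout the package (the native R /
#' GFF3 convention).
#'
#' @param config an [srna_sim_config()] object.
#' @return list of class `srna_reference` with elements `genome` (a named
#'   [Biostrings::DNAStringSet]) and `features` (a data.frame with columns
#'   `feature_id`, `category`, `chrom`, `start`, `end`, `strand`,
#'   `anticodon`).
#' @export
build_reference <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "reference"))

  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), config$chromosome_length,
                 replace = TRUE), collapse = "")
  }, character(1)))
  names(genome) <- chroms

  fpc <- config$features_per_category[config$features_per_category > 0]
  total <- sum(fpc)
  if (total == 0L) {
    feats <- data.frame(feature_id = character(), category = character(),
                        chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        anticodon = character(), stringsAsFactors = FALSE)
    out <- list(genome = genome, features = feats)
    class(out) <- "srna_reference"
    return(out)
  }

  # occupied intervals per chromosome, grown as features are placed
  occupied <- lapply(chroms, function(ch) matrix(numeric(0), ncol = 2))
  names(occupied) <- chroms

  rows <- vector("list", total)
  i <- 0L
  for (cat in names(fpc)) {
    rng <- config$category_length_ranges[[cat]]
    n_cat <- fpc[[cat]]
    anticodons <- if (cat == "tRNA") {
      aa <- sample(names(ANTICODON_TABLE), n_cat, replace = TRUE,
                   prob = ANTICODON_WEIGHTS)
      paste0(aa, "_", ANTICODON_TABLE[aa])
    } else rep(NA_character_, n_cat)
    for (j in seq_len(n_cat)) {
      len <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
      placed <- FALSE
      for (attempt in seq_len(1000L)) {
        ch <- sample(chroms, 1L)
        if (config$chromosome_length < len) break
        start <- sample.int(config$chromosome_length - len + 1L, 1L)
        end <- start + len - 1L
        occ <- occupied[[ch]]
        if (nrow(occ) == 0L || all(end < occ[, 1] | start > occ[, 2])) {
          occupied[[ch]] <- rbind(occ, c(start, end))
          strand <- if (config$mixed_strands) sample(c("+", "-"), 1L) else "+"
          i <- i + 1L
          fid <- if (cat == "tRNA") {
            sprintf("tRNA-%s-%d", anticodons[j], j)
          } else sprintf("%s-sim-%d", cat, j)
          rows[[i]] <- data.frame(
            feature_id = fid, category = cat, chrom = ch,
            start = start, end = end, strand = strand,
            anticodon = anticodons[j], stringsAsFactors = FALSE
          )
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("capacity error: could not place a ", cat, " feature of ", len,
             " nt without overlap after 1000 attempts; ",
             "increase chromosome_length or reduce features_per_category")
      }
    }
  }
  feats <- do.call(rbind, rows[seq_len(i)])
  rownames(feats) <- NULL
  out <- list(genome = genome, features = feats)
  class(out) <- "srna_reference"
  out
}

#' @export
print.srna_reference <- function(x, ...) {
  cat("srna_reference: ", length(x$genome), " chromosome(s), ",
      nrow(x$features), " feature(s)\n", sep = "")
  print(table(x$features$category))
  invisible(x)
}

#' Extract feature sequences in biological 5'->3' orientation
#'
#' @param reference an `srna_reference` (or a list with `genome` and
#'   `features` in the same layout).
#' @return named character vector of feature sequences; minus-strand features
#'   are reverse-complemented.
#' @export
feature_sequences <- function(reference) {
  feats <- reference$features
  if (nrow(feats) == 0L) return(setNames(character(0), character(0)))
  seqs <- as.character(Biostrings::subseq(
    reference$genome[feats$chrom], start = feats$start, end = feats$end
  ))
  neg <- feats$strand == "-"
  if (any(neg)) {
    seqs[neg] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[neg]))
    )
  }
  setNames(seqs, feats$feature_id)
}

#' Write a reference to FASTA + GFF3
#'
#' @param reference an `srna_reference`.
#' @param fasta_path,gff3_path output paths.
#' @export
write_reference <- function(reference, fasta_path, gff3_path) {
  Biostrings::writeXStringSet(reference$genome, fasta_path)
  export_features_gff3(reference$features, gff3_path)
  invisible(c(fasta = fasta_path, gff3 = gff3_path))
}

#' Export a feature table as GFF3
#'
#' `type` carries the sRNA category; tRNA records carry an `anticodon`
#' attribute. Coordinates are written 1-based inclusive.
#' @param features feature data.frame (see [build_reference()]).
#' @param path output path.
#' @export
export_features_gff3 <- function(features, path) {
  gr <- features_to_granges(features)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Import a GFF3 feature annotation into the package's feature table
#'
#' @param path GFF3 file whose `type` column holds the sRNA category.
#' @return feature data.frame as produced by [build_reference()].
#' @export
import_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  feats <- data.frame(
    feature_id = as.character(md$ID),
    category = as.character(md$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    anticodon = if ("anticodon" %in% names(md)) {
      as.character(md$anticodon)
    } else NA_character_,
    stringsAsFactors = FALSE
  )
  validate_features(feats)
  feats
}

features_to_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand,
    type = features$category,
    ID = features$feature_id,
    anticodon = features$anticodon
  )
}

validate_features <- function(features) {
  stopifnot(all(c("feature_id", "category", "chrom", "start", "end",
                  "strand", "anticodon") %in% names(features)))
  if (!all(features$category %in% SRNA_CATEGORIES)) {
    stop("unknown feature category: ",
         paste(setdiff(features$category, SRNA_CATEGORIES), collapse = ", "))
  }
  if (any(features$start > features$end) || any(features$start < 1)) {
    stop("invalid feature coordinates (must be 1-based inclusive, start <= end)")
  }
  trna <- features$category == "tRNA"
  if (any(trna & is.na(features$anticodon))) {
    stop("tRNA features must carry an anticodon label")
  }
  if (any(!trna & !is.na(features$anticodon))) {
    stop("anticodon labels are only valid on tRNA features")
  }
  invisible(features)
}
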