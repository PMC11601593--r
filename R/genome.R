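# Genome model and marker maps

# sacCer3 nuclear chromosome lengths (bp), chrI..chrXVI.
.SACCER3_LENGTHS <- c(
  chrI    = 230218L,
  chrII   = 813184L,
  chrIII  = 316620L,
  chrIV   = 1531933L,
  chrV    = 576874L,
  chrVI   = 270161L,
  chrVII  = 1090940L,
  chrVIII = 562643L,
  chrIX   = 439888L,
  chrX    = 745751L,
  chrXI   = 666816L,
  chrXII  = 1078177L,
  chrXIII = 924431L,
  chrXIV  = 784333L,
  chrXV   = 1091291L,
  chrXVI  = 948066L
)

#' Construct a genome model
#'
#' A genome model is an ordered set of chromosomes with their lengths in base
#' pairs. It anchors marker maps, LOD tracks and the 100-kb genomic binning.
#'
#' @param chromosomes Character vector of unique chromosome names.
#' @param lengths Integer vector of chromosome lengths in bp (all `> 0`).
#'
#' @return An object of class `genome_model`: a data frame with columns
#'   `chrom` and `length`.
#' @seealso [saccer3_genome()] for the default S. cerevisiae genome.
#' @export
genome_model <- function(chromosomes, lengths) {
  chromosomes <- as.character(chromosomes)
  lengths <- as.numeric(lengths)
  if (length(chromosomes) != length(lengths))
    stop("chromosomes and lengths must have equal length")
  if (anyDuplicated(chromosomes))
    stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  g <- data.frame(chrom = chromosomes, length = lengths,
                  stringsAsFactors = FALSE)
  class(g) <- c("genome_model", "data.frame")
  g
}

#' The sacCer3 nuclear genome
#'
#' The 16 nuclear chromosomes of the S. cerevisiae reference genome (sacCer3)
#' with their standard lengths. This genome partitions into exactly 128
#' consecutive 100-kb bins, the binning used for QTL hotspot summaries.
#'
#' @return A [genome_model()] with 16 chromosomes.
#' @export
saccer3_genome <- function() {
  genome_model(names(.SACCER3_LENGTHS), unname(.SACCER3_LENGTHS))
}

#' Uniformly spaced marker map
#'
#' Builds a synthetic biallelic marker map with approximately `n_markers`
#' positions spread uniformly across the genome, allocated to chromosomes
#' proportionally to their length. This is a desk-scale stand-in for a real
#' SNP list (the cross segregating in the study carries 18,871 high-confidence
#' variants; the generator scales from ~2,000 up to that density).
#'
#' @param genome A [genome_model()].
#' @param n_markers Approximate total marker count (default 2000).
#'
#' @return A `marker_map`: data frame with columns `chrom`, `pos` (1-based bp,
#'   strictly increasing within each chromosome).
#' @export
uniform_marker_map <- function(genome, n_markers = 2000) {
  stopifnot(inherits(genome, "genome_model"), n_markers >= 1)
  total <- sum(genome$length)
  maps <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    k <- max(1L, round(n_markers * len / total))
    # place markers at the midpoints of k equal slices: stays in (0, len]
    pos <- unique(pmax(1, round((seq_len(k) - 0.5) * len / k)))
    data.frame(chrom = genome$chrom[i], pos = pos, stringsAsFactors = FALSE)
  })
  mm <- do.call(rbind, maps)
  rownames(mm) <- NULL
  class(mm) <- c("marker_map", "data.frame")
  mm
}

#' Validate a marker map against a genome
#'
#' @param markers A `marker_map` data frame (`chrom`, `pos`).
#' @param genome A [genome_model()].
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_marker_map <- function(markers, genome) {
  stopifnot(is.data.frame(markers), all(c("chrom", "pos") %in% names(markers)))
  bad_chrom <- setdiff(unique(markers$chrom), genome$chrom)
  if (length(bad_chrom))
    stop("markers on unknown chromosome(s): ", paste(bad_chrom, collapse = ", "))
  len <- stats::setNames(genome$length, genome$chrom)
  if (any(markers$pos < 1 | markers$pos > len[markers$chrom]))
    stop("marker position outside chromosome bounds")
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("marker positions must be strictly increasing within ", ch)
  }
  invisible(TRUE)
}
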