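# Pooled allele counts: ingestion, frequency filter, smoothed tracks

#' Construct an allele count table
#'
#' Per-marker BY/RM read counts for one sequenced pool.
#'
#' @param chrom,pos,count_BY,count_RM,sample Column vectors; counts must be
#'   nonnegative, positions sorted within each chromosome.
#' @return An `allele_count_table` data frame.
#' @export
allele_count_table <- function(chrom, pos, count_BY, count_RM, sample = "pool") {
  tab <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                    count_BY = as.numeric(count_BY),
                    count_RM = as.numeric(count_RM),
                    sample = as.character(sample), stringsAsFactors = FALSE)
  if (any(tab$count_BY < 0) || any(tab$count_RM < 0))
    stop("allele counts must be nonnegative")
  tab <- tab[order(match(tab$chrom, unique(tab$chrom)), tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("allele_count_table", "data.frame")
  tab
}

#' Read pooled allele counts from TSV or VCF
#'
#' The TSV dialect has columns `chrom pos count_BY count_RM sample` (header
#' optional when columns are in this order). VCF input (4.x) uses the
#' per-sample `AD` field of biallelic records; the REF/RM orientation is
#' declared by `ref_allele` (default `"BY"`: the reference genome is
#' essentially the BY background, so REF counts are BY counts). Multiallelic
#' records and records without a parseable AD are skipped and counted in the
#' `skipped` attribute.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"` (default guessed from the extension).
#' @param ref_allele Which parent the VCF REF allele belongs to, `"BY"` or
#'   `"RM"`.
#' @param sample_id Sample label for VCF input (defaults to the VCF sample
#'   name).
#'
#' @return An [allele_count_table()] with attribute `skipped` (records
#'   dropped as multiallelic or AD-less).
#' @export
read_allele_counts <- function(path, format = c("auto", "tsv", "vcf"),
                               ref_allele = c("BY", "RM"), sample_id = NULL) {
  format <- match.arg(format)
  ref_allele <- match.arg(ref_allele)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    first <- readLines(path, n = 1)
    has_header <- grepl("chrom", first, fixed = TRUE)
    tab <- if (has_header)
      utils::read.table(path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    else
      utils::read.table(path, header = FALSE, sep = "\t",
                        stringsAsFactors = FALSE,
                        col.names = c("chrom", "pos", "count_BY", "count_RM",
                                      "sample"))
    need <- c("chrom", "pos", "count_BY", "count_RM", "sample")
    if (!all(need %in% names(tab)))
      stop("TSV is missing required column(s): ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    out <- allele_count_table(tab$chrom, tab$pos, tab$count_BY, tab$count_RM,
                              tab$sample)
    attr(out, "skipped") <- 0L
    return(out)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  biallelic <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "."
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) stop("VCF has no AD field")
  ad <- ad[, 1]
  parts <- strsplit(ifelse(is.na(ad), "", ad), ",", fixed = TRUE)
  ok_ad <- lengths(parts) == 2
  keep <- biallelic & ok_ad
  skipped <- sum(!keep)
  ref_n <- as.numeric(vapply(parts[keep], `[`, "", 1))
  alt_n <- as.numeric(vapply(parts[keep], `[`, "", 2))
  if (ref_allele == "BY") {
    by_n <- ref_n; rm_n <- alt_n
  } else {
    by_n <- alt_n; rm_n <- ref_n
  }
  if (is.null(sample_id))
    sample_id <- if (length(colnames(v@gt)) > 1) colnames(v@gt)[2] else "sample"
  out <- allele_count_table(fix[keep, "CHROM"], as.numeric(fix[keep, "POS"]),
                            by_n, rm_n, sample_id)
  attr(out, "skipped") <- skipped
  out
}

#' Write an allele count table as TSV
#' @param table An [allele_count_table()].
#' @param path Output path.
#' @export
write_allele_counts_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an allele count table as a minimal VCF 4.2
#'
#' Encodes each marker as a biallelic record with the per-sample AD field
#' carrying `count_BY,count_RM` (REF is taken as the BY allele).
#'
#' @param table An [allele_count_table()].
#' @param path Output path.
#' @export
write_allele_counts_vcf <- function(table, path) {
  sample_name <- table$sample[1]
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_name))
  body <- sprintf("%s\t%d\t.\tA\tG\t.\tPASS\t.\tAD\t%d,%d",
                  table$chrom, as.integer(table$pos),
                  as.integer(table$count_BY), as.integer(table$count_RM))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Filter markers with extreme raw allele frequencies
#'
#' Removes markers whose raw RM frequency is lower than `lo` or higher than
#' `hi` (boundary values are kept). Zero-depth markers, where the frequency
#' is undefined, are dropped first and counted separately. Applied per
#' sample.
#'
#' @param table An [allele_count_table()].
#' @param lo,hi Frequency bounds (defaults 0.1 and 0.9).
#'
#' @return Filtered table with attributes `n_extreme` and `n_zero_depth`.
#' @export
filter_extreme_frequencies <- function(table, lo = 0.1, hi = 0.9) {
  depth <- table$count_BY + table$count_RM
  nonzero <- depth > 0
  f <- table$count_RM[nonzero] / depth[nonzero]
  keep <- f >= lo & f <= hi
  out <- table[nonzero, , drop = FALSE][keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_zero_depth") <- sum(!nonzero)
  attr(out, "n_extreme") <- sum(!keep)
  class(out) <- class(table)
  out
}

#' Smooth allele frequencies along each chromosome
#'
#' Local-linear (degree 1) regression of the raw RM allele frequency on
#' genomic position with a tricube kernel of fixed genomic bandwidth,
#' evaluated at the marker positions. A fixed genomic window (rather than a
#' fraction of markers) keeps the smoothing scale constant when marker
#' density varies. Chromosomes with fewer than `min_markers` markers pass
#' through unsmoothed and are flagged.
#'
#' @param table An [allele_count_table()] (zero-depth markers are excluded).
#' @param bandwidth_bp Full window span in bp (default 40000; the kernel
#'   half-width is half of this).
#' @param min_markers Minimum markers per chromosome for smoothing.
#'
#' @return A `frequency_track`: data frame `chrom`, `pos`, `raw_f`,
#'   `smoothed_f` (clipped to `[0, 1]`), `sample`; attribute
#'   `unsmoothed_chroms` lists pass-through chromosomes.
#' @export
smooth_frequency <- function(table, bandwidth_bp = 40000, min_markers = 10) {
  depth <- table$count_BY + table$count_RM
  tab <- table[depth > 0, , drop = FALSE]
  depth <- tab$count_BY + tab$count_RM
  raw_f <- tab$count_RM / depth
  half <- bandwidth_bp / 2
  smoothed <- numeric(nrow(tab))
  flagged <- character(0)
  for (ch in unique(tab$chrom)) {
    i <- which(tab$chrom == ch)
    if (length(i) < min_markers) {
      smoothed[i] <- raw_f[i]
      flagged <- c(flagged, ch)
    } else {
      smoothed[i] <- .local_linear_smooth(tab$pos[i], raw_f[i], tab$pos[i], half)
    }
  }
  out <- data.frame(chrom = tab$chrom, pos = tab$pos, raw_f = raw_f,
                    smoothed_f = pmin(1, pmax(0, smoothed)),
                    sample = tab$sample, stringsAsFactors = FALSE)
  attr(out, "unsmoothed_chroms") <- flagged
  class(out) <- c("frequency_track", "data.frame")
  out
}

#' RM allele-frequency difference between high and low pools
#'
#' `delta_af = smoothed_f(high) - smoothed_f(low)` at the markers the two
#' tracks share. A positive value means the RM allele is associated with
#' higher UPS activity (it is enriched in the high-activity pool).
#'
#' @param high,low `frequency_track`s from [smooth_frequency()].
#'
#' @return A `delta_af_track`: data frame `chrom`, `pos`, `delta_af`.
#' @export
compute_delta_af <- function(high, low) {
  j <- merge(high[, c("chrom", "pos", "smoothed_f")],
             low[, c("chrom", "pos", "smoothed_f")],
             by = c("chrom", "pos"), suffixes = c("_high", "_low"),
             sort = FALSE)
  if (nrow(j) == 0) stop("high and low tracks share no markers")
  j <- j[order(match(j$chrom, unique(high$chrom)), j$pos), , drop = FALSE]
  out <- data.frame(chrom = j$chrom, pos = j$pos,
                    delta_af = j$smoothed_f_high - j$smoothed_f_low,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("delta_af_track", "data.frame")
  out
}

#' Write a per-position track as bedGraph
#'
#' Converts the package's 1-based marker positions to bedGraph's 0-based
#' half-open single-bp intervals.
#'
#' @param track Data frame with `chrom`, `pos` and one value column.
#' @param value_col Name of the value column.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, value_col, path) {
  lines <- sprintf("%s\t%d\t%d\t%g", track$chrom,
                   as.integer(track$pos) - 1L, as.integer(track$pos),
                   track[[value_col]])
  writeLines(lines, path)
  invisible(path)
}
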