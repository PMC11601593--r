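# Shared fixtures built in code

two_chrom_genome <- function() {
  genome_model(c("chrA", "chrB"), c(500000, 400000))
}

# evenly spaced markers on one chromosome
chrom_markers <- function(chrom = "chrA", length_bp = 500000, n = 50) {
  mm <- data.frame(chrom = chrom,
                   pos = round((seq_len(n) - 0.5) * length_bp / n))
  class(mm) <- c("marker_map", "data.frame")
  mm
}

# a qtl_table row set for classification tests
mk_qtls <- function(chrom, peak, delta_af, lod = 10,
                    reporter = "R1", environment = "SC", replicate = "rep1") {
  n <- length(peak)
  out <- data.frame(chrom = rep_len(chrom, n), peak = peak,
                    ci_lo = peak - 20000, ci_hi = peak + 20000,
                    lod = rep_len(lod, n), delta_af = rep_len(delta_af, n),
                    reporter = rep_len(reporter, n),
                    environment = rep_len(environment, n),
                    replicate = rep_len(replicate, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("qtl_table", "data.frame")
  out
}

# replicate pair + reconciliation bundle for classify_gxe()
mk_env_set <- function(qtls1, qtls2) {
  list(rep1 = qtls1, rep2 = qtls2,
       reconciled = reconcile_replicates(qtls1, qtls2))
}

# allele counts with given RM frequencies at given positions
mk_counts <- function(pos, f_rm, depth = 100, chrom = "chrA", sample = "pool") {
  allele_count_table(chrom, pos, round(depth * (1 - f_rm)),
                     round(depth * f_rm), sample)
}

# place n_loci planted loci on distinct chromosomes of a marker map,
# avoiding the outer 10% of each chromosome
plant_loci <- function(genome, markers, n_loci = 2) {
  big <- genome$chrom[genome$length >= 300000]
  chs <- sample(big, n_loci)
  pos <- vapply(chs, function(ch) {
    L <- genome$length[genome$chrom == ch]
    p <- markers$pos[markers$chrom == ch]
    p[which.min(abs(p - stats::runif(1, 0.1 * L, 0.9 * L)))]
  }, numeric(1))
  list(chrom = chs, pos = unname(pos))
}
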