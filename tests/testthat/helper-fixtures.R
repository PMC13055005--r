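# Small in-code fixtures.

# one-row gene-model table
make_gene <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                      exon_starts, exon_ends,
                      cds_starts = exon_starts, cds_ends = exon_ends,
                      rank = 1) {
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   start = min(exon_starts), end = max(exon_ends),
                   stringsAsFactors = FALSE)
  df$exon_starts <- list(exon_starts); df$exon_ends <- list(exon_ends)
  df$cds_starts <- list(cds_starts); df$cds_ends <- list(cds_ends)
  df$rank <- rank
  rownames(df) <- gene_id
  df
}

# minimal variant panel from a dosage matrix (sites x samples)
make_panel <- function(geno, pos = seq_len(nrow(geno)) * 10L,
                       chrom = "chr1", groups = NULL, chrom_len = 10000L,
                       ref = NULL, alt = NULL) {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("s%02d", seq_len(ncol(geno)))
  if (is.null(groups))
    groups <- setNames(rep("G1", ncol(geno)), colnames(geno))
  if (is.null(ref)) ref <- rep("A", nrow(geno))
  if (is.null(alt)) alt <- rep("G", nrow(geno))
  variant_panel(rep(chrom, nrow(geno)), pos, ref, alt, geno, groups,
                setNames(chrom_len, chrom))
}

# four-population panel with per-group allele frequencies given as a list of
# equal-length vectors (P1, P2, P3, OUT); genotypes are binomial(2, p)
make_four_pop_panel <- function(p1, p2, p3, pout = rep(0, length(p1)),
                                n_per_pop = 20, chrom_len = 1e6,
                                pos = NULL, seed = 1) {
  m <- length(p1)
  if (is.null(pos)) pos <- sort(sample.int(chrom_len, m))
  withr::with_seed(seed, {
    gmat <- cbind(
      matrix(rbinom(m * n_per_pop, 2, rep(p1, n_per_pop)), m),
      matrix(rbinom(m * n_per_pop, 2, rep(p2, n_per_pop)), m),
      matrix(rbinom(m * n_per_pop, 2, rep(p3, n_per_pop)), m),
      matrix(rbinom(m * n_per_pop, 2, rep(pout, n_per_pop)), m))
  })
  samples <- sprintf("s%03d", seq_len(4 * n_per_pop))
  colnames(gmat) <- samples
  groups <- setNames(rep(c("P1", "P2", "P3", "OUT"), each = n_per_pop), samples)
  variant_panel(rep("chr1", m), pos, rep("A", m), rep("G", m), gmat, groups,
                c(chr1 = chrom_len))
}
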