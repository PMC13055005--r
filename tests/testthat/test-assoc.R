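# tiny genome: one chromosome, one + strand gene and one - strand gene
make_assoc_world <- function() {
  withr::with_seed(71, {
    nts <- c("A", "C", "G", "T")
    chars <- sample(nts, 4000, replace = TRUE)
    # + strand gene, two exons with an intron: CDS = [1001..1030] + [1101..1130]
    cdsA <- "ATGTTTAAACCCGGGACTCATGAAGCATGCTTATCGCGATACGATAGCATGCATTTTCAA"
    chars[1001:1030] <- strsplit(substr(cdsA, 1, 30), "")[[1]]
    chars[1101:1130] <- strsplit(substr(cdsA, 31, 60), "")[[1]]
    gA <- make_gene("gA", strand = "+", exon_starts = c(1001L, 1101L),
                    exon_ends = c(1030L, 1130L))
    # - strand gene: genomic = revcomp(CDS)
    cdsB <- "ATGCCTGAACGATTTAGGCATCATCCAGAC"
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cdsB)))
    chars[2001:2030] <- strsplit(rc, "")[[1]]
    gB <- make_gene("gB", strand = "-", exon_starts = 2001L, exon_ends = 2030L)
    genome <- Biostrings::DNAStringSet(c(chr1 = paste(chars, collapse = "")))
    list(genome = genome, gA = gA, gB = gB,
         models = rbind(gA, gB))
  })
}

test_that("coding effects follow the genetic code, strand-aware", {
  w <- make_assoc_world()
  # gA codon 2 is TTT at 1004..1006; third position 1006: T->C synonymous
  eff <- classify_coding_effect("chr1", 1006L, "T", "C", w$gA, w$genome)
  expect_equal(eff$effect, "synonymous")
  expect_equal(eff$ref_aa, "F"); expect_equal(eff$alt_aa, "F")
  # T->A at the same position: Phe -> Leu, non-synonymous
  eff2 <- classify_coding_effect("chr1", 1006L, "T", "A", w$gA, w$genome)
  expect_equal(eff2$effect, "nonsynonymous")
  expect_equal(eff2$alt_aa, "L")
  expect_equal(eff2$codon_index, 2L)
  # intron position is noncoding
  base <- as.character(Biostrings::subseq(w$genome[["chr1"]], 1050L, 1050L))
  eff3 <- classify_coding_effect("chr1", 1050L, base, setdiff(c("A","C","G","T"), base)[1],
                                 w$gA, w$genome)
  expect_equal(eff3$effect, "noncoding")
  # codon 11 starts at 1101 (first base of exon 2): TTA -> GTA, Leu -> Val
  eff4 <- classify_coding_effect("chr1", 1101L, "T", "G", w$gA, w$genome)
  expect_equal(eff4$codon_index, 11L)
  expect_equal(eff4$effect, "nonsynonymous")
  # reference mismatch is a hard error
  expect_error(classify_coding_effect("chr1", 1006L, "G", "A", w$gA, w$genome),
               "mismatch")
})

test_that("minus-strand effects agree with an exhaustive codon oracle", {
  w <- make_assoc_world()
  # gB CDS runs 2030 -> 2001 genomically; check every position and every alt
  cdsB <- "ATGCCTGAACGATTTAGGCATCATCCAGAC"
  for (t in seq_len(30)) {
    gpos <- 2031L - t
    ref <- as.character(Biostrings::subseq(w$genome[["chr1"]], gpos, gpos))
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      got <- classify_coding_effect("chr1", gpos, ref, alt, w$gB, w$genome)
      # oracle: substitute on the transcript directly
      tx_alt <- c(A = "T", C = "G", G = "C", T = "A")[[alt]]
      mut <- cdsB
      substr(mut, t, t) <- tx_alt
      ci <- (t - 1) %/% 3 + 1
      aa_ref <- Biostrings::GENETIC_CODE[[substr(cdsB, 3 * ci - 2, 3 * ci)]]
      aa_alt <- Biostrings::GENETIC_CODE[[substr(mut, 3 * ci - 2, 3 * ci)]]
      want <- if (aa_alt == "*") "stop_gain"
        else if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
      expect_equal(got$effect, want, info = sprintf("t=%d alt=%s", t, alt))
    }
  }
})

test_that("het/MAF filters drop what the thresholds say, in any order", {
  geno <- rbind(
    c(rep(1, 3), rep(0, 7)),     # het 0.30 -> dropped
    c(1, rep(0, 8), 2),          # het 0.10, maf 0.20 -> retained
    c(rep(0, 9), 1),             # maf 0.05 -> retained (boundary)
    c(rep(0, 10)),               # maf 0 -> dropped
    c(rep(NA, 10)))              # empty -> dropped
  colnames(geno) <- sprintf("s%02d", 1:10)
  f <- filter_assoc_snps(geno, het_max = 0.2, maf_min = 0.05)
  expect_equal(f$keep, c(2L, 3L))
  expect_equal(unname(f$reasons["het"]), 1L)

  # order independence: het-then-maf equals maf-then-het
  f_het <- filter_assoc_snps(geno, het_max = 0.2, maf_min = 0)
  f_both <- filter_assoc_snps(geno[f_het$keep, , drop = FALSE],
                              het_max = 1, maf_min = 0.05)
  expect_equal(f_het$keep[f_both$keep], f$keep)
})

test_that("haplotype classes concatenate homozygous alleles only", {
  geno <- rbind(c(0, 0, 2, 1, 0), c(2, 0, 2, 0, NA))
  colnames(geno) <- sprintf("s%d", 1:5)
  hap <- build_gene_haplotypes(geno, ref = c("G", "A"), alt = c("T", "C"))
  expect_equal(unname(hap$classes),
               c("GC", "GA", "TC", "het/other", "het/other"))
  # single SNP, 0/0 with ref T -> class "T"
  hap1 <- build_gene_haplotypes(matrix(0, 1, 2, dimnames = list(NULL, c("a", "b"))),
                                ref = "T", alt = "A")
  expect_equal(unname(hap1$classes), c("T", "T"))
})

test_that("haplotype-phenotype test picks the favorable class and errors out", {
  classes <- setNames(rep(c("T", "A", "het/other"), c(12, 12, 4)),
                      sprintf("s%02d", 1:28))
  withr::with_seed(15, {
    pheno <- setNames(c(rnorm(12, 12, 1.5), rnorm(12, 5, 1.5), rnorm(4, 8, 1.5)),
                      names(classes))
  })
  res <- haplotype_phenotype_test(classes, pheno)
  expect_true(res$testable)
  expect_lt(res$p, 0.001)
  expect_equal(res$favorable, "T")
  expect_equal(res$n1 + res$n2, 24)

  # identical distributions: same values in both classes -> t = 0, p = 1
  ph2 <- pheno
  ph2[classes == "A"] <- ph2[classes == "T"]
  res2 <- haplotype_phenotype_test(classes, ph2)
  expect_equal(res2$p, 1)
  expect_equal(res2$favorable, "none")

  # fewer than two classes with two samples: not testable
  res3 <- haplotype_phenotype_test(classes[classes == "T"], pheno)
  expect_false(res3$testable)
})

test_that("assoc_scan finds a planted causal gene end to end", {
  cfg <- sim_config(seed = 27, n_chromosomes = 1, chrom_length = 400000,
                    n_genes = 60, pop_snp_rate = 0.005,
                    introgression_fraction = 0, introgressed_interval = NULL,
                    divergent_interval = NULL,
                    pheno_effect = 6, pheno_noise_sd = 2)
  sim <- simulate_diploid(cfg)
  pop <- simulate_population(cfg, genome = sim$hap1, models = sim$models1)
  ph <- simulate_phenotype(pop$truth$causal$copies, cfg)
  res <- assoc_scan(pop$panel, sim$models1, sim$hap1,
                    setNames(ph$pe_ug_per_g, ph$sample))
  causal <- pop$truth$causal
  expect_true(causal$gene_id %in% res$gene_id)
  row <- res[res$gene_id == causal$gene_id, ]
  expect_lt(row$p, 1e-6)
  kept <- as.integer(strsplit(row$positions, ",")[[1]])
  at <- match(causal$positions, kept)
  expect_false(anyNA(at))
  expect_equal(paste(strsplit(row$favorable, "")[[1]][at], collapse = ""),
               causal$favorable)
})
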