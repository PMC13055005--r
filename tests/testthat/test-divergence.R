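test_that("codon alignment handles identity, deletions and internal stops", {
  cds <- "ATGAAACCCGGGTTTCTGCATGAAGCAAAC"  # 10 codons, no stop
  al <- align_codons(cds, cds)
  expect_equal(al$n_codons_used, 10L)
  expect_equal(al$n_codons_dropped, 0L)

  # drop one full codon from the partner: 9 aligned, 1 dropped
  del <- paste0(substr(cds, 1, 12), substr(cds, 16, 30))
  al2 <- align_codons(cds, del)
  expect_equal(al2$n_codons_used, 9L)
  expect_equal(al2$n_codons_dropped, 1L)

  # non-multiple-of-3 input is an error
  expect_error(align_codons("ATGA", cds), "multiple of 3")

  # internal stop excludes the pair with a reason
  stopcds <- paste0(substr(cds, 1, 9), "TAA", substr(cds, 13, 30))
  al3 <- align_codons(cds, stopcds)
  expect_true(al3$excluded)
  expect_equal(al3$reason, "internal_stop")
  expect_true(is.na(ng86(al3)$Ka))

  # a terminal stop is tolerated and counted as dropped
  al4 <- align_codons(paste0(cds, "TGA"), paste0(cds, "TGA"))
  expect_equal(al4$n_codons_used, 10L)
  expect_equal(al4$n_codons_dropped, 1L)
})

test_that("ng86 matches hand-derived single-codon cases", {
  # identical sequences: zero everything, Ka/Ks undefined
  k0 <- ng86(align_codons("ATGAAACCC", "ATGAAACCC"))
  expect_equal(k0$Nd, 0); expect_equal(k0$Sd, 0)
  expect_equal(k0$Ka, 0); expect_equal(k0$Ks, 0)
  expect_true(is.na(k0$kaks))

  # TTT -> TTA is Phe -> Leu: one non-synonymous difference
  k1 <- ng86(align_codons("TTT", "TTA"))
  expect_equal(k1$Nd, 1); expect_equal(k1$Sd, 0)
  # sites: S(TTT) = 1/3 (third position), S(TTA) = 2/3 -> S = 0.5
  expect_equal(k1$S, 0.5); expect_equal(k1$N, 2.5)

  # third-position synonymous change: TTT -> TTC (Phe -> Phe)
  k2 <- ng86(align_codons("TTT", "TTC"))
  expect_equal(k2$Nd, 0); expect_equal(k2$Sd, 1)
})

test_that("ng86 equals the brute-force site/pathway oracle and is symmetric", {
  withr::with_seed(7, {
    for (i in 1:20) {
      rp <- random_codon_pair(n_codons = 12, n_mut = sample(1:8, 1))
      al <- align_codons(paste(rp$a, collapse = ""), paste(rp$b, collapse = ""))
      got <- ng86(al)
      want <- oracle_ng86(rp$a, rp$b)
      expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
      expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
      expect_equal(got$N, want$N, tolerance = 1e-12)
      expect_equal(got$S, want$S, tolerance = 1e-12)
      expect_equal(got$Ka, want$Ka, tolerance = 1e-12)
      expect_equal(got$Ks, want$Ks, tolerance = 1e-12)
      # symmetry
      rev_ <- ng86(align_codons(paste(rp$b, collapse = ""), paste(rp$a, collapse = "")))
      expect_equal(got[c("Nd", "Sd", "N", "S", "Ka", "Ks")],
                   rev_[c("Nd", "Sd", "N", "S", "Ka", "Ks")])
    }
  })
})

test_that("Ka and Ks are monotone in pN and pS through the JC correction", {
  p <- seq(0, 0.74, by = 0.02)
  d <- jc_correct(p)
  expect_true(all(diff(d) > 0))
  expect_true(is.na(jc_correct(0.75)))
  expect_true(is.na(jc_correct(0.8)))
})

test_that("cds_identity counts gaps as mismatches", {
  cds <- paste(rep("ATGAAACCCGGGTTTCTGCATGAAGCAAACCAA", 3), collapse = "")
  al <- align_codons(cds, cds)
  expect_equal(cds_identity(al), 1.0)

  # exactly one mismatching nucleotide among 99 aligned
  mut <- cds
  substr(mut, 4, 4) <- "C"  # AAA -> CAA, Lys -> Gln
  expect_equal(cds_identity(align_codons(cds, mut)), 98 / 99)

  # one deleted codon: 3 gap columns count as mismatches
  del <- paste0(substr(cds, 1, 12), substr(cds, 16, nchar(cds)))
  expect_equal(cds_identity(align_codons(cds, del)), 96 / 99)
  expect_equal(cds_identity(align_codons(cds, del), count_gaps = FALSE), 1.0)
})

test_that("flank divergence recovers planted substitution rates and truncates", {
  withr::with_seed(11, {
    L <- 10000L
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    # gene body at 5001..5300, + strand, single exon
    cds <- strsplit("ATG", "")[[1]]
    g <- make_gene(exon_starts = 5001L, exon_ends = 5300L)
    chars2 <- chars
    # plant exactly 20 substitutions in the 2 kb upstream flank
    up_pos <- sample(3001:5000, 20)
    for (p in up_pos) chars2[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    g1 <- Biostrings::DNAStringSet(c(chr1 = paste(chars, collapse = "")))
    g2 <- Biostrings::DNAStringSet(c(chr1 = paste(chars2, collapse = "")))
    fl <- flank_divergence(g1, g2, g, g)
    expect_equal(fl$flank_up_rate, -0.75 * log(1 - 4 / 3 * 0.01), tolerance = 1e-9)
    expect_equal(fl$flank_down_rate, 0)

    # identical flanks -> exactly zero
    fl0 <- flank_divergence(g1, g1, g, g)
    expect_equal(fl0$flank_up_rate, 0)

    # gene near the chromosome start: upstream truncated, length recorded
    gs <- make_gene(exon_starts = 501L, exon_ends = 800L)
    fls <- flank_divergence(g1, g1, gs, gs)
    expect_equal(fls$up_len, 500L)
    expect_equal(fls$flank_up_rate, 0)

    # flank shorter than 100 bp -> missing
    gt <- make_gene(exon_starts = 31L, exon_ends = 330L)
    expect_true(is.na(flank_divergence(g1, g1, gt, gt)$flank_up_rate))
  })
})

test_that("selection contrast runs a Welch test and respects error contracts", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  same <- compare_selection(x, x)
  expect_true(same$run)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # one finite value in a group -> not run
  nr <- compare_selection(c(0.5, NA, Inf), x)
  expect_false(nr$run)
  expect_true(is.na(nr$p))
  expect_equal(nr$n_excluded, 2L)

  # power: N(0.5, 0.1) vs N(0.3, 0.1), n = 200 -> p < 1e-6 essentially always
  withr::with_seed(3, {
    hits <- sum(vapply(1:50, function(i) {
      compare_selection(rnorm(200, 0.5, 0.1), rnorm(200, 0.3, 0.1))$p < 1e-6
    }, TRUE))
  })
  expect_gte(hits, 48)
})

test_that("neutral diploid simulation yields Ka/Ks near 1 over many pairs", {
  sim <- default_sim()
  cds1 <- cds_seqs(sim$hap1, sim$models1)
  cds2 <- cds_seqs(sim$hap2, sim$models2)
  anchors <- find_anchors(sim$models1, sim$models2, cds1, cds2)
  pairs <- call_alleles(chain_syntenic_blocks(anchors))
  expect_gte(nrow(pairs), 200)
  kaks <- vapply(seq_len(nrow(pairs)), function(i)
    ng86(align_codons(cds1[[pairs$gene_a[i]]], cds2[[pairs$gene_b[i]]]))$kaks,
    0)
  m <- mean(kaks[is.finite(kaks)])
  expect_gte(m, 0.7)
  expect_lte(m, 1.4)
})
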