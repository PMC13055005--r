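# small helper: gene set with given CDS sequences laid out along a chromosome
toy_geneset <- function(cds_list, chrom = "chr1", prefix = "g") {
  n <- length(cds_list)
  models <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- 10000L * i
    make_gene(sprintf("%s%02d", prefix, i), chrom = chrom,
              exon_starts = s, exon_ends = s + nchar(cds_list[[i]]) - 1L,
              rank = i)
  }))
  models$rank <- seq_len(n)
  cds <- Biostrings::DNAStringSet(setNames(unlist(cds_list), models$gene_id))
  list(models = models, cds = cds)
}

random_cds_str <- function(n_codons) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(c("ATG", sample(sense, n_codons - 1, replace = TRUE)), collapse = "")
}

test_that("anchors: identity, duplicates, and threshold behaviour", {
  withr::with_seed(31, {
    cds <- replicate(6, random_cds_str(60))
    a <- toy_geneset(cds, prefix = "a")
    b <- toy_geneset(cds, prefix = "b")
    anch <- find_anchors(a$models, b$models, a$cds, b$cds)
    # every gene's reciprocal best hit is its own copy at similarity 1
    rbh <- anch[anch$reciprocal, ]
    expect_equal(nrow(rbh), 6L)
    expect_true(all(rbh$similarity == 1))
    expect_equal(sub("a", "", rbh$gene_a), sub("b", "", rbh$gene_b))

    # two identical genes in a, one copy in b: one reciprocal anchor,
    # the duplicate still reported as a non-reciprocal hit
    a2 <- toy_geneset(list(cds[[1]], cds[[1]]), prefix = "a")
    b2 <- toy_geneset(list(cds[[1]]), prefix = "b")
    anch2 <- find_anchors(a2$models, b2$models, a2$cds, b2$cds)
    expect_equal(nrow(anch2), 2L)
    expect_equal(sum(anch2$reciprocal), 1L)
    expect_true(all(anch2$similarity == 1))

    # dissimilar sequences below threshold: no anchors
    c1 <- toy_geneset(list(cds[[1]]), prefix = "a")
    c2 <- toy_geneset(list(cds[[2]]), prefix = "b")
    anch3 <- find_anchors(c1$models, c2$models, c1$cds, c2$cds,
                          min_kmer_share = 0)
    # unrelated random proteins: similarity far below 0.7, and the single
    # candidate pair is mutually best, so at most the RBH remains
    expect_true(all(anch3$similarity < 0.7))

    # empty input warns and returns nothing
    expect_warning(e <- find_anchors(a$models[0, ], b$models, a$cds, b$cds),
                   "empty")
    expect_equal(nrow(e), 0L)
  })
})

test_that("chaining finds collinear blocks and honours min_block and max_gap", {
  mk_anchors <- function(ra, rb, chrom_b = "chr1") {
    n <- length(ra)
    data.frame(gene_a = sprintf("a%02d", seq_len(n)),
               gene_b = sprintf("b%02d", seq_len(n)),
               similarity = 1, reciprocal = TRUE,
               chrom_a = "chr1", chrom_b = chrom_b,
               rank_a = ra, rank_b = rb, start_a = 100L * ra,
               stringsAsFactors = FALSE)
  }
  # 10 perfectly collinear anchors -> one block of 10
  ch <- chain_syntenic_blocks(mk_anchors(1:10, 1:10))
  expect_equal(nrow(ch$blocks), 1L)
  expect_equal(ch$blocks$n_anchors, 10L)
  expect_equal(ch$blocks$orientation, "same")

  # one anchor displaced to another chromosome: block of 9, displaced
  # anchor unassigned
  anc <- mk_anchors(1:10, 1:10)
  anc$chrom_b[5] <- "chr2"
  ch2 <- chain_syntenic_blocks(anc)
  expect_equal(ch2$blocks$n_anchors, 9L)
  expect_true(is.na(ch2$anchors$block_id[ch2$anchors$gene_a == "a05"]))

  # 4 collinear anchors with min_block = 5: nothing
  ch3 <- chain_syntenic_blocks(mk_anchors(1:4, 1:4), min_block = 5)
  expect_equal(nrow(ch3$blocks), 0L)

  # a rank gap beyond max_gap splits the chain
  ch4 <- chain_syntenic_blocks(mk_anchors(c(1:6, 40:45), c(1:6, 40:45)),
                               min_block = 5, max_gap = 25)
  expect_equal(sort(ch4$blocks$n_anchors), c(6L, 6L))

  # inverted block
  ch5 <- chain_syntenic_blocks(mk_anchors(1:8, 8:1))
  expect_equal(ch5$blocks$orientation, "inverted")
  expect_equal(ch5$blocks$n_anchors, 8L)
})

test_that("DP chaining equals exhaustive enumeration on random instances", {
  withr::with_seed(77, {
    for (rep in 1:40) {
      n <- sample(5:12, 1)
      ra <- sample(1:30, n)
      rb <- sample(1:30, n)
      anc <- data.frame(gene_a = sprintf("a%02d", 1:n),
                        gene_b = sprintf("b%02d", 1:n),
                        similarity = 1, reciprocal = TRUE,
                        chrom_a = "c", chrom_b = "c",
                        rank_a = ra, rank_b = rb, start_a = ra,
                        stringsAsFactors = FALSE)
      ch <- chain_syntenic_blocks(anc, min_block = 2, max_gap = 10)
      got <- if (nrow(ch$blocks)) max(ch$blocks$n_anchors) else 0L
      want <- oracle_best_chain_len(ra, rb, max_gap = 10)
      if (want < 2) want <- 0L   # chains below min_block are discarded
      expect_equal(got, want, info = sprintf("rep %d", rep))
    }
  })
})

test_that("allele calling: self-pairs on identical haplotypes, empty input", {
  withr::with_seed(41, {
    cds <- replicate(8, random_cds_str(60))
    a <- toy_geneset(cds, prefix = "g")
    anch <- find_anchors(a$models, a$models, a$cds, a$cds)
    pairs <- call_alleles(chain_syntenic_blocks(anch))
    expect_equal(nrow(pairs), 8L)
    expect_equal(pairs$gene_a, pairs$gene_b)
    # no gene appears twice
    expect_false(any(duplicated(pairs$gene_a)))
    expect_false(any(duplicated(pairs$gene_b)))

    empty <- call_alleles(chain_syntenic_blocks(anch[0, ]))
    expect_equal(nrow(empty), 0L)
  })
})

test_that("reversing one haplotype's gene order yields inverted-block pairs", {
  sim <- default_sim()
  on_chr1 <- sim$models1$chrom == "chr1"
  m1 <- sim$models1[on_chr1, ][1:30, ]
  cds1 <- cds_seqs(sim$hap1, m1)
  # same genes with reversed ranks (as if the chromosome were flipped)
  m1r <- m1
  m1r$rank <- rev(m1r$rank)
  anch <- find_anchors(m1, m1r, cds1, cds1)
  ch <- chain_syntenic_blocks(anch)
  expect_equal(unique(ch$blocks$orientation), "inverted")
  pairs <- call_alleles(ch)
  expect_equal(nrow(pairs), 30L)
  expect_equal(pairs$gene_a, pairs$gene_b)
})
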