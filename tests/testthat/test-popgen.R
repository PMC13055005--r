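test_that("windowed pi matches the two-haplotype closed form", {
  # one diploid sample, heterozygous at 4 sites within the first 1 kb:
  # per site h = 2 * 0.5 * 0.5 * 2/(2-1) = 1, so pi = 4 / 1000
  geno <- matrix(c(1, 1, 1, 1), ncol = 1)
  panel <- make_panel(geno, pos = c(100L, 300L, 600L, 900L), chrom_len = 1000L)
  w <- pi_windows(panel, window = 1000, step = 1000)
  expect_equal(w$value, 0.004)
  expect_equal(w$n_sites, 4L)

  # monomorphic sites contribute zero
  panel0 <- make_panel(matrix(c(0, 2, 0, 2), 2), pos = c(100L, 200L),
                       chrom_len = 1000L)
  w0 <- pi_windows(panel0, window = 1000, step = 1000)
  expect_equal(w0$value, 0)

  # a window with no genotyped site is missing
  panelNA <- make_panel(matrix(NA_real_, 1, 2), pos = 100L, chrom_len = 1000L)
  expect_true(is.na(pi_windows(panelNA, window = 1000, step = 1000)$value))
})

test_that("window tiling covers each bp by window/step windows except edges", {
  w <- tile_windows(100000, 10000, 5000)
  mid <- 50001
  covering <- sum(w$start0 < mid & w$end >= mid)
  expect_equal(covering, 2L)  # ceiling(window / step)
  expect_equal(w$start0[1], 0L)
  expect_equal(max(w$end), 100000L)
})

test_that("genome-wide pi matches the Balding-Nichols closed form within 5%", {
  cfg <- sim_config(seed = 61, n_chromosomes = 1, chrom_length = 3e6,
                    pop_snp_rate = 0.02, causal_n_snps = 0,
                    introgression_fraction = 0, introgressed_interval = NULL,
                    divergent_interval = NULL)
  pop <- simulate_population(cfg)
  # P1 drifts through p12 then p1: composite F = 1 - (1-F12)(1-F1);
  # E[2p'(1-p')] = (1-F) * 2 E[p(1-p)] with p ~ U(0.05, 0.95):
  # E[p(1-p)] = 1/2 - (Var + 1/4) = 0.25 - 0.0675
  Fcomp <- 1 - (1 - 0.05) * (1 - 0.1)
  expected <- cfg$pop_snp_rate * (1 - Fcomp) * 2 * (0.25 - 0.9^2 / 12)
  got <- pi_global(pop$panel, group = "P1")
  expect_lt(abs(got - expected) / expected, 0.05)
})

test_that("Weir-Cockerham window Fst hits 1 on fixed differences", {
  geno <- matrix(c(rep(0, 10), rep(2, 10)), nrow = 1)
  geno <- geno[rep(1, 50), ]
  panel <- make_panel(geno, pos = seq(10L, by = 19L, length.out = 50),
                      chrom_len = 1000L,
                      groups = setNames(rep(c("A", "B"), each = 10),
                                        sprintf("s%02d", 1:20)))
  w <- fst_wc_windows(panel, "A", "B", window = 1000, step = 1000)
  expect_equal(w$value, 1)
  expect_equal(w$n_sites, 50L)
})

test_that("per-site W&C components equal the literal 1984 transcription", {
  withr::with_seed(99, {
    m <- 200
    p <- runif(m, 0.02, 0.98)
    gA <- matrix(rbinom(m * 12, 2, rep(p, 12)), m)
    gB <- matrix(rbinom(m * 15, 2, rep(.rbn_test(p, 0.15), 15)), m)
    gA[sample(length(gA), 50)] <- NA  # some missing genotypes
    geno <- cbind(gA, gB)
    colnames(geno) <- sprintf("s%02d", 1:27)
    groups <- setNames(rep(c("A", "B"), c(12, 15)), colnames(geno))
    panel <- make_panel(geno, pos = sort(sample.int(1e5, m)),
                        chrom_len = 1e5L, groups = groups)
    got <- fst_wc_windows(panel, "A", "B", window = 1e5, step = 1e5)
    # literal transcription, site by site
    abc <- t(vapply(seq_len(m), function(i)
      oracle_wc_abc(geno[i, 1:12], geno[i, 13:27]), c(a = 0, b = 0, c = 0)))
    ok <- apply(is.finite(abc), 1, all)
    want <- sum(abc[ok, "a"]) / sum(abc[ok, ])
    expect_equal(got$value, want, tolerance = 1e-12)
    expect_equal(got$n_sites, sum(ok))
  })
})

test_that("mean Fst increases monotonically with drift", {
  fst_at <- function(drift, seed) {
    cfg <- sim_config(seed = seed, n_chromosomes = 1, chrom_length = 5e5,
                      pop_snp_rate = 0.01, causal_n_snps = 0,
                      pop_drift = c(p12 = 0.02, p1 = drift, p2 = drift, p3 = drift),
                      introgression_fraction = 0, introgressed_interval = NULL,
                      divergent_interval = NULL)
    pop <- simulate_population(cfg)
    w <- fst_wc_windows(pop$panel, "P1", "P2")
    mean(w$value, na.rm = TRUE)
  }
  vals <- vapply(seq_along(c(0.02, 0.05, 0.1, 0.2, 0.4)), function(i)
    fst_at(c(0.02, 0.05, 0.1, 0.2, 0.4)[i], seed = 50 + i), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("sweep selection takes exactly the planted top windows and merges", {
  stats <- data.frame(chrom = "chr1",
                      start0 = seq(0L, by = 5000L, length.out = 100),
                      end = seq(10000L, by = 5000L, length.out = 100),
                      n_sites = 10L, value = 0.05)
  stats$value[c(20, 21, 50, 80, 99)] <- c(0.9, 0.8, 0.7, 0.95, 0.85)
  sw <- select_sweeps(stats, top_frac = 0.05)
  # the two adjacent hot windows merge into one region
  expect_equal(nrow(sw$regions), 4L)
  expect_true(all(sw$regions$end > sw$regions$start0))
  # boundary: top_frac = 1 selects every non-missing window
  sw_all <- select_sweeps(stats, top_frac = 1)
  expect_equal(nrow(sw_all$regions), 1L)  # all windows merge into one span
  expect_error(select_sweeps(stats[1:10, ]), "20")
})

test_that("D statistic symmetry, single-site value, and undefined case", {
  # p1 == p2 at every site: D exactly 0
  p <- runif(50, 0.2, 0.8)
  panel <- make_four_pop_panel(p, p, runif(50, 0.2, 0.8), seed = 2)
  # force identical P1/P2 genotype columns for exact symmetry
  g <- panel$geno
  g[, panel$groups == "P2"] <- g[, panel$groups == "P1"]
  panel$geno <- g
  d <- d_statistic(panel, "P1", "P2", "P3", "OUT", block_bp = 1e4)
  expect_equal(d$D, 0)

  # single site with derived pattern (0, 1, 1, 0): pure ABBA
  panel1 <- make_four_pop_panel(0, 1, 1, 0, n_per_pop = 5, pos = 500L, seed = 3)
  d1 <- d_statistic(panel1, "P1", "P2", "P3", "OUT")
  expect_equal(d1$D, 1)
  expect_equal(d1$abba_sum, 1)
  expect_equal(d1$baba_sum, 0)

  # no informative sites: D undefined
  panel0 <- make_four_pop_panel(rep(0, 5), rep(0, 5), rep(0, 5), n_per_pop = 4,
                                seed = 4)
  expect_true(is.na(d_statistic(panel0, "P1", "P2", "P3", "OUT")$D))
})

test_that("polymorphic outgroup sites are excluded from polarization", {
  # outgroup at derived frequency 0.5 -> site skipped entirely
  panel <- make_four_pop_panel(c(0.5, 0), c(0.5, 1), c(0.5, 1), c(0.5, 0),
                               n_per_pop = 30, pos = c(100L, 200L), seed = 6)
  d <- d_statistic(panel, "P1", "P2", "P3", "OUT")
  expect_equal(d$n_sites_used, 1L)
})

test_that("fd limits: complete sharing gives 1, no asymmetry gives 0", {
  withr::with_seed(8, {
    m <- 60
    p23 <- runif(m, 0.3, 0.9)
    # p2 == p3 at every site (genotypes drawn independently but frequencies
    # equal), p1 = 0: expected fd = 1 exactly at the frequency level; use
    # identical genotype columns to make it exact
    panel <- make_four_pop_panel(rep(0, m), p23, p23, n_per_pop = 10,
                                 pos = sort(sample.int(99000, m)), seed = 9)
    g <- panel$geno
    g[, panel$groups == "P3"] <- g[, panel$groups == "P2"]
    panel$geno <- g
    fd <- fd_windows(panel, "P1", "P2", "P3", "OUT", window = 1e6, step = 1e6,
                     min_sites = 1)
    expect_equal(fd$value[1], 1)

    # p1 == p2 everywhere: numerator 0 -> fd = 0
    p <- runif(m, 0.2, 0.8)
    panel2 <- make_four_pop_panel(p, p, runif(m, 0.2, 0.8), n_per_pop = 10,
                                  pos = sort(sample.int(99000, m)), seed = 10)
    g2 <- panel2$geno
    g2[, panel2$groups == "P2"] <- g2[, panel2$groups == "P1"]
    panel2$geno <- g2
    fd2 <- fd_windows(panel2, "P1", "P2", "P3", "OUT", window = 1e6,
                      step = 1e6, min_sites = 1)
    expect_equal(fd2$value[1], 0)

    # too few informative sites -> missing
    fd3 <- fd_windows(panel2, "P1", "P2", "P3", "OUT", window = 1e6,
                      step = 1e6, min_sites = m + 1)
    expect_true(all(is.na(fd3$value)))
  })
})
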