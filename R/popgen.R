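# Population-genetic scans: VCF loading with depth/biallelic filters,
# windowed nucleotide diversity, Weir-Cockerham (1984) Fst with top-quantile
# sweep calling, Patterson's D with block-jackknife Z, and Martin's fd.

#' Construct a variant panel
#'
#' @param chrom,pos,ref,alt per-site vectors (positions 1-based)
#' @param geno sites x samples matrix of alt-allele dosage (0/1/2, NA missing)
#' @param groups named character vector mapping sample -> group label
#' @param chrom_lens named vector of chromosome lengths
#' @return object of class `variant_panel`
#' @export
variant_panel <- function(chrom, pos, ref, alt, geno, groups, chrom_lens) {
  stopifnot(length(chrom) == nrow(geno), length(pos) == nrow(geno),
            !is.null(colnames(geno)), all(colnames(geno) %in% names(groups)))
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = ref, alt = alt, geno = geno,
                 samples = colnames(geno),
                 groups = groups[colnames(geno)],
                 chrom_lens = chrom_lens),
            class = "variant_panel")
}

#' @export
print.variant_panel <- function(x, ...) {
  cat("variant_panel:", nrow(x$geno), "sites x", ncol(x$geno), "samples;",
      "groups:", paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Load a population VCF into a variant panel
#'
#' Non-biallelic sites are dropped; genotypes with per-sample read depth
#' below `min_dp` are set missing; sites left with no called genotype are
#' dropped. Every VCF sample must appear in the group table.
#'
#' @param path VCF file
#' @param group_table data.frame with columns `sample`, `group`
#' @param min_dp minimum per-genotype read depth
#' @return a [variant_panel()]
#' @export
load_vcf <- function(path, group_table, min_dp = 5) {
  vcf <- VariantAnnotation::readVcf(path)
  smp <- colnames(vcf)
  missing_smp <- setdiff(smp, group_table$sample)
  if (length(missing_smp))
    stop("samples absent from group table: ", paste(missing_smp, collapse = ", "))
  n0 <- nrow(vcf)
  biallelic <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf)) == 1L
  vcf <- vcf[biallelic]
  gt <- VariantAnnotation::geno(vcf)$GT
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  dos[gt %in% c("1/1", "1|1")] <- 2
  dp <- VariantAnnotation::geno(vcf)$DP
  n_masked <- 0L
  if (!is.null(dp)) {
    mask <- !is.na(dp) & dp < min_dp
    n_masked <- sum(mask & !is.na(dos))
    dos[mask] <- NA_real_
  }
  called <- rowSums(!is.na(dos)) > 0
  rr <- SummarizedExperiment::rowRanges(vcf)[called]
  dos <- dos[called, , drop = FALSE]
  message(sprintf("load_vcf: %d sites read, %d non-biallelic dropped, %d genotypes depth-masked, %d empty sites dropped",
                  n0, n0 - sum(biallelic), n_masked, sum(!called)))
  sl <- GenomeInfoDb::seqlengths(rr)
  if (all(is.na(sl))) sl <- tapply(BiocGenerics::start(rr),
                                   as.character(GenomeInfoDb::seqnames(rr)), max)
  variant_panel(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(rr$REF),
    alt = vapply(rr$ALT, function(a) as.character(a)[1], ""),
    geno = dos,
    groups = setNames(group_table$group, group_table$sample),
    chrom_lens = sl
  )
}

.group_cols <- function(panel, group) {
  cols <- which(panel$groups == group)
  if (!length(cols)) stop("no samples in group ", group)
  cols
}

# per-site alt-allele frequency and called-allele count for one group
.group_freq <- function(panel, group) {
  g <- panel$geno[, .group_cols(panel, group), drop = FALSE]
  n <- 2 * rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / n
  p[n == 0] <- NA_real_
  list(p = p, n = n)
}

.window_apply <- function(panel, window, step, site_fun) {
  chroms <- names(panel$chrom_lens)
  out <- list()
  for (ch in chroms) {
    w <- tile_windows(panel$chrom_lens[[ch]], window, step)
    if (nrow(w) == 0L) next
    idx <- which(panel$chrom == ch)
    res <- site_fun(idx)
    pos <- panel$pos[idx]
    stats <- t(vapply(seq_len(nrow(w)), function(k) {
      inw <- pos > w$start0[k] & pos <= w$end[k]
      res$window(which(inw), w$start0[k], w$end[k])
    }, c(n_sites = 0, value = 0)))
    out[[ch]] <- data.frame(chrom = ch, start0 = w$start0, end = w$end,
                            n_sites = as.integer(stats[, 1]),
                            value = stats[, 2], stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Windowed nucleotide diversity
#'
#' Per-site unbiased heterozygosity 2p(1-p) * n/(n-1) with n the called
#' allele count; a window's value is the sum over its sites divided by the
#' window length in bp (monomorphic positions contribute zero; every
#' position is assumed callable).
#'
#' @param panel a [variant_panel()]
#' @param group optional group label to restrict samples (default all)
#' @param window,step window and step in bp
#' @param min_sites windows with fewer genotyped sites are missing
#' @return data.frame with columns `chrom`, `start0`, `end`, `n_sites`,
#'   `value`
#' @export
pi_windows <- function(panel, group = NULL, window = 10000, step = 5000,
                       min_sites = 1) {
  cols <- if (is.null(group)) seq_len(ncol(panel$geno)) else .group_cols(panel, group)
  g <- panel$geno[, cols, drop = FALSE]
  n <- 2 * rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / pmax(n, 1)
  h <- ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), NA_real_)
  .window_apply(panel, window, step, function(idx) {
    hh <- h[idx]
    list(window = function(rows, s0, e) {
      usable <- rows[!is.na(hh[rows])]
      if (length(usable) < min_sites) return(c(length(usable), NA_real_))
      c(length(usable), sum(hh[usable]) / (e - s0))
    })
  })
}

# per-site Weir & Cockerham (1984) variance components for two populations
.wc_site_components <- function(p1, n1, h1, p2, n2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  ok <- n1 >= 1 & n2 >= 1 & nbar > 1
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
         (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
         (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  ok <- ok & is.finite(a) & is.finite(b) & is.finite(cc) & nc > 0
  list(a = a, b = b, c = cc, ok = ok)
}

#' Genome-wide nucleotide diversity
#'
#' Sum of per-site unbiased heterozygosity over all sites divided by the
#' total genome length (every position assumed callable).
#'
#' @inheritParams pi_windows
#' @return a single number
#' @export
pi_global <- function(panel, group = NULL) {
  cols <- if (is.null(group)) seq_len(ncol(panel$geno)) else .group_cols(panel, group)
  g <- panel$geno[, cols, drop = FALSE]
  n <- 2 * rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / pmax(n, 1)
  h <- ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), 0)
  sum(h) / sum(panel$chrom_lens)
}

#' Windowed Weir-Cockerham Fst between two groups
#'
#' Per-site variance components a, b, c (Weir & Cockerham 1984, two
#' populations, genotype counts and observed heterozygosity); window
#' weighted Fst = sum(a) / sum(a + b + c) over usable sites. Sites where a
#' population has fewer than two called alleles are skipped; windows with
#' no usable site or a non-positive denominator are missing.
#'
#' @param panel a [variant_panel()]
#' @param group1,group2 group labels
#' @param window,step window and step in bp
#' @param min_sites windows with fewer usable sites are missing
#' @return data.frame with columns `chrom`, `start0`, `end`, `n_sites`,
#'   `value`
#' @export
fst_wc_windows <- function(panel, group1, group2, window = 10000, step = 5000,
                           min_sites = 1) {
  c1 <- .group_cols(panel, group1); c2 <- .group_cols(panel, group2)
  stat_pop <- function(cols) {
    g <- panel$geno[, cols, drop = FALSE]
    n <- rowSums(!is.na(g))                      # individuals genotyped
    p <- rowSums(g, na.rm = TRUE) / pmax(2 * n, 1)
    h <- rowSums(g == 1, na.rm = TRUE) / pmax(n, 1)
    list(p = p, n = n, h = h)
  }
  s1 <- stat_pop(c1); s2 <- stat_pop(c2)
  comp <- .wc_site_components(s1$p, s1$n, s1$h, s2$p, s2$n, s2$h)
  .window_apply(panel, window, step, function(idx) {
    a <- comp$a[idx]; b <- comp$b[idx]; cc <- comp$c[idx]; ok <- comp$ok[idx]
    list(window = function(rows, s0, e) {
      use <- rows[ok[rows]]
      if (length(use) < min_sites) return(c(length(use), NA_real_))
      den <- sum(a[use] + b[use] + cc[use])
      if (den <= 0) return(c(length(use), NA_real_))
      c(length(use), sum(a[use]) / den)
    })
  })
}

#' Select putative sweep regions from windowed Fst
#'
#' Windows at or above the (1 - top_frac) quantile of non-missing values are
#' merged when overlapping or adjacent; genes overlapping the merged regions
#' are reported.
#'
#' @param stats window table from [fst_wc_windows()]
#' @param top_frac upper tail fraction (0.05 = top 5 percent)
#' @param genes optional gene-model table for overlap reporting
#' @return list with `threshold`, `regions` (chrom, start0, end) and `genes`
#' @export
select_sweeps <- function(stats, top_frac = 0.05, genes = NULL) {
  v <- stats$value
  if (all(is.na(v))) stop("all windows missing; cannot select sweeps")
  if (sum(!is.na(v)) < 20) stop("need >= 20 non-missing windows")
  thr <- stats::quantile(v, 1 - top_frac, na.rm = TRUE, names = FALSE)
  sel <- stats[!is.na(v) & v >= thr, , drop = FALSE]
  if (nrow(sel) == 0L)
    return(list(threshold = thr,
                regions = data.frame(chrom = character(), start0 = integer(),
                                     end = integer()), genes = character()))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    sel$chrom, IRanges::IRanges(sel$start0 + 1L, sel$end)))
  regions <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                        start0 = BiocGenerics::start(gr) - 1L,
                        end = BiocGenerics::end(gr), stringsAsFactors = FALSE)
  hit_genes <- character()
  if (!is.null(genes) && nrow(genes)) {
    ggr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start, genes$end))
    hit_genes <- genes$gene_id[unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(ggr, gr)))]
  }
  list(threshold = thr, regions = regions, genes = hit_genes)
}

# derived-allele frequencies on (((P1,P2),P3),O): the outgroup defines the
# ancestral allele; sites where the outgroup's minor-allele frequency
# exceeds `poly_tol` are dropped.
.polarized_freqs <- function(panel, p1, p2, p3, out, poly_tol = 0.1) {
  f <- lapply(c(p1, p2, p3, out), function(g) .group_freq(panel, g)$p)
  q4 <- f[[4]]
  usable <- !is.na(f[[1]]) & !is.na(f[[2]]) & !is.na(f[[3]]) & !is.na(q4)
  alt_derived <- usable & q4 <= poly_tol
  ref_derived <- usable & q4 >= 1 - poly_tol
  d <- lapply(f, function(p) ifelse(alt_derived, p,
                             ifelse(ref_derived, 1 - p, NA_real_)))
  keep <- alt_derived | ref_derived
  list(dp1 = d[[1]], dp2 = d[[2]], dp3 = d[[3]], dp4 = d[[4]], keep = keep)
}

#' Patterson's D (ABBA-BABA) with block-jackknife Z
#'
#' Frequency-based D on the topology (((P1,P2),P3),O) with derived-allele
#' polarization by the outgroup. Positive D = excess ABBA = allele sharing
#' between P2 and P3 (Durand convention). Z is computed by a delete-one
#' block jackknife over `block_bp` blocks; the block size is shrunk if fewer
#' than `min_blocks` non-empty blocks result.
#'
#' @param panel a [variant_panel()]
#' @param p1,p2,p3,out group labels on the tree (((P1,P2),P3),O)
#' @param block_bp jackknife block size in bp
#' @param poly_tol outgroup polymorphism tolerance for polarization
#' @param min_blocks minimum number of jackknife blocks
#' @return list with `D`, `Z`, `n_blocks`, `abba_sum`, `baba_sum`,
#'   `n_sites_used`
#' @export
d_statistic <- function(panel, p1, p2, p3, out, block_bp = 1e6,
                        poly_tol = 0.1, min_blocks = 20) {
  pf <- .polarized_freqs(panel, p1, p2, p3, out, poly_tol)
  keep <- which(pf$keep)
  abba <- (1 - pf$dp1[keep]) * pf$dp2[keep] * pf$dp3[keep] * (1 - pf$dp4[keep])
  baba <- pf$dp1[keep] * (1 - pf$dp2[keep]) * pf$dp3[keep] * (1 - pf$dp4[keep])
  A <- sum(abba); B <- sum(baba)
  if (A + B == 0)
    return(list(D = NA_real_, Z = NA_real_, n_blocks = 0L,
                abba_sum = A, baba_sum = B, n_sites_used = length(keep)))
  D <- (A - B) / (A + B)
  # jackknife blocks: contiguous block_bp segments along each chromosome
  total_span <- sum(panel$chrom_lens)
  if (total_span / block_bp < min_blocks) block_bp <- ceiling(total_span / min_blocks)
  blk <- paste(panel$chrom[keep], (panel$pos[keep] - 1) %/% block_bp)
  ublk <- unique(blk)
  nb <- length(ublk)
  if (nb >= 2) {
    Aj <- vapply(split(abba, blk), sum, 0)
    Bj <- vapply(split(baba, blk), sum, 0)
    Dminus <- (A - Aj - (B - Bj)) / (A - Aj + B - Bj)
    Dminus <- Dminus[is.finite(Dminus)]
    m <- length(Dminus)
    se <- sqrt((m - 1) / m * sum((Dminus - mean(Dminus))^2))
    Z <- if (se > 0) D / se else NA_real_
  } else Z <- NA_real_
  list(D = D, Z = Z, n_blocks = nb, abba_sum = A, baba_sum = B,
       n_sites_used = length(keep))
}

#' Windowed fd admixture-fraction estimate
#'
#' Martin et al.'s fd: the ABBA-BABA numerator normalized by the same
#' numerator computed with a per-site complete-sharing donor PD (whichever
#' of P2/P3 has the higher derived-allele frequency). Windows whose
#' numerator is negative (D-sign negative), with fewer than `min_sites`
#' informative sites, or with a non-positive denominator are missing.
#'
#' @inheritParams d_statistic
#' @param window,step window and step in bp
#' @param min_sites minimum informative sites per window
#' @return data.frame with columns `chrom`, `start0`, `end`, `n_sites`,
#'   `value`
#' @export
fd_windows <- function(panel, p1, p2, p3, out, window = 1e5, step = 5e4,
                       min_sites = 10, poly_tol = 0.1) {
  pf <- .polarized_freqs(panel, p1, p2, p3, out, poly_tol)
  dp1 <- pf$dp1; dp2 <- pf$dp2; dp3 <- pf$dp3; dp4 <- pf$dp4
  num <- (1 - dp1) * dp2 * dp3 * (1 - dp4) - dp1 * (1 - dp2) * dp3 * (1 - dp4)
  pd <- pmax(dp2, dp3)
  den <- (1 - dp1) * pd * pd * (1 - dp4) - dp1 * (1 - pd) * pd * (1 - dp4)
  keep <- pf$keep
  .window_apply(panel, window, step, function(idx) {
    nu <- num[idx]; de <- den[idx]; kp <- keep[idx]
    list(window = function(rows, s0, e) {
      use <- rows[kp[rows] & !is.na(nu[rows])]
      if (length(use) < min_sites) return(c(length(use), NA_real_))
      sn <- sum(nu[use]); sd_ <- sum(de[use])
      if (sn < 0 || sd_ <= 0) return(c(length(use), NA_real_))
      c(length(use), sn / sd_)
    })
  })
}
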