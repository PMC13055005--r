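# Candidate-gene haplotype -> metabolite association: coding-effect
# classification of SNPs against gene models, het/MAF filtering,
# homozygote-only haplotype construction, and a Welch t-test of the
# phenotype between the two major haplotype classes.

#' Classify the coding effect of a SNP
#'
#' Strand-aware codon reconstruction from the gene model and genome,
#' substitution of the alternate allele, and translation with the standard
#' genetic code.
#'
#' @param chrom,pos,ref,alt SNP description (1-based position; ref/alt on the
#'   + strand of the reference)
#' @param model one-row gene-model table
#' @param genome DNAStringSet keyed by chromosome
#' @return list with `effect` (synonymous / nonsynonymous / stop_gain /
#'   noncoding), `codon_index`, `ref_aa`, `alt_aa`
#' @export
classify_coding_effect <- function(chrom, pos, ref, alt, model, genome) {
  gbase <- as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
  if (gbase != ref)
    stop(sprintf("reference mismatch at %s:%d (VCF %s, genome %s)",
                 chrom, pos, ref, gbase))
  if (chrom != model$chrom)
    return(list(effect = "noncoding", codon_index = NA_integer_,
                ref_aa = NA_character_, alt_aa = NA_character_))
  cs <- model$cds_starts[[1]]; ce <- model$cds_ends[[1]]
  inside <- which(pos >= cs & pos <= ce)
  if (length(inside) == 0L)
    return(list(effect = "noncoding", codon_index = NA_integer_,
                ref_aa = NA_character_, alt_aa = NA_character_))
  i <- inside[1]
  if (model$strand == "+") {
    cds_pos <- sum(pmax(0L, ce[seq_len(i - 1)] - cs[seq_len(i - 1)] + 1L)) +
      (pos - cs[i] + 1L)
  } else {
    after <- setdiff(seq_along(cs), seq_len(i))
    cds_pos <- sum(ce[after] - cs[after] + 1L) + (ce[i] - pos + 1L)
  }
  cds <- as.character(cds_seqs(genome, model)[[1]])
  codon_index <- (cds_pos - 1L) %/% 3L + 1L
  off <- (cds_pos - 1L) %% 3L + 1L
  codon <- substring(cds, 3L * (codon_index - 1L) + 1L, 3L * codon_index)
  tx_ref <- if (model$strand == "-")
    as.character(Biostrings::complement(Biostrings::DNAString(ref))) else ref
  tx_alt <- if (model$strand == "-")
    as.character(Biostrings::complement(Biostrings::DNAString(alt))) else alt
  stopifnot(substring(codon, off, off) == tx_ref)
  alt_codon <- codon
  substring(alt_codon, off, off) <- tx_alt
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[codon]); alt_aa <- unname(code[alt_codon])
  effect <- if (alt_aa == "*" && ref_aa != "*") "stop_gain"
    else if (ref_aa == alt_aa) "synonymous" else "nonsynonymous"
  list(effect = effect, codon_index = codon_index,
       ref_aa = ref_aa, alt_aa = alt_aa)
}

#' Filter association SNPs by heterozygosity and minor-allele frequency
#'
#' Drops SNPs whose observed heterozygote fraction exceeds `het_max` or whose
#' minor-allele frequency falls below `maf_min`, both computed over
#' non-missing genotypes.
#'
#' @param geno sites x samples dosage matrix (0/1/2/NA)
#' @param het_max maximum heterozygote fraction
#' @param maf_min minimum minor-allele frequency
#' @return list with `keep` (row indices retained), `het`, `maf`, and a
#'   `reasons` summary of exclusions
#' @export
filter_assoc_snps <- function(geno, het_max = 0.2, maf_min = 0.05) {
  n <- rowSums(!is.na(geno))
  het <- rowSums(geno == 1, na.rm = TRUE) / pmax(n, 1)
  p <- rowSums(geno, na.rm = TRUE) / pmax(2 * n, 1)
  maf <- pmin(p, 1 - p)
  drop_het <- het > het_max
  drop_maf <- maf < maf_min
  keep <- which(n > 0 & !drop_het & !drop_maf)
  list(keep = keep, het = het, maf = maf,
       reasons = c(het = sum(drop_het), maf = sum(drop_maf & !drop_het),
                   empty = sum(n == 0)))
}

#' Build per-sample haplotype classes for one gene
#'
#' Samples homozygous at every retained SNP get the concatenated allele
#' string (reference or alternate base per SNP); any heterozygous or missing
#' genotype yields the class "het/other".
#'
#' @param geno retained-SNP x samples dosage matrix
#' @param ref,alt allele characters per retained SNP
#' @return list with `classes` (named character vector, sample -> class) and
#'   `census` (class counts, decreasing)
#' @export
build_gene_haplotypes <- function(geno, ref, alt) {
  geno <- rbind(geno)
  stopifnot(nrow(geno) == length(ref), length(ref) == length(alt))
  classes <- vapply(seq_len(ncol(geno)), function(s) {
    g <- geno[, s]
    if (any(is.na(g)) || any(g == 1)) return("het/other")
    paste(ifelse(g == 0, ref, alt), collapse = "")
  }, "")
  names(classes) <- colnames(geno)
  list(classes = classes, census = sort(table(classes), decreasing = TRUE))
}

#' Haplotype-phenotype association test for one gene
#'
#' Welch two-sample t-test of the phenotype between the two most frequent
#' homozygous haplotype classes; the favorable haplotype is the
#' higher-mean class when p < alpha. Per-group and high/low-phenotype
#' haplotype frequencies are reported alongside.
#'
#' @param classes named sample -> haplotype class vector from
#'   [build_gene_haplotypes()]
#' @param pheno named numeric vector of phenotype values (same samples)
#' @param groups optional named sample -> group labels for frequency tables
#' @param alpha significance level
#' @param split how to split samples into high/low phenotype groups for the
#'   frequency table (default median)
#' @return list with `testable`, `class1`, `class2`, `mean1`, `mean2`, `t`,
#'   `p`, `favorable`, `n1`, `n2`, `census`, `group_freq`, `pheno_group_freq`
#' @export
haplotype_phenotype_test <- function(classes, pheno, groups = NULL,
                                     alpha = 0.05, split = stats::median) {
  common <- intersect(names(classes), names(pheno))
  cl <- classes[common]; ph <- pheno[common]
  hom <- cl[cl != "het/other"]
  census <- sort(table(hom), decreasing = TRUE)
  big <- names(census)[census >= 2]
  not_testable <- list(testable = FALSE, class1 = NA_character_,
                       class2 = NA_character_, mean1 = NA_real_,
                       mean2 = NA_real_, t = NA_real_, p = NA_real_,
                       favorable = "none", n1 = NA_integer_, n2 = NA_integer_,
                       census = census, group_freq = NULL,
                       pheno_group_freq = NULL)
  if (length(big) < 2L) return(not_testable)
  c1 <- big[1]; c2 <- big[2]
  x1 <- ph[names(hom)[hom == c1]]; x2 <- ph[names(hom)[hom == c2]]
  tt <- stats::t.test(x1, x2, var.equal = FALSE)
  favorable <- if (tt$p.value < alpha) {
    if (mean(x1) >= mean(x2)) c1 else c2
  } else "none"
  gf <- NULL
  if (!is.null(groups)) {
    g <- groups[common]
    gf <- prop.table(table(group = g, class = cl), margin = 1)
  }
  cut <- split(ph)
  pg <- prop.table(table(pe = ifelse(ph > cut, "high", "low"), class = cl),
                   margin = 1)
  list(testable = TRUE, class1 = c1, class2 = c2,
       mean1 = mean(x1), mean2 = mean(x2),
       t = unname(tt$statistic), p = tt$p.value, favorable = favorable,
       n1 = length(x1), n2 = length(x2), census = census,
       group_freq = gf, pheno_group_freq = pg)
}

#' Scan genes for non-synonymous haplotype-phenotype associations
#'
#' For each gene: collect panel SNPs inside the CDS, classify coding
#' effects, keep non-synonymous SNPs passing the het/MAF filters, build
#' homozygote haplotype classes, and run the two-class Welch test.
#'
#' @param panel a [variant_panel()]
#' @param models gene-model table
#' @param genome DNAStringSet of the reference haplotype
#' @param pheno named numeric phenotype vector (sample -> value)
#' @param genes optional character vector of gene ids (default: all genes)
#' @param het_max,maf_min SNP filters (see [filter_assoc_snps()])
#' @param alpha significance level
#' @return data.frame with one row per gene with >= 1 retained SNP:
#'   `gene_id`, `n_snps`, `class1`, `class2`, `mean1`, `mean2`, `t`, `p`,
#'   `p_bh`, `favorable`, `n1`, `n2`
#' @export
assoc_scan <- function(panel, models, genome, pheno, genes = NULL,
                       het_max = 0.2, maf_min = 0.05, alpha = 0.05) {
  if (is.null(genes)) genes <- models$gene_id
  rows <- list()
  for (gid in genes) {
    model <- models[gid, , drop = FALSE]
    cs <- model$cds_starts[[1]]; ce <- model$cds_ends[[1]]
    idx <- which(panel$chrom == model$chrom & panel$pos >= model$start &
                   panel$pos <= model$end)
    idx <- idx[vapply(panel$pos[idx], function(p) any(p >= cs & p <= ce), TRUE)]
    if (!length(idx)) next
    eff <- vapply(idx, function(k) classify_coding_effect(
      panel$chrom[k], panel$pos[k], panel$ref[k], panel$alt[k],
      model, genome)$effect, "")
    idx <- idx[eff == "nonsynonymous"]
    if (!length(idx)) next
    flt <- filter_assoc_snps(panel$geno[idx, , drop = FALSE], het_max, maf_min)
    idx <- idx[flt$keep]
    if (!length(idx)) next
    hap <- build_gene_haplotypes(panel$geno[idx, , drop = FALSE],
                                 panel$ref[idx], panel$alt[idx])
    res <- haplotype_phenotype_test(hap$classes, pheno, groups = panel$groups,
                                    alpha = alpha)
    rows[[gid]] <- data.frame(
      gene_id = gid, n_snps = length(idx),
      positions = paste(panel$pos[idx], collapse = ","),
      class1 = res$class1, class2 = res$class2,
      mean1 = res$mean1, mean2 = res$mean2, t = res$t, p = res$p,
      favorable = res$favorable, n1 = res$n1 %||% NA_integer_,
      n2 = res$n2 %||% NA_integer_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) return(data.frame())
  out$p_bh <- bh_adjust(out$p)
  out
}
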