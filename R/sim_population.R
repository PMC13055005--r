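# Simulation of a four-population variant panel on the topology
# (((P1,P2),P3),O): Balding-Nichols drift around uniform ancestral
# frequencies, a planted introgressed segment (donor P3 -> recipient P2), an
# optional locally divergent locus (extra drift on the P3 branch), and an
# optional causal non-synonymous haplotype in one gene.

.rbn <- function(p, F) {
  # Balding-Nichols: Beta(p(1-F)/F, (1-p)(1-F)/F); degenerate at F -> 0
  if (F <= 0) return(p)
  rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

.in_interval <- function(chrom, pos, interval) {
  if (is.null(interval)) return(rep(FALSE, length(pos)))
  chrom == interval$chrom & pos >= interval$start & pos <= interval$end
}

#' Simulate a four-population variant panel
#'
#' Segregating sites are placed uniformly at `pop_snp_rate` per bp; the
#' ancestral alternate-allele frequency is Uniform(0.05, 0.95); descendant
#' frequencies follow Balding-Nichols drift along the branches of
#' (((P1,P2),P3),O). Inside `introgressed_interval`, recipient (P2)
#' frequencies are replaced by (1-f) own + f donor (P3). Inside
#' `divergent_interval`, P3 receives an extra drift boost (`divergent_drift`),
#' the planted truth for sweep recovery. Genotypes are binomial(2, freq); the
#' outgroup is fixed for the ancestral (reference) allele. Per-genotype read
#' depths are Poisson(`mean_dp`) and genotypes below `min_dp` are masked in
#' the returned panel, exactly as [load_vcf()] would mask them.
#'
#' If `genome`/`models` are supplied, reference alleles match the hap1 genome
#' and `causal_n_snps` non-synonymous causal SNPs (in perfect linkage) are
#' planted in `causal_gene`, with the alternate allele as the favorable
#' variant.
#'
#' @param cfg a [sim_config()]
#' @param genome optional hap1 DNAStringSet (reference alleles, causal gene)
#' @param models optional hap1 gene-model table
#' @param causal_gene gene id for the causal haplotype (default: the middle
#'   gene of the first chromosome)
#' @return list with `panel` (a [variant_panel()], depth-masked), `dp` (depth
#'   matrix), `geno_raw` (pre-mask dosages, as written to VCF),
#'   `group_table`, and `truth` (introgression, divergent locus, causal gene)
#' @export
simulate_population <- function(cfg, genome = NULL, models = NULL,
                                causal_gene = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(sub_seed(cfg$seed, "population"), {
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    chrom_lens <- setNames(rep(cfg$chrom_length, cfg$n_chromosomes), chroms)
    iv <- cfg$introgressed_interval
    if (!is.null(iv) && cfg$introgression_fraction > 0) {
      if (!(iv$chrom %in% chroms) || iv$start < 1 || iv$end > chrom_lens[[iv$chrom]])
        stop("introgressed_interval outside simulated chromosomes")
    }
    pos <- list(); chrom <- list()
    for (ch in chroms) {
      n <- rbinom(1, chrom_lens[[ch]], cfg$pop_snp_rate)
      pos[[ch]] <- sort(sample.int(chrom_lens[[ch]], n))
      chrom[[ch]] <- rep(ch, n)
    }
    pos <- unlist(pos, use.names = FALSE)
    chrom <- unlist(chrom, use.names = FALSE)
    m <- length(pos)

    p_anc <- runif(m, 0.05, 0.95)
    F <- cfg$pop_drift
    p12 <- .rbn(p_anc, F[["p12"]])
    p1 <- .rbn(p12, F[["p1"]])
    p2 <- .rbn(p12, F[["p2"]])
    p3 <- .rbn(p_anc, F[["p3"]])
    div <- .in_interval(chrom, pos, cfg$divergent_interval)
    if (any(div)) p3[div] <- .rbn(p3[div], cfg$divergent_drift)
    intro <- .in_interval(chrom, pos, iv)
    if (any(intro) && cfg$introgression_fraction > 0)
      p2[intro] <- (1 - cfg$introgression_fraction) * p2[intro] +
        cfg$introgression_fraction * p3[intro]

    freq_chrom <- chrom; freq_pos <- pos   # site order of the freq vectors
    npp <- cfg$n_samples_per_pop
    groups_vec <- rep(c("P1", "P2", "P3", "OUT"), each = npp)
    samples <- sprintf("S%03d", seq_along(groups_vec))
    geno <- matrix(0, m, length(samples), dimnames = list(NULL, samples))
    freqs <- list(P1 = p1, P2 = p2, P3 = p3)
    for (g in names(freqs)) {
      cols <- which(groups_vec == g)
      geno[, cols] <- rbinom(m * npp, 2, rep(freqs[[g]], npp))
    }
    # outgroup stays fixed for the ancestral (reference) allele: dosage 0

    # alleles
    nts <- c("A", "C", "G", "T")
    if (!is.null(genome)) {
      ref <- vapply(seq_len(m), function(i)
        as.character(Biostrings::subseq(genome[[chrom[i]]], pos[i], pos[i])), "")
    } else ref <- sample(nts, m, replace = TRUE)
    alt <- .other_base(ref)

    # causal non-synonymous haplotype
    causal <- NULL
    if (!is.null(genome) && !is.null(models) && cfg$causal_n_snps > 0) {
      if (is.null(causal_gene)) {
        on1 <- models[models$chrom == chroms[1], , drop = FALSE]
        causal_gene <- on1$gene_id[ceiling(nrow(on1) / 2)]
      }
      model <- models[causal_gene, , drop = FALSE]
      cds_positions <- unlist(lapply(seq_along(model$cds_starts[[1]]), function(k)
        model$cds_starts[[1]][k]:model$cds_ends[[1]][k]))
      cand <- sample(cds_positions)
      cpos <- integer(); calt <- character()
      for (p in cand) {
        if (length(cpos) == cfg$causal_n_snps) break
        r <- as.character(Biostrings::subseq(genome[[model$chrom]], p, p))
        hit <- NA_character_
        for (a in sample(setdiff(nts, r))) {
          eff <- classify_coding_effect(model$chrom, p, r, a, model, genome)
          if (eff$effect == "nonsynonymous") { hit <- a; break }
        }
        if (!is.na(hit)) { cpos <- c(cpos, p); calt <- c(calt, hit) }
      }
      if (length(cpos) < cfg$causal_n_snps)
        stop("configuration error: could not plant causal non-synonymous SNPs")
      ord <- order(cpos); cpos <- cpos[ord]; calt <- calt[ord]
      # latent favorable-haplotype copies per sample: mostly homozygous
      copies <- ifelse(runif(length(samples)) < cfg$causal_het_frac, 1L,
                       2L * rbinom(length(samples), 1, cfg$causal_hom_freq))
      cref <- vapply(cpos, function(p)
        as.character(Biostrings::subseq(genome[[model$chrom]], p, p)), "")
      # the causal gene's coding variation is exactly its causal haplotype:
      # background sites inside its CDS are removed (they would be in full
      # within-gene LD in the clonal accessions this design emulates, which
      # the linkage-equilibrium background cannot represent)
      drop <- chrom == model$chrom & pos %in% cds_positions
      if (any(drop)) {
        keep <- !drop
        pos <- pos[keep]; chrom <- chrom[keep]; ref <- ref[keep]; alt <- alt[keep]
        geno <- geno[keep, , drop = FALSE]
      }
      cgeno <- matrix(rep(copies, each = length(cpos)), length(cpos),
                      length(samples), dimnames = list(NULL, samples))
      pos <- c(pos, cpos); chrom <- c(chrom, rep(model$chrom, length(cpos)))
      ref <- c(ref, cref); alt <- c(alt, calt)
      geno <- rbind(geno, cgeno)
      ord <- order(match(chrom, chroms), pos)
      pos <- pos[ord]; chrom <- chrom[ord]; ref <- ref[ord]; alt <- alt[ord]
      geno <- geno[ord, , drop = FALSE]
      causal <- list(gene_id = causal_gene, positions = cpos,
                     favorable = paste(calt, collapse = ""),
                     other = paste(cref, collapse = ""),
                     copies = setNames(copies, samples))
    }

    dp <- matrix(rpois(length(geno), cfg$mean_dp), nrow(geno), ncol(geno),
                 dimnames = dimnames(geno))
    masked <- geno
    masked[dp < cfg$min_dp] <- NA
    group_table <- data.frame(sample = samples, group = groups_vec,
                              stringsAsFactors = FALSE)
    panel <- variant_panel(chrom, pos, ref, alt, masked,
                           setNames(groups_vec, samples), chrom_lens)
    # freqs are indexed by the pre-causal-insertion site order
    list(panel = panel, dp = dp, geno_raw = geno, group_table = group_table,
         freqs = list(anc = p_anc, p1 = p1, p2 = p2, p3 = p3,
                      chrom = freq_chrom, pos = freq_pos),
         truth = list(introgression = c(iv, list(
                        fraction = cfg$introgression_fraction,
                        donor = "P3", recipient = "P2")),
                      divergent = cfg$divergent_interval,
                      causal = causal))
  })
}

#' Write a variant panel to VCF v4.2
#'
#' Emits biallelic sites with GT:DP genotype fields and contig header lines.
#'
#' @param pop result of [simulate_population()] (uses the pre-mask genotypes
#'   and simulated depths)
#' @param path output path
#' @return the path, invisibly
#' @export
write_population_vcf <- function(pop, path) {
  panel <- pop$panel
  geno <- pop$geno_raw
  dp <- pop$dp
  gt_char <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow(geno), ncol(geno))
  body <- matrix(paste0(gt_char, ":", dp), nrow(geno), ncol(geno))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=haploscent_simulate_population",
    sprintf("##contig=<ID=%s,length=%d>", names(panel$chrom_lens),
            panel$chrom_lens),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  ), con)
  lines <- paste(panel$chrom, panel$pos, ".", panel$ref, panel$alt, ".",
                 "PASS", ".", "GT:DP",
                 apply(body, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
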