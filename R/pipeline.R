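# End-to-end demo pipeline: simulate -> pair alleles -> divergence -> ASE ->
# SV attribution -> population scans -> association, with truth-recovery
# scores and a deterministic JSON + markdown report.

.log <- function(...) message("[haploscent] ", sprintf(...))

#' Write the simulated diploid inputs to disk
#'
#' @param sim result of [simulate_diploid()]
#' @param outdir output directory (created if absent)
#' @return named vector of written paths, invisibly
#' @export
write_diploid <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(hap1_fa = file.path(outdir, "hap1.fa"),
             hap2_fa = file.path(outdir, "hap2.fa"),
             hap1_gff = file.path(outdir, "hap1.gff3"),
             hap2_gff = file.path(outdir, "hap2.gff3"),
             sv = file.path(outdir, "sv.tsv"),
             truth = file.path(outdir, "truth.json"))
  Biostrings::writeXStringSet(sim$hap1, paths["hap1_fa"], width = 60)
  Biostrings::writeXStringSet(sim$hap2, paths["hap2_fa"], width = 60)
  write_gene_models_gff3(sim$models1, paths["hap1_gff"])
  write_gene_models_gff3(sim$models2, paths["hap2_gff"])
  write_tsv(sim$svs, paths["sv"])
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates every input at the configured scale, runs allele pairing,
#' divergence, ASE classification, the consistent-vs-inconsistent selection
#' contrast, SV attribution, the population scans (pi, Fst + sweeps, D, fd)
#' and the haplotype-phenotype association, writes all intermediate tables
#' under `outdir`, and collects a deterministic report (`report.json`,
#' `report.md`) including truth-recovery scores.
#'
#' @param outdir output directory
#' @param seed master seed (overrides `cfg$seed`)
#' @param cfg a [sim_config()]; defaults to the stated demo scale
#' @return the report, invisibly
#' @export
run_pipeline <- function(outdir, seed = 17, cfg = NULL) {
  if (is.null(cfg)) cfg <- sim_config(seed = seed) else cfg$seed <- seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = cfg[setdiff(names(cfg), "sv_count_chrom")])

  ## stage 1: simulate ----------------------------------------------------
  .log("stage simulate: diploid genome pair (%d x %d bp, %d genes)",
       cfg$n_chromosomes, cfg$chrom_length, cfg$n_genes)
  sim <- simulate_diploid(cfg)
  write_diploid(sim, outdir)
  expr <- simulate_expression(sim$truth$ase_classes, cfg)
  write_tsv(expr$counts, file.path(outdir, "counts.tsv"))
  pop <- simulate_population(cfg, genome = sim$hap1, models = sim$models1)
  write_population_vcf(pop, file.path(outdir, "population.vcf"))
  write_tsv(pop$group_table, file.path(outdir, "groups.tsv"))
  pheno <- simulate_phenotype(pop$truth$causal$copies, cfg,
                              groups = pop$panel$groups)
  write_tsv(pheno, file.path(outdir, "phenotype.tsv"))

  ## stage 2: allele pairing ----------------------------------------------
  .log("stage pair-alleles")
  cds1 <- cds_seqs(sim$hap1, sim$models1)
  cds2 <- cds_seqs(sim$hap2, sim$models2)
  anchors <- find_anchors(sim$models1, sim$models2, cds1, cds2)
  chained <- chain_syntenic_blocks(anchors)
  pairs <- call_alleles(chained)
  write_tsv(pairs, file.path(outdir, "pairs.tsv"))
  write_tsv(chained$blocks, file.path(outdir, "blocks.tsv"))
  correct <- sum(pairs$gene_a == pairs$gene_b)
  report$pairing <- list(n_anchors = nrow(anchors), n_blocks = nrow(chained$blocks),
                         n_pairs = nrow(pairs),
                         recovery = correct / cfg$n_genes)
  .log("  %d pairs, truth recovery %.3f", nrow(pairs), correct / cfg$n_genes)

  ## stage 3: divergence --------------------------------------------------
  .log("stage divergence (%d pairs)", nrow(pairs))
  div <- divergence_table(pairs, sim$hap1, sim$hap2, sim$models1, sim$models2,
                          cds1, cds2)
  write_tsv(div, file.path(outdir, "divergence.tsv"))
  report$divergence <- list(
    n_pairs = nrow(div),
    median_cds_identity = stats::median(div$cds_identity, na.rm = TRUE),
    frac_with_nonsyn = mean(div$n_nonsyn_subs > 0, na.rm = TRUE),
    frac_purifying = mean(div$kaks < 1, na.rm = TRUE),
    mean_kaks = mean(div$kaks[is.finite(div$kaks)]))

  ## stage 4: ASE classification ------------------------------------------
  .log("stage ase")
  tests <- stage_tests_all(expr$counts)
  calls <- classify_ase(tests, n_stages = cfg$n_stages)
  summ <- summarize_classes(calls)
  write_tsv(tests, file.path(outdir, "ase_stage_tests.tsv"))
  write_tsv(calls, file.path(outdir, "ase_calls.tsv"))
  jsonlite::write_json(summ, file.path(outdir, "ase_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  truth_cls <- sim$truth$ase_classes$class[match(calls$pair_id,
                                                 sim$truth$ase_classes$gene_id)]
  report$ase <- list(summary = summ,
                     recovery = mean(calls$class == truth_cls))
  .log("  class recovery %.3f", report$ase$recovery)

  ## stage 5: selection contrast ------------------------------------------
  cls_of <- calls$class[match(div$pair_id, calls$pair_id)]
  report$selection_contrast <- lapply(
    c(kaks = "kaks", flank_up = "flank_up_rate", flank_down = "flank_down_rate"),
    function(metric) compare_selection(div[[metric]][cls_of == "consistent"],
                                       div[[metric]][cls_of == "inconsistent"]))

  ## stage 6: SV attribution ----------------------------------------------
  .log("stage sv-annotate")
  att <- attribute_svs(sim$svs, sim$models1,
                       chrom_lens = setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                                             paste0("chr", seq_len(cfg$n_chromosomes))))
  write_tsv(att$attribution, file.path(outdir, "sv_attribution.tsv"))
  jsonlite::write_json(att$distribution, file.path(outdir, "sv_distribution.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sv_truth <- sim$truth$sv_truth
  sv_match <- mean(att$attribution$region ==
                     sv_truth$region[match(att$attribution$id, sv_truth$id)])
  report$sv <- list(distribution = att$distribution, truth_match = sv_match)

  ## stage 7: population scans --------------------------------------------
  .log("stage popgen")
  vcf_path <- file.path(outdir, "population.vcf")
  if (!file.exists(vcf_path)) stop("popgen stage: missing VCF ", vcf_path)
  panel <- load_vcf(vcf_path, pop$group_table, min_dp = cfg$min_dp)
  pi_all <- pi_windows(panel)
  write_tsv(pi_all, file.path(outdir, "pi_windows.tsv"))
  pi_groups <- vapply(c("P1", "P2", "P3"), function(g) pi_global(panel, g), 0)
  fst <- fst_wc_windows(panel, "P2", "P3")
  write_tsv(fst, file.path(outdir, "fst_windows.tsv"))
  sweeps <- select_sweeps(fst, top_frac = 0.05, genes = sim$models1)
  write_tsv(sweeps$regions, file.path(outdir, "sweep_regions.tsv"))
  dres <- d_statistic(panel, "P1", "P2", "P3", "OUT")
  fd <- fd_windows(panel, "P1", "P2", "P3", "OUT")
  write_tsv(fd, file.path(outdir, "fd_windows.tsv"))
  jsonlite::write_json(dres, file.path(outdir, "d_statistic.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  div_iv <- cfg$divergent_interval
  sweep_hit <- any(sweeps$regions$chrom == div_iv$chrom &
                     sweeps$regions$end > div_iv$start - 1 &
                     sweeps$regions$start0 < div_iv$end)
  fd_ok <- !is.na(fd$value)
  top_fd <- fd[fd_ok, ][which.max(fd$value[fd_ok]), ]
  iv <- cfg$introgressed_interval
  fd_hit <- nrow(top_fd) == 1 && top_fd$chrom == iv$chrom &&
    top_fd$end > iv$start - 1 && top_fd$start0 < iv$end
  report$popgen <- list(
    pi_genomewide = pi_global(panel),
    pi_by_group = as.list(pi_groups),
    fst_threshold = sweeps$threshold, n_sweep_regions = nrow(sweeps$regions),
    n_sweep_genes = length(sweeps$genes), sweep_overlaps_truth = sweep_hit,
    D = dres$D, Z = dres$Z, n_blocks = dres$n_blocks,
    top_fd_window_in_truth = fd_hit)
  .log("  D=%.4f Z=%.2f; sweep truth overlap: %s; top-fd in truth: %s",
       dres$D, dres$Z, sweep_hit, fd_hit)

  ## stage 8: association --------------------------------------------------
  .log("stage assoc")
  pheno_vec <- setNames(pheno$pe_ug_per_g, pheno$sample)
  assoc <- assoc_scan(panel, sim$models1, sim$hap1, pheno_vec)
  write_tsv(assoc, file.path(outdir, "association.tsv"))
  causal <- pop$truth$causal
  hit <- FALSE
  if (nrow(assoc) > 0 && causal$gene_id %in% assoc$gene_id) {
    row <- assoc[assoc$gene_id == causal$gene_id, ]
    # compare the favorable class at the causal SNP positions only (the
    # gene may carry additional retained non-synonymous SNPs)
    kept <- as.integer(strsplit(row$positions, ",")[[1]])
    at <- match(causal$positions, kept)
    fav_at_causal <- if (row$favorable == "none" || anyNA(at)) NA_character_
      else paste(strsplit(row$favorable, "")[[1]][at], collapse = "")
    hit <- is.finite(row$p) && row$p < 0.05 &&
      identical(fav_at_causal, causal$favorable)
  }
  report$assoc <- list(n_genes_tested = nrow(assoc),
                       causal_gene = causal$gene_id,
                       causal_detected = hit)
  .log("  causal gene %s detected: %s", causal$gene_id, hit)

  ## report ----------------------------------------------------------------
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  md <- c(
    "# haploscent demo report", "",
    sprintf("- seed: %d", cfg$seed),
    sprintf("- allele pairs: %d (truth recovery %.3f)",
            report$pairing$n_pairs, report$pairing$recovery),
    sprintf("- median CDS identity: %.4f; pairs with nonsyn subs: %.2f%%; Ka/Ks < 1: %.2f%%",
            report$divergence$median_cds_identity,
            100 * report$divergence$frac_with_nonsyn,
            100 * report$divergence$frac_purifying),
    sprintf("- ASE classes: %s (recovery %.3f)",
            paste(sprintf("%s %d (%.2f%%)", summ$class, summ$count, summ$pct),
                  collapse = ", "), report$ase$recovery),
    sprintf("- SV truth match: %.3f", report$sv$truth_match),
    sprintf("- genome-wide pi: %.6f", report$popgen$pi_genomewide),
    sprintf("- Fst top-5%% threshold: %.4f; sweep regions: %d; overlaps planted locus: %s",
            report$popgen$fst_threshold, report$popgen$n_sweep_regions,
            report$popgen$sweep_overlaps_truth),
    sprintf("- D = %.4f (Z = %.2f, %d blocks); top-fd window in planted interval: %s",
            report$popgen$D, report$popgen$Z, report$popgen$n_blocks,
            report$popgen$top_fd_window_in_truth),
    sprintf("- causal gene %s detected: %s", report$assoc$causal_gene,
            report$assoc$causal_detected))
  writeLines(md, file.path(outdir, "report.md"))
  invisible(report)
}

#' Divergence statistics for a set of allele pairs
#'
#' Codon-aware alignment, CDS identity, NG86 Ka/Ks and flanking-region
#' divergence for every pair, one row each.
#'
#' @param pairs pair table from [call_alleles()]
#' @param hap1,hap2 genome DNAStringSets
#' @param models1,models2 gene-model tables
#' @param cds1,cds2 optional precomputed CDS sets (else extracted here)
#' @param up_bp,down_bp flank sizes in bp
#' @return data.frame, one row per pair, with alignment, NG86 and flank
#'   fields plus an exclusion flag/reason
#' @export
divergence_table <- function(pairs, hap1, hap2, models1, models2,
                             cds1 = NULL, cds2 = NULL,
                             up_bp = 2000, down_bp = 1000) {
  if (is.null(cds1)) cds1 <- cds_seqs(hap1, models1)
  if (is.null(cds2)) cds2 <- cds_seqs(hap2, models2)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    aln <- align_codons(cds1[[ga]], cds2[[gb]])
    k <- ng86(aln)
    fl <- flank_divergence(hap1, hap2, models1[ga, , drop = FALSE],
                           models2[gb, , drop = FALSE], up_bp, down_bp)
    rows[[i]] <- data.frame(
      pair_id = ga, gene_a = ga, gene_b = gb,
      cds_identity = cds_identity(aln),
      n_codons_used = aln$n_codons_used,
      n_codons_dropped = aln$n_codons_dropped,
      excluded = aln$excluded, reason = aln$reason,
      n_nonsyn_subs = k$Nd, n_syn_subs = k$Sd,
      N_sites = k$N, S_sites = k$S, pN = k$pN, pS = k$pS,
      Ka = k$Ka, Ks = k$Ks, kaks = k$kaks,
      saturated = isTRUE(k$saturated),
      flank_up_rate = fl$flank_up_rate, flank_down_rate = fl$flank_down_rate,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
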