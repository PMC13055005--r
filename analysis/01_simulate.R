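#!/usr/bin/env Rscript
# Generate every synthetic input for the analysis: a phased diploid genome
# pair with gene models and SVs, stage x replicate allelic expression counts,
# a four-population resequencing panel with a planted introgressed segment
# and a locally divergent locus, and a 2-phenylethanol-like phenotype driven
# by a causal non-synonymous haplotype.

suppressMessages(library(haploscent))
seed <- as.integer(Sys.getenv("HAPLOSCENT_SEED", "17"))
data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)

sim <- simulate_diploid(cfg)
write_diploid(sim, data_dir)

expr <- simulate_expression(sim$truth$ase_classes, cfg)
write.table(expr$counts, file.path(data_dir, "counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

pop <- simulate_population(cfg, genome = sim$hap1, models = sim$models1)
write_population_vcf(pop, file.path(data_dir, "population.vcf"))
write.table(pop$group_table, file.path(data_dir, "groups.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(pop$truth, file.path(data_dir, "pop_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

pheno <- simulate_phenotype(pop$truth$causal$copies, cfg,
                            groups = pop$panel$groups)
write.table(pheno, file.path(data_dir, "phenotype.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf(
  "simulated: %d chromosomes x %d bp, %d genes, %d SVs, %d population sites, %d samples\n",
  cfg$n_chromosomes, cfg$chrom_length, cfg$n_genes, nrow(sim$svs),
  nrow(pop$panel$geno), ncol(pop$panel$geno)))
cat(sprintf("causal gene: %s (favorable haplotype %s)\n",
            pop$truth$causal$gene_id, pop$truth$causal$favorable))
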