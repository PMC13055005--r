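#!/usr/bin/env Rscript
# Population scans on the resequencing panel: windowed nucleotide diversity,
# Weir-Cockerham Fst (10 kb / 5 kb) with top-5% sweep calling, Patterson's D
# with block-jackknife Z, and Martin's fd (100 kb / 50 kb).

suppressMessages(library(haploscent))

groups <- read.delim("results/data/groups.tsv")
panel <- load_vcf("results/data/population.vcf", groups, min_dp = 5)
models1 <- read_gene_models("results/data/hap1.gff3")

pi_w <- pi_windows(panel, window = 10000, step = 5000)
write.table(pi_w, "results/pi_windows.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("genome-wide pi: %.3e (per group: %s)\n", pi_global(panel),
            paste(sprintf("%s %.3e", c("P1", "P2", "P3"),
                          vapply(c("P1", "P2", "P3"),
                                 function(g) pi_global(panel, g), 0)),
                  collapse = ", ")))

fst <- fst_wc_windows(panel, "P2", "P3", window = 10000, step = 5000)
write.table(fst, "results/fst_windows.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sweeps <- select_sweeps(fst, top_frac = 0.05, genes = models1)
write.table(sweeps$regions, "results/sweep_regions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(sweeps$genes, "results/sweep_genes.txt")
cat(sprintf("Fst top-5%% threshold %.4f -> %d sweep regions spanning %d genes\n",
            sweeps$threshold, nrow(sweeps$regions), length(sweeps$genes)))

d <- d_statistic(panel, "P1", "P2", "P3", "OUT", block_bp = 1e6)
jsonlite::write_json(d, "results/d_statistic.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat(sprintf("Patterson's D = %.4f, Z = %.2f over %d jackknife blocks\n",
            d$D, d$Z, d$n_blocks))

fd <- fd_windows(panel, "P1", "P2", "P3", "OUT", window = 1e5, step = 5e4)
write.table(fd, "results/fd_windows.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
ok <- !is.na(fd$value)
if (any(ok)) {
  top <- fd[ok, ][which.max(fd$value[ok]), ]
  cat(sprintf("top fd window: %s:%d-%d (fd = %.3f)\n",
              top$chrom, top$start0, top$end, top$value))
}
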