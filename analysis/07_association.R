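#!/usr/bin/env Rscript
# Candidate-gene haplotype -> 2-PE association: non-synonymous SNPs against
# the gene models, het <= 0.2 / MAF >= 0.05 filters, homozygote haplotype
# classes, Welch t-test, favorable-haplotype call.

suppressMessages(library(haploscent))

groups <- read.delim("results/data/groups.tsv")
panel <- load_vcf("results/data/population.vcf", groups, min_dp = 5)
models1 <- read_gene_models("results/data/hap1.gff3")
hap1 <- Biostrings::readDNAStringSet("results/data/hap1.fa")
names(hap1) <- sub(" .*", "", names(hap1))
pheno_tab <- read.delim("results/data/phenotype.tsv")
pheno <- setNames(pheno_tab$pe_ug_per_g, pheno_tab$sample)

assoc <- assoc_scan(panel, models1, hap1, pheno,
                    het_max = 0.2, maf_min = 0.05, alpha = 0.05)
write.table(assoc, "results/association.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

hits <- assoc[!is.na(assoc$p) & assoc$p < 0.05, ]
hits <- hits[order(hits$p), ]
cat(sprintf("%d genes tested; %d with p < 0.05\n", nrow(assoc), nrow(hits)))
if (nrow(hits)) {
  top <- hits[1, ]
  cat(sprintf(
    "top gene %s: haplotype %s mean %.4f ug/g vs %s mean %.4f ug/g (p = %.3g) -> favorable '%s'\n",
    top$gene_id, top$class1, top$mean1, top$class2, top$mean2, top$p,
    top$favorable))
}

truth <- jsonlite::read_json("results/data/pop_truth.json")
cat(sprintf("planted causal gene %s among hits: %s\n",
            truth$causal$gene_id, truth$causal$gene_id %in% hits$gene_id))
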