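#!/usr/bin/env Rscript
# Allele-pair divergence: CDS identity, non-synonymous substitution counts,
# NG86 Ka/Ks with Jukes-Cantor correction, and 2 kb upstream / 1 kb
# downstream flank substitution rates.

suppressMessages(library(haploscent))
data_dir <- "results/data"

hap1 <- Biostrings::readDNAStringSet(file.path(data_dir, "hap1.fa"))
hap2 <- Biostrings::readDNAStringSet(file.path(data_dir, "hap2.fa"))
names(hap1) <- sub(" .*", "", names(hap1))
names(hap2) <- sub(" .*", "", names(hap2))
models1 <- read_gene_models(file.path(data_dir, "hap1.gff3"))
models2 <- read_gene_models(file.path(data_dir, "hap2.gff3"))
pairs <- read.delim("results/pairs.tsv")

div <- divergence_table(pairs, hap1, hap2, models1, models2)
write.table(div, "results/divergence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("median CDS identity: %.4f\n",
            median(div$cds_identity, na.rm = TRUE)))
cat(sprintf("%.2f%% of pairs carry at least one non-synonymous substitution\n",
            100 * mean(div$n_nonsyn_subs > 0, na.rm = TRUE)))
cat(sprintf("%.2f%% of pairs with defined Ka/Ks are under purifying selection (Ka/Ks < 1)\n",
            100 * mean(div$kaks[is.finite(div$kaks)] < 1)))
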