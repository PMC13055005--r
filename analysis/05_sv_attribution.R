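#!/usr/bin/env Rscript
# Attribute structural variants to gene-region classes (promoter 2 kb /
# exon / intron / downstream 1 kb / intergenic) by largest overlap.

suppressMessages(library(haploscent))

svs <- read.delim("results/data/sv.tsv")
models1 <- read_gene_models("results/data/hap1.gff3")
hap1 <- Biostrings::readDNAStringSet("results/data/hap1.fa")
chrom_lens <- setNames(Biostrings::width(hap1), sub(" .*", "", names(hap1)))

att <- attribute_svs(svs, models1, chrom_lens = chrom_lens)
write.table(att$attribution, "results/sv_attribution.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(att$distribution, "results/sv_distribution.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("SV distribution over gene regions:\n")
print(att$distribution, row.names = FALSE)
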