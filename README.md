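# haploscent

Haplotype-resolved analysis of allelic imbalance, allele divergence, and
introgression for phased diploid plant genomes, motivated by the genetics of
floral scent (2-phenylethanol, 2-PE) in rugosa rose. The package re-implements,
as tested reusable functions plus a numbered analysis workflow, the chain of
analyses that links a phased assembly to a scent phenotype:

1. **Allele pairing** — reciprocal-best translated-CDS anchors between the two
   haplotype assemblies, chained into collinear (MCScan-style) syntenic blocks
   by dynamic programming; paired genes in the same block are called alleles.
2. **Allele divergence** — codon-aware alignment of allele CDS pairs; CDS
   identity; non-synonymous substitution counts; Nei–Gojobori (1986) Ka/Ks
   with Jukes–Cantor correction
   (d = −¾ ln(1 − 4p/3)); substitution rates in the 2 kb upstream and 1 kb
   downstream flanks; Welch t contrasts of these metrics between ASE classes.
3. **Allelic imbalance (ASE)** — per flower stage, an exact binomial test of
   the hap1 pooled count against the library-size expectation
   p₀ = T₁/(T₁+T₂), gated by fold change ≥ 2 and BH-FDR < 0.05; allele pairs
   are classified **consistent** (same haplotype significantly higher in all
   four stages), **inconsistent** (significant somewhere, but not
   consistently), or **noASE** (never significant).
4. **SV attribution** — each structural variant is assigned the gene-region
   class (promoter = 2 kb up to the start codon, exon, intron,
   downstream = 1 kb past the stop codon, intergenic) with the largest
   overlap.
5. **Population scans** — windowed nucleotide diversity π; Weir–Cockerham
   (1984) weighted Fst (Σa/Σ(a+b+c)) in 10 kb/5 kb windows with top-5% sweep
   calling; Patterson's D = (ΣABBA−ΣBABA)/(ΣABBA+ΣBABA) on (((P1,P2),P3),O)
   with block-jackknife Z; Martin's fd in 100 kb/50 kb windows.
6. **Haplotype–phenotype association** — non-synonymous SNPs per candidate
   gene (het ≤ 0.2, MAF ≥ 0.05), homozygote-only haplotype classes, Welch
   t-test of the phenotype between the two major classes, favorable-haplotype
   call.

Because the deposited rose data are not redistributable at desk scale, the
package ships a first-class **synthetic-data generator** (`sim_config()`,
`simulate_diploid()`, `simulate_expression()`, `simulate_population()`,
`simulate_phenotype()`) that emulates the assumed data structure — a diploid
pair at ~1.5% heterozygosity, planted ASE classes, Balding–Nichols
four-population drift with a planted introgressed segment, and a phenotype
driven by a causal non-synonymous haplotype — with full ground truth for
parameter-recovery testing.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on synthetic
data and write their tables under `results/` (set `HAPLOSCENT_SEED` to change
the seed; default 17):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_pair_alleles.R
Rscript analysis/03_divergence.R
Rscript analysis/04_ase.R
Rscript analysis/05_sv_attribution.R
Rscript analysis/06_popgen.R
Rscript analysis/07_association.R
```

Output printed at seed 17 (abridged):

```
simulated: 2 chromosomes x 750000 bp, 300 genes, 40 SVs, 14877 population sites, 100 samples
296 anchors -> 2 syntenic blocks -> 296 allele pairs (98.7% of genes)
median CDS identity: 0.9848
98.99% of pairs carry at least one non-synonymous substitution
49.39% of pairs with defined Ka/Ks are under purifying selection (Ka/Ks < 1)
ASE classes: consistent 28 (9.33%), inconsistent 94 (31.33%), noASE 178 (59.33%)
SV distribution: promoter 47.5%, intron 25.0%, downstream 27.5%, exon 0.0%
genome-wide pi: 3.790e-03
Fst top-5% threshold 0.3098 -> 2 sweep regions spanning 19 genes
Patterson's D = 0.0012, Z = 0.17 over 20 jackknife blocks
top fd window: chr2:200000-300000 (fd = 0.155)
top gene gene0075: haplotype TT mean 7.8980 ug/g vs CC mean 20.1500 ug/g
  (p = 2.37e-36) -> favorable 'CC'
```

Reading the numbers: the allele pairer recovers 296 of 300 planted pairs (the
four missing genes acquired a premature stop from two SNPs hitting the same
codon and are skipped as untranslatable). CDS identity centers at the planted
~1.5% heterozygosity. Ka/Ks ≈ 1 (about half the pairs below 1) because the
simulator plants *neutral* coding changes — the strong purifying excess seen
in real data is deliberately absent from the null world. The ASE classes
recover the planted 10/30/60 mix, the SV class mix matches its planted
50/30/20 promoter/intron/downstream distribution, the top-5% Fst windows land
on the planted locally divergent locus, the strongest fd window sits inside
the planted introgressed interval, and the association scan singles out the
planted causal gene with the correct favorable haplotype.

`run_pipeline(outdir, seed)` runs the same stages in-process and writes a
deterministic `report.json`/`report.md` with truth-recovery scores.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package's full pipeline end to end on freshly simulated
inputs (every stage above, at the default scale) and writes the results JSON
to `--out`.
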