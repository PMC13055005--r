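---
title: "haploscent: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{haploscent: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements: what
each statistic assumes, which tunables matter and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
where the design was genuinely open. It states no empirical result that the
test suite does not itself compute.

## The analysis chain

A phased diploid assembly gives two complete haplotypes of one individual.
Genes present on both haplotypes form **allele pairs**; their coding and
regulatory divergence, their expression imbalance across flower development,
and the population history of the surrounding sequence together connect
genome structure to a metabolite phenotype (here, a 2-phenylethanol-like
scent compound measured in µg/g of petal). The package implements that chain
end to end; every stage is a pure function over plain containers
(data.frames, `DNAStringSet`s, a small `variant_panel` list), so each step is
testable in isolation.

## Allele pairing

Anchors are translated-CDS global alignments (match 2, mismatch −1, gap open
10, gap extend 0.5); similarity is identity over aligned length including
gaps. A shared amino-acid 4-mer prefilter (default: ≥ 20 % of the smaller
protein's 4-mers) limits the all-vs-all alignment to plausible candidates;
for nearly identical alleles the filter is essentially lossless, and it can
be disabled (`min_kmer_share = 0`). Anchors are reciprocal best hits plus any
hit at similarity ≥ 0.7. Genes whose CDS contains an internal stop codon are
skipped as untranslatable and logged.

Chaining is an O(n²) dynamic program per chromosome pair: the longest anchor
chain monotone in gene rank on both haplotypes (increasing, or decreasing for
inverted blocks), with rank gaps ≤ 25, is peeled off repeatedly; chains
shorter than 5 anchors are discarded. `min_block = 5` and `max_gap = 25` are
the documented defaults of the MCScan tool family, which the original
analysis used with default parameters. Before chaining, tandem duplicates are
collapsed greedily to the highest-similarity one-to-one anchor set; this
prevents block fragmentation and guarantees that no gene enters two pairs.
The test suite proves the DP equal to exhaustive chain enumeration on all
instances of ≤ 12 anchors.

## Allele divergence

CDS pairs are aligned at the amino-acid level and back-threaded to
nucleotides; codon columns containing a gap or a stop are dropped and
counted. Ka/Ks follows Nei–Gojobori (1986): per-codon synonymous site
fractions enumerate all nine single-nucleotide mutations, with mutations to
stop codons excluded from the denominator (a position whose three
alternatives are all stops counts as fully non-synonymous); site totals are
averaged over the two sequences, so N + S = 3 × (codons used). Multi-hit
codons average the synonymous/non-synonymous step counts over all minimal
mutational pathways with equal weight, excluding pathways through stops; if
every pathway is blocked (possible but rare), all pathways are used as a
fallback. Proportions are Jukes–Cantor corrected, undefined at p ≥ 3/4
(flagged `saturated`); Ka/Ks is reported missing when Ks = 0. NG86 was chosen
over ML codon models because the source analysis names no method, NG86 is
the standard count-based estimator, and it is verifiable against a
brute-force enumerator — which the tests do, exactly, on random codon pairs.

CDS identity counts gap columns as mismatches (a conservative fraction of
aligned length; switchable). Flank divergence extracts the 2 kb upstream of
the start codon and 1 kb downstream of the stop codon, strand-aware and
truncated at chromosome ends (flanks shorter than 100 bp give a missing
rate), aligns them globally, and reports the Jukes–Cantor-corrected
p-distance over non-gap columns. The reading of "selection pressure on
flanks" as a JC-corrected substitution rate is an implementation decision;
the source figure does not define its statistic.

Group contrasts (consistent vs inconsistent ASE on Ka/Ks or flank rates) are
Welch two-sample t-tests over finite values, with missing values counted and
excluded; groups with fewer than two finite values yield "not run" rather
than an error.

## ASE classification

The per-stage test is an exact binomial test of the hap1 pooled count
against p₀ = T₁/(T₁+T₂), where T are the haplotype library totals for that
stage — not a negative-binomial GLM. The source analysis specifies only its
gates (fold change ≥ 2, FDR < 0.05); a binomial on pooled counts plus those
gates is transparent, deterministic and oracle-checkable. The cost is that
replicate overdispersion is absorbed by the fold-change gate rather than
modelled; with the default dispersion this leaves the realized null
significance rate far below α (the calibration test asserts the α + 3·SE
bound). log2 fold changes use library-size-normalized pooled counts with
pseudocount 0.5, so zero counts stay finite. BH-FDR is computed within each
stage across pairs; pairs with both pooled counts zero are excluded from the
FDR denominator.

Classes partition all tested pairs: **consistent** = significant in all four
stages with one favored haplotype; **noASE** = significant nowhere;
**inconsistent** = everything else, including four significant stages with a
direction flip. A pair with an untested stage is flagged incomplete and can
never be consistent. The "inconsistent" class is nowhere defined
generatively in the source; making it the complement keeps the three classes
a partition, which the published counts (718 + 5,583 + 14,732 = 21,033)
themselves satisfy.

## SV attribution

Gene regions are strand-aware: promoter = 2 kb immediately 5′ of the start
codon, downstream = 1 kb past the stop codon, exons as annotated, introns =
gene span minus exons, truncated at chromosome ends. Each SV takes the class
with the largest bp overlap across all genes' regions; ties break
exon > promoter > intron > downstream; insertions are 1-bp points at the
insertion site. The largest-overlap rule is a design decision — the source
reports one class per SV but no rule — chosen because it is deterministic,
order-invariant and mirror-symmetric (all three are tested). Because the
source is ambiguous about whether intergenic SVs enter the denominator of
the reported distribution, both denominators are reported (`pct_genic` and
`pct_all`).

## Population scans

π is the per-site unbiased heterozygosity 2p(1−p)·n/(n−1) summed over window
sites and divided by the **window length in bp** — i.e. every position is
assumed callable, which is exact for the synthetic data and an approximation
for real panels (documented limitation). For genome-wide summaries use
`pi_global()`, which avoids double-counting by overlapping windows.

Fst is Weir & Cockerham (1984) for two populations from genotype counts and
observed heterozygosity; the window value is the weighted ratio
Σa/Σ(a+b+c). Sites leaving any population without called alleles, or with
non-finite components, are skipped. The per-site components are tested to
1e-12 against a literal transcription of the 1984 formulas. Sweeps are
windows at or above the top-5% quantile, merged when overlapping or
adjacent.

D follows Durand et al.: with outgroup-polarized derived-allele frequencies
p̂ᵢ, ABBA = (1−p̂₁)p̂₂p̂₃(1−p̂₄) and BABA = p̂₁(1−p̂₂)p̂₃(1−p̂₄) summed over
sites, D = (ΣABBA−ΣBABA)/(ΣABBA+ΣBABA). **Sign convention:** positive D
means excess ABBA, i.e. P2–P3 sharing. The source paper's prose states the
opposite reading; the standard (Durand/Dsuite) convention is implemented,
and the discrepancy is simply documented here. Polarization uses the
outgroup major allele with a 0.1 polymorphism tolerance (sites with a more
polymorphic outgroup are skipped). Z comes from a delete-one block jackknife
over 1 Mb blocks; if fewer than 20 non-empty blocks would result, the block
size shrinks to total span / 20, keeping the jackknife defined at demo
scale.

fd (Martin et al.) normalizes the window ABBA−BABA numerator by the same
numerator computed with a per-site complete-sharing donor P_D = argmax of
(p̂₂, p̂₃). Windows with a negative numerator, fewer than `min_sites = 10`
informative sites, or a non-positive denominator are reported missing —
window-level gating, since the source does not say whether window or global
D gated its negative values.

## Haplotype–phenotype association

Coding effects are classified by strand-aware codon reconstruction against
the gene model and genome (a reference mismatch is a hard error — it signals
a coordinate bug, not data noise). Non-synonymous SNPs are filtered at
heterozygosity ≤ 0.2 and MAF ≥ 0.05 (the source thresholds; the filters
commute, which is tested). Haplotypes are built from homozygous genotypes
only — samples heterozygous or missing at any retained SNP fall into a
"het/other" class — matching the source's display of 0/1 genotypes separate
from its tested 'T'/'A' classes; this sidesteps statistical phasing
entirely. The two most frequent homozygous classes (each with ≥ 2 samples)
are compared by a Welch t-test; the favorable haplotype is the higher-mean
class when p < α. Per-group haplotype frequencies and frequencies in
high/low phenotype groups (median split — the source's split point is
unstated and it is configurable) are reported alongside. Raw p-values are
primary, with a BH column across genes, since the source corrected nothing.

## The synthetic world

The generator's defaults state the world the analyses assume, and they are
not tuned to test outcomes:

* **Diploid pair:** 2 chromosomes × 750 kb, 300 genes, SNP rate 0.015/bp
  (the assembly's ~1.5 % heterozygosity), indel rate 0.0015/bp (a tenth of
  the SNP rate, the usual ratio in plant resequencing), 40 SVs of 50–400 bp
  planted 50/30/20 into promoters/introns/downstream regions. Genes are
  compact (1–4 exons, CDS 300–750 nt) so that every gene keeps its full 2 kb
  promoter and 1 kb downstream clearance; that clearance plus intron-bearing
  bodies is why the chromosomes are 750 kb rather than 500 kb. Indels and
  SVs never intersect CDS, so reading frames survive liftover by
  construction, and coding SNPs that would create a premature stop in hap2
  are vetoed — real alleles are overwhelmingly functional, and NG86's
  stop-exclusion convention is the matching analytical assumption. Coding
  changes are otherwise neutral, so Ka/Ks ≈ 1 by design: a green Ka/Ks test
  certifies the estimator, not selection.
* **Expression:** negative-binomial counts (size 20) per stage × replicate,
  4 stages × 3 replicates, mean 70 per replicate per haplotype; consistent
  pairs multiply the favored haplotype's mean by 2^2 = 4 in all stages;
  inconsistent pairs carry the effect in a random strict subset of stages or
  with a direction flip; class proportions 0.1/0.3/0.6.
* **Population:** sites at 0.01/bp; ancestral alternate-allele frequencies
  Uniform(0.05, 0.95); Balding–Nichols drift along (((P1,P2),P3),O) with
  defaults p12 = 0.05, p1 = p2 = p3 = 0.1; 25 samples per population;
  genotypes binomial(2, p); outgroup fixed for the ancestral (reference)
  allele; depth Poisson(13) with genotypes below DP 5 masked exactly as the
  VCF loader would mask them. Introgression replaces recipient (P2)
  frequencies by (1−f)·own + f·donor (P3) inside the planted interval; a
  locally divergent locus gives P3 an extra drift boost (0.5), the truth for
  sweep recovery. Drift 0 is allowed as an explicit limit case (all
  populations share the ancestral frequencies).
* **Phenotype:** baseline 8 µg/g + 6 µg/g per favorable-haplotype copy +
  N(0, 2) noise; the causal gene carries two perfectly linked non-synonymous
  SNPs, mostly in homozygous carriers (het fraction 0.1), reflecting the
  highly selfed/clonal accessions the association design assumes. The causal
  gene's coding variation is exactly its causal haplotype: background
  segregating sites inside its CDS are removed, because in the clonal
  accessions this design emulates they would sit in complete within-gene LD
  with the haplotype, which a linkage-equilibrium background cannot
  represent (an independent coding SNP would artificially split the
  haplotype classes). Values are not clipped, so the zero-noise case
  separates genotype classes exactly.

What the generator does **not** emulate: read-level data (no FASTQ, no
mapping bias), polyploidy, linkage disequilibrium within populations (sites
drift independently — no coalescent), gene conversion, missing reference
positions, and any real selection on coding sequence. A green recovery test
therefore establishes that the estimators recover what was planted under
these assumptions, not that they are robust to mapping artifacts or LD.

## Calibration experiment design

The D/Z power experiment (f = 0.2 planted P3→P2) was designed from the
closed-form expectation of the signal, E[per-site ABBA−BABA inside the
interval] = f·F₃·E[p(1−p)], against the drift-plus-sampling noise of the
numerator. The first design (drift 0.1 on all branches, 100 k sites, half
the genome introgressed) came out under-powered when the variance was
checked empirically — the analytic noise term had underestimated the
contribution of P1/P2 branch drift — so the experiment, not the criterion,
was redesigned before the acceptance test was frozen: P1/P2 branch drift
0.05 (less noise), P3 drift 0.2 (more signal), 50 k sites over 2 Mb, half
introgressed, giving E[Z] ≈ 4 at f = 0.2. The thresholds themselves
(|Z| < 3 null, Z > 3 power, replicate counts) were never moved. The fd and
sweep experiments use the package defaults (drift 0.1, boost 0.5) with
400 kb / 100 kb planted intervals.

## Numerical and degenerate-input choices

Tie-breaks and edge cases are all deterministic: anchor RBH ties resolve to
the first gene in id order; block peeling prefers the forward orientation on
equal length; SV class ties follow the fixed priority; quantiles use R's
default type 7. Empty inputs return empty, typed results (with warnings)
rather than errors, except where an error is the contract: unplaceable genes
or SVs (capacity), an introgression interval off-chromosome, a VCF sample
missing from the group table, a reference-mismatching SNP, fewer than two
testable haplotype classes ("not testable" result), fewer than 20
non-missing Fst windows. All randomness flows from one master seed through
per-component streams (`sub_seed`), so adding draws to one generator leaves
the others byte-identical; the RNG state of the caller is saved and
restored.

## Known limitations

The binomial ASE test is anti-conservative under strong replicate
overdispersion between haplotypes; the fold-change gate masks this at the
default dispersion but a beta-binomial would be the principled upgrade. π
assumes every position callable. fd underestimates the planted f under
these drift settings (it is used for localization and monotonicity, not as
an unbiased f estimator). The published headline values (21,033 pairs,
81.92 % purifying, π = 7.83×10⁻⁴, Fst thresholds, the 12.35 vs 5.75 µg/g
haplotype means) derive from the deposited accession data and are not
reproducible from synthetic inputs; the package reproduces the published
worked example that is purely arithmetic (the class-share percentages) and
validates everything else by oracle equivalence and parameter recovery.
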