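#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator with defaults that
#' state the emulated world: a phased diploid pair at ~1.5 percent
#' heterozygosity, allele pairs planted as consistent / inconsistent / noASE
#' across 4 stages x 3 replicates, a four-population panel on the topology
#' (((P1,P2),P3),O) with Balding-Nichols drift and a planted introgressed
#' segment, and a metabolite phenotype driven by a causal non-synonymous
#' haplotype.
#'
#' @param n_chromosomes number of chromosomes
#' @param chrom_length chromosome length in bp
#' @param n_genes total number of genes across chromosomes
#' @param snp_rate per-bp SNP rate between haplotypes (heterozygosity)
#' @param indel_rate per-bp small-indel rate (planted outside CDS)
#' @param sv_count number of structural variants between haplotypes
#' @param sv_min_len,sv_max_len SV length range in bp (min >= 50)
#' @param sv_region_mix named fractions over gene-region classes used to
#'   place SVs (promoter / intron / downstream)
#' @param ase_class_proportions fractions of consistent / inconsistent /
#'   noASE allele pairs (must sum to 1)
#' @param ase_log2_effect planted allelic fold change, log2 scale
#' @param nb_dispersion negative-binomial size parameter of replicate counts
#' @param mean_depth mean count per replicate per haplotype
#' @param n_stages,n_reps expression design (stages x replicates)
#' @param pop_snp_rate per-bp density of population segregating sites
#' @param pop_drift named per-branch Balding-Nichols drift: `p12` (internal
#'   branch to the P1/P2 ancestor), `p1`, `p2`, `p3`
#' @param introgression_fraction admixture fraction f from donor P3 into
#'   recipient P2 inside the introgressed interval
#' @param introgressed_interval list(chrom, start, end), 1-based inclusive
#' @param divergent_interval list(chrom, start, end): locus where P3 gets an
#'   extra drift boost (sweep-recovery truth)
#' @param divergent_drift Balding-Nichols coefficient of the local boost
#' @param n_samples_per_pop samples per population
#' @param mean_dp mean simulated per-genotype read depth
#' @param min_dp depth below which genotypes are masked (as at VCF load)
#' @param causal_n_snps number of causal non-synonymous SNPs in one gene
#' @param causal_hom_freq frequency of the favorable homozygous haplotype
#' @param causal_het_frac fraction of heterozygous carriers
#' @param pheno_effect phenotype shift per favorable-haplotype copy (ug/g)
#' @param pheno_noise_sd phenotype noise SD (ug/g)
#' @param pheno_baseline baseline phenotype (ug/g)
#' @param seed master seed; every component derives its own stream from it
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length = 750000,
                       n_genes = 300,
                       snp_rate = 0.015,
                       indel_rate = 0.0015,
                       sv_count = 40,
                       sv_min_len = 50,
                       sv_max_len = 400,
                       sv_region_mix = c(promoter = 0.5, intron = 0.3, downstream = 0.2),
                       ase_class_proportions = c(consistent = 0.1,
                                                 inconsistent = 0.3,
                                                 noASE = 0.6),
                       ase_log2_effect = 2,
                       nb_dispersion = 20,
                       mean_depth = 70,
                       n_stages = 4,
                       n_reps = 3,
                       pop_snp_rate = 0.01,
                       pop_drift = c(p12 = 0.05, p1 = 0.1, p2 = 0.1, p3 = 0.1),
                       introgression_fraction = 0.2,
                       introgressed_interval = list(chrom = "chr2",
                                                    start = 100001, end = 400000),
                       divergent_interval = list(chrom = "chr1",
                                                 start = 300001, end = 400000),
                       divergent_drift = 0.5,
                       n_samples_per_pop = 25,
                       mean_dp = 13,
                       min_dp = 5,
                       causal_n_snps = 2,
                       causal_hom_freq = 0.4,
                       causal_het_frac = 0.1,
                       pheno_effect = 6,
                       pheno_noise_sd = 2,
                       pheno_baseline = 8,
                       seed = 1) {
  cfg <- as.list(environment())
  frac01 <- function(x) all(x >= 0 & x <= 1)
  if (abs(sum(ase_class_proportions) - 1) > 1e-9)
    stop("ase_class_proportions must sum to 1")
  if (sv_min_len < 50) stop("sv_min_len must be >= 50")
  if (!frac01(c(snp_rate, indel_rate, pop_snp_rate, introgression_fraction,
                causal_hom_freq, causal_het_frac)))
    stop("rates must lie in [0, 1]")
  if (!all(pop_drift >= 0 & pop_drift < 1) || !(divergent_drift >= 0 && divergent_drift < 1))
    stop("drift parameters must lie in [0, 1)")
  if (nb_dispersion <= 0 || mean_depth <= 0 || pheno_noise_sd < 0)
    stop("nb_dispersion and mean_depth must be positive; pheno_noise_sd >= 0")
  if (n_stages < 2) stop("invalid design: n_stages must be >= 2")
  if (abs(sum(sv_region_mix) - 1) > 1e-9) stop("sv_region_mix must sum to 1")
  structure(cfg, class = "sim_config")
}
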