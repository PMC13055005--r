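# Simulation of the metabolite phenotype: baseline + effect per favorable
# haplotype copy + Gaussian noise.

#' Simulate a per-sample metabolite phenotype
#'
#' phenotype = `pheno_baseline` + `pheno_effect` x (copies of the favorable
#' haplotype) + Normal(0, `pheno_noise_sd`), in ug/g. The default baseline
#' keeps values positive with high probability; values are not clipped so
#' that the zero-noise case separates genotype classes exactly.
#'
#' @param copies named integer vector (sample -> favorable-haplotype copies,
#'   0/1/2), e.g. `truth$causal$copies` from [simulate_population()]
#' @param cfg a [sim_config()]
#' @param groups optional named sample -> group vector for the output table
#' @return data.frame with columns `sample`, `group`, `pe_ug_per_g`
#' @export
simulate_phenotype <- function(copies, cfg, groups = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(names(copies))) stop("configuration error: copies must be named by sample")
  with_seed(sub_seed(cfg$seed, "phenotype"), {
    y <- cfg$pheno_baseline + cfg$pheno_effect * as.numeric(copies) +
      rnorm(length(copies), 0, cfg$pheno_noise_sd)
    data.frame(sample = names(copies),
               group = if (is.null(groups)) NA_character_ else
                 unname(groups[names(copies)]),
               pe_ug_per_g = y, stringsAsFactors = FALSE)
  })
}
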