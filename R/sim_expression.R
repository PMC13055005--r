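# Simulation of allelic expression counts: negative-binomial replicate
# counts per stage and haplotype, with the planted ASE class deciding which
# stages (if any) carry the allelic fold change.

#' Simulate stage x replicate allelic counts for planted ASE classes
#'
#' Counts are negative-binomial with mean `mean_depth` (per replicate per
#' haplotype) and size `nb_dispersion`. "consistent" pairs have the favored
#' haplotype's mean multiplied by `2^ase_log2_effect` in every stage;
#' "inconsistent" pairs carry the effect in a strict subset of stages or in
#' all stages with at least one direction flip (chosen by the seeded RNG);
#' "noASE" pairs are symmetric.
#'
#' @param ase_classes data.frame with columns `gene_id`, `class`, `favored`
#'   (from `simulate_diploid()`'s truth, or built directly)
#' @param cfg a [sim_config()]
#' @return list with `counts` (long table: `pair_id`, `haplotype`, `stage`,
#'   `replicate`, `count`) and `stage_truth` (per pair and stage, the planted
#'   favored haplotype or "none")
#' @export
simulate_expression <- function(ase_classes, cfg) {
  stopifnot(inherits(cfg, "sim_config"),
            all(c("gene_id", "class", "favored") %in% names(ase_classes)),
            all(ase_classes$class %in% c("consistent", "inconsistent", "noASE")))
  if (cfg$n_stages < 2) stop("invalid design: n_stages must be >= 2")
  with_seed(sub_seed(cfg$seed, "expression"), {
    n_stages <- cfg$n_stages; n_reps <- cfg$n_reps
    mult <- 2^cfg$ase_log2_effect
    rows <- vector("list", nrow(ase_classes))
    truth_rows <- vector("list", nrow(ase_classes))
    for (i in seq_len(nrow(ase_classes))) {
      cl <- ase_classes$class[i]
      fav_stage <- rep("none", n_stages)
      if (cl == "consistent") {
        fav_stage <- rep(ase_classes$favored[i], n_stages)
      } else if (cl == "inconsistent") {
        k <- sample(n_stages, 1)
        affected <- sort(sample(n_stages, k))
        dirs <- sample(c("hap1", "hap2"), k, replace = TRUE)
        if (k == n_stages) {
          while (length(unique(dirs)) == 1L)
            dirs <- sample(c("hap1", "hap2"), k, replace = TRUE)
        }
        fav_stage[affected] <- dirs
      }
      mu1 <- ifelse(fav_stage == "hap1", cfg$mean_depth * mult, cfg$mean_depth)
      mu2 <- ifelse(fav_stage == "hap2", cfg$mean_depth * mult, cfg$mean_depth)
      c1 <- rnbinom(n_stages * n_reps, mu = rep(mu1, each = n_reps),
                    size = cfg$nb_dispersion)
      c2 <- rnbinom(n_stages * n_reps, mu = rep(mu2, each = n_reps),
                    size = cfg$nb_dispersion)
      rows[[i]] <- data.frame(
        pair_id = ase_classes$gene_id[i],
        haplotype = rep(c("hap1", "hap2"), each = n_stages * n_reps),
        stage = rep(rep(seq_len(n_stages), each = n_reps), 2),
        replicate = rep(seq_len(n_reps), 2 * n_stages),
        count = c(c1, c2), stringsAsFactors = FALSE)
      truth_rows[[i]] <- data.frame(
        pair_id = ase_classes$gene_id[i], stage = seq_len(n_stages),
        favored = fav_stage, stringsAsFactors = FALSE)
    }
    list(counts = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         stage_truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))))
  })
}
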