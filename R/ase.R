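# Allele-specific expression: per-stage exact binomial tests on pooled
# allelic counts with fold-change and FDR gates, and the
# consistent / inconsistent / noASE trichotomy over four flower stages.

#' Reads per kilobase per million mapped reads
#'
#' RPKM = 1e6 * C / (N * L / 1e3) = 1e9 * C / (N * L), with C the reads
#' uniquely aligned to the gene, N the library total of uniquely aligned
#' reads, and L the gene length in bp.
#'
#' @param count reads aligned to the gene (C)
#' @param library_total total aligned reads in the library (N), > 0
#' @param length_bp gene length in bp (L), > 0
#' @return RPKM value(s)
#' @export
rpkm <- function(count, library_total, length_bp) {
  if (any(library_total <= 0) || any(length_bp <= 0))
    stop("library_total and length_bp must be positive")
  1e9 * count / (library_total * length_bp)
}

#' Pool an allelic count table by pair, haplotype and stage
#'
#' @param counts long-format data.frame with columns `pair_id`, `haplotype`
#'   ("hap1"/"hap2"), `stage`, `replicate`, `count`
#' @return data.frame with one row per pair x stage and columns `count1`,
#'   `count2` (pooled over replicates), plus per-stage haplotype library
#'   totals `total1`, `total2`
#' @export
pool_stage_counts <- function(counts) {
  stopifnot(all(c("pair_id", "haplotype", "stage", "replicate", "count") %in% names(counts)),
            all(counts$haplotype %in% c("hap1", "hap2")), all(counts$count >= 0))
  agg <- stats::aggregate(count ~ pair_id + stage + haplotype, counts, sum)
  w <- stats::reshape(agg, idvar = c("pair_id", "stage"), timevar = "haplotype",
                      direction = "wide")
  names(w)[names(w) == "count.hap1"] <- "count1"
  names(w)[names(w) == "count.hap2"] <- "count2"
  w$count1[is.na(w$count1)] <- 0L; w$count2[is.na(w$count2)] <- 0L
  tot <- stats::aggregate(cbind(count1, count2) ~ stage, w, sum)
  names(tot) <- c("stage", "total1", "total2")
  out <- merge(w, tot, by = "stage", sort = FALSE)
  out[order(out$stage, out$pair_id), c("pair_id", "stage", "count1", "count2", "total1", "total2")]
}

#' Per-stage allelic imbalance test
#'
#' Exact binomial test of the hap1 pooled count against the library-size
#' expectation p0 = T1 / (T1 + T2), two-sided; Benjamini-Hochberg FDR across
#' pairs within the stage. log2 fold change uses library-size-normalized
#' pooled counts with pseudocount 0.5. A pair is significant when
#' fdr < alpha AND |log2FC| >= log2(min_fc); `favored` is the haplotype with
#' the larger normalized count among significant pairs. Pairs with both
#' pooled counts zero are "untested" and excluded from the FDR denominator.
#'
#' @param pooled output of [pool_stage_counts()] restricted to one stage, or
#'   the full table plus `stage` to select one
#' @param stage stage to test (must match `pooled$stage`)
#' @param alpha FDR threshold
#' @param min_fc minimum fold change (linear scale)
#' @return data.frame with columns `pair_id`, `stage`, `ratio`, `log2fc`,
#'   `p`, `fdr`, `significant`, `favored`, `tested`
#' @export
stage_test <- function(pooled, stage, alpha = 0.05, min_fc = 2) {
  d <- pooled[pooled$stage == stage, , drop = FALSE]
  if (nrow(d) == 0L) stop("no pairs for stage ", stage)
  t1 <- d$total1[1]; t2 <- d$total2[1]
  p0 <- t1 / (t1 + t2)
  n <- d$count1 + d$count2
  tested <- n > 0
  p <- rep(NA_real_, nrow(d))
  for (i in which(tested))
    p[i] <- stats::binom.test(d$count1[i], n[i], p = p0)$p.value
  fdr <- bh_adjust(p)
  norm1 <- (d$count1 + 0.5) / t1
  norm2 <- (d$count2 + 0.5) / t2
  log2fc <- log2(norm1 / norm2)
  sig <- tested & !is.na(fdr) & fdr < alpha & abs(log2fc) >= log2(min_fc)
  favored <- ifelse(!sig, "none", ifelse(log2fc > 0, "hap1", "hap2"))
  data.frame(pair_id = d$pair_id, stage = stage, ratio = norm1 / norm2,
             log2fc = log2fc, p = p, fdr = fdr, significant = sig,
             favored = favored, tested = tested, stringsAsFactors = FALSE)
}

#' Run the allelic-imbalance test for every stage
#'
#' @inheritParams stage_test
#' @param counts long-format allelic count table (see [pool_stage_counts()])
#' @return row-bound [stage_test()] results for all stages
#' @export
stage_tests_all <- function(counts, alpha = 0.05, min_fc = 2) {
  pooled <- pool_stage_counts(counts)
  do.call(rbind, lapply(sort(unique(pooled$stage)), function(s)
    stage_test(pooled, s, alpha = alpha, min_fc = min_fc)))
}

#' Classify allele pairs into consistent / inconsistent / noASE
#'
#' consistent: significant in all stages with the same favored haplotype;
#' noASE: significant in no stage; inconsistent: everything else
#' (significant in some but not all stages, or in all stages with a
#' direction flip). Pairs with an untested stage are flagged `incomplete`
#' and can never be "consistent".
#'
#' @param results stage-test table from [stage_tests_all()]
#' @param n_stages expected number of stages (default: all stages present)
#' @return data.frame with columns `pair_id`, `class`, `favored`,
#'   `n_significant`, `incomplete`
#' @export
classify_ase <- function(results, n_stages = length(unique(results$stage))) {
  if (n_stages < 2L) stop("invalid design: need at least 2 stages")
  sp <- split(results, results$pair_id)
  rows <- lapply(sp, function(r) {
    incomplete <- sum(r$tested) < n_stages
    nsig <- sum(r$significant)
    fav <- unique(r$favored[r$significant])
    if (!incomplete && nsig == n_stages && length(fav) == 1L) {
      cls <- "consistent"; favored <- fav
    } else if (nsig == 0L) {
      cls <- "noASE"; favored <- "none"
    } else {
      cls <- "inconsistent"; favored <- "none"
    }
    data.frame(pair_id = r$pair_id[1], class = cls, favored = favored,
               n_significant = nsig, incomplete = incomplete,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize ASE class counts and percentages
#'
#' @param calls ASE call table from [classify_ase()], or a named vector of
#'   class counts
#' @return data.frame with columns `class`, `count`, `pct` (percent of all
#'   pairs, 2 decimal places)
#' @export
summarize_classes <- function(calls) {
  counts <- if (is.data.frame(calls)) table(factor(calls$class,
      levels = c("consistent", "inconsistent", "noASE"))) else calls
  counts <- counts[c("consistent", "inconsistent", "noASE")]
  counts[is.na(counts)] <- 0
  total <- sum(counts)
  if (total == 0) stop("no calls to summarize")
  data.frame(class = c("consistent", "inconsistent", "noASE"),
             count = as.integer(counts),
             pct = round(100 * as.numeric(counts) / total, 2),
             stringsAsFactors = FALSE)
}
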