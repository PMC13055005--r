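# Allele identification between two phased haplotypes: translated-CDS anchor
# finding, collinear (MCScan-like) block chaining by dynamic programming, and
# allele-pair calling from retained blocks.

.translate_cds <- function(cds) {
  aa <- suppressWarnings(as.character(Biostrings::translate(
    cds, if.fuzzy.codon = "X")))
  aa <- sub("\\*$", "", aa)  # strip terminal stop
  ok <- !grepl("\\*", aa)    # internal stop -> untranslatable, skip
  list(aa = aa, ok = ok)
}

.protein_kmers <- function(aa, k = 4) {
  n <- nchar(aa)
  if (n < k) return(aa)
  unique(substring(aa, 1:(n - k + 1), k:n))
}

#' Find anchors between two haplotypes' gene sets
#'
#' All-vs-all translated-CDS similarity (global alignment identity over
#' aligned length, affine gaps), restricted by a shared amino-acid k-mer
#' prefilter for speed. Returns reciprocal best hits plus any hit with
#' similarity >= `min_similarity`.
#'
#' @param models_a,models_b gene-model tables for hap1 and hap2
#' @param cds_a,cds_b DNAStringSets of CDS sequences keyed by gene id
#' @param min_similarity anchor similarity threshold
#' @param k,min_kmer_share prefilter: candidate pairs must share at least
#'   `min_kmer_share` of the smaller protein's k-mers (set
#'   `min_kmer_share = 0` to disable)
#' @param match,mismatch,gap_open,gap_ext protein alignment scoring constants
#' @return data.frame with columns `gene_a`, `gene_b`, `similarity`,
#'   `reciprocal`, plus chromosome/rank/coordinate columns used by the
#'   chaining step
#' @export
find_anchors <- function(models_a, models_b, cds_a, cds_b,
                         min_similarity = 0.7, k = 4, min_kmer_share = 0.2,
                         match = 2, mismatch = -1, gap_open = 10, gap_ext = 0.5) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      similarity = numeric(), reciprocal = logical(),
                      chrom_a = character(), chrom_b = character(),
                      rank_a = numeric(), rank_b = numeric(),
                      start_a = integer(), stringsAsFactors = FALSE)
  if (nrow(models_a) == 0L || nrow(models_b) == 0L) {
    warning("empty gene set; no anchors")
    return(empty)
  }
  ta <- .translate_cds(cds_a[models_a$gene_id])
  tb <- .translate_cds(cds_b[models_b$gene_id])
  if (any(!ta$ok)) message(sum(!ta$ok), " hap1 gene(s) with internal stop skipped")
  if (any(!tb$ok)) message(sum(!tb$ok), " hap2 gene(s) with internal stop skipped")
  ia <- which(ta$ok); ib <- which(tb$ok)
  if (length(ia) == 0L || length(ib) == 0L) return(empty)

  # k-mer prefilter: shared-kmer fraction of the smaller set
  cand <- if (min_kmer_share > 0) {
    ka <- lapply(ta$aa[ia], .protein_kmers, k = k)
    kb <- lapply(tb$aa[ib], .protein_kmers, k = k)
    kmer_index <- new.env(parent = emptyenv())
    for (j in seq_along(kb)) for (km in kb[[j]])
      kmer_index[[km]] <- c(kmer_index[[km]], j)
    do.call(rbind, lapply(seq_along(ka), function(i) {
      hits <- unlist(lapply(ka[[i]], function(km) kmer_index[[km]]), use.names = FALSE)
      if (is.null(hits)) return(NULL)
      tab <- table(hits)
      js <- as.integer(names(tab))
      share <- as.integer(tab) / pmin(length(ka[[i]]), lengths(kb)[js])
      js <- js[share >= min_kmer_share]
      if (!length(js)) return(NULL)
      cbind(i = i, j = js)
    }))
  } else as.matrix(expand.grid(i = seq_along(ia), j = seq_along(ib)))
  if (is.null(cand) || nrow(cand) == 0L) return(empty)

  submat <- .aa_submat(match, mismatch)
  sims <- numeric(nrow(cand))
  for (j in unique(cand[, "j"])) {
    sel <- which(cand[, "j"] == j)
    pats <- Biostrings::AAStringSet(ta$aa[ia][cand[sel, "i"]])
    aln <- Biostrings::pairwiseAlignment(
      pats, Biostrings::AAString(tb$aa[ib][j]),
      substitutionMatrix = submat, gapOpening = gap_open,
      gapExtension = gap_ext, type = "global")
    sims[sel] <- Biostrings::pid(aln, type = "PID2") / 100
  }

  df <- data.frame(
    gene_a = models_a$gene_id[ia][cand[, "i"]],
    gene_b = models_b$gene_id[ib][cand[, "j"]],
    similarity = sims, stringsAsFactors = FALSE)
  # reciprocal best hits among scored candidates
  best_a <- tapply(seq_len(nrow(df)), df$gene_a, function(r) r[which.max(df$similarity[r])])
  best_b <- tapply(seq_len(nrow(df)), df$gene_b, function(r) r[which.max(df$similarity[r])])
  df$reciprocal <- seq_len(nrow(df)) %in% intersect(unlist(best_a), unlist(best_b))
  df <- df[df$reciprocal | df$similarity >= min_similarity, , drop = FALSE]
  if (nrow(df) == 0L) return(empty)

  df$chrom_a <- models_a[df$gene_a, "chrom"]
  df$chrom_b <- models_b[df$gene_b, "chrom"]
  df$rank_a <- models_a[df$gene_a, "rank"]
  df$rank_b <- models_b[df$gene_b, "rank"]
  df$start_a <- models_a[df$gene_a, "start"]
  rownames(df) <- NULL
  df
}

# longest monotone chain with rank gaps <= max_gap on both axes; O(n^2) DP.
# `dir` = +1 (rank_b increasing) or -1 (decreasing). Returns indices into
# the anchor rows (ordered along the chain) of one maximum-length chain.
.best_chain <- function(ra, rb, max_gap, dir) {
  n <- length(ra)
  ord <- order(ra, dir * rb)
  ra <- ra[ord]; rb <- rb[ord]
  score <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (ra[i] <= ra[j]) next
      if (ra[i] - ra[j] > max_gap) next
      db <- dir * (rb[i] - rb[j])
      if (db <= 0 || db > max_gap) next
      if (score[j] + 1L > score[i]) { score[i] <- score[j] + 1L; prev[i] <- j }
    }
  }
  top <- which.max(score)
  chain <- integer(score[top])
  k <- score[top]; i <- top
  while (i != 0L) { chain[k] <- i; k <- k - 1L; i <- prev[i] }
  ord[chain]
}

#' Chain anchors into syntenic blocks
#'
#' Per chromosome pair, repeatedly extracts the maximum-length chain of
#' anchors monotone in gene rank on both haplotypes (increasing, or
#' decreasing for inverted blocks) with rank gaps <= `max_gap`; chains
#' shorter than `min_block` anchors are discarded. Tandem duplicates are
#' collapsed to the highest-similarity representative before chaining, so
#' each gene enters at most one anchor.
#'
#' @param anchors anchor table from [find_anchors()]
#' @param min_block minimum number of anchors per block
#' @param max_gap maximum rank gap between consecutive anchors
#' @return list with `anchors` (input rows retained after tandem collapse,
#'   plus `block_id`, NA if unassigned) and `blocks` (one row per block:
#'   `block_id`, `chrom_a`, `chrom_b`, `n_anchors`, `orientation`)
#' @export
chain_syntenic_blocks <- function(anchors, min_block = 5, max_gap = 25) {
  blocks <- data.frame(block_id = integer(), chrom_a = character(),
                       chrom_b = character(), n_anchors = integer(),
                       orientation = character(), stringsAsFactors = FALSE)
  if (nrow(anchors) == 0L)
    return(list(anchors = cbind(anchors, block_id = integer(0)), blocks = blocks))
  # tandem collapse: greedy one-to-one by similarity
  a <- anchors[order(-anchors$similarity, anchors$gene_a, anchors$gene_b), , drop = FALSE]
  used_a <- new.env(parent = emptyenv()); used_b <- new.env(parent = emptyenv())
  sel <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (!is.null(used_a[[a$gene_a[i]]]) || !is.null(used_b[[a$gene_b[i]]])) next
    sel[i] <- TRUE
    used_a[[a$gene_a[i]]] <- TRUE; used_b[[a$gene_b[i]]] <- TRUE
  }
  a <- a[sel, , drop = FALSE]
  a$block_id <- NA_integer_
  bid <- 0L
  for (cp in split(seq_len(nrow(a)), paste(a$chrom_a, a$chrom_b, sep = "\r"))) {
    remaining <- cp
    repeat {
      if (length(remaining) < min_block) break
      ra <- a$rank_a[remaining]; rb <- a$rank_b[remaining]
      fwd <- .best_chain(ra, rb, max_gap, +1L)
      rev_ <- .best_chain(ra, rb, max_gap, -1L)
      use_fwd <- length(fwd) >= length(rev_)
      chain <- if (use_fwd) fwd else rev_
      if (length(chain) < min_block) break
      bid <- bid + 1L
      rows <- remaining[chain]
      a$block_id[rows] <- bid
      blocks <- rbind(blocks, data.frame(
        block_id = bid, chrom_a = a$chrom_a[rows[1]], chrom_b = a$chrom_b[rows[1]],
        n_anchors = length(rows),
        orientation = if (use_fwd) "same" else "inverted",
        stringsAsFactors = FALSE))
      remaining <- setdiff(remaining, rows)
    }
  }
  list(anchors = a, blocks = blocks)
}

#' Call allele pairs from syntenic blocks
#'
#' Every anchor inside a retained block becomes an allele pair. Should a
#' gene ever appear in anchors of two blocks, it is kept in the larger block
#' (ties to the lower block id). Output is sorted by hap1 coordinates.
#'
#' @param chained result of [chain_syntenic_blocks()]
#' @return data.frame with columns `gene_a`, `gene_b`, `block_id`,
#'   `similarity`
#' @export
call_alleles <- function(chained) {
  a <- chained$anchors
  a <- a[!is.na(a$block_id), , drop = FALSE]
  if (nrow(a) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      block_id = integer(), similarity = numeric(),
                      stringsAsFactors = FALSE))
  sizes <- chained$blocks$n_anchors[match(a$block_id, chained$blocks$block_id)]
  pref <- order(-sizes, a$block_id)
  a <- a[pref, , drop = FALSE]
  a <- a[!duplicated(a$gene_a) & !duplicated(a$gene_b), , drop = FALSE]
  a <- a[order(a$chrom_a, a$start_a), , drop = FALSE]
  rownames(a) <- NULL
  a[, c("gene_a", "gene_b", "block_id", "similarity")]
}
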