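# Attribution of structural-variant intervals to gene-region classes:
# promoter (2 kb up to the start codon), exon, intron, downstream (1 kb past
# the stop codon), or intergenic.

#' Labeled gene-region intervals for one gene model
#'
#' Strand-aware: the promoter is the `up_bp` immediately 5' of the start
#' codon and the downstream region the `down_bp` immediately 3' of the stop
#' codon; exons are the annotated exon intervals; introns are the gene span
#' minus the exons. Intervals are truncated at chromosome ends.
#'
#' @param gene one-row gene-model table (see [read_gene_models()])
#' @param up_bp promoter size in bp
#' @param down_bp downstream-region size in bp
#' @param chrom_len chromosome length for truncation (Inf if unknown)
#' @return data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `region`, `gene_id`
#' @export
gene_regions <- function(gene, up_bp = 2000, down_bp = 1000, chrom_len = Inf) {
  plus <- gene$strand == "+"
  # anchor on the start/stop codon (CDS extremes) when CDS is annotated
  has_cds <- length(gene$cds_starts[[1]]) > 0
  lo <- if (has_cds) min(gene$cds_starts[[1]]) else gene$start
  hi <- if (has_cds) max(gene$cds_ends[[1]]) else gene$end
  prom <- if (plus) c(lo - up_bp, lo - 1) else c(hi + 1, hi + up_bp)
  down <- if (plus) c(hi + 1, hi + down_bp) else c(lo - down_bp, lo - 1)
  rows <- list(
    data.frame(start = prom[1], end = prom[2], region = "promoter"),
    data.frame(start = down[1], end = down[2], region = "downstream")
  )
  es <- gene$exon_starts[[1]]; ee <- gene$exon_ends[[1]]
  if (length(es))
    rows[[length(rows) + 1L]] <- data.frame(start = es, end = ee, region = "exon")
  # introns: gene span minus exons
  if (length(es) > 1L) {
    is_ <- ee[-length(ee)] + 1L; ie <- es[-1L] - 1L
    ok <- ie >= is_
    if (any(ok))
      rows[[length(rows) + 1L]] <- data.frame(start = is_[ok], end = ie[ok],
                                              region = "intron")
  }
  out <- do.call(rbind, rows)
  out$start <- pmax(1, out$start)
  out$end <- pmin(chrom_len, out$end)
  out <- out[out$end >= out$start, , drop = FALSE]
  out$chrom <- gene$chrom
  out$gene_id <- gene$gene_id
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "region", "gene_id")]
}

#' Gene-region class of point positions
#'
#' Labels 1-based positions with the gene-region class they fall in
#' (priority exon > promoter > intron > downstream; otherwise intergenic).
#'
#' @param models gene-model table
#' @param chrom,pos parallel vectors of positions
#' @param up_bp,down_bp,chrom_len as in [gene_regions()]
#' @return character vector of region classes
#' @export
point_region <- function(models, chrom, pos, up_bp = 2000, down_bp = 1000,
                         chrom_len = Inf) {
  regions <- do.call(rbind, lapply(seq_len(nrow(models)), function(i)
    gene_regions(models[i, ], up_bp, down_bp, chrom_len = chrom_len)))
  reg_gr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start, regions$end))
  pt <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(pt, reg_gr)
  prio <- c(exon = 1L, promoter = 2L, intron = 3L, downstream = 4L)
  out <- rep("intergenic", length(pos))
  if (length(hits)) {
    hdf <- data.frame(q = S4Vectors::queryHits(hits),
                      pr = prio[regions$region[S4Vectors::subjectHits(hits)]],
                      reg = regions$region[S4Vectors::subjectHits(hits)])
    hdf <- hdf[order(hdf$q, hdf$pr), ]
    hdf <- hdf[!duplicated(hdf$q), ]
    out[hdf$q] <- hdf$reg
  }
  out
}

#' Attribute structural variants to gene-region classes
#'
#' Each SV is assigned the region class with the largest bp overlap across
#' all genes' labeled regions; ties break by the priority exon > promoter >
#' intron > downstream; SVs overlapping no labeled region are intergenic.
#' Insertions are treated as 1-bp points at the insertion site.
#'
#' @param svs data.frame with columns `chrom`, `start0` (0-based), `end`
#'   (half-open), `type` (DEL/INS/INV), `id`
#' @param models gene-model table
#' @param up_bp,down_bp region sizes passed to [gene_regions()]
#' @param chrom_lens optional named vector of chromosome lengths
#' @return list with `attribution` (one row per SV: `id`, `gene_id`,
#'   `region`, `overlap_bp`) and `distribution` (class percentages over
#'   genic SVs, plus `pct_all` including intergenic in the denominator)
#' @export
attribute_svs <- function(svs, models, up_bp = 2000, down_bp = 1000,
                          chrom_lens = NULL) {
  stopifnot(all(c("chrom", "start0", "end", "type", "id") %in% names(svs)))
  known <- unique(models$chrom)
  bad <- !(svs$chrom %in% known)
  if (any(bad)) {
    warning(sum(bad), " SV(s) on unknown chromosome(s) skipped")
    svs <- svs[!bad, , drop = FALSE]
  }
  regions <- do.call(rbind, lapply(seq_len(nrow(models)), function(i) {
    cl <- if (!is.null(chrom_lens)) chrom_lens[[models$chrom[i]]] else Inf
    gene_regions(models[i, ], up_bp, down_bp, chrom_len = cl)
  }))
  reg_gr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start, regions$end))
  sv_start <- svs$start0 + 1L
  sv_end <- ifelse(svs$type == "INS", svs$start0 + 1L, svs$end)
  sv_gr <- GenomicRanges::GRanges(svs$chrom, IRanges::IRanges(sv_start, sv_end))
  hits <- GenomicRanges::findOverlaps(sv_gr, reg_gr)
  ov <- IRanges::width(IRanges::pintersect(
    sv_gr[S4Vectors::queryHits(hits)], reg_gr[S4Vectors::subjectHits(hits)]))
  prio <- c(exon = 1L, promoter = 2L, intron = 3L, downstream = 4L)
  att <- data.frame(id = svs$id, gene_id = NA_character_,
                    region = "intergenic", overlap_bp = 0L,
                    stringsAsFactors = FALSE)
  if (length(hits)) {
    hdf <- data.frame(q = S4Vectors::queryHits(hits),
                      s = S4Vectors::subjectHits(hits), ov = ov)
    for (q in unique(hdf$q)) {
      h <- hdf[hdf$q == q, , drop = FALSE]
      h$prio <- prio[regions$region[h$s]]
      h <- h[order(-h$ov, h$prio), , drop = FALSE]
      att$gene_id[q] <- regions$gene_id[h$s[1]]
      att$region[q] <- regions$region[h$s[1]]
      att$overlap_bp[q] <- h$ov[1]
    }
  }
  genic <- att$region != "intergenic"
  classes <- c("promoter", "exon", "intron", "downstream")
  cnt <- table(factor(att$region[genic], levels = classes))
  cnt_all <- table(factor(att$region, levels = c(classes, "intergenic")))
  dist <- data.frame(region = names(cnt_all),
                     count = as.integer(cnt_all),
                     pct_genic = NA_real_,
                     pct_all = round(100 * as.integer(cnt_all) / max(1L, nrow(att)), 2))
  dist$pct_genic[match(classes, dist$region)] <-
    round(100 * as.integer(cnt) / max(1L, sum(genic)), 2)
  list(attribution = att, distribution = dist)
}
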