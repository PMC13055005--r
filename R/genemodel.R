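#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features into a plain gene-model table. One
#' transcript per gene is assumed (the first mRNA child if several exist).
#' Coordinates are 1-based inclusive, as in GFF3.
#'
#' @param path path to a GFF3 file
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `rank` (ordinal position of the gene along its chromosome) and
#'   list-columns `exon_starts`, `exon_ends`, `cds_starts`, `cds_ends`
#'   (sorted ascending).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  mrna <- gr[typ == "mRNA"]
  exon <- gr[typ == "exon"]
  cds  <- gr[typ == "CDS"]
  first_parent <- function(x) vapply(x$Parent, function(p) as.character(p)[1], "")
  mrna_by_gene <- split(as.character(mrna$ID), first_parent(mrna))
  exon_by_tx <- split(seq_along(exon), first_parent(exon))
  cds_by_tx  <- split(seq_along(cds),  first_parent(cds))

  n <- length(genes)
  out <- data.frame(
    gene_id = as.character(genes$ID),
    chrom = as.character(GenomeInfoDb::seqnames(genes)),
    strand = as.character(BiocGenerics::strand(genes)),
    start = BiocGenerics::start(genes),
    end = BiocGenerics::end(genes),
    stringsAsFactors = FALSE
  )
  es <- ee <- cs <- ce <- vector("list", n)
  for (i in seq_len(n)) {
    tx <- mrna_by_gene[[out$gene_id[i]]][1]
    ei <- exon_by_tx[[tx]] %||% integer()
    ci <- cds_by_tx[[tx]] %||% integer()
    eo <- order(BiocGenerics::start(exon)[ei])
    co <- order(BiocGenerics::start(cds)[ci])
    es[[i]] <- BiocGenerics::start(exon)[ei][eo]; ee[[i]] <- BiocGenerics::end(exon)[ei][eo]
    cs[[i]] <- BiocGenerics::start(cds)[ci][co];  ce[[i]] <- BiocGenerics::end(cds)[ci][co]
  }
  out$exon_starts <- es; out$exon_ends <- ee
  out$cds_starts <- cs; out$cds_ends <- ce
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$rank <- stats::ave(out$start, out$chrom, FUN = function(x) rank(x, ties.method = "first"))
  rownames(out) <- out$gene_id
  out
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS features with ID/Parent attributes and correct
#' CDS phase, via rtracklayer.
#'
#' @param models gene-model table as returned by [read_gene_models()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_gene_models_gff3 <- function(models, path) {
  rows <- list()
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    gid <- g$gene_id; tid <- paste0(g$gene_id, ".t1")
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom, start = g$start, end = g$end, strand = g$strand,
      type = c("gene", "mRNA"), ID = c(gid, tid), Parent = c(NA, gid),
      phase = NA_integer_, stringsAsFactors = FALSE
    )
    es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom, start = es, end = ee, strand = g$strand,
      type = "exon", ID = paste0(tid, ".exon", seq_along(es)), Parent = tid,
      phase = NA_integer_, stringsAsFactors = FALSE
    )
    cs <- g$cds_starts[[1]]; ce <- g$cds_ends[[1]]
    # phase: number of bases to remove to reach the next codon start,
    # accumulated along the transcript (5' to 3', strand-aware)
    lens <- ce - cs + 1L
    ord <- if (g$strand == "-") rev(seq_along(cs)) else seq_along(cs)
    phase <- integer(length(cs))
    acc <- 0L
    for (j in ord) { phase[j] <- (3L - acc %% 3L) %% 3L; acc <- acc + lens[j] }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom, start = cs, end = ce, strand = g$strand,
      type = "CDS", ID = paste0(tid, ".cds", seq_along(cs)), Parent = tid,
      phase = phase, stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand
  )
  gr$source <- "haploscent"
  gr$type <- df$type
  gr$phase <- df$phase
  gr$ID <- df$ID
  gr$Parent <- ifelse(is.na(df$Parent), NA_character_, df$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Extract CDS sequences for a set of gene models
#'
#' CDS intervals are concatenated in ascending genomic order; minus-strand
#' genes are reverse-complemented so every returned sequence starts at the
#' start codon.
#'
#' @param genome a [Biostrings::DNAStringSet] keyed by chromosome name
#' @param models gene-model table
#' @return named [Biostrings::DNAStringSet] of CDS sequences
#' @export
cds_seqs <- function(genome, models) {
  out <- character(nrow(models))
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    chr <- genome[[g$chrom]]
    parts <- Biostrings::DNAStringSet(chr, start = g$cds_starts[[1]], end = g$cds_ends[[1]])
    s <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
    if (g$strand == "-") s <- Biostrings::reverseComplement(s)
    out[i] <- as.character(s)
  }
  Biostrings::DNAStringSet(setNames(out, models$gene_id))
}
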