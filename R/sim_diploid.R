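# Simulation of a phased diploid genome pair: hap1 is drawn de novo with
# protein-coding gene models; hap2 is derived from it by applying SNPs,
# small indels (outside CDS) and structural variants (in promoter / intron /
# downstream regions), with gene models lifted over to hap2 coordinates.

.SENSE_CODONS <- NULL
.sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*" & names(code) != "ATG"]
}

# random coding sequence: ATG + sense codons + stop, total length len nt
.random_cds <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  body <- sample(.sense_codons(), len / 3 - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(c("TAA", "TGA", "TAG"), 1))
}

# lay out genes along one chromosome: each gene occupies a slot with 2 kb
# promoter clearance before and 1 kb after the gene body
.layout_genes <- function(chrom, chrom_length, n, id_offset, up_bp = 2000,
                          down_bp = 1000, max_retry = 50) {
  slot <- floor(chrom_length / n)
  if (slot < up_bp + down_bp + 400)
    stop("placement capacity error: chromosome too short for ", n,
         " genes with promoter/downstream clearance")
  budget <- slot - up_bp - down_bp - 60
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (r in seq_len(max_retry)) {
      n_ex <- sample(1:4, 1, prob = c(0.3, 0.3, 0.25, 0.15))
      cds_len <- 3 * sample(100:250, 1)
      intron_budget <- budget - cds_len
      if (n_ex > 1 && intron_budget < 80 * (n_ex - 1)) next
      introns <- if (n_ex > 1)
        sample(80:max(80, min(300, floor(intron_budget / (n_ex - 1)))),
               n_ex - 1, replace = TRUE) else integer()
      span <- cds_len + sum(introns)
      if (span > budget) next
      ok <- TRUE
      break
    }
    if (!ok) stop("placement capacity error: no gene structure fits slot")
    # split CDS into n_ex exon pieces, each >= 30 nt
    if (n_ex > 1) {
      repeat {
        cuts <- sort(sample(seq(30, cds_len - 30), n_ex - 1))
        pieces <- diff(c(0, cuts, cds_len))
        if (all(pieces >= 30)) break
      }
    } else pieces <- cds_len
    gstart <- (i - 1) * slot + up_bp + sample(0:50, 1)
    es <- integer(n_ex); ee <- integer(n_ex)
    pos <- gstart
    for (k in seq_len(n_ex)) {
      es[k] <- pos
      ee[k] <- pos + pieces[k] - 1L
      pos <- ee[k] + 1L + if (k < n_ex) introns[k] else 0L
    }
    rows[[i]] <- data.frame(
      gene_id = sprintf("gene%04d", id_offset + i),
      chrom = chrom, strand = sample(c("+", "-"), 1),
      start = es[1], end = ee[n_ex], stringsAsFactors = FALSE)
    rows[[i]]$exon_starts <- list(es); rows[[i]]$exon_ends <- list(ee)
    rows[[i]]$cds_starts <- list(es); rows[[i]]$cds_ends <- list(ee)
  }
  do.call(rbind, rows)
}

# write the coding sequence of one gene into a chromosome character vector
.write_gene_seq <- function(chars, model) {
  cds <- .random_cds(sum(model$cds_ends[[1]] - model$cds_starts[[1]] + 1L))
  genomic <- if (model$strand == "-")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds))) else cds
  gchars <- strsplit(genomic, "")[[1]]
  off <- 0L
  for (k in seq_along(model$cds_starts[[1]])) {
    s <- model$cds_starts[[1]][k]; e <- model$cds_ends[[1]][k]
    chars[s:e] <- gchars[(off + 1L):(off + e - s + 1L)]
    off <- off + e - s + 1L
  }
  chars
}

.other_base <- function(base) {
  nts <- c("A", "C", "G", "T")
  vapply(base, function(b) sample(setdiff(nts, b), 1), "")
}

# sample non-overlapping intervals avoiding forbidden (exon) ranges
.sample_sv_intervals <- function(cfg, models, chrom) {
  mix <- cfg$sv_region_mix
  genes <- models[models$chrom == chrom, , drop = FALSE]
  n_sv <- cfg$sv_count_chrom[[chrom]]
  if (n_sv == 0L || nrow(genes) == 0L) return(NULL)
  classes <- sample(names(mix), n_sv, replace = TRUE, prob = mix)
  out <- list(); occupied <- IRanges::IRanges()
  for (i in seq_len(n_sv)) {
    placed <- FALSE
    for (r in 1:100) {
      g <- genes[sample(nrow(genes), 1), , drop = FALSE]
      regs <- gene_regions(g, chrom_len = cfg$chrom_length)
      regs <- regs[regs$region == classes[i], , drop = FALSE]
      if (nrow(regs) == 0L) next
      reg <- regs[sample(nrow(regs), 1), , drop = FALSE]
      avail <- reg$end - reg$start - 1L
      if (avail < cfg$sv_min_len) next
      len <- sample(cfg$sv_min_len:min(cfg$sv_max_len, avail), 1)
      s <- reg$start + sample(0:(avail - len), 1)
      iv <- IRanges::IRanges(s, s + len - 1L)
      if (length(IRanges::findOverlaps(iv, occupied))) next
      occupied <- c(occupied, iv)
      out[[i]] <- data.frame(chrom = chrom, start = s, end = s + len - 1L,
                             type = sample(c("DEL", "INS", "INV"), 1),
                             region = classes[i], gene_id = g$gene_id,
                             stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) stop("placement capacity error: could not place SV ", i,
                      " in region class ", classes[i])
  }
  do.call(rbind, out)
}

#' Simulate a phased diploid genome pair
#'
#' Draws haplotype 1 (random background plus protein-coding gene models with
#' clean reading frames), then derives haplotype 2 by applying SNPs at
#' `snp_rate`, small indels at `indel_rate` (outside CDS, so frames stay
#' intact) and `sv_count` structural variants (DEL/INS/INV placed in
#' promoter / intron / downstream regions per `sv_region_mix`). Gene models
#' are lifted over to hap2 coordinates. Every applied variant, the planted
#' per-gene ASE class, and the SV region labels are recorded in the truth
#' set.
#'
#' @param cfg a [sim_config()]
#' @return list with `hap1`, `hap2` (DNAStringSets), `models1`, `models2`
#'   (gene-model tables), `svs` (BED-like 0-based half-open table on hap1
#'   coordinates), and `truth` (list: `ase_classes`, `variants`, `sv_truth`)
#' @export
simulate_diploid <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(sub_seed(cfg$seed, "diploid"), {
    nts <- c("A", "C", "G", "T")
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    per <- rep(cfg$n_genes %/% cfg$n_chromosomes, cfg$n_chromosomes)
    if (cfg$n_genes %% cfg$n_chromosomes)
      per[seq_len(cfg$n_genes %% cfg$n_chromosomes)] <-
        per[seq_len(cfg$n_genes %% cfg$n_chromosomes)] + 1L
    # distribute SV count proportionally to gene numbers
    svc <- round(cfg$sv_count * per / sum(per))
    svc[1] <- svc[1] + cfg$sv_count - sum(svc)
    cfg$sv_count_chrom <- setNames(as.list(svc), chroms)

    models1 <- list(); hap1 <- hap2 <- setNames(vector("list", length(chroms)), chroms)
    models2 <- list(); svs <- list(); variants <- list()
    id_offset <- 0L
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      m <- .layout_genes(ch, cfg$chrom_length, per[ci], id_offset)
      id_offset <- id_offset + per[ci]
      chars <- sample(nts, cfg$chrom_length, replace = TRUE)
      for (i in seq_len(nrow(m))) chars <- .write_gene_seq(chars, m[i, ])
      models1[[ch]] <- m
      hap1[[ch]] <- paste(chars, collapse = "")

      L <- cfg$chrom_length
      in_cds <- logical(L)
      gene_of <- integer(L); tpos_of <- integer(L)
      tx_gpos <- vector("list", nrow(m))
      for (i in seq_len(nrow(m))) {
        gp <- unlist(lapply(seq_along(m$cds_starts[[i]]), function(k)
          m$cds_starts[[i]][k]:m$cds_ends[[i]][k]))
        if (m$strand[i] == "-") gp <- rev(gp)
        tx_gpos[[i]] <- gp
        in_cds[gp] <- TRUE
        gene_of[gp] <- i
        tpos_of[gp] <- seq_along(gp)
      }

      # SVs first (they own intervals other variants must avoid)
      sv <- .sample_sv_intervals(cfg, m, ch)
      sv_occupied <- logical(L)
      if (!is.null(sv))
        for (i in seq_len(nrow(sv))) sv_occupied[sv$start[i]:sv$end[i]] <- TRUE

      n_snp <- rbinom(1, L, cfg$snp_rate)
      snp_pos <- sort(sample.int(L, n_snp))
      snp_pos <- snp_pos[!sv_occupied[snp_pos]]
      snp_alt <- .other_base(chars[snp_pos])
      # functional alleles: reject SNPs that would put a premature stop in
      # the hap2 reading frame (NG86 likewise excludes mutations to stops)
      code <- Biostrings::GENETIC_CODE
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      keep_snp <- rep(TRUE, length(snp_pos))
      for (si in which(in_cds[snp_pos])) {
        p <- snp_pos[si]
        gi <- gene_of[p]; t <- tpos_of[p]
        ci <- (t - 1L) %/% 3L
        if (3L * ci + 3L > length(tx_gpos[[gi]])) { keep_snp[si] <- FALSE; next }
        gpos <- tx_gpos[[gi]][(3L * ci + 1L):(3L * ci + 3L)]
        minus <- m$strand[gi] == "-"
        codon <- chars[gpos]; if (minus) codon <- comp[codon]
        off <- (t - 1L) %% 3L + 1L
        if (ci == length(tx_gpos[[gi]]) / 3L - 1L) next  # terminal codon free
        ok_alt <- NA_character_
        for (a in sample(setdiff(c("A", "C", "G", "T"), chars[p]))) {
          mut <- codon; mut[off] <- if (minus) comp[[a]] else a
          if (code[[paste(mut, collapse = "")]] != "*") { ok_alt <- a; break }
        }
        if (is.na(ok_alt)) keep_snp[si] <- FALSE else snp_alt[si] <- ok_alt
      }
      snp_pos <- snp_pos[keep_snp]; snp_alt <- snp_alt[keep_snp]

      n_ind <- rbinom(1, L, cfg$indel_rate)
      ind_pos <- sort(sample.int(L, min(n_ind, L)))
      ind_pos <- ind_pos[!in_cds[ind_pos] & !sv_occupied[ind_pos]]
      if (length(ind_pos) > 1L)
        ind_pos <- ind_pos[c(TRUE, diff(ind_pos) > 12)]  # no overlap between indels
      ind_len <- sample(1:10, length(ind_pos), replace = TRUE)
      ind_del <- sample(c(TRUE, FALSE), length(ind_pos), replace = TRUE)
      # deletions must stay outside CDS and SVs over their whole length
      keep <- vapply(seq_along(ind_pos), function(i) {
        if (!ind_del[i]) return(TRUE)
        e <- min(L, ind_pos[i] + ind_len[i] - 1L)
        !any(in_cds[ind_pos[i]:e]) && !any(sv_occupied[ind_pos[i]:e])
      }, TRUE)
      ind_pos <- ind_pos[keep]; ind_len <- ind_len[keep]; ind_del <- ind_del[keep]

      # --- build hap2 ---
      chars2 <- chars
      chars2[snp_pos] <- snp_alt
      # inversions in place (no length change)
      if (!is.null(sv))
        for (i in which(sv$type == "INV")) {
          s <- sv$start[i]; e <- sv$end[i]
          chars2[s:e] <- strsplit(as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(paste(chars2[s:e], collapse = "")))), "")[[1]]
        }
      # length-changing events: (pos, ref_len, alt_seq)
      ev <- data.frame(pos = integer(), ref_len = integer(),
                       alt = character(), stringsAsFactors = FALSE)
      if (length(ind_pos))
        ev <- rbind(ev, data.frame(
          pos = ind_pos, ref_len = ifelse(ind_del, ind_len, 0L),
          alt = ifelse(ind_del, "",
                       vapply(ind_len, function(l)
                         paste(sample(nts, l, replace = TRUE), collapse = ""), "")),
          stringsAsFactors = FALSE))
      if (!is.null(sv)) {
        for (i in seq_len(nrow(sv))) {
          if (sv$type[i] == "DEL")
            ev <- rbind(ev, data.frame(pos = sv$start[i],
                                       ref_len = sv$end[i] - sv$start[i] + 1L,
                                       alt = "", stringsAsFactors = FALSE))
          if (sv$type[i] == "INS")
            ev <- rbind(ev, data.frame(pos = sv$start[i], ref_len = 0L,
                                       alt = paste(sample(nts, sv$end[i] - sv$start[i] + 1L,
                                                          replace = TRUE), collapse = ""),
                                       stringsAsFactors = FALSE))
        }
      }
      ev <- ev[order(ev$pos), , drop = FALSE]
      # splice hap2 and record cumulative shifts for liftover
      if (nrow(ev)) {
        segs <- character(2 * nrow(ev) + 1L)
        cur <- 1L
        for (i in seq_len(nrow(ev))) {
          segs[2 * i - 1L] <- if (ev$pos[i] > cur)
            paste(chars2[cur:(ev$pos[i] - 1L)], collapse = "") else ""
          segs[2 * i] <- ev$alt[i]
          cur <- ev$pos[i] + ev$ref_len[i]
        }
        segs[2 * nrow(ev) + 1L] <- paste(chars2[cur:L], collapse = "")
        hap2[[ch]] <- paste(segs, collapse = "")
        shift_at <- ev$pos
        shift_cum <- cumsum(nchar(ev$alt) - ev$ref_len)
      } else {
        hap2[[ch]] <- paste(chars2, collapse = "")
        shift_at <- integer(); shift_cum <- integer()
      }
      lift <- function(x) {
        if (!length(shift_at)) return(x)
        i <- findInterval(x, shift_at + ev$ref_len)  # events entirely before x
        x + ifelse(i > 0, shift_cum[pmax(i, 1)], 0L)
      }
      m2 <- m
      for (i in seq_len(nrow(m2))) {
        m2$exon_starts[[i]] <- lift(m2$exon_starts[[i]])
        m2$exon_ends[[i]] <- lift(m2$exon_ends[[i]])
        m2$cds_starts[[i]] <- lift(m2$cds_starts[[i]])
        m2$cds_ends[[i]] <- lift(m2$cds_ends[[i]])
        m2$start[i] <- m2$exon_starts[[i]][1]
        m2$end[i] <- m2$exon_ends[[i]][length(m2$exon_ends[[i]])]
      }
      models2[[ch]] <- m2
      svs[[ch]] <- sv
      variants[[ch]] <- data.frame(
        chrom = rep(ch, length(snp_pos) + length(ind_pos)),
        pos = c(snp_pos, ind_pos),
        type = c(rep("SNP", length(snp_pos)),
                 ifelse(ind_del, "DEL_small", "INS_small")),
        stringsAsFactors = FALSE)
    }
    models1 <- do.call(rbind, models1); rownames(models1) <- models1$gene_id
    models2 <- do.call(rbind, models2); rownames(models2) <- models2$gene_id
    models1$rank <- stats::ave(models1$start, models1$chrom,
                               FUN = function(x) rank(x, ties.method = "first"))
    models2$rank <- stats::ave(models2$start, models2$chrom,
                               FUN = function(x) rank(x, ties.method = "first"))
    sv_all <- do.call(rbind, svs[!vapply(svs, is.null, TRUE)])
    if (is.null(sv_all))
      sv_all <- data.frame(chrom = character(), start = integer(),
                           end = integer(), type = character(),
                           region = character(), gene_id = character())
    sv_bed <- data.frame(
      chrom = sv_all$chrom, start0 = sv_all$start - 1L,
      end = ifelse(sv_all$type == "INS", sv_all$start, sv_all$end),
      type = sv_all$type,
      id = if (nrow(sv_all)) sprintf("sv%03d", seq_len(nrow(sv_all))) else character(),
      stringsAsFactors = FALSE)

    # gene-region class of every applied variant position (hap1 coordinates)
    var_all <- do.call(rbind, variants)
    if (!is.null(var_all) && nrow(var_all))
      var_all$region <- point_region(models1, var_all$chrom, var_all$pos,
                                     chrom_len = cfg$chrom_length)

    # planted ASE classes
    cls <- sample(names(cfg$ase_class_proportions), cfg$n_genes,
                  replace = TRUE, prob = cfg$ase_class_proportions)
    favored <- ifelse(cls == "consistent",
                      sample(c("hap1", "hap2"), cfg$n_genes, replace = TRUE),
                      "none")
    ase_classes <- data.frame(gene_id = models1$gene_id, class = cls,
                              favored = favored, stringsAsFactors = FALSE)

    list(hap1 = Biostrings::DNAStringSet(unlist(hap1)),
         hap2 = Biostrings::DNAStringSet(unlist(hap2)),
         models1 = models1, models2 = models2, svs = sv_bed,
         truth = list(ase_classes = ase_classes,
                      variants = var_all,
                      sv_truth = cbind(sv_bed,
                                       region = sv_all$region,
                                       gene_id = sv_all$gene_id)))
  })
}
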