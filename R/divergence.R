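# Allele-pair divergence: codon-aware alignment, CDS identity, Nei-Gojobori
# (1986) Ka/Ks with Jukes-Cantor correction, flanking-region divergence, and
# group contrasts of selection statistics.

.aa_submat <- function(match = 2, mismatch = -1) {
  key <- paste0("aamat_", match, "_", mismatch)
  if (!is.null(.haploscent_cache[[key]])) return(.haploscent_cache[[key]])
  letters <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  .haploscent_cache[[key]] <- m
  m
}

# NG86 per-codon synonymous site counts. Mutations creating a stop codon are
# excluded from the denominator; a position whose three alternatives are all
# stops contributes 0 synonymous sites (counts as fully non-synonymous).
.ng86_site_table <- function() {
  if (!is.null(.haploscent_cache$ng86_sites)) return(.haploscent_cache$ng86_sites)
  code <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  syn <- setNames(numeric(length(code)), names(code))
  for (cod in names(code)) {
    if (code[[cod]] == "*") { syn[[cod]] <- NA_real_; next }
    s <- 0
    chars <- strsplit(cod, "")[[1]]
    for (pos in 1:3) {
      n_ok <- 0L; n_syn <- 0L
      for (nt in setdiff(nts, chars[pos])) {
        mut <- chars; mut[pos] <- nt
        aa <- code[[paste(mut, collapse = "")]]
        if (aa == "*") next
        n_ok <- n_ok + 1L
        if (aa == code[[cod]]) n_syn <- n_syn + 1L
      }
      if (n_ok > 0L) s <- s + n_syn / n_ok
    }
    syn[[cod]] <- s
  }
  .haploscent_cache$ng86_sites <- syn
  syn
}

.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) for (p in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# NG86 between-codon substitution counts: average synonymous/non-synonymous
# steps over all minimal mutational pathways, equally weighted, pathways
# passing through a stop codon excluded. If every pathway is blocked by a
# stop (rare), all pathways are used as a fallback.
.ng86_pair_counts <- function() {
  if (!is.null(.haploscent_cache$ng86_pairs)) return(.haploscent_cache$ng86_pairs)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  nd <- sd <- matrix(0, length(sense), length(sense), dimnames = list(sense, sense))
  for (a in sense) {
    ca <- strsplit(a, "")[[1]]
    for (b in sense) {
      if (a >= b) next   # fill symmetric half later
      cb <- strsplit(b, "")[[1]]
      diffs <- which(ca != cb)
      if (length(diffs) == 0L) next
      paths <- .perms(diffs)
      tally <- function(require_no_stop) {
        res <- NULL
        for (p in paths) {
          cur <- ca; ns <- 0; nn <- 0; ok <- TRUE
          for (pos in p) {
            nxt <- cur; nxt[pos] <- cb[pos]
            aa1 <- code[[paste(cur, collapse = "")]]
            aa2 <- code[[paste(nxt, collapse = "")]]
            if (aa2 == "*" && require_no_stop) { ok <- FALSE; break }
            if (aa1 == aa2) ns <- ns + 1 else nn <- nn + 1
            cur <- nxt
          }
          if (ok) res <- rbind(res, c(ns, nn))
        }
        res
      }
      res <- tally(TRUE)
      if (is.null(res)) res <- tally(FALSE)
      sd[a, b] <- sd[b, a] <- mean(res[, 1])
      nd[a, b] <- nd[b, a] <- mean(res[, 2])
    }
  }
  .haploscent_cache$ng86_pairs <- list(nd = nd, sd = sd)
  .haploscent_cache$ng86_pairs
}

#' Codon-aware alignment of two coding sequences
#'
#' Translates both CDS, globally aligns the amino-acid sequences (affine
#' gaps), and back-threads the nucleotides. Codon columns containing a gap or
#' a stop codon in either sequence are dropped and counted.
#'
#' @param cds_a,cds_b coding sequences (character or DNAString), lengths
#'   multiples of 3, start-to-stop reading frame
#' @param match,mismatch,gap_open,gap_ext amino-acid alignment scoring
#'   constants
#' @return object of class `codon_alignment`: list with `codons_a`,
#'   `codons_b` (retained gap- and stop-free codon columns),
#'   `aln_a`, `aln_b` (all aligned codon columns, `---` for gaps),
#'   `n_codons_used`, `n_codons_dropped`, `excluded`, `reason`
#' @export
align_codons <- function(cds_a, cds_b, match = 2, mismatch = -1,
                         gap_open = 10, gap_ext = 0.5) {
  a <- toupper(as.character(cds_a)); b <- toupper(as.character(cds_b))
  if (nchar(a) %% 3L != 0L || nchar(b) %% 3L != 0L)
    stop("CDS length must be a multiple of 3")
  code <- Biostrings::GENETIC_CODE
  split_codons <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  cod_a <- split_codons(a); cod_b <- split_codons(b)
  aa_a <- unname(code[cod_a]); aa_b <- unname(code[cod_b])
  bad <- function(aa) any(is.na(aa)) ||
    (length(aa) > 1L && any(aa[-length(aa)] == "*"))
  empty <- list(codons_a = character(), codons_b = character(),
                aln_a = character(), aln_b = character(),
                n_codons_used = 0L, n_codons_dropped = 0L)
  if (bad(aa_a) || bad(aa_b)) {
    out <- c(empty, list(excluded = TRUE, reason = "internal_stop"))
    class(out) <- "codon_alignment"
    return(out)
  }
  # trim a terminal stop before amino-acid alignment; it is counted as dropped
  trim_a <- length(aa_a) > 0L && aa_a[length(aa_a)] == "*"
  trim_b <- length(aa_b) > 0L && aa_b[length(aa_b)] == "*"
  pa <- if (trim_a) aa_a[-length(aa_a)] else aa_a
  pb <- if (trim_b) aa_b[-length(aa_b)] else aa_b
  if (length(pa) == 0L || length(pb) == 0L) {
    out <- c(empty, list(excluded = TRUE, reason = "empty_after_stop_trim"))
    class(out) <- "codon_alignment"
    return(out)
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(pa, collapse = "")),
    Biostrings::AAString(paste(pb, collapse = "")),
    substitutionMatrix = .aa_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_ext, type = "global"
  )
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- ib <- 0L
  aln_a <- aln_b <- character(length(sa))
  keep <- logical(length(sa))
  for (k in seq_along(sa)) {
    ga <- sa[k] == "-"; gb <- sb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    aln_a[k] <- if (ga) "---" else cod_a[ia]
    aln_b[k] <- if (gb) "---" else cod_b[ib]
    keep[k] <- !ga && !gb
  }
  n_used <- sum(keep)
  n_dropped <- sum(!keep) + max(as.integer(trim_a), as.integer(trim_b))
  out <- list(codons_a = aln_a[keep], codons_b = aln_b[keep],
              aln_a = aln_a, aln_b = aln_b,
              n_codons_used = n_used, n_codons_dropped = n_dropped,
              excluded = FALSE, reason = NA_character_)
  class(out) <- "codon_alignment"
  out
}

#' Nei-Gojobori (1986) Ka/Ks on a codon alignment
#'
#' Synonymous site fractions per codon enumerate all nine single-nucleotide
#' mutations, excluding mutations to stop codons; site totals are averaged
#' over the two sequences. Multi-hit codons are resolved by averaging the
#' synonymous/non-synonymous step counts over all minimal mutational
#' pathways with equal weight, excluding pathways through stop codons.
#' Proportions are Jukes-Cantor corrected; Ka/Ks is NA when Ks = 0.
#'
#' @param alignment a `codon_alignment` from [align_codons()]
#' @return list with `Nd`, `Sd`, `N`, `S`, `pN`, `pS`, `Ka`, `Ks`, `kaks`,
#'   `n_codons_used`, and a `saturated` flag (pN or pS >= 3/4, correction
#'   undefined)
#' @export
ng86 <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  if (isTRUE(alignment$excluded) || alignment$n_codons_used < 1L)
    return(list(Nd = NA_real_, Sd = NA_real_, N = NA_real_, S = NA_real_,
                pN = NA_real_, pS = NA_real_, Ka = NA_real_, Ks = NA_real_,
                kaks = NA_real_, n_codons_used = alignment$n_codons_used,
                saturated = NA))
  sites <- .ng86_site_table()
  pairs <- .ng86_pair_counts()
  ca <- alignment$codons_a; cb <- alignment$codons_b
  S <- (sum(sites[ca]) + sum(sites[cb])) / 2
  N <- 3 * alignment$n_codons_used - S
  Nd <- sum(pairs$nd[cbind(ca, cb)])
  Sd <- sum(pairs$sd[cbind(ca, cb)])
  pN <- if (N > 0) Nd / N else NA_real_
  pS <- if (S > 0) Sd / S else NA_real_
  Ka <- jc_correct(pN); Ks <- jc_correct(pS)
  saturated <- (!is.na(pN) && pN >= 0.75) || (!is.na(pS) && pS >= 0.75)
  kaks <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  list(Nd = Nd, Sd = Sd, N = N, S = S, pN = pN, pS = pS, Ka = Ka, Ks = Ks,
       kaks = kaks, n_codons_used = alignment$n_codons_used,
       saturated = saturated)
}

#' CDS identity of a codon alignment
#'
#' Matching nucleotide columns divided by total aligned columns; gap columns
#' count as mismatches (three per gapped codon column).
#'
#' @param alignment a `codon_alignment`
#' @param count_gaps if FALSE, gap columns are excluded from the denominator
#' @return fraction in [0, 1], NA for an empty alignment
#' @export
cds_identity <- function(alignment, count_gaps = TRUE) {
  stopifnot(inherits(alignment, "codon_alignment"))
  cols_a <- if (count_gaps) alignment$aln_a else alignment$codons_a
  cols_b <- if (count_gaps) alignment$aln_b else alignment$codons_b
  if (length(cols_a) == 0L) return(NA_real_)
  na <- strsplit(paste(cols_a, collapse = ""), "")[[1]]
  nb <- strsplit(paste(cols_b, collapse = ""), "")[[1]]
  sum(na == nb & na != "-") / length(na)
}

.extract_flank <- function(genome, model, side = c("up", "down"), len) {
  side <- match.arg(side)
  chr <- genome[[model$chrom]]
  cs <- min(model$cds_starts[[1]]); ce <- max(model$cds_ends[[1]])
  # upstream = 5' of the start codon, downstream = 3' of the stop codon
  left_of_gene <- (side == "up") == (model$strand == "+")
  if (left_of_gene) { s <- cs - len; e <- cs - 1L }
  else { s <- ce + 1L; e <- ce + len }
  s <- max(1L, as.integer(s)); e <- min(length(chr), as.integer(e))
  if (e < s) return(Biostrings::DNAString(""))
  seq <- Biostrings::subseq(chr, s, e)
  if (model$strand == "-") seq <- Biostrings::reverseComplement(seq)
  seq
}

#' Flanking-region divergence of an allele pair
#'
#' Strand-aware extraction of the region upstream of the start codon
#' (default 2 kb) and downstream of the stop codon (default 1 kb) on both
#' haplotypes, pairwise global alignment, and Jukes-Cantor-corrected
#' p-distance per flank. Flanks are truncated at chromosome ends; a flank
#' shorter than `min_len` bp yields a missing rate.
#'
#' @param genome_a,genome_b DNAStringSets for the two haplotypes
#' @param model_a,model_b one-row gene-model tables for the paired genes
#' @param up_bp,down_bp flank sizes in bp
#' @param min_len minimum usable flank length in bp
#' @return list with `flank_up_rate`, `flank_down_rate`, `up_len`, `down_len`
#' @export
flank_divergence <- function(genome_a, genome_b, model_a, model_b,
                             up_bp = 2000, down_bp = 1000, min_len = 100) {
  one <- function(side, len) {
    fa <- .extract_flank(genome_a, model_a, side, len)
    fb <- .extract_flank(genome_b, model_b, side, len)
    n <- min(length(fa), length(fb))
    if (n < min_len) return(list(rate = NA_real_, len = n))
    aln <- Biostrings::pairwiseAlignment(
      fa, fb, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1),
      gapOpening = 10, gapExtension = 0.5
    )
    sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ok <- sa != "-" & sb != "-"
    p <- sum(sa[ok] != sb[ok]) / sum(ok)
    list(rate = jc_correct(p), len = n)
  }
  up <- one("up", up_bp); down <- one("down", down_bp)
  list(flank_up_rate = up$rate, flank_down_rate = down$rate,
       up_len = up$len, down_len = down$len)
}

#' Compare a selection metric between two groups of allele pairs
#'
#' Welch two-sample t-test on the finite values of a divergence metric
#' (e.g. Ka/Ks or a flank substitution rate) between two groups, as used to
#' contrast consistent vs inconsistent ASE pairs.
#'
#' @param x1,x2 numeric vectors (NA/Inf excluded and counted)
#' @return list with `run` (logical), `mean1`, `mean2`, `t`, `p`, `n1`, `n2`,
#'   `n_excluded`
#' @export
compare_selection <- function(x1, x2) {
  f1 <- x1[is.finite(x1)]; f2 <- x2[is.finite(x2)]
  n_excl <- (length(x1) - length(f1)) + (length(x2) - length(f2))
  if (length(f1) < 2L || length(f2) < 2L)
    return(list(run = FALSE, mean1 = NA_real_, mean2 = NA_real_,
                t = NA_real_, p = NA_real_,
                n1 = length(f1), n2 = length(f2), n_excluded = n_excl))
  tt <- stats::t.test(f1, f2, var.equal = FALSE)
  list(run = TRUE, mean1 = mean(f1), mean2 = mean(f2),
       t = unname(tt$statistic), p = tt$p.value,
       n1 = length(f1), n2 = length(f2), n_excluded = n_excl)
}
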