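# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (genetic-code lookups, literal formula
# transcriptions, exhaustive enumeration) and share no counting logic with
# the package implementation.

GC <- Biostrings::GENETIC_CODE
NTS <- c("A", "C", "G", "T")

# --- NG86 oracle: enumerate sites and pathways directly -------------------

oracle_codon_sites <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; tot <- 0
    for (nt in NTS) {
      if (nt == chars[pos]) next
      mut <- chars; mut[pos] <- nt
      aa <- GC[[paste(mut, collapse = "")]]
      if (aa == "*") next
      tot <- tot + 1
      if (aa == GC[[codon]]) syn <- syn + 1
    }
    if (tot > 0) s <- s + syn / tot
  }
  c(S = s, N = 3 - s)
}

# all permutations of a vector (tiny n)
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  out
}

oracle_codon_path_counts <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  diffs <- which(a != b)
  if (!length(diffs)) return(c(Sd = 0, Nd = 0))
  run <- function(no_stop) {
    acc <- NULL
    for (ord in oracle_perms(diffs)) {
      cur <- a; sd_ <- 0; nd <- 0; valid <- TRUE
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- b[pos]
        aa1 <- GC[[paste(cur, collapse = "")]]
        aa2 <- GC[[paste(nxt, collapse = "")]]
        if (no_stop && aa2 == "*") { valid <- FALSE; break }
        if (aa1 == aa2) sd_ <- sd_ + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (valid) acc <- rbind(acc, c(sd_, nd))
    }
    acc
  }
  acc <- run(TRUE)
  if (is.null(acc)) acc <- run(FALSE)
  c(Sd = mean(acc[, 1]), Nd = mean(acc[, 2]))
}

# full NG86 on two equal-length, gap-free, stop-free codon vectors
oracle_ng86 <- function(codons_a, codons_b) {
  sa <- t(vapply(codons_a, oracle_codon_sites, c(S = 0, N = 0)))
  sb <- t(vapply(codons_b, oracle_codon_sites, c(S = 0, N = 0)))
  S <- (sum(sa[, "S"]) + sum(sb[, "S"])) / 2
  N <- (sum(sa[, "N"]) + sum(sb[, "N"])) / 2
  d <- t(mapply(oracle_codon_path_counts, codons_a, codons_b))
  Sd <- sum(d[, "Sd"]); Nd <- sum(d[, "Nd"])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
       Ka = jc(pN), Ks = jc(pS))
}

# random sense-codon sequence and a mutated partner (no stops, no indels)
random_codon_pair <- function(n_codons, n_mut) {
  sense <- names(GC)[GC != "*"]
  a <- sample(sense, n_codons, replace = TRUE)
  b <- a
  sites <- sample(3L * n_codons, n_mut)
  for (s in sites) {
    ci <- (s - 1) %/% 3 + 1; off <- (s - 1) %% 3 + 1
    repeat {
      mut <- strsplit(b[ci], "")[[1]]
      mut[off] <- sample(setdiff(NTS, mut[off]), 1)
      cand <- paste(mut, collapse = "")
      if (GC[[cand]] != "*") { b[ci] <- cand; break }
    }
  }
  list(a = a, b = b)
}

# --- Weir & Cockerham (1984) oracle: literal per-site transcription --------

oracle_wc_abc <- function(geno1, geno2) {
  # geno*: vector of 0/1/2 dosages (one site, one population), NA = missing
  g1 <- geno1[!is.na(geno1)]; g2 <- geno2[!is.na(geno2)]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 1 || n2 < 1) return(c(a = NA, b = NA, c = NA))
  r <- 2
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  nbar <- (n1 + n2) / r
  if (nbar <= 1) return(c(a = NA, b = NA, c = NA))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Balding-Nichols draw used when constructing test panels
.rbn_test <- function(p, F) rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)

# --- synteny chaining oracle: exhaustive subset enumeration ----------------

oracle_best_chain_len <- function(ra, rb, max_gap) {
  n <- length(ra)
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) <= best) next
    o <- idx[order(ra[idx])]
    if (any(duplicated(ra[o])) || any(duplicated(rb[o]))) next
    da <- diff(ra[o]); db <- diff(rb[o])
    fwd <- all(db > 0) && all(da <= max_gap) && all(db <= max_gap)
    rev_ <- all(db < 0) && all(da <= max_gap) && all(-db <= max_gap)
    if (fwd || rev_) best <- length(idx)
  }
  best
}

# --- shared default simulation (memoized across test files) ----------------

.fixture_env <- new.env()
default_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(seed = 42)
    .fixture_env$cfg <- cfg
    .fixture_env$sim <- simulate_diploid(cfg)
  }
  .fixture_env$sim
}
default_cfg <- function() { default_sim(); .fixture_env$cfg }
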