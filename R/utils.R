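`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Each stochastic component draws from its own RNG stream, seeded by a hash
#' of the master seed and a stream name. Adding draws to one component then
#' leaves every other component's output unchanged.
#'
#' @param seed master integer seed
#' @param name stream name (character scalar)
#' @return an integer seed in [1, 2^31 - 2]
#' @export
sub_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) * 48271 + h * 16807 + 12345) %% 2147483646 + 1)
}

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores `.Random.seed`, so library internals can consume
#' randomness without disturbing the caller's stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Jukes-Cantor correction of a proportion of differing sites
#'
#' d = -(3/4) log(1 - (4/3) p). Undefined (NA) at or beyond saturation
#' (p >= 3/4).
#' @param p proportion of differing sites in [0, 1]
#' @return corrected substitution rate per site, NA if saturated
#' @export
jc_correct <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - (4 / 3) * p[ok])
  out
}

#' Tile a chromosome into sliding windows
#'
#' Windows are half-open [start0, end) in 0-based coordinates, placed at
#' `step` intervals; the last window is truncated at the chromosome end.
#' @param chrom_len chromosome length in bp
#' @param window window size in bp
#' @param step step size in bp (must satisfy 0 < step <= window)
#' @return data.frame with columns start0, end
#' @export
tile_windows <- function(chrom_len, window, step) {
  stopifnot(window >= step, step > 0)
  if (chrom_len <= 0) return(data.frame(start0 = integer(), end = integer()))
  starts <- seq(0L, max(0L, as.integer(chrom_len) - 1L), by = as.integer(step))
  starts <- starts[starts < chrom_len]
  data.frame(start0 = starts, end = pmin(starts + as.integer(window), as.integer(chrom_len)))
}

# BH false-discovery-rate adjustment over non-NA entries, preserving NAs
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

# write a data.frame as TSV without quoting or row names
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
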