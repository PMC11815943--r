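## Small shared helpers. All coordinates in this package are 1-based, closed
## intervals on the forward strand of the locus; genomic coordinates appear
## only at I/O boundaries via the locus coordinate_origin.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

is_dna <- function(x) {
  grepl("^[ACGTN]+$", x)
}

check_dna <- function(x, what = "sequence") {
  if (length(x) != 1L || !is.character(x) || is.na(x) || nchar(x) == 0L) {
    stop(sprintf("%s must be a single non-empty character string", what),
         call. = FALSE)
  }
  x <- toupper(x)
  if (!is_dna(x)) {
    stop(sprintf("%s contains characters other than A/C/G/T/N", what),
         call. = FALSE)
  }
  x
}

## closed-interval helpers
iv_width <- function(iv) iv[2L] - iv[1L] + 1L

iv_contains <- function(outer, inner) {
  inner[1L] >= outer[1L] && inner[2L] <= outer[2L]
}

iv_overlaps <- function(a, b) {
  a[1L] <= b[2L] && b[1L] <= a[2L]
}

check_interval <- function(iv, what = "interval") {
  if (length(iv) != 2L || any(is.na(iv)) || iv[1L] > iv[2L] || iv[1L] < 1L) {
    stop(sprintf("%s must be a valid 1-based (start, end) pair", what),
         call. = FALSE)
  }
  as.integer(iv)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`; `c(NA, NA)` when `n == 0`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

## deterministic RNG scoping: run `expr` under `seed` without disturbing the
## caller's RNG stream when a seed is supplied
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}
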