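# Internal helpers shared across modules.
#
# Coordinate convention: all spans inside the package are 0-based half-open
# [start, end); conversion to 1-based inclusive happens only in GFF3 output.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a fixed RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators are pure
#' functions of (inputs, seed) and never perturb the session stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# substring under the internal 0-based half-open convention
substr0 <- function(x, start, end) {
  if (end <= start) return("")
  substring(x, start + 1L, end)
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE))
}

# round-half-up, used for reported percentages (base round() is round-half-even)
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Count character mismatches between two equal-length strings
#' @noRd
str_mismatches <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(av) == length(bv))
  sum(av != bv)
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
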