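# Pairwise alignment layer. Two sequences at a time is all the toolkit ever
# needs (LTR vs LTR for dating, CDS vs CDS for divergence), so exact global
# affine-gap alignment replaces a multiple-sequence aligner throughout.

.ltrtrace_env <- new.env(parent = emptyenv())

# Nucleotide scoring matrix over A,C,G,T,N. N is scored 0 against everything
# so that ambiguous columns neither help nor hurt; they are later dropped from
# the identity and p-distance counts.
.dna_score_matrix <- function(match = 2, mismatch = -2) {
  key <- paste0("dna_", match, "_", mismatch)
  m <- .ltrtrace_env[[key]]
  if (is.null(m)) {
    letters5 <- c("A", "C", "G", "T", "N")
    m <- matrix(mismatch, 5L, 5L, dimnames = list(letters5, letters5))
    diag(m) <- match
    m["N", ] <- 0
    m[, "N"] <- 0
    .ltrtrace_env[[key]] <- m
  }
  m
}

.blosum62 <- function() {
  m <- .ltrtrace_env$blosum62
  if (is.null(m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    .ltrtrace_env$blosum62 <- m
  }
  m
}

#' Global pairwise alignment of two nucleotide sequences
#'
#' Needleman-Wunsch alignment with affine gap costs. A gap of length L is
#' charged `gap_open + L * gap_extend`. Defaults (+2 match, -2 mismatch,
#' open 6, extend 1) are deliberately gap-averse so that short LTR pairs are
#' not over-gapped before Jukes-Cantor dating.
#'
#' @param a,b Nucleotide strings (A/C/G/T/N), both non-empty.
#' @param match,mismatch Per-column substitution scores.
#' @param gap_open,gap_extend Non-negative gap penalties (subtracted).
#' @return An object of class `ltr_alignment`: a list with gapped strings
#'   `a` and `b` and the optimal `score`.
#' @examples
#' aln <- align_global("ACGT", "ACGA")
#' aln$score
#' @export
align_global <- function(a, b, match = 2, mismatch = -2,
                         gap_open = 6, gap_extend = 1) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L ||
      length(b) != 1L || !nzchar(a) || !nzchar(b)) {
    stop("align_global: both sequences must be non-empty strings")
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = .dna_score_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend
  )
  structure(
    list(
      a = as.character(Biostrings::alignedPattern(pa)),
      b = as.character(Biostrings::alignedSubject(pa)),
      score = BiocGenerics::score(pa)
    ),
    class = "ltr_alignment"
  )
}

#' @export
print.ltr_alignment <- function(x, ...) {
  cat("Global alignment (score ", x$score, ", ", nchar(x$a), " columns)\n",
      sep = "")
  invisible(x)
}

# Column classification shared by identity_metrics() and p_distance().
# Columns where either side is N are excluded entirely.
.alignment_columns <- function(alignment) {
  if (inherits(alignment, "ltr_alignment")) {
    a <- alignment$a
    b <- alignment$b
  } else if (is.character(alignment) && length(alignment) == 2L) {
    a <- alignment[[1L]]
    b <- alignment[[2L]]
  } else {
    stop("expected an ltr_alignment or a character vector of 2 aligned strings")
  }
  if (nchar(a) != nchar(b)) stop("aligned strings differ in length")
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  keep <- av != "N" & bv != "N"
  av <- av[keep]
  bv <- bv[keep]
  gap <- av == "-" | bv == "-"
  list(
    I = sum(!gap & av == bv),
    M = sum(!gap & av != bv),
    G = sum(gap)
  )
}
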