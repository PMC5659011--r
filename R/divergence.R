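# Sequence-divergence metrics: the two identity formulas (gaps excluded /
# included), Nei-Gojobori (1986) Ka/Ks, reciprocal-best-hit single-copy
# orthologs, and the ortholog identity distribution with its peak.

#' Identity metrics of a pairwise alignment
#'
#' Columns are classified as identical (I), mismatch (M) or gap (G; either
#' side gapped); columns containing N are excluded entirely. The two
#' reported percentages are `100 * I / (I + M)` (gaps excluded) and
#' `100 * I / (I + M + G)` (gaps included).
#'
#' @param alignment An `ltr_alignment` or character vector of two aligned
#'   strings.
#' @return An `identity_result` list: `I`, `M`, `G`,
#'   `identity_without_gaps`, `identity_with_gaps`.
#' @examples
#' identity_metrics(c("AC-GT", "ACTGT"))
#' @export
identity_metrics <- function(alignment) {
  cols <- .alignment_columns(alignment)
  if (cols$I + cols$M == 0L) {
    stop("identity_metrics: no aligned (non-gap) columns")
  }
  structure(
    list(I = cols$I, M = cols$M, G = cols$G,
         identity_without_gaps = 100 * cols$I / (cols$I + cols$M),
         identity_with_gaps = 100 * cols$I / (cols$I + cols$M + cols$G)),
    class = "identity_result"
  )
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("I=%d M=%d G=%d | identity %.2f%% (no gaps) %.2f%% (gaps)\n",
              x$I, x$M, x$G, x$identity_without_gaps, x$identity_with_gaps))
  invisible(x)
}

# --- Nei-Gojobori (1986) -----------------------------------------------------

# per-codon synonymous site count: at each position, the fraction of the
# three single-nucleotide changes that preserve the amino acid. Changes to
# stop codons count as nonsynonymous, keeping s + n = 3 per codon.
.codon_syn_sites <- function(codon) {
  v <- strsplit(codon, "", fixed = TRUE)[[1L]]
  aa <- translate_codon(codon)
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(DNA_BASES, v[pos])) {
      w <- v
      w[pos] <- alt
      alt_codon <- paste(w, collapse = "")
      if (translate_codon(alt_codon) == aa && !is_stop_codon(alt_codon)) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

# average synonymous/nonsynonymous differences between two codons over all
# orderings of the observed substitutions, skipping pathways that pass
# through stop codons (falling back to all pathways if every one is blocked)
.codon_path_diffs <- function(c1, c2) {
  v1 <- strsplit(c1, "", fixed = TRUE)[[1L]]
  v2 <- strsplit(c2, "", fixed = TRUE)[[1L]]
  diff_pos <- which(v1 != v2)
  nd <- length(diff_pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- .permutations(diff_pos)
  res <- matrix(NA_real_, nrow = length(perms), ncol = 2L)
  blocked <- logical(length(perms))
  for (pi in seq_along(perms)) {
    cur <- v1
    sd <- 0
    ndf <- 0
    for (pos in perms[[pi]]) {
      nxt <- cur
      nxt[pos] <- v2[pos]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      if (is_stop_codon(to) && !identical(nxt, v2)) blocked[pi] <- TRUE
      if (translate_codon(from) == translate_codon(to)) {
        sd <- sd + 1
      } else {
        ndf <- ndf + 1
      }
      cur <- nxt
    }
    res[pi, ] <- c(sd, ndf)
  }
  use <- if (all(blocked)) seq_along(perms) else which(!blocked)
  c(sd = mean(res[use, 1L]), nd = mean(res[use, 2L]))
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

#' Nei-Gojobori (1986) Ka/Ks between two aligned coding sequences
#'
#' Synonymous and nonsynonymous sites are counted per codon (averaged over
#' the two sequences); differences in codons carrying several substitutions
#' are averaged over all substitution pathways, skipping pathways through
#' stop codons; the synonymous and nonsynonymous proportions are then each
#' Jukes-Cantor corrected.
#'
#' @param cds_a,cds_b Gap-free coding sequences of equal length, divisible
#'   by 3, without internal stop codons (use [codon_align()] first when the
#'   raw CDSs differ in length).
#' @return A `kaks_result` list: `Ka`, `Ks`, `ratio` (NA with
#'   `ratio_defined = FALSE` when Ks = 0), plus the underlying site and
#'   difference counts `N`, `S`, `Nd`, `Sd`.
#' @export
ng86_kaks <- function(cds_a, cds_b) {
  la <- nchar(cds_a)
  if (la != nchar(cds_b)) stop("ng86_kaks: sequences differ in length")
  if (la %% 3L != 0L) stop("ng86_kaks: length not divisible by 3")
  codons_a <- substring(cds_a, seq(1L, la, 3L), seq(3L, la, 3L))
  codons_b <- substring(cds_b, seq(1L, la, 3L), seq(3L, la, 3L))
  if (any(vapply(codons_a, is_stop_codon, logical(1L))) ||
      any(vapply(codons_b, is_stop_codon, logical(1L)))) {
    stop("ng86_kaks: internal stop codon")
  }
  s_a <- sum(vapply(codons_a, .codon_syn_sites, numeric(1L)))
  s_b <- sum(vapply(codons_b, .codon_syn_sites, numeric(1L)))
  S <- (s_a + s_b) / 2
  N <- la - S
  Sd <- 0
  Nd <- 0
  for (i in seq_along(codons_a)) {
    d <- .codon_path_diffs(codons_a[i], codons_b[i])
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  if (ps >= 0.75 || pn >= 0.75) {
    stop("ng86_kaks: substitution proportion saturated (>= 3/4)")
  }
  Ks <- jukes_cantor(ps)
  Ka <- jukes_cantor(pn)
  structure(
    list(Ka = Ka, Ks = Ks,
         ratio = if (Ks > 0) Ka / Ks else NA_real_,
         ratio_defined = Ks > 0,
         N = N, S = S, Nd = Nd, Sd = Sd),
    class = "kaks_result"
  )
}

#' Codon-aware alignment of two coding sequences
#'
#' Aligns the translated peptides globally (BLOSUM62), back-maps the
#' alignment to nucleotides and drops gapped codon columns, returning two
#' gap-free, equal-length, frame-preserving CDSs suitable for [ng86_kaks()].
#'
#' @param cds_a,cds_b Coding sequences. Trailing incomplete codons are
#'   trimmed.
#' @param mask_stops Drop codon columns where either sequence carries a
#'   stop codon (degenerate retroelement ORFs accumulate in-frame stops;
#'   masking them is the standard preparation for Ka/Ks).
#' @return List with elements `a` and `b`.
#' @export
codon_align <- function(cds_a, cds_b, mask_stops = FALSE) {
  trim <- function(x) substr(x, 1L, nchar(x) - nchar(x) %% 3L)
  cds_a <- trim(cds_a)
  cds_b <- trim(cds_b)
  pep_a <- as.character(Biostrings::translate(Biostrings::DNAString(cds_a),
                                              if.fuzzy.codon = "X"))
  pep_b <- as.character(Biostrings::translate(Biostrings::DNAString(cds_b),
                                              if.fuzzy.codon = "X"))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pep_a), Biostrings::AAString(pep_b),
    type = "global", substitutionMatrix = .blosum62(),
    gapOpening = 11, gapExtension = 1
  )
  av <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  bv <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  ia <- 0L
  ib <- 0L
  keep_a <- integer(0L)
  keep_b <- integer(0L)
  for (col in seq_along(av)) {
    ga <- av[col] == "-"
    gb <- bv[col] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      keep_a <- c(keep_a, ia)
      keep_b <- c(keep_b, ib)
    }
  }
  codon_of <- function(cds, i) substr(cds, 3L * i - 2L, 3L * i)
  ca <- vapply(keep_a, function(i) codon_of(cds_a, i), character(1L))
  cb <- vapply(keep_b, function(i) codon_of(cds_b, i), character(1L))
  if (mask_stops && length(ca)) {
    ok <- !vapply(ca, is_stop_codon, logical(1L)) &
      !vapply(cb, is_stop_codon, logical(1L))
    ca <- ca[ok]
    cb <- cb[ok]
  }
  list(a = paste(ca, collapse = ""), b = paste(cb, collapse = ""))
}

# does a CDS contain an internal stop or a broken frame?
.cds_invalid <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L || n < 3L) return(TRUE)
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  internal <- codons[-length(codons)]
  any(vapply(internal, is_stop_codon, logical(1L)))
}

#' Reciprocal-best-hit single-copy orthologs
#'
#' Scores every cross-set pair by global alignment of the translated
#' peptides (BLOSUM62) and reports pair (a, b) iff b is a's unique
#' best-scoring partner and vice versa; genes with tied best scores are
#' excluded, as are sequences with frame errors or internal stop codons.
#'
#' @param cds_set_a,cds_set_b Named character vectors of CDSs.
#' @return data.frame with columns `a`, `b`, `score` (possibly empty).
#' @export
rbh_orthologs <- function(cds_set_a, cds_set_b) {
  if (length(cds_set_a) == 0L || length(cds_set_b) == 0L) {
    stop("rbh_orthologs: both sets must be non-empty")
  }
  ok_a <- !vapply(cds_set_a, .cds_invalid, logical(1L))
  ok_b <- !vapply(cds_set_b, .cds_invalid, logical(1L))
  cds_set_a <- cds_set_a[ok_a]
  cds_set_b <- cds_set_b[ok_b]
  empty <- data.frame(a = character(0L), b = character(0L),
                      score = numeric(0L), stringsAsFactors = FALSE)
  if (length(cds_set_a) == 0L || length(cds_set_b) == 0L) return(empty)
  pep <- function(x) as.character(
    Biostrings::translate(Biostrings::DNAString(x), if.fuzzy.codon = "X")
  )
  pa <- vapply(cds_set_a, pep, character(1L))
  pb <- vapply(cds_set_b, pep, character(1L))
  S <- matrix(NA_real_, length(pa), length(pb),
              dimnames = list(names(pa), names(pb)))
  for (i in seq_along(pa)) {
    for (j in seq_along(pb)) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(pa[[i]]), Biostrings::AAString(pb[[j]]),
        type = "global", substitutionMatrix = .blosum62(),
        gapOpening = 11, gapExtension = 1
      )
      S[i, j] <- BiocGenerics::score(al)
    }
  }
  unique_best <- function(v) {
    m <- max(v)
    w <- which(v == m)
    if (length(w) == 1L) w else NA_integer_
  }
  best_a <- apply(S, 1L, unique_best)   # for each a: its unique best b
  best_b <- apply(S, 2L, unique_best)   # for each b: its unique best a
  pairs <- empty
  for (i in seq_along(best_a)) {
    j <- best_a[i]
    if (!is.na(j) && !is.na(best_b[j]) && best_b[j] == i) {
      pairs <- rbind(pairs, data.frame(
        a = rownames(S)[i], b = colnames(S)[j], score = S[i, j],
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(pairs) <- NULL
  pairs
}

#' Histogram of percent identities with its peak
#'
#' Fixed-width bins anchored at 0, right-open; the peak is the midpoint of
#' the highest-count bin, ties broken toward the higher-identity bin.
#'
#' @param values Percent identities (>= 1 value).
#' @param bin_width Bin width in percent.
#' @return An `identity_distribution` list: `values`, `bin_width`,
#'   `histogram` (data.frame of `bin_start`, `bin_end`, `count`), `peak`.
#' @export
identity_distribution <- function(values, bin_width = 1) {
  if (length(values) == 0L) stop("identity_distribution: no values")
  stopifnot(bin_width > 0)
  bin <- floor(values / bin_width)
  tab <- table(bin)
  starts <- as.numeric(names(tab))
  counts <- as.integer(tab)
  best <- which(counts == max(counts))
  peak_bin <- max(starts[best])          # tie toward the higher-identity bin
  structure(
    list(values = values, bin_width = bin_width,
         histogram = data.frame(bin_start = starts * bin_width,
                                bin_end = (starts + 1) * bin_width,
                                count = counts),
         peak = (peak_bin + 0.5) * bin_width),
    class = "identity_distribution"
  )
}

#' @export
print.identity_distribution <- function(x, ...) {
  cat(sprintf("Identity distribution: n=%d, bin width %g%%, peak %.2f%%\n",
              length(x$values), x$bin_width, x$peak))
  invisible(x)
}
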