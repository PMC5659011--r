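# Family clustering (80/80 LTR rule) and superfamily classification from
# internal protein-domain order.

#' Group elements into families by the 80/80 LTR rule
#'
#' Two elements are linked when a global alignment of their 5' LTRs shows
#' identity (gaps excluded) strictly above `identity_threshold` percent over
#' an aligned (non-gap) span covering at least `coverage_threshold` percent
#' of the shorter LTR. Families are the single-linkage (transitive closure)
#' clusters of this relation; single linkage is used because the rule is a
#' pairwise criterion, and the 5' LTR is used for determinism.
#'
#' @param ltr_seqs Named character vector of 5' LTR sequences (names are
#'   element ids).
#' @param identity_threshold Percent identity an edge must exceed.
#' @param coverage_threshold Minimum aligned coverage of the shorter LTR,
#'   percent.
#' @return List of `family` objects, each with `family_id`, `members`
#'   (element ids) and `representative` (id of the longest member LTR);
#'   families are ordered by first member appearance.
#' @export
cluster_families <- function(ltr_seqs, identity_threshold = 80,
                             coverage_threshold = 80) {
  n <- length(ltr_seqs)
  if (n == 0L) stop("cluster_families: no elements supplied")
  ids <- names(ltr_seqs)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("cluster_families: ltr_seqs must carry unique names")
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (ltr_pair_linked(ltr_seqs[[i]], ltr_seqs[[j]],
                            identity_threshold, coverage_threshold)) {
          ri <- find(i)
          rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  fams <- list()
  for (r in unique(roots)) {
    members <- ids[roots == r]
    rep_id <- members[which.max(nchar(ltr_seqs[members]))]
    fams[[length(fams) + 1L]] <- structure(
      list(family_id = sprintf("FAM%02d", length(fams) + 1L),
           members = members, representative = rep_id),
      class = "ltr_family"
    )
  }
  fams
}

#' Does one LTR pair satisfy the 80/80 edge criterion?
#'
#' @inheritParams cluster_families
#' @param a,b LTR sequences.
#' @return TRUE when identity (gaps excluded) > `identity_threshold` and the
#'   aligned non-gap span covers >= `coverage_threshold` percent of the
#'   shorter sequence.
#' @export
ltr_pair_linked <- function(a, b, identity_threshold = 80,
                            coverage_threshold = 80) {
  aln <- align_global(a, b)
  m <- identity_metrics(aln)
  aligned <- m$I + m$M
  aligned >= coverage_threshold / 100 * min(nchar(a), nchar(b)) &&
    m$identity_without_gaps > identity_threshold
}

#' Detect protein domains in an internal region
#'
#' Translates all six frames and locally aligns each packaged consensus
#' peptide (see [ltr_domain_peptides()]) against every frame with BLOSUM62
#' affine-gap scoring. At most the single best-scoring hit per domain is
#' reported, and only above `min_score`.
#'
#' @param internal Nucleotide string (internal region or whole element).
#' @param domain_library Named character vector of consensus peptides.
#' @param min_score Minimum Smith-Waterman score for a call. The default is
#'   set far above the empirical null of random sequence (max local scores
#'   of ~40) and far below a true embedded-domain self-score (>= 200).
#' @param gap_open,gap_extend Affine gap penalties for the peptide
#'   alignment.
#' @return data.frame of hits sorted by nucleotide start: `name`, `frame`
#'   (0-2 forward, 3-5 reverse), `start`, `end` (0-based half-open,
#'   nucleotide coordinates on the input), `score`, `pident`.
#' @export
detect_domains <- function(internal, domain_library = ltr_domain_peptides(),
                           min_score = 100, gap_open = 11, gap_extend = 1) {
  if (!nzchar(internal)) stop("detect_domains: empty sequence")
  frames <- translate_frames(internal)
  n <- nchar(internal)
  hits <- list()
  for (dom in names(domain_library)) {
    pep <- Biostrings::AAString(domain_library[[dom]])
    best <- NULL
    for (fi in seq_along(frames)) {
      aa <- frames[[fi]]
      if (!nzchar(aa)) next
      pa <- Biostrings::pairwiseAlignment(
        pep, Biostrings::AAString(aa), type = "local",
        substitutionMatrix = .blosum62(),
        gapOpening = gap_open, gapExtension = gap_extend
      )
      sc <- BiocGenerics::score(pa)
      if (sc < min_score) next
      if (is.null(best) || sc > best$score) {
        sub <- pa@subject@range            # 1-based aa span on the frame
        aa_start <- BiocGenerics::start(sub)
        aa_end <- BiocGenerics::end(sub)
        off <- (fi - 1L) %% 3L             # frame offset within its strand
        nt_start <- off + 3L * (aa_start - 1L)
        nt_end <- off + 3L * aa_end
        if (fi > 3L) {                     # reverse strand: map back
          tmp <- n - nt_end
          nt_end <- n - nt_start
          nt_start <- tmp
        }
        pid <- 100 * Biostrings::nmatch(pa) /
          (Biostrings::nmatch(pa) + Biostrings::nmismatch(pa))
        best <- list(name = dom, frame = fi - 1L, start = nt_start,
                     end = nt_end, score = sc, pident = pid)
      }
    }
    if (!is.null(best)) hits[[length(hits) + 1L]] <- best
  }
  if (length(hits) == 0L) {
    return(data.frame(name = character(0L), frame = integer(0L),
                      start = integer(0L), end = integer(0L),
                      score = numeric(0L), pident = numeric(0L),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(hits, as.data.frame,
                               stringsAsFactors = FALSE))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call the superfamily of an element from its domain hits
#'
#' The relative order of integrase (INT) and reverse transcriptase (RT)
#' along the internal region distinguishes the two autonomous superfamilies
#' (INT before RT: Copia; RT before INT: Gypsy). Elements with neither
#' domain and a short internal region are non-autonomous TRIM elements.
#'
#' @param hits data.frame from [detect_domains()].
#' @param internal_length Internal-region length in bp.
#' @param trim_max_internal Maximum internal length for a TRIM call.
#' @return One of `"Copia"`, `"Gypsy"`, `"TRIM"`, `"unknown"`.
#' @export
classify_superfamily <- function(hits, internal_length,
                                 trim_max_internal = 3000L) {
  has_int <- "INT" %in% hits$name
  has_rt <- "RT" %in% hits$name
  if (has_int && has_rt) {
    int_start <- hits$start[hits$name == "INT"][1L]
    rt_start <- hits$start[hits$name == "RT"][1L]
    if (int_start < rt_start) return("Copia")
    if (rt_start < int_start) return("Gypsy")
    return("unknown")
  }
  if (!has_int && !has_rt) {
    if (internal_length <= trim_max_internal) return("TRIM")
    return("unknown")
  }
  "unknown"
}
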