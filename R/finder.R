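# Structural finder for intact LTR retrotransposons.
#
# Strategy: exact k-mer self-matching within a distance window, anchor
# chaining by diagonal, mismatch-tolerant extension of the repeat, then an
# exhaustive local search for the boundary pair at which a listed terminal
# dinucleotide motif and a valid TSD co-occur (codifying the manual
# inspection step of structural annotation). Fragments, solo LTRs and
# nested/truncated elements are never reported.

#' Parameters for the structural LTR-RT finder
#'
#' Length defaults are generous bounds around the observed non-canonical
#' element families (LTRs 152-266 bp, elements 2129-5114 bp).
#'
#' @param min_ltr,max_ltr LTR length bounds in bp.
#' @param min_element,max_element Whole-element length bounds in bp.
#' @param anchor_k Exact k-mer size used for self-matching (>= 8).
#' @param min_ltr_pair_identity Minimum percent identity of a global
#'   alignment of the two LTRs (gaps excluded) for a candidate to be kept.
#' @param tsd_min,tsd_max TSD length bounds in bp.
#' @param tsd_max_mismatch Mismatches tolerated between the two TSD copies.
#' @param motif_list List of `c(start, end)` terminal dinucleotide pairs
#'   considered named motifs.
#' @return A `finder_params` list.
#' @export
finder_params <- function(min_ltr = 100L, max_ltr = 3000L,
                          min_element = 1000L, max_element = 20000L,
                          anchor_k = 15L, min_ltr_pair_identity = 85,
                          tsd_min = 4L, tsd_max = 6L, tsd_max_mismatch = 1L,
                          motif_list = list(c("TG", "CA"), c("TG", "TT"),
                                            c("AA", "CA"))) {
  stopifnot(min_ltr < max_ltr, min_element < max_element,
            tsd_min <= tsd_max, anchor_k >= 8L)
  structure(
    list(min_ltr = as.integer(min_ltr), max_ltr = as.integer(max_ltr),
         min_element = as.integer(min_element),
         max_element = as.integer(max_element),
         anchor_k = as.integer(anchor_k),
         min_ltr_pair_identity = min_ltr_pair_identity,
         tsd_min = as.integer(tsd_min), tsd_max = as.integer(tsd_max),
         tsd_max_mismatch = as.integer(tsd_max_mismatch),
         motif_list = motif_list),
    class = "finder_params"
  )
}

# empty ElementRecord table (0-based half-open spans; plus-strand coords)
.empty_elements <- function() {
  data.frame(
    element_id = character(0L), contig = character(0L),
    strand = character(0L), start = integer(0L), end = integer(0L),
    ltr5_start = integer(0L), ltr5_end = integer(0L),
    ltr3_start = integer(0L), ltr3_end = integer(0L),
    ltr_identity = numeric(0L),
    start_dinuc = character(0L), end_dinuc = character(0L),
    motif_label = character(0L),
    tsd_left = character(0L), tsd_right = character(0L),
    tsd_len = integer(0L), tsd_mismatch = integer(0L),
    tsd_status = character(0L),
    stringsAsFactors = FALSE
  )
}

# integer encoding of a contig: A,C,G,T -> 0..3, anything else NA
.encode_dna <- function(contig) {
  map <- rep(NA_integer_, 128L)
  map[utf8ToInt("A")] <- 0L
  map[utf8ToInt("C")] <- 1L
  map[utf8ToInt("G")] <- 2L
  map[utf8ToInt("T")] <- 3L
  map[utf8ToInt(contig)]
}

# rolling k-mer codes (base-4, exact, fits in a double for k <= 26)
.kmer_codes <- function(base, k) {
  n <- length(base)
  m <- n - k + 1L
  if (m < 1L) return(numeric(0L))
  code <- numeric(m)
  for (j in 0:(k - 1L)) {
    code <- code + base[(1L + j):(m + j)] * 4^(k - 1L - j)
  }
  code
}

#' Discover intact LTR-RT candidates in a contig
#'
#' Returns candidate records whose two LTR spans align globally with
#' identity at or above `min_ltr_pair_identity` and whose spans satisfy all
#' length bounds. TSD and motif fields are left unset; see [validate_tsd()]
#' and [check_terminal_motif()]. Overlapping candidates are resolved by
#' keeping the higher-identity (then longer) one. Direct-repeat detection is
#' strand-symmetric, so both strands are covered by a single plus-strand
#' scan and coordinates are always reported on the plus strand.
#'
#' @param contig Nucleotide string.
#' @param params A [finder_params()] object.
#' @param contig_id Id recorded in the output.
#' @return data.frame of element records ordered by start (possibly empty).
#' @export
find_ltr_candidates <- function(contig, params = finder_params(),
                                contig_id = "contig1") {
  stopifnot(inherits(params, "finder_params"))
  if (!is.character(contig) || length(contig) != 1L || !nzchar(contig)) {
    stop("find_ltr_candidates: contig must be a non-empty string")
  }
  k <- params$anchor_k
  n <- nchar(contig)
  out <- .empty_elements()
  if (n < params$min_element) return(out)

  base <- .encode_dna(contig)
  code <- .kmer_codes(base, k)
  pos <- which(!is.na(code)) - 1L          # 0-based k-mer starts
  code <- code[pos + 1L]

  # anchor pairs: identical k-mers whose separation is compatible with the
  # distance D between the two LTR starts of one element
  d_min <- params$min_ltr
  d_max <- params$max_element - params$min_ltr
  ord0 <- order(code, pos)
  cs <- code[ord0]
  ps <- pos[ord0]
  grp_start <- which(c(TRUE, cs[-1L] != cs[-length(cs)]))
  grp_len <- diff(c(grp_start, length(cs) + 1L))
  dup <- which(grp_len >= 2L & grp_len <= 100L)
  if (length(dup) == 0L) return(out)
  pair_i <- vector("list", length(dup))
  pair_j <- vector("list", length(dup))
  for (g in seq_along(dup)) {
    s0 <- grp_start[dup[g]]
    p <- ps[s0:(s0 + grp_len[dup[g]] - 1L)]
    cmb <- utils::combn(p, 2L)
    pair_i[[g]] <- cmb[1L, ]
    pair_j[[g]] <- cmb[2L, ]
  }
  ai <- unlist(pair_i, use.names = FALSE)
  aj <- unlist(pair_j, use.names = FALSE)
  d <- aj - ai
  keep <- d >= d_min & d <= d_max
  ai <- ai[keep]
  d <- d[keep]
  if (length(ai) == 0L) return(out)

  # chain anchors into clusters by (diagonal, position)
  ord <- order(d, ai)
  ai <- ai[ord]
  d <- d[ord]
  cl <- integer(length(ai))
  cur <- 1L
  cl[1L] <- 1L
  if (length(ai) > 1L) {
    for (t in 2:length(ai)) {
      if (d[t] - d[t - 1L] > 20L ||
          abs(ai[t] - ai[t - 1L]) > params$max_ltr) {
        cur <- cur + 1L
      }
      cl[t] <- cur
    }
  }

  sv <- strsplit(contig, "", fixed = TRUE)[[1L]]
  cands <- list()
  for (cid in unique(cl)) {
    idx <- which(cl == cid)
    D <- as.integer(round(stats::median(d[idx])))
    i_min <- min(ai[idx])
    i_max <- max(ai[idx]) + k            # one-past-end of last anchor
    ref <- .refine_candidate(sv, n, D, i_min, i_max, params)
    if (!is.null(ref)) cands[[length(cands) + 1L]] <- ref
  }
  if (length(cands) == 0L) return(out)

  rec <- do.call(rbind, lapply(cands, function(z) {
    data.frame(
      element_id = NA_character_, contig = contig_id, strand = "+",
      start = z$start, end = z$end,
      ltr5_start = z$start, ltr5_end = z$start + z$ltr_len,
      ltr3_start = z$end - z$ltr_len, ltr3_end = z$end,
      ltr_identity = z$identity,
      start_dinuc = NA_character_, end_dinuc = NA_character_,
      motif_label = NA_character_,
      tsd_left = NA_character_, tsd_right = NA_character_,
      tsd_len = NA_integer_, tsd_mismatch = NA_integer_,
      tsd_status = NA_character_,
      stringsAsFactors = FALSE
    )
  }))
  rec <- rec[order(rec$start, rec$end), , drop = FALSE]

  # overlap resolution: higher identity wins, ties broken by longer element
  keep <- rep(TRUE, nrow(rec))
  for (p in seq_len(nrow(rec))) {
    if (!keep[p]) next
    for (q in seq_len(nrow(rec))) {
      if (q == p || !keep[q]) next
      if (rec$start[p] < rec$end[q] && rec$start[q] < rec$end[p]) {
        lp <- rec$end[p] - rec$start[p]
        lq <- rec$end[q] - rec$start[q]
        drop_q <- rec$ltr_identity[q] < rec$ltr_identity[p] ||
          (rec$ltr_identity[q] == rec$ltr_identity[p] && lq < lp) ||
          (rec$ltr_identity[q] == rec$ltr_identity[p] && lq == lp && q > p)
        if (drop_q) keep[q] <- FALSE else keep[p] <- FALSE
        if (!keep[p]) break
      }
    }
  }
  rec <- rec[keep, , drop = FALSE]
  rec$element_id <- sprintf("%s_e%02d", contig_id, seq_len(nrow(rec)))
  rownames(rec) <- NULL
  rec
}

# Extend an anchor cluster into an approximate repeat, then search the
# neighbourhood of its boundaries for the (element start, element end) pair
# at which a listed terminal motif and a valid TSD co-occur. Returns NULL
# when nothing passes the length or identity gates.
.refine_candidate <- function(sv, n, D, i_min, i_max, params) {
  xdrop <- 30L
  # X-drop extension of the repeat (comparing x against x + D, 0-based):
  # +1 per matching column, -1 per mismatch; the boundary estimate is the
  # argmax of the running score, abandoning once it falls xdrop below it
  x <- i_min
  s <- 0L
  best <- 0L
  a_apx <- i_min
  while (x - 1L >= 0L && (x - 1L + D) < n) {
    x <- x - 1L
    s <- s + (if (sv[x + 1L] == sv[x + D + 1L]) 1L else -1L)
    if (s > best) {
      best <- s
      a_apx <- x
    } else if (s < best - xdrop) {
      break
    }
  }
  # rightward extension (y is one-past-end of the 5' copy)
  y <- i_max
  s <- 0L
  best <- 0L
  e5_apx <- i_max
  while (y + D + 1L <= n && y + 1L <= n) {
    s <- s + (if (sv[y + 1L] == sv[y + D + 1L]) 1L else -1L)
    if (s > best) {
      best <- s
      e5_apx <- y + 1L
    } else if (s < best - xdrop) {
      break
    }
    y <- y + 1L
  }
  L_apx <- e5_apx - a_apx
  if (L_apx < params$min_ltr - 10L || L_apx > params$max_ltr + 10L) {
    return(NULL)
  }

  slack <- 25L
  best <- NULL
  a_lo <- max(0L, a_apx - slack)
  a_hi <- min(a_apx + slack, n - 1L)
  e_ctr <- a_apx + D + L_apx
  for (a in a_lo:a_hi) {
    e_lo <- max(a + params$min_element, e_ctr - slack)
    e_hi <- min(n, e_ctr + slack, a + params$max_element)
    if (e_lo > e_hi) next
    for (e in e_lo:e_hi) {
      L <- e - a - D
      if (L < params$min_ltr || L > params$max_ltr || L > D) next
      tsd <- .tsd_at(sv, n, a, e, params)
      if (is.null(tsd)) next
      # terminal dinucleotides of both LTRs, plus-strand reading
      s5 <- paste0(sv[a + 1L], sv[a + 2L])
      s3 <- paste0(sv[a + D + 1L], sv[a + D + 2L])
      e5 <- paste0(sv[a + L - 1L], sv[a + L])
      e3 <- paste0(sv[e - 1L], sv[e])
      consistent <- (s5 == s3) && (e5 == e3)
      motif_ok <- consistent && .motif_listed(s5, e3, params$motif_list)
      # ungapped LTR match score (+1 match, -1 mismatch): maximal at the
      # true repeat extent, penalising both outward junk and inward trims
      mscore <- sum((sv[(a + 1L):(a + L)] ==
                       sv[(a + D + 1L):(a + D + L)]) * 2L - 1L)
      cand <- list(start = a, end = e, ltr_len = L,
                   score = .boundary_score(mscore, motif_ok, tsd, params),
                   drift = abs(a - a_apx) + abs(e - e_ctr))
      if (is.null(best) || .cand_better(cand, best)) best <- cand
    }
  }
  if (is.null(best)) {
    # no TSD-consistent boundary: fall back to the extension estimate (the
    # record will normally be rejected downstream by validate_tsd)
    a <- a_apx
    e <- a_apx + D + L_apx
    L <- L_apx
    if (L > D || e > n || L < params$min_ltr || L > params$max_ltr ||
        (e - a) < params$min_element || (e - a) > params$max_element) {
      return(NULL)
    }
    best <- list(start = a, end = e, ltr_len = L)
  }
  ltr5 <- paste(sv[(best$start + 1L):(best$start + best$ltr_len)],
                collapse = "")
  ltr3 <- paste(sv[(best$end - best$ltr_len + 1L):best$end], collapse = "")
  aln <- align_global(ltr5, ltr3)
  id <- identity_metrics(aln)$identity_without_gaps
  if (id < params$min_ltr_pair_identity) return(NULL)
  list(start = best$start, end = best$end, ltr_len = best$ltr_len,
       identity = id)
}

# longest qualifying TSD at boundaries (a, e); NULL when none qualifies
.tsd_at <- function(sv, n, a, e, params) {
  for (t in params$tsd_max:params$tsd_min) {
    if (a - t < 0L || e + t > n) next
    left <- sv[(a - t + 1L):a]
    right <- sv[(e + 1L):(e + t)]
    mm <- sum(left != right)
    if (mm <= params$tsd_max_mismatch) {
      return(list(left = paste(left, collapse = ""),
                  right = paste(right, collapse = ""),
                  len = t, mismatch = mm))
    }
  }
  NULL
}

# is the (start, end) dinucleotide pair a listed motif on either strand?
.motif_listed <- function(start_dinuc, end_dinuc, motif_list) {
  minus_start <- revcomp(end_dinuc)
  minus_end <- revcomp(start_dinuc)
  for (m in motif_list) {
    if ((m[1L] == start_dinuc && m[2L] == end_dinuc) ||
        (m[1L] == minus_start && m[2L] == minus_end)) {
      return(TRUE)
    }
  }
  FALSE
}

# Additive boundary evidence score. The ungapped LTR match score (+1
# match, -1 mismatch) is maximal at the true repeat extent and penalises
# both outward junk and inward trimming; a listed terminal-motif pair and
# a longer or more exact TSD each add a bonus on the same scale as a few
# matching columns (their approximate log-odds against chance). A strict
# lexicographic preference ("outermost first", or motif above the match
# score) is brittle: spurious short TSDs in the flanks, or chance in-repeat
# motif readings, can then out-rank the true boundary.
.boundary_score <- function(mscore, motif_ok, tsd, params) {
  mscore + 6L * motif_ok + 2L * (tsd$len - params$tsd_min) -
    8L * tsd$mismatch
}

# ordering: evidence score, then proximity to the extension estimate
.cand_better <- function(cand, best) {
  if (cand$score != best$score) return(cand$score > best$score)
  if (cand$drift != best$drift) return(cand$drift < best$drift)
  FALSE
}

#' Validate the target site duplication of a candidate element
#'
#' Window lengths from `tsd_max` down to `tsd_min` are examined; the longest
#' length whose left flank (immediately 5' of the element) matches the right
#' flank (immediately 3') with at most `tsd_max_mismatch` mismatches is
#' accepted. A candidate too close to the contig edge is rejected with
#' status `"edge"`; one with no qualifying window with status `"none"`.
#'
#' @param contig Nucleotide string the record refers to.
#' @param record One-row element record data.frame.
#' @param params A [finder_params()] object.
#' @return The record with `tsd_left`, `tsd_right`, `tsd_len`,
#'   `tsd_mismatch` and `tsd_status` (`"ok"`, `"none"` or `"edge"`) filled.
#' @export
validate_tsd <- function(contig, record, params = finder_params()) {
  stopifnot(nrow(record) == 1L)
  n <- nchar(contig)
  a <- record$start
  e <- record$end
  if (a - params$tsd_max < 0L || e + params$tsd_max > n) {
    record$tsd_status <- "edge"
    return(record)
  }
  sv <- strsplit(contig, "", fixed = TRUE)[[1L]]
  tsd <- .tsd_at(sv, n, a, e, params)
  if (is.null(tsd)) {
    record$tsd_status <- "none"
  } else {
    record$tsd_left <- tsd$left
    record$tsd_right <- tsd$right
    record$tsd_len <- tsd$len
    record$tsd_mismatch <- tsd$mismatch
    record$tsd_status <- "ok"
  }
  record
}

#' Label the terminal dinucleotide motif of a candidate element
#'
#' Reads the first two bases of each LTR and the last two bases of each LTR.
#' Both LTRs must show identical terminal dinucleotides for a named label;
#' otherwise the label is `"inconsistent"`. A consistent pair present in
#' `motif_list` is labelled by concatenation (e.g. `"TGTT"`) on the plus
#' strand; a pair whose reverse-complement reading is listed is labelled by
#' that reading with strand `"-"`; anything else is `"other"`.
#'
#' @param contig Nucleotide string.
#' @param record One-row element record.
#' @param motif_list List of `c(start, end)` dinucleotide pairs.
#' @return The record with `start_dinuc`, `end_dinuc`, `motif_label` and
#'   `strand` filled.
#' @export
check_terminal_motif <- function(contig, record,
                                 motif_list = finder_params()$motif_list) {
  stopifnot(nrow(record) == 1L)
  s5 <- substr0(contig, record$ltr5_start, record$ltr5_start + 2L)
  s3 <- substr0(contig, record$ltr3_start, record$ltr3_start + 2L)
  e5 <- substr0(contig, record$ltr5_end - 2L, record$ltr5_end)
  e3 <- substr0(contig, record$ltr3_end - 2L, record$ltr3_end)
  record$start_dinuc <- s5
  record$end_dinuc <- e3
  if (s5 != s3 || e5 != e3) {
    record$motif_label <- "inconsistent"
    return(record)
  }
  plus_listed <- any(vapply(motif_list,
                            function(m) m[1L] == s5 && m[2L] == e3,
                            logical(1L)))
  if (plus_listed) {
    record$motif_label <- paste0(s5, e3)
    record$strand <- "+"
    return(record)
  }
  ms <- revcomp(e3)
  me <- revcomp(s5)
  minus_listed <- any(vapply(motif_list,
                             function(m) m[1L] == ms && m[2L] == me,
                             logical(1L)))
  if (minus_listed) {
    record$motif_label <- paste0(ms, me)
    record$strand <- "-"
    return(record)
  }
  record$motif_label <- "other"
  record
}

#' Full structural annotation of a contig set
#'
#' Runs candidate discovery, TSD validation (dropping rejected candidates)
#' and motif labelling over every contig.
#'
#' @param contigs Named character vector of contigs.
#' @param params A [finder_params()] object.
#' @return Combined element record data.frame.
#' @export
find_elements <- function(contigs, params = finder_params()) {
  stopifnot(length(names(contigs)) == length(contigs))
  res <- lapply(names(contigs), function(id) {
    rec <- find_ltr_candidates(contigs[[id]], params, contig_id = id)
    if (nrow(rec) == 0L) return(rec)
    rows <- lapply(seq_len(nrow(rec)), function(i) {
      r <- validate_tsd(contigs[[id]], rec[i, , drop = FALSE], params)
      if (r$tsd_status != "ok") return(NULL)
      check_terminal_motif(contigs[[id]], r, params$motif_list)
    })
    rows <- rows[!vapply(rows, is.null, logical(1L))]
    if (length(rows) == 0L) return(.empty_elements())
    do.call(rbind, rows)
  })
  out <- do.call(rbind, c(res, list(.empty_elements())))
  rownames(out) <- NULL
  out
}
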