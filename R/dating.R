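# Insertion-time dating from LTR-LTR divergence.
#
# The two LTRs of an element are identical at insertion and accumulate
# substitutions independently afterwards, so the Jukes-Cantor corrected
# divergence K between them converts to an insertion time T = K / (2 r)
# given a substitution rate r per site per year.

#' Proportion of differing aligned sites
#'
#' Gap columns and columns containing N are excluded from both numerator
#' and denominator, so p reflects substitutions only.
#'
#' @param alignment An `ltr_alignment` (or character vector of two aligned
#'   strings).
#' @return p in \[0, 1\].
#' @export
p_distance <- function(alignment) {
  cols <- .alignment_columns(alignment)
  usable <- cols$I + cols$M
  if (usable == 0L) stop("p_distance: no usable (non-gap, non-N) columns")
  cols$M / usable
}

#' Jukes-Cantor correction of an observed divergence
#'
#' K = -(3/4) log(1 - 4p/3), the expected number of substitutions per site
#' under the one-parameter model, correcting p for multiple hits.
#'
#' @param p Observed proportion of differing sites, 0 <= p < 0.75.
#' @return K >= p.
#' @examples
#' jukes_cantor(0.1)
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0)) stop("jukes_cantor: p must be non-negative")
  if (any(p >= 0.75)) {
    stop("jukes_cantor: p >= 0.75 is saturated under the JC model")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Convert a corrected divergence into an insertion time
#'
#' T = K / (2 r). The default rate r = 1.3e-8 substitutions per site per
#' year is the average LTR substitution rate commonly applied to plant
#' retrotransposons.
#'
#' @param K Substitutions per site (>= 0).
#' @param r Rate per site per year (> 0).
#' @return Time in years.
#' @examples
#' insertion_time(0.026)  # 1 My at the default rate
#' @export
insertion_time <- function(K, r = 1.3e-8) {
  if (any(K < 0)) stop("insertion_time: K must be non-negative")
  if (!is.numeric(r) || r <= 0) stop("insertion_time: r must be positive")
  K / (2 * r)
}

#' Date every element of a record table
#'
#' Extracts both LTR spans from their contigs, aligns them globally,
#' computes p, K and T per element. Elements with p = 0 are flagged as
#' having identical LTRs (T = 0).
#'
#' @param elements Element record data.frame (from [find_elements()]).
#' @param contigs Named character vector of contigs.
#' @param r Substitution rate per site per year.
#' @return data.frame with `element_id`, `p`, `K`, `T_years`,
#'   `identical_ltrs`.
#' @export
estimate_ages <- function(elements, contigs, r = 1.3e-8) {
  if (nrow(elements) == 0L) {
    return(data.frame(element_id = character(0L), p = numeric(0L),
                      K = numeric(0L), T_years = numeric(0L),
                      identical_ltrs = logical(0L), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(elements)), function(i) {
    rec <- elements[i, ]
    s <- contigs[[rec$contig]]
    ltr5 <- substr0(s, rec$ltr5_start, rec$ltr5_end)
    ltr3 <- substr0(s, rec$ltr3_start, rec$ltr3_end)
    p <- p_distance(align_global(ltr5, ltr3))
    K <- jukes_cantor(p)
    data.frame(element_id = rec$element_id, p = p, K = K,
               T_years = insertion_time(K, r),
               identical_ltrs = p == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize insertion ages by activity class
#'
#' Ages are binned into three classes: younger than 1 Mya, 1-3 Mya
#' (inclusive at both ends), and older than 3 Mya. Percentages are rounded
#' half-up to two decimals. The identical-LTR share is computed over all
#' estimates.
#'
#' @param ages data.frame from [estimate_ages()] (needs `T_years` and
#'   `identical_ltrs`); a numeric vector of ages in years is also accepted
#'   (then `identical_ltrs` defaults to `T_years == 0`).
#' @param family Optional character vector of family labels (same length)
#'   for a per-family mean-age roll-up.
#' @return An `age_summary` list: `n_total`, `counts`, `percentages` (named
#'   `lt1`, `from1to3`, `gt3`), `n_identical_ltr`, `pct_identical_ltr`, and
#'   optionally `family_mean_my`.
#' @examples
#' s <- summarize_ages(c(rep(0.5e6, 65), rep(2e6, 21), rep(4e6, 5)))
#' s$percentages  # 71.43 23.08 5.49
#' @export
summarize_ages <- function(ages, family = NULL) {
  if (is.numeric(ages)) {
    ages <- data.frame(T_years = ages, identical_ltrs = ages == 0)
  }
  n <- nrow(ages)
  if (n == 0L) stop("summarize_ages: no age estimates supplied")
  my <- ages$T_years / 1e6
  counts <- c(lt1 = sum(my < 1), from1to3 = sum(my >= 1 & my <= 3),
              gt3 = sum(my > 3))
  stopifnot(sum(counts) == n)
  out <- list(
    n_total = n,
    counts = counts,
    percentages = round_half_up(100 * counts / n, 2L),
    n_identical_ltr = sum(ages$identical_ltrs),
    pct_identical_ltr = round_half_up(100 * sum(ages$identical_ltrs) / n, 2L)
  )
  if (!is.null(family)) {
    stopifnot(length(family) == n)
    out$family_mean_my <- c(tapply(my, family, mean))
  }
  structure(out, class = "age_summary")
}

#' @export
print.age_summary <- function(x, ...) {
  cat("Insertion-age summary over", x$n_total, "elements\n")
  cat(sprintf("  <1 Mya : %3d (%6.2f%%)\n", x$counts["lt1"],
              x$percentages["lt1"]))
  cat(sprintf("  1-3 Mya: %3d (%6.2f%%)\n", x$counts["from1to3"],
              x$percentages["from1to3"]))
  cat(sprintf("  >3 Mya : %3d (%6.2f%%)\n", x$counts["gt3"],
              x$percentages["gt3"]))
  cat(sprintf("  identical LTRs: %d (%.2f%%)\n", x$n_identical_ltr,
              x$pct_identical_ltr))
  invisible(x)
}
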