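# Synthetic-genome module: plants aged LTR retrotransposons with full ground
# truth, and simulates single-copy ortholog CDS pairs, so every downstream
# stage is testable without external genome assemblies.

#' Generate a random background contig
#'
#' Bases are drawn i.i.d. with P(G) + P(C) = `gc`, split evenly within the
#' GC and AT pairs.
#'
#' @param length Contig length in bp (> 0).
#' @param gc GC fraction in \[0, 1\].
#' @param seed Integer seed; the same seed yields a byte-identical contig.
#' @return A single nucleotide string.
#' @examples
#' nchar(generate_background(1000, 0.4, 1))
#' @export
generate_background <- function(length, gc = 0.4, seed = 1L) {
  if (!is.numeric(length) || length(length) != 1L || length <= 0) {
    stop("generate_background: length must be a positive number")
  }
  if (!is.numeric(gc) || gc < 0 || gc > 1) {
    stop("generate_background: gc must lie in [0, 1]")
  }
  with_seed(seed, random_dna(as.integer(length), gc))
}

#' Specify the structure of a synthetic LTR retrotransposon
#'
#' @param ltr_length LTR length in bp (>= 50).
#' @param internal_length Internal-region length in bp (>= 0).
#' @param start_dinuc,end_dinuc Two-letter terminal dinucleotides over ACGT
#'   (the 5' LTR starts with `start_dinuc`, both LTRs end with `end_dinuc`).
#' @param tsd_length Target-site-duplication length, 4-6 bp.
#' @param domain_order Character vector drawn from GAG, PR, INT, RT, RH
#'   giving the order of coding domains embedded in the internal region;
#'   may be empty (TRIM-like) only when `internal_length > 0`.
#' @param family_label Free-text family label carried into the truth record.
#' @return An `element_spec` list.
#' @export
element_spec <- function(ltr_length = 180L, internal_length = 4693L,
                         start_dinuc = "TG", end_dinuc = "TT",
                         tsd_length = 5L,
                         domain_order = c("GAG", "PR", "INT", "RT", "RH"),
                         family_label = "FAM1") {
  stopifnot(ltr_length >= 50L, internal_length >= 0L,
            tsd_length >= 4L, tsd_length <= 6L)
  for (d in c(start_dinuc, end_dinuc)) {
    if (nchar(d) != 2L || grepl("[^ACGT]", d)) {
      stop("element_spec: terminal dinucleotides must be 2 letters over ACGT")
    }
  }
  domain_order <- as.character(domain_order)
  bad <- setdiff(domain_order, names(.DOMAIN_PEPTIDES))
  if (length(bad)) stop("element_spec: unknown domain(s): ",
                        paste(bad, collapse = ", "))
  if (length(domain_order) == 0L && internal_length == 0L) {
    stop("element_spec: empty domain_order requires internal_length > 0")
  }
  structure(
    list(ltr_length = as.integer(ltr_length),
         internal_length = as.integer(internal_length),
         start_dinuc = start_dinuc, end_dinuc = end_dinuc,
         tsd_length = as.integer(tsd_length),
         domain_order = domain_order, family_label = family_label),
    class = "element_spec"
  )
}

#' Build a fresh (zero-age) synthetic element
#'
#' The sequence is LTR + internal + LTR with the two LTRs byte-identical,
#' as at the moment of insertion. Domain consensus peptides are
#' back-translated and embedded in the internal region in the order given,
#' separated by evenly sized random spacers.
#'
#' @param spec An [element_spec()].
#' @param seed Integer seed.
#' @return An `ltr_element` list with fields `seq`, `ltr_length`,
#'   `internal_length`, `spec`, and `domains` (a data.frame of embedded
#'   domain spans, 0-based half-open, relative to the internal region).
#' @export
build_element <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "element_spec"))
  dom_nt <- vapply(spec$domain_order,
                   function(d) back_translate(.DOMAIN_PEPTIDES[[d]]),
                   character(1L))
  total_dom <- sum(nchar(dom_nt))
  if (spec$internal_length < total_dom) {
    stop("build_element: internal_length (", spec$internal_length,
         ") too short for the requested domains (", total_dom, " nt)")
  }
  with_seed(seed, {
    ltr <- paste0(spec$start_dinuc,
                  random_dna(spec$ltr_length - 4L),
                  spec$end_dinuc)
    nd <- length(dom_nt)
    slack <- spec$internal_length - total_dom
    spacer_len <- rep(slack %/% (nd + 1L), nd + 1L)
    extra <- slack %% (nd + 1L)
    if (extra > 0L) spacer_len[seq_len(extra)] <- spacer_len[seq_len(extra)] + 1L
    pieces <- character(0L)
    starts <- integer(nd)
    pos <- 0L
    for (i in seq_len(nd + 1L)) {
      pieces <- c(pieces, random_dna(spacer_len[i]))
      pos <- pos + spacer_len[i]
      if (i <= nd) {
        starts[i] <- pos
        pieces <- c(pieces, dom_nt[i])
        pos <- pos + nchar(dom_nt[i])
      }
    }
    internal <- paste(pieces, collapse = "")
    stopifnot(nchar(internal) == spec$internal_length)
    domains <- if (nd > 0L) {
      data.frame(name = spec$domain_order, start = starts,
                 end = starts + nchar(dom_nt), stringsAsFactors = FALSE)
    } else {
      data.frame(name = character(0L), start = integer(0L), end = integer(0L))
    }
    structure(
      list(seq = paste0(ltr, internal, ltr),
           ltr_length = spec$ltr_length,
           internal_length = spec$internal_length,
           domains = domains, spec = spec),
      class = "ltr_element"
    )
  })
}

#' Age an element by simulating post-insertion substitutions
#'
#' Each site mutates independently with probability `1 - exp(-r * T)`, the
#' replacement drawn uniformly from the three alternative bases; both LTRs
#' and the internal region evolve at the same rate and no indels are
#' introduced. The expected divergence between the two LTRs is close to the
#' Jukes-Cantor expectation for 2rT substitutions per site, which is what
#' the dating module inverts.
#'
#' @param element An `ltr_element` (or any list with `seq`).
#' @param T_years Elapsed time in years (>= 0).
#' @param r Substitution rate per site per year (> 0).
#' @param seed Integer seed.
#' @return The element with a mutated `seq` (same length).
#' @export
age_element <- function(element, T_years, r = 1.3e-8, seed = 1L) {
  stopifnot(is.list(element), !is.null(element$seq))
  if (!is.numeric(T_years) || T_years < 0) {
    stop("age_element: T_years must be non-negative")
  }
  if (!is.numeric(r) || r <= 0) stop("age_element: r must be positive")
  q <- 1 - exp(-r * T_years)
  out <- element
  out$seq <- with_seed(seed, mutate_uniform_(element$seq, q))
  out
}

# substitute each site independently with probability q; caller manages RNG
mutate_uniform_ <- function(seq, q) {
  if (q <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(v)) < q)
  if (length(hit)) {
    for (i in hit) {
      v[i] <- sample(setdiff(DNA_BASES, v[i]), 1L)
    }
  }
  paste(v, collapse = "")
}

#' Apply a fixed expected per-site divergence to a sequence
#'
#' Convenience wrapper around the same substitution process as
#' [age_element()], parameterised directly by the per-site substitution
#' probability instead of (T, r). Used to construct family radiations in
#' scenario simulations.
#'
#' @param seq Nucleotide string.
#' @param divergence Per-site substitution probability in \[0, 0.75\].
#' @param seed Integer seed.
#' @return Mutated string of the same length.
#' @export
mutate_sequence <- function(seq, divergence, seed = 1L) {
  stopifnot(divergence >= 0, divergence <= 0.75)
  with_seed(seed, mutate_uniform_(seq, divergence))
}

#' Re-insert an element, resetting its two LTRs to identical copies
#'
#' Models retrotransposition: a new genomic copy starts life with two
#' identical LTRs (both derived from one template LTR), regardless of how
#' diverged the template element's own LTR pair had become.
#'
#' @param element An `ltr_element`.
#' @return An `ltr_element` whose 3' LTR is a byte-copy of the 5' LTR.
#' @export
retranspose <- function(element) {
  stopifnot(inherits(element, "ltr_element"))
  L <- element$ltr_length
  Ilen <- element$internal_length
  ltr5 <- substr0(element$seq, 0L, L)
  internal <- substr0(element$seq, L, L + Ilen)
  out <- element
  out$seq <- paste0(ltr5, internal, ltr5)
  out
}

#' Plant an element into a contig with a target site duplication
#'
#' The `tsd_length` bases immediately 5' of `position` are duplicated so
#' that they flank the element on both sides, exactly as an integrase
#' leaves a staggered-cut repair footprint. The contig grows by
#' `nchar(element) + tsd_length`.
#'
#' @param genome Contig string.
#' @param element An `ltr_element` or plain nucleotide string.
#' @param position 0-based insertion offset, `tsd_length <= position <=
#'   nchar(genome)`.
#' @param tsd_length TSD length, 4-6 bp.
#' @param contig Contig id recorded in the truth record.
#' @param t_true True age in years (bookkeeping only).
#' @param family_label Family label (bookkeeping only).
#' @return List with the new `genome` string and a `truth` record holding
#'   the planted spans (0-based half-open), TSD sequence, age and labels.
#' @export
plant_element <- function(genome, element, position, tsd_length = 5L,
                          contig = "contig1", t_true = NA_real_,
                          family_label = NA_character_) {
  seq <- if (is.list(element)) element$seq else element
  ltr_len <- if (is.list(element)) element$ltr_length else NA_integer_
  n <- nchar(genome)
  if (tsd_length < 4L || tsd_length > 6L) {
    stop("plant_element: tsd_length must be 4-6 bp")
  }
  if (position < tsd_length || position > n) {
    stop("plant_element: position out of range [tsd_length, contig length]")
  }
  tsd <- substr0(genome, position - tsd_length, position)
  new_genome <- paste0(
    substr0(genome, 0L, position), seq, tsd, substr0(genome, position, n)
  )
  len <- nchar(seq)
  motif <- paste0(substr(seq, 1L, 2L), substr(seq, len - 1L, len))
  truth <- list(
    contig = contig,
    start = position, end = position + len,
    ltr5_start = position, ltr5_end = position + ltr_len,
    ltr3_start = position + len - ltr_len, ltr3_end = position + len,
    tsd = tsd, tsd_length = tsd_length,
    t_true = t_true, family_label = family_label, motif = motif
  )
  list(genome = new_genome, truth = truth)
}

#' Shuffle a contig in dinucleotide blocks
#'
#' Permutes non-overlapping 2-bp blocks, approximately preserving
#' dinucleotide composition while destroying all long repeats; used as a
#' negative control for the structural finder.
#'
#' @param seq Contig string.
#' @param seed Integer seed.
#' @return Shuffled string of the same length.
#' @export
dinucleotide_shuffle <- function(seq, seed = 1L) {
  n <- nchar(seq)
  nb <- n %/% 2L
  blocks <- substring(seq, seq(1L, by = 2L, length.out = nb),
                      seq(2L, by = 2L, length.out = nb))
  tail_base <- if (n %% 2L == 1L) substr(seq, n, n) else ""
  with_seed(seed, paste0(paste(sample(blocks), collapse = ""), tail_base))
}

.SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]

#' Simulate single-copy ortholog CDS pairs with a target identity spectrum
#'
#' Pair i is a random stop-free CDS plus a copy carrying point substitutions
#' (a mix of synonymous and nonsynonymous changes, never creating internal
#' stops or frameshifts) placed to hit a per-pair target identity drawn from
#' Normal(mean, sd) truncated to (0, 100]. Defaults reproduce the observed
#' apple-peach single-copy ortholog identity distribution
#' (86.57% +/- 3.59%, n = 822).
#'
#' @param n_pairs Number of pairs.
#' @param target_identity_mean,target_identity_sd Percent identity
#'   distribution parameters.
#' @param cds_length CDS length in bp, >= 30 and divisible by 3.
#' @param seed Integer seed.
#' @return data.frame with columns `id`, `a`, `b`, `target_identity`,
#'   `identity` (realised ungapped percent identity).
#' @export
simulate_ortholog_pairs <- function(n_pairs = 822L,
                                    target_identity_mean = 86.57,
                                    target_identity_sd = 3.59,
                                    cds_length = 900L, seed = 1L) {
  stopifnot(n_pairs >= 1L)
  if (target_identity_mean <= 0 || target_identity_mean > 100) {
    stop("simulate_ortholog_pairs: mean identity must lie in (0, 100]")
  }
  if (target_identity_sd < 0) stop("simulate_ortholog_pairs: sd must be >= 0")
  if (cds_length < 30L || cds_length %% 3L != 0L) {
    stop("simulate_ortholog_pairs: cds_length must be >= 30 and divisible by 3")
  }
  with_seed(seed, {
    n_codons <- cds_length %/% 3L
    res <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      a <- paste(sample(.SENSE_CODONS, n_codons, replace = TRUE),
                 collapse = "")
      target <- NA_real_
      for (try in seq_len(1000L)) {
        t0 <- stats::rnorm(1L, target_identity_mean, target_identity_sd)
        if (t0 > 0 && t0 <= 100) { target <- t0; break }
      }
      if (is.na(target)) {
        stop("simulate_ortholog_pairs: could not draw a target identity in ",
             "(0, 100] after 1000 attempts")
      }
      m <- round((1 - target / 100) * cds_length)
      b <- mutate_cds_(a, m)
      res[[i]] <- data.frame(
        id = sprintf("og%04d", i), a = a, b = b,
        target_identity = target,
        identity = 100 * (cds_length - m) / cds_length,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, res)
  })
}

# apply exactly m point substitutions to a CDS without creating stop codons;
# caller manages RNG
mutate_cds_ <- function(cds, m) {
  if (m <= 0L) return(cds)
  v <- strsplit(cds, "", fixed = TRUE)[[1L]]
  n <- length(v)
  free <- sample(n)                      # candidate positions, random order
  done <- 0L
  k <- 1L
  while (done < m && k <= n) {
    pos <- free[k]
    k <- k + 1L
    codon_i <- (pos - 1L) %/% 3L
    off <- (pos - 1L) %% 3L + 1L
    codon <- v[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
    alts <- sample(setdiff(DNA_BASES, v[pos]))
    for (alt in alts) {
      cand <- codon
      cand[off] <- alt
      if (!is_stop_codon(paste(cand, collapse = ""))) {
        v[pos] <- alt
        done <- done + 1L
        break
      }
    }
  }
  if (done < m) stop("mutate_cds_: could not place all requested substitutions")
  paste(v, collapse = "")
}
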