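test_that("a planted aged element is recovered with exact boundaries", {
  pl <- plant_one(50000, 20000, 0.5e6, seed = 11)
  cand <- find_ltr_candidates(pl$genome, finder_params(), "c1")
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, pl$truth$start)
  expect_equal(cand$end, pl$truth$end)
  expect_gte(cand$ltr_identity, 85)
  # reported identity is the divergence module's gaps-excluded identity
  # recomputed on the reported spans (single source of truth)
  ltr5 <- substring(pl$genome, cand$ltr5_start + 1, cand$ltr5_end)
  ltr3 <- substring(pl$genome, cand$ltr3_start + 1, cand$ltr3_end)
  m <- identity_metrics(align_global(ltr5, ltr3))
  expect_equal(cand$ltr_identity, m$identity_without_gaps)
})

test_that("two non-overlapping elements are reported in start order", {
  g <- generate_background(80000, 0.38, 21)
  e1 <- age_element(build_element(element_spec(), 22), 0.3e6, seed = 23)
  e2 <- age_element(build_element(element_spec(family_label = "FAM2"), 24),
                    0.8e6, seed = 25)
  p1 <- plant_element(g, e1, 60000, 5)
  p2 <- plant_element(p1$genome, e2, 20000, 5)
  cand <- find_ltr_candidates(p2$genome, finder_params(), "c1")
  expect_equal(nrow(cand), 2L)
  expect_true(all(diff(cand$start) > 0))
  expect_equal(cand$start, c(20000L, 60000L + 5058L))
})

test_that("dinucleotide-shuffled contigs yield zero candidates", {
  pl <- plant_one(50000, 20000, 0.5e6, seed = 31)
  for (s in 1:3) {
    sh <- dinucleotide_shuffle(pl$genome, seed = s)
    expect_equal(nrow(find_ltr_candidates(sh, finder_params(), "s")), 0L)
  }
})

test_that("TSD validation accepts up to one mismatch and rejects beyond", {
  params <- finder_params()
  # construct a contig with a known element span and controlled flanks
  el <- build_element(element_spec(), 41)
  mk <- function(left, right) {
    rec <- data.frame(element_id = "e", contig = "c", strand = "+",
                      start = nchar(left), end = nchar(left) + 5053L,
                      ltr5_start = 0L, ltr5_end = 180L,
                      ltr3_start = 0L, ltr3_end = 180L,
                      ltr_identity = 100,
                      start_dinuc = NA, end_dinuc = NA, motif_label = NA,
                      tsd_left = NA, tsd_right = NA, tsd_len = NA,
                      tsd_mismatch = NA, tsd_status = NA,
                      stringsAsFactors = FALSE)
    list(contig = paste0(left, el$seq, right), rec = rec)
  }
  pad <- "CCCCCCCCCC"
  exact <- mk(paste0(pad, "GATCA"), paste0("GATCA", pad))
  r <- validate_tsd(exact$contig, exact$rec, params)
  expect_identical(r$tsd_status, "ok")
  expect_identical(r$tsd_left, "GATCA")
  expect_identical(r$tsd_right, "GATCA")
  expect_equal(r$tsd_len, 5L)
  expect_equal(r$tsd_mismatch, 0L)

  one_mm <- mk(paste0(pad, "GATCA"), paste0("GATCC", pad))
  r <- validate_tsd(one_mm$contig, one_mm$rec, params)
  expect_identical(r$tsd_status, "ok")
  expect_equal(r$tsd_mismatch, 1L)

  none <- mk(paste0(pad, "GATCA"), paste0("GGGCC", pad))
  r <- validate_tsd(none$contig, none$rec, params)
  expect_identical(r$tsd_status, "none")

  edge <- mk("GAT", paste0("GATCA", pad))
  r <- validate_tsd(edge$contig, edge$rec, params)
  expect_identical(r$tsd_status, "edge")
})

test_that("terminal motifs are labelled, including strand and consistency", {
  mk_contig <- function(start_d, end_d, mutate_3ltr_start = FALSE) {
    spec <- element_spec(start_dinuc = start_d, end_dinuc = end_d,
                         internal_length = 1800L,
                         domain_order = character(0))
    el <- build_element(spec, 42)
    s <- el$seq
    if (mutate_3ltr_start) {
      # damage the first base of the 3' LTR only
      pos <- nchar(s) - 180L + 1L
      base <- substr(s, pos, pos)
      substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), base)[1]
    }
    rec <- data.frame(element_id = "e", contig = "c", strand = "+",
                      start = 0L, end = nchar(s),
                      ltr5_start = 0L, ltr5_end = 180L,
                      ltr3_start = nchar(s) - 180L, ltr3_end = nchar(s),
                      ltr_identity = 100, start_dinuc = NA, end_dinuc = NA,
                      motif_label = NA, tsd_left = NA, tsd_right = NA,
                      tsd_len = NA, tsd_mismatch = NA, tsd_status = NA,
                      stringsAsFactors = FALSE)
    list(contig = s, rec = rec)
  }
  motifs <- finder_params()$motif_list
  for (case in list(c("TG", "TT", "TGTT"), c("AA", "CA", "AACA"),
                    c("TG", "CA", "TGCA"))) {
    x <- mk_contig(case[1], case[2])
    r <- check_terminal_motif(x$contig, x$rec, motifs)
    expect_identical(r$motif_label, case[3])
    expect_identical(r$strand, "+")
  }
  x <- mk_contig("GG", "GG")
  r <- check_terminal_motif(x$contig, x$rec, motifs)
  expect_identical(r$motif_label, "other")
  x <- mk_contig("TG", "TT", mutate_3ltr_start = TRUE)
  r <- check_terminal_motif(x$contig, x$rec, motifs)
  expect_identical(r$motif_label, "inconsistent")
  # minus-strand reading: an AACA element under a TGTT-only motif list
  x <- mk_contig("AA", "CA")
  r <- check_terminal_motif(x$contig, x$rec, list(c("TG", "TT")))
  expect_identical(r$motif_label, "TGTT")
  expect_identical(r$strand, "-")
})

test_that("reverse-complementing a contig mirrors coordinates and flips strand", {
  pl <- plant_one(40000, 15000, 0.3e6, seed = 51)
  params <- finder_params(motif_list = list(c("TG", "TT")))
  fwd <- find_elements(c(c1 = pl$genome), params)
  rev <- find_elements(c(c1 = revcomp_str(pl$genome)), params)
  n <- nchar(pl$genome)
  expect_equal(nrow(fwd), 1L)
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$start, n - fwd$end)
  expect_equal(rev$end, n - fwd$start)
  expect_identical(fwd$strand, "+")
  expect_identical(rev$strand, "-")
  expect_identical(fwd$motif_label, rev$motif_label)
  expect_equal(fwd$ltr_identity, rev$ltr_identity)
})

test_that("small multi-element genomes are recovered with tight boundaries", {
  # 5 elements, ages up to 2 My, one contig; shuffled control stays clean
  g <- generate_background(200000, 0.38, 61)
  ages <- c(0, 0.5e6, 1e6, 1.5e6, 2e6)
  truths <- list()
  offset <- 0L
  for (i in seq_along(ages)) {
    el <- age_element(build_element(element_spec(), 100 + i), ages[i],
                      seed = 200 + i)
    pl <- plant_element(g, el, 10000L + (i - 1L) * 40000L + offset, 5,
                        t_true = ages[i])
    g <- pl$genome
    offset <- offset + (pl$truth$end - pl$truth$start) + 5L
    truths[[i]] <- pl$truth
  }
  found <- find_elements(c(c1 = g), finder_params())
  expect_equal(nrow(found), 5L)
  for (t in truths) {
    hit <- found[found$start < t$end & found$end > t$start, ]
    expect_equal(nrow(hit), 1L)
    expect_lte(abs(hit$start - t$start), 2L)
    expect_lte(abs(hit$end - t$end), 2L)
  }
  sh <- dinucleotide_shuffle(g, 1)
  expect_equal(nrow(find_ltr_candidates(sh, finder_params(), "s")), 0L)
})
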