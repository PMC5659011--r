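test_that("background generation honours length, composition and seed", {
  g <- generate_background(10000, 0.4, 7)
  expect_equal(nchar(g), 10000L)

  at_only <- generate_background(1000, 0.0, 1)
  expect_false(grepl("[GC]", at_only))

  expect_identical(generate_background(500, 0.5, 3),
                   generate_background(500, 0.5, 3))
  expect_false(identical(generate_background(500, 0.5, 3),
                         generate_background(500, 0.5, 4)))
  expect_error(generate_background(0, 0.5, 1), "positive")
  expect_error(generate_background(100, 1.2, 1), "gc")
})

test_that("built elements have the specified structure", {
  spec <- element_spec(ltr_length = 180L, internal_length = 4693L,
                       start_dinuc = "TG", end_dinuc = "TT")
  el <- build_element(spec, 2)
  expect_equal(nchar(el$seq), 2L * 180L + 4693L)
  expect_identical(substr(el$seq, 1, 2), "TG")
  expect_identical(substr(el$seq, 179, 180), "TT")
  # the two LTRs are byte-identical at age zero
  ltr5 <- substr(el$seq, 1, 180)
  ltr3 <- substr(el$seq, nchar(el$seq) - 179, nchar(el$seq))
  expect_identical(ltr5, ltr3)
  # domains embedded in the requested order
  expect_identical(el$domains$name, c("GAG", "PR", "INT", "RT", "RH"))
  expect_true(all(diff(el$domains$start) > 0))
  # each embedded domain back-translates the packaged peptide
  internal <- substr(el$seq, 181, 180 + 4693)
  for (i in seq_len(nrow(el$domains))) {
    d <- el$domains[i, ]
    expect_identical(substr(internal, d$start + 1, d$end),
                     back_translate(ltr_domain_peptides()[[d$name]]))
  }
})

test_that("element specs are validated", {
  expect_error(element_spec(ltr_length = 10), "ltr_length")
  expect_error(element_spec(start_dinuc = "TGX"), "dinucleotides")
  expect_error(element_spec(domain_order = c("GAG", "XYZ")), "unknown domain")
  expect_error(element_spec(domain_order = character(0),
                            internal_length = 0L))
  # internal region too short for the requested domains
  expect_error(build_element(element_spec(internal_length = 100L), 1),
               "too short")
  # TRIM-like spec with no domains is fine
  el <- build_element(element_spec(internal_length = 1800L,
                                   domain_order = character(0)), 1)
  expect_equal(nrow(el$domains), 0L)
})

test_that("aging leaves T = 0 untouched, is deterministic, adds no indels", {
  el <- build_element(element_spec(), 3)
  expect_identical(age_element(el, 0, seed = 5)$seq, el$seq)
  a1 <- age_element(el, 2e6, seed = 5)
  expect_identical(a1$seq, age_element(el, 2e6, seed = 5)$seq)
  expect_false(identical(a1$seq, age_element(el, 2e6, seed = 6)$seq))
  expect_equal(nchar(a1$seq), nchar(el$seq))
  expect_error(age_element(el, -1), "non-negative")
  expect_error(age_element(el, 1e6, r = 0), "positive")
})

test_that("mean LTR-LTR divergence after aging matches the JC expectation", {
  # 200 replicates, 200-bp LTRs, T = 1 My at r = 1.3e-8 (2rT = 0.026);
  # E(p) = 3/4 (1 - exp(-8rT/3)) under Jukes-Cantor
  spec <- element_spec(ltr_length = 200L, internal_length = 100L,
                       domain_order = character(0))
  el <- build_element(spec, 1)
  ps <- vapply(1:200, function(i) {
    aged <- age_element(el, 1e6, 1.3e-8, seed = i)
    ltr5 <- substr(aged$seq, 1, 200)
    ltr3 <- substr(aged$seq, nchar(aged$seq) - 199, nchar(aged$seq))
    str_mm <- sum(strsplit(ltr5, "")[[1]] != strsplit(ltr3, "")[[1]])
    str_mm / 200
  }, numeric(1))
  expected <- 0.75 * (1 - exp(-4 * 0.026 / 3))
  se <- sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - expected), 3 * se)
})

test_that("planting duplicates the target site and is reversible", {
  g <- generate_background(10000, 0.4, 11)
  el <- build_element(element_spec(), 12)
  pl <- plant_element(g, el, 100, tsd_length = 5)
  expect_equal(nchar(pl$genome), 10000L + 5053L + 5L)
  # bases [95,100) of the original reappear immediately after the element
  expect_identical(substr(g, 96, 100),
                   substr(pl$genome, 100 + 5053 + 1, 100 + 5053 + 5))
  expect_equal(pl$truth$end - pl$truth$start, 5053L)
  expect_equal(pl$truth$ltr5_end - pl$truth$ltr5_start, 180L)
  # removing the element and one TSD copy restores the original contig
  restored <- paste0(substr(pl$genome, 1, 100),
                     substr(pl$genome, 100 + 5053 + 5 + 1,
                            nchar(pl$genome)))
  expect_identical(restored, g)
  expect_error(plant_element(g, el, 3, tsd_length = 5), "out of range")
  expect_error(plant_element(g, el, 20000, tsd_length = 5), "out of range")
})

test_that("ortholog pair simulation hits the target identity spectrum", {
  op <- simulate_ortholog_pairs(10, cds_length = 300, seed = 3)
  expect_equal(nrow(op), 10L)
  expect_true(all(nchar(op$a) == 300L & nchar(op$b) == 300L))
  # no internal stops, frame preserved
  has_stop <- function(cds) {
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    any(Biostrings::GENETIC_CODE[codons] == "*")
  }
  expect_false(any(vapply(op$a, has_stop, logical(1))))
  expect_false(any(vapply(op$b, has_stop, logical(1))))
  # realised identity equals the mismatch count actually applied
  mm <- unname(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, op$a, op$b))
  expect_equal(op$identity, 100 * (300 - mm) / 300)

  # a perfect-identity target yields identical sequences
  ident <- simulate_ortholog_pairs(3, target_identity_mean = 100,
                                   target_identity_sd = 0,
                                   cds_length = 300, seed = 4)
  expect_identical(ident$a, ident$b)

  expect_error(simulate_ortholog_pairs(5, target_identity_mean = 0),
               "identity")
  expect_error(simulate_ortholog_pairs(5, cds_length = 100), "cds_length")
})

test_that("at the observed apple-peach parameters the realised mean tracks the target", {
  op <- simulate_ortholog_pairs(822, 86.57, 3.59, cds_length = 900, seed = 9)
  expect_lt(abs(mean(op$identity) - 86.57), 0.5)
})

test_that("retransposition resets the LTR pair to identity", {
  el <- age_element(build_element(element_spec(), 7), 5e6, seed = 8)
  n <- nchar(el$seq)
  expect_false(substr(el$seq, 1, 180) == substr(el$seq, n - 179, n))
  re <- retranspose(el)
  expect_identical(substr(re$seq, 1, 180), substr(re$seq, n - 179, n))
  expect_equal(nchar(re$seq), n)
})

test_that("dinucleotide shuffling preserves length and is seeded", {
  g <- generate_background(5001, 0.4, 2)
  s <- dinucleotide_shuffle(g, 1)
  expect_equal(nchar(s), nchar(g))
  expect_identical(s, dinucleotide_shuffle(g, 1))
  expect_false(identical(s, g))
})
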