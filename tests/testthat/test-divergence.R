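test_that("identity metrics implement I/(I+M) and I/(I+M+G)", {
  m <- identity_metrics(c("ACGT", "ACGA"))
  expect_equal(c(m$I, m$M, m$G), c(3L, 1L, 0L))
  expect_equal(m$identity_without_gaps, 75)
  expect_equal(m$identity_with_gaps, 75)

  m <- identity_metrics(c("AC-GT", "ACTGT"))
  expect_equal(c(m$I, m$M, m$G), c(4L, 0L, 1L))
  expect_equal(m$identity_without_gaps, 100)
  expect_equal(m$identity_with_gaps, 80)

  expect_error(identity_metrics(c("--", "AA")), "no aligned")
})

test_that("gap-included identity never exceeds gap-excluded identity", {
  set.seed(161)
  for (i in 1:40) {
    a <- random_seq(sample(20:60, 1))
    b <- random_seq(sample(20:60, 1))
    m <- identity_metrics(align_global(a, b))
    expect_lte(m$identity_with_gaps, m$identity_without_gaps)
    if (m$G == 0) {
      expect_equal(m$identity_with_gaps, m$identity_without_gaps)
    }
  }
})

test_that("NG86 handles identical sequences and pure substitution classes", {
  a <- "TTTGCTAAAGATCGT"
  r <- ng86_kaks(a, a)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_false(r$ratio_defined)
  expect_true(is.na(r$ratio))
  # one synonymous change on a long enough CDS: Ka = 0, Ks > 0
  r <- ng86_kaks("TTTGCTAAAGATCGT", "TTCGCTAAAGATCGT")
  expect_equal(r$Ka, 0)
  expect_gt(r$Ks, 0)
  # one nonsynonymous change at a nondegenerate position: Ks = 0, Ka > 0
  r <- ng86_kaks("ATGGCTAAAGATCGT", "CTGGCTAAAGATCGT")
  expect_equal(r$Ks, 0)
  expect_gt(r$Ka, 0)
  expect_error(ng86_kaks("TTT", "TTTTTT"), "length")
  expect_error(ng86_kaks("TTTT", "TTTT"), "divisible")
  expect_error(ng86_kaks("TAATTT", "TAATTT"), "stop")
})

test_that("NG86 equals the pathway-enumeration oracle on random codon pairs", {
  set.seed(171)
  checked <- 0
  while (checked < 100) {
    n_codons <- sample(1:5, 1)
    a <- random_sense_cds(n_codons)
    b <- random_sense_cds(n_codons)
    res <- tryCatch(ng86_kaks(a, b), error = function(e) e)
    ora <- tryCatch(oracle_ng86(a, b), error = function(e) e)
    if (inherits(res, "error") || inherits(ora, "error") ||
        !is.finite(ora$Ka) || !is.finite(ora$Ks)) {
      # saturated pair (common at 1-2 codons): both routes must refuse
      if (inherits(res, "error")) {
        expect_true(inherits(ora, "error") || ora$ps >= 0.75 ||
                      ora$pn >= 0.75)
      }
      next
    }
    expect_equal(res$Ka, ora$Ka, tolerance = 1e-12)
    expect_equal(res$Ks, ora$Ks, tolerance = 1e-12)
    checked <- checked + 1
  }
  # symmetry in the arguments
  for (i in 1:10) {
    a <- random_sense_cds(10)
    b <- mutate_to_codons(a, 4, seed = 300 + i)
    r1 <- ng86_kaks(a, b)
    r2 <- ng86_kaks(b, a)
    expect_equal(r1$Ka, r2$Ka)
    expect_equal(r1$Ks, r2$Ks)
  }
})

test_that("codon-aware alignment produces NG86-ready pairs", {
  set.seed(181)
  a <- random_sense_cds(40)
  # delete two codons from the middle of b and mutate a little
  b <- paste0(substr(a, 1, 30), substr(a, 37, nchar(a)))
  ca <- codon_align(a, b)
  expect_equal(nchar(ca$a) %% 3, 0)
  expect_equal(nchar(ca$a), nchar(ca$b))
  r <- ng86_kaks(ca$a, ca$b)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
})

test_that("reciprocal best hits recover planted orthologs and obey tie rules", {
  set.seed(191)
  # singletons always pair
  x <- random_sense_cds(60)
  xp <- mutate_to_codons(x, 20, seed = 192)
  rb <- rbh_orthologs(c(g1 = x), c(h1 = xp))
  expect_equal(nrow(rb), 1L)
  # 10x10 planted one-to-one at ~85% identity plus unrelated decoys
  a <- vapply(1:10, function(i) random_sense_cds(100), character(1))
  names(a) <- paste0("a", 1:10)
  b <- vapply(seq_along(a),
              function(i) mutate_to_codons(a[[i]], 45, seed = 400 + i),
              character(1))
  names(b) <- paste0("b", 1:10)
  decoys <- vapply(1:5, function(i) random_sense_cds(100), character(1))
  names(decoys) <- paste0("d", 1:5)
  rb <- rbh_orthologs(a, c(b, decoys))
  expect_equal(nrow(rb), 10L)
  expect_identical(sub("a", "", rb$a), sub("b", "", rb$b))
  # a gene with two equally scoring best partners is excluded
  rb <- rbh_orthologs(c(g1 = x), c(h1 = xp, h2 = xp))
  expect_equal(nrow(rb), 0L)
  # sequences with internal stops are excluded up front
  stopcds <- paste0("ATG", "TAA", "GCT")
  rb <- rbh_orthologs(c(g1 = x, g2 = stopcds), c(h1 = xp))
  expect_equal(nrow(rb), 1L)
  expect_error(rbh_orthologs(character(0), c(h1 = xp)), "non-empty")
})

test_that("identity histograms anchor at zero and break ties upward", {
  d <- identity_distribution(rep(86.0, 7))
  expect_equal(d$peak, 86.5)
  d <- identity_distribution(c(rep(70.5, 10), rep(90.5, 10)))
  expect_equal(d$peak, 90.5)
  d <- identity_distribution(c(70.2, 70.9, 83.3), bin_width = 5)
  expect_equal(d$peak, 72.5)
  expect_error(identity_distribution(numeric(0)), "no values")
  # peak lies within the data range
  set.seed(201)
  for (i in 1:10) {
    v <- runif(50, 40, 100)
    d <- identity_distribution(v)
    expect_gte(d$peak, min(v) - 0.5)
    expect_lte(d$peak, max(v) + 0.5)
  }
})

test_that("822 draws at the printed parameters peak near the printed mean", {
  set.seed(211)
  v <- rnorm(822, 86.57, 3.59)
  expect_lt(abs(identity_distribution(v)$peak - 86.57), 1.5)
})
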