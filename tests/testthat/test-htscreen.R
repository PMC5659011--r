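mk_identity <- function(excl, incl) {
  structure(list(I = NA, M = NA, G = NA,
                 identity_without_gaps = excl,
                 identity_with_gaps = incl),
            class = "identity_result")
}

test_that("the identity screen compares strictly against both peaks", {
  d_excl <- identity_distribution(rep(86.3, 9))   # peak 86.5
  d_incl <- identity_distribution(rep(69.4, 9))   # peak 69.5
  expect_true(screen_pair(mk_identity(92.26, 89.05), d_excl, d_incl))
  expect_false(screen_pair(mk_identity(80, 60), d_excl, d_incl))
  # exactly at the peak: strict inequality fails
  expect_false(screen_pair(mk_identity(86.5, 89.05), d_excl, d_incl))
  expect_false(screen_pair(mk_identity(92.26, 69.5), d_excl, d_incl))
  # monotone: raising identity never flips TRUE -> FALSE
  prev <- FALSE
  for (idv in seq(60, 100, by = 2)) {
    cur <- screen_pair(mk_identity(idv, idv), d_excl, d_incl)
    expect_false(prev && !cur)
    prev <- cur
  }
})

test_that("Ks asymmetry names the low-Ks side only outside the noise band", {
  r <- ks_asymmetry(c(0.01, 0.02, 0.03), c(0.5, 0.7, 1.1), "pp", "md")
  expect_identical(r$recipient, "pp")
  r <- ks_asymmetry(c(0.25, 0.35), c(0.26, 0.36), "a", "b")
  expect_identical(r$recipient, "inconclusive")
  # single values have sd 0: any difference is decisive
  r <- ks_asymmetry(0.8, 0.02, "a", "b")
  expect_identical(r$recipient, "b")
  expect_error(ks_asymmetry(numeric(0), 0.5), "non-empty")
})

test_that("neighbor joining solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 2, 4,
                2, 0, 4,
                4, 4, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))
  # degenerate matrix: all branch lengths zero
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(nj_tree(z)$edge.length == 0))
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
  bad <- d
  bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
})

test_that("NJ recovers additive 4-taxon trees exactly", {
  tr0 <- ape::read.tree(text = "((a:1,b:2):1.5,(c:0.5,d:3):1);")
  D <- ape::cophenetic.phylo(tr0)[letters[1:4], letters[1:4]]
  tr <- nj_tree(D)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr0), tr)), 0)
  expect_equal(sort(round(ape::cophenetic.phylo(tr)[letters[1:4],
                                                    letters[1:4]], 9)),
               sort(D))
})

test_that("NJ recovers 50 random additive 6-taxon topologies and matches ape", {
  set.seed(221)
  for (i in 1:50) {
    tr0 <- ape::rtree(6, rooted = FALSE)
    D <- ape::cophenetic.phylo(tr0)
    tr <- nj_tree(D)
    expect_equal(as.numeric(ape::dist.topo(tr0, tr)), 0)
    # independent cross-check against ape's NJ
    expect_equal(as.numeric(ape::dist.topo(ape::nj(D), tr)), 0)
  }
})

test_that("species monophyly is read off unrooted splits", {
  t1 <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  m <- species_monophyly(t1, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_true(all(m$per_species))
  expect_false(m$monophyly_violation)

  t2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  m <- species_monophyly(t2, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_false(any(m$per_species))
  expect_true(m$monophyly_violation)

  # single-leaf species are monophyletic by definition
  t3 <- ape::read.tree(text = "((a1:1,c1:1):1,(a2:1,b1:1):1);")
  m <- species_monophyly(t3, c(a1 = "A", a2 = "A", b1 = "B", c1 = "C"))
  expect_true(m$per_species[["B"]])
  expect_true(m$per_species[["C"]])
  expect_false(m$per_species[["A"]])
  expect_true(m$monophyly_violation)
  expect_error(species_monophyly(t3, c(a1 = "A")), "unmapped")
})

test_that("a vertical-only two-species family is never called HT", {
  set.seed(231)
  # two species that split long ago, each with young vertical copies
  anc <- build_element(element_spec())
  a_anc <- retranspose(age_element(anc, 8e6, seed = 232))
  b_anc <- retranspose(age_element(anc, 8e6, seed = 233))
  seqs <- c(
    a1 = age_element(a_anc, 1e6, seed = 234)$seq,
    a2 = age_element(a_anc, 2e6, seed = 235)$seq,
    b1 = age_element(b_anc, 1e6, seed = 236)$seq,
    b2 = age_element(b_anc, 2e6, seed = 237)$seq
  )
  species <- c(a1 = "spA", a2 = "spA", b1 = "spB", b2 = "spB")
  d_excl <- identity_distribution(rnorm(500, 86.57, 3.59))
  d_incl <- identity_distribution(rnorm(500, 69.80, 3.59))
  scr <- screen_family_ht(seqs, species, d_excl, d_incl)
  expect_equal(nrow(scr$report), 1L)
  expect_identical(scr$report$final_call, "vertical")
  expect_false(scr$report$identity_test)
})
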