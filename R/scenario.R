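# End-to-end synthetic horizontal-transfer scenario.
#
# Three species carry one Copia-like element family:
#   * species A (donor): four copies inserted 0.9-3.0 Mya. Each descends
#     from a source lineage that diverged from the family ancestor 0-8 Mya
#     and received fresh identical LTRs at insertion, decoupling the
#     family radiation depth (which drives intra-A integrase Ks) from the
#     insertion age (which drives LTR-LTR divergence) — exactly as
#     retrotransposition does;
#   * species C (vertical outgroup): the family was already present in the
#     A/C common ancestor; C's two copies sit on a long shared lineage
#     branch, so their identity to A elements falls below the host-gene
#     ortholog identity peak, as vertical descent predicts;
#   * species B (recipient): a copy of A's youngest element, carrying extra
#     template divergence, re-inserted ~0.4-0.6 Mya with freshly reset
#     identical LTRs. Its ~92% identity to the donor exceeds the ortholog
#     peak, its clade nests inside A's radiation (breaking A's monophyly
#     once C anchors the rest of the tree), and its intra-species Ks is
#     near zero.
#
# Host-gene divergence is emulated by simulated single-copy ortholog CDS
# pairs with the observed apple-peach identity spectrum (86.57 +/- 3.59, n
# = 822).

#' Simulate a three-species horizontal-transfer scenario
#'
#' @param seed Integer seed driving every random choice.
#' @param donor_ages_my Insertion ages (My) of the donor-species copies;
#'   the first is the donor element itself.
#' @param donor_radiation_my Divergence (My) of each donor copy's source
#'   lineage from the family ancestor, accrued before insertion.
#' @param outgroup_split_my Age (My) of the donor/outgroup lineage split
#'   carried by the outgroup copies.
#' @param outgroup_ages_my Insertion ages (My) of the outgroup copies.
#' @param transfer_divergence Extra per-site divergence of the transferred
#'   template relative to the donor element (0.07 puts the pair at ~92%
#'   identity).
#' @param recipient_ages_my Insertion ages (My) of the recipient copies.
#' @param background_bp Background contig length per species.
#' @param n_ortholog_pairs,ortholog_identity_mean,ortholog_identity_sd
#'   Ortholog simulation parameters.
#' @param r Substitution rate per site per year.
#' @return List with `genomes` (named contig strings), `truth` (data.frame
#'   of planted spans and ages), `species_of_contig`, `orthologs`
#'   (data.frame from [simulate_ortholog_pairs()]), `donor_element`
#'   (truth id of the donor copy) and the parameters used.
#' @export
simulate_ht_scenario <- function(seed = 1L,
                                 donor_ages_my = c(0.9, 1.5, 2.5, 3.0),
                                 donor_radiation_my = c(0, 4.0, 6.0, 8.0),
                                 outgroup_split_my = 10,
                                 outgroup_ages_my = c(2.0, 3.0),
                                 transfer_divergence = 0.07,
                                 recipient_ages_my = c(0.43, 0.6),
                                 background_bp = 130000L,
                                 n_ortholog_pairs = 822L,
                                 ortholog_identity_mean = 86.57,
                                 ortholog_identity_sd = 3.59,
                                 r = 1.3e-8) {
  seed <- as.integer(seed)
  spec <- element_spec(ltr_length = 180L, internal_length = 4693L,
                      start_dinuc = "TG", end_dinuc = "TT",
                      tsd_length = 5L, family_label = "TGTT1")
  ancestor <- build_element(spec, seed = seed)

  # donor species: each copy diverges along its source lineage, then is
  # re-inserted with fresh identical LTRs and ages in place
  stopifnot(length(donor_radiation_my) == length(donor_ages_my))
  donors <- lapply(seq_along(donor_ages_my), function(i) {
    src <- retranspose(age_element(ancestor, donor_radiation_my[i] * 1e6,
                                   r, seed = seed + 20L + i))
    age_element(src, donor_ages_my[i] * 1e6, r, seed = seed + 10L + i)
  })

  # outgroup species: lineage split first, then its own insertions with
  # freshly reset LTR pairs
  out_anc <- retranspose(
    age_element(ancestor, outgroup_split_my * 1e6, r, seed = seed + 30L)
  )
  outs <- lapply(seq_along(outgroup_ages_my), function(i) {
    age_element(out_anc, outgroup_ages_my[i] * 1e6, r, seed = seed + 40L + i)
  })

  # recipient species: template = donor element plus extra divergence,
  # re-inserted (LTRs reset to identical), then aged briefly
  template <- donors[[1L]]
  template$seq <- mutate_sequence(template$seq, transfer_divergence,
                                  seed = seed + 60L)
  reinserted <- retranspose(template)
  recips <- lapply(seq_along(recipient_ages_my), function(i) {
    age_element(reinserted, recipient_ages_my[i] * 1e6, r,
                seed = seed + 70L + i)
  })

  plant_all <- function(contig_id, bg_seed, elements, ages_my, prefix) {
    genome <- generate_background(background_bp, gc = 0.38, seed = bg_seed)
    # plant in ascending position order, offsetting each position by the
    # cumulative inserted length, so every recorded truth span stays valid
    truths <- list()
    offset <- 0L
    for (i in seq_along(elements)) {
      pos <- 10000L + (i - 1L) * 30000L + offset
      pl <- plant_element(genome, elements[[i]], pos,
                          tsd_length = 5L, contig = contig_id,
                          t_true = ages_my[i] * 1e6,
                          family_label = "TGTT1")
      genome <- pl$genome
      offset <- offset + (pl$truth$end - pl$truth$start) + 5L
      truths[[i]] <- c(list(truth_id = sprintf("%s%d", prefix, i)),
                       pl$truth)
    }
    list(genome = genome, truth = truths)
  }

  gA <- plant_all("chrA", seed + 101L, donors, donor_ages_my, "A")
  gB <- plant_all("chrB", seed + 102L, recips, recipient_ages_my, "B")
  gC <- plant_all("chrC", seed + 103L, outs, outgroup_ages_my, "C")

  truth <- do.call(rbind, lapply(c(gA$truth, gB$truth, gC$truth),
                                 function(t) as.data.frame(t, stringsAsFactors = FALSE)))
  truth$species <- c(rep("speciesA", length(donors)),
                     rep("speciesB", length(recips)),
                     rep("speciesC", length(outs)))

  orthologs <- simulate_ortholog_pairs(
    n_pairs = n_ortholog_pairs,
    target_identity_mean = ortholog_identity_mean,
    target_identity_sd = ortholog_identity_sd,
    cds_length = 900L, seed = seed + 200L
  )

  list(
    genomes = c(chrA = gA$genome, chrB = gB$genome, chrC = gC$genome),
    species_of_contig = c(chrA = "speciesA", chrB = "speciesB",
                          chrC = "speciesC"),
    truth = truth,
    orthologs = orthologs,
    donor_element = "A1",
    params = list(seed = seed, donor_ages_my = donor_ages_my,
                  donor_radiation_my = donor_radiation_my,
                  outgroup_split_my = outgroup_split_my,
                  outgroup_ages_my = outgroup_ages_my,
                  transfer_divergence = transfer_divergence,
                  recipient_ages_my = recipient_ages_my, r = r)
  )
}
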