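# Horizontal-transfer screening.
#
# Evidence stack mirrors comparative-genomic HTT detection: (1) a
# cross-species element pair whose identity exceeds the peak of the
# host-gene (single-copy ortholog) identity distribution is anomalous under
# vertical descent; (2) phylogenetic incongruence — elements failing to
# group by host species; (3) intra-family Ks asymmetry assigns the
# donor/recipient direction (the recipient's copies radiated recently and
# show low synonymous divergence).

#' Identity screen of a cross-species element pair
#'
#' TRUE iff the pair's identity with gaps excluded strictly exceeds the
#' peak of the gaps-excluded ortholog identity distribution AND its
#' identity with gaps included strictly exceeds the peak of the
#' gaps-included distribution.
#'
#' @param te_identity An `identity_result` for the element pair.
#' @param ortholog_dist_excl,ortholog_dist_incl `identity_distribution`
#'   objects of ortholog identities, gaps excluded / included.
#' @return Logical.
#' @export
screen_pair <- function(te_identity, ortholog_dist_excl,
                        ortholog_dist_incl) {
  stopifnot(inherits(te_identity, "identity_result"),
            inherits(ortholog_dist_excl, "identity_distribution"),
            inherits(ortholog_dist_incl, "identity_distribution"))
  te_identity$identity_without_gaps > ortholog_dist_excl$peak &&
    te_identity$identity_with_gaps > ortholog_dist_incl$peak
}

#' Donor/recipient direction from intra-family Ks asymmetry
#'
#' The side whose intra-family synonymous divergence is lower radiated more
#' recently and is the recipient candidate — but only when the two means
#' differ by more than the larger of the two standard deviations.
#'
#' @param family_ks_a,family_ks_b Numeric vectors (>= 1 value each) of
#'   intra-family Ks values for the two species.
#' @param label_a,label_b Names used in the verdict.
#' @return List with per-side `mean`/`sd` and `recipient` (one of the
#'   labels, or `"inconclusive"`).
#' @export
ks_asymmetry <- function(family_ks_a, family_ks_b,
                         label_a = "A", label_b = "B") {
  if (length(family_ks_a) == 0L || length(family_ks_b) == 0L) {
    stop("ks_asymmetry: both Ks lists must be non-empty")
  }
  m_a <- mean(family_ks_a)
  m_b <- mean(family_ks_b)
  s_a <- if (length(family_ks_a) > 1L) stats::sd(family_ks_a) else 0
  s_b <- if (length(family_ks_b) > 1L) stats::sd(family_ks_b) else 0
  recipient <- if (abs(m_a - m_b) > max(s_a, s_b)) {
    if (m_a < m_b) label_a else label_b
  } else {
    "inconclusive"
  }
  list(mean_a = m_a, sd_a = s_a, mean_b = m_b, sd_b = s_b,
       recipient = recipient)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining. Negative branch lengths are
#' clamped to zero with the deficit transferred to the sister branch; ties
#' in the Q criterion are broken deterministically by the smallest label
#' index pair.
#'
#' @param d Symmetric numeric matrix with zero diagonal, n >= 3.
#' @param labels Leaf labels (defaults to the matrix dimnames).
#' @return An [ape::read.tree()] `phylo` object (unrooted).
#' @export
nj_tree <- function(d, labels = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("nj_tree: need at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0)) {
    stop("nj_tree: distance matrix must be symmetric with zero diagonal")
  }
  if (is.null(labels)) labels <- rownames(d) %||% paste0("t", seq_len(n))
  stopifnot(length(labels) == n, !anyDuplicated(labels))

  fmt <- function(x) sprintf("%.10g", max(x, 0))
  # clamp a pair of sister branch lengths, moving any deficit to the sister
  clamp2 <- function(vi, vj) {
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    c(max(vi, 0), max(vj, 0))
  }
  nodes <- as.list(labels)     # Newick fragment per active node
  act <- seq_len(n)            # original label index carried for tie-breaks
  D <- d
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(D)
    best <- NULL
    for (i in 1:(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (min(act[i], act[j]) < min(act[best$i], act[best$j]) ||
              (min(act[i], act[j]) == min(act[best$i], act[best$j]) &&
               max(act[i], act[j]) < max(act[best$i], act[best$j]))))) {
          best <- list(i = i, j = j, q = q)
        }
      }
    }
    i <- best$i
    j <- best$j
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    v <- clamp2(vi, vj)
    new_frag <- paste0("(", nodes[[i]], ":", fmt(v[1L]), ",",
                       nodes[[j]], ":", fmt(v[2L]), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- matrix(0, m - 1L, m - 1L)
    if (length(keep)) {
      D2[seq_along(keep), seq_along(keep)] <- D[keep, keep, drop = FALSE]
      D2[m - 1L, seq_along(keep)] <- dk[keep]
      D2[seq_along(keep), m - 1L] <- dk[keep]
    }
    nodes <- c(nodes[keep], new_frag)
    act <- c(act[keep], min(act[c(i, j)]))
    D <- D2
  }
  # terminal join of the last three nodes at a single internal vertex
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- paste0("(", nodes[[1L]], ":", fmt(v1), ",",
                   nodes[[2L]], ":", fmt(v2), ",",
                   nodes[[3L]], ":", fmt(v3), ");")
  ape::read.tree(text = newick)
}

#' Species monophyly on an unrooted tree
#'
#' A species is monophyletic iff some edge of the unrooted tree splits
#' exactly that species' leaves from all others (single-leaf species are
#' monophyletic by definition). The overall violation flag is TRUE when any
#' species with at least two leaves is non-monophyletic.
#'
#' @param tree A `phylo` object.
#' @param species Named character vector mapping every leaf label to its
#'   species.
#' @return List with `per_species` (named logical) and
#'   `monophyly_violation`.
#' @export
species_monophyly <- function(tree, species) {
  tips <- tree$tip.label
  unmapped <- setdiff(tips, names(species))
  if (length(unmapped)) {
    stop("species_monophyly: unmapped leaf label(s): ",
         paste(unmapped, collapse = ", "))
  }
  species <- species[tips]
  ntip <- length(tips)
  # descendant tip sets of every internal node = one side of every split
  splits <- lapply(ape::prop.part(tree), function(ix) sort(ix))
  per <- vapply(unique(species), function(sp) {
    leaves <- sort(which(species == sp))
    if (length(leaves) <= 1L || length(leaves) == ntip) return(TRUE)
    comp <- sort(setdiff(seq_len(ntip), leaves))
    any(vapply(splits, function(s) identical(s, leaves) ||
                 identical(s, comp), logical(1L)))
  }, logical(1L))
  names(per) <- unique(species)
  list(
    per_species = per,
    monophyly_violation = any(!per & table(species)[names(per)] >= 2L)
  )
}

#' Screen one element family for horizontal transfer
#'
#' For each pair of species represented in the family, the maximum-identity
#' cross-species element pair (identified by global alignment of whole
#' elements, as in manual HT candidate selection) is screened against the
#' ortholog identity peaks; a neighbor-joining tree of Jukes-Cantor
#' element distances is tested for species-monophyly violation; and
#' intra-species integrase Ks values assign the donor/recipient direction.
#' The final call is `"HT-candidate"` only when the identity test passes
#' AND monophyly is violated; `"vertical"` when the identity test fails;
#' `"inconclusive"` otherwise.
#'
#' @param seqs Named character vector of full element sequences (one
#'   family).
#' @param species Named character vector mapping element ids to species.
#' @param ortholog_dist_excl,ortholog_dist_incl Ortholog
#'   `identity_distribution` objects (gaps excluded / included).
#' @param min_domain_score Score threshold for integrase detection.
#' @return List with `report` (one row per species pair: ids, identities,
#'   peaks, tests, Ks means, recipient, final call), `tree` (`phylo` or
#'   NULL when fewer than 3 elements), and `monophyly`.
#' @export
screen_family_ht <- function(seqs, species, ortholog_dist_excl,
                             ortholog_dist_incl, min_domain_score = 100) {
  ids <- names(seqs)
  stopifnot(!is.null(ids), all(ids %in% names(species)))
  species <- species[ids]
  n <- length(seqs)
  report <- data.frame(
    species_a = character(0L), species_b = character(0L),
    element_a = character(0L), element_b = character(0L),
    identity_without_gaps = numeric(0L), identity_with_gaps = numeric(0L),
    peak_excl = numeric(0L), peak_incl = numeric(0L),
    identity_test = logical(0L), monophyly_violation = logical(0L),
    ks_mean_a = numeric(0L), ks_sd_a = numeric(0L),
    ks_mean_b = numeric(0L), ks_sd_b = numeric(0L),
    recipient = character(0L), final_call = character(0L),
    stringsAsFactors = FALSE
  )
  sp_levels <- unique(species)
  if (length(sp_levels) < 2L) {
    return(list(report = report, tree = NULL, monophyly = NULL))
  }

  # all-pairs alignment: identities + JC distances from one pass
  idm <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  idg <- idm
  Djc <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- align_global(seqs[[i]], seqs[[j]])
      m <- identity_metrics(aln)
      idm[i, j] <- idm[j, i] <- m$identity_without_gaps
      idg[i, j] <- idg[j, i] <- m$identity_with_gaps
      Djc[i, j] <- Djc[j, i] <- jukes_cantor(p_distance(aln))
    }
  }

  tree <- NULL
  mono <- NULL
  violation <- NA
  if (n >= 3L) {
    tree <- nj_tree(Djc)
    mono <- species_monophyly(tree, species)
    violation <- mono$monophyly_violation
  }

  # intra-species integrase Ks lists
  int_cds <- lapply(seqs, function(s) {
    hits <- detect_domains(s, min_score = min_domain_score)
    if (!"INT" %in% hits$name) return(NULL)
    h <- hits[hits$name == "INT", ][1L, ]
    substr0(s, h$start, h$end)
  })
  ks_list <- lapply(sp_levels, function(sp) {
    members <- ids[species == sp]
    cds <- Filter(Negate(is.null), int_cds[members])
    if (length(cds) < 2L) return(numeric(0L))
    out <- numeric(0L)
    nm <- length(cds)
    for (i in 1:(nm - 1L)) {
      for (j in (i + 1L):nm) {
        ca <- codon_align(cds[[i]], cds[[j]], mask_stops = TRUE)
        out <- c(out, tryCatch(ng86_kaks(ca$a, ca$b)$Ks,
                               error = function(e) NA_real_))
      }
    }
    out[!is.na(out)]
  })
  names(ks_list) <- sp_levels

  for (ai in 1:(length(sp_levels) - 1L)) {
    for (bi in (ai + 1L):length(sp_levels)) {
      sa <- sp_levels[ai]
      sb <- sp_levels[bi]
      ia <- which(species == sa)
      ib <- which(species == sb)
      sub <- idm[ia, ib, drop = FALSE]
      w <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
      ea <- ids[ia[w[1L]]]
      eb <- ids[ib[w[2L]]]
      idr <- structure(
        list(I = NA, M = NA, G = NA,
             identity_without_gaps = idm[ea, eb],
             identity_with_gaps = idg[ea, eb]),
        class = "identity_result"
      )
      id_test <- screen_pair(idr, ortholog_dist_excl, ortholog_dist_incl)
      ks <- if (length(ks_list[[sa]]) >= 1L && length(ks_list[[sb]]) >= 1L) {
        ks_asymmetry(ks_list[[sa]], ks_list[[sb]], sa, sb)
      } else {
        list(mean_a = NA_real_, sd_a = NA_real_, mean_b = NA_real_,
             sd_b = NA_real_, recipient = "inconclusive")
      }
      call <- if (!id_test) {
        "vertical"
      } else if (isTRUE(violation)) {
        "HT-candidate"
      } else {
        "inconclusive"
      }
      report <- rbind(report, data.frame(
        species_a = sa, species_b = sb, element_a = ea, element_b = eb,
        identity_without_gaps = idm[ea, eb],
        identity_with_gaps = idg[ea, eb],
        peak_excl = ortholog_dist_excl$peak,
        peak_incl = ortholog_dist_incl$peak,
        identity_test = id_test,
        monophyly_violation = isTRUE(violation),
        ks_mean_a = ks$mean_a, ks_sd_a = ks$sd_a,
        ks_mean_b = ks$mean_b, ks_sd_b = ks$sd_b,
        recipient = ks$recipient, final_call = call,
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(report) <- NULL
  list(report = report, tree = tree, monophyly = mono)
}
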