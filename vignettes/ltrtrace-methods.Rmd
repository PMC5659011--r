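---
title: "Models and methods behind ltrtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ltrtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ltrtrace` annotates intact LTR retrotransposons (LTR-RTs) with
non-canonical terminal dinucleotides, groups them into families, dates
their insertions from LTR divergence, and screens cross-species element
pairs for horizontal transfer (HT) against a host-gene divergence null.
This vignette documents the models, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the design choices made where more than one defensible construction
existed. Nothing here states an empirical result that the package's tests
or `scripts/acceptance.R` do not themselves compute.

## The structural model of an intact element

An intact LTR-RT is modelled as

```
5'-TSD | LTR ... internal ... LTR | TSD-3'
```

with two near-identical long terminal repeats (LTRs), byte-identical at
the moment of insertion; a 4–6 bp target site duplication (TSD) — host
sequence duplicated on both flanks by the integrase's staggered cut; and
terminal dinucleotides at the outer ends of the LTRs, canonically TG…CA
but here also TG…TT and AA…CA. The internal region of an autonomous
element encodes GAG and the pol-domain chain (PR, INT, RT, RH);
non-autonomous TRIM elements have short, non-coding internal regions.
Coordinates are 0-based half-open everywhere inside the toolkit and are
converted to 1-based inclusive only in GFF3 output.

## Structural discovery

`find_ltr_candidates()` works in three stages:

1. **Anchoring.** All exact `anchor_k`-mer matches (default k = 15)
   whose separation is compatible with the distance between the two LTR
   starts of a plausible element (derived from the length bounds) are
   collected and chained into clusters by diagonal (±20 bp) and position
   (gap ≤ `max_ltr`). k = 15 makes chance anchors rare (4⁻¹⁵ per position
   pair) while divergent LTR pairs of a few percent still share many
   clean 15-mers.
2. **Extension.** Each cluster is extended outward with an X-drop scheme:
   +1 per matching column, −1 per mismatch, abandoning 30 below the
   running maximum; the argmax is the boundary estimate. This tolerates
   the mismatch density of aged LTRs while stopping within a few bp of
   the repeat edge.
3. **Boundary refinement.** Within ±25 bp of the extension estimate,
   every (element start, element end) pair with a qualifying TSD is
   scored additively:

   * ungapped LTR match score (+1 match / −1 mismatch), which is maximal
     at the true repeat extent;
   * +6 when a listed terminal-dinucleotide pair co-occurs consistently
     on both LTRs (on either strand reading);
   * +2 per TSD base above the 4-bp minimum, −8 per TSD mismatch.

   The weights approximate the log-odds of each signal against chance on
   the match-column scale (a chance exact 4-bp TSD pair occurs at ~0.5%
   per boundary pair; a chance listed motif reading at ~0.4%). We found a
   strict lexicographic preference — e.g. "outermost boundary with motif
   and TSD first" — brittle in both directions: spurious one-mismatch
   TSDs in random flanks drag boundaries outward, and when aging has
   mutated a terminal dinucleotide, chance in-repeat motif readings beat
   the true boundary. The additive score resolves both failure modes and
   recovers planted elements to ≤2 bp (see the acceptance suite).

Direct-repeat structure is strand-symmetric, so one plus-strand scan
covers both strands; the strand is assigned from the motif reading
(an element reading AA…CA on the plus strand is a minus-strand TG…TT
element when only TG…TT is listed). Overlapping candidates keep the
higher LTR identity, ties broken by length. Fragments, solo LTRs and
nested elements are out of scope and never reported.

`validate_tsd()` re-examines windows from `tsd_max` (6) down to
`tsd_min` (4) and accepts the longest window with at most
`tsd_max_mismatch` (1) mismatches, the standard annotation rule;
candidates at a contig edge are rejected explicitly.

The candidate gate `min_ltr_pair_identity` (default 85%) is a package
decision — structural annotators do not publish an equivalent threshold —
and is exposed as a parameter. It trades sensitivity to very old elements
against false positives; at the default, dinucleotide-shuffled controls
of multi-element genomes yield zero candidates.

## Families and superfamilies

`cluster_families()` implements the 80/80 rule: an edge between two
elements exists when a global alignment of their 5′ LTRs shows identity
(gaps excluded) strictly above 80% over an aligned span of at least 80%
of the shorter LTR; families are single-linkage components. Single
linkage is the natural closure of a pairwise criterion (the rule itself
names no linkage); the 5′ LTR is used for determinism. Both thresholds
are parameters. Sub-groups that differ in length but still satisfy the
rule stay in one family; no special-casing.

`detect_domains()` translates all six frames and locally aligns each
packaged consensus peptide with BLOSUM62 (gap open 11, extend 1),
reporting at most the best hit per domain above `min_score` (default
100). The packaged peptides are fixed synthetic consensus sequences
carrying each domain's canonical catalytic motifs (DTGA in PR, the
"xPFGL…YxDD" RT signature, and so on); they are not derived from any
external profile database, and the same strings are what the synthetic
genome embeds, so detection is closed over the toolkit's own ground
truth. The default threshold sits far above the empirical null on random
sequence (maximum local scores around 40–50 over 2-kb draws) and far
below a true hit (≥ 176 even after several My of simulated divergence).

`classify_superfamily()` uses domain order: INT before RT is *Copia*,
RT before INT is *Gypsy*; neither domain plus an internal region of at
most `trim_max_internal` (default 3000 bp, generalising observed TRIM
internals of 1641–2042 bp) is TRIM; anything else is unknown.

## Dating

For each element the two LTR spans are aligned globally and

* p = mismatched non-gap columns / all non-gap columns (gap and N
  columns excluded — the correction below models substitutions only);
* K = −(3/4)·ln(1 − 4p/3), the Jukes–Cantor multiple-hit correction,
  with a saturation error at p ≥ 3/4;
* T = K/(2r), with r = 1.3 × 10⁻⁸ substitutions per site per year, the
  LTR rate commonly applied in plants. The factor 2 is there because both
  LTRs accumulate substitutions independently after insertion.

`summarize_ages()` bins ages into [0, 1), [1, 3] and (3, ∞) Mya —
exactly 1.0 or 3.0 My falls in the middle class — and rounds percentages
half-up to two decimals, reproducing printed spectra exactly from their
integer counts. The identical-LTR share (p = 0) is reported over all
estimates.

Alignment scoring defaults (match +2, mismatch −2, gap open 6, extend 1,
a gap of length L costing open + L·extend) are deliberately gap-averse so
that short LTR pairs, which diverge by substitutions in this model, are
not over-gapped; they are exposed as arguments. Tie-breaking among
equally optimal alignments follows the underlying alignment engine and
is deterministic; only the optimal score is contractually fixed (and is
verified against an exhaustive dynamic-programming oracle in the tests).

## Divergence metrics

`identity_metrics()` classifies alignment columns into identical (I),
mismatch (M) and gap (G; N columns are excluded entirely) and reports
both 100·I/(I+M) (gaps excluded) and 100·I/(I+M+G) (gaps included);
the latter never exceeds the former.

`ng86_kaks()` implements Nei–Gojobori (1986): synonymous site fractions
per codon position (changes to stop codons count as nonsynonymous,
keeping s + n = 3), site counts averaged over the two sequences, observed
differences averaged over all substitution pathways for multi-hit codons
(pathways through stop codons are skipped unless all are blocked), and
Jukes–Cantor correction applied separately to the synonymous and
nonsynonymous proportions. NG86 was chosen over a maximum-likelihood
counterpart because it is fully specifiable and checkable against an
independent pathway-enumeration oracle; downstream conclusions use Ks
only ordinally (is one side's intra-family Ks much lower than the
other's), for which the counting method is immaterial. Note that very
short inputs saturate: a single codon with one synonymous difference has
ps = 3, so the correction is undefined and an error is raised — Ka/Ks is
a gene-scale statistic.

`codon_align()` aligns translations globally, back-maps to nucleotides
and drops gapped codon columns; with `mask_stops = TRUE` it also drops
codon columns where either sequence carries an in-frame stop, the
standard preparation for Ka/Ks on degenerate retroelement ORFs.

`rbh_orthologs()` applies the reciprocal-best-hit criterion on global
alignment scores of translated peptides, excluding genes with tied best
scores and sequences with frame errors or internal stops — mirroring the
practice of excluding frame-shifted or stop-containing gene models from
divergence estimates.

`identity_distribution()` bins percent identities into fixed-width,
right-open bins anchored at 0 (width 1% by default) and reports the
midpoint of the modal bin as the peak, ties resolved toward the higher
bin, so the peak is bit-reproducible. The peak, not the mean, indexes
overall genomic divergence: it is robust to the low-identity tail of
fast-evolving genes.

## Horizontal-transfer screening

The evidence stack for calling a cross-species element pair horizontal:

1. **Identity above the host-gene peak** (`screen_pair`): the pair's
   identity with gaps excluded must strictly exceed the peak of the
   gaps-excluded ortholog identity distribution, and its identity with
   gaps included the gaps-included peak. A transposon more conserved
   across species than single-copy host genes is anomalous under
   vertical descent.
2. **Phylogenetic incongruence** (`nj_tree` + `species_monophyly`): a
   neighbor-joining tree of Jukes–Cantor distances over the family's full
   element sequences; a species is monophyletic iff some edge of the
   unrooted tree splits exactly its leaves from the rest (single-leaf
   species trivially so), and the violation flag is set when any species
   with ≥2 leaves fails. NJ replaces a bootstrapped ML tree because the
   argument needs topology, not support values, and NJ is deterministic
   and exactly checkable (it recovers additive matrices, verified over
   random 6-taxon trees and cross-checked against an independent NJ
   implementation). Negative NJ branch lengths are clamped to zero with
   the deficit moved to the sister branch; Q-criterion ties break by
   smallest label index.
3. **Direction from Ks asymmetry** (`ks_asymmetry`): intra-family
   integrase Ks per species; the lower-mean side is the recipient
   candidate (its copies radiated only since the transfer), but only
   when the means differ by more than the larger standard deviation.
   Direction never affects the HT call itself.

`screen_family_ht()` composes these per family: for each species pair it
screens the maximum-identity cross-species element pair (as a manual
analysis would pick the most similar pair), and calls it
`HT-candidate` only when the identity test passes *and* monophyly is
violated; `vertical` when the identity test fails; `inconclusive`
otherwise.

One structural point deserves emphasis. With only two species in a
family, a single introduced clade can never violate split-based
monophyly: the edge leading to the introduced clade always separates
exactly it from everything else, so both species remain monophyletic no
matter where the clade attaches. Real HT cases are diagnosed against
additional family members from other lineages, which anchor the tree and
expose the donor species' paraphyly. The synthetic end-to-end scenario
therefore includes a third, vertically inheriting species (below).

## The synthetic-data generator

What it emulates: background contigs of configurable GC (default 0.38,
a plant-like euchromatic value); elements with configurable LTR length,
internal length, terminal dinucleotides, embedded domain order and 4–6 bp
TSDs; post-insertion divergence as independent per-site substitutions at
rate r on both LTRs and the internal region (per-site substitution
probability 1 − e^(−rT), replacement uniform over the three
alternatives — the small-divergence approximation whose expectation the
Jukes–Cantor dating inverts, Monte-Carlo-verified in the tests);
retrotransposition (`retranspose()`) resetting the LTR pair to identity;
and single-copy ortholog CDS pairs hitting a target identity spectrum
(default mean 86.57%, sd 3.59%, n 822, the observed apple–peach
single-copy ortholog distribution) through stop-free point substitutions.

What it does not emulate — hence what passing tests do not show about
real data: no indels (the dating formula models substitutions; gapped
alignment is exercised with constructed cases instead), no nested or
truncated elements, no solo LTRs, no transposition bursts, no rate
variation across loci or lineages, and no selection (aged ORFs
accumulate in-frame stops, which is why the HT screen masks stop codons
before Ka/Ks). Structured real genomes (tandem repeats, segmental
duplications) will stress the finder in ways i.i.d. backgrounds do not.

`simulate_ht_scenario()` builds the full three-species test case:

* **species A (donor)**: four copies inserted 0.9–3.0 Mya whose source
  lineages diverged 0–8 My from the family ancestor. Splitting radiation
  depth from insertion age mirrors retrotransposition (new copies get
  fresh identical LTRs from an already-diverged template) and produces
  the observed pattern of young LTR ages alongside substantial
  intra-family integrase Ks;
* **species C (vertical outgroup)**: the family predates the A/C split
  (10 My); C's own copies are 2–3 My old. Their ~83% identity to A
  elements sits below the ortholog identity peak, as vertical descent
  predicts, while still above the 80/80 family threshold;
* **species B (recipient)**: the donor element's sequence plus 7% extra
  template divergence, re-inserted 0.43–0.6 Mya. The transferred pair
  lands at ≈92% identity — above the ortholog peak — with young LTR ages
  in B, a B clade nested inside A's radiation (breaking A's monophyly
  once C anchors the tree), and near-zero intra-B Ks.

All generators are pure functions of (inputs, seed); the RNG state of the
calling session is saved and restored around every draw.

## Problem sizes and runtime choices

The acceptance suite uses the study-scale problem sizes throughout: the
printed 91-element age spectrum; 20 planted elements in a 2-Mb genome
(recovery to ≤2 bp, shuffled control clean); 200 elements with 500-bp
LTRs for dating-rate recovery at T = 1 My; 200 random short pairs against
the exhaustive alignment oracle; 100 random codon pairs against the NG86
pathway oracle; 50 additive 6-taxon matrices for NJ; and the three-species
HT scenario with 822 simulated ortholog pairs. Unit tests use smaller
replicates of the same constructions. The whole suite runs in a few
minutes on one CPU; the dominant cost is the 822 ortholog pair alignments
and the ~30 full-length (5-kb) element alignments of the HT scenario.

## Known limitations

* The finder assumes substitution-only divergence between LTR copies;
  large indels inside one LTR would break the single-diagonal anchoring
  assumption (real annotators face the same trade-off and fall back to
  manual inspection).
* Family identity uses the 5′ LTR only; elements whose 5′ LTR was
  locally degraded could mis-cluster even when the 3′ LTR is intact.
* The Ks-based identity measure sometimes quoted alongside the two
  gap-based identities has no published transformation from Ks to
  percent identity; it is deliberately not implemented.
* `ks_asymmetry` needs at least one intra-species integrase pair per
  side; families represented by a single copy per species get direction
  `inconclusive` (the HT call itself does not depend on direction).
* Bootstrap support values for trees are out of scope; NJ topology plus
  the split test carry the monophyly argument.
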