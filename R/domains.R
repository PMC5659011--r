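# Internal protein-domain library for superfamily classification.
#
# Each entry is a short synthetic consensus peptide standing in for the
# corresponding retroelement domain (GAG capsid, PR protease, INT integrase,
# RT reverse transcriptase, RH ribonuclease H). The strings are fixed,
# invented consensus sequences that carry the canonical catalytic motifs of
# each domain (DTGA in PR, the zinc-binding/DDE flavour in INT, the
# "xPFGL...YxDD" signature in RT); they are NOT extracted from any external
# profile database. The same library is used by the synthetic-genome module
# to embed detectable coding regions, so detection is closed over the
# toolkit's own ground truth.

.DOMAIN_PEPTIDES <- c(
  GAG = "MSSNKGKEPAVEWTREELQALFAEWGISRSAYNRRLNGQMKLSPEQAA",
  PR  = "LVDTGASDNFARPETVQRLGLKVEPLSKPLSVSLAD",
  INT = "GHFGVQKTYDRVRREFYWPGMKREIERYVSECDVCQRNKSETQKPAGLLQPLPI",
  RT  = "KTAFRTHEGHYEYLVMPFGLTNAPATFQALMNDVLRPFLDKFVVVYLDDILVYSRTLEE",
  RH  = "LRGKLYANRSKCAFGQREVEFLGHIVSAEGIKPDPEKVQAIREWPTPT"
)

#' Packaged domain consensus peptides
#'
#' Returns the named character vector of synthetic consensus peptides used
#' both to build synthetic internal regions and to detect domains in
#' candidate elements. Names are the five retroelement domains
#' GAG, PR, INT, RT, RH.
#' @return Named character vector of amino-acid strings.
#' @export
ltr_domain_peptides <- function() .DOMAIN_PEPTIDES

# Most-frequent-codon back-translation table (one fixed codon per residue;
# deterministic by construction).
.PREFERRED_CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
  Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
  L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
  S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT"
)

#' Back-translate a peptide with fixed preferred codons
#' @param peptide Amino-acid string (20 standard residues).
#' @return Nucleotide string of length `3 * nchar(peptide)`.
#' @export
back_translate <- function(peptide) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  bad <- setdiff(aa, names(.PREFERRED_CODON))
  if (length(bad)) stop("back_translate: unsupported residue(s): ",
                        paste(unique(bad), collapse = ", "))
  paste(.PREFERRED_CODON[aa], collapse = "")
}

.GENETIC_CODE <- Biostrings::GENETIC_CODE

translate_codon <- function(codon) unname(.GENETIC_CODE[codon])

is_stop_codon <- function(codon) translate_codon(codon) == "*"

#' Translate a nucleotide string in all six frames
#'
#' @param seq Nucleotide string.
#' @return List of six amino-acid strings named f0,f1,f2 (forward frames,
#'   offsets 0-2) and r0,r1,r2 (frames of the reverse complement). Stop
#'   codons appear as `*`.
#' @export
translate_frames <- function(seq) {
  one <- function(s, off) {
    n <- nchar(s) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, off + 1L, off + n)),
      if.fuzzy.codon = "X"
    ))
  }
  rc <- revcomp(seq)
  list(
    f0 = one(seq, 0L), f1 = one(seq, 1L), f2 = one(seq, 2L),
    r0 = one(rc, 0L), r1 = one(rc, 1L), r2 = one(rc, 2L)
  )
}
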