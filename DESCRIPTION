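Package: ltrtrace
Title: Discovery, Dating and Horizontal-Transfer Screening of
    Non-Canonical LTR Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Structural discovery of intact long terminal repeat (LTR)
    retrotransposons with non-canonical terminal dinucleotides (TG..TT,
    AA..CA) in genomic contigs, validation of 4-6 bp target site
    duplications, grouping of elements into families by the 80/80 LTR
    identity rule, superfamily calls (Copia/Gypsy/TRIM) from internal
    protein-domain order, Jukes-Cantor dating of insertions from LTR
    divergence (T = K/2r), Nei-Gojobori (1986) Ka/Ks, reciprocal-best-hit
    single-copy orthologs, and screening of candidate horizontal
    transposon transfers by comparing cross-species element identity
    against an orthologous-gene identity null distribution together with
    neighbor-joining species-monophyly tests. A synthetic-genome module
    plants aged elements with full ground truth so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
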