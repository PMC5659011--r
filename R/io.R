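# File formats and the pipeline driver.
#
# Internally every span is 0-based half-open; GFF3 output converts to
# 1-based inclusive. FASTA handling goes through Biostrings.

#' Read a FASTA file into a named contig vector
#'
#' Record order and ids (first whitespace-delimited token of each header)
#' are preserved; sequence is uppercased.
#'
#' @param path FASTA file.
#' @return Named character vector of contigs.
#' @export
read_fasta_contigs <- function(path) {
  if (!file.exists(path)) stop("read_fasta_contigs: no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("read_fasta_contigs: duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- toupper(as.character(set))
  names(out) <- ids
  out
}

#' Write contigs to FASTA
#' @param contigs Named character vector.
#' @param path Output file.
#' @param width Line width.
#' @export
write_fasta <- function(contigs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(contigs)) {
    writeLines(paste0(">", id), con)
    s <- contigs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

# attribute-string helpers for round-tripping element records through GFF3
.gff_escape <- function(x) gsub(";", "%3B", gsub("=", "%3D", x))

#' Write element records as GFF3
#'
#' Each element becomes an `LTR_retrotransposon` feature with
#' `long_terminal_repeat` children and (when a TSD was validated) two
#' `target_site_duplication` children linked by `Parent`. Coordinates are
#' converted from the internal 0-based half-open convention to GFF3's
#' 1-based inclusive one. All record fields are carried as attributes so
#' the file round-trips through [read_gff3_elements()].
#'
#' @param elements Element record data.frame.
#' @param path Output file.
#' @export
write_gff3 <- function(elements, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(elements))) {
    r <- elements[i, ]
    attr_main <- sprintf(
      paste0("ID=%s;ltr_identity=%.15g;start_dinuc=%s;end_dinuc=%s;",
             "motif_label=%s;tsd_left=%s;tsd_right=%s;tsd_len=%s;",
             "tsd_mismatch=%s;tsd_status=%s"),
      r$element_id, r$ltr_identity, .gff_escape(r$start_dinuc),
      .gff_escape(r$end_dinuc), .gff_escape(r$motif_label),
      r$tsd_left, r$tsd_right, r$tsd_len, r$tsd_mismatch, r$tsd_status
    )
    row9 <- function(type, s, e, attrs) {
      sprintf("%s\tltrtrace\t%s\t%d\t%d\t.\t%s\t.\t%s",
              r$contig, type, s + 1L, e, r$strand, attrs)
    }
    lines <- c(
      lines,
      row9("LTR_retrotransposon", r$start, r$end, attr_main),
      row9("long_terminal_repeat", r$ltr5_start, r$ltr5_end,
           sprintf("ID=%s_ltr5;Parent=%s", r$element_id, r$element_id)),
      row9("long_terminal_repeat", r$ltr3_start, r$ltr3_end,
           sprintf("ID=%s_ltr3;Parent=%s", r$element_id, r$element_id))
    )
    if (!is.na(r$tsd_status) && r$tsd_status == "ok") {
      lines <- c(
        lines,
        row9("target_site_duplication", r$start - r$tsd_len, r$start,
             sprintf("ID=%s_tsd5;Parent=%s", r$element_id, r$element_id)),
        row9("target_site_duplication", r$end, r$end + r$tsd_len,
             sprintf("ID=%s_tsd3;Parent=%s", r$element_id, r$element_id))
      )
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read element records back from GFF3 written by [write_gff3()]
#'
#' @param path GFF3 file.
#' @return Element record data.frame equivalent to the one written.
#' @export
read_gff3_elements <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) return(.empty_elements())
  f <- strsplit(lines, "\t", fixed = TRUE)
  parse_attrs <- function(s) {
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    stats::setNames(vapply(kv, function(x) if (length(x) > 1L) x[2L] else "",
                           character(1L)),
                    vapply(kv, `[[`, character(1L), 1L))
  }
  main <- f[vapply(f, `[[`, character(1L), 3L) == "LTR_retrotransposon"]
  ltrs <- f[vapply(f, `[[`, character(1L), 3L) == "long_terminal_repeat"]
  rows <- lapply(main, function(x) {
    at <- parse_attrs(x[9L])
    id <- at[["ID"]]
    my_ltrs <- Filter(function(l) {
      a <- parse_attrs(l[9L])
      identical(a[["Parent"]], id)
    }, ltrs)
    stopifnot(length(my_ltrs) == 2L)
    l_starts <- vapply(my_ltrs, function(l) as.integer(l[4L]) - 1L,
                       integer(1L))
    l_ends <- vapply(my_ltrs, function(l) as.integer(l[5L]), integer(1L))
    o <- order(l_starts)
    to_int <- function(v) if (v == "NA") NA_integer_ else as.integer(v)
    data.frame(
      element_id = id, contig = x[1L], strand = x[7L],
      start = as.integer(x[4L]) - 1L, end = as.integer(x[5L]),
      ltr5_start = l_starts[o[1L]], ltr5_end = l_ends[o[1L]],
      ltr3_start = l_starts[o[2L]], ltr3_end = l_ends[o[2L]],
      ltr_identity = as.numeric(at[["ltr_identity"]]),
      start_dinuc = at[["start_dinuc"]], end_dinuc = at[["end_dinuc"]],
      motif_label = at[["motif_label"]],
      tsd_left = at[["tsd_left"]], tsd_right = at[["tsd_right"]],
      tsd_len = to_int(at[["tsd_len"]]),
      tsd_mismatch = to_int(at[["tsd_mismatch"]]),
      tsd_status = at[["tsd_status"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# TSV writer with the coordinate-convention header comment
.write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based half-open", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' @param genomes Named character vector of FASTA paths, one per species
#'   (names are species ids); alternatively a named list of in-memory
#'   contig vectors via `genome_seqs`.
#' @param genome_seqs Optional named list (species -> named contig vector)
#'   used instead of reading `genomes` from disk.
#' @param species_of_contig Named character vector mapping contig ids to
#'   species (defaults to one species per input genome, all contigs).
#' @param ortholog_pairs Optional data.frame with CDS columns `a` and `b`
#'   (e.g. from [simulate_ortholog_pairs()]) supplying the host-gene
#'   identity null distribution.
#' @param finder A [finder_params()] object.
#' @param r Substitution rate per site per year.
#' @param bin_width Identity-histogram bin width (percent).
#' @param identity_threshold,coverage_threshold Family-clustering
#'   thresholds (percent).
#' @param min_domain_score Domain-calling score threshold.
#' @param seed Integer seed recorded in the run log.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genomes = NULL, genome_seqs = NULL,
                            species_of_contig = NULL,
                            ortholog_pairs = NULL,
                            finder = finder_params(), r = 1.3e-8,
                            bin_width = 1,
                            identity_threshold = 80,
                            coverage_threshold = 80,
                            min_domain_score = 100,
                            seed = 1L, out_dir = tempfile("ltrtrace_run_")) {
  if (is.null(genomes) && is.null(genome_seqs)) {
    stop("pipeline_config: supply genomes (FASTA paths) or genome_seqs")
  }
  if (!is.numeric(r) || r <= 0) stop("pipeline_config: r must be positive")
  structure(
    list(genomes = genomes, genome_seqs = genome_seqs,
         species_of_contig = species_of_contig,
         ortholog_pairs = ortholog_pairs, finder = finder, r = r,
         bin_width = bin_width, identity_threshold = identity_threshold,
         coverage_threshold = coverage_threshold,
         min_domain_score = min_domain_score,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the whole pipeline: find, classify, date, divergence, HT screen
#'
#' Executes structural discovery on every contig, TSD validation and motif
#' labelling, family clustering, superfamily classification, insertion-time
#' dating, ortholog identity distributions, and HT screening of every
#' family present in more than one species. Writes GFF3, TSVs, Newick trees
#' and a YAML run log into `config$out_dir`; outputs are a pure function of
#' (inputs, config, seed).
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list bundle with `elements`, `families`,
#'   `family_table`, `ages`, `age_summary`, `ortholog_identity`,
#'   `ht_reports`, `trees` and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- load genomes -----------------------------------------------------
  genome_seqs <- config$genome_seqs
  if (is.null(genome_seqs)) {
    genome_seqs <- lapply(config$genomes, read_fasta_contigs)
    names(genome_seqs) <- names(config$genomes)
  }
  contigs <- do.call(c, unname(genome_seqs))
  species_of_contig <- config$species_of_contig
  if (is.null(species_of_contig)) {
    species_of_contig <- unlist(lapply(names(genome_seqs), function(sp) {
      stats::setNames(rep(sp, length(genome_seqs[[sp]])),
                      names(genome_seqs[[sp]]))
    }))
  }

  # ---- find -------------------------------------------------------------
  elements <- find_elements(contigs, config$finder)
  element_seq <- function(r) substr0(contigs[[r$contig]], r$start, r$end)
  ltr5_seq <- function(r) substr0(contigs[[r$contig]], r$ltr5_start,
                                  r$ltr5_end)

  # ---- classify ---------------------------------------------------------
  families <- list()
  fam_of <- character(0L)
  superfam <- character(0L)
  if (nrow(elements) > 0L) {
    ltrs <- vapply(seq_len(nrow(elements)),
                   function(i) ltr5_seq(elements[i, ]), character(1L))
    names(ltrs) <- elements$element_id
    families <- cluster_families(ltrs, config$identity_threshold,
                                 config$coverage_threshold)
    fam_of <- stats::setNames(
      rep(vapply(families, `[[`, character(1L), "family_id"),
          vapply(families, function(f) length(f$members), integer(1L))),
      unlist(lapply(families, `[[`, "members"))
    )
    superfam <- vapply(seq_len(nrow(elements)), function(i) {
      r <- elements[i, ]
      internal <- substr0(contigs[[r$contig]], r$ltr5_end, r$ltr3_start)
      if (!nzchar(internal)) return("unknown")
      hits <- detect_domains(internal, min_score = config$min_domain_score)
      classify_superfamily(hits, nchar(internal))
    }, character(1L))
    elements$family <- unname(fam_of[elements$element_id])
    elements$superfamily <- superfam
    elements$species <- unname(species_of_contig[elements$contig])
  }

  # ---- date -------------------------------------------------------------
  ages <- estimate_ages(elements, contigs, config$r)
  age_summary <- if (nrow(ages) > 0L) {
    summarize_ages(ages, family = elements$family)
  } else {
    NULL
  }

  # ---- divergence -------------------------------------------------------
  ortho_identity <- NULL
  dist_excl <- NULL
  dist_incl <- NULL
  if (!is.null(config$ortholog_pairs)) {
    op <- config$ortholog_pairs
    mets <- lapply(seq_len(nrow(op)), function(i) {
      identity_metrics(align_global(op$a[i], op$b[i]))
    })
    ortho_identity <- data.frame(
      id = if (!is.null(op$id)) op$id else sprintf("og%04d", seq_len(nrow(op))),
      identity_without_gaps = vapply(mets, `[[`, numeric(1L),
                                     "identity_without_gaps"),
      identity_with_gaps = vapply(mets, `[[`, numeric(1L),
                                  "identity_with_gaps"),
      stringsAsFactors = FALSE
    )
    dist_excl <- identity_distribution(ortho_identity$identity_without_gaps,
                                       config$bin_width)
    dist_incl <- identity_distribution(ortho_identity$identity_with_gaps,
                                       config$bin_width)
  }

  # ---- HT screen --------------------------------------------------------
  ht_reports <- list()
  trees <- list()
  if (!is.null(dist_excl) && nrow(elements) > 0L) {
    for (fam in families) {
      members <- fam$members
      sp <- elements$species[match(members, elements$element_id)]
      if (length(unique(sp)) < 2L) next
      seqs <- vapply(members, function(id) {
        element_seq(elements[elements$element_id == id, ])
      }, character(1L))
      scr <- screen_family_ht(seqs, stats::setNames(sp, members),
                              dist_excl, dist_incl,
                              config$min_domain_score)
      scr$report$family <- fam$family_id
      ht_reports[[fam$family_id]] <- scr$report
      if (!is.null(scr$tree)) trees[[fam$family_id]] <- scr$tree
    }
  }
  ht_table <- if (length(ht_reports)) {
    do.call(rbind, c(ht_reports, list(make.row.names = FALSE)))
  } else {
    NULL
  }

  # ---- outputs ----------------------------------------------------------
  for (sp in names(genome_seqs)) {
    sub <- elements[nrow(elements) > 0L &
                      elements$contig %in% names(genome_seqs[[sp]]), ,
                    drop = FALSE]
    write_gff3(sub[, setdiff(names(sub),
                             c("family", "superfamily", "species")),
                   drop = FALSE],
               file.path(config$out_dir, paste0(sp, ".gff3")))
  }
  .write_tsv(elements, file.path(config$out_dir, "elements.tsv"))
  fam_table <- family_table(elements, ages)
  .write_tsv(fam_table, file.path(config$out_dir, "families.tsv"))
  .write_tsv(ages, file.path(config$out_dir, "ages.tsv"))
  if (!is.null(age_summary)) {
    .write_tsv(
      data.frame(class = c("lt1", "from1to3", "gt3", "identical_ltr"),
                 count = c(age_summary$counts, age_summary$n_identical_ltr),
                 percent = c(age_summary$percentages,
                             age_summary$pct_identical_ltr)),
      file.path(config$out_dir, "age_summary.tsv")
    )
  } else {
    .write_tsv(data.frame(class = character(0L), count = integer(0L),
                          percent = numeric(0L)),
               file.path(config$out_dir, "age_summary.tsv"))
  }
  if (!is.null(ortho_identity)) {
    .write_tsv(ortho_identity,
               file.path(config$out_dir, "ortholog_identities.tsv"))
  }
  if (!is.null(ht_table)) {
    .write_tsv(ht_table, file.path(config$out_dir, "ht_report.tsv"))
  } else {
    .write_tsv(data.frame(), file.path(config$out_dir, "ht_report.tsv"))
  }
  for (fid in names(trees)) {
    ape::write.tree(trees[[fid]],
                    file.path(config$out_dir, paste0(fid, ".nwk")))
  }
  log <- list(
    seed = config$seed, r = config$r, bin_width = config$bin_width,
    identity_threshold = config$identity_threshold,
    coverage_threshold = config$coverage_threshold,
    min_domain_score = config$min_domain_score,
    finder = config$finder[setdiff(names(config$finder), "motif_list")],
    motif_list = vapply(config$finder$motif_list, paste0, character(1L),
                        collapse = ""),
    genomes = if (!is.null(config$genomes)) as.list(config$genomes) else
      "in-memory",
    n_elements = nrow(elements), n_families = length(families)
  )
  yaml::write_yaml(log, file.path(config$out_dir, "run_log.yaml"))

  invisible(list(
    elements = elements, families = families, family_table = fam_table,
    ages = ages, age_summary = age_summary,
    ortholog_identity = ortho_identity,
    ortholog_dist_excl = dist_excl, ortholog_dist_incl = dist_incl,
    ht_reports = ht_table, trees = trees, out_dir = config$out_dir
  ))
}

#' Per-family summary table
#'
#' One row per family: member count, mean LTR and element lengths, modal
#' terminal dinucleotides, modal TSD length, mean age and superfamily.
#'
#' @param elements Element record data.frame (with `family` and
#'   `superfamily` columns).
#' @param ages data.frame from [estimate_ages()].
#' @return data.frame, one row per family.
#' @export
family_table <- function(elements, ages) {
  empty <- data.frame(family = character(0L), superfamily = character(0L),
                      n = integer(0L), mean_ltr_bp = numeric(0L),
                      mean_element_bp = numeric(0L), motif = character(0L),
                      tsd_len = integer(0L), mean_age_my = numeric(0L),
                      stringsAsFactors = FALSE)
  if (nrow(elements) == 0L || is.null(elements$family)) return(empty)
  age_of <- stats::setNames(ages$T_years, ages$element_id)
  rows <- lapply(split(elements, elements$family), function(g) {
    modal <- function(x) names(sort(table(x), decreasing = TRUE))[1L]
    data.frame(
      family = g$family[1L],
      superfamily = modal(g$superfamily),
      n = nrow(g),
      mean_ltr_bp = mean(g$ltr5_end - g$ltr5_start),
      mean_element_bp = mean(g$end - g$start),
      motif = modal(g$motif_label),
      tsd_len = as.integer(modal(g$tsd_len)),
      mean_age_my = mean(age_of[g$element_id]) / 1e6,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
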