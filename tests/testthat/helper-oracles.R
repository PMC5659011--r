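# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive re-derivation (exhaustive dynamic programming,
# explicit pathway enumeration, transitive closure) kept separate from the
# package's own code paths.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# --- exhaustive affine-gap global alignment score (Gotoh) -------------------
# Convention matches the package: a gap of length L costs open + L * extend.
oracle_global_score <- function(a, b, match = 2, mismatch = -2,
                                gap_open = 6, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) {
    X[i + 1, 1] <- -(gap_open + i * gap_extend)
  }
  for (j in seq_len(m)) {
    Y[1, j + 1] <- -(gap_open + j * gap_extend)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- brute-force NG86 -------------------------------------------------------
GC <- Biostrings::GENETIC_CODE

oracle_syn_sites <- function(codon) {
  v <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(BASES, v[pos])) {
      w <- v
      w[pos] <- alt
      cw <- paste(w, collapse = "")
      if (GC[[cw]] != "*" && GC[[cw]] == GC[[codon]]) s <- s + 1
    }
  }
  s / 3
}

# recursive enumeration of every substitution ordering between two codons
oracle_codon_paths <- function(c1, c2) {
  v1 <- strsplit(c1, "")[[1]]
  v2 <- strsplit(c2, "")[[1]]
  pos <- which(v1 != v2)
  if (length(pos) == 0) return(list(sd = 0, nd = 0))
  paths <- list()
  walk <- function(cur, remaining, sd, nd, through_stop) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- list(sd = sd, nd = nd,
                                          blocked = through_stop)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- v2[p]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      syn <- GC[[from]] == GC[[to]]
      hit_stop <- GC[[to]] == "*" && !identical(nxt, v2)
      walk(nxt, setdiff(remaining, p),
           sd + as.integer(syn), nd + as.integer(!syn),
           through_stop || hit_stop)
    }
  }
  walk(v1, pos, 0, 0, FALSE)
  ok <- Filter(function(p) !p$blocked, paths)
  if (length(ok) == 0) ok <- paths
  list(sd = mean(vapply(ok, `[[`, numeric(1), "sd")),
       nd = mean(vapply(ok, `[[`, numeric(1), "nd")))
}

oracle_ng86 <- function(cds_a, cds_b) {
  n <- nchar(cds_a)
  ca <- substring(cds_a, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(cds_b, seq(1, n, 3), seq(3, n, 3))
  S <- (sum(vapply(ca, oracle_syn_sites, numeric(1))) +
          sum(vapply(cb, oracle_syn_sites, numeric(1)))) / 2
  N <- n - S
  Sd <- 0
  Nd <- 0
  for (i in seq_along(ca)) {
    d <- oracle_codon_paths(ca[i], cb[i])
    Sd <- Sd + d$sd
    Nd <- Nd + d$nd
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NaN else -0.75 * log(1 - 4 * p / 3)
  list(Ka = jc(pn), Ks = jc(ps), ps = ps, pn = pn)
}

random_sense_cds <- function(n_codons) {
  sense <- names(GC)[GC != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# --- transitive closure over the pairwise 80/80 edge matrix -----------------
oracle_families <- function(ltr_seqs, identity_threshold = 80,
                            coverage_threshold = 80) {
  n <- length(ltr_seqs)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && ltr_pair_linked(ltr_seqs[[i]], ltr_seqs[[j]],
                                   identity_threshold,
                                   coverage_threshold)) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  for (k in seq_len(n)) {                 # Floyd-Warshall closure
    adj <- adj | (adj[, k] %o% adj[k, ])
  }
  comp <- integer(n)
  next_id <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      next_id <- next_id + 1
      comp[adj[i, ]] <- next_id
    }
  }
  split(names(ltr_seqs), comp)
}

# canonical form of a family partition for comparison
partition_of <- function(fams) {
  unname(lapply(fams, function(f) sort(if (is.list(f)) f$members else f)))
}
same_partition <- function(p1, p2) {
  key <- function(p) sort(vapply(p, paste, character(1), collapse = "|"))
  identical(key(partition_of(p1)), key(partition_of(p2)))
}

# one aged, planted element on a fresh background; returns contig + truth
plant_one <- function(bg_len, position, age_years, seed,
                      spec = element_spec(), r = 1.3e-8) {
  el <- age_element(build_element(spec, seed), age_years, r, seed + 1000L)
  g <- generate_background(bg_len, 0.38, seed + 2000L)
  plant_element(g, el, position, spec$tsd_length, t_true = age_years)
}

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# seeded wrapper around the package's stop-free CDS mutator
mutate_to_codons <- function(cds, m, seed) {
  ltrtrace:::with_seed(seed, ltrtrace:::mutate_cds_(cds, m))
}
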