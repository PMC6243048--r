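# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the package's own primitives: reverse
# complements are computed by string reversal + chartr, ordering by a
# C-locale radix sort, counting by base::table.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

oracle_canon <- function(x) {
  rc <- oracle_revcomp(x)
  vapply(seq_along(x), function(i) {
    sort(c(x[i], rc[i]), method = "radix")[1L]
  }, "")
}

oracle_windows <- function(s, w) {
  n <- nchar(s)
  if (n < w) return(character(0))
  substring(s, 1:(n - w + 1L), w:n)
}

# brute-force canonical k-mer counting over reads
oracle_kmer_counts <- function(reads, k) {
  km <- unlist(lapply(reads, oracle_windows, w = k), use.names = FALSE)
  km <- km[!grepl("[^ACGT]", km)]
  tab <- table(oracle_canon(km))
  stats::setNames(as.integer(tab), names(tab))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small diamond locus fixture used by several test files
diamond_fixture <- function(seed, coverage = 20, error_rate = 0,
                            abundances = NULL) {
  model <- make_mutually_exclusive_gene(seed = seed)
  isos <- isoform_set(model)
  sim <- simulate_read_pairs(isos, abundances = abundances,
                             coverage = coverage, error_rate = error_rate,
                             seed = seed + 1000L)
  list(model = model, isos = isos, pairs = sim$pairs, truth = sim$truth)
}

run_diamond_assembly <- function(fx, k = 47L) {
  g <- build_graph(c(fx$pairs$mate1, fx$pairs$mate2),
                   graph_params(k = k), color = "s1")
  ug <- suppressMessages(collapse_unitigs(g, "s1"))
  ug <- suppressMessages(
    filter_unitigs_by_mean_coverage(ug, 4, color = "s1"))
  subs <- suppressMessages(
    extract_seed_subgraphs(ug, c(psi = fx$model$exons[["psi"]])))
  sub <- suppressMessages(prune_tips(subs[[1L]]))
  suppressMessages(enumerate_candidates(sub))
}

# exhaustive grid-search maximizer of the equivalence-class multinomial
# likelihood (two-stage refinement); returns estimated counts
oracle_em_grid <- function(classes, counts, lengths, eff = TRUE,
                           fragment_mean = 200) {
  tx <- sort(unique(unlist(classes)))
  stopifnot(length(tx) == 3L)
  el <- if (eff) pmax(lengths[tx] - fragment_mean + 1, 1) else lengths[tx]
  loglik <- function(th1, th2) {
    th3 <- 1 - th1 - th2
    ll <- 0
    for (i in seq_along(classes)) {
      mem <- tx %in% classes[[i]]
      p <- sum((c(th1, th2, th3) / el)[mem])
      ll <- ll + counts[i] * log(p)
    }
    ll
  }
  eval_grid <- function(r1, r2) {
    best <- c(NA, NA, -Inf)
    for (t1 in r1) {
      for (t2 in r2) {
        if (t1 + t2 > 1 - 1e-12) next
        v <- loglik(t1, t2)
        if (!is.nan(v) && v > best[3L]) best <- c(t1, t2, v)
      }
    }
    best
  }
  b <- eval_grid(seq(0, 1, by = 0.01), seq(0, 1, by = 0.01))
  b <- eval_grid(seq(max(0, b[1L] - 0.02), min(1, b[1L] + 0.02), by = 1e-4),
                 seq(max(0, b[2L] - 0.02), min(1, b[2L] + 0.02), by = 1e-4))
  th <- c(b[1L], b[2L], 1 - b[1L] - b[2L])
  stats::setNames(th * sum(counts), tx)
}

# random DAG over `n` unitig-like nodes for path-enumeration tests; returns
# an edge list (from, to) with all edges pointing from lower to higher index
random_dag_edges <- function(n, p = 0.35) {
  edges <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (runif(1L) < p) edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  if (length(edges) == 0L) edges[[1L]] <- c(1L, 2L)
  do.call(rbind, edges)
}
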