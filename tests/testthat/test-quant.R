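# substring-search oracle for pseudoalignment of error-free pairs
oracle_compat <- function(m1, m2, candidates) {
  hit <- vapply(candidates, function(tx) {
    ok1 <- grepl(m1, tx, fixed = TRUE) ||
      grepl(oracle_revcomp(m1), tx, fixed = TRUE)
    ok2 <- grepl(m2, tx, fixed = TRUE) ||
      grepl(oracle_revcomp(m2), tx, fixed = TRUE)
    ok1 && ok2
  }, logical(1))
  sort(names(candidates)[hit])
}

diamond_quant_fixture <- function(seed = 71) {
  fx <- diamond_fixture(seed = seed)
  list(fx = fx, cands = fx$isos, index = kmer_index(fx$isos, 47L))
}

test_that("pseudoalignment resolves unique and shared regions correctly", {
  dq <- diamond_quant_fixture()
  model <- dq$fx$model
  alpha_read <- substr(model$exons[["alpha"]], 10L, 134L)
  psi_read <- substr(model$exons[["psi"]], 100L, 224L)
  psi_read2 <- substr(model$exons[["psi"]], 200L, 324L)
  a_iso <- grep("^alpha", names(dq$cands), value = TRUE)
  expect_setequal(pseudoalign_pair(alpha_read, psi_read, dq$index), a_iso)
  ## a pair entirely inside the shared core hits all four isoforms
  expect_setequal(pseudoalign_pair(psi_read, psi_read2, dq$index),
                  names(dq$cands))
  ## a foreign pair is unassigned
  set.seed(72)
  expect_length(pseudoalign_pair(random_dna(125L), random_dna(125L),
                                 dq$index), 0L)
})

test_that("pseudoalignment of simulated pairs equals the substring oracle", {
  dq <- diamond_quant_fixture(seed = 73)
  pr <- dq$fx$pairs[1:150]
  for (i in seq_len(nrow(pr))) {
    got <- pseudoalign_pair(pr$mate1[i], pr$mate2[i], dq$index)
    expect_identical(got, oracle_compat(pr$mate1[i], pr$mate2[i], dq$cands))
  }
})

test_that("equivalence classes tally pairs by compatibility set", {
  dq <- diamond_quant_fixture(seed = 74)
  pr <- dq$fx$pairs
  ec <- suppressMessages(build_ec_counts(pr, dq$cands, 47L,
                                         index = dq$index))
  expect_equal(sum(ec$classes$count), ec$total_reads)
  expect_equal(ec$total_reads + ec$n_unassigned, nrow(pr))
  ## class counts match a brute-force tally
  keys <- vapply(seq_len(nrow(pr)), function(i) {
    paste(oracle_compat(pr$mate1[i], pr$mate2[i], dq$cands), collapse = "|")
  }, "")
  exp <- table(keys[nzchar(keys)])
  got_keys <- vapply(ec$classes$tx, paste, "", collapse = "|")
  expect_setequal(got_keys, names(exp))
  expect_identical(ec$classes$count[match(names(exp), got_keys)],
                   as.integer(exp))
  ## no pairs -> empty classes
  ec0 <- build_ec_counts(list(mate1 = character(0), mate2 = character(0)),
                         dq$cands, 47L, index = dq$index)
  expect_equal(nrow(ec0$classes), 0L)
  expect_equal(ec0$total_reads, 0L)
})

make_ec <- function(classes, counts, tx_ids = sort(unique(unlist(classes)))) {
  structure(list(
    classes = data.table::data.table(class_id = seq_along(classes),
                                     tx = classes,
                                     count = as.integer(counts)),
    total_reads = sum(counts), n_unassigned = 0L, tx_ids = tx_ids),
    class = "EquivalenceClassCounts")
}

test_that("EM reduces to raw counts for singleton classes and splits ties", {
  ec <- make_ec(list("t1", "t2"), c(30L, 12L))
  est <- em_abundance(ec, c(t1 = 500, t2 = 700))
  expect_equal(est$est_counts, c(t1 = 30, t2 = 12))
  ## fully shared class over equal lengths: symmetric 50/50
  ec2 <- make_ec(list(c("t1", "t2")), 100L)
  est2 <- em_abundance(ec2, c(t1 = 600, t2 = 600))
  expect_equal(unname(est2$est_counts), c(50, 50), tolerance = 1e-9)
})

test_that("EM matches a brute-force likelihood grid search to 3 decimals", {
  cases <- list(
    list(classes = list("a", "b", "c", c("a", "b"), c("a", "b", "c")),
         counts = c(40L, 25L, 10L, 50L, 30L),
         lengths = c(a = 1200, b = 800, c = 500)),
    list(classes = list("a", c("a", "b"), c("b", "c"), c("a", "c")),
         counts = c(15L, 60L, 45L, 20L),
         lengths = c(a = 900, b = 900, c = 400)),
    list(classes = list(c("a", "b"), c("b", "c"), "c"),
         counts = c(80L, 40L, 5L),
         lengths = c(a = 700, b = 1100, c = 600))
  )
  for (cs in cases) {
    ec <- make_ec(cs$classes, cs$counts)
    est <- em_abundance(ec, cs$lengths, filter_params(em_tolerance = 1e-12))
    oracle <- oracle_em_grid(cs$classes, cs$counts, cs$lengths)
    n <- sum(cs$counts)
    expect_lt(max(abs(est$est_counts[names(oracle)] - oracle)) / n, 1e-3)
  }
})

test_that("estimated counts are conserved in EM and in bootstraps", {
  set.seed(75)
  for (rep in 1:5) {
    ntx <- sample(2:5, 1L)
    tx <- paste0("t", seq_len(ntx))
    ncl <- sample(2:6, 1L)
    classes <- lapply(seq_len(ncl), function(i) {
      sort(sample(tx, sample(seq_len(ntx), 1L)))
    })
    counts <- sample(1:50, ncl, replace = TRUE)
    lens <- stats::setNames(sample(300:1500, ntx), tx)
    ec <- make_ec(classes, counts, tx)
    est <- em_abundance(ec, lens)
    expect_equal(sum(est$est_counts), ec$total_reads, tolerance = 1e-6)
    bs <- bootstrap_support(ec, lens,
                            filter_params(n_bootstrap = 20L, min_support_samples = 19L,
                                          rng_seed = rep))
    expect_equal(sum(bs$point_estimate), ec$total_reads, tolerance = 1e-6)
    expect_true(all(bs$support >= 0L & bs$support <= 20L))
  }
})

test_that("bootstrap support is saturated for unambiguous transcripts", {
  ec <- make_ec(list("t1"), 40L, tx_ids = c("t1", "t2"))
  bs <- bootstrap_support(ec, c(t1 = 500, t2 = 500),
                          filter_params(rng_seed = 76))
  expect_equal(unname(bs$support["t1"]), 100L)
  expect_equal(unname(bs$support["t2"]), 0L)  # transcript in no class
})

test_that("bootstrap support is deterministic given the seed", {
  ec <- make_ec(list("t1", c("t1", "t2"), "t2"), c(10L, 30L, 3L))
  lens <- c(t1 = 800, t2 = 600)
  b1 <- bootstrap_support(ec, lens, filter_params(rng_seed = 77))
  b2 <- bootstrap_support(ec, lens, filter_params(rng_seed = 77))
  expect_identical(b1$support, b2$support)
})

test_that("retention thresholds are inclusive and monotone", {
  fake <- structure(list(support = c(a = 95L, b = 94L, c = 100L, d = 0L),
                         n_bootstrap = 100L, min_count = 1,
                         point_estimate = c(a = 5, b = 5, c = 50, d = 0)),
                    class = "BootstrapSupport")
  expect_setequal(retain_candidates(fake, filter_params()), c("a", "c"))
  ## raising the support threshold never enlarges the retained set
  set.seed(78)
  for (rep in 1:10) {
    sup <- structure(list(support = stats::setNames(
      sample(0:100, 6L, replace = TRUE), paste0("t", 1:6)),
      n_bootstrap = 100L, min_count = 1, point_estimate = NULL),
      class = "BootstrapSupport")
    prev <- retain_candidates(sup, filter_params(min_support_samples = 0L))
    for (thr in c(25L, 50L, 75L, 95L, 100L)) {
      cur <- retain_candidates(sup,
                               filter_params(min_support_samples = thr))
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("unexpressed chimeric paths are rejected when fragments span the core", {
  ## Two of four isoforms silent. With a core shorter than the fragment
  ## length, read pairs bridge both alternate exons, so the equivalence
  ## classes identify the expressed pair and EM starves the two chimeric
  ## paths; the bootstrap filter must then reject them.  (With a core longer
  ## than the fragment the likelihood is flat along the chimera ridge and no
  ## quantifier could make this call.)
  for (sd in c(79L, 179L)) {
    model <- make_mutually_exclusive_gene(core_lengths = c(psi = 100L),
                                          seed = sd)
    isos <- isoform_set(model)
    sim <- simulate_read_pairs(isos,
                               abundances = c(alpha_psi_gamma = 1,
                                              beta_psi_delta = 1,
                                              alpha_psi_delta = 0,
                                              beta_psi_gamma = 0),
                               coverage = 30, seed = sd + 1L)
    g <- build_graph(c(sim$pairs$mate1, sim$pairs$mate2), graph_params(),
                     color = "s1")
    ug <- suppressMessages(collapse_unitigs(g, "s1"))
    ug <- suppressMessages(filter_unitigs_by_mean_coverage(ug, 4,
                                                           color = "s1"))
    sub <- suppressMessages(extract_seed_subgraphs(
      ug, c(psi = model$exons[["psi"]])))[[1L]]
    cand <- suppressMessages(enumerate_candidates(
      suppressMessages(prune_tips(sub))))
    expect_equal(nrow(cand), 4L)  # the diamond still admits 4 paths
    quant <- suppressMessages(quantify_candidates(
      stats::setNames(cand$sequence, cand$candidate_id), sim$pairs, 47L,
      filter_params(rng_seed = sd + 2L)))
    kept_seq <- stats::setNames(
      cand$sequence, cand$candidate_id)[quant[retained == TRUE, tx]]
    expressed <- isos[c("alpha_psi_gamma", "beta_psi_delta")]
    expect_setequal(unname(kept_seq), unname(expressed))
  }
})
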