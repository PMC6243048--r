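test_that("the edit-distance filter is strict at its bound", {
  alns <- data.table::data.table(
    read_id = paste0("r", 1:6), target = "t",
    role = "primary", edit_distance = c(0L, 3L, 4L, 5L, 6L, 12L))
  kept <- filter_ccs_alignments(alns, max_nm_exclusive = 5)
  expect_setequal(kept$read_id, c("r1", "r2", "r3"))
  ## predicate oracle on random NM values
  set.seed(81)
  nm <- sample(0:10, 200L, replace = TRUE)
  rand <- data.table::data.table(read_id = paste0("x", seq_along(nm)),
                                 target = "t", role = "primary",
                                 edit_distance = nm)
  expect_setequal(filter_ccs_alignments(rand)$read_id,
                  rand$read_id[nm < 5L])
})

test_that("reads aggregate to one alternate region, neither, or excluded", {
  region_map <- c(a_tx = "alpha", b_tx = "beta", core_tx = "psi")
  alns <- data.table::data.table(
    read_id = c("r1", "r2", "r2", "r3", "r3", "r4"),
    target = c("a_tx", "core_tx", "core_tx", "a_tx", "b_tx", "b_tx"),
    role = c("primary", "primary", "supplementary", "primary",
             "supplementary", "secondary"))
  expect_message(
    grp <- group_ccs_by_region(alns, region_map, c("alpha", "beta")),
    "both regions")
  g <- stats::setNames(grp$group, grp$read_id)
  expect_equal(unname(g["r1"]), "alpha")
  expect_equal(unname(g["r2"]), "neither")  # core only
  expect_true(is.na(g["r3"]))               # contradictory
  ## secondary alignments do not drive membership
  expect_equal(unname(g["r4"]), "neither")
})

test_that("unique-locus counting zeroes reads spanning several loci", {
  locus_map <- c(t1 = "A", t2 = "A", t3 = "B")
  alns <- data.table::data.table(
    read_id = c("r1", "r1", "r1", "r2", "r2", "r3"),
    target = c("t1", "t2", "t1", "t1", "t3", "t3"))
  counts <- count_unique_locus_reads(alns, locus_map)
  expect_equal(counts, c(A = 1L, B = 1L))
  ## invariant to order and duplication of records
  shuffled <- rbind(alns[sample(nrow(alns))], alns)
  expect_equal(count_unique_locus_reads(shuffled, locus_map), counts)
  ## brute-force per-read predicate on random tables
  set.seed(82)
  for (rep in 1:5) {
    tx <- paste0("t", 1:6)
    lm <- stats::setNames(sample(c("A", "B", "C"), 6L, replace = TRUE), tx)
    rand <- data.table::data.table(
      read_id = sample(paste0("r", 1:8), 30L, replace = TRUE),
      target = sample(tx, 30L, replace = TRUE))
    got <- count_unique_locus_reads(rand, lm)
    uni <- unlist(lapply(split(rand$target, rand$read_id), function(tg) {
      loci <- unique(unname(lm[tg]))
      if (length(loci) == 1L) loci else character(0)
    }), use.names = FALSE)
    exp_vec <- stats::setNames(as.integer(table(uni)), names(table(uni)))
    expect_equal(length(got), length(exp_vec))
    if (length(exp_vec)) {
      expect_equal(got, exp_vec[sort(names(exp_vec))])
    }
    expect_lte(sum(got), length(unique(rand$read_id)))
  }
})

test_that("threading CCS reads adds group colors without touching short reads", {
  fx <- diamond_fixture(seed = 83)
  g <- build_graph(c(fx$pairs$mate1, fx$pairs$mate2), graph_params(),
                   color = "sr")
  ccs <- simulate_ccs_reads(fx$isos,
                            c(alpha_psi_delta = 2L, beta_psi_gamma = 1L),
                            seed = 84)
  joined <- suppressMessages(thread_ccs(
    g, ccs$reads,
    ifelse(grepl("^alpha", ccs$truth$isoform[
      match(names(ccs$reads), ccs$truth$read_id)]), "ccs_alpha",
      "ccs_beta")))
  expect_setequal(joined$colors, c("sr", "ccs_alpha", "ccs_beta"))
  expect_identical(joined$cov[g$kmers, "sr"], g$cov[, "sr"])
  expect_identical(joined$edges[["sr"]], g$edges[["sr"]])
  ## the alpha-group color covers exactly the alpha/psi/delta unitigs
  ug <- suppressMessages(collapse_unitigs(joined, "sr"))
  iso_km <- oracle_canon(oracle_windows(fx$isos[["alpha_psi_delta"]], 47L))
  covered <- ug$unitigs$id[ug$mean_cov[, "ccs_alpha"] > 0]
  exp_covered <- unique(ug$node_map[kmer %in% iso_km, unitig])
  expect_setequal(covered, exp_covered)
  ## empty CCS set leaves the graph unchanged
  expect_identical(thread_ccs(g, character(0), character(0)), g)
})

test_that("CCS-covered unitig sets survive 1% indel errors via k-mer overlap", {
  fx <- diamond_fixture(seed = 85)
  g <- build_graph(c(fx$pairs$mate1, fx$pairs$mate2), graph_params(),
                   color = "sr")
  ccs <- simulate_ccs_reads(fx$isos, c(beta_psi_delta = 4L),
                            indel_rate = 0.01, seed = 86)
  joined <- suppressMessages(thread_ccs(g, ccs$reads,
                                        rep("grp", length(ccs$reads))))
  ## oracle: exact intersection of read k-mers with the short-read node set
  ccs_km <- unique(oracle_canon(unlist(
    lapply(ccs$reads, oracle_windows, w = 47L), use.names = FALSE)))
  ccs_km <- ccs_km[!grepl("[^ACGT]", ccs_km)]
  exp_nodes <- intersect(g$kmers, ccs_km)
  got_nodes <- rownames(joined$cov)[joined$cov[, "grp"] > 0]
  expect_setequal(intersect(got_nodes, g$kmers), exp_nodes)
})

test_that("joined-graph pruning removes weakly covered unitigs", {
  set.seed(87)
  strong <- random_dna(150L)
  weak <- random_dna(100L)
  g <- build_graph(c(rep(strong, 3L), weak), graph_params(), color = "sr")
  ug <- suppressMessages(prune_joined_graph(g, "sr", threshold = 2))
  expect_equal(nrow(ug$unitigs), 1L)
  expect_true(ug$unitigs$sequence %in% c(strong, revcomp(strong)))
})

test_that("the internal aligner recovers provenance and 5' truncation", {
  model <- make_mutually_exclusive_gene(seed = 88)
  targets <- c(alpha = model$exons[["alpha"]], beta = model$exons[["beta"]],
               psi = model$exons[["psi"]])
  iso <- isoform_set(model)
  full <- simulate_ccs_reads(iso, c(alpha_psi_delta = 1L), seed = 89)
  alns <- align_ccs(full$reads, targets)
  grp <- group_ccs_by_region(alns, c(alpha = "alpha", beta = "beta",
                                     psi = "psi"), c("alpha", "beta"))
  expect_equal(grp$group, "alpha")
  ## 5'-truncated read loses the alternate first exon: lands in "neither"
  trunc <- simulate_ccs_reads(iso, c(alpha_psi_delta = 1L),
                              truncate_5p = 220L, seed = 90)
  alns_t <- align_ccs(trunc$reads, targets)
  expect_false("alpha" %in% alns_t$target)
  grp_t <- group_ccs_by_region(alns_t, c(alpha = "alpha", beta = "beta",
                                         psi = "psi"), c("alpha", "beta"))
  expect_equal(grp_t$group, "neither")
  ## edit distances: exact read aligns at NM 0 to its regions
  expect_true(all(alns$edit_distance[alns$target != "beta"] == 0L))
})

test_that("SAM ingestion extracts CIGAR, NM, and alignment roles", {
  sam <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:t1\tLN:1000",
    "r1\t0\tt1\t1\t60\t100M\t*\t0\t0\tACGT\t*\tNM:i:2\tAS:i:90",
    "r1\t256\tt2\t1\t0\t50M50S\t*\t0\t0\tACGT\t*\tNM:i:7",
    "r1\t2048\tt3\t1\t0\t30M\t*\t0\t0\tACGT\t*\tNM:i:1",
    "r2\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\t*"
  )
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, path)
  got <- read_sam(path)
  expect_equal(nrow(got), 3L)  # unmapped dropped
  expect_equal(got$role, c("primary", "secondary", "supplementary"))
  expect_equal(got$edit_distance, c(2L, 7L, 1L))
  expect_equal(got$cigar, c("100M", "50M50S", "30M"))
  expect_error(read_sam({
    p <- withr::local_tempfile(fileext = ".sam")
    writeLines("r1\t0\tt1", p)
    p
  }), "malformed")
})
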