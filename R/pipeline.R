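#' Assemble a pipeline configuration
#'
#' @param samples named list, one element per sample. Each element is either
#'   a `data.table`/`data.frame` with columns `mate1` and `mate2` (in-memory
#'   read pairs) or a character vector of two FASTQ/FASTA paths.
#' @param seeds named character vector of seed/core-region sequences, or a
#'   FASTA path.
#' @param graph a [graph_params()] object.
#' @param filter a [filter_params()] object.
#' @param tip_min_kmers tip-pruning threshold in k-mers (default 47).
#' @param max_paths simple-path cap per subgraph (default 10000).
#' @param out_dir optional output directory for artifacts.
#' @param seed global RNG seed; per-sample bootstrap seeds are derived from
#'   it.
#' @return a `PipelineConfig`.
#' @export
pipeline_config <- function(samples, seeds, graph = graph_params(),
                            filter = filter_params(), tip_min_kmers = 47L,
                            max_paths = 10000L, out_dir = NULL, seed = 1L) {
  stopifnot(is.list(samples), length(samples) >= 1L, !is.null(names(samples)))
  if (is.character(seeds) && length(seeds) == 1L && file.exists(seeds)) {
    seeds <- read_sequences(seeds)
  }
  structure(
    list(samples = samples, seeds = seeds, graph = graph, filter = filter,
         tip_min_kmers = as.integer(tip_min_kmers),
         max_paths = as.integer(max_paths), out_dir = out_dir,
         seed = as.integer(seed)),
    class = "PipelineConfig"
  )
}

.load_sample_pairs <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 2L)
    return(read_paired_reads(x[1L], x[2L]))
  }
  as.data.table(x)
}

#' Run the seed-guided assembly pipeline
#'
#' Per sample: build the colored De Bruijn graph from both mates, collapse
#' into unitigs (adjacency from the sample color only), remove unitigs under
#' the mean-coverage threshold, extract seed subgraphs, prune short tips,
#' enumerate tip-to-tip simple paths, and retain candidates by the
#' pseudoalignment/EM/bootstrap support rule. Retained candidates are then
#' combined across samples with reverse-complement deduplication.
#'
#' When `out_dir` is set, the retained candidate FASTA, per-sample
#' quantification TSVs, a GFA per seed subgraph, and a JSON manifest with
#' full parameter and seed provenance are written; a rerun with an identical
#' configuration produces identical primary outputs.
#'
#' @param config a [pipeline_config()].
#' @return list with `candidates` (deduplicated retained set), `per_sample`
#'   (quantification tables), `n_candidates_enumerated`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  seeds <- toupper(as.character(config$seeds))
  names(seeds) <- names(config$seeds)
  retained_sets <- list()
  per_sample <- list()
  n_enum <- stats::setNames(integer(length(config$samples)),
                            names(config$samples))
  gfa_paths <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  for (si in seq_along(config$samples)) {
    sample <- names(config$samples)[si]
    stage <- function(what) paste0("sample ", sample, ": ", what)
    pairs <- .load_sample_pairs(config$samples[[si]])
    reads <- c(pairs$mate1, pairs$mate2)

    g <- build_graph(reads, config$graph, color = sample)
    ug <- collapse_unitigs(g, collapse_colors = sample)
    ug <- filter_unitigs_by_mean_coverage(
      ug, config$graph$min_unitig_mean_coverage, color = sample)
    subs <- extract_seed_subgraphs(ug, seeds)
    if (length(subs) == 0L) {
      message(stage("no seed subgraph; sample yields no candidates"))
      per_sample[[sample]] <- data.table(tx = character(0),
                                         length = integer(0),
                                         est_count = numeric(0),
                                         support = integer(0),
                                         retained = logical(0))
      next
    }
    cands <- list()
    for (bi in seq_along(subs)) {
      sub <- prune_tips(subs[[bi]], min_kmers = config$tip_min_kmers)
      cc <- enumerate_candidates(sub, max_paths = config$max_paths)
      if (!is.null(config$out_dir) && nrow(cc)) {
        gp <- file.path(config$out_dir, sprintf("%s_seed%02d.gfa", sample, bi))
        export_gfa(sub$ug, gp)
        gfa_paths <- c(gfa_paths, gp)
      }
      cands[[bi]] <- cc
    }
    cands <- rbindlist(cands)
    n_enum[sample] <- nrow(cands)
    if (nrow(cands) == 0L) {
      message(stage("no candidate paths"))
      per_sample[[sample]] <- data.table(tx = character(0),
                                         length = integer(0),
                                         est_count = numeric(0),
                                         support = integer(0),
                                         retained = logical(0))
      next
    }
    cand_seqs <- stats::setNames(cands$sequence,
                                 paste0(sample, "_", cands$candidate_id))
    fp <- config$filter
    fp$rng_seed <- (config$seed + si) %% .Machine$integer.max
    quant <- quantify_candidates(cand_seqs, pairs, config$graph$k, fp)
    per_sample[[sample]] <- quant
    kept <- quant[retained == TRUE, tx]
    retained_sets[[sample]] <- data.table(
      sequence = unname(cand_seqs[kept]),
      seed = cands$seed[match(kept, paste0(sample, "_", cands$candidate_id))]
    )
  }

  if (length(retained_sets) == 0L) {
    candidates <- data.table(sequence = character(0), samples = character(0),
                             n_samples = integer(0), seeds = character(0))
  } else {
    candidates <- dedupe_candidates(retained_sets)
  }

  manifest <- list(
    tool = "isograph",
    version = as.character(utils::packageVersion("isograph")),
    k = config$graph$k,
    min_unitig_mean_coverage = config$graph$min_unitig_mean_coverage,
    tip_min_kmers = config$tip_min_kmers,
    max_paths = config$max_paths,
    n_bootstrap = config$filter$n_bootstrap,
    min_count = config$filter$min_count,
    min_support_samples = config$filter$min_support_samples,
    seed = config$seed,
    samples = names(config$samples),
    seeds = names(seeds),
    n_candidates_enumerated = as.list(n_enum),
    n_candidates_retained = nrow(candidates)
  )

  if (!is.null(config$out_dir)) {
    if (nrow(candidates)) {
      write_fasta(stats::setNames(candidates$sequence,
                                  sprintf("tx_%04d samples=%s",
                                          seq_len(nrow(candidates)),
                                          candidates$samples)),
                  file.path(config$out_dir, "retained_candidates.fasta"))
    }
    for (sample in names(per_sample)) {
      data.table::fwrite(per_sample[[sample]],
                         file.path(config$out_dir,
                                   paste0(sample, "_quant.tsv")),
                         sep = "\t")
    }
    cfg_path <- file.path(config$out_dir, "config.json")
    jsonlite::write_json(manifest, cfg_path, auto_unbox = TRUE, digits = NA)
    manifest$config_hash <- unname(tools::md5sum(cfg_path))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(candidates = candidates, per_sample = per_sample,
       n_candidates_enumerated = n_enum, manifest = manifest,
       gfa_paths = gfa_paths)
}
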