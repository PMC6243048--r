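## end degrees of every unitig: number of link stubs incident to the left
## (5' of the stored orientation) and right ends
.end_degrees <- function(ug) {
  ids <- ug$unitigs$id
  dl <- stats::setNames(integer(length(ids)), as.character(ids))
  dr <- dl
  if (nrow(ug$links)) {
    lk <- unique(ug$links[, .(from, from_orient, to, to_orient)])
    add <- function(tab, ids_hit) {
      if (length(ids_hit)) {
        t2 <- table(as.character(ids_hit))
        tab[names(t2)] <- tab[names(t2)] + as.integer(t2)
      }
      tab
    }
    dr <- add(dr, c(lk[from_orient == "+", from], lk[to_orient == "-", to]))
    dl <- add(dl, c(lk[from_orient == "-", from], lk[to_orient == "+", to]))
  }
  list(left = dl, right = dr)
}

## incoming/outgoing tip classification as oriented unitigs
.classify_tips <- function(ug) {
  d <- .end_degrees(ug)
  ids <- ug$unitigs$id
  key <- as.character(ids)
  incoming <- rbind(
    data.table(unitig = ids[d$left[key] == 0L], orient = "+"),
    data.table(unitig = ids[d$right[key] == 0L], orient = "-")
  )
  outgoing <- rbind(
    data.table(unitig = ids[d$right[key] == 0L], orient = "+"),
    data.table(unitig = ids[d$left[key] == 0L], orient = "-")
  )
  setorder(incoming, unitig, orient)
  setorder(outgoing, unitig, orient)
  list(incoming = incoming, outgoing = outgoing)
}

.new_seedsubgraph <- function(ug, seeds, seed_unitigs) {
  tips <- .classify_tips(ug)
  structure(
    list(ug = ug, seeds = seeds, seed_unitigs = sort(seed_unitigs),
         incoming_tips = tips$incoming, outgoing_tips = tips$outgoing),
    class = "SeedSubgraph"
  )
}

#' Extract seed-anchored subgraphs
#'
#' Traverses the unitig graph from every k-mer of every seed sequence and
#' returns, for each connected component (undirected reachability over links)
#' containing at least one seed k-mer, the component as a `SeedSubgraph`.
#' Transcripts extend a core region both 5' and 3', which is why reachability
#' ignores edge direction. Components hit by several seeds are returned once
#' with all seed names attached; seeds with no k-mer in the graph are
#' reported and yield nothing.
#'
#' @param ug a `UnitigGraph` (typically coverage-filtered).
#' @param seeds named character vector (or `DNAStringSet`) of seed/core-region
#'   sequences, each at least k bases long.
#' @return list of `SeedSubgraph` objects.
#' @export
extract_seed_subgraphs <- function(ug, seeds) {
  stopifnot(inherits(ug, "UnitigGraph"))
  seed_names <- names(seeds)
  seeds <- stats::setNames(toupper(as.character(seeds)), seed_names)
  if (is.null(names(seeds)) || any(!nzchar(names(seeds)))) {
    stop("seeds must be named")
  }
  k <- ug$params$k
  if (any(nchar(seeds) < k)) stop("every seed must be at least k bases long")

  ## component membership over undirected link structure
  ids <- as.character(ug$unitigs$id)
  g <- igraph::graph_from_data_frame(
    d = unique(ug$links[, .(from = as.character(from), to = as.character(to))]),
    directed = FALSE,
    vertices = data.frame(name = ids)
  )
  memb <- igraph::components(g)$membership[ids]

  seed_units <- lapply(seeds, function(s) {
    km <- unique(.canon_chr(.extract_kmers(s, k)))
    unique(ug$node_map[J(km), nomatch = NULL, unitig])
  })
  miss <- names(seeds)[vapply(seed_units, length, integer(1)) == 0L]
  if (length(miss)) {
    message("seed(s) with no k-mer in graph: ", paste(miss, collapse = ", "))
  }

  comp_of_seed <- lapply(seed_units, function(u) {
    unique(unname(memb[as.character(u)]))
  })
  comps <- sort(unique(unlist(comp_of_seed)))
  out <- lapply(comps, function(cmp) {
    sub_ids <- ug$unitigs$id[memb == cmp]
    hit <- vapply(comp_of_seed, function(cc) cmp %in% cc, logical(1))
    sub <- .subset_unitiggraph(ug, sub_ids)
    su <- intersect(unlist(seed_units[hit], use.names = FALSE), sub_ids)
    .new_seedsubgraph(sub, seeds[hit], su)
  })
  out
}

#' Prune short tips from a seed subgraph
#'
#' A tip is a unitig with a free end (no link on its left or right end). Tips
#' with fewer than `min_kmers` k-mers are removed; unitigs containing seed
#' k-mers are never removed. Removal can expose new short tips, so pruning
#' repeats until a fixpoint by default (`max_iterations` caps it; the
#' iteration count is reported).
#'
#' @param sub a `SeedSubgraph`.
#' @param min_kmers minimum k-mer count a tip needs to survive (default 47,
#'   i.e. one full k-mer length of sequence support); a tip of exactly
#'   `min_kmers` k-mers is kept.
#' @param max_iterations maximum pruning passes (default unbounded).
#' @return the pruned `SeedSubgraph`, with attribute `iterations`.
#' @export
prune_tips <- function(sub, min_kmers = 47L, max_iterations = Inf) {
  stopifnot(inherits(sub, "SeedSubgraph"))
  ug <- sub$ug
  it <- 0L
  repeat {
    if (it >= max_iterations) break
    d <- .end_degrees(ug)
    key <- as.character(ug$unitigs$id)
    is_tip <- d$left[key] == 0L | d$right[key] == 0L
    doomed <- ug$unitigs$id[is_tip &
                            ug$unitigs$kmer_count < min_kmers &
                            !(ug$unitigs$id %in% sub$seed_unitigs)]
    if (length(doomed) == 0L) break
    keep <- setdiff(ug$unitigs$id, doomed)
    if (length(keep) == 0L) {
      stop("tip pruning would empty the subgraph for seed(s): ",
           paste(names(sub$seeds), collapse = ", "))
    }
    ug <- .subset_unitiggraph(ug, keep)
    it <- it + 1L
  }
  message(sprintf("prune_tips: %d iteration(s), %d unitig(s) remain",
                  it, nrow(ug$unitigs)))
  out <- .new_seedsubgraph(ug, sub$seeds,
                           intersect(sub$seed_unitigs, ug$unitigs$id))
  attr(out, "iterations") <- it
  out
}

## oriented successor lists over links: "12+" -> c("7+", "9-"), sorted
.oriented_successors <- function(ug) {
  succ <- list()
  if (nrow(ug$links)) {
    lk <- unique(ug$links[, .(from, from_orient, to, to_orient)])
    a_from <- paste0(lk$from, lk$from_orient)
    a_to <- paste0(lk$to, lk$to_orient)
    b_from <- paste0(lk$to, data.table::fifelse(lk$to_orient == "+", "-", "+"))
    b_to <- paste0(lk$from, data.table::fifelse(lk$from_orient == "+", "-", "+"))
    dt <- unique(data.table(from = c(a_from, b_from), to = c(a_to, b_to)))
    succ <- lapply(split(dt$to, dt$from), function(x) sort(unique(x)))
  }
  succ
}

#' Enumerate tip-to-tip simple paths as candidate transcripts
#'
#' Performs a depth-first traversal from every incoming tip, following links
#' in both unitig orientations, and emits every simple path (no unitig
#' visited twice) that ends at an outgoing tip. Each path is rendered to a
#' nucleotide sequence by overlap-(k-1) concatenation of its oriented unitig
#' sequences. Because paths are simple, candidates cannot contain cycles. A
#' path and its reverse traversal describe the same molecule, so
#' reverse-complement duplicate sequences are merged; candidates containing a
#' seed sequence are reported in the seed's orientation, all others in
#' canonical (lexicographically smaller strand) orientation.
#'
#' @param sub a pruned `SeedSubgraph`.
#' @param max_paths hard cap on the number of paths; path counts grow
#'   exponentially with the number of branchings, so exceeding the cap is an
#'   error rather than a silent truncation.
#' @return `data.table` with columns `candidate_id`, `sequence`, `path`,
#'   `n_unitigs`, `length`, `seed`.
#' @export
enumerate_candidates <- function(sub, max_paths = 10000L) {
  stopifnot(inherits(sub, "SeedSubgraph"), max_paths >= 1L)
  ug <- sub$ug
  k <- ug$params$k
  succ <- .oriented_successors(ug)
  seq_of <- stats::setNames(ug$unitigs$sequence, as.character(ug$unitigs$id))

  starts <- sort(paste0(sub$incoming_tips$unitig, sub$incoming_tips$orient))
  paths <- list()
  n_paths <- 0L

  walk <- function(cur, visited, trail) {
    nx <- succ[[cur]]
    nx <- nx[!(.node_of(nx) %chin% visited)]
    if (is.null(succ[[cur]]) || length(succ[[cur]]) == 0L) {
      ## genuine outgoing tip
      n_paths <<- n_paths + 1L
      if (n_paths > max_paths) {
        stop("simple path count exceeds max_paths = ", max_paths,
             "; the subgraph is too branched to enumerate")
      }
      paths[[n_paths]] <<- trail
      return(invisible())
    }
    for (v in nx) {
      walk(v, c(visited, .node_of(v)), c(trail, v))
    }
    invisible()
  }
  for (s in starts) {
    walk(s, .node_of(s), s)
  }

  if (n_paths == 0L) {
    return(data.table(candidate_id = character(0), sequence = character(0),
                      path = character(0), n_unitigs = integer(0),
                      length = integer(0), seed = character(0)))
  }
  render <- function(trail) {
    un <- .node_of(trail)
    or <- substr(trail, nchar(trail), nchar(trail))
    sq <- data.table::fifelse(or == "+", seq_of[un],
                              revcomp(seq_of[un]))
    out <- sq[1L]
    for (i in seq_along(sq)[-1L]) {
      # links guarantee a k-1 overlap between consecutive oriented unitigs
      out <- paste0(out, substr(sq[i], k, nchar(sq[i])))
    }
    out
  }
  dt <- data.table(
    sequence = vapply(paths, render, ""),
    path = vapply(paths, function(tr) paste(paste0("u", tr), collapse = ","), ""),
    n_unitigs = vapply(paths, length, integer(1))
  )
  ## merge reverse-complement duplicate traversals, orient by seed
  rc <- revcomp(dt$sequence)
  dt[, canon := data.table::fifelse(rc < sequence, rc, sequence)]
  setorder(dt, canon, path)
  dt <- dt[, .SD[1L], by = canon]
  oriented <- vapply(seq_len(nrow(dt)), function(i) {
    s <- dt$sequence[i]
    r <- revcomp(s)
    for (sd in sub$seeds) {
      if (grepl(sd, s, fixed = TRUE)) return(s)
      if (grepl(sd, r, fixed = TRUE)) return(r)
    }
    if (r < s) r else s
  }, "")
  dt[, sequence := oriented]
  dt[, canon := NULL]
  setorder(dt, sequence, path)
  dt[, candidate_id := sprintf("cand_%03d", .I)]
  dt[, length := nchar(sequence)]
  dt[, seed := paste(names(sub$seeds), collapse = ",")]
  setcolorder(dt, c("candidate_id", "sequence", "path", "n_unitigs",
                    "length", "seed"))
  dt[]
}

#' Combine candidate sets across samples, removing duplicates
#'
#' Two candidates are duplicates when their sequences are equal or reverse
#' complements of each other. The retained representative is the
#' lexicographically smaller of (sequence, reverse complement); per-sample
#' provenance is kept as metadata.
#'
#' @param candidate_sets named list (one element per sample) of candidate
#'   tables as returned by [enumerate_candidates()], or of plain character
#'   vectors of sequences.
#' @return `data.table` with columns `sequence`, `samples`, `n_samples`,
#'   `seeds`.
#' @export
dedupe_candidates <- function(candidate_sets) {
  stopifnot(is.list(candidate_sets), length(candidate_sets) >= 1L)
  if (is.null(names(candidate_sets))) {
    names(candidate_sets) <- paste0("sample", seq_along(candidate_sets))
  }
  rows <- lapply(names(candidate_sets), function(nm) {
    x <- candidate_sets[[nm]]
    if (is.character(x)) {
      data.table(sequence = x, seed = NA_character_, sample = nm)
    } else {
      data.table(sequence = x$sequence,
                 seed = if ("seed" %in% names(x)) x$seed else NA_character_,
                 sample = nm)
    }
  })
  dt <- rbindlist(rows)
  rc <- revcomp(dt$sequence)
  dt[, canon := data.table::fifelse(rc < sequence, rc, sequence)]
  out <- dt[, .(
    sequence = canon[1L],
    samples = paste(sort(unique(sample)), collapse = ","),
    n_samples = length(unique(sample)),
    seeds = paste(sort(unique(stats::na.omit(seed))), collapse = ",")
  ), by = canon][, canon := NULL]
  setorder(out, sequence)
  out[]
}

#' @method print SeedSubgraph
#' @export
print.SeedSubgraph <- function(x, ...) {
  cat(sprintf(
    "SeedSubgraph [%s]: %d unitig(s), %d incoming / %d outgoing tip(s)\n",
    paste(names(x$seeds), collapse = ","), nrow(x$ug$unitigs),
    nrow(x$incoming_tips), nrow(x$outgoing_tips)))
  invisible(x)
}
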