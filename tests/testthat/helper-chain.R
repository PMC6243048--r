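# Chain-of-segment-groups models for path-enumeration and decomposition
# tests: groups of alternative segments alternate with shared segments; the
# isoform set is the full combination product.  Segments are rejected until
# no two share a k-mer, so the splice-graph topology is exact.

make_chain_segments <- function(sizes, seg_len = 120L, k = 47L, seed = 1L,
                                max_tries = 40L) {
  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      groups <- lapply(seq_along(sizes), function(gi) {
        stats::setNames(
          vapply(seq_len(sizes[gi]), function(j) random_dna(seg_len), ""),
          sprintf("g%d_%d", gi, seq_len(sizes[gi])))
      })
      all_seg <- unlist(groups)
      ksets <- lapply(all_seg, function(s) oracle_canon(oracle_windows(s, k)))
      bad <- FALSE
      for (i in seq_along(ksets)) {
        for (j in seq_len(i - 1L)) {
          if (length(intersect(ksets[[i]], ksets[[j]]))) bad <- TRUE
        }
      }
      if (!bad) {
        combos <- expand.grid(lapply(groups, names),
                              stringsAsFactors = FALSE)
        isos <- apply(combos, 1L, function(r) {
          paste(vapply(seq_along(r),
                       function(gi) groups[[gi]][[r[[gi]]]], ""),
                collapse = "")
        })
        names(isos) <- apply(combos, 1L, paste, collapse = "-")
        return(list(groups = groups, isoforms = isos))
      }
    }
    stop("could not build shared-k-mer-free chain model")
  })
}

# independent tip-to-tip simple-path enumeration over a UnitigGraph's links,
# via igraph on the doubled (oriented) graph
oracle_tip_paths <- function(ug) {
  flip <- function(o) ifelse(o == "+", "-", "+")
  verts <- c(paste0(ug$unitigs$id, "+"), paste0(ug$unitigs$id, "-"))
  lk <- unique(ug$links[, .(from, from_orient, to, to_orient)])
  if (nrow(lk)) {
    ed <- rbind(
      data.frame(a = paste0(lk$from, lk$from_orient),
                 b = paste0(lk$to, lk$to_orient)),
      data.frame(a = paste0(lk$to, flip(lk$to_orient)),
                 b = paste0(lk$from, flip(lk$from_orient)))
    )
    ed <- unique(ed)
  } else {
    ed <- data.frame(a = character(0), b = character(0))
  }
  g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                     vertices = data.frame(name = verts))
  din <- igraph::degree(g, mode = "in")
  dout <- igraph::degree(g, mode = "out")
  starts <- verts[din[verts] == 0L]
  ends <- verts[dout[verts] == 0L]
  unit_of <- function(v) sub("[+-]$", "", v)
  paths <- character(0)
  for (s in starts) {
    if (s %in% ends) {
      paths <- c(paths, paste0("u", s))
    }
    sp <- igraph::all_simple_paths(g, from = s, to = ends, mode = "out")
    for (p in sp) {
      vs <- names(p)
      if (anyDuplicated(unit_of(vs))) next  # not unitig-simple
      paths <- c(paths, paste(paste0("u", vs), collapse = ","))
    }
  }
  ## a traversal and its reverse-complement traversal are one path
  rev_path <- function(p) {
    vs <- strsplit(p, ",", fixed = TRUE)[[1L]]
    vs <- rev(vs)
    o <- substr(vs, nchar(vs), nchar(vs))
    paste(paste0(substr(vs, 1L, nchar(vs) - 1L), flip(o)), collapse = ",")
  }
  canon <- vapply(paths, function(p) min(p, rev_path(p)), "",
                  USE.NAMES = FALSE)
  sort(unique(canon))
}

canon_path_set <- function(paths) {
  flip <- function(o) ifelse(o == "+", "-", "+")
  rev_path <- function(p) {
    vs <- strsplit(p, ",", fixed = TRUE)[[1L]]
    vs <- rev(vs)
    o <- substr(vs, nchar(vs), nchar(vs))
    paste(paste0(substr(vs, 1L, nchar(vs) - 1L), flip(o)), collapse = ",")
  }
  sort(unique(vapply(paths, function(p) min(p, rev_path(p)), "",
                     USE.NAMES = FALSE)))
}

# independent greedy unitig decomposition oracle working on plain strings
oracle_unitig_partition <- function(reads, k) {
  nodes <- unique(oracle_canon(
    unlist(lapply(reads, oracle_windows, w = k), use.names = FALSE)))
  edges <- unique(oracle_canon(
    unlist(lapply(reads, oracle_windows, w = k + 1L), use.names = FALSE)))
  has_edge <- function(e) oracle_canon(e) %in% edges
  succ <- function(s) {
    out <- character(0)
    for (b in c("A", "C", "G", "T")) {
      if (has_edge(paste0(s, b))) {
        out <- c(out, paste0(substr(s, 2L, k), b))
      }
    }
    out
  }
  pred <- function(s) oracle_revcomp(succ(oracle_revcomp(s)))
  visited <- character(0)
  parts <- list()
  for (n in nodes) {
    if (n %in% visited) next
    chain <- n
    ## extend right
    cur <- n
    repeat {
      nx <- succ(cur)
      if (length(nx) != 1L) break
      if (length(pred(nx)) != 1L) break
      cn <- oracle_canon(nx)
      if (cn %in% oracle_canon(chain)) break
      chain <- c(chain, nx)
      cur <- nx
    }
    ## extend left
    cur <- n
    repeat {
      pv <- pred(cur)
      if (length(pv) != 1L) break
      if (length(succ(pv)) != 1L) break
      cn <- oracle_canon(pv)
      if (cn %in% oracle_canon(chain)) break
      chain <- c(pv, chain)
      cur <- pv
    }
    part <- sort(oracle_canon(chain))
    visited <- c(visited, part)
    parts[[length(parts) + 1L]] <- part
  }
  parts
}

## builds a diamond graph plus a spur of `m` k-mers hanging off the core
spur_subgraph <- function(m, seed = 54) {
  set.seed(seed)
  model <- make_mutually_exclusive_gene(seed = seed)
  isos <- isoform_set(model)
  psi <- model$exons[["psi"]]
  anchor_at <- 200L
  anchor <- substr(psi, anchor_at, anchor_at + 46L)
  spur_read <- paste0(anchor, random_dna(m))
  g <- build_graph(c(unname(isos), spur_read), graph_params(), color = "s")
  ug <- suppressMessages(collapse_unitigs(g, "s"))
  suppressMessages(extract_seed_subgraphs(ug, c(psi = psi)))[[1L]]
}

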