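## Oriented-node bookkeeping.  An oriented node is the canonical k-mer string
## with "+" or "-" appended; "+" reads the canonical string as stored, "-"
## reads its reverse complement.

.flip_orient <- function(x) {
  n <- nchar(x)
  o <- substr(x, n, n)
  paste0(substr(x, 1L, n - 1L), data.table::fifelse(o == "+", "-", "+"))
}

.node_of <- function(x) substr(x, 1L, nchar(x) - 1L)

## directed oriented adjacency implied by canonical (k+1)-mer edges,
## restricted to endpoints present in `kmers`; each physical edge contributes
## its two strand readings
.oriented_adjacency <- function(edges, k, kmers) {
  if (length(edges) == 0L) {
    return(data.table(from = character(0), to = character(0)))
  }
  p <- substr(edges, 1L, k)
  s <- substr(edges, 2L, k + 1L)
  cp <- .canon_chr(p)
  cs <- .canon_chr(s)
  ok <- cp %chin% kmers & cs %chin% kmers
  p <- p[ok]; s <- s[ok]; cp <- cp[ok]; cs <- cs[ok]
  op <- data.table::fifelse(p == cp, "+", "-")
  os <- data.table::fifelse(s == cs, "+", "-")
  fo <- paste0(cp, op)
  to <- paste0(cs, os)
  adj <- data.table(from = c(fo, .flip_orient(to)),
                    to   = c(to, .flip_orient(fo)))
  unique(adj)
}

#' Collapse a colored De Bruijn graph into unitigs
#'
#' Maximal runs of adjacent nodes with exactly one incoming and one outgoing
#' neighbor (except at run ends) are collapsed into unitigs, with adjacency
#' taken over the union of `collapse_colors`. Every node of the graph ends up
#' in exactly one unitig; isolated nodes become single-k-mer unitigs. Each
#' unitig records, per color, the arithmetic mean coverage of its constituent
#' k-mers, and inter-unitig links are recorded per color between unitig ends.
#'
#' Unitig sequences are reported in the lexicographically smaller of the two
#' strand orientations, so output is deterministic across runs.
#'
#' @param graph a `ColoredDBG`.
#' @param collapse_colors colors whose edge union defines adjacency. In a
#'   seed-guided assembly this should be the short-read sample color only, so
#'   that seed or long-read colors cannot introduce junctions; the default
#'   uses all colors.
#' @return a `UnitigGraph`.
#' @export
collapse_unitigs <- function(graph, collapse_colors = graph$colors) {
  stopifnot(inherits(graph, "ColoredDBG"))
  if (!all(collapse_colors %in% graph$colors) || length(collapse_colors) < 1L) {
    stop("collapse_colors must be a non-empty subset of graph colors")
  }
  k <- graph$params$k
  kmers <- graph$kmers
  if (length(kmers) == 0L) {
    return(.new_unitiggraph(graph, collapse_colors, list()))
  }
  E <- sort(unique(unlist(graph$edges[collapse_colors], use.names = FALSE)))
  adj <- .oriented_adjacency(E, k, kmers)

  ## unique successor where oriented out-degree is exactly one
  deg <- adj[, .N, by = from]
  uniq <- adj[from %chin% deg[N == 1L, from]]
  usucc <- stats::setNames(uniq$to, uniq$from)

  ## simple link u->v: u's unique successor is v AND v's unique predecessor
  ## is u (checked via the mirror orientation)
  if (length(usucc)) {
    back <- usucc[.flip_orient(unname(usucc))]
    ok <- !is.na(back) & back == .flip_orient(names(usucc))
    next_simple <- usucc[ok]
  } else {
    next_simple <- character(0)
  }
  prev_simple <- stats::setNames(names(next_simple), unname(next_simple))

  visited <- new.env(hash = TRUE, parent = emptyenv())
  chains <- vector("list", length(kmers))
  n_chain <- 0L
  for (x in kmers) {
    if (!is.null(visited[[x]])) next
    start <- paste0(x, "+")
    ## walk backward to the chain start (cycle-guarded)
    cur <- start
    seen <- new.env(hash = TRUE, parent = emptyenv())
    seen[[x]] <- TRUE
    repeat {
      p <- prev_simple[cur]
      if (is.na(p) || is.null(p) || length(p) == 0L) break
      p <- unname(p)
      pn <- .node_of(p)
      if (!is.null(seen[[pn]])) break  # cycle: start anywhere
      cur <- p
      seen[[pn]] <- TRUE
    }
    ## walk forward collecting the chain
    chain <- cur
    cn <- .node_of(cur)
    inchain <- new.env(hash = TRUE, parent = emptyenv())
    inchain[[cn]] <- TRUE
    repeat {
      nx <- next_simple[chain[length(chain)]]
      if (is.na(nx) || is.null(nx) || length(nx) == 0L) break
      nx <- unname(nx)
      nn <- .node_of(nx)
      if (!is.null(inchain[[nn]])) break  # closed the cycle
      chain <- c(chain, nx)
      inchain[[nn]] <- TRUE
    }
    for (id in chain) visited[[.node_of(id)]] <- TRUE
    n_chain <- n_chain + 1L
    chains[[n_chain]] <- chain
  }
  chains <- chains[seq_len(n_chain)]
  .new_unitiggraph(graph, collapse_colors, chains)
}

## assemble the UnitigGraph object from oriented-node chains
.new_unitiggraph <- function(graph, collapse_colors, chains) {
  k <- graph$params$k
  n <- length(chains)
  seqs <- character(n)
  node_rows <- vector("list", n)
  for (i in seq_len(n)) {
    chain <- chains[[i]]
    nodes <- .node_of(chain)
    orient <- substr(chain, nchar(chain), nchar(chain))
    oriented <- data.table::fifelse(orient == "+", nodes, revcomp(nodes))
    sq <- paste0(oriented[1L],
                 paste(substr(oriented[-1L], k, k), collapse = ""))
    rsq <- revcomp(sq)
    if (rsq < sq) {  # deterministic canonical orientation
      sq <- rsq
      nodes <- rev(nodes)
      orient <- rev(data.table::fifelse(orient == "+", "-", "+"))
    }
    seqs[i] <- sq
    node_rows[[i]] <- data.table(kmer = nodes, unitig = i,
                                 pos = seq_along(nodes), orient = orient)
  }
  unitigs <- data.table(id = seq_len(n), sequence = seqs,
                        kmer_count = vapply(chains, length, integer(1)))
  node_map <- if (n) rbindlist(node_rows) else
    data.table(kmer = character(0), unitig = integer(0),
               pos = integer(0), orient = character(0))
  setkey(node_map, kmer)

  mean_cov <- matrix(numeric(0), nrow = n, ncol = length(graph$colors),
                     dimnames = list(as.character(seq_len(n)), graph$colors))
  if (n) {
    mean_cov <- do.call(rbind, lapply(seq_len(n), function(i) {
      colMeans(graph$cov[node_rows[[i]]$kmer, , drop = FALSE])
    }))
    dimnames(mean_cov) <- list(as.character(seq_len(n)), graph$colors)
  }

  links <- .unitig_links(graph, unitigs, k)
  structure(
    list(params = graph$params, colors = graph$colors,
         collapse_colors = collapse_colors,
         unitigs = unitigs, mean_cov = mean_cov, links = links,
         node_map = node_map, graph = graph),
    class = "UnitigGraph"
  )
}

## per-color links between unitig ends: graph edges that are not internal to
## any unitig, expressed as (from unitig, orientation) -> (to unitig,
## orientation), mirror-deduplicated
.unitig_links <- function(graph, unitigs, k) {
  empty <- data.table(from = integer(0), from_orient = character(0),
                      to = integer(0), to_orient = character(0),
                      color = character(0))
  if (nrow(unitigs) == 0L) return(empty)
  internal <- unlist(lapply(unitigs$sequence, function(s) {
    if (nchar(s) < k + 1L) character(0) else .canon_chr(.windows(s, k + 1L))
  }), use.names = FALSE)

  L <- nchar(unitigs$sequence)
  first_f <- substr(unitigs$sequence, 1L, k)
  last_f <- substr(unitigs$sequence, L - k + 1L, L)
  ## oriented k-mer at which a traversal leaves / enters a unitig
  out_val <- data.table(unitig = rep(unitigs$id, 2L),
                        orient = rep(c("+", "-"), each = nrow(unitigs)),
                        end_kmer = c(last_f, revcomp(first_f)))
  in_val <- data.table(unitig = rep(unitigs$id, 2L),
                       orient = rep(c("+", "-"), each = nrow(unitigs)),
                       end_kmer = c(first_f, revcomp(last_f)))
  setkey(out_val, end_kmer); setkey(in_val, end_kmer)

  rows <- list()
  for (co in graph$colors) {
    e <- setdiff(graph$edges[[co]], internal)
    if (length(e) == 0L) next
    ## both strand readings of each junction edge
    p <- c(substr(e, 1L, k), revcomp(substr(e, 2L, k + 1L)))
    s <- c(substr(e, 2L, k + 1L), revcomp(substr(e, 1L, k)))
    fu <- out_val[J(p), nomatch = NA]
    tu <- in_val[J(s), nomatch = NA]
    ok <- !is.na(fu$unitig) & !is.na(tu$unitig)
    if (!any(ok)) next
    rows[[co]] <- data.table(from = fu$unitig[ok], from_orient = fu$orient[ok],
                             to = tu$unitig[ok], to_orient = tu$orient[ok],
                             color = co)
  }
  if (length(rows) == 0L) return(empty)
  links <- rbindlist(rows)
  ## mirror-deduplicate: a link and its reverse reading are one object
  key_a <- paste(links$from, links$from_orient, links$to, links$to_orient)
  key_b <- paste(links$to, data.table::fifelse(links$to_orient == "+", "-", "+"),
                 links$from,
                 data.table::fifelse(links$from_orient == "+", "-", "+"))
  links[, `:=`(canon_key = data.table::fifelse(key_a <= key_b, key_a, key_b))]
  links <- unique(links, by = c("canon_key", "color"))
  links[, canon_key := NULL]
  setorder(links, color, from, from_orient, to, to_orient)
  links[]
}

#' Remove unitigs by mean coverage
#'
#' A unitig is removed iff its mean k-mer coverage is strictly below
#' `threshold` (so a unitig at exactly the threshold survives). Links touching
#' removed unitigs are deleted. By default the graph is re-collapsed after
#' removal, since removing a unitig can merge formerly branching runs.
#'
#' @param ug a `UnitigGraph`.
#' @param threshold coverage threshold (default from the graph's parameters).
#' @param color color whose mean coverage is tested; `NULL` tests the sum of
#'   mean coverages across all colors (the joined view used after long-read
#'   threading).
#' @param recollapse re-run unitig collapsing on the surviving node set.
#' @return a `UnitigGraph`.
#' @export
filter_unitigs_by_mean_coverage <- function(ug,
                                            threshold =
                                              ug$params$min_unitig_mean_coverage,
                                            color = NULL,
                                            recollapse = TRUE) {
  stopifnot(inherits(ug, "UnitigGraph"))
  if (is.null(color)) {
    covv <- rowSums(ug$mean_cov)
  } else {
    if (!color %in% ug$colors) stop("unknown color: ", color)
    covv <- ug$mean_cov[, color]
  }
  keep_ids <- ug$unitigs$id[covv >= threshold]
  n_removed <- nrow(ug$unitigs) - length(keep_ids)
  message(sprintf("coverage filter: removed %d of %d unitig(s) below %s",
                  n_removed, nrow(ug$unitigs), format(threshold)))
  if (recollapse) {
    keep_kmers <- ug$node_map[unitig %in% keep_ids, kmer]
    sub <- .subset_graph(ug$graph, keep_kmers)
    return(collapse_unitigs(sub, ug$collapse_colors))
  }
  .subset_unitiggraph(ug, keep_ids)
}

## restrict a UnitigGraph to a set of unitig ids (ids are preserved)
.subset_unitiggraph <- function(ug, ids) {
  keep <- ug$unitigs$id %in% ids
  out <- ug
  out$unitigs <- ug$unitigs[keep]
  out$mean_cov <- ug$mean_cov[keep, , drop = FALSE]
  out$links <- ug$links[from %in% ids & to %in% ids]
  out$node_map <- ug$node_map[unitig %in% ids]
  out
}

#' Expand unitigs back to their constituent canonical k-mers
#'
#' @param ug a `UnitigGraph`.
#' @param ids unitig ids (default all).
#' @return character vector of canonical k-mers.
#' @export
unitig_kmers <- function(ug, ids = ug$unitigs$id) {
  ug$node_map[unitig %in% ids, kmer]
}

#' @method print UnitigGraph
#' @export
print.UnitigGraph <- function(x, ...) {
  cat(sprintf("UnitigGraph: k=%d, %d unitig(s), %d link row(s), colors: %s\n",
              x$params$k, nrow(x$unitigs), nrow(x$links),
              paste(x$colors, collapse = ", ")))
  invisible(x)
}
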