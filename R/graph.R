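#' Graph construction parameters
#'
#' @param k odd k-mer length in bases. The default of 47 gives specific
#'   anchoring in transcript-scale sequences while still tolerating moderate
#'   coverage; odd k guarantees no k-mer equals its own reverse complement.
#' @param min_unitig_mean_coverage unitigs whose mean k-mer coverage in the
#'   filtering color falls strictly below this value are removed (default 4).
#' @param ccs_prune_coverage after joining long-read colors, unitigs with a
#'   joined mean coverage strictly below this value are pruned (default 2).
#' @return a `GraphParams` object.
#' @export
graph_params <- function(k = 47L, min_unitig_mean_coverage = 4,
                         ccs_prune_coverage = 2) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L || k %% 2L == 0L) {
    stop("k must be an odd integer >= 3")
  }
  if (min_unitig_mean_coverage < 0 || ccs_prune_coverage < 0) {
    stop("coverage thresholds must be >= 0")
  }
  structure(
    list(k = k,
         min_unitig_mean_coverage = min_unitig_mean_coverage,
         ccs_prune_coverage = ccs_prune_coverage),
    class = "GraphParams"
  )
}

.new_coloreddbg <- function(params, kmers, cov, edges) {
  stopifnot(is.matrix(cov), nrow(cov) == length(kmers))
  rownames(cov) <- kmers
  structure(
    list(params = params, colors = colnames(cov), kmers = kmers,
         cov = cov, edges = edges),
    class = "ColoredDBG"
  )
}

#' Build a colored De Bruijn graph from reads
#'
#' Nodes are canonical k-mers; the coverage of a node is the number of
#' occurrences of the k-mer in either orientation across the reads. A directed
#' base edge exists between two nodes iff some read contains the corresponding
#' (k+1)-mer; edges are stored strand-symmetrically as canonical (k+1)-mers.
#' k-mer windows containing non-ACGT characters contribute nothing. Reads
#' shorter than k are skipped with a message.
#'
#' @param reads character vector (or `DNAStringSet`) of read sequences.
#' @param params a [graph_params()] object.
#' @param color label for this data source; one color per graph build.
#' @return a `ColoredDBG`.
#' @examples
#' g <- build_graph("ACGTA", graph_params(k = 3), color = "s1")
#' g$kmers
#' @export
build_graph <- function(reads, params = graph_params(), color = "reads") {
  reads <- toupper(as.character(reads))
  stopifnot(is.character(color), length(color) == 1L)
  if (length(reads) == 0L) stop("reads must be non-empty")
  k <- params$k
  usable <- nchar(reads) >= k
  if (sum(!usable) > 0L) {
    message(sprintf("build_graph [%s]: skipped %d read(s) shorter than k=%d",
                    color, sum(!usable), k))
  }
  if (!any(usable)) {
    warning("all reads shorter than k; returning empty graph")
    cov <- matrix(integer(0), nrow = 0L, ncol = 1L,
                  dimnames = list(NULL, color))
    return(.new_coloreddbg(params, character(0), cov,
                           stats::setNames(list(character(0)), color)))
  }
  reads <- reads[usable]
  km <- .canon_chr(.extract_kmers(reads, k))
  if (length(km) == 0L) {
    warning("no valid k-mers found; returning empty graph")
    cov <- matrix(integer(0), nrow = 0L, ncol = 1L,
                  dimnames = list(NULL, color))
    return(.new_coloreddbg(params, character(0), cov,
                           stats::setNames(list(character(0)), color)))
  }
  dt <- data.table(kmer = km)[, .N, by = kmer]
  setkey(dt, kmer)
  em <- sort(unique(.canon_chr(.extract_kmers(reads, k + 1L))))
  cov <- matrix(dt$N, ncol = 1L, dimnames = list(dt$kmer, color))
  .new_coloreddbg(params, dt$kmer, cov, stats::setNames(list(em), color))
}

#' Merge colored De Bruijn graphs over a shared node space
#'
#' Union of node sets; every input color's coverages and edges are preserved
#' unchanged. All graphs must share the same k and have disjoint color labels.
#'
#' @param graphs list of `ColoredDBG` objects.
#' @return a `ColoredDBG` whose colors are the concatenation of the inputs'.
#' @export
merge_graphs <- function(graphs) {
  stopifnot(is.list(graphs), length(graphs) >= 1L)
  lapply(graphs, function(g) stopifnot(inherits(g, "ColoredDBG")))
  ks <- vapply(graphs, function(g) g$params$k, integer(1))
  if (length(unique(ks)) != 1L) stop("all graphs must share the same k")
  cols <- unlist(lapply(graphs, function(g) g$colors), use.names = FALSE)
  if (anyDuplicated(cols)) stop("color labels must be disjoint across graphs")
  kmers <- sort(unique(unlist(lapply(graphs, function(g) g$kmers),
                              use.names = FALSE)))
  cov <- matrix(0L, nrow = length(kmers), ncol = length(cols),
                dimnames = list(kmers, cols))
  for (g in graphs) {
    if (length(g$kmers)) cov[g$kmers, g$colors] <- g$cov
  }
  edges <- do.call(c, lapply(graphs, function(g) g$edges))
  .new_coloreddbg(graphs[[1L]]$params, kmers, cov, edges)
}

#' Flatten several colors into one
#'
#' The new color's per-node coverage is the sum over the merged colors and its
#' edge set is their union; the merged colors are removed.
#'
#' @param graph a `ColoredDBG`.
#' @param colors subset of `graph$colors` to merge.
#' @param new_color label for the merged color.
#' @return a `ColoredDBG`.
#' @export
flatten_colors <- function(graph, colors, new_color) {
  stopifnot(inherits(graph, "ColoredDBG"))
  if (length(colors) == 0L) stop("colors to flatten must be non-empty")
  if (!all(colors %in% graph$colors)) stop("unknown color(s)")
  keep <- setdiff(graph$colors, colors)
  if (new_color %in% keep) stop("new_color collides with a remaining color")
  merged_cov <- as.integer(rowSums(graph$cov[, colors, drop = FALSE]))
  cov <- cbind(graph$cov[, keep, drop = FALSE],
               matrix(merged_cov, ncol = 1L, dimnames = list(NULL, new_color)))
  edges <- c(graph$edges[keep],
             stats::setNames(
               list(sort(unique(unlist(graph$edges[colors],
                                       use.names = FALSE)))),
               new_color))
  .new_coloreddbg(graph$params, graph$kmers, cov, edges)
}

## restrict a graph to a subset of canonical k-mers; edges with either
## endpoint outside the subset are dropped
.subset_graph <- function(graph, kmers_keep) {
  k <- graph$params$k
  keep <- graph$kmers %in% kmers_keep
  kmers <- graph$kmers[keep]
  cov <- graph$cov[keep, , drop = FALSE]
  edges <- lapply(graph$edges, function(e) {
    if (length(e) == 0L) return(e)
    p <- .canon_chr(substr(e, 1L, k))
    s <- .canon_chr(substr(e, 2L, k + 1L))
    e[p %chin% kmers & s %chin% kmers]
  })
  .new_coloreddbg(graph$params, kmers, cov, edges)
}

#' @method print ColoredDBG
#' @export
print.ColoredDBG <- function(x, ...) {
  cat(sprintf("ColoredDBG: k=%d, %d node(s), %d color(s)\n",
              x$params$k, length(x$kmers), length(x$colors)))
  for (co in x$colors) {
    cat(sprintf("  color %-20s cov sum %10d  edges %d\n", co,
                sum(x$cov[, co]), length(x$edges[[co]])))
  }
  invisible(x)
}

#' Serialize a colored De Bruijn graph to JSON
#'
#' Schema: `k`, `colors`, `kmers`, `coverage` (one integer vector per color,
#' parallel to `kmers`) and `edges` (one vector of canonical (k+1)-mers per
#' color).
#'
#' @param graph a `ColoredDBG`.
#' @param path output file path.
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "ColoredDBG"))
  obj <- list(
    k = graph$params$k,
    min_unitig_mean_coverage = graph$params$min_unitig_mean_coverage,
    ccs_prune_coverage = graph$params$ccs_prune_coverage,
    colors = as.list(graph$colors),
    kmers = graph$kmers,
    coverage = lapply(graph$colors, function(co) unname(graph$cov[, co])),
    edges = graph$edges
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- graph_params(obj$k,
                         obj$min_unitig_mean_coverage %||% 4,
                         obj$ccs_prune_coverage %||% 2)
  colors <- unlist(obj$colors)
  kmers <- as.character(obj$kmers %||% character(0))
  cov <- matrix(0L, nrow = length(kmers), ncol = length(colors),
                dimnames = list(kmers, colors))
  for (i in seq_along(colors)) {
    cov[, i] <- as.integer(obj$coverage[[i]])
  }
  edges <- lapply(obj$edges, function(e) as.character(e %||% character(0)))
  names(edges) <- colors
  .new_coloreddbg(params, kmers, cov, edges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
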