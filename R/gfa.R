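#' Export a unitig graph as GFA1
#'
#' S-lines carry unitig sequences with `KN:i` (k-mer count) and `MC:Z`
#' (per-color mean coverage, `color=value` pairs) tags. L-lines carry links
#' between unitig ends with the `0M` overlap convention (unitig sequences
#' already include their junction k-mers, so no bases are shared on the link
#' record itself); the link color is stored in a `CL:Z` tag. The header
#' records the k-mer size (`KL:i`) and color order (`CS:Z`).
#'
#' @param ug a `UnitigGraph`.
#' @param path optional output file; when `NULL` the GFA lines are returned.
#' @return character vector of GFA lines, invisibly when written to file.
#' @export
export_gfa <- function(ug, path = NULL) {
  stopifnot(inherits(ug, "UnitigGraph"))
  header <- sprintf("H\tVN:Z:1.0\tKL:i:%d\tCS:Z:%s", ug$params$k,
                    paste(ug$colors, collapse = ","))
  s_lines <- character(0)
  if (nrow(ug$unitigs)) {
    mc <- apply(ug$mean_cov, 1L, function(r) {
      paste(sprintf("%s=%.10g", ug$colors, r), collapse = ",")
    })
    s_lines <- sprintf("S\tu%d\t%s\tKN:i:%d\tMC:Z:%s",
                       ug$unitigs$id, ug$unitigs$sequence,
                       ug$unitigs$kmer_count, mc)
  }
  l_lines <- character(0)
  if (nrow(ug$links)) {
    l_lines <- sprintf("L\tu%d\t%s\tu%d\t%s\t0M\tCL:Z:%s",
                       ug$links$from, ug$links$from_orient,
                       ug$links$to, ug$links$to_orient, ug$links$color)
  }
  lines <- c(header, s_lines, l_lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a GFA1 file written by [export_gfa()]
#'
#' Restores the unitig table, per-color mean coverages, and links. The
#' underlying k-mer level graph is not part of the format, so the returned
#' `UnitigGraph` carries `graph = NULL` and an empty node map.
#'
#' @param x path to a GFA file, or a character vector of GFA lines.
#' @return a `UnitigGraph` (sequence/coverage/link content only).
#' @export
read_gfa <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  rec <- strsplit(lines, "\t", fixed = TRUE)
  types <- vapply(rec, `[`, "", 1L)
  h <- rec[types == "H"]
  if (length(h) != 1L) stop("expected exactly one GFA header line")
  h <- h[[1L]]
  tag <- function(fields, prefix) {
    hit <- grep(paste0("^", prefix), fields, value = TRUE)
    if (length(hit) != 1L) stop("missing GFA tag ", prefix)
    sub(paste0("^", prefix), "", hit)
  }
  k <- as.integer(tag(h, "KL:i:"))
  colors <- strsplit(tag(h, "CS:Z:"), ",", fixed = TRUE)[[1L]]

  s <- rec[types == "S"]
  ids <- integer(0); seqs <- character(0); kn <- integer(0)
  mean_cov <- matrix(numeric(0), 0L, length(colors),
                     dimnames = list(NULL, colors))
  if (length(s)) {
    ids <- as.integer(sub("^u", "", vapply(s, `[`, "", 2L)))
    seqs <- vapply(s, `[`, "", 3L)
    kn <- as.integer(vapply(s, function(f) tag(f, "KN:i:"), ""))
    mc <- lapply(s, function(f) {
      kv <- strsplit(strsplit(tag(f, "MC:Z:"), ",", fixed = TRUE)[[1L]],
                     "=", fixed = TRUE)
      stats::setNames(vapply(kv, function(p) as.numeric(p[2L]), 0),
                      vapply(kv, `[`, "", 1L))
    })
    mean_cov <- do.call(rbind, lapply(mc, function(m) m[colors]))
    dimnames(mean_cov) <- list(as.character(ids), colors)
  }
  l <- rec[types == "L"]
  links <- data.table(from = integer(0), from_orient = character(0),
                      to = integer(0), to_orient = character(0),
                      color = character(0))
  if (length(l)) {
    links <- data.table(
      from = as.integer(sub("^u", "", vapply(l, `[`, "", 2L))),
      from_orient = vapply(l, `[`, "", 3L),
      to = as.integer(sub("^u", "", vapply(l, `[`, "", 4L))),
      to_orient = vapply(l, `[`, "", 5L),
      color = vapply(l, function(f) tag(f, "CL:Z:"), "")
    )
  }
  structure(
    list(params = graph_params(k), colors = colors, collapse_colors = colors,
         unitigs = data.table(id = ids, sequence = seqs, kmer_count = kn),
         mean_cov = mean_cov, links = links,
         node_map = data.table(kmer = character(0), unitig = integer(0),
                               pos = integer(0), orient = character(0)),
         graph = NULL),
    class = "UnitigGraph"
  )
}
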