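#' Thread CCS long reads into a colored De Bruijn graph
#'
#' Each CCS read is converted to its own single-color graph; the per-read
#' colors of each group are then flattened into one group color (coverages
#' summed, edges unioned) and the group graphs are merged with the input
#' graph. Short-read colors are never altered.
#'
#' @param graph the short-read `ColoredDBG` to join onto.
#' @param ccs_reads named character vector of CCS read sequences.
#' @param group_labels character vector (parallel to `ccs_reads`) assigning
#'   each read to a group; each group becomes one color.
#' @return merged `ColoredDBG` with one additional color per group.
#' @export
thread_ccs <- function(graph, ccs_reads, group_labels) {
  stopifnot(inherits(graph, "ColoredDBG"))
  ccs_reads <- as.character(ccs_reads)
  if (length(ccs_reads) == 0L) {
    return(graph)
  }
  stopifnot(length(group_labels) == length(ccs_reads))
  if (is.null(names(ccs_reads))) {
    names(ccs_reads) <- paste0("ccs", seq_along(ccs_reads))
  }
  groups <- split(ccs_reads, group_labels)
  group_graphs <- lapply(names(groups), function(gl) {
    reads <- groups[[gl]]
    per_read <- lapply(names(reads), function(id) {
      build_graph(reads[[id]], graph$params, color = id)
    })
    g <- if (length(per_read) == 1L) per_read[[1L]] else merge_graphs(per_read)
    flatten_colors(g, g$colors, new_color = gl)
  })
  merge_graphs(c(list(graph), group_graphs))
}

#' Collapse a joined graph and prune weakly covered unitigs
#'
#' After long-read colors are joined, unitigs whose mean coverage summed over
#' all colors falls strictly below `threshold` are removed (default 2, from
#' the graph parameters).
#'
#' @param graph a joined `ColoredDBG`.
#' @param collapse_colors colors defining adjacency (typically the short-read
#'   sample color).
#' @param threshold coverage threshold.
#' @return a `UnitigGraph`.
#' @export
prune_joined_graph <- function(graph, collapse_colors = graph$colors,
                               threshold = graph$params$ccs_prune_coverage) {
  ug <- collapse_unitigs(graph, collapse_colors)
  filter_unitigs_by_mean_coverage(ug, threshold, color = NULL)
}

#' Filter CCS alignments by edit distance
#'
#' Keeps alignments with edit distance strictly below `max_nm_exclusive`
#' (default 5): NM = 4 is kept, NM = 5 is discarded.
#'
#' @param alns `data.frame`/`data.table` of alignments with a column
#'   `edit_distance`.
#' @param max_nm_exclusive exclusive upper bound on NM.
#' @return the filtered alignment table.
#' @export
filter_ccs_alignments <- function(alns, max_nm_exclusive = 5) {
  stopifnot("edit_distance" %in% names(alns))
  as.data.table(alns)[edit_distance < max_nm_exclusive]
}

#' Aggregate CCS reads by which alternate region they align to
#'
#' Each read is assigned to exactly one of the two named regions or to
#' "neither", based on its primary and supplementary alignments. Reads whose
#' alignments touch both regions are contradictory: they are flagged,
#' excluded (group `NA`), and reported.
#'
#' @param alns alignment table with columns `read_id`, `target`, `role`.
#' @param region_map named character vector mapping target ids to region
#'   labels.
#' @param regions length-2 character vector naming the two alternate regions
#'   (e.g. the two mutually exclusive first exons).
#' @return `data.table` with columns `read_id`, `group` (one of `regions`,
#'   `"neither"`, or `NA` for excluded reads).
#' @export
group_ccs_by_region <- function(alns, region_map, regions) {
  stopifnot(length(regions) == 2L)
  alns <- as.data.table(alns)
  stopifnot(all(c("read_id", "target", "role") %in% names(alns)))
  use <- alns[role %in% c("primary", "supplementary")]
  out <- lapply(unique(alns$read_id), function(rid) {
    tg <- use[read_id == rid, target]
    hit <- intersect(unique(unname(region_map[tg])), regions)
    grp <- if (length(hit) == 2L) NA_character_
           else if (length(hit) == 1L) hit
           else "neither"
    data.table(read_id = rid, group = grp)
  })
  res <- rbindlist(out)
  n_bad <- sum(is.na(res$group))
  if (n_bad) {
    message(sprintf(
      "group_ccs_by_region: excluded %d read(s) matching both regions", n_bad))
  }
  setorder(res, read_id)
  res[]
}

#' Count CCS reads that uniquely support one locus
#'
#' A read contributes one count to locus L iff every one of its surviving
#' alignments maps to a transcript assigned to L; reads whose alignments span
#' two or more loci contribute nothing. Apply [filter_ccs_alignments()]
#' first. Counts are invariant to alignment order and to duplicated
#' alignment records.
#'
#' @param alns alignment table with columns `read_id`, `target`.
#' @param locus_map named character vector mapping every target to a locus.
#' @return named integer vector of per-locus read counts (loci with zero
#'   reads omitted).
#' @export
count_unique_locus_reads <- function(alns, locus_map) {
  alns <- as.data.table(alns)
  stopifnot(all(c("read_id", "target") %in% names(alns)))
  if (nrow(alns) == 0L) return(stats::setNames(integer(0), character(0)))
  if (!all(alns$target %in% names(locus_map))) {
    stop("locus_map must cover every aligned target")
  }
  per <- alns[, .(loci = list(unique(unname(locus_map[target])))),
              by = read_id]
  uni <- per[vapply(loci, length, integer(1)) == 1L]
  if (nrow(uni) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(vapply(uni$loci, `[[`, "", 1L))
  out <- stats::setNames(as.integer(tab), names(tab))
  out[order(names(out))]
}

#' Align CCS reads to target sequences (internal aligner)
#'
#' Local alignment of each read against every target with edit-like scoring;
#' the edit distance reported is NM-style (substitutions plus inserted plus
#' deleted bases over the aligned region). Per read, the best alignment
#' (fewest matches lost) is labelled `primary`; other surviving alignments
#' covering a mostly disjoint stretch of the read are `supplementary` (split
#' alignments, as when consecutive exon regions each align), and alignments
#' overlapping the primary span are `secondary`. Alignments with fewer than
#' `min_match` matching bases are discarded as spurious.
#'
#' For users with external long-read alignments, [read_sam()] ingests SAM
#' records instead.
#'
#' @param ccs_reads named character vector of read sequences.
#' @param targets named character vector of target sequences.
#' @param min_match minimum number of matching bases for an alignment to be
#'   reported (default 47, one k-mer length).
#' @return `data.table` with columns `read_id`, `target`, `role`,
#'   `edit_distance`, `n_match`, `score`, `read_start`, `read_end`.
#' @export
align_ccs <- function(ccs_reads, targets, min_match = 47L) {
  stopifnot(!is.null(names(ccs_reads)), !is.null(names(targets)))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = TRUE)
  tg <- Biostrings::DNAStringSet(toupper(as.character(targets)))
  rows <- lapply(names(ccs_reads), function(rid) {
    pa <- Biostrings::pairwiseAlignment(tg,
                                        toupper(ccs_reads[[rid]]),
                                        type = "local",
                                        substitutionMatrix = submat,
                                        gapOpening = 2, gapExtension = 1)
    nm <- Biostrings::nmismatch(pa) +
      Biostrings::insertion(Biostrings::nindel(pa))[, "WidthSum"] +
      Biostrings::deletion(Biostrings::nindel(pa))[, "WidthSum"]
    sbj <- Biostrings::subject(pa)
    dt <- data.table(read_id = rid, target = names(targets),
                     edit_distance = as.integer(nm),
                     n_match = Biostrings::nmatch(pa),
                     score = Biostrings::score(pa),
                     read_start = BiocGenerics::start(sbj),
                     read_end = BiocGenerics::end(sbj))
    dt <- dt[n_match >= min_match]
    if (nrow(dt) == 0L) return(dt[, role := character(0)])
    setorder(dt, -n_match, edit_distance, target)
    ps <- dt$read_start[1L]
    pe <- dt$read_end[1L]
    role <- c("primary", vapply(seq_len(nrow(dt))[-1L], function(i) {
      ov <- max(0L, min(pe, dt$read_end[i]) - max(ps, dt$read_start[i]) + 1L)
      span <- min(pe - ps, dt$read_end[i] - dt$read_start[i]) + 1L
      if (ov / span < 0.5) "supplementary" else "secondary"
    }, ""))
    dt[, role := role]
    dt
  })
  out <- rbindlist(rows, use.names = TRUE)
  setcolorder(out, c("read_id", "target", "role", "edit_distance",
                     "n_match", "score", "read_start", "read_end"))
  out[]
}

#' Minimal SAM ingestion (CIGAR and NM only)
#'
#' Parses plain-text SAM records, keeping the query name, target, CIGAR, NM
#' tag, and the alignment role derived from FLAG bits (0x100 secondary,
#' 0x800 supplementary, otherwise primary). Unmapped records are dropped.
#'
#' @param path path to a SAM file (plain text).
#' @return `data.table` with columns `read_id`, `target`, `role`,
#'   `edit_distance`, `cigar`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) {
      stop("malformed SAM record at line ", i, ": fewer than 11 fields")
    }
    flag <- suppressWarnings(as.integer(f[2L]))
    if (is.na(flag)) stop("malformed FLAG at line ", i)
    if (bitwAnd(flag, 4L) != 0L) return(NULL)  # unmapped
    role <- if (bitwAnd(flag, 2048L) != 0L) "supplementary"
            else if (bitwAnd(flag, 256L) != 0L) "secondary"
            else "primary"
    nm_tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    nm <- if (length(nm_tag)) as.integer(sub("^NM:i:", "", nm_tag[1L]))
          else NA_integer_
    data.table(read_id = f[1L], target = f[3L], role = role,
               edit_distance = nm, cigar = f[6L])
  })
  rbindlist(Filter(Negate(is.null), rows))
}
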