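#' Parse a SAMv1 CIGAR string
#'
#' @param cigar CIGAR string (ops M, I, D, N, S, H, P, =, X).
#' @return `data.table` with columns `op` and `len`.
#' @export
parse_cigar <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L)
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1L]]
  if (m[1L] == -1L || sum(attr(m, "match.length")) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar)
  }
  tok <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  data.table(op = substr(tok, nchar(tok), nchar(tok)),
             len = as.integer(substr(tok, 1L, nchar(tok) - 1L)))
}

#' CIGAR match length
#'
#' The number of matched bases of an alignment: the summed lengths of M and
#' `=` operations minus the number of substitution mismatches. Soft/hard
#' clips, insertions, deletions, and skips contribute nothing. When NM values
#' are ingested from SAM, pass substitutions only (NM minus inserted and
#' deleted bases), since NM also counts indels.
#'
#' @param cigar CIGAR string.
#' @param substitution_mismatches number of substituted bases within the
#'   aligned region (default 0).
#' @return integer match length (never negative).
#' @examples
#' cigar_match_length("1008M52S")   # 1008
#' @export
cigar_match_length <- function(cigar, substitution_mismatches = 0L) {
  ops <- parse_cigar(cigar)
  aligned <- sum(ops[op %in% c("M", "="), len])
  if (substitution_mismatches > aligned) {
    stop("substitution_mismatches exceeds aligned bases")
  }
  max(0L, aligned - as.integer(substitution_mismatches))
}

#' Substitution count from a SAM NM tag
#'
#' NM counts substituted, inserted, and deleted bases; subtracting the indel
#' widths of the CIGAR leaves the substitutions needed by
#' [cigar_match_length()].
#'
#' @param cigar CIGAR string.
#' @param nm NM tag value.
#' @return non-negative integer substitution count.
#' @export
substitutions_from_nm <- function(cigar, nm) {
  ops <- parse_cigar(cigar)
  indel <- sum(ops[op %in% c("I", "D"), len])
  max(0L, as.integer(nm) - indel)
}

#' Similarity proportion of an assembled transcript to a reference
#'
#' `match_length / target_length`. Values above 1 can only arise from M runs
#' spanning indels; they are capped at 1 with a warning. Rounding to two
#' decimals is left to presentation (see [similarity_from_cigar()]).
#'
#' @param match_length matched bases (see [cigar_match_length()]).
#' @param target_length reference transcript length (>= 1).
#' @return proportion in `[0, 1]`.
#' @export
similarity_proportion <- function(match_length, target_length) {
  stopifnot(target_length >= 1)
  p <- match_length / target_length
  if (any(p > 1)) {
    warning("match length exceeds target length; capping similarity at 1")
    p <- pmin(p, 1)
  }
  p
}

#' Similarity table from alignment CIGAR strings
#'
#' Convenience wrapper computing, per row, the CIGAR match length and the
#' similarity proportion rounded to two decimals.
#'
#' @param reference reference transcript ids.
#' @param reference_length reference lengths.
#' @param cigar CIGAR strings.
#' @param substitutions substitution mismatch counts (default 0).
#' @param assembly optional assembly labels.
#' @return `data.table` with columns `reference`, `reference_length`,
#'   `assembly`, `match_length`, `similarity` (2 decimals), `cigar`.
#' @export
similarity_from_cigar <- function(reference, reference_length, cigar,
                                  substitutions = 0L, assembly = NA_character_) {
  n <- length(cigar)
  substitutions <- rep_len(substitutions, n)
  ml <- vapply(seq_len(n), function(i) {
    cigar_match_length(cigar[i], substitutions[i])
  }, integer(1))
  data.table(
    reference = rep_len(reference, n),
    reference_length = as.integer(rep_len(reference_length, n)),
    assembly = rep_len(assembly, n),
    match_length = ml,
    similarity = round(similarity_proportion(ml, rep_len(reference_length, n)),
                       2L),
    cigar = cigar
  )
}

#' Best-match similarity of assembled transcripts against references
#'
#' For each reference, every assembled transcript is aligned (local alignment
#' with the internal aligner) and scored by its number of matching bases; the
#' maximum match length over assemblies gives the reference's similarity.
#' Assembled transcripts are strandless, so both orientations are tried. A
#' reference that no assembly aligns to gets similarity 0 and is flagged.
#'
#' @param assembled named character vector of assembled transcripts.
#' @param references named character vector of reference transcripts.
#' @return `data.table` with columns `reference`, `reference_length`,
#'   `best_assembly`, `match_length`, `similarity` (2 decimals),
#'   `similarity_raw`, `aligned`.
#' @export
best_match_similarity <- function(assembled, references) {
  stopifnot(length(assembled) >= 1L, length(references) >= 1L,
            !is.null(names(assembled)), !is.null(names(references)))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = TRUE)
  fwd <- toupper(as.character(assembled))
  asm <- Biostrings::DNAStringSet(c(fwd, revcomp(fwd)))
  rows <- lapply(names(references), function(rf) {
    rl <- nchar(references[[rf]])
    pa <- Biostrings::pairwiseAlignment(asm, toupper(references[[rf]]),
                                        type = "local",
                                        substitutionMatrix = submat,
                                        gapOpening = 2, gapExtension = 1)
    ml <- Biostrings::nmatch(pa)
    best <- (which.max(ml) - 1L) %% length(assembled) + 1L
    ml <- pmax(ml[seq_along(assembled)],
               ml[seq_along(assembled) + length(assembled)])
    raw <- similarity_proportion(ml[best], rl)
    data.table(reference = rf, reference_length = rl,
               best_assembly = names(assembled)[best],
               match_length = ml[best],
               similarity = round(raw, 2L), similarity_raw = raw,
               aligned = ml[best] > 0L)
  })
  rbindlist(rows)
}
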