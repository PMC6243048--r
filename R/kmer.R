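#' Reverse complement of nucleotide strings
#'
#' @param x character vector of ACGT sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

## canonical form of ACGT-only strings: lexicographic min of (s, revcomp(s)).
## Direct `<` is safe here: every collation orders A < C < G < T for
## upper-case single letters (cross-checked against a C-locale radix sort in
## the test suite).
.canon_chr <- function(x) {
  if (length(x) == 0L) return(character(0))
  rc <- revcomp(x)
  data.table::fifelse(rc < x, rc, x)
}

#' Canonicalize k-mers
#'
#' Maps each k-mer to the lexicographic minimum of itself and its reverse
#' complement, the node identity used by the strand-symmetric graph. k-mers
#' containing characters outside ACGT are rejected (returned as `NA`) so that
#' callers can skip them.
#'
#' @param kmer character vector of k-mers.
#' @param k expected k-mer length; if given, any other length is an error.
#' @return list with `kmer` (canonical form, `NA` for invalid input) and
#'   `is_rc` (`TRUE` where the reverse complement was returned).
#' @examples
#' canonicalize(c("ACGT", "CGTA", "TACG"))
#' @export
canonicalize <- function(kmer, k = NULL) {
  if (!is.null(k) && any(nchar(kmer) != k)) {
    stop("all k-mers must have length ", k)
  }
  valid <- !grepl("[^ACGT]", kmer)
  out <- rep(NA_character_, length(kmer))
  flag <- rep(NA, length(kmer))
  if (any(valid)) {
    v <- kmer[valid]
    rc <- revcomp(v)
    take <- rc < v
    out[valid] <- data.table::fifelse(take, rc, v)
    flag[valid] <- take
  }
  list(kmer = out, is_rc = flag)
}

## all length-w windows of one string (character(0) when too short)
.windows <- function(x, w) {
  n <- nchar(x)
  if (n < w) return(character(0))
  substring(x, 1L:(n - w + 1L), w:n)
}

## all length-w windows over a vector of reads, invalid (non-ACGT) windows
## removed
.extract_kmers <- function(reads, w) {
  reads <- reads[nchar(reads) >= w]
  if (length(reads) == 0L) return(character(0))
  km <- unlist(lapply(reads, .windows, w = w), use.names = FALSE)
  km[!grepl("[^ACGT]", km)]
}

## evaluate expr under a temporary RNG seed, restoring global RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
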