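.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a gene model with mutually exclusive first and last exons
#'
#' Emulates a locus whose isoforms choose exactly one of several alternate 5'
#' exons and one of several alternate 3' exons around a shared core: the
#' diamond topology in which a De Bruijn graph shows two incoming tips, a
#' core unitig, and two outgoing tips. Exon sequences are uniform random over
#' ACGT; generation rejects draws in which any two exons share a k-mer (in
#' either orientation), and draws in which two alternate 5' exons end in the
#' same base or two alternate 3' exons start with the same base (a shared
#' terminal base would make some junction k-mers coincide), so the diamond
#' topology of the k-mer graph is exact.
#'
#' @param five_prime_lengths named lengths of the alternate 5' exons
#'   (defaults: `alpha`, `beta`, 200 bases each).
#' @param core_lengths named lengths of the shared core exon(s) (default
#'   `psi`, 500 bases).
#' @param three_prime_lengths named lengths of the alternate 3' exons
#'   (defaults: `gamma` 250, `delta` 300).
#' @param k k-mer length the exclusion constraint protects (default 47).
#' @param seed RNG seed; the model is deterministic given the seed.
#' @param max_tries rejection-sampling attempts before giving up.
#' @return a `GeneModel`: `exons` (named sequences), `groups`, `k`.
#' @export
make_mutually_exclusive_gene <- function(
    five_prime_lengths = c(alpha = 200L, beta = 200L),
    core_lengths = c(psi = 500L),
    three_prime_lengths = c(gamma = 250L, delta = 300L),
    k = 47L, seed = NULL, max_tries = 20L) {
  lens <- c(five_prime_lengths, core_lengths, three_prime_lengths)
  if (any(lens < k)) stop("every exon must be at least k bases long")
  if (anyDuplicated(names(lens))) stop("exon names must be unique")
  .with_seed(seed, {
    for (try in seq_len(max_tries)) {
      exons <- stats::setNames(
        vapply(lens, .random_seq, ""), names(lens))
      fp <- exons[names(five_prime_lengths)]
      tp <- exons[names(three_prime_lengths)]
      ## junction k-mers must be isoform-specific
      ok <- !anyDuplicated(substr(fp, nchar(fp), nchar(fp))) &&
        !anyDuplicated(substr(tp, 1L, 1L))
      ksets <- lapply(exons, function(e) unique(.canon_chr(.windows(e, k))))
      for (i in seq_along(ksets)) {
        for (j in seq_len(i - 1L)) {
          if (length(intersect(ksets[[i]], ksets[[j]]))) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (ok) {
        return(structure(
          list(exons = exons,
               groups = list(five_prime = names(five_prime_lengths),
                             core = names(core_lengths),
                             three_prime = names(three_prime_lengths)),
               k = as.integer(k)),
          class = "GeneModel"))
      }
    }
    stop("could not satisfy the shared k-mer exclusion in ", max_tries,
         " tries")
  })
}

#' Splice an isoform from a gene model
#'
#' Concatenates exons in genomic order: one (or no) alternate 5' exon, the
#' core exon(s), and one alternate 3' exon. Passing `five_prime = NULL`
#' yields a short version that starts at the core.
#'
#' @param model a [make_mutually_exclusive_gene()] model.
#' @param five_prime name of the 5' exon, or `NULL` for a short version.
#' @param three_prime name of the 3' exon.
#' @return named character scalar; the name joins the used exon names with
#'   `_`.
#' @export
splice_isoform <- function(model, five_prime, three_prime) {
  stopifnot(inherits(model, "GeneModel"))
  parts <- character(0)
  if (!is.null(five_prime) && !is.na(five_prime)) {
    if (!five_prime %in% model$groups$five_prime) {
      stop("unknown 5' exon: ", five_prime)
    }
    parts <- five_prime
  }
  parts <- c(parts, model$groups$core)
  if (!three_prime %in% model$groups$three_prime) {
    stop("unknown 3' exon: ", three_prime)
  }
  parts <- c(parts, three_prime)
  stats::setNames(paste(model$exons[parts], collapse = ""),
                  paste(parts, collapse = "_"))
}

#' All isoforms of a gene model
#'
#' @param model a `GeneModel`.
#' @param include_short also emit the short versions lacking a 5' exon.
#' @return named character vector of isoform sequences.
#' @export
isoform_set <- function(model, include_short = FALSE) {
  fp <- as.list(model$groups$five_prime)
  if (include_short) fp <- c(fp, list(NULL))
  out <- character(0)
  for (f in fp) {
    for (t in model$groups$three_prime) {
      out <- c(out, splice_isoform(model, f, t))
    }
  }
  out
}

## apply i.i.d. substitution errors to a vector of sequences
.add_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (length(hit) == 0L) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (i in hit) {
      ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    }
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate paired-end short reads from an isoform set
#'
#' Models a shotgun library at the molecule level: full-length transcript
#' copies are drawn per isoform in proportion to abundance, each copy is
#' fragmented sequentially into pieces of roughly `fragment_mean` bases, and
#' every piece at least `read_length` long is sequenced from both ends (the
#' second mate reverse-complemented). Because fragmentation pieces are
#' bounded by the molecule ends, transcript ends are covered like interior
#' bases — the property that lets an error-free library reconstruct
#' full-length isoforms. Substitution errors are applied per base. The number
#' of read pairs per isoform is proportional to abundance times length; with
#' unit abundances the realized per-base depth approximates `coverage`
#' (pieces lost to size selection make it land slightly below the target).
#'
#' @param isoforms named character vector of isoform sequences.
#' @param abundances named non-negative weights (default: all 1); not all
#'   zero.
#' @param read_length read length in bases (default 125, a 2 x 125 bp
#'   library).
#' @param fragment_mean,fragment_sd normal fragment-size model for the
#'   sequential cuts (defaults 300 / 25).
#' @param error_rate per-base substitution probability (default 0).
#' @param coverage target per-base depth for an abundance-1 isoform (default
#'   20); ignored when `n_molecules` is given.
#' @param n_molecules explicit number of molecule copies per abundance unit.
#' @param seed RNG seed.
#' @return list with `pairs` (`data.table`: `read_id`, `mate1`, `mate2`) and
#'   `truth` (`data.table`: `read_id`, `isoform`, `start`,
#'   `fragment_length`).
#' @export
simulate_read_pairs <- function(isoforms, abundances = NULL,
                                read_length = 125L, fragment_mean = 300,
                                fragment_sd = 25, error_rate = 0,
                                coverage = 20, n_molecules = NULL,
                                seed = NULL) {
  stopifnot(!is.null(names(isoforms)))
  if (is.null(abundances)) {
    abundances <- stats::setNames(rep(1, length(isoforms)), names(isoforms))
  }
  stopifnot(all(names(isoforms) %in% names(abundances)))
  a <- abundances[names(isoforms)]
  if (any(a < 0) || sum(a) == 0) stop("abundances must be >= 0, not all 0")
  if (read_length > fragment_mean) stop("read_length must be <= fragment_mean")
  len <- nchar(isoforms)
  ## one molecule yields ~2*read_length covered bases per fragment_mean of
  ## sequence, so this molecule count hits the coverage target
  if (is.null(n_molecules)) {
    n_molecules <- ceiling(coverage * fragment_mean / (2 * read_length))
  }
  m_per_iso <- round(n_molecules * a)
  .with_seed(seed, {
    rows <- list()
    n_row <- 0L
    for (iso in names(isoforms)) {
      L <- len[[iso]]
      for (mol in seq_len(m_per_iso[[iso]])) {
        pos <- 1L
        first <- TRUE
        while (pos <= L) {
          ## uniform first-piece length randomizes the cut phase so that
          ## coverage is stationary along the molecule
          fl <- if (first) {
            first <- FALSE
            max(1L, as.integer(ceiling(runif(1L, 0, fragment_mean))))
          } else {
            max(1L, as.integer(round(rnorm(1L, fragment_mean, fragment_sd))))
          }
          end <- min(L, pos + fl - 1L)
          if (end - pos + 1L >= read_length) {
            n_row <- n_row + 1L
            rows[[n_row]] <- c(iso, pos, end)
          }
          pos <- end + 1L
        }
      }
    }
    if (n_row == 0L) stop("no fragment survived size selection")
    iso <- vapply(rows, `[`, "", 1L)
    start <- as.integer(vapply(rows, `[`, "", 2L))
    end <- as.integer(vapply(rows, `[`, "", 3L))
    fl <- end - start + 1L
    frag_seq <- substr(isoforms[iso], start, end)
    m1 <- substr(frag_seq, 1L, read_length)
    m2 <- revcomp(substr(frag_seq, fl - read_length + 1L, fl))
    m1 <- .add_substitutions(m1, error_rate)
    m2 <- .add_substitutions(m2, error_rate)
    ids <- sprintf("pair_%05d", seq_len(n_row))
    list(
      pairs = data.table(read_id = ids, mate1 = unname(m1),
                         mate2 = unname(m2)),
      truth = data.table(read_id = ids, isoform = unname(iso),
                         start = start, fragment_length = fl)
    )
  })
}

## apply i.i.d. indel errors (insertions and deletions equally likely)
.add_indels <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  out <- character(0)
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(ch)) {
    r <- runif(1L)
    if (r < rate / 2) {
      next  # deletion
    } else if (r < rate) {
      out <- c(out, sample(bases, 1L), ch[i])  # insertion before base
    } else {
      out <- c(out, ch[i])
    }
  }
  paste(out, collapse = "")
}

#' Simulate long circular-consensus (CCS) reads
#'
#' Emits full-length isoform copies with optional indel errors and an
#' optional 5' truncation mode emulating the 5' loss seen in long-read
#' library preparation: truncated reads cover the core and 3' exon but not
#' the alternate 5' exon.
#'
#' @param isoforms named character vector of isoform sequences.
#' @param counts named non-negative integer copies per isoform.
#' @param indel_rate per-base indel probability (default 0).
#' @param truncate_5p number of bases removed from the 5' end of every read
#'   (default 0).
#' @param seed RNG seed.
#' @return list with `reads` (named character) and `truth` (`data.table`:
#'   `read_id`, `isoform`, `truncated_bases`).
#' @export
simulate_ccs_reads <- function(isoforms, counts, indel_rate = 0,
                               truncate_5p = 0L, seed = NULL) {
  stopifnot(!is.null(names(isoforms)), all(names(counts) %in% names(isoforms)))
  if (any(counts < 0)) stop("counts must be >= 0")
  .with_seed(seed, {
    reads <- character(0)
    truth <- list()
    idx <- 0L
    for (iso in names(counts)) {
      for (cp in seq_len(counts[[iso]])) {
        idx <- idx + 1L
        s <- isoforms[[iso]]
        if (truncate_5p > 0L) {
          if (truncate_5p >= nchar(s)) stop("truncation removes whole read")
          s <- substr(s, truncate_5p + 1L, nchar(s))
        }
        s <- .add_indels(s, indel_rate)
        id <- sprintf("ccs_%03d", idx)
        reads[[id]] <- s
        truth[[idx]] <- data.table(read_id = id, isoform = iso,
                                   truncated_bases = as.integer(truncate_5p))
      }
    }
    list(reads = reads,
         truth = if (idx) rbindlist(truth) else
           data.table(read_id = character(0), isoform = character(0),
                      truncated_bases = integer(0)))
  })
}
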