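#' Support-filter parameters
#'
#' Defaults implement the retention rule "estimated count of at least
#' `min_count` in at least `min_support_samples` of `n_bootstrap` bootstrap
#' replicates" with 1 in at least 95 of 100.
#'
#' @param n_bootstrap number of bootstrap replicates (default 100).
#' @param min_count estimated-count threshold per replicate, inclusive
#'   (default 1).
#' @param min_support_samples number of replicates that must meet
#'   `min_count`, inclusive (default 95).
#' @param em_tolerance EM stop criterion: maximum relative change of the
#'   abundance vector between iterations (default 1e-8).
#' @param em_max_iter EM iteration cap (default 1000).
#' @param fragment_mean mean fragment length used for effective lengths
#'   (default 200).
#' @param length_mode `"effective"` uses `max(1, L - fragment_mean + 1)`;
#'   `"plain"` uses the transcript length unchanged.
#' @param rng_seed seed for the bootstrap resampler; `NULL` leaves the RNG
#'   state alone.
#' @return a `FilterParams` object.
#' @export
filter_params <- function(n_bootstrap = 100L, min_count = 1,
                          min_support_samples = 95L,
                          em_tolerance = 1e-8, em_max_iter = 1000L,
                          fragment_mean = 200,
                          length_mode = c("effective", "plain"),
                          rng_seed = NULL) {
  n_bootstrap <- as.integer(n_bootstrap)
  min_support_samples <- as.integer(min_support_samples)
  if (min_support_samples < 0L || min_support_samples > n_bootstrap) {
    stop("min_support_samples must be in [0, n_bootstrap]")
  }
  if (min_count < 0) stop("min_count must be >= 0")
  structure(
    list(n_bootstrap = n_bootstrap, min_count = min_count,
         min_support_samples = min_support_samples,
         em_tolerance = em_tolerance, em_max_iter = as.integer(em_max_iter),
         fragment_mean = fragment_mean,
         length_mode = match.arg(length_mode), rng_seed = rng_seed),
    class = "FilterParams"
  )
}

#' Build a k-mer index over candidate transcripts
#'
#' @param candidates named character vector of candidate sequences.
#' @param k k-mer length (must match the graph k used for assembly).
#' @return a `KmerIndex`.
#' @export
kmer_index <- function(candidates, k) {
  stopifnot(length(candidates) >= 1L, !is.null(names(candidates)))
  candidates <- stats::setNames(toupper(as.character(candidates)),
                                names(candidates))
  rows <- lapply(names(candidates), function(tx) {
    km <- unique(.canon_chr(.extract_kmers(candidates[[tx]], k)))
    data.table(kmer = km, tx = tx)
  })
  map <- rbindlist(rows)
  setkey(map, kmer)
  structure(
    list(k = k, map = map, tx_ids = names(candidates),
         lengths = stats::setNames(nchar(candidates), names(candidates))),
    class = "KmerIndex"
  )
}

#' Pseudoalign a read pair to candidate transcripts
#'
#' Returns the intersection, over all valid k-mers of both mates
#' (strand-agnostic), of the candidate sets containing each k-mer. k-mers
#' absent from every candidate are skipped rather than forcing emptiness; a
#' pair with no indexed k-mer at all is unassigned (empty set).
#'
#' @param mate1,mate2 read sequences of the pair.
#' @param index a [kmer_index()].
#' @return sorted character vector of compatible transcript ids (possibly
#'   empty).
#' @export
pseudoalign_pair <- function(mate1, mate2, index) {
  stopifnot(inherits(index, "KmerIndex"))
  km <- unique(.canon_chr(c(.extract_kmers(toupper(mate1), index$k),
                            .extract_kmers(toupper(mate2), index$k))))
  if (length(km) == 0L) return(character(0))
  hit <- index$map[J(km), nomatch = NULL]
  if (nrow(hit) == 0L) return(character(0))
  sets <- split(hit$tx, hit$kmer)
  sort(Reduce(intersect, sets))
}

#' Group read pairs into pseudoalignment equivalence classes
#'
#' Pairs with identical compatibility sets form one class; unassigned pairs
#' are excluded from the classes and reported separately.
#'
#' @param pairs a list or data.frame with elements/columns `mate1` and
#'   `mate2`.
#' @param candidates named character vector of candidate sequences.
#' @param k k-mer length.
#' @param index optional prebuilt [kmer_index()] over `candidates`.
#' @param require_both_mates if `TRUE`, a pair is unassigned unless each mate
#'   individually shares at least one k-mer with some candidate (internal
#'   stand-in for a pre-mapping step that kept only pairs with both reads
#'   mapped).
#' @return an `EquivalenceClassCounts` object: `classes` (`data.table` of
#'   transcript-id sets and counts), `total_reads` (assigned pairs),
#'   `n_unassigned`, `tx_ids`.
#' @export
build_ec_counts <- function(pairs, candidates, k, index = NULL,
                            require_both_mates = FALSE) {
  if (is.null(index)) index <- kmer_index(candidates, k)
  m1 <- toupper(as.character(pairs$mate1))
  m2 <- toupper(as.character(pairs$mate2))
  stopifnot(length(m1) == length(m2))
  keys <- character(length(m1))
  for (i in seq_along(m1)) {
    if (require_both_mates) {
      h1 <- pseudoalign_pair(m1[i], "", index)
      h2 <- pseudoalign_pair(m2[i], "", index)
      if (length(h1) == 0L || length(h2) == 0L) {
        keys[i] <- ""
        next
      }
      set <- intersect(h1, h2)
      ## both mates hit, but possibly different candidates
      set <- sort(set)
    } else {
      set <- pseudoalign_pair(m1[i], m2[i], index)
    }
    keys[i] <- paste(set, collapse = "\r")
  }
  assigned <- nzchar(keys)
  tab <- data.table(ec_key = keys[assigned])[, .N, by = ec_key]
  classes <- data.table(
    class_id = seq_len(nrow(tab)),
    tx = lapply(strsplit(tab$ec_key, "\r", fixed = TRUE), identity),
    count = tab$N
  )
  n_un <- sum(!assigned)
  if (n_un) message(sprintf("build_ec_counts: %d unassigned pair(s)", n_un))
  structure(
    list(classes = classes, total_reads = sum(classes$count),
         n_unassigned = n_un, tx_ids = index$tx_ids),
    class = "EquivalenceClassCounts"
  )
}

## effective lengths under the fragment model
.eff_lengths <- function(lengths, params) {
  if (params$length_mode == "plain") return(lengths)
  pmax(lengths - params$fragment_mean + 1, 1)
}

## EM core on a dense class-membership matrix.
## A: classes x transcripts 0/1; y: class counts; el: effective lengths.
## Returns allocated read counts per transcript (sums to sum(y)).
.em_core <- function(A, y, el, tol, max_iter) {
  nt <- ncol(A)
  theta <- rep(1 / nt, nt)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    u <- theta / el
    denom <- as.vector(A %*% u)
    pos <- denom > 0
    w <- as.vector(crossprod(A[pos, , drop = FALSE], y[pos] / denom[pos])) * u
    s <- sum(w)
    theta_new <- if (s > 0) w / s else theta
    ## ignore components decaying to zero: their relative change never
    ## settles, but they no longer influence the allocation
    act <- theta_new > 1e-10
    delta <- if (any(act)) {
      max(abs(theta_new[act] - theta[act]) / theta_new[act])
    } else 0
    theta <- theta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(counts = theta * sum(y), theta = theta, n_iter = it,
       converged = converged)
}

## dense membership matrix for an EC object over a transcript universe
.ec_matrix <- function(ec, tx_ids) {
  A <- matrix(0, nrow = nrow(ec$classes), ncol = length(tx_ids),
              dimnames = list(NULL, tx_ids))
  for (i in seq_len(nrow(ec$classes))) {
    A[i, ec$classes$tx[[i]]] <- 1
  }
  A
}

#' EM abundance estimation over equivalence classes
#'
#' Iterates the E-step (allocate each class count to its members proportional
#' to abundance over effective length) and M-step (abundance proportional to
#' allocated counts) until the maximum relative change of the abundance
#' vector falls below `em_tolerance` or `em_max_iter` is hit. Allocated
#' counts sum to the number of assigned read pairs.
#'
#' @param ec an [build_ec_counts()] result.
#' @param lengths named numeric vector of transcript lengths covering every
#'   transcript that appears in a class.
#' @param params a [filter_params()] object.
#' @return an `AbundanceEstimate`: `est_counts` (named, summing to
#'   `ec$total_reads`), `eff_lengths`, `n_iter`, `converged`.
#' @export
em_abundance <- function(ec, lengths, params = filter_params()) {
  stopifnot(inherits(ec, "EquivalenceClassCounts"))
  used <- unique(unlist(ec$classes$tx, use.names = FALSE))
  if (!all(used %in% names(lengths))) {
    stop("lengths must cover every transcript appearing in a class")
  }
  tx_ids <- union(ec$tx_ids, used)
  est <- stats::setNames(numeric(length(tx_ids)), tx_ids)
  if (nrow(ec$classes) == 0L || ec$total_reads == 0L) {
    return(structure(list(est_counts = est,
                          eff_lengths = .eff_lengths(lengths, params),
                          n_iter = 0L, converged = TRUE),
                     class = "AbundanceEstimate"))
  }
  el_all <- .eff_lengths(lengths, params)
  A <- .ec_matrix(ec, used)
  fit <- .em_core(A, ec$classes$count, el_all[used],
                  params$em_tolerance, params$em_max_iter)
  if (!fit$converged) {
    warning("EM did not converge within ", params$em_max_iter, " iterations")
  }
  est[used] <- fit$counts
  structure(list(est_counts = est, eff_lengths = el_all,
                 n_iter = fit$n_iter, converged = fit$converged),
            class = "AbundanceEstimate")
}

#' Bootstrap support for candidate transcripts
#'
#' Resamples the equivalence-class counts multinomially (`total_reads` draws
#' with probabilities proportional to the observed class counts), re-runs the
#' EM on each replicate, and counts, per transcript, the replicates whose
#' estimated count reaches `min_count`. Deterministic given
#' `params$rng_seed`.
#'
#' @inheritParams em_abundance
#' @return a `BootstrapSupport`: `support` (named integer, in
#'   `[0, n_bootstrap]`), `n_bootstrap`, `min_count`, `point_estimate`.
#' @export
bootstrap_support <- function(ec, lengths, params = filter_params()) {
  stopifnot(inherits(ec, "EquivalenceClassCounts"))
  point <- em_abundance(ec, lengths, params)
  tx_ids <- names(point$est_counts)
  support <- stats::setNames(integer(length(tx_ids)), tx_ids)
  if (ec$total_reads == 0L || nrow(ec$classes) == 0L) {
    return(structure(list(support = support,
                          n_bootstrap = params$n_bootstrap,
                          min_count = params$min_count,
                          point_estimate = point$est_counts),
                     class = "BootstrapSupport"))
  }
  used <- unique(unlist(ec$classes$tx, use.names = FALSE))
  A <- .ec_matrix(ec, used)
  el <- .eff_lengths(lengths, params)[used]
  y <- ec$classes$count
  .with_seed(params$rng_seed, {
    for (b in seq_len(params$n_bootstrap)) {
      yb <- as.vector(rmultinom(1L, ec$total_reads, y / sum(y)))
      fit <- .em_core(A, yb, el, params$em_tolerance, params$em_max_iter)
      hit <- used[fit$counts >= params$min_count]
      support[hit] <- support[hit] + 1L
    }
  })
  structure(list(support = support, n_bootstrap = params$n_bootstrap,
                 min_count = params$min_count,
                 point_estimate = point$est_counts),
            class = "BootstrapSupport")
}

#' Retain candidates by bootstrap support
#'
#' A transcript is retained iff its support reaches `min_support_samples`
#' (both the per-replicate count threshold and the support threshold are
#' inclusive).
#'
#' @param support a [bootstrap_support()] result.
#' @param params the [filter_params()] the support was computed with.
#' @return sorted character vector of retained transcript ids.
#' @export
retain_candidates <- function(support, params = filter_params()) {
  stopifnot(inherits(support, "BootstrapSupport"))
  sort(names(support$support)[support$support >= params$min_support_samples])
}

#' Pseudoalign, estimate, bootstrap, and flag candidates in one call
#'
#' @param candidates named character vector of candidate sequences.
#' @param pairs list/data.frame with `mate1`, `mate2`.
#' @param k k-mer length.
#' @param params a [filter_params()] object.
#' @param require_both_mates see [build_ec_counts()].
#' @return `data.table` with columns `tx`, `length`, `est_count`, `support`,
#'   `retained`.
#' @export
quantify_candidates <- function(candidates, pairs, k,
                                params = filter_params(),
                                require_both_mates = FALSE) {
  index <- kmer_index(candidates, k)
  ec <- build_ec_counts(pairs, candidates, k, index = index,
                        require_both_mates = require_both_mates)
  bs <- bootstrap_support(ec, index$lengths, params)
  kept <- retain_candidates(bs, params)
  dt <- data.table(
    tx = names(bs$support),
    length = as.integer(index$lengths[names(bs$support)]),
    est_count = unname(bs$point_estimate[names(bs$support)]),
    support = unname(bs$support),
    retained = names(bs$support) %in% kept
  )
  setorder(dt, tx)
  dt[]
}
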