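#' Construct a partition of samples into subgroups
#'
#' A partition is a named integer vector (names = sample ids, values =
#' subgroup labels 1..k). Labels are canonicalised to be contiguous from 1
#' and, by default, ordered by decreasing cluster size so that "subgroup 1"
#' is always the largest — which keeps reports stable across runs whose
#' raw label arithmetic differs.
#'
#' @param labels integer/factor/character vector of cluster labels.
#' @param sample_ids sample identifiers; defaults to `names(labels)`.
#' @param by_size relabel in order of decreasing cluster size (ties broken
#'   by first appearance)?
#' @return named integer vector with attribute `k`.
#' @export
partition <- function(labels, sample_ids = names(labels), by_size = TRUE) {
  if (is.null(sample_ids))
    sample_ids <- paste0("S", seq_along(labels))
  stopifnot(length(sample_ids) == length(labels))
  if (anyNA(labels)) stop("every sample must be labelled")
  f <- factor(labels)
  if (by_size) {
    sizes <- table(f)
    ord <- names(sizes)[order(-as.vector(sizes), seq_along(sizes))]
    f <- factor(as.character(f), levels = ord)
  }
  out <- as.integer(f)
  names(out) <- sample_ids
  attr(out, "k") <- nlevels(f)
  out
}

#' Map partition labels onto reference labels by majority overlap
#'
#' Cluster labels are arbitrary; to compare a discovered (or predicted)
#' partition against reference labels — e.g. planted subgroups — each
#' partition label is mapped to the reference label holding the majority
#' of its samples. The mapping is learned on one cohort (say, discovery)
#' and can then be applied to another (say, validation predictions).
#'
#' @param p a [partition()] (named).
#' @param reference named reference labels over (a superset of) the same
#'   samples.
#' @return named vector: for each partition label, the majority reference
#'   label.
#' @export
map_labels <- function(p, reference) {
  ref <- reference[names(p)]
  tab <- table(as.integer(p), as.vector(ref))
  setNames(colnames(tab)[apply(tab, 1, which.max)], rownames(tab))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two partitions of the same samples:
#' `ARI = (sum_ij C(n_ij,2) - E) / (0.5 * (sum_i C(a_i,2) + sum_j C(b_j,2)) - E)`
#' with `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)`. 1 means identical
#' up to relabelling; independent partitions score near 0. If both inputs
#' are named, samples are matched by name.
#'
#' @param p,q label vectors (named or positional) over the same samples.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(p, q) {
  if (!is.null(names(p)) && !is.null(names(q))) {
    if (!setequal(names(p), names(q)))
      stop("partitions cover different sample sets")
    q <- q[names(p)]
  } else if (length(p) != length(q)) {
    stop("partitions cover different sample sets")
  }
  n <- length(p)
  pf <- as.integer(factor(p)); qf <- as.integer(factor(q))
  kp <- max(pf); kq <- max(qf)
  nij <- tabulate((pf - 1L) * kq + qf, nbins = kp * kq)
  ai <- tabulate(pf, nbins = kp)
  bj <- tabulate(qf, nbins = kq)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(nij))
  sum_a <- sum(ch2(ai))
  sum_b <- sum(ch2(bj))
  e <- sum_a * sum_b / ch2(n)
  denom <- (sum_a + sum_b) / 2 - e
  if (denom == 0) return(1)  # both partitions trivial (all-singletons or one block)
  (sum_ij - e) / denom
}
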