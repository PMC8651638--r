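# Internal cluster-validity indexes and ensemble voting for k.
#
# All indexes are computed from the samples-in-rows data matrix the
# clustering saw. Each registry entry records its orientation (whether
# larger values mean better clusterings), which the voter respects.

.index_registry <- new.env(parent = emptyenv())

#' Register an internal validity index
#'
#' @param name index name.
#' @param fn function(x, labels, dmat) -> scalar; `x` is samples x
#'   features, `dmat` the precomputed Euclidean distance matrix.
#' @param maximize `TRUE` if larger is better.
#' @export
register_index <- function(name, fn, maximize) {
  assign(name, list(fn = fn, maximize = maximize), envir = .index_registry)
  invisible(name)
}

#' @rdname register_index
#' @export
list_indexes <- function() sort(ls(.index_registry))

cluster_stats <- function(x, labels) {
  k <- max(labels)
  cents <- matrix(vapply(seq_len(k),
                         function(j) colMeans(x[labels == j, , drop = FALSE]),
                         numeric(ncol(x))),
                  nrow = k, ncol = ncol(x), byrow = TRUE)
  sizes <- tabulate(labels, k)
  wss <- sum((x - cents[labels, , drop = FALSE])^2)
  gc <- colMeans(x)
  bss <- sum(sizes * rowSums((cents - rep(gc, each = k))^2))
  list(k = k, centroids = cents, sizes = sizes, wss = wss, bss = bss)
}

local({
  register_index("silhouette", function(x, labels, dmat) {
    mean(cluster::silhouette(labels, dmat)[, "sil_width"])
  }, maximize = TRUE)

  register_index("calinski_harabasz", function(x, labels, dmat) {
    s <- cluster_stats(x, labels)
    n <- nrow(x)
    (s$bss / (s$k - 1)) / (s$wss / (n - s$k))
  }, maximize = TRUE)

  register_index("davies_bouldin", function(x, labels, dmat) {
    s <- cluster_stats(x, labels)
    disp <- vapply(seq_len(s$k), function(j) {
      xi <- x[labels == j, , drop = FALSE]
      mean(sqrt(rowSums((xi - rep(s$centroids[j, ], each = nrow(xi)))^2)))
    }, 0)
    cd <- as.matrix(dist(s$centroids))
    mean(vapply(seq_len(s$k), function(i) {
      r <- (disp[i] + disp[-i]) / cd[i, -i]
      max(r)
    }, 0))
  }, maximize = FALSE)

  register_index("dunn", function(x, labels, dmat) {
    dm <- as.matrix(dmat)
    same <- outer(labels, labels, "==")
    diam <- max(dm[same])
    sep <- min(dm[!same])
    sep / diam
  }, maximize = TRUE)

  register_index("connectivity", function(x, labels, dmat, L = 10L) {
    dm <- as.matrix(dmat)
    n <- nrow(dm)
    L <- min(L, n - 1L)
    total <- 0
    for (i in seq_len(n)) {
      nn <- order(dm[i, ])[2:(L + 1L)]
      viol <- labels[nn] != labels[i]
      total <- total + sum((1 / seq_len(L))[viol])
    }
    total
  }, maximize = FALSE)

  register_index("wb_ratio", function(x, labels, dmat) {
    s <- cluster_stats(x, labels)
    s$wss / max(s$bss, .Machine$double.eps)
  }, maximize = FALSE)

  register_index("pbm", function(x, labels, dmat) {
    s <- cluster_stats(x, labels)
    gc <- colMeans(x)
    e1 <- sum(sqrt(rowSums((x - rep(gc, each = nrow(x)))^2)))
    ek <- sum(sqrt(rowSums((x - s$centroids[labels, , drop = FALSE])^2)))
    dk <- max(dist(s$centroids))
    ((1 / s$k) * (e1 / max(ek, .Machine$double.eps)) * dk)^2
  }, maximize = TRUE)

  register_index("c_index", function(x, labels, dmat) {
    dv <- as.vector(dmat)
    same <- as.vector(as.dist(outer(labels, labels, "==")))
    sw <- sum(dv[same == 1])
    nw <- sum(same == 1)
    srt <- sort(dv)
    smin <- sum(srt[seq_len(nw)])
    smax <- sum(srt[seq(length(srt) - nw + 1L, length(srt))])
    (sw - smin) / max(smax - smin, .Machine$double.eps)
  }, maximize = FALSE)
})

#' Compute an internal cluster-validity index
#'
#' @param m expression matrix (genes x samples) or any feature matrix with
#'   samples in columns.
#' @param p partition (labels over the samples).
#' @param index_name one of [list_indexes()].
#' @return scalar score; attribute `maximize` records the orientation.
#' @export
internal_index <- function(m, p, index_name) {
  if (!exists(index_name, envir = .index_registry))
    stop("unknown index: ", index_name)
  labels <- as.integer(p)
  if (max(labels) < 2L)
    stop(index_name, " requires at least 2 clusters")
  x <- t(m)
  entry <- get(index_name, envir = .index_registry)
  d <- dist(x)
  structure(entry$fn(x, labels, d), maximize = entry$maximize)
}

#' Vote for the number of subgroups with an index ensemble
#'
#' Clusters the cohort at every candidate k (spectral clustering on the
#' RBF affinity), scores each partition with every index, lets each index
#' vote for its best k (respecting orientation), and returns the majority
#' k; ties go to the smaller k.
#'
#' @param m arcsinh-transformed expression matrix (genes x samples).
#' @param candidate_ks integer vector of candidate cluster numbers (>= 2).
#' @param indexes index names (default: all registered, >= 3 required).
#' @param seed integer seed.
#' @return object of class `k_vote`: list with `scores` (index x k
#'   matrix), `votes` (named integer per index), `tally` (table),
#'   `majority_k`, `partitions` (one per candidate k).
#' @export
vote_k <- function(m, candidate_ks = 2:8, indexes = list_indexes(),
                   seed = 1L) {
  candidate_ks <- sort(unique(as.integer(candidate_ks)))
  if (!length(candidate_ks)) stop("no candidate ks")
  if (any(candidate_ks < 2L) || any(candidate_ks > ncol(m)))
    stop("candidate ks must lie in [2, n]")
  if (length(indexes) < 1L) stop("need at least one index")
  aff <- rbf_affinity(m)
  parts <- lapply(candidate_ks, function(k)
    spectral_cluster(aff, k, seed = seed))
  names(parts) <- candidate_ks
  x <- t(m)
  d <- dist(x)
  scores <- matrix(NA_real_, length(indexes), length(candidate_ks),
                   dimnames = list(indexes, candidate_ks))
  for (i in seq_along(indexes)) {
    entry <- get(indexes[i], envir = .index_registry)
    for (j in seq_along(candidate_ks)) {
      scores[i, j] <- entry$fn(x, as.integer(parts[[j]]), d)
    }
  }
  votes <- vapply(indexes, function(nm) {
    entry <- get(nm, envir = .index_registry)
    s <- scores[nm, ]
    candidate_ks[if (entry$maximize) which.max(s) else which.min(s)]
  }, 0L)
  tally <- table(factor(votes, levels = candidate_ks))
  best <- max(tally)
  majority_k <- as.integer(names(tally)[tally == best][1L])  # ties -> smallest k
  structure(list(scores = scores, votes = votes, tally = tally,
                 majority_k = majority_k, partitions = parts),
            class = "k_vote")
}

#' @export
print.k_vote <- function(x, ...) {
  cat("Internal-index ensemble vote for k\n")
  print(x$tally)
  cat("majority k:", x$majority_k, "\n")
  invisible(x)
}
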