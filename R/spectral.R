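# Spectral clustering core: RBF affinity on samples, symmetric normalised
# Laplacian embedding, k-means in the embedded space.

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# squared Euclidean distances between the COLUMNS of m
sq_dist_cols <- function(m) {
  x <- t(m)
  g <- tcrossprod(x)
  sq <- diag(g)
  d2 <- outer(sq, sq, "+") - 2 * g
  d2[d2 < 0] <- 0
  d2
}

#' Radial basis function affinity between samples
#'
#' `A_ij = exp(-sigma * ||x_i - x_j||^2)` over the sample columns of an
#' expression matrix (the kernlab `rbfdot` parameterisation). With
#' `sigma = "auto"` the bandwidth is set to the reciprocal of the median
#' positive pairwise squared distance, so that a "typical" pair has
#' affinity `exp(-1)`.
#'
#' @param m arcsinh-transformed expression matrix (genes x samples), or any
#'   numeric matrix whose columns are the objects to compare.
#' @param sigma positive scalar or `"auto"`.
#' @return symmetric n x n affinity matrix with unit diagonal and
#'   attribute `sigma`.
#' @export
rbf_affinity <- function(m, sigma = "auto") {
  if (any(!is.finite(m))) stop("non-finite values in input")
  d2 <- sq_dist_cols(m)
  if (identical(sigma, "auto")) {
    pos <- d2[upper.tri(d2)]
    pos <- pos[pos > 0]
    sigma <- if (length(pos)) 1 / median(pos) else 1
  }
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  a <- exp(-sigma * d2)
  diag(a) <- 1
  dimnames(a) <- list(colnames(m), colnames(m))
  attr(a, "sigma") <- sigma
  a
}

#' Spectral clustering of an affinity matrix
#'
#' Embeds samples with the top-k eigenvectors of the symmetric normalised
#' affinity `D^-1/2 A D^-1/2` (equivalently the bottom eigenvectors of
#' `L_sym = I - D^-1/2 A D^-1/2`), row-normalises the embedding to the
#' unit sphere and partitions it with k-means (25 restarts, lowest
#' within-cluster SS kept). Deterministic for a given seed.
#'
#' @param a affinity matrix from [rbf_affinity()].
#' @param k number of clusters, `2 <= k <= n` (`k = n` returns singletons).
#' @param seed integer seed for the k-means restarts.
#' @param nstart k-means restarts.
#' @return a [partition()] with provenance attributes.
#' @export
spectral_cluster <- function(a, k, seed = 1L, nstart = 25L) {
  n <- nrow(a)
  if (k < 2 || k > n) stop("k must be in [2, n]")
  if (k == n) {
    return(partition(seq_len(n), colnames(a) %||% paste0("S", seq_len(n)),
                     by_size = FALSE))
  }
  n_comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(a > 1e-12, mode = "undirected")
  )$no
  if (n_comp > k)
    warning("affinity graph has ", n_comp, " components but k = ", k)
  d <- rowSums(a)
  dm12 <- 1 / sqrt(pmax(d, .Machine$double.eps))
  m <- a * tcrossprod(dm12)  # D^-1/2 A D^-1/2
  es <- eigen((m + t(m)) / 2, symmetric = TRUE)
  emb <- es$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(emb^2))
  emb <- emb / pmax(rn, .Machine$double.eps)
  km <- with_seed(seed, kmeans(emb, centers = k, nstart = nstart,
                               iter.max = 100L))
  p <- partition(km$cluster, colnames(a) %||% paste0("S", seq_len(n)))
  attr(p, "provenance") <- list(algorithm = "spectral",
                                sigma = attr(a, "sigma"),
                                seed = seed, nstart = nstart)
  p
}

#' Compare clustering algorithms by partitional consistency
#'
#' Runs several variations of each algorithm (different kernels, linkages
#' or seeds), computes the mean and SD of pairwise adjusted Rand indices
#' within each algorithm, and names the most self-consistent algorithm the
#' winner. High within-algorithm consistency is the selection signal: an
#' algorithm whose variations agree is picking up structure rather than
#' its own arbitrary choices.
#'
#' @param m arcsinh-transformed expression matrix (genes x samples).
#' @param k number of clusters to request from every variation.
#' @param variations named list (one element per algorithm) of lists of
#'   parameter sets; `NULL` uses a default set (spectral: three kernel
#'   bandwidths; k-means: three single-start seeds; hierarchical: three
#'   linkages).
#' @param seed integer seed.
#' @return data.frame with columns `algorithm`, `n_variations`,
#'   `mean_ari`, `sd_ari`; attribute `winner`; attribute `partitions`.
#' @export
compare_algorithms <- function(m, k, variations = NULL, seed = 1L) {
  x <- t(m)  # samples x genes
  if (is.null(variations)) {
    auto <- attr(rbf_affinity(m), "sigma")
    variations <- list(
      spectral = lapply(c(0.5, 1, 2) * auto, function(s) list(sigma = s)),
      kmeans = lapply(1:3, function(i) list(seed = seed + i)),
      hierarchical = lapply(c("ward.D2", "complete", "average"),
                            function(l) list(linkage = l))
    )
  }
  if (any(lengths(variations) < 2L))
    stop("need at least two variations per algorithm")
  parts <- lapply(names(variations), function(alg) {
    lapply(variations[[alg]], function(v) {
      switch(alg,
        spectral = spectral_cluster(rbf_affinity(m, v$sigma %||% "auto"), k,
                                    seed = v$seed %||% seed),
        kmeans = partition(with_seed(v$seed %||% seed,
                                     kmeans(x, k, nstart = v$nstart %||% 1L,
                                            iter.max = 100L))$cluster,
                           rownames(x)),
        hierarchical = partition(cutree(hclust(dist(x),
                                               method = v$linkage %||% "ward.D2"),
                                        k),
                                 rownames(x)),
        stop("unknown algorithm: ", alg))
    })
  })
  names(parts) <- names(variations)
  rows <- lapply(names(parts), function(alg) {
    ps <- parts[[alg]]
    pairs <- combn(length(ps), 2)
    aris <- apply(pairs, 2, function(ij)
      adjusted_rand_index(ps[[ij[1]]], ps[[ij[2]]]))
    data.frame(algorithm = alg, n_variations = length(ps),
               mean_ari = mean(aris), sd_ari = sd(aris))
  })
  out <- do.call(rbind, rows)
  attr(out, "winner") <- out$algorithm[which.max(out$mean_ari)]
  attr(out, "partitions") <- parts
  out
}
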