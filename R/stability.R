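#' Bootstrap cluster stability over candidate gene-set sizes
#'
#' For each candidate size, the top-`size` most variable genes are used to
#' cluster the cohort; the cohort is then bootstrap-resampled (samples
#' with replacement), reclustered, and each original cluster is matched to
#' its best bootstrap cluster by maximum Jaccard overlap (computed on the
#' unique samples present in the bootstrap draw — the `fpc::clusterboot`
#' convention). The size with the highest overall mean Jaccard wins; ties
#' go to the smallest size.
#'
#' @param m arcsinh-transformed expression matrix (genes x samples).
#' @param sizes candidate gene-set sizes (drawn from the variance ranking).
#' @param k number of clusters.
#' @param n_boot bootstrap replicates (>= 2; 100 at full scale).
#' @param seed integer seed.
#' @return object of class `stability_result`: list with `table`
#'   (data.frame size / mean_jaccard), `per_cluster` (list of per-cluster
#'   mean Jaccards), `n_boot`, `chosen_size`, `partitions` (the original
#'   partition per size).
#' @export
select_stable_geneset <- function(m, sizes, k, n_boot = 100L, seed = 1L) {
  if (n_boot < 2L) stop("n_boot must be at least 2")
  sizes <- sort(unique(as.integer(sizes)))
  sets <- rank_genes_by_variability(m, sizes)
  n <- ncol(m)
  per_cluster <- vector("list", length(sizes))
  partitions <- vector("list", length(sizes))
  mean_jac <- numeric(length(sizes))
  for (si in seq_along(sizes)) {
    sub <- m[sets[[si]], , drop = FALSE]
    aff <- rbf_affinity(sub)
    orig <- spectral_cluster(aff, k, seed = seed)
    partitions[[si]] <- orig
    cl_jac <- matrix(NA_real_, n_boot, k)
    for (b in seq_len(n_boot)) {
      idx <- with_seed(seed + 1000L * si + b,
                       sample.int(n, n, replace = TRUE))
      bm <- sub[, idx, drop = FALSE]
      colnames(bm) <- paste0("b", seq_len(n))
      bp <- spectral_cluster(rbf_affinity(bm), k, seed = seed + b)
      uniq <- unique(idx)
      # bootstrap clusters as sets of original sample indices
      bsets <- lapply(seq_len(k), function(j) unique(idx[bp == j]))
      for (ci in seq_len(k)) {
        oset <- intersect(which(orig == ci), uniq)
        if (!length(oset)) next
        jac <- vapply(bsets, function(bs)
          length(intersect(oset, bs)) / length(union(oset, bs)), 0)
        cl_jac[b, ci] <- max(jac)
      }
    }
    per_cluster[[si]] <- colMeans(cl_jac, na.rm = TRUE)
    mean_jac[si] <- mean(cl_jac, na.rm = TRUE)
  }
  tab <- data.frame(size = sizes, mean_jaccard = mean_jac)
  chosen <- sizes[which.max(mean_jac)]  # which.max takes first (smallest) on ties
  structure(list(table = tab, per_cluster = per_cluster, n_boot = n_boot,
                 chosen_size = chosen, partitions = partitions),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Bootstrap cluster stability (", x$n_boot, " replicates)\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("chosen gene-set size:", x$chosen_size, "\n")
  invisible(x)
}
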