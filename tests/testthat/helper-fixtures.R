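# Shared fixtures, built in code at test time.

# brute-force ARI oracle: count agreeing/disagreeing pairs explicitly
ari_pair_oracle <- function(p, q) {
  n <- length(p)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    sp <- p[i] == p[j]; sq <- q[i] == q[j]
    if (sp && sq) n11 <- n11 + 1
    else if (!sp && !sq) n00 <- n00 + 1
    else if (sp) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  den <- (n00 + n01) * (n01 + n11) + (n00 + n10) * (n10 + n11)
  if (den == 0) return(1)
  2 * (n00 * n11 - n01 * n10) / den
}

# all set partitions of n items as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, m) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in seq_len(m + 1L)) rec(c(prefix, v), max(m, v))
  }
  rec(integer(), 0L)
  out
}

# two well-separated Gaussian blobs; returns genes x samples matrix + labels
blob_fixture <- function(n_per = 30, centers = c(-10, 10), sd = 0.1,
                         dims = 2, seed = 1) {
  set.seed(seed)
  pts <- rbind(
    matrix(rnorm(n_per * dims, centers[1], sd), n_per),
    matrix(rnorm(n_per * dims, centers[2], sd), n_per))
  m <- t(pts)
  rownames(m) <- paste0("f", seq_len(dims))
  colnames(m) <- paste0("S", seq_len(2 * n_per))
  list(m = m, labels = rep(1:2, each = n_per))
}

# two concentric rings (non-convex clusters)
ring_fixture <- function(n_per = 60, radii = c(1, 6), noise = 0.1, seed = 1) {
  set.seed(seed)
  th <- runif(2 * n_per, 0, 2 * pi)
  r <- rep(radii, each = n_per) + rnorm(2 * n_per, 0, noise)
  m <- rbind(x = r * cos(th), y = r * sin(th))
  colnames(m) <- paste0("S", seq_len(2 * n_per))
  list(m = m, labels = rep(1:2, each = n_per))
}

# memoised default synthetic cohort (the study conditions), reused by tests
.fixture_env <- new.env()
fixture_cohort <- function(seed = 42) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_cohort(cohort_spec(seed = seed))
  .fixture_env[[key]]
}

fixture_preprocessed <- function(seed = 42) {
  key <- paste0("prep_", seed)
  if (is.null(.fixture_env[[key]])) {
    co <- fixture_cohort(seed)
    .fixture_env[[key]] <- arcsinh_transform(
      remove_sex_genes(filter_low_expression(co$expression), co$annotation))
  }
  .fixture_env[[key]]
}

# small raw expression matrix with controllable values
toy_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  expression_matrix(m, "raw")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
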