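# Gene signatures: one-vs-rest L1-penalised logistic models per subgroup
# with cross-validated lambda, top-coefficient extraction, fold changes
# with Bonferroni-adjusted tests, and marker-block expression summaries.

#' LASSO gene signatures per subgroup
#'
#' Fits a one-vs-rest L1-penalised logistic regression per subgroup on
#' standardised predictors, chooses lambda by cross-validated deviance
#' with the 1-SE rule, and flags each subgroup's top fraction (default
#' 5%) of nonzero coefficients by absolute standardised magnitude.
#'
#' @param m arcsinh-transformed expression matrix (genes x samples).
#' @param p a [partition()] over the samples.
#' @param n_folds CV folds, stratified by subgroup membership (default 5).
#' @param top_fraction fraction of nonzero coefficients highlighted
#'   (default 0.05).
#' @param seed integer seed.
#' @param lambda `"lambda.1se"` (default) or `"lambda.min"`.
#' @return object of class `gene_signature`: per subgroup a data.frame of
#'   nonzero genes with `coefficient` (standardised scale) and
#'   `in_top` flag, plus `lambda_chosen`.
#' @export
lasso_signatures <- function(m, p, n_folds = 5L, top_fraction = 0.05,
                             seed = 1L, lambda = "lambda.1se") {
  x <- t(m)
  if (!all(rownames(x) %in% names(p)))
    stop("partition does not cover the expression samples")
  # canonical sample/gene order so folds and fits are order-invariant
  x <- x[order(rownames(x)), order(colnames(x)), drop = FALSE]
  labs <- p[rownames(x)]
  ks <- sort(unique(as.integer(labs)))
  if (length(ks) < 2L) stop("need at least two subgroups")
  sds <- apply(x, 2, sd)
  per_group <- lapply(ks, function(g) {
    y <- as.integer(labs == g)
    if (min(table(y)) < n_folds)
      stop("subgroup ", g, " has fewer members than folds")
    foldid <- make_folds(y, n_folds, seed + g)
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                            standardize = TRUE, foldid = foldid)
    lam <- cv[[lambda]]
    b <- as.numeric(coef(cv, s = lam))[-1]
    bstd <- b * sds  # coefficient per SD of predictor
    nz <- which(b != 0)
    if (!length(nz)) {
      return(list(table = data.frame(gene = character(),
                                     coefficient = numeric(),
                                     in_top = logical()),
                  lambda = lam))
    }
    tab <- data.frame(gene = colnames(x)[nz], coefficient = bstd[nz],
                      stringsAsFactors = FALSE)
    tab <- tab[order(-abs(tab$coefficient)), ]
    n_top <- max(1L, ceiling(top_fraction * nrow(tab)))
    tab$in_top <- seq_len(nrow(tab)) <= n_top
    rownames(tab) <- NULL
    list(table = tab, lambda = lam)
  })
  names(per_group) <- ks
  structure(list(subgroups = lapply(per_group, `[[`, "table"),
                 lambda_chosen = vapply(per_group, `[[`, 0, "lambda"),
                 top_fraction = top_fraction),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  for (g in names(x$subgroups)) {
    tab <- x$subgroups[[g]]
    cat("subgroup ", g, ": ", nrow(tab), " nonzero genes, top ",
        sum(tab$in_top), " highlighted (lambda = ",
        signif(x$lambda_chosen[[g]], 3), ")\n", sep = "")
  }
  invisible(x)
}

#' Signature genes across all subgroups
#'
#' @param sig a [lasso_signatures()] result.
#' @param top_only keep only the highlighted top fraction?
#' @return character vector of gene ids.
#' @export
signature_genes <- function(sig, top_only = FALSE) {
  unique(unlist(lapply(sig$subgroups, function(tab)
    tab$gene[if (top_only) tab$in_top else TRUE])))
}

#' Fold changes between two subgroups
#'
#' log2 ratio of raw-TPM group means per gene, with a Welch two-sample
#' test (run on arcsinh-transformed values, whose variance is stable
#' across the TPM range) and Bonferroni adjustment over the gene list.
#' When a group mean is zero the smallest nonzero TPM in the table is
#' added to both means (pseudocount), and the gene is flagged.
#'
#' @param m raw-scale expression matrix.
#' @param p a [partition()].
#' @param genes gene ids to test.
#' @param group_a,group_b subgroup labels (numerator / denominator).
#' @return data.frame `gene`, `log2_fc`, `p`, `p_adj`, `pseudocount_used`.
#' @export
fold_changes <- function(m, p, genes, group_a, group_b) {
  if (transform_state(m) != "raw")
    stop("fold changes use the raw TPM scale")
  genes <- intersect(genes, rownames(m))
  labs <- p[colnames(m)]
  ia <- which(labs == group_a); ib <- which(labs == group_b)
  if (!length(ia) || !length(ib)) stop("empty group")
  sub <- m[genes, , drop = FALSE]
  mean_a <- rowMeans(sub[, ia, drop = FALSE])
  mean_b <- rowMeans(sub[, ib, drop = FALSE])
  pseudo <- min(sub[sub > 0])
  needs <- mean_a == 0 | mean_b == 0
  l2 <- log2((mean_a + ifelse(needs, pseudo, 0)) /
             (mean_b + ifelse(needs, pseudo, 0)))
  tsub <- asinh(sub)
  pv <- vapply(seq_along(genes), function(i) {
    tryCatch(t.test(tsub[i, ia], tsub[i, ib])$p.value,
             error = function(e) 1)
  }, 0)
  data.frame(gene = genes, log2_fc = as.numeric(l2), p = pv,
             p_adj = pmin(1, pv * length(genes)),
             pseudocount_used = needs, row.names = NULL)
}

#' Per-subgroup expression summary of a gene block
#'
#' Averages each sample over the block, summarises per subgroup
#' (median/quartiles) and tests the subgroup ordering with a Kruskal-
#' Wallis rank test.
#'
#' @param m expression matrix (any transform).
#' @param p a [partition()].
#' @param gene_block character vector of gene ids (non-empty).
#' @return list with `summary` (data.frame subgroup / q1 / median / q3 /
#'   mean), `sample_scores`, `rank_test_p`.
#' @export
signature_expression_summary <- function(m, p, gene_block) {
  gene_block <- intersect(gene_block, rownames(m))
  if (!length(gene_block)) stop("empty gene block")
  score <- colMeans(m[gene_block, , drop = FALSE])
  labs <- p[colnames(m)]
  sm <- do.call(rbind, lapply(sort(unique(labs)), function(g) {
    v <- score[labs == g]
    data.frame(subgroup = g, q1 = quantile(v, 0.25), median = median(v),
               q3 = quantile(v, 0.75), mean = mean(v), row.names = NULL)
  }))
  p_rank <- if (length(unique(labs)) > 1L)
    kruskal.test(score, factor(labs))$p.value else NA_real_
  list(summary = sm, sample_scores = score, rank_test_p = p_rank)
}
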