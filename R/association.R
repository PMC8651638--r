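# Association layer: bipartite Spearman correlation network between
# signature genes and clinical features, cross-cohort concordance, and
# delta-delta-Ct qPCR quantification.

spearman_pair <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || var(x) == 0 || var(y) == 0)
    return(c(rho = NA_real_, p = NA_real_, n = n))
  # exact null (AS89) for small n, t-approximation otherwise
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = n < 12L))
  c(rho = as.numeric(ct$estimate), p = ct$p.value, n = n)
}

#' Gene-clinical Spearman correlation network
#'
#' Computes Spearman's rho (average ranks on ties) with two-tailed
#' p-values for every gene x clinical-feature pair over their shared
#' samples, and keeps the edges with `|rho| >= rho_min` and `p < p_max`.
#' Constant variables yield undefined rho; those pairs are skipped with a
#' warning.
#'
#' @param m expression matrix (genes x samples; any transform — Spearman
#'   is invariant to monotone transforms).
#' @param t a [clinical_table()] with numeric(-encoded) features.
#' @param genes gene ids to consider.
#' @param features clinical feature names to consider.
#' @param rho_min minimum |rho| (default 0.25).
#' @param p_max p-value cutoff (default 1.11e-5).
#' @return object of class `correlation_network`: list with `edges`
#'   (data.frame gene / feature / rho / p / n), `all_pairs` (unfiltered),
#'   `rho_min`, `p_max`.
#' @export
build_network <- function(m, t, genes = rownames(m),
                          features = clin_features(t),
                          rho_min = 0.25, p_max = 1.11e-5) {
  shared <- intersect(colnames(m), t$data$sample_id)
  if (length(shared) < 10L) stop("need at least 10 overlapping samples")
  genes <- intersect(genes, rownames(m))
  x <- m[genes, shared, drop = FALSE]
  cd <- t$data[match(shared, t$data$sample_id), , drop = FALSE]
  rows <- list()
  skipped <- character()
  for (g in genes) {
    for (f in features) {
      v <- cd[[f]]
      if (is.ordered(v)) v <- as.integer(v)
      if (!is.numeric(v)) {
        skipped <- c(skipped, paste0(g, "~", f))
        next
      }
      sp <- spearman_pair(as.numeric(x[g, ]), v)
      if (is.na(sp["rho"])) {
        skipped <- c(skipped, paste0(g, "~", f))
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, feature = f, rho = sp[["rho"]],
                   p = sp[["p"]], n = sp[["n"]], stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    warning("skipped constant/degenerate pairs: ",
            paste(skipped, collapse = ", "))
  all_pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), feature = character(), rho = numeric(),
               p = numeric(), n = integer())
  edges <- all_pairs[abs(all_pairs$rho) >= rho_min & all_pairs$p < p_max, ,
                     drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, all_pairs = all_pairs,
                 rho_min = rho_min, p_max = p_max),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("Correlation network:", nrow(x$edges), "edges of",
      nrow(x$all_pairs), "pairs (|rho| >=", x$rho_min, ", p <",
      format(x$p_max), ")\n")
  invisible(x)
}

#' Sign concordance of correlations between two networks
#'
#' Fraction of shared gene-feature pairs whose rho has the same sign in
#' both networks. In strict mode only pairs passing both networks'
#' thresholds count as shared.
#'
#' @param net_a,net_b [build_network()] results.
#' @param strict compare threshold-passing edges only?
#' @return list with `concordance`, `n_shared`, `n_consistent`.
#' @export
correlation_concordance <- function(net_a, net_b, strict = FALSE) {
  ta <- if (strict) net_a$edges else net_a$all_pairs
  tb <- if (strict) net_b$edges else net_b$all_pairs
  key_a <- paste(ta$gene, ta$feature, sep = "~")
  key_b <- paste(tb$gene, tb$feature, sep = "~")
  shared <- intersect(key_a, key_b)
  if (!length(shared)) stop("no overlapping pairs")
  sa <- sign(ta$rho[match(shared, key_a)])
  sb <- sign(tb$rho[match(shared, key_b)])
  list(concordance = mean(sa == sb), n_shared = length(shared),
       n_consistent = sum(sa == sb))
}

#' qPCR table constructor
#'
#' Long-format Ct measurements. Duplicate (sample, assay) wells are
#' averaged on the Ct scale, the usual handling of technical duplicates.
#'
#' @param df data.frame with columns `sample_id`, `assay`, `ct` and
#'   optionally `group`.
#' @param reference_assay the endogenous control assay (GAPDH analogue).
#' @return object of class `qpcr_table`.
#' @export
qpcr_table <- function(df, reference_assay = "GAPDH") {
  stopifnot(all(c("sample_id", "assay", "ct") %in% names(df)))
  if (any(df$ct <= 0)) stop("Ct values must be positive")
  agg <- aggregate(df$ct,
                   by = df[intersect(c("sample_id", "assay", "group"),
                                     names(df))],
                   FUN = mean)
  names(agg)[names(agg) == "x"] <- "ct"
  have_ref <- unique(agg$sample_id[agg$assay == reference_assay])
  missing_ref <- setdiff(unique(agg$sample_id), have_ref)
  if (length(missing_ref))
    stop("samples without reference assay Ct: ",
         paste(missing_ref, collapse = ", "))
  structure(list(data = agg, reference_assay = reference_assay),
            class = "qpcr_table")
}

#' Relative quantities by the delta-delta-Ct method
#'
#' `dCt = Ct_target - Ct_reference` per sample;
#' `ddCt = dCt - mean(dCt of the calibrator group)` per assay;
#' `RQ = 2^(-ddCt)`. The calibrator group's RQ has geometric mean 1 by
#' construction.
#'
#' @param q a [qpcr_table()] with a `group` column.
#' @param calibrator_group the group used as calibrator.
#' @return data.frame `sample_id`, `assay`, `group`, `dct`, `ddct`, `rq`.
#' @export
delta_delta_ct <- function(q, calibrator_group) {
  d <- q$data
  ref <- d[d$assay == q$reference_assay, c("sample_id", "ct")]
  tgt <- d[d$assay != q$reference_assay, , drop = FALSE]
  tgt$dct <- tgt$ct - ref$ct[match(tgt$sample_id, ref$sample_id)]
  if (!calibrator_group %in% tgt$group) stop("calibrator group absent")
  out <- do.call(rbind, lapply(split(tgt, tgt$assay), function(a) {
    cal_mean <- mean(a$dct[a$group == calibrator_group])
    a$ddct <- a$dct - cal_mean
    a$rq <- 2^(-a$ddct)
    a
  }))
  rownames(out) <- NULL
  out[c("sample_id", "assay", "group", "dct", "ddct", "rq")]
}

#' Per-assay group comparison of qPCR expression
#'
#' log2 fold ratio between two groups computed from mean negative dCt
#' (equivalently the log2 ratio of RQ geometric means), with a two-sided
#' Welch t-test on -dCt.
#'
#' @param rq output of [delta_delta_ct()].
#' @param group_a,group_b groups to compare (a vs b).
#' @return data.frame `assay`, `log2_fold_ratio`, `p`.
#' @export
qpcr_group_comparison <- function(rq, group_a, group_b) {
  out <- do.call(rbind, lapply(split(rq, rq$assay), function(a) {
    na <- a$group == group_a; nb <- a$group == group_b
    if (sum(na) < 2L || sum(nb) < 2L) stop("singleton group for assay ", a$assay[1])
    # -dCt is log2 expression relative to the reference gene
    lfr <- mean(-a$dct[na]) - mean(-a$dct[nb])
    pv <- t.test(-a$dct[na], -a$dct[nb])$p.value
    data.frame(assay = a$assay[1], log2_fold_ratio = lfr, p = pv,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
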