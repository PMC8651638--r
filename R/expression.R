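#' Construct an expression matrix
#'
#' Light container for a genes x samples abundance matrix (TPM scale by
#' convention). The object is a plain numeric matrix carrying a
#' `transform` attribute (`"raw"` or `"arcsinh"`) so downstream stages can
#' refuse to operate on the wrong scale.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must
#'   have unique, non-empty rownames (gene ids) and colnames (sample ids).
#' @param transform `"raw"` or `"arcsinh"`.
#' @return numeric matrix with a `transform` attribute.
#' @export
expression_matrix <- function(values, transform = c("raw", "arcsinh")) {
  transform <- match.arg(transform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite values")
  if (transform == "raw" && any(values < 0))
    stop("raw TPM values must be non-negative")
  attr(values, "transform") <- transform
  values
}

#' @rdname expression_matrix
#' @param m an expression matrix.
#' @export
transform_state <- function(m) {
  ts <- attr(m, "transform")
  if (is.null(ts)) "raw" else ts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate transcript-level abundances to gene level
#'
#' Gene TPM is the sum of its member transcripts' TPM, so per-sample column
#' sums are preserved. Every transcript in the matrix must be present in
#' the map; unmapped transcripts are an error that names the offenders.
#'
#' @param tx_matrix transcripts x samples matrix (raw scale).
#' @param tx2gene data.frame with columns `transcript_id`, `gene_id`.
#' @return genes x samples [expression_matrix()].
#' @export
aggregate_transcripts <- function(tx_matrix, tx2gene) {
  stopifnot(is.data.frame(tx2gene),
            all(c("transcript_id", "gene_id") %in% names(tx2gene)))
  if (nrow(tx2gene) == 0L) stop("empty transcript-to-gene map")
  if (anyDuplicated(tx2gene$transcript_id))
    stop("duplicate transcript ids in map")
  if (transform_state(tx_matrix) != "raw")
    stop("aggregate on the raw scale, before any transform")
  tx <- rownames(tx_matrix)
  unmapped <- setdiff(tx, tx2gene$transcript_id)
  if (length(unmapped))
    stop("unmapped transcripts: ", paste(unmapped, collapse = ", "))
  gene <- tx2gene$gene_id[match(tx, tx2gene$transcript_id)]
  agg <- rowsum(tx_matrix, group = gene, reorder = FALSE)
  expression_matrix(as.matrix(agg), "raw")
}

#' Filter genes by minimum expression across samples
#'
#' Keeps genes whose abundance exceeds `min_reads` in at least
#' `ceiling(min_fraction * n_samples)` samples; gene order is preserved.
#' The threshold is applied to the matrix as given (TPM or counts) — which
#' scale the filter should see is a cohort-level decision the caller makes.
#'
#' @param m raw-scale expression matrix.
#' @param min_reads abundance a gene must exceed (default 2).
#' @param min_fraction minimum fraction of samples above `min_reads`
#'   (default 0.95).
#' @return filtered expression matrix; errors if nothing survives.
#' @export
filter_low_expression <- function(m, min_reads = 2, min_fraction = 0.95) {
  if (transform_state(m) != "raw")
    stop("expression filter operates on the raw scale")
  need <- ceiling(min_fraction * ncol(m))
  keep <- rowSums(m > min_reads) >= need
  if (!any(keep)) stop("no genes pass the expression filter")
  expression_matrix(m[keep, , drop = FALSE], "raw")
}

#' Remove sex-chromosome genes (and listed extras)
#'
#' Sex chromosomes dominate between-sample variance in mixed-sex whole
#' blood and would drive clustering toward sex rather than disease
#' biology; all chrX/chrY-annotated genes plus an optional user-supplied
#' exclusion list are dropped.
#'
#' @param m expression matrix.
#' @param annotation data.frame with columns `gene_id`, `chromosome`.
#' @param extra_exclusions character vector of additional gene ids.
#' @param sex_chromosomes chromosome labels treated as sex chromosomes.
#' @return expression matrix without the excluded genes.
#' @export
remove_sex_genes <- function(m, annotation,
                             extra_exclusions = character(),
                             sex_chromosomes = c("chrX", "chrY", "X", "Y")) {
  stopifnot(is.data.frame(annotation),
            all(c("gene_id", "chromosome") %in% names(annotation)))
  chrom <- annotation$chromosome[match(rownames(m), annotation$gene_id)]
  drop <- (!is.na(chrom) & chrom %in% sex_chromosomes) |
    rownames(m) %in% extra_exclusions
  expression_matrix(m[!drop, , drop = FALSE], transform_state(m))
}

#' Hyperbolic arcsine transform
#'
#' Elementwise `asinh(x) = log(x + sqrt(x^2 + 1))`: log-like compression of
#' heavy-tailed TPM values that is exact at 0 and defined without a
#' pseudocount. Applying it twice is an error.
#'
#' @param m raw-scale expression matrix.
#' @return transformed expression matrix (`transform == "arcsinh"`).
#' @export
arcsinh_transform <- function(m) {
  if (transform_state(m) != "raw")
    stop("matrix is already transformed")
  out <- asinh(m)
  attr(out, "transform") <- "arcsinh"
  out
}

#' Rank genes by expression variability and cut nested candidate sets
#'
#' Genes are sorted by decreasing sample variance (unbiased, n-1
#' denominator) on the transformed scale — the scale clustering sees —
#' and one nested gene set is returned per requested size.
#'
#' @param m arcsinh-transformed expression matrix.
#' @param sizes integer vector of candidate set sizes.
#' @return named list of character vectors (`size_<n>`), plus the full
#'   ranking as attribute `ranking`.
#' @export
rank_genes_by_variability <- function(m, sizes) {
  if (transform_state(m) != "arcsinh")
    stop("rank genes on the arcsinh scale")
  sizes <- as.integer(sizes)
  if (any(sizes < 1L) || any(sizes > nrow(m)))
    stop("sizes must be between 1 and the number of genes")
  v <- apply(m, 1L, var)
  ranking <- rownames(m)[order(v, decreasing = TRUE)]
  sets <- lapply(sizes, function(s) ranking[seq_len(s)])
  names(sets) <- paste0("size_", sizes)
  attr(sets, "ranking") <- ranking
  sets
}
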