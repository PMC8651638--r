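# Plain-text readers/writers binding the pipeline stages. Dialect:
# tab-separated matrices, UTF-8, "." decimal, NA token "NA".

#' Read / write an expression matrix (genes x samples TSV)
#'
#' Header row holds sample ids; first column gene ids.
#'
#' @param path file path.
#' @param transform scale recorded on the object on read.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, transform = "raw") {
  df <- read.delim(path, check.names = FALSE, row.names = 1L)
  if (anyDuplicated(rownames(df))) stop("duplicate gene ids in ", path)
  expression_matrix(as.matrix(df), transform)
}

#' @rdname read_expression_tsv
#' @param m expression matrix to write.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clinical table (data CSV + dictionary CSV)
#'
#' @param data_path CSV with `sample_id` plus feature columns.
#' @param dict_path CSV with `feature`, `type`, `levels` columns.
#' @return a [clinical_table()].
#' @export
read_clinical_csv <- function(data_path, dict_path) {
  data <- read.csv(data_path, check.names = FALSE)
  dict <- read.csv(dict_path, check.names = FALSE)
  for (i in seq_len(nrow(dict))) {
    f <- dict$feature[i]
    if (!f %in% names(data)) next
    if (dict$type[i] == "ordered" && !is.na(dict$levels[i])) {
      lv <- strsplit(dict$levels[i], "|", fixed = TRUE)[[1]]
      data[[f]] <- factor(data[[f]], levels = lv, ordered = TRUE)
    }
  }
  clinical_table(data, dict)
}

#' @rdname read_clinical_csv
#' @param t clinical table to write.
#' @export
write_clinical_csv <- function(t, data_path, dict_path) {
  write.csv(t$data, data_path, row.names = FALSE, quote = FALSE, na = "NA")
  write.csv(t$dictionary, dict_path, row.names = FALSE, quote = FALSE,
            na = "NA")
  invisible(data_path)
}

#' Read / write survival records (CSV: sample_id, time_days, event)
#' @param path file path.
#' @export
read_survival_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("sample_id", "time_days", "event") %in% names(df)))
  df
}

#' @rdname read_survival_csv
#' @param d survival data.frame.
#' @export
write_survival_csv <- function(d, path) {
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a partition (TSV: sample_id, subgroup)
#'
#' Non-contiguous labels on read are canonicalised with a warning.
#' @param path file path.
#' @export
read_partition_tsv <- function(path) {
  df <- read.delim(path)
  stopifnot(all(c("sample_id", "subgroup") %in% names(df)))
  labs <- df$subgroup
  if (is.numeric(labs) &&
      !identical(sort(unique(as.integer(labs))),
                 seq_len(length(unique(labs))))) {
    warning("non-contiguous subgroup labels; canonicalising")
  }
  partition(labs, df$sample_id, by_size = FALSE)
}

#' @rdname read_partition_tsv
#' @param p partition to write.
#' @export
write_partition_tsv <- function(p, path) {
  write.table(data.frame(sample_id = names(p), subgroup = as.integer(p)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a correlation network as edge-list TSV and GraphML
#' @param net a [build_network()] result.
#' @param tsv_path,graphml_path output paths (either may be `NULL`).
#' @export
write_network <- function(net, tsv_path = NULL, graphml_path = NULL) {
  if (!is.null(tsv_path))
    write.table(net$edges, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(graphml_path)) {
    if (nrow(net$edges)) {
      g <- igraph::graph_from_data_frame(
        net$edges[c("gene", "feature", "rho", "p")], directed = FALSE)
      igraph::V(g)$kind <- ifelse(igraph::V(g)$name %in% net$edges$gene,
                                  "gene", "clinical")
    } else {
      g <- igraph::make_empty_graph(directed = FALSE)
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(net)
}

#' Pipeline configuration
#'
#' All tunables of the end-to-end pipeline with their defaults:
#' expression filter (`min_reads = 2`, `min_fraction = 0.95`), candidate
#' gene-set sizes (including 300), candidate ks, bootstrap replicates,
#' signature sizes up to `s_max = 20`, network thresholds
#' (`rho_min = 0.25`, `p_max = 1.11e-5`), imputation (`m = 10`,
#' `iterations = 10`; `full_scale = TRUE` switches to m = 50, 20
#' iterations and 100 bootstrap replicates), and a single global seed
#' expanded into independent per-stage streams.
#'
#' @param ... overrides of the defaults.
#' @param full_scale use full-scale imputation/bootstrap settings?
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., full_scale = FALSE) {
  cfg <- list(
    min_reads = 2, min_fraction = 0.95,
    extra_sex_exclusions = character(),
    candidate_sizes = c(50, 300, 1000),
    candidate_ks = 2:8,
    stability_k = 3L,
    n_boot = if (full_scale) 100L else 20L,
    top_fraction = 0.05,
    s_max = 20L,
    families = c("svm", "rf", "lr", "knn"),
    n_folds = 5L,
    impute_m = if (full_scale) 50L else 10L,
    impute_iterations = if (full_scale) 20L else 10L,
    max_missing = 0.05,
    rho_min = 0.25, p_max = 1.11e-5,
    seed = 1L,
    full_scale = full_scale)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  structure(modifyList(cfg, ov), class = "pipeline_config")
}

stage_seed <- function(cfg, stage) {
  offs <- c(simulate = 1L, preprocess = 2L, discover = 3L, gene_sig = 4L,
            clin_sig = 5L, survive = 6L, network = 7L, qpcr = 8L)
  (cfg$seed * 1009L + offs[[stage]] * 9973L) %% 2147483647L
}

#' Run the full discovery-to-validation pipeline
#'
#' Executes, in order: preprocessing (filter, sex-gene removal, arcsinh),
#' subgroup discovery (stability gene-set sizing, spectral clustering,
#' index vote for k), gene signatures + fold changes, clinical cleaning /
#' imputation / signature search / composite classifier, transfer
#' classification of the validation cohort, survival validation
#' (KM, log-rank, Cox with age/sex covariates) and the gene-clinical
#' correlation network. Writes versioned outputs plus a manifest of input
#' hashes, parameters and seeds to `out_dir`; the manifest carries no
#' timestamps, so reruns under the same config are byte-identical.
#'
#' @param cohort discovery cohort as returned by [generate_cohort()] (or
#'   an equivalent list built from files).
#' @param validation validation cohort as from
#'   [generate_validation_cohort()] (optional).
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; `NULL` = no files written).
#' @return list of stage results (`preprocessed`, `stability`, `vote`,
#'   `partition`, `gene_signature`, `fold_changes`, `clinical_signatures`,
#'   `composite`, `validation_partition`, `survival`, `network`,
#'   `manifest`).
#' @export
run_pipeline <- function(cohort, validation = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list()

  # --- preprocess ------------------------------------------------------
  expr <- filter_low_expression(cohort$expression, config$min_reads,
                                config$min_fraction)
  expr <- remove_sex_genes(expr, cohort$annotation,
                           config$extra_sex_exclusions)
  texpr <- arcsinh_transform(expr)
  res$preprocessed <- texpr

  # --- discover --------------------------------------------------------
  sizes <- config$candidate_sizes[config$candidate_sizes <= nrow(texpr)]
  stab <- select_stable_geneset(texpr, sizes, k = config$stability_k,
                                n_boot = config$n_boot,
                                seed = stage_seed(config, "discover"))
  chosen <- rank_genes_by_variability(texpr, stab$chosen_size)[[1L]]
  sub <- texpr[chosen, , drop = FALSE]
  vote <- vote_k(sub, config$candidate_ks,
                 seed = stage_seed(config, "discover"))
  part <- vote$partitions[[as.character(vote$majority_k)]]
  res$stability <- stab
  res$vote <- vote
  res$partition <- part

  # --- gene signatures -------------------------------------------------
  gsig <- lasso_signatures(sub, part, n_folds = config$n_folds,
                           top_fraction = config$top_fraction,
                           seed = stage_seed(config, "gene_sig"))
  res$gene_signature <- gsig
  sg <- signature_genes(gsig)
  if (length(sg) >= 1L && vote$majority_k >= 2L) {
    res$fold_changes <- fold_changes(expr, part, sg, 1L, 2L)
  }

  # --- clinical signatures + transfer ---------------------------------
  cseed <- stage_seed(config, "clin_sig")
  clin <- clean_clinical(cohort$clinical, config$max_missing)
  imp <- impute_chained(clin, m = config$impute_m,
                        n_iterations = config$impute_iterations,
                        seed = cseed)
  train <- imp[[1L]]
  subgroups <- sort(unique(as.integer(part)))
  sigs <- lapply(subgroups, function(g)
    signature_search(train, part, g, sizes = seq_len(config$s_max),
                     families = config$families,
                     n_folds = config$n_folds, seed = cseed))
  comp <- fit_composite(train, part, sigs, n_folds = config$n_folds,
                        seed = cseed)
  res$clinical_signatures <- sigs
  res$composite <- comp

  if (!is.null(validation)) {
    # validation gets the SAME encoding but no fresh feature dropping:
    # which features exist was decided on the discovery cohort; the
    # composite is refit on every imputed training table and the
    # per-sample majority vote across refits is the final prediction
    vclin <- clean_clinical(validation$clinical, max_missing = 1)
    vimp <- impute_chained(vclin, m = 1L,
                           n_iterations = config$impute_iterations,
                           seed = cseed + 1L)
    res$validation_partition <- classify_pooled(imp, part, sigs, vimp,
                                                n_folds = config$n_folds,
                                                seed = cseed)
  }

  # --- survival --------------------------------------------------------
  surv <- cohort$survival
  ids <- names(part)
  idx <- match(ids, surv$sample_id)
  age <- cohort$clinical$data$age_diagnosis[
    match(ids, cohort$clinical$data$sample_id)]
  sexf <- cohort$clinical$data$sex_female[
    match(ids, cohort$clinical$data$sample_id)]
  sd_disc <- survival_data(surv$time_days[idx], surv$event[idx],
                           group = as.integer(part), sample_id = ids,
                           covariates = data.frame(
                             age_high = as.integer(age > median(age,
                                                                na.rm = TRUE)),
                             sex_female = sexf,
                             subgroup1 = as.integer(part == 1L)))
  res$survival <- list(
    km = km_estimate(sd_disc),
    logrank = logrank_test(sd_disc),
    cox = cox_fit(sd_disc, c("age_high", "sex_female", "subgroup1")))
  if (!is.null(validation) && !is.null(res$validation_partition)) {
    vp <- res$validation_partition
    vs <- validation$survival
    vidx <- match(names(vp), vs$sample_id)
    sd_val <- survival_data(vs$time_days[vidx], vs$event[vidx],
                            group = as.integer(vp), sample_id = names(vp))
    res$survival$validation_km <- km_estimate(sd_val)
    res$survival$validation_logrank <- logrank_test(sd_val)
  }

  # --- network ---------------------------------------------------------
  num_feats <- clin$dictionary$feature[clin$dictionary$type %in%
                                         c("numeric", "ordered")]
  res$network <- build_network(texpr, train,
                               genes = signature_genes(gsig),
                               features = num_feats,
                               rho_min = config$rho_min,
                               p_max = config$p_max)

  # --- manifest / outputs ----------------------------------------------
  manifest <- list(
    config = unclass(config),
    stage_seeds = lapply(setNames(nm = c("discover", "gene_sig",
                                         "clin_sig")),
                         function(s) stage_seed(config, s)),
    n_samples = ncol(cohort$expression),
    n_genes_input = nrow(cohort$expression),
    n_genes_after_preprocess = nrow(texpr),
    chosen_geneset_size = stab$chosen_size,
    majority_k = vote$majority_k,
    subgroup_sizes = as.vector(table(as.integer(part))),
    composite_features = comp$features,
    composite_cv_balanced_accuracy = round(comp$cv_balanced_accuracy, 6),
    n_network_edges = nrow(res$network$edges))
  res$manifest <- manifest

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_partition_tsv(part, file.path(out_dir, "partition.tsv"))
    jsonlite::write_json(stab$table, file.path(out_dir, "stability.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(votes = as.list(vote$votes),
                              majority_k = vote$majority_k),
                         file.path(out_dir, "vote.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(res$validation_partition))
      write_partition_tsv(res$validation_partition,
                          file.path(out_dir, "validation_partition.tsv"))
    write_network(res$network, file.path(out_dir, "network_edges.tsv"),
                  file.path(out_dir, "network.graphml"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
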