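# Clinical-feature pipeline: cleaning/encoding, chained-equation
# imputation with predictive mean matching, ensemble feature selection,
# per-subgroup signature search (s = 1..20 over SVM/RF/LR/kNN), composite
# multi-class classification and transfer prediction of new cohorts.

#' Construct a clinical table
#'
#' A clinical table couples a samples x features data.frame (first column
#' `sample_id`) with a feature dictionary declaring each feature's type:
#' `numeric`, `binary`, `categorical` or `ordered` (with enumerated
#' levels, `|`-separated). Missing values are `NA`.
#'
#' @param data data.frame with a `sample_id` column.
#' @param dictionary data.frame with columns `feature`, `type`, `levels`.
#' @return object of class `clinical_table` (list with `data`,
#'   `dictionary`).
#' @export
clinical_table <- function(data, dictionary) {
  stopifnot(is.data.frame(data), "sample_id" %in% names(data),
            is.data.frame(dictionary),
            all(c("feature", "type") %in% names(dictionary)))
  if (!"levels" %in% names(dictionary)) dictionary$levels <- NA_character_
  feats <- setdiff(names(data), "sample_id")
  undeclared <- setdiff(feats, dictionary$feature)
  if (length(undeclared))
    stop("features missing from dictionary: ",
         paste(undeclared, collapse = ", "))
  bad <- setdiff(dictionary$type,
                 c("numeric", "binary", "categorical", "ordered"))
  if (length(bad)) stop("unknown feature types: ", paste(bad, collapse = ", "))
  rownames(dictionary) <- NULL
  structure(list(data = data,
                 dictionary = dictionary[dictionary$feature %in% feats, ,
                                         drop = FALSE]),
            class = "clinical_table")
}

clin_features <- function(t) setdiff(names(t$data), "sample_id")

feature_type <- function(t, f) {
  t$dictionary$type[match(f, t$dictionary$feature)]
}

#' Drop high-missingness features and numerically encode the rest
#'
#' Features missing in more than `max_missing` of samples are dropped.
#' Remaining features are numerically encoded: binary to 0/1, ordered
#' factors to integer ranks, unordered categoricals to one-hot 0/1
#' indicator columns (`feature.level`, declared `binary` in the output
#' dictionary); numerics pass through. The drop report is attached as
#' attribute `drop_report`.
#'
#' @param t a [clinical_table()].
#' @param max_missing maximum tolerated missing fraction (default 0.05).
#' @param encode encode to numeric columns (default TRUE)?
#' @return encoded [clinical_table()].
#' @export
clean_clinical <- function(t, max_missing = 0.05, encode = TRUE) {
  stopifnot(inherits(t, "clinical_table"))
  feats <- clin_features(t)
  miss <- vapply(feats, function(f) mean(is.na(t$data[[f]])), 0)
  drop <- feats[miss > max_missing]
  keep <- setdiff(feats, drop)
  if (!length(keep)) stop("all features exceed the missingness threshold")
  report <- data.frame(feature = feats, missing_fraction = miss,
                       dropped = feats %in% drop, row.names = NULL)
  data <- t$data[c("sample_id", keep)]
  dict <- t$dictionary[t$dictionary$feature %in% keep, , drop = FALSE]
  if (encode) {
    newcols <- list(sample_id = data$sample_id)
    newdict <- list()
    for (f in keep) {
      ty <- feature_type(t, f)
      v <- data[[f]]
      if (ty == "numeric") {
        newcols[[f]] <- as.numeric(v)
        newdict[[f]] <- data.frame(feature = f, type = "numeric",
                                   levels = NA_character_)
      } else if (ty == "binary") {
        if (is.factor(v) || is.character(v)) {
          lv <- sort(unique(as.character(v[!is.na(v)])))
          v <- as.integer(as.character(v) == lv[length(lv)])
        }
        newcols[[f]] <- as.integer(v)
        newdict[[f]] <- data.frame(feature = f, type = "binary",
                                   levels = NA_character_)
      } else if (ty == "ordered") {
        lv <- strsplit(dict$levels[match(f, dict$feature)], "|",
                       fixed = TRUE)[[1]]
        newcols[[f]] <- as.integer(factor(as.character(v), levels = lv))
        newdict[[f]] <- data.frame(feature = f, type = "ordered",
                                   levels = paste(lv, collapse = "|"))
      } else {  # categorical -> one-hot
        lv <- sort(unique(as.character(v[!is.na(v)])))
        for (l in lv) {
          cn <- paste0(f, ".", l)
          newcols[[cn]] <- as.integer(as.character(v) == l)
          newdict[[cn]] <- data.frame(feature = cn, type = "binary",
                                      levels = NA_character_)
        }
      }
    }
    data <- as.data.frame(newcols, stringsAsFactors = FALSE)
    dict <- do.call(rbind, newdict)
  }
  out <- clinical_table(data, dict)
  attr(out, "drop_report") <- report
  out
}

# numeric predictor matrix for the imputation models (crude but stable:
# ordered -> rank, categorical -> integer code)
predictor_frame <- function(t) {
  feats <- clin_features(t)
  out <- lapply(feats, function(f) {
    v <- t$data[[f]]
    if (is.numeric(v)) v
    else if (is.ordered(v)) as.integer(v)
    else as.integer(factor(v))
  })
  names(out) <- feats
  as.data.frame(out)
}

impute_one <- function(t, order_vars, n_iterations, donors = 5L) {
  data <- t$data
  miss_idx <- lapply(order_vars, function(f) which(is.na(data[[f]])))
  names(miss_idx) <- order_vars
  # initialise by sampling observed values
  for (f in order_vars) {
    obs <- data[[f]][!is.na(data[[f]])]
    if (!length(obs)) stop("feature with zero observed values: ", f)
    data[[f]][miss_idx[[f]]] <- sample(obs, length(miss_idx[[f]]),
                                       replace = TRUE)
  }
  trace <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    for (f in order_vars) {
      mi <- miss_idx[[f]]
      if (!length(mi)) next
      tt <- t; tt$data <- data
      x <- predictor_frame(tt)
      x[[f]] <- NULL
      y <- data[[f]]
      ty <- feature_type(t, f)
      obs <- setdiff(seq_len(nrow(data)), mi)
      fitfr <- cbind(.y = y[obs], x[obs, , drop = FALSE])
      imp <- tryCatch({
        if (ty == "numeric") {
          fit <- lm(.y ~ ., data = fitfr)
          pred_obs <- predict(fit, x[obs, , drop = FALSE])
          pred_mis <- predict(fit, x[mi, , drop = FALSE])
          vapply(pred_mis, function(pm) {
            d <- abs(pred_obs - pm)
            pool <- obs[order(d)[seq_len(min(donors, length(obs)))]]
            y[sample(pool, 1L)]
          }, numeric(1))
        } else if (ty == "binary") {
          fit <- suppressWarnings(glm(.y ~ ., data = fitfr,
                                      family = binomial()))
          p <- predict(fit, x[mi, , drop = FALSE], type = "response")
          as.integer(runif(length(mi)) < p)
        } else if (ty == "ordered") {
          fy <- factor(y[obs])
          if (nlevels(fy) < 2L) stop("degenerate")
          fit <- suppressWarnings(
            MASS::polr(.y ~ ., data = cbind(.y = ordered(fy),
                                            x[obs, , drop = FALSE])))
          pr <- predict(fit, x[mi, , drop = FALSE], type = "probs")
          pr <- matrix(pr, nrow = length(mi))
          lv <- levels(fy)
          drawn <- apply(pr, 1L, function(p) sample(lv, 1L, prob = p))
          if (is.ordered(y)) ordered(drawn, levels = levels(y))
          else if (is.numeric(y)) as.numeric(drawn)
          else drawn
        } else {  # categorical
          fy <- factor(y[obs])
          fit <- nnet::multinom(.y ~ ., data = cbind(.y = fy,
                                                     x[obs, , drop = FALSE]),
                                trace = FALSE)
          pr <- predict(fit, x[mi, , drop = FALSE], type = "probs")
          pr <- matrix(pr, nrow = length(mi), ncol = nlevels(fy))
          lv <- levels(fy)
          apply(pr, 1L, function(p) sample(lv, 1L, prob = p))
        }
      }, error = function(e) sample(y[obs], length(mi), replace = TRUE))
      data[[f]][mi] <- imp
    }
    num <- order_vars[vapply(order_vars,
                             function(f) feature_type(t, f) == "numeric",
                             TRUE)]
    trace[[it]] <- vapply(num, function(f)
      mean(data[[f]][miss_idx[[f]]]), numeric(1))
  }
  list(data = data, trace = trace)
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Fills missing clinical values with `m` independent chained-equation
#' chains. Visiting order is by increasing missingness. Conditional
#' models: numeric features use predictive mean matching (linear model,
#' donor pool of the 5 observed cases with nearest predicted mean),
#' binary features a logistic draw, unordered categoricals a multinomial
#' logit draw, ordered factors an ordered logit draw. A model that cannot
#' be fitted (degenerate or separated data) falls back to drawing from
#' the observed marginal.
#'
#' @param t a [clinical_table()]; per-feature missingness must be < 50%.
#' @param m number of imputed tables (default 10; 50 at full scale).
#' @param n_iterations chained-equation sweeps per table (default 10; 20
#'   at full scale).
#' @param seed integer seed.
#' @return list of `m` completed [clinical_table()]s, with the per-chain
#'   convergence trace of imputed-value means as attribute `trace`.
#' @export
impute_chained <- function(t, m = 10L, n_iterations = 10L, seed = 1L) {
  stopifnot(inherits(t, "clinical_table"))
  feats <- clin_features(t)
  missfrac <- vapply(feats, function(f) mean(is.na(t$data[[f]])), 0)
  if (any(missfrac >= 0.5))
    stop("feature(s) with >= 50% missingness: ",
         paste(feats[missfrac >= 0.5], collapse = ", "))
  if (!any(missfrac > 0)) {
    out <- rep(list(t), m)
    attr(out, "trace") <- NULL
    return(out)
  }
  order_vars <- feats[missfrac > 0][order(missfrac[missfrac > 0])]
  chains <- lapply(seq_len(m), function(ch)
    with_seed(seed + 7919L * ch,
              impute_one(t, order_vars, n_iterations)))
  out <- lapply(chains, function(ch) {
    tt <- t; tt$data <- ch$data; tt
  })
  attr(out, "trace") <- lapply(chains, `[[`, "trace")
  out
}

clin_matrix <- function(t) {
  x <- as.matrix(predictor_frame(t))
  rownames(x) <- t$data$sample_id
  if (anyNA(x)) stop("clinical matrix still contains missing values; impute first")
  x
}

#' Ensemble feature selection for one subgroup
#'
#' Ranks clinical features for the one-vs-rest task "is this sample in
#' `subgroup`?" under three dissimilar selectors — univariate Welch
#' t-statistic magnitude, L1-penalised logistic regression coefficient
#' magnitude (standardised), and permutation importance from a random
#' forest — and aggregates them by mean rank (ties broken by the
#' univariate rank).
#'
#' @param t encoded, complete [clinical_table()].
#' @param p a [partition()] over the same samples.
#' @param subgroup subgroup label (integer).
#' @param seed integer seed.
#' @return data.frame ranked best-first with per-selector ranks; attribute
#'   `ranking` holds the ordered feature names.
#' @export
ensemble_select <- function(t, p, subgroup, seed = 1L) {
  x <- clin_matrix(t)
  if (!all(rownames(x) %in% names(p)))
    stop("partition does not cover the clinical samples")
  y <- as.integer(p[rownames(x)] == subgroup)
  if (!any(y)) stop("subgroup absent from partition")
  keep <- apply(x, 2, function(v) var(v) > 0)
  x <- x[, keep, drop = FALSE]

  tstat <- apply(x, 2, function(v) {
    s <- tryCatch(abs(t.test(v[y == 1], v[y == 0])$statistic),
                  error = function(e) 0)
    as.numeric(s)
  })
  r_uni <- rank(-tstat, ties.method = "first")

  cvfit <- with_seed(seed, glmnet::cv.glmnet(x, y, family = "binomial",
                                             alpha = 1, nfolds = 5))
  b <- as.numeric(coef(cvfit, s = "lambda.min"))[-1]
  bstd <- abs(b) * apply(x, 2, sd)
  r_l1 <- rank(-bstd, ties.method = "min")

  df <- data.frame(x, check.names = FALSE)
  df$.y <- factor(y)
  rf <- with_seed(seed, ranger::ranger(.y ~ ., data = df, num.trees = 300,
                                       importance = "permutation",
                                       seed = seed))
  r_rf <- rank(-rf$variable.importance[colnames(x)], ties.method = "min")

  mean_rank <- (r_uni + r_l1 + r_rf) / 3
  ord <- order(mean_rank, r_uni)
  out <- data.frame(feature = colnames(x), rank_univariate = r_uni,
                    rank_lasso = r_l1, rank_rf = r_rf,
                    mean_rank = mean_rank)[ord, ]
  rownames(out) <- NULL
  attr(out, "ranking") <- out$feature
  out
}

balanced_accuracy <- function(truth, pred) {
  truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  mean(vapply(levels(truth), function(l) {
    idx <- truth == l
    mean(pred[idx] == l)
  }, 0))
}

make_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (l in unique(y)) {
      idx <- sample(which(y == l))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

fit_family <- function(family, x, y, seed) {
  y <- factor(y)
  switch(family,
    # the probability model inside svm() is fit by internal CV on the
    # global RNG; seed it so refits of identical data are identical
    svm = with_seed(seed, e1071::svm(x, y, kernel = "linear", cost = 1,
                                     scale = FALSE, probability = TRUE)),
    rf = {
      df <- data.frame(x, check.names = FALSE); df$.y <- y
      ranger::ranger(.y ~ ., data = df, num.trees = 300, seed = seed,
                     probability = FALSE)
    },
    lr = if (nlevels(y) == 2L) {
      suppressWarnings(glm.fit2 <- glm(y ~ ., family = binomial(),
                                       data = data.frame(y = y, x,
                                                         check.names = FALSE)))
      glm.fit2
    } else {
      nnet::multinom(.y ~ ., data = {
        df <- data.frame(x, check.names = FALSE); df$.y <- y; df
      }, trace = FALSE)
    },
    knn = list(train = x, cl = y, k = 5L, seed = seed),
    stop("unknown family: ", family))
}

predict_family <- function(family, fit, x) {
  switch(family,
    svm = as.character(predict(fit, x)),
    rf = as.character(predict(fit, data.frame(x, check.names = FALSE))$predictions),
    lr = if (inherits(fit, "glm")) {
      p <- predict(fit, data.frame(x, check.names = FALSE), type = "response")
      levels(fit$model$y)[1L + as.integer(p > 0.5)]
    } else {
      as.character(predict(fit, data.frame(x, check.names = FALSE)))
    },
    # knn breaks vote ties at random; fix the stream so predictions are
    # a pure function of the data
    knn = as.character(with_seed(fit$seed,
                                 class::knn(fit$train, x, fit$cl,
                                            k = fit$k))))
}

cv_performance <- function(x, y, family, n_folds, seed) {
  fold <- make_folds(y, n_folds, seed)
  perf <- vapply(seq_len(n_folds), function(f) {
    tr <- fold != f
    fit <- fit_family(family, x[tr, , drop = FALSE], y[tr], seed)
    pred <- predict_family(family, fit, x[!tr, , drop = FALSE])
    balanced_accuracy(y[!tr], pred)
  }, 0)
  c(mean = mean(perf), se = sd(perf) / sqrt(n_folds))
}

#' Search signature sizes s = 1..s_max over classifier families
#'
#' For each size s, the top-s aggregate-ranked features feed a one-vs-rest
#' classifier from each family (linear SVM, random forest, logistic
#' regression, k-nearest neighbours) under stratified cross-validation
#' scored by balanced accuracy. The chosen signature is the smallest s
#' whose best family performs within one standard error of the overall
#' maximum — the usual parsimony compromise.
#'
#' @param t encoded, complete [clinical_table()].
#' @param p a [partition()].
#' @param subgroup subgroup label.
#' @param sizes candidate sizes (default 1:20).
#' @param families subset of `c("svm", "rf", "lr", "knn")`.
#' @param n_folds stratified CV folds (default 5).
#' @param seed integer seed.
#' @param ranking optional precomputed feature ranking (from
#'   [ensemble_select()]); computed if missing.
#' @return object of class `clinical_signature`: list with `subgroup`,
#'   `features`, `size`, `family`, `cv_performance`, `cv_table`,
#'   `coefficients` (from a linear SVM refit on the chosen features).
#' @export
signature_search <- function(t, p, subgroup, sizes = 1:20,
                             families = c("svm", "rf", "lr", "knn"),
                             n_folds = 5L, seed = 1L, ranking = NULL) {
  x_all <- scale(clin_matrix(t))
  x_all <- x_all[, !is.na(colSums(x_all)), drop = FALSE]
  y <- as.integer(p[rownames(x_all)] == subgroup)
  if (is.null(ranking))
    ranking <- attr(ensemble_select(t, p, subgroup, seed = seed), "ranking")
  ranking <- intersect(ranking, colnames(x_all))
  sizes <- sizes[sizes <= length(ranking)]
  if (!length(sizes)) stop("no admissible signature size")
  grid <- expand.grid(size = sizes, family = families,
                      stringsAsFactors = FALSE)
  res <- t(mapply(function(s, fam) {
    cv_performance(x_all[, ranking[seq_len(s)], drop = FALSE], y, fam,
                   n_folds, seed)
  }, grid$size, grid$family))
  grid$mean <- res[, "mean"]; grid$se <- res[, "se"]
  best <- which.max(grid$mean)
  thresh <- grid$mean[best] - grid$se[best]
  ok <- grid[grid$mean >= thresh, ]
  pick <- ok[order(ok$size, -ok$mean), ][1, ]
  feats <- ranking[seq_len(pick$size)]
  sv <- fit_family("svm", x_all[, feats, drop = FALSE], y, seed)
  w <- drop(t(sv$coefs) %*% sv$SV)
  structure(list(subgroup = subgroup, features = feats, size = pick$size,
                 family = pick$family,
                 cv_performance = pick$mean, cv_table = grid,
                 coefficients = setNames(as.numeric(w), feats)),
            class = "clinical_signature")
}

#' @export
print.clinical_signature <- function(x, ...) {
  cat("Clinical signature for subgroup", x$subgroup, "- size", x$size,
      "(", x$family, "), CV balanced accuracy",
      sprintf("%.3f", x$cv_performance), "\n")
  print(x$coefficients)
  invisible(x)
}

#' Fit the composite multi-class classifier
#'
#' Pools the per-subgroup signatures' features (union, no duplicates) and
#' fits a multi-class linear SVM on the standardised pooled features; the
#' scaling parameters are learned here and frozen, so validation cohorts
#' are projected through the training scaling (no leakage).
#'
#' @param t encoded, complete training [clinical_table()].
#' @param p training [partition()].
#' @param signatures list of [signature_search()] results.
#' @param n_folds CV folds for the reported confusion matrix.
#' @param seed integer seed.
#' @return object of class `composite_classifier`.
#' @export
fit_composite <- function(t, p, signatures, n_folds = 5L, seed = 1L) {
  if (length(signatures) < 2L) stop("need at least two per-subgroup signatures")
  feats <- unique(unlist(lapply(signatures, `[[`, "features")))
  x <- clin_matrix(t)[, feats, drop = FALSE]
  ctr <- colMeans(x); scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  y <- factor(p[rownames(x)])
  fold <- make_folds(y, n_folds, seed)
  preds <- character(length(y))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit <- fit_family("svm", xs[tr, , drop = FALSE], y[tr], seed)
    preds[!tr] <- predict_family("svm", fit, xs[!tr, , drop = FALSE])
  }
  conf <- table(truth = y, predicted = factor(preds, levels = levels(y)))
  model <- fit_family("svm", xs, y, seed)
  structure(list(features = feats, center = ctr, scale = scl,
                 model = model, levels = levels(y),
                 cv_confusion = conf,
                 cv_balanced_accuracy = balanced_accuracy(y, preds),
                 seed = seed),
            class = "composite_classifier")
}

#' Classify a cohort by pooling over multiple imputed tables
#'
#' Rubin-style pooling for class predictions: the composite classifier
#' is refit on each completed training table and applied to each
#' completed validation table; the per-sample majority vote across all
#' refit/validation pairs is returned (ties broken toward the
#' first-listed prediction).
#'
#' @param train_imputations list of completed training
#'   [clinical_table()]s (from [impute_chained()]).
#' @param p training [partition()].
#' @param signatures list of per-subgroup [signature_search()] results.
#' @param validation_imputations list of completed validation tables.
#' @param n_folds,seed passed to [fit_composite()].
#' @return majority-vote [partition()] over the validation samples.
#' @export
classify_pooled <- function(train_imputations, p, signatures,
                            validation_imputations, n_folds = 5L,
                            seed = 1L) {
  votes <- list()
  for (tr in train_imputations) {
    comp <- fit_composite(tr, p, signatures, n_folds = n_folds,
                          seed = seed)
    for (v in validation_imputations) {
      pred <- classify_cohort(comp, v)
      votes[[length(votes) + 1L]] <-
        setNames(as.integer(pred), names(pred))
    }
  }
  ids <- names(votes[[1L]])
  tally <- sapply(ids, function(id) {
    vs <- vapply(votes, `[[`, 0L, id)
    as.integer(names(sort(table(vs), decreasing = TRUE))[1L])
  })
  partition(tally, ids, by_size = FALSE)
}

#' Classify a new cohort with the composite classifier
#'
#' The validation table must contain every pooled feature (after the same
#' cleaning and encoding); a missing feature is an error naming it.
#' Features are standardised with the training scaling.
#'
#' @param classifier a [fit_composite()] result.
#' @param v encoded, complete validation [clinical_table()].
#' @return [partition()] of predicted subgroups (attribute
#'   `probabilities` holds the SVM class probabilities).
#' @export
classify_cohort <- function(classifier, v) {
  x <- clin_matrix(v)
  absent <- setdiff(classifier$features, colnames(x))
  if (length(absent))
    stop("validation cohort lacks required feature(s): ",
         paste(absent, collapse = ", "))
  xs <- scale(x[, classifier$features, drop = FALSE],
              classifier$center, classifier$scale)
  pred <- predict(classifier$model, xs, probability = TRUE)
  out <- partition(factor(as.character(pred), levels = classifier$levels),
                   sample_ids = rownames(x), by_size = FALSE)
  attr(out, "probabilities") <- attr(pred, "probabilities")
  out
}
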