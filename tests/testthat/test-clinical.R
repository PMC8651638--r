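toy_clinical <- function() {
  set.seed(1)
  n <- 40
  clinical_table(
    data.frame(
      sample_id = paste0("S", 1:n),
      num_ok = rnorm(n),                                   # fully observed
      num_miss6 = replace(rnorm(n), 1:3, NA),              # 7.5% missing
      num_miss2 = replace(rnorm(n), 1, NA),                # 2.5% missing
      bin = rbinom(n, 1, 0.5),
      cat = sample(c("a", "b", "c"), n, replace = TRUE),
      ord = factor(sample(c("I", "II", "III"), n, replace = TRUE),
                   levels = c("I", "II", "III"), ordered = TRUE)),
    data.frame(feature = c("num_ok", "num_miss6", "num_miss2", "bin",
                           "cat", "ord"),
               type = c("numeric", "numeric", "numeric", "binary",
                        "categorical", "ordered"),
               levels = c(NA, NA, NA, NA, NA, "I|II|III")))
}

test_that("cleaning drops features above the missingness threshold and encodes the rest", {
  t <- toy_clinical()
  cl <- clean_clinical(t, max_missing = 0.05)
  rep <- attr(cl, "drop_report")
  # hand enumeration: only num_miss6 exceeds 5% (3/40 = 7.5%)
  expect_equal(rep$feature[rep$dropped], "num_miss6")
  expect_false("num_miss6" %in% names(cl$data))
  # one-hot encoding of the categorical, integer ranks for the ordered
  expect_setequal(intersect(paste0("cat.", c("a", "b", "c")),
                            names(cl$data)),
                  paste0("cat.", c("a", "b", "c")))
  expect_true(is.integer(cl$data$ord))
  expect_equal(sort(unique(cl$data$ord)), 1:3)
  # fully observed features unchanged apart from encoding
  expect_equal(cl$data$num_ok, t$data$num_ok)
  # undeclared feature rejected at construction
  expect_error(clinical_table(data.frame(sample_id = "a", x = 1),
                              data.frame(feature = "y", type = "numeric")),
               "missing from dictionary")
})

test_that("chained imputation is exact on complete data and PMM draws from donors", {
  t <- toy_clinical()
  t$data$num_miss6 <- NULL
  t$data$num_miss2[1] <- 0.123
  t$dictionary <- t$dictionary[t$dictionary$feature != "num_miss6", ]
  imp <- impute_chained(t, m = 3, n_iterations = 2, seed = 1)
  expect_length(imp, 3)
  for (i in 1:3) expect_identical(imp[[i]]$data, t$data)

  # now with a hole: PMM imputes an observed donor value
  t2 <- toy_clinical()
  cl <- clean_clinical(t2, max_missing = 0.05)
  imp2 <- impute_chained(cl, m = 2, n_iterations = 3, seed = 2)
  miss_idx <- which(is.na(cl$data$num_miss2))
  donors <- cl$data$num_miss2[-miss_idx]
  for (i in 1:2) {
    filled <- imp2[[i]]$data$num_miss2[miss_idx]
    expect_false(anyNA(imp2[[i]]$data$num_miss2))
    expect_true(all(filled %in% donors))
  }
  # feature with zero observed values is an error
  t3 <- toy_clinical()
  t3$data$num_miss2 <- NA_real_
  expect_error(impute_chained(t3, m = 1, n_iterations = 1, seed = 1),
               ">= 50% missingness")
})

test_that("imputation under 10% MCAR recovers feature means within 5%", {
  co <- fixture_cohort()
  cl <- clean_clinical(co$clinical, max_missing = 0.05)
  complete_mean <- mean(cl$data$sixmwd, na.rm = TRUE)
  # punch 10% MCAR holes into a feature
  set.seed(4)
  holes <- sample(nrow(cl$data), round(0.1 * nrow(cl$data)))
  cl$data$sixmwd[holes] <- NA
  imp <- impute_chained(cl, m = 10, n_iterations = 10, seed = 5)
  pooled <- mean(vapply(imp, function(t) mean(t$data$sixmwd), 0))
  expect_lt(abs(pooled - complete_mean) / complete_mean, 0.05)
})

test_that("ensemble selection ranks a perfect separator first and planted features high", {
  set.seed(6)
  n <- 120
  y <- rep(1:2, each = n / 2)
  t <- clinical_table(
    data.frame(sample_id = paste0("S", 1:n),
               perfect = y + rnorm(n, 0, 0.01),
               noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n)),
    data.frame(feature = c("perfect", "noise1", "noise2", "noise3"),
               type = "numeric", levels = NA))
  p <- partition(y, paste0("S", 1:n), by_size = FALSE)
  r <- ensemble_select(t, p, 1, seed = 1)
  expect_equal(r$feature[1], "perfect")
  expect_equal(r$rank_univariate[1], 1L)
  expect_equal(r$rank_rf[1], 1L)
  expect_error(ensemble_select(t, p, 9), "absent")

  # planted cohort: shifted clinical features occupy top ranks
  co <- fixture_cohort()
  train <- impute_chained(clean_clinical(co$clinical), m = 1,
                          n_iterations = 3, seed = 1)[[1]]
  part <- partition(co$truth$labels)
  rr <- ensemble_select(train, part, 1, seed = 1)
  shifted <- c("crp", "ntprobnp", "sixmwd", "age_diagnosis", "bmi",
               "creatinine", "raa", "oxygen_sat", "who_fc")
  expect_gte(mean(head(rr$feature, 5) %in% shifted), 0.8)
})

test_that("signature search obeys s = 1 and the one-SE parsimony rule", {
  set.seed(7)
  n <- 90
  y <- rep(1:2, each = n / 2)
  t <- clinical_table(
    data.frame(sample_id = paste0("S", 1:n),
               strong = y * 2 + rnorm(n, 0, 0.3),
               weak = y + rnorm(n, 0, 2),
               noise = rnorm(n)),
    data.frame(feature = c("strong", "weak", "noise"), type = "numeric",
               levels = NA))
  p <- partition(y, paste0("S", 1:n), by_size = FALSE)
  sig <- signature_search(t, p, 1, sizes = 1:3,
                          families = c("svm", "lr"), seed = 1)
  expect_lte(sig$size, 2)                     # one strong feature suffices
  expect_equal(sig$features[1], "strong")
  expect_true(all(sig$cv_table$mean >= 0 & sig$cv_table$mean <= 1))
  sig1 <- signature_search(t, p, 1, sizes = 1, families = "svm", seed = 1)
  expect_equal(sig1$features, "strong")
})

test_that("composite classifier separates planted subgroups and collapses on permuted labels", {
  co <- fixture_cohort()
  part <- partition(co$truth$labels)
  train <- impute_chained(clean_clinical(co$clinical), m = 1,
                          n_iterations = 3, seed = 1)[[1]]
  rk <- attr(ensemble_select(train, part, 1, seed = 1), "ranking")
  sigs <- lapply(1:3, function(g)
    signature_search(train, part, g, sizes = 1:8,
                     families = c("svm", "lr"), seed = 1, ranking = rk))
  expect_setequal(fit_composite(train, part, sigs, seed = 1)$features,
                  unique(unlist(lapply(sigs, `[[`, "features"))))
  comp <- fit_composite(train, part, sigs, seed = 1)
  expect_gte(comp$cv_balanced_accuracy, 0.8)
  expect_error(fit_composite(train, part, sigs[1]), "at least two")

  # label permutation destroys the signal: CV accuracy near 1/3
  set.seed(2)
  perm <- partition(sample(as.integer(part)), names(part), by_size = FALSE)
  comp_null <- fit_composite(train, perm, sigs, seed = 1)
  expect_lt(comp_null$cv_balanced_accuracy, 0.45)
})

test_that("transfer classification is leakage-free and errors on missing features", {
  co <- fixture_cohort()
  va <- generate_validation_cohort(cohort_spec(seed = 42))
  part <- partition(co$truth$labels)
  train <- impute_chained(clean_clinical(co$clinical), m = 1,
                          n_iterations = 3, seed = 1)[[1]]
  rk <- attr(ensemble_select(train, part, 1, seed = 1), "ranking")
  sigs <- lapply(1:3, function(g)
    signature_search(train, part, g, sizes = 1:8,
                     families = c("svm", "lr"), seed = 1, ranking = rk))
  comp <- fit_composite(train, part, sigs, seed = 1)
  vimp <- impute_chained(clean_clinical(va$clinical, max_missing = 1),
                         m = 1, n_iterations = 3, seed = 2)[[1]]
  pred <- classify_cohort(comp, vimp)
  # resubstitution agreement is at least the CV estimate
  self <- classify_cohort(comp, train)
  expect_gte(balanced_accuracy(as.integer(part[names(self)]),
                               as.integer(self)),
             comp$cv_balanced_accuracy)
  # permuting and duplicating validation rows leaves predictions unchanged
  vperm <- vimp
  idx <- c(rev(seq_len(nrow(vperm$data))), 1L, 2L)
  vperm$data <- vperm$data[idx, ]
  pred2 <- classify_cohort(comp, vperm)
  expect_identical(as.integer(pred2[names(pred)]), as.integer(pred))
  # missing composite feature is a named error
  broken <- vimp
  broken$data[[comp$features[1]]] <- NULL
  broken$dictionary <- broken$dictionary[
    broken$dictionary$feature != comp$features[1], ]
  expect_error(classify_cohort(comp, broken), comp$features[1])
  # a single-table pool reduces to the plain classifier
  pooled <- classify_pooled(list(train), part, sigs, list(vimp), seed = 1)
  expect_identical(as.integer(pooled[names(pred)]), as.integer(pred))
})
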