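test_that("cohort specs validate their invariants", {
  expect_error(cohort_spec(subgroup_proportions = c(0.5, 0.5)), "simplex")
  expect_error(cohort_spec(n_subgroups = 4), "3 or 5")
  expect_error(cohort_spec(five_year_survival = c(0.5, 1.2, 0.7)), "0, 1")
  expect_error(cohort_spec(n_genes = 100), "too small")
  spec <- cohort_spec()
  # hazards follow from S(5) = exp(-5 * lambda)
  expect_equal(exp(-5 * spec$hazard_per_subgroup),
               c(0.53, 0.65, 0.78))
})

test_that("the same seed reproduces the cohort bit for bit", {
  a <- generate_cohort(cohort_spec(seed = 7, n_samples = 60,
                                   n_genes = 400, n_volatile = 20))
  b <- generate_cohort(cohort_spec(seed = 7, n_samples = 60,
                                   n_genes = 400, n_volatile = 20))
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical$data, b$clinical$data)
  expect_identical(a$survival, b$survival)
  expect_identical(a$genotype, b$genotype)
  expect_identical(a$truth$labels, b$truth$labels)
  v1 <- generate_validation_cohort(cohort_spec(seed = 7), n_samples = 50)
  v2 <- generate_validation_cohort(cohort_spec(seed = 7), n_samples = 50)
  expect_identical(v1$clinical$data, v2$clinical$data)
})

test_that("truth records are structurally sound", {
  co <- fixture_cohort()
  tr <- co$truth
  expect_equal(length(tr$labels), ncol(co$expression))
  expect_false(anyNA(tr$labels))
  blocks <- tr$marker_genes
  expect_equal(anyDuplicated(unlist(blocks)), 0L)    # disjoint marker sets
  expect_true(all(unlist(blocks) %in% rownames(co$expression)))
  # sex genes are annotated on sex chromosomes
  ann <- co$annotation
  expect_true(all(ann$chromosome[match(tr$sex_genes, ann$gene_id)] %in%
                    c("chrX", "chrY")))
})

test_that("no planted signal means no recoverable clustering", {
  spec <- cohort_spec(seed = 9, marker_effect = 0,
                      five_year_survival = c(0.65, 0.65, 0.65),
                      n_samples = 150, n_genes = 600, n_volatile = 20)
  co <- generate_cohort(spec)
  tx <- arcsinh_transform(remove_sex_genes(filter_low_expression(co$expression),
                                           co$annotation))
  sub <- tx[rank_genes_by_variability(tx, 150)$size_150, ]
  p <- spectral_cluster(rbf_affinity(sub), 3, seed = 1)
  expect_lt(abs(adjusted_rand_index(p, co$truth$labels)), 0.05)
})

test_that("empirical five-year survival tracks the planted hazards within 5 points", {
  # closed form: S(5) = exp(-5 * lambda); Monte-Carlo check at n = 300/group
  spec <- cohort_spec(seed = 123, n_samples = 900,
                      subgroup_proportions = rep(1 / 3, 3),
                      n_genes = 400, n_volatile = 20,
                      marker_block_sizes = c(immunoglobulin = 20L,
                                             alas2 = 5L, nog = 5L))
  co <- generate_cohort(spec)
  labs <- co$truth$labels[co$survival$sample_id]
  d <- survival_data(co$survival$time_days, co$survival$event, group = labs)
  s5 <- km_survival_at(km_estimate(d), 5 * 365.25)
  planted <- c(0.53, 0.65, 0.78)
  for (g in 1:3) expect_lt(abs(s5[[as.character(g)]] - planted[g]), 0.05)
})

test_that("clinical missingness rates honour the spec within 2 points", {
  spec <- cohort_spec(seed = 77)
  va <- generate_validation_cohort(spec, n_samples = 2000)
  for (f in names(spec$clinical_feature_specs)) {
    got <- mean(is.na(va$clinical$data[[f]]))
    expect_lt(abs(got - spec$clinical_feature_specs[[f]]$missing),
              0.02 + 1e-9)
  }
})

test_that("validation cohort shares the generative model of the discovery cohort", {
  spec <- cohort_spec(seed = 21)
  co <- generate_cohort(spec)
  va <- generate_validation_cohort(spec, n_samples = 197)
  expect_equal(nrow(va$clinical$data), 197)
  expect_null(va$expression)
  expect_identical(sort(names(va$clinical$data)),
                   sort(names(co$clinical$data)))
  # per-subgroup means agree within sampling error (z-test at alpha 0.001)
  for (f in c("sixmwd", "bmi", "creatinine")) {
    for (g in 1:3) {
      x <- co$clinical$data[[f]][co$truth$labels == g]
      y <- va$clinical$data[[f]][va$truth$labels == g]
      z <- (mean(x, na.rm = TRUE) - mean(y, na.rm = TRUE)) /
        sqrt(var(x, na.rm = TRUE) / sum(!is.na(x)) +
               var(y, na.rm = TRUE) / sum(!is.na(y)))
      expect_lt(abs(z), qnorm(0.9995))
    }
  }
})

test_that("genotype frequencies differ by subgroup in the planted direction", {
  spec <- cohort_spec(seed = 31, n_samples = 900,
                      subgroup_proportions = rep(1 / 3, 3),
                      n_genes = 400, n_volatile = 20,
                      marker_block_sizes = c(immunoglobulin = 20L,
                                             alas2 = 5L, nog = 5L))
  co <- generate_cohort(spec)
  labs <- co$truth$labels[match(co$genotype$sample_id,
                                names(co$truth$labels))]
  f_cc <- vapply(1:3, function(g)
    mean(co$genotype$hla_genotype[labs == g] == "C/C"), 0)
  expect_lt(f_cc[1], f_cc[3])          # C/C enriched in the good subgroup
  tt <- two_proportion_test(sum(co$genotype$hla_genotype[labs == 1] == "C/C"),
                            sum(labs == 1),
                            sum(co$genotype$hla_genotype[labs == 3] == "C/C"),
                            sum(labs == 3))
  expect_lt(tt$p, 0.05)
})

test_that("the optional five-subgroup layout adds two small shadow groups", {
  spec <- cohort_spec(seed = 41, n_subgroups = 5, n_samples = 359)
  co <- generate_cohort(spec)
  tab <- table(co$truth$labels)
  expect_equal(length(tab), 5L)
  expect_true(all(tab[c("4", "5")] < min(tab[c("1", "2", "3")])))
})
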