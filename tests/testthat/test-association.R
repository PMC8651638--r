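mini_clin <- function(df) {
  clinical_table(cbind(data.frame(sample_id = paste0("S", seq_len(nrow(df)))),
                       df),
                 data.frame(feature = names(df), type = "numeric",
                            levels = NA))
}

test_that("monotone transforms of a gene give |rho| = 1 edges", {
  set.seed(1)
  g <- matrix(rexp(30), 1, dimnames = list("gene1", paste0("S", 1:30)))
  t <- mini_clin(data.frame(up = exp(as.numeric(g)),      # monotone up
                            down = -rank(as.numeric(g)))) # monotone down
  net <- build_network(g, t, rho_min = 0.25, p_max = 0.05)
  e <- net$all_pairs
  expect_equal(e$rho[e$feature == "up"], 1)
  expect_equal(e$rho[e$feature == "down"], -1)
  expect_setequal(net$edges$feature, c("up", "down"))
})

test_that("Spearman rho is invariant to strictly monotone transforms", {
  set.seed(2)
  x <- matrix(rexp(40, 0.2), 1, dimnames = list("g", paste0("S", 1:40)))
  y <- rnorm(40) + 0.05 * as.numeric(x)
  t1 <- mini_clin(data.frame(f = y))
  t2 <- mini_clin(data.frame(f = exp(y / 3)))
  n1 <- build_network(x, t1, rho_min = 0, p_max = 1.1)
  n2 <- build_network(log(x + 1), t2, rho_min = 0, p_max = 1.1)
  expect_equal(n1$all_pairs$rho, n2$all_pairs$rho, tolerance = 1e-12)
})

test_that("network edges are monotone in the thresholds and constants are skipped", {
  set.seed(3)
  g <- matrix(rexp(25 * 4), 4,
              dimnames = list(paste0("g", 1:4), paste0("S", 1:25)))
  t <- mini_clin(data.frame(a = rnorm(25) + as.numeric(g[1, ]),
                            b = rnorm(25), const = rep(1, 25)))
  strict <- expect_warning(build_network(g, t, rho_min = 0.4, p_max = 1e-3),
                           "constant")
  loose <- suppressWarnings(build_network(g, t, rho_min = 0.2, p_max = 0.05))
  key <- function(net) paste(net$edges$gene, net$edges$feature)
  expect_true(all(key(strict) %in% key(loose)))
  expect_false(any(grepl("const", c(key(strict), key(loose)))))
  expect_error(build_network(g[, 1:5], mini_clin(data.frame(a = rnorm(5)))),
               "10 overlapping")
})

test_that("cross-network concordance is 1 against itself and 0 against a sign flip", {
  set.seed(4)
  g <- matrix(rexp(60 * 2), 2,
              dimnames = list(c("g1", "g2"), paste0("S", 1:60)))
  t <- mini_clin(data.frame(f1 = as.numeric(g[1, ]) + rnorm(60, 0, 0.5)))
  net <- build_network(g, t, rho_min = 0, p_max = 1.1)
  expect_equal(correlation_concordance(net, net)$concordance, 1)
  flipped <- net
  flipped$all_pairs$rho <- -flipped$all_pairs$rho
  expect_equal(correlation_concordance(net, flipped)$concordance, 0)
  empty <- net
  empty$all_pairs <- empty$all_pairs[0, ]
  expect_error(correlation_concordance(net, empty), "overlap")
})

test_that("two cohorts from one generator give concordant planted correlations", {
  co <- fixture_cohort()
  tx <- fixture_preprocessed()
  genes <- c(co$truth$marker_genes$alas2[1:5], co$truth$marker_genes$nog[1:5])
  feats <- c("crp", "sixmwd", "age_diagnosis", "bmi")
  half1 <- colnames(tx)[1:165]; half2 <- colnames(tx)[166:330]
  imp <- impute_chained(clean_clinical(co$clinical), m = 1,
                        n_iterations = 3, seed = 1)[[1]]
  sub_t <- function(ids) {
    t2 <- imp; t2$data <- t2$data[t2$data$sample_id %in% ids, ]; t2
  }
  n1 <- build_network(tx[, half1], sub_t(half1), genes, feats,
                      rho_min = 0, p_max = 1.1)
  n2 <- build_network(tx[, half2], sub_t(half2), genes, feats,
                      rho_min = 0, p_max = 1.1)
  cc <- correlation_concordance(n1, n2)
  expect_gte(cc$concordance, 0.7)
})

test_that("delta-delta-Ct arithmetic matches a worked spreadsheet", {
  # duplicates are averaged on the Ct scale first
  df <- data.frame(
    sample_id = rep(c("A1", "A2", "B1", "B2"), each = 4),
    assay = rep(c("GAPDH", "GAPDH", "NOG", "NOG"), times = 4),
    ct = c(20, 20.2, 26, 26.2,    # A1: ref 20.1, NOG 26.1 -> dCt 6
           20, 20, 27, 27,        # A2: dCt 7
           20, 20, 24, 24,        # B1: dCt 4
           20, 20, 25, 25),       # B2: dCt 5
    group = rep(c("I", "I", "II", "II"), each = 4))
  q <- qpcr_table(df, reference_assay = "GAPDH")
  rq <- delta_delta_ct(q, calibrator_group = "II")
  # calibrator mean dCt = 4.5; ddCt: A1 1.5, A2 2.5, B1 -0.5, B2 0.5
  expect_equal(rq$ddct[match(c("A1", "A2", "B1", "B2"), rq$sample_id)],
               c(1.5, 2.5, -0.5, 0.5))
  expect_equal(rq$rq, 2^(-rq$ddct))
  # calibrator group RQ has geometric mean exactly 1
  cal <- rq$rq[rq$group == "II"]
  expect_equal(exp(mean(log(cal))), 1)
  # ddCt = -1 doubles the relative quantity
  expect_equal(2^(-(-1)), 2)
  # missing reference Ct is an error
  expect_error(qpcr_table(df[df$assay != "GAPDH" | df$sample_id != "A1", ]),
               "A1")
  expect_error(qpcr_table(transform(df, ct = c(-1, ct[-1]))), "positive")
})

test_that("qPCR group comparison detects a planted cycle shift at the study group sizes", {
  # identical groups: fold ratio 0, p near 1
  set.seed(5)
  base <- rnorm(20, 25, 0.5)
  df <- data.frame(sample_id = rep(paste0("S", 1:20), 2),
                   assay = rep(c("GAPDH", "NOG"), each = 20),
                   ct = c(rep(20, 20), base),
                   group = rep(rep(c("I", "II"), each = 10), 2))
  rq <- delta_delta_ct(qpcr_table(df), "II")
  cmp <- qpcr_group_comparison(rq, "I", "II")
  expect_lt(abs(cmp$log2_fold_ratio), 0.5)

  # NOG-like assay shifted 1.5 cycles lower (higher expression) in the
  # good-prognosis group, n = 53 vs 38 as in the validation cohort
  set.seed(6)
  n1 <- 53; n2 <- 38
  ct_nog <- c(rnorm(n1, 26, 1), rnorm(n2, 24.5, 1))
  df2 <- data.frame(
    sample_id = rep(paste0("S", 1:(n1 + n2)), 2),
    assay = rep(c("GAPDH", "NOG"), each = n1 + n2),
    ct = c(rnorm(n1 + n2, 20, 0.3), ct_nog),
    group = rep(rep(c("I", "II"), c(n1, n2)), 2))
  rq2 <- delta_delta_ct(qpcr_table(df2), "II")
  cmp2 <- qpcr_group_comparison(rq2, "I", "II")
  expect_lt(cmp2$p, 0.01)
  expect_lt(cmp2$log2_fold_ratio, 0)     # lower in group I
  # exact cycle arithmetic: a +1 cycle shift in -dCt is a log2 ratio of 1
  rq3 <- rq2
  rq3$dct[rq3$group == "I"] <- mean(rq3$dct[rq3$group == "II"]) - 1
  cmp3 <- qpcr_group_comparison(rq3, "I", "II")
  expect_equal(cmp3$log2_fold_ratio, 1, tolerance = 1e-9)
  expect_error(qpcr_group_comparison(rq2[rq2$sample_id %in% c("S1", "S54"), ],
                                     "I", "II"),
               "singleton")
})
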