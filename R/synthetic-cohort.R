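# Synthetic cohort generator. Emulates the statistical structure the
# discovery pipeline assumes: latent subgroups with block-structured
# marker genes, sex-chromosome nuisance genes, subgroup-shifted clinical
# features, subgroup-specific survival hazards, a genotype with
# subgroup-dependent allele frequency, and clinical missingness.

#' Specification of a synthetic PAH-like cohort
#'
#' Defaults mirror the structure of a whole-blood IPAH discovery cohort:
#' three predominant subgroups ("poor", "moderate", "good" prognosis) with
#' sizes in proportion 129:89:112, an immunoglobulin-like marker block
#' ordered low/intermediate/high across them, an ALAS2-like block up in
#' the poor group, a NOG-like block up in the good group, exponential
#' survival calibrated so 5-year survival is 53%/65%/78%, and clinical
#' features (CRP, NT-proBNP, 6MWD, age at diagnosis, BMI, creatinine,
#' right atrial area, oxygen saturation, WHO functional class) shifted in
#' the directions seen in such cohorts. `n_subgroups = 5` adds two small
#' subgroups whose expression and hazards shadow the good and poor groups.
#'
#' @param n_samples cohort size (default 330 = 129 + 89 + 112).
#' @param n_genes total genes, including markers, sex genes and a block of
#'   high-variance "volatile" nuisance genes uncorrelated with subgroup.
#' @param n_subgroups 3 (default) or 5.
#' @param subgroup_proportions simplex weights (must sum to 1).
#' @param marker_block_sizes named counts: `immunoglobulin`, `alas2`, `nog`.
#' @param marker_effect log-scale shift of marker blocks between subgroups
#'   (1.0 ~ e-fold, consistent with >2-fold signature genes).
#' @param noise_sd log-scale within-group sd of ordinary genes.
#' @param n_volatile high-variance nuisance genes (log-sd `volatile_sd`).
#' @param volatile_sd log-scale sd of the volatile block.
#' @param n_sex_genes sex-chromosome genes (half chrY, half chrX).
#' @param female_fraction probability a sample is female.
#' @param five_year_survival per-subgroup 5-year survival fractions used
#'   to derive exponential hazards (`lambda = -log(S5)/5` per year).
#' @param censor_rate exponential censoring rate per year.
#' @param genotype_freqs per-subgroup C/C genotype frequency.
#' @param clinical_feature_specs per-feature generative specs; see
#'   [default_clinical_specs()].
#' @param missing_mechanism `"MCAR"` or `"MAR"` (MAR conditions the
#'   missingness probability on observed age at diagnosis).
#' @param seed integer seed; identical specs yield identical cohorts.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 330L,
                        n_genes = 2000L,
                        n_subgroups = 3L,
                        subgroup_proportions = NULL,
                        marker_block_sizes = c(immunoglobulin = 120L,
                                               alas2 = 20L, nog = 20L),
                        marker_effect = 2.0,
                        noise_sd = 0.5,
                        n_volatile = 55L,
                        volatile_sd = 2.4,
                        n_sex_genes = 40L,
                        female_fraction = 0.7,
                        five_year_survival = NULL,
                        censor_rate = 0.06,
                        genotype_freqs = NULL,
                        clinical_feature_specs = default_clinical_specs(),
                        missing_mechanism = c("MCAR", "MAR"),
                        seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  if (!n_subgroups %in% c(3L, 5L))
    stop("n_subgroups must be 3 or 5")
  if (is.null(subgroup_proportions)) {
    subgroup_proportions <- if (n_subgroups == 3L) {
      c(129, 89, 112) / 330
    } else {
      c(129, 89, 112, 19, 10) / 359
    }
  }
  if (length(subgroup_proportions) != n_subgroups ||
      abs(sum(subgroup_proportions) - 1) > 1e-8 ||
      any(subgroup_proportions <= 0))
    stop("subgroup_proportions must be a positive simplex of length n_subgroups")
  if (is.null(five_year_survival)) {
    five_year_survival <- c(0.53, 0.65, 0.78, 0.78, 0.53)[seq_len(n_subgroups)]
  }
  if (any(five_year_survival <= 0 | five_year_survival >= 1))
    stop("five_year_survival must lie in (0, 1)")
  if (is.null(genotype_freqs))
    genotype_freqs <- c(0.15, 0.25, 0.35, 0.35, 0.15)[seq_len(n_subgroups)]
  stopifnot(n_samples > 0, n_genes > 0, marker_effect >= 0,
            censor_rate > 0, all(genotype_freqs > 0 & genotype_freqs < 1))
  n_marker <- sum(marker_block_sizes)
  if (n_genes < n_marker + n_sex_genes + n_volatile)
    stop("n_genes too small for the requested blocks")
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_subgroups = as.integer(n_subgroups),
    subgroup_proportions = subgroup_proportions,
    subgroup_names = c("poor", "moderate", "good",
                       "small_good", "small_poor")[seq_len(n_subgroups)],
    marker_block_sizes = marker_block_sizes,
    marker_effect = marker_effect, noise_sd = noise_sd,
    n_volatile = as.integer(n_volatile), volatile_sd = volatile_sd,
    n_sex_genes = as.integer(n_sex_genes),
    female_fraction = female_fraction,
    five_year_survival = five_year_survival,
    hazard_per_subgroup = -log(five_year_survival) / 5,
    censor_rate = censor_rate, genotype_freqs = genotype_freqs,
    clinical_feature_specs = clinical_feature_specs,
    missing_mechanism = missing_mechanism,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' Default clinical feature generative specs
#'
#' Each element describes one feature: `type` (`"normal"`, `"lognormal"`,
#' `"binary"`, `"ordered"`), per-subgroup location parameters (ordered
#' poor / moderate / good; the two optional small subgroups reuse the good
#' and poor columns), dispersion, and a missingness rate. Directions of
#' the subgroup shifts follow the clinical picture of transcriptomic PAH
#' subgroups: the poor-prognosis group is older at diagnosis with higher
#' CRP, NT-proBNP, creatinine, BMI and right atrial area, and lower
#' six-minute walk distance and oxygen saturation. `junk_score` is pure
#' noise with 8% missingness, so the >5% missingness filter always has
#' something to drop.
#'
#' @return named list of feature specs.
#' @export
default_clinical_specs <- function() {
  list(
    crp = list(type = "lognormal", meanlog = log(c(16, 7, 3)), sdlog = 0.6,
               missing = 0.02, units = "mg/L"),
    ntprobnp = list(type = "lognormal", meanlog = log(c(2000, 800, 250)),
                    sdlog = 0.8, missing = 0.02, units = "ng/L"),
    sixmwd = list(type = "normal", mean = c(260, 340, 420), sd = 90,
                  missing = 0.02, units = "m"),
    age_diagnosis = list(type = "normal", mean = c(60, 52, 46), sd = 12,
                         missing = 0, units = "years"),
    bmi = list(type = "normal", mean = c(30, 27, 25), sd = 4,
               missing = 0.02, units = "kg/m2"),
    creatinine = list(type = "normal", mean = c(100, 85, 75), sd = 18,
                      missing = 0.02, units = "umol/L"),
    raa = list(type = "normal", mean = c(28, 24, 21), sd = 5,
               missing = 0.02, units = "cm2"),
    oxygen_sat = list(type = "normal", mean = c(91, 93.5, 95.5), sd = 3,
                      missing = 0.02, units = "%"),
    who_fc = list(type = "ordered", levels = c("I", "II", "III", "IV"),
                  probs = rbind(c(0.01, 0.14, 0.60, 0.25),
                                c(0.05, 0.30, 0.60, 0.05),
                                c(0.12, 0.45, 0.41, 0.02)),
                  missing = 0.02),
    heart_rate = list(type = "normal", mean = c(80, 78, 76), sd = 12,
                      missing = 0.02, units = "bpm"),
    albumin = list(type = "normal", mean = c(40, 40, 40), sd = 4,
                   missing = 0.03, units = "g/L"),
    platelets = list(type = "normal", mean = c(250, 250, 250), sd = 60,
                     missing = 0.03, units = "1e9/L"),
    junk_score = list(type = "normal", mean = c(0, 0, 0), sd = 1,
                      missing = 0.08, units = "au")
  )
}

# map subgroup index -> column of the 3-wide parameter vectors
param_col <- function(g) c(1L, 2L, 3L, 3L, 1L)[g]

draw_clinical <- function(spec, labels, prefix) {
  n <- length(labels)
  specs <- spec$clinical_feature_specs
  out <- list()
  dict <- list()
  for (nm in names(specs)) {
    fs <- specs[[nm]]
    col <- param_col(labels)
    v <- switch(fs$type,
      normal = rnorm(n, fs$mean[col], fs$sd),
      lognormal = rlnorm(n, fs$meanlog[col], fs$sdlog),
      binary = rbinom(n, 1L, fs$prob[col]),
      ordered = {
        lv <- fs$levels
        idx <- vapply(col, function(ci)
          sample.int(length(lv), 1L, prob = fs$probs[ci, ]), 0L)
        factor(lv[idx], levels = lv, ordered = TRUE)
      },
      stop("unknown clinical feature type: ", fs$type))
    out[[nm]] <- v
    dict[[nm]] <- data.frame(
      feature = nm,
      type = switch(fs$type, normal = "numeric", lognormal = "numeric",
                    binary = "binary", ordered = "ordered"),
      levels = if (fs$type == "ordered")
        paste(fs$levels, collapse = "|") else NA_character_)
  }
  df <- data.frame(sample_id = paste0(prefix, sprintf("%03d", seq_len(n))),
                   out, stringsAsFactors = FALSE)
  # sex as an explicit binary feature
  sex <- rbinom(n, 1L, spec$female_fraction)  # 1 = female
  df$sex_female <- sex
  dict$sex_female <- data.frame(feature = "sex_female", type = "binary",
                                levels = NA_character_)
  # inject missingness
  for (nm in names(specs)) {
    rate <- specs[[nm]]$missing
    if (rate <= 0) next
    if (spec$missing_mechanism == "MCAR") {
      miss <- runif(n) < rate
    } else {
      # MAR: older patients (always observed) more likely to have gaps
      a <- df$age_diagnosis
      sc <- scale(a)[, 1]
      pr <- plogis(qlogis(rate) + 0.8 * sc)
      miss <- runif(n) < pr
    }
    df[[nm]][miss] <- NA
  }
  clinical_table(df, do.call(rbind, dict))
}

draw_survival <- function(spec, labels, sample_ids) {
  haz <- spec$hazard_per_subgroup[labels]
  t_event <- rexp(length(labels), rate = haz)
  t_cens <- rexp(length(labels), rate = spec$censor_rate)
  time_years <- pmin(t_event, t_cens)
  data.frame(sample_id = sample_ids,
             time_days = pmax(1, round(time_years * 365.25)),
             event = as.integer(t_event <= t_cens),
             time_origin = "sampling",
             stringsAsFactors = FALSE)
}

draw_genotype <- function(spec, labels, sample_ids) {
  f <- spec$genotype_freqs[labels]
  p <- sqrt(f)  # Hardy-Weinberg allele frequency giving P(C/C) = f
  g <- vapply(p, function(pi)
    sample(c("C/C", "C/T", "T/T"), 1L,
           prob = c(pi^2, 2 * pi * (1 - pi), (1 - pi)^2)), "")
  data.frame(sample_id = sample_ids, hla_genotype = g,
             stringsAsFactors = FALSE)
}

draw_labels <- function(spec, n) {
  labels <- sample.int(spec$n_subgroups, n, replace = TRUE,
                       prob = spec$subgroup_proportions)
  if (length(unique(labels)) < spec$n_subgroups)
    stop("a subgroup received zero samples; increase n_samples")
  labels
}

#' Generate a synthetic discovery cohort
#'
#' Draws expression, clinical, survival and genotype data plus the ground
#' truth (planted labels, marker sets, hazards, shifts) from a
#' [cohort_spec()]. Expression is log-normal around subgroup-specific
#' block means: the immunoglobulin-like block is shifted
#' `-effect / 0 / +effect` across the poor / moderate / good subgroups,
#' the ALAS2-like block is up in the poor group and the NOG-like block up
#' in the good group. Sex-chromosome genes vary with the simulated sex,
#' and a volatile high-variance block mimics genes (interferon response,
#' haemoglobin) that fluctuate independently of subgroup.
#'
#' @param spec a [cohort_spec()].
#' @return list with `expression` ([expression_matrix()], raw TPM scale),
#'   `annotation` (gene_id / chromosome), `clinical` ([clinical_table()]),
#'   `survival`, `genotype` (data.frames) and `truth` (class
#'   `synthetic_truth`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    labels <- draw_labels(spec, n)
    sample_ids <- paste0("P", sprintf("%03d", seq_len(n)))
    sex <- rbinom(n, 1L, spec$female_fraction)  # 1 = female

    mb <- spec$marker_block_sizes
    gene_ids <- c(sprintf("IGVL%03d", seq_len(mb[["immunoglobulin"]])),
                  sprintf("ALAS2L%02d", seq_len(mb[["alas2"]])),
                  sprintf("NOGL%02d", seq_len(mb[["nog"]])))
    n_y <- spec$n_sex_genes %/% 2L
    n_x <- spec$n_sex_genes - n_y
    sex_ids <- c(sprintf("YG%03d", seq_len(n_y)),
                 sprintf("XG%03d", seq_len(n_x)))
    n_rest <- spec$n_genes - length(gene_ids) - spec$n_sex_genes
    rest_ids <- sprintf("G%04d", seq_len(n_rest))
    all_ids <- c(gene_ids, sex_ids, rest_ids)

    chrom <- c(sample(paste0("chr", 1:22), length(gene_ids), replace = TRUE),
               rep("chrY", n_y), rep("chrX", n_x),
               sample(paste0("chr", 1:22), n_rest, replace = TRUE))
    annotation <- data.frame(gene_id = all_ids, chromosome = chrom,
                             stringsAsFactors = FALSE)

    eff <- spec$marker_effect
    # per-gene x per-subgroup log-scale shifts (3-wide, mapped for 5
    # groups). The moderate subgroup's immunoglobulin pattern is MIXED:
    # alternating genes low/high, so its block mean is intermediate while
    # its expression profile is not collinear with the poor-good axis —
    # the "mixed gene expression pattern" such intermediate subgroups show.
    n_ig <- mb[["immunoglobulin"]]
    ig_mixed <- rep(c(-1, 1), length.out = n_ig) * eff
    shift3 <- rbind(
      cbind(rep(-eff, n_ig), ig_mixed, rep(eff, n_ig)),
      matrix(rep(c(eff, 0, 0), each = mb[["alas2"]]), ncol = 3),
      matrix(rep(c(0, 0, eff), each = mb[["nog"]]), ncol = 3))
    base_marker <- rnorm(nrow(shift3), 4.0, 0.3)
    logm_marker <- base_marker + shift3[, param_col(labels), drop = FALSE]
    vals_marker <- exp(logm_marker + rnorm(length(logm_marker), 0, spec$noise_sd))
    dim(vals_marker) <- c(nrow(shift3), n)

    # sex genes: chrY nearly silent in females, chrX higher in females
    base_y <- rnorm(n_y, 1.5, 0.3)
    logm_y <- outer(base_y, ifelse(sex == 1L, -4, 0), "+")
    base_x <- rnorm(n_x, 1.5, 0.3)
    logm_x <- outer(base_x, ifelse(sex == 1L, 0.7, 0), "+")
    vals_sex <- exp(rbind(logm_y, logm_x) +
                      rnorm((n_y + n_x) * n, 0, spec$noise_sd))

    # volatile block + ordinary background genes, no subgroup structure;
    # volatile genes are abundant (interferon-response/haemoglobin-like),
    # background genes span the expression-filter boundary
    sds <- c(rep(spec$volatile_sd, spec$n_volatile),
             rep(spec$noise_sd, n_rest - spec$n_volatile))
    base_rest <- c(rnorm(spec$n_volatile, 5.0, 0.3),
                   rnorm(n_rest - spec$n_volatile, 2.0, 0.8))
    vals_rest <- exp(base_rest + matrix(rnorm(n_rest * n, 0, sds),
                                        nrow = n_rest, ncol = n))

    values <- rbind(vals_marker, vals_sex, vals_rest)
    rownames(values) <- all_ids
    colnames(values) <- sample_ids

    clinical <- draw_clinical(spec, labels, prefix = "P")
    clinical$data$sex_female <- sex  # keep expression sex and clinical sex coherent
    surv <- draw_survival(spec, labels, sample_ids)
    geno <- draw_genotype(spec, labels, sample_ids)

    truth <- structure(list(
      labels = setNames(labels, sample_ids),
      subgroup_names = spec$subgroup_names,
      marker_genes = list(
        immunoglobulin = gene_ids[seq_len(mb[["immunoglobulin"]])],
        alas2 = gene_ids[mb[["immunoglobulin"]] + seq_len(mb[["alas2"]])],
        nog = gene_ids[mb[["immunoglobulin"]] + mb[["alas2"]] +
                         seq_len(mb[["nog"]])]),
      # genes whose planted level is UNIQUE to one subgroup (single-gene
      # one-vs-rest discriminators): the poor group is alone at the low
      # end of the ig genes the moderate group expresses highly (even
      # positions of the alternating pattern) and owns the ALAS2-like
      # block; symmetrically for the good group
      discriminators = list(
        poor = c(gene_ids[seq_len(mb[["immunoglobulin"]])][
          seq_len(mb[["immunoglobulin"]]) %% 2 == 0],
          gene_ids[mb[["immunoglobulin"]] + seq_len(mb[["alas2"]])]),
        good = c(gene_ids[seq_len(mb[["immunoglobulin"]])][
          seq_len(mb[["immunoglobulin"]]) %% 2 == 1],
          gene_ids[mb[["immunoglobulin"]] + mb[["alas2"]] +
                     seq_len(mb[["nog"]])])),
      sex_genes = sex_ids,
      sex = setNames(sex, sample_ids),
      planted_hazards = spec$hazard_per_subgroup,
      planted_clinical_shifts = spec$clinical_feature_specs,
      planted_genotype_freqs = spec$genotype_freqs),
      class = "synthetic_truth")

    list(expression = expression_matrix(values, "raw"),
         annotation = annotation, clinical = clinical,
         survival = surv, genotype = geno, truth = truth)
  })
}

#' Generate an independent clinical-only validation cohort
#'
#' Draws a second cohort (clinical + survival + genotype, no expression)
#' from the same generative model, with its own planted labels — the
#' substrate for transfer classification.
#'
#' @param spec the discovery [cohort_spec()] (shared feature dictionary).
#' @param n_samples validation cohort size (default 197).
#' @param seed seed; defaults to a stream independent of the discovery
#'   cohort's.
#' @return list with `clinical`, `survival`, `genotype`, `truth`.
#' @export
generate_validation_cohort <- function(spec, n_samples = 197L,
                                       seed = spec$seed + 104729L) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    labels <- draw_labels(spec, n_samples)
    sample_ids <- paste0("V", sprintf("%03d", seq_len(n_samples)))
    clinical <- draw_clinical(spec, labels, prefix = "V")
    surv <- draw_survival(spec, labels, sample_ids)
    geno <- draw_genotype(spec, labels, sample_ids)
    truth <- structure(list(labels = setNames(labels, sample_ids),
                            subgroup_names = spec$subgroup_names),
                       class = "synthetic_truth")
    list(clinical = clinical, survival = surv, genotype = geno,
         truth = truth)
  })
}
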