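# Survival validation layer: Kaplan-Meier curves, log-rank tests, Cox
# proportional-hazards models (Efron ties), and the categorical
# association tests used to compare risk-category and genotype
# proportions between subgroups. The estimators are the `survival`
# package's; this layer fixes conventions (time origin, event coding,
# tie handling) and returns flat result objects.

#' Assemble survival data
#'
#' @param time follow-up time in days (> 0).
#' @param event 1 = death/transplant, 0 = censored.
#' @param group group label per sample (e.g. subgroup).
#' @param sample_id optional sample identifiers.
#' @param covariates optional data.frame of covariates (age, sex, ...).
#' @param time_origin `"sampling"` or `"diagnosis"` — recorded so curves
#'   state which clock they run on.
#' @return data.frame of class `survival_data`.
#' @export
survival_data <- function(time, event, group = NULL, sample_id = NULL,
                          covariates = NULL,
                          time_origin = c("sampling", "diagnosis")) {
  time_origin <- match.arg(time_origin)
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  d <- data.frame(sample_id = sample_id %||% paste0("S", seq_along(time)),
                  time = as.numeric(time), event = as.integer(event),
                  stringsAsFactors = FALSE)
  if (!is.null(group)) d$group <- group
  if (!is.null(covariates)) d <- cbind(d, covariates)
  attr(d, "time_origin") <- time_origin
  class(d) <- c("survival_data", "data.frame")
  d
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_(t_i <= t) (1 - d_i / n_i)` with Greenwood standard
#' errors, per group if the data carry one.
#'
#' @param d a [survival_data()] (or data.frame with `time`, `event`, and
#'   optionally `group`).
#' @param by_group estimate one curve per group?
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`,
#'   `surv`, `std_err` (Greenwood SE of S); attribute `fit` keeps the
#'   underlying `survfit` object.
#' @export
km_estimate <- function(d, by_group = "group" %in% names(d)) {
  f <- if (by_group) survival::survfit(survival::Surv(time, event) ~ group,
                                       data = d)
       else survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  s <- summary(f, censored = TRUE)
  grp <- if (by_group) sub("^group=", "", as.character(s$strata))
         else rep("all", length(s$time))
  out <- data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                    n_event = s$n.event, surv = s$surv,
                    std_err = s$std.err, stringsAsFactors = FALSE)
  attr(out, "fit") <- f
  attr(out, "time_origin") <- attr(d, "time_origin")
  out
}

#' Survival probability at a time point, per group
#'
#' @param km result of [km_estimate()].
#' @param at time point (same units as the data).
#' @return named numeric vector of S(at) per group.
#' @export
km_survival_at <- function(km, at) {
  vapply(split(km, km$group), function(g) {
    g <- g[g$n_event > 0, , drop = FALSE]  # steps happen at event times
    idx <- g$time <= at
    if (!any(idx)) 1 else g$surv[max(which(idx))]
  }, 0)
}

#' Log-rank test between survival groups
#'
#' @param d a [survival_data()] with a `group` column (>= 2 groups).
#' @return list with `statistic` (chi-square), `df`, `p`.
#' @export
logrank_test <- function(d) {
  if (length(unique(d$group)) < 2L) stop("need at least two groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd$n) - 1L
  list(statistic = as.numeric(sd$chisq), df = df,
       p = pchisq(as.numeric(sd$chisq), df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling (Breslow selectable).
#' Monotone-likelihood / non-converged coefficients are flagged via
#' `converged` and a warning rather than returned silently.
#'
#' @param d a [survival_data()].
#' @param covariates character vector of covariate columns in `d`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_result`: data.frame with per-covariate
#'   `log_hr`, `hr`, `se`, `ci_lower`, `ci_upper`, `p`; attributes
#'   `converged`, `ties`, `fit`.
#' @export
cox_fit <- function(d, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  const <- covariates[vapply(covariates, function(v)
    length(unique(d[[v]][!is.na(d[[v]])])) < 2L, TRUE)]
  if (length(const)) stop("constant covariate(s): ",
                          paste(const, collapse = ", "))
  fm <- as.formula(paste("survival::Surv(time, event) ~",
                         paste(covariates, collapse = " + ")))
  # convergence is re-checked below from the coefficients themselves, so
  # coxph's own "coefficient may be infinite" chatter is redundant here
  fit <- suppressWarnings(survival::coxph(fm, data = d, ties = ties))
  s <- summary(fit)
  converged <- all(is.finite(coef(fit))) && all(abs(coef(fit)) < 15)
  if (!converged)
    warning("possible monotone likelihood (complete separation); ",
            "hazard ratios unreliable")
  out <- data.frame(covariate = rownames(s$coefficients),
                    log_hr = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    se = s$coefficients[, "se(coef)"],
                    ci_lower = s$conf.int[, "lower .95"],
                    ci_upper = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  attr(out, "converged") <- isTRUE(converged)
  attr(out, "ties") <- ties
  attr(out, "fit") <- fit
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Two-sample test for equality of proportions (continuity corrected)
#'
#' @param x1,n1 successes and total in group 1.
#' @param x2,n2 successes and total in group 2.
#' @return list with `statistic` (chi-square), `p`, `estimate`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group totals must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) stop("counts out of range")
  pt <- prop.test(c(x1, x2), c(n1, n2), correct = TRUE)
  list(statistic = as.numeric(pt$statistic), p = pt$p.value,
       estimate = as.numeric(pt$estimate))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by hypergeometric enumeration (all tables with the observed
#' margins whose probability does not exceed the observed table's).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  fisher.test(tab)$p.value
}
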