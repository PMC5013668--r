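#' Beta posterior for the per-sample detection probability
#'
#' Conjugate update of a Beta prior on P, the probability that a TP53
#' mutation is detected in a single normal cfDNA sample, after observing
#' `detections` detections in `n_samples` samples. With the default uniform
#' prior Beta(1, 1) and zero detections among nine healthy-donor samples the
#' posterior is Beta(1, 10).
#'
#' @param detections Number of samples with a detection (0 <= detections <=
#'   n_samples).
#' @param n_samples Number of samples observed.
#' @param prior_alpha,prior_beta Beta prior shape parameters (default the
#'   uniform prior, 1 and 1).
#' @return An object of class `beta_posterior` with fields `alpha` and `beta`.
#' @examples
#' beta_posterior(0, 9) # Beta(1, 10)
#' @export
beta_posterior <- function(detections, n_samples, prior_alpha = 1,
                           prior_beta = 1) {
  if (detections < 0 || n_samples < 0 || detections > n_samples) {
    abort("need 0 <= detections <= n_samples")
  }
  if (prior_alpha <= 0 || prior_beta <= 0) abort("prior shapes must be positive")
  structure(
    list(
      alpha = prior_alpha + detections,
      beta = prior_beta + n_samples - detections
    ),
    class = "beta_posterior"
  )
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) posterior for detection probability P\n",
              x$alpha, x$beta))
  cat(sprintf("  posterior mean %.4g\n", x$alpha / (x$alpha + x$beta)))
  invisible(x)
}

#' @method tidy beta_posterior
#' @export
tidy.beta_posterior <- function(x, ...) {
  tibble(
    alpha = x$alpha,
    beta = x$beta,
    mean = x$alpha / (x$alpha + x$beta)
  )
}

#' Beta-binomial posterior predictive mass function
#'
#' Probability of exactly `k` detections in `n` future samples when the
#' per-sample detection probability carries a Beta posterior:
#' `C(n,k) B(alpha+k, beta+n-k) / B(alpha, beta)`, evaluated in log space.
#'
#' @param k Number of detections (vectorised), 0 <= k <= n.
#' @param n Number of future samples.
#' @param posterior A [beta_posterior()].
#' @return Probabilities.
#' @examples
#' beta_binomial_pmf(0, 14, beta_posterior(0, 9)) # 10/24
#' @export
beta_binomial_pmf <- function(k, n, posterior) {
  stopifnot(inherits(posterior, "beta_posterior"))
  if (any(k < 0) || any(k > n)) abort("need 0 <= k <= n")
  a <- posterior$alpha
  b <- posterior$beta
  exp(lchoose(n, k) + lbeta(a + k, b + n - k) - lbeta(a, b))
}

#' Beta-binomial upper-tail posterior predictive probability
#'
#' `P(X >= k)` for the posterior predictive distribution of
#' [beta_binomial_pmf()]: the probability of observing at least `k`
#' detections in `n` samples by chance.
#'
#' @inheritParams beta_binomial_pmf
#' @return `P(X >= k)`.
#' @export
beta_binomial_sf <- function(k, n, posterior) {
  stopifnot(inherits(posterior, "beta_posterior"))
  if (any(k < 0) || any(k > n)) abort("need 0 <= k <= n")
  vapply(k, function(ki) sum(beta_binomial_pmf(ki:n, n, posterior)), numeric(1))
}

#' Fold change between two predictive probabilities
#'
#' Ratio of the baseline-arm to the treatment-arm posterior predictive
#' probability; a large ratio says the treatment-arm detection count is far
#' less likely under the no-effect (healthy-donor) detection rate.
#'
#' @param p_baseline,p_treatment Predictive probabilities; `p_treatment` must
#'   be positive.
#' @return `p_baseline / p_treatment`.
#' @export
predictive_fold_change <- function(p_baseline, p_treatment) {
  if (any(p_treatment <= 0)) abort("p_treatment must be positive")
  p_baseline / p_treatment
}

#' Posterior predictive test for emergence of detections under treatment
#'
#' Convenience wrapper tying the Bayesian pieces together: a healthy-donor
#' panel fixes the Beta posterior for the per-sample detection probability;
#' the baseline and treatment detection counts are then scored against that
#' posterior predictive distribution. Both the exact-count probability
#' (`pmf`) and the at-least-k tail (`sf`) are reported for the treatment arm,
#' together with the fold changes relative to the baseline probability.
#'
#' @param panel_detections,panel_n Detections and sample count in the
#'   healthy-donor panel used for the conjugate update.
#' @param baseline_detections,baseline_n Detections and sample count among
#'   pre-treatment (baseline) patient samples.
#' @param treatment_detections,treatment_n Detections and sample count among
#'   on-treatment patient samples.
#' @param prior_alpha,prior_beta Beta prior (default uniform).
#' @return A one-row tibble with the posterior shapes, the baseline
#'   predictive probability, the treatment predictive pmf and sf, and the two
#'   fold changes.
#' @export
detection_predictive_test <- function(panel_detections, panel_n,
                                      baseline_detections, baseline_n,
                                      treatment_detections, treatment_n,
                                      prior_alpha = 1, prior_beta = 1) {
  post <- beta_posterior(panel_detections, panel_n, prior_alpha, prior_beta)
  p_base <- beta_binomial_pmf(baseline_detections, baseline_n, post)
  p_treat_pmf <- beta_binomial_pmf(treatment_detections, treatment_n, post)
  p_treat_sf <- beta_binomial_sf(treatment_detections, treatment_n, post)
  tibble(
    posterior_alpha = post$alpha,
    posterior_beta = post$beta,
    p_baseline = p_base,
    p_treatment_pmf = p_treat_pmf,
    p_treatment_sf = p_treat_sf,
    fold_change_pmf = predictive_fold_change(p_base, p_treat_pmf),
    fold_change_sf = predictive_fold_change(p_base, p_treat_sf)
  )
}

#' Exact lower binomial tail
#'
#' `P(X <= k)` for `X ~ Binomial(n, p)`. For the fair-coin case `p = 1/2` the
#' tail is the exact rational `sum(choose(n, 0:k)) / 2^n`, evaluated as such:
#' for the n encountered here the binomial coefficients, their partial sums
#' and the power-of-two denominator are all exactly representable in double
#' precision, so the result is exact to the last bit. Other `p` use
#' [stats::pbinom()]. Used for the transversion-spectrum test: is the
#' observed transversion count compatible with a 50% transversion frequency?
#'
#' @param k Observed count, 0 <= k <= n.
#' @param n Number of trials.
#' @param p Success probability in (0, 1).
#' @return `P(X <= k)`.
#' @examples
#' binomial_tail_lower(3, 15, 0.5) # 576/32768 = 0.017578125
#' @export
binomial_tail_lower <- function(k, n, p = 0.5) {
  if (k < 0 || k > n) abort("need 0 <= k <= n")
  if (p <= 0 || p >= 1) abort("p must lie in (0, 1)")
  if (p == 0.5 && n <= 1000) {
    sum(choose(n, 0:k)) * 2^(-n)
  } else {
    stats::pbinom(k, n, p)
  }
}

#' Pearson correlation test with Fisher-Z confidence interval
#'
#' Pearson correlation between two numeric vectors with the standard t test
#' on n-2 degrees of freedom and the asymptotic 95% confidence interval from
#' the Fisher Z-transform, `tanh(atanh(r) +/- z_0.975 / sqrt(n - 3))`
#' (as computed by [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length n >= 3 with non-zero variance.
#' @param conf_level Confidence level for the Fisher-Z interval.
#' @return A one-row tibble: `estimate` (r), `n`, `df`, `statistic` (t),
#'   `p.value` (two-sided), `conf.low`, `conf.high` (`NA` when n < 4; equal to
#'   `estimate` when |r| = 1, where the interval degenerates to a point).
#' @export
pearson_test <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3) abort("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("constant input: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf_level)
  r <- unname(ct$estimate)
  ci <- if (n >= 4) {
    if (abs(r) >= 1 - 1e-15) c(r, r) else as.numeric(ct$conf.int)
  } else {
    c(NA_real_, NA_real_)
  }
  tibble(
    estimate = r,
    n = n,
    df = n - 2L,
    statistic = unname(ct$statistic),
    p.value = ct$p.value,
    conf.low = ci[1],
    conf.high = ci[2]
  )
}

#' Linear-log regression of tumour-size change on mutation burden
#'
#' Ordinary least squares of the percent change in tumour size by CT on the
#' base-10 log of the allele burden (in percent), via [stats::lm()]. The
#' association is declared significant only when both the overall regression
#' F test and the slope t test reject at `alpha`. Only samples with positive
#' burden (i.e. detected samples) enter; a non-positive burden is an error
#' instructing the caller to restrict to detected samples first.
#'
#' @param data A data frame with the burden and CT-change columns, e.g. the
#'   output of [burden_series()] restricted to detected samples.
#' @param burden_col,ct_col Column names (defaults `burden_pct`,
#'   `ct_change_percent`).
#' @param alpha Significance level for the joint F/t rule.
#' @return An object of class `burden_lm`; see [tidy.burden_lm()] and
#'   [glance.burden_lm()].
#' @export
burden_regression <- function(data, burden_col = "burden_pct",
                              ct_col = "ct_change_percent", alpha = 0.05) {
  burden <- data[[burden_col]]
  ct <- data[[ct_col]]
  if (is.null(burden) || is.null(ct)) {
    abort(paste0("data must contain columns '", burden_col, "' and '", ct_col, "'"))
  }
  if (length(burden) < 3) abort("need at least 3 observations")
  if (anyNA(burden) || anyNA(ct)) abort("burden and CT change must be non-missing")
  if (any(burden <= 0)) {
    abort(paste0(
      "non-positive burden: log10 undefined; restrict to detected samples ",
      "(burden_pct > 0) before regressing"
    ))
  }
  df <- data.frame(ct_change = ct, log10_burden = log10(burden))
  fit <- stats::lm(ct_change ~ log10_burden, data = df)
  sm <- suppressWarnings(summary(fit))
  r2 <- if (is.nan(sm$r.squared)) 0 else sm$r.squared
  f <- sm$fstatistic
  f_p <- if (is.null(f)) NA_real_ else {
    unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE))
  }
  slope_row <- stats::coef(sm)["log10_burden", ]
  structure(
    list(
      fit = fit,
      n = length(ct),
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      slope_se = unname(slope_row["Std. Error"]),
      slope_t = unname(slope_row["t value"]),
      slope_p = unname(slope_row["Pr(>|t|)"]),
      f_stat = if (is.null(f)) NA_real_ else unname(f[1]),
      f_p = f_p,
      r_squared = r2,
      alpha = alpha,
      significant = isTRUE(f_p < alpha) &&
        isTRUE(unname(slope_row["Pr(>|t|)"]) < alpha)
    ),
    class = "burden_lm"
  )
}

#' @export
print.burden_lm <- function(x, ...) {
  cat("Linear-log regression: CT change ~ log10(allele burden %)\n")
  cat(sprintf("  n = %d, intercept = %.4g, slope = %.4g (t = %.3g, p = %.3g)\n",
              x$n, x$intercept, x$slope, x$slope_t, x$slope_p))
  cat(sprintf("  F = %.3g (p = %.3g), R^2 = %.3f, significant (joint rule): %s\n",
              x$f_stat, x$f_p, x$r_squared, x$significant))
  invisible(x)
}

#' @describeIn burden_regression Coefficient-level summary (one row per term).
#' @param x A `burden_lm` object.
#' @param ... Unused.
#' @method tidy burden_lm
#' @export
tidy.burden_lm <- function(x, ...) {
  sm <- stats::coef(summary(x$fit))
  tibble(
    term = c("intercept", "log10_burden"),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @describeIn burden_regression Model-level summary (one row).
#' @method glance burden_lm
#' @export
glance.burden_lm <- function(x, ...) {
  tibble(
    n = x$n,
    r_squared = x$r_squared,
    f_stat = x$f_stat,
    f_p = x$f_p,
    slope = x$slope,
    slope_se = x$slope_se,
    slope_t = x$slope_t,
    slope_p = x$slope_p,
    significant = x$significant
  )
}

#' Two-sample t test with group summaries
#'
#' Welch's unequal-variance t test by default (set `equal_var = TRUE` for the
#' pooled test), via [stats::t.test()], reporting the group means and
#' standard deviations alongside, as used for comparing pharmacokinetics and
#' tumour volume between patients with and without emergent mutations.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @param equal_var Assume equal variances (default `FALSE`, Welch).
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `mean_a`, `sd_a`,
#'   `n_a`, `mean_b`, `sd_b`, `n_b`.
#' @export
two_sample_t <- function(a, b, equal_var = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 observations")
  }
  tt <- stats::t.test(a, b, var.equal = equal_var)
  tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
    mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b)
  )
}

#' MDM2 copy number by the delta-delta-Ct method
#'
#' Relative quantitation from qPCR triplicates: `delta_ct = mean(Ct_target) -
#' mean(Ct_reference)`, `delta_delta_ct = delta_ct - calibrator_delta_ct`
#' (the calibrator is a normal diploid donor DNA), and `copy_number = 2 *
#' 2^(-delta_delta_ct)` (the factor 2 is the diploid calibrator copy count).
#' A sample is called amplified when the copy number strictly exceeds 5.
#'
#' @param ct_target Ct triplicate for the target (MDM2) assay. Fewer than 3
#'   replicates are tolerated with a warning; an empty vector is an error.
#' @param ct_reference Ct triplicate for the reference (RNase P) assay.
#' @param calibrator_delta_ct The calibrator sample's `delta_ct`.
#' @return A one-row tibble: `delta_ct`, `delta_delta_ct`, `copy_number`,
#'   `amplified`.
#' @examples
#' mdm2_copy_number(c(25, 25, 25), c(27, 27, 27), calibrator_delta_ct = -2)
#' @export
mdm2_copy_number <- function(ct_target, ct_reference, calibrator_delta_ct) {
  if (length(ct_target) == 0 || length(ct_reference) == 0) {
    abort("Ct replicate vectors must be non-empty")
  }
  if (length(ct_target) < 3 || length(ct_reference) < 3) {
    warn("fewer than 3 Ct replicates; using the mean of those provided")
  }
  delta_ct <- mean(ct_target) - mean(ct_reference)
  ddct <- delta_ct - calibrator_delta_ct
  cn <- 2 * 2^(-ddct)
  tibble(
    delta_ct = delta_ct,
    delta_delta_ct = ddct,
    copy_number = cn,
    amplified = cn > 5
  )
}
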