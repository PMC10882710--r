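# broom-style tidiers for the package's fitted objects.

#' Tidy an MR estimate
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A one-row tibble: `term, estimate, std.error, conf.low, conf.high,
#'   p.value, n_snp, model`.
#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble(
    term = x$method, estimate = x$estimate, std.error = x$se,
    conf.low = x$ci_lower, conf.high = x$ci_upper,
    p.value = x$pval, n_snp = x$n_snp, model = x$model
  )
}

#' @rdname tidy.mr_estimate
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble(
    method = x$method, n_snp = x$n_snp, model = x$model,
    Q = x$extras$Q %||% NA_real_, Q_df = x$extras$Q_df %||% NA_real_,
    egger_intercept = x$extras$egger_intercept %||% NA_real_,
    intercept_p = x$extras$intercept_p %||% NA_real_
  )
}

#' Tidy a survey-weighted GLM
#'
#' @param x An `svy_fit` from [weighted_glm()].
#' @param exponentiate Report odds ratios instead of log-odds.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term, estimate,
#'   std.error, statistic, p.value, conf.low, conf.high`.
#' @export
tidy.svy_fit <- function(x, exponentiate = FALSE, ...) {
  est <- x$coefficients
  se <- x$se
  out <- tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(est / se), p.value = norm_p(est, se),
    conf.low = unname(est - Z975 * se), conf.high = unname(est + Z975 * se)
  )
  if (exponentiate) {
    out <- mutate(out, across(c("estimate", "conf.low", "conf.high"), exp))
  }
  out
}

#' @rdname tidy.svy_fit
#' @export
glance.svy_fit <- function(x, ...) {
  tibble(family = x$family, n = x$n, df_design = x$df_design,
         logLik = x$loglik, deviance = x$deviance)
}

#' Tidy an MR-PRESSO result
#'
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @return The per-SNP outlier-test table with the global p attached as a
#'   column.
#' @export
tidy.mr_presso <- function(x, ...) {
  mutate(x$per_snp, global_pval = x$global_pval)
}

#' @rdname tidy.mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble(global_pval = x$global_pval, n_outliers = length(x$outliers),
         corrected_estimate = x$corrected$estimate,
         corrected_se = x$corrected$se, n_sim = x$n_sim)
}
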