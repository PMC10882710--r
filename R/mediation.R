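# Mediation decomposition on the log-odds scale: product-method per-mediator
# indirect effects (alpha * beta), difference-method joint indirect effect
# (gamma - gamma*), proportions mediated with CIs, and odds-ratio conversion.

#' Product-method indirect effect
#'
#' The indirect effect of the exposure through one mediator:
#' `alpha * beta`, where `alpha` is the exposure -> mediator effect and `beta`
#' the mediator -> outcome effect conditional on the exposure. The default
#' delta-method SE is `sqrt(alpha^2 se_beta^2 + beta^2 se_alpha^2)`
#' (independent samples); `se_method = "bootstrap"` resamples both
#' coefficients from independent normals.
#'
#' @param alpha,beta `mr_estimate`s (or `list(estimate=, se=)` /
#'   length-2 numerics).
#' @param se_method `"delta"` or `"bootstrap"`.
#' @param n_boot,seed Bootstrap controls.
#' @return A one-row tibble: `estimate, se, ci_lower, ci_upper, pval`.
#' @export
indirect_product <- function(alpha, beta, se_method = c("delta", "bootstrap"),
                             n_boot = 10000, seed = NULL) {
  se_method <- match.arg(se_method)
  a <- as_est_se(alpha, "alpha")
  b <- as_est_se(beta, "beta")
  est <- a$estimate * b$estimate
  se <- if (se_method == "delta") {
    sqrt(a$estimate^2 * b$se^2 + b$estimate^2 * a$se^2)
  } else {
    with_seed(seed, sd(rnorm(n_boot, a$estimate, a$se) * rnorm(n_boot, b$estimate, b$se)))
  }
  ci <- ci95(est, se)
  tibble(estimate = est, se = se, ci_lower = ci[1], ci_upper = ci[2],
         pval = norm_p(est, se))
}

#' Difference-method indirect effect
#'
#' The joint indirect effect as total minus direct, `gamma - gamma*`, with
#' `se = sqrt(se_total^2 + se_direct^2 - 2 cov)`. The two coefficients are
#' estimated from overlapping instrument sets, so they are positively
#' correlated; `cov = 0` (the default, their covariance being unreported in
#' summary-level work) therefore overstates the SE.
#'
#' @param total,direct `mr_estimate`s (or est/se pairs) on the same scale.
#' @param cov Covariance between the two estimates.
#' @return A one-row tibble: `estimate, se, ci_lower, ci_upper, pval`.
#' @export
indirect_difference <- function(total, direct, cov = 0) {
  t_ <- as_est_se(total, "total")
  d_ <- as_est_se(direct, "direct")
  est <- t_$estimate - d_$estimate
  v <- t_$se^2 + d_$se^2 - 2 * cov
  if (v < 0) abort("negative variance: cov is larger than the component variances allow")
  se <- sqrt(v)
  ci <- ci95(est, se)
  tibble(estimate = est, se = se, ci_lower = ci[1], ci_upper = ci[2],
         pval = norm_p(est, se))
}

#' Proportion of the total effect that is mediated
#'
#' `P = 100 * indirect / total` (percent). The delta-method CI uses
#' `var(P) ~ var(ind)/total^2 + ind^2 var(total)/total^4` (independence
#' approximation); the bootstrap alternative resamples both effects from
#' normals. When the indirect and total effects have opposite signs the
#' proportion is not interpretable as a share and `sign_consistent` is FALSE.
#'
#' @param indirect,total Effect/SE pairs (`mr_estimate`, list, or length-2
#'   numeric). `total` must be nonzero.
#' @param ci_method `"delta"` or `"bootstrap"`.
#' @param n_boot,seed Bootstrap controls.
#' @return A one-row tibble: `proportion` (percent), `se, ci_lower, ci_upper,
#'   sign_consistent`.
#' @export
proportion_mediated <- function(indirect, total, ci_method = c("delta", "bootstrap"),
                                n_boot = 10000, seed = NULL) {
  ci_method <- match.arg(ci_method)
  i_ <- as_est_se(indirect, "indirect")
  t_ <- as_est_se(total, "total")
  if (t_$estimate == 0) abort("total effect is zero; proportion undefined")
  p <- 100 * i_$estimate / t_$estimate
  if (ci_method == "delta") {
    v <- i_$se^2 / t_$estimate^2 + i_$estimate^2 * t_$se^2 / t_$estimate^4
    se <- 100 * sqrt(v)
    ci <- ci95(p, se)
  } else {
    boots <- with_seed(seed, {
      100 * rnorm(n_boot, i_$estimate, i_$se) / rnorm(n_boot, t_$estimate, t_$se)
    })
    se <- sd(boots)
    ci <- unname(quantile(boots, c(0.025, 0.975)))
  }
  tibble(proportion = p, se = se, ci_lower = ci[1], ci_upper = ci[2],
         sign_consistent = sign(i_$estimate) == sign(t_$estimate) ||
           i_$estimate == 0)
}

#' Convert a log-odds effect to an odds ratio
#'
#' @param beta Log-odds effect.
#' @param se Its SE (>= 0).
#' @return A one-row tibble: `or, ci_lower, ci_upper`.
#' @export
logodds_to_or <- function(beta, se = 0) {
  if (any(se < 0)) abort("se must be non-negative")
  beta <- unname(beta)
  se <- unname(se)
  tibble(or = exp(beta),
         ci_lower = exp(beta - Z975 * se),
         ci_upper = exp(beta + Z975 * se))
}

#' Full mediation decomposition
#'
#' Assembles, on the log-odds scale: the total effect `gamma`, the direct
#' effect `gamma*`, per-mediator product-method indirect effects
#' `alpha_m * beta_m`, the joint difference-method indirect effect
#' `gamma - gamma*`, and all proportions mediated with CIs. Proportions whose
#' indirect and total effects conflict in sign, or exceed 100% in magnitude,
#' are flagged (`suppression`), and indirect effects with p >= `null_alpha`
#' are labelled as showing no mediating effect rather than suppressed.
#'
#' @param total,direct `mr_estimate`s for gamma and gamma*.
#' @param alphas,betas Named lists of `mr_estimate`s (same mediator order):
#'   exposure -> mediator and adjusted mediator -> outcome effects.
#' @param se_method CI method passed to the indirect/proportion steps.
#' @param null_alpha Significance level for the "no mediating effect" label.
#' @param seed Seed for bootstrap CIs (unused under the delta method).
#' @return A `mediation_estimate` tibble, one row per mediator plus a
#'   `joint` row: `mediator, method, effect, se, ci_lower, ci_upper, pval,
#'   proportion, prop_ci_lower, prop_ci_upper, flag`.
#' @export
decompose_mediation <- function(total, direct, alphas, betas,
                                se_method = c("delta", "bootstrap"),
                                null_alpha = 0.05, seed = NULL) {
  se_method <- match.arg(se_method)
  if (length(alphas) != length(betas)) abort("alphas and betas differ in length")
  if (!identical(names(alphas), names(betas))) {
    abort("alphas and betas must carry identical mediator names, same order")
  }
  t_ <- as_est_se(total, "total")

  one_row <- function(name, ind, method) {
    pm <- proportion_mediated(list(estimate = ind$estimate, se = ind$se), t_,
                              ci_method = se_method, seed = seed)
    flag <- if (ind$pval >= null_alpha) {
      "no mediating effect"
    } else if (!pm$sign_consistent || abs(pm$proportion) > 100) {
      "suppression"
    } else {
      "ok"
    }
    tibble(
      mediator = name, method = method,
      effect = ind$estimate, se = ind$se,
      ci_lower = ind$ci_lower, ci_upper = ind$ci_upper, pval = ind$pval,
      proportion = pm$proportion,
      prop_ci_lower = pm$ci_lower, prop_ci_upper = pm$ci_upper,
      flag = flag
    )
  }

  rows <- imap(alphas, function(a, nm) {
    ind <- indirect_product(a, betas[[nm]], se_method = se_method, seed = seed)
    one_row(nm, ind, "product")
  })
  joint <- one_row("joint", indirect_difference(total, direct), "difference")
  out <- bind_rows(bind_rows(rows), joint)
  attr(out, "total") <- as_est_se(total)
  attr(out, "direct") <- as_est_se(direct)
  class(out) <- c("mediation_estimate", class(out))
  out
}
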