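# Survey-weighted observational arm: design-based logistic/linear regression
# (weighted IRLS point estimates, Taylor-linearized sandwich variance
# clustered on PSU within stratum), the education model ladder with trend
# tests, subgroup interaction tests, Rubin's-rules pooling, and the
# observational mediation coefficients (alpha', beta').

#' Survey-weighted generalized linear model
#'
#' Fits a weighted logistic (`binomial`) or linear (`gaussian`) regression by
#' weighted IRLS and computes design-based variance by Taylor linearization:
#' score contributions are summed within PSU and their between-PSU variance
#' within stratum (with the `n_h/(n_h - 1)` finite-cluster factor) is
#' sandwiched between the inverse weighted information. Without design
#' columns the variance is the weight-based HC0 sandwich. Coefficients and
#' design SEs are invariant to rescaling all weights by a constant, and
#' duplicating a row is identical to doubling its weight.
#'
#' @param data Survey data frame.
#' @param formula Model formula (factor reference levels are taken from the
#'   factor levels in `data`).
#' @param family `"binomial"` (logit link) or `"gaussian"`.
#' @param weights,strata,psu Names of the weight and design columns;
#'   `strata`/`psu` are used when both are present in `data`.
#' @return An `svy_fit`: coefficients, design-based `vcov` and SEs, weighted
#'   log-pseudo-likelihood (normalized weights), `n`, design df.
#' @export
weighted_glm <- function(data, formula, family = c("binomial", "gaussian"),
                         weights = "weight", strata = "stratum", psu = "psu") {
  family <- match.arg(family)
  data <- as_tibble(data)
  mf <- model.frame(formula, data = data, na.action = stats::na.omit)
  kept <- as.integer(rownames(mf))
  X <- model.matrix(formula, mf)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.null(data[[weights]])) abort(sprintf("weight column '%s' not found", weights))
  # fit on weights normalized to mean 1: coefficients and the linearized
  # variance are invariant to the scale of the weights, and IRLS is
  # numerically stable regardless of the population total
  w <- data[[weights]][kept]
  w <- w / mean(w)
  if (family == "binomial" && length(unique(y)) < 2) {
    abort("outcome is degenerate (single observed value)")
  }
  fam <- if (family == "binomial") quasibinomial() else gaussian()
  fit <- suppressWarnings(glm.fit(X, y, weights = w, family = fam))
  if (!fit$converged) {
    abort(sprintf("IRLS did not converge (last deviance %.4g)", fit$deviance))
  }
  mu <- fit$fitted.values
  if (family == "binomial" && any(mu > 1 - 1e-8 | mu < 1e-8) &&
      max(abs(fit$coefficients)) > 15) {
    abort("perfect separation detected")
  }
  beta <- fit$coefficients
  # working-model information and per-unit score contributions
  v_mu <- if (family == "binomial") mu * (1 - mu) else rep(1, length(mu))
  A <- crossprod(X, X * (w * v_mu))
  scores <- X * (w * (y - mu))
  has_design <- strata %in% names(data) && psu %in% names(data)
  if (has_design) {
    str_v <- as.character(data[[strata]][kept])
    psu_v <- paste(str_v, as.character(data[[psu]][kept]), sep = "\r")
    z <- rowsum(scores, psu_v)
    psu_stratum <- sub("\r.*$", "", rownames(z))
    G <- matrix(0, ncol(X), ncol(X))
    n_psu_total <- 0L
    for (hstr in unique(psu_stratum)) {
      zh <- z[psu_stratum == hstr, , drop = FALSE]
      nh <- nrow(zh)
      n_psu_total <- n_psu_total + nh
      if (nh < 2) next # single-PSU stratum contributes no variance
      zc <- sweep(zh, 2, colMeans(zh))
      G <- G + crossprod(zc) * nh / (nh - 1)
    }
    df_design <- n_psu_total - length(unique(psu_stratum))
  } else {
    G <- crossprod(scores)
    df_design <- length(y) - ncol(X)
  }
  Ainv <- tryCatch(chol2inv(chol(A)), error = function(e) solve(A))
  V <- Ainv %*% G %*% Ainv
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  # pseudo-log-likelihood on weights normalized to mean 1 (scale-free)
  wn <- w / mean(w)
  ll <- if (family == "binomial") {
    sum(wn * (y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12))))
  } else {
    s2 <- sum(wn * (y - mu)^2) / sum(wn)
    -0.5 * sum(wn) * (log(2 * pi * s2) + 1)
  }
  structure(
    list(
      coefficients = beta, vcov = V, se = sqrt(pmax(diag(V), 0)),
      family = family, formula = formula,
      loglik = ll, deviance = fit$deviance,
      n = length(y), df_design = df_design,
      fitted = mu, X = X, y = y, w = w
    ),
    class = "svy_fit"
  )
}

#' @export
print.svy_fit <- function(x, ...) {
  cat(sprintf("<svy_fit> %s, n = %d, design df = %d\n",
              x$family, x$n, x$df_design))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
coef.svy_fit <- function(object, ...) object$coefficients

#' @export
vcov.svy_fit <- function(object, ...) object$vcov

#' Education model ladder
#'
#' Fits a sequence of increasingly adjusted survey-weighted logistic models of
#' the outcome on education and reports the odds ratio per education level,
#' plus a trend test in which education enters as a single ordinal 0/1/2
#' term.
#'
#' @param data Survey data frame with an `education` factor and binary
#'   outcome.
#' @param ladder Named list of model formulas, each containing `education`.
#' @param education Name of the education column.
#' @param ... Passed to [weighted_glm()].
#' @return A tibble: `model, level, or, ci_lower, ci_upper, pval` with one
#'   `trend` row per model.
#' @export
model_ladder <- function(data, ladder, education = "education", ...) {
  data <- as_tibble(data)
  data[[education]] <- factor(data[[education]], ordered = FALSE,
                              levels = levels(factor(data[[education]])))
  map_dfr(names(ladder), function(nm) {
    f <- ladder[[nm]]
    fit <- weighted_glm(data, f, family = "binomial", ...)
    idx <- grep(paste0("^", education), names(fit$coefficients))
    rows <- map_dfr(idx, function(i) {
      est <- fit$coefficients[i]
      se <- fit$se[i]
      orr <- logodds_to_or(est, se)
      tibble(model = nm,
             level = sub(paste0("^", education), "", names(fit$coefficients)[i]),
             or = orr$or, ci_lower = orr$ci_lower, ci_upper = orr$ci_upper,
             pval = norm_p(est, se))
    })
    # trend: replace the factor with its ordinal 0/1/2 code
    data$`.edu_trend` <- as.integer(data[[education]]) - 1L
    f_trend <- update(f, as.formula(sprintf(". ~ . - %s + .edu_trend", education)))
    fit_t <- weighted_glm(data, f_trend, family = "binomial", ...)
    est_t <- fit_t$coefficients[[".edu_trend"]]
    se_t <- fit_t$se[[".edu_trend"]]
    bind_rows(rows, tibble(model = nm, level = "trend",
                           or = exp(est_t), ci_lower = exp(est_t - Z975 * se_t),
                           ci_upper = exp(est_t + Z975 * se_t),
                           pval = norm_p(est_t, se_t)))
  })
}

#' Subgroup analysis with interaction tests
#'
#' Refits the education model within each level of a stratification variable
#' (dropping that variable from the covariate set) and tests the
#' education-by-subgroup interaction two ways: a likelihood-ratio test on the
#' weighted pseudo-log-likelihood (2 x difference, chi-squared with the added
#' parameter count as df --- the conventional choice under informative
#' designs, with the caveat that pseudo-likelihoods are not true likelihoods)
#' and a Wald test on the interaction coefficients.
#'
#' @param data Survey data frame.
#' @param base_formula Outcome model including `education` and the subgroup
#'   variable among covariates.
#' @param subgroup_var Name of the (categorical) stratification column.
#' @param education Name of the education column.
#' @param ... Passed to [weighted_glm()].
#' @return A list: `strata` (tibble of per-stratum education ORs; degenerate
#'   strata skipped with a warning) and `interaction` (tibble with `lrt_p`,
#'   `wald_p`, df).
#' @export
subgroup_interaction <- function(data, base_formula, subgroup_var,
                                 education = "education", ...) {
  data <- as_tibble(data)
  strat_formula <- update(base_formula,
                          as.formula(sprintf(". ~ . - %s", subgroup_var)))
  levels_sub <- unique(as.character(data[[subgroup_var]]))
  strata_rows <- map_dfr(levels_sub, function(lv) {
    sub <- data[as.character(data[[subgroup_var]]) == lv, , drop = FALSE]
    fit <- tryCatch(weighted_glm(sub, strat_formula, family = "binomial", ...),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warn(sprintf("stratum '%s = %s' skipped (degenerate fit)", subgroup_var, lv))
      return(tibble())
    }
    idx <- grep(paste0("^", education), names(fit$coefficients))
    map_dfr(idx, function(i) {
      orr <- logodds_to_or(fit$coefficients[i], fit$se[i])
      tibble(subgroup = lv,
             level = sub(paste0("^", education), "", names(fit$coefficients)[i]),
             or = orr$or, ci_lower = orr$ci_lower, ci_upper = orr$ci_upper,
             pval = norm_p(fit$coefficients[i], fit$se[i]), n = fit$n)
    })
  })
  fit0 <- weighted_glm(data, base_formula, family = "binomial", ...)
  f1 <- update(base_formula,
               as.formula(sprintf(". ~ . + %s:%s", education, subgroup_var)))
  fit1 <- weighted_glm(data, f1, family = "binomial", ...)
  df <- length(fit1$coefficients) - length(fit0$coefficients)
  lrt <- 2 * (fit1$loglik - fit0$loglik)
  idx_int <- setdiff(names(fit1$coefficients), names(fit0$coefficients))
  bint <- fit1$coefficients[idx_int]
  vint <- fit1$vcov[idx_int, idx_int, drop = FALSE]
  wald <- as.numeric(t(bint) %*% solve(vint, bint))
  # F reference with design df: the chi-squared reference is anti-conservative
  # when the design variance rests on few PSUs
  df2 <- max(fit1$df_design - df + 1, 1)
  list(
    strata = strata_rows,
    interaction = tibble(
      lrt_stat = lrt, df = df, lrt_p = pchisq(lrt, df, lower.tail = FALSE),
      wald_stat = wald,
      wald_p = stats::pf(wald / df, df, df2, lower.tail = FALSE)
    )
  )
}

#' Rubin's rules for pooling multiply imputed estimates
#'
#' Pools `m` per-dataset estimates: pooled mean, total variance
#' `W + (1 + 1/m) B` (within + between components), and the standard
#' small-sample df `(m - 1)(1 + W / ((1 + 1/m) B))^2`.
#'
#' @param estimates,variances Numeric vectors of equal length `m >= 2`.
#' @return A one-row tibble: `pooled, total_var, se, df, ci_lower, ci_upper,
#'   pval` (t reference).
#' @export
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2 || length(variances) != m) {
    abort("need m >= 2 estimates with matching variances")
  }
  pooled <- mean(estimates)
  W <- mean(variances)
  B <- var(estimates)
  total_var <- W + (1 + 1 / m) * B
  df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
  se <- sqrt(total_var)
  tq <- if (is.finite(df)) stats::qt(0.975, df) else Z975
  pval <- if (is.finite(df)) 2 * stats::pt(-abs(pooled / se), df) else norm_p(pooled, se)
  tibble(pooled = pooled, total_var = total_var, se = se, df = df,
         ci_lower = pooled - tq * se, ci_upper = pooled + tq * se, pval = pval)
}

#' Observational mediation coefficients
#'
#' Estimates the two regression coefficients the observational mediation
#' decomposition needs: `alpha'`, the association of (binary, above-high-school)
#' education with the mediator --- weighted logistic for ever-smoking, weighted
#' linear for BMI --- and `beta'`, the mediator's coefficient in the outcome
#' model that also adjusts for education and the covariates.
#'
#' @param data Survey data frame (columns as produced by [simulate_survey()]).
#' @param mediator `"smoking"` (ever vs never) or `"bmi"`.
#' @param covariates Character vector of adjustment columns.
#' @param ... Passed to [weighted_glm()].
#' @return A list of `mr_estimate`-shaped lists `alpha` and `beta`
#'   (estimate/se/ci/pval), plus the underlying `svy_fit`s.
#' @export
observational_mediation <- function(data, mediator = c("smoking", "bmi"),
                                    covariates = c("age", "sex", "race", "marital",
                                                   "income", "alcohol", "activity",
                                                   "tv_hours", "htn_dm"),
                                    ...) {
  mediator <- match.arg(mediator)
  data <- as_tibble(data)
  data$edu_above_hs <- as.integer(as.character(data$education) == ">HS")
  data$smoke_ever <- as.integer(as.character(data$smoking) != "never")
  med_col <- if (mediator == "smoking") "smoke_ever" else "bmi"
  fam_med <- if (mediator == "smoking") "binomial" else "gaussian"
  f_alpha <- reformulate(c("edu_above_hs", covariates), response = med_col)
  fit_a <- weighted_glm(data, f_alpha, family = fam_med, ...)
  f_beta <- reformulate(c(med_col, "edu_above_hs", covariates), response = "lbp")
  fit_b <- weighted_glm(data, f_beta, family = "binomial", ...)
  grab <- function(fit, term, label) {
    est <- fit$coefficients[[term]]
    se <- fit$se[[term]]
    new_mr_estimate(label, est, se, n_snp = NA_integer_, model = "survey")
  }
  list(
    alpha = grab(fit_a, "edu_above_hs", paste0("alpha_prime:", mediator)),
    beta = grab(fit_b, med_col, paste0("beta_prime:", mediator)),
    fit_alpha = fit_a, fit_beta = fit_b
  )
}
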