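# Univariable two-sample MR estimators and sensitivity diagnostics:
# Wald ratio, IVW, MR-Egger, weighted median, weighted mode, Cochran's Q,
# leave-one-out, MR-PRESSO-style outlier handling, and the sample-overlap
# bias/type-I-error approximation.

#' Per-SNP Wald ratio
#'
#' The single-instrument causal estimate `by / bx`. The default first-order SE
#' `|se_y / bx|` ignores uncertainty in `bx`; `se_method = "second"` adds the
#' delta-method term for `se_x`.
#'
#' @param bx,se_x Exposure effect and SE (`bx` must be nonzero).
#' @param by,se_y Outcome effect and SE.
#' @param se_method `"first"` or `"second"` order delta SE.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(bx, se_x, by, se_y, se_method = c("first", "second")) {
  se_method <- match.arg(se_method)
  if (bx == 0) abort("wald_ratio undefined for bx = 0")
  est <- by / bx
  se <- switch(se_method,
    first = abs(se_y / bx),
    second = sqrt(se_y^2 / bx^2 + by^2 * se_x^2 / bx^4)
  )
  new_mr_estimate("wald_ratio", est, se, n_snp = 1L, model = se_method)
}

ivw_sums <- function(h) {
  w <- 1 / h$se_y^2
  list(w = w, sxx = sum(w * h$bx^2), sxy = sum(w * h$bx * h$by))
}

#' Inverse-variance-weighted estimator
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_y^2`, the primary two-sample MR estimator:
#' `estimate = sum(w bx by) / sum(w bx^2)`, fixed-effect
#' `SE = sum(w bx^2)^(-1/2)`. Under the default multiplicative random-effects
#' model the SE is inflated by `max(1, sqrt(Q/(n-1)))`, i.e. random effects
#' engage exactly when heterogeneity exceeds its expectation. A single SNP
#' delegates to [wald_ratio()].
#'
#' @param h Harmonized set (`bx, se_x, by, se_y`).
#' @param model `"multiplicative_re"` (default) or `"fixed"`.
#' @return An `mr_estimate` with `Q` and `Q_df` in `$extras`.
#' @export
mr_ivw <- function(h, model = c("multiplicative_re", "fixed")) {
  model <- match.arg(model)
  h <- as_mr_harmonized(h)
  n <- nrow(h)
  if (n == 0) abort("empty harmonized set")
  if (all(h$bx == 0)) abort("all exposure effects are zero")
  if (n == 1) return(wald_ratio(h$bx, h$se_x, h$by, h$se_y))
  s <- ivw_sums(h)
  est <- s$sxy / s$sxx
  se_fixed <- 1 / sqrt(s$sxx)
  q <- sum(s$w * (h$by - est * h$bx)^2)
  se <- if (model == "multiplicative_re") {
    se_fixed * max(1, sqrt(q / (n - 1)))
  } else {
    se_fixed
  }
  new_mr_estimate("ivw", est, se, n_snp = n, model = model,
                  extras = list(Q = q, Q_df = n - 1, se_fixed = se_fixed))
}

#' MR-Egger regression
#'
#' Weighted regression of `by` on `bx` *with* intercept (weights `1/se_y^2`)
#' after orienting all exposure effects non-negative. The slope is the causal
#' estimate; a nonzero intercept indicates directional pleiotropy and its
#' test is reported in `$extras` (`egger_intercept`, `intercept_se`,
#' `intercept_p`).
#'
#' @param h Harmonized set with at least 3 SNPs.
#' @return An `mr_estimate`.
#' @export
mr_egger <- function(h) {
  h <- as_mr_harmonized(h)
  n <- nrow(h)
  if (n < 3) abort("MR-Egger needs at least 3 SNPs")
  flip <- h$bx < 0
  bx <- ifelse(flip, -h$bx, h$bx)
  by <- ifelse(flip, -h$by, h$by)
  if (sd(bx) == 0) abort("degenerate exposure effects: zero variance")
  w <- 1 / h$se_y^2
  X <- cbind(1, bx)
  fit <- lm.wfit(X, by, w)
  cf <- fit$coefficients
  q <- sum(w * fit$residuals^2)
  scale <- max(1, sqrt(q / (n - 2)))
  xtx_inv <- chol2inv(chol(crossprod(X, X * w)))
  se <- sqrt(diag(xtx_inv)) * scale
  new_mr_estimate(
    "mr_egger", cf[[2]], se[[2]], n_snp = n, model = "multiplicative_re",
    extras = list(
      egger_intercept = cf[[1]], intercept_se = se[[1]],
      intercept_p = norm_p(cf[[1]], se[[1]]),
      Q = q, Q_df = n - 2
    )
  )
}

ratio_set <- function(h) {
  if (any(h$bx == 0)) {
    h <- h[h$bx != 0, , drop = FALSE]
  }
  ratio <- h$by / h$bx
  # first-order delta SE of the ratio
  se <- sqrt(h$se_y^2 / h$bx^2 + (h$by^2 * h$se_x^2) / h$bx^4)
  list(ratio = ratio, se = se, h = h)
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  k <- max(which(s < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted median estimator
#'
#' Orders the per-SNP Wald ratios and returns the value where the cumulative
#' inverse-variance weight crosses one half (linear interpolation between
#' bracketing ratios). Consistent when at least half the weight comes from
#' valid instruments. The SE is a seeded parametric bootstrap resampling
#' `(bx, by)` from their sampling normals.
#'
#' @param h Harmonized set with at least 3 SNPs.
#' @param n_boot Bootstrap replicates for the SE.
#' @param seed Integer seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  h <- as_mr_harmonized(h)
  if (nrow(h) < 3) abort("weighted median needs at least 3 SNPs")
  rs <- ratio_set(h)
  w <- 1 / rs$se^2
  est <- weighted_median_point(rs$ratio, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(nrow(rs$h), rs$h$bx, rs$h$se_x)
      by <- rnorm(nrow(rs$h), rs$h$by, rs$h$se_y)
      ok <- bx != 0
      r <- by[ok] / bx[ok]
      s <- sqrt(rs$h$se_y[ok]^2 / bx[ok]^2 + by[ok]^2 * rs$h$se_x[ok]^2 / bx[ok]^4)
      weighted_median_point(r, 1 / s^2)
    }, numeric(1))
  })
  new_mr_estimate("weighted_median", est, sd(boots), n_snp = nrow(rs$h),
                  model = "bootstrap")
}

weighted_mode_point <- function(ratio, w, phi) {
  w <- w / sum(w)
  bw <- phi * bw.nrd0(ratio)
  if (bw <= 0) return(ratio[1])
  grid <- seq(min(ratio), max(ratio), length.out = 512)
  dens <- vapply(grid, function(g) sum(w * dnorm((g - ratio) / bw)), numeric(1))
  grid[which.max(dens)]
}

#' Weighted mode estimator
#'
#' The mode of the Gaussian-kernel-smoothed, inverse-variance-weighted density
#' of per-SNP Wald ratios, evaluated on a 512-point grid over the ratio range.
#' Consistent when the largest group of instruments sharing a causal estimate
#' is valid. Bandwidth is `phi` times the Silverman rule-of-thumb bandwidth of
#' the ratio set; the SE is a seeded parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param phi Bandwidth multiplier.
#' @return An `mr_estimate`.
#' @export
mr_weighted_mode <- function(h, phi = 1.0, n_boot = 1000, seed = NULL) {
  h <- as_mr_harmonized(h)
  if (nrow(h) < 3) abort("weighted mode needs at least 3 SNPs")
  rs <- ratio_set(h)
  w <- 1 / rs$se^2
  est <- weighted_mode_point(rs$ratio, w, phi)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(nrow(rs$h), rs$h$bx, rs$h$se_x)
      by <- rnorm(nrow(rs$h), rs$h$by, rs$h$se_y)
      ok <- bx != 0
      r <- by[ok] / bx[ok]
      s <- sqrt(rs$h$se_y[ok]^2 / bx[ok]^2 + by[ok]^2 * rs$h$se_x[ok]^2 / bx[ok]^4)
      weighted_mode_point(r, 1 / s^2, phi)
    }, numeric(1))
  })
  new_mr_estimate("weighted_mode", est, sd(boots), n_snp = nrow(rs$h),
                  model = "bootstrap", extras = list(phi = phi))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum((by - fitted)^2 / se_y^2)` around the IVW (through-origin) or
#' Egger (with-intercept) fit, referred to chi-squared with `n_snp - 1` or
#' `n_snp - 2` degrees of freedom.
#'
#' @param h Harmonized set.
#' @param method `"ivw"` or `"egger"`.
#' @return A tibble: `Q, df, pval`, plus per-SNP contributions in
#'   `attr(, "contributions")`.
#' @export
cochran_q <- function(h, method = c("ivw", "egger")) {
  method <- match.arg(method)
  h <- as_mr_harmonized(h)
  n <- nrow(h)
  w <- 1 / h$se_y^2
  if (method == "ivw") {
    if (n < 2) abort("Q needs more SNPs than model parameters")
    est <- mr_ivw(h, model = "fixed")$estimate
    contrib <- w * (h$by - est * h$bx)^2
    df <- n - 1
  } else {
    if (n < 3) abort("Q needs more SNPs than model parameters")
    fit <- mr_egger(h)
    flip <- h$bx < 0
    bx <- ifelse(flip, -h$bx, h$bx)
    by <- ifelse(flip, -h$by, h$by)
    fitted <- fit$extras$egger_intercept + fit$estimate * bx
    contrib <- w * (by - fitted)^2
    df <- n - 2
  }
  q <- sum(contrib)
  out <- tibble(Q = q, df = df, pval = pchisq(q, df, lower.tail = FALSE))
  attr(out, "contributions") <- tibble(snp = h$snp, contribution = contrib)
  out
}

#' Leave-one-out IVW analysis
#'
#' One IVW estimate per omitted SNP, plus the all-SNP row, to expose
#' single-variant influence on the causal estimate.
#'
#' @param h Harmonized set with at least 3 SNPs.
#' @return A tibble with `n_snp + 1` rows: `omitted, estimate, se, ci_lower,
#'   ci_upper, pval`.
#' @export
leave_one_out <- function(h) {
  h <- as_mr_harmonized(h)
  n <- nrow(h)
  if (n < 3) abort("leave-one-out needs at least 3 SNPs")
  rows <- map_dfr(c(seq_len(n), 0L), function(i) {
    sub <- if (i == 0) h else h[-i, , drop = FALSE]
    fit <- mr_ivw(sub)
    tibble(omitted = if (i == 0) "none" else h$snp[i],
           estimate = fit$estimate, se = fit$se,
           ci_lower = fit$ci_lower, ci_upper = fit$ci_upper, pval = fit$pval)
  })
  class(rows) <- c("mr_loo", class(rows))
  rows
}

#' MR-PRESSO-style global pleiotropy test and outlier correction
#'
#' Re-implementation of the published pleiotropy residual sum of squares and
#' outlier logic: the observed weighted RSS around leave-one-out IVW expected
#' values is compared with `n_sim` parametric simulations under the
#' no-pleiotropy model (rank-based global p); each SNP's observed residual is
#' compared with its simulated distribution and flagged at a Bonferroni
#' threshold `outlier_alpha / n_snp`; the corrected estimate is IVW on the
#' non-flagged SNPs.
#'
#' @param h Harmonized set with at least 4 SNPs.
#' @param n_sim Parametric simulations for the null distribution.
#' @param outlier_alpha Familywise level of the per-SNP outlier test.
#' @param seed Integer seed.
#' @return A list of class `mr_presso`: `global_pval`, `outliers` (SNP ids),
#'   `corrected` (`mr_estimate` on non-outliers), `raw` (all-SNP IVW),
#'   `per_snp` tibble of observed residual statistics and p-values.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = NULL) {
  h <- as_mr_harmonized(h)
  n <- nrow(h)
  if (n < 4) abort("MR-PRESSO needs at least 4 SNPs")
  w <- 1 / h$se_y^2
  sxx <- sum(w * h$bx^2)
  sxy <- sum(w * h$bx * h$by)
  # leave-one-out IVW expected value for each SNP
  beta_loo <- (sxy - w * h$bx * h$by) / (sxx - w * h$bx^2)
  exp_by <- h$bx * beta_loo
  obs_stat <- w * (h$by - exp_by)^2
  rss_obs <- sum(obs_stat)
  res <- with_seed(seed, {
    by_sim <- matrix(rnorm(n_sim * n, mean = rep(exp_by, each = n_sim),
                           sd = rep(h$se_y, each = n_sim)), n_sim, n)
    sxy_sim <- by_sim %*% (w * h$bx)
    beta_loo_sim <- (matrix(sxy_sim, n_sim, n) -
                       sweep(by_sim, 2, w * h$bx, "*")) /
      matrix(sxx - w * h$bx^2, n_sim, n, byrow = TRUE)
    stat_sim <- sweep((by_sim - sweep(beta_loo_sim, 2, h$bx, "*"))^2, 2, w, "*")
    rss_sim <- rowSums(stat_sim)
    p_global <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
    p_snp <- (1 + colSums(sweep(stat_sim, 2, obs_stat, ">="))) / (n_sim + 1)
    list(p_global = p_global, p_snp = p_snp)
  })
  outlier <- res$p_snp < outlier_alpha / n
  if (all(outlier)) abort("no instruments survive outlier removal")
  corrected <- mr_ivw(h[!outlier, , drop = FALSE])
  structure(
    list(
      global_pval = res$p_global,
      outliers = h$snp[outlier],
      corrected = corrected,
      raw = mr_ivw(h),
      per_snp = tibble(snp = h$snp, rss = obs_stat, pval = res$p_snp,
                       outlier = outlier),
      n_sim = n_sim
    ),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("<mr_presso> global p = %.4g (%d simulations), %d outlier(s)\n",
              x$global_pval, x$n_sim, length(x$outliers)))
  if (length(x$outliers)) cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  cat("  corrected "); print(x$corrected)
  invisible(x)
}

#' Sample-overlap bias and type-I-error approximation
#'
#' Approximates the bias of a two-sample MR estimate when a fraction `c` of
#' participants is shared between the exposure and outcome GWAS: the
#' weak-instrument bias interpolates from 0 (no overlap) toward the
#' confounded observational association, attenuated by instrument strength,
#' `bias = c * confounded_assoc / mean_F`. The implied type-I error of a
#' nominal-level test is `P(|Z| > z_(1-alpha/2))` with
#' `Z ~ Normal(bias / se_iv, 1)`.
#'
#' @param overlap_frac Overlap fraction `c` in `[0, 1]`.
#' @param mean_f Mean instrument F statistic (> 1).
#' @param confounded_assoc Confounded (observational) exposure-outcome
#'   association on the analysis scale.
#' @param se_iv SE of the MR estimate.
#' @param alpha Nominal test level.
#' @return A tibble: `overlap_frac, bias, type1`.
#' @export
overlap_bias <- function(overlap_frac, mean_f, confounded_assoc, se_iv,
                         alpha = 0.05) {
  if (any(overlap_frac < 0 | overlap_frac > 1)) abort("overlap_frac must be in [0, 1]")
  if (mean_f <= 1) abort("mean_f must exceed 1")
  bias <- overlap_frac * confounded_assoc / mean_f
  z <- qnorm(1 - alpha / 2)
  mu <- bias / se_iv
  type1 <- pnorm(-z - mu) + pnorm(-z + mu)
  tibble(overlap_frac = overlap_frac, bias = bias, type1 = type1)
}

#' Run the full univariable estimator and diagnostic suite
#'
#' Convenience wrapper returning IVW, MR-Egger, weighted median and weighted
#' mode estimates as one tidy table, with heterogeneity and pleiotropy
#' diagnostics attached.
#'
#' @param h Harmonized set.
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @param seed Integer seed.
#' @return A tibble of tidied estimates (one row per method) with `Q`
#'   statistics and the Egger intercept test in `attr(, "diagnostics")`.
#' @export
mr_all_methods <- function(h, n_boot = 1000, seed = NULL) {
  h <- as_mr_harmonized(h)
  fits <- list(
    mr_ivw(h),
    mr_egger(h),
    mr_weighted_median(h, n_boot = n_boot, seed = seed),
    mr_weighted_mode(h, n_boot = n_boot, seed = if (is.null(seed)) NULL else seed + 1)
  )
  out <- map_dfr(fits, tidy)
  egger <- fits[[2]]
  attr(out, "diagnostics") <- list(
    q_ivw = cochran_q(h, "ivw"),
    q_egger = cochran_q(h, "egger"),
    egger_intercept = tibble(
      estimate = egger$extras$egger_intercept,
      se = egger$extras$intercept_se,
      pval = egger$extras$intercept_p
    )
  )
  out
}
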