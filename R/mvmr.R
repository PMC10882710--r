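# Multivariable MR: joint estimation of the direct exposure effect and
# mediator effects on the outcome from a SNP x trait effect matrix, plus an
# L1-penalized variant that downweights invalid (pleiotropic) instruments.

#' Assemble a multivariable MR dataset
#'
#' Combines per-trait harmonized sets (each trait harmonized against the same
#' outcome) into one SNP x trait effect matrix. The SNP set is the union of
#' the per-trait instruments; rows are re-oriented to the outcome's original
#' effect allele so the shared outcome column is consistent; SNPs missing
#' from any trait are dropped and logged (the default policy --- imputing 0
#' would bias the joint fit).
#'
#' @param h_list Named list of `mr_harmonized` sets, one per exposure/mediator
#'   trait, all against the same outcome.
#' @return An `mv_dataset` tibble: `snp, by, se_y`, plus `bx_<trait>` /
#'   `se_<trait>` columns; dropped SNPs in [exclusions()], trait names in
#'   `attr(, "traits")`.
#' @export
assemble_mv <- function(h_list) {
  if (length(h_list) < 2) abort("multivariable MR needs at least 2 traits")
  if (is.null(names(h_list)) || any(names(h_list) == "")) {
    abort("h_list must be named by trait")
  }
  # undo per-trait allele flips so every set is on the outcome's orientation
  oriented <- map(h_list, function(h) {
    h <- as_mr_harmonized(h)
    fl <- if ("flipped" %in% names(h)) h$flipped else rep(FALSE, nrow(h))
    mutate(h, bx = ifelse(fl, -.data$bx, .data$bx),
           by = ifelse(fl, -.data$by, .data$by))
  })
  union_snps <- sort(unique(unlist(map(oriented, "snp"))))
  d <- tibble(snp = union_snps)
  for (nm in names(oriented)) {
    idx <- match(union_snps, oriented[[nm]]$snp)
    d[[paste0("bx_", nm)]] <- oriented[[nm]]$bx[idx]
    d[[paste0("se_", nm)]] <- oriented[[nm]]$se_x[idx]
    by_nm <- oriented[[nm]]$by[idx]
    se_nm <- oriented[[nm]]$se_y[idx]
    if (!("by" %in% names(d))) {
      d$by <- by_nm
      d$se_y <- se_nm
    } else {
      d$by <- ifelse(is.na(d$by), by_nm, d$by)
      d$se_y <- ifelse(is.na(d$se_y), se_nm, d$se_y)
    }
  }
  complete <- complete.cases(d)
  out <- d[complete, , drop = FALSE]
  K <- length(h_list)
  if (nrow(out) <= K) abort("fewer complete SNPs than traits; cannot fit MVMR")
  out <- append_log(out, exclusion_log(d$snp[!complete], "assemble_mv",
                                       "missing from at least one trait"))
  attr(out, "traits") <- names(h_list)
  class(out) <- c("mv_dataset", class(out))
  out
}

mv_matrices <- function(d, traits = NULL) {
  traits <- traits %||% attr(d, "traits") %||%
    sub("^bx_", "", grep("^bx_", names(d), value = TRUE))
  X <- as.matrix(d[paste0("bx_", traits)])
  colnames(X) <- traits
  list(X = X, by = d$by, w = 1 / d$se_y^2, traits = traits)
}

#' Multivariable IVW estimator
#'
#' Weighted least squares of the outcome effects on the trait-effect matrix
#' without intercept, weights `1/se_y^2`: the coefficient on the exposure is
#' its direct effect and each mediator coefficient is its effect conditional
#' on the other traits. Coefficient SEs come from the weighted information
#' matrix, scaled by `max(1, sqrt(Q/(n_snp - K)))` under the default
#' multiplicative random-effects model.
#'
#' @param d An [assemble_mv()] dataset (or tibble with `bx_<trait>`, `se_y`,
#'   `by` columns).
#' @param model `"multiplicative_re"` or `"fixed"`.
#' @return A named list of `mr_estimate`s, one per trait, with the joint `Q`
#'   in each `$extras`.
#' @export
mvmr_ivw <- function(d, model = c("multiplicative_re", "fixed")) {
  model <- match.arg(model)
  m <- mv_matrices(d)
  n <- nrow(m$X)
  K <- ncol(m$X)
  if (n <= K) abort("need more SNPs than traits")
  qr_x <- qr(sqrt(m$w) * m$X)
  if (qr_x$rank < K) {
    bad <- m$traits[qr_x$pivot[(qr_x$rank + 1):K]]
    abort(sprintf("rank-deficient trait matrix; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  xtwx <- crossprod(m$X, m$X * m$w)
  xtwy <- crossprod(m$X, m$w * m$by)
  inv <- chol2inv(chol(xtwx))
  est <- as.vector(inv %*% xtwy)
  q <- sum(m$w * (m$by - as.vector(m$X %*% est))^2)
  scale <- if (model == "multiplicative_re") max(1, sqrt(q / (n - K))) else 1
  se <- sqrt(diag(inv)) * scale
  setNames(
    map(seq_len(K), function(k) {
      new_mr_estimate(paste0("mvmr_ivw:", m$traits[k]), est[k], se[k],
                      n_snp = n, model = model,
                      extras = list(Q = q, Q_df = n - K))
    }),
    m$traits
  )
}

#' L1-penalized multivariable MR (mv-lasso)
#'
#' Augments the multivariable IVW regression with one intercept per SNP,
#' penalized at level `lambda`: valid instruments get intercept exactly 0,
#' pleiotropic ones a nonzero intercept. Fitted by coordinate descent
#' (soft-thresholding the weighted residual of each SNP). The reported
#' estimate is post-selection [mvmr_ivw()] on the SNPs whose intercept is
#' zero at the selected lambda; lambda is chosen as the smallest grid value
#' whose valid-set heterogeneity Q has p > 0.05.
#'
#' @param d An [assemble_mv()] dataset.
#' @param lambda_grid Decreasingly sorted penalty grid; default is a
#'   30-point log-spaced grid below the smallest lambda that zeroes every
#'   intercept. Must be positive: `lambda = 0` leaves one free intercept per
#'   observation and the model is unidentified.
#' @return A list: `estimates` (per-trait `mr_estimate`s on the valid set),
#'   `lambda` (selected), `invalid` (SNP ids with nonzero intercepts),
#'   `path` tibble (lambda, number invalid, valid-set Q p-value).
#' @export
mvmr_lasso <- function(d, lambda_grid = NULL) {
  m <- mv_matrices(d)
  n <- nrow(m$X)
  K <- ncol(m$X)
  if (n <= K) abort("need more SNPs than traits")
  se_y <- 1 / sqrt(m$w)
  theta0 <- vapply(mvmr_ivw(d, model = "fixed"), function(e) e$estimate, numeric(1))
  if (!is.null(lambda_grid) && any(lambda_grid <= 0)) {
    abort("lambda must be positive: lambda = 0 gives one free intercept per SNP (unidentified)")
  }
  r0 <- m$by - as.vector(m$X %*% theta0)
  lmax <- max(abs(r0) / se_y^2) * 1.05
  if (is.null(lambda_grid)) {
    lambda_grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 30))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  fit_one <- function(lambda) {
    theta <- theta0
    a <- numeric(n)
    for (it in seq_len(200)) {
      r <- m$by - as.vector(m$X %*% theta)
      a_new <- sign(r) * pmax(abs(r) - lambda * se_y^2, 0)
      wls <- lm.wfit(m$X, m$by - a_new, m$w)
      theta_new <- wls$coefficients
      delta <- max(abs(a_new - a), abs(theta_new - theta))
      theta <- theta_new
      a <- a_new
      if (delta < 1e-10) break
    }
    list(theta = theta, alpha = a)
  }

  path <- map(lambda_grid, fit_one)
  valid_sets <- map(path, function(f) which(f$alpha == 0))
  qp <- map_dbl(valid_sets, function(v) {
    if (length(v) <= K) return(NA_real_)
    sub <- d[v, , drop = FALSE]
    attr(sub, "traits") <- m$traits
    fits <- mvmr_ivw(sub, model = "fixed")
    q <- fits[[1]]$extras$Q
    pchisq(q, length(v) - K, lower.tail = FALSE)
  })
  ok <- which(!is.na(qp) & qp > 0.05)
  sel <- if (length(ok)) max(ok) else which.max(qp) # smallest lambda passing Q
  valid <- valid_sets[[sel]]
  if (length(valid) <= K) abort("no valid instrument set at any lambda")
  sub <- d[valid, , drop = FALSE]
  attr(sub, "traits") <- m$traits
  list(
    estimates = mvmr_ivw(sub),
    lambda = lambda_grid[[sel]],
    invalid = d$snp[-valid],
    path = tibble(lambda = lambda_grid,
                  n_invalid = map_dbl(path, ~ sum(.x$alpha != 0)),
                  q_pval = qp)
  )
}
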