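# Internal helpers shared across modules.

Z975 <- qnorm(0.975)

# two-sided normal p-value for an estimate/se pair (se = 0 degenerates to
# certainty: p = 1 for a zero estimate, 0 otherwise)
norm_p <- function(estimate, se) {
  p <- 2 * pnorm(-abs(estimate / se))
  degenerate <- se == 0
  p[degenerate] <- ifelse(estimate[degenerate] == 0, 1, 0)
  p
}

ci95 <- function(estimate, se) c(estimate - Z975 * se, estimate + Z975 * se)

# Constructor for a single causal-effect estimate (log-odds per SD for binary
# outcomes, per-SD otherwise). Wald-type: ci95 = estimate +/- 1.96 se.
new_mr_estimate <- function(method, estimate, se, n_snp,
                            model = NA_character_, pval = NULL,
                            extras = list()) {
  pval <- pval %||% norm_p(estimate, se)
  ci <- ci95(estimate, se)
  structure(
    list(
      method = method, estimate = estimate, se = se,
      ci_lower = ci[[1]], ci_upper = ci[[2]], pval = pval,
      n_snp = n_snp, model = model, extras = extras
    ),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "<mr_estimate> %s: %.4f (SE %.4f, 95%% CI %.4f to %.4f), p = %.3g, %d SNP(s)\n",
    x$method, x$estimate, x$se, x$ci_lower, x$ci_upper, x$pval, x$n_snp
  ))
  if (length(x$extras)) {
    ex <- vapply(x$extras, function(v) format(v, digits = 4), character(1))
    cat("  extras:", paste(names(ex), ex, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

# accept an mr_estimate, a list(estimate=, se=), or a length-2 numeric
as_est_se <- function(x, arg = "x") {
  if (inherits(x, "mr_estimate")) return(list(estimate = x$estimate, se = x$se))
  if (is.list(x) && all(c("estimate", "se") %in% names(x))) {
    return(list(estimate = x$estimate, se = x$se))
  }
  if (is.numeric(x) && length(x) == 2) {
    return(list(estimate = x[[1]], se = x[[2]]))
  }
  abort(sprintf("`%s` must be an mr_estimate, list(estimate=, se=), or numeric of length 2.", arg))
}

stopifnot_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# seeded evaluation that leaves the caller's RNG state untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# exclusion log helpers: a tibble (snp, stage, reason) carried as an attribute
exclusion_log <- function(snp = character(), stage = character(),
                          reason = character()) {
  tibble(snp = as.character(snp), stage = as.character(stage),
         reason = as.character(reason))
}

append_log <- function(x, log_new) {
  old <- attr(x, "exclusions") %||% exclusion_log()
  attr(x, "exclusions") <- bind_rows(old, log_new)
  x
}

#' Retrieve the exclusion log attached to a filtered summary table
#'
#' Instrument-selection and harmonization steps record every dropped SNP with
#' the stage and reason; this extracts that provenance log.
#'
#' @param x An object returned by an instrument-selection or harmonization
#'   function.
#' @return A tibble with columns `snp`, `stage`, `reason` (zero rows when
#'   nothing was dropped).
#' @export
exclusions <- function(x) attr(x, "exclusions") %||% exclusion_log()
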