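# Instrument selection and harmonization: genome-wide significance filtering,
# greedy LD clumping, outcome-association exclusion, F-statistic screening,
# and allele alignment of exposure/mediator/outcome summary statistics.

#' Filter a summary table at an exposure p-value threshold
#'
#' Retains exactly the rows with `pval < threshold` (strict inequality),
#' preserving the input order. Genome-wide significance (`5e-8`) is the
#' conventional instrument-relevance screen.
#'
#' @param stats A summary-statistics tibble (see [validate_summary_table()]).
#' @param threshold P-value threshold in (0, 1).
#' @return The filtered tibble; errors (rather than returning an empty table)
#'   when nothing passes.
#' @export
select_by_pvalue <- function(stats, threshold = 5e-8) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must lie in (0, 1)")
  stopifnot_cols(stats, c("snp", "pval"), "stats")
  keep <- stats$pval < threshold
  if (!any(keep)) {
    abort(sprintf("no instruments: no SNP has p < %g", threshold))
  }
  out <- stats[keep, , drop = FALSE]
  append_log(out, exclusion_log(stats$snp[!keep], "pvalue_filter",
                                sprintf("p >= %g", threshold)))
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p unassigned SNP as an index SNP and drops
#' all unassigned SNPs on the same chromosome within `window_kb` whose squared
#' correlation with it exceeds `r2_max`. Ties in p are broken by lexicographic
#' SNP id, so the result is invariant to input row order. The window is the
#' pairwise distance to the index SNP, `|pos - pos_index| <= window_kb * 1000`
#' (positions 1-based, bounds inclusive).
#'
#' @param stats Summary-statistics tibble.
#' @param ld An [ld_matrix()] covering every SNP in `stats`.
#' @param r2_max Maximum allowed squared correlation between retained SNPs
#'   within a window.
#' @param window_kb Window half-width in kilobases.
#' @return Index SNPs as a tibble sorted by p-value, with the dropped SNPs in
#'   [exclusions()].
#' @export
clump <- function(stats, ld, r2_max = 0.001, window_kb = 10000) {
  stopifnot_cols(stats, c("snp", "chr", "pos", "pval"), "stats")
  missing <- setdiff(stats$snp, rownames(ld))
  if (length(missing)) {
    abort(sprintf("SNP(s) missing from LD matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  ord <- order(stats$pval, stats$snp)
  s <- stats[ord, , drop = FALSE]
  r2 <- unclass(ld)[s$snp, s$snp, drop = FALSE]^2
  window_bp <- window_kb * 1000
  n <- nrow(s)
  state <- rep("unassigned", n)
  dropped_by <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (state[i] != "unassigned") next
    state[i] <- "index"
    near <- state == "unassigned" & s$chr == s$chr[i] &
      abs(s$pos - s$pos[i]) <= window_bp & r2[i, ] > r2_max
    state[near] <- "dropped"
    dropped_by[near] <- s$snp[i]
  }
  out <- s[state == "index", , drop = FALSE]
  append_log(out, exclusion_log(
    s$snp[state == "dropped"], "clump",
    sprintf("r2 > %g with index %s", r2_max, dropped_by[state == "dropped"])
  ))
}

#' Drop instruments associated with the outcome
#'
#' Removes candidate instruments whose p-value in the outcome GWAS falls below
#' `threshold` (a guard against reverse causation / direct outcome effects).
#' Instruments absent from the outcome table are retained and logged.
#'
#' @param stats Instrument summary table.
#' @param outcome Outcome summary table.
#' @param threshold Outcome-association p-value threshold.
#' @return Filtered tibble with a drop/retention log in [exclusions()].
#' @export
exclude_outcome_associated <- function(stats, outcome, threshold = 5e-6) {
  stopifnot_cols(stats, "snp", "stats")
  stopifnot_cols(outcome, c("snp", "pval"), "outcome")
  p_out <- outcome$pval[match(stats$snp, outcome$snp)]
  drop <- !is.na(p_out) & p_out < threshold
  absent <- is.na(p_out)
  out <- stats[!drop, , drop = FALSE]
  log <- bind_rows(
    exclusion_log(stats$snp[drop], "outcome_association",
                  sprintf("outcome p = %.3g < %g", p_out[drop], threshold)),
    exclusion_log(stats$snp[absent], "outcome_association",
                  "absent from outcome table; retained")
  )
  append_log(out, log)
}

#' Per-SNP F statistics and weak-instrument screening
#'
#' Computes the per-SNP instrument-strength statistic `F = (beta/se)^2` and
#' the mean F over retained SNPs. SNPs with `F <= f_min` are weak instruments;
#' by default they are dropped (`action = "drop"`), or kept and flagged with
#' `action = "flag"`.
#'
#' @param stats Instrument summary table.
#' @param f_min Weak-instrument threshold (conventionally 10).
#' @param action `"drop"` weak instruments or `"flag"` (keep, mark).
#' @return The table with columns `f_stat` and `weak` added, `mean_f` as an
#'   attribute, and any drops logged in [exclusions()].
#' @export
f_statistics <- function(stats, f_min = 10, action = c("drop", "flag")) {
  action <- match.arg(action)
  stopifnot_cols(stats, c("snp", "beta", "se"), "stats")
  if (any(stats$se <= 0)) abort("se must be positive")
  out <- mutate(stats, f_stat = (.data$beta / .data$se)^2,
                weak = .data$f_stat <= f_min)
  log <- exclusion_log()
  if (action == "drop" && any(out$weak)) {
    log <- exclusion_log(out$snp[out$weak], "f_statistic",
                         sprintf("F = %.2f <= %g", out$f_stat[out$weak], f_min))
    out <- out[!out$weak, , drop = FALSE]
    if (nrow(out) == 0) abort("no instruments survive the F screen")
  }
  attr(out, "mean_f") <- mean(out$f_stat)
  append_log(out, log)
}

#' Mean F statistic of a screened instrument set
#' @param x Output of [f_statistics()].
#' @return The mean per-SNP F over retained instruments.
#' @export
mean_f <- function(x) attr(x, "mean_f") %||% mean((x$beta / x$se)^2)

#' Remove mediator instruments shared with the exposure
#'
#' Mediator instruments minus any SNP id present in the exposure instrument
#' list, so the mediator's unadjusted effect is not estimated through
#' exposure-driven variants.
#'
#' @param mediator_ivs,exposure_ivs Summary tables of instruments.
#' @return Filtered mediator instruments (warns when nothing is left).
#' @export
remove_overlapping_instruments <- function(mediator_ivs, exposure_ivs) {
  shared <- mediator_ivs$snp %in% exposure_ivs$snp
  out <- mediator_ivs[!shared, , drop = FALSE]
  if (nrow(out) == 0) warn("all mediator instruments overlap the exposure instruments")
  append_log(out, exclusion_log(mediator_ivs$snp[shared], "exposure_overlap",
                                "instrument shared with exposure"))
}

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

# classify one exposure/other allele pair: "keep", "flip", or "drop"
# (palindromic pairs resolved by allele frequency when informative)
align_alleles <- function(ea1, oa1, eaf1, ea2, oa2, eaf2, band) {
  palindromic <- ALLELE_COMPLEMENT[ea1] == oa1
  if (palindromic) {
    if (!(ea2 %in% c(ea1, oa1)) || !(oa2 %in% c(ea1, oa1)) || ea2 == oa2) {
      return("drop_mismatch")
    }
    if (abs(eaf1 - 0.5) < band || abs(eaf2 - 0.5) < band) {
      return("drop_palindromic")
    }
    # allele labels carry no strand information for palindromic SNPs:
    # the frequency alone identifies the physical effect allele
    freq_agrees <- (eaf1 < 0.5) == (eaf2 < 0.5)
    return(if (freq_agrees) "keep" else "flip")
  }
  if (ea2 == ea1 && oa2 == oa1) return("keep")
  if (ea2 == oa1 && oa2 == ea1) return("flip")
  cea2 <- ALLELE_COMPLEMENT[ea2]
  coa2 <- ALLELE_COMPLEMENT[oa2]
  if (identical(unname(cea2), ea1) && identical(unname(coa2), oa1)) return("keep")
  if (identical(unname(cea2), oa1) && identical(unname(coa2), ea1)) return("flip")
  "drop_mismatch"
}

harmonize_pair <- function(exposure, other, band) {
  m <- match(exposure$snp, other$snp)
  present <- !is.na(m)
  o <- other[m[present], , drop = FALSE]
  e <- exposure[present, , drop = FALSE]
  action <- vapply(seq_len(nrow(e)), function(i) {
    align_alleles(e$ea[i], e$oa[i], e$eaf[i], o$ea[i], o$oa[i], o$eaf[i], band)
  }, character(1))
  beta <- ifelse(action == "flip", -o$beta, o$beta)
  eaf <- ifelse(action == "flip", 1 - o$eaf, o$eaf)
  list(
    snp = e$snp, keep = action %in% c("keep", "flip"),
    flipped = action == "flip", beta = beta, se = o$se, eaf = eaf,
    pval = o$pval,
    absent = exposure$snp[!present], action = action
  )
}

#' Harmonize exposure, outcome (and mediator) summary statistics
#'
#' Aligns every shared SNP to the exposure's effect allele: swapped
#' effect/other alleles flip the outcome beta sign and `eaf -> 1 - eaf`;
#' strand flips (A<->T, C<->G complements) are resolved by complementing;
#' palindromic SNPs (A/T or C/G pairs) are dropped when the effect-allele
#' frequency is uninformative (`|eaf - 0.5| < palindrome_eaf_band` in either
#' table) and otherwise aligned by frequency; non-matching allele pairs are
#' dropped. Harmonizing an already-harmonized pair is a no-op.
#'
#' @param exposure Exposure instrument summary table.
#' @param outcome Outcome summary table.
#' @param mediators Optional named list of mediator summary tables; SNPs must
#'   harmonize against every listed trait to be retained, and aligned mediator
#'   effects are returned as `bx_<name>` / `se_<name>` columns.
#' @param palindrome_eaf_band Half-width of the uninformative-frequency band
#'   around 0.5.
#' @return An `mr_harmonized` tibble: `snp, ea, oa, bx, se_x, by, se_y,
#'   flipped` (+ mediator columns), drops logged in [exclusions()].
#' @export
harmonize <- function(exposure, outcome, mediators = list(),
                      palindrome_eaf_band = 0.08) {
  stopifnot_cols(exposure, SUMMARY_COLS, "exposure")
  stopifnot_cols(outcome, SUMMARY_COLS, "outcome")
  if (!any(exposure$snp %in% outcome$snp)) {
    abort("no shared SNPs between exposure and outcome")
  }
  p_out <- harmonize_pair(exposure, outcome, palindrome_eaf_band)
  log <- exclusion_log(p_out$absent, "harmonize", "absent from outcome table")
  keep <- p_out$keep
  for (bad in c("drop_palindromic", "drop_mismatch")) {
    idx <- p_out$action == bad
    log <- bind_rows(log, exclusion_log(
      p_out$snp[idx], "harmonize",
      if (bad == "drop_palindromic") "palindromic, eaf uninformative" else "allele mismatch"
    ))
  }
  e_idx <- match(p_out$snp, exposure$snp)
  h <- tibble(
    snp = p_out$snp,
    ea = exposure$ea[e_idx], oa = exposure$oa[e_idx],
    eaf_x = exposure$eaf[e_idx], eaf_y = p_out$eaf,
    bx = exposure$beta[e_idx], se_x = exposure$se[e_idx],
    by = p_out$beta, se_y = p_out$se, p_y = p_out$pval,
    flipped = p_out$flipped
  )
  for (nm in names(mediators)) {
    pm <- harmonize_pair(exposure, mediators[[nm]], palindrome_eaf_band)
    ok <- rep(FALSE, nrow(h))
    idx <- match(pm$snp, h$snp)
    ok[idx] <- pm$keep
    beta_m <- se_m <- rep(NA_real_, nrow(h))
    beta_m[idx] <- pm$beta
    se_m[idx] <- pm$se
    log <- bind_rows(log, exclusion_log(
      h$snp[!ok & keep], "harmonize",
      sprintf("not harmonizable against mediator '%s'", nm)
    ))
    keep <- keep & ok
    h[[paste0("bx_", nm)]] <- beta_m
    h[[paste0("se_", nm)]] <- se_m
  }
  h <- h[keep, , drop = FALSE]
  if (nrow(h) == 0) abort("no SNPs survived harmonization")
  h <- append_log(h, log)
  class(h) <- c("mr_harmonized", class(h))
  h
}

# minimal coercion used by estimators: any data frame with the core columns
as_mr_harmonized <- function(x) {
  stopifnot_cols(x, c("bx", "se_x", "by", "se_y"), "harmonized set")
  if (!inherits(x, "mr_harmonized")) class(x) <- c("mr_harmonized", class(x))
  if (!("snp" %in% names(x))) x$snp <- sprintf("snp%03d", seq_len(nrow(x)))
  x
}
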