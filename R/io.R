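# Reading/writing the tabular interchange formats: GWAS summary statistics
# (tab-delimited, header SNP CHR POS EA OA EAF BETA SE P N), LD matrices
# (CSV with snp ids as header row and first column), survey datasets (CSV),
# and YAML simulation configs.

SUMMARY_COLS <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "pval", "n")

#' Validate a GWAS summary-statistics table
#'
#' Checks the per-SNP association-table contract used throughout the package:
#' columns `snp, chr, pos, ea, oa, eaf, beta, se, pval, n`; unique SNP ids;
#' positive SEs; p-values in (0, 1]; allele frequencies in (0, 1); and (unless
#' `check_pval = FALSE`) p-values consistent with `2*pnorm(-|beta/se|)` to
#' within 10% on the z scale.
#'
#' @param x A data frame of per-SNP associations.
#' @param check_pval Cross-check the p-value column against the normal
#'   approximation. Disable for tables with exact small-sample p-values.
#' @return `x` as a tibble, invisibly usable downstream.
#' @export
validate_summary_table <- function(x, check_pval = TRUE) {
  x <- as_tibble(x)
  stopifnot_cols(x, SUMMARY_COLS, "summary table")
  if (anyDuplicated(x$snp)) abort("summary table has duplicated SNP ids")
  if (any(x$se <= 0)) abort("summary table has non-positive SEs")
  if (any(x$pval <= 0 | x$pval > 1)) abort("p-values must lie in (0, 1]")
  if (any(x$eaf <= 0 | x$eaf >= 1)) abort("effect-allele frequencies must lie in (0, 1)")
  if (check_pval) {
    z_obs <- abs(qnorm(pmax(x$pval / 2, 1e-300)))
    z_exp <- abs(x$beta / x$se)
    # the comparison saturates once p underflows double precision (z ~ 38)
    bad <- z_exp > 1 & z_exp < 35 & abs(z_obs - z_exp) > 0.1 * z_exp
    if (any(bad)) {
      abort(sprintf("p-values inconsistent with |beta/se| for %d SNP(s), e.g. %s",
                    sum(bad), x$snp[which(bad)[1]]))
    }
  }
  x
}

#' Read or write a summary-statistics table
#'
#' Tab-delimited text with header `SNP CHR POS EA OA EAF BETA SE P N`.
#'
#' @param path File path.
#' @param x Table to write (validated first).
#' @return `read_summary_table` returns a validated tibble;
#'   `write_summary_table` returns `path` invisibly.
#' @export
read_summary_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  raw <- rename(raw, pval = "p")
  validate_summary_table(as_tibble(raw))
}

#' @rdname read_summary_table
#' @export
write_summary_table <- function(x, path) {
  x <- validate_summary_table(x)
  out <- x[SUMMARY_COLS]
  names(out) <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct, read, or write an LD correlation matrix
#'
#' The LD matrix pairs an ordered SNP-id vector with a symmetric correlation
#' matrix (unit diagonal, positive semi-definite within `1e-8`). On disk it is
#' a CSV whose header row and first column carry the SNP ids.
#'
#' @param r Square numeric matrix of pairwise correlations in `[-1, 1]`.
#' @param snp_ids Character vector of SNP ids matching the matrix order.
#' @param path File path.
#' @param x An `ld_matrix`.
#' @return An object of class `ld_matrix`: the correlation matrix with SNP-id
#'   dimnames.
#' @export
ld_matrix <- function(r, snp_ids) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r) || nrow(r) != length(snp_ids)) {
    abort("LD matrix must be square with one row/column per SNP id")
  }
  if (max(abs(r - t(r))) > 1e-10) abort("LD matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-10) abort("LD matrix diagonal must be 1")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort("LD matrix must be positive semi-definite")
  dimnames(r) <- list(snp_ids, snp_ids)
  structure(r, class = c("ld_matrix", "matrix", "array"))
}

#' @rdname ld_matrix
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  ld_matrix(as.matrix(raw), rownames(raw))
}

#' @rdname ld_matrix
#' @export
write_ld_matrix <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  invisible(path)
}

#' Read or write a survey dataset
#'
#' Person-level CSV with one row per participant: positive sampling `weight`,
#' optional `stratum`/`psu` design identifiers, and the analysis covariates.
#'
#' @param path File path.
#' @param x Survey data frame.
#' @return A tibble (`read_survey`) or `path` invisibly (`write_survey`).
#' @export
read_survey <- function(path) {
  x <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_survey(x)
}

#' @rdname read_survey
#' @export
write_survey <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

validate_survey <- function(x) {
  x <- as_tibble(x)
  stopifnot_cols(x, c("id", "weight", "lbp"), "survey dataset")
  if (any(x$weight <= 0)) abort("survey weights must be positive")
  if ("psu" %in% names(x) && !("stratum" %in% names(x))) {
    abort("survey data with `psu` must also carry `stratum`")
  }
  x
}

#' Read or write a simulation config as YAML
#'
#' The YAML schema mirrors the [sim_config()] field names.
#'
#' @param path File path.
#' @param config A `sim_config` list.
#' @return `read_sim_config` returns a validated [sim_config()];
#'   `write_sim_config` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # yaml reads named vectors back as lists; restore the numeric vectors
  vec_fields <- c("n_per_cohort", "maf_range", "effect_edu_on_mediator",
                  "effect_mediator_on_outcome", "confounder_effects",
                  "h2_mediator")
  for (f in intersect(names(raw), vec_fields)) raw[[f]] <- unlist(raw[[f]])
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$true_total_effect <- NULL # derived, recomputed on read
  # named vectors must become maps, or yaml drops the names
  named <- vapply(cfg, function(x) is.numeric(x) && !is.null(names(x)), logical(1))
  cfg[named] <- lapply(cfg[named], as.list)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
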