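# Config-driven orchestration of the two arms: the MR arm
# (select -> clump -> exclude -> harmonize -> UVMR -> mediator screening ->
# MVMR -> mediation) and the observational arm (filters, model ladder,
# subgroups, observational mediation), plus merged reporting.

#' Pipeline run configuration
#'
#' Bundles the inputs (either in-memory tables / a survey data frame, or the
#' simulation configs to generate them), the instrument-selection threshold
#' block, estimator and mediation options, and the master seed. Exactly one
#' of `tables`/`sim` must be supplied for the MR arm, and at most one of
#' `survey`/`survey_sim` for the observational arm.
#'
#' @param tables Named list of summary tables (`education`, mediators,
#'   `outcome`) or `NULL`.
#' @param ld An [ld_matrix()] covering the exposure/mediator tables.
#' @param sim A [sim_config()] used to generate `tables`/`ld` when they are
#'   not given.
#' @param survey A survey data frame, or `survey_sim` a [survey_config()].
#' @param p_exposure,p_outcome_exclude,r2_max,window_kb,f_min Instrument
#'   thresholds: exposure significance, outcome-association exclusion, LD
#'   clumping, weak-instrument F.
#' @param bonferroni_m Number of tests behind the significance label
#'   `p < 0.05 / bonferroni_m`.
#' @param screen_alpha Level used to screen mediators (UVMR-null mediators
#'   are excluded before MVMR; MVMR-null mediators before mediation).
#' @param mediation_se_method `"delta"` or `"bootstrap"` CIs in the
#'   mediation step.
#' @param bmi_band Optional length-2 BMI inclusion band for the
#'   observational arm (e.g. `c(18.5, 40)`), `NULL` to keep everyone.
#' @param seed Master seed; every stochastic step derives from it.
#' @return A `run_config` list.
#' @export
run_config <- function(tables = NULL, ld = NULL, sim = NULL,
                       survey = NULL, survey_sim = NULL,
                       p_exposure = 5e-8, p_outcome_exclude = 5e-6,
                       r2_max = 0.001, window_kb = 10000, f_min = 10,
                       bonferroni_m = 13, screen_alpha = 0.05,
                       mediation_se_method = "delta",
                       bmi_band = NULL, seed = 1L) {
  if (is.null(tables) == is.null(sim)) {
    abort("supply exactly one of `tables` or `sim` for the MR arm")
  }
  if (!is.null(survey) && !is.null(survey_sim)) {
    abort("supply at most one of `survey` or `survey_sim`")
  }
  if (any(c(p_exposure, p_outcome_exclude, r2_max, window_kb, f_min) <= 0)) {
    abort("thresholds must be positive")
  }
  structure(
    list(tables = tables, ld = ld, sim = sim, survey = survey,
         survey_sim = survey_sim,
         p_exposure = p_exposure, p_outcome_exclude = p_outcome_exclude,
         r2_max = r2_max, window_kb = window_kb, f_min = f_min,
         bonferroni_m = bonferroni_m, screen_alpha = screen_alpha,
         mediation_se_method = mediation_se_method,
         bmi_band = bmi_band, seed = as.integer(seed)),
    class = "run_config"
  )
}

stage <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", label, conditionMessage(e)))
  })
}

#' Run the Mendelian-randomization arm
#'
#' Executes the full MR pipeline: instrument selection for the exposure
#' (p-value filter, LD clumping, outcome-association exclusion, F screen),
#' harmonization, the UVMR suite for the total effect and every
#' exposure -> mediator / mediator -> outcome path, screening out mediators
#' with a null unadjusted outcome effect, multivariable MR for the direct
#' effect and adjusted mediator effects, screening out MVMR-null mediators,
#' and the mediation decomposition. Bonferroni significance labels
#' (`p < 0.05 / bonferroni_m`) are applied to the estimate tables.
#'
#' @param config A [run_config()] with an MR-arm input.
#' @return An `mr_bundle` list: `estimates` (tidy UVMR/MVMR table),
#'   `mediation` ([decompose_mediation()] table), `instruments`,
#'   `diagnostics` (Q, Egger intercept, PRESSO, per-stage exclusion log,
#'   mean F), `screening` (mediator decisions), `truth` (when simulated),
#'   `config`.
#' @export
run_mr_arm <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  if (!is.null(config$sim)) {
    simc <- config$sim
    simc$seed <- seed
    sim <- stage("simulate", simulate_cohorts(simc))
    tables <- sim$tables
    ld <- sim$ld
    truth <- sim$truth
  } else {
    tables <- config$tables
    ld <- config$ld
    truth <- NULL
  }
  mediators <- setdiff(names(tables), c("education", "outcome"))

  # the exclusion log is carried on the tibble attribute and accumulates
  # across stages
  select_ivs <- function(tab, drop_overlap = NULL) {
    ivs <- select_by_pvalue(tab, config$p_exposure)
    ivs <- clump(ivs, ld, r2_max = config$r2_max, window_kb = config$window_kb)
    if (!is.null(drop_overlap)) {
      ivs <- remove_overlapping_instruments(ivs, drop_overlap)
    }
    ivs <- exclude_outcome_associated(ivs, tables$outcome, config$p_outcome_exclude)
    f_statistics(ivs, f_min = config$f_min)
  }

  edu_ivs <- stage("exposure instruments", select_ivs(tables$education))
  h_total <- stage("harmonize", harmonize(edu_ivs, tables$outcome))
  uvmr_total <- stage("uvmr total", mr_all_methods(h_total, seed = seed + 1))
  gamma <- mr_ivw(h_total)
  presso <- if (nrow(h_total) >= 4) {
    stage("mr-presso", mr_presso(h_total, seed = seed + 2))
  } else {
    NULL
  }

  est_rows <- mutate(tidy(gamma), trait = "education", relation = "total")
  alphas <- list()
  betas_unadj <- list()
  med_h <- list()
  for (m in mediators) {
    h_a <- stage(paste("alpha", m), harmonize(edu_ivs, tables[[m]]))
    a_fit <- mr_ivw(h_a)
    alphas[[m]] <- a_fit
    est_rows <- bind_rows(est_rows,
                          mutate(tidy(a_fit), trait = m, relation = "edu_on_mediator"))
    m_ivs <- stage(paste("instruments", m), select_ivs(tables[[m]], drop_overlap = edu_ivs))
    h_m <- stage(paste("harmonize", m), harmonize(m_ivs, tables$outcome))
    med_h[[m]] <- h_m
    b_fit <- mr_ivw(h_m)
    betas_unadj[[m]] <- b_fit
    est_rows <- bind_rows(est_rows,
                          mutate(tidy(b_fit), trait = m, relation = "mediator_on_outcome_unadj"))
  }

  # screen 1: mediators with a null unadjusted effect on the outcome leave now
  keep1 <- names(keep(betas_unadj, ~ .x$pval < config$screen_alpha))
  screening <- tibble(
    mediator = mediators,
    uvmr_pval = map_dbl(betas_unadj[mediators], "pval"),
    passed_uvmr = mediators %in% keep1
  )

  mvmr_fits <- NULL
  direct <- NULL
  mediation <- NULL
  keep2 <- character()
  if (length(keep1) > 0) {
    union_snps <- unique(c(edu_ivs$snp, unlist(map(med_h[keep1], "snp"))))
    h_list <- c(
      list(education = harmonize(
        filter(tables$education, .data$snp %in% union_snps), tables$outcome
      )),
      map(setNames(keep1, keep1), function(m) {
        harmonize(filter(tables[[m]], .data$snp %in% union_snps), tables$outcome)
      })
    )
    d <- stage("assemble_mv", assemble_mv(h_list))
    mvmr_fits <- stage("mvmr", mvmr_ivw(d))
    direct <- mvmr_fits$education
    est_rows <- bind_rows(
      est_rows,
      map_dfr(names(mvmr_fits), function(t) {
        mutate(tidy(mvmr_fits[[t]]), trait = t,
               relation = if (t == "education") "direct" else "mediator_on_outcome_adj")
      })
    )
    # screen 2: MVMR-null mediators leave before mediation
    keep2 <- names(keep(mvmr_fits[keep1], ~ .x$pval < config$screen_alpha))
    screening$mvmr_pval <- map_dbl(mediators, function(m) {
      if (m %in% names(mvmr_fits)) mvmr_fits[[m]]$pval else NA_real_
    })
    screening$passed_mvmr <- mediators %in% keep2
    if (length(keep2) > 0) {
      mediation <- stage("mediation", decompose_mediation(
        total = gamma, direct = direct,
        alphas = alphas[keep2], betas = mvmr_fits[keep2],
        se_method = config$mediation_se_method, seed = seed + 3
      ))
    }
  }

  est_rows$significant <- est_rows$p.value < 0.05 / config$bonferroni_m
  structure(
    list(
      arm = "mr",
      estimates = est_rows,
      uvmr_methods = uvmr_total,
      mediation = mediation,
      mvmr = mvmr_fits,
      instruments = list(education = edu_ivs),
      harmonized = c(list(education = h_total), med_h),
      diagnostics = list(
        q_ivw = cochran_q(h_total, "ivw"),
        q_egger = cochran_q(h_total, "egger"),
        egger_intercept = attr(uvmr_total, "diagnostics")$egger_intercept,
        presso = presso,
        mean_f = mean_f(edu_ivs),
        loo = leave_one_out(h_total),
        exclusions = exclusions(edu_ivs)
      ),
      screening = screening,
      truth = truth,
      config = config
    ),
    class = "mr_bundle"
  )
}

default_ladder <- function() {
  list(
    crude = lbp ~ education,
    model1 = lbp ~ education + age + sex + race + marital + income,
    model2 = lbp ~ education + age + sex + race + marital + income +
      tv_hours + alcohol + activity + htn_dm,
    model3 = lbp ~ education + age + sex + race + marital + income +
      tv_hours + alcohol + activity + htn_dm + smoking,
    model4 = lbp ~ education + age + sex + race + marital + income +
      tv_hours + alcohol + activity + htn_dm + bmi,
    model5 = lbp ~ education + age + sex + race + marital + income +
      tv_hours + alcohol + activity + htn_dm + smoking + bmi
  )
}

#' Run the observational (survey) arm
#'
#' Applies the inclusion filters (age >= 20; optional BMI band), fits the
#' education model ladder with trend tests, the subgroup interaction
#' analyses, and the observational mediation decomposition (alpha' x beta'
#' product per mediator, total-minus-direct joint difference, proportions
#' mediated) on binary above-high-school education.
#'
#' @param config A [run_config()] with a survey input.
#' @param ladder Named list of ladder formulas; defaults to a crude model
#'   plus five increasingly adjusted models ending with both mediators.
#' @return An `obs_bundle` list: `ladder` tibble, `subgroups`, `mediation`,
#'   `totals` (gamma, gamma* with SEs), `data_n`, `config`.
#' @export
run_observational_arm <- function(config, ladder = default_ladder()) {
  stopifnot(inherits(config, "run_config"))
  data <- if (!is.null(config$survey)) {
    validate_survey(config$survey)
  } else {
    sc <- config$survey_sim %||% survey_config()
    sc$seed <- config$seed
    stage("simulate survey", simulate_survey(sc))
  }
  n0 <- nrow(data)
  data <- filter(data, .data$age >= 20)
  if (!is.null(config$bmi_band)) {
    data <- filter(data, .data$bmi >= config$bmi_band[1],
                   .data$bmi <= config$bmi_band[2])
  }
  lad <- stage("model ladder", model_ladder(data, ladder))
  data$smoke_ever <- as.integer(as.character(data$smoking) != "never")
  data$high_bmi <- as.integer(data$bmi >= 25)
  data$tv_high <- as.integer(data$tv_hours >= 3)
  base <- ladder[[length(ladder)]]
  subgroups <- list(
    smoking = stage("subgroup smoking",
                    subgroup_interaction(data, base, "smoking")),
    alcohol = stage("subgroup alcohol",
                    subgroup_interaction(data, base, "alcohol"))
  )
  med <- stage("observational mediation", {
    data$edu_above_hs <- as.integer(as.character(data$education) == ">HS")
    covs <- c("age", "sex", "race", "marital", "income", "alcohol",
              "activity", "tv_hours", "htn_dm")
    f_total <- reformulate(c("edu_above_hs", covs), response = "lbp")
    f_direct <- reformulate(c("edu_above_hs", "smoke_ever", "bmi", covs),
                            response = "lbp")
    fit_total <- weighted_glm(data, f_total, family = "binomial")
    fit_direct <- weighted_glm(data, f_direct, family = "binomial")
    gamma <- new_mr_estimate("survey_total", fit_total$coefficients[["edu_above_hs"]],
                             fit_total$se[["edu_above_hs"]], NA_integer_, "survey")
    gamma_star <- new_mr_estimate("survey_direct", fit_direct$coefficients[["edu_above_hs"]],
                                  fit_direct$se[["edu_above_hs"]], NA_integer_, "survey")
    om_smoke <- observational_mediation(data, "smoking", covariates = covs)
    om_bmi <- observational_mediation(data, "bmi", covariates = covs)
    dec <- decompose_mediation(
      total = gamma, direct = gamma_star,
      alphas = list(smoking = om_smoke$alpha, bmi = om_bmi$alpha),
      betas = list(smoking = om_smoke$beta, bmi = om_bmi$beta),
      se_method = config$mediation_se_method, seed = config$seed + 11
    )
    list(decomposition = dec, total = gamma, direct = gamma_star,
         alpha_beta = list(smoking = om_smoke, bmi = om_bmi))
  })
  structure(
    list(arm = "observational", ladder = lad, subgroups = subgroups,
         mediation = med$decomposition,
         totals = list(total = med$total, direct = med$direct),
         alpha_beta = med$alpha_beta,
         data_n = c(input = n0, analyzed = nrow(data)),
         config = config),
    class = "obs_bundle"
  )
}

#' Merge arm results into report tables
#'
#' Produces the ladder-shaped association table, a mediation table with one
#' block per arm (columns mediator, arm, effect with CI, p, proportion with
#' CI, flag), and a diagnostics appendix (Q statistics, Egger intercept,
#' PRESSO outliers, instrument strength, per-stage exclusions). Columns for
#' an absent arm are absent, not empty.
#'
#' @param ... One or more `mr_bundle` / `obs_bundle` objects.
#' @return An `mr_report` list of tibbles: `estimates`, `mediation`,
#'   `ladder`, `diagnostics`.
#' @export
report <- function(...) {
  bundles <- list(...)
  if (length(bundles) == 0) abort("need at least one bundle")
  arms <- map(bundles, "arm")
  med_rows <- map_dfr(bundles, function(b) {
    if (is.null(b$mediation)) return(tibble())
    mutate(as_tibble(b$mediation),
           arm = if (b$arm == "mr") "MR" else "observational")
  })
  mr_b <- bundles[arms == "mr"]
  obs_b <- bundles[arms == "observational"]
  out <- list(mediation = med_rows)
  if (length(mr_b)) {
    out$estimates <- map_dfr(mr_b, "estimates")
    b <- mr_b[[1]]
    out$diagnostics <- list(
      q_ivw = b$diagnostics$q_ivw, q_egger = b$diagnostics$q_egger,
      egger_intercept = b$diagnostics$egger_intercept,
      presso_outliers = if (!is.null(b$diagnostics$presso)) b$diagnostics$presso$outliers else character(),
      presso_global_p = if (!is.null(b$diagnostics$presso)) b$diagnostics$presso$global_pval else NA_real_,
      mean_f = b$diagnostics$mean_f,
      exclusions = b$diagnostics$exclusions,
      screening = b$screening
    )
  }
  if (length(obs_b)) {
    out$ladder <- map_dfr(obs_b, "ladder")
  }
  structure(out, class = "mr_report")
}

#' Write a report to CSV/JSON files
#'
#' @param x An [report()] object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly. Writes `mediation.csv`, `estimates.csv`,
#'   `ladder.csv` (when present) and `report.json`.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "mr_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("mediation", "estimates", "ladder")) {
    if (!is.null(x[[nm]]) && nrow(x[[nm]]) > 0) {
      utils::write.csv(x[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  json <- purrr::map(unclass(x), function(el) {
    if (is.data.frame(el)) as.data.frame(el) else el
  })
  json$diagnostics$exclusions <- NULL
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Read back a JSON report
#' @param path Path to `report.json`.
#' @return A list mirroring the [report()] structure (tibbles for the
#'   tabular elements).
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in intersect(names(raw), c("mediation", "estimates", "ladder"))) {
    raw[[nm]] <- as_tibble(raw[[nm]])
  }
  raw
}
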