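small_survey <- function(n = 1500, seed = 21, ...) {
  simulate_survey(survey_config(n = n, seed = seed, ...))
}

test_that("weighted GLM with unit weights matches ordinary ML", {
  d <- small_survey(1200, seed = 51)
  d$weight <- 1
  d$stratum <- NULL
  d$psu <- NULL
  f <- lbp ~ education + age + sex + bmi
  fit <- weighted_glm(d, f)
  ref <- glm(f, family = binomial(), data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)

  # gaussian family against lm
  fitg <- weighted_glm(d, bmi ~ education + age, family = "gaussian")
  refg <- lm(bmi ~ education + age, data = d)
  expect_equal(unname(fitg$coefficients), unname(coef(refg)), tolerance = 1e-8)
})

test_that("weighting semantics: duplication == doubled weight; scale invariance", {
  d <- small_survey(400, seed = 52)
  d$stratum <- NULL
  d$psu <- NULL
  f <- lbp ~ education + age
  dup <- dplyr::bind_rows(d, d[7, ])
  dw <- d
  dw$weight[7] <- 2 * dw$weight[7]
  expect_equal(weighted_glm(dup, f)$coefficients,
               weighted_glm(dw, f)$coefficients, tolerance = 1e-10)

  d2 <- small_survey(800, seed = 53)
  fit1 <- weighted_glm(d2, f)
  d2k <- d2
  d2k$weight <- d2k$weight * 137
  fit2 <- weighted_glm(d2k, f)
  expect_equal(fit2$coefficients, fit1$coefficients, tolerance = 1e-10)
  expect_equal(fit2$se, fit1$se, tolerance = 1e-8)
})

test_that("changing the reference level changes coefficients, not fitted probabilities", {
  d <- small_survey(600, seed = 54)
  f <- lbp ~ education + sex
  fit1 <- weighted_glm(d, f)
  d2 <- d
  d2$education <- stats::relevel(factor(d2$education, ordered = FALSE), ">HS")
  fit2 <- weighted_glm(d2, f)
  expect_false(isTRUE(all.equal(fit1$coefficients[["(Intercept)"]],
                                fit2$coefficients[["(Intercept)"]])))
  expect_lt(max(abs(fit1$fitted - fit2$fitted)), 1e-10)
})

test_that("degenerate outcomes and separation raise errors", {
  d <- small_survey(300, seed = 55)
  d$lbp <- 1L
  expect_error(weighted_glm(d, lbp ~ age), "degenerate")
  d2 <- small_survey(300, seed = 56)
  d2$sep <- as.numeric(d2$lbp == 1)
  expect_error(weighted_glm(d2, lbp ~ sep + age), "separation|converge")
})

test_that("design-based SE agrees with a Rao-Wu PSU bootstrap within 15 percent", {
  d <- simulate_survey(survey_config(n = 2000, n_strata = 8,
                                     psus_per_stratum = 5, seed = 57))
  f <- lbp ~ education + age
  fit <- weighted_glm(d, f)
  target <- "education>HS"
  psus <- split(seq_len(nrow(d)), paste(d$stratum, d$psu))
  stratum_of <- sapply(psus, function(i) d$stratum[i[1]])
  # Rao-Wu rescaling bootstrap: draw n_h - 1 PSUs with replacement per
  # stratum, reweight by n_h / (n_h - 1)
  boots <- withr::with_seed(58, {
    sapply(1:400, function(b) {
      db <- do.call(rbind, lapply(unique(stratum_of), function(h) {
        hp <- which(stratum_of == h)
        nh <- length(hp)
        take <- sample(hp, nh - 1, replace = TRUE)
        dh <- d[unlist(psus[take]), , drop = FALSE]
        dh$weight <- dh$weight * nh / (nh - 1)
        dh
      }))
      fb <- tryCatch(weighted_glm(db, f), error = function(e) NULL)
      if (is.null(fb)) NA_real_ else fb$coefficients[[target]]
    })
  })
  boot_se <- sd(boots, na.rm = TRUE)
  expect_lt(abs(fit$se[[target]] - boot_se) / boot_se, 0.15)
})

test_that("weighted Wald CIs cover the generating education effect", {
  hits <- 0
  n_rep <- 120
  for (s in 1:n_rep) {
    d <- simulate_survey(survey_config(
      n = 900, seed = 6000 + s,
      coef_lbp = list(edu_hs = -0.165, edu_above_hs = -0.33, smoking = 0,
                      bmi = 0, female = 0, htn_dm = 0, tv_hours = 0)
    ))
    fit <- weighted_glm(d, lbp ~ education)
    est <- fit$coefficients[["education>HS"]]
    se <- fit$se[["education>HS"]]
    if (abs(est + 0.33) <= 1.96 * se) hits <- hits + 1
  }
  expect_gt(hits / n_rep, 0.95 - 3 * sqrt(0.05 * 0.95 / n_rep))
  expect_lt(hits / n_rep, 0.95 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("model ladder reduces to weighted_glm for a single crude model and adds trend rows", {
  d <- small_survey(1000, seed = 59)
  lad <- model_ladder(d, list(crude = lbp ~ education))
  fit <- weighted_glm(dplyr::mutate(d, education = factor(education, ordered = FALSE)),
                      lbp ~ education)
  expect_equal(lad$or[lad$level == ">HS"],
               exp(fit$coefficients[["education>HS"]]), tolerance = 1e-10)
  expect_true("trend" %in% lad$level)
  expect_equal(nrow(lad), 3) # two non-reference levels + trend
})

test_that("two identical strata give identical stratified ORs", {
  d <- small_survey(700, seed = 60)
  d$grp <- "A"
  d2 <- d
  d2$grp <- "B"
  both <- dplyr::bind_rows(d, d2)
  res <- subgroup_interaction(both, lbp ~ education + age + grp, "grp")
  wide <- tidyr::pivot_wider(res$strata[, c("subgroup", "level", "or")],
                             names_from = "subgroup", values_from = "or")
  expect_equal(wide$A, wide$B, tolerance = 1e-8)
})

test_that("interaction tests detect a planted education-by-subgroup effect", {
  pv <- withr::with_seed(61, sapply(1:8, function(s) {
    d <- simulate_survey(survey_config(n = 10000, seed = 7000 + s,
                                       weight_sdlog = 0))
    # plant an interaction: flip outcomes for educated drinkers
    lp_shift <- 0.8 * (as.integer(d$education) - 1) * d$alcohol
    d$lbp <- rbinom(nrow(d), 1, plogis(qlogis(pmin(pmax(0.39, 0.01), 0.99)) +
                                         -0.3 * (as.integer(d$education) - 1) +
                                         lp_shift))
    subgroup_interaction(d, lbp ~ education + age + sex + alcohol,
                         "alcohol")$interaction$lrt_p
  }))
  expect_gte(mean(pv < 0.05), 0.8)
})

test_that("Rubin pooling matches hand computation", {
  out <- rubin_pool(c(0.5, 0.7), c(0.04, 0.04))
  expect_equal(out$pooled, 0.6)
  expect_equal(out$total_var, 0.04 + 1.5 * var(c(0.5, 0.7)))
  expect_equal(out$total_var, 0.07)

  same <- rubin_pool(rep(0.31, 5), rep(0.02, 5))
  expect_equal(same$total_var, 0.02)
  expect_equal(same$pooled, 0.31)
  expect_error(rubin_pool(0.5, 0.04), "m >= 2")

  # pooling m copies of one fit reproduces that fit
  d <- small_survey(500, seed = 62)
  fit <- weighted_glm(d, lbp ~ education + age)
  est <- fit$coefficients[["education>HS"]]
  v <- fit$se[["education>HS"]]^2
  pooled <- rubin_pool(rep(est, 3), rep(v, 3))
  expect_equal(pooled$pooled, est)
  expect_equal(pooled$total_var, v)
})

test_that("observational mediation recovers generating coefficients and null flags", {
  # alpha'_smoke generated at log(0.62) per education level; beta at log(1.24)
  d <- simulate_survey(survey_config(n = 12000, seed = 63,
                                     coef_smoking = list(education = log(0.62))))
  om <- observational_mediation(d, "smoking")
  expect_lt(om$alpha$estimate, 0)
  expect_estimate_close(om$beta, log(1.24), n_se = 3)

  # mediator independent of education: alpha' within 3 SE of zero
  d0 <- simulate_survey(survey_config(n = 6000, seed = 64,
                                      coef_smoking = list(education = 0)))
  om0 <- observational_mediation(d0, "smoking")
  expect_lt(abs(om0$alpha$estimate), 3 * om0$alpha$se)

  # BMI arm with zero alpha': decomposition carries the no-mediating-effect flag
  db <- simulate_survey(survey_config(n = 6000, seed = 65,
                                      coef_bmi = list(education = 0)))
  omb <- observational_mediation(db, "bmi")
  total <- list(estimate = -0.3, se = 0.05)
  dec <- decompose_mediation(total, total,
                             alphas = list(bmi = omb$alpha),
                             betas = list(bmi = omb$beta))
  expect_equal(dec$flag[dec$mediator == "bmi"], "no mediating effect")
})
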