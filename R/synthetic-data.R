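# Synthetic-data generators: (i) multi-trait GWAS summary statistics from an
# explicit structural model genotype -> education -> {mediators} -> outcome,
# with block-AR(1) LD, a shared confounder, configurable pleiotropy and
# cohort overlap; (ii) an NHANES-like stratified multistage survey population.
# Every downstream stage of the pipeline is testable against the recorded
# generating truth.

#' Configuration for the structural GWAS simulator
#'
#' Defines the causal diagram education -> mediators -> binary outcome that the
#' summary-statistic generator instantiates. Continuous traits are built to
#' unit variance, so `effect_edu_on_mediator` (alpha) is per SD of education
#' and `direct_effect_edu_on_outcome` (gamma*) / `effect_mediator_on_outcome`
#' (beta) are log-odds per SD. The implied total effect
#' `gamma = gamma* + sum(alpha * beta)` is recorded in the config.
#'
#' Default effect sizes are the mediation-model coefficients for an
#' education -> {smoking, BMI} -> low-back-pain system (direct effect -0.476
#' log-odds/SD; alpha -0.22 per mediator; beta log(1.46) and log(1.18)), with
#' outcome prevalence 0.074 as in a population-registry case-control GWAS.
#' Cohort sizes default to 20,000 (continuous traits) and 60,000 (outcome):
#' large enough that the genome-wide p < 5e-8 instrument threshold is usable
#' with the default per-instrument strength (see the methods vignette), small
#' enough to simulate on a laptop.
#'
#' @param n_snps Total SNPs simulated (instruments + mediator-specific +
#'   background).
#' @param n_per_cohort Named sample sizes, one per trait cohort
#'   (`education`, each mediator, `outcome`). A single unnamed number is
#'   recycled; the default gives the (case-control) outcome cohort three
#'   times the continuous-trait cohorts, mirroring the usual situation where
#'   the registry-based outcome GWAS is the largest. Must be at least
#'   `10 * n_snps` (per-SNP fits are unstable below that).
#' @param maf_range Minor-allele-frequency range, inside (0, 0.5).
#' @param ld_block_size,ld_rho LD structure: SNPs fall in independent blocks of
#'   `ld_block_size` with AR(1) latent correlation `ld_rho` in `[0, 1)`.
#' @param h2_exposure Proportion of education variance explained by its
#'   instruments (must be > 0).
#' @param h2_mediator Proportion of each mediator's variance from its own
#'   (education-independent) SNPs; scalar or named per mediator.
#' @param effect_edu_on_mediator Named alpha vector, per SD of education.
#' @param effect_mediator_on_outcome Named beta vector (log-odds per SD);
#'   names must match `effect_edu_on_mediator`.
#' @param direct_effect_edu_on_outcome gamma*, log-odds per SD of education.
#' @param confounder_effects Named loadings of the shared standard-normal
#'   confounder `U` on each trait (education, mediators, outcome).
#' @param pleiotropy_frac,pleiotropy_sd Fraction of SNPs given direct outcome
#'   effects, drawn `N(0, pleiotropy_sd^2)` on the liability.
#' @param overlap_frac Fraction `c` of the outcome cohort reusing exposure
#'   cohort individuals (sample overlap between the two GWAS).
#' @param outcome_prevalence Case fraction in the outcome cohort, in (0, 1).
#' @param n_instruments_exposure,n_instruments_mediator Number of causal
#'   blocks assigned to education and to each mediator (one causal SNP per
#'   block, so clumping to independence keeps the signal).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A `sim_config` list; `$true_total_effect` holds the implied gamma.
#' @export
sim_config <- function(n_snps = 400,
                       n_per_cohort = NULL,
                       maf_range = c(0.1, 0.45),
                       ld_block_size = 4,
                       ld_rho = 0.4,
                       h2_exposure = 0.25,
                       h2_mediator = 0.2,
                       effect_edu_on_mediator = c(smoking = -0.22, bmi = -0.22),
                       effect_mediator_on_outcome = c(smoking = log(1.46), bmi = log(1.18)),
                       direct_effect_edu_on_outcome = -0.476,
                       confounder_effects = NULL,
                       pleiotropy_frac = 0,
                       pleiotropy_sd = 0.05,
                       overlap_frac = 0,
                       outcome_prevalence = 0.074,
                       n_instruments_exposure = 40,
                       n_instruments_mediator = 25,
                       seed = 1L) {
  mediators <- names(effect_edu_on_mediator) %||% character()
  if (length(effect_edu_on_mediator) > 0 && !length(mediators)) {
    abort("effect_edu_on_mediator must be a named vector")
  }
  if (!identical(sort(mediators), sort(names(effect_mediator_on_outcome) %||% character()))) {
    abort("mediator names must match between alpha and beta vectors")
  }
  effect_mediator_on_outcome <- effect_mediator_on_outcome[mediators]
  traits <- c("education", mediators, "outcome")
  if (is.null(n_per_cohort)) {
    n_per_cohort <- setNames(c(rep(20000, length(traits) - 1), 60000), traits)
  }
  if (is.null(names(n_per_cohort))) {
    n_per_cohort <- setNames(rep(n_per_cohort[[1]], length(traits)), traits)
  }
  if (!all(traits %in% names(n_per_cohort))) {
    abort("n_per_cohort must cover every trait cohort")
  }
  n_per_cohort <- n_per_cohort[traits]
  if (is.null(confounder_effects)) {
    confounder_effects <- setNames(rep(0.3, length(traits)), traits)
  }
  if (length(h2_mediator) == 1 && length(mediators) > 0) {
    h2_mediator <- setNames(rep(h2_mediator, length(mediators)), mediators)
  }
  if (n_snps < 1) abort("n_snps must be >= 1")
  if (h2_exposure <= 0) abort("h2_exposure must be > 0")
  if (any(n_per_cohort < 10 * n_snps)) {
    abort("each cohort must have n >= 10 * n_snps for stable per-SNP fits")
  }
  if (outcome_prevalence <= 0 || outcome_prevalence >= 1) {
    abort("outcome_prevalence must lie in (0, 1)")
  }
  if (overlap_frac < 0 || overlap_frac > 1) abort("overlap_frac must be in [0, 1]")
  if (pleiotropy_frac < 0 || pleiotropy_frac > 1) abort("pleiotropy_frac must be in [0, 1]")
  if (maf_range[1] <= 0 || maf_range[2] >= 0.5 || maf_range[1] > maf_range[2]) {
    abort("maf_range must lie inside (0, 0.5)")
  }
  if (ld_rho < 0 || ld_rho >= 1) abort("ld_rho must be in [0, 1)")
  gamma <- direct_effect_edu_on_outcome +
    sum(effect_edu_on_mediator * effect_mediator_on_outcome)
  if (!is.finite(gamma)) abort("implied total effect is not finite")
  structure(
    list(
      n_snps = as.integer(n_snps), n_per_cohort = n_per_cohort,
      maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
      ld_rho = ld_rho, h2_exposure = h2_exposure, h2_mediator = h2_mediator,
      effect_edu_on_mediator = effect_edu_on_mediator,
      effect_mediator_on_outcome = effect_mediator_on_outcome,
      direct_effect_edu_on_outcome = direct_effect_edu_on_outcome,
      confounder_effects = confounder_effects,
      pleiotropy_frac = pleiotropy_frac, pleiotropy_sd = pleiotropy_sd,
      overlap_frac = overlap_frac, outcome_prevalence = outcome_prevalence,
      n_instruments_exposure = as.integer(n_instruments_exposure),
      n_instruments_mediator = as.integer(n_instruments_mediator),
      seed = as.integer(seed),
      true_total_effect = gamma
    ),
    class = "sim_config"
  )
}

# genotype dosages for one cohort: two latent-Gaussian haplotypes per
# individual, thresholded at qnorm(maf), block-AR(1) correlation
draw_genotypes <- function(n, maf, block_id, rho) {
  J <- length(maf)
  G <- matrix(0L, n, J)
  for (b in unique(block_id)) {
    idx <- which(block_id == b)
    k <- length(idx)
    if (k == 1 || rho == 0) {
      Z1 <- matrix(rnorm(n * k), n, k)
      Z2 <- matrix(rnorm(n * k), n, k)
    } else {
      S <- rho^abs(outer(seq_len(k), seq_len(k), "-"))
      L <- chol(S)
      Z1 <- matrix(rnorm(n * k), n, k) %*% L
      Z2 <- matrix(rnorm(n * k), n, k) %*% L
    }
    thr <- qnorm(maf[idx])
    G[, idx] <- (sweep(Z1, 2, thr, "<") + sweep(Z2, 2, thr, "<"))
  }
  storage.mode(G) <- "double"
  G
}

# vectorized per-SNP simple linear regression (normal-approximation p-values)
per_snp_linear <- function(G, y) {
  n <- length(y)
  gc <- scale(G, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  ssg <- colSums(gc^2)
  sxy <- as.vector(crossprod(gc, yc))
  beta <- sxy / ssg
  sse <- sum(yc^2) - beta^2 * ssg
  se <- sqrt(pmax(sse, 0) / (n - 2) / ssg)
  tibble(beta = beta, se = se, pval = pmax(norm_p(beta, se), 1e-300))
}

# per-SNP logistic regression (log-OR scale): two-parameter Newton-Raphson
# with a closed-form 2x2 solve, much faster than glm.fit in a loop
per_snp_logistic <- function(G, y, max_iter = 25, tol = 1e-10) {
  J <- ncol(G)
  beta <- se <- numeric(J)
  for (j in seq_len(J)) {
    g <- G[, j]
    a <- qlogis(mean(y))
    b <- 0
    for (it in seq_len(max_iter)) {
      mu <- plogis(a + b * g)
      w <- mu * (1 - mu)
      r <- y - mu
      u1 <- sum(r)
      u2 <- sum(r * g)
      i11 <- sum(w)
      i12 <- sum(w * g)
      i22 <- sum(w * g^2)
      det <- i11 * i22 - i12^2
      da <- (i22 * u1 - i12 * u2) / det
      db <- (i11 * u2 - i12 * u1) / det
      a <- a + da
      b <- b + db
      if (max(abs(da), abs(db)) < tol) break
    }
    mu <- plogis(a + b * g)
    w <- mu * (1 - mu)
    i11 <- sum(w)
    i12 <- sum(w * g)
    i22 <- sum(w * g^2)
    beta[j] <- b
    se[j] <- sqrt(i11 / (i11 * i22 - i12^2))
  }
  tibble(beta = beta, se = se, pval = pmax(norm_p(beta, se), 1e-300))
}

#' Simulate multi-trait GWAS summary statistics from the structural model
#'
#' Draws genotype dosages with block-AR(1) LD (Gaussian-copula haplotypes),
#' builds education, each mediator and the binary outcome from the structural
#' equations in [sim_config()], and computes per-SNP univariate summary
#' statistics in each trait's own cohort (linear regression for continuous
#' traits, logistic for the outcome). Cohorts are disjoint except that the
#' first `ceiling(overlap_frac * n_outcome)` outcome individuals reuse
#' exposure-cohort individuals. The outcome liability carries standard
#' logistic noise and is dichotomized at the empirical quantile giving
#' `outcome_prevalence`, so the structural coefficients live on the log-odds
#' scale that the per-SNP logistic fits estimate.
#'
#' @param config A [sim_config()].
#' @return A list:
#' \describe{
#'   \item{tables}{named list of summary-statistic tibbles, one per trait
#'     (`education`, mediators, `outcome`), columns
#'     `snp, chr, pos, ea, oa, eaf, beta, se, pval, n`.}
#'   \item{ld}{the empirical [ld_matrix()] of exposure-cohort dosages.}
#'   \item{truth}{generating values: per-SNP instrument effects, structural
#'     alpha/beta/gamma*/implied gamma, pleiotropic SNPs.}
#' }
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  mediators <- names(cfg$effect_edu_on_mediator)
  with_seed(cfg$seed, {
    J <- cfg$n_snps
    maf <- runif(J, cfg$maf_range[1], cfg$maf_range[2])
    block_id <- ceiling(seq_len(J) / cfg$ld_block_size)
    n_blocks <- max(block_id)
    snp <- sprintf("rs%05d", seq_len(J))
    pos <- seq_len(J) * 10000L
    alleles <- matrix(sample(c("A", "C", "G", "T"), 2 * J, replace = TRUE), J, 2)
    same <- alleles[, 1] == alleles[, 2]
    while (any(same)) {
      alleles[same, 2] <- sample(c("A", "C", "G", "T"), sum(same), replace = TRUE)
      same <- alleles[, 1] == alleles[, 2]
    }

    # assign causal blocks: education first, then one slab per mediator
    need <- cfg$n_instruments_exposure +
      length(mediators) * cfg$n_instruments_mediator
    if (need > n_blocks) {
      abort("not enough LD blocks for the requested instrument counts; increase n_snps")
    }
    first_snp_of_block <- match(unique(block_id), block_id)
    edu_causal <- first_snp_of_block[seq_len(cfg$n_instruments_exposure)]
    med_causal <- list()
    offset <- cfg$n_instruments_exposure
    for (m in mediators) {
      med_causal[[m]] <- first_snp_of_block[offset + seq_len(cfg$n_instruments_mediator)]
      offset <- offset + cfg$n_instruments_mediator
    }

    dos_var <- 2 * maf * (1 - maf)
    # education instrument effects, scaled so the score variance is h2_exposure
    b_edu <- numeric(J)
    raw <- rnorm(length(edu_causal))
    b_edu[edu_causal] <- raw * sqrt(cfg$h2_exposure / sum(raw^2 * dos_var[edu_causal]))
    b_med <- list()
    for (m in mediators) {
      bm <- numeric(J)
      raw <- rnorm(length(med_causal[[m]]))
      bm[med_causal[[m]]] <- raw *
        sqrt(cfg$h2_mediator[[m]] / sum(raw^2 * dos_var[med_causal[[m]]]))
      b_med[[m]] <- bm
    }
    # direct SNP -> outcome (horizontal pleiotropy) effects
    b_pleio <- numeric(J)
    if (cfg$pleiotropy_frac > 0) {
      n_pl <- round(cfg$pleiotropy_frac * J)
      pl <- sample.int(J, n_pl)
      b_pleio[pl] <- rnorm(n_pl, 0, cfg$pleiotropy_sd)
    }

    c_eff <- cfg$confounder_effects
    alpha <- cfg$effect_edu_on_mediator
    beta <- cfg$effect_mediator_on_outcome
    gstar <- cfg$direct_effect_edu_on_outcome

    build_traits <- function(G, U) {
      n <- nrow(G)
      v_eps_edu <- 1 - cfg$h2_exposure - c_eff[["education"]]^2
      if (v_eps_edu <= 0) abort("h2_exposure + confounder loading^2 must be < 1")
      edu <- as.vector(G %*% b_edu) + c_eff[["education"]] * U +
        rnorm(n, 0, sqrt(v_eps_edu))
      med <- list()
      for (m in mediators) {
        v_eps <- 1 - alpha[[m]]^2 - cfg$h2_mediator[[m]] - c_eff[[m]]^2 -
          2 * alpha[[m]] * c_eff[["education"]] * c_eff[[m]]
        if (v_eps <= 0) abort(sprintf("mediator '%s' structural variances exceed 1", m))
        med[[m]] <- alpha[[m]] * edu + as.vector(G %*% b_med[[m]]) +
          c_eff[[m]] * U + rnorm(n, 0, sqrt(v_eps))
      }
      lp <- gstar * edu + c_eff[["outcome"]] * U + as.vector(G %*% b_pleio)
      for (m in mediators) lp <- lp + beta[[m]] * med[[m]]
      list(edu = edu, med = med, lp = lp)
    }

    cohort <- function(n) {
      G <- draw_genotypes(n, maf, block_id, cfg$ld_rho)
      U <- rnorm(n)
      c(list(G = G, U = U), build_traits(G, U))
    }

    n_c <- cfg$n_per_cohort
    exp_cohort <- cohort(n_c[["education"]])
    med_cohorts <- lapply(setNames(mediators, mediators),
                          function(m) cohort(n_c[[m]]))

    # outcome cohort: first ceil(c * n) individuals reused from the exposure cohort
    n_out <- n_c[["outcome"]]
    n_ov <- min(ceiling(cfg$overlap_frac * n_out), n_c[["education"]], n_out)
    if (n_ov > 0) {
      fresh <- cohort(n_out - n_ov)
      idx <- seq_len(n_ov)
      out_cohort <- list(
        G = rbind(exp_cohort$G[idx, , drop = FALSE], fresh$G),
        U = c(exp_cohort$U[idx], fresh$U),
        edu = c(exp_cohort$edu[idx], fresh$edu),
        lp = c(exp_cohort$lp[idx], fresh$lp)
      )
    } else {
      out_cohort <- cohort(n_out)
    }
    liability <- out_cohort$lp + rlogis(n_out)
    y <- as.double(liability > quantile(liability, 1 - cfg$outcome_prevalence))

    mk_table <- function(assoc, G, n) {
      validate_summary_table(tibble(
        snp = snp, chr = 1L, pos = pos, ea = alleles[, 1], oa = alleles[, 2],
        eaf = pmin(pmax(colMeans(G) / 2, 1e-6), 1 - 1e-6),
        beta = assoc$beta, se = assoc$se, pval = assoc$pval, n = n
      ))
    }

    tables <- list(
      education = mk_table(per_snp_linear(exp_cohort$G, exp_cohort$edu),
                           exp_cohort$G, n_c[["education"]])
    )
    for (m in mediators) {
      tables[[m]] <- mk_table(per_snp_linear(med_cohorts[[m]]$G, med_cohorts[[m]]$med[[m]]),
                              med_cohorts[[m]]$G, n_c[[m]])
    }
    tables$outcome <- mk_table(per_snp_logistic(out_cohort$G, y),
                               out_cohort$G, n_out)

    ld <- ld_matrix(cor(exp_cohort$G), snp)

    list(
      tables = tables,
      ld = ld,
      truth = list(
        b_edu = setNames(b_edu, snp), b_mediator = lapply(b_med, setNames, snp),
        b_pleiotropy = setNames(b_pleio, snp),
        alpha = alpha, beta = beta,
        gamma_star = gstar, gamma = cfg$true_total_effect,
        maf = setNames(maf, snp), block = setNames(block_id, snp)
      )
    )
  })
}

#' Fast summary-level instrument generator
#'
#' Samples harmonized instrument effects directly from their sampling
#' distributions (`bx_hat ~ N(bx, se_x^2)`, `by_hat ~ N(gamma * bx +
#' pleiotropy, se_y^2)`) without simulating individuals. Intended for
#' replicate-heavy calibration studies of the estimators; `overlap_r` injects
#' the cross-cohort sampling correlation that overlapping cohorts create.
#'
#' @param n_snp Number of instruments.
#' @param gamma True causal effect of exposure on outcome.
#' @param bx True exposure effects (recycled; default `runif(0.03, 0.1)`).
#' @param se_x,se_y Sampling SEs of the exposure/outcome effects (recycled).
#' @param pleiotropy Per-SNP direct outcome effects (recycled; default 0).
#' @param overlap_r Correlation between the sampling errors of `bx` and `by`
#'   (≈ overlap fraction times the phenotypic correlation).
#' @param seed Integer seed.
#' @return An `mr_harmonized` tibble (`snp, bx, se_x, by, se_y`) with the
#'   generating values in `attr(, "truth")`.
#' @export
simulate_ivs <- function(n_snp = 50, gamma = 0, bx = NULL,
                         se_x = 0.005, se_y = 0.02,
                         pleiotropy = 0, overlap_r = 0, seed = NULL) {
  with_seed(seed, {
    bx_true <- if (is.null(bx)) runif(n_snp, 0.03, 0.1) else rep_len(bx, n_snp)
    se_x <- rep_len(se_x, n_snp)
    se_y <- rep_len(se_y, n_snp)
    pleiotropy <- rep_len(pleiotropy, n_snp)
    ex <- rnorm(n_snp)
    ey <- overlap_r * ex + sqrt(1 - overlap_r^2) * rnorm(n_snp)
    h <- tibble(
      snp = sprintf("rs%05d", seq_len(n_snp)),
      bx = bx_true + se_x * ex,
      se_x = se_x,
      by = gamma * bx_true + pleiotropy + se_y * ey,
      se_y = se_y
    )
    attr(h, "truth") <- list(gamma = gamma, bx = bx_true, pleiotropy = pleiotropy)
    class(h) <- c("mr_harmonized", class(h))
    h
  })
}

#' Configuration for the synthetic survey population
#'
#' Parameters of an NHANES-like stratified multistage sample: covariate
#' marginals, the education -> smoking and education -> BMI generating
#' equations, the logit coefficients of the binary low-back-pain outcome, and
#' the design (strata, PSUs, log-normal weights scaled to a population total).
#' Education enters the outcome logit through explicit per-level direct
#' effects (`edu_hs`, `edu_above_hs`, vs the below-high-school reference);
#' smoking enters as ever-vs-never, BMI per kg/m^2 centred at 28.
#'
#' Defaults encode a population in which education lowers smoking
#' (log-odds -0.478 per level), barely shifts BMI (-0.16 kg/m^2 per level),
#' and has adjusted direct effects log(0.93)/log(0.72) on the outcome, with
#' baseline outcome prevalence 0.39.
#'
#' @param n Sample size (>= 100).
#' @param n_strata,psus_per_stratum Survey design layout.
#' @param pop_size Population total the weights are scaled to.
#' @param weight_sdlog SD(log) of the raw log-normal weights.
#' @param lbp_intercept Outcome logit intercept (baseline prevalence
#'   `plogis(lbp_intercept)` must lie in (0.01, 0.99)).
#' @param coef_lbp Named list of outcome-logit coefficients: `edu_hs`,
#'   `edu_above_hs`, `smoking` (ever vs never), `bmi` (per kg/m^2, centred),
#'   `female`, `htn_dm`, `tv_hours`.
#' @param coef_smoking Named list for the ever-smoking logit: `intercept`,
#'   `education` (per ordinal level 0/1/2), `male`.
#' @param coef_bmi Named list for the BMI linear model: `intercept`,
#'   `education` (kg/m^2 per level), `sd`.
#' @param seed Integer seed.
#' @return A `survey_config` list.
#' @export
survey_config <- function(n = 5000, n_strata = 15, psus_per_stratum = 2,
                          pop_size = 2e8, weight_sdlog = 0.5,
                          lbp_intercept = qlogis(0.39),
                          coef_lbp = list(edu_hs = log(0.93), edu_above_hs = log(0.72),
                                          smoking = log(1.24), bmi = log(1.02),
                                          female = 0.15, htn_dm = 0.3, tv_hours = 0.03),
                          coef_smoking = list(intercept = 0.6, education = -0.478,
                                              male = 0.4),
                          coef_bmi = list(intercept = 28.5, education = -0.16, sd = 6.2),
                          seed = 1L) {
  if (n < 100) abort("survey n must be >= 100")
  base_prev <- plogis(lbp_intercept)
  if (base_prev <= 0.01 || base_prev >= 0.99) {
    abort("lbp_intercept implies a prevalence outside (0.01, 0.99)")
  }
  defaults <- formals(survey_config)
  coef_lbp <- modifyList(eval(defaults$coef_lbp), coef_lbp)
  coef_smoking <- modifyList(eval(defaults$coef_smoking), coef_smoking)
  coef_bmi <- modifyList(eval(defaults$coef_bmi), coef_bmi)
  if (!all(vapply(c(coef_lbp, coef_smoking, coef_bmi), is.finite, logical(1)))) {
    abort("all generating coefficients must be finite")
  }
  structure(
    list(n = as.integer(n), n_strata = as.integer(n_strata),
         psus_per_stratum = as.integer(psus_per_stratum),
         pop_size = pop_size, weight_sdlog = weight_sdlog,
         lbp_intercept = lbp_intercept, coef_lbp = coef_lbp,
         coef_smoking = coef_smoking, coef_bmi = coef_bmi,
         seed = as.integer(seed)),
    class = "survey_config"
  )
}

#' Simulate an NHANES-like weighted survey population
#'
#' Draws person-level covariates from fixed marginals, generates smoking and
#' BMI from their education equations, the binary outcome from the logit in
#' [survey_config()], and attaches a stratified design (strata, 2+ PSUs per
#' stratum, log-normal weights scaled to `pop_size`).
#'
#' @param config A [survey_config()].
#' @return A tibble with columns `id, weight, stratum, psu, age, sex, race,
#'   marital, income, education, smoking, alcohol, activity, tv_hours, bmi,
#'   htn_dm, lbp`. Education is an ordered factor `<HS < HS < >HS`.
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n
    age <- pmin(pmax(rnorm(n, 46, 16.4), 20), 85)
    sex <- sample(c("male", "female"), n, replace = TRUE)
    race <- sample(c("nh_white", "nh_black", "mexican_american", "other"),
                   n, replace = TRUE, prob = c(0.74, 0.10, 0.07, 0.09))
    marital <- sample(c("married_partner", "alone"), n, replace = TRUE,
                      prob = c(0.65, 0.35))
    income <- sample(c("low", "medium", "high"), n, replace = TRUE,
                     prob = c(0.21, 0.36, 0.43))
    # conceptually ordered but stored as a plain factor so model matrices use
    # treatment contrasts with <HS as the reference level
    education <- factor(
      sample(c("<HS", "HS", ">HS"), n, replace = TRUE, prob = c(0.28, 0.24, 0.48)),
      levels = c("<HS", "HS", ">HS")
    )
    edu_code <- as.integer(education) - 1L
    alcohol <- rbinom(n, 1, 0.73)
    activity <- sample(c("sedentary", "moderate", "vigorous"), n, replace = TRUE,
                       prob = c(0.35, 0.30, 0.35))
    tv_hours <- pmin(rlnorm(n, log(2.8), 0.6), 16)

    cs <- cfg$coef_smoking
    p_ever <- plogis(cs$intercept + cs$education * edu_code +
                       cs$male * (sex == "male"))
    ever <- rbinom(n, 1, p_ever)
    smoking <- ifelse(ever == 1,
                      ifelse(runif(n) < 0.45, "current", "former"), "never")
    smoking <- factor(smoking, levels = c("never", "former", "current"))

    cb <- cfg$coef_bmi
    bmi <- pmin(pmax(cb$intercept + cb$education * edu_code +
                       rnorm(n, 0, cb$sd), 15), 60)
    htn_dm <- rbinom(n, 1, plogis(-2.2 + 0.04 * (age - 46)))

    cl <- cfg$coef_lbp
    lp <- cfg$lbp_intercept +
      cl$edu_hs * (education == "HS") + cl$edu_above_hs * (education == ">HS") +
      cl$smoking * ever + cl$bmi * (bmi - 28) +
      cl$female * (sex == "female") + cl$htn_dm * htn_dm + cl$tv_hours * tv_hours
    lbp <- rbinom(n, 1, plogis(lp))

    stratum <- sample(sprintf("str%02d", seq_len(cfg$n_strata)), n, replace = TRUE)
    psu <- paste0(stratum, "_psu",
                  sample.int(cfg$psus_per_stratum, n, replace = TRUE))
    w <- rlnorm(n, 0, cfg$weight_sdlog)
    w <- w * cfg$pop_size / sum(w)

    validate_survey(tibble(
      id = seq_len(n), weight = w, stratum = stratum, psu = psu,
      age = age, sex = sex, race = race, marital = marital, income = income,
      education = education, smoking = smoking, alcohol = alcohol,
      activity = activity, tv_hours = tv_hours, bmi = bmi,
      htn_dm = htn_dm, lbp = lbp
    ))
  })
}
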