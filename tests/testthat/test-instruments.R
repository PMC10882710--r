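test_that("p-value selection is strict and errors on empty results", {
  tab <- toy_summary(3)
  tab$pval <- c(1e-9, 1e-7, 5e-8)
  out <- select_by_pvalue(tab, 5e-8)
  expect_identical(out$snp, tab$snp[1]) # strictly below the threshold only
  expect_equal(nrow(exclusions(out)), 2)
  tab$pval <- rep(0.5, 3)
  expect_error(select_by_pvalue(tab, 5e-8), "no instruments")
  expect_error(select_by_pvalue(tab, 2), "threshold")
})

test_that("null p-values pass the selection filter at the binomial rate", {
  withr::with_seed(11, {
    z <- rnorm(1000)
    tab <- tibble::tibble(
      snp = sprintf("rs%04d", 1:1000), chr = 1L, pos = 1:1000 * 1000L,
      ea = "A", oa = "G", eaf = 0.3, beta = z * 0.01, se = 0.01,
      pval = 2 * pnorm(-abs(z)), n = 1000L
    )
  })
  kept <- nrow(select_by_pvalue(tab, 0.05))
  band <- 2 * sqrt(1000 * 0.05 * 0.95) # ~14
  expect_lt(abs(kept - 50), band)
})

test_that("greedy clumping keeps index SNPs and matches the naive oracle", {
  tab <- toy_summary(3)
  ld0 <- ld_matrix(diag(3), tab$snp)
  expect_identical(sort(clump(tab, ld0)$snp), sort(tab$snp))

  # dominance: the smaller p of a correlated pair wins
  tab2 <- toy_summary(2)
  tab2$pval <- c(1e-10, 1e-9)
  tab2$pos <- c(1000L, 1000L)
  r <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2)
  out <- clump(tab2, ld_matrix(r, tab2$snp), r2_max = 0.001)
  expect_identical(out$snp, "rs00001")

  expect_error(clump(tab2, ld_matrix(diag(2), c("x1", "x2"))),
               "missing from LD matrix")

  # randomized 10-SNP instances against the loop-based oracle
  for (s in 1:8) {
    withr::with_seed(s, {
      t10 <- toy_summary(10, seed = s, pos_step = 400000L)
      a <- matrix(rnorm(100), 10)
      r10 <- cov2cor(crossprod(a) + diag(10) * 0.5)
    })
    ld10 <- ld_matrix(r10, t10$snp)
    got <- clump(t10, ld10, r2_max = 0.1, window_kb = 1000)
    want <- oracle_clump(t10, unclass(ld10), r2_max = 0.1,
                         window_bp = 1000 * 1000)
    expect_setequal(got$snp, want)
    # retained pairs within a window respect the r2 bound
    rr <- unclass(ld10)[got$snp, got$snp]^2
    pos <- got$pos
    for (i in seq_len(nrow(got))) {
      for (j in seq_len(nrow(got))) {
        if (i != j && abs(pos[i] - pos[j]) <= 1e6) expect_lte(rr[i, j], 0.1)
      }
    }
  }
})

test_that("clumping is invariant to input row order", {
  t10 <- toy_summary(10, seed = 21, pos_step = 2000L)
  withr::with_seed(21, {
    a <- matrix(rnorm(100), 10)
    r10 <- cov2cor(crossprod(a) + diag(10) * 0.3)
  })
  ld10 <- ld_matrix(r10, t10$snp)
  out1 <- clump(t10, ld10, r2_max = 0.2)
  out2 <- clump(t10[sample.int(10), ], ld10, r2_max = 0.2)
  expect_identical(out1$snp, out2$snp)
})

test_that("outcome-associated instruments are excluded, absent ones kept", {
  ivs <- toy_summary(6, seed = 4)
  outcome <- toy_summary(6, seed = 5)
  outcome$pval <- c(1e-7, 0.2, 0.3, 1e-8, 0.5, 0.6)
  outcome$snp[6] <- "rs_absent"
  out <- exclude_outcome_associated(ivs, outcome, threshold = 5e-6)
  expect_setequal(out$snp, ivs$snp[c(2, 3, 5, 6)])
  log <- exclusions(out)
  expect_equal(sum(grepl("retained", log$reason)), 1)

  # planted-truth count: exactly the 5 planted SNPs drop
  ivs2 <- toy_summary(50, seed = 6)
  out2 <- toy_summary(50, seed = 7)
  out2$pval <- runif(50, 0.1, 1)
  planted <- c(3, 11, 19, 27, 44)
  out2$pval[planted] <- 1e-9
  kept <- exclude_outcome_associated(ivs2, out2)
  expect_setequal(kept$snp, ivs2$snp[-planted])
})

test_that("F statistics follow (beta/se)^2 and the weak screen", {
  tab <- toy_summary(2)
  tab$beta <- c(0.4, 0.1)
  tab$se <- c(0.1, 0.1)
  tab$pval <- 2 * pnorm(-abs(tab$beta / tab$se))
  flagged <- f_statistics(tab, action = "flag")
  expect_equal(flagged$f_stat, c(16, 1))
  expect_equal(flagged$weak, c(FALSE, TRUE))
  dropped <- f_statistics(tab, action = "drop")
  expect_identical(dropped$snp, "rs00001")
  expect_equal(mean_f(dropped), 16)
})

test_that("mean F agrees with the (n-2) R^2 / (1 - R^2) oracle", {
  cfg <- sim_config(n_snps = 60, n_per_cohort = 6000, h2_exposure = 0.3,
                    effect_edu_on_mediator = c(m = 0),
                    effect_mediator_on_outcome = c(m = 0),
                    n_instruments_exposure = 10, n_instruments_mediator = 2,
                    seed = 19)
  sim <- simulate_cohorts(cfg)
  causal <- names(sim$truth$b_edu)[sim$truth$b_edu != 0]
  ivs <- f_statistics(dplyr::filter(sim$tables$education, snp %in% causal),
                      action = "flag")
  n <- 6000
  r2 <- sim$truth$b_edu[causal]^2 *
    (2 * sim$truth$maf[causal] * (1 - sim$truth$maf[causal]))
  f_oracle <- mean((n - 2) * r2 / (1 - r2))
  expect_lt(abs(mean_f(ivs) - f_oracle) / f_oracle, 0.1)
})

test_that("mediator instruments overlapping the exposure are removed", {
  med <- toy_summary(10, seed = 8)
  edu <- toy_summary(4, seed = 9)
  expect_identical(remove_overlapping_instruments(med, edu)$snp, med$snp[5:10])
  disjoint <- med
  disjoint$snp <- paste0("x", disjoint$snp)
  expect_identical(remove_overlapping_instruments(disjoint, med)$snp,
                   disjoint$snp)
  expect_warning(out <- remove_overlapping_instruments(med, med), "overlap")
  expect_equal(nrow(out), 0)

  med100 <- toy_summary(100, seed = 10)
  planted <- withr::with_seed(10, sample(med100$snp, 7))
  edu2 <- dplyr::filter(med100, snp %in% planted)
  expect_equal(nrow(remove_overlapping_instruments(med100, edu2)), 93)
})

test_that("harmonization follows the allele rule table", {
  base <- toy_summary(1, seed = 30)
  base$eaf <- 0.25
  base$beta <- 0.1
  mk <- function(ea, oa, eaf = 0.25, beta = 0.2) {
    out <- base
    out$ea <- ea
    out$oa <- oa
    out$eaf <- eaf
    out$beta <- beta
    out$pval <- 0.5
    out$se <- abs(beta) / 0.67 + 0.1
    out
  }
  exp_ag <- mk("A", "G", beta = 0.1)
  # hand-built expectations: (outcome ea, oa, eaf) -> harmonized by
  cases <- list(
    list("A", "G", 0.25, 0.2),   # identical
    list("G", "A", 0.75, -0.2),  # swapped -> sign flip
    list("T", "C", 0.25, 0.2),   # strand complement
    list("C", "T", 0.75, -0.2),  # complement + swap
    list("A", "C", 0.25, NA)     # mismatch -> drop
  )
  for (cs in cases) {
    out <- mk(cs[[1]], cs[[2]], cs[[3]])
    if (is.na(cs[[4]])) {
      expect_error(harmonize(exp_ag, out), "no SNPs survived")
    } else {
      h <- harmonize(exp_ag, out)
      expect_equal(h$by, cs[[4]])
      expect_equal(h$eaf_y, 0.25)
    }
  }

  # palindromic A/T: frequency decides, uninformative band drops
  exp_at <- mk("A", "T", eaf = 0.10, beta = 0.1)
  pal_cases <- list(
    list("A", "T", 0.12, 0.2),   # freq agrees -> keep
    list("A", "T", 0.88, -0.2),  # freq disagrees -> flip
    list("T", "A", 0.88, -0.2),
    list("T", "A", 0.12, 0.2),
    list("A", "T", 0.50, NA),    # uninformative -> drop
    list("A", "T", 0.455, NA)    # inside the 0.08 band -> drop
  )
  for (cs in pal_cases) {
    out <- mk(cs[[1]], cs[[2]], cs[[3]])
    if (is.na(cs[[4]])) {
      expect_error(harmonize(exp_at, out), "no SNPs survived")
    } else {
      h <- harmonize(exp_at, out)
      expect_equal(h$by, cs[[4]])
    }
  }
  # palindromic with uninformative exposure frequency also drops
  exp_mid <- mk("A", "T", eaf = 0.5, beta = 0.1)
  expect_error(harmonize(exp_mid, mk("A", "T", 0.10)), "no SNPs survived")
})

test_that("harmonization is an involution and exposure strand-flips are inert", {
  exposure <- toy_summary(12, seed = 31, alleles = c("A", "G"))
  outcome <- toy_summary(12, seed = 32, alleles = c("A", "G"))
  swap <- seq(2, 12, by = 3) # scramble some rows to exercise flips
  outcome$ea[swap] <- "G"
  outcome$oa[swap] <- "A"
  outcome$eaf[swap] <- 1 - outcome$eaf[swap]
  h1 <- harmonize(exposure, outcome)
  # rebuild the outcome in harmonized orientation and harmonize again: no-op
  outcome2 <- tibble::tibble(
    snp = h1$snp, chr = 1L, pos = exposure$pos[match(h1$snp, exposure$snp)],
    ea = h1$ea, oa = h1$oa, eaf = h1$eaf_y, beta = h1$by, se = h1$se_y,
    pval = outcome$pval[match(h1$snp, outcome$snp)], n = 10000L
  )
  h2 <- harmonize(exposure, outcome2)
  expect_equal(h2$by, h1$by)
  expect_equal(h2$flipped, rep(FALSE, nrow(h2)))

  # flipping every exposure row (alleles, beta sign, eaf) leaves MR unchanged
  flipped <- exposure
  flipped$ea <- exposure$oa
  flipped$oa <- exposure$ea
  flipped$beta <- -exposure$beta
  flipped$eaf <- 1 - exposure$eaf
  f1 <- mr_ivw(harmonize(exposure, outcome))
  f2 <- mr_ivw(harmonize(flipped, outcome))
  expect_equal(f2$estimate, f1$estimate, tolerance = 1e-12)
  expect_equal(f2$se, f1$se, tolerance = 1e-12)

  expect_error(harmonize(exposure, dplyr::mutate(outcome, snp = paste0("z", snp))),
               "no shared SNPs")
})
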