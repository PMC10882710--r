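test_that("Wald ratio arithmetic and SE options", {
  w <- wald_ratio(bx = 0.5, se_x = 0.02, by = 0.25, se_y = 0.1)
  expect_equal(w$estimate, 0.5)
  expect_equal(w$se, 0.2)
  expect_equal(wald_ratio(0.5, 0.02, 0, 0.1)$estimate, 0)
  expect_error(wald_ratio(0, 0.02, 0.1, 0.1), "bx = 0")

  # second-order delta SE against a large Monte-Carlo oracle
  bx <- 0.2; se_x <- 0.02; by <- 0.1; se_y <- 0.03
  w2 <- wald_ratio(bx, se_x, by, se_y, se_method = "second")
  mc <- withr::with_seed(77, {
    sd(rnorm(1e6, by, se_y) / rnorm(1e6, bx, se_x))
  })
  expect_lt(abs(w2$se - mc) / mc, 0.05)
})

test_that("IVW matches its closed form, the Wald ratio, and the meta-analytic identity", {
  h3 <- tibble::tibble(snp = c("a", "b", "c"),
                       bx = c(0.1, 0.2, 0.3), se_x = 0.01,
                       by = c(0.05, 0.10, 0.15), se_y = 0.01)
  fit <- mr_ivw(h3)
  expect_equal(fit$estimate, 0.5, tolerance = 1e-12)
  expect_equal(fit$extras$Q, 0, tolerance = 1e-20)
  expect_equal(fit$se, 1 / sqrt(1400), tolerance = 1e-12) # Q = 0 -> fixed SE

  h1 <- tibble::tibble(snp = "a", bx = 0.4, se_x = 0.05, by = 0.1, se_y = 0.08)
  expect_equal(mr_ivw(h1)$estimate, wald_ratio(0.4, 0.05, 0.1, 0.08)$estimate)
  expect_equal(mr_ivw(h1)$se, wald_ratio(0.4, 0.05, 0.1, 0.08)$se)

  # IVW == fixed-effect meta-analysis of Wald ratios weighted by bx^2/se_y^2
  h <- simulate_ivs(25, gamma = 0.4, seed = 3)
  ratio <- h$by / h$bx
  wts <- h$bx^2 / h$se_y^2
  expect_equal(mr_ivw(h, "fixed")$estimate, sum(wts * ratio) / sum(wts),
               tolerance = 1e-10)
  expect_equal(mr_ivw(h, "fixed")$se, 1 / sqrt(sum(wts)), tolerance = 1e-10)

  expect_error(mr_ivw(dplyr::mutate(h, bx = 0)), "zero")
})

test_that("estimators are equivariant under exposure rescaling and RE >= fixed SE", {
  h <- simulate_ivs(20, gamma = -0.5, seed = 8)
  k <- 2.5
  hk <- dplyr::mutate(h, bx = bx * k, se_x = se_x * k)
  expect_equal(mr_ivw(hk)$estimate, mr_ivw(h)$estimate / k, tolerance = 1e-10)
  expect_equal(mr_egger(hk)$estimate, mr_egger(h)$estimate / k, tolerance = 1e-10)
  wm <- mr_weighted_median(h, n_boot = 50, seed = 1)
  wmk <- mr_weighted_median(hk, n_boot = 50, seed = 1)
  expect_equal(wmk$estimate, wm$estimate / k, tolerance = 1e-10)
  expect_gte(mr_ivw(h)$se, mr_ivw(h, "fixed")$se)
})

test_that("MR-Egger recovers exact fits and planted directional pleiotropy", {
  h <- proportional_h(slope = 0.3)
  e <- mr_egger(h)
  expect_equal(e$estimate, 0.3, tolerance = 1e-10)
  expect_equal(e$extras$egger_intercept, 0, tolerance = 1e-12)
  # zero fitted intercept => Egger slope equals IVW
  expect_equal(e$estimate, mr_ivw(h)$estimate, tolerance = 1e-10)

  h2 <- simulate_ivs(60, gamma = -0.3, pleiotropy = 0.02, se_y = 0.01, seed = 14)
  e2 <- mr_egger(h2)
  expect_lt(abs(e2$extras$egger_intercept - 0.02), 3 * e2$extras$intercept_se)

  expect_error(mr_egger(dplyr::mutate(h, bx = 0.2)), "zero variance")
  expect_error(mr_egger(h[1:2, ]), "at least 3")
})

test_that("weighted median follows the interpolated-median rule", {
  h_same <- tibble::tibble(snp = letters[1:4], bx = c(0.1, 0.2, 0.25, 0.4),
                           se_x = 0.01, by = 0.4 * c(0.1, 0.2, 0.25, 0.4),
                           se_y = 0.02)
  expect_equal(mr_weighted_median(h_same, n_boot = 30, seed = 1)$estimate, 0.4,
               tolerance = 1e-10)
  # equal weights, ratios 1..5 -> interpolated median exactly 3
  # exactly equal ratio SEs (se_x = 0) so the weights are uniform
  h5 <- tibble::tibble(snp = letters[1:5], bx = 1, se_x = 0,
                       by = 1:5, se_y = 1)
  expect_equal(mr_weighted_median(h5, n_boot = 30, seed = 1)$estimate, 3)

  # median and mode stay inside the ratio range
  for (s in 1:5) {
    h <- simulate_ivs(15, gamma = 0.2, pleiotropy = rep(c(0, 0.05), length.out = 15),
                      seed = 100 + s)
    r <- range(h$by / h$bx)
    for (phi in c(1, 2)) {
      m <- mr_weighted_mode(h, phi = phi, n_boot = 10, seed = s)$estimate
      expect_gte(m, r[1]); expect_lte(m, r[2])
    }
    wm <- mr_weighted_median(h, n_boot = 10, seed = s)$estimate
    expect_gte(wm, r[1]); expect_lte(wm, r[2])
  }
})

test_that("weighted median resists invalid instruments better than IVW", {
  bias_m <- bias_i <- numeric(60)
  for (s in 1:60) {
    pl <- c(rep(0.15, 6), rep(0, 14)) # 30% invalid, large directional pleiotropy
    h <- simulate_ivs(20, gamma = 0.3, pleiotropy = pl, seed = 500 + s)
    bias_m[s] <- mr_weighted_median(h, n_boot = 2, seed = s)$estimate - 0.3
    bias_i[s] <- mr_ivw(h)$estimate - 0.3
  }
  expect_lt(abs(median(bias_m)), abs(median(bias_i)))
})

test_that("weighted mode finds the majority cluster", {
  h_same <- proportional_h(0.4, n = 5)
  expect_equal(mr_weighted_mode(h_same, n_boot = 10, seed = 1)$estimate, 0.4,
               tolerance = 1e-8)
  # 7 of 10 SNPs share ratio 0.5, three sit far away
  h <- tibble::tibble(
    snp = letters[1:10], bx = 0.2, se_x = 0.001,
    by = 0.2 * c(rep(0.5, 7), 1.8, 2.0, 2.2), se_y = 0.01
  )
  m <- mr_weighted_mode(h, n_boot = 10, seed = 2)$estimate
  grid_step <- diff(range(h$by / h$bx)) / 511
  expect_lt(abs(m - 0.5), grid_step + 0.05) # within kernel-smoothing wobble
})

test_that("Cochran's Q is zero for proportional data and sums contributions", {
  h <- proportional_h(0.25)
  q <- cochran_q(h, "ivw")
  expect_equal(q$Q, 0, tolerance = 1e-18)
  expect_equal(q$pval, 1)
  h3 <- tibble::tibble(snp = c("a", "b", "c"), bx = c(0.1, 0.2, 0.3),
                       se_x = 0.01, by = c(0.05, 0.10, 0.15), se_y = 0.01)
  expect_equal(cochran_q(h3, "ivw")$Q, 0, tolerance = 1e-18)
  h2 <- simulate_ivs(12, gamma = 0.3, seed = 4)
  q2 <- cochran_q(h2, "ivw")
  expect_equal(q2$Q, sum(attr(q2, "contributions")$contribution))
  expect_equal(q2$df, 11)
  expect_equal(cochran_q(h2, "egger")$df, 10)
})

test_that("leave-one-out produces n+1 rows and exposes planted outliers", {
  h <- simulate_ivs(12, gamma = 0.3, seed = 6)
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 13)
  full <- loo$estimate[loo$omitted == "none"]
  fixed_se <- mr_ivw(h, "fixed")$se
  expect_true(all(abs(loo$estimate - full) <= fixed_se))

  h$by[5] <- h$by[5] + 8 * h$se_y[5]
  loo2 <- leave_one_out(h)
  full2 <- loo2$estimate[loo2$omitted == "none"]
  deltas <- abs(loo2$estimate - full2)[loo2$omitted != "none"]
  expect_equal(loo2$omitted[which.max(abs(loo2$estimate - full2))], h$snp[5])
  expect_equal(max(deltas), abs(loo2$estimate[loo2$omitted == h$snp[5]] - full2))
})

test_that("MR-PRESSO flags a planted outlier, is seeded, and corrects the estimate", {
  h <- simulate_ivs(30, gamma = -0.3, seed = 301)
  h$by[7] <- h$by[7] + 10 * h$se_y[7]
  p1 <- mr_presso(h, n_sim = 1000, seed = 4)
  p2 <- mr_presso(h, n_sim = 1000, seed = 4)
  expect_identical(p1$outliers, p2$outliers)
  expect_equal(p1$global_pval, p2$global_pval)
  expect_true("rs00007" %in% p1$outliers)
  expect_equal(p1$corrected$n_snp, 30 - length(p1$outliers))
  expect_estimate_close(p1$corrected, -0.3, n_se = 3)
  expect_error(mr_presso(h[1:3, ]), "at least 4")
})

test_that("overlap bias formula has the stated boundary behaviour", {
  out <- overlap_bias(0, mean_f = 15, confounded_assoc = 0.4, se_iv = 0.05)
  expect_equal(out$bias, 0)
  expect_equal(out$type1, 0.05, tolerance = 1e-10)
  out2 <- overlap_bias(0.7, mean_f = 15, confounded_assoc = 0, se_iv = 0.05)
  expect_equal(out2$type1, 0.05, tolerance = 1e-10)
  expect_error(overlap_bias(1.5, 10, 0.1, 0.05), "overlap_frac")
  expect_error(overlap_bias(0.5, 0.5, 0.1, 0.05), "mean_f")
})

test_that("tidy and glance return the documented columns", {
  h <- simulate_ivs(10, gamma = 0.1, seed = 2)
  td <- tidy(mr_ivw(h))
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high",
                     "p.value", "n_snp", "model"))
  gl <- glance(mr_egger(h))
  expect_true(all(c("egger_intercept", "intercept_p") %in% names(gl)))
  all_m <- mr_all_methods(h, n_boot = 20, seed = 1)
  expect_equal(nrow(all_m), 4)
  expect_true(!is.null(attr(all_m, "diagnostics")$q_ivw))
})
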