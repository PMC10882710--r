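# Shared fixtures and independent oracles used across the test files.
# Everything here is built in code; the oracles deliberately use naive
# loop-based implementations so they share no code path with the package.

# a small valid summary table with arbitrary but consistent values
toy_summary <- function(n = 5, seed = 1, chr = 1L, pos_step = 1000L,
                        alleles = c("A", "G")) {
  withr::with_seed(seed, {
    beta <- rnorm(n, 0, 0.05)
    se <- runif(n, 0.005, 0.02)
    tibble::tibble(
      snp = sprintf("rs%05d", seq_len(n)),
      chr = chr, pos = seq_len(n) * pos_step,
      ea = alleles[1], oa = alleles[2],
      eaf = runif(n, 0.1, 0.9),
      beta = beta, se = se,
      pval = 2 * pnorm(-abs(beta / se)),
      n = 10000L
    )
  })
}

# naive reference clumping written directly from the procedure description:
# explicit loops, no shared code with clump()
oracle_clump <- function(stats, r2_mat, r2_max, window_bp) {
  remaining <- stats[order(stats$pval, stats$snp), , drop = FALSE]
  kept <- character()
  assigned <- character()
  while (nrow(remaining) > 0) {
    idx <- remaining$snp[1]
    kept <- c(kept, idx)
    assigned <- c(assigned, idx)
    drop <- c()
    for (k in seq_len(nrow(remaining))[-1]) {
      cand <- remaining[k, ]
      irow <- remaining[1, ]
      if (cand$chr == irow$chr &&
          abs(cand$pos - irow$pos) <= window_bp &&
          r2_mat[irow$snp, cand$snp]^2 > r2_max) {
        drop <- c(drop, k)
      }
    }
    remaining <- remaining[-c(1, drop), , drop = FALSE]
  }
  kept
}

# simple weighted-ratio data where every method should agree
proportional_h <- function(slope = 0.3, n = 5) {
  tibble::tibble(
    snp = sprintf("s%02d", seq_len(n)),
    bx = seq(0.1, by = 0.05, length.out = n), se_x = 0.01,
    by = slope * seq(0.1, by = 0.05, length.out = n), se_y = 0.02
  )
}

expect_estimate_close <- function(fit, truth, n_se = 3) {
  expect_lt(abs(fit$estimate - truth), n_se * fit$se)
}
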