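make_flat_trace <- function(id, init_total, n = 20) {
  cell_trace(id, time_min = (0:(n - 1)) * 5,
             nuc_p65 = rep(init_total / 2, n), cyt_p65 = rep(init_total / 2, n),
             venus = rep(0, n), t_stim_min = 25)
}

test_that("QC filter cuts at the inclusive 25th/99th percentile boundaries", {
  traces <- lapply(1:100, function(i) make_flat_trace(paste0("c", i), i))
  kept <- qc_filter(traces)
  expect_length(kept, 75)  # 1..24 and 100 removed from the 1..100 ladder
  kept_init <- vapply(kept, function(tr) tr$nuc_p65[1] + tr$cyt_p65[1], 1)
  expect_equal(range(kept_init), c(25, 99))
  expect_setequal(attr(kept, "rejected"),
                  paste0("c", c(1:24, 100)))
})

test_that("QC filter degenerate cases", {
  traces <- lapply(1:30, function(i) make_flat_trace(paste0("c", i), 50))
  expect_length(qc_filter(traces), 30)  # identical values: none removed
  expect_warning(kept <- qc_filter(traces[1]), "single cell")
  expect_length(kept, 1)
  expect_error(qc_filter(list()), "empty")
})

test_that("flat traces yield no peak and defined expression features", {
  tr <- linear_trace((0:40) * 5, rep(1, 41), t_stim = 50,
                     venus = seq(0, 400, length.out = 41))
  f <- extract_features(tr)
  expect_equal(f$n_peaks, 0)
  expect_true(is.na(f$peak_amplitude))
  expect_true(is.na(f$auc_steady))
  expect_equal(f$expr_max, 400)
  expect_equal(f$expr_p95, unname(quantile(tr$venus, 0.95)))
})

test_that("triangular pulse returning to baseline has near-zero AUC steady", {
  # baseline 1; peak to 3 at t = 15; back to 1 by t = 45; flat to t = 150
  t <- seq(0, 150, by = 5)
  r <- approx(c(0, 15, 45, 150), c(1, 3, 1, 1), xout = t)$y
  f <- extract_features(linear_trace(t, r, t_stim = 0))
  expect_equal(f$peak_amplitude, 2)
  expect_equal(f$time_to_peak_min, 15)
  expect_equal(f$auc_steady, 0)
})

test_that("post-peak plateau integrates by the trapezoid rule", {
  # pulse decays to a 1.5 plateau held for 100 min: AUC = 0.5 * 100
  t <- seq(0, 160, by = 5)
  r <- approx(c(0, 15, 60, 160), c(1, 3, 1.5, 1.5), xout = t)$y
  f <- extract_features(linear_trace(t, r, t_stim = 0))
  expect_equal(f$auc_steady, 0.5 * 100)
})

test_that("AUC steady is invariant to adding a constant to the trace", {
  t <- seq(0, 200, by = 5)
  set.seed(12)
  r <- 1 + 2 * exp(-(t - 20)^2 / 200) + 0.3 * (t > 60) + rnorm(length(t), 0, 0.01)
  f1 <- extract_features(linear_trace(t, r, t_stim = 5))
  f2 <- extract_features(linear_trace(t, r + 5, t_stim = 5))
  expect_equal(f2$auc_steady, f1$auc_steady, tolerance = 1e-10)
  expect_equal(f2$peak_amplitude, f1$peak_amplitude, tolerance = 1e-10)
})

test_that("responder calls use strict exceedance of the control threshold", {
  calls <- classify_responders(c(a = 1.5, b = 1.2, c = 1.0),
                               control_scores = runif(20, 0.8, 1.2) * 0 + 1.2)
  expect_equal(calls$status, c("responder", "non_responder", "non_responder"))
  expect_equal(unique(calls$threshold), 1.2)
  expect_error(classify_responders(1, numeric(0)), "control")
})

test_that("responder calling is scale-equivariant", {
  set.seed(13)
  scores <- c(rnorm(50, 3, 0.3), rnorm(250, 1, 0.05))
  controls <- rnorm(100, 1, 0.05)
  a <- classify_responders(scores, controls)
  b <- classify_responders(scores * 7, controls * 7)
  expect_identical(a$status, b$status)
})

test_that("bimodal synthetic population recovers the responder fraction", {
  set.seed(14)
  n <- 1000
  resp <- runif(n) < 0.15
  scores <- ifelse(resp, rnorm(n, 3, 0.3), rnorm(n, 1, 0.05))
  controls <- rnorm(400, 1, 0.05)
  calls <- classify_responders(scores, controls)
  rf <- responder_fraction(calls)
  expect_lt(abs(rf$fraction - 0.15), 3 * sqrt(0.15 * 0.85 / n) + 0.02)
  expect_true(rf$ci["low"] < 0.15 & 0.15 < rf$ci["high"])
})

test_that("Wilson interval matches the 15/100 reference", {
  rf <- responder_fraction(rep(c("responder", "non_responder"), c(15, 85)))
  expect_equal(rf$fraction, 0.15)
  expect_equal(unname(rf$ci), c(0.0932, 0.2329), tolerance = 1e-3)
  rf0 <- responder_fraction(rep("non_responder", 50))
  expect_equal(rf0$fraction, 0)
  expect_equal(unname(rf0$ci["low"]), 0)
  expect_equal(responder_fraction(rep("responder", 10))$fraction, 1)
})

test_that("bimodality coefficient has its analytic anchors", {
  set.seed(15)
  u <- runif(200000)
  expect_equal(bimodality_coefficient(u, log_scores = FALSE), 5 / 9,
               tolerance = 0.01, ignore_attr = TRUE)
  g <- rnorm(200000)
  expect_equal(bimodality_coefficient(g, log_scores = FALSE), 1 / 3,
               tolerance = 0.01, ignore_attr = TRUE)
  mix <- c(rnorm(1e5, 0, 0.05), rnorm(1e5, 3, 0.05))
  bc <- bimodality_coefficient(mix, log_scores = FALSE)
  expect_gt(bc, 5 / 9)
  expect_true(attr(bc, "bimodal"))
  expect_error(bimodality_coefficient(rep(2, 10)), "variance")
  expect_error(bimodality_coefficient(1:3), "at least 4")
})

test_that("feature correlations and dose regressions behave", {
  df <- data.frame(a = 1:9, b = 2 * log10(rep(c(1, 10, 100), each = 3)),
                   c = rep(5, 9),
                   concentration = rep(c(1, 10, 100), each = 3))
  fc <- feature_correlations(df)
  expect_equal(fc$R["a", "a"], 1)
  expect_true(is.na(fc$R["c", "a"]))  # constant feature: undefined, not 0
  expect_equal(unname(fc$r_squared["b"]), 1)  # exact log-linear dose response
})

test_that("uncorrelated latent expression stays near zero correlation", {
  set.seed(16)
  n <- 600
  amp <- rlnorm(n, 0, 0.3)
  expr <- rlnorm(n, 1, 0.4)  # independent of amplitude by construction
  fc <- feature_correlations(data.frame(amp = amp, expr = expr))
  expect_lt(abs(fc$R["amp", "expr"]), 0.12)
})

test_that("chi-squared count comparison has the stated conventions", {
  set.seed(17)
  a <- rpois(150, 2); b <- rpois(200, 20)
  res <- compare_count_distributions(a, b, n_bins = 10)
  expect_lte(res$df, 9)
  expect_gt(res$chi2, 0)
  expect_lt(res$p_value, 1e-10)

  # identical distributions: statistic 0, p = 1
  res0 <- compare_count_distributions(a, a)
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p_value, 1)

  # permutation symmetry in group labels
  res_ab <- compare_count_distributions(a, b)
  res_ba <- compare_count_distributions(b, a)
  expect_equal(res_ab$chi2, res_ba$chi2)
  expect_equal(res_ab$p_value, res_ba$p_value)
})
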