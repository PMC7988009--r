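test_that("generators are byte-identical under a fixed seed", {
  expect_identical(gen_trace_set(20, seed = 61), gen_trace_set(20, seed = 61))
  expect_identical(gen_monolayer_field(10, 3, seed = 62),
                   gen_monolayer_field(10, 3, seed = 62))
  expect_identical(gen_methyl_reads(50, 0.5, seed = 63),
                   gen_methyl_reads(50, 0.5, seed = 63))
  expect_identical(gen_dose_response(c(0.1, 1), 100, seed = 64),
                   gen_dose_response(c(0.1, 1), 100, seed = 64))
})

test_that("noise-free non-responders are exactly flat", {
  g <- gen_trace_set(30, responder_fraction = 0, noise_sd = 0,
                     baseline_sd = 0, seed = 65)
  for (tr in g$traces) {
    r <- nc_ratio(tr)
    expect_lt(diff(range(r)), 1e-9)
  }
})

test_that("pulsatile responders have ~zero AUC steady, oscillatory have more", {
  gp <- gen_trace_set(200, responder_fraction = 1, mode = "pulsatile",
                      noise_sd = 0.01, seed = 66)
  go <- gen_trace_set(200, responder_fraction = 1, mode = "oscillatory",
                      noise_sd = 0.01, seed = 66)
  auc <- function(g) {
    f <- do.call(rbind, lapply(g$traces, extract_features))
    median(f$auc_steady, na.rm = TRUE)
  }
  expect_gt(auc(go), 4 * max(auc(gp), 1))
})

test_that("end-to-end responder fraction is recovered from traces", {
  g <- gen_trace_set(600, responder_fraction = 0.15, seed = 67)
  ctrl <- gen_trace_set(200, responder_fraction = 0, seed = 68)
  score <- function(tr) max(nc_ratio(tr)[tr$time_min >= tr$t_stim_min])
  calls <- classify_responders(vapply(g$traces, score, 1),
                               vapply(ctrl$traces, score, 1))
  rf <- responder_fraction(calls)
  expect_true(rf$ci["low"] < 0.15 & 0.15 < rf$ci["high"])
})

test_that("monolayer fields collapse to points as displacement vanishes", {
  fld <- gen_monolayer_field(5, 3, disp_sd_um = 0, seed = 69)
  per_lineage <- split(fld$field, sub("_.*", "", fld$field$cell_id))
  for (df in per_lineage) {
    expect_lt(diff(range(df$x_um)), 1e-9)
    expect_lt(diff(range(df$y_um)), 1e-9)
  }
})

test_that("deterministic-heritage fields are all responders", {
  fld <- gen_monolayer_field(8, 3, p_on = 0, p_off = 0, initial_fraction = 1,
                             seed = 70)
  expect_true(all(fld$field$responder == 1))
})

test_that("methylation generator limits", {
  # no error, no missing: every read perfectly en bloc
  g <- gen_methyl_reads(100, 0.5, error_rate = 0, missing_rate = 0, seed = 71)
  cts <- window_unmeth_counts(g$matrix)
  expect_true(all(cts %in% c(0, attr(cts, "n_sites"))))
  expect_equal(unname(cts == attr(cts, "n_sites")),
               unname(g$truth[names(cts)] == "U"))
  # all calls missing: empty-matrix error propagates
  expect_error(gen_methyl_reads(50, 0.5, missing_rate = 1, seed = 72),
               "no reads")
})

test_that("10-bp grouping shares calls within a group", {
  pos <- c(-100, -96, -92, -70, -66)  # two groups: 3 sites + 2 sites
  g <- gen_methyl_reads(200, 0.5, positions = pos, error_rate = 0.3,
                        group_10bp = TRUE, seed = 73)
  m <- g$matrix
  expect_true(all(m[, 1] == m[, 2] & m[, 2] == m[, 3]))
  expect_true(all(m[, 4] == m[, 5]))
  # across groups, a 30% error rate must produce some disagreement
  expect_true(any(m[, 1] != m[, 4]))
})

test_that("dose-response saturates at f_max and halves at EC50", {
  d <- gen_dose_response(c(1e4, 0.1), n_cells = 5000, ec50 = 0.1, hill = 1,
                         f_max = 0.1538, seed = 74)
  expect_equal(d$p_true[1], 0.1538, tolerance = 1e-3)
  expect_equal(d$p_true[2], 0.1538 / 2)
  expect_lt(abs(d$fraction[1] - 0.1538), 3 * sqrt(0.154 * 0.846 / 5000))
  # default cap is the stationary fraction of the fitted switch
  d2 <- gen_dose_response(1e6, 2000, seed = 75)
  expect_equal(d2$p_true, stationary_fraction(0.01, 0.055), tolerance = 1e-4)
})
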