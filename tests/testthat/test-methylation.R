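test_that("LLR filtering and grouped-motif expansion follow the call rules", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_nanopolish_tsv(list(
    list(read = "r1", start = 890, llr = 2.3),                   # M
    list(read = "r1", start = 905, llr = 1.2),                   # ambiguous
    list(read = "r1", start = 920, llr = -4, num_motifs = 3,     # U x3 CpGs
         sequence = "AACGTTCGAACGTT"),
    list(read = "r2", start = 890, llr = -2.0)                   # U
  ), path)
  mat <- read_methyl_calls(path, tss = 1000, tss_strand = "+")
  # TSS-relative positions: 890 -> -110; 905 -> -95; group at 920,924,928
  expect_setequal(colnames(mat), c("-110", "-95", "-80", "-76", "-72"))
  expect_equal(unname(mat["r1", "-110"]), "M")
  expect_true(is.na(mat["r1", "-95"]))  # |LLR| <= 1.5 is ambiguous
  expect_equal(unname(mat["r1", c("-80", "-76", "-72")]), rep("U", 3))
  expect_equal(unname(mat["r2", "-110"]), "U")
})

test_that("minus-strand TSS conversion flips the sign of offsets", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_nanopolish_tsv(list(list(read = "r1", start = 1100, llr = 3)), path)
  mat <- read_methyl_calls(path, tss = 1000, tss_strand = "-")
  expect_equal(colnames(mat), "-100")  # downstream in genome = upstream of gene
})

test_that("missing columns raise a format error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("read_name\tstart\nr1\t100", path)
  expect_error(read_methyl_calls(path, tss = 0), "missing column")
})

test_that("window U counts match hand counts and apply the coverage rule", {
  pos <- seq(-110, -61, by = 7)  # 8 sites in the window
  mat <- matrix("M", 3, 8, dimnames = list(paste0("r", 1:3), pos))
  mat[1, ] <- "U"                       # all-U read: count 8
  mat[2, ] <- "M"                       # all-M read: count 0
  mat[3, ] <- c(rep("U", 5), "M", "M", NA)  # 5 U, 2 M, 1 missing: count 5
  class(mat) <- c("methyl_matrix", class(mat))
  cts <- window_unmeth_counts(mat, c(-110, -60), min_covered = 0.8)
  expect_equal(as.vector(cts), c(8, 0, 5))
  expect_equal(attr(cts, "n_sites"), 8)

  # read covering 6/8 = 75% < 80% is excluded
  mat[3, 7:8] <- NA
  cts <- window_unmeth_counts(mat, c(-110, -60), min_covered = 0.8)
  expect_equal(names(cts), c("r1", "r2"))
  expect_equal(attr(cts, "excluded"), "r3")
  expect_error(window_unmeth_counts(mat, c(100, 200)), "no CpG sites")
})

test_that("methylation percentages sum to 100 over non-missing calls", {
  mat <- matrix(c("U", "U", "M", NA, "M", "M", "U", "M", NA, "M"), 2, 5,
                dimnames = list(c("r1", "r2"), c(-100, -90, -80, -70, -60)))
  class(mat) <- c("methyl_matrix", class(mat))
  pct <- methylation_percentages(mat)
  expect_equal(sum(pct), 100)
  expect_equal(unname(pct["percent_U"]), 100 * 3 / 8)  # hand count: 3 U of 8 calls
  # window -100..-90: calls U,U (site -100) and M (site -90) -> 2/3 U
  expect_equal(unname(methylation_percentages(mat, c(-100, -90))["percent_U"]),
               100 * 2 / 3)
})

test_that("en bloc classification applies the discordance tolerance", {
  pos <- seq(-110, -61, by = 7)
  mat <- matrix(NA_character_, 4, 8, dimnames = list(paste0("r", 1:4), pos))
  mat[1, ] <- "U"                          # unmeth_block
  mat[2, ] <- c(rep("M", 7), "U")          # 7M 1U, tolerance 1 -> meth_block
  mat[3, ] <- c(rep("U", 4), rep("M", 4))  # mixed
  mat[4, ] <- c(rep("U", 7), "M")          # unmeth_block at tolerance 1
  class(mat) <- c("methyl_matrix", class(mat))
  lab <- classify_enbloc(mat, c(-110, -60), tolerance = 1)
  expect_equal(unname(lab), c("unmeth_block", "meth_block", "mixed",
                              "unmeth_block"))
})

test_that("EM recovers a synthetic 60/40 mixture", {
  g <- gen_methyl_reads(500, weight_unmeth = 0.6, error_rate = 0.05, seed = 51)
  cts <- window_unmeth_counts(g$matrix)
  fit <- fit_binomial_mixture(cts, attr(cts, "n_sites"), seed = 52)
  expect_true(fit$converged)
  expect_true(fit$bimodal)
  expect_lt(abs(fit$weight_unmeth - 0.6), 0.05)
  expect_lt(abs(fit$prob[2] - 0.95), 0.05)
  expect_lt(abs(fit$prob[1] - 0.05), 0.05)
})

test_that("EM degenerate and symmetric cases", {
  # all-methylated reads: unmethylated weight collapses to the boundary
  fit0 <- fit_binomial_mixture(rep(0L, 50), 8, seed = 53)
  expect_lt(fit0$weight_unmeth * fit0$prob[2] +
            (1 - fit0$weight_unmeth) * fit0$prob[1], 0.01)
  expect_false(fit0$bimodal)

  # equal component probabilities: a single effective mode, not bimodal
  set.seed(54)
  cts <- rbinom(200, 8, 0.5)
  fit1 <- fit_binomial_mixture(cts, 8, seed = 55)
  expect_false(fit1$bimodal)

  expect_error(fit_binomial_mixture(1:5, 8), "at least 10")
})

test_that("relabeling M<->U mirrors the mixture and the block labels", {
  g <- gen_methyl_reads(400, weight_unmeth = 0.7, error_rate = 0.03, seed = 56)
  cts <- window_unmeth_counts(g$matrix)
  n <- attr(cts, "n_sites")
  fit <- fit_binomial_mixture(cts, n, seed = 57)
  flip <- fit_binomial_mixture(n - cts, n, seed = 57)
  expect_equal(flip$weight_unmeth, 1 - fit$weight_unmeth, tolerance = 1e-4)
  expect_equal(sort(flip$prob), sort(1 - fit$prob), tolerance = 1e-4)

  mflip <- g$matrix
  mflip[g$matrix == "U"] <- "M"; mflip[g$matrix == "M"] <- "U"
  a <- classify_enbloc(g$matrix)
  b <- classify_enbloc(mflip)
  swapped <- c(unmeth_block = "meth_block", meth_block = "unmeth_block",
               mixed = "mixed")
  expect_equal(unname(swapped[a]), unname(b))
})

test_that("EM log-likelihood beats the single-binomial fit", {
  g <- gen_methyl_reads(300, weight_unmeth = 0.5, error_rate = 0.05, seed = 58)
  cts <- window_unmeth_counts(g$matrix)
  n <- attr(cts, "n_sites")
  fit <- fit_binomial_mixture(cts, n, seed = 59)
  single <- sum(dbinom(cts, n, mean(cts) / n, log = TRUE))
  expect_gte(fit$logLik, single)
})
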