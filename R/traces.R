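#' Construct a single-cell NF-kB trace
#'
#' A trace holds one cell's time series of nuclear and cytoplasmic p65 median
#' intensities and the destabilized transcriptional-reporter intensity, on a
#' fixed frame interval (5 min by default in the imaging protocol).
#'
#' @param cell_id identifier.
#' @param time_min strictly increasing time points (minutes).
#' @param nuc_p65,cyt_p65 nuclear / cytoplasmic p65 median intensities
#'   (positive, equal length to \code{time_min}).
#' @param venus reporter (nuclear + cytoplasmic median) intensity.
#' @param stimulus,concentration stimulus label and concentration.
#' @param t_stim_min stimulus-addition time (minutes), within the trace.
#' @return an object of class \code{cell_trace}.
#' @export
cell_trace <- function(cell_id, time_min, nuc_p65, cyt_p65, venus,
                       stimulus = NA_character_, concentration = NA_real_,
                       t_stim_min = NA_real_) {
  n <- length(time_min)
  if (any(diff(time_min) <= 0)) stop("time_min must be strictly increasing")
  if (length(nuc_p65) != n || length(cyt_p65) != n || length(venus) != n)
    stop("all series must have the same length as time_min")
  if (any(cyt_p65 <= 0) || any(nuc_p65 <= 0))
    stop("p65 intensities must be positive")
  structure(list(cell_id = as.character(cell_id), time_min = time_min,
                 nuc_p65 = nuc_p65, cyt_p65 = cyt_p65, venus = venus,
                 stimulus = stimulus, concentration = concentration,
                 t_stim_min = t_stim_min),
            class = "cell_trace")
}

#' @export
print.cell_trace <- function(x, ...) {
  cat(sprintf("<cell_trace> %s: %d frames (%.0f-%.0f min), stimulus %s @ %s, t_stim %s min\n",
              x$cell_id, length(x$time_min), min(x$time_min), max(x$time_min),
              x$stimulus, format(x$concentration), format(x$t_stim_min)))
  invisible(x)
}

#' Nuclear/cytoplasmic p65 ratio of a trace
#'
#' @param trace a \code{\link{cell_trace}}.
#' @return numeric vector, one value per frame.
#' @export
nc_ratio <- function(trace) trace$nuc_p65 / trace$cyt_p65

#' Reject cells with extreme initial NF-kB expression
#'
#' Standard imaging QC: cells whose initial total p65 expression (nuclear +
#' cytoplasmic, first frame) falls outside the \[25th, 99th\] percentile of
#' the population are rejected; both boundaries are inclusive.  Percentiles
#' use the inverse-ECDF definition (\code{quantile} type 1) so that on ranked
#' data the cut is exactly at the stated order statistics.
#'
#' @param traces a list of \code{\link{cell_trace}} objects.
#' @param low_pct,high_pct percentile bounds (defaults 25 and 99).
#' @return the filtered list; the rejected cell ids are in attribute
#'   \code{"rejected"}.
#' @export
qc_filter <- function(traces, low_pct = 25, high_pct = 99) {
  if (!length(traces)) stop("empty trace set")
  init <- vapply(traces, function(tr) tr$nuc_p65[1] + tr$cyt_p65[1], numeric(1))
  if (length(traces) == 1L) {
    warning("single cell: percentile filter is degenerate, cell kept")
    return(traces)
  }
  bounds <- stats::quantile(init, c(low_pct, high_pct) / 100, type = 1,
                            names = FALSE)
  keep <- init >= bounds[1] & init <= bounds[2]
  out <- traces[keep]
  attr(out, "rejected") <- vapply(traces[!keep], `[[`, character(1), "cell_id")
  out
}

# Local maxima with a topographic-style prominence: height above the higher
# of the two flanking minima (walking out to the nearest sample exceeding the
# peak, or the series end).
find_peaks <- function(y, min_prominence) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    p <- cand[i]
    lmin <- min(y[max(which(y[1:p] > y[p]), 1):p])
    right <- y[p:n]
    rmin <- min(right[1:min(which(right > y[p]), length(right))])
    keep[i] <- (y[p] - max(lmin, rmin)) >= min_prominence
  }
  cand[keep]
}

#' Extract scalar features from an NF-kB trace
#'
#' The baseline is the median nuclear/cytoplasmic ratio before stimulation.
#' The first translocation peak is the first post-stimulus local maximum with
#' prominence at least \code{min_prominence} (default 10% of baseline).
#' \code{auc_steady} -- a readout of sustained / oscillatory activity --
#' integrates the positive part of the baseline-subtracted ratio by the
#' trapezoid rule from the first trough after the first peak to the end of
#' the trace.  Expression features are the 95th percentile and the maximum of
#' the reporter.
#'
#' @param trace a \code{\link{cell_trace}} with \code{t_stim_min} inside the
#'   trace.
#' @param min_prominence peak prominence threshold in ratio units; default
#'   \code{0.1 * baseline}.
#' @return a one-row data.frame: \code{cell_id}, \code{baseline},
#'   \code{peak_amplitude}, \code{time_to_peak_min}, \code{n_peaks},
#'   \code{auc_steady}, \code{expr_p95}, \code{expr_max}.  Peak fields and
#'   \code{auc_steady} are \code{NA} when no peak is detected.
#' @export
extract_features <- function(trace, min_prominence = NULL) {
  t <- trace$time_min
  if (is.na(trace$t_stim_min) || trace$t_stim_min > max(t))
    stop("t_stim_min must lie within the trace")
  r <- nc_ratio(trace)
  pre <- t < trace$t_stim_min
  if (!any(!pre)) stop("no post-stimulus frames")
  baseline <- if (any(pre)) stats::median(r[pre]) else r[1]
  if (is.null(min_prominence)) min_prominence <- 0.1 * baseline
  post <- which(t >= trace$t_stim_min)
  rp <- r[post]; tp <- t[post]
  pk <- find_peaks(rp, min_prominence)
  feats <- data.frame(cell_id = trace$cell_id, baseline = baseline,
                      peak_amplitude = NA_real_, time_to_peak_min = NA_real_,
                      n_peaks = length(pk), auc_steady = NA_real_,
                      expr_p95 = unname(stats::quantile(trace$venus, 0.95)),
                      expr_max = max(trace$venus),
                      stringsAsFactors = FALSE)
  if (!length(pk)) return(feats)
  p1 <- pk[1]
  feats$peak_amplitude <- rp[p1] - baseline
  feats$time_to_peak_min <- tp[p1] - trace$t_stim_min
  # first trough: first local minimum after the peak (end of the decline)
  after <- rp[p1:length(rp)]
  tr_rel <- which(diff(sign(diff(after))) > 0) + 1L
  flat <- which(diff(after) >= 0)
  start <- if (length(tr_rel)) p1 + tr_rel[1] - 1L
           else if (length(flat)) p1 + flat[1] - 1L
           else length(rp)
  y <- pmax(rp[start:length(rp)] - baseline, 0)
  x <- tp[start:length(tp)]
  feats$auc_steady <- if (length(x) > 1)
    sum(diff(x) * (y[-1] + y[-length(y)]) / 2) else 0
  feats
}

#' Call responders against media controls
#'
#' A cell is a responder when its post-stimulus score (typically the maximum
#' nuclear/cytoplasmic p65 ratio over a fixed window) strictly exceeds the
#' threshold derived from media-control cells: the control maximum by default,
#' or a control quantile with \code{rule = "quantile"}.
#'
#' @param scores named numeric vector of per-cell scores.
#' @param control_scores scores of media-control cells.
#' @param rule \code{"max"} (default) or \code{"quantile"}.
#' @param q quantile for \code{rule = "quantile"} (default 0.99).
#' @return a data.frame with \code{cell_id}, \code{score}, \code{status}
#'   (\code{"responder"} / \code{"non_responder"}) and \code{threshold}.
#' @export
classify_responders <- function(scores, control_scores,
                                rule = c("max", "quantile"), q = 0.99) {
  rule <- match.arg(rule)
  if (!length(control_scores)) stop("empty control scores")
  if (length(control_scores) < 10)
    warning("fewer than 10 control cells; threshold may be unstable")
  threshold <- if (rule == "max") max(control_scores)
               else unname(stats::quantile(control_scores, q, type = 7))
  ids <- if (is.null(names(scores))) as.character(seq_along(scores))
         else names(scores)
  data.frame(cell_id = ids, score = unname(scores),
             status = ifelse(scores > threshold, "responder", "non_responder"),
             threshold = threshold, stringsAsFactors = FALSE)
}

#' Responder fraction with a Wilson score interval
#'
#' @param calls a data.frame from \code{\link{classify_responders}}, or a
#'   logical/character vector of statuses.
#' @param level confidence level (default 0.95).
#' @return a list with \code{fraction}, \code{n}, \code{n_responders} and
#'   \code{ci} (Wilson score interval, no continuity correction).
#' @export
responder_fraction <- function(calls, level = 0.95) {
  status <- if (is.data.frame(calls)) calls$status == "responder"
            else if (is.character(calls)) calls == "responder"
            else as.logical(calls)
  n <- length(status)
  if (!n) stop("no calls")
  x <- sum(status)
  ci <- if (x == 0 && n == 0) c(0, 1) else
    stats::prop.test(x, n, conf.level = level, correct = FALSE)$conf.int
  list(fraction = x / n, n = n, n_responders = x,
       ci = c(low = ci[1], high = ci[2]))
}

#' Sarle's bimodality coefficient
#'
#' \eqn{BC = (s^2 + 1) / k} with population (biased) skewness \eqn{s} and
#' non-excess kurtosis \eqn{k}.  A uniform distribution gives 5/9; values
#' above 5/9 indicate bimodality.  Scores are log-transformed by default,
#' matching how translocation-ratio histograms are displayed.
#'
#' @param scores numeric vector, length >= 4.
#' @param log_scores log-transform before computing moments (default TRUE).
#' @return the coefficient, with attribute \code{"bimodal"} (TRUE when
#'   > 5/9).
#' @export
bimodality_coefficient <- function(scores, log_scores = TRUE) {
  if (length(scores) < 4) stop("need at least 4 scores")
  x <- if (log_scores) log(scores) else scores
  m <- mean(x); v <- mean((x - m)^2)
  if (v == 0) stop("zero variance: bimodality coefficient undefined")
  skew <- mean((x - m)^3) / v^1.5
  kurt <- mean((x - m)^4) / v^2
  bc <- (skew^2 + 1) / kurt
  attr(bc, "bimodal") <- bc > 5 / 9
  bc
}

#' Correlation structure of trace features and dose dependence
#'
#' Pairwise Pearson correlations between per-cell features, plus the R^2 of
#' an ordinary linear regression of each feature on log10(concentration)
#' (stimulus concentrations span decades, so responses are modelled against
#' the log dose).
#'
#' @param features a data.frame of per-cell features including a
#'   \code{concentration} column.
#' @param feature_cols which columns to correlate (default: all numeric
#'   columns except \code{concentration}).
#' @return a list with \code{R} (correlation matrix; pairs with a constant
#'   member are \code{NA}), \code{max_R} (largest absolute off-diagonal
#'   correlation) and \code{r_squared} (named vector of per-feature dose
#'   R^2).
#' @export
feature_correlations <- function(features, feature_cols = NULL) {
  if (nrow(features) < 3) stop("need at least 3 cells")
  if (is.null(feature_cols)) {
    num <- vapply(features, is.numeric, logical(1))
    feature_cols <- setdiff(names(features)[num], "concentration")
  }
  X <- as.matrix(features[feature_cols])
  R <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  R[sds == 0, ] <- NA; R[, sds == 0] <- NA
  off <- abs(R[upper.tri(R)])
  r2 <- NULL
  if ("concentration" %in% names(features) &&
      length(unique(features$concentration)) >= 2) {
    lc <- log10(features$concentration)
    r2 <- vapply(feature_cols, function(f) {
      y <- features[[f]]
      ok <- is.finite(y) & is.finite(lc)
      if (sum(ok) < 3 || stats::sd(y[ok]) == 0) return(NA_real_)
      suppressWarnings(summary(stats::lm(y[ok] ~ lc[ok]))$r.squared)
    }, numeric(1))
  }
  list(R = R, max_R = if (length(off)) max(off, na.rm = TRUE) else NA_real_,
       r_squared = r2)
}

#' Compare two count distributions with a binned chi-squared test
#'
#' Counts from both groups are binned into \code{n_bins} shared equal-width
#' bins on the pooled range (rightmost bin closed), giving a 2 x n_bins
#' contingency table.  Bins whose smaller expected cell count is below 5 are
#' merged into their right neighbour (the last bin merges left); the test
#' statistic is Pearson's chi-squared on the surviving table with
#' \code{df = bins - 1}.
#'
#' @param counts_a,counts_b numeric count vectors (e.g. per-cell mRNA spot
#'   counts in two phenotype groups).
#' @param n_bins number of initial bins (default 10).
#' @return a list with \code{chi2}, \code{df}, \code{p_value},
#'   \code{table} (the tested contingency table) and \code{breaks}.
#' @export
compare_count_distributions <- function(counts_a, counts_b, n_bins = 10) {
  if (!length(counts_a) || !length(counts_b)) stop("both groups must be nonempty")
  pooled <- c(counts_a, counts_b)
  rng <- range(pooled)
  if (rng[1] == rng[2]) stop("all counts identical: nothing to bin")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- function(x) {
    b <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(b, nbins = n_bins)
  }
  tab <- rbind(a = bin(counts_a), b = bin(counts_b))
  # merge low-expectation bins rightward
  repeat {
    if (ncol(tab) <= 2) break
    exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    low <- which(apply(exp_tab, 2, min) < 5)
    if (!length(low)) break
    j <- low[1]
    if (j == ncol(tab)) {
      tab[, j - 1] <- tab[, j - 1] + tab[, j]
    } else {
      tab[, j + 1] <- tab[, j + 1] + tab[, j]
    }
    tab <- tab[, -j, drop = FALSE]
  }
  if (ncol(tab) < 2) stop("fewer than 2 bins survive merging")
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - exp_tab)^2 / exp_tab)
  df <- ncol(tab) - 1
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       table = tab, breaks = breaks)
}
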