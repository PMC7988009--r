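#' Median distance from each responder to its k nearest responders
#'
#' The spatial clustering readout for responders in a monolayer: for every
#' responder cell, the median of its Euclidean distances to the \code{k}
#' nearest other responders (default 5); the field summary is the median over
#' responders.  Tied distances at the k-th rank are all included in the
#' median, so the statistic is deterministic.
#'
#' @param positions an n x 2 numeric matrix (or data.frame with columns
#'   \code{x_um}, \code{y_um}) of cell coordinates in micrometres.
#' @param labels logical (or 0/1) responder flags, length n.
#' @param k number of nearest responders (default 5); requires at least
#'   \code{k + 1} responders.
#' @param jitter_seed seed used to break exactly duplicated coordinates with
#'   sub-0.01 um jitter.
#' @return a list with \code{per_responder} (named per-cell medians) and
#'   \code{summary} (the field median).
#' @export
responder_knn_statistic <- function(positions, labels, k = 5,
                                    jitter_seed = 1L) {
  pos <- as_positions(positions, jitter_seed)
  labels <- as.logical(labels)
  if (length(labels) != nrow(pos)) stop("labels must match positions")
  if (sum(labels) < k + 1)
    stop("need at least k + 1 = ", k + 1, " responders, found ", sum(labels))
  D <- as.matrix(stats::dist(pos[labels, , drop = FALSE]))
  per <- apply(D, 1, function(d) {
    d <- sort(d[-which.min(d)])  # drop self (distance 0)
    stats::median(d[d <= d[k]])
  })
  list(per_responder = per, summary = stats::median(per))
}

as_positions <- function(positions, jitter_seed) {
  if (is.data.frame(positions)) {
    cols <- intersect(c("x_um", "y_um", "x", "y"), names(positions))
    if (length(cols) < 2) stop("positions need x/y columns")
    positions <- as.matrix(positions[cols[1:2]])
  }
  pos <- as.matrix(positions)
  if (ncol(pos) != 2) stop("positions must be n x 2")
  dup <- duplicated(pos)
  if (any(dup)) {
    message(sum(dup), " duplicated coordinate(s) jittered by < 0.01 um")
    pos[dup, ] <- pos[dup, ] + with_seed(jitter_seed,
      matrix(stats::runif(2 * sum(dup), -0.005, 0.005), ncol = 2))
  }
  pos
}

#' Label-permutation test for spatial clustering of responders
#'
#' Tests whether responders sit closer to each other than expected if the
#' responder labels were scattered at random over the observed cell positions
#' (labels are permuted, preserving both the monolayer geometry and the
#' responder count).  The alternative is one-sided toward clustering (small
#' k-nearest-responder distances); the p-value uses the add-one convention
#' \eqn{p = (1 + \#\{null \le observed\}) / (1 + n_{perm})}.
#'
#' @inheritParams responder_knn_statistic
#' @param n_perm number of label permutations (default 1000; a warning is
#'   issued below 100).
#' @param seed integer seed for the permutations.
#' @return a list of class \code{spatial_perm_test}: \code{observed},
#'   \code{null} (permutation summaries), \code{p_value}, \code{k},
#'   \code{n_perm}.
#' @export
spatial_permutation_test <- function(positions, labels, k = 5, n_perm = 1000,
                                     seed = NULL, jitter_seed = 1L) {
  pos <- as_positions(positions, jitter_seed)
  labels <- as.logical(labels)
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value")
  n <- nrow(pos); m <- sum(labels)
  if (m < k + 1)
    stop("need at least k + 1 = ", k + 1, " responders, found ", m)
  D <- as.matrix(stats::dist(pos))
  stat <- function(idx) {
    Ds <- D[idx, idx, drop = FALSE]
    per <- apply(Ds, 1, function(d) {
      d <- sort(d[-which.min(d)])
      stats::median(d[d <= d[k]])
    })
    stats::median(per)
  }
  obs <- stat(which(labels))
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    stat(sample.int(n, m)), numeric(1)))
  p <- (1 + sum(null <= obs)) / (1 + n_perm)
  structure(list(observed = obs, null = null, p_value = p, k = k,
                 n_perm = n_perm, n_cells = n, n_responders = m),
            class = "spatial_perm_test")
}

#' @export
print.spatial_perm_test <- function(x, ...) {
  cat(sprintf("Label-permutation test for responder clustering (k = %d)\n", x$k))
  cat(sprintf("  %d cells, %d responders; observed median k-NN distance = %.3g um\n",
              x$n_cells, x$n_responders, x$observed))
  cat(sprintf("  null median = %.3g um (%d permutations); one-sided p = %.4g\n",
              stats::median(x$null), x$n_perm, x$p_value))
  invisible(x)
}

#' Read a cell-position table
#'
#' CSV with columns \code{cell_id}, \code{x_um}, \code{y_um},
#' \code{responder} (0/1) and optionally \code{field_id}.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_position_csv <- function(path) {
  tab <- utils::read.csv(path)
  req <- c("cell_id", "x_um", "y_um", "responder")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("position CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  tab
}
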