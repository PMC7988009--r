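#' Per-generation transition matrix of the responder-state switch
#'
#' The responder phenotype is modelled as a two-state Markov chain on cell
#' generations: a non-responder daughter becomes a responder with probability
#' \code{p_on}, a responder daughter silences with probability \code{p_off}.
#' States are ordered (non-responder, responder).
#'
#' @param p_on probability per generation of switching non-responder to
#'   responder, in \[0, 1\].
#' @param p_off probability per generation of switching responder to
#'   non-responder, in \[0, 1\].
#' @return a 2x2 row-stochastic matrix with dimnames \code{c("N","R")}.
#' @export
transition_matrix <- function(p_on, p_off) {
  check_prob(p_on, "p_on")
  check_prob(p_off, "p_off")
  matrix(c(1 - p_on, p_on, p_off, 1 - p_off), 2, 2, byrow = TRUE,
         dimnames = list(from = c("N", "R"), to = c("N", "R")))
}

#' Stationary responder fraction of the switching chain
#'
#' The long-run fraction of responder cells, \code{p_on / (p_on + p_off)} --
#' the fixed point of \code{\link{transition_matrix}}.  At the fitted rates
#' (0.01, 0.055) this is ~0.154, the observed cap on responding cells.
#'
#' @inheritParams transition_matrix
#' @return a probability.
#' @export
stationary_fraction <- function(p_on, p_off) {
  check_prob(p_on, "p_on")
  check_prob(p_off, "p_off")
  if (p_on + p_off == 0)
    stop("degenerate chain: p_on = p_off = 0 has no unique stationary fraction")
  p_on / (p_on + p_off)
}

check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("'", name, "' must be a single probability in [0, 1]")
  invisible(p)
}

#' Predict relaxation of the responder fraction toward its stationary value
#'
#' After a perturbation that raises the responder fraction (e.g. transient
#' demethylating-agent treatment), the fraction relaxes geometrically:
#' \deqn{f(g) = f_{ss} + (f_0 - f_{ss}) \lambda^g,\quad
#'       \lambda = 1 - p_{on} - p_{off},}
#' where \eqn{f_{ss}} is the stationary fraction.  An optional uncertainty
#' band propagates rate confidence intervals by evaluating the trajectory on
#' a grid of (p_on, p_off) pairs inside the CIs and taking the pointwise
#' envelope.
#'
#' @inheritParams transition_matrix
#' @param f0 responder fraction at generation 0.
#' @param n_generations number of generations to predict.
#' @param generation_time_h hours per generation, used to add a time axis
#'   (default 24).
#' @param ci_on,ci_off optional length-2 vectors (low, high) of 95% CIs for
#'   the rates; when both are given a pointwise envelope band is computed.
#' @param grid_n grid resolution per rate for the envelope (default 21).
#' @return a \code{decay_prediction} data.frame with columns
#'   \code{generation}, \code{time_h}, \code{fraction} and (with CIs)
#'   \code{band_low}, \code{band_high}.
#' @export
predict_fraction_decay <- function(p_on, p_off, f0, n_generations,
                                   generation_time_h = 24,
                                   ci_on = NULL, ci_off = NULL, grid_n = 21) {
  check_prob(p_on, "p_on"); check_prob(p_off, "p_off"); check_prob(f0, "f0")
  if (n_generations < 0) stop("n_generations must be >= 0")
  if (p_on + p_off > 1)
    warning("p_on + p_off > 1: approach to the stationary fraction oscillates")
  g <- 0:n_generations
  f_ss <- stationary_fraction(p_on, p_off)
  lambda <- 1 - p_on - p_off
  out <- data.frame(generation = g,
                    time_h = g * generation_time_h,
                    fraction = f_ss + (f0 - f_ss) * lambda^g)
  if (!is.null(ci_on) && !is.null(ci_off)) {
    pa <- seq(max(ci_on[1], 1e-12), ci_on[2], length.out = grid_n)
    pb <- seq(max(ci_off[1], 1e-12), ci_off[2], length.out = grid_n)
    grid <- expand.grid(p_on = pa, p_off = pb)
    traj <- mapply(function(a, b) {
      stationary_fraction(a, b) + (f0 - stationary_fraction(a, b)) * (1 - a - b)^g
    }, grid$p_on, grid$p_off)
    out$band_low <- apply(traj, 1, min)
    out$band_high <- apply(traj, 1, max)
  }
  attr(out, "rates") <- c(p_on = unname(p_on), p_off = unname(p_off))
  attr(out, "f_ss") <- f_ss
  class(out) <- c("decay_prediction", "data.frame")
  out
}

#' @export
print.decay_prediction <- function(x, ...) {
  r <- attr(x, "rates")
  cat(sprintf("<decay_prediction> f0 = %.3f -> f_ss = %.4f over %d generations (p_on = %.4g, p_off = %.4g)\n",
              x$fraction[1], attr(x, "f_ss"), max(x$generation), r["p_on"], r["p_off"]))
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat("  ... ", nrow(x) - 8, " more generations\n")
  invisible(x)
}

#' @export
plot.decay_prediction <- function(x, xaxis = c("generation", "days"), ...) {
  xaxis <- match.arg(xaxis)
  xv <- if (xaxis == "days") x$time_h / 24 else x$generation
  graphics::plot(xv, x$fraction, type = "n", ylim = c(0, max(x$fraction, x$band_high, na.rm = TRUE)),
                 xlab = if (xaxis == "days") "time (days)" else "generation",
                 ylab = "responder fraction", ...)
  if (!is.null(x$band_low))
    graphics::polygon(c(xv, rev(xv)), c(x$band_low, rev(x$band_high)),
                      col = grDevices::grey(0.85), border = NA)
  graphics::lines(xv, x$fraction, lwd = 2)
  graphics::abline(h = attr(x, "f_ss"), lty = 3)
  invisible(x)
}
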