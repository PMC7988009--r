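#' Fit per-generation switching probabilities to lineage data
#'
#' Maximum-likelihood estimation of the heritable switching model from
#' observed leaf phenotypes on lineage trees.  The likelihood is the exact
#' pruning likelihood (\code{\link{tree_log_likelihood}}) summed over trees;
#' optimization runs on the logit scale with multiple starts (including a
#' parsimony-informed start).  Confidence intervals are profile-likelihood
#' intervals by default (log-likelihood drop of \code{qchisq(level, 1)/2},
#' i.e. 1.92 at 95%) or percentile bootstrap over lineages.
#'
#' @param trees a list of \code{\link{lineage_tree}} objects (or one tree).
#' @param root_dist how the founder-state distribution is handled:
#'   \code{"free"} (estimated initial responder fraction, the default),
#'   \code{"stationary"} (tied to \code{p_on/(p_on+p_off)}), or
#'   \code{"fixed"} (supplied via \code{root_prob}).
#' @param root_prob founder responder probability when
#'   \code{root_dist = "fixed"}.
#' @param ci \code{"profile"}, \code{"bootstrap"} or \code{"none"}.
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap replicates when \code{ci = "bootstrap"}.
#' @param n_starts number of optimizer starts (>= 5 recommended).
#' @param seed integer seed (used by the bootstrap; fitting itself is
#'   deterministic).
#' @return an object of class \code{switch_fit} with components
#'   \code{coefficients} (\code{p_on}, \code{p_off}, and \code{root_frac}
#'   when free), \code{ci} (matrix of interval bounds), \code{logLik},
#'   \code{boundary} (named logical flags), \code{root_dist}, and data
#'   summaries.  Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{confint}, \code{logLik}, \code{predict}, \code{simulate},
#'   \code{plot}.
#' @export
fit_switching <- function(trees, root_dist = c("free", "stationary", "fixed"),
                          root_prob = NULL,
                          ci = c("profile", "bootstrap", "none"),
                          level = 0.95, n_boot = 1000, n_starts = 5,
                          seed = NULL) {
  root_dist <- match.arg(root_dist)
  ci <- match.arg(ci)
  if (inherits(trees, "lineage_tree")) trees <- list(trees)
  if (root_dist == "fixed") {
    if (is.null(root_prob)) stop("root_dist = 'fixed' requires root_prob")
    check_prob(root_prob, "root_prob")
  }
  fi <- forest_index(trees)
  if (fi$n_observed == 0L)
    stop("unidentifiable: no tree has an observed leaf status")
  opt <- ml_optimize(fi, root_dist, root_prob, n_starts, trees)
  est <- opt$par
  bnd <- est < 1e-6 | est > 1 - 1e-6
  ci_mat <- NULL
  if (ci == "profile") {
    ci_mat <- rbind(p_on = profile_ci(fi, opt, "p_on", root_dist, root_prob, level),
                    p_off = profile_ci(fi, opt, "p_off", root_dist, root_prob, level))
  } else if (ci == "bootstrap") {
    ci_mat <- bootstrap_ci(trees, opt, root_dist, root_prob, level, n_boot, seed)
  }
  structure(list(coefficients = est, ci = ci_mat, ci_method = ci,
                 level = level, logLik = opt$value, boundary = bnd,
                 root_dist = root_dist, root_prob_fixed = root_prob,
                 n_trees = length(trees), n_observed = fi$n_observed,
                 n_divisions = n_divisions(trees),
                 convergence = opt$convergence),
            class = "switch_fit")
}

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))
LOGIT_BOUND <- 18.4  # expit(+-18.4) ~ 1e-8 / 1 - 1e-8

clamp <- function(x) pmin(pmax(x, -LOGIT_BOUND), LOGIT_BOUND)

# negative log-likelihood over logit-scale parameters
neg_ll <- function(theta, fi, root_dist, root_prob) {
  theta <- clamp(theta)
  p_on <- expit(theta[1]); p_off <- expit(theta[2])
  rp <- switch(root_dist,
               free = expit(theta[3]),
               stationary = p_on / (p_on + p_off),
               fixed = root_prob)
  ll <- forest_loglik(fi, p_on, p_off, rp)
  if (!is.finite(ll)) 1e12 else -ll
}

ml_optimize <- function(fi, root_dist, root_prob, n_starts, trees) {
  f_obs <- mean(fi$leaf_state[!is.na(fi$leaf_state)] == "R")
  f_obs <- min(max(f_obs, 0.01), 0.99)
  pars_start <- pars_from_parsimony(trees, f_obs)
  grid <- rbind(pars_start,
                c(0.01, 0.05), c(0.05, 0.05), c(0.2, 0.2),
                c(0.02, 0.2), c(0.005, 0.01), c(0.1, 0.4))
  grid <- grid[seq_len(max(n_starts, 2L)), , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    th0 <- logit(pmin(pmax(grid[i, ], 1e-4), 1 - 1e-4))
    if (root_dist == "free") th0 <- c(th0, logit(f_obs))
    o <- stats::optim(th0, neg_ll, fi = fi, root_dist = root_dist,
                      root_prob = root_prob, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 2000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish
  o <- stats::optim(best$par, neg_ll, fi = fi, root_dist = root_dist,
                    root_prob = root_prob, method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 2000))
  if (o$value < best$value) best <- o
  par <- expit(clamp(best$par))
  names(par) <- c("p_on", "p_off", if (root_dist == "free") "root_frac")
  list(par = par, theta = clamp(best$par), value = -best$value,
       convergence = best$convergence == 0)
}

# Crude initial rates from Fitch parsimony: directional change counts over
# directional edge exposures, using the deterministic tie resolution.
pars_from_parsimony <- function(trees, f_obs) {
  n_on <- 0; n_off <- 0; e_N <- 0; e_R <- 0
  for (tr in trees) {
    fp <- tryCatch(fitch_parsimony(tr), error = function(e) NULL)
    if (is.null(fp)) next
    st <- sub("/.*", "", fp$states)  # resolve ties as N (reported "N/R")
    pid <- match(tr$parent_id, tr$node_id)
    for (k in which(!is.na(pid))) {
      ps <- st[[tr$node_id[pid[k]]]]; cs <- st[[tr$node_id[k]]]
      if (is.na(ps) || is.na(cs)) next
      if (ps == "N") { e_N <- e_N + 1; if (cs == "R") n_on <- n_on + 1 }
      else { e_R <- e_R + 1; if (cs == "N") n_off <- n_off + 1 }
    }
  }
  p_on <- if (e_N > 0) n_on / e_N else 0.01
  p_off <- if (e_R > 0) n_off / e_R else 0.05
  c(min(max(p_on, 1e-3), 0.5), min(max(p_off, 1e-3), 0.5))
}

# Profile-likelihood confidence interval for one rate.
profile_ci <- function(fi, opt, param, root_dist, root_prob, level) {
  j <- if (param == "p_on") 1L else 2L
  keep <- setdiff(seq_along(opt$theta), j)
  target <- opt$value - stats::qchisq(level, 1) / 2
  warm <- new.env()
  warm$last <- opt$theta[keep]
  prof <- function(psi_logit) {
    if (!length(keep)) stop("no nuisance parameters")  # cannot happen
    fn <- function(th_rest) {
      theta <- numeric(length(opt$theta))
      theta[j] <- psi_logit; theta[keep] <- th_rest
      neg_ll(theta, fi, root_dist, root_prob)
    }
    o <- if (length(keep) == 1L) {
      stats::optim(warm$last, fn, method = "Brent",
                   lower = -LOGIT_BOUND, upper = LOGIT_BOUND)
    } else {
      stats::optim(warm$last, fn, method = "Nelder-Mead",
                   control = list(reltol = 1e-9, maxit = 500))
    }
    warm$last <- o$par
    -o$value
  }
  mle_logit <- opt$theta[j]
  bound_ci <- function(dir) {
    step <- 0.25
    lo <- mle_logit
    repeat {
      hi <- lo + dir * step
      if (abs(hi) >= LOGIT_BOUND) return(expit(dir * LOGIT_BOUND))
      if (prof(hi) < target) break
      lo <- hi; step <- step * 2
    }
    # bisect the established bracket (prof(lo) >= target > prof(hi)) without
    # re-evaluating its endpoints: the warm-started inner optimization can
    # jitter a marginal endpoint across the target
    for (it in 1:40) {
      if (abs(hi - lo) < 1e-3) break
      mid <- (lo + hi) / 2
      if (prof(mid) >= target) lo <- mid else hi <- mid
    }
    expit((lo + hi) / 2)
  }
  c(low = bound_ci(-1), high = bound_ci(+1))
}

bootstrap_ci <- function(trees, opt, root_dist, root_prob, level, n_boot, seed) {
  with_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(trees), replace = TRUE)
      fib <- forest_index(trees[idx])
      th0 <- opt$theta
      o <- stats::optim(th0, neg_ll, fi = fib, root_dist = root_dist,
                        root_prob = root_prob, method = "Nelder-Mead",
                        control = list(reltol = 1e-9, maxit = 1000))
      expit(clamp(o$par[1:2]))
    }, numeric(2))
    a <- (1 - level) / 2
    rbind(p_on = stats::quantile(ests[1, ], c(a, 1 - a), names = FALSE),
          p_off = stats::quantile(ests[2, ], c(a, 1 - a), names = FALSE))
  })
}

#' @export
coef.switch_fit <- function(object, ...) object$coefficients

#' @export
logLik.switch_fit <- function(object, ...) {
  structure(object$logLik,
            df = length(object$coefficients), class = "logLik")
}

#' @export
confint.switch_fit <- function(object, parm, level, ...) {
  if (is.null(object$ci)) stop("fit was run with ci = 'none'")
  ci <- object$ci
  colnames(ci) <- c("low", "high")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.switch_fit <- function(x, digits = 4, ...) {
  cat("Heritable switching model fit (", x$n_trees, " lineages, ",
      x$n_divisions, " divisions, ", x$n_observed, " observed leaves)\n",
      sep = "")
  cat("  p_on  (N->R per generation): ", signif(x$coefficients["p_on"], digits),
      if (x$boundary["p_on"]) " [boundary]", "\n", sep = "")
  cat("  p_off (R->N per generation): ", signif(x$coefficients["p_off"], digits),
      if (x$boundary["p_off"]) " [boundary]", "\n", sep = "")
  if (!is.null(x$ci)) {
    cat("  ", format(100 * x$level), "% CI (", x$ci_method, "): p_on [",
        signif(x$ci["p_on", 1], digits), ", ", signif(x$ci["p_on", 2], digits),
        "], p_off [", signif(x$ci["p_off", 1], digits), ", ",
        signif(x$ci["p_off", 2], digits), "]\n", sep = "")
  }
  if (x$root_dist == "free")
    cat("  initial responder fraction: ",
        signif(x$coefficients["root_frac"], digits), "\n", sep = "")
  cat("  stationary responder fraction: ",
      signif(stationary_fraction(x$coefficients["p_on"],
                                 x$coefficients["p_off"]), digits),
      "\n  log-likelihood: ", format(x$logLik, digits = 7), "\n", sep = "")
  invisible(x)
}

#' @export
summary.switch_fit <- function(object, ...) {
  object$f_ss <- stationary_fraction(object$coefficients["p_on"],
                                     object$coefficients["p_off"])
  class(object) <- c("summary.switch_fit", class(object))
  object
}

#' @export
print.summary.switch_fit <- function(x, ...) {
  print.switch_fit(x, ...)
  if (any(x$boundary))
    cat("  note: estimate(s) at the parameter boundary: ",
        paste(names(x$boundary)[x$boundary], collapse = ", "), "\n", sep = "")
  cat("  root distribution: ", x$root_dist,
      if (x$root_dist == "fixed") paste0(" (", x$root_prob_fixed, ")"),
      "; optimizer converged: ", x$convergence, "\n", sep = "")
  invisible(x)
}

#' Predict responder-fraction relaxation from a fitted switching model
#'
#' @param object a \code{switch_fit}.
#' @param f0 starting responder fraction (e.g. 0.65 after demethylating-agent
#'   treatment).
#' @param n_generations generations to predict.
#' @param generation_time_h hours per generation (default 24).
#' @param band if \code{TRUE} and the fit has CIs, add the rate-CI envelope.
#' @param ... unused.
#' @return a \code{\link{predict_fraction_decay}} object.
#' @export
predict.switch_fit <- function(object, f0, n_generations,
                               generation_time_h = 24, band = TRUE, ...) {
  cf <- object$coefficients
  ci_on <- ci_off <- NULL
  if (band && !is.null(object$ci)) {
    ci_on <- object$ci["p_on", ]; ci_off <- object$ci["p_off", ]
  }
  predict_fraction_decay(cf["p_on"], cf["p_off"], f0, n_generations,
                         generation_time_h, ci_on = ci_on, ci_off = ci_off)
}

#' Simulate new lineages from a fitted switching model
#'
#' @param object a \code{switch_fit}.
#' @param nsim number of simulated forests.
#' @param seed integer seed.
#' @param n_lineages,max_generations,death_prob,division_prob forwarded to
#'   \code{\link{simulate_lineages}}.
#' @param ... unused.
#' @return a list of forests (\code{nsim = 1}: a single forest).
#' @export
simulate.switch_fit <- function(object, nsim = 1, seed = NULL,
                                n_lineages = object$n_trees,
                                max_generations = 5, death_prob = 0,
                                division_prob = 1, ...) {
  cf <- object$coefficients
  f0 <- switch(object$root_dist,
               free = cf["root_frac"],
               stationary = stationary_fraction(cf["p_on"], cf["p_off"]),
               fixed = object$root_prob_fixed)
  out <- with_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_lineages(cf["p_on"], cf["p_off"], f0, n_lineages,
                      max_generations, death_prob, division_prob)))
  if (nsim == 1) out[[1]] else out
}

#' @export
plot.switch_fit <- function(x, ...) {
  est <- x$coefficients[c("p_on", "p_off")]
  bp <- graphics::barplot(est, ylim = c(0, max(if (!is.null(x$ci)) x$ci else est) * 1.3),
                          ylab = "probability per generation",
                          names.arg = c("N → R (p_on)", "R → N (p_off)"), ...)
  if (!is.null(x$ci))
    graphics::arrows(bp, x$ci[, 1], bp, x$ci[, 2], angle = 90, code = 3,
                     length = 0.06)
  invisible(x)
}
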