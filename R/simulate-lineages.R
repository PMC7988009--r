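# Run code under a temporary RNG state when a seed is supplied; otherwise use
# (and advance) the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate cell lineages under heritable switching
#'
#' Grows each lineage from a single founder whose state is Bernoulli
#' (\code{initial_fraction}).  At every division both daughters inherit the
#' mother's state and then independently flip with the relevant per-generation
#' probability (\code{p_on} for non-responder mothers, \code{p_off} for
#' responder mothers).  Cells can be censored (death / migration out of the
#' field of view) with probability \code{death_prob} per generation, in which
#' case the phenotype is unobserved.  Surviving cells below
#' \code{max_generations} divide with probability \code{division_prob}
#' (default 1, i.e. synchronous complete expansion); cells that stop dividing
#' or reach the final generation are scored at the end of the experiment
#' (\code{fate = "terminal_observed"}).
#'
#' @inheritParams transition_matrix
#' @param initial_fraction probability that a founder is a responder.
#' @param n_lineages number of independent lineages (>= 1).
#' @param max_generations number of generations to simulate (>= 0).
#' @param death_prob per-generation probability of censoring.
#' @param division_prob per-generation probability that a surviving,
#'   non-final-generation cell divides; values < 1 emulate asynchronous
#'   cycling within a fixed observation window.
#' @param seed optional integer seed; output is deterministic given the seed.
#' @return a named list of \code{\link{lineage_tree}} objects.  Each tree
#'   carries the simulated hidden states in attribute \code{"true_state"}
#'   (named character vector, \code{"R"}/\code{"N"}).
#' @export
simulate_lineages <- function(p_on, p_off, initial_fraction, n_lineages,
                              max_generations, death_prob = 0,
                              division_prob = 1, seed = NULL) {
  check_prob(p_on, "p_on"); check_prob(p_off, "p_off")
  check_prob(initial_fraction, "initial_fraction")
  check_prob(death_prob, "death_prob"); check_prob(division_prob, "division_prob")
  if (n_lineages < 1) stop("n_lineages must be >= 1")
  if (max_generations < 0) stop("max_generations must be >= 0")
  with_seed(seed, {
    sim_forest(p_on, p_off, initial_fraction, as.integer(n_lineages),
               as.integer(max_generations), death_prob, division_prob)
  })
}

# One vectorized pass per generation over the joint frontier of all lineages.
sim_forest <- function(p_on, p_off, initial_fraction, n_lineages,
                       max_generations, death_prob, division_prob) {
  rec <- list()  # per-generation record blocks
  counter <- rep(1L, n_lineages)
  frontier <- data.frame(
    lineage = seq_len(n_lineages),
    id = rep(1L, n_lineages),
    parent = NA_integer_,
    gen = 0L,
    state = ifelse(stats::runif(n_lineages) < initial_fraction, "R", "N"),
    stringsAsFactors = FALSE)
  while (nrow(frontier)) {
    n <- nrow(frontier)
    dies <- stats::runif(n) < death_prob
    divides <- !dies & frontier$gen < max_generations &
      stats::runif(n) < division_prob
    fate <- ifelse(dies, ifelse(stats::runif(n) < 0.5, "died", "left_fov"),
                   ifelse(divides, "divided", "terminal_observed"))
    rec[[length(rec) + 1L]] <- data.frame(
      lineage = frontier$lineage, id = frontier$id, parent = frontier$parent,
      gen = frontier$gen, fate = fate,
      status = ifelse(fate == "terminal_observed", frontier$state, NA_character_),
      state = frontier$state, stringsAsFactors = FALSE)
    div <- frontier[divides, , drop = FALSE]
    if (!nrow(div)) break
    k <- nrow(div)
    mother <- div[rep(seq_len(k), each = 2L), , drop = FALSE]
    flip_p <- ifelse(mother$state == "R", p_off, p_on)
    flip <- stats::runif(2L * k) < flip_p
    dstate <- ifelse(flip, ifelse(mother$state == "R", "N", "R"), mother$state)
    within <- stats::ave(rep(1L, 2L * k), mother$lineage, FUN = cumsum)
    new_id <- counter[mother$lineage] + within
    newmax <- tapply(new_id, mother$lineage, max)
    counter[as.integer(names(newmax))] <- as.integer(newmax)
    frontier <- data.frame(lineage = mother$lineage, id = new_id,
                           parent = mother$id, gen = mother$gen + 1L,
                           state = dstate, stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rec)
  all <- all[order(all$lineage, all$id), , drop = FALSE]
  trees <- lapply(split(all, all$lineage), function(df) {
    tr <- data.frame(node_id = paste0("n", df$id),
                     parent_id = ifelse(is.na(df$parent), NA_character_,
                                        paste0("n", df$parent)),
                     generation = df$gen, fate = df$fate,
                     leaf_status = df$status, stringsAsFactors = FALSE)
    class(tr) <- c("lineage_tree", "data.frame")
    attr(tr, "true_state") <- stats::setNames(df$state, tr$node_id)
    tr
  })
  names(trees) <- sprintf("L%04d", seq_len(n_lineages))
  trees
}
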