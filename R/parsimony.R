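#' Fitch parsimony reconstruction of ancestral responder states
#'
#' Reconstructs the lineage's internal responder / non-responder states by
#' minimizing the number of parent-to-child state changes (two-state small
#' parsimony).  Censored leaves (died / left the field of view) are
#' uninformative: their state set is \{N, R\} and they never force a change.
#'
#' The top-down pass resolves each node to the parent's state whenever that is
#' compatible; an ambiguous root is reported as \code{"N/R"} (non-responder
#' listed first) and resolved to \code{"N"} for propagation, so output is
#' deterministic.
#'
#' @param tree a \code{\link{lineage_tree}} with at least one observed leaf.
#' @return a list with \code{states} (named character vector over all nodes,
#'   values \code{"N"}, \code{"R"} or \code{"N/R"}) and \code{min_switches}
#'   (the parsimony score).
#' @export
fitch_parsimony <- function(tree) {
  obs <- observed_leaves(tree)
  if (!nrow(obs)) stop("fitch_parsimony requires at least one observed leaf")
  n <- nrow(tree)
  ids <- tree$node_id
  pid <- match(tree$parent_id, ids)
  ord <- order(tree$generation, decreasing = TRUE)  # children before parents
  # state sets as 2-col logical matrix (N, R)
  set <- matrix(TRUE, n, 2, dimnames = list(ids, c("N", "R")))
  known <- !is.na(tree$leaf_status)
  set[known, 1] <- tree$leaf_status[known] == "N"
  set[known, 2] <- tree$leaf_status[known] == "R"
  children <- split(seq_len(n)[!is.na(pid)], pid[!is.na(pid)])
  switches <- 0L
  for (i in ord) {
    kids <- children[[as.character(i)]]
    if (is.null(kids)) next
    inter <- set[kids[1], ] & set[kids[2], ]
    if (any(inter)) {
      set[i, ] <- inter
    } else {
      set[i, ] <- set[kids[1], ] | set[kids[2], ]
      switches <- switches + 1L
    }
  }
  states <- character(n)
  for (i in rev(ord)) {  # parents before children
    if (is.na(pid[i])) {
      states[i] <- if (all(set[i, ])) "N/R" else c("N", "R")[set[i, ]]
    } else {
      ps <- sub("/.*", "", states[pid[i]])
      states[i] <- if (set[i, c(N = 1, R = 2)[ps]]) ps else c("N", "R")[set[i, ]]
    }
  }
  list(states = stats::setNames(states, ids), min_switches = switches)
}

#' Responder concordance by lineage relatedness
#'
#' For every observed responder leaf, classifies every other observed leaf in
#' the same tree by the depth of their most recent common ancestor, counted in
#' divisions from the focal cell (1 = sister, 2 = cousin, >= 3 = extended
#' relative), and reports the per-class probability that the relative is also
#' a responder.  Pairs of responders contribute in both directions, matching
#' the conditional definition P(relative is R | cell is R).
#'
#' @param trees a list of \code{\link{lineage_tree}} objects (or one tree).
#' @return a data.frame with columns \code{relation}, \code{n_pairs},
#'   \code{n_responder_relatives}, \code{concordance}.
#' @export
relatedness_concordance <- function(trees) {
  if (inherits(trees, "lineage_tree")) trees <- list(trees)
  cls <- c("sister", "cousin", "extended")
  n_pairs <- stats::setNames(integer(3), cls)
  n_resp <- stats::setNames(integer(3), cls)
  any_resp <- FALSE
  for (tr in trees) {
    obs <- observed_leaves(tr)
    if (nrow(obs) < 2) next
    ids <- tr$node_id
    pid <- match(tr$parent_id, ids)
    anc <- lapply(match(obs$node_id, ids), function(i) {
      path <- integer(0)
      while (!is.na(i)) { path <- c(path, i); i <- pid[i] }
      path
    })
    gen <- tr$generation
    for (a in seq_len(nrow(obs))) {
      if (obs$leaf_status[a] != "R") next
      any_resp <- TRUE
      for (b in seq_len(nrow(obs))) {
        if (b == a) next
        mrca <- intersect(anc[[a]], anc[[b]])[1]  # paths are leaf-to-root
        d <- gen[match(obs$node_id[a], ids)] - gen[mrca]
        k <- if (d <= 1) "sister" else if (d == 2) "cousin" else "extended"
        n_pairs[k] <- n_pairs[k] + 1L
        if (obs$leaf_status[b] == "R") n_resp[k] <- n_resp[k] + 1L
      }
    }
  }
  if (!any_resp) warning("no responder leaf observed; empty concordance table")
  data.frame(relation = cls, n_pairs = as.integer(n_pairs),
             n_responder_relatives = as.integer(n_resp),
             concordance = ifelse(n_pairs > 0, n_resp / n_pairs, NA_real_),
             row.names = NULL)
}
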