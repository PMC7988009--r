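#' Exact marginal likelihood of observed leaf states on lineage trees
#'
#' Computes the probability of the observed responder / non-responder leaf
#' phenotypes under the heritable switching model by post-order pruning over
#' the two hidden states (the standard peeling recursion for a discrete trait
#' on a tree).  Censored leaves (died / left the field of view) carry partial
#' likelihood 1 in both states, i.e. they are marginalized out while their
#' position preserves the tree topology.
#'
#' @param tree a \code{\link{lineage_tree}} or a list of them.
#' @inheritParams transition_matrix
#' @param root_prob probability that the founder cell is a responder.
#' @return the summed log-likelihood over trees; \code{-Inf} (with attribute
#'   \code{"impossible" = TRUE}) when the data have probability 0 under the
#'   given rates.
#' @export
tree_log_likelihood <- function(tree, p_on, p_off, root_prob) {
  check_prob(p_on, "p_on"); check_prob(p_off, "p_off")
  check_prob(root_prob, "root_prob")
  fi <- forest_index(tree)
  forest_loglik(fi, p_on, p_off, root_prob)
}

# Flatten a list of lineage trees into index vectors for fast repeated
# likelihood evaluation: nodes get global integer indices; internal nodes are
# grouped by generation so the pruning pass is a handful of matrix products.
forest_index <- function(trees) {
  if (inherits(trees, "lineage_tree")) trees <- list(trees)
  if (!length(trees)) stop("no trees supplied")
  sizes <- vapply(trees, nrow, integer(1))
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  n <- sum(sizes)
  tree_of <- rep(seq_along(trees), sizes)
  gen <- integer(n); child1 <- rep(NA_integer_, n); child2 <- rep(NA_integer_, n)
  leaf_state <- rep(NA_character_, n); root <- integer(length(trees))
  for (t in seq_along(trees)) {
    tr <- trees[[t]]
    idx <- offs[t] + seq_len(nrow(tr))
    gen[idx] <- tr$generation
    leaf_state[idx] <- tr$leaf_status
    pid <- match(tr$parent_id, tr$node_id)
    root[t] <- idx[which(is.na(pid))]
    kids <- which(!is.na(pid))
    for (k in kids) {
      p <- offs[t] + pid[k]
      if (is.na(child1[p])) child1[p] <- offs[t] + k else child2[p] <- offs[t] + k
    }
  }
  internal <- which(!is.na(child1))
  if (any(is.na(child2[internal])))
    stop("malformed tree: divided node with a single child")
  by_gen <- split(internal, gen[internal])
  by_gen <- by_gen[order(as.integer(names(by_gen)), decreasing = TRUE)]
  list(n = n, n_trees = length(trees), tree_of = tree_of, root = root,
       by_gen = by_gen, child1 = child1, child2 = child2,
       leaf_state = leaf_state,
       n_observed = sum(!is.na(leaf_state)))
}

forest_loglik <- function(fi, p_on, p_off, root_prob) {
  if (fi$n_observed == 0L) return(0)
  P <- matrix(c(1 - p_on, p_on, p_off, 1 - p_off), 2, 2, byrow = TRUE)
  L <- matrix(1, fi$n, 2)
  L[!is.na(fi$leaf_state) & fi$leaf_state == "R", 1] <- 0
  L[!is.na(fi$leaf_state) & fi$leaf_state == "N", 2] <- 0
  logscale <- numeric(fi$n_trees)
  tP <- t(P)
  for (idx in fi$by_gen) {
    M <- (L[fi$child1[idx], , drop = FALSE] %*% tP) *
         (L[fi$child2[idx], , drop = FALSE] %*% tP)
    s <- M[, 1] + M[, 2]
    if (any(s == 0)) {
      ll <- -Inf; attr(ll, "impossible") <- TRUE
      return(ll)
    }
    L[idx, ] <- M / s
    sc <- rowsum(log(s), fi$tree_of[idx], reorder = FALSE)
    logscale[as.integer(rownames(sc))] <- logscale[as.integer(rownames(sc))] + sc[, 1]
  }
  rootlik <- (1 - root_prob) * L[fi$root, 1] + root_prob * L[fi$root, 2]
  if (any(rootlik == 0)) {
    ll <- -Inf; attr(ll, "impossible") <- TRUE
    return(ll)
  }
  sum(log(rootlik) + logscale)
}
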