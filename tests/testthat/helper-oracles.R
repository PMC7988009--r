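# Independent oracles used to check the pruning likelihood, the parsimony
# count and the decay closed form against brute force / direct iteration.

# Build a lineage_tree from a compact edge description.
toy_tree <- function(parent, fate, status) {
  ids <- paste0("n", seq_along(parent))
  gen <- integer(length(parent))
  for (i in seq_along(parent))
    gen[i] <- if (is.na(parent[i])) 0L else gen[parent[i]] + 1L
  lineage_tree(data.frame(
    node_id = ids,
    parent_id = ifelse(is.na(parent), NA, paste0("n", parent)),
    generation = gen, fate = fate, leaf_status = status,
    stringsAsFactors = FALSE))
}

# cherry: one division, two observed leaves
cherry <- function(s1, s2) {
  toy_tree(parent = c(NA, 1, 1),
           fate = c("divided", "terminal_observed", "terminal_observed"),
           status = c(NA, s1, s2))
}

# Random topology with random censoring and leaf states, for oracle checks.
random_toy_tree <- function(max_gen) {
  repeat {
    parent <- NA_integer_; gen <- 0L
    frontier <- 1L
    while (length(frontier)) {
      nxt <- integer(0)
      for (i in frontier) {
        if (gen[i] < max_gen && stats::runif(1) < 0.6) {
          for (d in 1:2) {
            parent <- c(parent, i); gen <- c(gen, gen[i] + 1L)
            nxt <- c(nxt, length(parent))
          }
        }
      }
      frontier <- nxt
    }
    n <- length(parent)
    has_kids <- seq_len(n) %in% parent
    fate <- ifelse(has_kids, "divided",
                   sample(c("terminal_observed", "died", "left_fov"), n,
                          replace = TRUE, prob = c(0.7, 0.15, 0.15)))
    status <- ifelse(fate == "terminal_observed",
                     sample(c("R", "N"), n, replace = TRUE), NA)
    if (any(fate == "terminal_observed")) break  # need >= 1 observed leaf
  }
  toy_tree(parent, fate, status)
}

# All joint assignments of the hidden (internal + censored-leaf) states as an
# n x 2^k state matrix; observed leaves are fixed.  States coded 1 = N, 2 = R.
hidden_state_grid <- function(tree) {
  n <- nrow(tree)
  free <- which(is.na(tree$leaf_status))
  k <- length(free)
  st <- matrix(0L, n, 2^k)  # k = 0: a single fully-observed assignment
  if (k > 0)
    st[free, ] <- t(as.matrix(expand.grid(rep(list(1:2), k))))
  fixed <- setdiff(seq_len(n), free)
  st[fixed, ] <- ifelse(tree$leaf_status[fixed] == "R", 2L, 1L)
  st
}

# Brute-force marginal likelihood: sum the complete-data probability over
# every joint hidden-state assignment.
brute_force_loglik <- function(tree, p_on, p_off, root_prob) {
  pid <- match(tree$parent_id, tree$node_id)
  st <- hidden_state_grid(tree)
  logP <- log(matrix(c(1 - p_on, p_on, p_off, 1 - p_off), 2, 2, byrow = TRUE))
  kids <- which(!is.na(pid))
  edge_ll <- matrix(logP[cbind(as.vector(st[pid[kids], , drop = FALSE]),
                               as.vector(st[kids, , drop = FALSE]))],
                    nrow = length(kids), ncol = ncol(st))
  root_ll <- log(ifelse(st[which(is.na(pid)), ] == 2L, root_prob, 1 - root_prob))
  log(sum(exp(colSums(edge_ll) + root_ll)))
}

# Brute-force parsimony: minimize parent-child changes over all assignments
# of internal nodes and unobserved leaves.
brute_force_parsimony <- function(tree) {
  pid <- match(tree$parent_id, tree$node_id)
  st <- hidden_state_grid(tree)
  kids <- which(!is.na(pid))
  changes <- colSums(st[kids, , drop = FALSE] != st[pid[kids], , drop = FALSE])
  min(changes)
}

# Responder-fraction trajectory by explicit transition-matrix iteration.
iterate_fraction <- function(p_on, p_off, f0, n_generations) {
  P <- matrix(c(1 - p_on, p_on, p_off, 1 - p_off), 2, 2, byrow = TRUE)
  v <- c(1 - f0, f0)
  out <- numeric(n_generations + 1)
  out[1] <- v[2]
  for (g in seq_len(n_generations)) {
    v <- as.numeric(v %*% P)
    out[g + 1] <- v[2]
  }
  out
}

# Synthetic pulse trace with exact piecewise-linear geometry for hand AUC.
linear_trace <- function(time_min, ratio, t_stim = 0, venus = NULL) {
  if (is.null(venus)) venus <- rep(0, length(time_min))
  cell_trace("toy", time_min, nuc_p65 = ratio, cyt_p65 = rep(1, length(ratio)),
             venus = venus, t_stim_min = t_stim)
}

write_nanopolish_tsv <- function(rows, path) {
  header <- c("chromosome", "strand", "start", "end", "read_name",
              "log_lik_ratio", "log_lik_methylated", "log_lik_unmethylated",
              "num_calling_strands", "num_motifs", "sequence")
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chromosome = "chr4", strand = "+", start = r$start,
               end = r$start + 1, read_name = r$read,
               log_lik_ratio = r$llr, log_lik_methylated = 0,
               log_lik_unmethylated = 0, num_calling_strands = 1,
               num_motifs = r$num_motifs %||% 1,
               sequence = r$sequence %||% "AAACGAAA",
               stringsAsFactors = FALSE)
  }))
  names(df) <- header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
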