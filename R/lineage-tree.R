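#' Construct and validate a cell lineage tree
#'
#' A lineage tree records one founder cell and its descendants from a
#' time-lapse tracking experiment.  Each node is a cell-cycle interval; a cell
#' that divides has exactly two daughters, and the responder / non-responder
#' phenotype is observed only on cells still present at the end of the movie
#' (fate \code{"terminal_observed"}).  Cells that died or migrated out of the
#' field of view are retained as censored leaves with unknown status.
#'
#' @param nodes a data.frame with columns \code{node_id} (unique identifier),
#'   \code{parent_id} (identifier of the mother, \code{NA} or \code{"ROOT"}
#'   for the founder), \code{generation} (0 for the founder, parent + 1
#'   otherwise), \code{fate} (one of \code{"divided"}, \code{"died"},
#'   \code{"left_fov"}, \code{"terminal_observed"}) and \code{leaf_status}
#'   (\code{"R"}, \code{"N"} or \code{NA}; non-\code{NA} only on
#'   \code{terminal_observed} leaves).
#' @return an object of class \code{lineage_tree} (a validated data.frame).
#' @export
lineage_tree <- function(nodes) {
  req <- c("node_id", "parent_id", "generation", "fate", "leaf_status")
  miss <- setdiff(req, names(nodes))
  if (length(miss))
    stop("lineage table is missing column(s): ", paste(miss, collapse = ", "))
  nodes <- as.data.frame(nodes)[req]
  nodes$node_id <- as.character(nodes$node_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  nodes$parent_id[nodes$parent_id %in% "ROOT"] <- NA_character_
  nodes$generation <- as.integer(nodes$generation)
  nodes$fate <- as.character(nodes$fate)
  nodes$leaf_status <- as.character(nodes$leaf_status)
  nodes$leaf_status[nodes$leaf_status %in% c("", "NA")] <- NA_character_
  validate_lineage_tree(nodes)
  class(nodes) <- c("lineage_tree", "data.frame")
  nodes
}

validate_lineage_tree <- function(nodes) {
  if (anyDuplicated(nodes$node_id))
    stop("duplicated node_id: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "))
  is_root <- is.na(nodes$parent_id)
  if (sum(is_root) != 1L)
    stop("a lineage tree must have exactly one root, found ", sum(is_root))
  orphan <- !is_root & !(nodes$parent_id %in% nodes$node_id)
  if (any(orphan))
    stop("orphan node(s) referencing a missing parent: ",
         paste(nodes$node_id[orphan], collapse = ", "))
  bad_fate <- !nodes$fate %in% c("divided", "died", "left_fov", "terminal_observed")
  if (any(bad_fate))
    stop("invalid fate value(s): ", paste(unique(nodes$fate[bad_fate]), collapse = ", "))
  bad_status <- !is.na(nodes$leaf_status) & !nodes$leaf_status %in% c("R", "N")
  if (any(bad_status))
    stop("leaf_status must be 'R', 'N' or NA")
  n_child <- table(factor(nodes$parent_id, levels = nodes$node_id))
  div <- nodes$fate == "divided"
  if (any(n_child[nodes$node_id[div]] != 2L))
    stop("every divided node must have exactly 2 children; offending node(s): ",
         paste(nodes$node_id[div][n_child[nodes$node_id[div]] != 2L], collapse = ", "))
  if (any(n_child[nodes$node_id[!div]] != 0L))
    stop("non-divided node(s) with children: ",
         paste(nodes$node_id[!div][n_child[nodes$node_id[!div]] != 0L], collapse = ", "))
  if (any(!is.na(nodes$leaf_status) & nodes$fate != "terminal_observed"))
    stop("leaf_status may only be set on terminal_observed nodes")
  if (nodes$generation[is_root] != 0L)
    stop("root generation must be 0")
  pgen <- nodes$generation[match(nodes$parent_id, nodes$node_id)]
  bad_gen <- !is_root & nodes$generation != pgen + 1L
  if (any(bad_gen))
    stop("generation must increase by 1 from parent to child; offending node(s): ",
         paste(nodes$node_id[bad_gen], collapse = ", "))
  invisible(nodes)
}

#' @export
print.lineage_tree <- function(x, ...) {
  obs <- observed_leaves(x)
  cat(sprintf("<lineage_tree> %d nodes, %d divisions, depth %d; %d observed leaves (%d R / %d N)\n",
              nrow(x), sum(x$fate == "divided"), max(x$generation),
              nrow(obs), sum(obs$leaf_status == "R"), sum(obs$leaf_status == "N")))
  invisible(x)
}

observed_leaves <- function(tree) {
  tree[tree$fate == "terminal_observed" & !is.na(tree$leaf_status), , drop = FALSE]
}

n_divisions <- function(trees) {
  if (inherits(trees, "lineage_tree")) trees <- list(trees)
  sum(vapply(trees, function(t) sum(t$fate == "divided"), integer(1)))
}

#' Read / write lineage tables
#'
#' The on-disk format is a TSV with columns \code{lineage_id}, \code{node_id},
#' \code{parent_id} (\code{"ROOT"} marks the founder), \code{generation},
#' \code{fate} and \code{leaf_status} (\code{R} / \code{N} / \code{NA}).
#' Row order is irrelevant; one tree per \code{lineage_id}.
#'
#' @param path file path.
#' @return \code{read_lineage_tsv}: a named list of \code{lineage_tree}
#'   objects; \code{write_lineage_tsv}: \code{path}, invisibly.
#' @export
read_lineage_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = "NA")
  req <- c("lineage_id", "node_id", "parent_id", "generation", "fate", "leaf_status")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("lineage TSV missing column(s): ", paste(miss, collapse = ", "))
  trees <- lapply(split(tab, tab$lineage_id), function(df) {
    tryCatch(lineage_tree(df), error = function(e)
      stop("lineage '", df$lineage_id[1], "': ", conditionMessage(e), call. = FALSE))
  })
  trees[unique(tab$lineage_id)]
}

#' @rdname read_lineage_tsv
#' @param trees a list of \code{lineage_tree} objects (names become
#'   \code{lineage_id}s).
#' @export
write_lineage_tsv <- function(trees, path) {
  if (inherits(trees, "lineage_tree")) trees <- list(trees)
  if (is.null(names(trees)) || any(names(trees) == ""))
    names(trees) <- sprintf("L%03d", seq_along(trees))
  rows <- lapply(names(trees), function(id) {
    df <- as.data.frame(trees[[id]])
    df$parent_id[is.na(df$parent_id)] <- "ROOT"
    cbind(lineage_id = id, df)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
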