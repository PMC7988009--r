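#' Read / write single-cell trace tables
#'
#' Long-format CSV with one row per cell and frame: columns \code{cell_id},
#' \code{frame}, \code{time_min}, \code{nuc_p65}, \code{cyt_p65},
#' \code{venus}, \code{stimulus}, \code{concentration}, \code{t_stim_min}.
#' Rows may arrive in any order; duplicated (cell, frame) pairs and mixed
#' frame intervals within a cell are rejected.
#'
#' @param path file path.
#' @return \code{read_trace_csv}: a list of \code{\link{cell_trace}} objects;
#'   \code{write_trace_csv}: \code{path}, invisibly.
#' @export
read_trace_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "frame", "time_min", "nuc_p65", "cyt_p65", "venus",
           "stimulus", "concentration", "t_stim_min")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("trace CSV missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab[c("cell_id", "frame")]))
    stop("duplicated (cell_id, frame) row(s) in trace table")
  lapply(split(tab, tab$cell_id), function(df) {
    df <- df[order(df$frame), ]
    if (any(diff(df$time_min) <= 0))
      stop("cell ", df$cell_id[1], ": time_min not strictly increasing")
    iv <- diff(df$time_min)
    if (length(iv) > 1 && max(abs(iv - iv[1])) > 1e-6)
      stop("cell ", df$cell_id[1], ": mixed frame intervals")
    cell_trace(df$cell_id[1], df$time_min, df$nuc_p65, df$cyt_p65, df$venus,
               df$stimulus[1], df$concentration[1], df$t_stim_min[1])
  })
}

#' @rdname read_trace_csv
#' @param traces a list of \code{\link{cell_trace}} objects.
#' @export
write_trace_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(cell_id = tr$cell_id, frame = seq_along(tr$time_min),
               time_min = tr$time_min, nuc_p65 = tr$nuc_p65,
               cyt_p65 = tr$cyt_p65, venus = tr$venus,
               stimulus = tr$stimulus, concentration = tr$concentration,
               t_stim_min = tr$t_stim_min, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "NA")
  invisible(path)
}

run_config_defaults <- function() {
  list(
    seed = NULL,
    lineage = list(p_on = 0.01, p_off = 0.055, initial_fraction = NULL,
                   n_lineages = 58, max_generations = 5, death_prob = 0,
                   division_prob = 1, root_dist = "free", ci = "profile"),
    traces = list(low_pct = 25, high_pct = 99, rule = "max", q = 0.99,
                  min_prominence = NULL),
    spatial = list(k = 5, n_perm = 1000),
    methylation = list(llr_threshold = 1.5, window = c(-110, -60),
                       min_covered = 0.8, tolerance = 1),
    decay = list(f0 = 0.65, n_generations = 30, generation_time_h = 24)
  )
}

#' Load a run configuration
#'
#' Reads a YAML configuration, fills every stage parameter with its package
#' default and rejects unknown keys (with a closest-match suggestion).  An
#' empty file yields all defaults with a warning.  The resolved configuration
#' carries the source path in attribute \code{"source"} so it can be echoed
#' alongside results.
#'
#' @param path YAML file path.
#' @return a nested named list of stage parameters.
#' @export
load_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- run_config_defaults()
  if (is.null(user) || !length(user)) {
    warning("empty config: using all defaults")
    user <- list()
  }
  merged <- merge_config(defaults, user, prefix = NULL)
  attr(merged, "source") <- normalizePath(path)
  merged
}

merge_config <- function(defaults, user, prefix) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    key <- unknown[1]
    full <- if (is.null(prefix)) key else paste0(prefix, ".", key)
    sug <- agrep(key, names(defaults), max.distance = 0.3, value = TRUE)
    stop("unknown config key '", full, "'",
         if (length(sug)) paste0("; did you mean '", sug[1], "'?"))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]]))
        stop("config key '", k, "' must be a mapping")
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], prefix = k)
    } else {
      defaults[k] <- user[k]
    }
  }
  defaults
}
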