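#' Generate synthetic single-cell NF-kB trace sets
#'
#' Emulates the statistical structure of monolayer imaging data: a latent
#' responder fraction (default 0.15, the stationary fraction of the
#' epigenetic switch); responders show a single transient translocation pulse
#' (pulsatile mode, as for bacterial-lipopeptide stimulation) or a damped
#' oscillation persisting for hours (oscillatory mode); non-responders stay
#' flat.  The reporter integrates supra-threshold nuclear activity with
#' first-order decay, mimicking a destabilized (PEST-tagged) transcriptional
#' reporter whose expression trails signaling by tens of minutes.  Frames are
#' 5 min apart.
#'
#' @param n_cells number of cells.
#' @param responder_fraction latent probability of being a responder.
#' @param mode \code{"pulsatile"} or \code{"oscillatory"}.
#' @param n_frames total frames (default 150, i.e. 12.5 h at 5-min frames).
#' @param t_stim_min stimulus time (default 50 min).
#' @param baseline_mean,baseline_sd cell-to-cell variation of the resting
#'   nuclear/cytoplasmic ratio.
#' @param peak_mean,peak_sd responder pulse amplitude distribution (ratio
#'   units above baseline).
#' @param noise_sd frame-to-frame measurement noise on the ratio.
#' @param decay_min pulse decay time scale (minutes).
#' @param osc_period_min oscillation period in oscillatory mode.
#' @param reporter_rate,reporter_decay,reporter_threshold destabilized
#'   reporter kinetics: production per frame while the ratio exceeds
#'   baseline + threshold, and first-order decay per frame.
#' @param expr_mean,expr_sd log-normal total p65 expression (used by the QC
#'   filter).
#' @param seed integer seed.
#' @return a list with \code{traces} (list of \code{\link{cell_trace}}) and
#'   \code{truth} (data.frame of cell_id and latent responder state).
#' @export
gen_trace_set <- function(n_cells, responder_fraction = 0.15,
                          mode = c("pulsatile", "oscillatory"),
                          n_frames = 150, t_stim_min = 50,
                          baseline_mean = 1, baseline_sd = 0.05,
                          peak_mean = 2, peak_sd = 0.4, noise_sd = 0.03,
                          decay_min = 25, osc_period_min = 90,
                          reporter_rate = 12, reporter_decay = 0.04,
                          reporter_threshold = 0.5,
                          expr_mean = log(200), expr_sd = 0.4, seed = NULL) {
  mode <- match.arg(mode)
  check_prob(responder_fraction, "responder_fraction")
  with_seed(seed, {
    tmin <- (seq_len(n_frames) - 1) * 5
    traces <- vector("list", n_cells)
    is_resp <- stats::runif(n_cells) < responder_fraction
    for (i in seq_len(n_cells)) {
      base <- stats::rnorm(1, baseline_mean, baseline_sd)
      r <- rep(base, n_frames)
      if (is_resp[i]) {
        amp <- max(stats::rnorm(1, peak_mean, peak_sd), 0.5)
        dt <- tmin - (t_stim_min + 10)  # translocation peaks ~10 min post stimulus
        act <- ifelse(dt < 0, pmax(1 + dt / 10, 0),  # 10-min linear rise
                      if (mode == "pulsatile") exp(-dt / decay_min)
                      else exp(-dt / 300) * abs(cos(pi * dt / osc_period_min)))
        r <- r + amp * act
      }
      r <- pmax(r + stats::rnorm(n_frames, 0, noise_sd), 0.05)
      # destabilized reporter: leaky integration of supra-threshold activity
      on_lag <- c(FALSE, r[-n_frames] > base + reporter_threshold)
      rep_v <- as.numeric(stats::filter(reporter_rate * on_lag,
                                        1 - reporter_decay, "recursive"))
      rep_v <- rep_v + abs(stats::rnorm(n_frames, 0, 2))
      total <- stats::rlnorm(1, expr_mean, expr_sd)
      frac_nuc <- r / (1 + r)
      traces[[i]] <- cell_trace(sprintf("c%04d", i), tmin,
                                nuc_p65 = pmax(total * frac_nuc, 1e-3),
                                cyt_p65 = pmax(total * (1 - frac_nuc), 1e-3),
                                venus = rep_v, stimulus = "Pam3CSK4",
                                concentration = 1, t_stim_min = t_stim_min)
    }
    list(traces = traces,
         truth = data.frame(cell_id = sprintf("c%04d", seq_len(n_cells)),
                            responder = is_resp, stringsAsFactors = FALSE))
  })
}

#' Generate a monolayer field from expanding lineages
#'
#' Simulates lineages under the heritable switching model
#' (\code{\link{simulate_lineages}}); founders are scattered uniformly over
#' the field and every daughter is placed at its mother's position plus an
#' isotropic Gaussian displacement, so related cells -- which share the
#' heritable responder state -- end up spatially grouped.  Observed leaves
#' form the monolayer.
#'
#' @inheritParams simulate_lineages
#' @param field_um side length of the square field (micrometres).
#' @param disp_sd_um displacement standard deviation per division (default
#'   20 um, about one cell diameter).
#' @return a list with \code{field} (data.frame: cell_id, x_um, y_um,
#'   responder) and \code{trees} (the generating lineages).
#' @export
gen_monolayer_field <- function(n_lineages, max_generations,
                                p_on = 0.01, p_off = 0.055,
                                initial_fraction = NULL,
                                death_prob = 0, division_prob = 1,
                                field_um = 1000, disp_sd_um = 20,
                                seed = NULL) {
  if (is.null(initial_fraction))
    initial_fraction <- stationary_fraction(p_on, p_off)
  with_seed(seed, {
    trees <- simulate_lineages(p_on, p_off, initial_fraction, n_lineages,
                               max_generations, death_prob, division_prob)
    rows <- lapply(seq_along(trees), function(t) {
      tr <- trees[[t]]
      n <- nrow(tr)
      xy <- matrix(NA_real_, n, 2)
      pid <- match(tr$parent_id, tr$node_id)
      for (i in order(tr$generation)) {
        xy[i, ] <- if (is.na(pid[i])) stats::runif(2, 0, field_um)
                   else xy[pid[i], ] + stats::rnorm(2, 0, disp_sd_um)
      }
      obs <- tr$fate == "terminal_observed" & !is.na(tr$leaf_status)
      if (!any(obs)) return(NULL)
      data.frame(cell_id = paste0(names(trees)[t], "_", tr$node_id[obs]),
                 x_um = xy[obs, 1], y_um = xy[obs, 2],
                 responder = as.integer(tr$leaf_status[obs] == "R"),
                 stringsAsFactors = FALSE)
    })
    list(field = do.call(rbind, rows), trees = trees)
  })
}

#' Generate per-read promoter methylation matrices
#'
#' Each read draws a latent promoter state -- unmethylated (licensed) with
#' probability \code{weight_unmeth} -- and every CpG call copies that state,
#' flipped independently with \code{error_rate} and dropped with
#' \code{missing_rate}.  With \code{group_10bp = TRUE}, CpGs within 10 bp
#' share a single call draw, emulating the caller's grouped-motif convention.
#'
#' @param n_reads number of reads.
#' @param weight_unmeth probability a read is in the unmethylated state.
#' @param positions TSS-relative CpG positions; the default places 8 CpGs in
#'   the -110..-60 promoter window.
#' @param error_rate per-site call error probability.
#' @param missing_rate per-site missing-call probability.
#' @param group_10bp share one call draw among CpGs within 10 bp.
#' @param seed integer seed.
#' @return a list with \code{matrix} (a \code{methyl_matrix}) and
#'   \code{truth} (per-read latent state, \code{"U"}/\code{"M"}).
#' @export
gen_methyl_reads <- function(n_reads, weight_unmeth,
                             positions = c(-108, -102, -95, -88, -81, -74, -68, -61),
                             error_rate = 0.05, missing_rate = 0,
                             group_10bp = FALSE, seed = NULL) {
  check_prob(weight_unmeth, "weight_unmeth")
  check_prob(error_rate, "error_rate"); check_prob(missing_rate, "missing_rate")
  if (length(positions) < 2) stop("need at least 2 CpG positions")
  positions <- sort(positions)
  groups <- if (group_10bp) cumsum(c(1, diff(positions) > 10))
            else seq_along(positions)
  with_seed(seed, {
    state <- ifelse(stats::runif(n_reads) < weight_unmeth, "U", "M")
    n_grp <- max(groups)
    calls <- matrix(NA_character_, n_reads, length(positions))
    for (i in seq_len(n_reads)) {
      gcall <- ifelse(stats::runif(n_grp) < error_rate,
                      ifelse(state[i] == "U", "M", "U"), state[i])
      site_call <- gcall[groups]
      site_call[stats::runif(length(positions)) < missing_rate] <- NA
      calls[i, ] <- site_call
    }
    ids <- sprintf("read%04d", seq_len(n_reads))
    keep <- rowSums(!is.na(calls)) > 0
    if (!any(keep)) stop("no reads with calls overlapping the region")
    mat <- matrix(calls[keep, , drop = FALSE], ncol = length(positions),
                  dimnames = list(ids[keep], as.character(positions)))
    list(matrix = structure(mat, class = c("methyl_matrix", class(mat)),
                            region_label = "synthetic promoter"),
         truth = stats::setNames(state[keep], ids[keep]))
  })
}

#' Generate dose-response responder counts
#'
#' Per-cell response probability follows a Hill curve capped at \code{f_max}
#' (default: the stationary fraction of the switching chain, ~0.154 at the
#' fitted rates): \eqn{p(c) = f_{max} c^h / (c^h + EC_{50}^h)}.  Counts are
#' binomial per dose.
#'
#' @param concentrations stimulus concentrations (> 0).
#' @param n_cells cells per dose (scalar or vector).
#' @param ec50 half-maximal concentration.
#' @param hill Hill slope.
#' @param f_max maximum responder fraction.
#' @param p_on,p_off used for the default \code{f_max} via
#'   \code{\link{stationary_fraction}}.
#' @param seed integer seed.
#' @return a data.frame: \code{concentration}, \code{n}, \code{n_responders},
#'   \code{fraction}, \code{p_true}.
#' @export
gen_dose_response <- function(concentrations, n_cells, ec50 = 0.1, hill = 1,
                              f_max = NULL, p_on = 0.01, p_off = 0.055,
                              seed = NULL) {
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (is.null(f_max)) f_max <- stationary_fraction(p_on, p_off)
  check_prob(f_max, "f_max")
  n_cells <- rep_len(n_cells, length(concentrations))
  p <- f_max * concentrations^hill / (concentrations^hill + ec50^hill)
  with_seed(seed, {
    x <- stats::rbinom(length(p), n_cells, p)
    data.frame(concentration = concentrations, n = n_cells,
               n_responders = x, fraction = x / n_cells, p_true = p)
  })
}
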