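#' Parse a nanopolish-style per-read CpG methylation call table
#'
#' Reads a TSV of per-read, per-site log-likelihood ratios (columns
#' \code{read_name}, \code{chromosome}, \code{strand}, \code{start},
#' \code{log_lik_ratio}, \code{num_motifs}, \code{sequence}) and builds a
#' read x site call matrix in TSS-relative coordinates.  Calls are filtered
#' at |LLR| > \code{llr_threshold} (default 1.5): above +1.5 methylated (M),
#' below -1.5 unmethylated (U), ambiguous otherwise (missing).  Rows covering
#' a group of CpGs (\code{num_motifs} > 1; the caller cannot resolve CpGs
#' closer than 10 bp) assign the same call to every CpG in the group; group
#' CpG positions are recovered from the CG offsets in the \code{sequence}
#' context, anchored so the first CG sits at \code{start}.
#'
#' Genomic \code{start} coordinates are 0-based (BED convention).  The
#' TSS-relative coordinate of a cytosine at genomic position p is
#' \code{p - tss} on the + strand and \code{tss - p} on the - strand, so
#' upstream positions are negative.
#'
#' @param path TSV path.
#' @param tss 0-based genomic coordinate of the transcription start site.
#' @param tss_strand \code{"+"} or \code{"-"}.
#' @param llr_threshold absolute log-likelihood-ratio cutoff (default 1.5).
#' @param region optional length-2 TSS-relative range; reads with no call in
#'   it are dropped.
#' @return a \code{methyl_matrix}: character matrix (\code{"M"}, \code{"U"},
#'   \code{NA}) with reads as rows and sorted TSS-relative CpG positions as
#'   columns.
#' @export
read_methyl_calls <- function(path, tss, tss_strand = "+",
                              llr_threshold = 1.5, region = NULL) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  req <- c("read_name", "chromosome", "strand", "start", "log_lik_ratio",
           "num_motifs", "sequence")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("methylation call table missing column(s): ",
         paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    nm <- tab$num_motifs[i]
    pos <- tab$start[i]
    if (nm > 1) {
      offs <- gregexpr("CG", tab$sequence[i], fixed = TRUE)[[1]]
      if (length(offs) < nm)
        stop("row ", i, ": num_motifs = ", nm, " but only ", length(offs),
             " CG dinucleotides in sequence context")
      offs <- offs[seq_len(nm)]
      pos <- pos + (offs - offs[1])
    }
    llr <- tab$log_lik_ratio[i]
    call <- if (llr > llr_threshold) "M"
            else if (llr < -llr_threshold) "U" else NA_character_
    data.frame(read = tab$read_name[i], pos = pos, call = call,
               abs_llr = abs(llr), stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  calls$rel <- if (tss_strand == "+") calls$pos - tss else tss - calls$pos
  # duplicate read/site entries: keep the most confident call
  calls <- calls[order(-calls$abs_llr), ]
  calls <- calls[!duplicated(calls[c("read", "rel")]), ]
  methyl_matrix_from_calls(calls$read, calls$rel, calls$call, region)
}

methyl_matrix_from_calls <- function(read, rel, call, region = NULL,
                                     region_label = NULL) {
  if (!is.null(region)) {
    keep_reads <- unique(read[rel >= region[1] & rel <= region[2] & !is.na(call)])
    ok <- read %in% keep_reads
    read <- read[ok]; rel <- rel[ok]; call <- call[ok]
  }
  if (!length(read)) stop("no reads with calls overlapping the region")
  sites <- sort(unique(rel))
  reads <- unique(read)
  mat <- matrix(NA_character_, length(reads), length(sites),
                dimnames = list(reads, as.character(sites)))
  mat[cbind(match(read, reads), match(rel, sites))] <- call
  structure(mat, class = c("methyl_matrix", class(mat)),
            region_label = region_label)
}

#' @export
print.methyl_matrix <- function(x, ...) {
  cat(sprintf("<methyl_matrix> %d reads x %d CpG sites (%s..%s rel. TSS); %.1f%% M, %.1f%% U, %.1f%% missing\n",
              nrow(x), ncol(x), colnames(x)[1], colnames(x)[ncol(x)],
              100 * mean(x == "M", na.rm = TRUE) * mean(!is.na(x)),
              100 * mean(x == "U", na.rm = TRUE) * mean(!is.na(x)),
              100 * mean(is.na(x))))
  invisible(x)
}

window_sites <- function(mat, window) {
  pos <- as.integer(colnames(mat))
  which(pos >= window[1] & pos <= window[2])
}

#' Count unmethylated CpGs per read in a promoter window
#'
#' The per-read bimodality readout: the number of U calls over the CpG sites
#' inside the window (default -110..-60 relative to the TSS, both ends
#' inclusive).  Reads covering fewer than \code{min_covered} of the in-window
#' sites are excluded to avoid truncated-read artifacts.
#'
#' @param mat a \code{methyl_matrix}.
#' @param window length-2 TSS-relative inclusive range (default
#'   \code{c(-110, -60)}).
#' @param min_covered minimum fraction of in-window sites with a non-missing
#'   call (default 0.8).
#' @return a named integer vector of U counts; excluded read ids are in
#'   attribute \code{"excluded"}, the number of in-window sites in attribute
#'   \code{"n_sites"}.
#' @export
window_unmeth_counts <- function(mat, window = c(-110, -60),
                                 min_covered = 0.8) {
  ws <- window_sites(mat, window)
  if (!length(ws)) stop("no CpG sites inside the window")
  sub <- mat[, ws, drop = FALSE]
  cover <- rowSums(!is.na(sub)) / length(ws)
  keep <- cover >= min_covered
  counts <- rowSums(sub[keep, , drop = FALSE] == "U", na.rm = TRUE)
  structure(as.integer(counts), names = rownames(sub)[keep],
            excluded = rownames(sub)[!keep], n_sites = length(ws))
}

#' Percent methylated and unmethylated calls in a region
#'
#' @param mat a \code{methyl_matrix}.
#' @param window optional TSS-relative inclusive range; default all sites.
#' @return named numeric vector \code{c(percent_U, percent_M)} over
#'   non-missing calls (sums to 100).
#' @export
methylation_percentages <- function(mat, window = NULL) {
  if (!is.null(window)) mat <- mat[, window_sites(mat, window), drop = FALSE]
  calls <- mat[!is.na(mat)]
  if (!length(calls)) stop("no non-missing calls in the region")
  c(percent_U = 100 * mean(calls == "U"), percent_M = 100 * mean(calls == "M"))
}

#' Classify reads as en bloc methylated or unmethylated
#'
#' A read is \code{unmeth_block} when it carries at most \code{tolerance}
#' M calls inside the window, \code{meth_block} when at most \code{tolerance}
#' U calls, and \code{mixed} otherwise.
#'
#' @inheritParams window_unmeth_counts
#' @param tolerance number of discordant sites tolerated (default 1).
#' @return a named character vector of per-read labels.
#' @export
classify_enbloc <- function(mat, window = c(-110, -60), tolerance = 1,
                            min_covered = 0.8) {
  ws <- window_sites(mat, window)
  if (!length(ws)) stop("no CpG sites inside the window")
  sub <- mat[, ws, drop = FALSE]
  cover <- rowSums(!is.na(sub)) / length(ws)
  sub <- sub[cover >= min_covered, , drop = FALSE]
  nU <- rowSums(sub == "U", na.rm = TRUE)
  nM <- rowSums(sub == "M", na.rm = TRUE)
  lab <- ifelse(nM <= tolerance & nU > tolerance, "unmeth_block",
         ifelse(nU <= tolerance & nM > tolerance, "meth_block",
         ifelse(nM <= tolerance & nU <= tolerance,
                ifelse(nU >= nM, "unmeth_block", "meth_block"), "mixed")))
  stats::setNames(lab, rownames(sub))
}

#' Two-component binomial mixture of per-read unmethylated counts
#'
#' Fits \eqn{w_1 Binom(n, q_1) + w_2 Binom(n, q_2)} to per-read U counts by
#' EM (tolerance 1e-8 on the log-likelihood, up to 500 iterations, 10 seeded
#' restarts; the best solution is kept).  Components are ordered by
#' increasing U probability, so the second component is the unmethylated
#' (epigenetically licensed) one.  The fit is flagged bimodal when both
#' weights are at least 0.05 and the component probabilities differ by at
#' least 0.5.
#'
#' @param counts per-read U counts (>= 10 reads).
#' @param n_sites number of CpG sites per read (the binomial size).
#' @param n_restarts,max_iter,tol EM control parameters.
#' @param seed integer seed for the random restarts.
#' @return an object of class \code{binom_mix}: \code{weights}, \code{prob}
#'   (ordered ascending), \code{weight_unmeth}, \code{logLik},
#'   \code{converged}, \code{bimodal}, \code{boundary}, \code{n_iter}.
#' @export
fit_binomial_mixture <- function(counts, n_sites, n_restarts = 10,
                                 max_iter = 500, tol = 1e-8, seed = NULL) {
  if (length(counts) < 10) stop("need at least 10 reads")
  if (any(counts < 0 | counts > n_sites))
    stop("counts must lie in [0, n_sites]")
  inits <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) {
      if (r == 1) {
        lo <- counts[counts <= stats::median(counts)]
        hi <- counts[counts > stats::median(counts)]
        list(w = max(min(length(hi) / length(counts), 0.9), 0.1),
             q = c(mean(lo) / n_sites,
                   if (length(hi)) mean(hi) / n_sites else 0.9))
      } else {
        list(w = stats::runif(1, 0.1, 0.9),
             q = sort(stats::runif(2)))
      }
    })
  })
  best <- NULL
  for (init in inits) {
    fit <- binom_mix_em(counts, n_sites, init$w, init$q, max_iter, tol)
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }
  ord <- order(best$q)
  q <- best$q[ord]; w <- best$w[ord]
  structure(list(weights = w, prob = q, weight_unmeth = w[2],
                 logLik = best$logLik, converged = best$converged,
                 n_iter = best$n_iter,
                 bimodal = all(w >= 0.05) && diff(q) >= 0.5,
                 boundary = w[2] < 1e-6 || w[2] > 1 - 1e-6,
                 n_reads = length(counts), n_sites = n_sites),
            class = "binom_mix")
}

binom_mix_em <- function(counts, n, w1, q, max_iter, tol) {
  eps <- 1e-10
  w <- c(1 - w1, w1)
  q <- pmin(pmax(q, eps), 1 - eps)
  ll_old <- -Inf; converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dbinom(counts, n, q[1])
    d2 <- w[2] * stats::dbinom(counts, n, q[2])
    tot <- d1 + d2
    ll <- sum(log(pmax(tot, 1e-300)))
    r2 <- d2 / pmax(tot, 1e-300)
    w <- c(1 - mean(r2), mean(r2))
    q <- c(sum((1 - r2) * counts) / pmax(sum(1 - r2) * n, eps),
           sum(r2 * counts) / pmax(sum(r2) * n, eps))
    q <- pmin(pmax(q, eps), 1 - eps)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  d1 <- w[1] * stats::dbinom(counts, n, q[1])
  d2 <- w[2] * stats::dbinom(counts, n, q[2])
  list(w = w, q = q, logLik = sum(log(pmax(d1 + d2, 1e-300))),
       converged = converged, n_iter = it)
}

#' @export
print.binom_mix <- function(x, ...) {
  cat(sprintf("Binomial mixture (EM), %d reads x %d sites\n", x$n_reads, x$n_sites))
  cat(sprintf("  methylated component:   weight %.3f, U-probability %.3f\n",
              x$weights[1], x$prob[1]))
  cat(sprintf("  unmethylated component: weight %.3f, U-probability %.3f\n",
              x$weights[2], x$prob[2]))
  cat(sprintf("  logLik %.3f, converged %s, bimodal %s%s\n", x$logLik,
              x$converged, x$bimodal, if (x$boundary) " [boundary]" else ""))
  invisible(x)
}
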