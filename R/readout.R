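#' Population-average firing rate from spike times
#'
#' Bins spike times of a population into fixed-width bins, converts counts
#' to a population-average rate in Hz (count / (n_neurons * bin width)), and
#' smooths with a Gaussian kernel.  The estimate is linear in the raster:
#' the rate of a merged raster is the weighted sum of the component rates.
#'
#' @param spike_times spike times (ms) of all neurons in the population.
#' @param n_neurons number of neurons in the population (must be > 0).
#' @param trial_length trial length (ms).
#' @param bin bin width (ms).
#' @param smooth_sigma Gaussian smoothing sigma (ms); 0 disables smoothing.
#' @return a \code{rate_trace}: list with \code{time} (bin centres, ms) and
#'   \code{rate} (Hz).
#' @export
#' @examples
#' tr <- population_rate(rep(502, 100), 100, 1000, bin = 5, smooth_sigma = 0)
#' max(tr$rate)  # 100 spikes / (100 neurons * 5 ms) = 200 Hz
population_rate <- function(spike_times, n_neurons, trial_length,
                            bin = 5, smooth_sigma = 20) {
  if (n_neurons <= 0) stop("empty population")
  stopifnot(bin > 0)
  edges <- seq(0, trial_length, by = bin)
  if (edges[length(edges)] < trial_length)
    edges <- c(edges, edges[length(edges)] + bin)
  counts <- if (length(spike_times))
    graphics::hist(spike_times, breaks = edges, plot = FALSE)$counts
  else rep(0, length(edges) - 1)
  rate <- counts / (n_neurons * bin / 1000) # Hz
  if (smooth_sigma > 0) {
    half <- ceiling(3 * smooth_sigma / bin)
    kx <- (-half:half) * bin
    kern <- exp(-kx^2 / (2 * smooth_sigma^2))
    kern <- kern / sum(kern)
    padded <- c(rep(0, half), rate, rep(0, half))
    rate <- as.vector(stats::filter(padded, kern, sides = 2))[
      (half + 1):(half + length(rate))]
    rate[is.na(rate)] <- 0
  }
  structure(list(time = edges[-length(edges)] + bin / 2, rate = rate),
            class = "rate_trace")
}

#' Reported time of a Messenger rate trace
#'
#' The network's temporal report: the time at which the population-average
#' Messenger firing rate peaks, measured relative to stimulus onset.  Ties
#' are broken to the earliest bin.  Also returns the peak rate for
#' peak-magnitude analyses.
#'
#' @param trace a \code{rate_trace} (or list with \code{time} and
#'   \code{rate}).
#' @param onset stimulus onset (ms); only times >= onset are searched and
#'   the report is expressed relative to this onset.
#' @return list with \code{time} (ms) and \code{peak} (Hz).
#' @export
report_time <- function(trace, onset = 0) {
  keep <- trace$time >= onset
  if (!any(keep)) stop("no bins at or after the stimulus onset")
  r <- trace$rate[keep]
  tt <- trace$time[keep]
  i <- which.max(r) # which.max takes the earliest of tied maxima
  list(time = tt[i] - onset, peak = r[i])
}

#' Classify a trial as valid, epileptic, flat, or misordered
#'
#' Applies the validity heuristics, in fixed precedence order, to the
#' per-column Messenger rate traces of a trial: (1) \emph{epileptic} if any
#' column's average M rate exceeds \code{epileptic_hz} (default 180 Hz,
#' runaway recurrent excitation under excess disinhibition); (2) \emph{flat}
#' if any column's M rate range (max - min) is below \code{flat_hz}
#' (default 5 Hz, activity quashed by excess inhibition); (3)
#' \emph{misordered} if the per-column M peak times are not strictly
#' increasing in the trained order (or, when the baseline guard is enabled,
#' a column's peak fails to rise one standard deviation above its trace
#' baseline); otherwise \emph{valid}.
#'
#' @param traces a \code{rate_traces} object (bins x columns) of
#'   Messenger-population rates, e.g. from \code{\link{trial_rates}} or
#'   \code{\link{generate_fixture}}.
#' @param trained_order column order imposed during training (default
#'   1..n).
#' @param onset stimulus onset (ms).
#' @param epileptic_hz,flat_hz classification thresholds (Hz).
#' @param baseline_guard require each column's peak to exceed its trace
#'   mean by one standard deviation.
#' @return list with \code{status} (one of \code{"valid"},
#'   \code{"epileptic"}, \code{"flat"}, \code{"misordered"}) and
#'   diagnostics: \code{max_rate}, \code{rate_range} (per column),
#'   \code{peak_times}.
#' @export
classify_trial <- function(traces, trained_order = NULL, onset = 0,
                           epileptic_hz = 180, flat_hz = 5,
                           baseline_guard = TRUE) {
  rate <- traces$rate
  if (is.null(dim(rate))) rate <- matrix(rate, ncol = 1)
  n_col <- ncol(rate)
  if (is.null(trained_order)) trained_order <- seq_len(n_col)
  max_rate <- apply(rate, 2, max)
  rate_range <- max_rate - apply(rate, 2, min)
  reports <- lapply(seq_len(n_col), function(j)
    report_time(list(time = traces$time, rate = rate[, j]), onset))
  peak_times <- vapply(reports, `[[`, numeric(1), "time")
  peaks <- vapply(reports, `[[`, numeric(1), "peak")

  status <- if (any(max_rate > epileptic_hz)) {
    "epileptic"
  } else if (any(rate_range < flat_hz)) {
    "flat"
  } else {
    ordered <- all(diff(peak_times[trained_order]) > 0)
    guarded <- TRUE
    if (baseline_guard) {
      base <- colMeans(rate) + apply(rate, 2, stats::sd)
      guarded <- all(peaks >= base)
    }
    if (ordered && guarded) "valid" else "misordered"
  }
  list(status = status, max_rate = max_rate, rate_range = rate_range,
       peak_times = peak_times, peaks = peaks)
}

#' Functional range of g_opsin
#'
#' The maximal contiguous set of tested \code{g_opsin} levels, containing
#' the control level 0, over which at least \code{threshold} of independent
#' trials yield interpretable (valid) reports.
#'
#' @param valid_fraction named numeric vector (names = g_opsin levels) or
#'   data frame with columns \code{g_opsin} and \code{fraction}.
#' @param threshold validity threshold (default 0.8).
#' @return numeric vector of the g_opsin levels inside the range.
#' @export
#' @examples
#' functional_range(c("-2" = .1, "-1" = .9, "0" = 1, "1.5" = .85,
#'                    "2.5" = .3))
functional_range <- function(valid_fraction, threshold = 0.8) {
  if (is.data.frame(valid_fraction)) {
    levels <- valid_fraction$g_opsin
    frac <- valid_fraction$fraction
  } else {
    levels <- as.numeric(names(valid_fraction))
    frac <- as.numeric(valid_fraction)
  }
  o <- order(levels)
  levels <- levels[o]; frac <- frac[o]
  if (length(levels) < 3 || !any(levels == 0))
    stop("need at least 3 tested levels including g_opsin = 0")
  i0 <- which(levels == 0)
  if (frac[i0] < threshold)
    stop("control level below the validity threshold: network miscalibrated")
  lo <- i0
  while (lo > 1 && frac[lo - 1] >= threshold) lo <- lo - 1
  hi <- i0
  while (hi < length(levels) && frac[hi + 1] >= threshold) hi <- hi + 1
  levels[lo:hi]
}

#' Distribution summary of a g_opsin sweep
#'
#' Per-level (and per-column) summary of valid report times: median,
#' quartiles (linear interpolation, quantile type 7), SEM and the number of
#' valid trials.  Levels (or level-column cells) without a single valid
#' report are emitted with \code{NA} statistics and flagged missing.
#'
#' @param reports data frame with columns \code{g_opsin}, \code{column},
#'   \code{report_ms}, \code{peak_hz}, \code{status}.
#' @return data frame keyed by \code{g_opsin} and \code{column}.
#' @export
sweep_summary <- function(reports) {
  cells <- unique(reports[, c("g_opsin", "column")])
  cells <- cells[order(cells$g_opsin, cells$column), ]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- reports$g_opsin == cells$g_opsin[i] &
      reports$column == cells$column[i]
    v <- reports[sel & reports$status == "valid", ]
    n_valid <- nrow(v)
    if (n_valid == 0) {
      data.frame(g_opsin = cells$g_opsin[i], column = cells$column[i],
                 n_trials = sum(sel), n_valid = 0, median = NA_real_,
                 q1 = NA_real_, q3 = NA_real_, sem = NA_real_,
                 median_peak = NA_real_, missing = TRUE)
    } else {
      q <- quantile(v$report_ms, c(.25, .5, .75), type = 7, names = FALSE)
      data.frame(g_opsin = cells$g_opsin[i], column = cells$column[i],
                 n_trials = sum(sel), n_valid = n_valid, median = q[2],
                 q1 = q[1], q3 = q[3],
                 sem = if (n_valid > 1) sd(v$report_ms) / sqrt(n_valid) else 0,
                 median_peak = median(v$peak_hz), missing = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Two-way ANOVA of train and test conditions
#'
#' Fixed-effects two-way ANOVA of report times over the optogenetic
#' condition imposed during training and the condition imposed during
#' testing, with type-II sums of squares (identical to the classical
#' decomposition on balanced designs, and well-defined when invalid-trial
#' exclusion unbalances the cells), plus Bonferroni-corrected pairwise
#' post-hoc comparisons of the cell means.
#'
#' @param reports data frame with columns \code{report_ms}, \code{train},
#'   \code{test} (factors or coercible).
#' @return list of class \code{timernet_anova}: \code{effects} (per effect:
#'   \code{F}, \code{df1}, \code{df2}, \code{p}) and \code{posthoc}
#'   (Bonferroni-corrected p-value matrix over train:test cells).
#' @export
two_way_anova <- function(reports) {
  d <- data.frame(y = reports$report_ms,
                  train = factor(reports$train),
                  test = factor(reports$test))
  if (nlevels(d$train) < 2 || nlevels(d$test) < 2)
    stop("need at least 2 levels per factor")
  if (any(table(d$train, d$test) < 2))
    stop("every train x test cell needs at least 2 observations")
  fit <- lm(y ~ train * test, data = d)
  an <- car::Anova(fit, type = 2)
  df2 <- an["Residuals", "Df"]
  eff <- lapply(c(train = "train", test = "test",
                  interaction = "train:test"), function(term) {
    list(F = an[term, "F value"], df1 = an[term, "Df"], df2 = df2,
         p = an[term, "Pr(>F)"])
  })
  ph <- pairwise.t.test(d$y, interaction(d$train, d$test, sep = ":"),
                        p.adjust.method = "bonferroni")
  structure(list(effects = eff, posthoc = ph$p.value),
            class = "timernet_anova")
}

#' @export
print.timernet_anova <- function(x, ...) {
  for (nm in names(x$effects)) {
    e <- x$effects[[nm]]
    cat(sprintf("%-12s F(%d,%d) = %.3f, p = %.3g\n", nm, e$df1, e$df2,
                e$F, e$p))
  }
  invisible(x)
}
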