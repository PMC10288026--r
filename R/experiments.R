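#' Run recall trials and build the report table
#'
#' Challenges a trained network with a brief feed-forward pulse to its first
#' column and tabulates, per trial and column, the reported time (peak of
#' the Messenger population rate), the peak rate, and the validity
#' classification.  Weights are held constant.
#'
#' @param net a trained \code{timer_network}.
#' @param g_opsin optogenetic condition during recall (0 = control); the
#'   laser is active for the whole trial when non-zero.
#' @param n_trials number of independent trials.
#' @param trial_length trial length (ms); default 3000 for a single column,
#'   max trained time + 1000 for sequences.
#' @param seed master seed; trial seeds are derived per (condition, trial).
#' @param stim_columns which columns receive the pulse (default: column 1
#'   only, so sequences must reactivate from their own feed-forward
#'   projections).
#' @return data frame with columns \code{trial}, \code{g_opsin},
#'   \code{column}, \code{report_ms}, \code{peak_hz}, \code{status}.
#'   Reports of invalid trials are \code{NA}.
#' @export
run_recall <- function(net, g_opsin = 0, n_trials = 50,
                       trial_length = NULL, seed = 1L, stim_columns = 1) {
  cfg <- net$config
  if (is.null(trial_length)) {
    trial_length <- if (net$n_columns == 1) 3000
                    else max(net$targets %||% 2000) + 1000
  }
  stim <- pulse_protocol(rep(0, length(stim_columns)), cfg,
                         columns = stim_columns)
  opto <- opto_protocol(g_opsin, config = cfg)
  rd <- cfg$readout
  out <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    res <- run_trial(net, stim, opto = opto, trial_length = trial_length,
                     seed = derive_seed(seed, round(g_opsin * 1000), tr))
    m <- trial_rates(res, net, class = "M")
    cl <- classify_trial(m, epileptic_hz = rd$epileptic_hz,
                         flat_hz = rd$flat_hz,
                         baseline_guard = isTRUE(rd$baseline_guard))
    valid <- cl$status == "valid"
    out[[tr]] <- data.frame(
      trial = tr, g_opsin = g_opsin, column = seq_len(net$n_columns),
      report_ms = if (valid) cl$peak_times else NA_real_,
      peak_hz = if (valid) cl$peaks else NA_real_,
      status = cl$status
    )
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sweep g_opsin over a grid of recall conditions
#'
#' Runs \code{\link{run_recall}} at every level of a g_opsin grid and
#' returns the pooled report table plus the per-level valid fraction (from
#' which \code{\link{functional_range}} is computed).
#'
#' @param net a trained \code{timer_network}.
#' @param grid g_opsin levels (must include 0).
#' @param n_trials trials per level.
#' @param seed master seed.
#' @param ... passed to \code{\link{run_recall}}.
#' @return list with \code{reports} (pooled table), \code{valid}
#'   (data frame \code{g_opsin}, \code{fraction}) and \code{summary}
#'   (from \code{\link{sweep_summary}}).
#' @export
run_sweep <- function(net, grid, n_trials = 50, seed = 1L, ...) {
  stopifnot(0 %in% grid)
  reports <- do.call(rbind, lapply(grid, function(g)
    run_recall(net, g_opsin = g, n_trials = n_trials, seed = seed, ...)))
  per_trial <- unique(reports[, c("g_opsin", "trial", "status")])
  valid <- do.call(rbind, lapply(grid, function(g) {
    st <- per_trial$status[per_trial$g_opsin == g]
    data.frame(g_opsin = g, fraction = mean(st == "valid"))
  }))
  list(reports = reports, valid = valid, summary = sweep_summary(reports))
}

# ---------------------------------------------------------------------------
# declarative experiment protocols

new_experiment_config <- function(id, ...) {
  structure(c(list(id = id), list(...)), class = "experiment_config")
}

#' Experiment protocols
#'
#' Declarative configurations of the study's experiments.
#' \code{protocol_single_interval}: a single column trained to one interval
#' and tested under control, Disinhibition (g_opsin = 1.5) and Excess
#' Inhibition (g_opsin = -1.0).
#' \code{protocol_sequence}: a multi-column network trained to a sequence of
#' cumulative offsets and tested with stimulation of the first column only.
#' \code{protocol_gopsin_sweep}: recall of a trained network across a
#' g_opsin grid bracketing the printed manipulation levels, for
#' functional-range and dose-response analyses.
#' \code{protocol_train_test_crossing}: networks trained under each of
#' three optogenetic conditions and tested under all three, for the
#' compensation analysis (weight distributions and the train-by-test
#' ANOVA).
#'
#' @param target_ms,targets_ms trained time(s) (ms).
#' @param test_conditions named vector of g_opsin levels tested at recall.
#' @param grid g_opsin grid (must include 0).
#' @param train_conditions g_opsin levels imposed during training.
#' @param n_train_trials training trials per network.
#' @param n_test_trials,trials_per_level,trials_per_cell recall trials.
#' @param seed master seed for the whole experiment.
#' @return an \code{experiment_config} list; run it with
#'   \code{\link{run_experiment}} and round-trip it through
#'   \code{\link{write_experiment_config}} /
#'   \code{\link{read_experiment_config}}.
#' @export
protocol_single_interval <- function(target_ms = 750,
                                     test_conditions = c(control = 0,
                                                         disinhibition = 1.5,
                                                         excess_inhibition = -1.0),
                                     n_train_trials = 100,
                                     n_test_trials = 50, seed = 1L) {
  new_experiment_config(
    id = "single_interval", n_columns = 1, targets = target_ms,
    train_conditions = 0, test_conditions = as.list(test_conditions),
    n_train_trials = n_train_trials, n_test_trials = n_test_trials,
    seed = seed
  )
}

#' @rdname protocol_single_interval
#' @export
protocol_sequence <- function(targets_ms = c(500, 1000, 1500, 2000),
                              test_conditions = c(control = 0,
                                                  disinhibition = 1.5,
                                                  excess_inhibition = -1.0),
                              n_train_trials = 100, n_test_trials = 50,
                              seed = 1L) {
  new_experiment_config(
    id = "sequence", n_columns = length(targets_ms), targets = targets_ms,
    train_conditions = 0, test_conditions = as.list(test_conditions),
    n_train_trials = n_train_trials, n_test_trials = n_test_trials,
    seed = seed
  )
}

#' @rdname protocol_single_interval
#' @export
protocol_gopsin_sweep <- function(targets_ms = 600,
                                  grid = round(seq(-1.5, 2, by = 0.35), 2),
                                  trials_per_level = 100,
                                  n_train_trials = 100, seed = 1L) {
  if (!0 %in% grid) grid <- sort(c(0, grid))
  new_experiment_config(
    id = "gopsin_sweep", n_columns = length(targets_ms),
    targets = targets_ms, train_conditions = 0, grid = grid,
    n_train_trials = n_train_trials, n_test_trials = trials_per_level,
    seed = seed
  )
}

#' @rdname protocol_single_interval
#' @export
protocol_train_test_crossing <- function(target_ms = 600,
                                         train_conditions = c(-1.0, 0, 1.5),
                                         test_conditions = c(-1.0, 0, 1.5),
                                         n_train_trials = 100,
                                         trials_per_cell = 100, seed = 1L) {
  new_experiment_config(
    id = "train_test_crossing", n_columns = 1, targets = target_ms,
    train_conditions = train_conditions,
    test_conditions = as.list(test_conditions),
    n_train_trials = n_train_trials, n_test_trials = trials_per_cell,
    seed = seed
  )
}

#' Write / read an experiment configuration
#'
#' Plain-YAML serialization of an \code{experiment_config}; reading back
#' restores an identical configuration.
#'
#' @param config an \code{experiment_config}.
#' @param path file path.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  structure(yaml::read_yaml(path), class = "experiment_config")
}

#' Execute an experiment protocol
#'
#' Runs the full train-freeze-test loop of an \code{experiment_config}:
#' builds the network, trains it under each training condition, runs the
#' recall trials of every test condition (or g_opsin grid), and writes the
#' result bundle to \code{out_dir}: the report table
#' (\code{reports.csv}), per-condition trained-weight summaries
#' (\code{weights.csv}), sweep summaries, the train-by-test ANOVA
#' (\code{anova.json}) when the design crosses conditions, and a manifest
#' (\code{manifest.json}) with parameters and seeds.
#'
#' @param config an \code{experiment_config}.
#' @param out_dir output directory (created if needed); \code{NULL} skips
#'   writing and just returns the results.
#' @param model_config model constants (default \code{default_config()}).
#' @param progress print training progress.
#' @return invisibly, a list with \code{reports}, \code{summary},
#'   \code{weights}, \code{networks}, and \code{anova} (when computed).
#' @export
run_experiment <- function(config, out_dir = NULL,
                           model_config = default_config(),
                           progress = FALSE) {
  seed <- config$seed
  reports <- list(); weights <- list(); nets <- list(); anova <- NULL
  for (ci in seq_along(config$train_conditions)) {
    g_train <- config$train_conditions[[ci]]
    net <- build_network(config$n_columns, model_config,
                         seed = derive_seed(seed, 1, ci))
    opto_tr <- if (g_train != 0) opto_protocol(g_train, config = model_config)
    net <- train_network(net, config$targets, opto = opto_tr,
                         n_trials = config$n_train_trials,
                         seed = derive_seed(seed, 2, ci),
                         progress = progress)
    nets[[as.character(g_train)]] <- net
    weights[[length(weights) + 1]] <- data.frame(
      train = g_train,
      class = c("TT", "TM", if (config$n_columns > 1) "MT"),
      mean_weight = vapply(c("TT", "TM",
                             if (config$n_columns > 1) "MT"),
                           function(cl) weight_class_mean(net, cl),
                           numeric(1))
    )
    levels <- if (!is.null(config$grid)) config$grid
              else unlist(config$test_conditions)
    for (g_test in levels) {
      rep_g <- run_recall(net, g_opsin = g_test,
                          n_trials = config$n_test_trials,
                          seed = derive_seed(seed, 3, ci,
                                             round(g_test * 1000)))
      rep_g$train <- g_train
      reports[[length(reports) + 1]] <- rep_g
    }
  }
  reports <- do.call(rbind, reports)
  weights <- do.call(rbind, weights)
  reports$test <- reports$g_opsin
  summary <- sweep_summary(reports)

  if (length(config$train_conditions) > 1) {
    v <- reports[reports$status == "valid" &
                   reports$column == config$n_columns, ]
    if (nrow(v) > 0 && length(unique(v$train)) > 1 &&
        length(unique(v$test)) > 1)
      anova <- tryCatch(two_way_anova(v), error = function(e) NULL)
  }

  res <- list(reports = reports, summary = summary, weights = weights,
              networks = nets, anova = anova)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(reports, file.path(out_dir, "reports.csv"), row.names = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    write.csv(weights, file.path(out_dir, "weights.csv"), row.names = FALSE)
    if (!is.null(anova))
      jsonlite::write_json(
        list(effects = anova$effects,
             posthoc_bonferroni = as.data.frame(anova$posthoc)),
        file.path(out_dir, "anova.json"), auto_unbox = TRUE, digits = NA,
        na = "null")
    manifest <- list(config = unclass(config), seed = seed,
                     model_config = unclass(model_config),
                     package_version =
                       as.character(utils::packageVersion("timernet")),
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

#' Write a spike raster or rate-trace CSV
#'
#' Standard on-disk forms of a trial: the raster as (trial_id, neuron_id,
#' column_id, cell_class, spike_time_ms) and the rate traces as (trial_id,
#' time_ms, column_id, cell_class, mean_rate_hz).
#'
#' @param trial a \code{trial_result}.
#' @param net the network it was run on.
#' @param path output CSV path.
#' @param trial_id identifier written into the file.
#' @param classes cell classes for the rate export.
#' @export
write_raster_csv <- function(trial, path, trial_id = 1) {
  d <- data.frame(trial_id = trial_id,
                  neuron_id = trial$raster$neuron,
                  column_id = trial$raster$column,
                  cell_class = trial$raster$class,
                  spike_time_ms = trial$raster$time_ms)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
write_rates_csv <- function(trial, net, path, trial_id = 1,
                            classes = c("T", "I", "M")) {
  rows <- list()
  for (cl in classes) {
    tr <- trial_rates(trial, net, class = cl)
    for (col in seq_len(net$n_columns)) {
      rows[[length(rows) + 1]] <- data.frame(
        trial_id = trial_id, time_ms = tr$time, column_id = col,
        cell_class = cl, mean_rate_hz = tr$rate[, col])
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
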