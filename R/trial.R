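#' Simulate one trial
#'
#' Integrates the network for \code{trial_length} ms with Euler steps of
#' \code{dt} ms under a feed-forward stimulus and an optional optogenetic
#' protocol, with the weight matrix held constant.  State (voltages at
#' \code{E_L}, activations at zero) is fresh at trial start, so trials are
#' independent given their seeds, and a trial is bit-reproducible under a
#' fixed seed.
#'
#' @param net a \code{timer_network}.
#' @param stimulus a \code{\link{stimulus_protocol}}.
#' @param opto an \code{\link{opto_protocol}} (default: no opto).
#' @param trial_length trial length (ms).
#' @param seed integer seed for this trial.
#' @param collect_traces internal: snapshot eligibility traces at these
#'   times (ms) and return them (used by the training loop).
#' @param V0 optional initial membrane voltages (mV; default: all at
#'   \code{E_L}).  The final voltages are returned in \code{$V}.
#' @return an object of class \code{trial_result}: \code{raster} (data frame
#'   \code{neuron}, \code{column}, \code{class}, \code{time_ms}),
#'   \code{trial_length}, \code{dt}, the protocols, and (if requested) trace
#'   snapshots.
#' @export
run_trial <- function(net, stimulus, opto = NULL, trial_length = 3000,
                      seed = 1L, collect_traces = NULL, V0 = NULL) {
  cfg <- net$config
  dt <- cfg$dt
  if (is.null(opto)) opto <- opto_protocol(0, config = cfg)
  n_steps <- as.integer(floor(trial_length / dt))

  drive <- generate_poisson_drive(stimulus, net$channel_column,
                                  trial_length, dt,
                                  seed = derive_seed(seed, 1))
  lw <- schedule_steps(opto$schedule, trial_length, dt)
  targets <- opto_target_idx(net, opto)
  if (length(targets) == 0 && opto$g_opsin != 0 && length(lw$start) > 0)
    stop("laser scheduled on but the target population is empty")

  do_traces <- !is.null(collect_traces)
  snap_steps <- if (do_traces)
    as.integer(pmin(round(collect_traces / dt), n_steps) - 1L)
  else integer(0)

  res <- .sim_trial_cpp(
    W = net$W, sclass = net$sclass, V_th_i = net$V_th,
    Wslow = net$W_slow, tau_slow = cfg$synapse$tau_slow,
    rho_slow = cfg$synapse$rho_slow,
    Wgate = net$W_gate, tau_gate = cfg$synapse$tau_gate,
    rho_gate = cfg$synapse$rho, Win = net$Win,
    Yin = net$Yin, Yn = net$Y_launch, Gslow = net$G_slow,
    tau_y = cfg$synapse$tau_envelope,
    in_step = as.integer(drive$step), in_ch = as.integer(drive$channel - 1L),
    neuron = cfg$neuron, synapse = cfg$synapse, dt = dt, n_steps = n_steps,
    laser_start = lw$start, laser_end = lw$end,
    opto_targets = as.integer(targets - 1L),
    g_opsin = opto$g_opsin, N_eff = opto$N_eff, opto_sd = opto$noise_sd,
    do_traces = do_traces,
    plast_pre = as.integer(net$plastic$pre - 1L),
    plast_post = as.integer(net$plastic$post - 1L),
    trace_par = cfg$plasticity,
    snap_steps = snap_steps,
    seed = derive_seed(seed, 2),
    V0 = if (is.null(V0)) numeric(0) else V0
  )

  neuron <- res$spike_neuron + 1L
  raster <- data.frame(
    neuron = neuron,
    column = net$labels$column[neuron],
    class = net$labels$class[neuron],
    time_ms = res$spike_step * dt
  )
  out <- list(raster = raster, trial_length = trial_length, dt = dt,
              n_columns = net$n_columns, seed = seed,
              g_opsin = opto$g_opsin, V = res$V)
  if (do_traces) {
    out$Tp <- res$Tp
    out$Td <- res$Td
    out$trace_times <- collect_traces
  }
  class(out) <- "trial_result"
  out
}

#' @export
print.trial_result <- function(x, ...) {
  cat("<trial_result> ", nrow(x$raster), " spikes over ", x$trial_length,
      " ms (", x$n_columns, " column(s), g_opsin = ", x$g_opsin, ")\n",
      sep = "")
  invisible(x)
}

#' Population-average rate traces of a trial
#'
#' Computes the smoothed population-average firing rate of one cell class in
#' every column of a trial.  The two inhibitory subsets can be pooled with
#' \code{class = "I"}.
#'
#' @param trial a \code{trial_result}.
#' @param net the network the trial was run on.
#' @param class cell class: \code{"T"}, \code{"M"}, \code{"IT"},
#'   \code{"IM"}, or \code{"I"} for both inhibitory subsets.
#' @param bin,smooth_sigma rate bin and Gaussian smoothing width (ms);
#'   default from the network configuration.
#' @return a \code{rate_traces} object: list with \code{time} (bin centres,
#'   ms) and \code{rate} (matrix, bins x columns, Hz).
#' @export
trial_rates <- function(trial, net, class = "M",
                        bin = net$config$readout$bin,
                        smooth_sigma = net$config$readout$smooth_sigma) {
  cls <- if (class == "I") c("IT", "IM") else class
  n_cells <- sum(net$labels$class %in% cls & net$labels$column == 1)
  traces <- lapply(seq_len(net$n_columns), function(col) {
    sel <- trial$raster$class %in% cls & trial$raster$column == col
    population_rate(trial$raster$time_ms[sel], n_cells,
                    trial$trial_length, bin, smooth_sigma)
  })
  structure(list(time = traces[[1]]$time,
                 rate = vapply(traces, `[[`, numeric(length(traces[[1]]$time)),
                               "rate")),
            class = "rate_traces")
}
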