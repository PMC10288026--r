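#' Hebbian coactivity
#'
#' The Hebbian drive of an eligibility trace: the product of the pre- and
#' post-synaptic firing rates.  In the simulator, per-neuron rates are
#' estimated online by exponential filtering of the spike train with time
#' constant \code{tau_rate}; this function is the rule itself and the
#' reference for tests.
#'
#' @param pre_rate,post_rate firing rates (Hz), non-negative.
#' @return the Hebbian product (Hz^2).
#' @export
hebbian_coactivity <- function(pre_rate, post_rate) {
  stopifnot(all(pre_rate >= 0), all(post_rate >= 0))
  pre_rate * post_rate
}

#' Exponentially filtered firing-rate estimate
#'
#' Online rate signal feeding the Hebbian product: each spike adds
#' \code{1000 / tau_rate} Hz and the signal decays with time constant
#' \code{tau_rate}, so a stationary train of rate r Hz averages to r Hz.
#'
#' @param spike_times spike times (ms).
#' @param times evaluation times (ms).
#' @param tau_rate filter time constant (ms).
#' @return rate estimate (Hz) at each evaluation time.
#' @export
filtered_rate <- function(spike_times, times, tau_rate = 25) {
  vapply(times, function(t) {
    d <- t - spike_times[spike_times <= t]
    sum(exp(-d / tau_rate)) * 1000 / tau_rate
  }, numeric(1))
}

#' Euler update of the eligibility traces
#'
#' One Euler step of the competing LTP/LTD trace dynamics
#' \deqn{\tau^x dT^x/dt = -T^x + \eta^x H (T^x_{max} - T^x)/T^x_{max}}
#' for both trace types.  Traces grow with Hebbian activity, saturate at
#' \code{T_max} and decay exponentially.  Reference implementation of the
#' update performed inside the compiled training loop.
#'
#' @param Tp,Td current LTP and LTD trace values (vectors).
#' @param H Hebbian coactivity per synapse (Hz^2).
#' @param dt time step (ms).
#' @param par plasticity constants (a config \code{$plasticity} block).
#' @return list with updated \code{Tp} and \code{Td}.
#' @export
update_traces <- function(Tp, Td, H, dt, par = default_config()$plasticity) {
  stopifnot(dt > 0)
  Tp2 <- Tp + dt / par$tau_p *
    (-Tp + par$eta_p * H * (par$T_p_max - Tp) / par$T_p_max)
  Td2 <- Td + dt / par$tau_d *
    (-Td + par$eta_d * H * (par$T_d_max - Td) / par$T_d_max)
  tol <- 1e-9
  if (any(Tp2 > par$T_p_max + tol) || any(Td2 > par$T_d_max + tol))
    stop("eligibility trace exceeded its saturation value; dt too coarse")
  list(Tp = Tp2, Td = Td2)
}

#' Steady-state trace value under constant Hebbian drive
#'
#' Closed form of the trace fixed point, \eqn{T^* = \eta H T_{max} /
#' (T_{max} + \eta H)}, used to verify the simulated plateau.
#'
#' @param H constant Hebbian drive (Hz^2).
#' @param eta trace activation rate.
#' @param T_max trace saturation.
#' @return steady-state trace value.
#' @export
trace_steady_state <- function(H, eta, T_max) {
  eta * H * T_max / (T_max + eta * H)
}

#' Apply a delta reinforcement to the plastic weights
#'
#' Converts the eligibility-trace difference at the reinforcement instant
#' into a discrete weight update, \eqn{W \leftarrow W + \eta (T^p - T^d)},
#' clipped at a floor of zero and at the per-class ceiling.  When the two
#' traces are equal the update vanishes, which is the learning fixed point.
#'
#' @param W weight vector of the plastic synapses.
#' @param Tp,Td trace values at the reinforcement time.
#' @param eta reward learning rate.
#' @param floor,ceiling weight bounds (floor defaults to 0).
#' @return updated weight vector.
#' @export
apply_reinforcement <- function(W, Tp, Td, eta, floor = 0, ceiling = Inf) {
  pmin(pmax(W + eta * (Tp - Td), floor), ceiling)
}

#' Train a network on an interval or a sequence
#'
#' Runs the episodic training loop: on each trial the eligibility traces are
#' zeroed, the network is simulated under the training stimulus (and the
#' training optogenetic condition, if any) while the traces develop, and a
#' delta reinforcement at each element-transition time converts the traces
#' into weight changes on every plastic class.  The stimulus presents each
#' column's element at its onset; reinforcements occur at each subsequent
#' element onset and at the final element's trained offset.  After the loop
#' the weight matrix is frozen (recall trials never update it).
#'
#' The trial is simulated only up to the last reinforcement (plus a short
#' tail): later activity cannot influence the traces that are read out.
#'
#' @param net a naive (or previously trained) \code{timer_network}.
#' @param targets trained times (ms): a single value for one column, or one
#'   cumulative offset per column for a sequence (e.g. \code{c(500, 1000,
#'   1500, 2000)}).
#' @param opto optional \code{\link{opto_protocol}} active on every
#'   training trial (constant stimulation).
#' @param n_trials number of training trials.
#' @param seed master seed; per-trial seeds are derived from it.
#' @param progress print a line every 10 trials.
#' @return the trained network, with a \code{diagnostics} attribute: data
#'   frame of per-trial mean |T^p - T^d| at the reinforcement times and the
#'   mean weight of each plastic class, plus a \code{converged} flag (TRUE
#'   when the trace gap shrank over training).
#' @export
train_network <- function(net, targets, opto = NULL,
                          n_trials = net$config$plasticity$n_trials,
                          seed = 1L, progress = FALSE) {
  cfg <- net$config
  pl <- cfg$plasticity
  if (length(targets) != net$n_columns)
    stop("need one trained time per column")
  onsets <- c(0, targets[-length(targets)])
  rewards <- sort(unique(targets))
  stim <- pulse_protocol(onsets, cfg)
  trial_length <- max(rewards) + 50

  a <- cfg$architecture
  ceil <- c(TT = a$w_TT_max, TM = a$w_TM_max, MT = a$w_MT_max)
  eta_cls <- unlist(pl$eta_class)[net$plastic$class] * pl$eta
  ceil_cls <- ceil[net$plastic$class]
  widx <- cbind(net$plastic$post, net$plastic$pre)

  diag_rows <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    res <- run_trial(net, stim, opto = opto, trial_length = trial_length,
                     seed = derive_seed(seed, 100, tr),
                     collect_traces = rewards)
    dT <- res$Tp - res$Td
    # annealed reward learning rate: full steps while the representation
    # forms, smaller steps late so the weights settle at the equilibrium
    # instead of orbiting it
    anneal <- if (tr <= 0.5 * n_trials) 1
              else max(0.15, 1 - 2.1 * (tr / n_trials - 0.5))
    dW <- anneal * eta_cls * rowSums(dT)
    w <- pmin(pmax(net$W[widx] + dW, 0), ceil_cls)
    net$W[widx] <- w
    # learned launches ignite the next column's envelope in proportion to
    # their strength (saturating at the class ceiling)
    mt <- net$plastic$class == "MT"
    if (any(mt))
      net$Y_launch[widx[mt, , drop = FALSE]] <- cfg$input$rho_y_launch *
        pmin(w[mt] / cfg$architecture$w_MT_max, 1)
    diag_rows[[tr]] <- data.frame(
      trial = tr,
      trace_gap = mean(abs(dT[, ncol(dT)])),
      w_TT = mean(w[net$plastic$class == "TT"]),
      w_TM = mean(w[net$plastic$class == "TM"]),
      w_MT = if (any(net$plastic$class == "MT"))
        mean(w[net$plastic$class == "MT"]) else NA_real_
    )
    if (progress && tr %% 10 == 0)
      message(sprintf("trial %3d  gap %.4f  w_TT %.3e", tr,
                      diag_rows[[tr]]$trace_gap, diag_rows[[tr]]$w_TT))
  }
  diagnostics <- do.call(rbind, diag_rows)
  early <- mean(diagnostics$trace_gap[seq_len(min(10, n_trials))])
  late <- mean(diagnostics$trace_gap[seq(max(1, n_trials - 9), n_trials)])
  attr(net, "diagnostics") <- diagnostics
  attr(net, "converged") <- late < early
  net$trained <- TRUE
  net$targets <- targets
  net
}
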