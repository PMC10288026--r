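#' Laser schedule
#'
#' Builds the indicator schedule \eqn{L_I(t)} of the simulated laser.  Modes:
#' \code{"off"} (never on), \code{"full_trial"} (on for the whole trial) and
#' \code{"windowed"} (on inside the supplied half-open intervals).
#'
#' @param mode one of \code{"off"}, \code{"full_trial"}, \code{"windowed"}.
#' @param windows for \code{"windowed"}: data frame or 2-column matrix of
#'   \code{on}/\code{off} times (ms), non-overlapping and increasing.
#' @return an object of class \code{laser_schedule}; evaluate it at a time
#'   with \code{laser_on(schedule, t, trial_length)}.
#' @export
#' @examples
#' sch <- laser_schedule("windowed", data.frame(on = 500, off = 700))
#' laser_on(sch, 499, 3000); laser_on(sch, 500, 3000)
laser_schedule <- function(mode = c("off", "full_trial", "windowed"),
                           windows = NULL) {
  mode <- match.arg(mode)
  if (mode == "windowed") {
    windows <- as.data.frame(windows)
    names(windows)[1:2] <- c("on", "off")
    if (any(windows$off <= windows$on)) stop("inverted laser window")
    if (nrow(windows) > 1) {
      o <- order(windows$on)
      windows <- windows[o, ]
      if (any(windows$on[-1] < windows$off[-nrow(windows)]))
        stop("overlapping laser windows")
    }
  } else {
    windows <- NULL
  }
  structure(list(mode = mode, windows = windows), class = "laser_schedule")
}

#' @rdname laser_schedule
#' @param schedule a \code{laser_schedule}.
#' @param t time or vector of times (ms).
#' @param trial_length trial length (ms), needed for \code{"full_trial"}.
#' @export
laser_on <- function(schedule, t, trial_length = Inf) {
  switch(schedule$mode,
    off = rep(FALSE, length(t)),
    full_trial = t >= 0 & t < trial_length,
    windowed = {
      on <- rep(FALSE, length(t))
      for (w in seq_len(nrow(schedule$windows)))
        on <- on | (t >= schedule$windows$on[w] &
                      t < schedule$windows$off[w])
      on
    })
}

# schedule -> 0-based step windows for the compiled core
schedule_steps <- function(schedule, trial_length, dt) {
  n_steps <- floor(trial_length / dt)
  if (schedule$mode == "off")
    return(list(start = integer(0), end = integer(0)))
  if (schedule$mode == "full_trial")
    return(list(start = 0L, end = as.integer(n_steps)))
  list(start = as.integer(floor(schedule$windows$on / dt)),
       end = as.integer(pmin(floor(schedule$windows$off / dt), n_steps)))
}

#' Optogenetic stimulation protocol
#'
#' Defines the simulated optogenetic current
#' \eqn{I_{opto} = L_I(t)\, g_{opsin}\, N_{eff}\, \sigma_r(t)} injected into
#' the inhibitory population.  Following the figure-label convention,
#' positive \code{g_opsin} hyperpolarizes the targets (an inhibitory opsin:
#' network Disinhibition) and negative \code{g_opsin} depolarizes them (an
#' excitatory opsin: Excess Inhibition).  \eqn{\sigma_r(t)} is a per-neuron
#' per-step noise factor drawn from a normal distribution with mean 1 and
#' configurable standard deviation, so the expected current magnitude while
#' the laser is on is \eqn{|g_{opsin}| N_{eff}}.
#'
#' @param g_opsin signed conductance scale of the opsin (0 = no opto).
#' @param schedule a \code{\link{laser_schedule}}; default full trial when
#'   \code{g_opsin != 0}, off otherwise.
#' @param config model configuration (supplies \code{N_eff} and the noise
#'   std, both fixed across experiments).
#' @param targets which cells receive the current: \code{"I"} (all
#'   inhibitory cells, the default), or a character subset of
#'   \code{c("IT", "IM")}.
#' @return an object of class \code{opto_protocol}.
#' @export
opto_protocol <- function(g_opsin = 0, schedule = NULL,
                          config = default_config(), targets = "I") {
  if (is.null(schedule))
    schedule <- laser_schedule(if (g_opsin != 0) "full_trial" else "off")
  structure(list(g_opsin = g_opsin, schedule = schedule,
                 N_eff = config$opto$N_eff, noise_sd = config$opto$noise_sd,
                 targets = targets),
            class = "opto_protocol")
}

opto_target_idx <- function(net, protocol) {
  cls <- if (identical(protocol$targets, "I")) c("IT", "IM")
         else protocol$targets
  which(net$labels$class %in% cls)
}

#' Evaluate the optogenetic current at a time point
#'
#' Returns one draw of the per-target current at time \code{t}.  Zero
#' whenever the laser is off or \code{g_opsin = 0}; otherwise
#' \eqn{-g_{opsin} N_{eff} \sigma_r} per target (negative sign: positive
#' \code{g_opsin} is hyperpolarizing).  This is the reference implementation
#' of the current used inside the compiled integrator.
#'
#' @param protocol an \code{\link{opto_protocol}}.
#' @param t time (ms).
#' @param n_targets number of targeted neurons.
#' @param trial_length trial length (ms).
#' @param seed optional seed for the noise draw.
#' @return numeric vector of currents, one per target.
#' @export
opto_current <- function(protocol, t, n_targets, trial_length = Inf,
                         seed = NULL) {
  if (n_targets == 0 && protocol$g_opsin != 0 &&
      any(laser_on(protocol$schedule, t, trial_length)))
    stop("laser scheduled on but the target population is empty")
  if (protocol$g_opsin == 0 ||
      !laser_on(protocol$schedule, t, trial_length))
    return(rep(0, n_targets))
  draw <- function() 1 + protocol$noise_sd * rnorm(n_targets)
  sr <- if (is.null(seed)) draw() else with_seed(seed, draw())
  -protocol$g_opsin * protocol$N_eff * sr
}
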