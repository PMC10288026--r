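#' Feed-forward stimulus protocol
#'
#' Describes the Poisson feed-forward drive of a trial: one or more
#' per-column stimulation windows and the channel firing rate inside them.
#' Times are in ms relative to trial start; windows are half-open
#' \code{[onset, offset)}.
#'
#' @param windows data frame with columns \code{column}, \code{onset},
#'   \code{offset} (ms).  Each row opens every input channel of that column.
#' @param rate Poisson rate of each channel inside its window (Hz).
#' @return an object of class \code{stimulus_protocol}.
#' @export
#' @examples
#' stimulus_protocol(data.frame(column = 1, onset = 0, offset = 100))
stimulus_protocol <- function(windows, rate = NULL) {
  stopifnot(all(c("column", "onset", "offset") %in% names(windows)))
  if (any(windows$onset < 0)) stop("stimulus onsets must be non-negative")
  if (any(windows$offset <= windows$onset))
    stop("stimulus offsets must exceed onsets")
  if (!is.null(rate) && rate < 0) stop("rate must be non-negative")
  structure(list(windows = windows, rate = rate),
            class = "stimulus_protocol")
}

# the standard brief pulse: every column stimulated at its element onset
pulse_protocol <- function(onsets, config, columns = seq_along(onsets)) {
  stimulus_protocol(
    data.frame(column = columns, onset = onsets,
               offset = onsets + config$input$duration),
    rate = config$input$rate
  )
}

#' Generate Poisson feed-forward spike trains
#'
#' Draws, for every input channel of the network, a Bernoulli spike
#' indicator per Euler step with probability \code{rate * dt} inside the
#' channel's stimulation window(s) and zero outside.  Errors if
#' \code{rate * dt > 1}, which signals that the step is too coarse for the
#' requested rate.
#'
#' @param protocol a \code{\link{stimulus_protocol}}.
#' @param channel_column integer vector mapping each channel to its column
#'   (as stored in a \code{timer_network}).
#' @param trial_length trial length (ms).
#' @param dt Euler step (ms).
#' @param seed integer seed; the same seed reproduces the same trains.
#' @param rate optional override of the protocol rate (Hz).
#' @return data frame with columns \code{step} (0-based) and \code{channel}
#'   (1-based), sorted by step.
#' @export
generate_poisson_drive <- function(protocol, channel_column, trial_length,
                                   dt, seed, rate = NULL) {
  stopifnot(trial_length > 0)
  r <- if (!is.null(rate)) rate else protocol$rate
  if (is.null(r)) stop("no Poisson rate given")
  p <- r * dt / 1000 # rate in Hz, dt in ms
  if (p > 1) stop("rate * dt exceeds 1; dt too coarse for this rate")
  n_steps <- floor(trial_length / dt)
  out_step <- integer(0); out_ch <- integer(0)
  if (p > 0) {
    with_seed(seed, {
      for (w in seq_len(nrow(protocol$windows))) {
        col <- protocol$windows$column[w]
        ch <- which(channel_column == col)
        s0 <- floor(protocol$windows$onset[w] / dt)
        s1 <- min(floor(protocol$windows$offset[w] / dt), n_steps) - 1
        if (s1 < s0 || length(ch) == 0) next
        steps <- s0:s1
        m <- matrix(runif(length(ch) * length(steps)) < p,
                    nrow = length(ch))
        hit <- which(m, arr.ind = TRUE)
        out_step <- c(out_step, steps[hit[, 2]])
        out_ch <- c(out_ch, ch[hit[, 1]])
      }
    })
  }
  o <- order(out_step, out_ch)
  data.frame(step = out_step[o], channel = out_ch[o])
}
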