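#' Synthetic rate-trace fixtures
#'
#' Emulates per-column Messenger population rate traces with a controllable
#' peak time, peak height, noise level and pathology mode, so the readout
#' stage (report quantification and validity classification) can be tested
#' without running the simulator.  Each pathology satisfies its
#' classification criterion by construction: \code{"epileptic"} exceeds the
#' 180 Hz ceiling, \code{"flat"} keeps the rate range under 5 Hz, and
#' \code{"misordered"} permutes the column peak order.
#'
#' @param mode one of \code{"normal"}, \code{"epileptic"}, \code{"flat"},
#'   \code{"misordered"}.
#' @param peak_ms per-column peak times (ms); their length sets the number
#'   of columns.
#' @param peak_hz peak heights (Hz, recycled over columns).
#' @param width_ms Gaussian bump width (ms).
#' @param noise_hz std of additive rate noise (Hz; clipped at 0).
#' @param trial_length,bin time grid (ms).
#' @param seed seed for the noise.
#' @return a \code{rate_traces} object (list with \code{time} and matrix
#'   \code{rate}), as produced by \code{\link{trial_rates}}.
#' @export
#' @examples
#' fx <- generate_fixture("normal", peak_ms = 600)
#' report_time(list(time = fx$time, rate = fx$rate[, 1]))$time
generate_fixture <- function(mode = c("normal", "epileptic", "flat",
                                      "misordered"),
                             peak_ms = 600, peak_hz = 80, width_ms = 60,
                             noise_hz = 0.5, trial_length = NULL, bin = 5,
                             seed = 1L) {
  mode <- match.arg(mode)
  n_col <- length(peak_ms)
  peak_hz <- rep_len(peak_hz, n_col)
  if (is.null(trial_length)) trial_length <- max(peak_ms) + 500
  time <- seq(bin / 2, trial_length, by = bin)

  if (mode == "misordered") {
    if (n_col < 2) stop("misordered fixtures need at least 2 columns")
    # swap the last two peaks so the trained order is violated
    peak_ms[c(n_col - 1, n_col)] <- peak_ms[c(n_col, n_col - 1)]
  }
  if (mode == "epileptic") peak_hz[1] <- max(peak_hz[1], 200)

  rate <- with_seed(seed, {
    vapply(seq_len(n_col), function(j) {
      r <- if (mode == "flat") {
        rep(1, length(time)) + rnorm(length(time), sd = min(noise_hz, 0.3))
      } else {
        peak_hz[j] * exp(-(time - peak_ms[j])^2 / (2 * width_ms^2)) +
          rnorm(length(time), sd = noise_hz)
      }
      pmax(r, 0)
    }, numeric(length(time)))
  })
  structure(list(time = time, rate = rate), class = "rate_traces")
}
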