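#' Default model configuration
#'
#' Reads the packaged YAML configuration holding every numeric constant of
#' the model: neuron and synapse parameters, the columnar architecture and
#' its connection weights, the feed-forward input specification, the
#' optogenetic efficiency and noise constants, the eligibility-trace rule
#' constants, and the readout thresholds.  Pass \code{overrides} to change
#' individual entries without editing the file.
#'
#' @param file path to a YAML configuration; defaults to the packaged file.
#' @param overrides named list merged (recursively) over the file contents,
#'   e.g. \code{list(plasticity = list(eta = 1e-5))}.
#' @return a validated nested list of class \code{timernet_config}.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$neuron$V_hold
default_config <- function(file = system.file("extdata", "default_config.yaml",
                                              package = "timernet"),
                           overrides = NULL) {
  cfg <- yaml::read_yaml(file)
  if (!is.null(overrides)) cfg <- modify_list_deep(cfg, overrides)
  validate_config(cfg)
  class(cfg) <- c("timernet_config", "list")
  cfg
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  n <- cfg$neuron
  stopifnot(
    "reversal/threshold ordering violated (need E_I < V_hold < V_th < E_E)" =
      n$E_I < n$V_hold && n$V_hold < n$V_th && n$V_th < n$E_E,
    "refractory duration must be positive" = n$t_ref > 0,
    "leak-noise scale must be non-negative" = n$sigma_L >= 0,
    "capacitance and leak conductance must be positive" = n$C > 0 && n$g_L > 0
  )
  s <- cfg$synapse
  stopifnot(
    "activation increment rho must be in (0, 1]" = s$rho > 0 && s$rho <= 1,
    "synaptic time constants must be positive" =
      all(c(s$tau_T, s$tau_I, s$tau_M, s$tau_input) > 0)
  )
  a <- cfg$architecture
  if (a$n_T + a$n_IT + a$n_M + a$n_IM != a$neurons_per_column)
    stop("population sizes must sum to neurons_per_column (",
         a$neurons_per_column, "), got ",
         a$n_T + a$n_IT + a$n_M + a$n_IM)
  p <- cfg$plasticity
  stopifnot(
    "trace constants must be positive" =
      all(c(p$tau_p, p$tau_d, p$eta_p, p$eta_d, p$T_p_max, p$T_d_max,
            p$tau_rate, p$eta) > 0),
    "number of training trials must be >= 1" = p$n_trials >= 1
  )
  stopifnot(
    "opto efficiency N_eff must be positive" = cfg$opto$N_eff > 0,
    "opto noise must be non-negative" = cfg$opto$noise_sd >= 0,
    "Euler step must be positive" = cfg$dt > 0
  )
  invisible(cfg)
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer hash used everywhere a protocol needs independent
#' random streams (one per trial, per condition, ...).  Folding the stream
#' indices keeps every derived seed inside the 32-bit signed range while
#' making streams for different (condition, trial) pairs distinct, so any
#' single condition of an experiment can be reproduced in isolation.
#'
#' @param master integer master seed.
#' @param ... one or more integer stream indices.
#' @return a single integer in \code{[1, 2^31 - 2]}.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (i in idx) h <- (h * 69069 + as.double(i) + 1) %% 2147483647
  as.integer(h + 1)
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
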