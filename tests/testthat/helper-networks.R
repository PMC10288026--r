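# small shared objects for the unit tests; heavier trained networks are
# built (and cached) only by the acceptance suite
tiny_config <- function(overrides = NULL) {
  default_config(overrides = overrides)
}

# a quiet network: all chemical coupling removed, no noise
silent_network <- function(sigma_L = 0) {
  cfg <- default_config(overrides = list(neuron = list(sigma_L = sigma_L)))
  net <- build_network(1, cfg, seed = 1)
  net$W[] <- 0
  net$W_slow[] <- 0
  net$W_gate[] <- 0
  net$Win[] <- 0
  net$Yin[] <- 0
  net$Y_launch[] <- 0
  net$G_slow[] <- 0
  net
}

no_stim <- function() {
  stimulus_protocol(data.frame(column = 1, onset = 0, offset = 1), rate = 0)
}

pulse_stim <- function(cfg, columns = 1, onset = 0,
                       duration = cfg$input$duration) {
  stimulus_protocol(data.frame(column = columns, onset = onset,
                               offset = onset + duration),
                    rate = cfg$input$rate)
}

# independent oracle: classical sums-of-squares decomposition on a balanced
# two-way layout, computed from scratch
anova_bruteforce <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- length(y)
  gm <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, interaction(a, b), mean)
  nc <- table(interaction(a, b))[1]  # balanced: equal cell counts
  ssa <- nlevels(b) * nc * sum((ma - gm)^2)
  ssb <- nlevels(a) * nc * sum((mb - gm)^2)
  sscells <- nc * sum((mab - gm)^2)
  ssab <- sscells - ssa - ssb
  sse <- sum((y - mab[interaction(a, b)])^2)
  dfa <- nlevels(a) - 1; dfb <- nlevels(b) - 1; dfab <- dfa * dfb
  dfe <- n - nlevels(a) * nlevels(b)
  list(Fa = (ssa / dfa) / (sse / dfe), Fb = (ssb / dfb) / (sse / dfe),
       Fab = (ssab / dfab) / (sse / dfe), dfe = dfe)
}

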