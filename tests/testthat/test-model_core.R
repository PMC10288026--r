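# network construction and membrane/synapse integration

test_that("a column holds 400 neurons and the network scales linearly", {
  cfg <- default_config()
  net1 <- build_network(1, cfg, seed = 1)
  net4 <- build_network(4, cfg, seed = 1)
  expect_equal(nrow(net1$labels), 400)
  expect_equal(nrow(net4$labels), 1600)
  expect_equal(as.vector(table(net1$labels$class)[c("T", "IT", "M", "IM")]),
               c(160, 80, 80, 80))

  # intra-column synapse counts scale linearly with the number of columns
  intra1 <- sum(net1$W != 0)
  blocks4 <- vapply(1:4, function(col) {
    i <- net4$labels$column == col
    sum(net4$W[i, i] != 0)
  }, numeric(1))
  expect_equal(blocks4, rep(intra1, 4))

  # single column has no cross-column synapses at all
  expect_false(any(net1$plastic$class == "MT"))
  c1 <- net4$labels$column == 1
  expect_gt(sum(net4$W[!c1, c1] != 0), 0)  # M -> next column exists with 4

  expect_error(build_network(0, cfg), "n_columns")
  bad <- cfg
  bad$architecture$n_T <- 100
  expect_error(build_network(1, bad), "sum")
})

test_that("two seeds give identical topology but different initial weights", {
  cfg <- default_config()
  a <- build_network(2, cfg, seed = 1)
  b <- build_network(2, cfg, seed = 2)
  expect_equal(synapse_counts(a), synapse_counts(b))
  expect_equal(a$plastic, b$plastic)
  expect_false(any(class_weights(a, "TT") == class_weights(b, "TT")))
  # identical seeds reproduce the build exactly
  expect_identical(a$W, build_network(2, cfg, seed = 1)$W)
})

test_that("aggregate conductances match a dense brute-force loop", {
  net <- build_network(1, default_config(), seed = 3)
  set.seed(1)
  s <- runif(nrow(net$labels))
  got <- aggregate_conductances(net, s)
  # loop oracle over every synapse
  n <- nrow(net$labels)
  gE <- numeric(n); gI <- numeric(n)
  inh <- net$sclass == 1L
  for (i in seq_len(n)) {
    for (j in which(net$W[i, ] != 0)) {
      if (inh[j]) gI[i] <- gI[i] + net$W[i, j] * s[j]
      else gE[i] <- gE[i] + net$W[i, j] * s[j]
    }
  }
  expect_equal(got$g_E, gE, tolerance = 1e-12)
  expect_equal(got$g_I, gI, tolerance = 1e-12)
  expect_true(all(got$g_E >= 0) && all(got$g_I >= 0))

  # trivial cases: s = 0 and a single synapse product
  z <- aggregate_conductances(net, rep(0, n))
  expect_true(all(z$g_E == 0) && all(z$g_I == 0))
  net0 <- silent_network()
  net0$W[1, 2] <- 2
  s1 <- rep(0, n); s1[2] <- 0.5
  expect_equal(aggregate_conductances(net0, s1)$g_E[1], 1.0)
})

test_that("leak-only Euler integration matches the analytic exponential", {
  net <- silent_network(sigma_L = 0)
  cfg <- net$config
  V0 <- rep(cfg$neuron$E_L + 10, 400)
  res <- run_trial(net, no_stim(), trial_length = 1000, seed = 1, V0 = V0)
  expect_equal(nrow(res$raster), 0)  # -60 mV start stays subthreshold
  tau_m <- cfg$neuron$C / cfg$neuron$g_L
  analytic <- cfg$neuron$E_L + 10 * exp(-1000 / tau_m)
  expect_lt(max(abs(res$V - analytic)) / 10, 0.01)

  # V = E_L is a fixed point of the leak
  res0 <- run_trial(net, no_stim(), trial_length = 100, seed = 1)
  expect_equal(res0$V, rep(cfg$neuron$E_L, 400), tolerance = 1e-12)
})

test_that("suprathreshold start spikes once and holds at -61 mV for 2 ms", {
  net <- silent_network(sigma_L = 0)
  V0 <- rep(net$config$neuron$E_L, 400)
  V0[1] <- -50  # above every threshold in the spread
  res <- run_trial(net, no_stim(), trial_length = 1.5, seed = 1, V0 = V0)
  expect_equal(res$raster$neuron, 1)
  expect_equal(res$raster$time_ms, 0)
  # still inside the 2 ms refractory hold at trial end (1.5 ms)
  expect_equal(res$V[1], net$config$neuron$V_hold)
})

test_that("with zero weights and no opto the network is silent", {
  net <- silent_network(sigma_L = default_config()$neuron$sigma_L)
  res <- run_trial(net, no_stim(), trial_length = 500, seed = 7)
  expect_equal(nrow(res$raster), 0)
})

test_that("Poisson drive has binomial statistics and respects windows", {
  cfg <- default_config()
  proto <- stimulus_protocol(data.frame(column = 1, onset = 0, offset = 100),
                             rate = 500)
  ch_col <- rep(1, 200)
  d <- generate_poisson_drive(proto, ch_col, 1000, 0.1, seed = 11)
  # expected count: 200 channels * 500 Hz * 0.1 s = 10,000
  p <- 500 * 0.1 / 1000
  nsteps <- 1000
  expected <- 200 * nsteps * p
  se <- sqrt(200 * nsteps * p * (1 - p))
  expect_lt(abs(nrow(d) - expected), 3 * se)
  expect_true(all(d$step < 1000))  # no spikes after the 100 ms window

  expect_equal(nrow(generate_poisson_drive(proto, ch_col, 1000, 0.1,
                                           seed = 1, rate = 0)), 0)
  expect_error(generate_poisson_drive(proto, ch_col, 1000, dt = 3, seed = 1),
               "too coarse")
  # reproducible under a fixed seed
  expect_identical(d, generate_poisson_drive(proto, ch_col, 1000, 0.1,
                                             seed = 11))
})

test_that("a naive column bursts in T and I during the stimulus, not in M", {
  cfg <- default_config()
  net <- build_network(1, cfg, seed = 1)
  res <- run_trial(net, pulse_stim(cfg), trial_length = 800, seed = 21)
  rT <- trial_rates(res, net, "T"); rI <- trial_rates(res, net, "I")
  rM <- trial_rates(res, net, "M")
  expect_gt(max(rT$rate), 50)
  expect_gt(max(rI$rate), 20)
  expect_lt(max(rM$rate), 0.25 * max(rT$rate))
  # burst is stimulus-locked: T activity gone well after the pulse
  late <- rT$time > 500
  expect_lt(max(rT$rate[late]), 25)
})

test_that("trials are deterministic given the seed", {
  cfg <- default_config()
  net <- build_network(1, cfg, seed = 1)
  r1 <- run_trial(net, pulse_stim(cfg), trial_length = 400, seed = 33)
  r2 <- run_trial(net, pulse_stim(cfg), trial_length = 400, seed = 33)
  expect_identical(r1$raster, r2$raster)
  r3 <- run_trial(net, pulse_stim(cfg), trial_length = 400, seed = 34)
  expect_false(identical(r1$raster, r3$raster))
})

test_that("network snapshots round-trip through the text container", {
  cfg <- default_config()
  net <- build_network(1, cfg, seed = 4)
  dir <- file.path(tempdir(), "net-snap")
  save_network(net, dir)
  back <- load_network(dir)
  expect_equal(back$W, net$W, tolerance = 1e-12)
  expect_equal(back$n_columns, net$n_columns)
  unlink(dir, recursive = TRUE)
})
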