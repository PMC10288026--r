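# protocols, fixtures, seed derivation, output plumbing

test_that("experiment configs encode the study protocols and round-trip", {
  p2 <- protocol_single_interval(750)
  expect_equal(p2$n_columns, 1)
  expect_equal(p2$targets, 750)
  expect_equal(length(p2$test_conditions), 3)
  expect_equal(p2$test_conditions$disinhibition, 1.5)
  expect_equal(p2$test_conditions$excess_inhibition, -1.0)
  expect_equal(p2$n_train_trials, 100)

  seq4 <- protocol_sequence()
  expect_equal(seq4$n_columns, 4)
  expect_equal(seq4$targets, c(500, 1000, 1500, 2000))

  sw <- protocol_gopsin_sweep(600)
  expect_true(0 %in% sw$grid)
  expect_true(min(sw$grid) <= -1 && max(sw$grid) >= 1.5)

  cr <- protocol_train_test_crossing()
  expect_equal(cr$train_conditions, c(-1, 0, 1.5))

  # YAML round-trip identity
  f <- tempfile(fileext = ".yaml")
  write_experiment_config(seq4, f)
  back <- read_experiment_config(f)
  expect_equal(unclass(back), unclass(seq4))
  unlink(f)
})

test_that("seed derivation is deterministic, distinct and in 32-bit range", {
  s1 <- derive_seed(42, 1, 7)
  expect_identical(s1, derive_seed(42, 1, 7))
  expect_false(derive_seed(42, 1, 7) == derive_seed(42, 1, 8))
  expect_false(derive_seed(42, 1, 7) == derive_seed(43, 1, 7))
  seeds <- vapply(1:500, function(i) derive_seed(1, 3, i), integer(1))
  expect_equal(length(unique(seeds)), 500)
  expect_true(all(seeds > 0 & seeds < 2^31))
})

test_that("fixture generators satisfy their pathology by construction", {
  ep <- generate_fixture("epileptic", peak_ms = 600)
  expect_gt(max(ep$rate), 180)
  fl <- generate_fixture("flat", peak_ms = 600)
  expect_lt(max(fl$rate) - min(fl$rate), 5)
  mis <- generate_fixture("misordered", peak_ms = c(400, 800, 1200, 1600))
  peaks <- apply(mis$rate, 2, function(r) mis$time[which.max(r)])
  expect_false(all(diff(peaks) > 0))
  # normal fixture closes the loop on the readout
  nm <- generate_fixture("normal", peak_ms = 600, noise_hz = 0)
  expect_equal(report_time(list(time = nm$time, rate = nm$rate[, 1]))$time,
               597.5)  # 600 ms peak falls between bins; earlier bin wins
  expect_error(generate_fixture("misordered", peak_ms = 500), "2 columns")
})

test_that("raster and rate CSV exports have the documented columns", {
  cfg <- default_config()
  net <- build_network(1, cfg, seed = 1)
  res <- run_trial(net, pulse_stim(cfg), trial_length = 300, seed = 2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_raster_csv(res, f1, trial_id = 7)
  write_rates_csv(res, net, f2, trial_id = 7)
  r <- read.csv(f1)
  expect_equal(names(r), c("trial_id", "neuron_id", "column_id",
                           "cell_class", "spike_time_ms"))
  expect_true(all(r$trial_id == 7))
  expect_equal(nrow(r), nrow(res$raster))
  rt <- read.csv(f2)
  expect_equal(names(rt), c("trial_id", "time_ms", "column_id",
                            "cell_class", "mean_rate_hz"))
  expect_setequal(unique(rt$cell_class), c("T", "I", "M"))
  unlink(c(f1, f2))
})

test_that("run_experiment writes the documented result bundle", {
  # miniature protocol: enough trials to exercise the plumbing only
  proto <- protocol_single_interval(600, n_train_trials = 3,
                                    n_test_trials = 2, seed = 77)
  proto$test_conditions <- list(control = 0, disinhibition = 1.5)
  out <- file.path(tempdir(), "mini-exp")
  res <- run_experiment(proto, out_dir = out)
  expect_true(all(file.exists(file.path(out,
    c("reports.csv", "summary.csv", "weights.csv", "manifest.json")))))
  rep <- read.csv(file.path(out, "reports.csv"))
  expect_setequal(unique(rep$g_opsin), c(0, 1.5))
  expect_equal(nrow(rep), 4)  # 2 conditions x 2 trials x 1 column
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$config$id, "single_interval")
  expect_equal(man$seed, 77)
  unlink(out, recursive = TRUE)
})
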