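# readout stage: rates, report times, trial classification, sweeps, ANOVA

test_that("population rate is count/(N*bin) in Hz and linear in the raster", {
  # 100 neurons spiking once in one 5 ms bin -> 100/(100*0.005s) = 200 Hz
  tr <- population_rate(rep(502, 100), n_neurons = 100, trial_length = 1000,
                        bin = 5, smooth_sigma = 0)
  expect_equal(max(tr$rate), 200)
  expect_equal(tr$time[which.max(tr$rate)], 502.5)
  expect_equal(sum(tr$rate > 0), 1)

  # linearity: merged raster = sum of rates (same population size)
  a <- c(100, 250, 250, 700)
  b <- c(130, 250, 900)
  ra <- population_rate(a, 10, 1000, 5, 0)
  rb <- population_rate(b, 10, 1000, 5, 0)
  rab <- population_rate(c(a, b), 10, 1000, 5, 0)
  expect_equal(rab$rate, ra$rate + rb$rate)

  # empty raster -> all-zero trace; empty population errors
  expect_true(all(population_rate(numeric(0), 10, 500)$rate == 0))
  expect_error(population_rate(1, 0, 500), "empty")
})

test_that("Gaussian smoothing preserves the trace mass away from edges", {
  spikes <- rep(500, 50)
  raw <- population_rate(spikes, 50, 1000, 5, smooth_sigma = 0)
  sm <- population_rate(spikes, 50, 1000, 5, smooth_sigma = 20)
  expect_lt(abs(sum(sm$rate) - sum(raw$rate)) / sum(raw$rate), 0.01)
  expect_lt(max(sm$rate), max(raw$rate))
})

test_that("report time is the earliest argmax after onset", {
  time <- seq(2.5, 1500, by = 5)
  rate <- exp(-(time - 750)^2 / (2 * 40^2))
  rep <- report_time(list(time = time, rate = rate))
  expect_equal(rep$time, 747.5)  # symmetric peak: tie broken to earlier bin

  # tie broken to the earliest bin
  rate2 <- numeric(length(time))
  rate2[time %in% c(602.5, 902.5)] <- 7
  expect_equal(report_time(list(time = time, rate = rate2))$time, 602.5)

  # invariant to uniform rescaling, report relative to onset
  r1 <- report_time(list(time = time, rate = rate), onset = 100)
  r2 <- report_time(list(time = time, rate = 3.7 * rate), onset = 100)
  expect_equal(r1$time, r2$time)
  expect_equal(r1$time, 647.5)
})

test_that("classification applies the thresholds with fixed precedence", {
  fx <- function(mode, ...) generate_fixture(mode, ...)

  expect_equal(classify_trial(fx("normal", peak_ms = 600))$status, "valid")
  expect_equal(classify_trial(fx("epileptic", peak_ms = 600))$status,
               "epileptic")
  expect_equal(classify_trial(fx("flat", peak_ms = 600))$status, "flat")
  expect_equal(
    classify_trial(fx("misordered", peak_ms = c(400, 800, 1200, 1600)))$status,
    "misordered")
  expect_equal(
    classify_trial(fx("normal", peak_ms = c(400, 800, 1200, 1600)))$status,
    "valid")

  # 200 Hz peak is epileptic even when also misordered (precedence)
  bad <- fx("misordered", peak_ms = c(400, 800, 1200, 1600),
            peak_hz = c(200, 80, 80, 80))
  expect_equal(classify_trial(bad)$status, "epileptic")

  # thresholds sit exactly at the printed values
  at180 <- fx("normal", peak_ms = 600, peak_hz = 179.9, noise_hz = 0)
  expect_equal(classify_trial(at180)$status, "valid")
  over180 <- fx("normal", peak_ms = 600, peak_hz = 181, noise_hz = 0)
  expect_equal(classify_trial(over180)$status, "epileptic")
  under5 <- list(time = seq(2.5, 1000, 5),
                 rate = matrix(2 + 2.5 * sin(seq(2.5, 1000, 5) / 50), ncol = 1))
  expect_equal(classify_trial(under5, baseline_guard = FALSE)$status, "flat")
})

test_that("classification counts match a brute-force scan over fixtures", {
  modes <- c("normal", "epileptic", "flat", "misordered")
  set.seed(42)
  draws <- sample(modes, 60, replace = TRUE)
  got <- vapply(seq_along(draws), function(i) {
    fx <- generate_fixture(draws[i], peak_ms = c(500, 1000, 1500),
                           peak_hz = 90, seed = i)
    classify_trial(fx)$status
  }, character(1))
  # brute-force expectation: construction guarantees the label
  want <- ifelse(draws == "normal", "valid", draws)
  expect_equal(as.vector(table(factor(got, levels = unique(want)))),
               as.vector(table(factor(want, levels = unique(want)))))
  expect_equal(got, want)
})

test_that("functional range is the contiguous super-threshold set around 0", {
  fr <- functional_range(c("-2" = 0.1, "-1" = 0.9, "0" = 1.0,
                           "1.5" = 0.85, "2.5" = 0.3))
  expect_equal(fr, c(-1, 0, 1.5))
  # full interval when threshold is 0
  expect_equal(
    functional_range(c("-2" = 0.1, "0" = 1, "2" = 0.2), threshold = 0),
    c(-2, 0, 2))
  # all levels valid -> full tested interval
  expect_equal(functional_range(c("-1" = 1, "0" = 1, "1" = 1)), c(-1, 0, 1))
  # a gap on one side stops the range even if levels beyond pass
  fr2 <- functional_range(c("-2" = 0.9, "-1" = 0.5, "0" = 1, "1" = 0.9))
  expect_equal(fr2, c(0, 1))
  expect_error(functional_range(c("-1" = 1, "0" = 0.5, "1" = 1)),
               "miscalibrated")
  expect_error(functional_range(c("0" = 1, "1" = 1)), "at least 3")
})

test_that("sweep summary reports type-7 quartiles, SEM and missing levels", {
  reports <- data.frame(
    g_opsin = rep(c(0, 1), each = 3), column = 1,
    report_ms = c(500, 600, 700, NA, NA, NA),
    peak_hz = c(80, 90, 100, NA, NA, NA),
    status = rep(c("valid", "flat"), each = 3)
  )
  s <- sweep_summary(reports)
  s0 <- s[s$g_opsin == 0, ]
  expect_equal(s0$median, 600)
  expect_equal(s0$q1, 550)  # type-7 interpolation on {500,600,700}
  expect_equal(s0$q3, 650)
  expect_equal(s0$sem, sd(c(500, 600, 700)) / sqrt(3))
  expect_true(s[s$g_opsin == 1, "missing"])

  one <- sweep_summary(data.frame(g_opsin = 0, column = 1, report_ms = 600,
                                  peak_hz = 50, status = "valid"))
  expect_equal(one$median, 600)
  expect_equal(one$sem, 0)
})

test_that("two-way ANOVA equals brute-force SS on random balanced designs", {
  set.seed(7)
  for (rep in 1:5) {
    nl_a <- sample(2:3, 1); nl_b <- sample(2:3, 1); nc <- sample(3:6, 1)
    d <- expand.grid(train = seq_len(nl_a), test = seq_len(nl_b),
                     k = seq_len(nc))
    d$report_ms <- rnorm(nrow(d), mean = 600 + 30 * d$train - 20 * d$test +
                           10 * d$train * d$test, sd = 25)
    got <- two_way_anova(d)
    want <- anova_bruteforce(d$report_ms, d$train, d$test)
    expect_equal(got$effects$train$F, unname(want$Fa), tolerance = 1e-10)
    expect_equal(got$effects$test$F, unname(want$Fb), tolerance = 1e-10)
    expect_equal(got$effects$interaction$F, unname(want$Fab),
                 tolerance = 1e-10)
    expect_equal(got$effects$train$df2, want$dfe)
  }
})

test_that("ANOVA guards against degenerate designs", {
  d <- data.frame(report_ms = rnorm(8), train = rep(1, 8),
                  test = rep(1:2, 4))
  expect_error(two_way_anova(d), "2 levels")
  d2 <- data.frame(report_ms = rnorm(5), train = c(1, 1, 2, 2, 2),
                   test = c(1, 2, 1, 2, 2))
  expect_error(two_way_anova(d2), "at least 2 observations")
})
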