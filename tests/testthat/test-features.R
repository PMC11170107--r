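cfg <- scoring_config()

test_that("active-electrode and well QC thresholds are strict", {
  # 181 spikes / 1800 s = 0.1006 Hz -> in; 180 / 1800 s = exactly 0.1 Hz -> out
  rec <- make_well(list(seq(0, 1799, length.out = 181),
                        seq(0, 1799, length.out = 180)),
                   duration_s = 1800)
  expect_identical(active_electrodes(rec, 0.1), "e01")
  # all-silent -> empty set; homogeneous 1 Hz -> all in
  silent <- make_well(rep(list(numeric(0)), 16), duration_s = 100)
  expect_length(active_electrodes(silent), 0)
  busy <- make_well(rep(list(seq(0.5, 99.5, 1)), 16), duration_s = 100)
  expect_length(active_electrodes(busy), 16)
  # well QC: 7/16 = 43.75% passes, 6/16 = 37.5% fails, 0/16 fails
  mk <- function(n_active) make_well(c(rep(list(seq(0.5, 99.5, 1)), n_active),
                                       rep(list(numeric(0)), 16 - n_active)),
                                     duration_s = 100)
  expect_true(well_qc(mk(7), cfg))
  expect_false(well_qc(mk(6), cfg))
  expect_false(well_qc(mk(0), cfg))
  # a fraction exactly at the threshold fails (strict inequality):
  # 7/16 = 0.4375 is NOT > 0.4375
  cfg2 <- scoring_config(qc_active_fraction = 7 / 16)
  expect_false(well_qc(mk(7), cfg2))
})

test_that("WMFR equals the brute-force count oracle", {
  # homogeneous case: 16 electrodes x 1 Hz
  rec <- make_well(rep(list(seq(0.5, 1799.5, 1)), 16), duration_s = 1800)
  expect_equal(weighted_mean_firing_rate(rec), 1.0)
  # silent -> 0
  expect_equal(weighted_mean_firing_rate(
    make_well(rep(list(numeric(0)), 4))), 0)
  # random small wells: exact equality with hand count, and permutation
  # invariance of electrode order
  set.seed(42)
  for (i in 1:20) {
    n_el <- sample(2:16, 1)
    tss <- replicate(n_el, poisson_train(runif(1, 0.2, 1.5), 60),
                     simplify = FALSE)
    rec <- make_well(tss, duration_s = 60)
    act <- active_electrodes(rec)
    hand <- sum(lengths(tss)[match(act, sprintf("e%02d", seq_len(n_el)))]) /
      (60 * length(act))
    if (length(act) == 0) hand <- 0
    expect_identical(weighted_mean_firing_rate(rec, act), hand)
    perm <- make_well(rev(tss), duration_s = 60)
    expect_equal(weighted_mean_firing_rate(perm,
                                           active_electrodes(perm)), hand)
  }
  # seeded Poisson at 2 Hz: recovery within 3 SE of the generative rate
  set.seed(7)
  rec <- make_well(replicate(16, poisson_train(2, 1800), simplify = FALSE),
                   duration_s = 1800)
  se <- sqrt(2 / (16 * 1800))
  expect_lt(abs(weighted_mean_firing_rate(rec) - 2), 3 * se)
})

test_that("Poisson Surprise detection matches the exhaustive oracle", {
  set.seed(11)
  for (i in 1:25) {
    ts <- poisson_train(runif(1, 0.3, 1), 80)
    if (runif(1) < 0.7) {
      # inject a dense burst
      t0 <- runif(1, 10, 60)
      ts <- sort(unique(c(ts, t0 + sort(runif(sample(6:15, 1), 0, 0.4)))))
    }
    if (length(ts) < 3 || length(ts) > 100) next
    rate <- length(ts) / 80
    got <- detect_bursts(ts, duration_s = 80)
    want <- oracle_bursts(ts, rate)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start_s, unname(want[, "start_s"]))
      expect_equal(got$end_s, unname(want[, "end_s"]))
      expect_equal(got$n_spikes, unname(want[, "n_spikes"]))
      expect_equal(got$surprise, unname(want[, "surprise"]), tolerance = 1e-9)
    }
  }
})

test_that("burst detection satisfies its contracts", {
  # fewer spikes than min_spikes -> empty, not an error
  expect_equal(nrow(detect_bursts(c(1, 2, 3), duration_s = 10,
                                  min_spikes = 5)), 0)
  # injected burst example: surprise matches the direct tail sum
  set.seed(3)
  bg <- poisson_train(0.5, 100)
  inj <- 50 + sort(runif(20, 0, 0.5))
  ts <- sort(unique(c(bg, inj)))
  b <- detect_bursts(ts, duration_s = 100)
  expect_equal(nrow(b), 1)
  expect_lte(b$start_s, min(inj))
  expect_gte(b$end_s, max(inj))
  expect_equal(b$surprise,
               oracle_surprise(b$n_spikes,
                               length(ts) / 100 * (b$end_s - b$start_s)),
               tolerance = 1e-9)
  # false positives on pure Poisson trains are rare at threshold 10
  set.seed(21)
  nb <- vapply(1:100, function(i)
    nrow(detect_bursts(poisson_train(1, 1800), duration_s = 1800)),
    numeric(1))
  expect_lte(mean(nb), 0.1)
  # spikes in bursts never exceed the total; bursts never overlap
  set.seed(5)
  for (i in 1:10) {
    ts <- sort(unique(c(poisson_train(1, 50),
                        20 + sort(runif(15, 0, 0.3)))))
    b <- detect_bursts(ts, duration_s = 50)
    expect_lte(sum(b$n_spikes), length(ts))
    if (nrow(b) > 1) {
      b <- b[order(b$start_s), ]
      expect_true(all(b$start_s[-1] > b$end_s[-nrow(b)]))
    }
  }
})

test_that("mean burst duration follows the contract", {
  expect_true(is.na(mean_burst_duration(NULL)))
  b <- data.frame(start_s = c(0, 1), end_s = c(0.2, 1.4))
  expect_equal(mean_burst_duration(b), 0.3)
  expect_true(is.na(mean_burst_duration(b[0, ])))
})

test_that("median/mean ISI hits its analytic limits", {
  # constant ISI -> exactly 1
  expect_identical(median_over_mean_isi(seq(0, 99, 1)), 1)
  # exponential ISIs -> ln 2 within 0.02 at 1e4 ISIs
  set.seed(13)
  expect_lt(abs(median_over_mean_isi(cumsum(rexp(10001))) - log(2)), 0.02)
  # fewer than 2 spikes -> missing
  expect_true(is.na(median_over_mean_isi(3.0)))
  expect_true(is.na(median_over_mean_isi(numeric(0))))
})

test_that("AuCC orders synchrony correctly and is ~0 for independence", {
  set.seed(17)
  base <- poisson_train(1.5, 300)
  identical_rec <- make_well(list(base, base + 1e-4), duration_s = 300)
  jit5 <- make_well(list(base, sort(base + rnorm(length(base), 0, 0.005))),
                    duration_s = 300)
  jit50 <- make_well(list(base, sort(base + rnorm(length(base), 0, 0.05))),
                     duration_s = 300)
  a_id <- area_under_cross_correlation(identical_rec)
  a_5 <- area_under_cross_correlation(jit5)
  a_50 <- area_under_cross_correlation(jit50)
  # the correlogram area is conserved under jitter much smaller than the lag
  # window (mass moves between bins, not out of the window), so identical
  # and 5 ms agree; 50 ms jitter pushes pair mass beyond +/-100 ms lags
  expect_gte(a_id, a_5)
  expect_gt(a_5, a_50)
  expect_gt(a_id, a_50)
  expect_gte(a_50, 0)
  # < 2 active electrodes -> missing
  expect_true(is.na(area_under_cross_correlation(
    make_well(list(base), duration_s = 300))))
  # independent trains: mean AuCC within 3 SE of the trial-shuffle chance
  # level (shuffling one train of the pair destroys any real correlation,
  # so both share the clipping-induced floor)
  set.seed(19)
  vals <- t(vapply(1:40, function(i) {
    ta <- poisson_train(1, 600); tb <- poisson_train(1, 600)
    real <- area_under_cross_correlation(make_well(list(ta, tb),
                                                   duration_s = 600))
    shuf <- area_under_cross_correlation(
      make_well(list(ta, sort(runif(length(tb), 0, 600))),
                duration_s = 600))
    c(real, shuf)
  }, numeric(2)))
  d <- vals[, 1] - vals[, 2]
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
  # jitter monotonicity across seeded runs (sigma 5 ms vs 50 ms)
  set.seed(23)
  wins <- vapply(1:40, function(i) {
    drv <- poisson_train(1, 300)
    jit <- function(sd) lapply(1:4, function(e) {
      x <- sort(drv + rnorm(length(drv), 0, sd))
      x[x >= 0 & x < 300]
    })
    w5 <- make_well(jit(0.005), duration_s = 300)
    w50 <- make_well(jit(0.05), duration_s = 300)
    area_under_cross_correlation(w5) > area_under_cross_correlation(w50)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("network bursts recover the generative driver rate", {
  expect_equal(nrow(network_bursts(make_well(rep(list(numeric(0)), 16)),
                                   cfg)), 0)
  set.seed(29)
  dur <- 600
  d <- simulation_design(duration_s = dur, seed = 29)
  rec <- simulate_well(d, NULL, "baseline", seed = 123)
  nb <- network_bursts(rec, cfg)
  rate <- nrow(nb) / dur
  se <- sqrt(d$network_burst_rate_hz / dur / d$network_burst_shape)
  expect_lt(abs(rate - d$network_burst_rate_hz), 3 * se + 0.01)
  expect_true(all(nb$participation >= 0.5))
})

test_that("compute_features is deterministic, symmetric, and sane on edges", {
  set.seed(31)
  d <- simulation_design(duration_s = 120, seed = 31)
  rec <- simulate_well(d, NULL, "baseline", seed = 55)
  f1 <- compute_features(rec, cfg)
  f2 <- compute_features(rec, cfg)
  expect_identical(f1$extended, f2$extended)
  expect_identical(names(f1$extended),
                   setdiff(mea_parameter_panel(),
                           c("firing_cessation", "network_cessation")))
  expect_length(mea_parameter_panel(), 43)
  # relabeling electrodes does not change the features
  rec2 <- rec
  rec2$trains <- rev(rec2$trains)
  for (i in seq_along(rec2$trains))
    rec2$trains[[i]]$electrode_id <- sprintf("x%02d", i)
  names(rec2$trains) <- sprintf("x%02d", seq_along(rec2$trains))
  f3 <- compute_features(rec2, cfg)
  expect_equal(unname(f3$extended), unname(f1$extended), tolerance = 1e-12)
  # silent well: wmfr 0, burst/network parameters missing, QC fail
  fs <- compute_features(make_well(rep(list(numeric(0)), 16)), cfg)
  expect_equal(fs$wmfr_hz, 0)
  expect_true(is.na(fs$mean_burst_duration_s))
  expect_true(is.na(fs$aucc))
  expect_true(is.na(fs$median_over_mean_isi))
  expect_false(fs$qc_pass)
})

test_that("cessation flags respond to silencing and decoupling", {
  set.seed(37)
  d <- simulation_design(duration_s = 300, seed = 37)
  base <- compute_features(simulate_well(d, NULL, "baseline", seed = 1), cfg)
  # identical treated -> no flags
  same <- compute_features(simulate_well(d, NULL, "treated", seed = 2), cfg)
  expect_equal(unname(cessation_flags(base, same, cfg)), c(FALSE, FALSE))
  # fully silent treated -> both flags
  silent <- compute_features(make_well(rep(list(numeric(0)), 16),
                                       duration_s = 300, phase = "treated"),
                             cfg)
  expect_equal(unname(cessation_flags(base, silent, cfg)), c(TRUE, TRUE))
  # decoupling: rates preserved, common driver removed -> (FALSE, TRUE)
  dec <- compute_features(simulate_well(
    d, effect_profile(decouple_network = TRUE), "treated", seed = 3), cfg)
  expect_equal(unname(cessation_flags(base, dec, cfg)), c(FALSE, TRUE))
  # QC-failing baseline is a contract violation
  bad <- compute_features(make_well(rep(list(numeric(0)), 16)), cfg)
  expect_error(cessation_flags(bad, same, cfg), "QC")
})
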