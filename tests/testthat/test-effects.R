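# Minimal hand-built well_features pair for arithmetic tests.
fake_features <- function(values, well = "A1", phase = "baseline",
                          qc = TRUE) {
  panel <- setdiff(mea_parameter_panel(),
                   c("firing_cessation", "network_cessation"))
  ext <- setNames(rep(NA_real_, length(panel)), panel)
  ext[names(values)] <- unlist(values)
  structure(list(well_id = well, phase = phase, plate_id = "p",
                 wmfr_hz = ext[["wmfr_hz"]],
                 mean_burst_duration_s = ext[["mean_burst_duration_s"]],
                 aucc = ext[["aucc"]],
                 median_over_mean_isi = ext[["median_over_mean_isi"]],
                 firing_cessation = NA, network_cessation = NA,
                 n_active_electrodes = 16L, qc_pass = qc, extended = ext),
            class = "well_features")
}

test_that("baseline percent change follows the contract", {
  b <- fake_features(list(wmfr_hz = 2.0, aucc = 0.5))
  t1 <- fake_features(list(wmfr_hz = 1.0, aucc = 0.5), phase = "treated")
  expect_equal(baseline_pct_change(b, t1, "wmfr_hz"), -50)
  expect_equal(baseline_pct_change(b, t1, "aucc"), 0)
  # missing baseline -> missing
  expect_true(is.na(baseline_pct_change(b, t1, "mean_burst_duration_s")))
  # zero baseline -> missing with a logged reason
  b0 <- fake_features(list(wmfr_hz = 0))
  expect_message(v <- baseline_pct_change(b0, t1, "wmfr_hz"), "zero")
  expect_true(is.na(v))
  # negative baseline: |baseline| denominator keeps the direction meaningful
  bn <- fake_features(list(aucc = -2)); tn <- fake_features(list(aucc = -1))
  expect_equal(baseline_pct_change(bn, tn, "aucc"), 50)
})

test_that("vehicle normalization centers vehicles and shifts wells", {
  expect_equal(vehicle_normalize(-50, c(4, 6)), -55)
  # vehicle wells against their own mean: exactly centered
  veh <- c(-3, 1, 5, 9)
  expect_equal(mean(vehicle_normalize(veh, veh)), 0, tolerance = 1e-9)
  # all wells sharing one change -> all zero
  expect_equal(vehicle_normalize(rep(7, 5), rep(7, 3)), rep(0, 5))
  expect_error(vehicle_normalize(1, numeric(0)), "vehicle")
  # divide option
  expect_equal(vehicle_normalize(50, c(25), method = "divide"), 100)
})

test_that("exact rank-sum p-values match complete enumeration", {
  # 3 wells all above 3 vehicle wells: p = 2 / C(6,3) = 0.1
  es <- aggregate_condition(c(10, 11, 12), c(1, 2, 3))
  expect_equal(es$p_value, 0.1)
  expect_equal(es$n_wells, 3L)
  expect_equal(es$dd_pct, 11)
  expect_equal(es$sem, 1 / sqrt(3))
  # identical samples -> p = 1
  expect_equal(aggregate_condition(c(5, 5), c(5, 5))$p_value, 1.0)
  # single well: SEM 0, n = 1
  es1 <- aggregate_condition(3.3, c(0, 1))
  expect_equal(es1$sem, 0)
  expect_equal(es1$n_wells, 1L)
  # agreement with wilcox.test exact p on tie-free samples, n <= 8 vs 8
  set.seed(101)
  for (i in 1:20) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1))
    expect_equal(meahazard:::rank_sum_test(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # large samples switch to the normal approximation with tie correction
  set.seed(5)
  x <- round(rnorm(30), 1); y <- round(rnorm(30, 0.8), 1)
  expect_equal(meahazard:::rank_sum_test(x, y),
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 0.05)
})

test_that("plate-level effects pipeline produces centered vehicles", {
  set.seed(202)
  d <- simulation_design(duration_s = 120, n_vehicle = 4L, n_wells = 12L,
                         conditions = list(
                           list(compound = "drugA", role = "test",
                                concentration_um = 3, n_wells = 4L,
                                profile = effect_profile(rate_multiplier = 0.3)),
                           list(compound = "drugB", role = "test",
                                concentration_um = 1, n_wells = 4L,
                                profile = effect_profile())),
                         seed = 202)
  pl <- simulate_plate(d)
  wdf <- suppressMessages(well_effects(plate_features(pl$recordings),
                                       pl$map, scoring_config()))
  # vehicle-mean-centering invariant, every parameter
  for (p in unique(wdf$parameter)) {
    if (p %in% c("firing_cessation", "network_cessation")) next
    veh <- wdf$dd_pct[wdf$role == "vehicle" & wdf$parameter == p]
    if (all(is.na(veh))) next
    expect_equal(mean(veh, na.rm = TRUE), 0, tolerance = 1e-9)
  }
  cdf <- condition_effects(wdf)
  # aggregation is invariant to well ordering
  wdf2 <- wdf[rev(seq_len(nrow(wdf))), ]
  cdf2 <- condition_effects(wdf2)
  expect_equal(cdf$dd_pct, cdf2$dd_pct)
  expect_equal(cdf$p_value, cdf2$p_value)
  # the strong rate reduction is detected on WMFR
  a <- cdf[cdf$compound == "drugA" & cdf$parameter == "wmfr_hz", ]
  expect_lt(a$dd_pct, -50)
  expect_lt(a$p_value, 0.05)
  expect_equal(a$n_wells, 4L)
})
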