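mat <- default_scoring_matrix()
cuts <- toy_cutoffs(band = 20, strong_at = 60)
keys <- attr(mea_parameter_panel(), "key_continuous")
no_flags <- c(firing_cessation = FALSE, network_cessation = FALSE)

zero_effects <- setNames(rep(0, 4), keys)

test_that("zone assignment respects the severity tie rule", {
  z <- cuts$wmfr_hz
  expect_identical(as.character(assign_zone(0, z)), "no_effect")
  expect_identical(as.character(assign_zone(-100, z)), "strong_down")
  # boundary values go to the more severe zone
  expect_identical(as.character(assign_zone(20, z)), "mild_up")
  expect_identical(as.character(assign_zone(-20, z)), "mild_down")
  expect_identical(as.character(assign_zone(60, z)), "strong_up")
  expect_identical(as.character(assign_zone(-60, z)), "strong_down")
  expect_identical(as.character(assign_zone(59.999, z)), "mild_up")
  # missing -> no_effect, annotated not evaluable
  za <- assign_zone(NA_real_, z)
  expect_identical(as.character(za), "no_effect")
  expect_false(attr(za, "evaluable"))
})

test_that("condition scoring sums weighted points into the right label", {
  # all parameters no-effect, no flags -> 0 -> non-neuroactive
  r <- score_condition(zero_effects, no_flags, mat, cuts)
  expect_equal(r$total_score, 0)
  expect_identical(r$label, "non-neuroactive")
  expect_identical(r$color, "green")
  # hand-summed mixed case: strong_up WMFR (2) + strong_up AuCC (2) +
  # mild_up burst duration (1) = 5 -> high hazard
  eff <- setNames(c(75, 30, 75, 0), keys)
  r <- score_condition(eff, no_flags, mat, cuts)
  expect_equal(r$total_score, 2 + 1 + 2 + 0)
  expect_identical(r$label, "high hazard")
  # FS + NS alone: 3 + 2 = 5 -> at least hazard under the default matrix
  r <- score_condition(zero_effects,
                       c(firing_cessation = TRUE, network_cessation = TRUE),
                       mat, cuts)
  expect_equal(r$total_score, mat$fs_points + mat$ns_points)
  expect_true(r$label %in% c("hazard", "high hazard"))
  # missing key parameter -> contract error
  expect_error(score_condition(zero_effects[-1], no_flags, mat, cuts),
               "wmfr_hz")
  expect_error(score_condition(zero_effects, no_flags, mat, cuts[-1]),
               "cutoffs")
})

test_that("every attainable total maps to exactly one label, monotonically", {
  zones <- c("strong_down", "mild_down", "no_effect", "mild_up", "strong_up")
  zone_val <- c(strong_down = -70, mild_down = -30, no_effect = 0,
                mild_up = 30, strong_up = 70)
  grid <- expand.grid(a = zones, b = zones, c = zones, d = zones,
                      fs = c(FALSE, TRUE), ns = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  lab_rank <- function(l) match(l, c("non-neuroactive", "neuroactive",
                                     "hazard", "high hazard"))
  sev <- function(z) match(z, c("no_effect", "mild_down", "mild_up",
                                "strong_down", "strong_up"))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    eff <- setNames(zone_val[c(g$a, g$b, g$c, g$d)], keys)
    r <- score_condition(eff, c(firing_cessation = g$fs,
                                network_cessation = g$ns), mat, cuts)
    # label ranges cover the total exactly once (score_condition errors
    # otherwise); spot the brute-force expected total
    pts <- c(2, 1, 0, 1, 2)[match(c(g$a, g$b, g$c, g$d), zones)]
    expect_equal(r$total_score, sum(pts) + 3 * g$fs + 2 * g$ns)
    # monotone severity in the first parameter
    if (sev(g$a) < 5) {
      worse <- zones[c(5, 4, 5, 5, 5)[match(g$a, zones)]]
      eff2 <- eff; eff2[1] <- zone_val[worse]
      r2 <- score_condition(eff2, c(firing_cessation = g$fs,
                                    network_cessation = g$ns), mat, cuts)
      expect_gte(r2$total_score, r$total_score)
      expect_gte(lab_rank(r2$label), lab_rank(r$label))
    }
  }
  # determinism
  eff <- setNames(c(25, -65, 0, 61), keys)
  r1 <- score_condition(eff, no_flags, mat, cuts)
  r2 <- score_condition(eff, no_flags, mat, cuts)
  expect_identical(r1, r2)
})

test_that("concentration series are ordered with fCmax folds", {
  mk <- function(conc, label) structure(
    list(compound = "drugX", concentration_um = conc, zones = list(),
         points = list(), flags = no_flags, total_score = 0, label = label,
         color = "green"), class = "hazard_result")
  res <- list(mk(3, "hazard"), mk(0.3, "non-neuroactive"),
              mk(10, "high hazard"), mk(1, "neuroactive"))
  out <- score_concentration_series(res, fcmax_um = 1)
  expect_equal(out$concentration_um, c(0.3, 1, 3, 10))
  expect_equal(out$fold_fcmax, c(0.3, 1, 3, 10))
  single <- score_concentration_series(res[2])
  expect_equal(nrow(single), 1)
})

test_that("scoring matrices survive the JSON round trip", {
  path <- withr::local_tempfile(fileext = ".json")
  write_scoring_matrix(mat, path)
  back <- read_scoring_matrix(path)
  expect_equal(back$points, mat$points)
  expect_equal(back$fs_points, mat$fs_points)
  expect_equal(back$label_ranges$label, mat$label_ranges$label)
  expect_equal(back$label_ranges$max, mat$label_ranges$max)
  # a re-weighted matrix drops in without code change
  mat2 <- mat
  mat2$points$wmfr_hz["strong_up"] <- 4
  eff <- setNames(c(75, 0, 0, 0), keys)
  expect_equal(score_condition(eff, no_flags, mat2, cuts)$total_score, 4)
})
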