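# Separable three-class benchmark over the effect panel: inhibitory WMFR
# ~ -70, excitatory ~ +70 with an AuCC shift, vehicle ~ 0, within-class
# sd 10 on the informative columns.
make_direction_data <- function(n_per_class = 50, p = 10, sd = 10,
                                seed = 1) {
  set.seed(seed)
  y <- rep(c("inhibitory", "excitatory", "vehicle"), each = n_per_class)
  X <- matrix(rnorm(3 * n_per_class * p, 0, sd), ncol = p,
              dimnames = list(NULL, c("wmfr_hz", "aucc",
                                      sprintf("par%02d", 3:p))))
  X[y == "inhibitory", "wmfr_hz"] <- X[y == "inhibitory", "wmfr_hz"] - 70
  X[y == "excitatory", "wmfr_hz"] <- X[y == "excitatory", "wmfr_hz"] + 70
  X[y == "excitatory", "aucc"] <- X[y == "excitatory", "aucc"] + 40
  list(X = X, y = y)
}

test_that("direction model separates the synthetic benchmark", {
  d <- make_direction_data(seed = 11)
  hold <- make_direction_data(n_per_class = 30, seed = 12)
  model <- fit_direction_model(d$X, d$y, n_trees = 200, seed = 99)
  expect_gt(model$oob_accuracy, 0.9)
  preds <- predict_direction(model, hold$X)
  acc <- mean(vapply(preds, `[[`, "", "predicted") == hold$y)
  expect_gte(acc, 0.9)
  # opposite-sign classes are confused less often than either with vehicle
  pred <- vapply(preds, `[[`, "", "predicted")
  cross <- sum(pred == "excitatory" & hold$y == "inhibitory") +
    sum(pred == "inhibitory" & hold$y == "excitatory")
  with_veh <- sum(pred == "vehicle" & hold$y != "vehicle") +
    sum(pred != "vehicle" & hold$y == "vehicle")
  expect_lte(cross, with_veh)
})

test_that("probabilities live on the simplex and predictions are stable", {
  d <- make_direction_data(n_per_class = 30, seed = 21)
  model <- fit_direction_model(d$X, d$y, n_trees = 100, seed = 5)
  set.seed(31)
  probe <- matrix(rnorm(200 * ncol(d$X), 0, 50), ncol = ncol(d$X),
                  dimnames = list(NULL, colnames(d$X)))
  preds <- predict_direction(model, probe)
  for (p in preds) {
    tot <- p$p_inhibitory + p$p_excitatory + p$p_vehicle
    expect_equal(tot, 1, tolerance = 1e-9)
    expect_true(all(c(p$p_inhibitory, p$p_excitatory, p$p_vehicle) >= 0))
  }
  # all-zero profile -> vehicle is the argmax
  zero <- setNames(rep(0, ncol(d$X)), colnames(d$X))
  expect_identical(predict_direction(model, zero)$predicted, "vehicle")
  # class-centroid profiles -> their class
  inh <- setNames(c(-70, 0, rep(0, ncol(d$X) - 2)), colnames(d$X))
  expect_identical(predict_direction(model, inh)$predicted, "inhibitory")
  # determinism: same seed and data -> identical predictions
  m2 <- fit_direction_model(d$X, d$y, n_trees = 100, seed = 5)
  p1 <- predict_direction(model, probe)
  p2 <- predict_direction(m2, probe)
  expect_identical(vapply(p1, `[[`, 0, "p_vehicle"),
                   vapply(p2, `[[`, 0, "p_vehicle"))
  # permuting training rows (same seed policy) leaves accuracy intact
  perm <- sample(length(d$y))
  m3 <- fit_direction_model(d$X[perm, ], d$y[perm], n_trees = 100, seed = 5)
  p3 <- vapply(predict_direction(m3, d$X), `[[`, "", "predicted")
  expect_gt(mean(p3 == d$y), 0.9)
})

test_that("label shuffling drops accuracy to chance", {
  d <- make_direction_data(n_per_class = 30, seed = 41)
  set.seed(42)
  ysh <- sample(d$y)
  model <- fit_direction_model(d$X, ysh, n_trees = 100, seed = 7)
  hold <- make_direction_data(n_per_class = 40, seed = 43)
  pred <- vapply(predict_direction(model, hold$X), `[[`, "", "predicted")
  acc <- mean(pred == hold$y)
  se <- sqrt(1 / 3 * 2 / 3 / length(hold$y))
  expect_lt(abs(acc - 1 / 3), 3 * se)
})

test_that("models round-trip through the JSON persistence format", {
  d <- make_direction_data(n_per_class = 15, seed = 61)
  model <- fit_direction_model(d$X, d$y, n_trees = 30, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_direction_model(model, path)
  back <- read_direction_model(path)
  p1 <- predict_direction(model, d$X)
  p2 <- predict_direction(back, d$X)
  expect_identical(vapply(p1, `[[`, 0, "p_inhibitory"),
                   vapply(p2, `[[`, 0, "p_inhibitory"))
  expect_identical(vapply(p1, `[[`, "", "predicted"),
                   vapply(p2, `[[`, "", "predicted"))
  expect_error(read_direction_model(
    withr::local_tempfile(lines = "{\"format\": \"other\"}")), "not a")
})

test_that("schema violations are reported", {
  d <- make_direction_data(n_per_class = 10, seed = 51)
  expect_error(fit_direction_model(d$X[d$y != "vehicle", ],
                                   d$y[d$y != "vehicle"]), "vehicle")
  model <- fit_direction_model(d$X, d$y, n_trees = 20, seed = 1)
  bad <- d$X[1:2, -1]
  expect_error(predict_direction(model, bad), "wmfr_hz")
})
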