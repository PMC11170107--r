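# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: Poisson tails are summed directly, burst search is an
# exhaustive double loop over all windows, firing rates are counted by hand.

# -log10 P(X >= n) for X ~ Poisson(mu), by direct summation of the upper
# tail with the term recurrence (no ppois).
oracle_surprise <- function(n, mu) {
  if (mu <= 0) return(Inf)
  ks <- n:(n + max(60, ceiling(10 * mu)))
  -log10(sum(exp(-mu + ks * log(mu) - lgamma(ks + 1))))
}

# Exhaustive-window greedy burst maximizer: scan every (i, j) window,
# take the global surprise maximum (ties: larger window, then earlier
# start), recurse on the flanks. Mirrors the detector's contract, not its
# algorithm.
oracle_bursts <- function(ts, rate, min_spikes = 3, threshold = 10) {
  out <- NULL
  segs <- list(seq_along(ts))
  while (length(segs)) {
    ix <- segs[[1]]; segs <- segs[-1]
    if (length(ix) < min_spikes) next
    best <- NULL
    for (a in seq_along(ix)) {
      bs <- seq_along(ix)[seq_along(ix) - a + 1 >= min_spikes]
      if (!length(bs)) next
      ss <- vapply(bs, function(b)
        oracle_surprise(b - a + 1, rate * (ts[ix[b]] - ts[ix[a]])),
        numeric(1))
      for (k in seq_along(bs)) {
        b <- bs[k]; n <- b - a + 1; s <- ss[k]
        if (is.null(best) || s > best$s ||
            (s == best$s && (n > best$n || (n == best$n && a < best$a))))
          best <- list(s = s, a = a, b = b, n = n)
      }
    }
    if (best$s < threshold) next
    out <- rbind(out, c(start_s = ts[ix[best$a]], end_s = ts[ix[best$b]],
                        n_spikes = best$n, surprise = best$s))
    if (best$a > min_spikes) segs <- c(segs, list(ix[seq_len(best$a - 1)]))
    if (length(ix) - best$b >= min_spikes)
      segs <- c(segs, list(ix[seq(best$b + 1, length(ix))]))
  }
  if (is.null(out)) return(out)
  out[order(out[, "start_s"]), , drop = FALSE]
}

# Poisson spike train on [0, duration] (sorted, strictly increasing).
poisson_train <- function(rate, duration) {
  ts <- cumsum(rexp(ceiling(rate * duration + 4 * sqrt(rate * duration) + 10),
                    rate))
  ts <- ts[ts < duration]
  ts[c(TRUE, diff(ts) > 0)]
}

# Small well with the given per-electrode spike-time list.
make_well <- function(trains_ts, duration_s = 100, well_id = "A1",
                      phase = "baseline") {
  trains <- lapply(seq_along(trains_ts), function(i)
    spike_train(sprintf("e%02d", i), trains_ts[[i]], duration_s))
  well_recording(well_id, phase, trains, duration_s)
}

# Tiny calibration cutoffs for scoring tests: symmetric vehicle band
# [-band, band], strong beyond strong_at.
toy_cutoffs <- function(band = 20, strong_at = 60,
                        params = attr(mea_parameter_panel(),
                                      "key_continuous")) {
  out <- lapply(params, function(p)
    structure(list(parameter = p, no_effect = c(-band, band),
                   strong_down_edge = -strong_at, mild_down_edge = -band,
                   mild_up_edge = band, strong_up_edge = strong_at),
              class = "zone_cutoffs"))
  names(out) <- params
  out
}

# Scaled-down calibration + scoring world shared by simulator and
# acceptance tests: pooled cutoffs from n_cal plates of vehicle + two
# directional positive controls.
sweep_calibration <- function(duration_s = 150, n_cal = 4, seed0 = 1000) {
  calib_conds <- list(
    list(compound = "pos_inhibitory", role = "positive_control",
         concentration_um = 10, n_wells = 8L,
         profile = effect_profile(rate_multiplier = 0.25,
                                  burst_duration_multiplier = 0.6,
                                  synchrony_jitter_ms = 30)),
    list(compound = "pos_excitatory", role = "positive_control",
         concentration_um = 10, n_wells = 8L,
         profile = effect_profile(rate_multiplier = 2.5,
                                  burst_duration_multiplier = 2,
                                  synchrony_jitter_ms = 4)))
  wdfs <- lapply(seq_len(n_cal), function(p) {
    d <- simulation_design(duration_s = duration_s, n_vehicle = 8L,
                           n_wells = 24L, conditions = calib_conds,
                           seed = seed0 + p)
    pl <- simulate_plate(d, plate_id = paste0("cal", p))
    suppressMessages(well_effects(plate_features(pl$recordings), pl$map))
  })
  suppressWarnings(calibrate_cutoffs(do.call(rbind, wdfs)))
}
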