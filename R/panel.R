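# The fixed extended parameter panel. The six key parameters of the scoring
# system (WMFR, mean burst duration, AuCC, median/mean ISI, FS, NS) are part
# of the panel; the remaining names follow standard multiwell-MEA outputs so
# the selection machinery has a stable 43-dimensional input space.
.panel_well_level <- c(
  "wmfr_hz", "mean_firing_rate_hz", "n_spikes_total", "n_active_electrodes",
  "active_electrode_fraction", "firing_rate_cv_electrodes",
  "firing_rate_max_hz", "isi_mean_s", "isi_median_s", "isi_cv",
  "median_over_mean_isi", "n_bursts", "burst_rate_per_min",
  "mean_burst_duration_s", "burst_duration_median_s", "burst_duration_cv",
  "spikes_per_burst_mean", "spikes_per_burst_median", "pct_spikes_in_bursts",
  "intra_burst_rate_hz", "inter_burst_interval_mean_s",
  "inter_burst_interval_cv", "burst_surprise_mean", "n_bursting_electrodes",
  "intra_burst_isi_mean_s", "intra_burst_median_over_mean_isi",
  "pct_time_in_bursts", "n_network_bursts", "network_burst_rate_per_min",
  "network_burst_duration_mean_s", "network_burst_duration_cv",
  "network_burst_participation_mean", "inter_network_burst_interval_mean_s",
  "inter_network_burst_interval_cv", "network_burst_spikes_mean",
  "pct_spikes_in_network_bursts", "pct_time_in_network_bursts",
  "aucc", "aucc_peak", "aucc_width_s", "synchrony_index"
)

.key_continuous <- c("wmfr_hz", "mean_burst_duration_s", "aucc",
                     "median_over_mean_isi")
.key_flags <- c("firing_cessation", "network_cessation")

#' The fixed 43-name MEA parameter panel
#'
#' 41 well-level parameters plus the two pair-level cessation flags; the six
#' key scoring parameters are `wmfr_hz`, `mean_burst_duration_s`, `aucc`,
#' `median_over_mean_isi`, `firing_cessation`, `network_cessation`.
#'
#' @return Character vector of 43 parameter names, with attributes
#'   `key_continuous` and `key_flags`.
#' @export
mea_parameter_panel <- function() {
  structure(c(.panel_well_level, .key_flags),
            key_continuous = .key_continuous, key_flags = .key_flags)
}

.cv <- function(x) if (length(x) < 2 || mean(x) == 0) NA_real_ else sd(x) / mean(x)

#' Compute the full feature panel for one well/phase
#'
#' Populates the six key parameters, QC status, and the extended 41-name
#' well-level panel. Parameters whose defining event set is empty (e.g. burst
#' statistics of a burst-free well) are `NA`. The cessation flags need a
#' baseline/treated pair and are filled later by [cessation_flags()].
#'
#' @param rec A [well_recording()].
#' @param cfg A [scoring_config()].
#' @return A `well_features` object.
#' @export
compute_features <- function(rec, cfg = scoring_config()) {
  active <- active_electrodes(rec, cfg$qc_electrode_rate_hz)
  counts <- vapply(rec$trains, function(tr) length(tr$timestamps), integer(1))
  total <- sum(counts)
  dur <- rec$duration_s
  wmfr <- weighted_mean_firing_rate(rec, active)

  blist <- lapply(rec$trains[active], function(tr)
    detect_bursts(tr, duration_s = dur, min_spikes = cfg$burst$min_spikes,
                  rate_hz = cfg$burst$rate_hz,
                  surprise_threshold = cfg$burst$surprise_threshold))
  bursts <- if (length(blist))
    .fast_df(lapply(setNames(nm = names(blist[[1]])), function(cl)
      unlist(lapply(blist, `[[`, cl), use.names = FALSE)))
  else detect_bursts(numeric(0), duration_s = dur, rate_hz = 1)
  nb <- network_bursts(rec, cfg, bursts = bursts)
  xc <- .aucc_all(rec, cfg$aucc$bin_s, cfg$aucc$max_lag_s, active,
                  on = cfg$aucc$on)
  aucc <- xc$aucc
  xs <- c(peak = xc$peak, width = xc$width, central = xc$central)

  isi_all <- unlist(lapply(rec$trains[active], function(tr)
    if (length(tr$timestamps) > 1) diff(tr$timestamps) else numeric(0)))
  per_rate <- counts[active] / dur

  bd <- bursts$end_s - bursts$start_s
  spikes_in_bursts <- sum(bursts$n_spikes)
  b_by_el <- split(seq_len(nrow(bursts)), bursts$electrode_id)
  intra_isi <- unlist(lapply(names(b_by_el), function(eid) {
    ix <- b_by_el[[eid]]
    ts <- rec$trains[[eid]]$timestamps
    # bursts start/end exactly on spikes, so index slicing via findInterval
    i0 <- findInterval(bursts$start_s[ix] - 1e-12, ts) + 1L
    i1 <- findInterval(bursts$end_s[ix] + 1e-12, ts)
    unlist(lapply(seq_along(ix), function(k) diff(ts[i0[k]:i1[k]])))
  }))
  ibi <- unlist(lapply(b_by_el, function(ix) {
    if (length(ix) < 2) return(numeric(0))
    s <- sort(bursts$start_s[ix]); e <- sort(bursts$end_s[ix])
    s[-1] - e[-length(e)]
  }))

  nbd <- nb$end_s - nb$start_s
  inbi <- if (nrow(nb) > 1) nb$start_s[-1] - nb$end_s[-nrow(nb)] else numeric(0)
  all_ts <- sort(unlist(lapply(rec$trains, function(tr) tr$timestamps)))
  spikes_in_nb <- if (nrow(nb))
    sum(findInterval(nb$end_s + 1e-12, all_ts) -
          findInterval(nb$start_s - 1e-12, all_ts)) else 0
  nb_rate_min <- if (nrow(nb)) nrow(nb) / dur * 60 else 0

  ext <- c(
    wmfr_hz = wmfr,
    mean_firing_rate_hz = total / (16 * dur),
    n_spikes_total = as.numeric(total),
    n_active_electrodes = as.numeric(length(active)),
    active_electrode_fraction = length(active) / 16,
    firing_rate_cv_electrodes = .cv(per_rate),
    firing_rate_max_hz = if (length(counts)) max(counts) / dur else 0,
    isi_mean_s = if (length(isi_all)) mean(isi_all) else NA_real_,
    isi_median_s = if (length(isi_all)) median(isi_all) else NA_real_,
    isi_cv = .cv(isi_all),
    median_over_mean_isi = if (length(isi_all))
      median(isi_all) / mean(isi_all) else NA_real_,
    n_bursts = as.numeric(nrow(bursts)),
    burst_rate_per_min = nrow(bursts) / dur * 60,
    mean_burst_duration_s = mean_burst_duration(bursts),
    burst_duration_median_s = if (length(bd)) median(bd) else NA_real_,
    burst_duration_cv = .cv(bd),
    spikes_per_burst_mean = if (nrow(bursts)) mean(bursts$n_spikes) else NA_real_,
    spikes_per_burst_median = if (nrow(bursts))
      median(as.numeric(bursts$n_spikes)) else NA_real_,
    pct_spikes_in_bursts = if (total > 0) 100 * spikes_in_bursts / total else NA_real_,
    intra_burst_rate_hz = if (nrow(bursts))
      mean(bursts$n_spikes / pmax(bd, 1e-9)) else NA_real_,
    inter_burst_interval_mean_s = if (length(ibi)) mean(ibi) else NA_real_,
    inter_burst_interval_cv = .cv(ibi),
    burst_surprise_mean = if (nrow(bursts)) mean(bursts$surprise) else NA_real_,
    n_bursting_electrodes = as.numeric(length(unique(bursts$electrode_id))),
    intra_burst_isi_mean_s = if (length(intra_isi)) mean(intra_isi) else NA_real_,
    intra_burst_median_over_mean_isi = if (length(intra_isi))
      median(intra_isi) / mean(intra_isi) else NA_real_,
    pct_time_in_bursts = 100 * sum(bd) / (dur * max(1, length(active))),
    n_network_bursts = as.numeric(nrow(nb)),
    network_burst_rate_per_min = nb_rate_min,
    network_burst_duration_mean_s = if (length(nbd)) mean(nbd) else NA_real_,
    network_burst_duration_cv = .cv(nbd),
    network_burst_participation_mean = if (nrow(nb))
      mean(nb$participation) else NA_real_,
    inter_network_burst_interval_mean_s = if (length(inbi))
      mean(inbi) else NA_real_,
    inter_network_burst_interval_cv = .cv(inbi),
    network_burst_spikes_mean = if (nrow(nb))
      spikes_in_nb / nrow(nb) else NA_real_,
    pct_spikes_in_network_bursts = if (total > 0)
      100 * spikes_in_nb / total else NA_real_,
    pct_time_in_network_bursts = 100 * sum(nbd) / dur,
    aucc = aucc,
    aucc_peak = xs[["peak"]],
    aucc_width_s = xs[["width"]],
    synchrony_index = xs[["central"]]
  )
  stopifnot(identical(names(ext), .panel_well_level))

  structure(list(
    well_id = rec$well_id, phase = rec$phase, plate_id = rec$plate_id,
    wmfr_hz = wmfr,
    mean_burst_duration_s = ext[["mean_burst_duration_s"]],
    aucc = aucc,
    median_over_mean_isi = ext[["median_over_mean_isi"]],
    firing_cessation = NA, network_cessation = NA,
    n_active_electrodes = length(active),
    qc_pass = length(active) / 16 > cfg$qc_active_fraction,
    extended = ext
  ), class = "well_features")
}

#' @export
print.well_features <- function(x, ...) {
  cat(sprintf(
    "<well_features> %s [%s]: WMFR %.3f Hz, burst dur %s s, AuCC %s, med/mean ISI %s, QC %s\n",
    x$well_id, x$phase, x$wmfr_hz,
    format(x$mean_burst_duration_s, digits = 3),
    format(x$aucc, digits = 3), format(x$median_over_mean_isi, digits = 3),
    if (x$qc_pass) "pass" else "FAIL"))
  invisible(x)
}

#' Feature table for a set of recordings
#'
#' @param recordings List of [well_recording()] objects.
#' @param cfg A [scoring_config()].
#' @return Data frame, one row per (well, phase), one column per well-level
#'   panel parameter plus `well`, `phase`, `qc_pass`.
#' @export
features_table <- function(recordings, cfg = scoring_config()) {
  rows <- lapply(recordings, function(rec) {
    f <- compute_features(rec, cfg)
    cbind(data.frame(well = f$well_id, phase = f$phase, qc_pass = f$qc_pass,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(f$extended)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$well, out$phase), ]
}

#' Write a feature table CSV (missing values as empty cells)
#' @param features Data frame from [features_table()].
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}
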