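#' Active electrodes of a well
#'
#' An electrode is active when its mean firing rate strictly exceeds the
#' threshold (default 0.1 Hz, i.e. more than six spikes per minute). The
#' inequality is strict: an electrode at exactly the threshold is excluded.
#'
#' @param rec A [well_recording()].
#' @param rate_threshold_hz Strict lower bound on mean rate (Hz).
#' @return Character vector of active electrode ids.
#' @export
active_electrodes <- function(rec, rate_threshold_hz = 0.1) {
  stopifnot(rec$duration_s > 0)
  n <- vapply(rec$trains, function(tr) length(tr$timestamps), integer(1))
  names(n)[n / rec$duration_s > rate_threshold_hz]
}

#' Well-level quality control
#'
#' A well passes QC when strictly more than `qc_active_fraction` (default 40%)
#' of its 16 physical electrodes are active. Absent electrodes count in the
#' denominator. Failed wells are excluded from downstream normalization.
#'
#' @param rec A [well_recording()].
#' @param cfg A [scoring_config()].
#' @return Logical.
#' @export
well_qc <- function(rec, cfg = scoring_config()) {
  n_active <- length(active_electrodes(rec, cfg$qc_electrode_rate_hz))
  n_active / 16 > cfg$qc_active_fraction
}

#' Weighted mean firing rate (WMFR)
#'
#' Total spike count on active electrodes divided by (duration x number of
#' active electrodes); 0 when no electrode is active.
#'
#' @param rec A [well_recording()].
#' @param active Character vector of active electrode ids (defaults to the
#'   0.1 Hz rule).
#' @return Firing rate in Hz.
#' @export
weighted_mean_firing_rate <- function(rec, active = active_electrodes(rec)) {
  if (length(active) == 0) return(0)
  n <- sum(vapply(rec$trains[active],
                  function(tr) length(tr$timestamps), integer(1)))
  n / (rec$duration_s * length(active))
}

#' Poisson Surprise burst detection
#'
#' Finds maximal non-overlapping bursts on one spike train. The surprise of a
#' candidate window holding `n` spikes over span `T` is
#' `S = -log10 P(N >= n)` for `N ~ Poisson(rate * T)`. Because that tail
#' probability increases with `T`, the best window of a given spike count is
#' the minimal-span one, which lets the detector maximize `S` exactly rather
#' than by local extension heuristics: the globally best window of the train
#' is emitted if `S >= surprise_threshold`, then the search recurses on the
#' flanking spikes. Ties are broken toward more spikes, then earlier start.
#'
#' @param train A [spike_train()] or numeric timestamp vector.
#' @param duration_s Train duration, used for the default rate.
#' @param rate_hz Background Poisson rate; defaults to the train's own mean
#'   rate (`n / duration_s`).
#' @param min_spikes Minimum spikes per burst (default 3).
#' @param surprise_threshold Minimum surprise in -log10 units (default 10).
#' @return Data frame with columns `electrode_id, start_s, end_s, n_spikes,
#'   surprise`, ordered by `start_s`.
#' @export
detect_bursts <- function(train, duration_s = NULL, rate_hz = NULL,
                          min_spikes = 3L, surprise_threshold = 10) {
  if (inherits(train, "spike_train")) {
    ts <- train$timestamps
    eid <- train$electrode_id
  } else {
    ts <- as.numeric(train)
    eid <- ""
  }
  empty <- data.frame(electrode_id = character(0), start_s = numeric(0),
                      end_s = numeric(0), n_spikes = integer(0),
                      surprise = numeric(0))
  if (length(ts) < min_spikes) return(empty)
  if (is.null(rate_hz)) {
    if (is.null(duration_s)) stop("need duration_s or rate_hz")
    rate_hz <- length(ts) / duration_s
  }
  stopifnot(rate_hz > 0)
  m <- .ls_burst_scan(ts, rate_hz, as.integer(min_spikes), surprise_threshold)
  if (nrow(m) == 0) return(empty)
  ord <- order(ts[m[, "i"]])
  ii <- as.vector(m[ord, "i"]); jj <- as.vector(m[ord, "j"])
  .fast_df(list(electrode_id = rep(eid, nrow(m)), start_s = ts[ii],
                end_s = ts[jj], n_spikes = as.integer(jj - ii + 1),
                surprise = as.vector(m[ord, "surprise"])))
}

#' Mean burst duration
#'
#' @param bursts Burst data frame from [detect_bursts()].
#' @return Mean of (end - start) in seconds, or `NA` when no bursts.
#' @export
mean_burst_duration <- function(bursts) {
  if (is.null(bursts) || nrow(bursts) == 0) return(NA_real_)
  mean(bursts$end_s - bursts$start_s)
}

#' Median over mean inter-spike interval
#'
#' Ratio of the median to the mean ISI of one train: 1 for perfectly regular
#' trains, ln 2 (~0.693) for Poisson trains; low values flag heavy-tailed,
#' burst-organized firing.
#'
#' @param train A [spike_train()] or numeric timestamp vector.
#' @return Ratio, or `NA` with fewer than 2 spikes.
#' @export
median_over_mean_isi <- function(train) {
  ts <- if (inherits(train, "spike_train")) train$timestamps else as.numeric(train)
  if (length(ts) < 2) return(NA_real_)
  isi <- diff(ts)
  median(isi) / mean(isi)
}

# Normalized cross-correlogram of two sorted trains: counts per lag bin over
# [-max_lag, +max_lag) divided by the chance level n_a*n_b*bin/T for
# independent Poisson trains of the observed rates (independence -> 1 per bin).
.xcorr_norm <- function(ta, tb, bin_s, max_lag_s, duration_s) {
  counts <- .xcorr_counts(ta, tb, bin_s, max_lag_s)
  chance <- length(ta) * length(tb) * bin_s / duration_s
  counts / chance
}

#' Area under the cross-correlation (AuCC)
#'
#' Pairwise spike-train synchrony. For every unordered pair of active
#' electrodes the normalized cross-correlogram over lags within
#' `[-max_lag_s, +max_lag_s]` (chance level 1 per bin) is integrated as
#' `sum((normalized - 1) * bin_s)`, clipped below at 0; AuCC is the mean over
#' pairs. Independent trains give ~0, perfect synchrony the maximal value.
#'
#' @param rec A [well_recording()].
#' @param bin_s Correlogram bin width in seconds (default 5 ms).
#' @param max_lag_s Maximum lag in seconds (default 100 ms).
#' @param active Active electrode ids; defaults to the 0.1 Hz rule.
#' @param on Correlate `"spikes"` (default) or `"bursts"` (burst start times).
#' @param burst_args Extra arguments for [detect_bursts()] when `on="bursts"`.
#' @return Mean clipped excess area (seconds), or `NA` with < 2 active
#'   electrodes.
#' @export
area_under_cross_correlation <- function(rec, bin_s = 0.005, max_lag_s = 0.1,
                                         active = active_electrodes(rec),
                                         on = c("spikes", "bursts"),
                                         burst_args = list()) {
  on <- match.arg(on)
  .aucc_all(rec, bin_s, max_lag_s, active, on, burst_args)$aucc
}

# One pass over all active-electrode pairs: clipped excess area (AuCC) plus
# the pooled-correlogram summaries used by the extended panel.
.aucc_all <- function(rec, bin_s, max_lag_s, active, on = "spikes",
                      burst_args = list()) {
  na_out <- list(aucc = NA_real_, peak = NA_real_, width = NA_real_,
                 central = NA_real_)
  if (length(active) < 2) return(na_out)
  series <- lapply(rec$trains[active], function(tr) {
    if (on == "spikes") tr$timestamps
    else do.call(detect_bursts,
                 c(list(tr, duration_s = rec$duration_s), burst_args))$start_s
  })
  series <- series[vapply(series, length, integer(1)) > 0]
  if (length(series) < 2) return(na_out)
  pairs <- combn(length(series), 2)
  nbins <- round(2 * max_lag_s / bin_s)
  acc <- numeric(nbins)
  areas <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    norm <- .xcorr_norm(series[[pairs[1, k]]], series[[pairs[2, k]]],
                        bin_s, max_lag_s, rec$duration_s)
    acc <- acc + norm
    areas[k] <- max(0, sum((norm - 1) * bin_s))
  }
  acc <- acc / ncol(pairs)
  central <- acc[nbins %/% 2 + c(0, 1)]
  list(aucc = mean(areas), peak = max(acc) - 1,
       width = sum(acc > 1) * bin_s, central = max(0, mean(central) - 1))
}

#' Network burst detection
#'
#' Intervals where electrode-level bursts overlap on at least
#' `participation_fraction` of the well's active electrodes; adjacent
#' intervals closer than `merge_gap_s` are merged.
#'
#' @param rec A [well_recording()].
#' @param cfg A [scoring_config()] (participation and merge-gap settings).
#' @param bursts Optional precomputed per-electrode burst table (with an
#'   `electrode_id` column); detected on demand otherwise.
#' @return Data frame `start_s, end_s, n_participating, participation`.
#' @export
network_bursts <- function(rec, cfg = scoring_config(), bursts = NULL) {
  active <- active_electrodes(rec, cfg$qc_electrode_rate_hz)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_participating = integer(0), participation = numeric(0))
  if (length(active) == 0) return(empty)
  if (is.null(bursts)) {
    bursts <- do.call(rbind, lapply(rec$trains[active], function(tr)
      detect_bursts(tr, duration_s = rec$duration_s,
                    min_spikes = cfg$burst$min_spikes,
                    rate_hz = cfg$burst$rate_hz,
                    surprise_threshold = cfg$burst$surprise_threshold)))
  } else {
    bursts <- bursts[bursts$electrode_id %in% active, , drop = FALSE]
  }
  if (is.null(bursts) || nrow(bursts) == 0) return(empty)
  need <- max(1L, ceiling(cfg$network$participation_fraction * length(active)))
  # sweep line over burst start/end events, one concurrent-count profile;
  # an electrode bursting twice inside a window still counts once because its
  # bursts never overlap on the same electrode
  ev_t <- c(bursts$start_s, bursts$end_s)
  ev_d <- rep(c(1L, -1L), each = nrow(bursts))
  ord <- order(ev_t, -ev_d)
  ev_t <- ev_t[ord]; ev_d <- ev_d[ord]
  depth <- cumsum(ev_d)
  on <- depth >= need
  if (!any(on)) return(empty)
  starts <- ev_t[which(on & !c(FALSE, on[-length(on)]))]
  ends <- ev_t[which(!on & c(FALSE, on[-length(on)]))]
  if (length(ends) < length(starts)) ends <- c(ends, rec$duration_s)
  # merge windows separated by less than merge_gap_s
  keep_start <- starts[c(TRUE, starts[-1] - ends[-length(ends)] >=
                           cfg$network$merge_gap_s)]
  keep_end <- ends[c(starts[-1] - ends[-length(ends)] >=
                       cfg$network$merge_gap_s, TRUE)]
  part <- vapply(seq_along(keep_start), function(i) {
    inb <- bursts$start_s < keep_end[i] & bursts$end_s > keep_start[i]
    length(unique(bursts$electrode_id[inb]))
  }, integer(1))
  data.frame(start_s = keep_start, end_s = keep_end, n_participating = part,
             participation = part / length(active))
}

#' Firing- and network-cessation flags
#'
#' Compares a treated well against its own baseline. Firing cessation (FS):
#' treated WMFR below `fs_fraction` (default 5%) of baseline WMFR, or treated
#' active-electrode count below the well-QC minimum. Network cessation (NS):
#' the baseline had network bursts and the treated phase has none.
#'
#' @param baseline,treated `well_features` objects from [compute_features()].
#' @param cfg A [scoring_config()].
#' @return Named logical vector `c(firing_cessation=, network_cessation=)`.
#' @export
cessation_flags <- function(baseline, treated, cfg = scoring_config()) {
  if (!isTRUE(baseline$qc_pass))
    stop("cessation_flags requires a QC-passing baseline well")
  qc_min <- floor(cfg$qc_active_fraction * 16) + 1L
  fs <- treated$wmfr_hz < cfg$fs_fraction * baseline$wmfr_hz ||
    treated$n_active_electrodes < qc_min
  base_nb <- baseline$extended[["network_burst_rate_per_min"]]
  trt_nb <- treated$extended[["network_burst_rate_per_min"]]
  ns <- !is.na(base_nb) && base_nb > 0 && (is.na(trt_nb) || trt_nb == 0)
  c(firing_cessation = fs, network_cessation = ns)
}
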