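#' Howe's k-factor for a two-sided normal tolerance interval
#'
#' `k = z[(1+p)/2] * sqrt(nu * (1 + 1/n) / chisq[1-gamma, nu])` with
#' `nu = n - 1`. Decreases toward the standard-normal quantile as n grows;
#' increases in coverage `p` and confidence `gamma`.
#'
#' @param n Sample size (>= 2).
#' @param coverage_p Population proportion to be covered, in (0,1).
#' @param confidence_gamma Confidence level, in (0,1).
#' @return The k-factor.
#' @export
howe_k <- function(n, coverage_p = 0.95, confidence_gamma = 0.95) {
  stopifnot(n >= 2, coverage_p > 0, coverage_p < 1,
            confidence_gamma > 0, confidence_gamma < 1)
  nu <- n - 1
  z <- qnorm((1 + coverage_p) / 2)
  z * sqrt(nu * (1 + 1 / n) / qchisq(1 - confidence_gamma, nu))
}

#' Two-sided statistical tolerance interval
#'
#' An interval claimed, with confidence `gamma`, to contain at least a
#' proportion `p` of the sampled population. The default normal-theory
#' interval is `mean +/- k * sd` with Howe's k-factor. A distribution-free
#' order-statistic interval (Wilks) is available and is auto-selected when a
#' Shapiro-Wilk normality check rejects at alpha = 0.01 (n >= 8).
#'
#' @param samples Numeric sample (n >= 2, finite).
#' @param coverage_p,confidence_gamma Interval levels in (0,1).
#' @param method `"auto"`, `"normal"` or `"nonparametric"`.
#' @return A `tolerance_interval`: `lower, upper, coverage_p,
#'   confidence_gamma, n, k_factor, method`.
#' @export
normal_tolerance_interval <- function(samples, coverage_p = 0.95,
                                      confidence_gamma = 0.95,
                                      method = c("auto", "normal",
                                                 "nonparametric")) {
  method <- match.arg(method)
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n < 2) stop("tolerance interval requires at least 2 observations")
  if (!all(is.finite(samples))) stop("samples must be finite")
  if (method == "auto") {
    method <- "normal"
    # switch to the distribution-free interval only when normality is
    # rejected AND n supports it at the requested levels (r = 1 feasible)
    feasible <- 1 - pbeta(coverage_p, n - 1, 2) >= confidence_gamma
    if (feasible && sd(samples) > 0 &&
        shapiro.test(samples)$p.value < 0.01) method <- "nonparametric"
  }
  k <- howe_k(n, coverage_p, confidence_gamma)
  if (sd(samples) == 0) {
    warning("zero-variance sample: degenerate tolerance interval")
    ti <- list(lower = mean(samples), upper = mean(samples))
    method <- "normal"
  } else if (method == "normal") {
    m <- mean(samples); s <- sd(samples)
    ti <- list(lower = m - k * s, upper = m + k * s)
  } else {
    # narrowest symmetric order-statistic interval [x_(r), x_(n-r+1)]; its
    # coverage is Beta(n - 2r + 1, 2r), so the confidence of covering >= p is
    # 1 - pbeta(p, n - 2r + 1, 2r); falls back to the full range if r = 1 fails
    xs <- sort(samples)
    r_ok <- 0L
    for (r in seq_len(floor(n / 2))) {
      conf <- 1 - pbeta(coverage_p, n - 2 * r + 1, 2 * r)
      if (conf >= confidence_gamma) r_ok <- r else break
    }
    if (r_ok == 0L) {
      warning("sample too small for a distribution-free interval at the ",
              "requested levels; using the sample range")
      ti <- list(lower = xs[1], upper = xs[n])
    } else {
      ti <- list(lower = xs[r_ok], upper = xs[n - r_ok + 1])
    }
  }
  structure(list(lower = ti$lower, upper = ti$upper, coverage_p = coverage_p,
                 confidence_gamma = confidence_gamma, n = n, k_factor = k,
                 method = method),
            class = "tolerance_interval")
}

#' @export
print.tolerance_interval <- function(x, ...) {
  cat(sprintf("<tolerance_interval %s> [%.4g, %.4g] p=%.2f gamma=%.2f n=%d k=%.3f\n",
              x$method, x$lower, x$upper, x$coverage_p, x$confidence_gamma,
              x$n, x$k_factor))
  invisible(x)
}

#' Derive per-parameter zone cutoffs from vehicle and positive-control effects
#'
#' The no-effect zone is the vehicle tolerance interval; per direction, the
#' mild zone runs from the vehicle TI bound to the near bound of the
#' positive-control TI, and the strong zone lies beyond it. When only one
#' direction has a positive control, the other direction's boundary is
#' mirrored about the vehicle mean. A positive-control bound nested inside
#' the vehicle TI collapses that direction's mild zone (with a warning).
#'
#' @param vehicle_dd Per-well vehicle effect sizes.
#' @param positive_up_dd,positive_down_dd Per-well positive-control effect
#'   sizes for the increasing / decreasing direction (either may be NULL).
#' @param parameter Parameter name recorded in the result.
#' @param cfg A [scoring_config()] supplying TI levels.
#' @return A `zone_cutoffs` object with the boundary positions
#'   `strong_down_edge <= mild_down_edge < mild_up_edge <= strong_up_edge`.
#' @export
derive_cutoffs <- function(vehicle_dd, positive_up_dd = NULL,
                           positive_down_dd = NULL, parameter = "",
                           cfg = scoring_config()) {
  vti <- normal_tolerance_interval(vehicle_dd, cfg$ti_coverage,
                                   cfg$ti_confidence)
  center <- mean(vehicle_dd, na.rm = TRUE)
  if (is.null(positive_up_dd) && is.null(positive_down_dd))
    stop("at least one positive-control sample is required")
  up_edge <- if (!is.null(positive_up_dd) && sum(!is.na(positive_up_dd)) >= 2) {
    normal_tolerance_interval(positive_up_dd, cfg$ti_coverage,
                              cfg$ti_confidence)$lower
  } else NA_real_
  down_edge <- if (!is.null(positive_down_dd) &&
                   sum(!is.na(positive_down_dd)) >= 2) {
    normal_tolerance_interval(positive_down_dd, cfg$ti_coverage,
                              cfg$ti_confidence)$upper
  } else NA_real_
  if (is.na(up_edge)) up_edge <- 2 * center - down_edge
  if (is.na(down_edge)) down_edge <- 2 * center - up_edge
  if (up_edge <= vti$upper) {
    warning("positive-control bound nested inside the vehicle interval (",
            parameter, ", up); mild zone collapses")
    up_edge <- vti$upper
  }
  if (down_edge >= vti$lower) {
    warning("positive-control bound nested inside the vehicle interval (",
            parameter, ", down); mild zone collapses")
    down_edge <- vti$lower
  }
  structure(list(parameter = parameter, vehicle_ti = vti,
                 no_effect = c(vti$lower, vti$upper),
                 strong_down_edge = down_edge, mild_down_edge = vti$lower,
                 mild_up_edge = vti$upper, strong_up_edge = up_edge),
            class = "zone_cutoffs")
}

#' @export
print.zone_cutoffs <- function(x, ...) {
  cat(sprintf(
    "<zone_cutoffs %s> strong_down <= %.3g < mild_down <= %.3g < no_effect < %.3g <= mild_up < %.3g <= strong_up\n",
    x$parameter, x$strong_down_edge, x$mild_down_edge, x$mild_up_edge,
    x$strong_up_edge))
  invisible(x)
}

.serialize_cutoffs <- function(cutoffs) {
  lapply(cutoffs, function(z) list(
    parameter = z$parameter, no_effect = z$no_effect,
    strong_down_edge = z$strong_down_edge, mild_down_edge = z$mild_down_edge,
    mild_up_edge = z$mild_up_edge, strong_up_edge = z$strong_up_edge))
}

.rehydrate_cutoffs <- function(raw) {
  out <- lapply(raw, function(z) {
    z$no_effect <- as.numeric(unlist(z$no_effect))
    structure(z, class = "zone_cutoffs")
  })
  names(out) <- vapply(out, function(z) z$parameter, character(1))
  out
}

#' Calibrate the scoring cutoffs from a plate's well-level effects
#'
#' Pools vehicle wells for the no-effect interval and positive-control wells
#' (split by the sign of their condition-mean effect per parameter) for the
#' mild/strong boundaries, for each continuous key parameter.
#'
#' @param wdf Well-level effect table from [well_effects()] (several plates
#'   may be row-bound to pool calibration data).
#' @param cfg A [scoring_config()].
#' @param parameters Parameters to calibrate (default: the four continuous
#'   key parameters).
#' @return Named list of [derive_cutoffs()] results, one per parameter.
#' @export
calibrate_cutoffs <- function(wdf, cfg = scoring_config(),
                              parameters = .key_continuous) {
  out <- list()
  for (p in parameters) {
    sel <- wdf$parameter == p
    veh <- wdf$dd_pct[sel & wdf$role == "vehicle"]
    pos <- wdf[sel & wdf$role == "positive_control", , drop = FALSE]
    if (sum(!is.na(veh)) < 2)
      stop("fewer than 2 vehicle values for parameter ", p)
    if (nrow(pos) == 0)
      stop("no positive-control wells available to calibrate ", p)
    up <- down <- NULL
    for (grp in unique(paste(pos$compound, pos$concentration_um))) {
      gsel <- paste(pos$compound, pos$concentration_um) == grp
      vals <- pos$dd_pct[gsel]
      if (mean(vals, na.rm = TRUE) >= mean(veh, na.rm = TRUE))
        up <- c(up, vals) else down <- c(down, vals)
    }
    out[[p]] <- derive_cutoffs(veh, positive_up_dd = up,
                               positive_down_dd = down, parameter = p,
                               cfg = cfg)
  }
  out
}
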