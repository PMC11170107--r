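#' Baseline-corrected percent change of one parameter
#'
#' Each well serves as its own control:
#' `100 * (treated - baseline) / |baseline|`. Returns `NA` when the baseline
#' value is missing or zero (logged). The cessation flags are pair-level
#' booleans and pass through untransformed.
#'
#' @param baseline,treated `well_features` objects for the two phases of one
#'   well.
#' @param parameter Panel parameter name.
#' @return Percent change (or the flag value for cessation parameters).
#' @export
baseline_pct_change <- function(baseline, treated, parameter) {
  if (parameter %in% .key_flags) return(treated[[parameter]])
  b <- baseline$extended[[parameter]]
  t <- treated$extended[[parameter]]
  if (is.na(b) || is.na(t)) return(NA_real_)
  if (b == 0) {
    message("baseline value of ", parameter, " is zero in well ",
            baseline$well_id, "; percent change undefined")
    return(NA_real_)
  }
  100 * (t - b) / abs(b)
}

#' Vehicle normalization of per-well percent changes
#'
#' Subtracts the same-plate vehicle mean percent change, yielding the
#' vehicle-normalized effect size (the delta-delta percent change):
#' the vehicle wells' own mean is 0 by construction. Division by the vehicle
#' mean is available via `method = "divide"` (ratio re-expressed as % of the
#' vehicle mean change).
#'
#' @param well_changes Numeric per-well percent changes.
#' @param vehicle_changes Same-plate vehicle percent changes (QC-passing
#'   wells).
#' @param method `"subtract"` (default) or `"divide"`.
#' @return Numeric vector of the same length as `well_changes`.
#' @export
vehicle_normalize <- function(well_changes, vehicle_changes,
                              method = c("subtract", "divide")) {
  method <- match.arg(method)
  vehicle_changes <- vehicle_changes[!is.na(vehicle_changes)]
  if (length(vehicle_changes) == 0)
    stop("no QC-passing vehicle wells available for normalization")
  vm <- mean(vehicle_changes)
  if (method == "subtract") well_changes - vm
  else if (vm == 0) stop("vehicle mean change is zero; cannot divide")
  else 100 * well_changes / vm - 100
}

# Exact two-sided rank-sum p-value by complete enumeration over all
# C(n1+n2, n1) group assignments of the pooled midranks (handles ties); falls
# back to the normal approximation with tie correction for combined n > 20.
.combn_cache <- new.env(parent = emptyenv())
.cached_combn <- function(n, k) {
  key <- paste(n, k)
  if (is.null(.combn_cache[[key]])) .combn_cache[[key]] <- combn(n, k)
  .combn_cache[[key]]
}

rank_sum_test <- function(x, y, exact_max_n = 20L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  if (n1 + n2 <= exact_max_n) {
    combs <- .cached_combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[combs], nrow = n1))
    mu <- mean(w_all)
    mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    mu <- n1 * (n1 + n2 + 1) / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sig2 <= 0) return(1)
    z <- (abs(w_obs - mu) - 0.5) / sqrt(sig2)
    min(1, 2 * pnorm(-max(0, z)))
  }
}

#' Aggregate per-well effect sizes into a condition-level effect
#'
#' Mean, SEM and replicate count of the vehicle-normalized effect sizes of
#' one compound/concentration, with a two-sided Wilcoxon-Mann-Whitney p-value
#' against the plate's vehicle values (exact by complete enumeration for
#' combined n <= 20, normal approximation with tie correction above).
#'
#' @param dd Per-well vehicle-normalized percent changes for the condition.
#' @param vehicle_dd Per-well vehicle values on the same plate.
#' @param compound,concentration_um,parameter Metadata carried through.
#' @return An `effect_size` list: `compound, concentration_um, parameter,
#'   dd_pct, sem, n_wells, p_value`.
#' @export
aggregate_condition <- function(dd, vehicle_dd, compound = "",
                                concentration_um = NA_real_, parameter = "") {
  dd <- dd[!is.na(dd)]
  if (length(dd) == 0)
    return(structure(list(compound = compound,
                          concentration_um = concentration_um,
                          parameter = parameter, dd_pct = NA_real_,
                          sem = NA_real_, n_wells = 0L, p_value = NA_real_),
                     class = "effect_size"))
  sem <- if (length(dd) > 1) sd(dd) / sqrt(length(dd)) else 0
  structure(list(compound = compound, concentration_um = concentration_um,
                 parameter = parameter, dd_pct = mean(dd), sem = sem,
                 n_wells = length(dd),
                 p_value = rank_sum_test(dd, vehicle_dd)),
            class = "effect_size")
}

# Pair baseline/treated well_features by well id; baseline must pass QC
# (wells silent only after treatment are kept: silencing is signal).
.pair_features <- function(features) {
  wells <- unique(vapply(features, function(f) f$well_id, character(1)))
  pairs <- list()
  for (w in wells) {
    b <- Filter(function(f) f$well_id == w && f$phase == "baseline", features)
    t <- Filter(function(f) f$well_id == w && f$phase == "treated", features)
    if (length(b) == 1 && length(t) == 1 && isTRUE(b[[1]]$qc_pass))
      pairs[[w]] <- list(baseline = b[[1]], treated = t[[1]])
  }
  pairs
}

#' Per-well effect-size table for a plate
#'
#' Runs baseline correction, cessation flagging and vehicle normalization for
#' every QC-passing well. Wells whose baseline fails QC are dropped; wells
#' failing QC only after treatment are retained (their silencing feeds the
#' FS/NS flags).
#'
#' @param features List of `well_features` (both phases of every well), from
#'   [compute_features()].
#' @param map A [plate_map()].
#' @param cfg A [scoring_config()].
#' @return Data frame: `well, compound, concentration_um, role, parameter,
#'   pct_change, dd_pct` (flags appear as parameters with 0/1 values).
#' @export
well_effects <- function(features, map, cfg = scoring_config()) {
  pairs <- .pair_features(features)
  if (length(pairs) == 0) stop("no QC-passing baseline wells on this plate")
  params <- .panel_well_level
  rows <- list()
  for (w in names(pairs)) {
    b <- pairs[[w]]$baseline; t <- pairs[[w]]$treated
    flags <- cessation_flags(b, t, cfg)
    pc <- vapply(params, function(p) baseline_pct_change(b, t, p), numeric(1))
    mrow <- map[map$well == w, , drop = FALSE]
    if (nrow(mrow) != 1) stop("well ", w, " missing from the plate map")
    rows[[w]] <- data.frame(
      well = w, compound = mrow$compound,
      concentration_um = mrow$concentration_um, role = mrow$role,
      parameter = c(params, .key_flags),
      pct_change = c(pc, as.numeric(flags)),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  # vehicle normalization per parameter (flags stay untransformed)
  df$dd_pct <- NA_real_
  for (p in params) {
    sel <- df$parameter == p
    veh <- df$pct_change[sel & df$role == "vehicle"]
    df$dd_pct[sel] <- vehicle_normalize(df$pct_change[sel], veh,
                                        method = cfg$normalization)
  }
  fsel <- df$parameter %in% .key_flags
  df$dd_pct[fsel] <- df$pct_change[fsel]
  df
}

#' Condition-level effect table
#'
#' Aggregates [well_effects()] rows per (compound, concentration, parameter):
#' mean, SEM, n and rank-sum p-value vs vehicle. The cessation flags are
#' aggregated by majority vote across replicate wells.
#'
#' @param wdf Data frame from [well_effects()].
#' @return Data frame: `compound, concentration_um, parameter, dd_pct, sem,
#'   n_wells, p_value`.
#' @export
condition_effects <- function(wdf) {
  conds <- unique(wdf[wdf$role != "vehicle", c("compound", "concentration_um")])
  rows <- list()
  for (i in seq_len(nrow(conds))) {
    ci <- conds[i, ]
    for (p in unique(wdf$parameter)) {
      sel <- wdf$compound == ci$compound &
        wdf$concentration_um == ci$concentration_um & wdf$parameter == p
      veh <- wdf$dd_pct[wdf$role == "vehicle" & wdf$parameter == p]
      if (p %in% .key_flags) {
        v <- wdf$dd_pct[sel]
        v <- v[!is.na(v)]
        es <- list(compound = ci$compound,
                   concentration_um = ci$concentration_um, parameter = p,
                   dd_pct = as.numeric(mean(v) > 0.5), sem = NA_real_,
                   n_wells = length(v), p_value = NA_real_)
      } else {
        es <- aggregate_condition(wdf$dd_pct[sel], veh, ci$compound,
                                  ci$concentration_um, p)
      }
      rows[[length(rows) + 1L]] <- as.data.frame(unclass(es),
                                                 stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$compound, out$concentration_um, out$parameter), ]
}

#' Write a condition-effect table CSV
#' @param effects Data frame from [condition_effects()].
#' @param path Output path.
#' @export
write_effects <- function(effects, path) {
  write.csv(effects, path, row.names = FALSE, na = "")
  invisible(path)
}
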