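#' Spike train for one electrode
#'
#' @param electrode_id Electrode identifier (opaque string).
#' @param timestamps Numeric spike times in seconds from phase start, strictly
#'   increasing, all within `[0, duration_s]`.
#' @param duration_s Recording duration used to validate the upper bound.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(electrode_id, timestamps, duration_s = NULL) {
  timestamps <- as.numeric(timestamps)
  if (anyNA(timestamps)) stop("spike timestamps must be numeric and non-missing")
  if (is.unsorted(timestamps, strictly = TRUE))
    stop("spike timestamps must be strictly increasing")
  if (length(timestamps) && timestamps[1] < 0)
    stop("spike timestamps must be non-negative")
  if (!is.null(duration_s) && length(timestamps) &&
      timestamps[length(timestamps)] > duration_s)
    stop("spike timestamps exceed recording duration")
  structure(list(electrode_id = as.character(electrode_id),
                 timestamps = timestamps),
            class = "spike_train")
}

#' One well, one phase of an MEA recording
#'
#' A well holds up to 16 physical electrodes; absent electrodes are treated as
#' present with zero spikes for QC denominators (the denominator is fixed at 16).
#'
#' @param well_id Well identifier, e.g. `"A1"`.
#' @param phase `"baseline"` or `"treated"`.
#' @param trains List of [spike_train()] objects.
#' @param duration_s Phase duration in seconds (default 1800 = 30 min).
#' @param plate_id Plate identifier.
#' @return An object of class `well_recording`.
#' @export
well_recording <- function(well_id, phase, trains, duration_s = 1800,
                           plate_id = "plate1") {
  phase <- match.arg(phase, c("baseline", "treated"))
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be a positive real")
  if (length(trains) > 16L)
    stop("a well holds at most 16 electrode trains")
  ids <- vapply(trains, function(tr) tr$electrode_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate electrode ids in well ", well_id)
  names(trains) <- ids
  structure(list(well_id = as.character(well_id), phase = phase,
                 duration_s = duration_s, trains = trains,
                 plate_id = as.character(plate_id)),
            class = "well_recording")
}

#' @export
print.well_recording <- function(x, ...) {
  n <- sum(vapply(x$trains, function(tr) length(tr$timestamps), integer(1)))
  cat(sprintf("<well_recording> %s/%s [%s]: %d electrodes, %d spikes, %.0f s\n",
              x$plate_id, x$well_id, x$phase, length(x$trains), n, x$duration_s))
  invisible(x)
}

# Vendor export dialects map onto the canonical header via this alias table.
.column_aliases <- list(
  well = c("well", "Well"),
  electrode = c("electrode", "Electrode", "electrode_id"),
  phase = c("phase", "Phase"),
  time_s = c("time_s", "Time (s)", "time", "Time..s.", "timestamp_s")
)

.resolve_columns <- function(nms, required) {
  out <- character(0)
  for (canon in names(.column_aliases)) {
    hit <- intersect(.column_aliases[[canon]], nms)
    if (length(hit)) out[canon] <- hit[1]
  }
  missing <- setdiff(required, names(out))
  if (length(missing))
    stop("spike list is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  out
}

#' Read a spike-list CSV into well recordings
#'
#' Expects columns `well, electrode, phase, time_s` (vendor aliases such as
#' `"Time (s)"` and `"Electrode"` are auto-mapped); extra columns are ignored.
#' Returns one [well_recording()] per distinct (well, phase) pair, with
#' within-train timestamps sorted ascending. Exact duplicate
#' (well, electrode, phase, time) rows are collapsed with a warning.
#'
#' @param path CSV file path.
#' @param duration_s Recording duration in seconds for every phase.
#' @param plate_id Plate identifier attached to every recording.
#' @return Named list of `well_recording` objects, keyed `"well.phase"`.
#' @export
read_spike_list <- function(path, duration_s = 1800, plate_id = "plate1") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- .resolve_columns(names(df), c("well", "electrode", "phase", "time_s"))
  if (nrow(df) == 0) return(structure(list(), names = character(0)))
  tm <- suppressWarnings(as.numeric(df[[cols["time_s"]]]))
  bad <- which(is.na(tm) | tm < 0)
  if (length(bad))
    stop("non-numeric or negative spike time at data line ", bad[1] + 1L,
         " of ", path)
  d <- data.frame(well = as.character(df[[cols["well"]]]),
                  electrode = as.character(df[[cols["electrode"]]]),
                  phase = as.character(df[[cols["phase"]]]),
                  time_s = tm, stringsAsFactors = FALSE)
  bad_phase <- setdiff(unique(d$phase), c("baseline", "treated"))
  if (length(bad_phase))
    stop("unknown phase value(s): ", paste(bad_phase, collapse = ", "),
         " (allowed: baseline, treated)")
  ndup <- sum(duplicated(d))
  if (ndup > 0) {
    warning(ndup, " duplicate spike row(s) collapsed")
    d <- unique(d)
  }
  out <- list()
  for (key in unique(paste(d$well, d$phase, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- d[d$well == parts[1] & d$phase == parts[2], ]
    trains <- lapply(split(sub$time_s, sub$electrode), function(tt)
      spike_train(electrode_id = "", sort(tt), duration_s))
    for (eid in names(trains)) trains[[eid]]$electrode_id <- eid
    out[[paste(parts[1], parts[2], sep = ".")]] <-
      well_recording(parts[1], parts[2], unname(trains), duration_s, plate_id)
  }
  out[order(names(out))]
}

#' Write well recordings to a spike-list CSV
#'
#' Inverse of [read_spike_list()]; rows sorted by well, phase, electrode, time.
#' @param recordings List of `well_recording` objects.
#' @param path Output CSV path.
#' @export
write_spike_list <- function(recordings, path) {
  rows <- do.call(rbind, lapply(recordings, function(rec) {
    do.call(rbind, lapply(rec$trains, function(tr) {
      if (!length(tr$timestamps)) return(NULL)
      data.frame(well = rec$well_id, electrode = tr$electrode_id,
                 phase = rec$phase, time_s = tr$timestamps,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(rows)) rows <- data.frame(well = character(0),
                                        electrode = character(0),
                                        phase = character(0),
                                        time_s = numeric(0))
  rows <- rows[order(rows$well, rows$phase, rows$electrode, rows$time_s), ]
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.plate_roles <- c("vehicle", "negative_control", "positive_control", "test")

#' Read a plate-map CSV
#'
#' Columns: `well, role, compound, concentration_uM` (optional
#' `replicate_group`). Roles are validated against
#' vehicle / negative_control / positive_control / test; vehicle wells must
#' have an empty compound and zero concentration.
#'
#' @param path CSV file path.
#' @return A `plate_map` data frame.
#' @export
read_plate_map <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("well", "role", "compound", "concentration_uM")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("plate map is missing column(s): ", paste(missing, collapse = ", "))
  plate_map(well = as.character(df$well), role = as.character(df$role),
            compound = as.character(df$compound),
            concentration_um = suppressWarnings(as.numeric(df$concentration_uM)),
            replicate_group = if ("replicate_group" %in% names(df))
              as.character(df$replicate_group) else NULL)
}

#' Construct a validated plate map
#'
#' @param well,role,compound,concentration_um Per-well vectors.
#' @param replicate_group Optional grouping string; defaults to
#'   `compound@concentration`.
#' @return Data frame of class `plate_map`.
#' @export
plate_map <- function(well, role, compound, concentration_um,
                      replicate_group = NULL) {
  bad <- setdiff(unique(role), .plate_roles)
  if (length(bad))
    stop("unknown plate-map role(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.plate_roles, collapse = ", "), ")")
  if (anyNA(concentration_um) || any(concentration_um < 0))
    stop("concentrations must be non-negative reals")
  compound[is.na(compound)] <- ""
  veh <- role == "vehicle"
  if (any(veh & (compound != "" | concentration_um != 0)))
    stop("vehicle wells must have empty compound and zero concentration")
  if (is.null(replicate_group))
    replicate_group <- ifelse(veh, "vehicle",
                              paste0(compound, "@", concentration_um))
  out <- data.frame(well = well, role = role, compound = compound,
                    concentration_um = concentration_um,
                    replicate_group = replicate_group,
                    stringsAsFactors = FALSE)
  class(out) <- c("plate_map", "data.frame")
  out
}

#' Write a plate map CSV
#' @param map A [plate_map()].
#' @param path Output CSV path.
#' @export
write_plate_map <- function(map, path) {
  df <- data.frame(well = map$well, role = map$role, compound = map$compound,
                   concentration_uM = map$concentration_um,
                   replicate_group = map$replicate_group)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Scoring configuration
#'
#' Bundles every tunable of the pipeline: QC thresholds, burst-detection
#' settings, cross-correlation window, network-burst detector, cessation
#' thresholds, tolerance-interval levels, the scoring matrix, and the root
#' seed. Defaults follow the published QC values (active electrode > 0.1 Hz,
#' active well > 40% active electrodes) and documented package choices
#' elsewhere.
#'
#' @param ... Named overrides of the defaults (nested lists are replaced
#'   field-wise).
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(...) {
  cfg <- list(
    qc_electrode_rate_hz = 0.1,
    qc_active_fraction = 0.40,
    ti_coverage = 0.95,
    ti_confidence = 0.95,
    burst = list(min_spikes = 3L, surprise_threshold = 10, rate_hz = NULL),
    aucc = list(bin_s = 0.005, max_lag_s = 0.1, on = "spikes"),
    network = list(participation_fraction = 0.5, merge_gap_s = 0.1),
    fs_fraction = 0.05,
    normalization = "subtract",
    significance_gate = FALSE,
    fold_window = 30,
    matrix = default_scoring_matrix(),
    cutoffs = NULL,
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(over[[nm]]))) {
      for (sub in names(over[[nm]])) cfg[[nm]][[sub]] <- over[[nm]][[sub]]
    } else cfg[[nm]] <- over[[nm]]
  }
  stopifnot(cfg$ti_coverage > 0, cfg$ti_coverage < 1,
            cfg$ti_confidence > 0, cfg$ti_confidence < 1,
            cfg$qc_active_fraction > 0, cfg$qc_active_fraction < 1)
  class(cfg) <- "scoring_config"
  cfg
}

#' @rdname scoring_config
#' @param cfg A `scoring_config`.
#' @param path JSON file path.
#' @export
write_scoring_config <- function(cfg, path) {
  jsonlite::write_json(.config_to_raw(cfg), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname scoring_config
#' @export
read_scoring_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$matrix)) raw$matrix <- .rehydrate_matrix(raw$matrix)
  if (!is.null(raw$cutoffs)) raw$cutoffs <- .rehydrate_cutoffs(raw$cutoffs)
  do.call(scoring_config, raw)
}

#' Write a hazard report CSV
#'
#' One row per (compound, concentration): total score, label, color, and
#' per-parameter zone and points. Reading the file back reproduces score and
#' label fields exactly.
#'
#' @param results List of `hazard_result` objects or a hazard report data
#'   frame from [score_plate()].
#' @param path Output CSV path.
#' @export
write_report <- function(results, path) {
  df <- as_hazard_report(results)
  if (is.null(df) || nrow(df) == 0)
    stop("cannot write an empty hazard report")
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname write_report
#' @export
as_hazard_report <- function(results) {
  if (is.data.frame(results)) return(results)
  do.call(rbind, lapply(results, function(r) {
    row <- data.frame(compound = r$compound,
                      concentration_um = r$concentration_um,
                      total_score = r$total_score, label = r$label,
                      color = r$color, stringsAsFactors = FALSE)
    for (p in names(r$zones)) {
      row[[paste0(p, "_zone")]] <- r$zones[[p]]
      row[[paste0(p, "_points")]] <- r$points[[p]]
    }
    row$firing_cessation <- r$flags["firing_cessation"]
    row$network_cessation <- r$flags["network_cessation"]
    row
  }))
}
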