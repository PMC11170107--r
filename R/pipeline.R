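#' Compute well_features objects for a list of recordings
#'
#' @param recordings List of [well_recording()] objects.
#' @param cfg A [scoring_config()].
#' @return List of `well_features`.
#' @export
plate_features <- function(recordings, cfg = scoring_config()) {
  lapply(recordings, compute_features, cfg = cfg)
}

#' Run the full in-process pipeline on one plate
#'
#' features -> baseline correction -> vehicle normalization -> condition
#' aggregation -> (optional calibration) -> hazard scoring.
#'
#' @param recordings List of [well_recording()] (both phases per well).
#' @param map A [plate_map()].
#' @param cfg A [scoring_config()]; if `cfg$cutoffs` is `NULL` the cutoffs
#'   are calibrated from this plate's vehicle and positive-control wells.
#' @return List with `features`, `well_effects`, `condition_effects`,
#'   `cutoffs`, `results` (list of `hazard_result`), `report` (data frame).
#' @export
run_pipeline <- function(recordings, map, cfg = scoring_config()) {
  feats <- plate_features(recordings, cfg)
  wdf <- well_effects(feats, map, cfg)
  cdf <- condition_effects(wdf)
  cutoffs <- cfg$cutoffs
  if (is.null(cutoffs)) cutoffs <- calibrate_cutoffs(wdf, cfg)
  cfg$cutoffs <- cutoffs
  results <- score_plate(cdf, cfg)
  list(features = feats, well_effects = wdf, condition_effects = cdf,
       cutoffs = cutoffs, results = results,
       report = score_concentration_series(results))
}

# 31-bit polynomial rolling hash over a character string; manifests only
# need a stable, dependency-free content fingerprint, not a cryptographic
# hash.
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.file_digest <- function(path) {
  if (!file.exists(path)) return(NA_character_)
  .fnv1a(readChar(path, file.info(path)$size, useBytes = TRUE))
}

.config_to_raw <- function(cfg) {
  raw <- unclass(cfg)
  raw$matrix <- .serialize_matrix(raw$matrix)
  if (!is.null(raw$cutoffs) && inherits(raw$cutoffs[[1]], "zone_cutoffs"))
    raw$cutoffs <- .serialize_cutoffs(raw$cutoffs)
  raw
}

.write_manifest <- function(out_dir, stage, cfg, inputs, counts, seed) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("meahazard")),
    seed = seed,
    config_hash = .fnv1a(jsonlite::toJSON(.config_to_raw(cfg),
                                          auto_unbox = TRUE,
                                          digits = NA, null = "null")),
    input_digests = lapply(inputs, .file_digest),
    row_counts = counts)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

# A fully silenced well/phase writes no spike rows, so the file path would
# otherwise lose it; wells on the map missing a phase get an empty recording
# (silencing is signal, not dropout).
.complete_recordings <- function(recs, map, duration_s) {
  for (w in map$well) {
    for (ph in c("baseline", "treated")) {
      key <- paste(w, ph, sep = ".")
      if (is.null(recs[[key]]))
        recs[[key]] <- well_recording(w, ph, list(), duration_s)
    }
  }
  recs
}

.cli_usage <- function() {
  cat("usage: mea <subcommand> [--config PATH] [--seed INT] [--in PATH ...]",
      "[--out DIR] [--matrix PATH]\n",
      "subcommands: simulate features normalize calibrate score select",
      "classify evaluate\n")
}

.parse_flags <- function(args) {
  flags <- list(inputs = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% c("--config", "--seed", "--out", "--matrix", "--duration",
                 "--log-level")) {
      if (i == length(args)) stop("flag ", a, " needs a value")
      flags[[sub("^--", "", a)]] <- args[i + 1L]
      i <- i + 2L
    } else if (a == "--in") {
      flags$inputs <- c(flags$inputs, args[i + 1L])
      i <- i + 2L
    } else stop("unknown flag: ", a)
  }
  flags
}

#' Command-line entry point
#'
#' Orchestrates the pipeline as composable subcommands reading and writing
#' the package's text formats. Precedence: CLI flag > config file > built-in
#' default. Every run writes a manifest (config hash, seed, input digests,
#' package version, row counts) next to its outputs; identical config and
#' seed reproduce byte-identical outputs.
#'
#' Subcommands: `simulate` (spike list + plate map from the default design),
#' `features` (spike list -> feature table), `normalize` (spike list + map ->
#' well and condition effect tables), `calibrate` (well effects -> cutoffs
#' into a config JSON), `score` (condition effects + calibrated config ->
#' hazard report), `select` (labeled feature CSV -> selection report),
#' `classify` (training + query effect CSVs -> direction probabilities),
#' `evaluate` (hazard report + reference labels -> predictivity CSV).
#'
#' @param args Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Exit status, invisibly: 0 on success, 1 on validation failure,
#'   2 on usage error. Designed for
#'   `Rscript -e 'meahazard::mea_cli()' <subcommand> ...`.
#' @export
mea_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) { .cli_usage(); return(invisible(2L)) }
  sub <- args[1]
  known <- c("simulate", "features", "normalize", "calibrate", "score",
             "select", "classify", "evaluate")
  if (!sub %in% known) {
    message("unknown subcommand: ", sub)
    .cli_usage()
    return(invisible(2L))
  }
  status <- tryCatch({
    flags <- .parse_flags(args[-1])
    cfg <- if (!is.null(flags$config)) read_scoring_config(flags$config)
           else scoring_config()
    if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
    if (!is.null(flags$matrix)) cfg$matrix <- read_scoring_matrix(flags$matrix)
    out <- flags$out %||% "."
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    counts <- .cli_dispatch(sub, flags, cfg, out)
    .write_manifest(out, sub, cfg, as.list(setNames(flags$inputs,
                                                    flags$inputs)),
                    counts, cfg$seed)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.cli_dispatch <- function(sub, flags, cfg, out) {
  ins <- flags$inputs
  need <- function(n, what) {
    if (length(ins) < n) stop(sub, " needs ", what, " via --in")
  }
  if (sub == "simulate") {
    design <- simulation_design(
      seed = cfg$seed,
      duration_s = as.numeric(flags$duration %||% 1800))
    plate <- simulate_plate(design)
    write_spike_list(plate$recordings, file.path(out, "spike_list.csv"))
    write_plate_map(plate$map, file.path(out, "plate_map.csv"))
    return(list(recordings = length(plate$recordings),
                wells = nrow(plate$map)))
  }
  if (sub == "features") {
    need(1, "a spike-list CSV")
    recs <- read_spike_list(ins[1],
                            duration_s = as.numeric(flags$duration %||% 1800))
    ft <- features_table(recs, cfg)
    write_features(ft, file.path(out, "features.csv"))
    return(list(rows = nrow(ft)))
  }
  if (sub %in% c("normalize", "calibrate", "score")) {
    need(2, "a spike-list CSV and a plate-map CSV")
    dur <- as.numeric(flags$duration %||% 1800)
    recs <- read_spike_list(ins[1], duration_s = dur)
    map <- read_plate_map(ins[2])
    recs <- .complete_recordings(recs, map, dur)
    feats <- plate_features(recs, cfg)
    wdf <- well_effects(feats, map, cfg)
    if (sub == "normalize") {
      cdf <- condition_effects(wdf)
      write.csv(wdf, file.path(out, "well_effects.csv"), row.names = FALSE,
                na = "")
      write_effects(cdf, file.path(out, "condition_effects.csv"))
      return(list(well_rows = nrow(wdf), condition_rows = nrow(cdf)))
    }
    if (sub == "calibrate") {
      cfg$cutoffs <- calibrate_cutoffs(wdf, cfg)
      write_scoring_config(cfg, file.path(out, "calibrated_config.json"))
      cal <- do.call(rbind, lapply(cfg$cutoffs, function(z)
        data.frame(parameter = z$parameter, ti_lower = z$no_effect[1],
                   ti_upper = z$no_effect[2],
                   strong_down_edge = z$strong_down_edge,
                   strong_up_edge = z$strong_up_edge)))
      write.csv(cal, file.path(out, "calibration.csv"), row.names = FALSE)
      return(list(parameters = length(cfg$cutoffs)))
    }
    if (is.null(cfg$cutoffs))
      stop("no calibrated cutoffs: run the calibrate subcommand first or ",
           "pass a --config with cutoffs")
    cdf <- condition_effects(wdf)
    results <- score_plate(cdf, cfg)
    write_report(results, file.path(out, "hazard_report.csv"))
    return(list(conditions = length(results)))
  }
  if (sub == "select") {
    need(1, "a labeled feature CSV (label column + parameters)")
    df <- read.csv(ins[1], stringsAsFactors = FALSE)
    rep <- lasso_select(df[, setdiff(names(df), "label")], df$label,
                        seed = cfg$seed)
    write_selection_report(rep, file.path(out, "selection_report.csv"))
    return(list(parameters = length(rep$frequency)))
  }
  if (sub == "classify") {
    need(2, "a labeled training CSV and a query CSV")
    tr <- read.csv(ins[1], stringsAsFactors = FALSE)
    qu <- read.csv(ins[2], stringsAsFactors = FALSE)
    model <- fit_direction_model(tr[, setdiff(names(tr), "label")],
                                 tr$label, seed = cfg$seed)
    preds <- predict_direction(model, qu[, model$columns, drop = FALSE])
    if (inherits(preds, "direction_probabilities")) preds <- list(preds)
    pdf <- do.call(rbind, lapply(preds, function(p)
      data.frame(p_inhibitory = p$p_inhibitory,
                 p_excitatory = p$p_excitatory, p_vehicle = p$p_vehicle,
                 predicted = p$predicted)))
    write.csv(cbind(qu[, intersect(c("compound", "concentration_um"),
                                   names(qu)), drop = FALSE], pdf),
              file.path(out, "direction_report.csv"), row.names = FALSE)
    return(list(predictions = nrow(pdf)))
  }
  if (sub == "evaluate") {
    need(2, "a hazard report CSV and a reference-label CSV")
    rep <- evaluate_panel(read_report(ins[1]), read_reference_labels(ins[2]),
                          fold_window = cfg$fold_window)
    mdf <- do.call(rbind, lapply(names(rep$metrics), function(cl) {
      m <- rep$metrics[[cl]]
      data.frame(class = cl, tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 balanced_accuracy = m$balanced_accuracy, ber = m$ber,
                 ppv = m$ppv, npv = m$npv, kappa = m$kappa)
    }))
    write.csv(mdf, file.path(out, "predictivity.csv"), row.names = FALSE)
    return(list(classes = nrow(mdf)))
  }
  stop("unreachable")
}
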