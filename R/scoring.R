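.zone_levels <- c("strong_down", "mild_down", "no_effect", "mild_up",
                  "strong_up")
.label_levels <- c("non-neuroactive", "neuroactive", "hazard", "high hazard")
.label_colors <- c("non-neuroactive" = "green", "neuroactive" = "yellow",
                   "hazard" = "orange", "high hazard" = "red")

#' Default weighted scoring matrix
#'
#' Severity points per zone for the four continuous key parameters (mild = 1,
#' strong = 2, no effect = 0, same magnitude in both directions), fixed points
#' for the binary cessation flags (FS = 3, NS = 2), and score ranges mapping
#' the total to a hazard label: 0 non-neuroactive, 1-2 neuroactive, 3-4
#' hazard, >= 5 high hazard. The matrix is plain data (serializable to JSON):
#' the point values are configuration, not algorithm, and asymmetric
#' direction-specific weights can be dropped in without code change.
#'
#' @return A `scoring_matrix` list.
#' @export
default_scoring_matrix <- function() {
  pts <- c(strong_down = 2, mild_down = 1, no_effect = 0, mild_up = 1,
           strong_up = 2)
  structure(list(
    points = setNames(rep(list(pts), length(.key_continuous)),
                      .key_continuous),
    fs_points = 3, ns_points = 2,
    label_ranges = data.frame(
      min = c(0, 1, 3, 5), max = c(0, 2, 4, Inf),
      label = .label_levels, color = unname(.label_colors),
      stringsAsFactors = FALSE)
  ), class = "scoring_matrix")
}

.serialize_matrix <- function(matrix) {
  m <- unclass(matrix)
  m$points <- lapply(m$points, as.list)
  m$label_ranges$max[!is.finite(m$label_ranges$max)] <- NA
  m
}

.rehydrate_matrix <- function(raw) {
  raw$points <- lapply(raw$points, function(p) unlist(p))
  raw$label_ranges <- as.data.frame(raw$label_ranges,
                                    stringsAsFactors = FALSE)
  raw$label_ranges$max[!is.finite(raw$label_ranges$max) |
                         is.na(raw$label_ranges$max)] <- Inf
  structure(raw, class = "scoring_matrix")
}

#' @rdname default_scoring_matrix
#' @param matrix A `scoring_matrix`.
#' @param path JSON path.
#' @export
write_scoring_matrix <- function(matrix, path) {
  jsonlite::write_json(.serialize_matrix(matrix), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname default_scoring_matrix
#' @export
read_scoring_matrix <- function(path) {
  .rehydrate_matrix(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Assign an effect size to a zone
#'
#' Zones partition the effect axis; a value exactly on a boundary goes to the
#' more severe zone. A missing effect is treated as no effect but annotated
#' not-evaluable (`attr(, "evaluable")`).
#'
#' @param dd_pct Vehicle-normalized percent effect.
#' @param cutoffs A `zone_cutoffs` object from [derive_cutoffs()].
#' @return Zone name, one of `strong_down, mild_down, no_effect, mild_up,
#'   strong_up`.
#' @export
assign_zone <- function(dd_pct, cutoffs) {
  if (is.na(dd_pct))
    return(structure("no_effect", evaluable = FALSE))
  z <- if (dd_pct <= cutoffs$strong_down_edge) "strong_down"
  else if (dd_pct <= cutoffs$mild_down_edge) "mild_down"
  else if (dd_pct < cutoffs$mild_up_edge) "no_effect"
  else if (dd_pct < cutoffs$strong_up_edge) "mild_up"
  else "strong_up"
  structure(z, evaluable = TRUE)
}

#' Score one compound/concentration condition
#'
#' Sums the weighted points of the four continuous key parameters' zones and
#' the cessation-flag points, then maps the total through the label ranges.
#'
#' @param effects Named numeric of condition-level effect sizes for the
#'   continuous key parameters (missing entries allowed only if annotated by
#'   an `NA`; an absent key parameter is a contract error). Alternatively a
#'   `condition_effects()` data frame subset for one condition.
#' @param flags Named logical `c(firing_cessation=, network_cessation=)`.
#' @param matrix A `scoring_matrix`.
#' @param cutoffs Named list of `zone_cutoffs`, one per continuous key
#'   parameter.
#' @param compound,concentration_um Metadata carried into the result.
#' @param p_values Optional named p-values; when the config gates points on
#'   significance, a parameter with p >= 0.05 scores 0.
#' @param significance_gate Apply the p-value gate (default FALSE).
#' @return A `hazard_result`.
#' @export
score_condition <- function(effects, flags, matrix = default_scoring_matrix(),
                            cutoffs, compound = "",
                            concentration_um = NA_real_, p_values = NULL,
                            significance_gate = FALSE) {
  if (is.data.frame(effects)) {
    df <- effects
    effects <- setNames(df$dd_pct, df$parameter)[.key_continuous]
    if (is.null(p_values)) p_values <- setNames(df$p_value, df$parameter)
  }
  missing <- setdiff(names(matrix$points), names(effects))
  if (length(missing))
    stop("missing key parameter(s) in effects: ",
         paste(missing, collapse = ", "))
  missing_c <- setdiff(names(matrix$points), names(cutoffs))
  if (length(missing_c))
    stop("no calibrated cutoffs for: ", paste(missing_c, collapse = ", "))
  zones <- points <- list()
  for (p in names(matrix$points)) {
    z <- assign_zone(effects[[p]], cutoffs[[p]])
    pts <- matrix$points[[p]][[as.character(z)]]
    if (significance_gate && !is.null(p_values) &&
        !is.na(p_values[p]) && p_values[p] >= 0.05) pts <- 0
    zones[[p]] <- as.character(z)
    points[[p]] <- pts
  }
  flags <- c(firing_cessation = isTRUE(flags[["firing_cessation"]]),
             network_cessation = isTRUE(flags[["network_cessation"]]))
  total <- sum(unlist(points)) + matrix$fs_points * flags[["firing_cessation"]] +
    matrix$ns_points * flags[["network_cessation"]]
  lr <- matrix$label_ranges
  hit <- which(total >= lr$min & total <= lr$max)
  if (length(hit) != 1)
    stop("label ranges do not uniquely cover total score ", total)
  structure(list(compound = compound, concentration_um = concentration_um,
                 zones = zones, points = points, flags = flags,
                 total_score = total, label = lr$label[hit],
                 color = lr$color[hit]),
            class = "hazard_result")
}

#' @export
print.hazard_result <- function(x, ...) {
  cat(sprintf("<hazard_result> %s @ %g uM: score %g -> %s (%s)\n",
              x$compound, x$concentration_um, x$total_score, x$label, x$color))
  invisible(x)
}

#' Score every condition of a condition-effect table
#'
#' @param effects Data frame from [condition_effects()].
#' @param cfg A [scoring_config()] holding matrix and calibrated cutoffs.
#' @return List of `hazard_result` objects.
#' @export
score_plate <- function(effects, cfg) {
  if (is.null(cfg$cutoffs))
    stop("no calibrated cutoffs in the scoring config; run calibration first")
  conds <- unique(effects[, c("compound", "concentration_um")])
  lapply(seq_len(nrow(conds)), function(i) {
    sel <- effects$compound == conds$compound[i] &
      effects$concentration_um == conds$concentration_um[i]
    sub <- effects[sel, , drop = FALSE]
    flags <- c(
      firing_cessation = isTRUE(sub$dd_pct[sub$parameter ==
                                             "firing_cessation"] > 0),
      network_cessation = isTRUE(sub$dd_pct[sub$parameter ==
                                              "network_cessation"] > 0))
    score_condition(sub[sub$parameter %in% .key_continuous, , drop = FALSE],
                    flags, cfg$matrix, cfg$cutoffs,
                    compound = conds$compound[i],
                    concentration_um = conds$concentration_um[i],
                    significance_gate = isTRUE(cfg$significance_gate))
  })
}

#' Order hazard results as a concentration series
#'
#' @param results List of `hazard_result` for one compound (or a report data
#'   frame).
#' @param fcmax_um Optional free Cmax; adds a fold-over-fCmax column.
#' @return Data frame sorted by ascending concentration.
#' @export
score_concentration_series <- function(results, fcmax_um = NULL) {
  df <- as_hazard_report(results)
  df <- df[order(df$compound, df$concentration_um), , drop = FALSE]
  if (!is.null(fcmax_um)) df$fold_fcmax <- df$concentration_um / fcmax_um
  rownames(df) <- NULL
  df
}
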