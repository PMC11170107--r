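#' Reference labels for a compound panel
#'
#' @param compound Compound names (one label per compound).
#' @param risk_class One of `no_risk, low_risk, neuroactive,
#'   high_seizure_risk`.
#' @param fcmax_um Free peak plasma concentration (uM), or `NA`.
#' @return A `reference_labels` data frame.
#' @export
reference_labels <- function(compound, risk_class, fcmax_um = NA_real_) {
  allowed <- c("no_risk", "low_risk", "neuroactive", "high_seizure_risk")
  bad <- setdiff(unique(risk_class), allowed)
  if (length(bad))
    stop("unknown risk class(es): ", paste(bad, collapse = ", "))
  if (anyDuplicated(compound)) stop("one label per compound required")
  out <- data.frame(compound = compound, risk_class = risk_class,
                    fcmax_um = fcmax_um, stringsAsFactors = FALSE)
  class(out) <- c("reference_labels", "data.frame")
  out
}

#' @rdname reference_labels
#' @param path CSV path with columns `compound, risk_class, fcmax_um`.
#' @export
read_reference_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  reference_labels(df$compound, df$risk_class,
                   if ("fcmax_um" %in% names(df)) df$fcmax_um else NA_real_)
}

#' Default class -> positive mapping for predictivity evaluation
#'
#' For each evaluated class: which reference risk classes count as true
#' positive and which predicted hazard labels count as predicted positive.
#' The mapping is configuration (the reference partition behind per-class
#' predictivity is policy, not algorithm).
#'
#' @return Named list of `list(truth_positive=, pred_positive=)` rules.
#' @export
default_evaluation_mapping <- function() {
  list(
    high_seizure_risk = list(
      truth_positive = "high_seizure_risk",
      pred_positive = c("hazard", "high hazard")),
    neuroactive = list(
      truth_positive = "neuroactive",
      pred_positive = c("neuroactive", "hazard", "high hazard")),
    low_risk = list(
      truth_positive = c("low_risk", "neuroactive", "high_seizure_risk"),
      pred_positive = c("neuroactive", "hazard", "high hazard"))
  )
}

# Worst (most severe) label per compound over the admissible concentrations.
.worst_label <- function(df, fcmax_um, fold_window) {
  if (!is.na(fcmax_um) && !is.null(fold_window))
    df <- df[df$concentration_um <= fold_window * fcmax_um, , drop = FALSE]
  if (nrow(df) == 0) return(NA_character_)
  .label_levels[max(match(df$label, .label_levels))]
}

#' Evaluate hazard calls against reference risk classes
#'
#' Each compound's predicted label is its worst hazard label over tested
#' concentrations within `fold_window` x fCmax (when fCmax is known; default
#' 30-fold). For every class rule in `mapping`, a one-vs-rest confusion
#' matrix over the evaluated compounds yields [classification_metrics()].
#'
#' @param hazard_results Hazard report data frame (`compound,
#'   concentration_um, label`) or list of `hazard_result` objects.
#' @param labels A [reference_labels()] table.
#' @param mapping Per-class rules; see [default_evaluation_mapping()].
#' @param fold_window Concentration window as fold of fCmax (default 30).
#' @return A `predictivity_report`: per-class `confusion_metrics`, the calls
#'   table, and the compounds excluded for missing labels.
#' @export
evaluate_panel <- function(hazard_results, labels,
                           mapping = default_evaluation_mapping(),
                           fold_window = 30) {
  df <- as_hazard_report(hazard_results)
  common <- intersect(unique(df$compound), labels$compound)
  if (length(common) == 0)
    stop("no compounds in common between hazard results and labels")
  skipped <- setdiff(unique(df$compound), labels$compound)
  if (length(skipped))
    warning("compound(s) without reference label excluded: ",
            paste(skipped, collapse = ", "))
  calls <- do.call(rbind, lapply(common, function(cp) {
    lab <- labels[labels$compound == cp, ]
    data.frame(compound = cp, risk_class = lab$risk_class,
               predicted = .worst_label(df[df$compound == cp, , drop = FALSE],
                                        lab$fcmax_um, fold_window),
               stringsAsFactors = FALSE)
  }))
  calls <- calls[order(calls$compound), ]
  metrics <- lapply(mapping, function(rule) {
    truth <- calls$risk_class %in% rule$truth_positive
    pred <- calls$predicted %in% rule$pred_positive
    tp <- sum(truth & pred); fp <- sum(!truth & pred)
    tn <- sum(!truth & !pred); fn <- sum(truth & !pred)
    if (tp + fn == 0 || tn + fp == 0) {
      # a class absent from the panel: counts reported, ratios undefined
      structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                     sensitivity = NA_real_, specificity = NA_real_,
                     balanced_accuracy = NA_real_, ber = NA_real_,
                     ppv = NA_real_, npv = NA_real_, kappa = NA_real_),
                class = "confusion_metrics")
    } else classification_metrics(tp, fp, tn, fn)
  })
  structure(list(metrics = metrics, calls = calls, excluded = skipped,
                 fold_window = fold_window),
            class = "predictivity_report")
}

#' @export
print.predictivity_report <- function(x, ...) {
  for (cl in names(x$metrics)) {
    m <- x$metrics[[cl]]
    cat(sprintf("%-18s sens %.3f spec %.3f bacc %.3f\n", cl, m$sensitivity,
                m$specificity, m$balanced_accuracy))
  }
  invisible(x)
}
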