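#' Binary classification metrics from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, balanced accuracy
#' `(sensitivity+specificity)/2`, balanced error rate
#' `BER = 0.5*(FP/(TN+FP) + FN/(FN+TP))`, `PPV = TP/(TP+FP)`,
#' `NPV = TN/(TN+FN)` (reported `NA` when their denominators are 0), and
#' Cohen's kappa `2*(TP*TN - FN*FP) / ((TP+FP)*(FP+TN) + (TP+FN)*(FN+TN))`.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A `confusion_metrics` list.
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fp + tn + fn == 0)
    stop("all-zero confusion matrix: metrics undefined")
  if (tp + fn == 0 || tn + fp == 0)
    stop("metrics require tp+fn > 0 and tn+fp > 0")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  bacc <- (sens + spec) / 2
  ber <- 0.5 * (fp / (tn + fp) + fn / (fn + tp))
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  denom <- (tp + fp) * (fp + tn) + (tp + fn) * (fn + tn)
  kappa <- if (denom > 0) 2 * (tp * tn - fn * fp) / denom else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, sensitivity = sens,
                 specificity = spec, balanced_accuracy = bacc, ber = ber,
                 ppv = ppv, npv = npv, kappa = kappa),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(
    "<confusion_metrics> tp=%d fp=%d tn=%d fn=%d | sens %.3f spec %.3f bacc %.3f ber %.3f kappa %.3f\n",
    x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity,
    x$balanced_accuracy, x$ber, x$kappa))
  invisible(x)
}

# Multi-class balanced error rate: mean of per-class error rates (reduces to
# the printed two-class formula when there are two classes).
ber_multiclass <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  mean(vapply(unique(truth), function(cl) {
    sel <- truth == cl
    mean(pred[sel] != cl)
  }, numeric(1)))
}

.stratified_split <- function(y, fraction) {
  idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
    n_tr <- max(1L, round(fraction * length(ix)))
    sample(ix, n_tr)
  }))
  sort(idx)
}

#' Repeated-split LASSO parameter selection with frequency ranking
#'
#' For each repeat: stratified train/test split, penalized (multinomial or
#' binomial) fit with the penalty chosen by cross-validation on the training
#' split, record which parameters carry nonzero coefficients, and evaluate
#' the balanced error rate on the test split. Selection frequency of a
#' parameter is its selection count over the repeats; the retained set keeps
#' parameters at or above the frequency threshold (default 0.5).
#'
#' @param X Numeric matrix or data frame, rows = wells/conditions, columns =
#'   the parameter panel.
#' @param y Class label per row (2 or 3 classes).
#' @param n_repeats Number of split repeats (default 100).
#' @param split_fraction Training fraction (default 0.7, stratified).
#' @param threshold Retention frequency threshold (default 0.5).
#' @param seed Root seed for reproducibility.
#' @param nfolds CV folds for the penalty choice (default 5).
#' @param unpenalized Column names never penalized (always available to the
#'   fit, e.g. timepoint and dose covariates).
#' @return A `selection_report`: per-parameter `frequency`, `retained` set,
#'   per-repeat test `ber`.
#' @export
lasso_select <- function(X, y, n_repeats = 100L, split_fraction = 0.7,
                         threshold = 0.5, seed = 1L, nfolds = 5L,
                         unpenalized = character(0)) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) stop("lasso_select requires at least 2 classes")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  const <- apply(X, 2, function(col) sd(col) == 0)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  pf <- ifelse(colnames(X) %in% unpenalized, 0, 1)
  counts <- setNames(numeric(ncol(X)), colnames(X))
  bers <- numeric(n_repeats)
  set.seed(derive_seed(seed, "lasso_select"))
  for (r in seq_len(n_repeats)) {
    tr <- .stratified_split(y, split_fraction)
    te <- setdiff(seq_along(y), tr)
    cvfit <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr], family = fam,
                               nfolds = nfolds, penalty.factor = pf,
                               standardize = TRUE)
    co <- glmnet::coef.glmnet(cvfit, s = "lambda.min")
    nz <- if (fam == "binomial") {
      rownames(co)[as.vector(co != 0)]
    } else {
      unique(unlist(lapply(co, function(m) rownames(m)[as.vector(m != 0)])))
    }
    nz <- setdiff(nz, "(Intercept)")
    counts[nz] <- counts[nz] + 1
    pred <- predict(cvfit, X[te, , drop = FALSE], s = "lambda.min",
                    type = "class")
    bers[r] <- ber_multiclass(y[te], pred)
  }
  freq <- counts / n_repeats
  structure(list(frequency = sort(freq, decreasing = TRUE),
                 retained = names(freq)[freq >= threshold],
                 ber = bers, threshold = threshold, n_repeats = n_repeats),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d repeats, mean test BER %.3f\n",
              x$n_repeats, mean(x$ber)))
  cat("retained (freq >=", x$threshold, "):",
      paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname lasso_select
#' @param report A `selection_report`.
#' @param path Output CSV path.
#' @export
write_selection_report <- function(report, path) {
  df <- data.frame(parameter = names(report$frequency),
                   frequency = as.numeric(report$frequency),
                   retained = names(report$frequency) %in% report$retained)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Cross-validated BER of an LDA classifier on a column subset; the stepwise
# workhorse. Deterministic given the fold assignment.
.cv_ber <- function(X, y, cols, folds) {
  preds <- character(length(y))
  for (k in unique(folds)) {
    tr <- folds != k
    Xtr <- X[tr, cols, drop = FALSE]
    keep <- apply(Xtr, 2, function(col) sd(col) > 0)
    if (!any(keep)) {
      lev <- names(which.max(table(y[tr])))
      preds[!tr] <- lev
      next
    }
    fit <- MASS::lda(Xtr[, keep, drop = FALSE], grouping = y[tr])
    preds[!tr] <- as.character(predict(
      fit, X[!tr, cols, drop = FALSE][, keep, drop = FALSE])$class)
  }
  ber_multiclass(y, preds)
}

#' Stepwise parameter reduction on the balanced error rate
#'
#' Greedy forward selection with backward pruning: at each step the candidate
#' whose addition most lowers the cross-validated BER joins the model, then
#' any member whose removal lowers the BER leaves; the search stops when no
#' addition improves. Returns the selected subset and the BER-vs-size trace.
#'
#' @param X Feature matrix/data frame.
#' @param y Class labels.
#' @param candidate_params Columns to search over (default all).
#' @param seed Seed controlling the CV fold assignment.
#' @param nfolds CV folds (default 5).
#' @return A `stepwise_report`: `selected`, `trace` (data frame of step,
#'   n_params, ber).
#' @export
stepwise_reduce <- function(X, y, candidate_params = colnames(X), seed = 1L,
                            nfolds = 5L) {
  X <- as.matrix(X)
  y <- factor(y)
  if (length(candidate_params) == 0) stop("candidate_params must be non-empty")
  set.seed(derive_seed(seed, "stepwise"))
  folds <- integer(length(y))
  for (ix in split(seq_along(y), y))
    folds[ix] <- sample(rep_len(seq_len(nfolds), length(ix)))
  selected <- character(0)
  trace <- list()
  repeat {
    remaining <- setdiff(candidate_params, selected)
    if (length(remaining) == 0) break
    scores <- vapply(remaining, function(p)
      .cv_ber(X, y, c(selected, p), folds), numeric(1))
    best <- names(which.min(scores))
    best_ber <- scores[best]
    cur_ber <- if (length(selected))
      .cv_ber(X, y, selected, folds) else Inf
    if (best_ber >= cur_ber && length(selected) > 0) break
    selected <- c(selected, best)
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(trace) + 1L, n_params = length(selected),
      ber = best_ber, action = paste0("+", best), stringsAsFactors = FALSE)
    # backward pass: drop any member whose removal improves the BER
    if (length(selected) > 2) {
      repeat {
        drops <- vapply(selected, function(p)
          .cv_ber(X, y, setdiff(selected, p), folds), numeric(1))
        if (min(drops) < best_ber - 1e-12) {
          worst <- names(which.min(drops))
          selected <- setdiff(selected, worst)
          best_ber <- min(drops)
          trace[[length(trace) + 1L]] <- data.frame(
            step = length(trace) + 1L, n_params = length(selected),
            ber = best_ber, action = paste0("-", worst),
            stringsAsFactors = FALSE)
        } else break
      }
    }
  }
  structure(list(selected = selected, trace = do.call(rbind, trace)),
            class = "stepwise_report")
}
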