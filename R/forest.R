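# Bagged CART ensemble for effect-direction classification. Implemented in
# the package because the offline environment ships no tree learner; axis-
# aligned Gini splits, unrestricted depth, vote-fraction probabilities.

# Gini impurity decrease for every split position of one ordered feature.
# Returns the best (gain, threshold) or NULL when the feature is constant.
.best_split <- function(x, yint, nclass) {
  ord <- order(x)
  xs <- x[ord]; ys <- yint[ord]
  n <- length(xs)
  valid <- which(xs[-n] < xs[-1])          # split between distinct values
  if (!length(valid)) return(NULL)
  cum <- vapply(seq_len(nclass), function(k) cumsum(ys == k), numeric(n))
  tot <- cum[n, ]
  nl <- valid
  nr <- n - nl
  gl <- 1 - rowSums((cum[valid, , drop = FALSE] / nl)^2)
  right <- sweep(-cum[valid, , drop = FALSE], 2, tot, `+`)
  gr <- 1 - rowSums((right / nr)^2)
  parent <- 1 - sum((tot / n)^2)
  gain <- parent - (nl * gl + nr * gr) / n
  b <- which.max(gain)
  list(gain = gain[b], threshold = (xs[valid[b]] + xs[valid[b] + 1]) / 2)
}

.grow_tree <- function(X, yint, nclass, mtry, min_node = 1L) {
  nodes <- list()
  queue <- list(seq_len(nrow(X)))
  node_of <- integer(0)
  make_leaf <- function(rows) {
    counts <- tabulate(yint[rows], nclass)
    list(leaf = TRUE, pred = which.max(counts))
  }
  process <- function(rows) {
    if (length(rows) <= min_node || length(unique(yint[rows])) == 1)
      return(make_leaf(rows))
    feats <- sample.int(ncol(X), mtry)
    best <- NULL
    for (f in feats) {
      sp <- .best_split(X[rows, f], yint[rows], nclass)
      if (!is.null(sp) && (is.null(best) || sp$gain > best$gain))
        best <- c(sp, feature = f)
    }
    if (is.null(best) || best$gain <= 0) return(make_leaf(rows))
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         rows = rows)
  }
  # breadth-first growth; children indices patched in as they are created
  i <- 0L
  while (i < length(queue)) {
    i <- i + 1L
    res <- process(queue[[i]])
    if (res$leaf) {
      nodes[[i]] <- res
    } else {
      left_rows <- res$rows[X[res$rows, res$feature] <= res$threshold]
      right_rows <- setdiff(res$rows, left_rows)
      queue[[length(queue) + 1L]] <- left_rows
      li <- length(queue)
      queue[[length(queue) + 1L]] <- right_rows
      ri <- length(queue)
      nodes[[i]] <- list(leaf = FALSE, feature = res$feature,
                         threshold = res$threshold, left = li, right = ri)
    }
  }
  nodes
}

.predict_tree <- function(nodes, X) {
  out <- integer(nrow(X))
  assign_node <- rep(1L, nrow(X))
  todo <- unique(assign_node)
  while (length(todo)) {
    nxt <- integer(0)
    for (ni in todo) {
      rows <- which(assign_node == ni)
      nd <- nodes[[ni]]
      if (nd$leaf) {
        out[rows] <- nd$pred
      } else {
        go_left <- X[rows, nd$feature] <= nd$threshold
        assign_node[rows[go_left]] <- nd$left
        assign_node[rows[!go_left]] <- nd$right
        nxt <- c(nxt, nd$left, nd$right)
      }
    }
    todo <- unique(nxt)
  }
  out
}

.direction_levels <- c("inhibitory", "excitatory", "vehicle")

#' Fit the effect-direction classifier
#'
#' Bagged decision-tree ensemble over the vehicle-normalized effect panel,
#' classifying a condition as inhibitory, excitatory or vehicle-like.
#' Trees are grown to purity on bootstrap resamples with `mtry` features per
#' split; class probabilities are out-of-forest vote fractions. Out-of-bag
#' accuracy is computed during the fit.
#'
#' @param X Numeric matrix/data frame of effect sizes (rows = conditions,
#'   columns = parameter panel).
#' @param y Labels; all of `inhibitory`, `excitatory`, `vehicle` must be
#'   present.
#' @param n_trees Ensemble size (default 500).
#' @param mtry Features tried per split (default `floor(sqrt(p))`).
#' @param seed Seed; the same seed and data give identical forests.
#' @return A `direction_model` with elements `trees`, `levels`, `columns`,
#'   `oob_accuracy`.
#' @export
fit_direction_model <- function(X, y, n_trees = 500L, mtry = NULL,
                                seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  missing <- setdiff(.direction_levels, unique(y))
  if (length(missing))
    stop("training data is missing class(es): ",
         paste(missing, collapse = ", "))
  yint <- match(y, .direction_levels)
  if (anyNA(yint))
    stop("unknown label(s): ",
         paste(setdiff(unique(y), .direction_levels), collapse = ", "))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(derive_seed(seed, "direction_forest"))
  n <- nrow(X)
  trees <- vector("list", n_trees)
  oob_votes <- matrix(0, n, length(.direction_levels))
  for (b in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- list(
      nodes = .grow_tree(X[boot, , drop = FALSE], yint[boot],
                         length(.direction_levels), mtry),
      oob = setdiff(seq_len(n), boot))
    oob <- trees[[b]]$oob
    if (length(oob)) {
      p <- .predict_tree(trees[[b]]$nodes, X[oob, , drop = FALSE])
      oob_votes[cbind(oob, p)] <- oob_votes[cbind(oob, p)] + 1
    }
  }
  voted <- rowSums(oob_votes) > 0
  oob_pred <- max.col(oob_votes[voted, , drop = FALSE], ties.method = "first")
  structure(list(trees = trees, levels = .direction_levels,
                 columns = colnames(X), mtry = mtry, n_trees = n_trees,
                 oob_accuracy = mean(oob_pred == yint[voted])),
            class = "direction_model")
}

#' @export
print.direction_model <- function(x, ...) {
  cat(sprintf("<direction_model> %d trees, mtry %d, OOB accuracy %.3f\n",
              x$n_trees, x$mtry, x$oob_accuracy))
  invisible(x)
}

#' Predict effect direction probabilities
#'
#' @param model A `direction_model` from [fit_direction_model()].
#' @param effects Named numeric vector, one-row matrix or data frame whose
#'   columns match the training columns.
#' @return A `direction_probabilities` list: `p_inhibitory, p_excitatory,
#'   p_vehicle` (vote fractions summing to 1) and `predicted` (argmax label).
#' @export
predict_direction <- function(model, effects) {
  if (is.data.frame(effects)) effects <- as.matrix(effects)
  if (is.null(dim(effects))) {
    if (is.null(names(effects)))
      stop("effects must be named to match the training columns")
    effects <- matrix(effects, nrow = 1,
                      dimnames = list(NULL, names(effects)))
  }
  diff_cols <- c(setdiff(model$columns, colnames(effects)),
                 setdiff(colnames(effects), model$columns))
  if (length(diff_cols))
    stop("effect panel columns do not match the model: ",
         paste(unique(diff_cols), collapse = ", "))
  X <- effects[, model$columns, drop = FALSE]
  votes <- matrix(0, nrow(X), length(model$levels))
  for (tr in model$trees) {
    p <- .predict_tree(tr$nodes, X)
    votes[cbind(seq_len(nrow(X)), p)] <- votes[cbind(seq_len(nrow(X)), p)] + 1
  }
  probs <- votes / length(model$trees)
  res <- lapply(seq_len(nrow(X)), function(i) {
    structure(list(p_inhibitory = probs[i, 1], p_excitatory = probs[i, 2],
                   p_vehicle = probs[i, 3],
                   predicted = model$levels[which.max(probs[i, ])]),
              class = "direction_probabilities")
  })
  if (length(res) == 1) res[[1]] else res
}

#' Persist / restore a direction model
#'
#' The ensemble is written as versioned JSON (plain text); reading restores
#' a model whose predictions are identical to the original's.
#'
#' @param model A `direction_model`.
#' @param path JSON file path.
#' @export
write_direction_model <- function(model, path) {
  payload <- list(
    format = "meahazard_direction_model", version = 1L,
    package_version = as.character(utils::packageVersion("meahazard")),
    levels = model$levels, columns = model$columns, mtry = model$mtry,
    n_trees = model$n_trees, oob_accuracy = model$oob_accuracy,
    trees = lapply(model$trees, function(tr) lapply(tr$nodes, function(nd)
      if (nd$leaf) list(pred = nd$pred)
      else list(feature = nd$feature, threshold = nd$threshold,
                left = nd$left, right = nd$right))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_direction_model
#' @export
read_direction_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(raw$format, "meahazard_direction_model"))
    stop("not a direction-model file: ", path)
  trees <- lapply(raw$trees, function(tr) list(nodes = lapply(tr, function(nd)
    if (!is.null(nd$pred)) list(leaf = TRUE, pred = as.integer(nd$pred))
    else list(leaf = FALSE, feature = as.integer(nd$feature),
              threshold = as.numeric(nd$threshold),
              left = as.integer(nd$left), right = as.integer(nd$right)))))
  structure(list(trees = trees, levels = unlist(raw$levels),
                 columns = unlist(raw$columns), mtry = raw$mtry,
                 n_trees = raw$n_trees, oob_accuracy = raw$oob_accuracy),
            class = "direction_model")
}

#' @export
print.direction_probabilities <- function(x, ...) {
  cat(sprintf(
    "<direction_probabilities> inhibitory %.3f / excitatory %.3f / vehicle %.3f -> %s\n",
    x$p_inhibitory, x$p_excitatory, x$p_vehicle, x$predicted))
  invisible(x)
}
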