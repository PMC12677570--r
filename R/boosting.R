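# Multiclass gradient boosting on symmetric (oblivious) trees.
#
# The model keeps one score per class; each iteration fits a single
# vector-leaved oblivious tree to the negative gradient of the multinomial
# cross-entropy (y - p under softmax) and adds it scaled by the learning
# rate.  Split search is histogram-based over at most `n_threshold_bins`
# quantile borders per feature; the split criterion is the summed squared
# error of gradient vectors around leaf means.

#' Boosting configuration
#'
#' @param learning_rate Step size eta applied to every tree (search range
#'   0.005-0.5; tuned optimum 0.01).
#' @param depth Tree depth d, one shared split per level (range 3-7; tuned
#'   optimum 5).
#' @param iterations Number of boosting rounds M (range 10-100; tuned
#'   optimum 30).
#' @param patience Early-stopping patience in rounds when a validation set
#'   is supplied.
#' @param n_threshold_bins Maximum candidate split borders per feature.
#' @param seed Seed for operations that randomise (fold assignment).
#' @return A `boosting_config` list.
#' @export
boosting_config <- function(learning_rate = 0.01, depth = 5, iterations = 30,
                            patience = 10, n_threshold_bins = 32, seed = 1L) {
  stopifnot(learning_rate > 0, is_count(depth), is_count(iterations),
            is_count(patience), is_count(n_threshold_bins))
  structure(list(learning_rate = learning_rate, depth = as.integer(depth),
                 iterations = as.integer(iterations),
                 patience = as.integer(patience),
                 n_threshold_bins = as.integer(n_threshold_bins),
                 seed = as.integer(seed)),
            class = "boosting_config")
}

#' Row-wise softmax of raw class scores
#'
#' Max-shifted for overflow safety; every output row sums to 1.
#'
#' @param scores Numeric matrix n x K of raw scores.
#' @return Probability matrix n x K.
#' @export
softmax_scores <- function(scores) {
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1)
  if (any(!is.finite(scores))) stopf("scores must be finite")
  m <- apply(scores, 1, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

#' Mean multinomial cross-entropy loss
#'
#' Mean over samples of `-sum_k y_k log p_k`, with probabilities clipped to
#' `[1e-12, 1]`.
#'
#' @param probabilities n x K matrix with rows summing to 1.
#' @param labels One-hot n x K matrix.
#' @return Mean loss (scalar).
#' @export
multinomial_loss <- function(probabilities, labels) {
  if (!identical(dim(probabilities), dim(labels))) {
    stopf("probabilities and labels have mismatched shapes")
  }
  if (any(abs(rowSums(probabilities) - 1) > 1e-9)) {
    stopf("probability rows must sum to 1")
  }
  p <- pmin(pmax(probabilities, 1e-12), 1)
  mean(rowSums(-labels * log(p)))
}

#' Negative gradient of the multinomial loss w.r.t. raw scores
#'
#' Under softmax the negative gradient is simply `y - p`; each row sums to 0.
#'
#' @param labels One-hot n x K matrix.
#' @param probabilities n x K probability matrix.
#' @return Gradient matrix n x K.
#' @export
negative_gradient <- function(labels, probabilities) {
  if (!identical(dim(labels), dim(probabilities))) {
    stopf("labels and probabilities have mismatched shapes")
  }
  labels - probabilities
}

#' RMSE between predicted probabilities and one-hot labels
#'
#' `sqrt(mean over all n x K cells of (y - p)^2)`; the validation criterion
#' used for tuning and early stopping.
#'
#' @param probabilities n x K probability matrix.
#' @param labels One-hot n x K matrix.
#' @return RMSE (scalar).
#' @export
rmse_score <- function(probabilities, labels) {
  if (!identical(dim(probabilities), dim(labels))) {
    stopf("probabilities and labels have mismatched shapes")
  }
  sqrt(mean((labels - probabilities)^2))
}

#' Ordered target encoding of a categorical column
#'
#' Encodes category values using only strictly preceding samples under a
#' fixed permutation, preventing target leakage:
#' `encoded[i] = (sum of preceding same-category targets + a * p) /
#' (count of preceding same-category samples + a)`.
#' The first occurrence of any category encodes to the prior `p`.
#'
#' @param column Categorical values (character or factor).
#' @param targets Numeric per-sample target statistic.
#' @param a Regularization strength (> 0).
#' @param prior Prior `p`; defaults to `mean(targets)`.
#' @param permutation_seed Optional seed; when given, samples are processed
#'   in a seeded random order and results mapped back.  Default uses the
#'   input order as the permutation.
#' @return Numeric vector of encoded values in input order.
#' @export
ordered_target_encode <- function(column, targets, a = 1, prior = NULL,
                                  permutation_seed = NULL) {
  if (length(column) != length(targets)) {
    stopf("column and targets have different lengths")
  }
  if (!is.numeric(a) || length(a) != 1L || a <= 0) stopf("a must be > 0")
  p <- if (is.null(prior)) mean(targets) else prior
  ord <- seq_along(column)
  if (!is.null(permutation_seed)) {
    ord <- with_seed(permutation_seed, sample(length(column)))
  }
  col_o <- as.character(column)[ord]
  tgt_o <- targets[ord]
  enc_o <- numeric(length(col_o))
  sums <- new.env(parent = emptyenv())
  for (i in seq_along(col_o)) {
    key <- col_o[i]
    st <- if (is.null(sums[[key]])) c(0, 0) else sums[[key]]
    enc_o[i] <- (st[1] + a * p) / (st[2] + a)
    sums[[key]] <- st + c(tgt_o[i], 1)
  }
  enc <- numeric(length(col_o))
  enc[ord] <- enc_o
  enc
}

# Candidate split borders: midpoints between consecutive distinct values,
# thinned to at most `bins` evenly spaced quantile borders.
feature_borders <- function(x, bins = 32L) {
  u <- sort(unique(x))
  if (length(u) < 2L) return(numeric(0))
  mid <- (u[-1] + u[-length(u)]) / 2
  if (length(mid) > bins) {
    mid <- mid[unique(round(seq(1, length(mid), length.out = bins)))]
  }
  mid
}

#' Fit one symmetric (oblivious) tree to gradient vectors
#'
#' Greedy level-by-level choice of the single (feature, threshold) pair
#' minimising the summed squared error of gradient vectors around leaf means
#' over all current leaves.  Thresholds are restricted to per-feature
#' quantile borders.  A level with no candidate split anywhere becomes a
#' degenerate all-left split flagged in the result.
#'
#' @param features Numeric matrix n x F.
#' @param gradients Numeric matrix n x K of per-sample gradient vectors.
#' @param depth Tree depth (>= 1).
#' @param bins Maximum threshold candidates per feature.
#' @return A `symmetric_tree` list: `feature` (1-based column index per
#'   level, 0 = degenerate), `threshold`, `leaf_values` (2^depth x K),
#'   `gain`, `degenerate`, `leaf_assignment`.
#' @export
fit_symmetric_tree <- function(features, gradients, depth, bins = 32L) {
  if (nrow(features) < 2L) stopf("need at least 2 samples")
  borders <- lapply(seq_len(ncol(features)),
                    function(j) feature_borders(features[, j], bins))
  codes <- bin_feature_codes(features, borders)
  fit <- fit_oblivious_tree(codes, gradients, as.integer(depth), borders)
  structure(fit, class = "symmetric_tree")
}

one_hot <- function(labels, classes = levels(labels)) {
  labels <- factor(labels, levels = classes)
  y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  y[cbind(seq_along(labels), as.integer(labels))] <- 1
  y
}

#' Fit the boosting model
#'
#' Base scores are log empirical class frequencies (the zero-iteration model
#' reproduces the class prior).  Each round computes softmax probabilities,
#' gradients `y - p`, fits one oblivious tree on the gradients and adds it
#' scaled by the learning rate.  With a validation subset, training stops
#' once validation RMSE fails to improve for `patience` rounds and the
#' best-round ensemble is retained.
#'
#' @param fm A `feature_matrix` (or list with `x` and `labels`).
#' @param cfg A [boosting_config()].
#' @param validation Optional integer vector of row indices held out for
#'   early stopping (excluded from training).
#' @return A `boost_model` with trees, base scores, class list, per-feature
#'   importance (total split gain) and the training loss trace.
#' @export
fit_model <- function(fm, cfg = boosting_config(), validation = NULL) {
  x <- fm$x
  labels <- fm$labels
  classes <- levels(labels)
  if (length(classes) < 2L) stopf("need at least 2 classes")
  n <- nrow(x)
  train <- seq_len(n)
  if (!is.null(validation)) train <- setdiff(train, validation)
  if (!all(classes %in% labels[train])) {
    stopf("every class must be present in the training rows")
  }
  K <- length(classes)
  xt <- x[train, , drop = FALSE]
  yt <- one_hot(labels[train], classes)
  freq <- colMeans(yt)
  base <- log(freq)
  scores <- matrix(base, nrow(xt), K, byrow = TRUE)
  borders <- lapply(seq_len(ncol(xt)),
                    function(j) feature_borders(xt[, j], cfg$n_threshold_bins))
  codes <- bin_feature_codes(xt, borders)

  has_val <- !is.null(validation) && length(validation) > 0
  if (has_val) {
    xv <- x[validation, , drop = FALSE]
    yv <- one_hot(labels[validation], classes)
    val_scores <- matrix(base, nrow(xv), K, byrow = TRUE)
    best_rmse <- Inf
    best_iter <- 0L
    stall <- 0L
  }

  trees <- vector("list", cfg$iterations)
  loss_trace <- numeric(0)
  val_trace <- numeric(0)
  n_trees <- 0L
  for (m in seq_len(cfg$iterations)) {
    p <- softmax_scores(scores)
    g <- yt - p
    fit <- fit_oblivious_tree(codes, g, cfg$depth, borders)
    incr <- fit$leaf_values[fit$leaf_assignment + 1L, , drop = FALSE]
    scores <- scores + cfg$learning_rate * incr
    trees[[m]] <- fit[c("feature", "threshold", "leaf_values", "gain",
                        "degenerate")]
    n_trees <- m
    loss_trace <- c(loss_trace,
                    multinomial_loss(softmax_scores(scores), yt))
    if (has_val) {
      val_scores <- val_scores + cfg$learning_rate *
        predict_oblivious_tree(xv, fit$feature, fit$threshold,
                               fit$leaf_values)
      vr <- rmse_score(softmax_scores(val_scores), yv)
      val_trace <- c(val_trace, vr)
      if (vr < best_rmse - 1e-12) {
        best_rmse <- vr
        best_iter <- m
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
  }
  trees <- trees[seq_len(n_trees)]
  best_iteration <- n_trees
  if (has_val) {
    best_iteration <- best_iter
    trees <- trees[seq_len(best_iter)]
    loss_trace <- loss_trace[seq_len(best_iter)]
  }

  importance <- numeric(ncol(x))
  names(importance) <- colnames(x)
  for (tr in trees) {
    used <- tr$feature > 0
    if (any(used)) {
      agg <- tapply(tr$gain[used], tr$feature[used], sum)
      importance[as.integer(names(agg))] <-
        importance[as.integer(names(agg))] + agg
    }
  }

  structure(list(trees = trees, learning_rate = cfg$learning_rate,
                 classes = classes, base_scores = base,
                 feature_names = colnames(x), config = cfg,
                 importance = importance, loss_trace = loss_trace,
                 validation_rmse = if (has_val) val_trace else NULL,
                 best_iteration = best_iteration),
            class = "boost_model")
}

#' Predict class probabilities
#'
#' Softmax of the base scores plus the learning-rate-scaled sum of tree
#' outputs.  Rows sum to 1; an empty ensemble returns the class-frequency
#' prior for every row.
#'
#' @param model A `boost_model`.
#' @param features A `feature_matrix` or numeric matrix containing every
#'   feature column the model was trained on.
#' @return Probability matrix (rows = samples, columns = classes).
#' @export
predict_proba <- function(model, features) {
  x <- if (inherits(features, "feature_matrix")) features$x else features
  missing <- setdiff(model$feature_names, colnames(x))
  if (length(missing)) stopf("missing feature column: %s", missing[1])
  x <- x[, model$feature_names, drop = FALSE]
  scores <- matrix(model$base_scores, nrow(x), length(model$classes),
                   byrow = TRUE)
  for (tr in model$trees) {
    scores <- scores + model$learning_rate *
      predict_oblivious_tree(x, tr$feature, tr$threshold, tr$leaf_values)
  }
  p <- softmax_scores(scores)
  dimnames(p) <- list(rownames(x), model$classes)
  p
}

#' Predict class labels (argmax, ties to the lowest class index)
#'
#' @inheritParams predict_proba
#' @return Factor of predicted classes.
#' @export
predict_class <- function(model, features) {
  p <- predict_proba(model, features)
  factor(model$classes[apply(p, 1, which.max)], levels = model$classes)
}

# Stratified fold assignment: per class, a seeded shuffle is dealt
# round-robin over folds.  Singleton classes get fold NA (train-only).
stratified_folds <- function(labels, k, seed) {
  fold <- rep(NA_integer_, length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < 2L) next
      idx <- idx[sample(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Out-of-fold prediction outcomes under stratified cross-validation
#'
#' Every sample is predicted exactly once from the fold in which it is held
#' out; a sample is correct iff the argmax probability matches its label.
#' Singleton classes cannot be held out and are marked unevaluated (`NA`).
#'
#' @param fm A `feature_matrix`.
#' @param cfg A [boosting_config()] (no early stopping inside CV; exactly
#'   `iterations` trees per fold).
#' @param folds Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return List: `correct` (named 0/1 vector, `NA` = unevaluated),
#'   `predicted` (factor), `per_class_accuracy`, `fold` assignment.
#' @export
cross_validated_outcomes <- function(fm, cfg = boosting_config(), folds = 10L,
                                     seed = cfg$seed) {
  labels <- fm$labels
  if (any(table(labels) < 2L) && all(table(labels) < 2L)) {
    stopf("every class needs at least 2 members")
  }
  fold <- stratified_folds(labels, folds, derive_seed(seed, "cv-folds"))
  n <- nrow(fm$x)
  correct <- rep(NA_integer_, n)
  predicted <- rep(NA_character_, n)
  for (j in sort(unique(fold[!is.na(fold)]))) {
    test <- which(!is.na(fold) & fold == j)
    if (!length(test)) next
    train_fm <- structure(list(x = fm$x[-test, , drop = FALSE],
                               labels = droplevels(labels[-test])),
                          class = "feature_matrix")
    train_fm$labels <- factor(as.character(train_fm$labels),
                              levels = levels(labels))
    model <- fit_model(train_fm, cfg)
    pred <- predict_class(model, fm$x[test, , drop = FALSE])
    predicted[test] <- as.character(pred)
    correct[test] <- as.integer(pred == labels[test])
  }
  names(correct) <- rownames(fm$x)
  acc <- tapply(correct, labels, function(v) mean(v, na.rm = TRUE))
  list(correct = correct,
       predicted = factor(predicted, levels = levels(labels)),
       per_class_accuracy = acc, fold = fold)
}

#' Exhaustive hyperparameter grid search with early stopping
#'
#' Every (learning rate, depth, iterations) combination is scored by the
#' mean best validation RMSE over stratified k-fold cross-validation with
#' per-fold early stopping.  Ties are broken deterministically toward the
#' smaller learning rate, then depth, then iteration count.
#'
#' @param fm A `feature_matrix`.
#' @param grid List with elements `learning_rate`, `depth`, `iterations`.
#' @param folds k for the stratified CV (default 5; lowered with a warning
#'   when the smallest class has fewer members).
#' @param patience Early-stopping patience.
#' @param seed Seed for fold assignment.
#' @return List: `best` (a `boosting_config`), `table` (per-candidate mean
#'   validation RMSE and mean stopping round), `folds` used.
#' @export
grid_search <- function(fm, grid, folds = 5L, patience = 10L, seed = 1L) {
  if (!length(grid$learning_rate) || !length(grid$depth) ||
      !length(grid$iterations)) {
    stopf("empty grid")
  }
  min_class <- min(table(fm$labels))
  if (min_class < folds) {
    warnf("smallest class has %d members; lowering folds from %d", min_class,
          folds)
    folds <- max(2L, min_class)
  }
  fold <- stratified_folds(fm$labels, folds, derive_seed(seed, "grid-folds"))
  cand <- expand.grid(learning_rate = grid$learning_rate, depth = grid$depth,
                      iterations = grid$iterations, KEEP.OUT.ATTRS = FALSE)
  rmse <- numeric(nrow(cand))
  stop_round <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cfg <- boosting_config(learning_rate = cand$learning_rate[i],
                           depth = cand$depth[i],
                           iterations = cand$iterations[i],
                           patience = patience, seed = seed)
    per_fold <- vapply(sort(unique(fold[!is.na(fold)])), function(j) {
      val <- which(!is.na(fold) & fold == j)
      model <- fit_model(fm, cfg, validation = val)
      c(min(model$validation_rmse), model$best_iteration)
    }, numeric(2))
    rmse[i] <- mean(per_fold[1, ])
    stop_round[i] <- mean(per_fold[2, ])
  }
  tab <- cbind(cand, mean_val_rmse = rmse, mean_stop_round = stop_round)
  ord <- order(rmse, cand$learning_rate, cand$depth, cand$iterations)
  best_row <- ord[1]
  best <- boosting_config(learning_rate = cand$learning_rate[best_row],
                          depth = cand$depth[best_row],
                          iterations = cand$iterations[best_row],
                          patience = patience, seed = seed)
  list(best = best, table = tab, folds = folds)
}

#' Serialize a boosting model to a versioned JSON file
#'
#' Numbers are written at full precision so that a reloaded model reproduces
#' predictions bit-exactly.
#'
#' @param model A `boost_model`.
#' @param path Output path.
#' @export
write_boost_model <- function(model, path) {
  payload <- list(
    format = "regionboost-model", version = 1L,
    learning_rate = model$learning_rate, classes = model$classes,
    base_scores = model$base_scores, feature_names = model$feature_names,
    best_iteration = model$best_iteration,
    config = unclass(model$config),
    trees = lapply(model$trees, function(tr) {
      list(feature = tr$feature, threshold = tr$threshold,
           leaf_values = tr$leaf_values, gain = tr$gain,
           degenerate = tr$degenerate)
    }))
  # na = "string" keeps degenerate +Inf thresholds representable
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       always_decimal = FALSE, na = "string")
  invisible(path)
}

#' Load a boosting model written by [write_boost_model()]
#'
#' @param path Path to the JSON model file.
#' @return A `boost_model`.
#' @export
read_boost_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "regionboost-model")) {
    stopf("not a regionboost model file: %s", path)
  }
  trees <- lapply(seq_len(if (is.data.frame(j$trees)) nrow(j$trees) else
    length(j$trees)), function(i) {
      tr <- if (is.data.frame(j$trees)) lapply(j$trees, `[[`, i) else
        j$trees[[i]]
      lv <- tr$leaf_values
      if (!is.matrix(lv)) lv <- do.call(rbind, lv)
      list(feature = as.integer(unlist(tr$feature)),
           threshold = as.numeric(unlist(tr$threshold)),
           leaf_values = lv, gain = as.numeric(unlist(tr$gain)),
           degenerate = as.logical(unlist(tr$degenerate)))
    })
  cfg <- boosting_config(learning_rate = j$config$learning_rate,
                         depth = j$config$depth,
                         iterations = j$config$iterations,
                         patience = j$config$patience,
                         n_threshold_bins = j$config$n_threshold_bins,
                         seed = j$config$seed)
  structure(list(trees = trees, learning_rate = j$learning_rate,
                 classes = j$classes, base_scores = j$base_scores,
                 feature_names = j$feature_names, config = cfg,
                 importance = NULL, loss_trace = NULL,
                 validation_rmse = NULL,
                 best_iteration = j$best_iteration),
            class = "boost_model")
}
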