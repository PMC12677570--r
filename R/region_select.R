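# Informative region selection: random window subsets are drawn repeatedly,
# a classifier is cross-validated on each subset, and every (trial, sample)
# outcome is recorded.  A window is informative for a cancer type when its
# inclusion in the trial subset is enriched among correct predictions of
# that type (one-sided Fisher's exact test, BH FDR across windows).

#' Selection configuration
#'
#' @param subset_sizes Window counts drawn per trial (default
#'   `c(25, 50, 100, 150, 200)`).
#' @param repeats Trials per subset size (default 1000).
#' @param q_threshold BH q-value cutoff for significance (default 0.05).
#' @param folds Cross-validation folds per trial (default 10).
#' @param model_cfg Classifier settings used inside every trial (default:
#'   the tuned learning rate 0.01, depth 5, 30 iterations).
#' @param seed Base seed; every trial draws from a stream addressed by
#'   (size, repeat), so results are reproducible and order-independent.
#' @return A `selection_config` list.
#' @export
selection_config <- function(subset_sizes = c(25, 50, 100, 150, 200),
                             repeats = 1000L, q_threshold = 0.05,
                             folds = 10L, model_cfg = boosting_config(),
                             seed = 1L) {
  stopifnot(all(subset_sizes >= 1), is_count(repeats),
            q_threshold > 0, q_threshold < 1, is_count(folds))
  structure(list(subset_sizes = as.integer(subset_sizes),
                 repeats = as.integer(repeats), q_threshold = q_threshold,
                 folds = as.integer(folds), model_cfg = model_cfg,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Run the random-subset classification trials
#'
#' For each subset size and repeat, draws that many window columns uniformly
#' without replacement, restricts the feature matrix, and records every
#' sample's out-of-fold 0/1 correctness under [cross_validated_outcomes()].
#'
#' @param fm A `feature_matrix` (window columns are sampled; chromatin
#'   columns are ignored).
#' @param cfg A [selection_config()].
#' @return A `trial_ledger`: `subsets` (list of sorted window-column index
#'   vectors, 0-based into `window_cols`), `sizes`, `correct` (trials x
#'   samples 0/1/NA matrix), `labels`, `window_cols`, `seed`.
#' @export
run_random_subset_trials <- function(fm, cfg = selection_config()) {
  wcols <- fm$window_cols
  W <- length(wcols)
  if (any(cfg$subset_sizes > W)) {
    stopf("subset size exceeds available windows (%d)", W)
  }
  n_trials <- length(cfg$subset_sizes) * cfg$repeats
  subsets <- vector("list", n_trials)
  sizes <- integer(n_trials)
  correct <- matrix(NA_integer_, n_trials, nrow(fm$x),
                    dimnames = list(NULL, rownames(fm$x)))
  t <- 0L
  for (si in seq_along(cfg$subset_sizes)) {
    s <- cfg$subset_sizes[si]
    for (r in seq_len(cfg$repeats)) {
      t <- t + 1L
      draw_seed <- derive_seed(cfg$seed, "subset", s, r)
      idx <- sort(with_seed(draw_seed, sample.int(W, s)))
      sub <- subset_features(fm, wcols[idx])
      out <- cross_validated_outcomes(sub, cfg$model_cfg, folds = cfg$folds,
                                      seed = derive_seed(cfg$seed, "cv", s, r))
      subsets[[t]] <- idx - 1L
      sizes[t] <- s
      correct[t, ] <- out$correct
    }
  }
  structure(list(subsets = subsets, sizes = sizes, correct = correct,
                 labels = fm$labels, window_cols = wcols,
                 seed = cfg$seed),
            class = "trial_ledger")
}

# trials x windows inclusion indicator
inclusion_matrix <- function(ledger) {
  W <- length(ledger$window_cols)
  incl <- matrix(FALSE, length(ledger$subsets), W)
  for (t in seq_along(ledger$subsets)) {
    incl[t, ledger$subsets[[t]] + 1L] <- TRUE
  }
  incl
}

#' Contingency table linking a window's inclusion to prediction correctness
#'
#' Over all (trial, sample) pairs whose sample carries the given class label
#' and was evaluated: `a` = included & correct, `b` = included & incorrect,
#' `c` = excluded & correct, `d` = excluded & incorrect.
#'
#' @param ledger A `trial_ledger`.
#' @param window 0-based window column index.
#' @param class Cancer-type label.
#' @return Named integer vector `c(a, b, c, d)` of class `contingency_table`.
#' @export
build_contingency <- function(ledger, window, class) {
  if (!length(ledger$subsets)) stopf("ledger has no trials")
  cols <- which(as.character(ledger$labels) == class)
  if (!length(cols)) stopf("no samples of class %s", class)
  a <- b <- cc <- d <- 0L
  for (t in seq_along(ledger$subsets)) {
    inc <- window %in% ledger$subsets[[t]]
    outc <- ledger$correct[t, cols]
    outc <- outc[!is.na(outc)]
    ncorr <- sum(outc == 1L)
    nwrong <- length(outc) - ncorr
    if (inc) {
      a <- a + ncorr
      b <- b + nwrong
    } else {
      cc <- cc + ncorr
      d <- d + nwrong
    }
  }
  structure(c(a = a, b = b, c = cc, d = d), class = "contingency_table")
}

#' One-sided Fisher's exact test (enrichment of correctness when included)
#'
#' Upper hypergeometric tail `P(A >= a)` given the table margins, the
#' one-sided alternative that inclusion of the window is associated with
#' correct predictions.
#'
#' @param tab Numeric vector `c(a, b, c, d)` or `contingency_table`.
#' @return p-value in `[0, 1]`.
#' @export
fisher_one_sided <- function(tab) {
  a <- tab[[1]]; b <- tab[[2]]; cc <- tab[[3]]; d <- tab[[4]]
  if (any(c(a, b, cc, d) < 0)) stopf("negative cell count")
  if (a + b + cc + d == 0) stopf("empty contingency table")
  # margins: m correct pairs, n incorrect pairs, k included pairs
  phyper(a - 1, m = a + cc, n = b + d, k = a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

# Sample odds ratio with a 0.5 continuity correction in every cell, used
# only as a deterministic secondary sort key.
odds_ratio_cc <- function(a, b, cc, d) {
  ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
}

#' Rank windows by inclusion-correctness enrichment per cancer type
#'
#' For each class: one Fisher p-value per window (pairs pooled across all
#' subset sizes), BH adjustment across the windows of that class, and a
#' ranking by (p ascending, odds ratio descending, window index ascending).
#' Windows below the significance cutoff are appended after the significant
#' ones in the same order and flagged as fill, so top-s subsets of any size
#' are well defined.
#'
#' @param ledger A `trial_ledger`.
#' @param cfg A [selection_config()] (supplies `q_threshold`).
#' @return A `region_ranking` data.frame: `class`, `window` (0-based index),
#'   `window_col`, `p`, `q`, `odds_ratio`, `significant`, `fill`, `rank`.
#' @export
rank_informative_regions <- function(ledger, cfg = selection_config()) {
  if (!length(ledger$subsets)) stopf("ledger has no trials")
  incl <- inclusion_matrix(ledger)
  labels <- as.character(ledger$labels)
  res <- list()
  for (cl in sort(unique(labels))) {
    cols <- which(labels == cl)
    outc <- ledger$correct[, cols, drop = FALSE]
    corr_t <- rowSums(outc == 1L, na.rm = TRUE)
    eval_t <- rowSums(!is.na(outc))
    a <- as.numeric(crossprod(incl, corr_t))
    ab <- as.numeric(crossprod(incl, eval_t))
    b <- ab - a
    tot_corr <- sum(corr_t)
    tot_eval <- sum(eval_t)
    cc <- tot_corr - a
    d <- (tot_eval - tot_corr) - b
    p <- phyper(a - 1, m = tot_corr, n = tot_eval - tot_corr, k = ab,
                lower.tail = FALSE)
    q <- bh_adjust(p)
    or <- odds_ratio_cc(a, b, cc, d)
    sig <- q < cfg$q_threshold
    ord <- order(!sig, p, -or, seq_along(p))
    df <- data.frame(class = cl, window = ord - 1L,
                     window_col = ledger$window_cols[ord],
                     p = p[ord], q = q[ord], odds_ratio = or[ord],
                     significant = sig[ord], fill = !sig[ord],
                     rank = seq_along(ord), stringsAsFactors = FALSE)
    res[[cl]] <- df
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("region_ranking", "data.frame")
  out
}

#' Top-ranked window columns for one class
#'
#' @param ranking A `region_ranking`.
#' @param class Cancer-type label.
#' @param s Number of windows.
#' @return Character vector of window column names.
#' @export
top_regions <- function(ranking, class, s) {
  sub <- ranking[ranking$class == class, , drop = FALSE]
  if (s > nrow(sub)) stopf("s exceeds available windows")
  sub$window_col[seq_len(s)]
}

#' Accuracy sweep over subset sizes and selection modes
#'
#' For each cancer type and subset size, trains a multiclass model on the
#' chosen feature columns and reports that type's out-of-fold class
#' accuracy.  Modes: `informative` (the type's top-s ranked windows),
#' `random` (s windows drawn uniformly, accuracy averaged over
#' `n_random_draws` draws), `whole` (all windows, independent of size).
#'
#' @param fm A `feature_matrix`.
#' @param ranking A `region_ranking` (required for mode `informative`).
#' @param sizes Subset sizes (default `c(50, 100, 200, 300, 400, 500, 600)`).
#' @param mode One of `"informative"`, `"random"`, `"whole"`.
#' @param cfg A [selection_config()] (model settings, folds, seed).
#' @param n_random_draws Draws averaged in mode `random` (default 100).
#' @return A `sweep_result` data.frame: `mode`, `size`, `class`, `accuracy`.
#' @export
sweep_subset_sizes <- function(fm, ranking = NULL,
                               sizes = c(50, 100, 200, 300, 400, 500, 600),
                               mode = c("informative", "random", "whole"),
                               cfg = selection_config(),
                               n_random_draws = 100L) {
  mode <- match.arg(mode)
  classes <- levels(fm$labels)
  W <- length(fm$window_cols)
  rows <- list()
  cv_acc <- function(sub_fm, seed) {
    out <- cross_validated_outcomes(sub_fm, cfg$model_cfg, folds = cfg$folds,
                                    seed = seed)
    out$per_class_accuracy
  }
  if (mode == "whole") {
    # whole mode is the size-W limiting case of a single random draw, so it
    # shares that seed path and coincides with mode = "random" at s = W
    acc <- cv_acc(subset_features(fm, fm$window_cols),
                  derive_seed(cfg$seed, "sweep-cv", W, 1))
    rows[[1]] <- data.frame(mode = "whole", size = W, class = classes,
                            accuracy = as.numeric(acc[classes]),
                            stringsAsFactors = FALSE)
  } else if (mode == "random") {
    if (any(sizes > W)) stopf("size exceeds available windows (%d)", W)
    for (s in sizes) {
      acc_sum <- setNames(numeric(length(classes)), classes)
      for (r in seq_len(n_random_draws)) {
        idx <- with_seed(derive_seed(cfg$seed, "sweep-random", s, r),
                         sample.int(W, s))
        acc <- cv_acc(subset_features(fm, fm$window_cols[sort(idx)]),
                      derive_seed(cfg$seed, "sweep-cv", s, r))
        acc_sum <- acc_sum + as.numeric(acc[classes])
      }
      rows[[length(rows) + 1L]] <-
        data.frame(mode = "random", size = s, class = classes,
                   accuracy = acc_sum / n_random_draws,
                   stringsAsFactors = FALSE)
    }
  } else {
    if (is.null(ranking)) stopf("mode 'informative' needs a ranking")
    for (s in sizes) {
      for (cl in classes) {
        cols <- top_regions(ranking, cl, s)
        acc <- cv_acc(subset_features(fm, cols),
                      derive_seed(cfg$seed, "sweep-cv", s, cl))
        rows[[length(rows) + 1L]] <-
          data.frame(mode = "informative", size = s, class = cl,
                     accuracy = as.numeric(acc[cl]),
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Backward elimination of chromatin features
#'
#' Repeatedly fits the classifier under k-fold cross-validation on the
#' current chromatin columns, averages each feature's importance (total
#' squared-error split gain across trees and folds), and removes the
#' `ceiling((current - keep) / rounds_remaining)` least important features,
#' so that exactly `keep` features remain after at most `rounds` rounds.
#'
#' @param fm A `feature_matrix` whose chromatin columns are to be pruned
#'   (window columns, if any, are ignored).
#' @param rounds Maximum elimination rounds (default 20).
#' @param folds CV folds per round (default 10).
#' @param keep Number of features to retain (default 20).
#' @param cfg A [boosting_config()].
#' @param seed Seed for fold assignment.
#' @return Data.frame `feature`, `importance`, `rank` for the retained
#'   features, ranked by final-round importance.
#' @export
backward_eliminate_chromatin <- function(fm, rounds = 20L, folds = 10L,
                                         keep = 20L, cfg = boosting_config(),
                                         seed = 1L) {
  feats <- fm$chromatin_cols
  if (!length(feats)) stopf("feature matrix has no chromatin columns")
  cv_importance <- function(cols, round) {
    sub <- subset_features(fm, cols)
    fold <- stratified_folds(sub$labels, folds,
                             derive_seed(seed, "elim-folds", round))
    imp <- setNames(numeric(length(cols)), cols)
    for (j in sort(unique(fold[!is.na(fold)]))) {
      test <- which(!is.na(fold) & fold == j)
      train_fm <- structure(list(x = sub$x[-test, , drop = FALSE],
                                 labels = factor(
                                   as.character(sub$labels[-test]),
                                   levels = levels(sub$labels))),
                            class = "feature_matrix")
      model <- fit_model(train_fm, cfg)
      imp <- imp + model$importance[cols]
    }
    imp / length(unique(fold[!is.na(fold)]))
  }
  if (length(feats) <= keep) {
    warnf("only %d chromatin features; returning all", length(feats))
    imp <- cv_importance(feats, 1L)
    ord <- order(-imp, feats)
    return(data.frame(feature = feats[ord], importance = unname(imp[ord]),
                      rank = seq_along(ord), stringsAsFactors = FALSE))
  }
  imp <- NULL
  for (round in seq_len(rounds)) {
    imp <- cv_importance(feats, round)
    if (length(feats) <= keep) break
    n_remove <- ceiling((length(feats) - keep) / (rounds - round + 1L))
    # remove lowest importance; ties drop the lexicographically later id
    ord <- order(imp, rev(order(feats)))
    drop <- feats[ord][seq_len(n_remove)]
    feats <- setdiff(feats, drop)
  }
  imp <- cv_importance(feats, rounds + 1L)
  ord <- order(-imp, feats)
  data.frame(feature = feats[ord], importance = unname(imp[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Occurrence frequency of each window among correct predictions
#'
#' `count[class, window]` is the number of (trial, sample-of-class) pairs
#' where the sample was predicted correctly and the window was in the
#' trial's subset — the heatmap-style aggregation of which regions recur in
#' subsets that classify a cancer type correctly.  Identical to the `a` cell
#' of [build_contingency()] for every (class, window).
#'
#' @param ledger A `trial_ledger`.
#' @return Numeric matrix classes x windows.
#' @export
region_occurrence_frequency <- function(ledger) {
  if (!length(ledger$subsets)) stopf("ledger has no trials")
  incl <- inclusion_matrix(ledger)
  labels <- as.character(ledger$labels)
  classes <- sort(unique(labels))
  out <- matrix(0, length(classes), length(ledger$window_cols),
                dimnames = list(classes, ledger$window_cols))
  for (cl in classes) {
    cols <- which(labels == cl)
    corr_t <- rowSums(ledger$correct[, cols, drop = FALSE] == 1L, na.rm = TRUE)
    out[cl, ] <- as.numeric(crossprod(incl, corr_t))
  }
  out
}

#' Persist a trial ledger as TSV
#'
#' Columns: trial id, subset size, comma-joined 0-based window indices, and
#' the per-sample correctness string (`0`/`1`, `-` for unevaluated).
#'
#' @param ledger A `trial_ledger`.
#' @param path Output TSV path.
#' @export
write_trial_ledger <- function(ledger, path) {
  outc <- apply(ledger$correct, 1, function(v) {
    paste(ifelse(is.na(v), "-", v), collapse = "")
  })
  df <- data.frame(trial = seq_along(ledger$sizes), size = ledger$sizes,
                   windows = vapply(ledger$subsets, paste,
                                    character(1), collapse = ","),
                   outcomes = outc, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trial ledger written by [write_trial_ledger()]
#'
#' @param path TSV path.
#' @param labels Named class labels of the cohort samples (column order of
#'   the correctness strings).
#' @param window_cols Window column names of the feature space.
#' @return A `trial_ledger`.
#' @export
read_trial_ledger <- function(path, labels, window_cols) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("integer", "integer", "character",
                                  "character"))
  subsets <- lapply(strsplit(df$windows, ","), as.integer)
  correct <- t(vapply(strsplit(df$outcomes, ""), function(ch) {
    v <- suppressWarnings(as.integer(ch))
    v
  }, integer(nchar(df$outcomes[1]))))
  colnames(correct) <- names(labels)
  structure(list(subsets = subsets, sizes = df$size, correct = correct,
                 labels = factor(labels), window_cols = window_cols,
                 seed = NA_integer_),
            class = "trial_ledger")
}
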