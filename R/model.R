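# Classifier training, cross-validation, ensemble blending and greedy
# feature selection. The classifier is pluggable through a trainer
# function: trainer(x, y, seed) must return an object for which
# predict_prob(object, x) yields positive-class probabilities. The default
# trainer is a probability random forest (500 trees, sqrt(p) candidate
# features per split).

#' Positive-class probability of a fitted site classifier
#'
#' @param object A fitted classifier (from a trainer).
#' @param x Feature matrix.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(object, x, ...) UseMethod("predict_prob")

#' @export
predict_prob.site_rf <- function(object, x, ...) {
  x <- as.matrix(x)[, object$features, drop = FALSE]
  p <- predict(object$fit, data = as.data.frame(x),
               num.threads = 1L)$predictions
  as.numeric(p[, "1"])
}

#' Random-forest trainer factory
#'
#' Returns a trainer closure for [fit_site_classifier()], [kfold_cv()] and
#' [m6a_ensemble()]. The forest is a probability forest; training is
#' reproducible for a fixed seed.
#'
#' @param num_trees Number of trees (default 500).
#' @param mtry Candidate features per split; default `floor(sqrt(p))`.
#' @return A function `(x, y, seed)` returning a fitted `site_rf`.
#' @export
rf_trainer <- function(num_trees = 500L, mtry = NULL) {
  force(num_trees); force(mtry)
  function(x, y, seed = 1L) {
    y <- as_binary_labels(y)
    if (length(unique(y)) < 2L) {
      stop("training labels contain a single class", call. = FALSE)
    }
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
    m <- if (is.null(mtry)) max(1L, floor(sqrt(ncol(x)))) else mtry
    df <- data.frame(..y = factor(y, levels = c(0L, 1L)), x,
                     check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = "..y", data = df,
      num.trees = num_trees, mtry = m, probability = TRUE,
      num.threads = 1L, seed = as.integer(seed)
    )
    structure(list(fit = fit, features = colnames(x), seed = seed,
                   num_trees = num_trees, mtry = m),
              class = "site_rf")
  }
}

#' Train the site classifier
#'
#' @param x Feature matrix (n x p, named columns).
#' @param y Binary labels.
#' @param trainer Trainer function (default [rf_trainer()] with 500 trees).
#' @param seed Integer seed.
#' @return Fitted classifier exposing [predict_prob()].
#' @export
fit_site_classifier <- function(x, y, trainer = rf_trainer(), seed = 1L) {
  trainer(x, y, seed)
}

#' Stratified k-fold assignment
#'
#' @param y Binary labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`; within each class the fold
#'   sizes differ by at most 1.
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  y <- as_binary_labels(y)
  fold <- integer(length(y))
  rs <- local({ set.seed(as.integer(seed)); lapply(split(seq_along(y), y), sample) })
  # alternate the fold numbering direction between classes so the remainder
  # rows land on different folds and overall fold sizes differ by at most 1
  dir <- TRUE
  for (idx in rs) {
    ids <- if (dir) seq_len(k) else rev(seq_len(k))
    fold[idx] <- rep_len(ids, length(idx))
    dir <- !dir
  }
  fold
}

#' k-fold cross-validation of a site classifier
#'
#' Stratified folds; every row is predicted exactly once, by a model that
#' never saw it.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param k Folds (default 10).
#' @param seed Integer seed (drives both the fold assignment and each
#'   fold's trainer).
#' @param trainer Trainer function.
#' @return List with `prob` (out-of-fold probabilities), `fold`
#'   (assignments), `auc` (pooled out-of-fold AUC) and `fold_auc`.
#' @export
kfold_cv <- function(x, y, k = 10L, seed = 1L, trainer = rf_trainer()) {
  x <- as.matrix(x)
  yb <- as_binary_labels(y)
  fold <- stratified_folds(yb, k = k, seed = seed)
  prob <- numeric(length(yb))
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    te <- fold == f
    fit <- trainer(x[!te, , drop = FALSE], yb[!te], seed = seed + f)
    prob[te] <- predict_prob(fit, x[te, , drop = FALSE])
    fold_auc[f] <- if (length(unique(yb[te])) == 2L) {
      roc_auc(yb[te], prob[te])$auc
    } else NA_real_
  }
  list(prob = prob, fold = fold, auc = roc_auc(yb, prob)$auc,
       fold_auc = fold_auc)
}

#' Ensemble blend of two probability vectors
#'
#' `P_en = alpha * P_m + (1 - alpha) * P_lnc`: the weighted average of the
#' mRNA-trained and lncRNA-trained model probabilities.
#'
#' @param p_m Probabilities from the mRNA-trained model.
#' @param p_lnc Probabilities from the lncRNA-trained model.
#' @param alpha Blend weight in `[0, 1]` given to the mRNA model.
#' @return Blended probabilities.
#' @export
ensemble_probability <- function(p_m, p_lnc, alpha) {
  stopifnot(length(alpha) == 1L)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (any(p_m < 0 | p_m > 1) || any(p_lnc < 0 | p_lnc > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  alpha * p_m + (1 - alpha) * p_lnc
}

#' Grid search for the ensemble blend weight
#'
#' Evaluates the AUC of the blended probabilities on a validation set for
#' every grid value and returns the maximiser; ties go to the smaller
#' alpha.
#'
#' @param p_m,p_lnc Validation-set probabilities of the two models.
#' @param y_val Validation labels.
#' @param grid Candidate alphas (default 0, 0.1, ..., 1).
#' @return List with `alpha` (selected), `auc` (at the selection) and
#'   `curve` (data frame of alpha vs AUC).
#' @export
select_alpha <- function(p_m, p_lnc, y_val, grid = seq(0, 1, by = 0.1)) {
  if (length(grid) == 0L) stop("empty alpha grid", call. = FALSE)
  grid <- sort(grid)
  aucs <- vapply(grid, function(a) {
    roc_auc(y_val, ensemble_probability(p_m, p_lnc, a))$auc
  }, numeric(1))
  best <- which(aucs == max(aucs))[1]  # grid sorted: first max = smallest alpha
  list(alpha = grid[best], auc = aucs[best],
       curve = data.frame(alpha = grid, auc = aucs))
}

#' Rank features by single-feature cross-validated AUC
#'
#' Each feature is scored by the k-fold CV AUC of the classifier trained on
#' that feature alone; features are returned in descending order of that
#' AUC, with ties broken by catalog (input) order. The ranking is
#' classifier-agnostic; impurity-based importance from a single forest fit
#' is available via `method = "impurity"`.
#'
#' @param x Feature matrix with named columns.
#' @param y Binary labels.
#' @param k CV folds.
#' @param seed Integer seed.
#' @param trainer Trainer function.
#' @param method `"cv_auc"` (default) or `"impurity"`.
#' @return List with `ranked` (feature names, best first) and `score` (the
#'   per-feature criterion, in input order).
#' @export
rank_features <- function(x, y, k = 10L, seed = 1L, trainer = rf_trainer(),
                          method = c("cv_auc", "impurity")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (method == "impurity") {
    y2 <- as_binary_labels(y)
    df <- data.frame(..y = factor(y2, levels = c(0L, 1L)), x,
                     check.names = FALSE)
    fit <- ranger::ranger(dependent.variable.name = "..y", data = df,
                          num.trees = 500L, importance = "impurity",
                          probability = TRUE, num.threads = 1L,
                          seed = as.integer(seed))
    score <- fit$variable.importance[colnames(x)]
  } else {
    score <- vapply(seq_len(ncol(x)), function(j) {
      kfold_cv(x[, j, drop = FALSE], y, k = k, seed = seed,
               trainer = trainer)$auc
    }, numeric(1))
    names(score) <- colnames(x)
  }
  o <- order(-score, seq_along(score))
  list(ranked = colnames(x)[o], score = score)
}

#' Greedy forward feature selection over a ranked list
#'
#' Adds one feature at a time in ranked order, evaluates the k-fold CV AUC
#' of every prefix, and selects the prefix with the highest AUC (ties go to
#' the shortest prefix).
#'
#' @param ranked Feature names, best first (see [rank_features()]).
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param k CV folds.
#' @param seed Integer seed.
#' @param trainer Trainer function.
#' @return List of class `feature_selection` with `ranked`, `auc_curve`
#'   (AUC per prefix size), `n_selected` and `selected` (the chosen
#'   feature names).
#' @export
greedy_forward_selection <- function(ranked, x, y, k = 10L, seed = 1L,
                                     trainer = rf_trainer()) {
  x <- as.matrix(x)
  stopifnot(all(ranked %in% colnames(x)))
  auc_curve <- vapply(seq_along(ranked), function(m) {
    kfold_cv(x[, ranked[seq_len(m)], drop = FALSE], y, k = k, seed = seed,
             trainer = trainer)$auc
  }, numeric(1))
  n_sel <- which.max(auc_curve)  # first maximum = shortest prefix
  structure(list(ranked = ranked, auc_curve = auc_curve,
                 n_selected = n_sel, selected = ranked[seq_len(n_sel)]),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %d of %d features selected (CV AUC %.4f)\n",
              x$n_selected, length(x$ranked), x$auc_curve[x$n_selected]))
  cat("  top features:", paste(head(x$selected, 5), collapse = ", "), "\n")
  invisible(x)
}
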