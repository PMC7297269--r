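# The ensemble predictor: a classifier trained on mRNA sites and one
# trained on lncRNA sites, blended as
#
#   P_en = alpha * P_m + (1 - alpha) * P_lnc,  alpha in [0, 1].
#
# The rationale: single-base m6A data yield far more mRNA than lncRNA
# sites, so the data-rich mRNA model can stabilise the lncRNA model even
# though the two RNA classes show different methylation characteristics.
# The blend weight is chosen by grid search on a validation split carved
# from the lncRNA training data (never on test data).

#' Fit the mRNA/lncRNA ensemble site predictor
#'
#' Trains one classifier on the lncRNA sites and one on the mRNA sites,
#' then selects the blend weight `alpha` of the probability ensemble
#' `P_en = alpha * P_m + (1 - alpha) * P_lnc` by grid search: a validation
#' subset (default the last fifth of a seeded shuffle, stratified) is held
#' out of the lncRNA training data, both models score it, and the grid
#' value maximising validation AUC is kept (ties to the smaller alpha;
#' because the default grid contains 0 and 1, the selected blend is never
#' worse on the validation set than either model alone). The lncRNA model
#' is then refit on the full lncRNA training data.
#'
#' @param x_lnc,y_lnc lncRNA training feature matrix (144 frozen catalog
#'   columns, or any named columns) and binary labels.
#' @param x_m,y_m mRNA training feature matrix and labels.
#' @param alpha Fixed blend weight; when NULL (default) it is selected by
#'   grid search.
#' @param grid Alpha grid (default 0, 0.1, ..., 1).
#' @param validation_fraction Fraction of the lncRNA training data held out
#'   for alpha selection.
#' @param trainer Trainer function (default probability random forest with
#'   500 trees; see [rf_trainer()]).
#' @param seed Integer seed driving the validation split and both model
#'   fits.
#' @param mode,rna_class Optional metadata recorded in the fit.
#' @return Object of class `m6a_ensemble` with components `model_m`,
#'   `model_lnc`, `alpha`, `alpha_curve` (validation AUC per grid value, or
#'   NULL when alpha was fixed), `features` (the frozen training column
#'   names) and `seed`.
#' @examples
#' \donttest{
#' set.seed(7)
#' x_lnc <- matrix(rnorm(200 * 5), 200, dimnames = list(NULL, paste0("f", 1:5)))
#' y_lnc <- rbinom(200, 1, plogis(2 * x_lnc[, 1]))
#' x_m <- matrix(rnorm(400 * 5), 400, dimnames = list(NULL, paste0("f", 1:5)))
#' y_m <- rbinom(400, 1, plogis(2 * x_m[, 1]))
#' fit <- m6a_ensemble(x_lnc, y_lnc, x_m, y_m, seed = 1)
#' coef(fit)
#' }
#' @export
m6a_ensemble <- function(x_lnc, y_lnc, x_m, y_m, alpha = NULL,
                         grid = seq(0, 1, by = 0.1),
                         validation_fraction = 0.2,
                         trainer = rf_trainer(), seed = 1L,
                         mode = NULL, rna_class = "lncRNA") {
  x_lnc <- as.matrix(x_lnc); x_m <- as.matrix(x_m)
  if (!identical(colnames(x_lnc), colnames(x_m))) {
    stop("lncRNA and mRNA feature matrices must share identical columns",
         call. = FALSE)
  }
  y_lnc <- as_binary_labels(y_lnc); y_m <- as_binary_labels(y_m)
  model_m <- trainer(x_m, y_m, seed = seed)
  alpha_curve <- NULL
  selection_auc <- NULL
  if (is.null(alpha)) {
    fold <- stratified_folds(y_lnc, k = max(2L, round(1 / validation_fraction)),
                             seed = seed)
    val <- fold == max(fold)
    if (sum(val) < 2L || length(unique(y_lnc[val])) < 2L) {
      stop("validation split too small for alpha selection", call. = FALSE)
    }
    m_lnc_sub <- trainer(x_lnc[!val, , drop = FALSE], y_lnc[!val], seed = seed)
    p_m <- predict_prob(model_m, x_lnc[val, , drop = FALSE])
    p_lnc <- predict_prob(m_lnc_sub, x_lnc[val, , drop = FALSE])
    sel <- select_alpha(p_m, p_lnc, y_lnc[val], grid = grid)
    alpha <- sel$alpha
    alpha_curve <- sel$curve
    selection_auc <- sel$auc
  } else {
    if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  model_lnc <- trainer(x_lnc, y_lnc, seed = seed)
  structure(list(model_m = model_m, model_lnc = model_lnc, alpha = alpha,
                 alpha_curve = alpha_curve, selection_auc = selection_auc,
                 features = colnames(x_lnc),
                 n_lnc = nrow(x_lnc), n_m = nrow(x_m),
                 mode = mode, rna_class = rna_class, seed = seed),
            class = "m6a_ensemble")
}

check_features <- function(object, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || !identical(colnames(x), object$features)) {
    stop(paste0("feature columns of the new data do not match the catalog ",
                "the ensemble was trained on; refusing to predict"),
         call. = FALSE)
  }
  x
}

#' Predict methylation probabilities from an ensemble fit
#'
#' @param object An `m6a_ensemble` fit.
#' @param newdata Feature matrix with exactly the training columns (the
#'   frozen catalog is enforced; a mismatch is an error, not a reorder).
#' @param type `"prob"` for blended probabilities, `"class"` for binary
#'   calls at `threshold`, `"components"` for a matrix of the member and
#'   blended probabilities.
#' @param alpha Optional override of the fitted blend weight.
#' @param threshold Classification threshold for `type = "class"`; a call
#'   is positive iff probability > threshold.
#' @param ... Unused.
#' @return Numeric vector (prob), integer vector (class) or 3-column matrix
#'   (components).
#' @export
predict.m6a_ensemble <- function(object, newdata,
                                 type = c("prob", "class", "components"),
                                 alpha = NULL, threshold = 0.5, ...) {
  type <- match.arg(type)
  x <- check_features(object, newdata)
  a <- if (is.null(alpha)) object$alpha else alpha
  p_m <- predict_prob(object$model_m, x)
  p_lnc <- predict_prob(object$model_lnc, x)
  p <- ensemble_probability(p_m, p_lnc, a)
  switch(type,
         prob = p,
         class = as.integer(p > threshold),
         components = cbind(p_m = p_m, p_lnc = p_lnc, p_en = p))
}

#' @export
print.m6a_ensemble <- function(x, ...) {
  cat("<m6a_ensemble> blended m6A site predictor\n")
  cat(sprintf("  alpha = %.2f (weight of the mRNA-trained model)\n", x$alpha))
  cat(sprintf("  members: lncRNA model (n = %d), mRNA model (n = %d)\n",
              x$n_lnc, x$n_m))
  cat(sprintf("  features: %d; seed: %d\n", length(x$features), x$seed))
  invisible(x)
}

#' @method summary m6a_ensemble
#' @export
summary.m6a_ensemble <- function(object, ...) {
  cat("Ensemble m6A site predictor\n")
  cat(sprintf("  P_en = %.2f * P_m + %.2f * P_lnc\n",
              object$alpha, 1 - object$alpha))
  if (!is.null(object$mode)) cat(sprintf("  coordinate mode: %s\n", object$mode))
  cat(sprintf("  training sites: %d lncRNA, %d mRNA; %d features\n",
              object$n_lnc, object$n_m, length(object$features)))
  if (!is.null(object$alpha_curve)) {
    cat(sprintf("  alpha grid search (validation AUC at selection: %.4f):\n",
                object$selection_auc))
    print(object$alpha_curve, row.names = FALSE, digits = 4)
  } else {
    cat("  alpha was fixed by the caller (no grid search recorded)\n")
  }
  invisible(object)
}

#' Blend weight of an ensemble fit
#'
#' @param object An `m6a_ensemble`.
#' @param ... Unused.
#' @return Named numeric: the mRNA-model weight `alpha`.
#' @method coef m6a_ensemble
#' @export
coef.m6a_ensemble <- function(object, ...) c(alpha = object$alpha)

#' Plot the alpha grid-search curve
#'
#' Validation AUC of the blended predictor as a function of the blend
#' weight, with the selected alpha marked. Requires a fit whose alpha was
#' grid-searched.
#'
#' @param x An `m6a_ensemble`.
#' @param ... Passed to [plot()].
#' @method plot m6a_ensemble
#' @export
plot.m6a_ensemble <- function(x, ...) {
  if (is.null(x$alpha_curve)) {
    stop("no grid-search curve recorded (alpha was fixed)", call. = FALSE)
  }
  plot(x$alpha_curve$alpha, x$alpha_curve$auc, type = "b",
       xlab = expression(alpha), ylab = "validation AUC",
       main = "Ensemble blend-weight search", ...)
  abline(v = x$alpha, lty = 2)
  invisible(x)
}

#' Serialize an ensemble fit manifest
#'
#' Writes a plain-text manifest of the fit (feature catalog, alpha, seeds,
#' training sizes) used to verify compatibility before prediction on
#' external feature matrices.
#'
#' @param object An `m6a_ensemble`.
#' @param path Output file.
#' @export
write_ensemble_manifest <- function(object, path) {
  lines <- c(
    sprintf("alpha\t%g", object$alpha),
    sprintf("seed\t%d", object$seed),
    sprintf("n_lnc\t%d", object$n_lnc),
    sprintf("n_m\t%d", object$n_m),
    sprintf("mode\t%s", ifelse(is.null(object$mode), "NA", object$mode)),
    sprintf("feature\t%s", object$features)
  )
  writeLines(lines, path)
  invisible(path)
}
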