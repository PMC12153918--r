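#' First derivative of spectral features
#'
#' Adjacent-difference transform `x[i+1] - x[i]` across spectral points,
#' removing per-record baseline offsets; p points become p-1 features.
#'
#' @param spectra Data frame (optionally with a `record_id` column) or
#'   matrix of spectral points in wavelength order.
#' @return Same container type with derivative columns `d001..d<p-1>`.
#' @export
first_derivative <- function(spectra) {
  has_id <- is.data.frame(spectra) && "record_id" %in% colnames(spectra)
  x <- as.matrix(if (has_id) spectra[, setdiff(colnames(spectra), "record_id")]
                 else spectra)
  if (ncol(x) < 2) stop("need at least 2 spectral points")
  d <- x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]
  colnames(d) <- sprintf("d%03d", seq_len(ncol(d)))
  if (has_id)
    cbind(data.frame(record_id = spectra$record_id,
                     stringsAsFactors = FALSE), as.data.frame(d))
  else d
}

# Class factor with numerically ordered levels for numeric labels.
as_class_factor <- function(labels) {
  if (is.factor(labels)) return(labels)
  if (is.numeric(labels)) factor(labels, levels = sort(unique(labels)))
  else as.factor(labels)
}

# Stratified, seeded fold assignment. Every class must have >= folds members.
stratified_folds <- function(labels, folds, seed) {
  y <- as_class_factor(labels)
  counts <- table(y)
  if (any(counts < folds))
    stop("stratification error: class ", names(counts)[which.min(counts)],
         " has fewer members (", min(counts), ") than folds (", folds, ")")
  set.seed(seed)
  assign <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

# k x k confusion matrix, rows = predicted, columns = reference.
build_confusion <- function(predicted, reference, classes) {
  p <- factor(predicted, levels = classes)
  r <- factor(reference, levels = classes)
  m <- table(predicted = p, reference = r)
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(predicted = classes, reference = classes))
}

#' Global accuracy of a confusion matrix
#'
#' @param cm Square count matrix, rows = predicted, columns = reference.
#' @return `sum(diag(cm)) / sum(cm)`.
#' @export
confusion_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) == 0) stop("empty confusion matrix")
  sum(diag(cm)) / sum(cm)
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = trace/total` and expected agreement
#' `p_e = sum(rowsum_i * colsum_i) / total^2`.
#'
#' @param cm Square count matrix, rows = predicted, columns = reference.
#' @return Kappa coefficient in \[-1, 1\].
#' @export
confusion_kappa <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < .Machine$double.eps^0.5)
    stop("kappa undefined: expected agreement is 1 (single-cell matrix)")
  (po - pe) / (1 - pe)
}

# Clip negative PLS-DA indicator scores at zero and renormalize rows to
# probabilities; an all-non-positive row falls back to uniform.
scores_to_probabilities <- function(scores) {
  p <- pmax(scores, 0)
  rs <- rowSums(p)
  zero <- rs <= 0
  if (any(zero)) {
    p[zero, ] <- 1 / ncol(p)
    rs[zero] <- 1
  }
  p / rs
}

# Hard labels from a probability matrix: argmax, ties toward the lowest
# class index (columns must be in class order).
argmax_labels <- function(prob, classes) {
  classes[max.col(prob, ties.method = "first")]
}

# mixOmics requires named predictor columns; supply defaults when absent.
ensure_colnames <- function(x) {
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

fit_one <- function(spec, x, y) {
  if (spec$kind == "plsda") {
    mixOmics::plsda(x, y, ncomp = spec$n_components, scale = TRUE)
  } else if (spec$kind == "random_forest") {
    randomForest::randomForest(x, y, ntree = spec$n_trees, mtry = spec$mtry)
  } else stop("unknown classifier kind: ", spec$kind)
}

predict_prob_one <- function(spec, fit, x, classes) {
  if (spec$kind == "plsda") {
    pr <- stats::predict(fit, x)$predict[, , spec$n_components, drop = FALSE]
    prob <- scores_to_probabilities(matrix(pr, nrow = nrow(x),
                                           dimnames = list(NULL, dimnames(pr)[[2]])))
    prob[, as.character(classes), drop = FALSE]
  } else {
    pr <- stats::predict(fit, x, type = "vote")
    pr[, as.character(classes), drop = FALSE]
  }
}

#' Stratified cross-validation of a classifier specification
#'
#' Assigns seeded stratified folds (per-class fold sizes differ by at most
#' one), scores every record exactly once out-of-fold, and pools the
#' per-fold confusion matrices.
#'
#' @param features Numeric matrix or data frame of predictors.
#' @param labels Class labels (integers 1..k or factor).
#' @param model_spec List: `list(kind = "plsda", n_components = )` or
#'   `list(kind = "random_forest", n_trees = , mtry = )`.
#' @param folds Number of folds (>= 2); default 10.
#' @param seed Integer seed for the fold assignment.
#' @return List with `confusion` (pooled, predicted rows x reference
#'   columns), `accuracy`, `kappa`, `per_fold` (data frame), `fold_assign`,
#'   and `oof_probabilities`.
#' @export
cross_validate <- function(features, labels, model_spec, folds = 10,
                           seed = 1L) {
  stopifnot(folds >= 2)
  x <- ensure_colnames(as.matrix(features))
  y <- as_class_factor(labels)
  classes <- levels(y)
  fold_assign <- stratified_folds(y, folds, seed)
  oof_prob <- matrix(NA_real_, nrow(x), length(classes),
                     dimnames = list(NULL, classes))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_assign != f
    fit <- fit_one(model_spec, x[tr, , drop = FALSE], droplevels(y[tr]))
    prob <- predict_prob_one(model_spec, fit, x[!tr, , drop = FALSE], classes)
    oof_prob[!tr, ] <- prob
    pred <- argmax_labels(prob, classes)
    cmf <- build_confusion(pred, y[!tr], classes)
    per_fold[[f]] <- data.frame(fold = f, n = sum(!tr),
                                accuracy = confusion_accuracy(cmf),
                                kappa = confusion_kappa(cmf))
  }
  pred_all <- argmax_labels(oof_prob, classes)
  cm <- build_confusion(pred_all, y, classes)
  list(confusion = cm,
       accuracy = confusion_accuracy(cm),
       kappa = confusion_kappa(cm),
       per_fold = do.call(rbind, per_fold),
       fold_assign = fold_assign,
       oof_probabilities = oof_prob)
}

#' Fit a PLS-DA herd-state classifier with CV-selected components
#'
#' Partial-least-squares regression of the one-hot class indicator on
#' centered and scaled predictors. The number of components (up to
#' `max_components`, default 30) is chosen to maximize out-of-fold accuracy
#' over seeded stratified folds; each fold is fitted once at the maximum
#' and evaluated at every component count. Predicted indicator scores are
#' clipped at zero and renormalized into membership probabilities.
#'
#' @param features Predictor matrix or data frame.
#' @param labels Class labels.
#' @param max_components Upper bound on PLS components (default 30).
#' @param cv_folds Folds for component selection and reported metrics.
#' @param seed Integer seed.
#' @param feature_space Tag stored on the model (`"fa_traits"` or
#'   `"spectra_first_derivative"`).
#' @return Object of class `milkstate_classifier` with the fitted model,
#'   selected `n_components`, and `cv` metrics (accuracy, kappa, pooled
#'   confusion, per-fold table, per-component selection curve).
#' @export
fit_plsda <- function(features, labels, max_components = 30, cv_folds = 10,
                      seed = 1L, feature_space = "fa_traits") {
  x <- ensure_colnames(as.matrix(features))
  y <- as_class_factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (!all(is.finite(x))) stop("features must be finite")
  classes <- levels(y)
  ncomp_max <- min(max_components, ncol(x))
  fold_assign <- stratified_folds(y, cv_folds, seed)
  oof_scores <- array(NA_real_, c(nrow(x), length(classes), ncomp_max))
  for (f in seq_len(cv_folds)) {
    tr <- fold_assign != f
    fit <- mixOmics::plsda(x[tr, , drop = FALSE], droplevels(y[tr]),
                           ncomp = ncomp_max, scale = TRUE)
    pr <- stats::predict(fit, x[!tr, , drop = FALSE])$predict
    oof_scores[!tr, , ] <- pr[, classes, , drop = FALSE]
  }
  acc_by_ncomp <- vapply(seq_len(ncomp_max), function(nc) {
    pred <- argmax_labels(scores_to_probabilities(oof_scores[, , nc]), classes)
    mean(pred == as.character(y))
  }, numeric(1))
  n_components <- which.max(acc_by_ncomp)
  prob <- scores_to_probabilities(oof_scores[, , n_components])
  colnames(prob) <- classes
  pred <- argmax_labels(prob, classes)
  cm <- build_confusion(pred, y, classes)
  per_fold <- do.call(rbind, lapply(seq_len(cv_folds), function(f) {
    sel <- fold_assign == f
    cmf <- build_confusion(pred[sel], y[sel], classes)
    data.frame(fold = f, n = sum(sel), accuracy = confusion_accuracy(cmf),
               kappa = confusion_kappa(cmf))
  }))
  final <- mixOmics::plsda(x, y, ncomp = n_components, scale = TRUE)
  structure(list(kind = "plsda", feature_space = feature_space,
                 fit = final, classes = classes,
                 n_components = n_components,
                 cv = list(accuracy = confusion_accuracy(cm),
                           kappa = confusion_kappa(cm),
                           confusion = cm, per_fold = per_fold,
                           oof_probabilities = prob,
                           selection = data.frame(
                             n_components = seq_len(ncomp_max),
                             cv_accuracy = acc_by_ncomp))),
            class = "milkstate_classifier")
}

#' Fit a random-forest herd-state classifier with CV-tuned feature count
#'
#' Forest of Gini-split trees (default 500). The number of candidate
#' features per split (`mtry`) is selected by cross-validated accuracy over
#' a grid (default `sqrt(p)`, `p/3`, `p/2`); the out-of-fold confusion
#' matrix of the selected setting is retained. Membership probabilities are
#' tree-vote proportions.
#'
#' @param features Predictor matrix or data frame.
#' @param labels Class labels.
#' @param n_trees Number of trees (default 500).
#' @param mtry_grid Candidate feature counts; default
#'   `floor(c(sqrt(p), p/3, p/2))`.
#' @param cv_folds Folds for tuning and reported metrics.
#' @param seed Integer seed.
#' @param feature_space Tag stored on the model.
#' @return Object of class `milkstate_classifier` with the fitted forest,
#'   selected `mtry`, and `cv` metrics.
#' @export
fit_random_forest <- function(features, labels, n_trees = 500,
                              mtry_grid = NULL, cv_folds = 10, seed = 1L,
                              feature_space = "fa_traits") {
  x <- ensure_colnames(as.matrix(features))
  y <- as_class_factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (!all(is.finite(x))) stop("features must be finite")
  p <- ncol(x)
  if (is.null(mtry_grid))
    mtry_grid <- sort(unique(pmax(1, floor(c(sqrt(p), p / 3, p / 2)))))
  results <- vector("list", length(mtry_grid))
  for (i in seq_along(mtry_grid)) {
    set.seed(seed + i)
    results[[i]] <- cross_validate(
      x, y, list(kind = "random_forest", n_trees = n_trees,
                 mtry = mtry_grid[i]),
      folds = cv_folds, seed = seed)
  }
  acc <- vapply(results, `[[`, numeric(1), "accuracy")
  best <- which.max(acc)
  cvres <- results[[best]]
  set.seed(seed)
  final <- randomForest::randomForest(x, y, ntree = n_trees,
                                      mtry = mtry_grid[best])
  structure(list(kind = "random_forest", feature_space = feature_space,
                 fit = final, classes = levels(y),
                 n_trees = n_trees, mtry = mtry_grid[best],
                 cv = list(accuracy = cvres$accuracy, kappa = cvres$kappa,
                           confusion = cvres$confusion,
                           per_fold = cvres$per_fold,
                           oof_probabilities = cvres$oof_probabilities,
                           selection = data.frame(mtry = mtry_grid,
                                                  cv_accuracy = acc))),
            class = "milkstate_classifier")
}

#' Predict state-membership probabilities and hard labels
#'
#' Random-forest probabilities are the proportions of trees voting for each
#' state; PLS-DA probabilities are clipped-and-renormalized predicted
#' indicator scores. Rows sum to one. The hard label is the argmax with
#' ties broken toward the lowest state index.
#'
#' @param model A fitted `milkstate_classifier`.
#' @param features Predictors in the model's feature space.
#' @return List with `probabilities` (row-stochastic matrix, columns in
#'   class order) and `labels` (integer vector).
#' @export
predict_membership <- function(model, features) {
  x <- ensure_colnames(as.matrix(features))
  spec <- if (model$kind == "plsda")
    list(kind = "plsda", n_components = model$n_components)
  else list(kind = "random_forest", n_trees = model$n_trees,
            mtry = model$mtry)
  if (model$kind == "plsda" && ncol(x) != nrow(model$fit$loadings$X))
    stop("feature-dimension mismatch")
  if (model$kind == "random_forest" &&
      ncol(x) != length(model$fit$forest$ncat))
    stop("feature-dimension mismatch")
  prob <- predict_prob_one(spec, model$fit, x, model$classes)
  labels <- as.integer(argmax_labels(prob, model$classes))
  list(probabilities = prob, labels = labels)
}
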