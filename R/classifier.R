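## Two-feature (theta relative power, microstate complexity) SVM with
## stratified cross-validation and the confusion-matrix metrics used to
## report classifier performance.

.roundHalfUp <- function(x, digits = 1) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Confusion-matrix metrics
#'
#' Classification rate, sensitivity and specificity from the four confusion
#' counts, as percentages. Reported values are rounded half-away-from-zero
#' to one decimal; the unrounded values are retained.
#'
#' @param tp,fn,tn,fp nonnegative counts (positives = disease class).
#' @return A list of class `"ConfusionMetrics"`: the counts, `cr`,
#'   `sensitivity`, `specificity` (rounded, `NA` where a denominator is
#'   zero) and their `unrounded` counterparts.
#' @examples
#' confusionMetrics(tp = 8, fn = 1, tn = 5, fp = 2)$sensitivity # 88.9
#' @export
confusionMetrics <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  cr <- 100 * (tp + tn) / total
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  structure(
    list(
      tp = tp, fn = fn, tn = tn, fp = fp,
      cr = .roundHalfUp(cr), sensitivity = .roundHalfUp(sens),
      specificity = .roundHalfUp(spec),
      unrounded = c(cr = cr, sensitivity = sens, specificity = spec)
    ),
    class = "ConfusionMetrics"
  )
}

.featureMatrix <- function(features) {
  stopifnot(all(c("thetaRP", "C") %in% names(features)))
  as.matrix(features[, c("thetaRP", "C")])
}

## median-heuristic RBF bandwidth on standardized features
.medianGamma <- function(X) {
  d <- stats::dist(X)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) m <- 1
  1 / (2 * m^2)
}

#' Train the two-feature SVM
#'
#' Standardizes the `(thetaRP, C)` features (the scaler is part of the
#' model) and fits an SVM. The default kernel is RBF with unit cost and a
#' median-heuristic bandwidth; a linear kernel is available.
#'
#' @param features data.frame with columns `thetaRP`, `C`, `label` (the
#'   positive/disease class being the second factor level or, for
#'   character labels, `positive`).
#' @param kernel `"radial"` or `"linear"`.
#' @param cost SVM regularization constant.
#' @param positive the label treated as the disease class (default `"AD"`).
#' @return A list of class `"ClassifierModel"` with the fitted svm, scaler,
#'   kernel settings and a config hash.
#' @export
trainSVM <- function(features, kernel = c("radial", "linear"), cost = 1,
                     positive = "AD") {
  kernel <- match.arg(kernel)
  X <- .featureMatrix(features)
  y <- factor(features$label == positive, levels = c(FALSE, TRUE),
              labels = c("neg", "pos"))
  if (nlevels(droplevels(y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  gamma <- if (kernel == "radial") .medianGamma(Xs) else 1 / ncol(Xs)
  fit <- e1071::svm(Xs, y, kernel = kernel, cost = cost, gamma = gamma,
                    scale = FALSE)
  cfg <- list(kernel = kernel, cost = cost, positive = positive,
              features = c("thetaRP", "C"))
  structure(
    list(
      svm = fit, center = center, scale = scale, gamma = gamma,
      kernel = kernel, cost = cost, positive = positive,
      configHash = configHash(cfg)
    ),
    class = "ClassifierModel"
  )
}

#' Predict with a trained classifier
#'
#' @param model a `"ClassifierModel"` from [trainSVM()].
#' @param features data.frame with `thetaRP` and `C` columns.
#' @return data.frame with `predicted` (logical, disease class) and
#'   `decision` values.
#' @export
predictSVM <- function(model, features) {
  X <- .featureMatrix(features)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  pr <- stats::predict(model$svm, Xs, decision.values = TRUE)
  dec <- as.numeric(attr(pr, "decision.values"))
  data.frame(predicted = pr == "pos", decision = dec)
}

.stratifiedFolds <- function(y, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the SVM
#'
#' Stratified folds; the feature scaler and kernel bandwidth are re-fit on
#' each training fold only, and the pooled out-of-fold predictions are
#' aggregated into one confusion matrix.
#'
#' @param features data.frame with `thetaRP`, `C` and `label` columns.
#' @param folds number of folds (default 10).
#' @param kernel,cost,positive passed to [trainSVM()].
#' @param seed RNG seed for fold assignment.
#' @return A list with `metrics` (a [confusionMetrics()] result), `folds`
#'   (per-subject fold ids) and `predictions`.
#' @export
crossvalSVM <- function(features, folds = 10, kernel = "radial", cost = 1,
                        positive = "AD", seed = 1) {
  y <- features$label == positive
  if (sum(y) < 2 || sum(!y) < 2) {
    stop("need at least 2 subjects per class", call. = FALSE)
  }
  folds <- min(folds, sum(y), sum(!y))
  fold <- .stratifiedFolds(y, folds, seed = seed)
  pred <- logical(nrow(features))
  dec <- numeric(nrow(features))
  for (f in seq_len(folds)) {
    train <- features[fold != f, , drop = FALSE]
    model <- trainSVM(train, kernel = kernel, cost = cost,
                      positive = positive)
    out <- predictSVM(model, features[fold == f, , drop = FALSE])
    pred[fold == f] <- out$predicted
    dec[fold == f] <- out$decision
  }
  metrics <- confusionMetrics(
    tp = sum(pred & y), fn = sum(!pred & y),
    tn = sum(!pred & !y), fp = sum(pred & !y)
  )
  list(
    metrics = metrics, folds = fold,
    predictions = data.frame(
      label = features$label, predicted = pred, decision = dec
    )
  )
}

#' Apply a trained classifier to an independent cohort
#'
#' Predicts every subject of `features` with `model`. When true labels are
#' supplied, the tally is returned as [confusionMetrics()]; for an MCI
#' cohort, converters (`MCIc`) count as positives and stable patients
#' (`MCIs`) as negatives via the `positive` label stored in the model. A
#' feature-configuration hash mismatch is refused, since features computed
#' under a different configuration (collapse/normalization flags, band
#' edges, channel format) are not comparable — retrain on features computed
#' in the target format instead.
#'
#' @param model a `"ClassifierModel"`.
#' @param features data.frame with `thetaRP`, `C`, optionally `label` and
#'   `subject`.
#' @param featureConfigHash optional hash of the configuration the features
#'   were computed under; checked against the model's when both are present.
#' @param positiveLabels labels counted as true positives (default the
#'   model's positive label plus `"MCIc"`).
#' @return list with `predictions` (per subject) and, when labels are
#'   present, `metrics`.
#' @export
applyToCohort <- function(model, features, featureConfigHash = NULL,
                          positiveLabels = NULL) {
  if (!is.null(featureConfigHash) && !is.null(model$featureConfigHash) &&
      !identical(featureConfigHash, model$featureConfigHash)) {
    stop(
      "feature configuration mismatch: these features were computed under ",
      "a different configuration than the model was trained on; recompute ",
      "the features (or retrain the model) in the target format",
      call. = FALSE
    )
  }
  out <- predictSVM(model, features)
  if (!is.null(features$subject)) out$subject <- features$subject
  res <- list(predictions = out)
  if (!is.null(features$label)) {
    if (is.null(positiveLabels)) positiveLabels <- c(model$positive, "MCIc")
    y <- features$label %in% positiveLabels
    res$metrics <- confusionMetrics(
      tp = sum(out$predicted & y), fn = sum(!out$predicted & y),
      tn = sum(!out$predicted & !y), fp = sum(out$predicted & !y)
    )
    res$predictions$label <- features$label
  }
  res
}
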