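#' One-vs-rest confusion counts
#'
#' Tallies TP/TN/FP/FN treating `positive_class` against everything else.
#'
#' @param y_true,y_pred Equal-length class label vectors.
#' @param positive_class The label counted as positive.
#' @return A list of class `confusion_counts` with integer `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred, positive_class) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1)
    stop("confusion_counts: y_true and y_pred must be equal nonzero lengths")
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Percentages on the 0-100 scale:
#' accuracy `= 100 (TP+TN) / (TP+TN+FP+FN)`,
#' sensitivity `= 100 TP / (TP+FN)` (true-positive rate),
#' specificity `= 100 TN / (TN+FP)` (true-negative rate).
#' A zero denominator yields `NA_real_` — an explicit undefined marker,
#' never a silent zero.
#'
#' @param c A `confusion_counts` object (or list with TP/TN/FP/FN).
#' @return Percentage in `[0, 100]`, or `NA_real_` when undefined.
#' @export
accuracy <- function(c) {
  den <- c$TP + c$TN + c$FP + c$FN
  if (den == 0) return(NA_real_)
  100 * (c$TP + c$TN) / den
}

#' @rdname accuracy
#' @export
sensitivity <- function(c) {
  den <- c$TP + c$FN
  if (den == 0) return(NA_real_)
  100 * c$TP / den
}

#' @rdname accuracy
#' @export
specificity <- function(c) {
  den <- c$TN + c$FP
  if (den == 0) return(NA_real_)
  100 * c$TN / den
}

#' Per-class and macro-averaged metrics report
#'
#' Applies the one-vs-rest reduction to every class and reports each class's
#' counts and metrics plus their macro averages (the headline row for a
#' multi-class problem).
#'
#' @param y_true,y_pred Class label vectors.
#' @return A data.frame with one row per class plus a `"macro"` row.
#' @export
metrics_report <- function(y_true, y_pred) {
  classes <- sort(unique(as.character(y_true)))
  rows <- lapply(classes, function(cl) {
    cc <- confusion_counts(as.character(y_true), as.character(y_pred), cl)
    data.frame(class = cl, TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
               accuracy = accuracy(cc), sensitivity = sensitivity(cc),
               specificity = specificity(cc), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  macro <- data.frame(class = "macro", TP = NA, TN = NA, FP = NA, FN = NA,
                      accuracy = mean(out$accuracy, na.rm = TRUE),
                      sensitivity = mean(out$sensitivity, na.rm = TRUE),
                      specificity = mean(out$specificity, na.rm = TRUE),
                      stringsAsFactors = FALSE)
  rbind(out, macro)
}

#' Labelled dataset container
#'
#' @param features Numeric matrix (samples x features), no missing values.
#' @param labels Class labels, one per row, >= 2 classes.
#' @param feature_names Optional column names.
#' @return A list of class `labeled_dataset`.
#' @export
labeled_dataset <- function(features, labels, feature_names = NULL) {
  features <- as.matrix(features)
  if (anyNA(features)) stop("labeled_dataset: features contain missing values")
  if (nrow(features) != length(labels))
    stop("labeled_dataset: features and labels row counts differ")
  if (length(unique(labels)) < 2)
    stop("labeled_dataset: need at least 2 classes")
  if (is.null(feature_names))
    feature_names <- colnames(features)
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(ncol(features)))
  colnames(features) <- feature_names
  structure(list(features = features, labels = as.character(labels),
                 feature_names = feature_names),
            class = "labeled_dataset")
}

# z-standardize columns; zero-variance columns map to all zeros.
standardize_features <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  scale(x, center = mu, scale = sdv)
}

# squared Euclidean distances between rows of a and rows of b
sqdist_cross <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d[d < 0] <- 0
  d
}

# k-NN vote of test rows against train rows; deterministic tie-break by
# the nearest neighbour among tied classes.
knn_predict <- function(train_x, train_y, test_x, k) {
  D <- sqdist_cross(test_x, train_x)
  if (k == 1L)
    return(train_y[max.col(-D, ties.method = "first")])
  apply_rows <- seq_len(nrow(test_x))
  vapply(apply_rows, function(i) {
    ord <- order(D[i, ], seq_along(train_y))
    nb <- ord[seq_len(min(k, length(ord)))]
    votes <- table(train_y[nb])
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) == 1L) winners else {
      # nearest neighbour whose class is among the tied winners
      train_y[nb[match(TRUE, train_y[nb] %in% winners)]]
    }
  }, character(1))
}

#' Leave-one-out nearest-neighbour evaluation of a feature subset
#'
#' The built-in desk-scale evaluator standing in for a heavyweight
#' classifier inside the wrapper loop: per-feature z-standardization, then
#' a leave-one-out k-nearest-neighbour vote restricted to the flagged
#' feature columns. Deterministic and parameter-free at `k = 1`.
#'
#' @param dataset A [labeled_dataset()].
#' @param flags Binary vector over features; 1 = include.
#' @param k_neighbors Number of neighbours (default 1).
#' @return Fraction of samples classified correctly, in `[0, 1]`.
#' @export
knn_evaluate <- function(dataset, flags, k_neighbors = 1L) {
  sel <- which(flags == 1L)
  if (length(sel) < 1) stop("knn_evaluate: at least one feature must be selected")
  n <- nrow(dataset$features)
  if (n < k_neighbors + 1)
    stop("knn_evaluate: fewer samples than k_neighbors + 1")
  x <- standardize_features(dataset$features)[, sel, drop = FALSE]
  D <- sqdist_cross(x, x)
  diag(D) <- Inf
  y <- dataset$labels
  if (k_neighbors == 1L)
    return(mean(y[max.col(-D, ties.method = "first")] == y))
  pred <- vapply(seq_len(n), function(i) {
    ord <- order(D[i, ], seq_len(n))
    nb <- ord[seq_len(k_neighbors)]
    votes <- table(y[nb])
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) == 1L) winners else
      y[nb[match(TRUE, y[nb] %in% winners)]]
  }, character(1))
  mean(pred == y)
}

# stratified fold assignment: per class, shuffled then dealt round-robin,
# so per-class fold sizes differ by at most one
stratified_folds <- function(labels, k_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k_folds)
      stop("repeated_kfold_accuracy: class '", cl,
           "' has fewer members than k_folds")
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k_folds), length(idx))
  }
  fold
}

#' Repeated stratified k-fold accuracy
#'
#' Stratified k-fold cross-validation of the nearest-neighbour evaluator on
#' a flagged feature subset, repeated with fresh shuffles and averaged; the
#' default 10 folds x 10 repeats matches the reference evaluation protocol.
#'
#' @param dataset A [labeled_dataset()].
#' @param flags Binary feature-inclusion vector.
#' @param k_folds Folds per repeat (each class must have >= `k_folds` rows).
#' @param repeats Number of repeated shuffles.
#' @param k_neighbors Neighbours in the vote.
#' @param seed Integer seed for the shuffles.
#' @return A list with `mean_accuracy`, `per_repeat` (length `repeats`) and
#'   `predictions` of the final repeat.
#' @export
repeated_kfold_accuracy <- function(dataset, flags, k_folds = 10L,
                                    repeats = 10L, k_neighbors = 1L,
                                    seed = 0L) {
  sel <- which(flags == 1L)
  if (length(sel) < 1)
    stop("repeated_kfold_accuracy: at least one feature must be selected")
  x <- standardize_features(dataset$features)[, sel, drop = FALSE]
  y <- dataset$labels
  set.seed(seed)
  per_repeat <- numeric(repeats)
  pred_last <- NULL
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, k_folds)
    pred <- character(length(y))
    for (f in seq_len(k_folds)) {
      te <- which(fold == f)
      tr <- which(fold != f)
      pred[te] <- knn_predict(x[tr, , drop = FALSE], y[tr],
                              x[te, , drop = FALSE], k_neighbors)
    }
    per_repeat[r] <- mean(pred == y)
    pred_last <- pred
  }
  list(mean_accuracy = mean(per_repeat), per_repeat = per_repeat,
       predictions = pred_last)
}
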