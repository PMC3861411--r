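# Stratified (nested) cross-validation, ROC curves with retained thresholds,
# threshold-averaged ROC and avgROC summaries.

#' Stratified fold assignment
#'
#' Deterministic given the seed; within every fold each class's share matches
#' the global class proportions to within one item.
#'
#' @param labels Class labels.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Tibble with columns `index`, `label`, `fold` (folds in
#'   `1..n_folds`).
#' @export
#' @examples
#' stratified_folds(rep(c("a", "b"), each = 4), 4, seed = 1)
stratified_folds <- function(labels, n_folds, seed = 42L) {
  counts <- table(labels)
  if (any(counts < n_folds)) {
    stop(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                 names(counts)[which(counts < n_folds)[1L]],
                 min(counts), n_folds), call. = FALSE)
  }
  fold <- integer(length(labels))
  set.seed(seed)
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  tibble::tibble(index = seq_along(labels), label = labels, fold = fold)
}

#' ROC curve with retained thresholds
#'
#' Classifies positive at `score >= threshold` for every distinct score value
#' (tied scores grouped), tracing the curve from (0,0) to (1,1). The area
#' under the curve is the trapezoidal rule over these points, a deterministic
#' convention under ties.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Logical (or 0/1) true labels.
#' @return A tibble of class `roc_curve` with columns `threshold`, `fpr`,
#'   `tpr` (thresholds descending, `Inf` first) and attribute `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), any(labels), any(!labels))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  P <- sum(labels); N <- sum(!labels)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / P, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / N, numeric(1))
  out <- tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)
  class(out) <- c("roc_curve", class(out))
  attr(out, "auc") <- trapezoid_auc(fpr, tpr)
  out
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (head(tpr[o], -1) + tail(tpr[o], -1)) / 2)
}

#' Area under a ROC curve
#'
#' @param x A `roc_curve` (or scores when `labels` is given).
#' @param labels Optional labels; when supplied `x` is taken as scores.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(x, labels = NULL) {
  if (!is.null(labels)) x <- roc_curve(x, labels)
  attr(x, "auc")
}

# fpr/tpr achieved by cutting a curve's score at an arbitrary threshold t:
# positives are scores >= t, i.e. the smallest recorded threshold >= t.
eval_roc_at <- function(curve, t) {
  j <- findInterval(-t, -curve$threshold)  # thresholds are descending
  j <- pmax(j, 1L)
  c(fpr = curve$fpr[j], tpr = curve$tpr[j])
}

#' Threshold-averaged ROC curve
#'
#' Averages fold-wise ROC curves on the class-discrimination cutoffs: at each
#' pooled threshold the per-fold (FPR, TPR) operating points are averaged.
#' Averaging identical curves returns the same curve; the endpoints (0,0) and
#' (1,1) are preserved.
#'
#' @param curves List of `roc_curve` objects (thresholds retained).
#' @return A `roc_curve` over the pooled thresholds.
#' @export
threshold_avg_roc <- function(curves) {
  thr <- sort(unique(unlist(lapply(curves, function(c) c$threshold))),
              decreasing = TRUE)
  pts <- vapply(thr, function(t) {
    rowMeans(vapply(curves, eval_roc_at, numeric(2), t = t))
  }, numeric(2))
  out <- tibble::tibble(threshold = thr, fpr = pts[1L, ], tpr = pts[2L, ])
  class(out) <- c("roc_curve", class(out))
  attr(out, "auc") <- trapezoid_auc(out$fpr, out$tpr)
  out
}

#' Multiclass avgROC
#'
#' Unweighted mean of one-vs-rest AUCs across classes. Classes absent from
#' the labels are skipped with a warning.
#'
#' @param scores Matrix of per-class scores (columns named by class).
#' @param labels True class labels.
#' @param classes Classes to average over (default: score columns).
#' @return Mean AUC.
#' @export
avg_roc_multiclass <- function(scores, labels, classes = colnames(scores)) {
  aucs <- c()
  for (cl in classes) {
    if (!cl %in% labels) {
      warning(sprintf("class '%s' absent from labels; skipped", cl))
      next
    }
    aucs[cl] <- auc(scores[, cl], labels == cl)
  }
  mean(aucs)
}

resolve_features <- function(features, train_idx, n) {
  m <- if (is.function(features)) features(train_idx) else features
  stopifnot(nrow(m) == n)
  m
}

#' Stratified nested cross-validation
#'
#' Outer loop: held-out performance estimation; inner loop (on the outer
#' training data only): hyperparameter selection over `grid` by mean inner
#' AUC (binary) or inner avgROC (multiclass). The winning row is refit on the
#' full outer-training split and scored on the outer test split. Outer test
#' data never influences hyperparameter choice. `features` may be a fixed
#' matrix or a builder `function(train_idx)` returning the full feature
#' matrix computed from training-row information only (required for
#' homology-derived features, whose subject database must exclude test rows).
#'
#' @param features Feature matrix or builder function (see Details).
#' @param labels Class labels; with exactly two distinct values the first of
#'   `positive` marks the positive class.
#' @param spec Base [learner_spec()].
#' @param grid Hyperparameter data frame (default [default_grid()]).
#' @param outer,inner Fold counts (defaults 4 and 4).
#' @param seed Integer seed controlling both fold assignments.
#' @param positive For binary tasks, the positive label (default `"TF"` when
#'   present, else the first level).
#' @return A `nested_cv` object: per-outer-fold ROC curves and AUCs, chosen
#'   hyperparameters, the threshold-averaged curve, and `avg_roc` (the
#'   unweighted mean of fold AUCs).
#' @export
nested_cv <- function(features, labels, spec = learner_spec("svm"),
                      grid = default_grid(spec), outer = 4L, inner = 4L,
                      seed = 42L, positive = NULL) {
  n <- length(labels)
  classes <- unique(labels)
  binary <- length(classes) == 2L
  if (binary) {
    positive <- positive %||% (if ("TF" %in% classes) "TF" else classes[1L])
  }
  folds <- stratified_folds(labels, outer, seed = seed)
  fold_curves <- list()
  fold_auc <- numeric(outer)
  chosen <- vector("list", outer)
  for (f in seq_len(outer)) {
    tr <- folds$index[folds$fold != f]
    te <- folds$index[folds$fold == f]
    x_tr_full <- resolve_features(features, tr, n)
    # inner selection
    if (nrow(grid) > 1L) {
      inner_folds <- stratified_folds(labels[tr], inner, seed = seed + f)
      perf <- vapply(seq_len(nrow(grid)), function(g) {
        sp <- with_params(spec, grid[g, , drop = FALSE])
        mean(vapply(seq_len(inner), function(ifold) {
          itr <- tr[inner_folds$fold != ifold]
          ite <- tr[inner_folds$fold == ifold]
          x <- resolve_features(features, itr, n)
          cv_fold_score(x, labels, itr, ite, sp, binary, positive)
        }, numeric(1)))
      }, numeric(1))
      best <- which.max(perf)
    } else {
      best <- 1L
    }
    chosen[[f]] <- grid[best, , drop = FALSE]
    sp <- with_params(spec, grid[best, , drop = FALSE])
    if (binary) {
      fit <- fit_binary_learner(sp, x_tr_full[tr, , drop = FALSE],
                                labels[tr] == positive)
      sc <- predict_score(fit, x_tr_full[te, , drop = FALSE])
      fold_curves[[f]] <- roc_curve(sc, labels[te] == positive)
      fold_auc[f] <- auc(fold_curves[[f]])
    } else {
      fit <- one_vs_rest(x_tr_full[tr, , drop = FALSE], labels[tr], sp,
                         classes = classes)
      sc <- predict(fit, x_tr_full[te, , drop = FALSE])
      fold_auc[f] <- avg_roc_multiclass(as.matrix(sc[, classes]), labels[te])
      fold_curves[[f]] <- NULL
    }
  }
  structure(list(fold_curves = fold_curves, fold_auc = fold_auc,
                 chosen = chosen, avg_roc = mean(fold_auc),
                 threshold_avg = if (binary) threshold_avg_roc(fold_curves),
                 binary = binary, positive = if (binary) positive,
                 spec = spec, outer = outer, inner = inner, seed = seed),
            class = "nested_cv")
}

cv_fold_score <- function(x, labels, itr, ite, sp, binary, positive) {
  if (binary) {
    fit <- fit_binary_learner(sp, x[itr, , drop = FALSE],
                              labels[itr] == positive)
    sc <- predict_score(fit, x[ite, , drop = FALSE])
    if (length(unique(labels[ite])) < 2L) return(NA_real_)
    auc(sc, labels[ite] == positive)
  } else {
    fit <- one_vs_rest(x[itr, , drop = FALSE], labels[itr], sp,
                       classes = unique(labels))
    sc <- predict(fit, x[ite, , drop = FALSE])
    avg_roc_multiclass(as.matrix(sc[, unique(labels)]), labels[ite])
  }
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf("<nested_cv> %dx%d, %s, avgROC = %.3f\n",
              x$outer, x$inner, x$spec$method, x$avg_roc))
  invisible(x)
}

#' @export
tidy.nested_cv <- function(x, ...) {
  tibble::tibble(
    fold = seq_along(x$fold_auc),
    auc = x$fold_auc,
    params = purrr::map_chr(x$chosen, function(p) {
      if (NCOL(p) == 0) "" else paste(names(p), unlist(p), sep = "=",
                                      collapse = ", ")
    })
  )
}

#' @export
glance.nested_cv <- function(x, ...) {
  tibble::tibble(avg_roc = x$avg_roc, outer = x$outer, inner = x$inner,
                 learner = x$spec$method)
}
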