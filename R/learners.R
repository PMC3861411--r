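# Pluggable binary base learners behind one interface: the five families
# compared for TF classification (SVM with RBF or linear kernel, k-nearest
# neighbours, naive Bayes, decision tree, random forest). Every fitted
# learner exposes a numeric score (higher = more positive-like) plus the
# cutoff that turns the score into a binary outcome.

#' Specify a base learner
#'
#' @param method One of `"svm"` (RBF kernel), `"svm_linear"`, `"knn"`,
#'   `"nb"` (naive Bayes), `"tree"` (CART), `"rf"` (random forest).
#' @param params Named list of hyperparameters overriding the defaults
#'   (`cost`/`gamma` for SVMs, `k` for KNN, `ntree` for random forest,
#'   `cp` for the tree).
#' @param seed Seed applied before fitting any stochastic learner.
#' @return A `learner_spec` object.
#' @export
#' @examples
#' learner_spec("svm", list(cost = 10))
learner_spec <- function(method = c("svm", "svm_linear", "knn", "nb", "tree", "rf"),
                         params = list(), seed = 42L) {
  method <- match.arg(method)
  structure(list(method = method, params = params, seed = seed),
            class = "learner_spec")
}

#' Default hyperparameter grid for a learner
#'
#' The grids are tuned only inside the inner loop of [nested_cv()].
#'
#' @param spec A [learner_spec()].
#' @return A data frame, one row per hyperparameter combination (possibly a
#'   single empty row for learners tuned by their defaults).
#' @export
default_grid <- function(spec) {
  switch(spec$method,
    svm = expand.grid(cost = c(0.1, 1, 10, 100),
                      gamma = c(1e-3, 1e-2, 1e-1, 1)),
    svm_linear = expand.grid(cost = c(0.1, 1, 10, 100)),
    knn = expand.grid(k = c(1, 3, 5, 7)),
    rf = expand.grid(ntree = c(100, 500)),
    data.frame(row.names = "1")[, 0, drop = FALSE]
  )
}

with_params <- function(spec, row) {
  if (NCOL(row) > 0) spec$params <- utils::modifyList(spec$params, as.list(row))
  spec
}

#' Fit a binary base learner
#'
#' @param spec A [learner_spec()].
#' @param x Numeric feature matrix.
#' @param y Logical or 0/1 vector (TRUE = positive).
#' @return A `fitted_learner` with fields `model`, `cutoff` and the spec.
#' @export
fit_binary_learner <- function(spec, x, y) {
  y <- as.logical(y)
  stopifnot(any(y), any(!y))
  x <- as.matrix(x)
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  p <- spec$params
  set.seed(spec$seed)
  model <- switch(spec$method,
    svm = e1071::svm(x, yf, kernel = "radial",
                     cost = p$cost %||% 1,
                     gamma = p$gamma %||% (1 / ncol(x)), scale = FALSE),
    svm_linear = e1071::svm(x, yf, kernel = "linear",
                            cost = p$cost %||% 1, scale = FALSE),
    knn = list(x = x, y = yf, k = p$k %||% 3),
    nb = e1071::naiveBayes(x, yf),
    tree = rpart::rpart(y ~ ., data = data.frame(y = yf, x, check.names = FALSE),
                        method = "class",
                        control = rpart::rpart.control(cp = p$cp %||% 0.01,
                                                       minsplit = p$minsplit %||% 5)),
    rf = randomForest::randomForest(x, yf, ntree = p$ntree %||% 100)
  )
  cutoff <- if (spec$method %in% c("svm", "svm_linear")) 0 else 0.5
  structure(list(spec = spec, model = model, cutoff = cutoff,
                 colnames = colnames(x)),
            class = "fitted_learner")
}

#' Score new data with a fitted base learner
#'
#' SVMs return signed decision values oriented so that positive means the
#' positive class; all other learners return the positive-class probability.
#'
#' @param fit A `fitted_learner`.
#' @param x Feature matrix.
#' @return Numeric score vector.
#' @export
predict_score <- function(fit, x) {
  x <- as.matrix(x)
  m <- fit$model
  switch(fit$spec$method,
    svm = ,
    svm_linear = {
      pr <- predict(m, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      if (colnames(dv)[1L] == "neg/pos") -dv[, 1L] else dv[, 1L]
    },
    knn = {
      set.seed(fit$spec$seed)
      pr <- class::knn(m$x, x, m$y, k = m$k, prob = TRUE)
      p_win <- attr(pr, "prob")
      ifelse(pr == "pos", p_win, 1 - p_win)
    },
    nb = predict(m, x, type = "raw")[, "pos"],
    tree = predict(m, data.frame(x, check.names = FALSE), type = "prob")[, "pos"],
    rf = predict(m, x, type = "prob")[, "pos"]
  )
}

predict_bit <- function(fit, x) {
  as.integer(predict_score(fit, x) > fit$cutoff)
}
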