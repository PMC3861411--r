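test_that("stratified folds preserve class proportions and determinism", {
  lab <- rep(c("a", "b"), each = 4)
  f <- stratified_folds(lab, 4, seed = 1)
  counts <- table(f$fold, f$label)
  expect_true(all(counts == 1L))
  expect_identical(f, stratified_folds(lab, 4, seed = 1))
  expect_false(identical(f$fold, stratified_folds(lab, 4, seed = 2)$fold))
  # per-fold class shares within one item of the global proportions
  set.seed(51)
  lab2 <- sample(c(rep("x", 23), rep("y", 41), rep("z", 8)))
  f2 <- stratified_folds(lab2, 4, seed = 3)
  tab <- table(f2$fold, f2$label)
  for (cl in colnames(tab)) {
    expect_lte(max(tab[, cl]) - min(tab[, cl]), 1L)
  }
  expect_error(stratified_folds(c("a", "a", "b"), 2), "fewer members")
})

test_that("ROC curves honour the oracle, anti-oracle and constant scores", {
  y <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  expect_equal(auc(as.numeric(y), y), 1)
  expect_equal(auc(-as.numeric(y), y), 0)
  expect_equal(auc(rep(3.7, 6), y), 0.5)
  r <- roc_curve(as.numeric(y), y)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})

test_that("trapezoidal AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(52)
  for (i in 1:5) {
    y <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    s <- stats::rnorm(40) + y
    expect_equal(auc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-10)
  }
})

test_that("threshold averaging fixes identical curves and midpoints pairs", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  r <- roc_curve(c(4, 3, 2, 1), y)
  avg <- threshold_avg_roc(list(r, r))
  expect_equal(avg$fpr, r$fpr)
  expect_equal(avg$tpr, r$tpr)
  # two single-threshold-differing curves average to the midpoint operating
  # point: curve A separates perfectly, curve B inverts the middle pair
  rA <- roc_curve(c(4, 3, 2, 1), y)
  rB <- roc_curve(c(4, 2, 3, 1), y)
  avg2 <- threshold_avg_roc(list(rA, rB))
  # at threshold 3: A has (fpr 0, tpr 1), B has (fpr 1/2, tpr 1/2)
  at3 <- avg2[avg2$threshold == 3, ]
  expect_equal(at3$fpr, 0.25)
  expect_equal(at3$tpr, 0.75)
  expect_true(all(diff(avg2$fpr) >= 0) && all(diff(avg2$tpr) >= 0))
})

test_that("multiclass avgROC is the unweighted mean of one-vs-rest AUCs", {
  set.seed(53)
  lab <- rep(c("a", "b", "c"), each = 10)
  perfect <- sapply(c("a", "b", "c"), function(cl) as.numeric(lab == cl))
  expect_equal(avg_roc_multiclass(perfect, lab), 1)
  rand <- matrix(stats::rnorm(90), ncol = 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  manual <- mean(sapply(c("a", "b", "c"),
                        function(cl) auc(rand[, cl], lab == cl)))
  expect_equal(avg_roc_multiclass(rand, lab), manual)
  # permutation oracle: random scores hover near 1/2
  reps <- replicate(20, {
    r <- matrix(stats::rnorm(90), ncol = 3,
                dimnames = list(NULL, c("a", "b", "c")))
    avg_roc_multiclass(r, lab)
  })
  expect_lt(abs(mean(reps) - 0.5), 0.05)
  expect_warning(avg_roc_multiclass(rand, rep(c("a", "b"), 15)), "skipped")
})

test_that("nested CV scores oracle and uninformative learners at 1 and 1/2", {
  set.seed(54)
  lab <- sample(rep(c("TF", "non-TF"), each = 16))
  oracle_x <- cbind(ind = as.numeric(lab == "TF"))
  cv <- nested_cv(oracle_x, lab, learner_spec("knn", list(k = 1)),
                  grid = data.frame(k = 1), seed = 7)
  expect_equal(cv$avg_roc, 1)
  const_x <- cbind(z = rep(1, 32), z2 = rep(2, 32))
  cv0 <- nested_cv(const_x, lab, learner_spec("tree"),
                   grid = data.frame(cp = 0.01), seed = 7)
  expect_equal(cv0$avg_roc, 0.5)
})

test_that("feature builders only ever see training-row indices", {
  set.seed(55)
  lab <- sample(rep(c("TF", "non-TF"), each = 16))
  x <- cbind(f = as.numeric(lab == "TF") + stats::rnorm(32, sd = 0.3))
  seen <- list()
  builder <- function(train_idx) {
    seen[[length(seen) + 1L]] <<- train_idx
    x
  }
  cv <- nested_cv(builder, lab, learner_spec("svm_linear"),
                  grid = expand.grid(cost = c(0.1, 1)), outer = 4L,
                  inner = 4L, seed = 9)
  outer_folds <- stratified_folds(lab, 4, seed = 9)
  for (f in 1:4) {
    test_rows <- outer_folds$index[outer_folds$fold == f]
    # every builder call for this outer fold excludes its test rows
    train_calls <- Filter(function(ix) !any(test_rows %in% ix), seen)
    expect_gt(length(train_calls), 0)
  }
  # no builder call ever contains a full-data index set
  expect_true(all(vapply(seen, length, integer(1)) < 32))
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(nrow(tidy(cv)), 4L)
})
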