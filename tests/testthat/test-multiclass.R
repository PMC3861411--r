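published_code <- function() {
  rows <- rbind(
    "Other"            = rep(1L, 15),
    "Basic domain"     = c(0,0,0,0,0,0,0,0,1,1,1,1,1,1,1),
    "Zinc finger"      = c(0,0,0,0,1,1,1,1,0,0,0,0,1,1,1),
    "Helix-turn-helix" = c(0,0,1,1,0,0,1,1,0,0,1,1,0,0,1),
    "Beta scaffold"    = c(0,1,0,1,0,1,0,1,0,1,0,1,0,1,0))
  storage.mode(rows) <- "integer"
  rows
}

test_that("the five-superclass exhaustive code reproduces the printed table", {
  code <- superclass_code()
  expect_equal(ncol(code), 15L)
  ref <- published_code()
  expect_equal(unname(unclass(code)), unname(ref))
  expect_equal(rownames(code), rownames(ref))
})

test_that("exhaustive codes have the right shape across class counts", {
  expect_equal(ncol(exhaustive_code(letters[1:4])), 7L)
  code2 <- exhaustive_code(c("a", "b"))
  expect_equal(unname(unclass(code2)), matrix(c(1L, 0L), ncol = 1))
  for (k in 2:7) {
    code <- exhaustive_code(letters[1:k])
    expect_equal(ncol(code), 2L^(k - 1L) - 1L)
    # no constant, duplicate or complementary columns
    cols <- apply(code, 2, paste, collapse = "")
    comp <- apply(1L - code, 2, paste, collapse = "")
    expect_false(any(duplicated(cols)))
    expect_false(any(cols %in% comp))
    expect_false(any(cols %in% strrep(c("0", "1"), k)))
  }
  expect_error(exhaustive_code("a"))
  expect_error(exhaustive_code(letters[1:11]))
})

test_that("the code's error-correcting margin is 8 for five classes", {
  code <- superclass_code()
  pairs <- utils::combn(5, 2)
  dists <- apply(pairs, 2, function(p) sum(code[p[1], ] != code[p[2], ]))
  expect_equal(min(dists), 8L)
  expect_equal(code_min_hamming(code), 8L)
})

test_that("Hamming decoding assigns probability mass to nearest rows", {
  code <- superclass_code()
  p <- ecoc_decode(code["Zinc finger", ], code)
  expect_equal(unname(p["Zinc finger"]), 1)
  # hand-computed tie: distances (4, 4, 4, 8, 8) across the row order
  p2 <- ecoc_decode(c(0,0,0,0,1,1,1,1,1,1,1,1,1,1,1), code)
  expect_equal(unname(p2), c(1, 1, 1, 0, 0) / 3)
  p3 <- ecoc_decode(rep(1, 15), code)
  expect_equal(unname(p3["Other"]), 1)
  # decoding always yields a distribution, for arbitrary bit strings
  set.seed(41)
  for (i in 1:25) {
    pr <- ecoc_decode(sample(0:1, 15, replace = TRUE), code)
    expect_equal(sum(pr), 1)
    expect_true(all(pr >= 0))
  }
})

separable_blobs <- function(k, n_per = 8, p = 3, sd = 0.15, seed = 42) {
  set.seed(seed)
  centers <- diag(k)[, seq_len(min(k, p)), drop = FALSE] * 4
  if (p > k) centers <- cbind(centers, matrix(0, k, p - k))
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(stats::rnorm(n_per * p, mean = rep(centers[i, ], each = n_per),
                        sd = sd), ncol = p)
  }))
  list(x = x, labels = rep(letters[seq_len(k)], each = n_per))
}

test_that("ECOC training fits one base model per column and separates blobs", {
  d <- separable_blobs(5, p = 5)
  code <- exhaustive_code(letters[1:5])
  fit <- train_ecoc(d$x, d$labels, code, learner_spec("svm_linear"))
  expect_length(fit$fits, 15L)
  pred <- predict(fit, d$x)
  expect_equal(pred$.class, d$labels)
  expect_true(all(abs(rowSums(as.matrix(pred[, -1])) - 1) < 1e-12))
  g <- glance(fit)
  expect_equal(g$n_classifiers, 15L)
  expect_equal(g$min_hamming, 8L)
})

test_that("two-class ECOC degenerates to a single binary classifier", {
  d <- separable_blobs(2)
  fit <- train_ecoc(d$x, d$labels, exhaustive_code(c("a", "b")),
                    learner_spec("svm_linear"))
  expect_length(fit$fits, 1L)
  expect_equal(predict(fit, d$x)$.class, d$labels)
})

test_that("a column with an empty side fails with the column named", {
  code <- exhaustive_code(letters[1:3])
  d <- separable_blobs(3)
  keep <- d$labels == "a"  # only the all-ones row class present
  expect_error(train_ecoc(d$x[keep, ], d$labels[keep], code,
                          learner_spec("svm_linear")), "SVM1")
})

test_that("one-vs-rest trains per-class scorers usable for ranking", {
  d <- separable_blobs(5, p = 5)
  fit <- one_vs_rest(d$x, d$labels, learner_spec("svm_linear"))
  expect_length(fit$fits, 5L)
  pred <- predict(fit, d$x)
  expect_equal(pred$.class, d$labels)
  expect_error(one_vs_rest(d$x[c(1, 9:40), ], d$labels[c(1, 9:40)],
                           learner_spec("svm_linear")), "fewer than 2")
})

test_that("every base learner family fits and scores through one interface", {
  d <- separable_blobs(2, n_per = 12)
  y <- d$labels == "a"
  for (method in c("svm", "svm_linear", "knn", "nb", "tree", "rf")) {
    fit <- fit_binary_learner(learner_spec(method), d$x, y)
    sc <- predict_score(fit, d$x)
    expect_length(sc, nrow(d$x))
    expect_gt(auc(sc, y), 0.95)
  }
})
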