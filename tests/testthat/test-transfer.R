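test_that("best-match selection applies the dynamic threshold rule", {
  cfg <- transfer_config()
  cand <- tibble::tibble(id = c("a", "b", "c"),
                         predicted = c(0.93, 0.7, 0.4))
  sel <- select_best_matches(cand, cfg)
  expect_true(sel$possible)
  expect_equal(sel$threshold, 0.93)
  expect_equal(sel$selected$id, "a")
  expect_equal(sel$confidence, 0.93)
  # the threshold is capped at bmt_max, widening the selected set
  cand2 <- tibble::tibble(id = c("a", "b"), predicted = c(0.99, 0.96))
  sel2 <- select_best_matches(cand2, cfg)
  expect_equal(sel2$threshold, 0.95)
  expect_equal(sel2$selected$id, c("a", "b"))
  # nothing reaches the admissible range: a no-prediction outcome
  none <- select_best_matches(tibble::tibble(id = "a", predicted = 0.49), cfg)
  expect_false(none$possible)
  # static 0.95 rejects a best candidate at 0.93
  static <- transfer_config(bmt = 0.95)
  expect_false(select_best_matches(cand, static)$possible)
  expect_true(select_best_matches(cand, transfer_config(bmt = 0.9))$possible)
})

test_that("lowering the admissible threshold never shrinks the selection", {
  set.seed(101)
  for (i in 1:10) {
    cand <- tibble::tibble(id = letters[1:8], predicted = stats::runif(8))
    prev <- character()
    for (t in c(0.9, 0.7, 0.5, 0.3, 0.1)) {
      sel <- select_best_matches(cand, transfer_config(bmt = t,
                                                       bmt_min = 0.05))
      ids <- if (sel$possible) sel$selected$id else character()
      expect_true(all(prev %in% ids))
      prev <- ids
    }
  }
})

test_that("the outlier filter drops high-mean-distance PFMs, never all", {
  set.seed(102)
  p <- random_pfm(5, "p", sharp = TRUE)
  # identical PFMs: nothing removed
  same <- list(p, p, p)
  kept <- outlier_filter(same, tau = 1.5)
  expect_length(kept, 3L)
  expect_length(attr(kept, "removed"), 0L)
  # hand-computed mean-distance table: two identical plus one maximally
  # distant member; means are (0.5, 0.5, 1), grand mean 2/3, cutoff 1.0
  d <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), nrow = 3)
  kept2 <- outlier_filter(list(p, p, p), tau = 1.5, distmat = d)
  expect_equal(attr(kept2, "removed"), 3L)
  expect_length(kept2, 2L)
  # a single PFM always survives
  one <- outlier_filter(list(p), tau = 1.5)
  expect_length(one, 1L)
  # equidistant sets are never emptied
  d3 <- matrix(0.4, 3, 3); diag(d3) <- 0
  kept3 <- outlier_filter(list(p, p, p), tau = 1.5, distmat = d3)
  expect_length(kept3, 3L)
})

test_that("merging is idempotent and resolves orientation", {
  set.seed(103)
  X <- random_pfm(6, "X", sharp = TRUE)
  m <- merge_pfms(list(X, X))
  expect_equal(m$probabilities, unname(X$probabilities), ignore_attr = TRUE,
               tolerance = 1e-12)
  # merging X with its reverse complement recovers X up to orientation
  m2 <- merge_pfms(list(X, reverse_complement(X)))
  expect_equal(ncol(m2$counts), 6L)
  expect_lt(pfm_distance(m2, X), 1e-6)
})

test_that("sub-motif merging aligns at the brute-force best offset", {
  set.seed(104)
  X <- random_pfm(7, "X", sharp = TRUE)
  sub <- pfm(X$counts[, 2:5], id = "sub")
  pa <- list(probs = X$probabilities, w = rep(1, 7))
  pb <- list(probs = sub$probabilities, w = rep(1, 4))
  best <- tfannotate:::align_profiles(pa, pb)
  # brute force over forward offsets
  scores <- sapply(-(4 - 1):(7 - 1), function(shift) {
    cols <- max(1, shift + 1):min(7, shift + 4)
    if (length(cols) == 0) return(-Inf)
    sum(sapply(cols, function(j)
      tfannotate:::column_similarity(pa$probs[, j], pb$probs[, j - shift])))
  })
  expect_equal(best$score, max(scores), tolerance = 1e-12)
  expect_equal(best$shift, 1L)
  merged <- merge_pfms(list(X, sub))
  expect_equal(ncol(merged$counts), 7L)
  expect_equal(merged$probabilities[, 2:5],
               X$probabilities[, 2:5], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("SVR training needs enough pairs and tracks constant targets", {
  set.seed(105)
  few <- tibble::tibble(global_identity = runif(5), local_sim = runif(5),
                        mmk = runif(5), lak = runif(5), s_norm = runif(5))
  expect_error(train_pfm_svr(few), "pooling")
  n <- 40
  const <- tibble::tibble(global_identity = runif(n), local_sim = runif(n),
                          mmk = runif(n), lak = runif(n), s_norm = 0.6)
  fit <- train_pfm_svr(const)
  pred <- predict_pfm_similarity(fit, const)
  expect_true(all(abs(pred - 0.6) < 0.05))
  expect_true(all(pred >= 0 & pred <= 1))
})

test_that("a held-out twin with identical DBD and PFM transfers at distance 0", {
  ts <- transfer_fixture()
  twin_fam <- gen_tf_family(
    family_spec("Zinc finger", n_members = 3, divergence = 0, id = "twin"),
    seed = 99)
  train <- rbind(ts[, c("id", "superclass", "dbd_sequence", "pfm")],
                 twin_fam[-1, c("id", "superclass", "dbd_sequence", "pfm")])
  query <- twin_fam[1, ]
  cfg <- transfer_config()
  preps <- tfannotate:::pfm_prep_cache(train$pfm)
  pairs <- tfannotate:::transfer_pair_table(train, cfg, preps)
  models <- tfannotate:::train_transfer_models(pairs, seed = 1)
  res <- motif_transfer(query, train, models, cfg)
  expect_true(res$possible)
  expect_gte(res$threshold, 0.5)
  expect_lt(pfm_distance(res$pfm, query$pfm[[1]]), 0.05)
  # a static threshold above every prediction yields the no-prediction path
  res95 <- motif_transfer(query, ts[, c("id", "superclass", "dbd_sequence",
                                        "pfm")],
                          models, transfer_config(bmt = 0.95))
  expect_false(is.null(res95))
})
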