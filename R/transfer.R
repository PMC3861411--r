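# Workflow step 4: PFM transfer. Support vector regression predicts the
# normalized Smax similarity of the query's PFM to each annotated training
# TF from DBD sequence-similarity features; best matches are selected by a
# (dynamic or fixed) best-match threshold, their PFMs pass an outlier filter
# and are progressively merged along a UPGMA guide tree into the predicted
# motif.

#' Motif-transfer configuration
#'
#' @param bmt `"dynamic"` (threshold chosen at runtime as the largest value
#'   in `[bmt_min, bmt_max]` retaining at least one best match) or a fixed
#'   numeric threshold.
#' @param bmt_min,bmt_max Bounds of the dynamic threshold range.
#' @param tau Outlier factor: PFMs whose mean distance to the other selected
#'   matrices exceeds `tau` times the grand mean are dropped (`tau > 1`).
#' @param alpha_hit Per-window hit significance for Smax scoring.
#' @param pseudocount PFM pseudocount for log-odds scoring.
#' @param background Background nucleotide distribution.
#' @param beta LAK inverse temperature.
#' @param min_dbd_similarity Minimum normalized local-alignment similarity
#'   between DBDs for a pair to enter SVR training or candidacy.
#' @param scheme Protein [scoring_scheme()] for the DBD features.
#' @return A `transfer_config` list.
#' @export
transfer_config <- function(bmt = "dynamic", bmt_min = 0.5, bmt_max = 0.95,
                            tau = 1.5, alpha_hit = 0.01, pseudocount = 0.01,
                            background = rep(0.25, 4), beta = 0.5,
                            min_dbd_similarity = 0.3,
                            scheme = scoring_scheme()) {
  stopifnot(bmt_min > 0, bmt_min <= bmt_max, bmt_max < 1, tau > 1)
  if (!identical(bmt, "dynamic")) {
    stopifnot(is.numeric(bmt), bmt > 0, bmt < 1)
  }
  structure(list(bmt = bmt, bmt_min = bmt_min, bmt_max = bmt_max, tau = tau,
                 alpha_hit = alpha_hit, pseudocount = pseudocount,
                 background = background, beta = beta,
                 min_dbd_similarity = min_dbd_similarity, scheme = scheme),
            class = "transfer_config")
}

svr_feature_names <- function() c("global_identity", "local_sim", "mmk", "lak")

#' Train a PFM-similarity SVR model
#'
#' Epsilon-SVR (RBF kernel, epsilon = 0.01) regressing observed normalized
#' Smax similarities on DBD pair features; cost and gamma are tuned by an
#' internal 3-fold cross-validation over a small grid. Features are
#' standardized by the SVM machinery; predictions are clipped to `[0, 1]`.
#'
#' @param pairs Tibble of training pairs carrying the feature columns
#'   `global_identity`, `local_sim`, `mmk`, `lak` and the target `s_norm`
#'   (pairs should already satisfy the DBD-similarity cutoff).
#' @param min_pairs Minimum admissible number of pairs (default 20).
#' @param features Feature columns to use (allows ablation, e.g. dropping
#'   `mmk`/`lak`).
#' @param seed Seed for the tuning folds.
#' @return A `pfm_svr_fit`.
#' @export
train_pfm_svr <- function(pairs, min_pairs = 20L,
                          features = svr_feature_names(), seed = 42L) {
  if (nrow(pairs) < min_pairs) {
    stop(sprintf(
      "only %d training pairs (< %d); consider pooling superclasses",
      nrow(pairs), min_pairs), call. = FALSE)
  }
  x <- as.matrix(pairs[, features])
  y <- pairs$s_norm
  if (stats::sd(y) < 1e-10) {
    # degenerate targets: the SVM machinery cannot standardize a constant
    # response, and the best predictor is that constant
    return(structure(list(model = NULL, constant = y[1L],
                          features = features,
                          tuned = data.frame(cost = NA, gamma = NA),
                          n_pairs = nrow(x)),
                     class = "pfm_svr_fit"))
  }
  grid <- expand.grid(cost = c(1, 10, 100), gamma = c(0.1, 0.25, 1))
  set.seed(seed)
  fold <- sample(rep_len(1:3, nrow(x)))
  mse <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(1:3, function(f) {
      fit <- e1071::svm(x[fold != f, , drop = FALSE], y[fold != f],
                        type = "eps-regression", kernel = "radial",
                        cost = grid$cost[g], gamma = grid$gamma[g],
                        epsilon = 0.01)
      mean((predict(fit, x[fold == f, , drop = FALSE]) - y[fold == f])^2)
    }, numeric(1)))
  }, numeric(1))
  best <- grid[which.min(mse), ]
  model <- e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                      cost = best$cost, gamma = best$gamma, epsilon = 0.01)
  structure(list(model = model, features = features, tuned = best,
                 n_pairs = nrow(x)),
            class = "pfm_svr_fit")
}

#' Predict normalized PFM similarity from DBD pair features
#'
#' @param fit A `pfm_svr_fit`.
#' @param features Data frame with the fit's feature columns.
#' @return Predicted similarities clipped to `[0, 1]`.
#' @export
predict_pfm_similarity <- function(fit, features) {
  if (is.null(fit$model)) {
    return(rep(min(1, max(0, fit$constant)), nrow(features)))
  }
  p <- predict(fit$model, as.matrix(features[, fit$features]))
  pmin(1, pmax(0, unname(p)))
}

#' @export
print.pfm_svr_fit <- function(x, ...) {
  cat(sprintf("<pfm_svr_fit> %d pairs, features: %s (cost=%g, gamma=%g)\n",
              x$n_pairs, paste(x$features, collapse = ", "),
              x$tuned$cost, x$tuned$gamma))
  invisible(x)
}

#' @export
glance.pfm_svr_fit <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, cost = x$tuned$cost,
                 gamma = x$tuned$gamma,
                 features = paste(x$features, collapse = ","))
}

# per-superclass models with pooled fallback for data-poor superclasses
train_transfer_models <- function(pairs, min_pairs = 20L,
                                  features = svr_feature_names(),
                                  seed = 42L) {
  per_class <- list()
  for (cl in unique(pairs$superclass)) {
    sub <- pairs[pairs$superclass == cl, , drop = FALSE]
    if (nrow(sub) >= min_pairs) {
      per_class[[cl]] <- train_pfm_svr(sub, min_pairs, features, seed)
    }
  }
  pooled <- train_pfm_svr(pairs, min_pairs, features, seed)
  structure(list(per_class = per_class, pooled = pooled),
            class = "transfer_models")
}

predict_transfer_models <- function(models, features, superclass) {
  fit <- models$per_class[[superclass]] %||% models$pooled
  predict_pfm_similarity(fit, features)
}

#' Select best matches under a best-match threshold
#'
#' Dynamic mode: the threshold is the largest value in
#' `[bmt_min, bmt_max]` such that at least one candidate reaches it, i.e.
#' `min(bmt_max, max(predicted))`, provided the best candidate reaches
#' `bmt_min`. Static mode uses the fixed threshold. The prediction
#' confidence is the mean predicted similarity of the selected candidates.
#'
#' @param candidates Tibble with columns `id` and `predicted`.
#' @param config A [transfer_config()].
#' @return List with `possible`, `threshold`, `confidence` and `selected`
#'   (tibble subset); a best candidate below the admissible range yields a
#'   no-prediction outcome (`possible = FALSE`), which is not an error.
#' @export
select_best_matches <- function(candidates, config = transfer_config()) {
  none <- list(possible = FALSE, threshold = NA_real_,
               confidence = NA_real_, selected = candidates[0, ])
  if (nrow(candidates) == 0L) return(none)
  if (identical(config$bmt, "dynamic")) {
    best <- max(candidates$predicted)
    if (best < config$bmt_min) return(none)
    thr <- min(config$bmt_max, best)
  } else {
    thr <- config$bmt
  }
  sel <- candidates[candidates$predicted >= thr - 1e-12, , drop = FALSE]
  if (nrow(sel) == 0L) return(none)
  list(possible = TRUE, threshold = thr,
       confidence = mean(sel$predicted), selected = sel)
}

#' Outlier filter over selected PFMs
#'
#' Single pass: each PFM's mean Smax distance to the other selected matrices
#' is compared with the grand mean of those values; matrices exceeding
#' `tau` times the grand mean are dropped. The filter never empties the set
#' (a sole PFM, or the least-distant one, always survives).
#'
#' @param pfms List of [pfm()] objects.
#' @param tau Outlier factor (> 1).
#' @param distmat Optional precomputed distance matrix (as from
#'   [pfm_distance_matrix()]).
#' @param config A [transfer_config()] supplying Smax parameters when
#'   `distmat` is not given.
#' @return List of surviving `pfm`s (attribute `removed` holds the dropped
#'   indices).
#' @export
outlier_filter <- function(pfms, tau = 1.5, distmat = NULL,
                           config = transfer_config()) {
  n <- length(pfms)
  stopifnot(n >= 1L)
  if (n <= 2L) return(structure(pfms, removed = integer()))
  if (is.null(distmat)) {
    distmat <- pfm_distance_matrix(pfms, config$background, config$alpha_hit,
                                   config$pseudocount)
  }
  mean_d <- (rowSums(distmat)) / (n - 1L)
  grand <- mean(mean_d)
  if (grand < 1e-12) return(structure(pfms, removed = integer()))
  drop <- which(mean_d >= tau * grand - 1e-9)
  if (length(drop) == n) drop <- setdiff(drop, which.min(mean_d))
  keep <- setdiff(seq_len(n), drop)
  structure(pfms[keep], removed = drop)
}

# similarity of two probability columns: Pearson correlation, with a
# degenerate-column convention (equal constants match, unequal do not)
column_similarity <- function(a, b) {
  if (sd(a) < 1e-12 || sd(b) < 1e-12) {
    return(if (max(abs(a - b)) < 1e-9) 1 else 0)
  }
  cor(a, b)
}

# ungapped sliding alignment of profile b (probs + column weights) onto a,
# over both orientations, maximizing summed column similarity
align_profiles <- function(a, b) {
  rc <- function(p) list(probs = p$probs[c(4, 3, 2, 1),
                                         rev(seq_len(ncol(p$probs))),
                                         drop = FALSE],
                         w = rev(p$w))
  best <- NULL
  for (orient in c("forward", "reverse")) {
    bb <- if (orient == "forward") b else rc(b)
    La <- ncol(a$probs); Lb <- ncol(bb$probs)
    for (shift in (-(Lb - 1L)):(La - 1L)) {
      cols <- seq.int(max(1L, shift + 1L), min(La, shift + Lb))
      score <- sum(vapply(cols, function(j) {
        column_similarity(a$probs[, j], bb$probs[, j - shift])
      }, numeric(1)))
      if (is.null(best) || score > best$score + 1e-12) {
        best <- list(score = score, shift = shift, b = bb)
      }
    }
  }
  best
}

combine_profiles <- function(a, best) {
  b <- best$b; shift <- best$shift
  La <- ncol(a$probs); Lb <- ncol(b$probs)
  lo <- min(1L, shift + 1L); hi <- max(La, shift + Lb)
  L <- hi - lo + 1L
  probs <- matrix(0, 4L, L)
  w <- numeric(L)
  a_pos <- seq_len(La) - lo + 1L
  b_pos <- seq_len(Lb) + shift - lo + 1L
  w[a_pos] <- w[a_pos] + a$w
  w[b_pos] <- w[b_pos] + b$w
  probs[, a_pos] <- probs[, a_pos] + sweep(a$probs, 2L, a$w, "*")
  probs[, b_pos] <- probs[, b_pos] + sweep(b$probs, 2L, b$w, "*")
  probs <- sweep(probs, 2L, w, "/")
  probs <- sweep(probs, 2L, colSums(probs), "/")
  list(probs = probs, w = w)
}

#' Progressive PFM merging along a UPGMA guide tree
#'
#' Builds a UPGMA tree on pairwise Smax distances and merges child profiles
#' at each internal node by ungapped sliding-offset alignment over both
#' orientations (maximizing summed Pearson column similarity); aligned
#' columns are averaged weighted by the number of contributing source
#' matrices, overhangs are kept, and columns re-normalized.
#'
#' @param pfms List of [pfm()] objects (at least one).
#' @param distmat Optional precomputed distance matrix.
#' @param config A [transfer_config()].
#' @param id Identifier for the merged motif.
#' @return The consensus [pfm()].
#' @export
merge_pfms <- function(pfms, distmat = NULL, config = transfer_config(),
                       id = "consensus") {
  n <- length(pfms)
  stopifnot(n >= 1L)
  if (n == 1L) return(pfms[[1L]])
  profiles <- lapply(pfms, function(p) {
    list(probs = p$probabilities, w = rep(1, ncol(p$probabilities)))
  })
  if (n == 2L) {
    merged <- combine_profiles(profiles[[1L]],
                               align_profiles(profiles[[1L]], profiles[[2L]]))
    return(pfm(merged$probs, id = id))
  }
  if (is.null(distmat)) {
    distmat <- pfm_distance_matrix(pfms, config$background, config$alpha_hit,
                                   config$pseudocount)
  }
  hc <- stats::hclust(stats::as.dist(distmat), method = "average")
  nodes <- vector("list", nrow(hc$merge))
  get_node <- function(i) if (i < 0) profiles[[-i]] else nodes[[i]]
  for (r in seq_len(nrow(hc$merge))) {
    a <- get_node(hc$merge[r, 1L])
    b <- get_node(hc$merge[r, 2L])
    nodes[[r]] <- combine_profiles(a, align_profiles(a, b))
  }
  final <- nodes[[nrow(hc$merge)]]
  pfm(final$probs, id = id)
}

#' Transfer a DNA motif to a query TF
#'
#' Runs the full transfer for one query: DBD pair features against every
#' eligible training TF of the query's superclass (normalized local
#' alignment similarity above the config cutoff), SVR-predicted PFM
#' similarities, best-match selection, outlier filtering and progressive
#' merging.
#'
#' @param query List or one-row tibble with `dbd_sequence` and `superclass`.
#' @param train_set Tibble with columns `id`, `superclass`, `dbd_sequence`
#'   and `pfm` (list column of [pfm()]s).
#' @param models A `transfer_models` / `pfm_svr_fit` object.
#' @param config A [transfer_config()].
#' @return List with `possible`, `threshold`, `confidence`, `best_matches`
#'   (tibble with predictions and selection flags) and `pfm` (the merged
#'   motif, or `NULL` for a no-prediction outcome).
#' @export
motif_transfer <- function(query, train_set, models,
                           config = transfer_config()) {
  cand <- train_set[train_set$superclass == query$superclass[[1]], ,
                    drop = FALSE]
  if (nrow(cand) > 0L) {
    sim <- vapply(cand$dbd_sequence, function(s) {
      local_similarity(query$dbd_sequence[[1]], s, config$scheme)
    }, numeric(1))
    cand <- cand[sim > config$min_dbd_similarity, , drop = FALSE]
  }
  if (nrow(cand) == 0L) {
    return(list(possible = FALSE, threshold = NA_real_,
                confidence = NA_real_, best_matches = cand, pfm = NULL))
  }
  feats <- purrr::map_dfr(cand$dbd_sequence, function(s) {
    dbd_pair_features(query$dbd_sequence[[1]], s, config$scheme, config$beta)
  })
  cand$predicted <- if (inherits(models, "pfm_svr_fit")) {
    predict_pfm_similarity(models, feats)
  } else {
    predict_transfer_models(models, feats, query$superclass[[1]])
  }
  sel <- select_best_matches(cand[, c("id", "predicted")], config)
  if (!sel$possible) {
    return(list(possible = FALSE, threshold = NA_real_,
                confidence = NA_real_, best_matches = cand, pfm = NULL))
  }
  keep <- cand$id %in% sel$selected$id
  pfms <- cand$pfm[keep]
  filtered <- outlier_filter(pfms, config$tau, config = config)
  merged <- merge_pfms(filtered, config = config,
                       id = paste0("consensus_", nrow(sel$selected)))
  cand$selected <- keep
  list(possible = TRUE, threshold = sel$threshold,
       confidence = sel$confidence, best_matches = cand, pfm = merged)
}

# --- transfer evaluation protocol --------------------------------------------

#' Held-out SVR predictions of PFM similarity
#'
#' Stratified k-fold protocol isolating the regression stage: SVR models are
#' trained on the DBD pairs internal to each training split and used to
#' predict the normalized Smax similarity of every held-out-TF/training-TF
#' pair, alongside the realized similarity. Used to measure parameter
#' recovery (e.g. Spearman correlation of predicted vs realized similarity).
#'
#' @inheritParams pfm_transfer_eval
#' @return Tibble with `fold`, `query`, `train_id`, `superclass`,
#'   `predicted`, `realized`.
#' @export
svr_holdout_predictions <- function(tf_set, config = transfer_config(),
                                    n_folds = 4L, seed = 42L,
                                    features = svr_feature_names()) {
  preps <- pfm_prep_cache(tf_set$pfm, config$background, config$alpha_hit,
                          config$pseudocount)
  pairs <- transfer_pair_table(tf_set, config, preps)
  folds <- stratified_folds(tf_set$superclass, n_folds, seed = seed)
  out <- list()
  for (f in seq_len(n_folds)) {
    train_ids <- tf_set$id[folds$fold != f]
    test_ids <- tf_set$id[folds$fold == f]
    train_pairs <- pairs[pairs$id1 %in% train_ids & pairs$id2 %in% train_ids, ]
    models <- train_transfer_models(train_pairs, features = features,
                                    seed = seed)
    cand <- pairs[(pairs$id1 %in% test_ids & pairs$id2 %in% train_ids) |
                    (pairs$id2 %in% test_ids & pairs$id1 %in% train_ids), ]
    if (nrow(cand) == 0L) next
    pred <- vapply(seq_len(nrow(cand)), function(i) {
      predict_transfer_models(models, cand[i, , drop = FALSE],
                              cand$superclass[i])
    }, numeric(1))
    out[[f]] <- tibble::tibble(
      fold = f,
      query = ifelse(cand$id1 %in% test_ids, cand$id1, cand$id2),
      train_id = ifelse(cand$id1 %in% test_ids, cand$id2, cand$id1),
      superclass = cand$superclass,
      predicted = pred,
      realized = cand$s_norm)
  }
  dplyr::bind_rows(out)
}

# all same-superclass DBD pairs above the similarity cutoff, with features
# and realized normalized Smax similarity
transfer_pair_table <- function(tf_set, config, preps) {
  out <- list()
  for (cl in unique(tf_set$superclass)) {
    idx <- which(tf_set$superclass == cl)
    if (length(idx) < 2L) next
    for (a in seq_len(length(idx) - 1L)) {
      for (b in (a + 1L):length(idx)) {
        i <- idx[a]; j <- idx[b]
        ls <- local_similarity(tf_set$dbd_sequence[i], tf_set$dbd_sequence[j],
                               config$scheme)
        if (ls <= config$min_dbd_similarity) next
        f <- dbd_pair_features(tf_set$dbd_sequence[i], tf_set$dbd_sequence[j],
                               config$scheme, config$beta)
        out[[length(out) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(id1 = tf_set$id[i], id2 = tf_set$id[j],
                         superclass = cl), f,
          tibble::tibble(s_norm = snorm_from_preps(preps[[i]], preps[[j]])))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Cross-validated PFM transfer error and transfer rate
#'
#' Stratified (by superclass) k-fold protocol: for each held-out TF, motif
#' transfer is attempted from the training folds, and for every best-match
#' threshold on the grid the protocol records whether a prediction was
#' possible (transfer rate) and, when possible, the `[0, 1]` Smax distance
#' between the merged prediction and the annotated PFM (transfer error).
#' A dynamic-threshold row is appended for comparison with the fixed grid.
#'
#' @param tf_set Tibble with `id`, `superclass`, `dbd_sequence`, `pfm`
#'   (every TF carries an annotated PFM and a DBD sequence).
#' @param config A [transfer_config()].
#' @param n_folds Folds (default 4).
#' @param seed Fold seed.
#' @param thresholds Best-match threshold grid (default 10 values over
#'   `[0.5, 0.95]`).
#' @param features SVR feature columns (for ablation studies).
#' @return A `transfer_eval` tibble: `mode`, `threshold`, `transfer_rate`,
#'   `transfer_error`, `n_queries`, `n_predicted`.
#' @export
pfm_transfer_eval <- function(tf_set, config = transfer_config(),
                              n_folds = 4L, seed = 42L,
                              thresholds = seq(0.5, 0.95, by = 0.05),
                              features = svr_feature_names()) {
  n <- nrow(tf_set)
  preps <- pfm_prep_cache(tf_set$pfm, config$background, config$alpha_hit,
                          config$pseudocount)
  pairs <- transfer_pair_table(tf_set, config, preps)
  folds <- stratified_folds(tf_set$superclass, n_folds, seed = seed)
  modes <- c(as.list(thresholds), list("dynamic"))
  rec <- list()
  for (f in seq_len(n_folds)) {
    train_ids <- tf_set$id[folds$fold != f]
    test_idx <- which(folds$fold == f)
    train_pairs <- pairs[pairs$id1 %in% train_ids & pairs$id2 %in% train_ids, ]
    models <- train_transfer_models(train_pairs, features = features,
                                    seed = seed)
    for (qi in test_idx) {
      qid <- tf_set$id[qi]
      cand <- pairs[(pairs$id1 == qid & pairs$id2 %in% train_ids) |
                      (pairs$id2 == qid & pairs$id1 %in% train_ids), ]
      if (nrow(cand) > 0L) {
        cand_tbl <- tibble::tibble(
          id = ifelse(cand$id1 == qid, cand$id2, cand$id1),
          predicted = predict_transfer_models(models, cand,
                                              tf_set$superclass[qi]))
      } else {
        cand_tbl <- tibble::tibble(id = character(), predicted = numeric())
      }
      merge_cache <- new.env(parent = emptyenv())
      for (mode in modes) {
        cfg <- config
        cfg$bmt <- mode
        sel <- select_best_matches(cand_tbl, cfg)
        thr_label <- if (identical(mode, "dynamic")) NA_real_ else mode
        if (!sel$possible) {
          rec[[length(rec) + 1L]] <- tibble::tibble(
            mode = if (identical(mode, "dynamic")) "dynamic" else "static",
            threshold = thr_label, query = qid, predicted = FALSE,
            error = NA_real_)
          next
        }
        key <- paste(sort(sel$selected$id), collapse = "|")
        err <- merge_cache[[key]]
        if (is.null(err)) {
          sel_idx <- match(sel$selected$id, tf_set$id)
          sub_d <- outer(sel_idx, sel_idx, Vectorize(function(i, j) {
            if (i == j) 0 else
              min(1, max(0, 1 - snorm_from_preps(preps[[i]], preps[[j]])))
          }))
          filtered_idx <- sel_idx
          pfms <- tf_set$pfm[sel_idx]
          filt <- outlier_filter(pfms, cfg$tau, distmat = sub_d, config = cfg)
          kept <- setdiff(seq_along(pfms), attr(filt, "removed"))
          merged <- merge_pfms(filt, distmat = sub_d[kept, kept, drop = FALSE],
                               config = cfg)
          mp <- prep_pfm(merged, cfg$background, cfg$alpha_hit,
                         cfg$pseudocount)
          mprc <- prep_pfm(reverse_complement(merged), cfg$background,
                           cfg$alpha_hit, cfg$pseudocount)
          mprep <- list(fw = mp, rc = mprc,
                        self = max(smax_pair(mp, mp, mprc)$s))
          err <- min(1, max(0, 1 - snorm_from_preps(mprep, preps[[qi]])))
          merge_cache[[key]] <- err
        }
        rec[[length(rec) + 1L]] <- tibble::tibble(
          mode = if (identical(mode, "dynamic")) "dynamic" else "static",
          threshold = thr_label, query = qid, predicted = TRUE, error = err)
      }
    }
  }
  per_query <- dplyr::bind_rows(rec)
  out <- per_query |>
    dplyr::group_by(.data$mode, .data$threshold) |>
    dplyr::summarise(
      transfer_rate = mean(.data$predicted),
      transfer_error = mean(.data$error[.data$predicted]),
      n_queries = dplyr::n(),
      n_predicted = sum(.data$predicted),
      .groups = "drop") |>
    dplyr::arrange(.data$mode == "dynamic", .data$threshold)
  attr(out, "per_query") <- per_query
  class(out) <- c("transfer_eval", class(out))
  out
}
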