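# Smax log-odds PFM similarity.
#
# A "hit" of a motif is a length-L window whose log2-odds score (motif
# probabilities with pseudocount against an iid background) reaches a
# threshold chosen so that the exact background exceedance probability is at
# most alpha_hit. gamma_XY(k) is the probability that a random iid sequence
# carries a hit of X at position 0 and a hit of Y at offset k simultaneously;
# s(k) = log2(gamma(k) / (alpha_X * alpha_Y)) compares that joint probability
# with independence, and Smax maximizes s(k) over all overlapping offsets,
# both orders and both strand orientations. The normalized similarity is
# Smax(X,Y) / sqrt(Smax(X,X) * Smax(Y,Y)) and 1 minus it, clipped to [0, 1],
# is the PFM distance used to measure transfer error.
#
# All probabilities are computed exactly: score distributions by recursive
# convolution over positions, and gamma by enumerating the letters of the
# overlap window (the residual, non-shared positions of the two windows are
# independent given the overlap letters, so their exact tail probabilities
# factor out). Only when an overlap exceeds `max_shared` positions are the
# least-informative shared columns treated as non-shared (an approximation
# never reached at default motif lengths).

.sim_cache <- new.env(parent = emptyenv())

letters_matrix <- function(ov) {
  key <- as.character(ov)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  n <- 4L^ov
  m <- vapply(seq_len(ov), function(j) {
    as.integer(((seq_len(n) - 1L) %/% 4L^(j - 1L)) %% 4L) + 1L
  }, integer(n))
  m <- matrix(m, nrow = n)
  if (ov <= 8L) .sim_cache[[key]] <- m
  m
}

# per-position log2-odds scores of a pfm against the background
pfm_log_odds <- function(p, background = rep(0.25, 4), pseudocount = 0.01) {
  pr <- (p$probabilities + pseudocount) / (1 + 4 * pseudocount)
  log2(sweep(pr, 1L, background, "/"))
}

aggregate_dist <- function(support, prob, limit = 2e5) {
  key <- round(support * 1e9)
  if (length(key) > limit) {
    key <- round(support * 1e4)
    support <- key / 1e4
  }
  o <- order(key)
  key <- key[o]; support <- support[o]; prob <- prob[o]
  first <- c(TRUE, diff(key) != 0)
  grp <- cumsum(first)
  list(support = support[first],
       prob = as.numeric(rowsum(prob, grp)))
}

# exact distribution of the summed score over the given columns
score_distribution <- function(scores, cols, background) {
  support <- 0; prob <- 1
  for (j in cols) {
    support <- outer(support, scores[, j], "+")
    prob <- outer(prob, background, "*")
    d <- aggregate_dist(as.numeric(support), as.numeric(prob))
    support <- d$support; prob <- d$prob
  }
  list(support = support, prob = prob,
       tail = rev(cumsum(rev(prob))))
}

# P(S >= v) for each v, with a 1e-9 tolerance on the comparison
tail_prob <- function(dist, v) {
  idx <- findInterval(v - 1e-9, dist$support)
  c(dist$tail, 0)[idx + 1L]
}

#' Hit threshold and hit probability of a PFM
#'
#' Scores every length-L window by summed per-position log2-odds (motif
#' probabilities with pseudocount over the background) and returns the
#' smallest achievable score threshold whose exact background exceedance
#' probability is at most `alpha_hit`, together with that probability. If
#' even the maximum score is more probable than `alpha_hit`, the maximum
#' score is used. The score distribution is computed exactly by convolution
#' over positions.
#'
#' @param p A [pfm()].
#' @param background Nucleotide distribution (A, C, G, T), default uniform.
#' @param alpha_hit Per-window significance level (default 0.01).
#' @param pseudocount Added to each probability entry before log-odds.
#' @return List with `threshold`, `alpha` (exact exceedance probability at
#'   the threshold), and the per-position `scores` matrix.
#' @export
#' @examples
#' p <- pfm(matrix(c(1, 0, 0, 0), nrow = 4), id = "A")
#' hit_probability(p, alpha_hit = 0.3)$alpha  # 0.25: only A qualifies
hit_probability <- function(p, background = rep(0.25, 4), alpha_hit = 0.01,
                            pseudocount = 0.01) {
  stopifnot(length(background) == 4L, all(background > 0),
            abs(sum(background) - 1) < 1e-6)
  scores <- pfm_log_odds(p, background, pseudocount)
  dist <- score_distribution(scores, seq_len(ncol(scores)), background)
  ok <- dist$tail <= alpha_hit + 1e-12
  thr <- if (any(ok)) dist$support[which(ok)[1L]] else max(dist$support)
  alpha <- tail_prob(dist, thr)
  list(threshold = thr, alpha = alpha, scores = scores, dist = dist)
}

# prepared representation of one oriented pfm: scores, threshold, alpha and
# memoised residual (non-shared column) score distributions
prep_pfm <- function(p, background, alpha_hit, pseudocount) {
  hp <- hit_probability(p, background, alpha_hit, pseudocount)
  env <- new.env(parent = emptyenv())
  env$scores <- hp$scores
  env$L <- ncol(hp$scores)
  env$threshold <- hp$threshold
  env$alpha <- hp$alpha
  env$background <- background
  env$memo <- new.env(parent = emptyenv())
  env
}

residual_dist <- function(prep, cols) {
  key <- paste(cols, collapse = ",")
  d <- prep$memo[[key]]
  if (is.null(d)) {
    d <- score_distribution(prep$scores, cols, prep$background)
    prep$memo[[key]] <- d
  }
  d
}

# joint hit probability of X at positions 1..Lx and Y at positions
# (k+1)..(k+Ly) of a random iid sequence; offsets must overlap
gamma_offset <- function(px, py, k, max_shared = 10L) {
  ov <- seq.int(max(1L, k + 1L), min(px$L, k + py$L))
  stopifnot(length(ov) >= 1L)
  x_sh <- ov; y_sh <- ov - k
  x_res <- setdiff(seq_len(px$L), x_sh)
  y_res <- setdiff(seq_len(py$L), y_sh)
  if (length(ov) > max_shared) {
    info <- vapply(seq_along(ov), function(i) {
      diff(range(px$scores[, x_sh[i]])) + diff(range(py$scores[, y_sh[i]]))
    }, numeric(1))
    drop <- order(info)[seq_len(length(ov) - max_shared)]
    x_res <- sort(c(x_res, x_sh[drop]))
    y_res <- sort(c(y_res, y_sh[drop]))
    x_sh <- x_sh[-drop]; y_sh <- y_sh[-drop]
  }
  n_sh <- length(x_sh)
  M <- letters_matrix(n_sh)
  sx <- numeric(nrow(M)); sy <- numeric(nrow(M)); bgp <- rep(1, nrow(M))
  bg <- px$background
  for (j in seq_len(n_sh)) {
    sx <- sx + px$scores[M[, j], x_sh[j]]
    sy <- sy + py$scores[M[, j], y_sh[j]]
    bgp <- bgp * bg[M[, j]]
  }
  tx <- if (length(x_res) == 0L) {
    as.numeric(sx >= px$threshold - 1e-9)
  } else {
    tail_prob(residual_dist(px, x_res), px$threshold - sx)
  }
  ty <- if (length(y_res) == 0L) {
    as.numeric(sy >= py$threshold - 1e-9)
  } else {
    tail_prob(residual_dist(py, y_res), py$threshold - sy)
  }
  sum(bgp * tx * ty)
}

# max of s(k) over overlapping offsets for one orientation pair
smax_orientation <- function(px, py, orientation) {
  ks <- seq.int(-(py$L - 1L), px$L - 1L)
  s <- vapply(ks, function(k) {
    g <- gamma_offset(px, py, k)
    if (g <= 0) -Inf else log2(g / (px$alpha * py$alpha))
  }, numeric(1))
  tibble::tibble(orientation = orientation, offset = ks, s = s)
}

smax_pair <- function(px, py_fw, py_rc) {
  rbind(smax_orientation(px, py_fw, "forward"),
        smax_orientation(px, py_rc, "reverse"))
}

#' Smax log-odds similarity and distance of two PFMs
#'
#' Computes gamma, the per-offset log-odds scores, their maximum Smax over
#' offsets, orders and orientations, the similarity normalized by the
#' geometric mean of the self-similarities, and the `[0, 1]` distance
#' `1 - s_norm` (clipped). A pair with no co-occurrence signal (all gamma
#' zero, or negative Smax from anti-correlated motifs) gets `s_norm = 0`,
#' distance 1.
#'
#' @param x,y [pfm()] objects.
#' @inheritParams hit_probability
#' @return A `pfm_similarity`: list with `smax`, `s_norm`, `distance`,
#'   `alpha_x`, `alpha_y`, and `offsets` (tibble of per-offset scores).
#' @export
smax_similarity <- function(x, y, background = rep(0.25, 4),
                            alpha_hit = 0.01, pseudocount = 0.01) {
  px <- prep_pfm(x, background, alpha_hit, pseudocount)
  py <- prep_pfm(y, background, alpha_hit, pseudocount)
  px_rc <- prep_pfm(reverse_complement(x), background, alpha_hit, pseudocount)
  py_rc <- prep_pfm(reverse_complement(y), background, alpha_hit, pseudocount)
  offsets <- smax_pair(px, py, py_rc)
  smax_xy <- max(offsets$s)
  s_xx <- max(smax_pair(px, px, px_rc)$s)
  s_yy <- max(smax_pair(py, py, py_rc)$s)
  s_norm <- normalize_smax(smax_xy, s_xx, s_yy)
  structure(list(smax = smax_xy, s_norm = s_norm,
                 distance = min(1, max(0, 1 - s_norm)),
                 alpha_x = px$alpha, alpha_y = py$alpha,
                 smax_xx = s_xx, smax_yy = s_yy, offsets = offsets),
            class = "pfm_similarity")
}

normalize_smax <- function(smax_xy, s_xx, s_yy) {
  if (!is.finite(smax_xy) || smax_xy <= 0 || s_xx <= 0 || s_yy <= 0) return(0)
  smax_xy / sqrt(s_xx * s_yy)
}

#' @export
print.pfm_similarity <- function(x, ...) {
  cat(sprintf("<pfm_similarity> smax = %.3f, s_norm = %.3f, distance = %.3f\n",
              x$smax, x$s_norm, x$distance))
  invisible(x)
}

#' @export
glance.pfm_similarity <- function(x, ...) {
  tibble::tibble(smax = x$smax, s_norm = x$s_norm, distance = x$distance,
                 alpha_x = x$alpha_x, alpha_y = x$alpha_y)
}

#' PFM distance
#'
#' Convenience wrapper returning only the `[0, 1]` Smax distance.
#'
#' @inheritParams smax_similarity
#' @return Numeric distance in `[0, 1]`.
#' @export
pfm_distance <- function(x, y, background = rep(0.25, 4), alpha_hit = 0.01,
                         pseudocount = 0.01) {
  smax_similarity(x, y, background, alpha_hit, pseudocount)$distance
}

# cache of prepared orientations + self-smax, for repeated pair computations
pfm_prep_cache <- function(pfms, background = rep(0.25, 4), alpha_hit = 0.01,
                           pseudocount = 0.01) {
  lapply(pfms, function(p) {
    fw <- prep_pfm(p, background, alpha_hit, pseudocount)
    rc <- prep_pfm(reverse_complement(p), background, alpha_hit, pseudocount)
    list(fw = fw, rc = rc, self = max(smax_pair(fw, fw, rc)$s))
  })
}

snorm_from_preps <- function(pi, pj) {
  smax_xy <- max(smax_pair(pi$fw, pj$fw, pj$rc)$s)
  normalize_smax(smax_xy, pi$self, pj$self)
}

#' Pairwise Smax distance matrix
#'
#' @param pfms List of [pfm()] objects.
#' @inheritParams hit_probability
#' @return Symmetric matrix of `[0, 1]` distances (zero diagonal).
#' @export
pfm_distance_matrix <- function(pfms, background = rep(0.25, 4),
                                alpha_hit = 0.01, pseudocount = 0.01) {
  n <- length(pfms)
  preps <- pfm_prep_cache(pfms, background, alpha_hit, pseudocount)
  d <- matrix(0, n, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <-
          min(1, max(0, 1 - snorm_from_preps(preps[[i]], preps[[j]])))
      }
    }
  }
  ids <- vapply(pfms, `[[`, character(1), "id")
  dimnames(d) <- list(ids, ids)
  d
}
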