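# Independent oracles and shared fixtures. The oracles deliberately use
# plain, brute-force implementations (textbook DP, exhaustive enumeration)
# so they stay independent of the package's computational paths.

# textbook affine-gap Smith-Waterman, O(nm) with explicit state matrices
sw_oracle <- function(a, b, submat, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)      # match/mismatch state
  X <- matrix(-Inf, n + 1, m + 1)   # gap in b (vertical)
  Y <- matrix(-Inf, n + 1, m + 1)   # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) +
                          submat[A[i - 1], B[j - 1]])
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

random_protein <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q", "E",
                                           "G", "H", "I", "L", "K", "M", "F",
                                           "P", "S", "T", "W", "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# exhaustive joint-hit probability: enumerate every sequence of the covering
# window of X (at offset 0) and Y (at offset k), score both windows, count
gamma_oracle <- function(x_pfm, y_pfm, k, alpha_hit = 0.01) {
  hx <- hit_probability(x_pfm, alpha_hit = alpha_hit)
  hy <- hit_probability(y_pfm, alpha_hit = alpha_hit)
  Lx <- ncol(hx$scores); Ly <- ncol(hy$scores)
  lo <- min(1, k + 1); hi <- max(Lx, k + Ly)
  W <- hi - lo + 1
  letters <- as.matrix(expand.grid(rep(list(1:4), W)))
  score_at <- function(scores, cols_in_window, motif_cols) {
    idx <- cbind(as.vector(letters[, cols_in_window]),
                 rep(motif_cols, each = nrow(letters)))
    rowSums(matrix(scores[idx], ncol = length(motif_cols)))
  }
  sx <- score_at(hx$scores, (1:Lx) - lo + 1, 1:Lx)
  sy <- score_at(hy$scores, (k + 1):(k + Ly) - lo + 1, 1:Ly)
  sum((0.25^W) * (sx >= hx$threshold - 1e-9) * (sy >= hy$threshold - 1e-9))
}

random_pfm <- function(L, id = "p", sharp = FALSE) {
  counts <- matrix(stats::runif(4 * L, 0.5, 10), nrow = 4)
  if (sharp) {
    for (j in seq_len(L)) counts[sample(4, 1), j] <- 40
  }
  pfm(counts, id = id)
}

# shared heavy fixtures, built once per test run
.fixture_env <- new.env(parent = emptyenv())

transfer_fixture <- function() {
  if (is.null(.fixture_env$ts)) {
    .fixture_env$ts <- gen_transfer_set(n_families = 20,
                                        members_per_family = 4,
                                        divergence = 0.2, seed = 42)
  }
  .fixture_env$ts
}

proteome_fixture <- function() {
  if (is.null(.fixture_env$prot)) {
    prot <- gen_proteome(n_tf = c("Basic domain" = 12, "Zinc finger" = 12,
                                  "Helix-turn-helix" = 12,
                                  "Beta scaffold" = 12, "Other" = 12),
                         n_nontf = 120, seed = 42)
    prot$hits <- search_all(prot$records, prot$records, exclude_self = TRUE)
    .fixture_env$prot <- prot
  }
  .fixture_env$prot
}

toy_proteins <- function() {
  tibble::tibble(
    id = c("T1", "T2", "N1"),
    sequence = c("MKRERRKQSNRESARRSRLRK", "MKRERRKQSNKESARRSRLRK",
                 "GASTWNPQHKYVMDEFILCR"),
    label = c("TF", "TF", "non-TF"),
    superclass = c("Basic domain", "Basic domain", NA),
    source = "unit")
}
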