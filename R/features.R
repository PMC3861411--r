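# The five sequence feature encodings compared for TF classification:
# bit-score percentiles, compressed PSSM profiles, k-mer counts, pseudo
# amino-acid composition, and functional domain composition.

# --- bit-score percentile features -------------------------------------------

#' Bit-score percentile features for one query
#'
#' Summarizes the class-conditional bit-score distributions of a hit list by
#' five percentiles per class — minimum (p0), lower quartile (p25), median
#' (p50), upper quartile (p75) and maximum (p100) — concatenated in the given
#' class order. Quartiles use linear interpolation between order statistics
#' (quantile type 7); the rule matters for small hit lists and is therefore
#' fixed and documented. A class with no hits contributes a zero block and is
#' listed in the `missing_classes` attribute (predictions are impossible only
#' when *no* hit at all is found, not when one class block is empty).
#'
#' @param hits Hit tibble for a single query (see [search_db()]).
#' @param classes Ordered class vector, e.g. `c("TF", "non-TF")` or
#'   [tf_superclasses()].
#' @param class_col Column of `hits` holding the class of each subject
#'   (`"label"` for the binary task, `"superclass"` for superclasses).
#' @return Named numeric vector of length `5 * length(classes)` with attribute
#'   `missing_classes`.
#' @export
#' @examples
#' h <- tibble::tibble(query_id = "q", subject_id = letters[1:5],
#'                     label = c("TF", "TF", "TF", "non-TF", "non-TF"),
#'                     superclass = NA, raw_score = NA,
#'                     bits = c(30, 25, 20, 12, 10))
#' bitscore_percentiles(h, c("TF", "non-TF"))
bitscore_percentiles <- function(hits, classes, class_col = "label") {
  cls <- hits[[class_col]]
  out <- numeric(0)
  missing <- character(0)
  for (cl in classes) {
    b <- hits$bits[!is.na(cls) & cls == cl]
    if (length(b) == 0L) {
      block <- rep(0, 5)
      missing <- c(missing, cl)
    } else {
      block <- unname(quantile(b, probs = c(0, .25, .5, .75, 1), type = 7))
    }
    out <- c(out, block)
  }
  names(out) <- paste0(rep(gsub("[^A-Za-z]", "", classes), each = 5),
                       "_p", rep(c(0, 25, 50, 75, 100), length(classes)))
  attr(out, "missing_classes") <- missing
  out
}

#' Percentile feature matrix for a set of records
#'
#' Applies [bitscore_percentiles()] to every record's hits, optionally first
#' restricting the usable subjects (and hence the class labels consulted) to a
#' training subset — the restriction keeps cross-validation leakage-free.
#'
#' @param records Protein tibble (rows define the output rows, in order).
#' @param hits Hit tibble covering the records (column `query_id`).
#' @param classes,class_col As in [bitscore_percentiles()].
#' @param subject_ids Optional character vector; only hits whose `subject_id`
#'   is listed are used.
#' @return Numeric matrix, one row per record, `5 * length(classes)` columns.
#' @export
percentile_feature_matrix <- function(records, hits, classes,
                                      class_col = "label",
                                      subject_ids = NULL) {
  if (!is.null(subject_ids)) {
    hits <- hits[hits$subject_id %in% subject_ids, , drop = FALSE]
  }
  by_query <- split(hits, factor(hits$query_id, levels = records$id))
  m <- t(vapply(records$id, function(id) {
    as.numeric(bitscore_percentiles(by_query[[id]], classes, class_col))
  }, numeric(5L * length(classes))))
  colnames(m) <- names(bitscore_percentiles(empty_hit_tbl(), classes, class_col))
  rownames(m) <- records$id
  m
}

# --- PSSM profile features ---------------------------------------------------

# Robinson-Robinson background amino-acid frequencies (order of aa_alphabet)
aa_background <- function() {
  f <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
         Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
         L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
         S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  f[aa_alphabet()] / sum(f)
}

#' Compressed PSSM profile features
#'
#' Builds a position-specific scoring matrix for the query from the residues
#' its database hits align to each query position (single alignment pass,
#' +1 pseudocounts, log2-odds against the Robinson-Robinson background),
#' compresses the n x 20 PSSM to 20 x 20 by summing rows that share the same
#' query residue, divides by the sequence length, squashes every entry with
#' the logistic function g(x) = 1 / (1 + exp(-x)), and flattens row-major to
#' a 400-dimensional vector. With no hits the PSSM degenerates to the query's
#' own composition prior and the result carries attribute `no_hits = TRUE`.
#'
#' @param query Single-row protein tibble.
#' @param hit_db Protein tibble holding the hit subjects' sequences (usually
#'   the database rows matching a hit list from [search_db()]).
#' @param scheme A [scoring_scheme()] used to re-align hits to the query.
#' @return Named numeric vector of length 400, entries in (0, 1).
#' @export
pssm_features <- function(query, hit_db, scheme = scoring_scheme()) {
  aa <- aa_alphabet()
  qseq <- strsplit(query$sequence[[1]], "")[[1]]
  n <- length(qseq)
  counts <- matrix(0L, nrow = n, ncol = 20L, dimnames = list(NULL, aa))
  # the query itself always contributes
  qi <- match(qseq, aa)
  ok <- !is.na(qi)
  counts[cbind(which(ok), qi[ok])] <- counts[cbind(which(ok), qi[ok])] + 1L
  no_hits <- is.null(hit_db) || nrow(hit_db) == 0L
  if (!no_hits) {
    # pattern = hit set, subject = query (pairwiseAlignment vectorizes over
    # the pattern side); the query-side strings come from alignedSubject
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(hit_db$sequence),
      Biostrings::AAString(query$sequence[[1]]),
      substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
      type = "local"
    )
    pat <- as.character(Biostrings::alignedSubject(aln))  # query side
    sub <- as.character(Biostrings::alignedPattern(aln))  # hit side
    starts <- Biostrings::start(Biostrings::subject(aln))
    for (i in seq_along(pat)) {
      p <- strsplit(pat[i], "")[[1]]
      s <- strsplit(sub[i], "")[[1]]
      qpos <- starts[i] - 1L + cumsum(p != "-")
      keep <- p != "-" & s != "-"
      si <- match(s[keep], aa)
      qp <- qpos[keep]
      good <- !is.na(si)
      if (any(good)) {
        idx <- cbind(qp[good], si[good])
        # accumulate (duplicated rows possible only across hits, not within)
        for (r in seq_len(nrow(idx))) {
          counts[idx[r, 1L], idx[r, 2L]] <- counts[idx[r, 1L], idx[r, 2L]] + 1L
        }
      }
    }
  }
  bg <- aa_background()
  probs <- (counts + 1) / (rowSums(counts) + 20)
  pssm <- log2(sweep(probs, 2L, bg, "/"))
  # compress by query residue
  comp <- matrix(0, 20L, 20L, dimnames = list(aa, aa))
  for (a in aa) {
    rows <- which(qseq == a)
    if (length(rows) > 0L) {
      comp[a, ] <- colSums(pssm[rows, , drop = FALSE])
    }
  }
  v <- as.numeric(t(comp)) # row-major flatten
  v <- 1 / (1 + exp(-(v / n)))
  names(v) <- paste0(rep(aa, each = 20L), "_", rep(aa, 20L))
  v <- structure(v, no_hits = no_hits)
  v
}

# --- k-mer features ----------------------------------------------------------

#' Overlapping k-mer count features
#'
#' Counts occurrences of every length-k subsequence over the 20-letter
#' alphabet (overlapping windows, fixed lexicographic order following
#' [aa_alphabet()]), yielding a `20^k` vector. Windows containing a
#' non-canonical residue (`X`) are skipped.
#'
#' @param seq Amino-acid sequence (single string).
#' @param k Subsequence length (default 2, i.e. 400 dimensions).
#' @return Named integer vector of length `20^k`.
#' @export
#' @examples
#' kmer_features("ACA", k = 2)[c("AC", "CA")]
kmer_features <- function(seq, k = 2L) {
  aa <- aa_alphabet()
  stopifnot(k >= 1L)
  n <- nchar(seq)
  # lexicographic names: first character most significant
  dim_names <- Reduce(function(acc, .) as.vector(t(outer(acc, aa, paste0))),
                      seq_len(k - 1L), aa)
  counts <- setNames(integer(20L^k), dim_names)
  if (k > n) {
    warning("k exceeds sequence length; returning all-zero vector")
    return(counts)
  }
  code <- match(strsplit(seq, "")[[1]], aa)  # NA for non-canonical residues
  win <- vapply(0:(k - 1L), function(j) code[(1L + j):(n - k + 1L + j)],
                numeric(n - k + 1L))
  win <- matrix(win, ncol = k)
  idx <- as.vector(1L + (win - 1L) %*% 20L^((k - 1L):0))
  idx <- idx[!is.na(idx)]
  tab <- tabulate(idx, nbins = 20L^k)
  counts[] <- tab
  counts
}

# --- pseudo amino-acid features ----------------------------------------------

# Chou's original property triple: hydrophobicity, hydrophilicity and
# side-chain mass, in aa_alphabet() order.
aa_property_scales <- function() {
  aa <- aa_alphabet()
  h1 <- c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29, Q = -0.85,
          E = -0.74, G = 0.48, H = -0.40, I = 1.38, L = 1.06, K = -1.50,
          M = 0.64, F = 1.19, P = 0.12, S = -0.18, T = -0.05, W = 0.81,
          Y = 0.26, V = 1.08)
  h2 <- c(A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2, E = 3.0,
          G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0, M = -1.3,
          F = -2.5, P = 0.0, S = 0.3, T = -0.4, W = -3.4, Y = -2.3,
          V = -1.5)
  m <- c(A = 15, R = 101, N = 58, D = 59, C = 47, Q = 72, E = 73, G = 1,
         H = 82, I = 57, L = 57, K = 73, M = 75, F = 91, P = 42, S = 31,
         T = 45, W = 130, Y = 107, V = 43)
  scales <- rbind(h1[aa], h2[aa], m[aa])
  # standardize each property to zero mean / unit variance over the 20 residues
  t(apply(scales, 1L, function(x) (x - mean(x)) / sd(x)))
}

# squared-difference correlation of normalized properties, averaged over scales
theta_pair <- function(ci, cj, scales) {
  mean((scales[, ci] - scales[, cj])^2)
}

#' Pseudo amino-acid composition features
#'
#' Chou-style vector of length `20 + lambda`: the 20 amino-acid frequencies
#' plus `lambda` sequence-order correlation factors. The i-th tier factor is
#' the mean, over all residue pairs i positions apart, of the
#' squared-difference correlation of three standardized physicochemical
#' scales (hydrophobicity, hydrophilicity, side-chain mass). The final Chou
#' scaling divides both blocks by `sum(f) + w * sum(theta)`, so with
#' `lambda = 0` the result is exactly the normalized composition.
#'
#' @param seq Amino-acid sequence (single string).
#' @param lambda Number of correlation tiers (must be `< nchar(seq)`).
#' @param w Weight of the sequence-order block (default 0.05).
#' @return Named numeric vector of length `20 + lambda`.
#' @export
#' @examples
#' pseudo_aa_features("ARNDC", lambda = 2)
pseudo_aa_features <- function(seq, lambda = 4L, w = 0.05) {
  aa <- aa_alphabet()
  chars <- strsplit(seq, "")[[1]]
  code <- match(chars, aa)
  chars <- chars[!is.na(code)]
  code <- code[!is.na(code)]
  n <- length(code)
  if (lambda >= n) {
    stop("lambda must be smaller than the (canonical-residue) sequence length",
         call. = FALSE)
  }
  f <- tabulate(code, nbins = 20L) / n
  theta <- numeric(lambda)
  if (lambda > 0L) {
    scales <- aa_property_scales()
    for (i in seq_len(lambda)) {
      pairs <- cbind(code[seq_len(n - i)], code[(1L + i):n])
      theta[i] <- mean((scales[1L, pairs[, 1L]] - scales[1L, pairs[, 2L]])^2 +
                       (scales[2L, pairs[, 1L]] - scales[2L, pairs[, 2L]])^2 +
                       (scales[3L, pairs[, 1L]] - scales[3L, pairs[, 2L]])^2) / 3
    }
  }
  denom <- sum(f) + w * sum(theta)
  out <- c(f / denom, w * theta / denom)
  names(out) <- c(aa, if (lambda > 0L) paste0("theta", seq_len(lambda)))
  out
}

# --- functional domain composition features ----------------------------------

#' Domain vocabulary from training annotations
#'
#' @param annotations Domain annotation tibble (see [parse_domain_tsv()]).
#' @return Character vector of unique domain ids in first-seen order.
#' @export
domain_vocabulary <- function(annotations) {
  unique(annotations$domain_id)
}

#' Functional domain composition features
#'
#' Binary presence vector over a fixed training-time vocabulary: component i
#' is 1 iff domain i was annotated on the sequence. Domains outside the
#' vocabulary are ignored (their count is reported via a message).
#'
#' @param domains Character vector of domain ids annotated on one protein.
#' @param vocabulary Ordered domain ids fixed at training time.
#' @return Named integer 0/1 vector of length `length(vocabulary)`.
#' @export
domain_features <- function(domains, vocabulary) {
  unknown <- setdiff(domains, vocabulary)
  if (length(unknown) > 0L) {
    message(length(unknown), " out-of-vocabulary domain(s) ignored")
  }
  out <- as.integer(vocabulary %in% domains)
  names(out) <- vocabulary
  out
}

#' Domain feature matrix for a set of records
#'
#' @param records Protein tibble (defines row order).
#' @param annotations Domain annotation tibble with `protein_id`, `domain_id`.
#' @param vocabulary Ordered domain ids (default: built from `annotations`).
#' @return Binary matrix, one row per record.
#' @export
domain_feature_matrix <- function(records, annotations,
                                  vocabulary = domain_vocabulary(annotations)) {
  by_prot <- split(annotations$domain_id, annotations$protein_id)
  m <- t(vapply(records$id, function(id) {
    doms <- intersect(by_prot[[id]] %||% character(), vocabulary)
    as.integer(vocabulary %in% doms)
  }, integer(length(vocabulary))))
  colnames(m) <- vocabulary
  rownames(m) <- records$id
  m
}
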