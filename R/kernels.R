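# DNA-binding-domain pair similarity features feeding the PFM-similarity SVR:
# global alignment identity, normalized optimal local alignment score, the
# (k, m)-mismatch kernel by explicit neighborhood counting, and the
# beta-parameterized local alignment kernel (sum over all local alignments),
# the latter two self-normalized to [0, 1] via k(x,y)/sqrt(k(x,x) k(y,y)).

#' Normalized local alignment similarity of two sequences
#'
#' `S(a,b) / sqrt(S(a,a) * S(b,b))` with S the optimal local alignment raw
#' score under the scheme. This is the DBD sequence-similarity score used to
#' filter SVR training pairs (default cutoff 0.3 under BLOSUM62).
#'
#' @param a,b Amino-acid sequences.
#' @param scheme A [scoring_scheme()].
#' @return Similarity in `[0, 1]` (1 for identical sequences).
#' @export
local_similarity <- function(a, b, scheme = scoring_scheme()) {
  s_ab <- local_align(a, b, scheme)
  s_ab / sqrt(local_align(a, a, scheme) * local_align(b, b, scheme))
}

# neighborhood-count profile of a sequence: for every k-mer u, the number of
# k-mers of the sequence within m mismatches of u (explicit expansion)
mismatch_profile <- function(seq, k = 3L, m = 1L) {
  aa <- aa_alphabet()
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < k) return(new.env(parent = emptyenv()))
  counts <- new.env(parent = emptyenv())
  bump <- function(key) {
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  for (s in seq_len(n - k + 1L)) {
    kmer <- chars[s:(s + k - 1L)]
    if (any(!kmer %in% aa)) next
    bump(paste(kmer, collapse = ""))
    if (m >= 1L) {
      for (pos in seq_len(k)) {
        for (sub in setdiff(aa, kmer[pos])) {
          nb <- kmer
          nb[pos] <- sub
          bump(paste(nb, collapse = ""))
        }
      }
    }
  }
  counts
}

profile_dot <- function(p1, p2) {
  keys <- intersect(names(p1), names(p2))
  if (length(keys) == 0L) return(0)
  sum(vapply(keys, function(k) p1[[k]] * p2[[k]], numeric(1)))
}

#' Mismatch kernel between two sequences
#'
#' The (k, m)-mismatch string kernel computed by explicit neighborhood
#' counting, self-normalized. With `m = 0` it reduces to the dot product of
#' exact k-mer count vectors (the spectrum kernel).
#'
#' @param a,b Amino-acid sequences.
#' @param k k-mer length (default 3).
#' @param m Allowed mismatches (default 1).
#' @return Normalized kernel value in `[0, 1]`.
#' @export
mismatch_kernel <- function(a, b, k = 3L, m = 1L) {
  pa <- mismatch_profile(a, k, m)
  pb <- mismatch_profile(b, k, m)
  denom <- sqrt(profile_dot(pa, pa) * profile_dot(pb, pb))
  if (denom == 0) return(0)
  profile_dot(pa, pb) / denom
}

#' Local alignment kernel between two sequences
#'
#' The beta-parameterized sum over all local alignments of
#' `exp(beta * score)` with affine gaps, computed by dynamic programming in
#' C++ and self-normalized; `log(K)/beta` converges to the optimal local
#' alignment score as beta grows.
#'
#' @param a,b Amino-acid sequences.
#' @param scheme A [scoring_scheme()] supplying the substitution matrix and
#'   gap penalties.
#' @param beta Inverse-temperature parameter (default 0.5).
#' @param log Return `log K(a, b)` unnormalized instead.
#' @return Normalized kernel value in `(0, 1]`, or `log K` when `log = TRUE`.
#' @export
local_alignment_kernel <- function(a, b, scheme = scoring_scheme(),
                                   beta = 0.5, log = FALSE) {
  aa <- aa_alphabet()
  sub <- scheme$matrix[aa, aa]
  code <- function(s) match(strsplit(s, "")[[1]], aa)
  ca <- code(a); cb <- code(b)
  stopifnot(!anyNA(ca), !anyNA(cb))
  lab <- .lak_logk(ca, cb, sub, beta, scheme$gap_open, scheme$gap_extend)
  if (log) return(lab)
  laa <- .lak_logk(ca, ca, sub, beta, scheme$gap_open, scheme$gap_extend)
  lbb <- .lak_logk(cb, cb, sub, beta, scheme$gap_open, scheme$gap_extend)
  exp(lab - 0.5 * (laa + lbb))
}

#' DBD pair similarity features
#'
#' The four sequence-similarity features used to predict PFM similarity:
#' global alignment identity, normalized local alignment score, normalized
#' (k, m)-mismatch kernel and normalized local alignment kernel. Identical
#' sequences score 1 on all four.
#'
#' @param a,b DNA-binding-domain amino-acid sequences.
#' @param scheme A [scoring_scheme()].
#' @param beta LAK inverse temperature.
#' @param k,m Mismatch-kernel parameters.
#' @return One-row tibble with columns `global_identity`, `local_sim`,
#'   `mmk`, `lak`.
#' @export
#' @examples
#' dbd_pair_features("MKRHKLV", "MKRHKLV")
dbd_pair_features <- function(a, b, scheme = scoring_scheme(), beta = 0.5,
                              k = 3L, m = 1L) {
  stopifnot(nzchar(a), nzchar(b))
  ga <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = "global"
  )
  tibble::tibble(
    global_identity = Biostrings::pid(ga) / 100,
    local_sim = local_similarity(a, b, scheme),
    mmk = mismatch_kernel(a, b, k, m),
    lak = local_alignment_kernel(a, b, scheme, beta)
  )
}
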