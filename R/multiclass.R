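# Multiclass strategies for superclass prediction: one-vs-rest and the
# exhaustive error-correcting output code (ECOC) metaclassifier with
# minimum-Hamming-distance decoding and equal-probability tie handling.

#' Exhaustive error-correcting output code
#'
#' Dietterich's exhaustive code for k classes: `2^(k-1) - 1` columns (binary
#' base classifiers), the first class row all ones, and the remaining rows
#' enumerating the binary expansion of the column index so that no column is
#' constant and no two columns are equal or complementary. For the five TF
#' superclasses in the order Other, Basic domain, Zinc finger,
#' Helix-turn-helix, Beta scaffold this reproduces the published 5 x 15 code
#' table column for column.
#'
#' @param classes Ordered class names, `2 <= length(classes) <= 10`. The
#'   first class receives the all-ones row.
#' @return A `code_matrix`: binary matrix with classes as row names and
#'   columns `SVM1..SVML`.
#' @export
#' @examples
#' exhaustive_code(c("Other", rev(tf_superclasses()[1:4])))[, 1:4]
#' ncol(exhaustive_code(letters[1:4]))  # 7
exhaustive_code <- function(classes) {
  k <- length(classes)
  if (k < 2L || k > 10L) stop("exhaustive codes supported for 2..10 classes",
                              call. = FALSE)
  L <- 2L^(k - 1L) - 1L
  code <- matrix(0L, nrow = k, ncol = L,
                 dimnames = list(classes, paste0("SVM", seq_len(L))))
  code[1L, ] <- 1L
  for (j in seq_len(L)) {
    # row i (i >= 2) carries bit (k - i) of j - 1; row 2 is most significant
    bits <- as.integer(intToBits(j - 1L))[seq_len(k - 1L)]
    code[2L:k, j] <- rev(bits)
  }
  structure(code, class = c("code_matrix", class(code)))
}

#' ECOC code for the five TF superclasses
#'
#' The published row order (Other first, then Basic domain, Zinc finger,
#' Helix-turn-helix, Beta scaffold).
#'
#' @return A 5 x 15 `code_matrix`.
#' @export
superclass_code <- function() {
  exhaustive_code(c("Other", "Basic domain", "Zinc finger",
                    "Helix-turn-helix", "Beta scaffold"))
}

#' Minimum pairwise Hamming distance of a code
#'
#' The error-correcting margin of the code: the smallest Hamming distance
#' between any two class rows.
#'
#' @param code A `code_matrix`.
#' @return Integer distance.
#' @export
code_min_hamming <- function(code) {
  k <- nrow(code)
  min(apply(utils::combn(k, 2L), 2L,
            function(p) sum(code[p[1L], ] != code[p[2L], ])))
}

#' Write a code matrix as TSV
#'
#' @param code A `code_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_code_matrix <- function(code, path) {
  df <- data.frame(Superclass = rownames(code), unclass(code),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Train an ECOC metaclassifier
#'
#' One binary base model per code column; the positives of column j are all
#' samples whose class row carries bit 1 in that column.
#'
#' @param x Feature matrix.
#' @param labels Class labels (must all appear among the code's classes).
#' @param code A `code_matrix` (default: built from the observed classes).
#' @param spec Base [learner_spec()].
#' @return An `ecoc_model`.
#' @export
train_ecoc <- function(x, labels, code = exhaustive_code(unique(labels)),
                       spec = learner_spec("svm")) {
  stopifnot(all(labels %in% rownames(code)))
  x <- as.matrix(x)
  fits <- vector("list", ncol(code))
  for (j in seq_len(ncol(code))) {
    pos_classes <- rownames(code)[code[, j] == 1L]
    y <- labels %in% pos_classes
    if (!any(y) || all(y)) {
      stop(sprintf("column %s induces an empty side on this data",
                   colnames(code)[j]), call. = FALSE)
    }
    fits[[j]] <- fit_binary_learner(spec, x, y)
  }
  structure(list(code = code, fits = fits, spec = spec,
                 classes = rownames(code)),
            class = "ecoc_model")
}

#' Decode a predicted bit string against a code matrix
#'
#' Computes the Hamming distance of the bit string to every class row; the
#' minimum-distance row(s) share probability equally (`1/|argmin|`), all
#' other classes get 0.
#'
#' @param bits Integer 0/1 vector of length `ncol(code)`.
#' @param code A `code_matrix`.
#' @return Named probability vector over the code's classes (sums to 1).
#' @export
#' @examples
#' code <- superclass_code()
#' ecoc_decode(code["Zinc finger", ], code)
ecoc_decode <- function(bits, code) {
  stopifnot(length(bits) == ncol(code))
  d <- rowSums(sweep(code, 2L, as.integer(bits), `!=`))
  winners <- d == min(d)
  setNames(as.numeric(winners) / sum(winners), rownames(code))
}

#' @export
predict.ecoc_model <- function(object, x, ...) {
  x <- as.matrix(x)
  bits <- vapply(object$fits, predict_bit, integer(nrow(x)), x = x)
  bits <- matrix(bits, nrow = nrow(x))
  probs <- t(apply(bits, 1L, ecoc_decode, code = object$code))
  cls <- object$classes[apply(probs, 1L, which.max)]
  tibble::as_tibble(probs) |>
    dplyr::mutate(.class = cls, .before = 1L)
}

#' Train a one-vs-rest multiclass model
#'
#' One binary base model per class (that class positive, all others
#' negative); per-class scores are the base models' decision values and are
#' directly usable for ROC analysis.
#'
#' @param x Feature matrix.
#' @param labels Class labels (every class needs at least 2 examples).
#' @param spec Base [learner_spec()].
#' @param classes Ordered class set (default: observed order).
#' @return An `ovr_model`.
#' @export
one_vs_rest <- function(x, labels, spec = learner_spec("svm"),
                        classes = unique(labels)) {
  stopifnot(length(classes) >= 2L)
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L)) {
    stop(sprintf("class '%s' has fewer than 2 training examples",
                 names(counts)[which(counts < 2L)[1L]]), call. = FALSE)
  }
  x <- as.matrix(x)
  fits <- lapply(classes, function(cl) fit_binary_learner(spec, x, labels == cl))
  names(fits) <- classes
  structure(list(fits = fits, classes = classes, spec = spec),
            class = "ovr_model")
}

#' @export
predict.ovr_model <- function(object, x, ...) {
  x <- as.matrix(x)
  scores <- vapply(object$fits, predict_score, numeric(nrow(x)), x = x)
  scores <- matrix(scores, nrow = nrow(x),
                   dimnames = list(NULL, object$classes))
  cls <- object$classes[apply(scores, 1L, which.max)]
  tibble::as_tibble(scores) |>
    dplyr::mutate(.class = cls, .before = 1L)
}

#' @export
print.ecoc_model <- function(x, ...) {
  cat(sprintf("<ecoc_model> %d classes, %d base %s classifiers\n",
              length(x$classes), length(x$fits), x$spec$method))
  invisible(x)
}

#' @export
print.ovr_model <- function(x, ...) {
  cat(sprintf("<ovr_model> %d one-vs-rest %s classifiers\n",
              length(x$classes), x$spec$method))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.code_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(unclass(x),
                                        responseName = "bit")) |>
    dplyr::rename(superclass = "Var1", classifier = "Var2")
}

#' @export
glance.ecoc_model <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes),
                 n_classifiers = length(x$fits),
                 min_hamming = code_min_hamming(x$code),
                 base_learner = x$spec$method)
}

#' @export
glance.ovr_model <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes),
                 n_classifiers = length(x$fits),
                 base_learner = x$spec$method)
}
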