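# Position frequency matrices: construction, validation, reverse complement,
# and the two text dialects in common use (JASPAR 4-row blocks and
# TRANSFAC-like position-major blocks).

#' Construct a position frequency matrix
#'
#' @param counts 4 x L numeric matrix of nonnegative counts, rows A, C, G, T
#'   (a L x 4 matrix is transposed automatically).
#' @param id Motif identifier.
#' @param source Optional provenance tag.
#' @return A `pfm` object with fields `id`, `counts`, `probabilities`
#'   (column-normalized), `source`.
#' @export
#' @examples
#' pfm(matrix(c(8, 0, 0, 0, 0, 8, 0, 0), nrow = 4), id = "AC")
pfm <- function(counts, id = "pfm", source = NA_character_) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L && ncol(counts) == 4L) counts <- t(counts)
  stopifnot(nrow(counts) == 4L, ncol(counts) >= 1L)
  if (any(counts < 0)) stop("negative counts in PFM", call. = FALSE)
  cs <- colSums(counts)
  if (any(cs <= 0)) stop("PFM column with zero total count", call. = FALSE)
  rownames(counts) <- dna_alphabet()
  colnames(counts) <- NULL
  structure(list(id = id, counts = counts,
                 probabilities = sweep(counts, 2L, cs, "/"),
                 source = source),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %s (%d positions)\n", x$id, ncol(x$counts)))
  print(round(x$probabilities, 3))
  invisible(x)
}

#' Motif length of a PFM
#' @param x A `pfm`.
#' @return Integer number of positions.
#' @export
pfm_length <- function(x) ncol(x$counts)

#' Reverse complement of a PFM
#'
#' Reverses the positions and swaps A with T and C with G; applying it twice
#' returns the original matrix.
#'
#' @param x A `pfm`.
#' @return A `pfm`.
#' @export
reverse_complement <- function(x) {
  rc <- x$counts[c("T", "G", "C", "A"), rev(seq_len(ncol(x$counts))), drop = FALSE]
  pfm(rc, id = paste0(x$id, "_rc"), source = x$source)
}

#' @export
tidy.pfm <- function(x, ...) {
  tibble::tibble(
    id = x$id,
    position = rep(seq_len(ncol(x$counts)), each = 4L),
    base = rep(dna_alphabet(), ncol(x$counts)),
    count = as.numeric(x$counts),
    probability = as.numeric(x$probabilities)
  )
}

#' Read PFMs from a motif file
#'
#' Two dialects: `"jaspar"` — `>id` header followed by four rows
#' `A [ 1 2 3 ]` (brackets optional) in A/C/G/T order; `"transfac"` —
#' blocks with an `ID` line, a `P0  A  C  G  T` header, numbered
#' position-major rows, an `XX` terminator and `//` between records.
#'
#' @param path Input file.
#' @param dialect `"jaspar"` or `"transfac"`.
#' @return List of `pfm` objects.
#' @export
read_pfm <- function(path, dialect = c("jaspar", "transfac")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "jaspar") read_pfm_jaspar(lines) else read_pfm_transfac(lines)
}

read_pfm_jaspar <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0L) stop("no '>' headers found", call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  lapply(seq_along(starts), function(i) {
    id <- strsplit(sub("^>", "", lines[starts[i]]), "[ \t]+")[[1]][1L]
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4L) {
      stop(sprintf("motif '%s': expected 4 base rows, found %d", id,
                   length(body)), call. = FALSE)
    }
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGT]\\s*\\[?|\\]\\s*$", "", l)
      as.numeric(strsplit(trimws(l), "[ \t]+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop(sprintf("motif '%s': base rows of unequal length", id),
           call. = FALSE)
    }
    pfm(do.call(rbind, rows), id = id)
  })
}

read_pfm_transfac <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  recs <- split(lines, cumsum(dplyr::lag(trimws(lines) == "//",
                                         default = FALSE)))
  out <- list()
  for (rec in recs) {
    p0 <- grep("^P0\\b", trimws(rec))
    if (length(p0) == 0L) next
    idline <- grep("^(ID|NA|AC)\\b", trimws(rec), value = TRUE)
    id <- if (length(idline) > 0L) {
      strsplit(trimws(idline[1L]), "[ \t]+")[[1]][2L]
    } else "pfm"
    header <- strsplit(trimws(rec[p0]), "[ \t]+")[[1]][-1L]
    ord <- match(dna_alphabet(), header)
    if (anyNA(ord)) stop("P0 header must list A C G T", call. = FALSE)
    body <- rec[-seq_len(p0)]
    body <- body[grepl("^[0-9]+\\s", trimws(body))]
    rows <- lapply(body, function(l) {
      f <- strsplit(trimws(l), "[ \t]+")[[1]]
      as.numeric(f[2:5])[ord]
    })
    out[[length(out) + 1L]] <- pfm(t(do.call(rbind, rows)), id = id)
  }
  if (length(out) == 0L) stop("no TRANSFAC matrix blocks found", call. = FALSE)
  out
}

#' Write PFMs to a motif file
#'
#' @param pfms A `pfm` or list of `pfm`s.
#' @param path Output file.
#' @param dialect `"jaspar"` or `"transfac"`.
#' @return Invisibly, `path`.
#' @export
write_pfm <- function(pfms, path, dialect = c("jaspar", "transfac")) {
  dialect <- match.arg(dialect)
  if (inherits(pfms, "pfm")) pfms <- list(pfms)
  fmt <- function(v) format(v, trim = TRUE, scientific = FALSE)
  lines <- unlist(lapply(pfms, function(p) {
    if (dialect == "jaspar") {
      c(paste0(">", p$id),
        vapply(dna_alphabet(), function(b) {
          paste0(b, " [ ", paste(fmt(p$counts[b, ]), collapse = " "), " ]")
        }, character(1)))
    } else {
      c(paste("ID", p$id),
        "P0      A      C      G      T",
        vapply(seq_len(ncol(p$counts)), function(j) {
          paste(c(sprintf("%02d", j), fmt(p$counts[, j])), collapse = "  ")
        }, character(1)),
        "XX", "//")
    }
  }))
  writeLines(lines, path)
  invisible(path)
}
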