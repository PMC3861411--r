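# Local alignment against a labeled database with Karlin-Altschul bit-score
# conversion. This stands in for the BLAST scan feeding the percentile and
# PSSM features: Smith-Waterman optimal local alignment (no heuristic seeding),
# one hit per subject, filtering by bit score only.

#' Scoring scheme for protein local alignment
#'
#' Substitution matrix plus affine gap penalties and the Karlin-Altschul
#' constants used to convert raw alignment scores into bit scores,
#' `bits = (lambda * S - ln K) / ln 2`. Defaults mirror gapped BLAST with
#' BLOSUM62 and gap open/extend 11/1 (lambda = 0.267, K = 0.041). Whether the
#' original gapped or ungapped constants apply is not derivable from the
#' method description, so both the constants and the gap penalties are
#' configurable here.
#'
#' @param matrix Name of a substitution matrix available in Biostrings
#'   (default `"BLOSUM62"`), or a numeric matrix.
#' @param gap_open,gap_extend Nonnegative affine gap penalties; a gap of
#'   length g costs `gap_open + g * gap_extend`.
#' @param lambda,K Karlin-Altschul constants, both > 0.
#' @return An object of class `scoring_scheme`.
#' @export
#' @examples
#' scoring_scheme()
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  stopifnot(lambda > 0, K > 0, gap_open >= 0, gap_extend >= 0)
  if (is.character(matrix)) {
    name <- matrix
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    matrix <- get(name, envir = e)
  } else {
    name <- "custom"
  }
  structure(
    list(matrix = matrix, matrix_name = name, gap_open = gap_open,
         gap_extend = gap_extend, lambda = lambda, K = K),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> %s, gap %g/%g, lambda=%g, K=%g\n",
              x$matrix_name, x$gap_open, x$gap_extend, x$lambda, x$K))
  invisible(x)
}

#' Optimal local alignment raw score
#'
#' Smith-Waterman optimal local alignment score with affine gaps under the
#' scheme: the summed substitution-matrix scores across aligned residue pairs
#' minus gap costs, floored at 0 by the local-alignment definition.
#'
#' @param query,subject Amino-acid sequences (single strings).
#' @param scheme A [scoring_scheme()].
#' @return Numeric raw score S.
#' @export
#' @examples
#' local_align("ACDE", "ACDE")  # BLOSUM62 diagonal: 4 + 9 + 6 + 5 = 24
local_align <- function(query, subject, scheme = scoring_scheme()) {
  stopifnot(nzchar(query), nzchar(subject))
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = "local", scoreOnly = TRUE
  )
}

#' Convert a raw alignment score to a bit score
#'
#' @param S Raw score (vectorized).
#' @param scheme A [scoring_scheme()] supplying lambda and K.
#' @return Bit score `(lambda * S - ln K) / ln 2`.
#' @export
#' @examples
#' raw_to_bits(24)  # ~13.85 bits under the default scheme
raw_to_bits <- function(S, scheme = scoring_scheme()) {
  (scheme$lambda * S - log(scheme$K)) / log(2)
}

#' Search a labeled sequence database
#'
#' Aligns the query against every database record (optimal local alignment,
#' one hit per subject), converts raw scores to bit scores, and returns hits
#' at or above `min_bits` sorted by descending bit score. Labels travel with
#' the hits so that class-conditional bit-score distributions can be formed
#' downstream.
#'
#' @param query A single-row protein tibble (or a list with `id`, `sequence`).
#' @param db Protein tibble as from [read_fasta()].
#' @param scheme A [scoring_scheme()].
#' @param min_bits Bit-score threshold for reporting a hit.
#' @param exclude_self Drop database records whose id equals the query id
#'   (the database must not contain the input sequence itself).
#' @return Tibble with columns `query_id`, `subject_id`, `label`,
#'   `superclass`, `raw_score`, `bits`, sorted by `bits` descending.
#' @export
search_db <- function(query, db, scheme = scoring_scheme(), min_bits = 0,
                      exclude_self = TRUE) {
  stopifnot(nrow(db) >= 1L)
  qid <- query$id[[1]]
  qseq <- query$sequence[[1]]
  if (exclude_self) db <- db[db$id != qid, , drop = FALSE]
  if (nrow(db) == 0L) return(empty_hit_tbl(qid))
  S <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(db$sequence), Biostrings::AAString(qseq),
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = "local", scoreOnly = TRUE
  )
  bits <- raw_to_bits(S, scheme)
  keep <- bits >= min_bits
  out <- tibble::tibble(
    query_id = qid,
    subject_id = db$id[keep],
    label = (db$label %||% rep(NA_character_, nrow(db)))[keep],
    superclass = (db$superclass %||% rep(NA_character_, nrow(db)))[keep],
    raw_score = S[keep],
    bits = bits[keep]
  )
  dplyr::arrange(out, dplyr::desc(.data$bits))
}

empty_hit_tbl <- function(qid = character()) {
  tibble::tibble(query_id = qid[0], subject_id = character(),
                 label = character(), superclass = character(),
                 raw_score = numeric(), bits = numeric())
}

#' Search many queries against a database
#'
#' Convenience wrapper running [search_db()] for every record of `queries`
#' and binding the hit tables.
#'
#' @inheritParams search_db
#' @param queries Protein tibble of query records.
#' @return Hit tibble covering all queries.
#' @export
search_all <- function(queries, db, scheme = scoring_scheme(), min_bits = 0,
                       exclude_self = TRUE) {
  purrr::map_dfr(seq_len(nrow(queries)), function(i) {
    search_db(queries[i, ], db, scheme, min_bits, exclude_self)
  })
}

#' Ingest an external tabular homology result
#'
#' Reads 12-column tab-separated hit files (the BLAST `outfmt 6` dialect:
#' qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), joins class labels from `label_map`, and drops hits whose
#' subject is absent from the map (with a message stating the count). This
#' lets users substitute a real BLAST run for the built-in search.
#'
#' @param path Path to the tabular file (no header row).
#' @param label_map Data frame with columns `id`, `label` and optionally
#'   `superclass` keyed by subject id.
#' @return Hit tibble as from [search_db()] (raw scores are `NA`: the dialect
#'   carries bit scores only), sorted by query then descending bits.
#' @export
ingest_tabular_hits <- function(path, label_map) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    stop(sprintf("line %d: expected 12 tab-separated columns, found %d",
                 which(nf != 12L)[1L], nf[nf != 12L][1L]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  colnames(m) <- cols
  tbl <- tibble::as_tibble(m)
  tbl$bitscore <- as.numeric(tbl$bitscore)
  if (!"superclass" %in% names(label_map)) label_map$superclass <- NA_character_
  known <- tbl$sseqid %in% label_map$id
  if (any(!known)) {
    message(sum(!known), " hit(s) with subjects absent from label_map dropped")
  }
  tbl <- tbl[known, , drop = FALSE]
  idx <- match(tbl$sseqid, label_map$id)
  out <- tibble::tibble(
    query_id = tbl$qseqid,
    subject_id = tbl$sseqid,
    label = label_map$label[idx],
    superclass = label_map$superclass[idx],
    raw_score = NA_real_,
    bits = tbl$bitscore
  )
  dplyr::arrange(out, .data$query_id, dplyr::desc(.data$bits))
}

#' Export hits in the 12-column tabular dialect
#'
#' Only `qseqid`, `sseqid` and `bitscore` are meaningful for hits produced by
#' [search_db()]; the positional columns are written as zeros and the e-value
#' column as `NA` (e-values are deliberately not computed: all downstream
#' filtering is by bit score).
#'
#' @param hits Hit tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_tabular_hits <- function(hits, path) {
  n <- nrow(hits)
  out <- data.frame(hits$query_id, hits$subject_id, 0, 0L, 0L, 0L, 0L, 0L,
                    0L, 0L, NA, hits$bits)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
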