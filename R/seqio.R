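# Reading and writing labeled protein FASTA.
#
# Header dialect: fields pipe-delimited in the order id|label|superclass|source,
# with absent trailing fields omitted, e.g.
#   >P12345|TF|Basic domain|TRANSFAC
#   >Q99999|non-TF|UniProt
# Headers that do not parse against the closed vocabularies are kept verbatim
# as the id with no label (never silently mislabel).

protein_labels <- function() c("TF", "non-TF")

#' Read a labeled protein FASTA file
#'
#' Reads amino-acid FASTA and parses the pipe-delimited labeled-header dialect
#' (`id|label|superclass|source`; `label` is `TF`/`non-TF`, `superclass` one of
#' [tf_superclasses()], trailing fields optional). A header that does not fit
#' the dialect is retained wholesale as the record id with no label.
#'
#' @param path Path to a FASTA file.
#' @param allow_ambiguous If `TRUE`, non-canonical residues (X, B, Z, U, O, *)
#'   are mapped to `X` instead of raising an error. Composition-based feature
#'   functions ignore `X`.
#' @return A tibble with columns `id`, `sequence`, `label`, `superclass`,
#'   `source`, one row per FASTA entry, input order preserved.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">P12345|TF|Basic domain|TRANSFAC", "MKV"), f)
#' read_fasta(f)
read_fasta <- function(path, allow_ambiguous = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(empty_protein_tbl())
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    stop("malformed FASTA at line 1: sequence data before any '>' header",
         call. = FALSE)
  }
  entry <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  seqs <- vapply(
    split(lines[!is_header], entry[!is_header]),
    function(x) paste(x, collapse = ""), character(1)
  )
  # entries with no sequence lines at all
  missing <- setdiff(as.character(seq_along(headers)), names(seqs))
  if (length(missing) > 0L) {
    i <- as.integer(missing[1L])
    stop(sprintf("malformed FASTA near line %d: entry '%s' has an empty sequence",
                 which(is_header)[i], headers[i]), call. = FALSE)
  }
  seqs <- seqs[as.character(seq_along(headers))]
  parsed <- parse_fasta_headers(headers)
  parsed$sequence <- unname(toupper(seqs))
  parsed$sequence <- validate_sequences(parsed$sequence, parsed$id, allow_ambiguous)
  parsed[, c("id", "sequence", "label", "superclass", "source")]
}

empty_protein_tbl <- function() {
  tibble::tibble(id = character(), sequence = character(), label = character(),
                 superclass = character(), source = character())
}

parse_fasta_headers <- function(headers) {
  parts <- strsplit(headers, "|", fixed = TRUE)
  one <- function(h, p) {
    id <- p[1L]
    label <- superclass <- src <- NA_character_
    ok <- TRUE
    if (length(p) >= 2L) {
      if (p[2L] %in% protein_labels()) label <- p[2L] else ok <- FALSE
    }
    if (ok && length(p) >= 3L) {
      if (identical(label, "TF") && p[3L] %in% tf_superclasses()) {
        superclass <- p[3L]
        if (length(p) >= 4L) src <- p[4L]
      } else if (length(p) == 3L) {
        src <- p[3L]   # id|label|source form (non-TF or unclassed TF)
      } else {
        ok <- FALSE
      }
    }
    if (!ok || length(p) > 4L) {
      return(c(h, NA_character_, NA_character_, NA_character_))
    }
    c(id, label, superclass, src)
  }
  m <- t(mapply(one, headers, parts, USE.NAMES = FALSE))
  tibble::tibble(id = m[, 1L], label = m[, 2L], superclass = m[, 3L],
                 source = m[, 4L])
}

validate_sequences <- function(seqs, ids, allow_ambiguous) {
  canon <- paste(aa_alphabet(), collapse = "")
  bad <- !grepl(sprintf("^[%s]+$", canon), seqs)
  if (any(bad)) {
    if (!allow_ambiguous) {
      stop(sprintf(
        "sequence for record '%s' contains non-canonical residues; %s",
        ids[which(bad)[1L]],
        "use allow_ambiguous = TRUE to map them to X"), call. = FALSE)
    }
    seqs[bad] <- gsub(sprintf("[^%s]", canon), "X", seqs[bad])
  }
  if (any(!nzchar(seqs))) {
    stop(sprintf("record '%s' has an empty sequence", ids[which(!nzchar(seqs))[1L]]),
         call. = FALSE)
  }
  seqs
}

validate_protein_tbl <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  for (col in c("label", "superclass", "source")) {
    if (!col %in% names(records)) records[[col]] <- NA_character_
  }
  bad_label <- !is.na(records$label) & !records$label %in% protein_labels()
  if (any(bad_label)) {
    stop(sprintf("record '%s' has invalid label '%s'",
                 records$id[which(bad_label)[1L]],
                 records$label[which(bad_label)[1L]]), call. = FALSE)
  }
  bad_sc <- !is.na(records$superclass) &
    (!records$superclass %in% tf_superclasses() |
       is.na(records$label) | records$label != "TF")
  if (any(bad_sc)) {
    stop(sprintf("record '%s': superclass may only be set on TF records and must be one of the five superclasses",
                 records$id[which(bad_sc)[1L]]), call. = FALSE)
  }
  if (any(!nzchar(records$sequence) | is.na(records$sequence))) {
    stop("empty sequence in records", call. = FALSE)
  }
  tibble::as_tibble(records)
}

#' Write protein records as labeled FASTA
#'
#' Canonical form: pipe-delimited header `id|label|superclass|source` with
#' absent fields omitted, sequence wrapped at 60 columns.
#'
#' @param records A data frame with columns `id`, `sequence` and optionally
#'   `label`, `superclass`, `source` (as returned by [read_fasta()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  records <- validate_protein_tbl(records)
  seqs <- Biostrings::AAStringSet(records$sequence)
  hdr <- function(i) {
    fields <- c(records$id[i], records$label[i], records$superclass[i],
                records$source[i])
    paste(fields[!is.na(fields)], collapse = "|")
  }
  names(seqs) <- vapply(seq_len(nrow(records)), hdr, character(1))
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}
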