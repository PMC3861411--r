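# Workflow step 3: parse domain-scan output and identify DNA-binding domains
# by Gene Ontology subtree filtering. The DNA-binding molecular-function root
# used for domain filtering is GO:0003677; GO:0003700 ("sequence-specific DNA
# binding transcription factor activity") is used only in the non-TF label
# post-filter. Both are configurable.

GO_DNA_BINDING <- "GO:0003677"
GO_TF_ACTIVITY <- "GO:0003700"

#' Parse InterProScan-style domain annotations
#'
#' Reads a tab-separated table with columns protein id, domain (signature or
#' InterPro) accession, start, end, and a pipe-separated GO-term column
#' (which may be empty). Coordinates are 1-based inclusive.
#'
#' @param path Path to the TSV (no header row).
#' @return Tibble with columns `protein_id`, `domain_id`, `start`, `end`,
#'   `go` (list column of GO id character vectors).
#' @export
parse_domain_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_domain_tbl())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L | nf > 5L)) {
    bad <- which(nf < 4L | nf > 5L)[1L]
    stop(sprintf("line %d: expected 4-5 tab-separated columns, found %d",
                 bad, nf[bad]), call. = FALSE)
  }
  get <- function(i) vapply(fields, function(f) f[i], character(1))
  start <- suppressWarnings(as.integer(get(3L)))
  end <- suppressWarnings(as.integer(get(4L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    stop(sprintf("line %d: non-numeric domain coordinates", bad), call. = FALSE)
  }
  if (any(start < 1L | end < start)) {
    bad <- which(start < 1L | end < start)[1L]
    stop(sprintf("line %d: invalid interval [%d, %d]", bad, start[bad],
                 end[bad]), call. = FALSE)
  }
  go_raw <- vapply(fields, function(f) if (length(f) >= 5L) f[5L] else "",
                   character(1))
  go <- lapply(go_raw, function(g) {
    if (!nzchar(g)) character() else strsplit(g, "|", fixed = TRUE)[[1]]
  })
  tibble::tibble(protein_id = get(1L), domain_id = get(2L),
                 start = start, end = end, go = go)
}

empty_domain_tbl <- function() {
  tibble::tibble(protein_id = character(), domain_id = character(),
                 start = integer(), end = integer(), go = list())
}

#' Write domain annotations as TSV
#'
#' Inverse of [parse_domain_tsv()]; GO ids are pipe-joined.
#'
#' @param annotations Domain annotation tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_domain_tsv <- function(annotations, path) {
  go <- vapply(annotations$go, paste, character(1), collapse = "|")
  out <- data.frame(annotations$protein_id, annotations$domain_id,
                    annotations$start, annotations$end, go)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse a (possibly reduced) OBO 1.2 ontology file
#'
#' Minimal section parser retaining, for every `[Term]` stanza: id, name,
#' `is_a` parents and (optionally) `part_of` relationships. Sufficient for GO
#' subtree extraction; no installed R package provides OBO parsing.
#'
#' @param path Path to an OBO file.
#' @return Tibble with columns `id`, `name`, `parents` (list, is_a),
#'   `part_of` (list).
#' @export
parse_obo <- function(path) {
  lines <- readLines(path)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) {
    stop("no [Term] stanzas found in OBO file", call. = FALSE)
  }
  bounds <- c(term_starts, length(lines) + 1L)
  terms <- lapply(seq_along(term_starts), function(i) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    # stop at the next stanza of any kind (e.g. [Typedef])
    stanza <- which(startsWith(chunk, "["))
    if (length(stanza) > 0L) chunk <- chunk[seq_len(stanza[1L] - 1L)]
    val <- function(key) {
      v <- sub(paste0("^", key, ": "), "",
               grep(paste0("^", key, ": "), chunk, value = TRUE))
      sub(" !.*$", "", v)
    }
    rel <- val("relationship")
    part_of <- sub("^part_of ", "",
                   grep("^part_of ", rel, value = TRUE))
    list(id = val("id")[1L], name = val("name")[1L] %||% NA_character_,
         parents = val("is_a"), part_of = part_of)
  })
  tibble::tibble(
    id = vapply(terms, `[[`, character(1), "id"),
    name = vapply(terms, function(t) t$name %||% NA_character_, character(1)),
    parents = lapply(terms, `[[`, "parents"),
    part_of = lapply(terms, `[[`, "part_of")
  )
}

#' GO subtree rooted at a term
#'
#' The root plus all transitive descendants via `is_a` edges (and `part_of`
#' when `use_part_of = TRUE`; excluded by default, matching common
#' molecular-function subtree practice).
#'
#' @param ontology Path to an OBO file, or a tibble from [parse_obo()].
#' @param root Root GO id (default the DNA-binding molecular function).
#' @param use_part_of Also follow `part_of` edges.
#' @return A `go_subtree`: list with `root` and `members` (character set).
#' @export
go_descendants <- function(ontology, root = GO_DNA_BINDING,
                           use_part_of = FALSE) {
  if (is.character(ontology) && length(ontology) == 1L) {
    ontology <- parse_obo(ontology)
  }
  if (!root %in% ontology$id) {
    stop(sprintf("root term %s not present in ontology", root), call. = FALSE)
  }
  edge_list <- function(col) {
    n <- lengths(ontology[[col]])
    if (sum(n) == 0L) return(NULL)
    data.frame(from = rep(ontology$id, n), to = unlist(ontology[[col]]))
  }
  edges <- rbind(edge_list("parents"),
                 if (use_part_of) edge_list("part_of"))
  members <- root
  if (!is.null(edges) && nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(edges,
                                       vertices = unique(c(ontology$id,
                                                           edges$to)))
    # child -> parent edges; descendants reach the root along them
    reach <- igraph::subcomponent(g, root, mode = "in")
    members <- unique(c(root, names(reach)))
  }
  structure(list(root = root, members = members), class = "go_subtree")
}

#' @export
print.go_subtree <- function(x, ...) {
  cat(sprintf("<go_subtree> root %s, %d member term(s)\n", x$root,
              length(x$members)))
  invisible(x)
}

#' Filter DNA-binding domain annotations
#'
#' Keeps annotations whose GO set intersects the subtree members; input order
#' is preserved and filtering is idempotent.
#'
#' @param annotations Domain annotation tibble.
#' @param subtree A `go_subtree` (see [go_descendants()]).
#' @return Filtered annotation tibble.
#' @export
filter_dna_binding <- function(annotations, subtree) {
  keep <- vapply(annotations$go, function(g) any(g %in% subtree$members),
                 logical(1))
  annotations[keep, , drop = FALSE]
}

#' Per-protein DNA-binding-domain intervals
#'
#' Merges overlapping (or adjacent) DBD annotations on the same protein into
#' maximal intervals — downstream motif transfer consumes domain sequences,
#' and duplicated overlapping segments would double-weight residues.
#'
#' @param annotations DBD annotation tibble (typically the output of
#'   [filter_dna_binding()]).
#' @return Tibble `protein_id`, `start`, `end` (1-based inclusive).
#' @export
dbd_intervals <- function(annotations) {
  if (nrow(annotations) == 0L) {
    return(tibble::tibble(protein_id = character(), start = integer(),
                          end = integer()))
  }
  purrr::map_dfr(split(annotations, annotations$protein_id), function(a) {
    r <- IRanges::reduce(IRanges::IRanges(a$start, a$end))
    tibble::tibble(protein_id = a$protein_id[1L],
                   start = IRanges::start(r), end = IRanges::end(r))
  })
}

#' Extract DBD sequences for a record set
#'
#' @param records Protein tibble.
#' @param intervals Tibble from [dbd_intervals()].
#' @return Tibble `protein_id`, `start`, `end`, `dbd_sequence`.
#' @export
dbd_sequences <- function(records, intervals) {
  idx <- match(intervals$protein_id, records$id)
  stopifnot(!anyNA(idx))
  len <- nchar(records$sequence[idx])
  if (any(intervals$end > len)) {
    stop("DBD interval extends beyond protein length", call. = FALSE)
  }
  dplyr::mutate(intervals,
                dbd_sequence = substr(records$sequence[idx],
                                      intervals$start, intervals$end))
}

#' Post-filter candidate non-TF records
#'
#' Removes candidate non-TFs that are (a) present in a set of known TF ids
#' (obviously mislabeled) or (b) annotated with the TF-specific GO term for
#' sequence-specific DNA-binding transcription factor activity.
#'
#' @param records Candidate non-TF protein tibble.
#' @param go_map Named list / split tibble mapping protein id to GO ids, or a
#'   tibble with columns `protein_id`, `go` (list column).
#' @param tf_ids Character vector of known TF identifiers.
#' @param tf_go_term GO id triggering removal (default GO:0003700).
#' @return List with `records` (survivors), `removed_tf_entry` and
#'   `removed_go` counts.
#' @export
label_postfilter <- function(records, go_map, tf_ids,
                             tf_go_term = GO_TF_ACTIVITY) {
  if (is.data.frame(go_map)) {
    go_map <- setNames(go_map$go, go_map$protein_id)
  }
  in_tf <- records$id %in% tf_ids
  n_tf <- sum(in_tf)
  records <- records[!in_tf, , drop = FALSE]
  has_go <- vapply(records$id, function(id) {
    tf_go_term %in% (go_map[[id]] %||% character())
  }, logical(1))
  list(records = records[!has_go, , drop = FALSE],
       removed_tf_entry = n_tf, removed_go = sum(has_go))
}
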