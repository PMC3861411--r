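# The four-step annotation pipeline: (1) TF/non-TF discrimination,
# (2) superclass prediction for TFs, (3) DNA-binding-domain identification
# by GO filtering, (4) motif transfer. Proteins classified non-TF in step 1
# are not passed on to the later steps.

score_to_probability <- function(score, cutoff) {
  if (cutoff == 0) 1 / (1 + exp(-score)) else pmin(1, pmax(0, score))
}

#' Build a pipeline reference from a labeled database
#'
#' Trains the step-1 TF/non-TF classifier and the step-2 superclass model on
#' bit-score percentile features of an all-vs-self homology scan of the
#' database, prepares the GO subtree for DBD filtering and, when an
#' annotated TF set is supplied, the SVR models for motif transfer.
#'
#' @param db Labeled protein tibble (TF/non-TF, superclasses on TFs).
#' @param go Path to an OBO file or a `go_subtree` (default: the bundled
#'   synthetic subtree).
#' @param tf_set Optional tibble `id`, `superclass`, `dbd_sequence`, `pfm`
#'   enabling step 4.
#' @param spec Base [learner_spec()] for both classification steps.
#' @param multiclass `"ovr"` or `"ecoc"`.
#' @param config A [transfer_config()].
#' @param min_bits Hit-reporting threshold for the homology scan.
#' @param seed Seed for stochastic learners.
#' @return A `tf_reference` object.
#' @export
build_reference <- function(db, go = synthetic_go_path(), tf_set = NULL,
                            spec = learner_spec("svm"),
                            multiclass = c("ovr", "ecoc"),
                            config = transfer_config(), min_bits = 0,
                            seed = 42L) {
  multiclass <- match.arg(multiclass)
  spec$seed <- seed
  db <- validate_protein_tbl(db)
  hits <- search_all(db, db, config$scheme, min_bits = min_bits,
                     exclude_self = TRUE)
  x_bin <- percentile_feature_matrix(db, hits, protein_labels(), "label")
  fit_bin <- fit_binary_learner(spec, x_bin, db$label == "TF")
  tf_rows <- which(db$label == "TF" & !is.na(db$superclass))
  x_sc <- percentile_feature_matrix(db[tf_rows, ], hits, tf_superclasses(),
                                    "superclass")
  sc_labels <- db$superclass[tf_rows]
  sc_model <- if (multiclass == "ovr") {
    one_vs_rest(x_sc, sc_labels, spec, classes = tf_superclasses())
  } else {
    train_ecoc(x_sc, sc_labels,
               code = exhaustive_code(c("Other", "Basic domain",
                                        "Zinc finger", "Helix-turn-helix",
                                        "Beta scaffold")),
               spec = spec)
  }
  subtree <- if (inherits(go, "go_subtree")) go else go_descendants(go)
  transfer_models <- NULL
  if (!is.null(tf_set) && nrow(tf_set) >= 2L) {
    preps <- pfm_prep_cache(tf_set$pfm, config$background, config$alpha_hit,
                            config$pseudocount)
    pairs <- transfer_pair_table(tf_set, config, preps)
    if (nrow(pairs) >= 20L) {
      transfer_models <- train_transfer_models(pairs, seed = seed)
    } else {
      warning("too few DBD pairs to train transfer models; step 4 disabled")
    }
  }
  structure(list(db = db, hits = hits, fit_bin = fit_bin,
                 sc_model = sc_model, multiclass = multiclass,
                 subtree = subtree, tf_set = tf_set,
                 transfer_models = transfer_models, spec = spec,
                 config = config, min_bits = min_bits, seed = seed),
            class = "tf_reference")
}

#' @export
print.tf_reference <- function(x, ...) {
  cat(sprintf(
    "<tf_reference> %d db records (%d TF), %s base learner, %s multiclass%s\n",
    nrow(x$db), sum(x$db$label == "TF"), x$spec$method, x$multiclass,
    if (is.null(x$transfer_models)) "" else ", motif transfer enabled"))
  invisible(x)
}

#' Run the four-step annotation pipeline
#'
#' For every query: homology scan against the reference database, TF
#' probability from percentile features (step 1); for predicted TFs the
#' superclass distribution (step 2), GO-filtered DBD intervals from the
#' supplied domain annotations (step 3) and, when the reference carries
#' transfer models, the predicted DNA motif (step 4). Queries without any
#' homology hit receive a no-prediction outcome in step 1.
#'
#' @param queries Protein tibble.
#' @param reference A `tf_reference` from [build_reference()].
#' @param query_domains Optional domain annotation tibble for the queries
#'   (InterProScan-style; see [parse_domain_tsv()]).
#' @param tf_cutoff Probability cutoff calling a query a TF (default 0.5).
#' @return Tibble with one row per query: `id`, `n_hits`, `p_tf`, `tf_call`,
#'   `superclass`, `superclass_probs` (list), `dbd` (list of intervals),
#'   `motif_possible`, `bmt`, `confidence`, `pfm` (list).
#' @export
tf_pipeline <- function(queries, reference, query_domains = NULL,
                        tf_cutoff = 0.5) {
  queries <- validate_protein_tbl(queries)
  dbd_tbl <- if (!is.null(query_domains)) {
    dbd_intervals(filter_dna_binding(query_domains, reference$subtree))
  }
  purrr::map_dfr(seq_len(nrow(queries)), function(i) {
    q <- queries[i, ]
    hits <- search_db(q, reference$db, reference$config$scheme,
                      min_bits = reference$min_bits, exclude_self = TRUE)
    base <- tibble::tibble(id = q$id, n_hits = nrow(hits), p_tf = NA_real_,
                           tf_call = NA, superclass = NA_character_,
                           superclass_probs = list(NULL), dbd = list(NULL),
                           motif_possible = NA, bmt = NA_real_,
                           confidence = NA_real_, pfm = list(NULL))
    if (nrow(hits) == 0L) return(base)  # no hit, no prediction
    xb <- matrix(bitscore_percentiles(hits, protein_labels(), "label"),
                 nrow = 1)
    base$p_tf <- score_to_probability(predict_score(reference$fit_bin, xb),
                                      reference$fit_bin$cutoff)
    base$tf_call <- base$p_tf >= tf_cutoff
    if (!base$tf_call) return(base)
    xs <- matrix(bitscore_percentiles(hits, tf_superclasses(), "superclass"),
                 nrow = 1)
    sc_pred <- predict(reference$sc_model, xs)
    base$superclass <- sc_pred$.class[1L]
    base$superclass_probs <- list(sc_pred[1L, -1L])
    if (!is.null(dbd_tbl)) {
      ivals <- dbd_tbl[dbd_tbl$protein_id == q$id, , drop = FALSE]
      base$dbd <- list(ivals)
      if (nrow(ivals) > 0L && !is.null(reference$transfer_models)) {
        ivals <- dbd_sequences(queries, ivals)
        # transfer from the longest DBD; the query itself never serves as
        # its own training match
        dbd_seq <- ivals$dbd_sequence[which.max(nchar(ivals$dbd_sequence))]
        train_set <- reference$tf_set[reference$tf_set$id != q$id, ,
                                      drop = FALSE]
        res <- motif_transfer(
          list(dbd_sequence = dbd_seq, superclass = base$superclass),
          train_set, reference$transfer_models, reference$config)
        base$motif_possible <- res$possible
        base$bmt <- res$threshold
        base$confidence <- res$confidence
        base$pfm <- list(res$pfm)
      }
    }
    base
  })
}
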