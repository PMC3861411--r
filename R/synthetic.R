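# Synthetic data generator: labeled proteomes with superclass-specific
# DNA-binding-domain motifs, per-family PFMs whose distances track DBD
# sequence divergence, and domain/GO annotation tables. Every pipeline stage
# runs on these fixtures without any download; the emitted files are
# indistinguishable from real inputs at the parser level.

#' Superclass-specific DBD consensus sequences
#'
#' Thirty-residue seed consensi, one per structural superclass, with the
#' flavor of real DBD families (basic leucine-zipper, C2H2 zinc finger,
#' homeodomain, p53-like beta scaffold, HMG box).
#'
#' @return Named character vector over [tf_superclasses()].
#' @export
superclass_dbd_consensus <- function() {
  c("Basic domain"     = "MKRERRKQSNRESARRSRLRKQAETEELAR",
    "Zinc finger"      = "YKCPECGKSFSQSSNLQKHQRTHTGEKPYK",
    "Helix-turn-helix" = "RRKRTAYTRYQLLELEKEFHFNRYLTRRRR",
    "Beta scaffold"    = "SVTCTYSPALNKMFCQLAKTCPVQLWVDST",
    "Other"            = "GKGDPKKPRGKMSSYAFFVQTSREEHKKKH")
}

random_aa <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE, prob = aa_background()),
        collapse = "")
}

mutate_sequence <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(c) {
      sample(setdiff(aa_alphabet(), c), 1L)
    }, character(1))
  }
  list(sequence = paste(chars, collapse = ""), realized = mean(hit))
}

seed_pfm_from_consensus <- function(consensus, concentration = 20) {
  letters <- strsplit(consensus, "")[[1]]
  stopifnot(all(letters %in% dna_alphabet()))
  probs <- vapply(letters, function(l) {
    p <- rep(1, 4) + concentration * (dna_alphabet() == l)
    p / sum(p)
  }, numeric(4))
  probs
}

perturb_pfm <- function(seed_probs, mix) {
  L <- ncol(seed_probs)
  noise <- vapply(seq_len(L), function(j) {
    d <- stats::rgamma(4, 1)
    d / sum(d)
  }, numeric(4))
  (1 - mix) * seed_probs + mix * noise
}

random_dna <- function(n) {
  paste(sample(dna_alphabet(), n, replace = TRUE), collapse = "")
}

#' Specify a synthetic TF family
#'
#' A family shares a DBD consensus and a seed binding motif; members diverge
#' from the consensus at `divergence` per site and their PFMs are perturbed
#' with per-column Dirichlet mixing whose weight grows with each member's
#' realized DBD divergence — so PFM distance is a noisy increasing function
#' of DBD sequence distance, the structure the transfer SVR assumes.
#'
#' @param superclass Structural superclass of the family.
#' @param n_members Members to generate (>= 1).
#' @param divergence Per-site DBD mutation rate in `[0, 1)`.
#' @param dbd_consensus Seed DBD (default: the superclass consensus).
#' @param pfm_consensus Seed motif as a DNA string (default: random of
#'   length `motif_length`).
#' @param motif_length Motif length when `pfm_consensus` is not given.
#' @param concentration Sharpness of seed PFM columns (consensus-base
#'   probability `(1 + c) / (4 + c)`).
#' @param pfm_noise_scale Multiplier converting realized DBD divergence into
#'   the Dirichlet mixing weight (capped at 1).
#' @param flank_range Range of random flank lengths on either side.
#' @param id Family identifier.
#' @return A `family_spec` list.
#' @export
family_spec <- function(superclass, n_members = 4L, divergence = 0.2,
                        dbd_consensus = NULL, pfm_consensus = NULL,
                        motif_length = 6L, concentration = 20,
                        pfm_noise_scale = 1.5, flank_range = c(10L, 20L),
                        id = "fam1") {
  stopifnot(superclass %in% tf_superclasses(),
            divergence >= 0, divergence < 1, n_members >= 1L)
  dbd_consensus <- dbd_consensus %||% unname(superclass_dbd_consensus()[superclass])
  stopifnot(nchar(dbd_consensus) >= 5L,
            is.null(pfm_consensus) || nchar(pfm_consensus) >= 5L,
            motif_length >= 5L)
  structure(list(superclass = superclass, n_members = n_members,
                 divergence = divergence, dbd_consensus = dbd_consensus,
                 pfm_consensus = pfm_consensus, motif_length = motif_length,
                 concentration = concentration,
                 pfm_noise_scale = pfm_noise_scale,
                 flank_range = flank_range, id = id),
            class = "family_spec")
}

#' Generate one synthetic TF family
#'
#' Each member is random flank + mutated DBD consensus + random flank, with
#' a PFM derived from the family seed motif (see [family_spec()]).
#' Deterministic for a given seed.
#'
#' @param spec A [family_spec()].
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `sequence`, `label`, `superclass`,
#'   `source`, `family`, `dbd_start`, `dbd_end`, `dbd_sequence`,
#'   `divergence` (realized) and `pfm` (list of [pfm()]).
#' @export
gen_tf_family <- function(spec, seed = 42L) {
  set.seed(seed)
  pfm_consensus <- spec$pfm_consensus %||% random_dna(spec$motif_length)
  seed_probs <- seed_pfm_from_consensus(pfm_consensus, spec$concentration)
  rows <- lapply(seq_len(spec$n_members), function(i) {
    mut <- mutate_sequence(spec$dbd_consensus, spec$divergence)
    fl <- sample(spec$flank_range[1L]:spec$flank_range[2L], 2L, replace = TRUE)
    left <- random_aa(fl[1L]); right <- random_aa(fl[2L])
    probs <- perturb_pfm(seed_probs,
                         min(1, spec$pfm_noise_scale * mut$realized))
    tibble::tibble(
      id = sprintf("%s_m%02d", spec$id, i),
      sequence = paste0(left, mut$sequence, right),
      label = "TF", superclass = spec$superclass, source = "synthetic",
      family = spec$id,
      dbd_start = fl[1L] + 1L,
      dbd_end = fl[1L] + nchar(spec$dbd_consensus),
      dbd_sequence = mut$sequence,
      divergence = mut$realized,
      pfm = list(pfm(round(probs * 100, 3),
                     id = sprintf("%s_m%02d", spec$id, i),
                     source = "synthetic")))
  })
  dplyr::bind_rows(rows)
}

#' Generate a synthetic transfer-evaluation TF set
#'
#' Families are assigned to superclasses round-robin; each family's DBD
#' consensus is the superclass consensus carrying family-specific mutations,
#' so within-family DBD similarity is high and between-family similarity
#' lower, and each family has its own seed motif.
#'
#' @param n_families Number of families (default 20).
#' @param members_per_family Members per family (default 4).
#' @param divergence Within-family per-site DBD divergence (default 0.2).
#' @param family_divergence Mutation rate separating family consensi from
#'   the superclass consensus (default 0.3).
#' @param motif_length Seed motif length (default 6).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [family_spec()].
#' @return Tibble as from [gen_tf_family()], all families combined.
#' @export
gen_transfer_set <- function(n_families = 20L, members_per_family = 4L,
                             divergence = 0.2, family_divergence = 0.3,
                             motif_length = 6L, seed = 42L, ...) {
  set.seed(seed)
  scs <- rep_len(tf_superclasses(), n_families)
  fam_seeds <- sample.int(1e6, n_families)
  out <- lapply(seq_len(n_families), function(k) {
    set.seed(fam_seeds[k])
    cons <- mutate_sequence(unname(superclass_dbd_consensus()[scs[k]]),
                            family_divergence)$sequence
    motif <- random_dna(motif_length)
    sp <- family_spec(scs[k], members_per_family, divergence,
                      dbd_consensus = cons, pfm_consensus = motif,
                      motif_length = motif_length,
                      id = sprintf("fam%02d", k), ...)
    gen_tf_family(sp, seed = fam_seeds[k] + 1L)
  })
  dplyr::bind_rows(out)
}

synthetic_housekeeping_domains <- function() {
  tibble::tibble(
    domain_id = paste0("SYN_HK_", 1:6),
    go = list("GO:0016301", "GO:0003723", "GO:0005515", "GO:0016301",
              "GO:0003723", "GO:0005515"))
}

superclass_go_terms <- function() {
  list("Basic domain" = c("GO:0003677", "GO:0043565"),
       "Zinc finger" = c("GO:0003677", "GO:0000976"),
       "Helix-turn-helix" = c("GO:0003677", "GO:0043565"),
       "Beta scaffold" = c("GO:0003677", "GO:0000976"),
       "Other" = c("GO:0003677", "GO:0003690"))
}

#' Path of the bundled synthetic GO subtree
#'
#' A heavily reduced, synthetic OBO file around the DNA-binding molecular
#' function (GO:0003677) used by the generator and tests.
#'
#' @return File path.
#' @export
synthetic_go_path <- function() {
  system.file("extdata", "go_dna_binding_synthetic.obo",
              package = "tfannotate", mustWork = TRUE)
}

#' Generate a synthetic labeled proteome with annotations
#'
#' TFs are drawn from superclass-specific family pools; non-TFs are random
#' background sequences, a configurable fraction of which carry a decoy
#' DNA-binding-like segment (a mutated superclass DBD plus a DNA-binding GO
#' annotation under a non-TF label) emulating the confusability of, e.g.,
#' C2H2-type zinc-finger domains occurring in DNA-binding non-TF proteins.
#' The default superclass mixture follows [superclass_reference_counts()].
#'
#' @param n_tf Either a single total (split by the reference proportions) or
#'   a named vector of per-superclass counts.
#' @param n_nontf Number of non-TF records.
#' @param seed Integer seed.
#' @param members_per_family Family size for the TF pools.
#' @param divergence Within-family DBD divergence.
#' @param decoy_fraction Fraction of non-TFs carrying a decoy DBD segment.
#' @param mislabeled_fraction Fraction of non-TFs annotated with the
#'   TF-activity GO term (exercises the label post-filter).
#' @param motif_length Family motif length.
#' @param seq_length Approximate non-TF sequence length (TF lengths follow
#'   from flanks + DBD).
#' @param id_prefix Prefix prepended to every generated identifier (useful
#'   to keep query and database proteomes disjoint).
#' @return List with `records` (protein tibble), `domains` (annotation
#'   tibble), `tf_info` (TF tibble incl. `pfm`, `dbd_sequence`), `go_map`
#'   (protein to GO tibble) and `obo` (path to the bundled subtree).
#' @export
gen_proteome <- function(n_tf = 60L, n_nontf = 120L, seed = 42L,
                         members_per_family = 5L, divergence = 0.15,
                         decoy_fraction = 0.1, mislabeled_fraction = 0.02,
                         motif_length = 8L, seq_length = 60L,
                         id_prefix = "") {
  set.seed(seed)
  if (length(n_tf) == 1L && is.null(names(n_tf))) {
    ref <- superclass_reference_counts()
    alloc <- round(n_tf * ref$n / sum(ref$n))
    while (sum(alloc) < n_tf) alloc[which.max(ref$n)] <- alloc[which.max(ref$n)] + 1L
    while (sum(alloc) > n_tf) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
    n_tf <- setNames(pmax(alloc, 0L), ref$superclass)
  }
  stopifnot(all(names(n_tf) %in% tf_superclasses()), all(n_tf >= 0))
  fam_counter <- 0L
  tf_rows <- list()
  for (sc in names(n_tf)) {
    remaining <- n_tf[[sc]]
    while (remaining > 0L) {
      fam_counter <- fam_counter + 1L
      k <- min(members_per_family, remaining)
      fam_seed <- sample.int(1e6, 1L)
      set.seed(fam_seed)
      cons <- mutate_sequence(unname(superclass_dbd_consensus()[sc]),
                              0.25)$sequence
      sp <- family_spec(sc, k, divergence, dbd_consensus = cons,
                        motif_length = motif_length,
                        id = sprintf("TF%03d", fam_counter))
      tf_rows[[length(tf_rows) + 1L]] <- gen_tf_family(sp, seed = fam_seed)
      remaining <- remaining - k
    }
  }
  tf_info <- dplyr::bind_rows(tf_rows)
  set.seed(seed + 1L)
  hk <- synthetic_housekeeping_domains()
  sc_go <- superclass_go_terms()
  # non-TFs
  n_decoy <- round(n_nontf * decoy_fraction)
  nontf_rows <- list()
  domain_rows <- list()
  for (i in seq_len(n_nontf)) {
    id <- sprintf("NT%04d", i)
    if (i <= n_decoy) {
      sc <- sample(tf_superclasses(), 1L)
      seg <- mutate_sequence(unname(superclass_dbd_consensus()[sc]), 0.25)
      fl <- sample(10:20, 2L, replace = TRUE)
      seqc <- paste0(random_aa(fl[1L]), seg$sequence, random_aa(fl[2L]))
      domain_rows[[length(domain_rows) + 1L]] <- tibble::tibble(
        protein_id = id,
        domain_id = paste0("SYN_DBD_", gsub("[^A-Za-z]", "", sc)),
        start = fl[1L] + 1L,
        end = fl[1L] + nchar(seg$sequence),
        go = list(c("GO:0003690")))
    } else {
      seqc <- random_aa(max(20L, seq_length + sample(-10:10, 1L)))
      j <- sample.int(nrow(hk), 1L)
      domain_rows[[length(domain_rows) + 1L]] <- tibble::tibble(
        protein_id = id, domain_id = hk$domain_id[j],
        start = 2L, end = min(nchar(seqc), 25L),
        go = hk$go[j])
    }
    nontf_rows[[i]] <- tibble::tibble(
      id = id, sequence = seqc, label = "non-TF",
      superclass = NA_character_, source = "synthetic")
  }
  nontf <- dplyr::bind_rows(nontf_rows)
  # TF domain annotations: the DBD interval with DNA-binding GO terms
  tf_domains <- purrr::map_dfr(seq_len(nrow(tf_info)), function(i) {
    sc <- tf_info$superclass[i]
    tibble::tibble(protein_id = tf_info$id[i],
                   domain_id = paste0("SYN_DBD_", gsub("[^A-Za-z]", "", sc)),
                   start = tf_info$dbd_start[i], end = tf_info$dbd_end[i],
                   go = list(sc_go[[sc]]))
  })
  domains <- dplyr::bind_rows(tf_domains, dplyr::bind_rows(domain_rows))
  # a small fraction of non-TFs carry the TF-activity GO term (mislabeled)
  n_mis <- round(n_nontf * mislabeled_fraction)
  if (n_mis > 0L) {
    mis_ids <- sample(nontf$id, n_mis)
    domains <- dplyr::bind_rows(domains, tibble::tibble(
      protein_id = mis_ids, domain_id = "SYN_TFGO", start = 1L, end = 5L,
      go = rep(list("GO:0003700"), n_mis)))
  }
  records <- dplyr::bind_rows(
    tf_info[, c("id", "sequence", "label", "superclass", "source")], nontf)
  if (nzchar(id_prefix)) {
    records$id <- paste0(id_prefix, records$id)
    domains$protein_id <- paste0(id_prefix, domains$protein_id)
    tf_info$id <- paste0(id_prefix, tf_info$id)
    tf_info$pfm <- lapply(tf_info$pfm, function(p) {
      p$id <- paste0(id_prefix, p$id)
      p
    })
  }
  go_map <- domains |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(go = list(unique(unlist(.data$go))), .groups = "drop")
  list(records = records, domains = domains, tf_info = tf_info,
       go_map = go_map, obo = synthetic_go_path())
}

#' Write a synthetic proteome to disk
#'
#' Emits the formats the pipeline consumes: labeled FASTA, domain TSV,
#' JASPAR-dialect PFM library, a subject label map, and a copy of the
#' bundled GO subtree.
#'
#' @param proteome List from [gen_proteome()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named vector of written paths.
#' @export
write_proteome <- function(proteome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "proteome.fasta"),
    domains = file.path(dir, "domains.tsv"),
    pfms = file.path(dir, "pfms.jaspar"),
    labels = file.path(dir, "labels.tsv"),
    obo = file.path(dir, "go_subtree.obo"))
  write_fasta(proteome$records, paths["fasta"])
  write_domain_tsv(proteome$domains, paths["domains"])
  write_pfm(proteome$tf_info$pfm, paths["pfms"], dialect = "jaspar")
  utils::write.table(
    data.frame(id = proteome$records$id, label = proteome$records$label,
               superclass = proteome$records$superclass),
    paths["labels"], sep = "\t", quote = FALSE, row.names = FALSE)
  file.copy(proteome$obo, paths["obo"], overwrite = TRUE)
  invisible(paths)
}
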