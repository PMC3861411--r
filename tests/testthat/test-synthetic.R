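test_that("family generation is deterministic and respects the spec", {
  sp <- family_spec("Basic domain", n_members = 5, divergence = 0.2,
                    id = "famA")
  f1 <- gen_tf_family(sp, seed = 7)
  f2 <- gen_tf_family(sp, seed = 7)
  expect_identical(f1$sequence, f2$sequence)
  expect_identical(f1$pfm[[3]]$counts, f2$pfm[[3]]$counts)
  expect_equal(nrow(f1), 5L)
  expect_true(all(f1$superclass == "Basic domain"))
  # the DBD interval indexes the mutated consensus inside the flanks
  expect_equal(substr(f1$sequence[1], f1$dbd_start[1], f1$dbd_end[1]),
               f1$dbd_sequence[1])
  expect_error(family_spec("Basic domain", divergence = 1.2))
  expect_error(family_spec("Spiral"))
})

test_that("zero divergence yields identical DBDs and PFMs", {
  f <- gen_tf_family(family_spec("Other", n_members = 4, divergence = 0,
                                 id = "famB"), seed = 8)
  expect_equal(length(unique(f$dbd_sequence)), 1L)
  expect_true(all(f$divergence == 0))
  for (i in 2:4) expect_equal(f$pfm[[i]]$counts, f$pfm[[1]]$counts)
  expect_equal(pfm_distance(f$pfm[[1]], f$pfm[[2]]), 0)
})

test_that("PFM distance grows with DBD divergence within a family", {
  f <- gen_tf_family(family_spec("Helix-turn-helix", n_members = 20,
                                 divergence = 0.2, id = "famC"), seed = 9)
  d <- pfm_distance_matrix(f$pfm)
  pairs <- utils::combn(20, 2)
  pfm_sim <- 1 - d[t(pairs)]
  dbd_id <- apply(pairs, 2, function(p) {
    a <- strsplit(f$dbd_sequence[p[1]], "")[[1]]
    b <- strsplit(f$dbd_sequence[p[2]], "")[[1]]
    mean(a == b)
  })
  # within one family the realized divergences span a narrow range, so the
  # association is positive but moderate (computed: rho ~ 0.44 under these
  # conditions); across families with wider divergence spread it is stronger
  expect_gt(stats::cor(dbd_id, pfm_sim, method = "spearman"), 0.3)
  wide <- dplyr::bind_rows(
    gen_tf_family(family_spec("Helix-turn-helix", n_members = 10,
                              divergence = 0.05, id = "lo"), seed = 9),
    gen_tf_family(family_spec("Helix-turn-helix", n_members = 10,
                              divergence = 0.35, id = "hi",
                              pfm_consensus = "ACGTGA"), seed = 10))
  d2 <- pfm_distance_matrix(wide$pfm)
  pairs2 <- utils::combn(20, 2)
  sim2 <- 1 - d2[t(pairs2)]
  id2 <- apply(pairs2, 2, function(p) {
    a <- strsplit(wide$dbd_sequence[p[1]], "")[[1]]
    b <- strsplit(wide$dbd_sequence[p[2]], "")[[1]]
    mean(a == b)
  })
  expect_gt(stats::cor(id2, sim2, method = "spearman"), 0.5)
})

test_that("generated proteomes are fully cross-referenced", {
  prot <- gen_proteome(n_tf = c("Basic domain" = 4, "Zinc finger" = 4,
                                "Helix-turn-helix" = 4, "Beta scaffold" = 4,
                                "Other" = 4),
                       n_nontf = 20, seed = 5)
  expect_equal(sum(prot$records$label == "TF"), 20L)
  expect_equal(sum(prot$records$label == "non-TF"), 20L)
  expect_equal(unname(table(prot$records$superclass)[tf_superclasses()]),
               rep(4L, 5), ignore_attr = TRUE)
  # every TF has at least one domain row inside the DNA-binding subtree
  st <- go_descendants(prot$obo)
  dna <- filter_dna_binding(prot$domains, st)
  expect_true(all(prot$tf_info$id %in% dna$protein_id))
  # all annotation rows point at existing records with valid coordinates
  expect_true(all(prot$domains$protein_id %in% prot$records$id))
  len <- nchar(prot$records$sequence[match(prot$domains$protein_id,
                                           prot$records$id)])
  expect_true(all(prot$domains$end <= len))
  # a TF-only proteome has no non-TF records
  only_tf <- gen_proteome(n_tf = c("Other" = 3), n_nontf = 0, seed = 5)
  expect_true(all(only_tf$records$label == "TF"))
})

test_that("a numeric TF total splits by the reference proportions", {
  prot <- gen_proteome(n_tf = 60, n_nontf = 0, seed = 6)
  counts <- table(prot$records$superclass)
  ref <- superclass_reference_counts()
  expected <- round(60 * ref$n / sum(ref$n))
  expect_equal(sum(counts), 60L)
  # helix-turn-helix dominates and beta scaffold is rare, as in the
  # reference stratum sizes
  expect_equal(names(which.max(counts)), "Helix-turn-helix")
  expect_lte(abs(counts[["Beta scaffold"]] - expected[4]), 1)
})

test_that("written proteomes re-parse identically", {
  prot <- gen_proteome(n_tf = c("Other" = 3, "Zinc finger" = 3),
                       n_nontf = 6, seed = 12)
  dir <- withr::local_tempdir()
  paths <- write_proteome(prot, dir)
  back <- read_fasta(paths["fasta"])
  expect_equal(back$id, prot$records$id)
  expect_equal(back$sequence, prot$records$sequence)
  expect_equal(back$label, prot$records$label)
  ann <- parse_domain_tsv(paths["domains"])
  expect_equal(nrow(ann), nrow(prot$domains))
  pfms <- read_pfm(paths["pfms"], "jaspar")
  expect_length(pfms, nrow(prot$tf_info))
  expect_equal(pfms[[1]]$counts, prot$tf_info$pfm[[1]]$counts)
})

test_that("decoy non-TFs carry DNA-binding annotations under non-TF labels", {
  prot <- gen_proteome(n_tf = c("Other" = 3), n_nontf = 40, seed = 13,
                       decoy_fraction = 0.25, mislabeled_fraction = 0)
  st <- go_descendants(prot$obo)
  dna <- filter_dna_binding(prot$domains, st)
  decoys <- intersect(dna$protein_id,
                      prot$records$id[prot$records$label == "non-TF"])
  expect_equal(length(decoys), 10L)
})
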