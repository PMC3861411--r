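hit_tbl <- function(bits_by_class, class_col = "label") {
  purrr::imap_dfr(bits_by_class, function(b, cl) {
    tibble::tibble(query_id = "q", subject_id = paste0(cl, seq_along(b)),
                   label = if (class_col == "label") cl else "TF",
                   superclass = if (class_col == "superclass") cl
                                else NA_character_,
                   raw_score = NA_real_, bits = b)
  })
}

test_that("percentile blocks are the five order statistics per class", {
  # single-hit TF block, absent non-TF block
  h <- hit_tbl(list("TF" = 10))
  v <- bitscore_percentiles(h, c("TF", "non-TF"))
  expect_equal(as.vector(v), c(10, 10, 10, 10, 10, 0, 0, 0, 0, 0))
  expect_equal(attr(v, "missing_classes"), "non-TF")
  # {1..5} maps onto (min, q25, median, q75, max) under linear interpolation
  h <- hit_tbl(list("TF" = c(3, 1, 5, 2, 4)))
  expect_equal(as.vector(bitscore_percentiles(h, "TF")), c(1, 2, 3, 4, 5))
  # order statistics oracle with interpolating quantiles, random case
  set.seed(31)
  b <- stats::runif(11, 10, 300)
  v <- bitscore_percentiles(hit_tbl(list("TF" = b)), "TF")
  expect_equal(as.vector(v),
               unname(stats::quantile(b, c(0, .25, .5, .75, 1), type = 7)))
})

test_that("percentile features are permutation invariant with fixed widths", {
  set.seed(32)
  h <- hit_tbl(list("Basic domain" = runif(5, 20, 60),
                    "Zinc finger" = runif(3, 20, 60),
                    "Helix-turn-helix" = runif(8, 20, 60),
                    "Beta scaffold" = runif(2, 20, 60),
                    "Other" = runif(4, 20, 60)), class_col = "superclass")
  v <- bitscore_percentiles(h, tf_superclasses(), "superclass")
  expect_length(v, 25L)
  # sorted within blocks
  for (k in 0:4) {
    expect_true(all(diff(v[(5 * k + 1):(5 * k + 5)]) >= 0))
  }
  hp <- h[sample(nrow(h)), ]
  expect_equal(bitscore_percentiles(hp, tf_superclasses(), "superclass"), v)
  expect_length(bitscore_percentiles(h, c("TF", "non-TF")), 10L)
})

test_that("PSSM profile features are 400 sigmoid-squashed values", {
  q <- tibble::tibble(id = "q", sequence = "MKRHKLVDEW")
  db <- toy_proteins()
  v <- pssm_features(q, db)
  expect_length(v, 400L)
  expect_true(all(v > 0 & v < 1))
  expect_false(attr(v, "no_hits"))
  v0 <- pssm_features(q, db[0, ])
  expect_true(attr(v0, "no_hits"))
  expect_length(v0, 400L)
})

test_that("single-residue queries concentrate compressed PSSM mass in one row", {
  q <- tibble::tibble(id = "q", sequence = strrep("K", 12))
  v <- pssm_features(q, NULL)
  m <- matrix(v, 20, 20, byrow = TRUE,
              dimnames = list(tfannotate:::aa_alphabet(),
                              tfannotate:::aa_alphabet()))
  # rows of residues absent from the query sit exactly at g(0) = 1/2
  off <- m[rownames(m) != "K", ]
  expect_true(all(abs(off - 0.5) < 1e-12))
  expect_gt(max(abs(m["K", ] - 0.5)), 0.01)
})

test_that("k-mer counts enumerate overlapping windows exactly", {
  v <- kmer_features("AAA", k = 1)
  expect_equal(unname(v["A"]), 3L)
  expect_equal(sum(v), 3L)
  v2 <- kmer_features("ACA", k = 2)
  expect_equal(unname(v2[c("AC", "CA")]), c(1L, 1L))
  expect_equal(sum(v2), 2L)
  expect_length(v2, 400L)
  set.seed(33)
  for (k in 1:3) {
    s <- random_protein(50)
    v <- kmer_features(s, k)
    expect_equal(sum(v), 50 - k + 1)
    # windowed enumeration oracle
    wins <- vapply(seq_len(50 - k + 1), function(i) substr(s, i, i + k - 1),
                   character(1))
    tab <- table(wins)
    expect_equal(unname(v[names(tab)]), unname(as.integer(tab)))
  }
  expect_warning(vz <- kmer_features("ACD", k = 5), "exceeds")
  expect_true(all(vz == 0))
})

test_that("pseudo amino-acid features follow the Chou construction", {
  # lambda = 0 degenerates to the normalized composition
  s <- "ARNDCARND"
  expect_equal(unname(pseudo_aa_features(s, lambda = 0)),
               unname(kmer_features(s, 1) / nchar(s)))
  # homopolymers have vanishing sequence-order correlation
  v <- pseudo_aa_features(strrep("K", 10), lambda = 3)
  expect_length(v, 23L)
  expect_equal(unname(v[21:23]), c(0, 0, 0))
  # hand evaluation of theta_1 for ARN with the standardized property triple
  sc <- tfannotate:::aa_property_scales()
  th <- function(i, j) mean((sc[, i] - sc[, j])^2)
  theta1 <- mean(c(th(1, 2), th(2, 3)))  # A-R and R-N adjacent pairs
  w <- 0.05
  f <- rep(1 / 3, 3)
  denom <- 1 + w * theta1
  v <- pseudo_aa_features("ARN", lambda = 1, w = w)
  expect_equal(unname(v["theta1"]), w * theta1 / denom)
  expect_equal(unname(v[c("A", "R", "N")]), f / denom)
  expect_equal(sum(v), (1 + w * theta1) / denom)
  expect_error(pseudo_aa_features("ARN", lambda = 3), "lambda")
})

test_that("domain features are binary over a fixed vocabulary", {
  voc <- c("IPR001", "IPR002", "IPR003")
  expect_equal(unname(domain_features(character(), voc)), c(0L, 0L, 0L))
  expect_equal(unname(domain_features("IPR002", voc)), c(0L, 1L, 0L))
  expect_message(v <- domain_features(c("IPR002", "IPR999"), voc),
                 "out-of-vocabulary")
  expect_equal(sum(v), 1L)
  # vocabulary built from training annotations covers every domain seen
  ann <- tibble::tibble(protein_id = c("a", "a", "b", "c"),
                        domain_id = c("D1", "D2", "D1", "D3"))
  expect_equal(domain_vocabulary(ann), c("D1", "D2", "D3"))
  m <- domain_feature_matrix(tibble::tibble(id = c("a", "b", "c", "d")), ann)
  expect_equal(dim(m), c(4L, 3L))
  expect_equal(unname(m["a", ]), c(1L, 1L, 0L))
  expect_equal(unname(m["d", ]), c(0L, 0L, 0L))
})
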