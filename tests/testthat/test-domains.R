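test_that("domain TSV rows parse with coordinates and GO term sets", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\tIPR000001\t10\t60\tGO:0003677|GO:0043565",
               "P1\tIPR000002\t70\t90\t",
               "P2\tIPR000003\t5\t25"), f)
  a <- parse_domain_tsv(f)
  expect_equal(nrow(a), 3L)
  expect_equal(a$go[[1]], c("GO:0003677", "GO:0043565"))
  expect_equal(a$go[[2]], character())
  expect_equal(a$go[[3]], character())
  expect_equal(a$start[1], 10L)
  writeLines("P1\tIPR1", f)
  expect_error(parse_domain_tsv(f), "line 1")
  writeLines("P1\tIPR1\tten\t20\t", f)
  expect_error(parse_domain_tsv(f), "line 1")
  writeLines("P1\tIPR1\t30\t20\t", f)
  expect_error(parse_domain_tsv(f), "invalid interval")
})

test_that("domain annotations round-trip through write and parse", {
  set.seed(61)
  n <- 100
  ann <- tibble::tibble(
    protein_id = sprintf("P%03d", sample(30, n, TRUE)),
    domain_id = sprintf("IPR%06d", sample(500, n, TRUE)),
    start = sample(100, n, TRUE))
  ann$end <- ann$start + sample(10:50, n, TRUE)
  ann$go <- lapply(seq_len(n), function(i) {
    sprintf("GO:%07d", sample(1e5, sample(0:3, 1)))
  })
  f <- withr::local_tempfile(fileext = ".tsv")
  write_domain_tsv(ann, f)
  back <- parse_domain_tsv(f)
  expect_equal(as.data.frame(back), as.data.frame(ann))
})

write_toy_obo <- function(lines) {
  f <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", lines), f)
  f
}

test_that("GO subtrees are transitive closures over is_a", {
  f <- write_toy_obo(c(
    "[Term]", "id: GO:1", "name: root", "",
    "[Term]", "id: GO:2", "name: a", "is_a: GO:1 ! root", "",
    "[Term]", "id: GO:3", "name: b", "is_a: GO:1 ! root", "",
    "[Term]", "id: GO:4", "name: c", "is_a: GO:2 ! a", "",
    "[Term]", "id: GO:5", "name: unrelated", "",
    "[Term]", "id: GO:6", "name: partonly",
    "relationship: part_of GO:2 ! a"))
  st <- go_descendants(f, "GO:1")
  expect_setequal(st$members, c("GO:1", "GO:2", "GO:3", "GO:4"))
  leaf <- go_descendants(f, "GO:4")
  expect_equal(leaf$members, "GO:4")
  with_po <- go_descendants(f, "GO:1", use_part_of = TRUE)
  expect_true("GO:6" %in% with_po$members)
  expect_error(go_descendants(f, "GO:404"), "not present")
})

test_that("subtree membership equals brute-force reachability", {
  set.seed(62)
  n <- 25
  ids <- sprintf("GO:%02d", seq_len(n))
  parents <- lapply(seq_len(n), function(i) {
    if (i == 1) character() else sample(ids[seq_len(i - 1)], sample(0:2, 1))
  })
  lines <- unlist(lapply(seq_len(n), function(i) {
    c("[Term]", paste("id:", ids[i]), paste("name: t", i),
      paste("is_a:", parents[[i]]), "")
  }))
  f <- write_toy_obo(lines)
  # brute force: iterate child collection to a fixed point
  reach <- function(root) {
    members <- root
    repeat {
      kids <- ids[vapply(parents, function(p) any(p %in% members), logical(1))]
      new <- union(members, kids)
      if (setequal(new, members)) return(members)
      members <- new
    }
  }
  for (root in sample(ids, 5)) {
    expect_setequal(go_descendants(f, root)$members, reach(root))
  }
})

test_that("DNA-binding filtering keeps exactly the subtree-annotated rows", {
  st <- go_descendants(synthetic_go_path())
  expect_true(all(c("GO:0003677", "GO:0043565", "GO:0003700", "GO:0003690",
                    "GO:0000976") %in% st$members))
  expect_false(any(c("GO:0003723", "GO:0016301", "GO:0003676") %in%
                     st$members))
  ann <- tibble::tibble(
    protein_id = c("P1", "P1", "P2"),
    domain_id = c("D1", "D2", "D3"),
    start = c(1L, 40L, 1L), end = c(30L, 60L, 20L),
    go = list("GO:0003677", "GO:0003723", c("GO:0016301", "GO:0000976")))
  kept <- filter_dna_binding(ann, st)
  expect_equal(kept$domain_id, c("D1", "D3"))
  expect_equal(filter_dna_binding(kept, st), kept)
})

test_that("overlapping DBD annotations merge into maximal intervals", {
  ann <- tibble::tibble(protein_id = c("P1", "P1", "P1", "P2"),
                        domain_id = c("D1", "D1", "D2", "D1"),
                        start = c(10L, 25L, 80L, 5L),
                        end = c(30L, 50L, 90L, 9L),
                        go = list("GO:0003677", "GO:0003677", "GO:0003677",
                                  "GO:0003677"))
  iv <- dbd_intervals(ann)
  p1 <- iv[iv$protein_id == "P1", ]
  expect_equal(p1$start, c(10L, 80L))
  expect_equal(p1$end, c(50L, 90L))
  recs <- tibble::tibble(id = c("P1", "P2"),
                         sequence = c(strrep("K", 100), strrep("A", 9)))
  seqs <- dbd_sequences(recs, iv)
  expect_equal(nchar(seqs$dbd_sequence), c(41L, 11L, 5L))
})

test_that("the non-TF label post-filter removes TF entries and GO:0003700", {
  recs <- tibble::tibble(id = c("A", "B", "C", "D"),
                         sequence = "MKVL", label = "non-TF")
  go_map <- tibble::tibble(protein_id = c("B", "C"),
                           go = list("GO:0003700", "GO:0016301"))
  res <- label_postfilter(recs, go_map, tf_ids = "A")
  expect_equal(res$records$id, c("C", "D"))
  expect_equal(res$removed_tf_entry, 1L)
  expect_equal(res$removed_go, 1L)
})
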