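test_that("GMT and long-TSV pathway parsing round-trips and rejects bad input", {
  f <- write_lines_tmp(c("P1\tdesc one\tTP53\tMDM2", "P2\tdesc two\tATM"))
  db <- load_pathway_db(f, "gmt")
  expect_equal(db$pathway_id, c("P1", "P2"))
  expect_equal(db$members[[1]], c("MDM2", "TP53"))

  expect_length(load_pathway_db(write_lines_tmp(character(0)), "gmt")$pathway_id, 0)
  # a line with id+description but zero members violates the invariant
  expect_error(load_pathway_db(write_lines_tmp("P1\tdesc"), "gmt"), "line 1")
  expect_error(load_pathway_db(write_lines_tmp(c("P1\td\tA", "P1\td\tB")), "gmt"),
               "duplicate pathway_id")

  tsv <- write_lines_tmp(c("pathway_id\tgene", "P1\tTP53", "P1\tMDM2", "P2\tATM"))
  db2 <- load_pathway_db(tsv, "tsv")
  expect_equal(db2$members[[1]], c("MDM2", "TP53"))
})

test_that("SIF edges are undirected, deduplicated, and self-loops flagged", {
  f <- write_lines_tmp(c("A\tpp\tB", "B\tpp\tA", "C\tpp\tC"))
  e <- load_ppi(f)
  expect_equal(nrow(e), 2L)
  expect_equal(sum(e$self_loop), 1L)
  e2 <- load_ppi(write_lines_tmp(c("A\tB", "C\tD")))
  expect_equal(nrow(e2), 2L)
})

test_that("protein expansion finds pathway and PPI neighbours with provenance", {
  pw <- load_pathway_db(write_lines_tmp("P1\td\tG1\tG2"), "gmt")
  ed <- load_ppi(write_lines_tmp("G1\tpp\tG3"))
  focal <- expand_from_proteins("G1", pw, ed)
  expect_equal(focal$gene, c("G1", "G2", "G3"))
  expect_equal(focal$is_query, c(TRUE, FALSE, FALSE))
  expect_equal(focal$sources[focal$gene == "G2"], "pathway")
  expect_equal(focal$via[focal$gene == "G2"], "P1")
  expect_equal(focal$sources[focal$gene == "G3"], "ppi")
  expect_equal(focal$via[focal$gene == "G3"], "G1")

  # query absent from all snapshots: only itself, empty provenance
  lone <- expand_from_proteins("G9", pw, ed)
  expect_equal(lone$gene, "G9")
  expect_true(lone$is_query)
  expect_equal(lone$sources, "")

  # a query gene sharing a pathway with another query keeps is_query = TRUE
  # but gains pathway provenance
  both <- expand_from_proteins(c("G1", "G2"), pw, ed)
  g2 <- both[both$gene == "G2", ]
  expect_true(g2$is_query)
  expect_equal(g2$sources, "pathway")
})

test_that("pathway-name expansion is case-insensitive exact match", {
  pw <- load_pathway_db(write_lines_tmp(c("P1\tApoptosis\tG1", "P2\td\tG1\tG3")), "gmt")
  expect_equal(expand_from_pathways("p1", pw)$gene, "G1")
  expect_equal(expand_from_pathways("apoptosis", pw)$gene, "G1")
  expect_equal(expand_from_pathways(c("P1", "P2"), pw)$gene, c("G1", "G3"))
  expect_warning(res <- expand_from_pathways("absent", pw), "no pathway matched")
  expect_equal(nrow(res), 0L)
})

test_that("expansion matches the brute-force oracle on random snapshots", {
  set.seed(42)
  for (rep in 1:10) {
    genes <- paste0("G", 1:30)
    n_pw <- sample(2:6, 1)
    pw <- data.frame(pathway_id = paste0("P", 1:n_pw),
                     name = paste0("p", 1:n_pw), stringsAsFactors = FALSE)
    pw$members <- lapply(1:n_pw, function(i) sort(sample(genes, sample(2:8, 1))))
    pairs <- t(combn(genes, 2))
    keep <- runif(nrow(pairs)) < 0.05
    ed <- data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                     source = "x", self_loop = FALSE, stringsAsFactors = FALSE)
    queries <- sample(genes, sample(1:3, 1))
    got <- expand_from_proteins(queries, pw, ed)
    expect_equal(got$gene, oracle_focal(queries, pw, ed))
  }
})

test_that("expansion is monotone and superadditive in the query set", {
  set.seed(7)
  genes <- paste0("G", 1:25)
  pw <- data.frame(pathway_id = paste0("P", 1:4), name = paste0("p", 1:4),
                   stringsAsFactors = FALSE)
  pw$members <- lapply(1:4, function(i) sort(sample(genes, 6)))
  pairs <- t(combn(genes, 2))
  keep <- runif(nrow(pairs)) < 0.06
  ed <- data.frame(a = pairs[keep, 1], b = pairs[keep, 2], source = "x",
                   self_loop = FALSE, stringsAsFactors = FALSE)
  q1 <- c("G1", "G2"); q2 <- c("G5")
  f1 <- expand_from_proteins(q1, pw, ed)$gene
  f2 <- expand_from_proteins(q2, pw, ed)$gene
  f12 <- expand_from_proteins(c(q1, q2), pw, ed)$gene
  expect_true(all(union(f1, f2) %in% f12))
  # adding a pathway never removes a focal gene
  pw2 <- data.frame(pathway_id = c(pw$pathway_id, "P9"),
                    name = c(pw$name, "p9"), stringsAsFactors = FALSE)
  pw2$members <- c(pw$members, list(c("G1", "G20")))
  expect_true(all(f1 %in% expand_from_proteins(q1, pw2, ed)$gene))
})

test_that("source distribution counts non-query genes once per combination", {
  pw <- load_pathway_db(write_lines_tmp("P1\td\tG1\tG2\tG3"), "gmt")
  ed <- load_ppi(write_lines_tmp(c("G1\tpp\tG3", "G1\tpp\tG4")))
  focal <- expand_from_proteins("G1", pw, ed)
  dist <- source_distribution(focal)
  # G2 pathway-only, G4 ppi-only, G3 both
  expect_equal(unname(dist["pathway"]), 1L)
  expect_equal(unname(dist["ppi"]), 1L)
  expect_equal(unname(dist["both"]), 1L)
  expect_equal(sum(dist), sum(!focal$is_query & nzchar(focal$sources)))
  empty <- source_distribution(focal[0, ])
  expect_equal(sum(empty), 0L)
})

test_that("alias tables resolve accessions and report the unresolved", {
  f <- write_lines_tmp(c("alias\tsymbol", "P04637\tTP53", "Q00987\tMDM2"))
  al <- load_aliases(f)
  q <- resolve_queries(c("P04637", "BRCA1", "XXX"), al)
  expect_equal(as.character(q[1]), "TP53")
  expect_equal(as.character(q[2]), "BRCA1")
  expect_true("XXX" %in% attr(q, "unresolved"))
  bad <- write_lines_tmp(c("alias\tsymbol", "P1\tA", "P1\tB"))
  expect_error(load_aliases(bad), "multiple symbols")
})
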