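write_ann_fixture <- function(df, header = FALSE) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  path
}

test_that("load_annotations keeps resolving rows and closes the table", {
  g <- chain_graph()
  path <- write_ann_fixture(data.frame(gene = c("g1", "g2", "g3"),
                                       term = c("B", "A", "R")))
  tab <- load_annotations(path, g, universe = c("g1", "g2", "g3", "g4"))
  expect_true(tab$closed)
  # g1 on B propagates to A and R
  expect_setequal(tab$pairs$term[tab$pairs$gene == "g1"], c("B", "A", "R"))
  expect_identical(nrow(load_annotations(path, g, c("g1", "g2", "g3"),
                                         close = FALSE)$pairs), 3L)
})

test_that("unknown terms are dropped with a warning; too many unknowns error", {
  g <- chain_graph()
  mixed <- write_ann_fixture(data.frame(gene = c("g1", "g1", "g2"),
                                        term = c("B", "NOPE", "A")))
  expect_warning(tab <- load_annotations(mixed, g, c("g1", "g2")),
                 "dropped 1")
  expect_false("NOPE" %in% tab$pairs$term)

  allbad <- write_ann_fixture(data.frame(gene = "g1", term = "NOPE"))
  expect_error(load_annotations(allbad, g, "g1"), "wrong ontology")
  expect_error(load_annotations(tempfile(), g, "g1"), "not found")
  empty <- tempfile(); file.create(empty)
  expect_error(suppressWarnings(load_annotations(empty, g, "g1")), "empty|no lines")
})

test_that("an optional header row is detected and skipped", {
  g <- chain_graph()
  path <- write_ann_fixture(data.frame(gene_id = "g1", term_id = "B"),
                            header = TRUE)
  tab <- load_annotations(path, g, "g1", close = FALSE)
  expect_identical(tab$pairs, data.frame(gene = "g1", term = "B",
                                         stringsAsFactors = FALSE))
})

test_that("GAF reader uses columns 3 and 5 only", {
  g <- chain_graph()
  path <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.2",
               paste("DB", "ACC1", "g1", "", "B", "REF", "IDA", "", "P",
                     sep = "\t"),
               paste("DB", "ACC2", "g2", "NOT", "A", "REF", "IEA", "", "P",
                     sep = "\t")), path)
  tab <- load_gaf(path, g, c("g1", "g2"), close = FALSE)
  expect_setequal(paste(tab$pairs$gene, tab$pairs$term), c("g1 B", "g2 A"))
})

test_that("true-path closure matches the fixpoint oracle and is idempotent", {
  d <- diamond_graph()
  tab <- annotation_table(data.frame(gene = "g", term = "C"), "g")
  closed <- propagate_true_path(tab, d)
  expect_identical(nrow(closed$pairs), 4L)
  got <- closed$pairs[order(closed$pairs$gene, closed$pairs$term), ]
  rownames(got) <- NULL
  want <- oracle_closure(tab$pairs, d$parents)
  rownames(want) <- NULL
  expect_identical(got, want)
  # idempotence
  twice <- propagate_true_path(closed, d)
  expect_setequal(paste(twice$pairs$gene, twice$pairs$term),
                  paste(closed$pairs$gene, closed$pairs$term))
  # chain example
  g <- chain_graph()
  ch <- propagate_true_path(annotation_table(data.frame(gene = "g", term = "B"),
                                             "g"), g)
  expect_setequal(ch$pairs$term, c("B", "A", "R"))
})

test_that("closure never removes pairs on random inputs", {
  for (seed in 1:6) {
    g <- random_dag(15, p_edge = 0.3, seed = seed)
    raw <- random_annotations(g, sprintf("g%02d", 1:20), density = 0.1,
                              seed = seed, close = FALSE)
    closed <- propagate_true_path(raw, g)
    expect_gte(nrow(closed$pairs), nrow(raw$pairs))
    expect_true(all(paste(raw$pairs$gene, raw$pairs$term) %in%
                      paste(closed$pairs$gene, closed$pairs$term)))
  }
})

test_that("genes_with_all_terms is the intersection over conjunct terms", {
  # mirrors the published bicluster: five genes carrying both the
  # protein-metabolism and the phospho-amino-acid-binding term
  g <- ontology_graph(c("root", "GO:0044267", "GO:0045309"),
                      parents = list(root = character(0),
                                     `GO:0044267` = "root",
                                     `GO:0045309` = "root"))
  both <- c("Fbxw7", "Nedd4", "Btrc", "Cblb", "Socs3")
  universe <- c(both, "Socs1", "Cish", "Trim40")
  pairs <- rbind(
    data.frame(gene = c(both, "Socs1"), term = "GO:0044267"),
    data.frame(gene = c(both, "Cish"), term = "GO:0045309"))
  tab <- propagate_true_path(annotation_table(pairs, universe), g)
  expect_setequal(genes_with_all_terms(tab, c("GO:0044267", "GO:0045309")),
                  both)
  expect_setequal(genes_with_all_terms(tab, "GO:0045309"), c(both, "Cish"))
  # disjoint terms -> empty
  g2 <- ontology_graph(c("r", "x", "y"),
                       parents = list(r = character(0), x = "r", y = "r"))
  tab2 <- annotation_table(data.frame(gene = c("a", "b"), term = c("x", "y")),
                           c("a", "b"))
  expect_length(genes_with_all_terms(tab2, c("x", "y")), 0L)
  expect_error(genes_with_all_terms(tab2, character(0)), "non-empty")
})

test_that("coverage is anti-monotone in the term set", {
  for (seed in 1:5) {
    g <- random_dag(12, p_edge = 0.3, seed = seed)
    tab <- random_annotations(g, sprintf("g%02d", 1:25), density = 0.2,
                              seed = seed)
    terms <- unique(tab$pairs$term)
    if (length(terms) < 3) next
    t2 <- sample(terms, 2); t3 <- c(t2, sample(setdiff(terms, t2), 1))
    expect_true(all(genes_with_all_terms(tab, t3) %in%
                      genes_with_all_terms(tab, t2)))
  }
})
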