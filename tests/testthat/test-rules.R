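rules_fixture <- function() {
  g <- rules_graph()
  uni <- sprintf("g%02d", 1:10)
  pairs <- rbind(
    data.frame(gene = uni[c(1:5, 6)], term = "T1"),   # one false positive each,
    data.frame(gene = uni[c(1:5, 8)], term = "T2"),   # so only T1 AND T2 is pure
    data.frame(gene = uni[6:7], term = "T3"),
    data.frame(gene = uni[1:2], term = "T1a"),
    data.frame(gene = uni[9:10], term = "root"))  # every gene annotated
  tab <- propagate_true_path(annotation_table(pairs, uni), g)
  list(graph = g, tab = tab, uni = uni,
       lab = make_labeling(uni, uni[1:5]))
}

test_that("rule construction enforces non-redundancy and min_level", {
  g <- rules_graph()
  expect_error(rule(character(0)), "at least one term")
  expect_error(rule(c("T1", "T1a"), g), "ancestor")
  expect_error(rule(c("root", "T2"), g), "ancestor")
  expect_error(rule("T1", g, min_level = 2), "min_level")
  expect_silent(r <- rule(c("T2", "T1a"), g, min_level = 1))
  expect_identical(r$term_ids, c("T1a", "T2"))  # stored sorted
})

test_that("evaluate_rule computes confusion counts and the three scores", {
  fx <- rules_fixture()
  # T1 AND T2 covers exactly the five significant genes
  perfect <- evaluate_rule(rule(c("T1", "T2")), fx$lab, fx$tab)
  expect_setequal(perfect$covered, fx$uni[1:5])
  expect_equal(c(perfect$acc, perfect$auc, perfect$f1), c(1, 1, 1))
  # root covers everything: f1 = 2*5/(2*5+5+0), auc = 1/2
  allr <- evaluate_rule(rule("root"), fx$lab, fx$tab)
  expect_equal(allr$f1, 2 / 3)
  expect_equal(allr$auc, 0.5)
  expect_equal(allr$acc, 0.5)
  # hand-built tp=3 fp=1 fn=2 tn=4 on a 10-gene universe
  uni <- sprintf("h%02d", 1:10)
  g2 <- flat_graph("t")
  tab2 <- annotation_table(data.frame(gene = uni[c(1:3, 6)], term = "t"),
                           uni, closed = TRUE)
  sc <- evaluate_rule(rule("t"), make_labeling(uni, uni[1:5]), tab2)
  expect_identical(c(sc$tp, sc$fp, sc$fn, sc$tn), c(3L, 1L, 2L, 4L))
  expect_equal(sc$f1, 6 / 9)
  expect_equal(sc$acc, 0.7)
  expect_equal(sc$auc, (3 / 5 + 4 / 5) / 2)
  # contract violations surface when a graph is supplied
  expect_error(evaluate_rule(rule(c("T1", "T1a")), fx$lab, fx$tab, fx$graph),
               "ancestor")
})

test_that("refine adds non-redundant terms and specialises into children", {
  g <- rules_graph()
  cand <- c("T1", "T2", "T3", "T1a")
  refs <- refine(rule("T1"), g, cand)
  keys <- vapply(refs, function(r) paste(r$term_ids, collapse = "+"), "")
  expect_true("T1+T2" %in% keys)
  expect_true("T1a" %in% keys)          # child replacement
  expect_false("T1+T1a" %in% keys)      # redundancy ban
  # at max_conjuncts only specialisations remain
  refs2 <- refine(rule(c("T1", "T2")), g, cand, max_conjuncts = 2)
  keys2 <- vapply(refs2, function(r) paste(r$term_ids, collapse = "+"), "")
  expect_true(all(vapply(refs2, function(r) length(r$term_ids), 1L) == 2L))
  expect_true("T1a+T2" %in% keys2)
})

test_that("enforce_min_level filters by shortest-path level", {
  g <- rules_graph()
  expect_setequal(enforce_min_level(g$ids, g, 0), g$ids)
  expect_setequal(enforce_min_level(g$ids, g, 2), "T1a")
  expect_length(enforce_min_level(g$ids, g, 6), 0L)
  ch <- chain_graph()
  expect_identical(enforce_min_level(c("R", "A", "B"), ch, 2), "B")
})

test_that("induce_rules recovers a planted conjunction and respects contracts", {
  fx <- rules_fixture()
  for (fn in c("ACC", "AUC", "F1")) {
    res <- induce_rules(fx$lab, fx$tab, fx$graph,
                        search_config(eval_fn = fn, max_conjuncts = 2))
    expect_identical(res[[1]]$rule$term_ids, c("T1", "T2"))
    expect_equal(res[[1]]$score[[tolower(fn)]], 1)
  }
  # a single perfectly-separating term ranks first
  uni <- sprintf("g%02d", 1:10)
  tab <- annotation_table(
    rbind(data.frame(gene = uni[1:5], term = "T1"),
          data.frame(gene = uni[6:9], term = "T2")), uni, closed = TRUE)
  g <- flat_graph(c("T1", "T2"))
  tab <- propagate_true_path(annotation_table(tab$pairs, uni), g)
  res <- induce_rules(make_labeling(uni, uni[1:5]), tab, g,
                      search_config(eval_fn = "F1"))
  expect_identical(res[[1]]$rule$term_ids, "T1")
  # min_level above all levels: empty with warning
  expect_warning(empty <- induce_rules(fx$lab, fx$tab, fx$graph,
                                       search_config(min_level = 6)),
                 "no eligible term")
  expect_length(empty, 0L)
})

test_that("returned rules satisfy min_level, non-redundancy and beat the seeds", {
  for (seed in 1:5) {
    g <- make_ontology(14, depth = 3, branching = 2, seed = seed)
    genes <- sprintf("g%02d", 1:50)
    tab <- random_annotations(g, genes, density = 0.12, seed = seed)
    set.seed(seed * 7)
    lab <- make_labeling(genes, sample(genes, 18))
    cfg <- search_config(eval_fn = "F1", min_level = 1, max_conjuncts = 2)
    res <- induce_rules(lab, tab, g, cfg)
    if (!length(res)) next
    eligible <- enforce_min_level(unique(tab$pairs$term), g, 1)
    best_seed <- max(vapply(eligible, function(t)
      evaluate_rule(rule(t), lab, tab)$f1, 1.0))
    expect_gte(res[[1]]$score$f1, best_seed)
    for (e in res) {
      expect_silent(validate_rule(e$rule, g, min_level = 1))
    }
    # scores are sorted descending
    f1s <- vapply(res, function(e) e$score$f1, 1.0)
    expect_identical(f1s, sort(f1s, decreasing = TRUE))
  }
})

test_that("distinct-coverage deduplication collapses to the shortest rule", {
  # T1 and T1a have identical annotated sets after closure below
  g <- rules_graph()
  uni <- sprintf("g%02d", 1:6)
  tab <- propagate_true_path(
    annotation_table(data.frame(gene = uni[1:3], term = "T1a"), uni), g)
  res <- induce_rules(make_labeling(uni, uni[1:3]), tab, g,
                      search_config(eval_fn = "ACC", max_conjuncts = 2))
  covs <- vapply(res, function(e) paste(e$score$covered, collapse = "|"), "")
  expect_false(anyDuplicated(covs) > 0)
  # the perfect-coverage representative is a singleton (shortest), T1 or T1a
  expect_length(res[[1]]$rule$term_ids, 1L)
})
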