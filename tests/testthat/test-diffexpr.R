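toy_cq <- function(values, tissues = NULL, ref = "Hsp90") {
  if (is.null(tissues)) tissues <- rep(c("stomach", "colon"), each = ncol(values) / 2)
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  cq_matrix(values, stats::setNames(tissues, colnames(values)),
            reference_gene = ref)
}

test_that("cq_matrix validates its invariants", {
  v <- matrix(c(20, 21, 24, 25), 2, byrow = TRUE,
              dimnames = list(c("Hsp90", "g1"), NULL))
  expect_error(toy_cq(v, tissues = c("colon", "colon")), ">= 2 tissues")
  v2 <- v; v2["Hsp90", 1] <- NA
  expect_error(toy_cq(v2), "missing Cq")
  v3 <- v; v3["g1", 1] <- 46
  expect_error(toy_cq(v3), "\\(0, 45\\]")
})

test_that("impute_missing applies the per-gene max-plus-two rule", {
  v <- matrix(c(20, 20.5, 21, 20, NA, 22, 25, 26, NA, NA, NA, NA),
              4, 3, byrow = TRUE,
              dimnames = list(c("Hsp90", "g1", "g2", "g3"), NULL))
  cq <- toy_cq(v, tissues = c("stomach", "stomach", "colon"))
  expect_warning(imp <- impute_missing(cq), "g3")
  expect_identical(unname(imp$values["g1", ]), c(20, 24, 22))
  expect_identical(unname(imp$values["g2", ]), c(25, 26, 28))
  expect_false("g3" %in% rownames(imp$values))
  expect_identical(unname(imp$imputed["g1", ]), c(FALSE, TRUE, FALSE))
  # no missing -> identity, nothing flagged
  vc <- v[c("Hsp90", "g2"), ]; vc["g2", 3] <- 27
  clean <- impute_missing(toy_cq(vc, tissues = c("stomach", "stomach", "colon")))
  expect_identical(clean$values,
                   toy_cq(vc, tissues = c("stomach", "stomach", "colon"))$values)
  expect_false(any(clean$imputed))
})

test_that("normalize_cq yields -deltaCq (log2 relative quantity)", {
  v <- matrix(c(20, 21, 24, 25, 20, 21), 3, 2, byrow = TRUE,
              dimnames = list(c("Hsp90", "g1", "same_as_ref"), NULL))
  e <- normalize_cq(toy_cq(v))
  expect_equal(unname(e$values["g1", ]), c(-4, -4))
  expect_equal(unname(e$values["same_as_ref", ]), c(0, 0))
  expect_false("Hsp90" %in% rownames(e$values))
  # natural-log switch is a constant rescaling
  eln <- normalize_cq(toy_cq(v), base = "ln")
  expect_equal(eln$values, e$values * log(2))
})

test_that("normalisation is invariant to per-sample constant Cq shifts", {
  set.seed(7)
  v <- matrix(runif(12, 20, 30), 4, 3,
              dimnames = list(c("Hsp90", "g1", "g2", "g3"), NULL))
  shift <- c(1.5, -2, 0.3)
  a <- normalize_cq(toy_cq(v, tissues = c("stomach", "stomach", "colon")))
  b <- normalize_cq(toy_cq(sweep(v, 2, -shift),
                           tissues = c("stomach", "stomach", "colon")))
  expect_equal(a$values, b$values)
})

test_that("anova_tukey agrees with base aov/TukeyHSD on random data", {
  set.seed(11)
  tissues <- rep(c("stomach", "small_intestine", "colon"), each = 3)
  for (i in 1:5) {
    x <- rnorm(9, sd = 1.2) + rep(rnorm(3, sd = 1), each = 3)
    v <- rbind(Hsp90 = rep(20, 9), g1 = 20 - x)
    colnames(v) <- paste0("s", 1:9)
    expr <- normalize_cq(cq_matrix(v, stats::setNames(tissues, colnames(v))))
    got <- anova_tukey(expr)
    fit <- stats::aov(x ~ g, data.frame(x = x, g = factor(tissues, levels = unique(tissues))))
    hsd <- stats::TukeyHSD(fit)$g
    for (j in seq_len(nrow(got$pairs))) {
      key1 <- paste0(got$pairs$second[j], "-", got$pairs$first[j])
      key2 <- paste0(got$pairs$first[j], "-", got$pairs$second[j])
      k <- intersect(c(key1, key2), rownames(hsd))
      sign <- if (k == key1) -1 else 1
      expect_equal(unname(got$p_adj["g1", j]), unname(hsd[k, "p adj"]),
                   tolerance = 1e-8)
      expect_equal(unname(got$mean_diff["g1", j]), sign * unname(hsd[k, "diff"]),
                   tolerance = 1e-10)
    }
    expect_equal(unname(got$anova_p["g1"]),
                 summary(fit)[[1]][["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("anova_tukey handles symmetry, separation and degeneracy", {
  tissues <- rep(c("a", "b", "c"), each = 3)
  mk <- function(x) {
    v <- rbind(Hsp90 = rep(20, 9), g1 = 20 - x)
    colnames(v) <- paste0("s", 1:9)
    anova_tukey(normalize_cq(cq_matrix(v, stats::setNames(tissues, colnames(v)))))
  }
  # identical group means, nonzero variance: F = 0, nothing significant
  eq <- mk(rep(c(-1, 0, 1), 3))
  expect_equal(unname(eq$anova_p["g1"]), 1)
  expect_true(all(eq$p_adj["g1", ] > 0.99))
  # huge separation with tiny jitter: the separated pairs are significant
  sep <- mk(c(0, 0.01, -0.01, 10, 10.01, 9.99, 0, 0.01, -0.01))
  expect_lt(sep$p_adj["g1", "a vs b"], 0.01)
  expect_gt(sep$p_adj["g1", "a vs c"], 0.5)
  # zero variance everywhere: degenerate flag, p = 0 for differing means
  deg <- mk(rep(c(0, 5, 0), each = 3))
  expect_true(deg$degenerate["g1"])
  expect_identical(unname(deg$p_adj["g1", "a vs b"]), 0)
  expect_identical(unname(deg$p_adj["g1", "a vs c"]), 1)
})

test_that("label_groups uses strict inequality and signs directions", {
  pairs <- data.frame(first = c("si", "st", "st"), second = c("co", "co", "si"),
                      stringsAsFactors = FALSE)
  genes <- c("g1", "g2", "g3")
  p <- matrix(c(0.005, 0.01, 0.5), 3, 3,
              dimnames = list(genes, paste(pairs$first, pairs$second, sep = " vs ")))
  d <- matrix(c(-2, 1, 0.2), 3, 3, dimnames = dimnames(p))
  st <- structure(list(tissues = c("si", "st", "co"), pairs = pairs,
                       p_adj = p, mean_diff = d,
                       anova_p = stats::setNames(rep(0.001, 3), genes),
                       degenerate = stats::setNames(rep(FALSE, 3), genes)),
                  class = "TukeyResult")
  labs <- label_groups(st, alpha = 0.01)
  expect_named(labs, c("si vs co", "st vs co", "st vs si"))
  l <- labs[["si vs co"]]
  expect_true(l$significant[["g1"]])
  expect_identical(l$up_in[["g1"]], "co")     # negative diff -> up in second
  expect_false(l$significant[["g2"]])         # p == alpha is NOT significant
  expect_identical(l$up_in[["g2"]], "none")
  expect_false(l$significant[["g3"]])
})

test_that("count_upregulated unions genes across a tissue's comparisons", {
  uni <- c("g1", "g2", "g3")
  labs <- list(
    `si vs co` = make_labeling(uni, c("g1", "g2"), c("si", "co")),
    `st vs co` = make_labeling(uni, "g1", c("st", "co")),
    `st vs si` = make_labeling(uni, character(0), c("st", "si")))
  # redirect g1/g2 upward labels: make_labeling marks up in first tissue
  labs$`si vs co`$up_in[c("g1", "g2")] <- c("co", "co")
  labs$`st vs co`$up_in["g1"] <- "co"
  counts <- count_upregulated(labs)
  expect_identical(unname(counts["co"]), 2L)   # g1 counted once, g2 once
  expect_setequal(attr(counts, "genes")$co, c("g1", "g2"))
  expect_identical(unname(counts["si"]), 0L)
  # multiset variant double-counts g1
  expect_identical(unname(count_upregulated(labs, distinct = FALSE)["co"]), 3L)
})

test_that("dss_separation_filter requires both the 1.25 gap and full separation", {
  mk2 <- function(vals, n) {
    m <- matrix(vals, nrow = length(vals) / n, ncol = n, byrow = TRUE)
    rownames(m) <- paste0("g", seq_len(nrow(m)))
    colnames(m) <- paste0("s", seq_len(n))
    make_expr(m, rep("colon", n))
  }
  treated <- mk2(c(-5.0, -5.2, -5.1,   -3.0, -1.0, -2.0,  -2.0, -2.0, -2.0), 3)
  control <- mk2(c(-2.0, -2.3,          -2.0, -2.1,        -0.75, -0.75), 2)
  res <- dss_separation_filter(treated, control)
  expect_identical(res$gene, "g1")            # separated, |diff| = 3.0
  expect_identical(res$direction, "down-in-treated")
  expect_equal(res$mean_diff, -2.95)
  # g2 overlaps despite big mean diff; g3 gap exactly 1.25 -> excluded
  expect_false(any(c("g2", "g3") %in% res$gene))
})

test_that("dss filter membership is sign-symmetric", {
  set.seed(3)
  tv <- matrix(rnorm(30, sd = 2), 10, 3,
               dimnames = list(paste0("g", 1:10), paste0("t", 1:3)))
  cv <- matrix(rnorm(20, sd = 2), 10, 2,
               dimnames = list(paste0("g", 1:10), paste0("c", 1:2)))
  a <- dss_separation_filter(make_expr(tv, rep("colon", 3)),
                             make_expr(cv, rep("colon", 2)))
  b <- dss_separation_filter(make_expr(-tv, rep("colon", 3)),
                             make_expr(-cv, rep("colon", 2)))
  expect_setequal(a$gene, b$gene)
  if (nrow(a)) {
    expect_identical(sort(a$direction),
                     sort(ifelse(b$direction == "up-in-treated",
                                 "down-in-treated", "up-in-treated")))
  }
})

test_that("read_cq round-trips a TSV + sample sheet", {
  v <- matrix(c(20, 20, 24, 23), 2, 2, byrow = TRUE,
              dimnames = list(c("Hsp90", "g1"), c("s1", "s2")))
  cqp <- tempfile(fileext = ".tsv"); shp <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene_id = rownames(v), v, check.names = FALSE),
                     cqp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = c("s1", "s2"),
                                tissue = c("stomach", "colon")),
                     shp, sep = "\t", quote = FALSE, row.names = FALSE)
  cq <- read_cq(cqp, shp)
  expect_identical(unname(cq$sample_tissue["s2"]), "colon")
  expect_equal(cq$values["g1", "s2"], 23)
})
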