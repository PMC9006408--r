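#' Hypergeometric term enrichment against a significance labeling
#'
#' For every ontology term annotating at least one universe gene, builds the
#' 2x2 contingency table (a = significant & annotated, b = significant & not,
#' c = non-significant & annotated, d = non-significant & not) and computes
#' the one-sided hypergeometric tail probability of observing `a` or more
#' annotated genes among the significant set — the classical
#' over-representation enrichment score. Raw p-values are reported; a
#' Benjamini-Hochberg column is added for convenience but plays no role in
#' the default significance call.
#'
#' @param labeling a [comparison_labeling()] covering the gene universe.
#' @param annotations a true-path-closed [annotation_table()] over the same
#'   universe.
#' @param alpha raw-p threshold for the `enriched` flag (default 0.05).
#' @return Data frame, one row per term: `term`, `a`, `b`, `c`, `d`, `p`,
#'   `p_bh`, `enriched`, sorted by `p`.
#' @export
term_enrichment <- function(labeling, annotations, alpha = 0.05) {
  stopifnot(inherits(labeling, "ComparisonLabeling"),
            inherits(annotations, "AnnotationTable"))
  universe <- annotations$universe
  if (!all(universe %in% names(labeling$significant))) {
    stop("labeling does not cover the annotation universe")
  }
  sig <- names(labeling$significant)[labeling$significant]
  sig <- intersect(sig, universe)
  n_sig <- length(sig)
  n_uni <- length(universe)
  by_term <- split(annotations$pairs$gene, annotations$pairs$term)
  a <- vapply(by_term, function(g) length(intersect(g, sig)), 1L)
  ann <- lengths(by_term)
  # P(X >= a) with X ~ Hypergeometric(annotated, not annotated, drawn = n_sig)
  p <- stats::phyper(a - 1L, ann, n_uni - ann, n_sig, lower.tail = FALSE)
  out <- data.frame(term = names(by_term),
                    a = a, b = n_sig - a, c = ann - a,
                    d = (n_uni - n_sig) - (ann - a),
                    p = unname(p), stringsAsFactors = FALSE, row.names = NULL)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$p < alpha
  out[order(out$p, out$term), , drop = FALSE]
}

# round half-up to `digits` decimals (base round() is half-to-even)
round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Per-tissue coverage percentages of a term
#'
#' For each tissue class, the percentage of that class's upregulated genes
#' annotated (post-closure) to the term:
#' 100 * |upregulated(T) intersect annotated(term)| / |upregulated(T)|,
#' rounded half-up to two decimals. An empty upregulated set reports 0.00
#' and is flagged in the `"empty"` attribute.
#'
#' @param upregulated_sets named list, tissue -> character vector of
#'   upregulated gene ids (e.g. the `"genes"` attribute of
#'   [count_upregulated()]).
#' @param annotations a closed [annotation_table()].
#' @param term_id a single term id.
#' @return Named numeric vector of percentages per tissue, with attribute
#'   `"empty"` flagging tissues with no upregulated genes.
#' @export
coverage_percentages <- function(upregulated_sets, annotations, term_id) {
  stopifnot(inherits(annotations, "AnnotationTable"), length(term_id) == 1L)
  ann_genes <- annotations$pairs$gene[annotations$pairs$term == term_id]
  empty <- lengths(upregulated_sets) == 0L
  pct <- vapply(upregulated_sets, function(g) {
    if (length(g) == 0L) return(0)
    round_half_up(100 * length(intersect(g, ann_genes)) / length(g), 2L)
  }, 1.0)
  attr(pct, "empty") <- empty
  pct
}

#' Table of enriched terms with per-tissue coverage
#'
#' Joins [term_enrichment()] with [coverage_percentages()] and the member
#' genes per tissue class, mirroring a term-by-tissue coverage report.
#'
#' @inheritParams term_enrichment
#' @param upregulated_sets named list, tissue -> upregulated gene ids.
#' @param graph optional [ontology_graph()] used to add term names.
#' @return Data frame with enrichment columns plus `pct_<tissue>` and
#'   `genes_<tissue>` columns.
#' @export
enrichment_report <- function(labeling, annotations, upregulated_sets,
                              graph = NULL, alpha = 0.05) {
  enr <- term_enrichment(labeling, annotations, alpha = alpha)
  if (!is.null(graph)) {
    enr$name <- unname(graph$name[enr$term])
  }
  for (t in names(upregulated_sets)) {
    enr[[paste0("pct_", gsub("\\s+", "_", t))]] <- NA_real_
    enr[[paste0("genes_", gsub("\\s+", "_", t))]] <- NA_character_
  }
  by_term <- split(annotations$pairs$gene, annotations$pairs$term)
  for (i in seq_len(nrow(enr))) {
    pct <- coverage_percentages(upregulated_sets, annotations, enr$term[i])
    ann <- by_term[[enr$term[i]]]
    for (t in names(upregulated_sets)) {
      tt <- gsub("\\s+", "_", t)
      enr[[paste0("pct_", tt)]][i] <- pct[[t]]
      enr[[paste0("genes_", tt)]][i] <-
        paste(sort(intersect(upregulated_sets[[t]], ann)), collapse = ",")
    }
  }
  enr
}

#' Fisher exact test for categorical contingency tables
#'
#' Two-sided Fisher exact test for r x c count tables, e.g. distributions of
#' ontology classes across tissues. 2x2 tables and small r x c tables
#' (total count <= 30) are tested exactly; larger r x c tables fall back to
#' a seeded Monte-Carlo p-value.
#'
#' @param contingency non-negative integer matrix, at least 2x2. Rows or
#'   columns whose margin is zero are dropped with a warning.
#' @param seed integer seed for the Monte-Carlo branch.
#' @param B number of Monte-Carlo draws (default 1e5).
#' @return The two-sided p-value.
#' @export
category_fisher <- function(contingency, seed = 1L, B = 1e5) {
  m <- as.matrix(contingency)
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need at least a 2x2 table")
  zr <- rowSums(m) == 0; zc <- colSums(m) == 0
  if (any(zr) || any(zc)) {
    warning(sprintf("dropped %d zero-margin row(s) and %d column(s)",
                    sum(zr), sum(zc)))
    m <- m[!zr, !zc, drop = FALSE]
    if (nrow(m) < 2L || ncol(m) < 2L) stop("table degenerate after dropping zero margins")
  }
  if (nrow(m) == 2L && ncol(m) == 2L) {
    return(stats::fisher.test(m)$p.value)
  }
  if (sum(m) <= 30) {
    return(stats::fisher.test(m, workspace = 2e7)$p.value)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stats::fisher.test(m, simulate.p.value = TRUE, B = as.integer(B))$p.value
}
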