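#' Construct a gene-to-term annotation table
#'
#' Holds (gene, term) incidence pairs over a fixed gene universe (every gene
#' measured on the array, annotated or not). Rules and enrichment always
#' query the true-path-closed table: a gene annotated to a term is implicitly
#' annotated to all the term's ancestors.
#'
#' @param pairs data frame with character columns `gene` and `term`.
#' @param universe character vector of all measured gene identifiers.
#' @param closed logical; whether `pairs` is already closed under the
#'   true-path rule.
#' @return An object of class `AnnotationTable`.
#' @export
annotation_table <- function(pairs, universe, closed = FALSE) {
  stopifnot(is.data.frame(pairs), all(c("gene", "term") %in% names(pairs)))
  pairs <- unique(data.frame(gene = as.character(pairs$gene),
                             term = as.character(pairs$term),
                             stringsAsFactors = FALSE))
  universe <- unique(as.character(universe))
  bad <- setdiff(pairs$gene, universe)
  if (length(bad)) stop("annotated gene(s) outside universe: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  structure(list(pairs = pairs, universe = universe, closed = closed),
            class = "AnnotationTable")
}

#' @export
print.AnnotationTable <- function(x, ...) {
  cat(sprintf("AnnotationTable: %d pairs, %d annotated / %d universe genes, %d terms, %s\n",
              nrow(x$pairs), length(unique(x$pairs$gene)), length(x$universe),
              length(unique(x$pairs$term)),
              if (x$closed) "true-path closed" else "not closed"))
  invisible(x)
}

#' Load gene-to-term annotations from a two-column table
#'
#' Reads tabular text with columns `gene_id`, `term_id` (header optional,
#' detected by a non-resolving first row whose second field is not a graph
#' term). Rows with terms absent from `graph` are dropped with a warning
#' count; genes outside `universe` are dropped silently. The result is
#' true-path closed against `graph`.
#'
#' @param path path to a TSV/whitespace-delimited two-column file.
#' @param graph an [ontology_graph()].
#' @param universe character vector of measured gene ids.
#' @param close logical; propagate the true-path rule after loading
#'   (default `TRUE`).
#' @return An [annotation_table()].
#' @export
load_annotations <- function(path, graph, universe, close = TRUE) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           comment.char = "#", blank.lines.skip = TRUE)
  if (nrow(raw) == 0L) stop("annotation file is empty: ", path)
  if (ncol(raw) < 2L) stop("annotation file must have two columns (gene, term)")
  raw <- raw[, 1:2]
  names(raw) <- c("gene", "term")
  # header row: second field resolves to no term and looks like a label
  if (!raw$term[1] %in% graph$ids &&
      grepl("term", raw$term[1], ignore.case = TRUE)) {
    raw <- raw[-1, , drop = FALSE]
    if (nrow(raw) == 0L) stop("annotation file has a header but no rows: ", path)
  }
  known <- raw$term %in% graph$ids
  n_unknown <- sum(!known)
  if (n_unknown == nrow(raw)) {
    stop("no annotation term resolves in the ontology; wrong ontology file?")
  }
  if (n_unknown > nrow(raw) / 2) {
    stop(sprintf("%d of %d annotation terms unknown (>50%%); wrong ontology file?",
                 n_unknown, nrow(raw)))
  }
  if (n_unknown > 0L) {
    warning(sprintf("dropped %d annotation row(s) with unknown terms", n_unknown))
  }
  raw <- raw[known & raw$gene %in% universe, , drop = FALSE]
  tab <- annotation_table(raw, universe)
  if (close) propagate_true_path(tab, graph) else tab
}

#' Read gene annotations from a GAF 2.x file
#'
#' Convenience reader restricted to column 3 (gene symbol) and column 5
#' (ontology term id); all other GAF columns, including evidence codes, are
#' ignored.
#'
#' @inheritParams load_annotations
#' @return An [annotation_table()].
#' @export
load_gaf <- function(path, graph, universe, close = TRUE) {
  if (!file.exists(path)) stop("GAF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) stop("GAF file has no annotation rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 5L
  if (any(short)) stop("GAF rows with fewer than 5 columns: ", sum(short))
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(
    data.frame(gene = vapply(fields, `[[`, "", 3L),
               term = vapply(fields, `[[`, "", 5L)),
    tmp, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  load_annotations(tmp, graph, universe, close = close)
}

#' Close an annotation table under the true-path rule
#'
#' Every (gene, term) pair is expanded to (gene, ancestor) for all ancestors
#' of the term. Idempotent; never removes pairs.
#'
#' @param table an [annotation_table()].
#' @param graph the [ontology_graph()] the terms live in.
#' @return A closed `AnnotationTable`.
#' @export
propagate_true_path <- function(table, graph) {
  stopifnot(inherits(table, "AnnotationTable"))
  bad <- setdiff(table$pairs$term, graph$ids)
  if (length(bad)) stop("unknown term id: ", bad[1])
  anc <- ancestors_all(graph)
  expanded <- anc[table$pairs$term]
  n <- lengths(expanded)
  out <- data.frame(gene = rep(table$pairs$gene, n),
                    term = unlist(expanded, use.names = FALSE),
                    stringsAsFactors = FALSE)
  annotation_table(out, table$universe, closed = TRUE)
}

#' Genes annotated to every term of a conjunction
#'
#' The coverage primitive behind conjunctive rules: a gene satisfies a rule
#' iff it is annotated (post-closure) to every term in it.
#'
#' @param table an [annotation_table()].
#' @param term_ids non-empty character vector of term ids.
#' @return Character vector of gene ids carrying all the terms.
#' @export
genes_with_all_terms <- function(table, term_ids) {
  stopifnot(inherits(table, "AnnotationTable"))
  term_ids <- unique(as.character(term_ids))
  if (length(term_ids) == 0L) stop("term_ids must be non-empty")
  per_term <- lapply(term_ids, function(t) table$pairs$gene[table$pairs$term == t])
  sort(Reduce(intersect, per_term))
}

# Dense logical incidence matrix (universe x annotated terms) for fast
# repeated coverage queries during rule search.
annotation_matrix <- function(table) {
  terms <- sort(unique(table$pairs$term))
  m <- matrix(FALSE, nrow = length(table$universe), ncol = length(terms),
              dimnames = list(table$universe, terms))
  m[cbind(table$pairs$gene, table$pairs$term)] <- TRUE
  m
}
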