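#' Construct an ontology graph
#'
#' An `OntologyGraph` is a directed acyclic graph of ontology terms linked by
#' parent edges (`is_a`, and optionally `part_of`). Terms with no parents are
#' roots; a merged multi-namespace graph may have several roots, each at
#' level 0.
#'
#' @param ids character vector of unique term identifiers (e.g. `"GO:0044267"`).
#' @param names character vector of human-readable labels, parallel to `ids`.
#' @param parents named list mapping each term id to a character vector of
#'   parent term ids (possibly empty).
#' @param namespaces character vector of source-ontology tags, parallel to
#'   `ids` (recycled if length 1).
#' @return An object of class `OntologyGraph` with components `ids`, `name`,
#'   `namespace`, `parents`, `children`, `roots` and precomputed `level`.
#' @export
ontology_graph <- function(ids, names = ids, parents = NULL,
                           namespaces = "default") {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate term ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (is.null(parents)) parents <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  parents <- parents[ids]
  names(parents) <- ids
  parents <- lapply(parents, function(p) unique(as.character(p)))
  unknown <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(unknown)) {
    stop("parent ids not present in graph: ", paste(unknown, collapse = ", "))
  }
  if (length(namespaces) == 1L) namespaces <- rep(namespaces, length(ids))
  g <- structure(
    list(
      ids = ids,
      name = stats::setNames(as.character(names), ids),
      namespace = stats::setNames(as.character(namespaces), ids),
      parents = parents,
      children = invert_edges(parents, ids),
      roots = ids[vapply(parents, length, 1L) == 0L]
    ),
    class = "OntologyGraph"
  )
  if (length(g$roots) == 0L && length(ids) > 0L) {
    stop("ontology has no root term; parent edges contain a cycle")
  }
  g$level <- compute_levels(g)
  if (anyNA(g$level)) {
    stop("cyclic parent closure involving term(s): ",
         paste(ids[is.na(g$level)], collapse = ", "))
  }
  g
}

invert_edges <- function(parents, ids) {
  children <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (t in ids) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  children
}

# Level = length of the SHORTEST parent-edge path to any root (roots are 0).
# Computed by breadth-first relaxation from the roots; terms never reached
# (only possible inside a cycle) come back NA, which the constructor rejects.
compute_levels <- function(g) {
  lev <- stats::setNames(rep(NA_integer_, length(g$ids)), g$ids)
  frontier <- g$roots
  lev[frontier] <- 0L
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(g$children[frontier], use.names = FALSE))
    nxt <- nxt[is.na(lev[nxt])]
    lev[nxt] <- d
    frontier <- nxt
  }
  lev
}

#' @export
print.OntologyGraph <- function(x, ...) {
  cat(sprintf("OntologyGraph: %d terms, %d root(s), max level %d, namespaces: %s\n",
              length(x$ids), length(x$roots),
              if (length(x$ids)) max(x$level) else 0L,
              paste(unique(x$namespace), collapse = ", ")))
  invisible(x)
}

#' Parse an OBO flat file into an ontology graph
#'
#' Reads `[Term]` stanzas with `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of` and `is_obsolete` tags. Obsolete terms are
#' excluded; `is_a` and (by default) `part_of` both become parent edges,
#' following true-path practice. Parent references to terms outside the file
#' are dropped (cross-ontology links are out of scope).
#'
#' @param path path to an OBO-format text file.
#' @param use_part_of logical; treat `relationship: part_of` as a parent edge
#'   (default `TRUE`).
#' @param namespace default namespace tag for terms without an explicit
#'   `namespace:` line; defaults to the file name.
#' @return An [ontology_graph()].
#' @export
load_obo <- function(path, use_part_of = TRUE,
                     namespace = basename(path)) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s*!.*$", "", lines)   # trailing comments
  lines <- trimws(lines)

  stanza_starts <- which(lines == "[Term]")
  if (!length(stanza_starts)) stop("no [Term] stanzas found in ", path)
  other_headers <- grepl("^\\[.*\\]$", lines)
  bounds <- c(stanza_starts, length(lines) + 1L)

  ids <- character(0); nms <- character(0); nss <- character(0)
  parents <- list()
  for (k in seq_along(stanza_starts)) {
    i0 <- stanza_starts[k] + 1L
    i1 <- min(c(which(other_headers & seq_along(lines) > stanza_starts[k]),
                length(lines) + 1L)) - 1L
    body <- lines[seq.int(i0, i1)]
    body <- body[nzchar(body)]
    tags <- sub(":.*$", "", body)
    vals <- trimws(sub("^[^:]*:", "", body))
    id <- vals[tags == "id"]
    if (length(id) != 1L || !nzchar(id)) {
      stop(sprintf("malformed [Term] stanza #%d (line %d): expected exactly one id",
                   k, stanza_starts[k]))
    }
    if (any(tags == "is_obsolete" & vals == "true")) next
    nm <- vals[tags == "name"]
    ns <- vals[tags == "namespace"]
    par <- vals[tags == "is_a"]
    if (use_part_of) {
      rel <- vals[tags == "relationship"]
      par <- c(par, sub("^part_of\\s+", "", rel[grepl("^part_of\\s", rel)]))
    }
    ids <- c(ids, id)
    nms <- c(nms, if (length(nm)) nm[1] else id)
    nss <- c(nss, if (length(ns)) ns[1] else namespace)
    parents[[id]] <- unique(par)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate term id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  # drop dangling parent references (obsolete or external terms)
  parents <- lapply(parents, function(p) intersect(p, ids))
  ontology_graph(ids, nms, parents, nss)
}

#' Merge ontology graphs from different namespaces
#'
#' Merging is disjoint on term id; a shared id is an error. No super-root is
#' added: each source ontology keeps its own roots, all at level 0, so the
#' minimum-level constraint applies per source ontology.
#'
#' @param ... two or more `OntologyGraph` objects.
#' @return A single merged `OntologyGraph`.
#' @export
merge_ontologies <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && is.list(gs[[1]]) && !inherits(gs[[1]], "OntologyGraph")) {
    gs <- gs[[1]]
  }
  stopifnot(all(vapply(gs, inherits, TRUE, "OntologyGraph")))
  ids <- unlist(lapply(gs, `[[`, "ids"), use.names = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("cannot merge: duplicate term id(s) across ontologies: ",
         paste(dup, collapse = ", "))
  }
  ontology_graph(
    ids,
    unlist(lapply(gs, `[[`, "name"), use.names = FALSE),
    do.call(c, lapply(gs, `[[`, "parents")),
    unlist(lapply(gs, `[[`, "namespace"), use.names = FALSE)
  )
}

check_term <- function(graph, term_id) {
  if (!term_id %in% graph$ids) stop("unknown term id: ", term_id)
  invisible(term_id)
}

#' Ancestors of a term (reflexive-transitive closure)
#'
#' @param graph an `OntologyGraph`.
#' @param term_id a term identifier present in `graph`.
#' @return Character vector of term ids: the term itself plus every term
#'   reachable through parent edges.
#' @export
ancestors <- function(graph, term_id) {
  check_term(graph, term_id)
  seen <- character(0)
  stack <- term_id
  while (length(stack)) {
    t <- stack[[1]]; stack <- stack[-1]
    if (t %in% seen) next
    seen <- c(seen, t)
    stack <- c(stack, setdiff(graph$parents[[t]], seen))
  }
  seen
}

#' Ancestor sets for every term at once
#'
#' Computed in one topological sweep; used by true-path closure.
#'
#' @param graph an `OntologyGraph`.
#' @return Named list mapping each term id to its reflexive ancestor set.
#' @export
ancestors_all <- function(graph) {
  ord <- graph$ids[order(graph$level)]
  anc <- stats::setNames(vector("list", length(ord)), ord)
  for (t in ord) {
    anc[[t]] <- unique(c(t, unlist(anc[graph$parents[[t]]], use.names = FALSE)))
  }
  anc[graph$ids]
}

#' Specificity level of a term
#'
#' The level is the length of the shortest parent-edge path from the term to
#' any root; roots have level 0. This is the quantity constrained by the
#' minimum-level parameter of rule induction.
#'
#' @inheritParams ancestors
#' @return Non-negative integer.
#' @export
term_level <- function(graph, term_id) {
  check_term(graph, term_id)
  unname(graph$level[term_id])
}

#' One-line summary statistics of an ontology
#'
#' @param graph an `OntologyGraph`.
#' @return Invisibly, a list with `n_terms`, `n_roots`, `max_depth`.
#' @export
ontology_stats <- function(graph) {
  out <- list(n_terms = length(graph$ids), n_roots = length(graph$roots),
              max_depth = if (length(graph$ids)) max(graph$level) else 0L)
  cat(sprintf("terms: %d\nroots: %d\nmax depth: %d\n",
              out$n_terms, out$n_roots, out$max_depth))
  invisible(out)
}
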