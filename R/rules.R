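#' Construct a conjunctive ontology-term rule
#'
#' A rule is a conjunction T1 AND ... AND Tk of ontology terms; a gene
#' satisfies it iff annotated (post true-path closure) to every term.
#' Within a rule no term may be an ancestor of another — after closure such
#' a conjunct would be redundant.
#'
#' @param term_ids non-empty character vector of term ids; stored sorted.
#' @param graph optional [ontology_graph()]; when given, ancestor-redundancy
#'   and `min_level` are validated.
#' @param min_level minimum specificity level every term must meet.
#' @return An object of class `Rule`.
#' @export
rule <- function(term_ids, graph = NULL, min_level = 0L) {
  term_ids <- sort(unique(as.character(term_ids)))
  if (length(term_ids) == 0L) stop("a rule needs at least one term")
  r <- structure(list(term_ids = term_ids), class = "Rule")
  if (!is.null(graph)) validate_rule(r, graph, min_level)
  r
}

#' @export
print.Rule <- function(x, ...) {
  cat("Rule:", paste(x$term_ids, collapse = " AND "), "\n")
  invisible(x)
}

#' Validate a rule against a graph and a minimum level
#'
#' @param r a [rule()].
#' @inheritParams rule
#' @return Invisibly `r`; errors on violation.
#' @export
validate_rule <- function(r, graph, min_level = 0L) {
  for (t in r$term_ids) check_term(graph, t)
  lev <- graph$level[r$term_ids]
  if (any(lev < min_level)) {
    stop("term(s) below min_level ", min_level, ": ",
         paste(r$term_ids[lev < min_level], collapse = ", "))
  }
  if (length(r$term_ids) > 1L) {
    for (t in r$term_ids) {
      anc <- setdiff(ancestors(graph, t), t)
      bad <- intersect(anc, r$term_ids)
      if (length(bad)) {
        stop("redundant conjunction: ", bad[1], " is an ancestor of ", t)
      }
    }
  }
  invisible(r)
}

#' Search configuration for rule induction
#'
#' @param eval_fn evaluation function: `"ACC"` (accuracy), `"AUC"` (balanced
#'   accuracy of the Boolean predictor) or `"F1"`.
#' @param min_level minimum ontology level for any term in a rule.
#' @param max_rules maximum number of rules returned (default 10).
#' @param max_conjuncts maximum rule length (default 3).
#' @param beam_width beam size of the search (default 20; must be >=
#'   `max_rules`).
#' @param seed integer seed, used only when `candidate_cap` subsamples
#'   candidate terms.
#' @param candidate_cap optional cap on the number of candidate terms
#'   (`Inf` = use all).
#' @return An object of class `SearchConfig`.
#' @export
search_config <- function(eval_fn = c("F1", "ACC", "AUC"), min_level = 0L,
                          max_rules = 10L, max_conjuncts = 3L,
                          beam_width = 20L, seed = 1L, candidate_cap = Inf) {
  eval_fn <- match.arg(toupper(eval_fn[1]), c("F1", "ACC", "AUC"))
  stopifnot(max_rules >= 1L, beam_width >= max_rules, max_conjuncts >= 1L,
            min_level >= 0L)
  structure(list(eval_fn = eval_fn, min_level = as.integer(min_level),
                 max_rules = as.integer(max_rules),
                 max_conjuncts = as.integer(max_conjuncts),
                 beam_width = as.integer(beam_width),
                 seed = as.integer(seed), candidate_cap = candidate_cap),
            class = "SearchConfig")
}

# confusion counts and scores from a logical coverage vector
score_coverage <- function(covered, significant) {
  tp <- sum(covered & significant)
  fp <- sum(covered & !significant)
  fn <- sum(!covered & significant)
  tn <- sum(!covered & !significant)
  n <- tp + fp + fn + tn
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       acc = (tp + tn) / n,
       auc = (sens + spec) / 2,
       f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0)
}

#' Score a rule against a significance labeling
#'
#' Covered genes are those annotated to every term of the rule. Significant
#' genes are the positive class. ACC = (tp+tn)/n; F1 = 2tp/(2tp+fp+fn);
#' AUC = (sensitivity + specificity)/2, the balanced accuracy — the AUC of
#' a single Boolean predictor.
#'
#' @param r a [rule()].
#' @param labeling a [comparison_labeling()] covering the universe.
#' @param annotations a closed [annotation_table()].
#' @param graph optional graph for contract validation.
#' @param min_level level constraint checked when `graph` is given.
#' @return An object of class `RuleScore`: `covered` (gene ids), `tp`, `fp`,
#'   `tn`, `fn`, `acc`, `auc`, `f1`.
#' @export
evaluate_rule <- function(r, labeling, annotations, graph = NULL,
                          min_level = 0L) {
  stopifnot(inherits(r, "Rule"), inherits(labeling, "ComparisonLabeling"),
            inherits(annotations, "AnnotationTable"))
  if (!is.null(graph)) validate_rule(r, graph, min_level)
  universe <- annotations$universe
  covered_genes <- intersect(genes_with_all_terms(annotations, r$term_ids),
                             universe)
  covered <- universe %in% covered_genes
  sig <- labeling$significant[universe]
  if (anyNA(sig)) stop("labeling does not cover the universe")
  sc <- score_coverage(covered, unname(sig))
  structure(c(list(covered = sort(covered_genes)), sc), class = "RuleScore")
}

#' @export
print.RuleScore <- function(x, ...) {
  cat(sprintf("RuleScore: %d covered | tp=%d fp=%d tn=%d fn=%d | acc=%.3f auc=%.3f f1=%.3f\n",
              length(x$covered), x$tp, x$fp, x$tn, x$fn, x$acc, x$auc, x$f1))
  invisible(x)
}

#' Terms meeting the minimum specificity level
#'
#' @param term_ids candidate term ids.
#' @param graph an [ontology_graph()].
#' @param min_level minimum level (shortest path to a root).
#' @return The subset of `term_ids` with level >= `min_level`.
#' @export
enforce_min_level <- function(term_ids, graph, min_level) {
  term_ids <- intersect(term_ids, graph$ids)
  term_ids[graph$level[term_ids] >= min_level]
}

# is `anc` an ancestor (proper or reflexive) of `t`, using a precomputed
# ancestor list?
related_terms <- function(anc_list, a, b) {
  a %in% anc_list[[b]] || b %in% anc_list[[a]]
}

#' Refinements of a rule
#'
#' Top-down refinement operator: (a) extend the conjunction by one new term
#' that is neither an ancestor nor a descendant of an existing conjunct, and
#' (b) specialise one conjunct by replacing it with one of its children.
#' All outputs satisfy `min_level` and the non-redundancy invariant.
#'
#' @param r a [rule()].
#' @param graph an [ontology_graph()].
#' @param candidate_terms eligible term ids (already level-filtered).
#' @param max_conjuncts rule-length cap for extension refinements.
#' @param anc_list optional precomputed [ancestors_all()] list.
#' @return List of `Rule` objects (possibly empty).
#' @export
refine <- function(r, graph, candidate_terms, max_conjuncts = 3L,
                   anc_list = NULL) {
  if (is.null(anc_list)) anc_list <- ancestors_all(graph)
  out <- list()
  ok_with <- function(terms, new) {
    all(vapply(terms, function(t) !related_terms(anc_list, t, new), TRUE))
  }
  if (length(r$term_ids) < max_conjuncts) {
    for (t in setdiff(candidate_terms, r$term_ids)) {
      if (ok_with(r$term_ids, t)) out[[length(out) + 1L]] <- rule(c(r$term_ids, t))
    }
  }
  for (old in r$term_ids) {
    rest <- setdiff(r$term_ids, old)
    for (ch in intersect(graph$children[[old]], candidate_terms)) {
      if (ch %in% rest) next
      if (length(rest) == 0L || all(vapply(rest, function(t) !related_terms(anc_list, t, ch), TRUE))) {
        out[[length(out) + 1L]] <- rule(c(rest, ch))
      }
    }
  }
  keys <- vapply(out, function(x) paste(x$term_ids, collapse = "|"), "")
  out[!duplicated(keys)]
}

rule_key <- function(term_ids) paste(sort(term_ids), collapse = "|")

#' Induce discriminative conjunctive rules by beam search
#'
#' Seeds the beam with every eligible single-term rule, then repeatedly
#' applies [refine()] keeping the `beam_width` best rules by the configured
#' evaluation function (ties: fewer conjuncts first, then lexicographically
#' smallest term ids). The search stops when refinement no longer changes
#' the beam or rules reach `max_conjuncts`. All rules ever scored are kept
#' in an archive; the return value is the archive's top `max_rules` rules
#' after collapsing rules with identical covered-gene sets to the shortest
#' (then lexicographically smallest) representative, so the result can never
#' be worse than the best seed.
#'
#' @param labeling a [comparison_labeling()].
#' @param annotations a closed [annotation_table()].
#' @param graph an [ontology_graph()].
#' @param config a [search_config()].
#' @return List of entries `list(rule =, score =)` sorted by the evaluation
#'   function, length <= `max_rules`; empty (with a warning) when no term is
#'   eligible.
#' @export
induce_rules <- function(labeling, annotations, graph, config = search_config()) {
  stopifnot(inherits(config, "SearchConfig"))
  universe <- annotations$universe
  if (length(universe) == 0L) stop("empty gene universe")
  sig <- labeling$significant[universe]
  if (anyNA(sig)) stop("labeling does not cover the universe")
  sig <- unname(sig)
  if (!any(sig) || all(sig)) stop("need at least one significant and one non-significant gene")

  M <- annotation_matrix(annotations)
  candidates <- enforce_min_level(colnames(M), graph, config$min_level)
  candidates <- candidates[colSums(M[, candidates, drop = FALSE]) > 0L]
  if (length(candidates) == 0L) {
    warning("no eligible term at min_level ", config$min_level)
    return(list())
  }
  if (is.finite(config$candidate_cap) && length(candidates) > config$candidate_cap) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(config$seed)
    candidates <- sort(sample(candidates, config$candidate_cap))
  }
  anc_list <- ancestors_all(graph)
  eval_col <- tolower(config$eval_fn)

  archive <- new.env(parent = emptyenv())
  score_rule <- function(terms) {
    key <- rule_key(terms)
    if (!is.null(archive[[key]])) return(archive[[key]])
    cov <- if (length(terms) == 1L) M[, terms] else rowSums(M[, terms, drop = FALSE]) == length(terms)
    sc <- score_coverage(cov, sig)
    entry <- list(terms = sort(terms), key = key, score = sc[[eval_col]],
                  sc = sc, covered = rownames(M)[cov])
    archive[[key]] <- entry
    entry
  }
  order_entries <- function(entries) {
    if (!length(entries)) return(entries)
    s <- vapply(entries, `[[`, 1.0, "score")
    len <- vapply(entries, function(e) length(e$terms), 1L)
    key <- vapply(entries, `[[`, "", "key")
    entries[order(-s, len, key, method = "radix")]
  }

  beam <- order_entries(lapply(candidates, score_rule))
  beam <- utils::head(beam, config$beam_width)
  repeat {
    new_entries <- list()
    for (e in beam) {
      refs <- refine(rule(e$terms), graph, candidates,
                     max_conjuncts = config$max_conjuncts, anc_list = anc_list)
      for (r in refs) {
        if (is.null(archive[[rule_key(r$term_ids)]])) {
          new_entries[[length(new_entries) + 1L]] <- score_rule(r$term_ids)
        }
      }
    }
    if (!length(new_entries)) break
    merged <- order_entries(c(beam, new_entries))
    merged <- utils::head(merged, config$beam_width)
    if (identical(vapply(merged, `[[`, "", "key"),
                  vapply(beam, `[[`, "", "key"))) break
    beam <- merged
  }

  all_entries <- order_entries(as.list(archive))
  # collapse identical coverage to shortest / lexicographically smallest rule
  cov_key <- vapply(all_entries, function(e) paste(e$covered, collapse = "|"), "")
  all_entries <- all_entries[!duplicated(cov_key)]
  top <- utils::head(all_entries, config$max_rules)
  lapply(top, function(e) {
    list(rule = rule(e$terms),
         score = structure(c(list(covered = e$covered), e$sc), class = "RuleScore"))
  })
}
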