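#' Run rule induction over a grid of settings
#'
#' Runs [induce_rules()] for every combination of comparison group,
#' evaluation function and minimum ontology level, then pools the rules.
#' The default grid (3 groups x 3 evaluation functions x 6 levels = 54 runs)
#' mirrors the protocol of scanning minLevel over 0, 2, 3, 4, 5, 6 with all
#' supported evaluation functions. Entries are deduplicated on
#' (comparison, covered-gene set); every contributing run is kept as a
#' provenance record. A failing run is logged and skipped.
#'
#' @param labelings named list of [comparison_labeling()] objects.
#' @param annotations a closed [annotation_table()].
#' @param graph an [ontology_graph()].
#' @param eval_fns character vector of evaluation functions.
#' @param min_levels integer vector of minimum levels.
#' @param max_rules,max_conjuncts,beam_width,seed passed to [search_config()].
#' @param quiet suppress per-run progress messages.
#' @return An object of class `RulePool`: list with `entries`, each
#'   `list(comparison, rule, score, provenance)` where provenance is a list
#'   of the configs that produced the rule.
#' @export
run_grid <- function(labelings, annotations, graph,
                     eval_fns = c("ACC", "AUC", "F1"),
                     min_levels = c(0L, 2L, 3L, 4L, 5L, 6L),
                     max_rules = 10L, max_conjuncts = 3L, beam_width = 20L,
                     seed = 1L, quiet = TRUE) {
  entries <- list()
  index <- character(0)   # comparison || coverage key
  n_runs <- 0L; n_failed <- 0L
  for (cmp in names(labelings)) {
    for (fn in eval_fns) {
      for (lev in min_levels) {
        n_runs <- n_runs + 1L
        cfg <- search_config(eval_fn = fn, min_level = lev,
                             max_rules = max_rules,
                             max_conjuncts = max_conjuncts,
                             beam_width = beam_width, seed = seed)
        res <- tryCatch(
          withCallingHandlers(
            induce_rules(labelings[[cmp]], annotations, graph, cfg),
            warning = function(w) {
              if (!quiet) message("run ", n_runs, ": ", conditionMessage(w))
              invokeRestart("muffleWarning")
            }),
          error = function(e) {
            n_failed <<- n_failed + 1L
            message(sprintf("grid run failed (%s, %s, minLevel=%d): %s",
                            cmp, fn, lev, conditionMessage(e)))
            NULL
          })
        if (is.null(res)) next
        for (entry in res) {
          key <- paste(cmp, paste(entry$score$covered, collapse = "|"), sep = "||")
          prov <- list(eval_fn = fn, min_level = lev, comparison = cmp)
          hit <- match(key, index)
          if (is.na(hit)) {
            index <- c(index, key)
            entries[[length(entries) + 1L]] <-
              list(comparison = cmp, rule = entry$rule, score = entry$score,
                   provenance = list(prov))
          } else {
            entries[[hit]]$provenance <-
              c(entries[[hit]]$provenance, list(prov))
          }
        }
      }
    }
  }
  structure(list(entries = entries, n_runs = n_runs, n_failed = n_failed),
            class = "RulePool")
}

#' @export
print.RulePool <- function(x, ...) {
  cat(sprintf("RulePool: %d entries from %d run(s) (%d failed)\n",
              length(x$entries), x$n_runs, x$n_failed))
  invisible(x)
}

# Welch two-sample t statistic; NA when either side has < 2 values or both
# variances are zero.
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  vx <- stats::var(x); vy <- stats::var(y)
  denom <- sqrt(vx / length(x) + vy / length(y))
  if (denom == 0) return(NA_real_)
  (mean(x) - mean(y)) / denom
}

#' Filter and rank pooled rules by t-score and significant-gene surplus
#'
#' Each pooled rule is kept iff its surplus of significant over
#' non-significant covered genes, difference = tp - fp (or |tp - fp| with
#' `difference = "absolute"`), is at least `min_difference`. Retained rules
#' are sorted descending by t-score — the Welch two-sample t statistic
#' comparing the per-gene mean expression contrast of the rule's comparison
#' (mean over the first tissue minus mean over the second) between covered
#' and uncovered genes; by default its absolute value, so coherent down- and
#' up-regulated clusters rank alike — then descending by the difference.
#' The sort is stable: full ties keep pool order.
#'
#' @param pool a [run_grid()] `RulePool`.
#' @param expr the `ExpressionTable` the labelings were derived from
#'   (needed for the t-score); `NULL` ranks by difference only.
#' @param min_difference minimum tp - fp surplus (default 3).
#' @param difference `"signed"` (default) or `"absolute"`.
#' @param t_score `"absolute"` (default) or `"signed"`.
#' @return A `RulePool` whose entries carry `t_score` and `difference`,
#'   filtered and sorted; empty with a warning if nothing survives.
#' @export
select_rules <- function(pool, expr = NULL, min_difference = 3L,
                         difference = c("signed", "absolute"),
                         t_score = c("absolute", "signed")) {
  stopifnot(inherits(pool, "RulePool"))
  difference <- match.arg(difference)
  t_score <- match.arg(t_score)
  entries <- pool$entries

  contrasts <- list()
  if (!is.null(expr)) {
    for (cmp in unique(vapply(entries, `[[`, "", "comparison"))) {
      pair <- strsplit(cmp, " vs ", fixed = TRUE)[[1]]
      if (length(pair) == 2L && all(pair %in% expr$sample_tissue)) {
        m1 <- rowMeans(expr$values[, expr$sample_tissue == pair[1], drop = FALSE])
        m2 <- rowMeans(expr$values[, expr$sample_tissue == pair[2], drop = FALSE])
        contrasts[[cmp]] <- m1 - m2
      }
    }
  }

  for (i in seq_along(entries)) {
    e <- entries[[i]]
    d <- e$score$tp - e$score$fp
    entries[[i]]$difference <- if (difference == "absolute") abs(d) else d
    ct <- contrasts[[e$comparison]]
    entries[[i]]$t_score <- if (is.null(ct)) NA_real_ else {
      tv <- welch_t(ct[names(ct) %in% e$score$covered],
                    ct[!names(ct) %in% e$score$covered])
      if (t_score == "absolute") abs(tv) else tv
    }
  }

  keep <- vapply(entries, function(e) e$difference >= min_difference, TRUE)
  entries <- entries[keep]
  if (!length(entries)) {
    warning("no rule meets min_difference = ", min_difference)
    return(structure(list(entries = list(), n_runs = pool$n_runs,
                          n_failed = pool$n_failed), class = "RulePool"))
  }
  ts <- vapply(entries, function(e) if (is.na(e$t_score)) -Inf else e$t_score, 1.0)
  diffs <- vapply(entries, `[[`, 1L, "difference")
  entries <- entries[order(-ts, -diffs, method = "radix")]  # radix sort is stable
  structure(list(entries = entries, n_runs = pool$n_runs,
                 n_failed = pool$n_failed), class = "RulePool")
}

#' Flatten a rule pool to a data frame
#'
#' @param pool a `RulePool`.
#' @param graph optional graph to add term names.
#' @return Data frame: one row per entry with comparison, terms, scores,
#'   selection columns (when present), covered genes and provenance count.
#' @export
pool_as_data_frame <- function(pool, graph = NULL) {
  stopifnot(inherits(pool, "RulePool"))
  if (!length(pool$entries)) {
    return(data.frame(comparison = character(0), terms = character(0)))
  }
  rows <- lapply(pool$entries, function(e) {
    data.frame(
      comparison = e$comparison,
      terms = paste(e$rule$term_ids, collapse = " AND "),
      term_names = if (is.null(graph)) NA_character_ else
        paste(graph$name[e$rule$term_ids], collapse = " AND "),
      n_terms = length(e$rule$term_ids),
      tp = e$score$tp, fp = e$score$fp, tn = e$score$tn, fn = e$score$fn,
      acc = e$score$acc, auc = e$score$auc, f1 = e$score$f1,
      t_score = if (is.null(e$t_score)) NA_real_ else e$t_score,
      difference = if (is.null(e$difference)) e$score$tp - e$score$fp else e$difference,
      covered = paste(e$score$covered, collapse = ","),
      n_provenance = length(e$provenance),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
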