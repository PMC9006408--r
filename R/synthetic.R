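#' Generate a random layered ontology DAG
#'
#' Terms are arranged in `depth + 1` layers; layer 0 holds a single root and
#' layer sizes grow geometrically with `branching` until `n_terms` are
#' placed (every layer keeps at least one term). Each non-root term draws
#' 1-2 parents uniformly from the layer directly above, so the graph is
#' acyclic by construction and a term's level equals its layer.
#'
#' @param n_terms total number of terms (must be >= depth; a single term
#'   yields just the root).
#' @param depth requested number of layers below the root; capped at
#'   `n_terms - 1`.
#' @param branching target growth factor of layer sizes.
#' @param seed integer seed.
#' @param prefix term-id prefix (ids look like `"SYN:0000012"`).
#' @return An [ontology_graph()].
#' @export
make_ontology <- function(n_terms, depth = 3L, branching = 2L, seed = 1L,
                          prefix = "SYN") {
  if (n_terms < depth) stop("infeasible: n_terms < depth")
  stopifnot(depth >= 1L, branching >= 1L, n_terms >= 1L)
  depth <- min(depth, n_terms - 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (n_terms == 1L) {
    return(ontology_graph(sprintf("%s:%07d", prefix, 1L),
                          "synthetic term 1", namespaces = prefix))
  }

  sizes <- pmax(1L, round(branching^(0:depth)))
  # scale to n_terms while keeping >= 1 per layer and exactly 1 root
  sizes[1] <- 1L
  rest <- n_terms - 1L
  w <- sizes[-1] / sum(sizes[-1])
  alloc <- pmax(1L, floor(rest * w))
  while (sum(alloc) > rest) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < rest) alloc[which.max(w)] <- alloc[which.max(w)] + 1L
  sizes <- c(1L, alloc)

  ids <- sprintf("%s:%07d", prefix, seq_len(sum(sizes)))
  layer <- rep(seq_along(sizes) - 1L, sizes)
  parents <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (i in which(layer > 0L)) {
    above <- ids[layer == layer[i] - 1L]
    np <- if (length(above) > 1L) sample(1:2, 1L) else 1L
    parents[[ids[i]]] <- sample(above, min(np, length(above)))
  }
  ontology_graph(ids, paste("synthetic term", seq_along(ids)), parents,
                 namespaces = prefix)
}

#' Plant a conjunctive rule in synthetic annotations and labels
#'
#' Chooses `rule_length` mutually non-ancestral terms at level >= 2 as the
#' planted rule, annotates a target gene subset to all of them, sprinkles
#' random background annotations at `base_density`, closes everything under
#' the true-path rule, and derives the significant label from the planted
#' rule's actual post-closure coverage with independent label flips at
#' probability `noise`. At noise 0 the significant set equals the rule's
#' covered set exactly, so the planted rule scores F1 = 1.
#'
#' @param graph an [ontology_graph()] with >= `rule_length` terms at
#'   level >= 2.
#' @param n_genes number of genes in the universe.
#' @param rule_length number of conjuncts in the planted rule (default 2).
#' @param base_density probability a (gene, term) background annotation is
#'   drawn (default 0.05).
#' @param noise label-flip probability in [0, 0.5).
#' @param seed integer seed.
#' @param target_frac fraction of genes annotated to the full planted
#'   conjunction (default 0.15).
#' @return List: `annotations` (closed [annotation_table()]), `labeling`
#'   (a [comparison_labeling()] with pseudo-comparison `signal vs background`),
#'   `rule` (the planted [rule()]), `flipped` (gene ids whose label was
#'   flipped).
#' @export
plant_rule_scenario <- function(graph, n_genes = 200L, rule_length = 2L,
                                base_density = 0.05, noise = 0.05, seed = 1L,
                                target_frac = 0.15) {
  stopifnot(noise >= 0, noise < 0.5)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  deep <- graph$ids[graph$level >= 2L]
  if (length(deep) < rule_length) stop("graph needs >= rule_length terms at level >= 2")
  anc_list <- ancestors_all(graph)
  # rejection-sample a mutually non-ancestral term set
  planted <- NULL
  for (i in 1:200) {
    cand <- sample(deep, rule_length)
    ok <- TRUE
    if (rule_length > 1L) {
      for (a in seq_len(rule_length - 1L)) {
        for (b in seq.int(a + 1L, rule_length)) {
          if (related_terms(anc_list, cand[a], cand[b])) ok <- FALSE
        }
      }
    }
    if (ok) { planted <- sort(cand); break }
  }
  if (is.null(planted)) stop("could not find mutually non-ancestral terms")

  genes <- sprintf("g%03d", seq_len(n_genes))
  n_target <- max(2L, round(target_frac * n_genes))
  target <- sample(genes, n_target)
  pairs <- data.frame(gene = rep(target, each = rule_length),
                      term = rep(planted, n_target),
                      stringsAsFactors = FALSE)
  bg <- which(matrix(stats::runif(n_genes * length(graph$ids)) < base_density,
                     n_genes, length(graph$ids)), arr.ind = TRUE)
  if (nrow(bg)) {
    pairs <- rbind(pairs, data.frame(gene = genes[bg[, 1L]],
                                     term = graph$ids[bg[, 2L]],
                                     stringsAsFactors = FALSE))
  }
  tab <- propagate_true_path(annotation_table(pairs, genes), graph)

  covered <- genes %in% genes_with_all_terms(tab, planted)
  flip <- stats::runif(n_genes) < noise
  sig <- xor(covered, flip)
  labeling <- comparison_labeling(
    c("signal", "background"),
    stats::setNames(sig, genes),
    stats::setNames(ifelse(sig, "signal", "none"), genes),
    stats::setNames(ifelse(sig, 0.001, 0.5), genes))
  list(annotations = tab, labeling = labeling,
       rule = rule(planted), flipped = genes[flip])
}

#' Simulate a qPCR Cq matrix with planted tissue effects
#'
#' Cq(g, s) = baseline(g) - effect(g, tissue(s)) + N(0, sigma^2); a larger
#' effect lowers Cq, i.e. raises expression. The reference gene is added at
#' a stable Cq of 20 (sd 0.05) and is never missing. Missingness emulates
#' qPCR dropout of weakly expressed targets: target-gene cells are
#' right-censored at the empirical (1 - missing_rate) quantile of all
#' target Cq values, so exactly the highest-Cq cells drop out.
#'
#' @param n_genes number of target genes.
#' @param tissues character vector of tissue labels (default stomach /
#'   small_intestine / colon).
#' @param replicates samples per tissue (default 3).
#' @param effect_map numeric matrix genes x tissues of expression effects in
#'   Cq cycles (positive = upregulated), or `NULL` for no effect. Row names
#'   may name genes (`"g001"`-style); missing rows mean zero effect.
#' @param sigma residual Cq standard deviation (default 0.5 cycles).
#' @param missing_rate fraction of target cells censored, in [0, 0.3).
#' @param seed integer seed.
#' @param baseline_range Cq range the per-gene baselines are drawn from.
#' @param reference_gene name of the reference row (default `"Hsp90"`).
#' @return A [cq_matrix()] with attribute `"truth"` carrying the baselines
#'   and the effect matrix actually applied.
#' @export
simulate_cq <- function(n_genes = 370L, tissues = c("stomach", "small_intestine", "colon"),
                        replicates = 3L, effect_map = NULL, sigma = 0.5,
                        missing_rate = 0.05, seed = 1L,
                        baseline_range = c(22, 32), reference_gene = "Hsp90") {
  stopifnot(sigma > 0, missing_rate >= 0, missing_rate < 0.3)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  genes <- sprintf("g%03d", seq_len(n_genes))
  samples <- paste(rep(tissues, each = replicates),
                   rep(seq_len(replicates), length(tissues)), sep = "_")
  tis <- stats::setNames(rep(tissues, each = replicates), samples)

  eff <- matrix(0, n_genes, length(tissues), dimnames = list(genes, tissues))
  if (!is.null(effect_map)) {
    effect_map <- as.matrix(effect_map)
    common_g <- intersect(rownames(effect_map), genes)
    common_t <- intersect(colnames(effect_map), tissues)
    eff[common_g, common_t] <- effect_map[common_g, common_t]
  }
  baseline <- stats::runif(n_genes, baseline_range[1], baseline_range[2])
  v <- matrix(NA_real_, n_genes, length(samples), dimnames = list(genes, samples))
  for (s in samples) {
    v[, s] <- baseline - eff[, tis[s]] + stats::rnorm(n_genes, 0, sigma)
  }
  v <- pmin(v, 45)  # instrument cycle ceiling
  if (missing_rate > 0) {
    ceiling_cq <- stats::quantile(v, 1 - missing_rate, names = FALSE)
    v[v > ceiling_cq] <- NA_real_
  }
  ref <- pmin(pmax(20 + stats::rnorm(length(samples), 0, 0.05), 1), 45)
  v <- rbind(v, matrix(ref, 1, dimnames = list(reference_gene, samples)))
  out <- cq_matrix(v, tis, reference_gene = reference_gene)
  attr(out, "truth") <- list(baseline = stats::setNames(baseline, genes),
                             effect = eff, sigma = sigma, seed = seed)
  out
}

#' Assemble a full synthetic scenario with planted structure
#'
#' Builds an ontology, plants a conjunctive rule, and ties the rule's
#' covered genes to a tissue expression effect so the whole pipeline —
#' imputation, normalisation, ANOVA/Tukey labeling, enrichment, rule
#' induction, selection — can be verified against known truth. The default
#' sizes mirror a 370-gene, 3-tissue, 3-replicate profiling design with an
#' effect of 3 standard deviations for planted genes in the colon.
#'
#' @param seed integer seed driving every random choice.
#' @param n_genes,n_terms,depth,branching,rule_length,base_density,noise,
#'   target_frac,sigma,missing_rate,replicates see [make_ontology()],
#'   [plant_rule_scenario()] and [simulate_cq()].
#' @param effect_size planted expression effect in Cq cycles (default
#'   3 * sigma).
#' @param effect_tissue tissue carrying the planted effect (default colon).
#' @return An object of class `SyntheticScenario`: list with `graph`,
#'   `annotations`, `planted_rule`, `cq`, `labeling_truth`, `flipped`,
#'   `params`.
#' @export
synthetic_scenario <- function(seed = 1L, n_genes = 370L, n_terms = 60L,
                               depth = 4L, branching = 3L, rule_length = 2L,
                               base_density = 0.03, noise = 0.0,
                               target_frac = 0.12, sigma = 0.5,
                               missing_rate = 0.05, replicates = 3L,
                               effect_size = 3 * sigma,
                               effect_tissue = "colon") {
  graph <- make_ontology(n_terms, depth = depth, branching = branching,
                         seed = seed)
  plant <- plant_rule_scenario(graph, n_genes = n_genes,
                               rule_length = rule_length,
                               base_density = base_density, noise = noise,
                               seed = seed + 1L, target_frac = target_frac)
  covered <- plant$labeling$significant
  eff <- matrix(0, n_genes, 3,
                dimnames = list(names(covered),
                                c("stomach", "small_intestine", "colon")))
  eff[names(covered)[covered], effect_tissue] <- effect_size
  cq <- simulate_cq(n_genes = n_genes, replicates = replicates,
                    effect_map = eff, sigma = sigma,
                    missing_rate = missing_rate, seed = seed + 2L)
  structure(list(graph = graph, annotations = plant$annotations,
                 planted_rule = plant$rule, cq = cq,
                 labeling_truth = plant$labeling, flipped = plant$flipped,
                 params = list(seed = seed, n_genes = n_genes,
                               sigma = sigma, noise = noise,
                               effect_size = effect_size,
                               effect_tissue = effect_tissue)),
            class = "SyntheticScenario")
}

#' Write a synthetic scenario to plain-text files
#'
#' Emits an OBO file, a two-column annotation TSV, a Cq TSV, a sample sheet
#' and a truth JSON into `dir` — the exact inputs the pipeline reads.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of written paths.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(obo = file.path(dir, "ontology.obo"),
                annotations = file.path(dir, "annotations.tsv"),
                cq = file.path(dir, "cq.tsv"),
                samples = file.path(dir, "samples.tsv"),
                truth = file.path(dir, "truth.json"))
  g <- scenario$graph
  con <- file(paths$obo, "w")
  writeLines("format-version: 1.2", con)
  for (t in g$ids) {
    writeLines(c("", "[Term]", paste0("id: ", t),
                 paste0("name: ", g$name[[t]]),
                 paste0("is_a: ", g$parents[[t]])), con)
  }
  close(con)
  ann <- scenario$annotations
  utils::write.table(ann$pairs, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  cq <- scenario$cq
  utils::write.table(
    data.frame(gene_id = rownames(cq$values), cq$values, check.names = FALSE),
    paths$cq, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = colnames(cq$values),
               tissue = unname(cq$sample_tissue[colnames(cq$values)])),
    paths$samples, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(planted_rule = scenario$planted_rule$term_ids,
         significant = names(scenario$labeling_truth$significant)[
           scenario$labeling_truth$significant],
         flipped = scenario$flipped,
         params = scenario$params),
    paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
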