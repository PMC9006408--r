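# Independent oracles used to check the implementation by a second route.
# Nothing in here calls the code path it verifies.

# --- small graph fixtures -------------------------------------------------

chain_graph <- function() {
  # R -> A -> B (parent edges point upward)
  ontology_graph(c("R", "A", "B"),
                 parents = list(R = character(0), A = "R", B = "A"))
}

flat_graph <- function(terms) {
  ontology_graph(c("root", terms),
                 parents = c(list(root = character(0)),
                             stats::setNames(rep(list("root"), length(terms)),
                                             terms)))
}

# root -> {T1, T2, T3}; T1 -> T1a
rules_graph <- function() {
  ontology_graph(c("root", "T1", "T2", "T3", "T1a"),
                 parents = list(root = character(0), T1 = "root",
                                T2 = "root", T3 = "root", T1a = "T1"))
}

diamond_graph <- function() {
  # R -> {A, B} -> C
  ontology_graph(c("R", "A", "B", "C"),
                 parents = list(R = character(0), A = "R", B = "R",
                                C = c("A", "B")))
}

# random DAG on n nodes: edges only from later to earlier topological ranks
random_dag <- function(n, p_edge = 0.3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("T%02d", seq_len(n))
  parents <- stats::setNames(rep(list(character(0)), n), ids)
  for (i in seq_len(n)[-1]) {
    cand <- ids[seq_len(i - 1L)]
    pick <- cand[stats::runif(i - 1L) < p_edge]
    # keep the DAG connected enough that nodes can still be roots sometimes
    parents[[ids[i]]] <- pick
  }
  ontology_graph(ids, parents = parents)
}

# --- graph oracles (exhaustive path enumeration) --------------------------

# all ancestors by naive repeated expansion over an edge list
oracle_ancestors <- function(parents, term) {
  acc <- term
  repeat {
    nxt <- unique(c(acc, unlist(parents[acc], use.names = FALSE)))
    if (length(nxt) == length(acc)) return(sort(acc))
    acc <- nxt
  }
}

# shortest path to any root by exhaustive enumeration of ALL upward paths
oracle_level <- function(parents, term) {
  best <- Inf
  walk <- function(t, d) {
    ps <- parents[[t]]
    if (!length(ps)) { best <<- min(best, d); return(invisible()) }
    for (p in ps) walk(p, d + 1L)
  }
  walk(term, 0L)
  best
}

# true-path closure by fixpoint iteration on the raw pair list
oracle_closure <- function(pairs, parents) {
  repeat {
    extra <- unique(do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      ps <- parents[[pairs$term[i]]]
      if (!length(ps)) return(NULL)
      data.frame(gene = pairs$gene[i], term = ps, stringsAsFactors = FALSE)
    })))
    merged <- unique(rbind(pairs, extra))
    if (nrow(merged) == nrow(pairs)) return(merged[order(merged$gene, merged$term), ])
    pairs <- merged
  }
}

# --- exact-test oracles ---------------------------------------------------

# hypergeometric upper tail P(X >= a) by direct summation of the pmf built
# from binomial coefficients (no phyper)
oracle_hyper_upper <- function(a, annotated, universe, drawn) {
  xs <- max(0L, drawn - (universe - annotated)):min(annotated, drawn)
  pmf <- choose(annotated, xs) * choose(universe - annotated, drawn - xs) /
    choose(universe, drawn)
  sum(pmf[xs >= a])
}

# two-sided Fisher p for a 2x2 table by full enumeration over tables with
# the observed margins
oracle_fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  xs <- max(0L, c1 - (n - r1)):min(r1, c1)
  pmf <- choose(r1, xs) * choose(n - r1, c1 - xs) / choose(n, c1)
  p_obs <- pmf[xs == m[1, 1]]
  sum(pmf[pmf <= p_obs * (1 + 1e-7)])
}

# --- studentized range oracle --------------------------------------------

# P(range of k iid standard normals <= r) by numerical integration
oracle_prange <- function(r, k) {
  if (r <= 0) return(0)
  f <- function(z) k * stats::dnorm(z) *
    (stats::pnorm(z) - stats::pnorm(z - r))^(k - 1)
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-11, abs.tol = 1e-13)$value
}

# P(Q_{k,df} > q): integrate the range CDF against the density of
# S = sqrt(chi^2_df / df). Independent of stats::ptukey.
oracle_ptukey_upper <- function(q, k, df) {
  dens_s <- function(s) {
    exp(log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
          (df - 1) * log(s) - df * s^2 / 2)
  }
  inner <- Vectorize(function(s) dens_s(s) * oracle_prange(q * s, k))
  1 - stats::integrate(inner, 0, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# --- rule-search oracle ---------------------------------------------------

# exhaustive optimum over all valid conjunctions of length <= 2:
# every eligible term and every mutually non-ancestral pair
oracle_best_conjunction <- function(annotations, graph, significant,
                                    eval_fn = c("f1", "acc", "auc"),
                                    min_level = 0L) {
  eval_fn <- match.arg(eval_fn)
  universe <- annotations$universe
  sig <- significant[universe]
  by_term <- split(annotations$pairs$gene, annotations$pairs$term)
  terms <- names(by_term)
  terms <- terms[graph$level[terms] >= min_level]
  score_set <- function(genes) {
    cov <- universe %in% genes
    tp <- sum(cov & sig); fp <- sum(cov & !sig)
    fn <- sum(!cov & sig); tn <- sum(!cov & !sig)
    switch(eval_fn,
           acc = (tp + tn) / length(universe),
           f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
           auc = ((if (tp + fn > 0) tp / (tp + fn) else 0) +
                    (if (tn + fp > 0) tn / (tn + fp) else 0)) / 2)
  }
  anc <- lapply(stats::setNames(graph$ids, graph$ids),
                function(t) oracle_ancestors(graph$parents, t))
  best <- -Inf; best_terms <- NULL
  for (t in terms) {
    s <- score_set(by_term[[t]])
    if (s > best) { best <- s; best_terms <- t }
  }
  if (length(terms) >= 2L) {
    for (i in seq_along(terms)[-length(terms)]) {
      for (j in seq.int(i + 1L, length(terms))) {
        a <- terms[i]; b <- terms[j]
        if (a %in% anc[[b]] || b %in% anc[[a]]) next
        s <- score_set(intersect(by_term[[a]], by_term[[b]]))
        if (s > best) { best <- s; best_terms <- c(a, b) }
      }
    }
  }
  list(score = best, terms = best_terms)
}

# --- misc fixtures --------------------------------------------------------

make_labeling <- function(universe, sig_genes,
                          comparison = c("signal", "background")) {
  sig <- stats::setNames(universe %in% sig_genes, universe)
  comparison_labeling(comparison, sig,
                      stats::setNames(ifelse(sig, comparison[1], "none"), universe),
                      stats::setNames(ifelse(sig, 0.001, 0.6), universe))
}

# random annotation table over a graph (raw, pre-closure)
random_annotations <- function(graph, genes, density = 0.08, seed = 1,
                               close = TRUE) {
  set.seed(seed)
  hits <- which(matrix(stats::runif(length(genes) * length(graph$ids)) < density,
                       length(genes), length(graph$ids)), arr.ind = TRUE)
  pairs <- data.frame(gene = genes[hits[, 1]], term = graph$ids[hits[, 2]],
                      stringsAsFactors = FALSE)
  if (!nrow(pairs)) pairs <- data.frame(gene = genes[1], term = graph$ids[1])
  tab <- annotation_table(pairs, genes)
  if (close) propagate_true_path(tab, graph) else tab
}

# small ExpressionTable straight from a numeric matrix
make_expr <- function(values, tissues) {
  structure(list(values = values,
                 sample_tissue = stats::setNames(tissues, colnames(values)),
                 condition = NULL,
                 imputed = values & FALSE),
            class = "ExpressionTable")
}

write_obo_fixture <- function(lines, path = tempfile(fileext = ".obo")) {
  writeLines(lines, path)
  path
}
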