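#' Construct a Cq matrix
#'
#' Raw qPCR quantification cycles (Cq), one row per gene, one column per
#' sample, with a sample-to-tissue map and a designated reference gene used
#' for delta-Cq normalisation. Higher Cq means lower expression; missing
#' entries represent dropout (no amplification before the cycle ceiling).
#'
#' @param values numeric matrix, genes x samples, with row and column names;
#'   `NA` marks missing measurements. Values must lie in (0, 45].
#' @param sample_tissue named character vector mapping each sample (column)
#'   to a tissue label; at least two tissues required.
#' @param reference_gene row name of the normalisation reference
#'   (default `"Hsp90"`); must be observed in every sample.
#' @param condition optional named character vector mapping samples to an
#'   experimental condition (e.g. treated/control).
#' @return An object of class `CqMatrix`.
#' @export
cq_matrix <- function(values, sample_tissue, reference_gene = "Hsp90",
                      condition = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (!all(colnames(values) %in% names(sample_tissue))) {
    stop("every sample column needs a tissue label")
  }
  sample_tissue <- sample_tissue[colnames(values)]
  if (length(unique(sample_tissue)) < 2L) stop("need >= 2 tissues")
  if (!reference_gene %in% rownames(values)) {
    stop("reference gene not in matrix: ", reference_gene)
  }
  if (anyNA(values[reference_gene, ])) {
    stop("reference gene has missing Cq values")
  }
  obs <- values[!is.na(values)]
  if (any(obs <= 0 | obs > 45)) stop("Cq values must lie in (0, 45]")
  structure(list(values = values, sample_tissue = sample_tissue,
                 reference_gene = reference_gene, condition = condition,
                 imputed = is.na(values) & FALSE),
            class = "CqMatrix")
}

#' @export
print.CqMatrix <- function(x, ...) {
  cat(sprintf("CqMatrix: %d genes x %d samples, tissues: %s, ref: %s, %d missing\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$sample_tissue), collapse = "/"),
              x$reference_gene, sum(is.na(x$values))))
  invisible(x)
}

#' Impute missing Cq values by the max-plus-two rule
#'
#' Each missing cell of a gene is set to that gene's maximum observed Cq
#' across all samples plus 2 cycles, i.e. missingness is read as expression
#' below the detection limit. Genes with no observed value at all are
#' dropped with a warning. Imputed cells are flagged.
#'
#' @param cq a [cq_matrix()].
#' @return A `CqMatrix` with no missing entries and an `imputed` flag matrix.
#' @export
impute_missing <- function(cq) {
  stopifnot(inherits(cq, "CqMatrix"))
  v <- cq$values
  all_na <- rowSums(!is.na(v)) == 0L
  if (any(all_na)) {
    warning(sprintf("dropped %d gene(s) with no observed Cq: %s",
                    sum(all_na), paste(rownames(v)[all_na], collapse = ", ")))
    v <- v[!all_na, , drop = FALSE]
  }
  imputed <- is.na(v)
  if (any(imputed)) {
    fill <- apply(v, 1L, max, na.rm = TRUE) + 2
    idx <- which(imputed, arr.ind = TRUE)
    v[idx] <- fill[idx[, 1L]]
  }
  out <- cq
  out$values <- v
  out$imputed <- imputed
  out
}

#' Normalise Cq values to log2 relative expression
#'
#' Per sample s and gene g, delta-Cq(g,s) = Cq(g,s) - Cq(ref,s) and
#' expression = -delta-Cq, the log2 relative quantity (RQ = 2^-dCq, so
#' log2 RQ = -dCq; with `base = "ln"` the natural-log scale ln(2) * (-dCq)
#' is returned instead). The reference row is removed. Imputation must be
#' applied first if the matrix has missing entries.
#'
#' @param cq an imputed [cq_matrix()].
#' @param base `"log2"` (default) or `"ln"`.
#' @return An object of class `ExpressionTable`: list with `values`
#'   (genes x samples, log-scale relative expression), `sample_tissue`,
#'   `condition` and per-cell `imputed` provenance flags.
#' @export
normalize_cq <- function(cq, base = c("log2", "ln")) {
  stopifnot(inherits(cq, "CqMatrix"))
  base <- match.arg(base)
  if (anyNA(cq$values)) stop("missing Cq entries; run impute_missing() first")
  ref <- cq$values[cq$reference_gene, ]
  keep <- setdiff(rownames(cq$values), cq$reference_gene)
  expr <- -sweep(cq$values[keep, , drop = FALSE], 2L, ref)
  if (base == "ln") expr <- expr * log(2)
  structure(list(values = expr, sample_tissue = cq$sample_tissue,
                 condition = cq$condition,
                 imputed = cq$imputed[keep, , drop = FALSE]),
            class = "ExpressionTable")
}

#' @export
print.ExpressionTable <- function(x, ...) {
  cat(sprintf("ExpressionTable: %d genes x %d samples (log2 relative), tissues: %s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$sample_tissue), collapse = "/")))
  invisible(x)
}

#' Per-gene one-way ANOVA with Tukey HSD post-hoc tests
#'
#' Fits a fixed-effects one-way ANOVA of expression on tissue for every gene
#' and computes Tukey honestly-significant-difference adjusted p-values for
#' every tissue pair from the studentized range distribution. Genes with
#' zero pooled within-group variance are flagged degenerate and get p = 0
#' for every pair with a non-zero mean difference (p = 1 otherwise).
#'
#' @param expr an [normalize_cq()] `ExpressionTable`.
#' @return A list of class `TukeyResult`: `tissues`; `pairs` (data frame
#'   `first`/`second`); matrices `p_adj` and `mean_diff` (genes x pairs,
#'   difference = first - second); `anova_p`; logical `degenerate`.
#' @export
anova_tukey <- function(expr) {
  stopifnot(inherits(expr, "ExpressionTable"))
  tis <- expr$sample_tissue
  tissues <- unique(tis)
  k <- length(tissues)
  n_per <- vapply(tissues, function(t) sum(tis == t), 1L)
  if (any(n_per < 2L)) stop("need >= 2 replicates per tissue")
  v <- expr$values
  N <- ncol(v)
  df_err <- N - k

  means <- sapply(tissues, function(t) rowMeans(v[, tis == t, drop = FALSE]))
  ss_within <- sapply(tissues, function(t) {
    x <- v[, tis == t, drop = FALSE]
    rowSums((x - rowMeans(x))^2)
  })
  if (is.null(dim(means))) { # single-gene edge case
    means <- matrix(means, nrow = 1, dimnames = list(rownames(v), tissues))
    ss_within <- matrix(ss_within, nrow = 1, dimnames = list(rownames(v), tissues))
  }
  mse <- rowSums(ss_within) / df_err
  grand <- rowMeans(v)
  ss_between <- as.vector((means - grand)^2 %*% n_per)
  f_stat <- (ss_between / (k - 1)) / mse
  anova_p <- stats::pf(f_stat, k - 1, df_err, lower.tail = FALSE)

  degenerate <- mse == 0
  cmb <- utils::combn(tissues, 2L)
  pair_names <- paste(cmb[1L, ], cmb[2L, ], sep = " vs ")
  p_adj <- mean_diff <- matrix(NA_real_, nrow = nrow(v), ncol = ncol(cmb),
                               dimnames = list(rownames(v), pair_names))
  for (j in seq_len(ncol(cmb))) {
    t1 <- cmb[1L, j]; t2 <- cmb[2L, j]
    d <- means[, t1] - means[, t2]
    se <- sqrt(mse / 2 * (1 / n_per[t1] + 1 / n_per[t2]))
    q <- abs(d) / se
    p <- stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
    p[degenerate] <- ifelse(d[degenerate] != 0, 0, 1)
    p_adj[, j] <- p
    mean_diff[, j] <- d
  }
  anova_p[degenerate] <- ifelse(ss_between[degenerate] > 0, 0, 1)

  structure(list(tissues = tissues,
                 pairs = data.frame(first = cmb[1L, ], second = cmb[2L, ],
                                    stringsAsFactors = FALSE),
                 p_adj = p_adj, mean_diff = mean_diff,
                 anova_p = anova_p, degenerate = degenerate),
            class = "TukeyResult")
}

#' Construct a comparison labeling
#'
#' @param comparison length-2 character vector: the ordered tissue pair.
#' @param significant named logical vector over the gene universe.
#' @param up_in named character vector: for each gene, the tissue it is
#'   upregulated in, or `"none"`; must be `"none"` exactly when not
#'   significant.
#' @param p_value named numeric vector of adjusted pairwise p-values.
#' @return An object of class `ComparisonLabeling`.
#' @export
comparison_labeling <- function(comparison, significant, up_in, p_value) {
  stopifnot(length(comparison) == 2L,
            identical(names(significant), names(up_in)),
            identical(names(significant), names(p_value)))
  if (any(significant != (up_in != "none"))) {
    stop("up_in must be 'none' exactly for non-significant genes")
  }
  bad <- setdiff(unique(up_in), c(comparison, "none"))
  if (length(bad)) stop("up_in contains labels outside the comparison: ",
                        paste(bad, collapse = ", "))
  structure(list(comparison = comparison, significant = significant,
                 up_in = up_in, p_value = p_value),
            class = "ComparisonLabeling")
}

#' @export
print.ComparisonLabeling <- function(x, ...) {
  cat(sprintf("ComparisonLabeling %s vs %s: %d/%d significant (%d up in %s, %d up in %s)\n",
              x$comparison[1], x$comparison[2], sum(x$significant),
              length(x$significant),
              sum(x$up_in == x$comparison[1]), x$comparison[1],
              sum(x$up_in == x$comparison[2]), x$comparison[2]))
  invisible(x)
}

#' Split genes into significant / non-significant per tissue pair
#'
#' For each pairwise tissue comparison a gene is significant iff its
#' Tukey-adjusted p-value is strictly below `alpha`; the direction comes
#' from the sign of the mean expression difference. With three tissues the
#' three labelings are the study's Groups A/B/C.
#'
#' @param stats a [anova_tukey()] `TukeyResult`.
#' @param alpha significance level (default 0.01, strict `<`).
#' @return Named list of [comparison_labeling()] objects, one per pair.
#' @export
label_groups <- function(stats, alpha = 0.01) {
  stopifnot(inherits(stats, "TukeyResult"))
  out <- list()
  for (j in seq_len(nrow(stats$pairs))) {
    t1 <- stats$pairs$first[j]; t2 <- stats$pairs$second[j]
    p <- stats$p_adj[, j]
    d <- stats$mean_diff[, j]
    sig <- p < alpha
    up <- ifelse(!sig, "none", ifelse(d > 0, t1, t2))
    nm <- paste(t1, t2, sep = " vs ")
    out[[nm]] <- comparison_labeling(c(t1, t2),
                                     stats::setNames(sig, rownames(stats$p_adj)),
                                     stats::setNames(up, rownames(stats$p_adj)),
                                     stats::setNames(p, rownames(stats$p_adj)))
  }
  out
}

#' Count genes upregulated per tissue
#'
#' A gene counts as upregulated in tissue T if it is significant and
#' up-in-T in at least one pairwise comparison involving T. Each gene is
#' counted once per tissue (distinct-gene union over the tissue's
#' comparisons); set `distinct = FALSE` for the multiset sum across
#' comparisons instead.
#'
#' @param labelings list of [comparison_labeling()] objects.
#' @param distinct logical; count distinct genes (default) or sum pairwise
#'   lists with double counting.
#' @return Named integer vector, tissue -> count. The per-tissue gene sets
#'   are attached as attribute `"genes"`.
#' @export
count_upregulated <- function(labelings, distinct = TRUE) {
  tissues <- unique(unlist(lapply(labelings, `[[`, "comparison")))
  sets <- stats::setNames(vector("list", length(tissues)), tissues)
  counts <- stats::setNames(integer(length(tissues)), tissues)
  for (t in tissues) {
    per_cmp <- lapply(labelings[vapply(labelings, function(l) t %in% l$comparison, TRUE)],
                      function(l) names(l$up_in)[l$up_in == t])
    sets[[t]] <- sort(unique(unlist(per_cmp)))
    counts[t] <- if (distinct) length(sets[[t]]) else sum(lengths(per_cmp))
  }
  attr(counts, "genes") <- sets
  counts
}

#' Two-group filter by mean difference and complete separation
#'
#' Designed for designs too small for hypothesis testing (e.g. 3 treated vs
#' 2 control animals). A gene is selected iff (a) the absolute difference of
#' group means on the log2 relative expression (delta-Cq) scale is strictly
#' greater than `delta` cycles AND (b) the two groups' sample ranges do not
#' overlap (every value of the higher group above every value of the lower
#' group). Both criteria are required.
#'
#' @param treated,control `ExpressionTable`s over the same gene universe.
#' @param delta minimum absolute mean difference in delta-Cq units
#'   (default 1.25, strict `>`).
#' @return Data frame of selected genes: `gene`, `mean_treated`,
#'   `mean_control`, `mean_diff`, `direction`
#'   (`"up-in-treated"` / `"down-in-treated"`).
#' @export
dss_separation_filter <- function(treated, control, delta = 1.25) {
  stopifnot(inherits(treated, "ExpressionTable"), inherits(control, "ExpressionTable"))
  genes <- intersect(rownames(treated$values), rownames(control$values))
  if (length(genes) < nrow(treated$values) || length(genes) < nrow(control$values)) {
    warning("gene universes differ; using the intersection")
  }
  tv <- treated$values[genes, , drop = FALSE]
  cv <- control$values[genes, , drop = FALSE]
  mt <- rowMeans(tv); mc <- rowMeans(cv)
  d <- mt - mc
  sep_up <- apply(tv, 1L, min) > apply(cv, 1L, max)   # treated entirely above
  sep_dn <- apply(tv, 1L, max) < apply(cv, 1L, min)   # treated entirely below
  keep <- abs(d) > delta & (sep_up | sep_dn)
  data.frame(gene = genes[keep],
             mean_treated = unname(mt[keep]),
             mean_control = unname(mc[keep]),
             mean_diff = unname(d[keep]),
             direction = ifelse(d[keep] > 0, "up-in-treated", "down-in-treated"),
             stringsAsFactors = FALSE)
}

#' Read a Cq matrix and sample sheet from TSV files
#'
#' @param cq_path TSV with first column `gene_id`, remaining columns one per
#'   sample.
#' @param sheet_path TSV with columns `sample_id`, `tissue` and optionally
#'   `condition`.
#' @param reference_gene row used for normalisation (default `"Hsp90"`).
#' @return A [cq_matrix()].
#' @export
read_cq <- function(cq_path, sheet_path, reference_gene = "Hsp90") {
  tab <- utils::read.delim(cq_path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  sheet <- utils::read.delim(sheet_path, colClasses = "character")
  if (!all(c("sample_id", "tissue") %in% names(sheet))) {
    stop("sample sheet needs columns sample_id and tissue")
  }
  cond <- if ("condition" %in% names(sheet)) {
    stats::setNames(sheet$condition, sheet$sample_id)
  }
  cq_matrix(m, stats::setNames(sheet$tissue, sheet$sample_id),
            reference_gene = reference_gene, condition = cond)
}
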