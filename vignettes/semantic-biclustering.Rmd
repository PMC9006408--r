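---
title: "Semantic biclustering of qPCR profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic biclustering of qPCR profiles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontorules)
```

This vignette documents the statistical model behind `ontorules`, the
parameters that matter, the design decisions taken where the problem was
genuinely open, and what the synthetic-data tests do and do not establish.

## 1. From Cq to expression

qPCR reports a quantification cycle Cq per gene and sample; each extra
cycle is a twofold drop in template abundance. The pipeline works on

$$\Delta C_q(g,s) = C_q(g,s) - C_q(\mathrm{ref}, s), \qquad
\mathrm{expr}(g,s) = -\Delta C_q(g,s) = \log_2 \mathrm{RQ}(g,s),$$

the log2 relative quantity against a stably expressed reference gene
(default `Hsp90`). Working on $-\Delta C_q$ keeps every downstream
criterion linear in Cq — in particular the 1.25-ΔCq separation threshold
applies directly. A `base = "ln"` switch rescales by $\ln 2$ for users who
prefer natural logs; it changes no test decision because every test
statistic here is scale-equivariant.

**Missing data.** A missing Cq is read as "no amplification before the
cycle ceiling", i.e. expression below the detection limit, not as missing
at random. Each missing cell is imputed as the gene's maximum observed Cq
across *all* samples plus 2 cycles, on the Cq scale and before
normalisation (larger Cq = less expressed, so max + 2 is "a bit below the
weakest observed signal"). Genes observed nowhere are dropped with a
warning — there is no information to place them. Imputed cells carry a
provenance flag through normalisation.

## 2. Significance labeling

Per gene, a fixed-effects one-way ANOVA across tissues is followed by
Tukey HSD pairwise comparisons. The pairwise p-value is
$P\{Q_{k,\nu} > q\}$ for the studentized range distribution with $k$
groups and $\nu = N - k$ error degrees of freedom, with
$q = |\bar y_i - \bar y_j| / \sqrt{\widehat{\mathrm{MSE}}/2\,(1/n_i + 1/n_j)}$
(the Tukey–Kramer form; equal $n$ reduces to the classical statistic).
A gene is significant for a pair iff the adjusted p is **strictly** below
α = 0.01; the direction is the sign of the mean difference. With three
tissues the three pairwise labelings correspond to the comparison groups
small-intestine vs colon, stomach vs colon, and stomach vs small intestine.

Degenerate genes (zero pooled within-group variance) cannot be tested; they
are flagged and assigned p = 0 for pairs with different means and p = 1
otherwise, which is the limit behaviour as the variance goes to zero.

**Calibration.** Tukey HSD controls the *familywise* error over the
pairwise comparisons: under a complete null the probability that a gene is
significant in at least one pair is α. The rate for one fixed pair is
strictly smaller (measured ≈ 0.004 at α = 0.01, k = 3, n = 3). The type-I
acceptance test therefore checks the familywise fraction against two-sided
binomial 99% bounds around α and the per-pair fractions against the upper
bound only.

**Power at the study's scale.** With n = 3 per tissue and α = 0.01 the
studentized-range oracle puts the power to detect a 3σ mean shift in a
fixed pair at only ≈ 0.36; ≈ 5.5–6σ is needed for power 0.9. The synthetic
generator's default planted effect stays at 3σ — a realistic qPCR effect
of 1.5 cycles at σ = 0.5 — so simulated recoveries are intentionally
partial, exactly as real studies at this design size are; tests that need
near-complete recovery plant 6–8σ effects and say so. The package's power
behaviour is verified by agreement with the independent oracle, not by
asserting an unattainable recovery rate.

**Upregulated-per-tissue counts** are distinct-gene unions: gene g counts
for tissue T if it is significant and up-in-T in at least one of T's two
comparisons. The multiset reading (double-counting genes up in both
comparisons) is available via `distinct = FALSE`; the union is the default
because "the number of upregulated genes of a tissue" is naturally a set
cardinality.

## 3. The two-group separation filter

For treated-vs-control designs too small to test (3 vs 2 animals), a gene
is *selected* iff

1. $|\overline{\mathrm{expr}}_{\mathrm{treated}} -
   \overline{\mathrm{expr}}_{\mathrm{control}}| > 1.25$ ΔCq units
   (strict), and
2. the two sample ranges are disjoint (the minimum of the higher group
   exceeds the maximum of the lower group).

Both criteria are conjunctive by construction: a large mean gap with
overlapping ranges is rejected, as is perfect separation with a gap of
exactly 1.25. The filter is symmetric under sign flips (membership
invariant, direction reversed).

## 4. Enrichment and coverage

Term enrichment is the one-sided hypergeometric tail (over-representation
among significant genes) on the 2×2 table
(significant × annotated-post-closure). Raw p-values are reported and the
default "enriched" call is raw p < 0.05; a Benjamini–Hochberg column is
emitted for users who want FDR control, but it does not drive the call —
the reference analysis style for this kind of targeted panel reports raw
exact p-values. Coverage percentages are rounded **half-up** to two
decimals (base R's `round` is half-to-even, which would print 13.63 where
the conventional table shows 13.64).

Categorical r×c tables use the exact Fisher network algorithm when the
total count is ≤ 30 and a seeded Monte-Carlo p-value (10⁵ draws) above
that; 2×2 is always exact two-sided.

## 5. Rule induction

A rule is a conjunction of ontology terms; its extension is the set of
genes annotated to every conjunct after **true-path closure** (a gene
annotated to a term is annotated to all its ancestors). Closure happens
once at load time; two consequences matter:

* a conjunct that is an ancestor of another conjunct is redundant, so such
  rules are forbidden outright;
* rules with different term sets can have identical extensions — the
  search deduplicates on the covered set, keeping the shortest, then
  lexicographically smallest representative.

**Levels.** A term's level is the *shortest* parent-path distance to a
root (roots are level 0). The alternative, longest-path depth, was
rejected because the shortest path makes the minLevel constraint a
conservative generality filter: a term passes only if *no* short route to
the root exists. `part_of` edges count as parent edges by default (standard
true-path practice); an `is_a`-only switch exists. Merged multi-ontology
graphs keep each source's roots at level 0 — no artificial super-root that
would shift every level by one.

**Search.** Top-down beam search: seed with all eligible single-term
rules, refine by (a) conjoining a new non-redundant term or (b)
specialising a conjunct into one of its children, keep the `beam_width`
best by the configured evaluation function, stop when the beam stabilises
or rules reach `max_conjuncts`. Ties break toward fewer conjuncts, then
lexicographically smaller term ids, making the search fully deterministic;
the seed only matters if `candidate_cap` subsamples candidate terms. All
scored rules are archived, so the returned optimum can never be worse than
the best seed, and for ontologies where all singletons fit in the beam the
length-≤2 optimum is found *exactly* (this is what the
exhaustive-enumeration equivalence test exploits).

**Scores.** With significant genes as the positive class and the covered
set as the prediction: ACC = (tp+tn)/n, F1 = 2tp/(2tp+fp+fn), and AUC is
the balanced accuracy (sensitivity + specificity)/2 — the AUC of a
single Boolean predictor, which is the only sensible reduction when the
"classifier" has one operating point. `max_conjuncts` defaults to 3:
reported biclusters in this domain use 2-term conjunctions, and 3 leaves
headroom without combinatorial blow-up.

## 6. Grid pooling and selection

The grid runs induction for every comparison × evaluation function
(ACC, AUC, F1) × minLevel (0, 2, 3, 4, 5, 6) — 54 runs for three
comparisons — and pools rules, deduplicated on (comparison, extension)
with full provenance. Selection then:

* keeps rules with **difference** = tp − fp ≥ 3 (the surplus of
  significant over non-significant covered genes; an absolute-value
  variant is a flag, since a rule capturing mostly *non*-significant genes
  could also be deemed interesting);
* ranks by **t-score**: the Welch two-sample t statistic of the
  comparison's per-gene expression contrast (mean over first tissue minus
  mean over second) between covered and uncovered genes. The absolute
  value is used by default so coherent down-regulated clusters rank with
  up-regulated ones; a signed variant is a flag. Rules covering fewer than
  two genes get t = NA and sort last. The sort is stable, so full ties
  preserve pool order.

Both definitions are deliberate choices: the source protocol names
"t-score" and "number of differences" without formulas, so the package
fixes defensible defaults and keeps both pluggable.

## 7. The synthetic world

`make_ontology` builds layered DAGs (each non-root has 1–2 parents in the
layer above, so level = layer). `plant_rule_scenario` picks mutually
non-ancestral terms at level ≥ 2 as a planted rule, annotates ~15% of
genes to the full conjunction, adds Bernoulli(0.05) background
annotations, closes, and labels genes by the rule's *actual post-closure
coverage* with independent 5% label flips — so at noise 0 the planted rule
scores F1 = 1 by construction, and the planted-recovery test measures
robustness, not luck. `simulate_cq` draws baselines from Cq 22–32,
residual σ = 0.5 cycles (typical inter-animal plus technical spread for a
curated panel), subtracts planted effects, and right-censors the highest
(1 − missing rate) quantile of Cq values — dropout hits weak expression
first, matching how qPCR actually fails and matching the max+2 imputation
model. Defaults mirror the emulated design: 370 genes, 3 tissues, 3
replicates.

What a green synthetic test establishes: the machinery (closure, Tukey,
enrichment arithmetic, search, selection) is correct at desk scale under
the stated generative model. What it does not establish: recovery of the
published real-data gene lists — those depend on the exact array content,
annotation release and ontology versions, none of which are public —
nor behaviour under correlated noise, plate effects, or annotation bias,
which the generator does not model.

## 8. Numerical choices and degenerate inputs

* Tukey p-values come from `stats::ptukey`; the test suite checks them to
  1e-6 against an independent numerical integration of the studentized
  range distribution, and the hypergeometric/Fisher p-values against
  brute-force enumeration over fixed-margin tables.
* Strict inequalities everywhere the protocol states a threshold
  (p < 0.01, gap > 1.25, flips < 0.5).
* Coverage rounding is half-up at two decimals, applied at the reporting
  boundary only.
* Empty upregulated classes report 0.00% with an explicit flag rather
  than NaN.
* An annotation file whose terms mostly (> 50%) fail to resolve aborts —
  that is almost always the wrong ontology, not sparse data.
* The Monte-Carlo Fisher branch re-seeds locally and restores the RNG
  state, as do all generators, so library calls never perturb a user's
  random stream.

## 9. Known limitations

* Single-factor designs only; no mixed models, no qPCR efficiency
  correction.
* Rule search is heuristic beyond length 2; the exhaustive-equivalence
  guarantee is for length-≤2 conjunctions with all singletons in the beam.
* No disjunctions or negated conjuncts in rules.
* Gene identifiers are matched exactly (case-normalised symbols); no alias
  resolution.
* The final "interesting rules" judgement of a study remains human; the
  package stops at the ranked, provenance-tagged pool.
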