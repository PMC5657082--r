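---
title: "Semantic biclustering: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic biclustering: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sembic)
```

## The problem and the formal model

Binary expression atlases record, for each gene and each *situation* (an
anatomical location, a developmental stage, a sample), whether the gene is
expressed there.  Biclustering looks for rectangular submatrices dense in
1s; *semantic* biclustering additionally demands that each rectangle be
describable by ontology terms on both axes, so that the result reads as a
biological statement rather than as a list of identifiers.

An ordinary bicluster is a pair of index sets; a system of them covers the
union of their rectangles, and its training accuracy is the agreement
between that coverage indicator and the matrix.  Perfect training accuracy
holds exactly when the system covers all 1s and no 0s, which is trivially
attainable with one bicluster per 1-cell — hence the regularized score
`accuracy + lambda / |B|` exposed by `regularized_score()`.

A semantic bicluster is a pair of weighted term sets.  Against closed
annotation relations it *induces* the ordinary bicluster of entities
complying with all its literals; an empty side is a vacuous conjunction and
induces every entity of that dimension, so biclusters described solely by
one dimension's terms remain expressible.  The soft classifier generalizes
the conjunction: a pair (g, s) is supported when the matched gene-side
weights reach θ_G and the matched situation-side weights reach θ_S.  The
same machinery serves both strategies because crisp rule-derived biclusters
are weight-1 term sets; negated literals (from tree paths) match when the
term is *absent* from the closed annotation and then contribute their weight
to the sum.  One subtlety is worth stating: an empty side supports every
entity regardless of θ.  Without this rule a one-sided bicluster would be
unusable at θ ≥ 1, contradicting the induced-bicluster semantics.

## The greedy bicluster miner

`greedy_bicluster()` concretizes a noise-tolerant cover search with an
explicit cost: each bicluster pays its number of rows plus columns
(description), each covered 0 and uncovered 1 pays ρ.  Candidates are grown
in two phases, mirroring how approximate boolean-decomposition miners
behave:

1. *Noise-free core.*  From a seed column, the rows holding its uncovered 1s
   form the initial block; the best-supported remaining column (the one
   preserving most core rows) is added — shrinking the rows to keep the
   block pure — while the block's description-minus-coverage value does not
   increase.  Support-first ranking matters: at small ρ the value of a pure
   two-column block is nearly independent of its height, so choosing columns
   by value alone degenerately favors one-row blocks.
2. *Noise-tolerant extension and trim.*  Columns and then rows are appended
   whenever the appendage does not increase the total system cost (this is
   where 0-cells enter a bicluster), to a fixpoint; rows/columns whose
   removal strictly lowers the cost are then trimmed, and extension is
   attempted once more.

Candidates are grown from a beam of the 16 columns richest in uncovered 1s,
and the one with the most negative cost delta is accepted; the search stops
when no candidate strictly decreases the cost, so the cost sequence is
strictly decreasing and termination is guaranteed.  A single-seed variant
(always the globally densest column) was tried first and discarded: when two
planted rectangles share a group of columns, the densest column lies in the
shared group, the seed rows mix both row sets, and the resulting merged
bicluster — a genuine local optimum of the cost — conflates two patterns
that the beam keeps apart.

The noise parameter ρ is chosen without supervision by `select_rho()`:
candidates (default 0.5, 1, 2) are run and the system with the lowest total
cost at the reference scale ρ = 1 wins, ties to the smallest candidate.

## Enrichment, weights and threshold calibration

Each non-trivial bicluster (more than one gene *and* more than one
situation) is annotated per dimension by a one-sided hypergeometric test of
every term annotating at least one member, against the background of all
matrix entities on that dimension — not the whole ontology universe, since
the matrix defines the sampled population.  Retained terms carry weight
`max(1e-6, 1 - p)`: the mapping keeps weights in (0;1], orders them by
significance, and makes multi-term weight sums commensurate with the θ grid.
Annotations are closed over the ontology first (all of `is_a`, `part_of`,
`develops_from` treated as transitive), so ancestor terms compete with the
leaves that implied them; this redundancy is deliberate — it is what GO-style
vocabularies look like — and no decorrelation (elim-style) is attempted.

Significance thresholds may be fixed per dimension (defaults 0.05 for
genes, 0.1 for situations, reflecting that situation vocabularies are
smaller and shallower so weaker situation terms still help generalization)
or, by default in `run_pipeline()`, calibrated by permutation:
entity-to-annotation assignments are shuffled (100 times), all bicluster
term p-values recomputed on identical index sets, and the largest candidate
threshold whose estimated FDR — mean permuted count at or below it over the
real count — stays within 0.05 is taken.  Calibration is the default because
fixed thresholds let small noise-clump biclusters keep handfuls of weakly
enriched terms; with a vacuous opposite side such a bicluster supports whole
rows or columns and measurably inflates the false-positive rate.  Biclusters
retaining no term on either side are dropped; one empty side is allowed.

## The reduction strategy

`unroll()` produces one instance per cell in row-major order: gene-term
indicators, situation-term indicators, expression class.  The two
vocabularies must be disjoint — term identifiers double as feature names.
`select_features()` removes features occurring in fewer than
`ceiling(min_fraction * instances)` rows (default 1‰), which both speeds
learning and discards terms too rare to generalize.

`learn_rules()` is a compact separate-and-conquer learner of the
incremental-reduced-error-pruning family: per rule, the still-uncovered
instances are split 2:1 grow/prune (stratified, seeded); literals — positive
presence only, matching the conjunctive rule language — are added by maximal
FOIL gain until no negative is covered; the rule is pruned back to the
final-literal prefix maximizing (p − n)/(p + n) on the prune split, ties
keeping more literals (aggressive tie-pruning destroyed exact conjunctions
on clean fixtures); learning stops when a rule's prune-split error exceeds
50% or positives run out, and covered positives are removed between rules.
Confidences are Laplace-corrected, `(p + 1)/(p + n + 2)`, counted on the
instances active when the rule was learned; prediction uses first-match
semantics with a no-expression default.

`learn_tree()` grows a binary gain-ratio tree (features never reused along a
path, growth stopping on purity, node size below `min_leaf = 2`, or absent
information gain) and applies reduced-error pruning against an internal
stratified 20% holdout.  A subtree is collapsed when the replacement leaf
makes strictly fewer holdout errors, or ties while the subtree already errs
on its build instances: a tie against a build-perfect subtree only reflects
holdout sparsity, and collapsing on such ties broke the exactness of
noiseless trees.  No global MDL optimization (rules) or pessimistic pruning
(trees) is attempted; behavioral equivalence on clean fixtures, not parity
with any particular toolkit, is the design target.

Every rule and every positive-leaf path converts to a crisp semantic
bicluster, and the covered cells of a rule always form the rectangle
(induced genes) × (induced situations) — the propositional form guarantees
it, and a thousand-fixture randomized test pins it.

## Evaluation protocol

`split_matrix()` realizes "70% of the elements" as equal per-dimension
retention: round(|G|·√f) genes × round(|S|·√f) situations.  This rule is
adopted because it uniquely reproduces both published split shapes
(6,510×100 → 5,447×84 and 1,207×72 → 1,010×60) from f = 0.7; per-dimension
rounding is the only free choice and round-to-nearest is used.  Held-out
cells carry region tags kG/kL/bd; their counts satisfy
|kG| = |G_tr|·|S_te|, |kL| = |G_te|·|S_tr|, |bd| = |G_te|·|S_te|.

Soft systems are evaluated on the θ grid {1, 5, 10, 50}² — 16 binary
classifiers — and aggregated by the upper convex hull (monotone-chain, ties
on FPr keep the best TPr; (0,0) and (1,1) always included) with trapezoid
area.  Confidence models are evaluated by the standard ranked sweep with
ties grouped; the plain trapezoid area is reported alongside the hull area.
A single rectangular split per run is used, seeded; repeated splits are a
loop at the caller's level, since cross-validation has no analogue in the
two-dimensional holdout geometry.

## What the generator emulates — and what it does not

`plant_biclusters()` draws two rooted random DAGs (every non-root term on a
random level, one or two parents from shallower levels; edge types mostly
`is_a`), picks leaf terms to define each planted bicluster, assigns them to
its member entities and — at `background_density` — elsewhere, then sets the
matrix to the *induced* extension of the planted system and applies
independent 0→1 / 1→0 flips.  Because membership is defined through the
annotations, background-annotated entities can legitimately join a
rectangle; the clean labels are therefore exactly what the ground-truth
semantic system classifies, a property the tests exploit.

Defaults are the package's study conditions: a 1,000 × 72 matrix (the scale
of an imaginal-disc style dataset), vocabularies of 150 gene and 60
situation terms of depth 4, three planted biclusters defined by three leaf
terms per side covering 15% of genes and 20% of situations each, 2% flip
noise, and background annotation density 0.02.  Vocabulary depth and the
three-leaf descriptions are sized so that closed planted descriptions carry
roughly 10–20 enriched terms per side, which is what gives the fixed θ grid
usable resolution between "any one term" and "at least five"; shallow
two-term first drafts left biclusters with four to seven terms, exactly
straddling θ = 5, and made the grid nearly binary.  The background density
keeps every entity annotated: with a fully unannotated background even
near-root terms become spuriously specific and enrichment cross-activates
biclusters through shared ancestors — an artifact real, densely annotated
genomes do not show.

The generator does **not** emulate realistic GO topology statistics (term
fan-out, annotation power laws), expression autocorrelation, or
vocabulary-specific annotation quality.  Passing tests on generator output
therefore demonstrate correctness of the machinery and recoverability under
the stated conditions, not performance on any real atlas.

## Numerical choices and degenerate inputs

* Hypergeometric p-values come from `phyper(k − 1, K, N − K, n,
  lower.tail = FALSE)`; an exhaustive binomial-coefficient oracle checks all
  configurations with N ≤ 12.
* Weights are clamped below by 1e-6 so they stay strictly positive.
* FOIL gain requires strictly positive improvement (tolerance 1e-12);
  feature ties break by column order everywhere, which fixes learning
  outcomes under permutation of equally-good features.
* Empty rule coverage on a prune split scores value −1 and error 0: the
  rule is neither preferred nor rejected on no evidence.
* Degenerate ROC inputs (single-class test sets) raise errors in the overall
  sweep but are reported as absent (`NA`) per region, where small regions
  are routine.
* Trivial biclusters are skipped by annotation (`NULL`, not an error);
  empty systems error only where a quantity (regularizer, cost-based ρ
  choice, enriched proportion) is undefined without biclusters.

## Known limitations

* The miner is greedy: strongly overlapping rectangles can still merge when
  chance-extended memberships make the union locally cost-optimal (observed
  on some generator draws); the beam mitigates but does not eliminate this.
* Flip noise bounds attainable hold-out AUROC well below 1 (at 2% noise a
  perfect binary classifier tops out near 0.94 on this geometry), so
  low-noise end-to-end results around 0.88–0.93 are expected, not a defect.
* Ancestor terms are enriched alongside their leaves by design; vocabularies
  whose upper levels are narrow make soft classification at θ = 1
  permissive.
* Test-suite problem sizes: property tests run on matrices up to ~120 × 30
  with vocabularies of a few dozen terms; the end-to-end and acceptance
  checks use the default 1,000 × 72 conditions.  The 6,510 × 100 shape
  appears only in split/unroll arithmetic, which is exact at any scale.
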