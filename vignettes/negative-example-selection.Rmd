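---
title: "Selecting negative examples for protein function from GO annotations"
author: "GOnegatives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting negative examples for protein function from GO annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GOnegatives)
```

## Background and model

Gene Ontology annotation is positive-only: the absence of an annotation
does not assert the absence of function. Training a function classifier
therefore faces a positive-unlabeled (PU) problem, and the quality of the
*negative* training examples directly limits prediction quality. This
package implements passive negative-example selectors that use nothing
but GO itself, exploiting the bias encoded in co-annotation patterns:
functions that never co-occur in annotated genes are unlikely to co-occur
in reality.

All selectors operate on the binary gene × term matrix $A$ obtained after
propagating annotations upward through the ontology (the true path rule:
an annotation to a term implies annotations to all its ancestors, across
`is_a` and, by default, `part_of` edges). Rows are restricted to genes
with at least one annotation; columns span all three branches jointly.

**SNOB.** The empirical conditional probability of term $a$ given term
$m$ is $p(a \mid m) = n_{m,a} / n_m$, the fraction of $m$-annotated genes
also carrying $a$. A gene $i$ with annotation count $W_{ii}$ receives the
score

$$ s_i(a) \;=\; \frac{1}{W_{ii}} \sum_{m:\,A_{im}=1} p(a \mid m), $$

the $a$ column of $W^{-1} A P$. Positive genes of $a$ (IEA evidence
included) are removed and the $n$ lowest-scoring candidates are the
negatives, with ties broken by gene identifier so results are
reproducible. A positive gene always scores at least $1/W_{ii}$ because
the identity term contributes $p(a \mid a) = 1$. Rows of $P$ for terms
with no annotated genes are zero by convention, avoiding $0/0$; such
terms cannot occur among an annotated gene's terms anyway.

**ALBNeg** applies the stricter zero-probability rule to curated
annotations only: a candidate qualifies when every one of its
*most-specific* annotations (those with no annotated child in the same
gene) has never co-occurred with the target term. It returns a
fixed-size set. IEA usage is a flag; the default follows the method's
published curated-only form, so its positive class is likewise the
curated one.

**NETL** treats each gene as a document whose words are its propagated
annotations (IEA included). A latent Dirichlet allocation model is fit
with the number of topics set to the count of annotated direct children
of the three branch roots — far fewer topics than vocabulary words, which
a topic model needs, while still covering the DAG once negatives are
propagated downward by the inverse true path rule. The positive class is
summarised by the renormalised mean of the positives' posterior topic
distributions (unweighted: there is no principled annotation-count weight
and the mean of distributions is already a distribution), and candidates
are ranked by the distributional overlap score

$$ \mathrm{DOS}(p, q) = \sum_i \min(p_i, q_i), $$

lowest overlap first. For unit-sum vectors this is symmetric, bounded in
$[0,1]$, equals 1 iff $p = q$, 0 iff the supports are disjoint, and is
identical to $1 - \tfrac12\lVert p - q\rVert_1$ (one minus total
variation distance), so it is a bounded symmetric surrogate for
Kullback–Leibler-style divergence. We chose this form because it is the
simplest functional satisfying all of those stated properties.

**Baselines.** PU-Rocchio builds prototype vectors from length-normalised
tf-idf documents with the classic constants $\alpha = 16$, $\beta = 4$
(tf is the 0/1 annotation indicator after propagation, idf is
$\log(N/\mathrm{df})$) and scores candidates by
$\cos(v, c_{\mathrm{unl}}) - \cos(v, c_{\mathrm{pos}})$. 1-DNF returns
non-positive genes free of "enriched" terms — terms whose document
frequency proportion among positives strictly exceeds that among
unlabeled genes. The sibling heuristic returns genes annotated to a
direct parent of the term but not the term itself (curated annotations
only), falling back to all non-positive genes when that set is empty.
The random baseline samples uniformly without replacement from the full
gene universe minus the positives — including unannotated genes, which
the other algorithms never score; this asymmetry is why algorithms can
occasionally trail the baseline when new annotations concentrate on
already-annotated genes.

## Temporal-holdout evaluation

Methods are trained on an earlier annotation snapshot and judged by how
many predicted negatives gain the annotation in a later snapshot. An IEA
annotation gained at validation time counts as a false negative by
default (extra stringency; switchable). Only terms with 3–300 training
annotations and at least one new validation annotation are evaluated —
below 3 no method has signal, above 300 terms are so general that
negatives are uninteresting, and without new annotations no error is
observable. False-negative counts are sampled over a grid of negative-set
sizes (100/200/500/1000/2000/3000 by default; a genome-fraction grid
from 0.1% to 20% is provided for organism-scale summaries), averaged per
branch, and optionally split into the specificity buckets 3–10, 11–30,
31–100 and 101–300 training annotations.

Curves are summarised by the trapezoid area under the false-negative
curve, anchored at the origin (predicting nothing gives no errors),
relative to the random baseline's area: summing areas before dividing
weights general terms more, dividing per term first weights every term
equally. Methods that emit a single fixed-size set appear as one point;
their baseline comparison is computed at that same size, since comparing
a point's area against a curve integrated over a different size range
would be meaningless. The equal-positives error rate sets $n$ to each
term's positive count and totals errors over terms. Averages across terms
and across random replicates may be fractional.

For golden sets — terms whose positives *and* negatives are exhaustively
known — the package scores genes by stratified cross-validation: each
held-out gene's training annotations to the gold term **and its
descendants** are removed (removing only the term itself would leave its
children implying it back), the matrix and conditional probabilities are
rebuilt, and held-out genes are scored. Genes left with no annotations
after masking receive score 0, the most negative-looking value, since
nothing links them to the term. The ROC treats the negative class as the
class of interest; tied scores share one threshold, so constant scores
give exactly AUC 0.5 and the AUC is invariant under strictly monotone
score transforms.

## The synthetic benchmark

`generate_synthetic()` emulates the statistical structure the selectors
exploit — *mutually exclusive functions are never co-annotated* — at a
size where every method runs in seconds:

- Three branches of 60 terms each, layered to depth 4; every non-root
  term has a primary `is_a` parent one level up, with occasional extra
  same-subtree parents (20%, of which 30% `part_of`) so the graph is a
  proper multi-parent DAG. Subtrees never cross, which keeps the planted
  modules disjoint.
- Three function modules occupy distinct subtrees under the BP root.
  Each gene belongs to one module (80% of genes, uniformly) or to the
  background (20%). A module gene carries each term of its module with
  probability 0.6 — strong but imperfect co-occurrence — plus one or a
  few background annotations in MF/CC shared across all genes, so
  conditional probabilities are not trivially 0/1. Background genes
  annotate only non-module terms.
- Evidence codes are IEA with probability 0.3, mirroring a realistic
  electronic-annotation share.
- The t1 snapshot is the complete truth; t0 hides 20% of the module
  annotation records. The holdout hides *records*, never a gene's entire
  module signal: a gene with no visible annotation for its function at
  t0 is unlearnable for any annotation-based selector, and real genomes'
  partially annotated genes are the population these methods score.
- The ground-truth negatives of every module term are the genes of the
  other modules. Background genes are left unlabeled, as in real data.

The golden set labels the entire universe for one designated term: the
most-annotated direct child of the first module's anchor, ties broken by
identifier. A mid-depth term is designated deliberately: under the
masking rule above, holding out a module's topmost term would remove the
whole module from a held-out gene — leaving nothing to score with —
whereas a mid-depth term keeps its correlated non-descendant module
siblings in place, which is exactly the situation of a real, exhaustively
verified mid-ontology term.

What the generator does **not** emulate: realistic GO topology statistics
(term fan-out, depth distribution), annotation-count power laws,
homology-correlated annotation bias, or curation artefacts. Passing the
synthetic benchmark therefore demonstrates correct mechanics and the
expected qualitative ordering of methods under planted exclusivity — not
performance magnitudes on real genomes.

## Numerical and implementation choices

- **LDA**: batch variational Bayes with symmetric priors
  $\alpha = 1/t$, $\eta = 0.01$, at most 100 EM sweeps, converged when
  the mean absolute change of the expected topic-word distributions
  falls below $10^{-4}$ (per-document inner loop capped at 50 updates,
  tolerance $10^{-5}$). The topic-word initialisation is drawn
  Gamma(100, 100) from the supplied seed, and the fit is bit-reproducible
  given that seed. Topic models have no canonical bit-exact reference, so
  NETL's contract is statistical (cluster recovery, method ordering)
  rather than numeric equality.
- **Evidence of inferred ancestors**: propagation assigns an inferred
  record the code of its contributing descendants, preferring any
  non-IEA code (ties alphabetical). This makes IEA filtering commute
  with propagation for every term that has curated support.
- **Edge relations**: `is_a` and `part_of` both propagate by default and
  the set is configurable, since curated ontologies guarantee the true
  path rule across both.
- **Determinism**: all orderings are sorted (genes, terms), all ranking
  ties break by identifier, and every stochastic step takes a seed.
- **Degenerate inputs**: terms with no positives raise an error when
  scored; $n$ larger than the candidate pool returns all candidates with
  a warning; grid points beyond the pool are clamped and flagged;
  zero-area baselines are skipped with a warning in per-term mode; an
  empty sibling rule falls back as published.
- **Problem sizes**: the test suite and the acceptance script run the
  benchmark at 500 genes × 180 terms over five seeds with the size grid
  25–200, and smaller 150-gene datasets for plumbing tests — sizes at
  which the full pipeline, LDA included, completes in seconds while the
  method ordering is stable across seeds.

## Known limitations

- Conditional probabilities are estimated without smoothing; very rare
  terms yield coarse probabilities (0, 1/2, 1), which is why evaluation
  excludes terms with fewer than 3 annotations.
- The dense per-column SNOB scoring is economical up to tens of
  thousands of terms but the full $P$ matrix should not be densified for
  genome-scale ontologies.
- Cross-organism transfer of co-annotation probabilities and
  non-GO feature data are out of scope; so is obsolete-term remapping
  (`replaced_by`) in the OBO parser.
- The golden-set cross-validation masks only GO annotations; with real
  feature-based classifiers, information leakage between folds would
  need separate treatment.
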