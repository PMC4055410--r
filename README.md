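# GOnegatives

Selection and evaluation of **negative examples** for protein function
from Gene Ontology (GO) annotation data.

## The problem

Supervised protein function prediction needs genes that do *not* carry a
function, but GO records essentially only positive annotations: a gene
lacking an annotation may be a true negative or simply unstudied. This is
a positive-unlabeled (PU) learning problem. GOnegatives implements the
*passive* first step of 2-step PU learning — choosing reliable negative
examples from GO data alone — together with a temporal-holdout framework
that measures how often chosen negatives later turn out to be positives.

## Methods implemented

- **SNOB** (Selection of Negatives through Observed Bias). From the binary
  gene × term annotation matrix **A** (propagated by the true path rule,
  IEA annotations included, all three branches jointly), the empirical
  conditional probability of seeing term *a* given term *m* is

      p(a | m) = n_{m,a} / n_m

  where `n_{m,a}` counts genes annotated to both terms and `n_m` genes
  annotated to *m*. A gene's negativity score for *a* is the average of
  `p(a | m)` over its annotations — the *a* column of **W**⁻¹**A P**,
  with **W** the diagonal matrix of per-gene annotation counts and
  **P** the conditional probability matrix. The *n* lowest-scoring
  non-positive genes are the negatives.
- **ALBNeg** — SNOB's predecessor: genes whose most-specific curated
  annotations have zero conditional probability of co-occurring with the
  target term (fixed-size output).
- **NETL** (Negative Examples from Topic Likelihood). Each gene is a
  "document" whose "words" are its GO annotations; a latent Dirichlet
  allocation model with one topic per annotated direct child of the three
  branch roots yields a posterior topic distribution θ per gene.
  Candidates are ranked by the distributional overlap score
  DOS(p, q) = Σᵢ min(pᵢ, qᵢ) against the positive-class average, lowest
  overlap first.
- **Baselines**: PU-Rocchio (tf-idf prototypes, score =
  UnlabeledSimilarity − PositiveSimilarity), 1-DNF (genes free of
  positively enriched terms), the sibling heuristic (annotated to a parent
  but not the term), and a 100-replicate uniform random sampler from the
  full gene universe.
- **Evaluation**: false-negative curves over negative-set sizes, branch
  averages and specificity buckets, trapezoid area ratios against the
  random baseline (annotation-weighted or per-term), the error rate when
  predicting as many negatives as positives, and golden-set ROC/AUC via
  cross-validation with the gold term (and its descendants) masked from
  held-out genes.
- **Negative propagation**: by the inverse true path rule, a negative for
  a term is a negative for all of its descendants
  (`propagate_negatives_down()`).

A synthetic-data generator plants mutually exclusive function modules in
a three-branch DAG with two temporal snapshots and known true negatives,
so the whole pipeline is testable end to end.

## Worked example

```r
library(GOnegatives)

gen <- generate_synthetic(synthetic_spec(seed = 1))
ont <- gen$ontology
ann <- propagate_annotations(gen$train, ont)
am  <- build_annotation_matrix(ann, ont)
#> annotation_matrix: 500 genes x 180 terms, 7458 ones
cp  <- conditional_probability(am)

term <- names(gen$truth$modules)[1]       # a planted function module
ranking <- snob_rank(am, cp, term, n = 10)
head(ranking, 5)
#>   rank  gene      score
#> 1    1 G0005 0.03674374
#> 2    2 G0185 0.05144124
#> 3    3 G0382 0.05847791
#> 4    4 G0274 0.06430155
#> 5    5 G0102 0.06729554

holdout <- holdout_pair(ann, gen$validate, ont)
count_false_negatives(ranking$gene, term, holdout)
#> [1] 0

methods <- list(snob = method_snob(am, cp),
                random = method_random(ann, reps = 100, seed = 1))
ev <- evaluate_methods(methods, holdout, grid = c(25, 50, 100, 150, 200))
ev$ratios
#>   method branch area_ratio
#> 1   snob     BP          0
#> 2 random     BP          1
```

The scores are average co-annotation probabilities: G0005 carries
annotations that essentially never co-occur with the target term, so it
is the most confident negative. None of the ten predicted negatives gains
the annotation in the later snapshot (zero false negatives), and over the
eligible terms of the BP branch SNOB's false-negative curve has zero area
relative to the random baseline's (an area ratio of 1 would mean no
better than random).

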