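# Temporal-holdout evaluation: train on an early annotation snapshot,
# count as errors the predicted negatives that gain the annotation by a
# later snapshot. False-negative curves, branch averages, area ratios
# against the random baseline, equal-positives error rates, and golden-set
# ROC via cross-validated term masking.

#' Standard negative-set size grids
#'
#' `DEFAULT_FN_GRID` is the absolute sampling grid used for per-branch
#' false-negative curves; `GENOME_FRACTION_GRID` is the genome-relative
#' grid (0.1%, 0.5%, 1%, 2.5%, 5%, 10%, 15%, 20%) multiplied by the genome
#' size for organism-level summaries.
#'
#' @export
DEFAULT_FN_GRID <- c(100, 200, 500, 1000, 2000, 3000)

#' @rdname DEFAULT_FN_GRID
#' @export
GENOME_FRACTION_GRID <- c(0.001, 0.005, 0.01, 0.025, 0.05, 0.10, 0.15, 0.20)

#' Pair two annotation snapshots for temporal-holdout evaluation
#'
#' @param train the earlier [annotation_set()] (t0).
#' @param validate the later [annotation_set()] (t1).
#' @param ont the shared [go_ontology()].
#' @param include_iea_validation count an IEA annotation gained at t1 as
#'   evidence of false negativity? (Extra stringency; on by default.)
#' @return An object of class `holdout_pair` with both sets propagated.
#' @export
holdout_pair <- function(train, validate, ont,
                         include_iea_validation = TRUE) {
  if (identical(train$snapshot_label, validate$snapshot_label))
    warning("train and validation snapshots carry the same label")
  structure(list(train = propagate_annotations(train, ont),
                 validate = propagate_annotations(validate, ont),
                 ontology = ont,
                 include_iea_validation = include_iea_validation),
            class = "holdout_pair")
}

#' Newly annotated genes of a term under the holdout
#'
#' Validation-snapshot positives (IEA counted per the holdout flag) that
#' were not training-snapshot positives (IEA-inclusive). These are the only
#' observable false negatives for the term.
#'
#' @param holdout a [holdout_pair()].
#' @param term term identifier.
#' @return Sorted character vector of genes.
#' @export
new_positive_genes <- function(holdout, term) {
  v <- positive_genes(holdout$validate, term, holdout$include_iea_validation)
  t0 <- positive_genes(holdout$train, term, include_iea = TRUE)
  setdiff(v, t0)
}

#' Count false negatives in a predicted negative set
#'
#' A predicted negative that carries a (propagated) positive annotation to
#' the term in the validation snapshot is an error.
#'
#' @param negatives character vector of predicted negative genes (disjoint
#'   from the training positives).
#' @param term term identifier.
#' @param holdout a [holdout_pair()].
#' @return Integer count.
#' @export
count_false_negatives <- function(negatives, term, holdout) {
  v <- positive_genes(holdout$validate, term, holdout$include_iea_validation)
  sum(negatives %in% v)
}

#' Terms eligible for evaluation
#'
#' Keeps, per branch, the terms with a training annotation count between
#' `min_ann` and `max_ann` (3 and 300 by default) and at least one new
#' validation annotation — categories without new annotations give no
#' observable errors.
#'
#' @param holdout a [holdout_pair()].
#' @param min_ann,max_ann inclusive bounds on the training count.
#' @return Named list of sorted term vectors over `c("BP", "MF", "CC")`.
#' @export
eligible_terms <- function(holdout, min_ann = 3, max_ann = 300) {
  counts <- table(holdout$train$records$term)
  cand <- names(counts)[counts >= min_ann & counts <= max_ann]
  keep <- cand[vapply(cand, function(t)
    length(new_positive_genes(holdout, t)) > 0, logical(1))]
  ont <- holdout$ontology
  lapply(stats::setNames(nm = c("BP", "MF", "CC")), function(b)
    sort(keep[ont$branch[keep] == b]))
}

#' Wrap a selection algorithm as an evaluable method
#'
#' A `negative_method` bundles a label, a type and a `rank(term, n)`
#' closure. `type = "ranking"` methods return the top-`n` genes of a nested
#' ranking; `"point"` methods ignore `n` and return their fixed set;
#' `"stochastic"` methods return a list of replicate gene vectors whose
#' false-negative counts are averaged.
#'
#' @param label method name.
#' @param type one of `"ranking"`, `"point"`, `"stochastic"`.
#' @param rank_fun function of `(term, n)`.
#' @return A `negative_method` object.
#' @export
negative_method <- function(label, type = c("ranking", "point", "stochastic"),
                            rank_fun) {
  structure(list(label = label, type = match.arg(type), rank = rank_fun),
            class = "negative_method")
}

#' Ready-made method wrappers
#'
#' Constructors binding each selection algorithm to training data, for use
#' with [fn_curve()] and friends. Positivity of the target term is
#' IEA-inclusive except for the sibling heuristic.
#'
#' @param am training [annotation_matrix()] (IEA included).
#' @param cp matching [conditional_probability()].
#' @param am_noiea,cp_noiea matrix and probabilities built with
#'   `include_iea = FALSE`, for ALBNeg.
#' @param ont the [go_ontology()].
#' @param ann training [annotation_set()].
#' @param model an [fit_lda()] result.
#' @param corpus a [tfidf_corpus()].
#' @param universe full gene universe for the random baseline.
#' @param reps,seed random-baseline replication controls.
#' @return A [negative_method()].
#' @name method_wrappers
NULL

.term_positives <- function(am, term)
  am$genes[as.numeric(am$A[, term]) > 0]

#' @rdname method_wrappers
#' @export
method_snob <- function(am, cp) {
  negative_method("snob", "ranking", function(term, n)
    snob_rank(am, cp, term, n)$gene)
}

#' @rdname method_wrappers
#' @export
method_albneg <- function(am_noiea, cp_noiea, ont) {
  negative_method("albneg", "point", function(term, n)
    albneg_negatives(am_noiea, cp_noiea, ont, term))
}

#' @rdname method_wrappers
#' @export
method_netl <- function(model, am) {
  negative_method("netl", "ranking", function(term, n)
    netl_rank(model, .term_positives(am, term), n, term = term)$gene)
}

#' @rdname method_wrappers
#' @export
method_rocchio <- function(corpus, am) {
  negative_method("rocchio", "ranking", function(term, n) {
    pos <- .term_positives(am, term)
    s <- rocchio_scores(corpus, pos)
    rank_negatives(s, pos, n, decreasing = TRUE, method = "rocchio",
                   term = term)$gene
  })
}

#' @rdname method_wrappers
#' @export
method_one_dnf <- function(am) {
  negative_method("one_dnf", "point", function(term, n)
    one_dnf_negatives(am, term))
}

#' @rdname method_wrappers
#' @export
method_sibling <- function(ann, ont) {
  negative_method("sibling", "point", function(term, n)
    as.character(sibling_negatives(ann, ont, term)))
}

#' @rdname method_wrappers
#' @export
method_random <- function(ann, universe = ann$gene_universe, reps = 100,
                          seed = NULL) {
  force(universe); force(reps)
  negative_method("random", "stochastic", function(term, n) {
    pos <- positive_genes(ann, term, include_iea = TRUE)
    n <- min(n, length(setdiff(universe, pos)))
    # distinct but reproducible stream per term
    s <- if (is.null(seed)) NULL else
      (seed + sum(utf8ToInt(term))) %% .Machine$integer.max
    random_negatives(universe, pos, n, reps = reps, seed = s)
  })
}

#' False-negative curve for one term
#'
#' For each negative-set size in `grid`, selects that many negatives with
#' the method and counts the false negatives under the holdout. Ranking
#' methods are ranked once and truncated (so the curve is monotone);
#' stochastic methods average counts over replicates (fractional values);
#' point methods yield a single point at their fixed size. Grid values
#' exceeding the candidate pool are clamped and flagged.
#'
#' @param method a [negative_method()].
#' @param holdout a [holdout_pair()].
#' @param term term identifier.
#' @param grid negative-set sizes; the default follows the standard
#'   100/200/500/1000/2000/3000 sampling grid. For genome-relative grids
#'   multiply [GENOME_FRACTION_GRID] by the genome size.
#' @return An `fn_curve`: data.frame with columns `size`, `fn`; attributes
#'   `term`, `method`, `new_annotation_count`, `clamped`.
#' @export
fn_curve <- function(method, holdout, term, grid = DEFAULT_FN_GRID) {
  grid <- sort(unique(grid))
  newpos <- new_positive_genes(holdout, term)
  clamped <- logical(0)
  if (method$type == "point") {
    set <- method$rank(term, NA)
    sizes <- length(set)
    fns <- count_false_negatives(set, term, holdout)
  } else if (method$type == "stochastic") {
    sets <- method$rank(term, max(grid))
    avail <- length(sets[[1]])
    sizes <- pmin(grid, avail)
    clamped <- grid > avail
    fns <- vapply(sizes, function(s)
      mean(vapply(sets, function(g)
        count_false_negatives(g[seq_len(s)], term, holdout), numeric(1))),
      numeric(1))
  } else {
    full <- suppressWarnings(method$rank(term, max(grid)))
    sizes <- pmin(grid, length(full))
    clamped <- grid > length(full)
    fns <- vapply(sizes, function(s)
      count_false_negatives(full[seq_len(s)], term, holdout), numeric(1))
  }
  structure(data.frame(size = sizes, fn = fns),
            class = c("fn_curve", "data.frame"),
            term = term, method = method$label,
            new_annotation_count = length(newpos),
            clamped = any(clamped))
}

#' Average false-negative curves across terms
#'
#' Unweighted mean of the per-term curves. Ranking/stochastic curves must
#' share the size grid; point-method curves (one row each, varying sizes)
#' are averaged in both coordinates, matching how single-size heuristics
#' are displayed as one averaged point.
#'
#' @param curves list of `fn_curve` objects (typically one per eligible
#'   term of a branch).
#' @return An `fn_curve` with attribute `term = "average"`.
#' @export
branch_average <- function(curves) {
  stopifnot(length(curves) > 0)
  nrows <- vapply(curves, nrow, integer(1))
  if (all(nrows == 1L)) {
    out <- data.frame(size = mean(vapply(curves, function(cv) cv$size[1],
                                         numeric(1))),
                      fn = mean(vapply(curves, function(cv) cv$fn[1],
                                       numeric(1))))
  } else {
    grids <- unique(lapply(curves, `[[`, "size"))
    if (length(grids) != 1)
      stop("curves use different size grids; cannot average")
    out <- data.frame(size = grids[[1]],
                      fn = rowMeans(sapply(curves, `[[`, "fn")))
  }
  structure(out, class = c("fn_curve", "data.frame"), term = "average",
            method = attr(curves[[1]], "method"),
            new_annotation_count = mean(vapply(curves, attr, numeric(1),
                                               "new_annotation_count")))
}

#' Split curves into specificity buckets
#'
#' Buckets terms by their training annotation count into the standard
#' specificity classes 3-10, 11-30, 31-100 and 101-300 and averages the
#' curves within each bucket.
#'
#' @param curves named list of `fn_curve` objects (names = terms).
#' @param t0_counts named integer vector of training annotation counts.
#' @return Named list of averaged `fn_curve`s (empty buckets dropped).
#' @export
specificity_buckets <- function(curves, t0_counts) {
  lower <- c(3, 11, 31, 101)
  upper <- c(10, 30, 100, 300)
  labels <- c("3-10", "11-30", "31-100", "101-300")
  cnt <- t0_counts[names(curves)]
  out <- list()
  for (i in seq_along(labels)) {
    sel <- names(curves)[cnt >= lower[i] & cnt <= upper[i]]
    if (length(sel) > 0) out[[labels[i]]] <- branch_average(curves[sel])
  }
  out
}

#' Area under a false-negative curve
#'
#' Trapezoid rule with the curve anchored at the origin (predicting no
#' negatives gives no errors).
#'
#' @param curve an `fn_curve`.
#' @return Scalar area.
#' @export
area_under_fn_curve <- function(curve) {
  x <- c(0, curve$size)
  y <- c(0, curve$fn)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Area ratio of a method against the random baseline
#'
#' `"weighted"` mode sums the per-term areas for the method and for the
#' baseline before dividing, so heavily annotated categories dominate;
#' `"per-term"` mode divides per term first and averages the ratios, so
#' every category contributes equally. Terms whose baseline area is zero
#' are skipped with a warning in per-term mode.
#'
#' @param curves an `fn_curve` or named list of them (names = terms).
#' @param baselines matching baseline curve(s).
#' @param mode `"weighted"` or `"per-term"`.
#' @return Scalar ratio (1 means indistinguishable from random; smaller is
#'   better).
#' @export
area_ratio <- function(curves, baselines, mode = c("weighted", "per-term")) {
  mode <- match.arg(mode)
  if (inherits(curves, "fn_curve")) curves <- list(curves)
  if (inherits(baselines, "fn_curve")) baselines <- list(baselines)
  stopifnot(length(curves) == length(baselines))
  a <- vapply(curves, area_under_fn_curve, numeric(1))
  b <- vapply(baselines, area_under_fn_curve, numeric(1))
  if (mode == "weighted") {
    if (sum(b) == 0) {
      warning("baseline total area is zero")
      return(if (sum(a) == 0) 0 else Inf)
    }
    sum(a) / sum(b)
  } else {
    ok <- b > 0
    if (any(!ok)) warning(sum(!ok), " term(s) with zero baseline area skipped")
    if (!any(ok)) { warning("no terms with positive baseline area"); return(0) }
    mean(a[ok] / b[ok])
  }
}

#' Error rate when predicting as many negatives as positives
#'
#' For each term the negative-set size is set to its training positive
#' count; false negatives and predicted negatives are totalled over the
#' terms and the ratio returned.
#'
#' @param method a [negative_method()].
#' @param holdout a [holdout_pair()].
#' @param terms character vector of terms (typically one branch's eligible
#'   terms).
#' @return Scalar rate in `[0, 1]` with attribute `per_term` (data.frame
#'   term/size/fn).
#' @export
equal_positives_fn_rate <- function(method, holdout, terms) {
  total_fn <- 0
  total_n <- 0
  rows <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    term <- terms[i]
    n <- length(positive_genes(holdout$train, term, include_iea = TRUE))
    if (method$type == "point") {
      set <- method$rank(term, NA)
      fn <- count_false_negatives(set, term, holdout)
      size <- length(set)
    } else if (method$type == "stochastic") {
      sets <- method$rank(term, n)
      fn <- mean(vapply(sets, count_false_negatives, numeric(1),
                        term, holdout))
      size <- length(sets[[1]])
    } else {
      set <- suppressWarnings(method$rank(term, n))
      fn <- count_false_negatives(set, term, holdout)
      size <- length(set)
    }
    total_fn <- total_fn + fn
    total_n <- total_n + size
    rows[[i]] <- data.frame(term = term, size = size, fn = fn)
  }
  structure(if (total_n == 0) 0 else total_fn / total_n,
            per_term = do.call(rbind, rows))
}

#' Evaluate methods on a holdout: curves and area ratios
#'
#' Runs [fn_curve()] for every method over the eligible terms of each
#' branch and summarises each method's area ratio against the random
#' baseline.
#'
#' @param methods named list of [negative_method()]s; must include one
#'   labelled `"random"` to serve as the baseline.
#' @param holdout a [holdout_pair()].
#' @param grid negative-set size grid.
#' @param terms optional named list (per branch) overriding
#'   [eligible_terms()].
#' @param mode area-ratio mode, see [area_ratio()].
#' @return List with `curves` (method -> branch -> term -> `fn_curve`),
#'   `averages` (method -> branch averaged curve) and `ratios` (data.frame
#'   method/branch/area_ratio).
#' @export
evaluate_methods <- function(methods, holdout, grid = DEFAULT_FN_GRID,
                             terms = NULL, mode = "weighted") {
  if (is.null(names(methods)))
    names(methods) <- vapply(methods, `[[`, character(1), "label")
  if (!"random" %in% names(methods))
    stop("methods must include the random baseline")
  if (is.null(terms)) terms <- eligible_terms(holdout)
  terms <- terms[vapply(terms, length, integer(1)) > 0]
  if (length(unlist(terms)) == 0) stop("no eligible terms to evaluate")

  curves <- lapply(methods, function(m)
    lapply(terms, function(ts)
      stats::setNames(lapply(ts, function(t)
        fn_curve(m, holdout, t, grid)), ts)))
  averages <- lapply(curves, function(by_branch)
    lapply(by_branch, branch_average))
  # a point method is compared against the baseline sampled at the point's
  # own size, not at the shared grid
  ratios <- do.call(rbind, lapply(names(methods), function(mn) {
    do.call(rbind, lapply(names(terms), function(b) {
      mc <- curves[[mn]][[b]]
      bc <- if (methods[[mn]]$type == "point") {
        stats::setNames(lapply(names(mc), function(t)
          fn_curve(methods[["random"]], holdout, t,
                   grid = mc[[t]]$size)), names(mc))
      } else curves[["random"]][[b]]
      data.frame(method = mn, branch = b,
                 area_ratio = area_ratio(mc, bc, mode = mode))
    }))
  }))
  list(curves = curves, averages = averages, ratios = ratios)
}

#' ROC curve for negativity scores against gold labels
#'
#' The negative class is the class of interest: sweeping a threshold over
#' the scores, a gene is predicted negative when its score is at or below
#' the threshold; the true positive rate is the fraction of gold negatives
#' recovered and the false positive rate the fraction of gold positives
#' wrongly asserted negative. Ties share a threshold, so constant scores
#' give exactly AUC 0.5, and the AUC is invariant under strictly monotone
#' score transforms.
#'
#' @param scores named numeric negativity scores (low = more negative).
#' @param gold_positives,gold_negatives disjoint gene sets covering the
#'   scored genes of interest; genes outside both are dropped.
#' @return List with `points` (data.frame fpr/tpr including the (0,0) and
#'   (1,1) anchors) and trapezoid `auc`.
#' @export
golden_set_roc <- function(scores, gold_positives, gold_negatives) {
  if (length(intersect(gold_positives, gold_negatives)) > 0)
    stop("gold classes overlap")
  genes <- intersect(names(scores), c(gold_positives, gold_negatives))
  if (length(genes) == 0) stop("no scored genes carry gold labels")
  s <- scores[genes]
  is_neg <- genes %in% gold_negatives
  n_neg <- sum(is_neg)
  n_pos <- sum(!is_neg)
  if (n_neg == 0 || n_pos == 0) stop("both gold classes must be non-empty")
  ord <- order(s)
  s <- s[ord]; is_neg <- is_neg[ord]
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(is_neg)[last_of_group] / n_neg)
  fpr <- c(0, cumsum(!is_neg)[last_of_group] / n_pos)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Cross-validated SNOB scores with gold-term masking
#'
#' Stratified k-fold scoring for golden-set evaluation: in each fold the
#' held-out genes' training annotations to the gold term and all its
#' descendants are removed, the annotation matrix and conditional
#' probabilities are rebuilt from the remaining records, and the held-out
#' genes are scored for the gold term. Held-out genes left with no
#' annotations after masking receive score 0 (nothing links them to the
#' term). Folds are stratified by training positivity so each fold keeps
#' positives; if the positives cannot cover the folds the fold count is
#' reduced with a warning.
#'
#' @param ann training [annotation_set()].
#' @param ont the [go_ontology()].
#' @param term the gold term.
#' @param genes genes to score (the gold universe).
#' @param folds number of folds.
#' @param seed integer seed controlling fold assignment.
#' @param include_iea build the training matrix with IEA records?
#' @return Named numeric vector of out-of-fold scores over `genes`.
#' @export
cv_masked_snob_scores <- function(ann, ont, term, genes, folds = 5,
                                  seed = 1L, include_iea = TRUE) {
  ann <- propagate_annotations(ann, ont)
  masked_terms <- c(term, term_descendants(ont, term))
  pos <- intersect(genes, positive_genes(ann, term, include_iea = TRUE))
  if (length(pos) < folds) {
    folds <- max(2L, length(pos))
    warning("too few positives for the requested folds; using ", folds)
  }
  set.seed(seed)
  fold_of <- stats::setNames(integer(length(genes)), genes)
  fold_of[sample(pos)] <- rep_len(seq_len(folds), length(pos))
  rest <- setdiff(genes, pos)
  fold_of[sample(rest)] <- rep_len(seq_len(folds), length(rest))

  out <- stats::setNames(rep(0, length(genes)), genes)
  for (f in seq_len(folds)) {
    held <- genes[fold_of == f]
    rec <- ann$records
    drop <- rec$gene %in% held & rec$term %in% masked_terms
    rec <- rec[!drop, , drop = FALSE]
    train <- annotation_set(rec, snapshot_label = ann$snapshot_label,
                            gene_universe = ann$gene_universe,
                            propagated = TRUE)
    am <- build_annotation_matrix(train, ont, include_iea = include_iea)
    cp <- conditional_probability(am)
    s <- snob_scores(am, cp, term)
    scored <- intersect(held, names(s))
    out[scored] <- s[scored]
  }
  out
}
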