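test_that("count_false_negatives intersects negatives with validation positives", {
  counts <- c("GO:0000002" = 4)
  ho <- flat_holdout(counts, c("GO:0000002" = 2))
  negs <- c("GO:0000002_new1", "GO:0000002_new2", "u1", "u2", "u3")
  expect_equal(count_false_negatives(negs, "GO:0000002", ho), 2)
  expect_equal(count_false_negatives(character(0), "GO:0000002", ho), 0)
})

test_that("IEA validation annotations count as errors only when requested", {
  terms <- c("GO:0000001", "GO:0000002")
  ont <- go_ontology(terms,
                     data.frame(child = "GO:0000002",
                                parent = "GO:0000001", relation = "is_a"),
                     setNames(c("BP", "BP"), terms))
  t0 <- annotation_set(data.frame(gene = "a", term = "GO:0000002",
                                  evidence = "EXP"), "t0",
                       gene_universe = c("a", "b"))
  t1 <- annotation_set(data.frame(gene = c("a", "b"),
                                  term = "GO:0000002",
                                  evidence = c("EXP", "IEA")), "t1",
                       gene_universe = c("a", "b"))
  strict <- holdout_pair(t0, t1, ont, include_iea_validation = TRUE)
  lax <- holdout_pair(t0, t1, ont, include_iea_validation = FALSE)
  expect_equal(count_false_negatives("b", "GO:0000002", strict), 1)
  expect_equal(count_false_negatives("b", "GO:0000002", lax), 0)
})

test_that("eligibility honours the 3-300 count window and the new-annotation rule", {
  counts <- c("GO:0000002" = 2, "GO:0000003" = 3, "GO:0000004" = 10,
              "GO:0000005" = 10, "GO:0000006" = 300, "GO:0000007" = 301)
  new <- c("GO:0000002" = 1, "GO:0000003" = 1, "GO:0000004" = 1,
           "GO:0000005" = 0, "GO:0000006" = 1, "GO:0000007" = 1)
  ho <- flat_holdout(counts, new)
  et <- eligible_terms(ho)
  expect_equal(et$BP, c("GO:0000003", "GO:0000004", "GO:0000006"))
  expect_length(et$MF, 0)
})

test_that("fn curves are monotone for nested rankings and clamp to the pool", {
  counts <- c("GO:0000002" = 5)
  ho <- flat_holdout(counts, c("GO:0000002" = 3))
  # a fixed ranking method: worst genes (future positives) first
  worst <- negative_method("worst", "ranking", function(term, n) {
    pool <- c(paste0(term, "_new", 1:3), paste0("u", 1:17))
    pool[seq_len(min(n, length(pool)))]
  })
  cv <- fn_curve(worst, ho, "GO:0000002", grid = c(1, 2, 5, 100))
  expect_equal(cv$fn, c(1, 2, 3, 3))
  expect_true(all(diff(cv$fn) >= 0))
  expect_equal(cv$size[4], 20)          # clamped to candidate pool
  expect_true(attr(cv, "clamped"))
  expect_equal(attr(cv, "new_annotation_count"), 3)
  # perfect method: all-zero curve
  perfect <- negative_method("perfect", "ranking", function(term, n)
    paste0("u", seq_len(min(n, 17))))
  expect_equal(fn_curve(perfect, ho, "GO:0000002", c(1, 5))$fn, c(0, 0))
})

test_that("branch averages mean matching grids and average point methods twice", {
  mk <- function(sizes, fns, term = "t") {
    structure(data.frame(size = sizes, fn = fns),
              class = c("fn_curve", "data.frame"), term = term,
              method = "m", new_annotation_count = 1)
  }
  avg <- branch_average(list(mk(c(10, 20), c(0, 0)),
                             mk(c(10, 20), c(2, 4))))
  expect_equal(avg$fn, c(1, 2))
  expect_equal(branch_average(list(mk(c(10, 20), c(0, 2))))$fn, c(0, 2))
  # single-point curves of differing sizes average in both coordinates
  pt <- branch_average(list(mk(10, 1), mk(30, 3)))
  expect_equal(pt$size, 20)
  expect_equal(pt$fn, 2)
  expect_error(branch_average(list(mk(c(1, 2), c(0, 0)),
                                   mk(c(1, 3), c(0, 0)))), "grids")
})

test_that("specificity buckets split on the 10/11, 30/31 and 100/101 boundaries", {
  mk <- function(term) structure(data.frame(size = c(5, 10), fn = c(0, 1)),
                                 class = c("fn_curve", "data.frame"),
                                 term = term, method = "m",
                                 new_annotation_count = 1)
  curves <- setNames(lapply(letters[1:8], mk), letters[1:8])
  cnt <- setNames(c(3, 10, 11, 30, 31, 100, 101, 300), letters[1:8])
  b <- specificity_buckets(curves, cnt)
  expect_named(b, c("3-10", "11-30", "31-100", "101-300"))
})

test_that("area ratios behave as trapezoid areas anchored at the origin", {
  mk <- function(sizes, fns)
    structure(data.frame(size = sizes, fn = fns),
              class = c("fn_curve", "data.frame"), term = "t",
              method = "m", new_annotation_count = 1)
  base <- mk(c(10, 20), c(2, 4))
  expect_equal(area_under_fn_curve(base), 10 * 1 + 10 * 3)  # trapezoids
  expect_equal(area_ratio(base, base), 1)
  expect_equal(area_ratio(mk(c(10, 20), c(0, 0)), base), 0)
  # two-term hand computation in both modes
  a1 <- mk(c(10, 20), c(1, 1)); b1 <- mk(c(10, 20), c(2, 2))
  a2 <- mk(c(10, 20), c(0, 2)); b2 <- mk(c(10, 20), c(2, 4))
  # areas: a1 = 5+10 = 15, b1 = 10+20 = 30, a2 = 0+10 = 10, b2 = 40
  expect_equal(area_ratio(list(t1 = a1, t2 = a2), list(t1 = b1, t2 = b2),
                          mode = "weighted"), (15 + 10) / (30 + 40))
  expect_equal(area_ratio(list(t1 = a1, t2 = a2), list(t1 = b1, t2 = b2),
                          mode = "per-term"), mean(c(15 / 30, 10 / 40)))
  # a zero-area baseline term is skipped; with none left the ratio is 0
  expect_warning(
    r <- area_ratio(list(t1 = a1, t2 = a2),
                    list(t1 = b1, t2 = mk(c(10, 20), c(0, 0))),
                    mode = "per-term"), "skipped")
  expect_equal(r, 15 / 30)
  expect_equal(suppressWarnings(
    area_ratio(a1, mk(c(10, 20), c(0, 0)), mode = "per-term")), 0)
})

test_that("equal-positives error rate spans the perfect and worst cases", {
  counts <- c("GO:0000002" = 3)
  ho <- flat_holdout(counts, c("GO:0000002" = 3))
  perfect <- negative_method("perfect", "ranking", function(term, n)
    paste0("u", seq_len(min(n, 17))))
  worst <- negative_method("worst", "ranking", function(term, n)
    paste0(term, "_new", seq_len(min(n, 3))))
  expect_equal(as.numeric(
    equal_positives_fn_rate(perfect, ho, "GO:0000002")), 0)
  expect_equal(as.numeric(
    equal_positives_fn_rate(worst, ho, "GO:0000002")), 1)
  pt <- attr(equal_positives_fn_rate(worst, ho, "GO:0000002"), "per_term")
  expect_equal(pt$size, 3)  # n tied to the t0 positive count
})

test_that("golden-set ROC spans separation, ties and monotone invariance", {
  scores <- c(n1 = 0.1, n2 = 0.2, p1 = 0.8, p2 = 0.9)
  roc <- golden_set_roc(scores, gold_positives = c("p1", "p2"),
                        gold_negatives = c("n1", "n2"))
  expect_equal(roc$auc, 1)
  # constant scores: exactly chance
  expect_equal(golden_set_roc(c(a = 1, b = 1, c = 1, d = 1),
                              c("a", "b"), c("c", "d"))$auc, 0.5)
  # strictly monotone transforms leave the AUC untouched
  set.seed(3)
  s <- setNames(runif(40), paste0("g", 1:40))
  pos <- paste0("g", 1:15); neg <- paste0("g", 16:40)
  a1 <- golden_set_roc(s, pos, neg)$auc
  a2 <- golden_set_roc(exp(3 * s) + 2, pos, neg)$auc
  expect_equal(a1, a2)
  expect_error(golden_set_roc(s, pos, c(neg, "g1")), "overlap")
})

test_that("ROC/AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  s <- setNames(c(rnorm(30, 0.4, 0.2), rnorm(30, 0.6, 0.2)),
                paste0("g", 1:60))
  neg <- paste0("g", 1:30); pos <- paste0("g", 31:60)
  ours <- golden_set_roc(s, pos, neg)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = factor(c(rep("neg", 30), rep("pos", 30))),
    predictor = unname(s), levels = c("pos", "neg"), direction = ">")))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("random scores give chance-level golden-set AUC on average", {
  aucs <- vapply(1:10, function(seed) {
    set.seed(seed)
    s <- setNames(runif(200), paste0("g", 1:200))
    golden_set_roc(s, paste0("g", 1:60), paste0("g", 61:200))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("cross-validated masked SNOB scoring separates the synthetic golden set", {
  gen <- generate_synthetic(small_spec())
  gs <- synthetic_golden_set(gen)
  ann <- propagate_annotations(gen$train, gen$ontology)
  sc <- cv_masked_snob_scores(ann, gen$ontology, gs$term,
                              genes = gen$train$gene_universe, seed = 2)
  roc <- golden_set_roc(sc, gs$gold_positives, gs$gold_negatives)
  expect_gt(roc$auc, 0.8)
  # out-of-fold scores exist for every gene
  expect_setequal(names(sc), gen$train$gene_universe)
})
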