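test_that("parse_obo loads terms and retained edges, skips obsolete, detects cycles", {
  path <- write_temp_obo(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: a",
    "namespace: biological_process", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: b",
    "namespace: biological_process", "is_a: GO:0000001",
    "relationship: part_of GO:0000002", "",
    "[Term]", "id: GO:0000009", "name: gone",
    "namespace: biological_process", "is_a: GO:0000001",
    "is_obsolete: true", ""))
  ont <- suppressWarnings(parse_obo(path))
  expect_setequal(ont$terms, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(nrow(ont$edges), 3)
  expect_equal(sort(ont$edges$relation), c("is_a", "is_a", "part_of"))
  expect_equal(unname(ont$roots["BP"]), "GO:0000001")

  # dropping part_of from the retained relations drops that edge
  ont2 <- parse_obo(path, relations = "is_a")
  expect_equal(nrow(ont2$edges), 2)
  expect_true(all(ont2$edges$relation == "is_a"))

  cyc <- write_temp_obo(c(
    "[Term]", "id: GO:0000001", "namespace: biological_process",
    "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000002", "namespace: biological_process",
    "is_a: GO:0000001", ""))
  expect_error(parse_obo(cyc), "cycle")
})

test_that("ancestor and descendant queries match a recursive oracle", {
  ont <- toy_ontology()
  expect_equal(term_ancestors(ont, "GO:0000003"),
               c("GO:0000001", "GO:0000002"))
  expect_equal(term_descendants(ont, "GO:0000001"),
               sort(setdiff(ont$terms, "GO:0000001")))
  for (seed in 1:5) {
    dag <- random_dag(25, seed)
    for (t in sample(dag$terms, 5))
      expect_equal(term_ancestors(dag, t), oracle_ancestors(dag, t))
  }
})

test_that("annotation parsing dedups, drops NOT rows and keeps IEA verbatim", {
  ont <- toy_ontology()
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("g1\tGO:0000002\tEXP", "g1\tGO:0000002\tEXP",
               "g2\tGO:0000003\tIEA"), tsv)
  ann <- parse_annotations(tsv, ont)
  expect_equal(nrow(ann$records), 2)
  expect_true("IEA" %in% ann$records$evidence)

  gaf <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1",
               paste("DB", "ID1", "g1", "", "GO:0000002", "REF", "EXP",
                     sep = "\t"),
               paste("DB", "ID2", "g2", "NOT", "GO:0000003", "REF", "IDA",
                     sep = "\t"),
               paste("DB", "ID3", "g3", "", "GO:0000004", "REF", "IEA",
                     sep = "\t")), gaf)
  ann2 <- parse_annotations(gaf, ont)
  expect_equal(sort(ann2$records$gene), c("g1", "g3"))
  expect_equal(ann2$records$evidence[ann2$records$gene == "g3"], "IEA")

  # unknown terms are skipped with a warning, count retained
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("g1\tGO:0000002\tEXP", "g1\tGO:9999999\tEXP"), bad)
  expect_warning(ann3 <- parse_annotations(bad, ont), "skipped 1")
  expect_equal(attr(ann3, "n_skipped"), 1)
  expect_equal(nrow(ann3$records), 1)
})

test_that("upward propagation closes over ancestors, is idempotent and monotone", {
  ont <- toy_ontology()
  ann <- ann_from_records(gene = "g1", term = "GO:0000003",
                          evidence = "EXP")
  prop <- propagate_annotations(ann, ont)
  expect_setequal(prop$records$term,
                  c("GO:0000001", "GO:0000002", "GO:0000003"))
  # annotating a root is a fixpoint
  root_ann <- ann_from_records(gene = "g1", term = "GO:0000001",
                               evidence = "EXP")
  expect_equal(propagate_annotations(root_ann, ont)$records,
               root_ann$records)
  # idempotence + monotonicity on random DAGs
  for (seed in 1:5) {
    dag <- random_dag(30, seed)
    a <- random_annotations(dag, 15, seed)
    p1 <- propagate_annotations(a, dag)
    p2 <- propagate_annotations(p1, dag)
    expect_identical(p1$records, p2$records)
    expect_true(all(paste(a$records$gene, a$records$term) %in%
                      paste(p1$records$gene, p1$records$term)))
  }
})

test_that("inferred ancestor records inherit a non-IEA code when one contributes", {
  ont <- toy_ontology()
  ann <- ann_from_records(
    gene = c("g1", "g1"), term = c("GO:0000003", "GO:0000005"),
    evidence = c("EXP", "IEA"))
  prop <- propagate_annotations(ann, ont)
  rec <- prop$records
  # the root is reached by both an EXP and an IEA path: non-IEA wins
  expect_equal(rec$evidence[rec$term == "GO:0000001"], "EXP")
  expect_equal(rec$evidence[rec$term == "GO:0000002"], "EXP")
  # ancestors supported only by the IEA record stay IEA
  expect_equal(rec$evidence[rec$term == "GO:0000004"], "IEA")
})

test_that("negative propagation downward copies the set to every descendant", {
  ont <- toy_ontology()
  down <- propagate_negatives_down(c("g2", "g1", "g3"), "GO:0000001", ont)
  expect_setequal(names(down), ont$terms)
  for (s in down) expect_equal(s, c("g1", "g2", "g3"))
  expect_equal(names(propagate_negatives_down("g1", "GO:0000003", ont)),
               "GO:0000003")
  empty <- propagate_negatives_down(character(0), "GO:0000004", ont)
  expect_true(all(lengths(empty) == 0))
  # brute force per-descendant copying on random DAGs up to 50 terms
  for (seed in 1:3) {
    dag <- random_dag(50, seed)
    t <- sample(dag$terms, 1)
    down <- propagate_negatives_down(c("x", "y"), t, dag)
    desc <- sort(unique(unlist(lapply(dag$terms, function(u)
      if (t %in% oracle_ancestors(dag, u)) u else NULL))))
    expect_setequal(names(down), c(t, desc))
  }
})

test_that("annotation matrix is binary, deterministic, upward-closed and IEA-filterable", {
  ont <- toy_ontology()
  ann <- ann_from_records(
    gene = c("g1", "g2", "g3"),
    term = c("GO:0000003", "GO:0000002", "GO:0000005"),
    evidence = c("EXP", "EXP", "IEA"))
  am <- build_annotation_matrix(ann, ont)
  # hand-enumerated incidence after propagation
  expect_equal(am$genes, c("g1", "g2", "g3"))
  expect_equal(unname(am$w), c(3, 2, 3))
  expect_equal(as.numeric(am$A["g1", ]), c(1, 1, 1, 0, 0))
  expect_equal(as.numeric(am$A["g3", ]), c(1, 0, 0, 1, 1))
  # IEA-only gene disappears when IEA records are excluded
  am2 <- build_annotation_matrix(ann, ont, include_iea = FALSE)
  expect_equal(am2$genes, c("g1", "g2"))
  # root-only annotations leave other columns empty
  am3 <- build_annotation_matrix(
    ann_from_records(gene = "g1", term = "GO:0000001", evidence = "EXP"),
    ont)
  expect_equal(sum(am3$A[, setdiff(ont$terms, "GO:0000001")]), 0)
  # closure property on random DAGs
  for (seed in 1:4) {
    dag <- random_dag(20, seed)
    a <- random_annotations(dag, 12, seed)
    m <- build_annotation_matrix(a, dag)
    ones <- which(as.matrix(m$A) == 1, arr.ind = TRUE)
    for (r in sample(nrow(ones), min(25, nrow(ones)))) {
      t <- m$terms[ones[r, 2]]
      for (anc in dag$parents[[t]])
        expect_equal(as.numeric(m$A[ones[r, 1], anc]), 1)
    }
  }
  expect_error(build_annotation_matrix(
    annotation_set(data.frame(gene = "g", term = "GO:0000001",
                              evidence = "IEA")), ont,
    include_iea = FALSE), "no annotated genes")
})

test_that("TSV round trip preserves the record set", {
  ont <- toy_ontology()
  ann <- random_annotations(toy_ontology(), 10, 3)
  path <- tempfile(fileext = ".tsv")
  write_annotations_tsv(ann, path)
  back <- parse_annotations(path, ont, format = "tsv")
  expect_identical(back$records, ann$records)
})

test_that("OBO round trip preserves the ontology", {
  ont <- tri_branch_ontology()
  path <- tempfile(fileext = ".obo")
  write_obo(ont, path)
  back <- parse_obo(path)
  expect_identical(back$terms, ont$terms)
  expect_identical(back$edges, ont$edges)
  expect_identical(back$branch, ont$branch)
})

test_that("MTX cache round trip restores the annotation matrix", {
  am <- am_from_list(list(g1 = c("T1", "T2"), g2 = "T1", g3 = c("T2", "T3")))
  dir <- tempfile()
  write_annotation_matrix(am, dir)
  back <- read_annotation_matrix(dir)
  expect_equal(as.matrix(back$A), as.matrix(am$A))
  expect_equal(back$w, am$w)
})

test_that("annotated root children are counted per branch", {
  ont <- tri_branch_ontology()
  ann <- ann_from_records(
    gene = c("g1", "g2", "g3", "g4"),
    term = c("GO:0000101", "GO:0000102", "GO:0000201", "GO:0000301"),
    evidence = "EXP")
  expect_equal(annotated_root_children(ont, ann),
               c(BP = 2L, MF = 1L, CC = 1L))
  # a branch with no annotations below the root contributes 0
  ann2 <- ann_from_records(gene = "g1", term = "GO:0000101",
                           evidence = "EXP")
  expect_equal(annotated_root_children(ont, ann2),
               c(BP = 1L, MF = 0L, CC = 0L))
})
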