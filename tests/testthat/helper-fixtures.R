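# Hand-built toy fixtures and independent brute-force oracles. The oracles
# deliberately use naive loops/recursion so they share no code path with
# the implementations they check.

# single-branch 5-term DAG:  root <- M <- L,  root <- S1 <- S2 (part_of)
toy_ontology <- function() {
  go_ontology(
    terms = c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004",
              "GO:0000005"),
    edges = data.frame(
      child  = c("GO:0000002", "GO:0000003", "GO:0000004", "GO:0000005"),
      parent = c("GO:0000001", "GO:0000002", "GO:0000001", "GO:0000004"),
      relation = c("is_a", "is_a", "is_a", "part_of")),
    branch = setNames(rep("BP", 5),
                      c("GO:0000001", "GO:0000002", "GO:0000003",
                        "GO:0000004", "GO:0000005")))
}

# three branches with 2/1/1 annotated root children (plus one unannotated)
tri_branch_ontology <- function() {
  terms <- c("GO:0000100", "GO:0000101", "GO:0000102", "GO:0000103",
             "GO:0000200", "GO:0000201", "GO:0000202",
             "GO:0000300", "GO:0000301")
  branch <- setNames(c(rep("BP", 4), rep("MF", 3), rep("CC", 2)), terms)
  edges <- data.frame(
    child  = c("GO:0000101", "GO:0000102", "GO:0000103",
               "GO:0000201", "GO:0000202", "GO:0000301"),
    parent = c("GO:0000100", "GO:0000100", "GO:0000100",
               "GO:0000200", "GO:0000200", "GO:0000300"),
    relation = "is_a")
  go_ontology(terms, edges, branch)
}

# annotation matrix straight from a gene -> terms list (no propagation)
am_from_list <- function(doc) {
  terms <- sort(unique(unlist(doc)))
  A <- matrix(0, length(doc), length(terms),
              dimnames = list(names(doc), terms))
  for (g in names(doc)) A[g, doc[[g]]] <- 1
  annotation_matrix(A)
}

ann_from_records <- function(...) {
  rec <- data.frame(...)
  annotation_set(rec)
}

# brute-force transitive ancestors by naive recursion
oracle_ancestors <- function(ont, term) {
  ps <- ont$parents[[term]]
  if (length(ps) == 0) return(character(0))
  sort(unique(c(ps, unlist(lapply(ps, oracle_ancestors, ont = ont)))))
}

# brute-force conditional probability p(a | m) from a gene -> terms list
oracle_condprob <- function(doc, m, a) {
  n_m <- sum(vapply(doc, function(ts) m %in% ts, logical(1)))
  if (n_m == 0) return(0)
  n_ma <- sum(vapply(doc, function(ts) m %in% ts && a %in% ts, logical(1)))
  n_ma / n_m
}

# per-gene loop oracle for the SNOB score of `gene` for `term`
oracle_snob <- function(doc, gene, term) {
  ts <- doc[[gene]]
  mean(vapply(ts, function(m) oracle_condprob(doc, m, term), numeric(1)))
}

# random layered single-branch DAG + random annotations, for property tests
random_dag <- function(n_terms, seed) {
  set.seed(seed)
  ids <- sprintf("GO:%07d", 9000000 + seq_len(n_terms))
  child <- parent <- character(0)
  for (i in seq(2, n_terms)) {
    p <- sample(seq_len(i - 1), 1)
    child <- c(child, ids[i]); parent <- c(parent, ids[p])
    if (i > 2 && runif(1) < 0.3) {
      p2 <- sample(setdiff(seq_len(i - 1), p), 1)
      child <- c(child, ids[i]); parent <- c(parent, ids[p2])
    }
  }
  go_ontology(ids, data.frame(child = child, parent = parent,
                              relation = "is_a"),
              setNames(rep("BP", n_terms), ids))
}

random_annotations <- function(ont, n_genes, seed, p_iea = 0.3) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  rec <- do.call(rbind, lapply(genes, function(g) {
    k <- sample(1:4, 1)
    data.frame(gene = g, term = sample(ont$terms, k),
               evidence = ifelse(runif(k) < p_iea, "IEA", "EXP"))
  }))
  annotation_set(rec)
}

write_temp_obo <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  path
}

# small synthetic dataset reused by several files (kept cheap)
small_spec <- function(seed = 11)
  synthetic_spec(n_genes = 150, terms_per_branch = 20, dag_depth = 3,
                 seed = seed)

# flat one-branch holdout fixture with controlled t0 counts and new
# annotations per child term
flat_holdout <- function(counts, new_counts, include_iea_validation = TRUE) {
  terms <- c("GO:0000001", names(counts))
  ont <- go_ontology(
    terms,
    data.frame(child = names(counts), parent = "GO:0000001",
               relation = "is_a"),
    setNames(rep("BP", length(terms)), terms))
  rec0 <- do.call(rbind, lapply(names(counts), function(t) {
    if (counts[[t]] == 0) return(NULL)
    data.frame(gene = paste0(t, "_g", seq_len(counts[[t]])), term = t,
               evidence = "EXP")
  }))
  rec1 <- rbind(rec0, do.call(rbind, lapply(names(new_counts), function(t) {
    if (new_counts[[t]] == 0) return(NULL)
    data.frame(gene = paste0(t, "_new", seq_len(new_counts[[t]])),
               term = t, evidence = "EXP")
  })))
  universe <- unique(c(rec0$gene, rec1$gene, paste0("u", 1:20)))
  holdout_pair(annotation_set(rec0, "t0", gene_universe = universe),
               annotation_set(rec1, "t1", gene_universe = universe),
               ont, include_iea_validation = include_iea_validation)
}
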