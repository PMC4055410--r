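# GO DAG structure, OBO/GAF/TSV parsing, true-path-rule propagation and the
# binary gene x term annotation matrix every selection algorithm consumes.

GO_NAMESPACES <- c(biological_process = "BP",
                   molecular_function = "MF",
                   cellular_component = "CC")

#' Construct a GO ontology object
#'
#' An ontology is a directed acyclic graph of terms in up to three rooted
#' branches (BP, MF, CC) with typed child-to-parent edges (`is_a`,
#' `part_of`). Usually built by [parse_obo()] or
#' [generate_synthetic()]; the constructor validates acyclicity, branch
#' consistency (a term's parents lie in its own branch) and the existence of
#' exactly one parentless root per populated branch.
#'
#' @param terms character vector of term identifiers.
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#' @param branch named character vector mapping each term to `"BP"`, `"MF"`
#'   or `"CC"`.
#' @return An object of class `go_ontology` with elements `terms`, `edges`,
#'   `parents`, `children`, `branch` and `roots` (named by branch).
#' @export
go_ontology <- function(terms, edges, branch) {
  terms <- sort(unique(as.character(terms)))
  stopifnot(is.data.frame(edges),
            all(c("child", "parent", "relation") %in% names(edges)))
  edges <- unique(data.frame(child = as.character(edges$child),
                             parent = as.character(edges$parent),
                             relation = as.character(edges$relation),
                             stringsAsFactors = FALSE))
  edges <- edges[order(edges$child, edges$parent, edges$relation), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  missing <- setdiff(unique(c(edges$child, edges$parent)), terms)
  if (length(missing) > 0)
    stop("edges reference unknown terms: ", paste(missing, collapse = ", "))
  branch <- branch[terms]
  if (anyNA(branch))
    stop("every term needs a branch assignment (BP/MF/CC)")
  if (!all(branch %in% c("BP", "MF", "CC")))
    stop("branch labels must be BP, MF or CC")
  bad <- branch[edges$child] != branch[edges$parent]
  if (any(bad))
    stop("cross-branch edge(s): ",
         paste(edges$child[bad], "->", edges$parent[bad], collapse = "; "))

  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       directed = TRUE,
                                       vertices = data.frame(name = terms))
    if (!igraph::is_dag(g))
      stop("ontology graph contains a cycle")
  }

  parents <- split(edges$parent, factor(edges$child, levels = terms))
  children <- split(edges$child, factor(edges$parent, levels = terms))
  has_parent <- lengths(parents) > 0
  roots <- vapply(c("BP", "MF", "CC"), function(b) {
    cand <- terms[branch == b & !has_parent]
    if (length(cand) == 0) return(NA_character_)
    if (length(cand) > 1)
      stop("branch ", b, " has ", length(cand), " parentless terms; expected ",
           "a single root")
    cand
  }, character(1))

  structure(list(terms = terms, edges = edges, parents = parents,
                 children = children, branch = branch, roots = roots),
            class = "go_ontology")
}

#' @export
print.go_ontology <- function(x, ...) {
  cat("go_ontology:", length(x$terms), "terms,", nrow(x$edges), "edges\n")
  tb <- table(factor(x$branch, levels = c("BP", "MF", "CC")))
  cat("  branches:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Parse an OBO 1.2 ontology file
#'
#' Loads all non-obsolete `[Term]` stanzas. `is_a` edges and
#' `relationship: part_of` edges are retained by default; all other
#' relationship types are dropped. Branches are taken from the `namespace`
#' field (inherited from the parent when absent).
#'
#' @param path path to an OBO-formatted file.
#' @param relations character vector of edge types to retain.
#' @return A [go_ontology()] object.
#' @export
parse_obo <- function(path, relations = c("is_a", "part_of")) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(trimws(lines) == "[Term]")
  other_stanza <- which(grepl("^\\[", trimws(lines)) &
                          trimws(lines) != "[Term]")
  if (length(starts) == 0) stop("no [Term] stanzas found in ", path)

  ids <- character(0)
  ns <- character(0)
  edge_child <- edge_parent <- edge_rel <- character(0)
  for (s in starts) {
    ends <- c(starts[starts > s], other_stanza[other_stanza > s],
              length(lines) + 1L)
    block_lines <- lines[seq(s + 1L, min(ends) - 1L)]
    block_lines <- block_lines[nzchar(trimws(block_lines))]
    keyed <- regmatches(block_lines,
                        regexec("^([A-Za-z_]+):\\s*(.*)$", block_lines))
    bad <- which(lengths(keyed) != 3L)
    if (length(bad) > 0)
      stop("malformed OBO stanza near line ", s + bad[1],
           ": ", block_lines[bad[1]])
    key <- vapply(keyed, `[`, character(1), 2L)
    val <- vapply(keyed, `[`, character(1), 3L)
    val <- sub("\\s*!.*$", "", val)  # strip trailing OBO comments
    id <- val[key == "id"][1]
    if (is.na(id)) stop("OBO [Term] stanza at line ", s, " has no id")
    if (any(key == "is_obsolete" & grepl("true", val))) next
    ids <- c(ids, id)
    nsv <- val[key == "namespace"][1]
    ns <- c(ns, if (is.na(nsv)) NA_character_ else unname(GO_NAMESPACES[nsv]))
    if ("is_a" %in% relations) {
      for (p in val[key == "is_a"]) {
        edge_child <- c(edge_child, id)
        edge_parent <- c(edge_parent, trimws(p))
        edge_rel <- c(edge_rel, "is_a")
      }
    }
    for (r in val[key == "relationship"]) {
      parts <- strsplit(trimws(r), "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] %in% relations) {
        edge_child <- c(edge_child, id)
        edge_parent <- c(edge_parent, parts[2])
        edge_rel <- c(edge_rel, parts[1])
      }
    }
  }
  if (anyDuplicated(ids)) stop("duplicate term ids in ", path)
  names(ns) <- ids

  keep <- edge_parent %in% ids  # edges to obsolete/undefined parents dropped
  if (any(!keep))
    warning("dropped ", sum(!keep), " edge(s) to terms absent from the file")
  edges <- data.frame(child = edge_child[keep], parent = edge_parent[keep],
                      relation = edge_rel[keep], stringsAsFactors = FALSE)

  # inherit missing namespaces from parents (iterate: depth is finite)
  for (i in seq_len(length(ids))) {
    if (!anyNA(ns)) break
    for (id in ids[is.na(ns[ids])]) {
      pn <- ns[edges$parent[edges$child == id]]
      pn <- pn[!is.na(pn)]
      if (length(pn) > 0) ns[id] <- pn[1]
    }
  }
  if (anyNA(ns))
    stop("could not resolve a namespace for: ",
         paste(ids[is.na(ns[ids])], collapse = ", "))

  go_ontology(ids, edges, ns)
}

#' Ancestors / descendants of a term
#'
#' Transitive closure over the retained edge set, excluding the query term
#' itself.
#'
#' @param ont a [go_ontology()].
#' @param term a term identifier present in `ont`.
#' @return Sorted character vector of term identifiers.
#' @export
term_ancestors <- function(ont, term) {
  .closure(ont$parents, ont, term)
}

#' @rdname term_ancestors
#' @export
term_descendants <- function(ont, term) {
  .closure(ont$children, ont, term)
}

.closure <- function(adj, ont, term) {
  if (!term %in% ont$terms) stop("unknown term: ", term)
  seen <- character(0)
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(setdiff(seen, term))
}

#' Construct an annotation set
#'
#' A dated collection of (gene, term, evidence code) records plus the gene
#' universe the organism provides (which may exceed the annotated genes).
#' Duplicate triples are collapsed and records are kept in a deterministic
#' sorted order.
#'
#' @param records data.frame with character columns `gene`, `term`,
#'   `evidence`.
#' @param snapshot_label free-text label, typically a date.
#' @param gene_universe optional character vector; defaults to the annotated
#'   genes.
#' @param propagated logical, whether `records` is already closed under the
#'   true path rule.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(records, snapshot_label = "",
                           gene_universe = NULL, propagated = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("gene", "term", "evidence") %in% names(records)))
  records <- unique(data.frame(gene = as.character(records$gene),
                               term = as.character(records$term),
                               evidence = as.character(records$evidence),
                               stringsAsFactors = FALSE))
  records <- records[order(records$gene, records$term, records$evidence), ,
                     drop = FALSE]
  rownames(records) <- NULL
  if (is.null(gene_universe)) gene_universe <- unique(records$gene)
  gene_universe <- sort(unique(as.character(gene_universe)))
  if (!all(records$gene %in% gene_universe))
    stop("records contain genes outside gene_universe")
  structure(list(records = records, snapshot_label = snapshot_label,
                 gene_universe = gene_universe, propagated = propagated),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set [", x$snapshot_label, "]: ",
      nrow(x$records), " records, ",
      length(unique(x$records$gene)), " annotated genes of ",
      length(x$gene_universe), " in universe",
      if (x$propagated) ", propagated" else "", "\n", sep = "")
  invisible(x)
}

#' Parse annotations from GAF 2.x or the 3-column TSV dialect
#'
#' GAF rows with a `NOT` qualifier are excluded from the positive records;
#' evidence codes are kept verbatim; duplicate triples collapse to one.
#' Records whose term is not in the companion ontology are skipped with a
#' warning (the count is kept in the `n_skipped` attribute).
#'
#' The TSV dialect is `gene \t GO-term \t evidence-code`, UTF-8, with an
#' optional header line.
#'
#' @param path input file.
#' @param ontology companion [go_ontology()] used to validate terms.
#' @param format `"auto"` (GAF when rows have >= 7 tab-separated fields),
#'   `"gaf"` or `"tsv"`.
#' @param snapshot_label label for the snapshot; defaults to the file name.
#' @param gene_universe optional universe to attach.
#' @return An [annotation_set()].
#' @export
parse_annotations <- function(path, ontology,
                              format = c("auto", "gaf", "tsv"),
                              snapshot_label = basename(path),
                              gene_universe = NULL) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  body <- lines[!startsWith(lines, "!")]
  if (length(body) == 0) stop("no annotation rows in ", path)
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (format == "auto")
    format <- if (length(fields[[1]]) >= 7) "gaf" else "tsv"

  if (format == "gaf") {
    gene <- term <- evidence <- character(length(fields))
    keep <- logical(length(fields))
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) < 7)
        stop("unreadable GAF row ", i, " in ", path,
             " (", length(f), " fields)")
      qualifier <- f[4]
      if (grepl("(^|\\|)NOT($|\\|)", qualifier)) next
      gene[i] <- if (nzchar(f[3])) f[3] else f[2]
      term[i] <- f[5]
      evidence[i] <- f[7]
      keep[i] <- TRUE
    }
    rec <- data.frame(gene = gene[keep], term = term[keep],
                      evidence = evidence[keep], stringsAsFactors = FALSE)
  } else {
    n_fields <- lengths(fields)
    if (any(n_fields < 3))
      stop("unreadable TSV row ", which(n_fields < 3)[1], " in ", path)
    first <- fields[[1]]
    if (!grepl("^GO:", first[2]) && length(fields) > 1)
      fields <- fields[-1]  # header line
    rec <- data.frame(gene = vapply(fields, `[`, character(1), 1L),
                      term = vapply(fields, `[`, character(1), 2L),
                      evidence = vapply(fields, `[`, character(1), 3L),
                      stringsAsFactors = FALSE)
  }

  unknown <- !(rec$term %in% ontology$terms)
  if (any(unknown)) {
    warning("skipped ", sum(unknown),
            " record(s) with terms absent from the ontology")
    rec <- rec[!unknown, , drop = FALSE]
  }
  out <- annotation_set(rec, snapshot_label = snapshot_label,
                        gene_universe = gene_universe)
  attr(out, "n_skipped") <- sum(unknown)
  out
}

#' Write an annotation set in the TSV dialect
#'
#' @param ann an [annotation_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(ann, path) {
  utils::write.table(ann$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Propagate annotations upward (true path rule)
#'
#' An annotation of a gene to a term implies annotations to all ancestral
#' terms. The evidence code of an inferred ancestor record is inherited from
#' the contributing descendant records, preferring any non-IEA code (so that
#' filtering IEA records before or after propagation agrees wherever a
#' non-IEA record supports the term). Idempotent.
#'
#' @param ann an [annotation_set()].
#' @param ont the companion [go_ontology()].
#' @return A propagated [annotation_set()].
#' @export
propagate_annotations <- function(ann, ont) {
  if (isTRUE(ann$propagated)) return(ann)
  rec <- ann$records
  if (!all(rec$term %in% ont$terms))
    stop("annotation records reference terms absent from the ontology")
  uterms <- unique(rec$term)
  anc <- lapply(uterms, function(t) c(t, term_ancestors(ont, t)))
  names(anc) <- uterms
  reps <- lengths(anc)[rec$term]
  ex <- data.frame(gene = rep(rec$gene, reps),
                   term = unlist(anc[rec$term], use.names = FALSE),
                   evidence = rep(rec$evidence, reps),
                   stringsAsFactors = FALSE)
  # deterministic evidence choice: any non-IEA code wins, ties alphabetical
  ord <- order(ex$gene, ex$term, ex$evidence == "IEA", ex$evidence)
  ex <- ex[ord, , drop = FALSE]
  ex <- ex[!duplicated(ex[, c("gene", "term")]), , drop = FALSE]
  annotation_set(ex, snapshot_label = ann$snapshot_label,
                 gene_universe = ann$gene_universe, propagated = TRUE)
}

#' Propagate negative examples downward (inverse true path rule)
#'
#' A gene that is a negative example for a term is implicitly a negative for
#' every descendant of that term.
#'
#' @param negatives character vector of gene identifiers.
#' @param term the term the negatives were selected for.
#' @param ont a [go_ontology()].
#' @return Named list mapping `term` and each of its descendants to the
#'   (sorted) negative gene set.
#' @export
propagate_negatives_down <- function(negatives, term, ont) {
  targets <- c(term, term_descendants(ont, term))
  negatives <- sort(unique(as.character(negatives)))
  stats::setNames(rep(list(negatives), length(targets)), targets)
}

#' Build the binary gene x term annotation matrix
#'
#' Rows are the genes retaining at least one record (after the optional IEA
#' filter), columns are all ontology terms, both in sorted order. The input
#' is propagated internally when needed, so the matrix is always closed
#' upward: `A[i, t] = 1` implies `A[i, anc] = 1` for every ancestor of `t`.
#'
#' @param ann an [annotation_set()].
#' @param ont the companion [go_ontology()].
#' @param include_iea keep IEA-evidence records? When `FALSE` they are
#'   dropped before propagation.
#' @return An object of class `annotation_matrix`: list with the sparse
#'   binary matrix `A` (dimnames gene x term), `genes`, `terms`, the
#'   per-gene annotation totals `w` (row sums), and `include_iea`.
#' @export
build_annotation_matrix <- function(ann, ont, include_iea = TRUE) {
  rec <- ann$records
  if (!include_iea) rec <- rec[rec$evidence != "IEA", , drop = FALSE]
  if (nrow(rec) == 0) stop("no annotated genes")
  sub <- annotation_set(rec, snapshot_label = ann$snapshot_label,
                        gene_universe = ann$gene_universe,
                        propagated = isTRUE(ann$propagated) && include_iea)
  sub <- propagate_annotations(sub, ont)
  rec <- sub$records
  genes <- sort(unique(rec$gene))
  terms <- sort(ont$terms)
  ij <- unique(cbind(match(rec$gene, genes), match(rec$term, terms)))
  A <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1,
                            dims = c(length(genes), length(terms)),
                            dimnames = list(genes, terms))
  annotation_matrix(A, include_iea = include_iea)
}

#' Wrap a binary matrix as an annotation matrix
#'
#' Low-level constructor for callers that already hold a binary incidence
#' matrix (e.g. fixtures). Validates binary entries and non-empty rows.
#'
#' @param A binary matrix or sparse Matrix with gene rownames and term
#'   colnames.
#' @param include_iea bookkeeping flag describing how `A` was built.
#' @return An `annotation_matrix` object.
#' @export
annotation_matrix <- function(A, include_iea = TRUE) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                               "dMatrix"), "CsparseMatrix")
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stop("A needs gene rownames and term colnames")
  if (!all(A@x %in% c(0, 1))) stop("annotation matrix entries must be 0/1")
  A <- Matrix::drop0(A)
  w <- Matrix::rowSums(A)
  if (any(w < 1)) stop("every gene row must carry at least one annotation")
  structure(list(A = A, genes = rownames(A), terms = colnames(A),
                 w = w, include_iea = include_iea),
            class = "annotation_matrix")
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat("annotation_matrix:", length(x$genes), "genes x", length(x$terms),
      "terms,", sum(x$A), "ones",
      if (!x$include_iea) "(IEA excluded)" else "", "\n")
  invisible(x)
}

#' Positive genes of a term
#'
#' @param ann a propagated [annotation_set()].
#' @param term term identifier.
#' @param include_iea count IEA-evidence records as positive?
#' @return Sorted character vector of genes.
#' @export
positive_genes <- function(ann, term, include_iea = TRUE) {
  rec <- ann$records
  keep <- rec$term == term
  if (!include_iea) keep <- keep & rec$evidence != "IEA"
  sort(unique(rec$gene[keep]))
}

#' Count annotated direct descendants of the branch roots
#'
#' For each branch root, the number of direct children carrying at least one
#' annotated gene. The sum over branches is the NETL topic count.
#'
#' @param ont a [go_ontology()].
#' @param ann an [annotation_set()] (propagated internally if needed).
#' @return Named integer vector over `c("BP", "MF", "CC")`.
#' @export
annotated_root_children <- function(ont, ann) {
  ann <- propagate_annotations(ann, ont)
  annotated <- unique(ann$records$term)
  vapply(c("BP", "MF", "CC"), function(b) {
    root <- ont$roots[[b]]
    if (is.na(root)) return(0L)
    kids <- ont$children[[root]]
    sum(kids %in% annotated)
  }, integer(1))
}

#' Cache an annotation matrix as MatrixMarket plus index files
#'
#' Writes `matrix.mtx`, `genes.txt` and `terms.txt` into `dir`;
#' [read_annotation_matrix()] restores the object.
#'
#' @param am an `annotation_matrix`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_annotation_matrix <- function(am, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(am$A, file.path(dir, "matrix.mtx"))
  writeLines(am$genes, file.path(dir, "genes.txt"))
  writeLines(am$terms, file.path(dir, "terms.txt"))
  invisible(dir)
}

#' @rdname write_annotation_matrix
#' @export
read_annotation_matrix <- function(dir) {
  A <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  dimnames(A) <- list(readLines(file.path(dir, "genes.txt")),
                      readLines(file.path(dir, "terms.txt")))
  annotation_matrix(A)
}
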