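# Comparison methods: PU-Rocchio over tf-idf "documents", 1-DNF enriched
# words, the sibling heuristic, and the uniform random baseline.

#' tf-idf vectors over the GO-term vocabulary
#'
#' Treats each gene as a document and its (propagated, binary) annotations
#' as words: tf is the 0/1 count, idf is `log(N / df)` so a term annotated
#' to every gene contributes nothing.
#'
#' @param am an [annotation_matrix()].
#' @return Object of class `tfidf_corpus`: sparse `vectors` (gene x term)
#'   and the `idf` vector.
#' @export
tfidf_corpus <- function(am) {
  N <- length(am$genes)
  df <- Matrix::colSums(am$A)
  idf <- ifelse(df > 0, log(N / df), 0)
  V <- methods::as(am$A %*% Matrix::Diagonal(x = idf), "CsparseMatrix")
  dimnames(V) <- dimnames(am$A)
  structure(list(vectors = V, idf = stats::setNames(idf, am$terms)),
            class = "tfidf_corpus")
}

#' PU-Rocchio negativity scores
#'
#' Builds prototype vectors for the positive and unlabeled classes from
#' length-normalised tf-idf documents,
#' `c_pos = alpha * mean(P) - beta * mean(U)` and symmetrically `c_unl`,
#' then scores each unlabeled gene as
#' `cos(v, c_unl) - cos(v, c_pos)` (UnlabeledSimilarity minus
#' PositiveSimilarity). High scores mark confident negatives, so rank with
#' `decreasing = TRUE`.
#'
#' @param corpus a [tfidf_corpus()].
#' @param positives genes positive for the target term (IEA-inclusive).
#' @param alpha,beta classic PU-Rocchio prototype weights.
#' @return Named numeric vector of scores over the unlabeled genes.
#' @export
rocchio_scores <- function(corpus, positives, alpha = 16, beta = 4) {
  V <- corpus$vectors
  genes <- rownames(V)
  pos <- intersect(genes, positives)
  unl <- setdiff(genes, positives)
  if (length(pos) == 0) stop("empty positive class")
  if (length(unl) == 0) stop("no unlabeled genes")
  norms <- sqrt(Matrix::rowSums(V^2))
  norms[norms == 0] <- 1
  Vn <- Matrix::Diagonal(x = 1 / norms) %*% V
  rownames(Vn) <- genes
  mp <- Matrix::colMeans(Vn[pos, , drop = FALSE])
  mu <- Matrix::colMeans(Vn[unl, , drop = FALSE])
  c_pos <- alpha * mp - beta * mu
  c_unl <- alpha * mu - beta * mp
  cos_to <- function(M, c) {
    cn <- sqrt(sum(c^2))
    if (cn == 0) return(stats::setNames(rep(0, nrow(M)), rownames(M)))
    num <- as.numeric(M %*% c)
    den <- sqrt(Matrix::rowSums(M^2)) * cn
    out <- ifelse(den > 0, num / den, 0)
    stats::setNames(out, rownames(M))
  }
  U <- V[unl, , drop = FALSE]
  cos_to(U, c_unl) - cos_to(U, c_pos)
}

#' 1-DNF negative set
#'
#' Enriched words are the terms whose document frequency proportion among
#' the positives strictly exceeds that among the unlabeled genes; the
#' negatives are all non-positive genes carrying none of the enriched
#' terms. Fixed-size output.
#'
#' @param am an [annotation_matrix()].
#' @param term target term (positives default to its annotated genes).
#' @param positives optional explicit positive gene set.
#' @return Sorted character vector of genes.
#' @export
one_dnf_negatives <- function(am, term, positives = NULL) {
  if (is.null(positives)) {
    if (!term %in% am$terms) stop("unknown term: ", term)
    positives <- am$genes[as.numeric(am$A[, term]) > 0]
  }
  pos <- intersect(am$genes, positives)
  unl <- setdiff(am$genes, positives)
  if (length(pos) == 0) stop("empty positive class")
  dfp <- Matrix::colSums(am$A[pos, , drop = FALSE]) / length(pos)
  dfu <- if (length(unl) > 0)
    Matrix::colSums(am$A[unl, , drop = FALSE]) / length(unl)
  else rep(0, length(am$terms))
  enriched <- which(dfp > dfu)
  if (length(enriched) == 0) return(sort(unl))
  hits <- as.numeric(am$A[unl, enriched, drop = FALSE] %*%
                       rep(1, length(enriched)))
  sort(unl[hits == 0])
}

#' Sibling-heuristic negative set
#'
#' Genes annotated to a direct parent of the term but not to the term
#' itself (so siblings' annotations and parent-only annotations qualify).
#' The positive class excludes IEA annotations here, following the
#' heuristic's published form. When the rule yields nothing the heuristic
#' falls back to all annotated non-positive genes; the `fallback` attribute
#' records which branch fired.
#'
#' @param ann an [annotation_set()] (propagated internally).
#' @param ont the companion [go_ontology()].
#' @param term target term; must not be a branch root.
#' @param include_iea count IEA records when determining membership?
#' @return Sorted character vector of genes with attribute `fallback`.
#' @export
sibling_negatives <- function(ann, ont, term, include_iea = FALSE) {
  if (!term %in% ont$terms) stop("unknown term: ", term)
  parents <- ont$parents[[term]]
  if (length(parents) == 0) stop("term is a branch root: ", term)
  ann <- propagate_annotations(ann, ont)
  rec <- ann$records
  if (!include_iea) rec <- rec[rec$evidence != "IEA", , drop = FALSE]
  pos <- unique(rec$gene[rec$term == term])
  parent_genes <- unique(rec$gene[rec$term %in% parents])
  neg <- setdiff(parent_genes, pos)
  fallback <- length(neg) == 0
  if (fallback) neg <- setdiff(unique(rec$gene), pos)
  structure(sort(neg), fallback = fallback)
}

#' Random-baseline negative sets
#'
#' Uniform samples without replacement from the full gene universe minus
#' the positive class (unannotated genes included, unlike the GO-restricted
#' algorithms). Replicated `reps` times; downstream evaluation averages
#' false-negative counts across replicates. With `n` equal to the full
#' complement every replicate is the "all non-positive as negative"
#' heuristic.
#'
#' @param universe character vector of all genes.
#' @param positives genes positive for the target term (IEA-inclusive).
#' @param n negatives per replicate.
#' @param reps number of replicates.
#' @param seed optional integer seed.
#' @return List of `reps` character vectors.
#' @export
random_negatives <- function(universe, positives, n, reps = 100,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cand <- sort(setdiff(unique(universe), positives))
  if (n > length(cand))
    stop("n = ", n, " exceeds the ", length(cand), " candidate genes")
  lapply(seq_len(reps), function(r) sample(cand, n))
}
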