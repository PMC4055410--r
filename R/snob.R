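# SNOB: negatives ranked by the average conditional probability of the
# target term given each of a gene's annotations, S = W^-1 A P. ALBNeg is
# the leaf-annotation zero-probability predecessor.

#' Pairwise conditional co-annotation probabilities
#'
#' For every ordered pair of terms, `P[m, a] = p(a | m) = n_{m,a} / n_m`,
#' where `n_{m,a}` counts genes annotated to both terms and `n_m` genes
#' annotated to `m`, computed jointly across all three GO branches. Rows of
#' terms with no annotated gene are zero by convention.
#'
#' @param am an [annotation_matrix()] (propagated, binary).
#' @return An object of class `cooccurrence_probability`: list with the
#'   sparse matrix `P` (term x term), the per-term counts `n`, and `terms`.
#' @export
conditional_probability <- function(am) {
  C <- methods::as(Matrix::crossprod(am$A), "CsparseMatrix")  # n_{m,a}
  n <- Matrix::diag(C)
  inv <- ifelse(n > 0, 1 / n, 0)
  P <- methods::as(Matrix::Diagonal(x = inv) %*% C, "CsparseMatrix")
  dimnames(P) <- list(am$terms, am$terms)
  structure(list(P = P, n = stats::setNames(n, am$terms), terms = am$terms),
            class = "cooccurrence_probability")
}

#' @export
print.cooccurrence_probability <- function(x, ...) {
  cat("cooccurrence_probability:", length(x$terms), "terms,",
      sum(x$n > 0), "with >=1 annotated gene\n")
  invisible(x)
}

#' SNOB negativity scores for one target term
#'
#' Each gene's score is the average, over its annotations `m` (all branches,
#' IEA included when the matrix was built that way), of `p(term | m)`; the
#' vector of scores is the `term` column of `W^-1 A P`. Low scores mark
#' likely negative examples.
#'
#' @param am an [annotation_matrix()].
#' @param cp the [conditional_probability()] of `am`.
#' @param term target term identifier.
#' @return Named numeric vector of scores in `[0, 1]` over all annotated
#'   genes (positives included; ranking removes them).
#' @export
snob_scores <- function(am, cp, term) {
  if (!term %in% cp$terms) stop("unknown term: ", term)
  if (cp$n[[term]] == 0) stop("term has no positive examples: ", term)
  s <- as.numeric(am$A %*% cp$P[, term]) / am$w
  stats::setNames(s, am$genes)
}

#' Rank candidate genes by negativity score
#'
#' Removes the positive genes, sorts the rest by score (ascending by
#' default: lowest score = most confident negative), breaks ties by gene
#' identifier and keeps the first `n`. If `n` exceeds the candidate pool all
#' candidates are returned with a warning.
#'
#' @param scores named numeric vector of per-gene scores.
#' @param positives genes positive for the target term (excluded).
#' @param n number of negatives requested.
#' @param decreasing set `TRUE` for methods where high scores mark
#'   negatives (Rocchio).
#' @param method label recorded on the ranking.
#' @param term optional term identifier recorded on the ranking.
#' @return A `negative_ranking`: data.frame with columns `rank`, `gene`,
#'   `score`, attributes `method` and `term`.
#' @export
rank_negatives <- function(scores, positives, n, decreasing = FALSE,
                           method = "", term = NULL) {
  stopifnot(n >= 0)
  cand <- setdiff(names(scores), positives)
  s <- scores[cand]
  ord <- order(if (decreasing) -s else s, cand)
  if (n > length(cand)) {
    warning("requested ", n, " negatives but only ", length(cand),
            " candidates; returning all")
    n <- length(cand)
  }
  idx <- ord[seq_len(n)]
  out <- data.frame(rank = seq_len(n), gene = cand[idx],
                    score = unname(s[idx]), stringsAsFactors = FALSE)
  structure(out, class = c("negative_ranking", "data.frame"),
            method = method, term = term)
}

#' Write a negative ranking as rank/gene/score TSV
#'
#' Methods without a per-gene score emit `NA` in the score field.
#'
#' @param ranking a `negative_ranking` (or plain gene vector).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  if (is.character(ranking))
    ranking <- data.frame(rank = seq_along(ranking), gene = ranking,
                          score = NA_real_)
  utils::write.table(ranking[, c("rank", "gene", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' SNOB ranking for one term
#'
#' Convenience wrapper: scores, removes the term's positives (IEA-inclusive
#' positivity, matching how the matrix was built) and ranks ascending.
#'
#' @inheritParams snob_scores
#' @param n number of negatives.
#' @return A `negative_ranking`.
#' @export
snob_rank <- function(am, cp, term, n) {
  s <- snob_scores(am, cp, term)
  pos <- am$genes[as.numeric(am$A[, term]) > 0]
  rank_negatives(s, pos, n, method = "snob", term = term)
}

#' ALBNeg negative set for one term
#'
#' Returns the genes, not positive for `term`, all of whose most-specific
#' annotations (terms with no annotated child in the same gene) have zero
#' conditional probability of co-occurring with `term`. Classically run on
#' curated (non-IEA) annotations: build `am`/`cp` with `include_iea =
#' FALSE`. Fixed-size output; no `n` parameter.
#'
#' @inheritParams snob_scores
#' @param ont the [go_ontology()] supplying child links.
#' @return Sorted character vector of genes.
#' @export
albneg_negatives <- function(am, cp, ont, term) {
  if (!term %in% cp$terms) stop("unknown term: ", term)
  if (cp$n[[term]] == 0) stop("term has no positive examples: ", term)
  A <- am$A
  ed <- ont$edges
  ed <- ed[ed$child %in% am$terms & ed$parent %in% am$terms, , drop = FALSE]
  # child indicator: Cind[parent, child] = 1
  Cind <- Matrix::sparseMatrix(i = match(ed$parent, am$terms),
                               j = match(ed$child, am$terms), x = 1,
                               dims = c(length(am$terms), length(am$terms)))
  n_ann_children <- A %*% Matrix::t(Cind)  # gene x term
  leafmost <- A * (n_ann_children == 0)    # gene's most specific terms
  pcol <- as.numeric(cp$P[, term])
  # a gene is excluded iff any leaf-most term co-occurs with `term`
  hits <- as.numeric(leafmost %*% (pcol > 0))
  pos <- am$genes[as.numeric(A[, term]) > 0]
  sort(setdiff(am$genes[hits == 0], pos))
}
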