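# NETL: protein-as-document topic model. A gene's document is its set of
# propagated GO annotations (IEA included, all branches); a variational
# latent Dirichlet allocation fit supplies per-gene posterior topic
# distributions; candidates are ranked by the distributional overlap of
# their posterior with the positive-class average.

#' Topic count from annotated root children
#'
#' The number of latent topics is the total number of annotated direct
#' descendants of the three branch roots, giving far fewer topics than
#' vocabulary words while still covering the whole DAG once negatives are
#' propagated downward.
#'
#' @param ont a [go_ontology()].
#' @param ann an [annotation_set()].
#' @return Integer topic count.
#' @export
choose_topic_count <- function(ont, ann) {
  k <- sum(annotated_root_children(ont, ann))
  if (k == 0) stop("no annotated root children")
  as.integer(k)
}

#' Fit latent Dirichlet allocation on the annotation corpus
#'
#' Batch variational Bayes with symmetric Dirichlet priors (document prior
#' `alpha = 1/k`, topic-word prior `eta = 0.01`). Documents are the rows of
#' the annotation matrix (each annotated term appearing once); the
#' vocabulary is the set of terms with at least one annotated gene. The fit
#' is deterministic for a fixed `seed`.
#'
#' @param am an [annotation_matrix()] built with `include_iea = TRUE` from
#'   all three branches.
#' @param k number of topics; must satisfy `1 <= k <` vocabulary size.
#'   Defaults via [choose_topic_count()] require calling it yourself.
#' @param seed integer seed for the topic-word initialisation.
#' @param alpha,eta Dirichlet hyperparameters.
#' @param max_iter cap on variational EM sweeps; a warning is issued and the
#'   best-so-far fit returned when the cap is hit before `tol`.
#' @param tol convergence threshold on the mean absolute change of the
#'   expected topic-word distributions.
#' @return An object of class `lda_topics`: `theta` (gene x topic posterior
#'   rows summing to 1), `beta` (topic x word distributions), `k`,
#'   `iterations`, `converged`.
#' @export
fit_lda <- function(am, k, seed = 1L, alpha = 1 / k, eta = 0.01,
                    max_iter = 100L, tol = 1e-4) {
  vocab <- am$terms[Matrix::colSums(am$A) > 0]
  V <- length(vocab)
  if (k < 1 || k >= V)
    stop("topic count k must satisfy 1 <= k < vocabulary size (", V, ")")
  A <- am$A[, vocab, drop = FALSE]
  docs <- apply(A, 1L, function(r) which(r > 0), simplify = FALSE)
  D <- length(docs)

  set.seed(seed)
  lambda <- matrix(stats::rgamma(k * V, shape = 100, rate = 100),
                   nrow = k, ncol = V)
  gamma_mat <- matrix(alpha + vapply(docs, length, numeric(1)) / k,
                      nrow = D, ncol = k)
  Ebeta_old <- lambda / rowSums(lambda)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Elogbeta <- digamma(lambda) - digamma(rowSums(lambda))
    expElogbeta <- exp(Elogbeta)
    sstats <- matrix(0, nrow = k, ncol = V)
    for (d in seq_len(D)) {
      ids <- docs[[d]]
      betad <- expElogbeta[, ids, drop = FALSE]
      gammad <- gamma_mat[d, ]
      expEtheta <- exp(digamma(gammad) - digamma(sum(gammad)))
      for (inner in 1:50) {
        phinorm <- as.numeric(crossprod(betad, expEtheta)) + 1e-100
        gnew <- alpha + expEtheta * as.numeric(betad %*% (1 / phinorm))
        delta <- mean(abs(gnew - gammad))
        gammad <- gnew
        expEtheta <- exp(digamma(gammad) - digamma(sum(gammad)))
        if (delta < 1e-5) break
      }
      gamma_mat[d, ] <- gammad
      phinorm <- as.numeric(crossprod(betad, expEtheta)) + 1e-100
      sstats[, ids] <- sstats[, ids, drop = FALSE] +
        outer(expEtheta, 1 / phinorm)
    }
    lambda <- eta + sstats * expElogbeta
    Ebeta <- lambda / rowSums(lambda)
    drift <- mean(abs(Ebeta - Ebeta_old))
    Ebeta_old <- Ebeta
    if (drift < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("LDA reached the iteration cap (", max_iter,
            ") before converging; returning the current fit")

  theta <- gamma_mat / rowSums(gamma_mat)
  dimnames(theta) <- list(am$genes, paste0("topic", seq_len(k)))
  beta <- lambda / rowSums(lambda)
  dimnames(beta) <- list(paste0("topic", seq_len(k)), vocab)
  structure(list(theta = theta, beta = beta, k = as.integer(k),
                 iterations = it, converged = converged, seed = seed),
            class = "lda_topics")
}

#' @export
print.lda_topics <- function(x, ...) {
  cat("lda_topics:", x$k, "topics,", nrow(x$theta), "documents,",
      ncol(x$beta), "words;", x$iterations, "iterations",
      if (x$converged) "(converged)" else "(cap reached)", "\n")
  invisible(x)
}

#' Distributional-overlap score between two topic posteriors
#'
#' `DOS(p, q) = sum_i min(p_i, q_i)`: symmetric, bounded in `[0, 1]` for
#' unit-sum vectors (equivalently `1 -` total variation distance), `1` iff
#' the distributions coincide and `0` iff their supports are disjoint. Low
#' overlap with the positive class marks likely negatives.
#'
#' @param p,q non-negative numeric vectors of equal length summing to 1.
#' @return Scalar in `[0, 1]`.
#' @export
dos <- function(p, q) {
  if (length(p) != length(q))
    stop("posterior vectors differ in length")
  sum(pmin(p, q))
}

#' NETL ranking for one term
#'
#' The positive class is summarised by the renormalised arithmetic mean of
#' the positives' posterior topic distributions; annotated non-positive
#' genes are ranked ascending by DOS to that mean (lowest overlap = most
#' likely negative), ties broken by gene identifier.
#'
#' @param model an [fit_lda()] result covering every candidate gene.
#' @param positives genes positive for the target term.
#' @param n number of negatives.
#' @param term optional term label recorded on the ranking.
#' @return A `negative_ranking`.
#' @export
netl_rank <- function(model, positives, n, term = NULL) {
  theta <- model$theta
  pos <- intersect(positives, rownames(theta))
  if (length(pos) == 0) stop("no positives with a topic posterior")
  m <- colMeans(theta[pos, , drop = FALSE])
  m <- m / sum(m)
  cand <- setdiff(rownames(theta), positives)
  tc <- theta[cand, , drop = FALSE]
  scores <- rowSums(pmin(tc, matrix(m, nrow = length(cand),
                                    ncol = model$k, byrow = TRUE)))
  rank_negatives(stats::setNames(scores, cand), character(0), n,
                 method = "netl", term = term)
}

#' Dump an LDA model as TSV files
#'
#' Writes `topics.tsv` (topic x word distributions) and `posteriors.tsv`
#' (gene x topic) into `dir`.
#'
#' @param model an `lda_topics` object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_lda_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(model$beta, file.path(dir, "topics.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(model$theta, file.path(dir, "posteriors.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(dir)
}
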