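#' Wilks' Lambda of a gene subset
#'
#' `Lambda = det(W) / det(W + B)`, the ratio of within-group to total
#' scatter determinants; values near 0 indicate strong multivariate group
#' separation. Reference implementation of the criterion used by the
#' greedy forward selector.
#'
#' @param x samples-by-genes matrix of the subset.
#' @param labels class factor.
#' @return List with `lambda` and the scatter matrices `W` and `T`.
#' @export
wilks_lambda <- function(x, labels) {
  x <- as.matrix(x)
  labels <- factor(labels)
  n <- nrow(x); k <- ncol(x); G <- nlevels(labels)
  if (k >= n - G + 1) stop("too many variables for the residual df")
  xc <- sweep(x, 2, colMeans(x))
  Tt <- crossprod(xc)
  W <- matrix(0, k, k)
  for (l in levels(labels)) {
    xg <- x[labels == l, , drop = FALSE]
    xg <- sweep(xg, 2, colMeans(xg))
    W <- W + crossprod(xg)
  }
  lambda <- det(W) / det(Tt)
  list(lambda = lambda, W = W, T = Tt)
}

#' Partial-Lambda F test for one added variable
#'
#' For a candidate added to a `p`-variable model, the partial Lambda is
#' `Lambda_{p+1} / Lambda_p` and
#' `F = ((n - G - p) / (G - 1)) * (1 - pL) / pL` on
#' `(G - 1, n - G - p)` df.
#'
#' @param lambda_new,lambda_old Wilks Lambda with and without the
#'   candidate.
#' @param n,n_classes,p_current sample count, group count, size of the
#'   model before the addition.
#' @return List with `partial_lambda`, `statistic`, `df`, `p_value`.
#' @export
wilks_partial_test <- function(lambda_new, lambda_old, n, n_classes,
                               p_current) {
  pl <- min(lambda_new / lambda_old, 1)
  df1 <- n_classes - 1
  df2 <- n - n_classes - p_current
  if (df2 < 1) stop("insufficient residual df")
  f <- (df2 / df1) * (1 - pl) / pl
  list(partial_lambda = pl, statistic = f, df = c(df1, df2),
       p_value = pf(f, df1, df2, lower.tail = FALSE))
}

#' Greedy Wilks-Lambda forward selection
#'
#' Starting from the empty model, iteratively adds the gene with the
#' smallest partial-Lambda p-value as long as that p-value is below
#' `alpha` (the selection "niveau"), up to `max_steps` genes. The first
#' step is the overall F statistic (partial Lambda against the empty
#' model).
#'
#' @param x samples-by-genes matrix (full pool), or a [ratio_matrix()]
#'   (then genes are rows and `labels` defaults to its time factor).
#' @param labels class factor.
#' @param alpha significance level for entering the model.
#' @param max_steps hard cap on the selected-set size (a safety valve;
#'   typical data-driven sizes are 5-10).
#' @return Data frame of the insertion order: `gene_id`, `lambda`,
#'   `statistic`, `p_value`. Zero rows (with a warning) when no gene
#'   passes at step 1.
#' @export
greedy_forward <- function(x, labels = NULL, alpha = 0.001,
                           max_steps = 10) {
  if (inherits(x, "ratio_matrix")) {
    if (is.null(labels)) labels <- time_factor(x)
    x <- t(x$ratios)
  } else x <- as.matrix(x)
  labels <- factor(labels)
  res <- cpp_greedy_forward(x, as.integer(labels), nlevels(labels),
                            alpha, max_steps)
  if (length(res$selected) == 0) {
    warning("no gene passed the entry level alpha = ", alpha)
  }
  ids <- colnames(x)
  if (is.null(ids)) ids <- sprintf("g%04d", seq_len(ncol(x)))
  data.frame(gene_id = ids[res$selected],
             index = res$selected,
             lambda = res$lambda,
             statistic = res$F,
             p_value = res$p_value,
             stringsAsFactors = FALSE)
}

#' Greedy/LDA selection inside a leave-one-out wrapper
#'
#' For each of the n leave-one-out folds, runs the greedy Wilks-Lambda
#' forward selection on the n-1 training samples, fits the linear
#' discriminant on the selected genes, and predicts the held-out sample.
#' Reports the gene frequency ranking over the n training selections and
#' the overall LOOCV error. Folds with an empty selection predict the
#' majority (first) class and are flagged.
#'
#' @param pool [ratio_matrix()] or genes-by-samples matrix.
#' @param labels class factor per sample.
#' @param alpha entry level of the forward selection.
#' @param max_steps per-fold cap on selected genes.
#' @return Object of class `greedy_run`: `ranking` (gene frequencies over
#'   folds), `loocv_error`, per-fold `selections` and `set_sizes`, and
#'   `n_empty_folds`.
#' @export
greedy_loocv <- function(pool, labels = NULL, alpha = 0.001,
                         max_steps = 10) {
  st <- selector_state(pool, labels)
  n <- length(st$y)
  preds <- integer(n)
  selections <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    xtr <- st$Xt[tr, , drop = FALSE]
    ytr <- st$y[tr]
    sel <- cpp_greedy_forward(xtr, ytr, st$G, alpha, max_steps)$selected
    selections[[i]] <- st$gene_ids[sel]
    if (length(sel) == 0) {
      preds[i] <- 1L                        # majority-class fallback
      next
    }
    preds[i] <- cpp_mlhd_predict(xtr[, sel, drop = FALSE], ytr,
                                 st$Xt[i, sel, drop = FALSE], st$G, 1e-8)
  }
  empty <- vapply(selections, length, integer(1)) == 0
  structure(list(
    method = "greedy",
    ranking = rank_by_frequency(selections, st$gene_ids),
    loocv_error = mean(preds != st$y),
    predictions = factor(levels(st$labels)[preds],
                         levels = levels(st$labels)),
    selections = selections,
    set_sizes = vapply(selections, length, integer(1)),
    n_empty_folds = sum(empty),
    alpha = alpha, max_steps = max_steps),
    class = "greedy_run")
}

#' @export
print.greedy_run <- function(x, ...) {
  cat(sprintf("greedy_run: LOOCV error %.3f; per-fold set sizes %d-%d%s\n",
              x$loocv_error, min(x$set_sizes), max(x$set_sizes),
              if (x$n_empty_folds > 0)
                sprintf(" (%d empty folds)", x$n_empty_folds) else ""))
  invisible(x)
}

#' Random-forest gene ranking by Gini importance
#'
#' Fits a random forest on the pool (default settings of the underlying
#' implementation as used in the study: 500 trees, `mtry` equal to the
#' number of genes, terminal node size 1) and ranks genes by mean
#' decrease in the Gini criterion (or permutation importance), reporting
#' the out-of-bag error.
#'
#' @param pool [ratio_matrix()] or genes-by-samples matrix.
#' @param labels class factor per sample.
#' @param n_trees,m_try,node_size forest settings; `m_try` defaults to
#'   all genes.
#' @param importance `"gini"` or `"permutation"`.
#' @param seed RNG seed.
#' @return Object of class `rf_run`: `ranking` (gene, importance, rank),
#'   `oob_error`, and the fitted forest in `$forest`.
#' @export
rf_rank <- function(pool, labels = NULL, n_trees = 500, m_try = NULL,
                    node_size = 1, importance = c("gini", "permutation"),
                    seed = NULL) {
  importance <- match.arg(importance)
  st <- selector_state(pool, labels)
  if (st$G < 2) stop("need at least two classes")
  if (is.null(m_try)) m_try <- st$n_genes
  stopifnot(n_trees >= 1, m_try >= 1, m_try <= st$n_genes)
  with_seed(seed, {
    x <- st$Xt
    colnames(x) <- st$gene_ids
    fit <- randomForest::randomForest(
      x = x, y = st$labels, ntree = n_trees, mtry = m_try,
      nodesize = node_size, importance = (importance == "permutation"))
    imp <- if (importance == "gini") {
      fit$importance[, "MeanDecreaseGini"]
    } else fit$importance[, "MeanDecreaseAccuracy"]
    ord <- order(-imp, names(imp))
    ranking <- data.frame(gene_id = names(imp)[ord],
                          importance = unname(imp[ord]),
                          rank = seq_along(imp),
                          stringsAsFactors = FALSE)
    oob <- fit$err.rate[n_trees, "OOB"]
    structure(list(method = "rf", ranking = ranking,
                   oob_error = unname(oob), importance_type = importance,
                   forest = fit),
              class = "rf_run")
  })
}

#' @export
print.rf_run <- function(x, ...) {
  cat(sprintf("rf_run: OOB error %.3f (%s importance); top genes: %s ...\n",
              x$oob_error, x$importance_type,
              paste(head(x$ranking$gene_id, 5), collapse = ", ")))
  invisible(x)
}
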