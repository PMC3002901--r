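#' Fit the maximum-likelihood (linear) discriminant
#'
#' Classifier shared by all wrapper selectors: class-wise Gaussians with a
#' pooled within-class covariance and equal priors (the design is balanced
#' by construction), which is linear discriminant analysis. The
#' discriminant score of class g for observation x is
#' `d_g(x) = mu_g' S^-1 x - 0.5 * mu_g' S^-1 mu_g`, prediction is the
#' argmax. A singular pooled covariance gets a ridge `eps * mean(diag)`
#' added (logged via attribute), escalated once before erroring.
#'
#' @param x numeric matrix, training samples in rows, genes in columns.
#' @param labels factor of class labels, >= 2 samples per class.
#' @param ridge_eps ridge guard relative magnitude (default 1e-8).
#' @return Object of class `mlhd` with class `means`, pooled `cov`, its
#'   inverse, and the class `levels`.
#' @export
mlhd_fit <- function(x, labels, ridge_eps = 1e-8) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (any(table(labels) < 2)) stop("every class needs >= 2 training samples")
  n <- nrow(x); k <- ncol(x); G <- nlevels(labels)
  if (k >= n - G + 1 && k > 1) {
    warning("subset size ", k, " is large for ", n - G,
            " residual df; pooled covariance may be ill-conditioned")
  }
  means <- matrix(0, G, k, dimnames = list(levels(labels), colnames(x)))
  for (l in levels(labels)) {
    means[l, ] <- colMeans(x[labels == l, , drop = FALSE])
  }
  W <- matrix(0, k, k)
  for (l in levels(labels)) {
    xc <- sweep(x[labels == l, , drop = FALSE], 2, means[l, ])
    W <- W + crossprod(xc)
  }
  S <- W / (n - G)
  ridge_used <- 0
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv)) {
    md <- mean(diag(S)); if (md <= 0) md <- 1
    for (eps in c(ridge_eps, 1e-4)) {
      Sinv <- tryCatch(solve(S + eps * md * diag(k)), error = function(e) NULL)
      if (!is.null(Sinv)) { ridge_used <- eps; break }
    }
    if (is.null(Sinv)) stop("pooled covariance singular after ridge guard")
  }
  structure(list(means = means, cov = S, cov_inv = Sinv,
                 levels = levels(labels), ridge_used = ridge_used,
                 n_train = n),
            class = "mlhd")
}

#' @export
print.mlhd <- function(x, ...) {
  cat("mlhd discriminant:", length(x$levels), "classes,",
      ncol(x$means), "genes,", x$n_train, "training samples\n")
  if (x$ridge_used > 0) cat("  ridge guard applied (eps =", x$ridge_used, ")\n")
  invisible(x)
}

#' Predict class membership from an mlhd fit
#'
#' @param object an `mlhd` fit.
#' @param newdata matrix of observations in rows.
#' @param ... unused.
#' @return Factor of predicted classes.
#' @export
predict.mlhd <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  A <- object$means %*% object$cov_inv          # G x k
  const <- 0.5 * rowSums(A * object$means)
  scores <- newdata %*% t(A)
  scores <- sweep(scores, 2, const)
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

#' Leave-one-out cross-validated accuracy of a gene subset
#'
#' Refits the MLHD classifier n times, each time holding out one sample,
#' and reports the fraction of correctly predicted held-out samples --
#' the fitness used by all wrapper selectors. Deterministic for fixed
#' input.
#'
#' @param x genes-by-samples matrix restricted to the subset under test
#'   (or samples-by-genes; see `genes_in_rows`).
#' @param labels factor of class labels per sample.
#' @param genes_in_rows is `x` genes x samples (default TRUE, the ratio
#'   matrix orientation)?
#' @param ridge_eps ridge guard for singular pooled covariances.
#' @return Object of class `loocv_fitness`: `accuracy`, per-fold
#'   `predictions` (factor), and the gene ids tested.
#' @export
loocv_accuracy <- function(x, labels, genes_in_rows = TRUE,
                           ridge_eps = 1e-8) {
  x <- as.matrix(x)
  if (genes_in_rows) x <- t(x)
  labels <- factor(labels)
  n <- nrow(x); G <- nlevels(labels)
  if (n < G + 1) stop("need more samples than classes")
  if (any(table(labels) < 2)) {
    stop("a left-out fold would lose a class: every class needs >= 2 samples")
  }
  res <- cpp_loocv(x, as.integer(labels), G, ridge_eps)
  structure(list(genes = colnames(x),
                 accuracy = res$accuracy,
                 predictions = factor(levels(labels)[res$predictions],
                                      levels = levels(labels)),
                 labels = labels),
            class = "loocv_fitness")
}

#' @export
print.loocv_fitness <- function(x, ...) {
  cat("LOOCV fitness:", format(x$accuracy, digits = 4), "over",
      length(x$predictions), "folds (genes:",
      paste(x$genes, collapse = ", "), ")\n")
  invisible(x)
}

# resubstitution (training) accuracy, C++ path
resub_accuracy <- function(x, labels, genes_in_rows = TRUE,
                           ridge_eps = 1e-8) {
  x <- as.matrix(x)
  if (genes_in_rows) x <- t(x)
  labels <- factor(labels)
  cpp_resub_accuracy(x, as.integer(labels), nlevels(labels), ridge_eps)
}

#' Generalization curve: training vs LOOCV error by subset size
#'
#' The overfitting diagnostic: for each subset size, draws random gene
#' subsets and averages the resubstitution (training) error and the
#' leave-one-out (test) error. With ~30 samples the test error starts
#' rising beyond roughly 20 variables while the training error keeps
#' falling -- the signature of overfitting that motivates small (5-gene)
#' chromosomes.
#'
#' @param rm a [ratio_matrix()] or genes-by-samples matrix.
#' @param labels class factor (taken from the time factor of `rm` when
#'   missing).
#' @param sizes subset sizes to scan (default 2:30).
#' @param draws random subsets per size (default 1000).
#' @param seed RNG seed.
#' @return Data frame (class `generalization_curve`) with columns `size`,
#'   `train_error`, `test_error`.
#' @export
generalization_curve <- function(rm, labels = NULL, sizes = 2:30,
                                 draws = 1000, seed = NULL) {
  if (inherits(rm, "ratio_matrix")) {
    if (is.null(labels)) labels <- time_factor(rm)
    X <- rm$ratios
  } else X <- as.matrix(rm)
  labels <- factor(labels)
  if (draws < 1) stop("draws must be >= 1")
  if (max(sizes) > nrow(X)) {
    stop("largest size (", max(sizes), ") exceeds available genes (",
         nrow(X), ")")
  }
  if (any(diff(sizes) <= 0)) stop("sizes must be strictly increasing")
  Xt <- t(X)
  y <- as.integer(labels); G <- nlevels(labels)
  with_seed(seed, {
    res <- vapply(sizes, function(k) {
      tr <- te <- numeric(draws)
      for (d in seq_len(draws)) {
        idx <- sample.int(nrow(X), k)
        sub <- Xt[, idx, drop = FALSE]
        tr[d] <- 1 - cpp_resub_accuracy(sub, y, G, 1e-8)
        te[d] <- 1 - cpp_loocv(sub, y, G, 1e-8)$accuracy
      }
      c(mean(tr), mean(te))
    }, numeric(2))
    out <- data.frame(size = sizes, train_error = res[1, ],
                      test_error = res[2, ])
    class(out) <- c("generalization_curve", "data.frame")
    out
  })
}

#' Write a generalization curve to TSV
#'
#' @param curve a `generalization_curve`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_generalization_curve <- function(curve, path) {
  write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
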