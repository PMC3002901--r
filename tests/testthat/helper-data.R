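# shared fixtures, all generated in code

# perfectly separated 5-class toy: class g lives at 10 * e_g in 5 dims
make_separated_toy <- function(seed = 1, n_per_class = 6, noise = 0.1) {
  crhnet:::with_seed(seed, {
    labels <- factor(rep(1:5, each = n_per_class))
    x <- 10 * outer(1:5, as.integer(labels), "==") +
      matrix(rnorm(5 * length(labels), 0, noise), 5)
    rownames(x) <- paste0("g", 1:5)
    list(x = x, labels = labels)
  })
}

# paper-shaped sample sheet: 5 times x 6 replicates, dye 3/3
make_design <- function() {
  crhnet:::synth_design(synth_config(n_spots = 1))
}

# direct Gaussian-likelihood classifier: argmin Mahalanobis distance under
# the pooled covariance (equal priors) -- independent oracle for MLHD
likelihood_classify <- function(xtrain, labels, xtest) {
  labels <- factor(labels)
  G <- nlevels(labels); n <- nrow(xtrain)
  mu <- matrix(0, G, ncol(xtrain), dimnames = list(levels(labels), NULL))
  for (l in levels(labels)) {
    mu[l, ] <- colMeans(xtrain[labels == l, , drop = FALSE])
  }
  W <- matrix(0, ncol(xtrain), ncol(xtrain))
  for (l in levels(labels)) {
    xc <- sweep(xtrain[labels == l, , drop = FALSE], 2, mu[l, ])
    W <- W + crossprod(xc)
  }
  S <- W / (n - G)
  Sinv <- solve(S)
  pred <- apply(xtest, 1, function(v) {
    d2 <- apply(mu, 1, function(m) {
      dv <- v - m
      as.numeric(t(dv) %*% Sinv %*% dv)
    })
    levels(labels)[which.min(d2)]
  })
  factor(pred, levels = levels(labels))
}

# exhaustive search over all k-subsets of a pool; returns the subsets
# attaining the best LOOCV accuracy
exhaustive_best_subsets <- function(x, labels, k = 5) {
  xt <- t(x); y <- as.integer(factor(labels)); G <- nlevels(factor(labels))
  combs <- utils::combn(nrow(x), k)
  acc <- apply(combs, 2, function(idx) {
    crhnet:::cpp_loocv_acc(xt[, idx, drop = FALSE], y, G, 1e-8)
  })
  list(best = max(acc),
       subsets = lapply(which(acc == max(acc)),
                        function(j) sort(combs[, j])))
}

# planted-edge recovery of a ggm_network against a truth edge data frame
edge_recovery <- function(net, truth_edges) {
  tkey <- paste(truth_edges$gene_i, truth_edges$gene_j)
  ekey <- paste(net$edges$gene_i, net$edges$gene_j)
  c(recall = if (length(tkey)) mean(tkey %in% ekey) else NA_real_,
    precision = if (length(ekey)) mean(ekey %in% tkey) else NA_real_)
}
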