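#' PCA of candidate genes against time-point samples
#'
#' Row-centers the genes-by-samples ratio matrix (each gene's mean ratio
#' removed) and decomposes it by principal components: scores place the
#' genes, loadings place the time-point replicate samples, so the first
#' two components give the classic candidate-gene biplot.
#'
#' @param x [ratio_matrix()] or genes-by-samples matrix, >= 2 genes and
#'   >= 2 samples.
#' @return Object of class `pca_result`: `scores` (genes x PCs),
#'   `loadings` (samples x PCs), `sdev` and `var_explained` (fractions
#'   summing to 1).
#' @export
pca_biplot <- function(x) {
  if (inherits(x, "ratio_matrix")) x <- x$ratios
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least 2 genes and 2 samples")
  xc <- x - rowMeans(x)
  if (all(abs(xc) < 1e-300)) stop("zero-variance matrix")
  pc <- prcomp(xc, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(scores = pc$x, loadings = pc$rotation, sdev = pc$sdev,
                 var_explained = ev / sum(ev), centered = xc),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "genes,", nrow(x$loadings),
      "samples\n  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(min(4, length(x$var_explained))),
                    100 * x$var_explained[seq_len(min(4, length(x$var_explained)))]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Trapezoid time weights for dynamic correlation estimation
#'
#' Weights each observation by the share of the time axis it covers: each
#' time point spans from the midpoint to its left neighbour to the
#' midpoint to its right neighbour, with the grid reflected at both ends
#' (so an equally spaced grid gives uniform weights). Sparsely sampled
#' late time points thus outweigh the dense early grid; replicates at a
#' time point split that point's weight equally. Weights are normalized
#' to sum 1.
#'
#' @param time_h numeric vector of hours, one per sample.
#' @return Numeric vector of per-sample weights.
#' @export
dynamic_weights <- function(time_h) {
  tp <- sort(unique(time_h))
  if (length(tp) < 2) {
    warning("single time point; using uniform weights")
    return(rep(1 / length(time_h), length(time_h)))
  }
  k <- length(tp)
  ext <- c(2 * tp[1] - tp[2], tp, 2 * tp[k] - tp[k - 1])
  span <- (ext[3:(k + 2)] - ext[1:k]) / 2
  w_tp <- span / sum(span)
  reps <- table(factor(time_h, levels = tp))
  w <- w_tp[match(time_h, tp)] / as.numeric(reps[match(time_h, tp)])
  unname(w / sum(w))
}

#' Shrinkage estimate of the partial-correlation matrix
#'
#' Computes a (optionally time-weighted) correlation matrix of the genes,
#' shrinks it toward the identity with an analytically estimated
#' intensity `lambda* = sum var(r_ij) / sum r_ij^2` (clipped to [0, 1]),
#' and converts the inverse to partial correlations
#' `r_p(i, j) = -O_ij / sqrt(O_ii O_jj)`. Genes are mean-centered across
#' samples before correlation. The shrinkage makes the estimate
#' well-conditioned at small sample sizes (11 genes, 30 samples).
#'
#' @param x [ratio_matrix()] or genes-by-samples matrix, >= 3 genes
#'   (with exactly 2 the partial correlation equals the shrunk
#'   correlation).
#' @param weights per-sample weights (e.g. [dynamic_weights()]); uniform
#'   when `NULL`.
#' @param lambda fixed shrinkage intensity overriding the analytic
#'   estimate.
#' @return Partial-correlation matrix with attributes `lambda` and
#'   `correlation` (the shrunk correlation matrix).
#' @export
shrinkage_pcor <- function(x, weights = NULL, lambda = NULL) {
  if (inherits(x, "ratio_matrix")) x <- x$ratios
  x <- as.matrix(x)
  p <- nrow(x); n <- ncol(x)
  if (p < 2) stop("need at least 2 genes")
  if (is.null(weights)) weights <- rep(1 / n, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  w <- weights / sum(weights)
  h1 <- 1 / (1 - sum(w^2))
  m <- as.vector(x %*% w)
  xc <- x - m
  v <- h1 * as.vector(xc^2 %*% w)
  v[v <= 0] <- 1e-300
  z <- xc / sqrt(v)
  wbar <- z %*% (t(z) * w)                # p x p, E_w[z_i z_j]
  R <- h1 * wbar
  diag(R) <- 1
  R[R > 1] <- 1; R[R < -1] <- -1
  if (is.null(lambda)) {
    # unbiased variance of each r_ij = h1^2 * var of the weighted mean of
    # the products z_i z_j (the Ledoit-Wolf / Schafer-Strimmer plug-in)
    num <- 0; den <- 0
    vm_factor <- sum(w^2) / (1 - sum(w^2))
    for (i in seq_len(p - 1)) {
      zi <- z[i, ]
      prods <- z[(i + 1):p, , drop = FALSE] *
        matrix(zi, p - i, n, byrow = TRUE)
      mbar <- as.vector(prods %*% w)
      varr <- h1^2 * vm_factor * as.vector(((prods - mbar)^2) %*% w)
      num <- num + sum(varr)
      den <- den + sum(R[i, (i + 1):p]^2)
    }
    lambda <- if (den <= 0) 1 else min(1, max(0, num / den))
  }
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1
  omega <- solve(Rs)
  d <- sqrt(diag(omega))
  pc <- -omega / outer(d, d)
  diag(pc) <- 1
  pc <- (pc + t(pc)) / 2
  ids <- rownames(x)
  if (!is.null(ids)) dimnames(pc) <- list(ids, ids)
  attr(pc, "lambda") <- lambda
  attr(pc, "correlation") <- Rs
  pc
}

#' Edge p-values under the null distribution of partial correlations
#'
#' Under the null, partial correlations follow the density
#' `f(r) proportional to (1 - r^2)^((kappa - 3) / 2)` (equivalently,
#' `r^2 ~ Beta(1/2, (kappa - 1)/2)`). The effective degrees of freedom
#' `kappa` are estimated by maximum likelihood from the full ensemble of
#' off-diagonal partial correlations, assuming most edges are null; the
#' two-sided tail probability is reported per edge. With fewer than 5
#' edges the ML fit is unstable and `kappa = n - (p - 2)` is used, with a
#' warning.
#'
#' @param pcor partial-correlation matrix from [shrinkage_pcor()].
#' @param n_samples number of samples (only needed for the small-ensemble
#'   fallback).
#' @param kappa fixed degrees of freedom overriding the ML estimate.
#' @return Symmetric matrix of p-values (diagonal `NA`), with attribute
#'   `kappa`.
#' @export
edge_significance <- function(pcor, n_samples = NULL, kappa = NULL) {
  p <- nrow(pcor)
  r <- pcor[upper.tri(pcor)]
  if (is.null(kappa)) {
    if (length(r) < 5) {
      if (is.null(n_samples)) {
        stop("need n_samples for the small-ensemble kappa fallback")
      }
      kappa <- max(n_samples - (p - 2), 4)
      warning("fewer than 5 edges; using kappa = n - (p - 2) = ", kappa)
    } else {
      kappa <- fit_kappa_ml(r)
    }
  }
  pv <- matrix(NA_real_, p, p, dimnames = dimnames(pcor))
  up <- upper.tri(pv)
  pv[up] <- pbeta(pmin(r^2, 1), 0.5, (kappa - 1) / 2, lower.tail = FALSE)
  pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
  attr(pv, "kappa") <- kappa
  pv
}

# ML fit of the null degrees of freedom from the pcor ensemble
fit_kappa_ml <- function(r) {
  r2 <- pmin(r^2, 1 - 1e-12)
  s <- sum(log1p(-r2))
  m <- length(r)
  negll <- function(kappa) {
    m * lbeta(0.5, (kappa - 1) / 2) - ((kappa - 3) / 2) * s
  }
  if (s == 0) return(1e6)                  # all pcor exactly 0
  optimize(negll, interval = c(3 + 1e-8, 1e6))$minimum
}

#' Assemble the thresholded graphical Gaussian network
#'
#' Keeps edges satisfying `|pcor| > pcor_min` AND `p < p_max` (the
#' conjunctive filter); unconnected nodes stay in the node set.
#'
#' @param pcor partial-correlation matrix.
#' @param pvals matching p-value matrix from [edge_significance()].
#' @param pcor_min,p_max thresholds (defaults 0.35 and 0.05).
#' @return Object of class `ggm_network`: `nodes`, `edges` (gene_i,
#'   gene_j with i < j, pcor, p_value, sign), `unconnected`, and the
#'   thresholds.
#' @export
build_network <- function(pcor, pvals, pcor_min = 0.35, p_max = 0.05) {
  stopifnot(all(dim(pcor) == dim(pvals)))
  ids <- rownames(pcor)
  if (is.null(ids)) ids <- sprintf("g%04d", seq_len(nrow(pcor)))
  up <- which(upper.tri(pcor), arr.ind = TRUE)
  keep <- abs(pcor[up]) > pcor_min & pvals[up] < p_max
  edges <- data.frame(gene_i = ids[up[keep, 1]],
                      gene_j = ids[up[keep, 2]],
                      pcor = pcor[up][keep],
                      p_value = pvals[up][keep],
                      sign = ifelse(pcor[up][keep] > 0, "positive",
                                    "negative"),
                      stringsAsFactors = FALSE)
  connected <- unique(c(edges$gene_i, edges$gene_j))
  structure(list(nodes = ids, edges = edges,
                 unconnected = setdiff(ids, connected),
                 pcor_min = pcor_min, p_max = p_max,
                 pcor = pcor, p_values = pvals),
            class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  cat(sprintf("ggm_network: %d nodes, %d edges (|pcor| > %g & p < %g)\n",
              length(x$nodes), nrow(x$edges), x$pcor_min, x$p_max))
  if (nrow(x$edges) > 0) {
    apply(x$edges, 1, function(e) {
      cat(sprintf("  %s -- %s  pcor %+0.3f  p %.3g\n", e["gene_i"],
                  e["gene_j"], as.numeric(e["pcor"]),
                  as.numeric(e["p_value"])))
    })
  }
  if (length(x$unconnected) > 0) {
    cat("  unconnected:", paste(x$unconnected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' One-call graphical Gaussian network for a candidate subset
#'
#' Dynamic (trapezoid time-weighted) shrinkage partial correlations, edge
#' significance from the null ensemble, and the conjunctive threshold
#' filter.
#'
#' @param rm [ratio_matrix()] restricted to the candidate genes, or a
#'   plain matrix plus `time_h`.
#' @param time_h hours per sample (for the dynamic weights); `NULL`
#'   disables weighting (static estimation).
#' @param pcor_min,p_max edge thresholds.
#' @return A `ggm_network`.
#' @export
ggm_network <- function(rm, time_h = NULL, pcor_min = 0.35, p_max = 0.05) {
  if (inherits(rm, "ratio_matrix")) {
    if (is.null(time_h)) time_h <- rm$samples$time_h
    x <- rm$ratios
  } else x <- as.matrix(rm)
  w <- if (is.null(time_h)) NULL else dynamic_weights(time_h)
  pc <- shrinkage_pcor(x, weights = w)
  pv <- edge_significance(pc, n_samples = ncol(x))
  build_network(pc, pv, pcor_min = pcor_min, p_max = p_max)
}

#' Write a network edge list to TSV (and optionally GraphML)
#'
#' @param net a `ggm_network`.
#' @param path edge-list TSV path.
#' @param graphml_path optional GraphML output (requires igraph).
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, graphml_path = NULL) {
  write.table(net$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(graphml_path)) {
    if (!requireNamespace("igraph", quietly = TRUE)) {
      stop("igraph is required for GraphML output")
    }
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = data.frame(name = net$nodes))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(path)
}
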