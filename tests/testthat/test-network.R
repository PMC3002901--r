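test_that("PCA biplot satisfies the spectral identities", {
  set.seed(110)
  x <- matrix(rnorm(24), 4, 6)
  p <- pca_biplot(x)
  expect_equal(sum(p$var_explained), 1)
  # reconstruction identity: scores %*% t(loadings) = row-centered matrix
  expect_lt(max(abs(p$scores %*% t(p$loadings) - (x - rowMeans(x)))), 1e-8)
  # oracle: compose an SVD by hand
  sv <- svd(x - rowMeans(x))
  expect_equal(abs(p$scores[, 1]), abs(sv$u[, 1] * sv$d[1]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(abs(p$loadings[, 1]), abs(sv$v[, 1]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PCA degenerate and symmetry cases behave", {
  # rank-1 matrix: PC1 explains everything
  x <- outer(c(1, 2, 3), c(1, -1, 2, 0.5))
  x <- x + rnorm(12, 0, 1e-10)
  p <- pca_biplot(x)
  expect_gt(p$var_explained[1], 1 - 1e-6)
  # mirror-profile genes get opposite PC1 scores
  v <- c(1, 3, -2, 0.5, 2, -1)
  x2 <- rbind(v, -v) + matrix(rnorm(12, 0, 1e-8), 2)
  p2 <- pca_biplot(x2)
  expect_lt(p2$scores[1, 1] * p2$scores[2, 1], 0)
  expect_error(pca_biplot(matrix(1, 3, 4)), "zero-variance")
})

test_that("trapezoid time weights match the hand-computed grid values", {
  t30 <- rep(c(1, 3, 6, 12, 24), each = 6)
  w <- dynamic_weights(t30)
  # hand trapezoid with reflected ends: midpoints (-1..2, 2..4.5, 4.5..9,
  # 9..18, 18..30) give spans (2, 2.5, 4.5, 9, 12), total 30; each time
  # point's weight split over its 6 replicates
  hand <- rep(c(2, 2.5, 4.5, 9, 12) / 30 / 6, each = 6)
  expect_equal(w, hand, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(w), 1)
  expect_gt(w[25], w[7])               # 24 h outweighs 3 h
  # equal spacing, equal replication: uniform
  expect_equal(dynamic_weights(rep(c(1, 2, 3), each = 2)), rep(1 / 6, 6),
               ignore_attr = TRUE)
  expect_warning(w1 <- dynamic_weights(rep(5, 4)), "single")
  expect_equal(w1, rep(0.25, 4))
})

test_that("two-gene partial correlation equals the shrunk correlation", {
  set.seed(111)
  x <- matrix(rnorm(60), 2, 30)
  x[2, ] <- 0.7 * x[1, ] + 0.5 * x[2, ]
  pc <- shrinkage_pcor(x)
  R <- attr(pc, "correlation")
  expect_equal(pc[1, 2], R[1, 2], tolerance = 1e-10)
})

test_that("forced full shrinkage zeroes all partial correlations", {
  set.seed(112)
  x <- matrix(rnorm(150), 5, 30)
  pc <- shrinkage_pcor(x, lambda = 1)
  expect_true(all(abs(pc[upper.tri(pc)]) < 1e-12))
})

test_that("increasing shrinkage contracts every partial correlation", {
  set.seed(113)
  cfg <- synth_config(n_spots = 10, network_genes = 10, seed = 113)
  x <- synth_ratio_matrix(cfg)$data$ratios
  p1 <- shrinkage_pcor(x, lambda = 0.2)
  p2 <- shrinkage_pcor(x, lambda = 0.6)
  up <- upper.tri(p1)
  # contraction holds up to tiny inversion cross-terms on near-zero entries
  expect_true(all(abs(p2[up]) <= abs(p1[up]) + 0.05))
  expect_lt(max(abs(p2[up])), max(abs(p1[up])))
  expect_lt(mean(abs(p2[up])), mean(abs(p1[up])))
  expect_true(all(abs(p1[up]) <= 1))
  expect_equal(p1, t(p1))
})

test_that("chain structure zeroes the conditioned pair at large n", {
  P <- matrix(c(1, .6, 0, .6, 1, .6, 0, .6, 1), 3)
  cfg <- synth_config(n_spots = 3, network_genes = 3, planted_pcor = P,
                      replicates_per_time = 2000, seed = 114)
  x <- synth_ratio_matrix(cfg)$data$ratios
  pc <- shrinkage_pcor(x)
  expect_lt(abs(pc[1, 3]), 0.05)
  expect_equal(pc[1, 2], 0.6, tolerance = 0.05)
})

test_that("edge p-values are monotone in |pcor| with p = 1 at zero", {
  pc <- diag(1, 4)
  pc[1, 2] <- pc[2, 1] <- 0
  pc[1, 3] <- pc[3, 1] <- 0.3
  pc[1, 4] <- pc[4, 1] <- -0.6
  pc[2, 3] <- pc[3, 2] <- 0.1
  pc[2, 4] <- pc[4, 2] <- 0.45
  pc[3, 4] <- pc[4, 3] <- 0.8
  pv <- edge_significance(pc, n_samples = 30, kappa = 25)
  expect_equal(pv[1, 2], 1)
  r <- abs(pc[upper.tri(pc)]); p <- pv[upper.tri(pv)]
  expect_true(all(diff(p[order(r)]) <= 0))
  # fewer than 5 edges: fallback kappa with warning
  expect_warning(pv2 <- edge_significance(pc[1:3, 1:3], n_samples = 30),
                 "fewer than 5")
  expect_equal(attr(pv2, "kappa"), 30 - (3 - 2))
})

test_that("edge p-values are not anti-conservative under the null", {
  fr <- vapply(1:150, function(s) {
    x <- crhnet:::with_seed(400 + s, matrix(rnorm(11 * 30), 11, 30))
    pv <- edge_significance(shrinkage_pcor(x), 30)
    mean(pv[upper.tri(pv)] < 0.05)
  }, numeric(1))
  expect_lte(mean(fr), 0.07)
})

test_that("the conjunctive edge filter keeps exactly the strong significant pairs", {
  pc <- diag(1, 3)
  pv <- matrix(NA_real_, 3, 3)
  set_pair <- function(i, j, r, p) {
    pc[i, j] <<- pc[j, i] <<- r
    pv[i, j] <<- pv[j, i] <<- p
  }
  set_pair(1, 2, 0.5, 0.01)   # kept
  set_pair(1, 3, 0.5, 0.2)    # dropped: p too large
  set_pair(2, 3, 0.2, 0.001)  # dropped: pcor too small
  net <- build_network(pc, pv)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$gene_i, "g0001")
  expect_equal(net$edges$sign, "positive")
  expect_setequal(net$unconnected, "g0003")
  # all-zero pcor: edgeless network containing all nodes
  net0 <- build_network(diag(1, 4), matrix(1, 4, 4))
  expect_equal(nrow(net0$edges), 0)
  expect_length(net0$nodes, 4)
})

test_that("planted four-cluster networks are recovered at design scale", {
  res <- vapply(1:10, function(s) {
    cfg <- synth_config(n_spots = 10, network_genes = 10, seed = 500 + s)
    out <- synth_ratio_matrix(cfg)
    edge_recovery(ggm_network(out$data), out$truth$edges)
  }, numeric(2))
  expect_gte(mean(res["recall", ]), 0.6)
  expect_gte(mean(res["precision", ], na.rm = TRUE), 0.6)
})

test_that("network edge lists export to TSV and GraphML", {
  cfg <- synth_config(n_spots = 10, network_genes = 10, seed = 7)
  net <- ggm_network(synth_ratio_matrix(cfg)$data)
  tsv <- tempfile(fileext = ".tsv"); gml <- tempfile(fileext = ".graphml")
  write_network(net, tsv, gml)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
  expect_true(file.exists(gml))
})
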