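test_that("two-way ANOVA matches hand-computed SS on a toy 2x2 design", {
  # 2 times x 2 dyes, n = 2 per cell, cell means (0, 0, 1, 1) by time
  x <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 1)
  time <- factor(rep(c(1, 1, 2, 2), each = 2))
  dye <- factor(rep(c("a", "b", "a", "b"), each = 2))
  # hand SS: grand mean 0.5; SS_time = 4*(0.5)^2 * 2 = 2; all else 0
  res <- anova_time_dye(x, time, dye, interaction = TRUE)
  expect_true(res$degenerate[1])           # zero residual -> flagged
  expect_true(is.nan(res$p_time[1]))
  # with noise the decomposition must agree with stats::aov exactly
  set.seed(10)
  x2 <- x + matrix(rnorm(8, 0, 0.3), 1)
  res2 <- anova_time_dye(x2, time, dye, interaction = TRUE)
  fit <- stats::aov(x2[1, ] ~ time * dye)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  expect_equal(res2$F_time[1], tab["time", "F value"], tolerance = 1e-10)
  expect_equal(res2$p_time[1], tab["time", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(res2$F_int[1], tab["time:dye", "F value"], tolerance = 1e-10)
})

test_that("ANOVA agrees with stats::aov on the paper-shaped design", {
  cfg <- synth_config(n_spots = 6, n_de_genes = 2, n_interaction_genes = 2,
                      seed = 17)
  out <- synth_ratio_matrix(cfg)
  tf <- factor(out$data$samples$time_h)
  df <- factor(out$data$samples$dye)
  resI <- anova_time_dye(out$data, interaction = TRUE)
  resN <- anova_time_dye(out$data, interaction = FALSE)
  for (g in 1:6) {
    tabI <- summary(stats::aov(out$data$ratios[g, ] ~ tf * df))[[1]]
    rownames(tabI) <- trimws(rownames(tabI))
    expect_equal(resI$p_int[g], tabI["tf:df", "Pr(>F)"], tolerance = 1e-9)
    expect_equal(resI$p_dye[g], tabI["df", "Pr(>F)"], tolerance = 1e-9)
    tabN <- summary(stats::aov(out$data$ratios[g, ] ~ tf + df))[[1]]
    rownames(tabN) <- trimws(rownames(tabN))
    expect_equal(resN$p_time[g], tabN["tf", "Pr(>F)"], tolerance = 1e-9)
  }
  expect_equal(unique(resI$df_residual), 20)
  expect_equal(unique(resN$df_residual), 24)
})

test_that("sums of squares decompose the total to 1e-8", {
  cfg <- synth_config(n_spots = 50, n_de_genes = 10, n_interaction_genes = 5,
                      seed = 19)
  out <- synth_ratio_matrix(cfg)
  X <- out$data$ratios
  tf <- factor(out$data$samples$time_h); df <- out$data$samples$dye
  gm <- rowMeans(X)
  ss_tot <- rowSums((X - gm)^2)
  gs <- function(f) {
    G <- crhnet:::model_matrix_means(factor(f))
    m <- X %*% G
    rowSums(sweep((m - gm)^2, 2, as.numeric(table(f)), "*"))
  }
  cell <- interaction(tf, df)
  ss_res <- ss_tot - gs(cell)
  ss_int <- gs(cell) - gs(tf) - gs(df)
  expect_lt(max(abs(gs(tf) + gs(df) + ss_int + ss_res - ss_tot)), 1e-8)
})

test_that("ANOVA rejects unbalanced designs rather than choosing an SS type", {
  x <- matrix(rnorm(29), 1)
  time <- factor(rep(1:5, c(6, 6, 6, 6, 5)))
  dye <- factor(rep_len(c("a", "b"), 29))
  expect_error(anova_time_dye(x, time, dye), "unbalanced")
})

test_that("null time-effect p-values are uniform", {
  cfg <- synth_config(n_spots = 2000, seed = 23)
  out <- synth_ratio_matrix(cfg)
  res <- anova_time_dye(out$data, interaction = FALSE)
  ks <- suppressWarnings(stats::ks.test(res$p_time, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  # p(i) * m / i then cumulative minimum from the largest rank
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  p <- c(0.001, 0.02, 0.9, 0.04)
  # hand: sorted p * m / i = (0.004, 0.04, 0.0533, 0.9); cumulative min
  # from the largest rank leaves (0.004, 0.04, 0.0533, 0.9)
  expect_equal(bh_fdr(p), c(0.004, 0.04, 0.9, 0.04 * 4 / 3),
               tolerance = 1e-12)
  # permutation invariance
  set.seed(1); p2 <- runif(50)
  o <- sample(50)
  expect_equal(bh_fdr(p2)[o], bh_fdr(p2[o]))
  # NA propagation: NAs excluded from m
  expect_equal(bh_fdr(c(0.01, NA, 0.02))[2], NA_real_)
  expect_equal(bh_fdr(c(0.01, NA, 0.02))[c(1, 3)], bh_fdr(c(0.01, 0.02)))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
})

test_that("q-values dominate p-values and keep the step-up monotonicity", {
  set.seed(2)
  p <- runif(200)^2
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-12))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("trimmed Levene test matches the deviation-score ANOVA oracle", {
  set.seed(30)
  a <- rnorm(6); b <- 10 * rnorm(6)
  v <- c(a, b); g <- factor(rep(1:2, each = 6))
  lt <- levene_trimmed(v, g, trim = 0.25)
  # oracle: explicit one-way ANOVA on |x - trimmed group mean|
  dev <- abs(v - ave(v, g, FUN = function(z) mean(z, trim = 0.25)))
  oracle <- summary(stats::aov(dev ~ g))[[1]]
  rownames(oracle) <- trimws(rownames(oracle))
  expect_equal(lt$statistic, oracle["g", "F value"], tolerance = 1e-10)
  expect_equal(lt$p_value, oracle["g", "Pr(>F)"], tolerance = 1e-10)
})

test_that("trimmed Levene agrees with car::leveneTest", {
  skip_if_not_installed("car")
  set.seed(31)
  v <- rnorm(30, sd = rep(c(1, 3), 15))
  g <- factor(rep(1:5, each = 6))
  lt <- levene_trimmed(v, g, trim = 0.25)
  ct <- car::leveneTest(v, g, center = mean, trim = 0.25)
  expect_equal(lt$statistic, ct[1, "F value"], tolerance = 1e-10)
  expect_equal(lt$p_value, ct[1, "Pr(>F)"], tolerance = 1e-10)
  # trim = 0 reduces to the plain Levene test on means
  lt0 <- levene_trimmed(v, g, trim = 0)
  ct0 <- car::leveneTest(v, g, center = mean)
  expect_equal(lt0$statistic, ct0[1, "F value"], tolerance = 1e-10)
})

test_that("Levene degenerate and symmetric cases behave", {
  g <- factor(rep(1:2, each = 6))
  v <- c(1:6, 6:1)                         # identical up to permutation
  lt <- levene_trimmed(v, g, trim = 0)
  expect_equal(lt$statistic, 0, tolerance = 1e-12)
  expect_equal(lt$p_value, 1)
  expect_silent(levene_trimmed(rep(1, 12), g))   # zero spread, no error
})

test_that("Shapiro-Wilk per gene flags degenerates and detects non-normality", {
  x <- rbind(bimodal = rep(c(0, 1), each = 15),
             constant = rep(2, 30),
             normal = rnorm(30))
  rm <- ratio_matrix(x, make_design())
  res <- shapiro_per_gene(rm)
  expect_lt(res$p_value[1], 0.001)
  expect_true(res$degenerate[2])
  # reference statistic for the fixed bimodal vector
  ref <- stats::shapiro.test(rep(c(0, 1), each = 15))
  expect_equal(res$p_value[1], ref$p.value)
})

test_that("Shapiro-Wilk holds its level under normal sampling", {
  set.seed(33)
  p <- replicate(1000, stats::shapiro.test(rnorm(30))$p.value)
  expect_gte(mean(p > 0.05), 0.9)
})

test_that("prefilter excludes interaction genes and keeps DE genes", {
  cfg <- synth_config(n_spots = 200, n_de_genes = 10,
                      n_interaction_genes = 10, de_effect = 5 * 0.25,
                      seed = 41)
  out <- synth_ratio_matrix(cfg)
  pf <- prefilter(out$data)
  expect_gte(mean(out$truth$interaction_genes %in% pf$excluded$gene_id), 0.9)
  expect_true(all(out$truth$de_genes$gene_id %in% pf$preselected$gene_id))
  expect_length(intersect(pf$preselected$gene_id, pf$excluded$gene_id), 0)
  # interaction_alpha = 0 excludes nothing
  pf0 <- prefilter(out$data, interaction_alpha = 0)
  expect_equal(nrow(pf0$excluded), 0)
})

test_that("null exclusion fraction tracks the interaction alpha", {
  fr <- vapply(1:4, function(s) {
    out <- synth_ratio_matrix(synth_config(n_spots = 500, seed = 50 + s))
    nrow(prefilter(out$data)$excluded) / 500
  }, numeric(1))
  # ~ Binomial(500, 0.01) per seed; +/- 2 s.e. around 0.01 over 4 seeds
  expect_lt(abs(mean(fr) - 0.01), 2 * sqrt(0.01 * 0.99 / 2000))
})
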