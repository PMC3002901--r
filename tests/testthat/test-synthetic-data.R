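test_that("null configuration yields identical channels and zero ratios", {
  cfg <- synth_config(n_spots = 40, n_print_tips = 2, n_de_genes = 0,
                      noise_sd = 0, dye_bias_amplitude = 0, seed = 1)
  out <- synth_two_color(cfg)
  expect_equal(out$data$cy3, out$data$cy5, tolerance = 1e-12)
  rm0 <- synth_ratio_matrix(cfg)
  expect_true(all(rm0$data$ratios == 0))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- synth_config(n_spots = 100, n_print_tips = 4, n_de_genes = 10,
                      n_interaction_genes = 5, seed = 77)
  a <- synth_two_color(cfg); b <- synth_two_color(cfg)
  expect_identical(a$data$cy3, b$data$cy3)
  expect_identical(a$truth$de_genes, b$truth$de_genes)
  ra <- synth_ratio_matrix(cfg); rb <- synth_ratio_matrix(cfg)
  expect_identical(ra$data$ratios, rb$data$ratios)
})

test_that("noiseless ratio matrix reproduces planted profiles exactly", {
  cfg <- synth_config(n_spots = 30, n_de_genes = 6, noise_sd = 0,
                      de_effect = 1, seed = 3)
  out <- synth_ratio_matrix(cfg)
  tf <- factor(out$data$samples$time_h)
  for (g in seq_len(6)) {
    means <- tapply(out$data$ratios[g, ], tf, mean)
    expect_equal(as.numeric(means), as.numeric(out$truth$profile_means[g, ]),
                 tolerance = 1e-12)
  }
})

test_that("interaction genes carry the configured dye contrast at every time", {
  eff <- 0.9
  cfg <- synth_config(n_spots = 20, n_interaction_genes = 4, noise_sd = 0,
                      interaction_effect = eff, seed = 5)
  out <- synth_ratio_matrix(cfg)
  sm <- out$data$samples
  for (g in match(out$truth$interaction_genes, out$data$gene_ids)) {
    for (t in unique(sm$time_h)) {
      d1 <- mean(out$data$ratios[g, sm$time_h == t & sm$dye == "treated_cy3"])
      d2 <- mean(out$data$ratios[g, sm$time_h == t & sm$dye == "treated_cy5"])
      expect_equal(abs(d1 - d2), eff, tolerance = 1e-12)
    }
    # alternating sign: the residual dye main effect is only eff / 5
    d1 <- mean(out$data$ratios[g, sm$dye == "treated_cy3"])
    d2 <- mean(out$data$ratios[g, sm$dye == "treated_cy5"])
    expect_equal(d1 - d2, eff / 5, tolerance = 1e-12)
  }
})

test_that("planted chain network zeroes the 1,3 partial correlation at large n", {
  P <- matrix(c(1, .6, 0, .6, 1, .6, 0, .6, 1), 3)
  cfg <- synth_config(n_spots = 3, network_genes = 3, planted_pcor = P,
                      replicates_per_time = 2000, seed = 11)
  out <- synth_ratio_matrix(cfg)
  # oracle: invert the sample covariance directly
  S <- cov(t(out$data$ratios))
  O <- solve(S)
  pc13 <- -O[1, 3] / sqrt(O[1, 1] * O[3, 3])
  pc12 <- -O[1, 2] / sqrt(O[1, 1] * O[2, 2])
  expect_lt(abs(pc13), 0.05)
  expect_equal(pc12, 0.6, tolerance = 0.05)
})

test_that("network-gene covariance converges to the planted covariance", {
  cfg <- synth_config(n_spots = 10, network_genes = 10,
                      replicates_per_time = 2000, seed = 13)
  out <- synth_ratio_matrix(cfg)
  emp <- cov(t(out$data$ratios))
  P <- default_planted_pcor(10)
  sig <- solve(crhnet:::pcor_to_precision(P))
  d <- sqrt(diag(sig))
  sig <- (sig / outer(d, d)) * cfg$noise_sd^2
  expect_lt(max(abs(emp - sig)), 0.05)
})

test_that("invalid configurations are rejected with diagnostics", {
  expect_error(synth_config(replicates_per_time = 5), "even")
  expect_error(synth_config(n_spots = 5, n_de_genes = 4,
                            n_interaction_genes = 4), "exceed")
  bad <- matrix(0.9, 3, 3); diag(bad) <- 1   # jointly impossible triangle
  expect_error(synth_config(n_spots = 3, network_genes = 3,
                            planted_pcor = bad), "positive definite")
})

test_that("injected dye bias shows up in raw M and is removed by loess", {
  cfg <- synth_config(n_spots = 400, n_print_tips = 4, noise_sd = 0.2,
                      dye_bias_amplitude = 0.8, seed = 31)
  out <- synth_two_color(cfg)
  ma <- compute_ma(out$data)
  # oracle: the injected smooth bias function per print tip
  amp <- out$truth$bias$amplitude_per_tip
  ar <- out$truth$bias$a_range
  worst_raw <- 0; worst_norm_list <- c()
  man <- loess_normalize(ma)
  for (tip in c(1, 4)) {
    rows <- which(ma$print_tip == tip)
    a <- ma$A[rows, 1]
    as <- 2 * (a - ar[1]) / (ar[2] - ar[1]) - 1
    bias <- amp[tip] * (as + out$truth$bias$curvature * as^2)
    resid_raw <- ma$M[rows, 1] - out$truth$true_M[rows, 1] *
      ifelse(out$data$arrays$dye[1] == "treated_cy3", 1, -1) - bias
    # raw M minus truth equals the injected bias (exactly, by construction)
    expect_lt(max(abs(resid_raw)), 1e-10)
    # after normalization the binned trend sits below the noise level
    bins <- cut(a, stats::quantile(a, 0:5 / 5), include.lowest = TRUE)
    trend <- tapply(man$M[rows, 1] - mean(man$M[rows, 1]), bins, mean)
    expect_lt(max(abs(trend)), cfg$noise_sd)
  }
})

test_that("truth JSON round-trips the planted gene sets", {
  cfg <- synth_config(n_spots = 30, n_de_genes = 4, n_interaction_genes = 3,
                      seed = 2)
  out <- synth_ratio_matrix(cfg)
  path <- tempfile(fileext = ".json")
  write_synth_truth(out$truth, path)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(got$interaction_genes, out$truth$interaction_genes)
  expect_equal(got$de_genes$gene_id, out$truth$de_genes$gene_id)
})
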