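make_tc <- function(cy3, cy5, tips = rep(1, nrow(cy3)),
                    dye = rep("treated_cy3", ncol(cy3))) {
  two_color_set(cy3, cy5, tips,
                data.frame(sample_id = paste0("a", seq_len(ncol(cy3))),
                           time_h = 1, dye = dye,
                           replicate = seq_len(ncol(cy3))))
}

test_that("background erasure removes the bottom fraction deterministically", {
  tc <- make_tc(matrix(1:10, 10), matrix(rep(100, 10), 10))
  f <- suppressWarnings(filter_background(tc, 0.10))  # constant cy5 fixture
  expect_identical(which(!f$mask[, 1]), 1L)      # the value 1, via cy3
  expect_identical(filter_background(tc, 0)$mask, tc$mask)
  # ties at the boundary: 20 values, many equal; floor(0.1 * 20) = 2 erased
  v <- c(rep(1, 5), 2:16)
  tc2 <- make_tc(matrix(v, 20), matrix(rep(100, 20), 20))
  f2 <- suppressWarnings(filter_background(tc2, 0.10))
  # oracle by stable sort on (intensity, spot order): spots 1 and 2
  expect_identical(which(!f2$mask[, 1]), c(1L, 2L))
  expect_equal(unname(attr(f2, "n_erased")[1, "cy3"]), 2L)
})

test_that("MA values, orientation and the algebraic inverse are exact", {
  tc <- make_tc(matrix(1024, 1), matrix(1024, 1))
  ma <- compute_ma(tc)
  expect_equal(unname(ma$M[1, 1]), 0)
  expect_equal(unname(ma$A[1, 1]), 10)
  tc2 <- make_tc(matrix(4096, 1), matrix(1024, 1))
  expect_equal(unname(compute_ma(tc2)$M[1, 1]), 2)
  tc3 <- make_tc(matrix(4096, 1), matrix(1024, 1), dye = "treated_cy5")
  expect_equal(unname(compute_ma(tc3)$M[1, 1]), -2)
  # inverse: I = 2^(A +/- Mchan/2) reproduces the inputs
  cy3 <- matrix(runif(20, 10, 1e4), 10); cy5 <- matrix(runif(20, 10, 1e4), 10)
  tc4 <- make_tc(cbind(cy3), cbind(cy5))
  ma4 <- compute_ma(tc4)
  expect_equal(2^(ma4$A + ma4$M / 2), unname(tc4$cy3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(2^(ma4$A - ma4$M / 2), unname(tc4$cy5), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("zero intensities are masked, not propagated", {
  cy3 <- matrix(c(0, 100, 200), 3); cy5 <- matrix(c(50, 100, 200), 3)
  ma <- compute_ma(make_tc(cy3, cy5))
  expect_false(ma$mask[1, 1])
  expect_true(all(is.na(ma$M[1, 1])))
  expect_true(all(is.finite(ma$M[2:3, 1])))
})

test_that("loess normalization flattens constant and linear trends", {
  set.seed(4)
  a <- seq(2, 12, length.out = 200)
  # constant M
  tcc <- make_tc(matrix(2^(a + 0.25), ncol = 1), matrix(2^(a - 0.25), ncol = 1))
  mac <- loess_normalize(compute_ma(tcc))
  expect_lt(max(abs(mac$M)), 1e-8)
  # exact linear M(A) = 0.5 A: interior residuals at machine precision,
  # oracle = the known generating line
  m <- 0.5 * a
  tcl <- make_tc(matrix(2^(a + m / 2), ncol = 1), matrix(2^(a - m / 2), ncol = 1))
  mal <- loess_normalize(compute_ma(tcl))
  expect_lt(max(abs(mal$M[20:180, 1])), 1e-6)
})

test_that("loess normalization is idempotent on smooth trends", {
  # idempotence holds where the trend lies in the local-regression span
  # (smooth quadratic bias, no replicate noise)
  set.seed(21)
  a <- sort(runif(250, 3, 13))
  m <- 0.3 * (a - 8) + 0.05 * (a - 8)^2
  tc <- make_tc(matrix(2^(a + m / 2), ncol = 1),
                matrix(2^(a - m / 2), ncol = 1))
  m1 <- loess_normalize(compute_ma(tc))
  m2 <- loess_normalize(m1)
  expect_lt(max(abs(m2$M - m1$M), na.rm = TRUE), 1e-6)
})

test_that("small print-tip groups fall back to a whole-array fit with warning", {
  set.seed(9)
  a <- runif(40, 4, 12)
  tc <- make_tc(matrix(2^(a + 0.1), ncol = 1), matrix(2^(a - 0.1), ncol = 1),
                tips = c(rep(1, 36), rep(2, 4)))
  expect_warning(loess_normalize(compute_ma(tc), min_spots = 10),
                 "whole-array")
})

test_that("complete-case filtering keeps exactly the everywhere-present spots", {
  cfg <- synth_config(n_spots = 12, n_print_tips = 2, seed = 6)
  ma <- compute_ma(synth_two_color(cfg)$data)
  ma$mask[2, 3] <- FALSE
  ma$M[2, 3] <- NA
  rm <- complete_case_filter(ma)
  expect_equal(nrow(rm$ratios), 11)
  expect_false("g0002" %in% rm$gene_ids)
  # no masking -> identity on row count
  ma2 <- compute_ma(synth_two_color(cfg)$data)
  expect_equal(nrow(complete_case_filter(ma2)$ratios), 12)
})

test_that("background erasure survivors match an independent presence scan", {
  cfg <- synth_config(n_spots = 200, n_print_tips = 2, seed = 14)
  tc <- filter_background(synth_two_color(cfg)$data, 0.10)
  ma <- loess_normalize(compute_ma(tc), min_spots = 10)
  rm <- complete_case_filter(ma)
  # oracle: boolean all-present reduction on the mask
  expect_equal(nrow(rm$ratios), sum(rowSums(tc$mask) == ncol(tc$mask)))
  # filtering never invents values: every output entry occurs in the
  # normalized M matrix
  expect_true(all(rm$ratios %in% ma$M[!is.na(ma$M)]))
})

test_that("end-to-end dye relabeling negates M and preserves A", {
  cfg <- synth_config(n_spots = 120, n_print_tips = 2, n_de_genes = 5,
                      dye_bias_amplitude = 0.4, seed = 8)
  tc <- synth_two_color(cfg)$data
  tcf <- tc
  tcf$arrays$dye <- ifelse(tc$arrays$dye == "treated_cy3",
                           "treated_cy5", "treated_cy3")
  m1 <- loess_normalize(compute_ma(tc))
  m2 <- loess_normalize(compute_ma(tcf))
  expect_equal(m2$M, -m1$M, tolerance = 1e-10)
  expect_equal(m2$A, m1$A)
})
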