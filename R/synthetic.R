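#' Configuration for the synthetic two-color time-course generator
#'
#' Describes a paper-shaped dye-swap experiment: five time points after CRH
#' stimulation, six technical replicates per time point (three per dye
#' orientation), spots laid out in print-tip groups. The generator plants
#' known structure -- time-profile differentially expressed (DE) genes,
#' dye-by-time interaction genes, and a sparse partial-correlation network
#' -- so that every downstream stage can be tested against ground truth.
#'
#' @param n_spots number of spots/genes.
#' @param n_print_tips number of print-tip groups (default 48).
#' @param time_points_h sampling times in hours.
#' @param replicates_per_time technical replicates per time point; must be
#'   even (half per dye orientation).
#' @param n_de_genes number of planted DE genes, cycled over `de_profiles`.
#' @param de_profiles named list of unit-scale per-time mean log2-ratio
#'   profiles; defaults to early-up, mid-up and late-up shapes typical of
#'   immediate-early, metabolic and long-term CRH response genes.
#' @param de_effect multiplier applied to the unit profiles, in log2 units.
#'   Defaults to `3 * noise_sd`.
#' @param n_interaction_genes number of planted dye-by-time interaction
#'   genes. Their dye-orientation offset has magnitude `interaction_effect`
#'   at every time point with alternating sign over time, so nearly all of
#'   the dye contrast loads on the time-by-dye interaction (the residual
#'   dye main effect is `interaction_effect / n_times`).
#' @param interaction_effect log2 difference between dye orientations.
#' @param network_genes number of genes carrying the planted
#'   partial-correlation structure (mean profile zero).
#' @param planted_pcor partial-correlation matrix for the network genes
#'   (diagonal 1). Defaults to a four-cluster topology of ten genes with
#'   one negative edge and one unconnected node when `network_genes == 10`.
#' @param weak_de_sd standard deviation of random weak per-time mean
#'   profiles given to background genes (0 = pure null background). Use a
#'   positive value to emulate a pool of univariately preselected genes,
#'   all of which carry some time signal.
#' @param noise_sd replicate noise, log2 units.
#' @param dye_bias_amplitude maximum amplitude of the intensity-dependent
#'   print-tip dye bias on M (log2 units); per-tip amplitudes are spread
#'   over `[-amplitude, amplitude]`.
#' @param dye_bias_curvature weight of the quadratic term of the bias as a
#'   function of scaled average log-intensity A.
#' @param a_range range of A (average log2 intensity); each spot gets a
#'   persistent baseline drawn uniformly over this range (intensity is
#'   log-uniform), so dim spots are dim on every array, as expression
#'   level dictates on real arrays.
#' @param a_jitter_sd per-array jitter of a spot's average log2 intensity
#'   around its baseline.
#' @param background_floor additive intensity offset applied to both
#'   channels (scanner floor).
#' @param seed integer seed governing all randomness of the generator.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_spots = 400,
                         n_print_tips = 48,
                         time_points_h = c(1, 3, 6, 12, 24),
                         replicates_per_time = 6,
                         n_de_genes = 0,
                         de_profiles = default_de_profiles(),
                         de_effect = 3 * noise_sd,
                         n_interaction_genes = 0,
                         interaction_effect = 3 * noise_sd,
                         network_genes = 0,
                         planted_pcor = NULL,
                         weak_de_sd = 0,
                         noise_sd = 0.25,
                         dye_bias_amplitude = 0,
                         dye_bias_curvature = 1,
                         a_range = c(6, 16),
                         a_jitter_sd = 0.5,
                         background_floor = 0,
                         seed = NULL) {
  cfg <- list(n_spots = as.integer(n_spots),
              n_print_tips = as.integer(n_print_tips),
              time_points_h = as.numeric(time_points_h),
              replicates_per_time = as.integer(replicates_per_time),
              n_de_genes = as.integer(n_de_genes),
              de_profiles = de_profiles,
              de_effect = de_effect,
              n_interaction_genes = as.integer(n_interaction_genes),
              interaction_effect = interaction_effect,
              network_genes = as.integer(network_genes),
              planted_pcor = planted_pcor,
              weak_de_sd = weak_de_sd,
              noise_sd = noise_sd,
              dye_bias_amplitude = dye_bias_amplitude,
              dye_bias_curvature = dye_bias_curvature,
              a_range = a_range,
              a_jitter_sd = a_jitter_sd,
              background_floor = background_floor,
              seed = seed)
  if (cfg$replicates_per_time %% 2L != 0L) {
    stop("replicates_per_time must be even (half per dye orientation)")
  }
  if (cfg$n_de_genes + cfg$n_interaction_genes + cfg$network_genes >
      cfg$n_spots) {
    stop("planted genes exceed n_spots")
  }
  for (p in cfg$de_profiles) {
    if (length(p) != length(cfg$time_points_h)) {
      stop("each DE profile must have one value per time point")
    }
  }
  if (cfg$network_genes > 0) {
    P <- cfg$planted_pcor
    if (is.null(P)) P <- default_planted_pcor(cfg$network_genes)
    if (!isTRUE(all.equal(P, t(P))) || any(diag(P) != 1)) {
      stop("planted_pcor must be symmetric with unit diagonal")
    }
    omega <- pcor_to_precision(P)
    ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) {
      stop("planted partial-correlation network is not positive definite ",
           "(minimum precision eigenvalue ", signif(min(ev), 3), ")")
    }
    cfg$planted_pcor <- P
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Default unit-scale DE time profiles
#'
#' Early-up (immediate-early response, high at 1 h, decayed and slightly
#' reversed by 24 h), mid-up (metabolic response peaking at 6-12 h) and
#' late-up (long-term response at 24 h) shapes.
#'
#' @return Named list of numeric length-5 vectors.
#' @export
default_de_profiles <- function() {
  list(early = c(1, 0.5, 0.1, -0.1, -0.3),
       mid   = c(0, 0.45, 1, 0.6, 0.1),
       late  = c(-0.3, -0.15, 0.05, 0.55, 1))
}

#' Default planted partial-correlation topology
#'
#' Four clusters over ten nodes -- a pair, a chain of three, a negatively
#' correlated pair and a positive pair -- plus one unconnected node,
#' mirroring the cluster structure typically recovered among CRH-regulated
#' candidate genes.
#'
#' Tightly co-regulated pairs get a strong partial correlation (0.8 by
#' default: cluster members share essentially one expression profile up
#' to replicate noise); the three-gene chain uses 0.65, near the largest
#' value for which the chain precision matrix stays positive definite.
#' These magnitudes make the planted structure detectable at the
#' 30-sample design scale under shrinkage estimation with the
#' `|pcor| > 0.35` edge filter.
#'
#' @param n number of network genes (must be >= 2).
#' @param strength absolute planted partial correlation for pair edges.
#' @param chain_strength partial correlation along the three-gene chain.
#' @return An `n` x `n` partial-correlation matrix with unit diagonal.
#' @export
default_planted_pcor <- function(n, strength = 0.8,
                                 chain_strength = 0.65) {
  if (n < 2) stop("need at least 2 network genes")
  P <- diag(1, n)
  edges <- list(c(1, 2, strength))
  if (n >= 5) edges <- c(edges, list(c(3, 4, chain_strength),
                                     c(4, 5, chain_strength)))
  if (n >= 7) edges <- c(edges, list(c(6, 7, -strength)))
  if (n >= 9) edges <- c(edges, list(c(8, 9, strength)))
  for (e in edges) {
    i <- e[1]; j <- e[2]
    if (j <= n) P[i, j] <- P[j, i] <- e[3]
  }
  P
}

# precision matrix with unit diagonal whose implied partial correlations
# equal the off-diagonal entries of P
pcor_to_precision <- function(P) {
  omega <- -P
  diag(omega) <- 1
  omega
}

# design frame: samples in time-major order, dye orientations 3/3 within
# each time point
synth_design <- function(cfg) {
  nt <- length(cfg$time_points_h)
  reps <- cfg$replicates_per_time
  half <- reps %/% 2L
  data.frame(
    sample_id = sprintf("t%02dr%d", rep(seq_len(nt), each = reps),
                        rep(seq_len(reps), nt)),
    time_h = rep(cfg$time_points_h, each = reps),
    dye = rep(rep(c("treated_cy3", "treated_cy5"), c(half, reps - half)), nt),
    replicate = rep(seq_len(reps), nt),
    stringsAsFactors = FALSE)
}

# per-gene planted mean log2 ratio for every (time, dye) cell, plus truth
plant_structure <- function(cfg) {
  nt <- length(cfg$time_points_h)
  n <- cfg$n_spots
  ids <- sprintf("g%04d", seq_len(n))
  profile <- matrix(0, n, nt, dimnames = list(ids, NULL))
  roles <- rep("background", n)
  de_label <- rep(NA_character_, n)
  idx <- 0L
  if (cfg$n_de_genes > 0) {
    pn <- names(cfg$de_profiles)
    for (i in seq_len(cfg$n_de_genes)) {
      g <- idx + i
      lab <- pn[((i - 1L) %% length(pn)) + 1L]
      profile[g, ] <- cfg$de_effect * cfg$de_profiles[[lab]]
      roles[g] <- "de"
      de_label[g] <- lab
    }
    idx <- idx + cfg$n_de_genes
  }
  # interaction genes: dye offset +/- interaction_effect/2 with sign
  # alternating over time, so the time-by-dye interaction carries almost
  # the full configured magnitude (a constant-sign offset would be a pure
  # dye main effect with zero interaction SS)
  int_sign <- rep_len(c(1, -1), nt)
  if (cfg$n_interaction_genes > 0) {
    roles[idx + seq_len(cfg$n_interaction_genes)] <- "interaction"
    idx <- idx + cfg$n_interaction_genes
  }
  if (cfg$network_genes > 0) {
    roles[idx + seq_len(cfg$network_genes)] <- "network"
    idx <- idx + cfg$network_genes
  }
  if (cfg$weak_de_sd > 0) {
    bg <- which(roles == "background")
    profile[bg, ] <- matrix(rnorm(length(bg) * nt, 0, cfg$weak_de_sd),
                            length(bg), nt)
  }
  P <- cfg$planted_pcor
  edges <- NULL
  sigma <- NULL
  if (cfg$network_genes > 0) {
    omega <- pcor_to_precision(P)
    sig <- solve(omega)
    d <- sqrt(diag(sig))
    sigma <- (sig / outer(d, d)) * cfg$noise_sd^2
    up <- which(upper.tri(P) & P != 0, arr.ind = TRUE)
    net_ids <- ids[roles == "network"]
    edges <- data.frame(gene_i = net_ids[up[, 1]], gene_j = net_ids[up[, 2]],
                        pcor = P[up], stringsAsFactors = FALSE)
  }
  list(ids = ids, profile = profile, roles = roles, de_label = de_label,
       int_sign = int_sign, sigma = sigma,
       truth = list(
         de_genes = data.frame(gene_id = ids[roles == "de"],
                               profile = de_label[roles == "de"],
                               stringsAsFactors = FALSE),
         interaction_genes = ids[roles == "interaction"],
         network_genes = ids[roles == "network"],
         edges = edges,
         profile_means = profile))
}

# mean log2 ratio of gene g in sample s (time t, dye d)
cell_means <- function(cfg, st, design) {
  nt <- length(cfg$time_points_h)
  tidx <- match(design$time_h, cfg$time_points_h)
  dsign <- ifelse(design$dye == "treated_cy3", 1, -1)
  mu <- st$profile[, tidx, drop = FALSE]
  if (cfg$n_interaction_genes > 0) {
    int_rows <- which(st$roles == "interaction")
    off <- 0.5 * cfg$interaction_effect * st$int_sign[tidx] * dsign
    mu[int_rows, ] <- sweep(mu[int_rows, , drop = FALSE], 2, off, "+")
  }
  mu
}

#' Generate a planted genes-by-samples log2-ratio matrix
#'
#' Shortcut generator that skips intensity space: samples the ratio matrix
#' directly from the planted per-(time, dye) means, replicate noise, and
#' (for network genes) the planted partial-correlation structure.
#'
#' @param config a [synth_config()].
#' @return List with elements `data` (a [ratio_matrix()]) and `truth`
#'   (planted DE genes with profile labels, interaction gene ids, network
#'   gene ids, true edges, and the per-gene mean profile matrix).
#' @examples
#' out <- synth_ratio_matrix(synth_config(n_spots = 50, n_de_genes = 6,
#'                                        seed = 42))
#' out$data
#' out$truth$de_genes
#' @export
synth_ratio_matrix <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    design <- synth_design(config)
    st <- plant_structure(config)
    mu <- cell_means(config, st, design)
    n <- config$n_spots
    ns <- nrow(design)
    X <- mu + matrix(rnorm(n * ns, 0, config$noise_sd), n, ns)
    if (config$network_genes > 0) {
      net <- which(st$roles == "network")
      L <- chol(st$sigma)
      Z <- matrix(rnorm(length(net) * ns), length(net), ns)
      X[net, ] <- mu[net, , drop = FALSE] + t(L) %*% Z
    }
    rownames(X) <- st$ids
    list(data = ratio_matrix(X, design), truth = st$truth)
  })
}

#' Generate a planted two-color intensity dataset
#'
#' Full-path generator: per-spot Cy3/Cy5 intensities on 30 arrays (5 time
#' points x 6 replicates by default), with the planted log2 ratios, a
#' smooth intensity- and print-tip-dependent dye bias injected on the
#' channel-space log ratio, and log-uniform average intensities, so that
#' MA computation, background erasure and print-tip loess normalization
#' can be tested against the injected truth.
#'
#' @param config a [synth_config()].
#' @return List with elements `data` (a `two_color_set`) and `truth` (as
#'   in [synth_ratio_matrix()], plus the bias function parameters).
#' @export
synth_two_color <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    design <- synth_design(config)
    st <- plant_structure(config)
    mu <- cell_means(config, st, design)
    n <- config$n_spots
    ns <- nrow(design)
    M_true <- mu + if (config$noise_sd > 0) {
      matrix(rnorm(n * ns, 0, config$noise_sd), n, ns)
    } else 0
    if (config$network_genes > 0 && config$noise_sd > 0) {
      net <- which(st$roles == "network")
      L <- chol(st$sigma)
      Z <- matrix(rnorm(length(net) * ns), length(net), ns)
      M_true[net, ] <- mu[net, , drop = FALSE] + t(L) %*% Z
    }
    a_base <- runif(n, config$a_range[1], config$a_range[2])
    A <- a_base + matrix(rnorm(n * ns, 0, config$a_jitter_sd), n, ns)
    A <- pmin(pmax(A, config$a_range[1]), config$a_range[2])
    tip <- rep(seq_len(config$n_print_tips), length.out = n)
    amp <- if (config$n_print_tips > 1) {
      config$dye_bias_amplitude *
        seq(-1, 1, length.out = config$n_print_tips)
    } else config$dye_bias_amplitude
    As <- 2 * (A - config$a_range[1]) /
      (config$a_range[2] - config$a_range[1]) - 1
    bias <- amp[tip] * (As + config$dye_bias_curvature * As^2)
    dsign <- ifelse(design$dye == "treated_cy3", 1, -1)
    # channel-space log ratio log2(Cy3) - log2(Cy5): physical dye bias is
    # orientation-independent, the biological ratio flips with orientation
    M_chan <- sweep(M_true, 2, dsign, "*") + bias
    cy3 <- 2^(A + M_chan / 2) + config$background_floor
    cy5 <- 2^(A - M_chan / 2) + config$background_floor
    rownames(cy3) <- rownames(cy5) <- st$ids
    colnames(cy3) <- colnames(cy5) <- design$sample_id
    tc <- two_color_set(cy3 = cy3, cy5 = cy5, print_tip = tip,
                        arrays = design)
    truth <- st$truth
    truth$true_M <- M_true
    truth$bias <- list(amplitude_per_tip = amp,
                       curvature = config$dye_bias_curvature,
                       a_range = config$a_range)
    list(data = tc, truth = truth)
  })
}

#' Write planted truth to JSON
#'
#' @param truth the `truth` element returned by the generators.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_synth_truth <- function(truth, path) {
  keep <- truth[c("de_genes", "interaction_genes", "network_genes", "edges")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Construct a pool with a unique perfectly discriminating 5-gene subset
#'
#' Builds a 20-gene, 30-sample instance (5 time classes, 6 replicates) in
#' which exactly one 5-subset attains leave-one-out accuracy 1: three
#' "step" genes each carrying one class boundary, plus a complementary
#' pair that carries the remaining boundary only jointly (each member is
#' swamped by shared noise on its own). The remaining genes are pure
#' noise. Exhaustive search over all choose(20, 5) = 15504 subsets can
#' verify uniqueness, which makes the instance an oracle for the
#' stochastic wrapper selectors.
#'
#' @param seed integer seed.
#' @param n_noise number of pure-noise genes appended (default 15).
#' @return List with `x` (genes x samples matrix), `labels` (factor with 5
#'   levels, 6 samples each) and `signal_genes` (indices of the planted
#'   subset).
#' @export
synth_oracle_pool <- function(seed = NULL, n_noise = 15) {
  with_seed(seed, {
    classes <- rep(1:5, each = 6)
    n <- length(classes)
    sep <- 4; sd_step <- 0.35; sd_shared <- 3; sd_noise <- 1
    step <- function(b) sep * (classes > b)
    g1 <- step(1) + rnorm(n, 0, sd_step)
    g2 <- step(2) + rnorm(n, 0, sd_step)
    g3 <- step(3) + rnorm(n, 0, sd_step)
    u <- rnorm(n, 0, sd_shared)
    g4 <- step(4) / 2 + u + rnorm(n, 0, sd_step)
    g5 <- step(4) / 2 - u + rnorm(n, 0, sd_step)
    noise <- matrix(rnorm(n_noise * n, 0, sd_noise), n_noise, n)
    x <- rbind(g1, g2, g3, g4, g5, noise)
    rownames(x) <- sprintf("g%04d", seq_len(nrow(x)))
    colnames(x) <- sprintf("s%02d", seq_len(n))
    list(x = x, labels = factor(classes), signal_genes = 1:5)
  })
}
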