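#' Parameters of the simulated-annealing selector (INSEL)
#'
#' Input selection by simulated annealing over fixed-size gene subsets:
#' the energy of a chromosome is its LOOCV classification error under the
#' linear discriminant, a mutation exchanges one gene against a random
#' pool gene, moves are accepted by the Metropolis rule, and the starting
#' temperature is calibrated from the energy landscape itself (mean
#' variation of the error over randomly drawn chromosomes). Published
#' settings: chromosome size 5, 1000 energy evaluations per search,
#' 10000 calibration chromosomes, up to 2500 solutions collected.
#'
#' @param k chromosome size.
#' @param maxit total energy evaluations per search (including the
#'   initial chromosome).
#' @param n_calibration random chromosomes for the temperature estimate.
#' @param max_solutions number of annealing searches per run.
#' @param goal_accuracy LOOCV accuracy a returned chromosome must reach
#'   (re-evaluated, not trusted from the search) to count as a solution.
#' @param tmax evaluations per temperature step of the logarithmic
#'   cooling schedule `T_t = T0 / ln(((t-1) %/% tmax) * tmax + e)`.
#' @param temp_floor floor applied when the calibrated temperature is 0.
#' @param seed RNG seed for [run_insel()].
#' @return List of class `sa_params`.
#' @export
sa_params <- function(k = 5, maxit = 1000, n_calibration = 10000,
                      max_solutions = 2500, goal_accuracy = 1.0,
                      tmax = 10, temp_floor = 1e-3, seed = NULL) {
  stopifnot(k >= 2, maxit >= 1, n_calibration >= 2, max_solutions >= 0,
            tmax >= 1, temp_floor > 0)
  structure(list(k = as.integer(k), maxit = as.integer(maxit),
                 n_calibration = as.integer(n_calibration),
                 max_solutions = as.integer(max_solutions),
                 goal_accuracy = goal_accuracy, tmax = as.integer(tmax),
                 temp_floor = temp_floor, seed = seed),
            class = "sa_params")
}

#' Calibrate the starting temperature from the energy landscape
#'
#' Draws `n_calibration` random chromosomes, computes each one's LOOCV
#' classification error (the generalized energy), and returns the mean
#' absolute difference between successive energies in this stream. A
#' degenerate constant-energy landscape yields 0 and is replaced by
#' `temp_floor`, with a warning.
#'
#' @inheritParams evolve_one_solution
#' @param params an [sa_params()].
#' @return Starting temperature (energy units). Uses the current RNG
#'   stream.
#' @export
estimate_initial_temperature <- function(pool, labels = NULL,
                                         params = sa_params()) {
  st <- selector_state(pool, labels)
  if (st$n_genes < params$k) stop("pool smaller than chromosome size")
  energies <- vapply(seq_len(params$n_calibration), function(i) {
    1 - fitness_of(st, random_chromosome(st, params$k))
  }, numeric(1))
  t0 <- mean(abs(diff(energies)))
  if (t0 <= 0) {
    warning("constant energy landscape; starting temperature floored at ",
            params$temp_floor)
    t0 <- params$temp_floor
  }
  t0
}

#' Metropolis acceptance rule
#'
#' Accepts an energy change `delta_e` at temperature `T` with probability
#' `min(1, exp(-delta_e / T))`.
#'
#' @param delta_e energy difference (candidate minus current).
#' @param temperature current temperature, must be > 0.
#' @return Logical. Uses the current RNG stream.
#' @export
metropolis_accept <- function(delta_e, temperature) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (delta_e <= 0) return(TRUE)
  runif(1) < exp(-delta_e / temperature)
}

#' One simulated-annealing search over gene subsets
#'
#' Starts from a random chromosome and performs `maxit` energy
#' evaluations in total: each step proposes a neighbor differing in
#' exactly one gene (uniform position, uniform replacement from outside
#' the chromosome), accepted by the Metropolis rule at the scheduled
#' temperature. Returns the best-ever chromosome.
#'
#' @inheritParams estimate_initial_temperature
#' @param t0 starting temperature; calibrated via
#'   [estimate_initial_temperature()] when `NULL`.
#' @return List with `chromosome`, `genes`, `energy` (LOOCV error),
#'   `accuracy`, and `n_evaluations` (always exactly `maxit`).
#' @export
sa_search <- function(pool, labels = NULL, params = sa_params(),
                      t0 = NULL) {
  st <- selector_state(pool, labels)
  if (st$n_genes < params$k) stop("pool smaller than chromosome size")
  if (is.null(t0)) t0 <- estimate_initial_temperature(pool, labels, params)
  sa_search_st(st, params, t0)
}

sa_search_st <- function(st, params, t0) {
  current <- random_chromosome(st, params$k)
  e_cur <- 1 - fitness_of(st, current)
  best <- current; e_best <- e_cur
  n_eval <- 1L
  while (n_eval < params$maxit) {
    n_eval <- n_eval + 1L
    temp <- t0 / log(((n_eval - 1L) %/% params$tmax) * params$tmax + exp(1))
    cand <- current
    slot <- sample.int(params$k, 1)
    cand[slot] <- sample_nonmember(st$n_genes, current)
    e_cand <- 1 - fitness_of(st, cand)
    if (metropolis_accept(e_cand - e_cur, temp)) {
      current <- cand; e_cur <- e_cand
    }
    if (e_cand < e_best) { best <- cand; e_best <- e_cand }
  }
  best <- sort.int(best)
  list(chromosome = best, genes = st$gene_ids[best], energy = e_best,
       accuracy = 1 - e_best, n_evaluations = n_eval)
}

#' Run the INSEL selector and frequency-rank the genes
#'
#' Calibrates the temperature once, performs `max_solutions` annealing
#' searches, keeps the returned chromosomes whose re-evaluated LOOCV
#' accuracy reaches `goal_accuracy`, and ranks genes by frequency across
#' the kept solutions.
#'
#' @inheritParams sa_search
#' @param seed overrides `params$seed`.
#' @return A `selection_run` (method `"insel"`) with the calibrated
#'   temperature in `$t0`.
#' @export
run_insel <- function(pool, labels = NULL, params = sa_params(),
                      seed = NULL) {
  st <- selector_state(pool, labels)
  if (st$n_genes < params$k) stop("pool smaller than chromosome size")
  if (is.null(seed)) seed <- params$seed
  with_seed(seed, {
    t0 <- if (params$max_solutions > 0) {
      energies <- vapply(seq_len(params$n_calibration), function(i) {
        1 - fitness_of(st, random_chromosome(st, params$k))
      }, numeric(1))
      tt <- mean(abs(diff(energies)))
      if (tt <= 0) {
        warning("constant energy landscape; temperature floored")
        tt <- params$temp_floor
      }
      tt
    } else NA_real_
    sols <- vector("list", params$max_solutions)
    nsol <- 0L
    for (i in seq_len(params$max_solutions)) {
      res <- sa_search_st(st, params, t0)
      # solution filter: recompute the accuracy, never trust the cache of
      # the annealer's own bookkeeping
      acc <- cpp_loocv_acc(st$Xt[, res$chromosome, drop = FALSE], st$y,
                           st$G, 1e-8)
      if (acc >= params$goal_accuracy) {
        nsol <- nsol + 1L
        sols[[nsol]] <- res$genes
      }
    }
    if (nsol == 0L && params$max_solutions > 0L) {
      warning("no chromosome reached the goal accuracy; empty ranking")
    }
    selection_run("insel", params, sols[seq_len(nsol)], st$gene_ids,
                  n_attempted = params$max_solutions,
                  extra = list(seed = seed, t0 = t0))
  })
}
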