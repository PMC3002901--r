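#' Parameters of the genetic-algorithm wrapper selector
#'
#' The search evolves fixed-size gene subsets ("chromosomes", default five
#' genes) toward perfect leave-one-out classification of the time points.
#' Published settings: chromosome size 5, goal fitness 100% accuracy, up
#' to 2500 solutions collected, at most 200 generations per solution. The
#' internal GA settings (population size, crossover and mutation rates)
#' follow common practice and are configurable.
#'
#' @param k chromosome size.
#' @param goal_fitness LOOCV accuracy at which a chromosome is a solution.
#' @param max_solutions independent GA restarts collected per run.
#' @param max_generations generation cap per restart.
#' @param population_size chromosomes per generation.
#' @param crossover_rate probability a child is produced by single-point
#'   crossover (else it copies one parent).
#' @param mutation_rate per-slot probability of replacing a gene with a
#'   random pool gene not already in the chromosome.
#' @param seed RNG seed for [run_ga()].
#' @return List of class `ga_params`.
#' @export
ga_params <- function(k = 5, goal_fitness = 1.0, max_solutions = 2500,
                      max_generations = 200, population_size = 100,
                      crossover_rate = 1.0, mutation_rate = 0.05,
                      seed = NULL) {
  stopifnot(k >= 2, goal_fitness >= 0, goal_fitness <= 1,
            max_solutions >= 0, max_generations >= 1,
            population_size >= 2,
            crossover_rate > 0, crossover_rate <= 1,
            mutation_rate > 0, mutation_rate <= 1)
  structure(list(k = as.integer(k), goal_fitness = goal_fitness,
                 max_solutions = as.integer(max_solutions),
                 max_generations = as.integer(max_generations),
                 population_size = as.integer(population_size),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, seed = seed),
            class = "ga_params")
}

# shared selector state: samples-by-genes matrix, integer labels and a
# memoizing LOOCV fitness (chromosomes recur heavily within a GA run)
selector_state <- function(pool, labels) {
  if (inherits(pool, "ratio_matrix")) {
    if (is.null(labels)) labels <- time_factor(pool)
    X <- pool$ratios
  } else X <- as.matrix(pool)
  labels <- factor(labels)
  list(Xt = t(X), y = as.integer(labels), G = nlevels(labels),
       labels = labels, gene_ids = rownames(X), n_genes = nrow(X),
       cache = new.env(parent = emptyenv()))
}

fitness_of <- function(st, chrom) {
  key <- paste(sort.int(chrom), collapse = ",")
  hit <- st$cache[[key]]
  if (!is.null(hit)) return(hit)
  acc <- cpp_loocv_acc(st$Xt[, chrom, drop = FALSE], st$y, st$G, 1e-8)
  st$cache[[key]] <- acc
  acc
}

random_chromosome <- function(st, k) sample.int(st$n_genes, k)

# draw one gene index outside `exclude` (rejection sampling: the pool is
# much larger than a chromosome)
sample_nonmember <- function(n, exclude) {
  repeat {
    g <- sample.int(n, 1L)
    if (!any(g == exclude)) return(g)
  }
}

# replace duplicate slots with random genes not in the chromosome
repair_chromosome <- function(st, chrom) {
  dup <- which(duplicated(chrom))
  for (s in dup) chrom[s] <- sample_nonmember(st$n_genes, chrom)
  chrom
}

#' Evolve one solution chromosome
#'
#' One GA restart: a random initial population, fitness-proportional
#' parent selection (on goal-shifted fitness), single-point crossover on
#' the sorted gene-id representation, per-slot mutation, and one elite
#' carried over, until some chromosome reaches the goal fitness or the
#' generation cap is hit.
#'
#' @param pool [ratio_matrix()] or genes-by-samples matrix of the
#'   (preselected) gene pool.
#' @param labels class factor per sample; defaults to the time factor of
#'   a `ratio_matrix` pool.
#' @param params a [ga_params()].
#' @return List with `chromosome` (gene indices), `genes` (ids),
#'   `fitness` and `generations`, or `NULL` when no chromosome reached
#'   the goal. Uses the current RNG stream.
#' @export
evolve_one_solution <- function(pool, labels = NULL, params = ga_params()) {
  st <- selector_state(pool, labels)
  if (st$n_genes < params$k) stop("pool smaller than chromosome size")
  evolve_one_solution_st(st, params)
}

evolve_one_solution_st <- function(st, params) {
  k <- params$k; P <- params$population_size
  pop <- replicate(P, random_chromosome(st, k), simplify = FALSE)
  for (gen in seq_len(params$max_generations)) {
    fit <- vapply(pop, function(ch) fitness_of(st, ch), numeric(1))
    best <- which.max(fit)
    if (fit[best] >= params$goal_fitness) {
      ch <- sort.int(pop[[best]])
      return(list(chromosome = ch, genes = st$gene_ids[ch],
                  fitness = fit[best], generations = gen))
    }
    if (gen == params$max_generations) break
    w <- fit - min(fit) + 0.01
    newpop <- vector("list", P)
    newpop[[1]] <- pop[[best]]                       # elitism
    parents <- matrix(sample.int(P, 2 * (P - 1), replace = TRUE,
                                 prob = w), nrow = 2)
    for (i in 2:P) {
      p1 <- sort.int(pop[[parents[1, i - 1]]])
      p2 <- sort.int(pop[[parents[2, i - 1]]])
      child <- if (runif(1) < params$crossover_rate) {
        cp <- sample.int(k - 1, 1)
        repair_chromosome(st, c(p1[seq_len(cp)], p2[(cp + 1):k]))
      } else p1
      mut <- runif(k) < params$mutation_rate
      for (s in which(mut)) {
        child[s] <- sample_nonmember(st$n_genes, child)
      }
      newpop[[i]] <- child
    }
    pop <- newpop
  }
  NULL
}

#' Run the GA selector and frequency-rank the genes
#'
#' Repeats [evolve_one_solution()] up to `max_solutions` times
#' (independent restarts), stores every chromosome that reached the goal
#' fitness, and ranks genes by their frequency across the stored
#' solutions.
#'
#' @inheritParams evolve_one_solution
#' @param seed overrides `params$seed`.
#' @return A `selection_run` (method `"ga"`).
#' @export
run_ga <- function(pool, labels = NULL, params = ga_params(), seed = NULL) {
  st <- selector_state(pool, labels)
  if (st$n_genes < params$k) stop("pool smaller than chromosome size")
  if (is.null(seed)) seed <- params$seed
  with_seed(seed, {
    sols <- vector("list", params$max_solutions)
    nsol <- 0L
    for (i in seq_len(params$max_solutions)) {
      res <- evolve_one_solution_st(st, params)
      if (!is.null(res)) {
        nsol <- nsol + 1L
        sols[[nsol]] <- res$genes
      }
    }
    if (nsol == 0L && params$max_solutions > 0L) {
      warning("no chromosome reached the goal fitness; empty ranking")
    }
    selection_run("ga", params, sols[seq_len(nsol)], st$gene_ids,
                  n_attempted = params$max_solutions,
                  extra = list(seed = seed))
  })
}

#' Repeated selector runs with derived seeds
#'
#' Runs a selector several times (the published protocol uses four
#' repetitions with identical settings), each with an independent seed
#' derived from the master seed.
#'
#' @param fun selector function (`run_ga` or `run_insel`).
#' @param pool,labels,params passed to `fun`.
#' @param runs number of repetitions.
#' @param seed master seed.
#' @return List of `selection_run` objects.
#' @export
repeat_selection <- function(fun, pool, labels = NULL, params, runs = 4,
                             seed = NULL) {
  seeds <- derive_seeds(seed, runs)
  lapply(seeds, function(s) fun(pool, labels, params, seed = s))
}
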