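#' Pairwise overlap accounting between selected gene lists
#'
#' Mirrors the method-comparison table of the screening strategy: for
#' each list, the intersection with the reference list (the GA selection
#' by convention) as a count "x of y" and a fraction, plus the full
#' pairwise intersection matrix.
#'
#' @param lists named list of character vectors of gene ids (>= 2).
#' @param reference name of the reference list (default: the first).
#' @return Object of class `overlap_report`: data frame `vs_reference`
#'   and matrix `pairwise` of intersection counts.
#' @export
overlap_report <- function(lists, reference = names(lists)[1]) {
  if (length(lists) < 2) stop("need at least two lists")
  if (is.null(names(lists)) || any(names(lists) == "")) {
    stop("lists must be named")
  }
  ref <- lists[[reference]]
  vs <- do.call(rbind, lapply(names(lists), function(nm) {
    n_int <- length(intersect(lists[[nm]], ref))
    denom <- length(ref)
    data.frame(list = nm, overlap = n_int, of = denom,
               fraction = if (denom == 0) 0 else n_int / denom,
               flagged_empty = length(lists[[nm]]) == 0 || denom == 0,
               stringsAsFactors = FALSE)
  }))
  nm <- names(lists)
  pw <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in nm) for (j in nm) {
    pw[i, j] <- length(intersect(lists[[i]], lists[[j]]))
  }
  structure(list(vs_reference = vs, pairwise = pw, reference = reference),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap_report (reference:", x$reference, ")\n")
  for (i in seq_len(nrow(x$vs_reference))) {
    r <- x$vs_reference[i, ]
    if (r$list == x$reference) next
    cat(sprintf("  %s: %d/%d (%.0f%%)\n", r$list, r$overlap, r$of,
                100 * r$fraction))
  }
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end screen with its
#' default, plus the master seed that deterministically drives all
#' stochastic stages.
#'
#' @param synth a [synth_config()] for the synthetic input (used when no
#'   `ratio_matrix` is supplied to [run_pipeline()]).
#' @param background_fraction,span preprocessing parameters.
#' @param interaction_alpha,time_alpha prefilter thresholds.
#' @param ga a [ga_params()]; `insel` an [sa_params()].
#' @param greedy_alpha,greedy_max_steps greedy selector settings.
#' @param rf_trees random-forest tree count.
#' @param runs selector repetitions; `top`, `min_runs` consensus rule.
#' @param pcor_min,p_max network edge thresholds.
#' @param stages character vector of selector stages to run (subset of
#'   `"ga"`, `"insel"`, `"greedy"`, `"rf"`).
#' @param seed master seed.
#' @param out_dir output directory (`NULL` = no files written).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(n_de_genes = 10,
                                                 weak_de_sd = 0.3),
                            background_fraction = 0.10, span = 0.75,
                            interaction_alpha = 0.01, time_alpha = 0.01,
                            ga = ga_params(), insel = sa_params(),
                            greedy_alpha = 0.001, greedy_max_steps = 10,
                            rf_trees = 500, runs = 4, top = 50,
                            min_runs = 3, pcor_min = 0.35, p_max = 0.05,
                            stages = c("ga", "insel", "greedy", "rf"),
                            seed = 1, out_dir = NULL) {
  stopifnot(all(stages %in% c("ga", "insel", "greedy", "rf")))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Preprocess (when starting from intensities) -> two-stage ANOVA
#' prefilter -> the enabled wrapper selectors (GA repetitions with
#' consensus, INSEL, greedy/LDA, random forest) -> cross-method overlap
#' report -> graphical Gaussian network on the candidate genes. Every
#' artifact is collected in the returned object and, when `out_dir` is
#' set, written as TSV/JSON with a manifest of all parameters and seeds.
#'
#' @param config a [pipeline_config()].
#' @param rm optional [ratio_matrix()] input; when `NULL` a synthetic
#'   dataset is generated from `config$synth` (intensity space, then
#'   preprocessed).
#' @return List of class `pipeline_run` with elements `prefilter`,
#'   `ga_runs`, `consensus`, `insel`, `greedy`, `rf`, `overlaps`,
#'   `network`, `truth` (for synthetic input) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), rm = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 8)
  truth <- NULL
  stage <- "input"
  out <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(rm)) {
    gen <- run_stage("synthetic_data", {
      cfg <- config$synth
      cfg$seed <- seeds[1]
      synth_two_color(cfg)
    })
    truth <- gen$truth
    rm <- run_stage("preprocess", {
      preprocess_two_color(gen$data,
                           background_fraction = config$background_fraction,
                           span = config$span)
    })
  }
  pre <- run_stage("prefilter", {
    prefilter(rm, interaction_alpha = config$interaction_alpha,
              time_alpha = config$time_alpha)
  })
  pool <- pre$matrix
  labels <- time_factor(pool)
  lists <- list()
  ga_runs <- cons <- insel_run <- greedy_run <- rf_run <- NULL
  if ("ga" %in% config$stages) {
    ga_runs <- run_stage("ga_select", {
      repeat_selection(run_ga, pool, labels, config$ga,
                       runs = config$runs, seed = seeds[2])
    })
    cons <- consensus(ga_runs, top = config$top,
                      min_runs = min(config$min_runs, config$runs))
    lists$ga <- top_genes(ga_runs[[1]], config$top)
  }
  if ("insel" %in% config$stages) {
    insel_run <- run_stage("sa_select", {
      run_insel(pool, labels, config$insel, seed = seeds[3])
    })
    lists$insel <- top_genes(insel_run, config$top)
  }
  if ("greedy" %in% config$stages) {
    greedy_run <- run_stage("baseline_select", {
      greedy_loocv(pool, labels, alpha = config$greedy_alpha,
                   max_steps = config$greedy_max_steps)
    })
    lists$greedy <- top_genes(greedy_run$ranking,
                              min(config$top, nrow(greedy_run$ranking)))
  }
  if ("rf" %in% config$stages) {
    rf_run <- run_stage("baseline_select", {
      rf_rank(pool, labels, n_trees = config$rf_trees, seed = seeds[4])
    })
    lists$rf <- top_genes(rf_run, config$top)
  }
  overlaps <- if (length(lists) >= 2) overlap_report(lists) else NULL
  candidates <- if (!is.null(cons) && length(cons) >= 3) {
    cons
  } else if (length(lists) > 0) {
    head(lists[[1]], 11)
  } else character(0)
  network <- NULL
  if (length(candidates) >= 3) {
    network <- run_stage("network", {
      ggm_network(subset_genes(pool, intersect(candidates, pool$gene_ids)),
                  pcor_min = config$pcor_min, p_max = config$p_max)
    })
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("crhnet")),
    master_seed = config$seed,
    stage_seeds = as.list(setNames(seeds[1:4],
                                   c("synthetic_data", "ga", "insel", "rf"))),
    stages = c("prefilter", config$stages,
               if (!is.null(network)) "network"),
    parameters = list(
      background_fraction = config$background_fraction, span = config$span,
      interaction_alpha = config$interaction_alpha,
      time_alpha = config$time_alpha,
      ga = unclass(config$ga), insel = unclass(config$insel),
      greedy_alpha = config$greedy_alpha,
      greedy_max_steps = config$greedy_max_steps,
      rf_trees = config$rf_trees, runs = config$runs, top = config$top,
      min_runs = config$min_runs, pcor_min = config$pcor_min,
      p_max = config$p_max))
  res <- structure(list(matrix = rm, prefilter = pre, ga_runs = ga_runs,
                        consensus = cons, insel = insel_run,
                        greedy = greedy_run, rf = rf_run,
                        overlaps = overlaps, candidates = candidates,
                        network = network, truth = truth,
                        manifest = manifest),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) write_pipeline(res, config$out_dir)
  res
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run\n")
  cat("  preselected genes:", nrow(x$prefilter$preselected), "\n")
  if (!is.null(x$consensus)) {
    cat("  GA consensus (", length(x$consensus), " genes): ",
        paste(head(x$consensus, 12), collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$greedy)) {
    cat(sprintf("  greedy LOOCV error: %.3f\n", x$greedy$loocv_error))
  }
  if (!is.null(x$rf)) cat(sprintf("  RF OOB error: %.3f\n", x$rf$oob_error))
  if (!is.null(x$network)) {
    cat("  network:", nrow(x$network$edges), "edges over",
        length(x$network$nodes), "candidate genes\n")
  }
  invisible(x)
}

# write all artifacts of a pipeline run, plus the manifest
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  write_ratio_matrix(res$matrix, fp("ratio_matrix.tsv"), fp("samples.tsv"))
  write.table(res$prefilter$preselected, fp("preselected.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$ga_runs)) {
    for (i in seq_along(res$ga_runs)) {
      write_ranked_list(res$ga_runs[[i]], fp(sprintf("ga_run%d.tsv", i)))
    }
    writeLines(res$consensus, fp("consensus_genes.txt"))
  }
  if (!is.null(res$insel)) write_ranked_list(res$insel, fp("insel.tsv"))
  if (!is.null(res$greedy)) {
    write_ranked_list(res$greedy$ranking, fp("greedy.tsv"))
  }
  if (!is.null(res$rf)) write_ranked_list(res$rf$ranking, fp("rf.tsv"))
  if (!is.null(res$network)) write_network(res$network, fp("network.tsv"))
  jsonlite::write_json(res$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
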