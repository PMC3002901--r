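#' Rank genes by their frequency in solution chromosomes
#'
#' Counts, for every gene, the number of solution chromosomes containing
#' it and sorts descending. Ties are broken by gene id ascending so the
#' ranking is reproducible. Duplicate chromosomes are counted as stored
#' (occurrence accounting); pass unique chromosomes for unique-chromosome
#' accounting.
#'
#' @param solutions list of character vectors of gene ids (chromosomes).
#' @param gene_ids optional universe of gene ids used to validate members.
#' @return Data frame with columns `gene_id`, `frequency`, `rank`.
#' @export
rank_by_frequency <- function(solutions, gene_ids = NULL) {
  if (length(solutions) == 0) {
    return(data.frame(gene_id = character(0), frequency = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  all_genes <- as.character(unlist(solutions, use.names = FALSE))
  if (length(all_genes) == 0) {
    return(data.frame(gene_id = character(0), frequency = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  if (!is.null(gene_ids) && !all(all_genes %in% gene_ids)) {
    stop("solution chromosomes contain ids outside the pool")
  }
  tab <- table(all_genes)
  ord <- order(-as.integer(tab), names(tab))
  data.frame(gene_id = names(tab)[ord],
             frequency = as.integer(tab)[ord],
             rank = seq_along(tab),
             stringsAsFactors = FALSE)
}

# assemble a classed run object shared by the GA / SA / greedy selectors
selection_run <- function(method, params, solutions, gene_ids,
                          n_attempted, extra = list()) {
  ranking <- rank_by_frequency(solutions, gene_ids)
  structure(c(list(method = method, params = params,
                   solutions = solutions, ranking = ranking,
                   n_attempted = n_attempted,
                   n_solutions = length(solutions)),
              extra),
            class = "selection_run")
}

#' @export
print.selection_run <- function(x, ...) {
  cat(sprintf("selection_run [%s]: %d solution chromosomes from %d attempts\n",
              x$method, x$n_solutions, x$n_attempted))
  if (nrow(x$ranking) > 0) {
    cat("  top genes:",
        paste(head(x$ranking$gene_id, 8), collapse = ", "), "...\n")
  } else cat("  empty ranking\n")
  invisible(x)
}

#' Top-N gene list of a selection run
#'
#' @param run a `selection_run` (or a ranking data frame).
#' @param top list length (default 50). A shorter ranking contributes all
#'   of it, with a warning.
#' @return Character vector of gene ids.
#' @export
top_genes <- function(run, top = 50) {
  ranking <- if (is.list(run) && !is.data.frame(run) &&
                 is.data.frame(run$ranking)) run$ranking else run
  if (!is.data.frame(ranking) || is.null(ranking$gene_id)) {
    stop("run must be a selection result or a ranking data frame")
  }
  if (nrow(ranking) < top) {
    warning("ranking has only ", nrow(ranking), " genes (< top = ", top, ")")
  }
  head(ranking$gene_id, top)
}

#' Multi-run consensus gene set
#'
#' Genes present in the top-`top` ranking of at least `min_runs` of the
#' supplied selection runs (the "at least 3 of 4 repetitions" rule).
#'
#' @param runs list of `selection_run` objects.
#' @param top per-run list length (default 50).
#' @param min_runs minimum number of runs a gene must appear in.
#' @return Character vector of consensus gene ids (sorted).
#' @export
consensus <- function(runs, top = 50, min_runs = 3) {
  if (length(runs) < min_runs) {
    stop("need at least min_runs = ", min_runs, " runs, got ", length(runs))
  }
  lists <- lapply(runs, top_genes, top = top)
  tab <- table(unlist(lapply(lists, unique)))
  sort(names(tab)[tab >= min_runs])
}

#' Write a ranked gene list to TSV
#'
#' @param run a `selection_run` or ranking data frame.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_ranked_list <- function(run, path) {
  ranking <- if (inherits(run, "selection_run")) run$ranking else run
  write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
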