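#' Construct a ratio matrix with sample factors
#'
#' The central data container: a genes-by-samples matrix of normalized log2
#' treated/control expression ratios together with the sample factors of
#' the dye-swap time-course design (time in hours and dye orientation).
#'
#' @param ratios numeric matrix, genes in rows, samples in columns. Row
#'   names are spot/gene ids (generated when absent).
#' @param samples data frame with one row per column of `ratios` and
#'   columns `sample_id`, `time_h` (numeric hours), `dye` (orientation,
#'   two levels) and `replicate`.
#' @return An object of class `ratio_matrix`: a list with elements
#'   `ratios`, `samples` and `gene_ids`.
#' @examples
#' rm <- synth_ratio_matrix(synth_config(n_spots = 20, seed = 1))$data
#' rm
#' @export
ratio_matrix <- function(ratios, samples) {
  ratios <- as.matrix(ratios)
  if (is.null(rownames(ratios))) {
    rownames(ratios) <- sprintf("g%04d", seq_len(nrow(ratios)))
  }
  samples <- as.data.frame(samples)
  req <- c("sample_id", "time_h", "dye", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0) {
    stop("sample metadata is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(samples) != ncol(ratios)) {
    stop("sample metadata has ", nrow(samples), " rows but the matrix has ",
         ncol(ratios), " columns")
  }
  if (anyNA(ratios)) stop("ratio matrix must not contain missing values")
  samples$time_h <- as.numeric(samples$time_h)
  samples$dye <- factor(samples$dye)
  if (nlevels(samples$dye) > 2) stop("dye orientation must have two levels")
  colnames(ratios) <- as.character(samples$sample_id)
  structure(list(ratios = ratios, samples = samples,
                 gene_ids = rownames(ratios)),
            class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat("ratio_matrix:", nrow(x$ratios), "genes x", ncol(x$ratios), "samples\n")
  tt <- table(x$samples$time_h)
  cat("  time points (h):",
      paste(sprintf("%g (n=%d)", as.numeric(names(tt)), tt), collapse = ", "),
      "\n")
  cat("  dye orientations:",
      paste(sprintf("%s (n=%d)", levels(x$samples$dye),
                    table(x$samples$dye)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ratio_matrix <- function(x) dim(x$ratios)

# time factor as used throughout: 5 ordered levels by hour
time_factor <- function(rm) factor(rm$samples$time_h,
                                   levels = sort(unique(rm$samples$time_h)))

#' Read a ratio matrix and its sample metadata from TSV files
#'
#' @param matrix_path TSV with gene ids in the first column and one column
#'   per sample.
#' @param meta_path TSV with columns `sample_id`, `time_h`, `dye`,
#'   `replicate`, one row per sample, in matrix column order.
#' @return A [ratio_matrix()].
#' @export
read_ratio_matrix <- function(matrix_path, meta_path) {
  mat <- read.delim(matrix_path, check.names = FALSE)
  genes <- as.character(mat[[1]])
  x <- as.matrix(mat[, -1, drop = FALSE])
  rownames(x) <- genes
  meta <- read.delim(meta_path, check.names = FALSE)
  req <- c("sample_id", "time_h", "dye", "replicate")
  miss <- setdiff(req, names(meta))
  if (length(miss) > 0) {
    stop("metadata file lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(meta) != ncol(x)) {
    stop("metadata rows (", nrow(meta), ") do not match matrix columns (",
         ncol(x), ")")
  }
  ratio_matrix(x, meta)
}

#' Write a ratio matrix and sample metadata to TSV files
#'
#' @param rm a [ratio_matrix()].
#' @param matrix_path,meta_path output file paths.
#' @return Invisibly, `rm`.
#' @export
write_ratio_matrix <- function(rm, matrix_path, meta_path) {
  df <- data.frame(gene_id = rm$gene_ids, rm$ratios, check.names = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(rm$samples, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(rm)
}
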