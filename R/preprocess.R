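#' Construct a two-color array set
#'
#' Raw per-spot Cy3/Cy5 intensities for a set of arrays sharing one spot
#' universe, with print-tip assignment per spot and time / dye-orientation
#' / replicate metadata per array.
#'
#' @param cy3,cy5 numeric matrices, spots x arrays, non-negative.
#' @param print_tip integer vector of print-tip group per spot.
#' @param arrays data frame with columns `sample_id`, `time_h`, `dye`
#'   (`"treated_cy3"` or `"treated_cy5"`), `replicate`.
#' @param mask logical matrix, `TRUE` where a spot is present (defaults to
#'   all present).
#' @return Object of class `two_color_set`.
#' @export
two_color_set <- function(cy3, cy5, print_tip, arrays, mask = NULL) {
  cy3 <- as.matrix(cy3); cy5 <- as.matrix(cy5)
  stopifnot(all(dim(cy3) == dim(cy5)),
            length(print_tip) == nrow(cy3),
            nrow(arrays) == ncol(cy3))
  if (any(cy3 < 0, na.rm = TRUE) || any(cy5 < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative")
  }
  if (!all(arrays$dye %in% c("treated_cy3", "treated_cy5"))) {
    stop("dye orientation must be 'treated_cy3' or 'treated_cy5'")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(cy3), ncol(cy3))
  if (is.null(rownames(cy3))) {
    rownames(cy3) <- rownames(cy5) <- sprintf("g%04d", seq_len(nrow(cy3)))
  }
  structure(list(cy3 = cy3, cy5 = cy5, mask = mask,
                 spot_id = rownames(cy3),
                 print_tip = as.integer(print_tip),
                 arrays = as.data.frame(arrays)),
            class = "two_color_set")
}

#' @export
print.two_color_set <- function(x, ...) {
  cat("two_color_set:", nrow(x$cy3), "spots x", ncol(x$cy3), "arrays;",
      length(unique(x$print_tip)), "print-tip groups;",
      sum(!x$mask), "masked spot measurements\n")
  invisible(x)
}

#' Erase background intensities
#'
#' Marks the lowest `fraction` of present intensity values as background,
#' per array and per channel. A spot with a background value in either
#' channel is masked on that array (a ratio with one background channel is
#' meaningless). Exactly `floor(fraction * n_present)` values are erased
#' per array/channel, with ties broken by (intensity, spot order) so the
#' operation is deterministic.
#'
#' @param tc a [two_color_set()].
#' @param fraction proportion of values to erase, in `[0, 1)`.
#' @return The filtered `two_color_set`; attribute `"n_erased"` carries
#'   the per-array-per-channel erasure counts.
#' @export
filter_background <- function(tc, fraction = 0.10) {
  stopifnot(inherits(tc, "two_color_set"), fraction >= 0, fraction < 1)
  if (fraction == 0) {
    attr(tc, "n_erased") <- matrix(0L, ncol(tc$cy3), 2,
                                   dimnames = list(NULL, c("cy3", "cy5")))
    return(tc)
  }
  n_arr <- ncol(tc$cy3)
  counts <- matrix(0L, n_arr, 2, dimnames = list(NULL, c("cy3", "cy5")))
  for (a in seq_len(n_arr)) {
    erase <- integer(0)
    for (ch in c("cy3", "cy5")) {
      # both channels are thresholded against the array's original mask,
      # then the union of background spots is masked
      v <- tc[[ch]][, a]
      present <- which(tc$mask[, a] & !is.na(v))
      k <- floor(fraction * length(present))
      counts[a, ch] <- k
      if (k == 0) next
      if (length(unique(v[present])) == 1L) {
        warning("array ", a, " channel ", ch,
                ": all intensities identical; erasing first ", k,
                " spots by stable order")
      }
      ord <- present[order(v[present], present)]
      erase <- union(erase, ord[seq_len(k)])
    }
    tc$mask[erase, a] <- FALSE
  }
  attr(tc, "n_erased") <- counts
  tc
}

#' Compute MA values from channel intensities
#'
#' M is the orientation-resolved log2 ratio treated minus control: for a
#' `treated_cy3` array `M = log2(Cy3) - log2(Cy5)`, for a `treated_cy5`
#' array the sign is flipped. `A = (log2(Cy3) + log2(Cy5)) / 2`. Spots
#' with zero or missing intensity in either channel are masked.
#'
#' @param tc a [two_color_set()].
#' @return Object of class `ma_set` with matrices `M`, `A`, the presence
#'   `mask`, `print_tip` and the array metadata.
#' @export
compute_ma <- function(tc) {
  stopifnot(inherits(tc, "two_color_set"))
  bad <- (!is.na(tc$cy3) & tc$cy3 == 0) | (!is.na(tc$cy5) & tc$cy5 == 0) |
    is.na(tc$cy3) | is.na(tc$cy5)
  mask <- tc$mask & !bad
  l3 <- suppressWarnings(log2(tc$cy3))
  l5 <- suppressWarnings(log2(tc$cy5))
  M_chan <- l3 - l5
  A <- (l3 + l5) / 2
  s <- ifelse(tc$arrays$dye == "treated_cy3", 1, -1)
  M <- sweep(M_chan, 2, s, "*")
  M[!mask] <- NA_real_
  A[!mask] <- NA_real_
  structure(list(M = M, A = A, mask = mask, spot_id = tc$spot_id,
                 print_tip = tc$print_tip, arrays = tc$arrays),
            class = "ma_set")
}

#' @export
print.ma_set <- function(x, ...) {
  cat("ma_set:", nrow(x$M), "spots x", ncol(x$M), "arrays;",
      sum(!x$mask), "masked\n")
  invisible(x)
}

#' Print-tip loess normalization
#'
#' Within each (array, print-tip group), fits a robust local regression of
#' M on A (degree 2, symmetric family, the given span) and subtracts the
#' fit: `M_norm = M - Mhat(A)`. Groups with fewer than `min_spots` present
#' spots fall back to a whole-array fit, with a warning.
#'
#' @param ma an `ma_set` from [compute_ma()].
#' @param span loess span (default 0.75).
#' @param min_spots minimum present spots per print-tip group.
#' @param iterations robustness iterations of the symmetric family.
#' @return The `ma_set` with normalized `M`.
#' @export
loess_normalize <- function(ma, span = 0.75, min_spots = 10,
                            iterations = 4) {
  stopifnot(inherits(ma, "ma_set"))
  ctrl <- loess.control(surface = "direct", iterations = iterations)
  fit_group <- function(m, a) {
    fit <- loess(m ~ a, span = span, degree = 2, family = "symmetric",
                 control = ctrl)
    predict(fit, a)
  }
  for (arr in seq_len(ncol(ma$M))) {
    present <- ma$mask[, arr]
    small <- character(0)
    whole_fit <- NULL
    for (tip in sort(unique(ma$print_tip))) {
      rows <- which(ma$print_tip == tip & present)
      if (length(rows) == 0) next
      if (length(rows) < min_spots) {
        if (is.null(whole_fit)) {
          wrows <- which(present)
          whole_fit <- list(rows = wrows,
                            pred = fit_group(ma$M[wrows, arr],
                                             ma$A[wrows, arr]))
        }
        idx <- match(rows, whole_fit$rows)
        ma$M[rows, arr] <- ma$M[rows, arr] - whole_fit$pred[idx]
        small <- c(small, tip)
        next
      }
      ma$M[rows, arr] <- ma$M[rows, arr] -
        fit_group(ma$M[rows, arr], ma$A[rows, arr])
    }
    if (length(small) > 0) {
      warning("array ", arr, ": print-tip group(s) ",
              paste(small, collapse = ", "), " below ", min_spots,
              " spots; used whole-array fit")
    }
  }
  ma
}

#' Keep only spots present on every array
#'
#' Assembles the genes-by-samples ratio matrix from spots whose M value is
#' present (unmasked) on all arrays, attaching the time and dye factors.
#'
#' @param ma an `ma_set`.
#' @return A [ratio_matrix()].
#' @export
complete_case_filter <- function(ma) {
  stopifnot(inherits(ma, "ma_set"))
  keep <- rowSums(ma$mask) == ncol(ma$mask)
  if (!any(keep)) stop("no spot is present on all arrays")
  X <- ma$M[keep, , drop = FALSE]
  rownames(X) <- ma$spot_id[keep]
  ratio_matrix(X, ma$arrays)
}

#' One-call preprocessing of a two-color array set
#'
#' Background erasure, MA computation, print-tip loess normalization and
#' complete-case filtering in the standard order.
#'
#' @param tc a [two_color_set()].
#' @param background_fraction bottom quantile erased per array/channel.
#' @param span loess span.
#' @param min_spots minimum spots per print-tip group for a group-wise fit.
#' @return A [ratio_matrix()].
#' @export
preprocess_two_color <- function(tc, background_fraction = 0.10,
                                 span = 0.75, min_spots = 10) {
  tc <- filter_background(tc, background_fraction)
  ma <- compute_ma(tc)
  ma <- loess_normalize(ma, span = span, min_spots = min_spots)
  complete_case_filter(ma)
}
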