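#' Imputation settings for paired TAD matrices
#'
#' Controls the three-stage treatment of missing values applied to a pair
#' of TAD-level matrices before testing: (i) square all-missing blocks on
#' the diagonal (the signature of structural-variant deletions or
#' duplications) of side at least `min_sv_block` are filled with the
#' constant `sv_fill`; (ii) bins whose row has a missing proportion greater
#' than `row_missing_threshold` in either matrix are removed from both
#' matrices; (iii) every remaining missing entry is filled with the median
#' of the observed entries at the same genomic distance within the same
#' matrix.
#'
#' @param sv_fill constant used to fill all-missing SV blocks (default 1).
#' @param row_missing_threshold bins are removed when the missing
#'   proportion of their row strictly exceeds this fraction (default 0.5).
#' @param min_sv_block minimal side of an all-missing square block treated
#'   as an SV signature (default 3).
#' @param sv_mode enable stage (i) (default `TRUE`).
#' @return A list of class `imputation_config`.
#' @export
imputation_config <- function(sv_fill = 1, row_missing_threshold = 0.5,
                              min_sv_block = 3L, sv_mode = TRUE) {
  stopifnot(is.finite(sv_fill),
            row_missing_threshold > 0, row_missing_threshold < 1,
            min_sv_block >= 1)
  structure(list(sv_fill = sv_fill,
                 row_missing_threshold = row_missing_threshold,
                 min_sv_block = as.integer(min_sv_block),
                 sv_mode = isTRUE(sv_mode)),
            class = "imputation_config")
}

#' Find all-missing square blocks on the diagonal
#'
#' Scans for maximal diagonal-anchored square blocks whose entries are all
#' missing and whose side is at least `min_sv_block`. These are the
#' footprint left in balanced matrices by deletions and duplications.
#'
#' @param A numeric matrix (or `ContactMatrix`) with `NA` marking missing.
#' @param min_sv_block minimal reported side.
#' @return A data frame with columns `start_bin`, `end_bin` (1-based,
#'   inclusive) and `side`; zero rows when there is no such block.
#' @export
find_sv_blocks <- function(A, min_sv_block = 3L) {
  A <- as_values(A)
  n <- nrow(A)
  na <- is.na(A)
  side <- integer(n)
  for (i in seq_len(n)) {
    m <- 0L
    while (i + m <= n && all(na[i:(i + m), i:(i + m)])) m <- m + 1L
    side[i] <- m
  }
  starts <- integer(0); sides <- integer(0)
  for (i in seq_len(n)) {
    if (side[i] < min_sv_block) next
    contained <- any(starts <= i & starts + sides >= i + side[i])
    if (!contained) {
      starts <- c(starts, i); sides <- c(sides, side[i])
    }
  }
  data.frame(start_bin = starts, end_bin = starts + sides - 1L,
             side = sides)
}

# fill NA entries with the median of observed entries at the same distance
# (same |j - i|); a distance with no observed entry falls back to the
# global median of the matrix
fill_by_distance_median <- function(M) {
  n <- nrow(M)
  if (!anyNA(M)) return(M)
  global_med <- median(M[!is.na(M)])
  fallback_used <- FALSE
  for (k in 0:(n - 1)) {
    i <- 1:(n - k); j <- (1 + k):n
    idx <- cbind(i, j)
    v <- M[idx]
    if (!anyNA(v)) next
    obs <- v[!is.na(v)]
    if (length(obs) == 0) {
      fill <- global_med
      fallback_used <- TRUE
    } else {
      fill <- median(obs)
    }
    v[is.na(v)] <- fill
    M[idx] <- v
    M[idx[, c(2, 1), drop = FALSE]] <- v
  }
  if (fallback_used) {
    message("some distance strata had no observed entries; ",
            "filled with the global median")
  }
  M
}

#' Impute a pair of TAD matrices
#'
#' Applies the three imputation stages of [imputation_config()] jointly to
#' the two condition matrices. Bin removal is synchronized: a bin exceeding
#' the row-missing threshold in either matrix is dropped from both.
#'
#' @param A1,A2 numeric matrices (or `ContactMatrix` objects) of identical
#'   dimension, `NA` marking missing entries.
#' @param config an [imputation_config()].
#' @return A list with elements `A1`, `A2` (complete, symmetric matrices)
#'   and `kept_bins` (indices into the original bins that survived
#'   removal).
#' @export
impute_pair <- function(A1, A2, config = imputation_config()) {
  A1 <- as_values(A1); A2 <- as_values(A2)
  if (!all(dim(A1) == dim(A2))) {
    stop("condition matrices must have identical dimensions", call. = FALSE)
  }
  n <- nrow(A1)
  if (config$sv_mode) {
    for (nm in c("A1", "A2")) {
      A <- get(nm)
      blocks <- find_sv_blocks(A, config$min_sv_block)
      for (b in seq_len(nrow(blocks))) {
        idx <- blocks$start_bin[b]:blocks$end_bin[b]
        A[idx, idx] <- config$sv_fill
      }
      assign(nm, A)
    }
  }
  # row-missing proportion over non-corner entries (|j - i| <= n - 2)
  row_prop <- function(A) {
    na <- is.na(A)
    if (n >= 2) {
      na[1, n] <- NA; na[n, 1] <- NA  # corners excluded from the count
    }
    rowMeans(na, na.rm = TRUE)
  }
  bad <- row_prop(A1) > config$row_missing_threshold |
    row_prop(A2) > config$row_missing_threshold
  kept <- which(!bad)
  if (length(kept) == 0) {
    stop(structure(class = c("tadshift_degenerate_error", "error",
                             "condition"),
                   list(message = "all bins removed during imputation",
                        call = NULL)))
  }
  A1 <- A1[kept, kept, drop = FALSE]
  A2 <- A2[kept, kept, drop = FALSE]
  list(A1 = fill_by_distance_median(A1),
       A2 = fill_by_distance_median(A2),
       kept_bins = kept)
}
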