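#' Collection of single-cell contact maps
#'
#' Stores one sparse contact map per cell at a fixed resolution over a
#' shared bin table. Each map is a data frame with columns `bin1`, `bin2`
#' (0-based indices relative to the window) and `count` (non-negative
#' integer contact counts).
#'
#' @param cells list of per-cell data frames (`bin1`, `bin2`, `count`).
#' @param n_bins number of bins in the shared window.
#' @param chrom,start_bp,resolution_bp genomic anchoring of the window.
#' @param cell_ids,cell_types optional per-cell annotations.
#' @return A list of class `CellMapCollection`.
#' @export
cell_map_collection <- function(cells, n_bins, chrom = "chr1",
                                start_bp = 0, resolution_bp = 1L,
                                cell_ids = NULL, cell_types = NULL) {
  stopifnot(is.list(cells), n_bins >= 1)
  for (cc in cells) {
    stopifnot(all(c("bin1", "bin2", "count") %in% names(cc)))
    if (nrow(cc) > 0) {
      stopifnot(all(cc$count >= 0), all(cc$count == round(cc$count)),
                all(cc$bin1 >= 0), all(cc$bin2 >= 0),
                all(cc$bin1 < n_bins), all(cc$bin2 < n_bins))
    }
  }
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_along(cells))
  structure(list(cells = cells, n_bins = as.integer(n_bins),
                 chrom = as.character(chrom), start_bp = start_bp,
                 resolution_bp = resolution_bp,
                 cell_ids = as.character(cell_ids),
                 cell_types = cell_types),
            class = "CellMapCollection")
}

#' @export
print.CellMapCollection <- function(x, ...) {
  cat(sprintf("CellMapCollection: %d cells, %d bins @ %d bp on %s\n",
              length(x$cells), x$n_bins, as.integer(x$resolution_bp),
              x$chrom))
  invisible(x)
}

#' Read per-cell contact maps from a manifest
#'
#' The manifest is a TSV with header columns `cell_id`, `path`,
#' `cell_type`; each path points to a triplet file (`bin1 bin2 count`,
#' 0-based window-relative bins). Relative paths are resolved against the
#' manifest's directory.
#'
#' @param manifest_path manifest TSV.
#' @param n_bins,chrom,start_bp,resolution_bp window description.
#' @return A [cell_map_collection()].
#' @export
read_cell_maps <- function(manifest_path, n_bins, chrom = "chr1",
                           start_bp = 0, resolution_bp = 1L) {
  man <- read.table(manifest_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "path", "cell_type") %in% names(man)))
  base <- dirname(manifest_path)
  cells <- lapply(man$path, function(p) {
    if (!file.exists(p)) p <- file.path(base, p)
    tab <- read.table(p, header = FALSE,
                      col.names = c("bin1", "bin2", "count"))
    tab
  })
  cell_map_collection(cells, n_bins, chrom, start_bp, resolution_bp,
                      cell_ids = man$cell_id, cell_types = man$cell_type)
}

# dense symmetric count matrix from triplet rows (duplicates summed)
triplets_to_dense <- function(bin1, bin2, count, n_bins) {
  m <- matrix(0, n_bins, n_bins)
  if (length(bin1) > 0) {
    i <- pmin(bin1, bin2) + 1L
    j <- pmax(bin1, bin2) + 1L
    lin <- (j - 1) * n_bins + i  # upper-triangle linear index
    agg <- rowsum(as.numeric(count), lin)
    idx <- as.numeric(rownames(agg))
    m[idx] <- agg[, 1]
    tm <- t(m)
    m[lower.tri(m)] <- tm[lower.tri(m)]
  }
  m
}

dense_cell_map <- function(cell, n_bins) {
  triplets_to_dense(cell$bin1, cell$bin2, cell$count, n_bins)
}

#' Pseudo-bulk contact matrix from sampled cells
#'
#' Sums raw contact counts over `k` cells sampled without replacement
#' (all cells when `k` is `NULL`). Sums rather than means are used; the
#' downstream test is scale invariant, so the choice is immaterial.
#'
#' @param collection a [cell_map_collection()].
#' @param k number of cells to sample; `NULL` uses all cells.
#' @param seed RNG seed for the sampling (set when given).
#' @return A `ContactMatrix` of summed counts (explicit zeros, no `NA`).
#' @export
pseudobulk <- function(collection, k = NULL, seed = NULL) {
  stopifnot(inherits(collection, "CellMapCollection"))
  ncell <- length(collection$cells)
  if (is.null(k)) {
    pick <- seq_len(ncell)
  } else {
    if (k <= 0) stop("k must be positive", call. = FALSE)
    if (k > ncell) stop("k exceeds the number of cells", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    pick <- sample.int(ncell, k)
  }
  all_trip <- do.call(rbind, collection$cells[pick])
  m <- triplets_to_dense(all_trip$bin1, all_trip$bin2, all_trip$count,
                         collection$n_bins)
  contact_matrix(m, chrom = collection$chrom,
                 start_bp = collection$start_bp,
                 resolution_bp = collection$resolution_bp)
}

#' Jaccard index of two identifier sets
#'
#' `|A intersect B| / |A union B|`; two empty sets are defined as
#' identical (index 1).
#'
#' @param a,b vectors of identifiers.
#' @return A number in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) {
    message("both sets empty; Jaccard index defined as 1")
    return(1)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Reproducibility of reorganized-TAD calls versus cell number
#'
#' Repeatedly builds pseudo-bulk maps from `k` sampled cells per
#' condition, reruns the reorganization test, and measures the agreement
#' (Jaccard index) of the significant set with the reference set obtained
#' from all cells.
#'
#' @param collection1,collection2 [cell_map_collection()] objects for the
#'   two cell types.
#' @param tads a [tad_set()] (condition 1 TADs).
#' @param k_grid vector of cell numbers to sample; values exceeding a
#'   collection's size are clipped with a warning; `NA` means all cells.
#' @param n_repeats resamples per grid point.
#' @param config a [tad_test_config()].
#' @param seed base RNG seed; each resample uses `seed + counter`.
#' @return A data frame with columns `k`, `rep`, `n_significant`,
#'   `prop_reorganized` (significant / tested) and `jaccard` (vs the
#'   all-cell reference).
#' @export
reproducibility_curve <- function(collection1, collection2, tads, k_grid,
                                  n_repeats = 3,
                                  config = tad_test_config(), seed = 1) {
  ref <- run_genomewide(pseudobulk(collection1), pseudobulk(collection2),
                        tads, config)
  ref_set <- which(!is.na(ref$significant) & ref$significant)
  n1 <- length(collection1$cells); n2 <- length(collection2$cells)
  rows <- list()
  counter <- 0
  for (k in k_grid) {
    k1 <- if (is.na(k)) n1 else min(k, n1)
    k2 <- if (is.na(k)) n2 else min(k, n2)
    if (!is.na(k) && (k > n1 || k > n2)) {
      warning(sprintf("k = %s exceeds cell count; clipped to (%d, %d)",
                      format(k), as.integer(k1), as.integer(k2)),
              call. = FALSE)
    }
    for (r in seq_len(n_repeats)) {
      counter <- counter + 1
      pb1 <- pseudobulk(collection1, k1, seed = seed + 2 * counter)
      pb2 <- pseudobulk(collection2, k2, seed = seed + 2 * counter + 1)
      res <- run_genomewide(pb1, pb2, tads, config)
      sig <- which(!is.na(res$significant) & res$significant)
      tested <- sum(res$status == "tested")
      rows[[length(rows) + 1]] <- data.frame(
        k = if (is.na(k)) max(n1, n2) else k, rep = r,
        n_significant = length(sig),
        prop_reorganized = if (tested > 0) length(sig) / tested else NA,
        jaccard = suppressMessages(jaccard_index(sig, ref_set)))
    }
  }
  do.call(rbind, rows)
}

#' Smoothing imputation of a sparse single-cell map
#'
#' A deliberately simple imputer for testing and simulation work:
#' library-size scaling to a common total followed by Gaussian kernel
#' smoothing, plus a small pseudocount so every entry is positive.
#' Dedicated single-cell Hi-C imputation methods are out of scope; any
#' externally imputed dense per-cell map can be supplied to the analysis
#' functions instead.
#'
#' @param collection a [cell_map_collection()].
#' @param index cell index.
#' @param target_total total count after library-size scaling.
#' @param smooth_sd_bins Gaussian kernel standard deviation in bins.
#' @param pseudocount added after smoothing.
#' @return A `ContactMatrix` with strictly positive entries.
#' @export
impute_cell_map <- function(collection, index, target_total = 1e4,
                            smooth_sd_bins = 1, pseudocount = 0.1) {
  m <- dense_cell_map(collection$cells[[index]], collection$n_bins)
  tot <- sum(m)
  if (tot > 0) m <- m * (target_total / tot)
  r <- max(1L, ceiling(2 * smooth_sd_bins))
  g <- dnorm(-r:r, sd = smooth_sd_bins)
  g <- g / sum(g)
  n <- nrow(m)
  pad <- matrix(0, n + 2 * r, n + 2 * r)
  pad[(r + 1):(r + n), (r + 1):(r + n)] <- m
  sm <- matrix(0, n, n)
  for (a in -r:r) for (b in -r:r) {
    sm <- sm + g[a + r + 1] * g[b + r + 1] *
      pad[(r + 1 + a):(r + n + a), (r + 1 + b):(r + n + b)]
  }
  sm <- (sm + t(sm)) / 2 + pseudocount
  contact_matrix(sm, chrom = collection$chrom,
                 start_bp = collection$start_bp,
                 resolution_bp = collection$resolution_bp)
}

#' Cell-to-population variability of TADs
#'
#' Tests every (TAD, cell) pair: the cell's imputed contact map for the
#' TAD against the pseudo-bulk map of the population. The resulting
#' P-value matrix is clustered (Ward linkage on Euclidean distances of
#' `-log10 P` rows, capped to limit the influence of vanishing P values)
#' into three classes labelled by descending variability: `high` (small
#' P), `median`, `low` (large P).
#'
#' @param tads a [tad_set()].
#' @param cell_maps list of dense per-cell `ContactMatrix` objects (e.g.
#'   from [impute_cell_map()] or an external imputation method).
#' @param bulk pseudo-bulk `ContactMatrix` for the population.
#' @param config a [tad_test_config()].
#' @param nlog_cap cap applied to `-log10 P` before clustering
#'   (default 16).
#' @return A list with `pvalues` (TADs x cells matrix), `labels` (per
#'   clustered TAD: `high`/`median`/`low`), `tads` (rows actually
#'   clustered) and `dropped` (TAD indices untestable in every cell).
#' @export
cell_to_population <- function(tads, cell_maps, bulk,
                               config = tad_test_config(),
                               nlog_cap = 16) {
  n_tad <- nrow(tads); n_cell <- length(cell_maps)
  P <- matrix(NA_real_, n_tad, n_cell)
  for (t in seq_len(n_tad)) {
    subB <- try(suppressWarnings(
      extract_submatrix(bulk, tads$start[t], tads$end[t])), silent = TRUE)
    if (inherits(subB, "try-error")) next
    for (cidx in seq_len(n_cell)) {
      subC <- try(suppressWarnings(
        extract_submatrix(cell_maps[[cidx]], tads$start[t],
                          tads$end[t])), silent = TRUE)
      if (inherits(subC, "try-error")) next
      tt <- test_tad(subC, subB, config)
      if (tt$status == "tested") P[t, cidx] <- tt$pvalue
    }
  }
  all_na <- rowSums(!is.na(P)) == 0
  dropped <- which(all_na)
  keep <- which(!all_na)
  Pk <- P[keep, , drop = FALSE]
  # row-mean imputation of untestable (TAD, cell) entries for clustering
  for (t in seq_len(nrow(Pk))) {
    miss <- is.na(Pk[t, ])
    if (any(miss)) Pk[t, miss] <- mean(Pk[t, !miss])
  }
  X <- pmin(-log10(pmax(Pk, 1e-300)), nlog_cap)
  k <- min(3L, nrow(Pk), max(1L, nrow(unique(round(X, 8)))))
  if (nrow(Pk) < 1) stop("no clusterable TADs", call. = FALSE)
  if (k >= 2) {
    cl <- cutree(hclust(dist(X), method = "ward.D2"), k = k)
  } else {
    cl <- rep(1L, nrow(Pk))
  }
  mean_p <- vapply(seq_len(k), function(g) mean(Pk[cl == g, ]),
                   numeric(1))
  lab_names <- switch(k, if (mean_p > 0.5) "low" else "high",
                      c("high", "low"), c("high", "median", "low"))
  labels <- lab_names[match(cl, order(mean_p))]
  list(pvalues = P, labels = labels, tads = keep, dropped = dropped)
}

#' Pairwise cell-to-cell TAD comparison with a permutation baseline
#'
#' Tests every TAD in every cross pair of cells from two groups, counts
#' per TAD in how many partner pairs it is called reorganized, and builds
#' a random baseline in which each pair's significant calls are
#' redistributed uniformly over the tested TADs (preserving each pair's
#' total), which destroys TAD identity while keeping per-pair call rates.
#'
#' @param maps_a,maps_b lists of dense per-cell `ContactMatrix` objects.
#' @param tads a [tad_set()].
#' @param config a [tad_test_config()]; significance is taken at
#'   `config$alpha` on BH-adjusted P values within each pair.
#' @param seed RNG seed for the baseline redistribution.
#' @return A list with `proportion` (cells-A x cells-B matrix of the
#'   fraction of tested TADs called reorganized per pair), `counts`
#'   (TADs x cells-A matrix: for each A cell, in how many B cells the TAD
#'   is reorganized) and `baseline_counts` (same shape, randomized).
#' @export
cell_to_cell <- function(maps_a, maps_b, tads,
                         config = tad_test_config(), seed = 1) {
  nA <- length(maps_a); nB <- length(maps_b); nT <- nrow(tads)
  prop <- matrix(NA_real_, nA, nB)
  sig_arr <- array(FALSE, c(nT, nA, nB))
  base_arr <- array(FALSE, c(nT, nA, nB))
  set.seed(seed)
  for (a in seq_len(nA)) for (b in seq_len(nB)) {
    p <- rep(NA_real_, nT)
    for (t in seq_len(nT)) {
      sub1 <- try(suppressWarnings(
        extract_submatrix(maps_a[[a]], tads$start[t], tads$end[t])),
        silent = TRUE)
      sub2 <- try(suppressWarnings(
        extract_submatrix(maps_b[[b]], tads$start[t], tads$end[t])),
        silent = TRUE)
      if (inherits(sub1, "try-error") || inherits(sub2, "try-error")) next
      tt <- test_tad(sub1, sub2, config)
      if (tt$status == "tested") p[t] <- tt$pvalue
    }
    q <- adjust_pvalues(p, config$adjust_method)
    sig <- !is.na(q) & q <= config$alpha
    tested <- which(!is.na(q))
    prop[a, b] <- if (length(tested) > 0) sum(sig) / length(tested)
      else NA
    sig_arr[, a, b] <- sig
    n_sig <- sum(sig)
    if (length(tested) > 0 && n_sig > 0) {
      base_arr[tested[sample.int(length(tested), n_sig)], a, b] <- TRUE
    }
  }
  counts <- apply(sig_arr, c(1, 2), sum)
  baseline <- apply(base_arr, c(1, 2), sum)
  list(proportion = prop, counts = counts, baseline_counts = baseline)
}
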