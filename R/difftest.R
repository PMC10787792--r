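#' Log-ratio difference of two contact matrices
#'
#' Computes `log(A1) - log(A2)` entrywise. Entries where either matrix is
#' zero or missing have no defined log-ratio; they are masked and, when
#' `fill = TRUE` (the default), replaced by the median of the observed
#' difference values at the same genomic distance, mirroring the
#' distance-median imputation rule. The logarithm base is irrelevant
#' downstream: a change of base rescales every off-diagonal uniformly and
#' is removed by [stratified_standardize()].
#'
#' @param A1,A2 numeric matrices (or `ContactMatrix` objects) of identical
#'   dimension.
#' @param fill replace masked entries by the distance-median of the
#'   difference matrix (default `TRUE`).
#' @return Numeric matrix of differences (with `NA` at masked entries when
#'   `fill = FALSE`).
#' @export
log_difference <- function(A1, A2, fill = TRUE) {
  A1 <- as_values(A1); A2 <- as_values(A2)
  if (!all(dim(A1) == dim(A2))) {
    stop("condition matrices must have identical dimensions", call. = FALSE)
  }
  mask <- !is.finite(A1) | !is.finite(A2) | A1 <= 0 | A2 <= 0
  D <- suppressWarnings(log(A1) - log(A2))
  D[mask] <- NA_real_
  if (fill && anyNA(D)) {
    if (all(is.na(D))) {
      stop(structure(class = c("tadshift_degenerate_error", "error",
                               "condition"),
                     list(message = "no entry has a defined log-ratio",
                          call = NULL)))
    }
    D <- fill_by_distance_median(D)
  }
  D
}

#' Distance-stratified standardization of a difference matrix
#'
#' Each off-diagonal `k` (entries with `|j - i| = k`,
#' `k = 0, ..., N - 2`) of the symmetric difference matrix is centred by
#' its sample mean and scaled by its sample standard deviation, removing
#' both the 1D-distance dependence of Hi-C signal and any global offset
#' caused by read-depth differences between conditions. The single-entry
#' corner diagonals (`|k| = N - 1`) are set to 0. Constant diagonals
#' (zero standard deviation) are set to 0 rather than dropped, keeping the
#' matrix square.
#'
#' The population (1/n) standard deviation is used so each standardized
#' diagonal has exactly unit variance, matching the null model in which
#' the standardized entries are standard Gaussian; with the `(n-1)`
#' divisor the short diagonals near the corner would be systematically
#' shrunk (variance `(n-1)/n`, down to 1/2 for the two-entry diagonal),
#' which measurably distorts the Tracy-Widom tail at TAD sizes. When
#' `goe_diag = TRUE` (default) the main diagonal is rescaled to variance
#' 2, the Gaussian Orthogonal Ensemble convention under which the
#' Tracy-Widom approximation to the largest-eigenvalue law is most
#' accurate at finite `N`; the asymptotic law is unaffected.
#'
#' @param D symmetric numeric matrix with finite entries, `N >= 3`.
#' @param goe_diag rescale the standardized main diagonal by `sqrt(2)`
#'   (default `TRUE`).
#' @return An object of class `NormalizedDifference`: a list with
#'   `d_matrix` (the standardized matrix), `diag_means` and `diag_sds`
#'   (per-`k` statistics, `k = 0, ..., N - 2`) and `n_bins`.
#' @export
stratified_standardize <- function(D, goe_diag = TRUE) {
  D <- as_values(D)
  n <- nrow(D)
  if (n < 3) {
    stop(structure(class = c("tadshift_degenerate_error", "error",
                             "condition"),
                   list(message = "matrix must have at least 3 bins",
                        call = NULL)))
  }
  if (!all(is.finite(D))) {
    stop("difference matrix must be finite; impute first", call. = FALSE)
  }
  mu <- numeric(n - 1)
  sg <- numeric(n - 1)
  for (k in 0:(n - 2)) {
    idx <- cbind(1:(n - k), (1 + k):n)
    v <- D[idx]
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))  # population SD: unit variance per stratum
    mu[k + 1] <- m
    sg[k + 1] <- s
    z <- if (s > 0) (v - m) / s else rep(0, length(v))
    if (k == 0 && goe_diag) z <- z * sqrt(2)
    D[idx] <- z
    D[idx[, c(2, 1), drop = FALSE]] <- z
  }
  D[1, n] <- 0
  D[n, 1] <- 0
  structure(list(d_matrix = D, diag_means = mu, diag_sds = sg,
                 n_bins = n),
            class = "NormalizedDifference")
}

#' Largest eigenvalue of the scaled difference matrix
#'
#' Returns the largest eigenvalue of \eqn{D/\sqrt{N}} computed with a full
#' symmetric eigensolver. Under the null of no reorganization this value
#' fluctuates around 2.
#'
#' @param nd a `NormalizedDifference` (or a symmetric numeric matrix).
#' @return The largest eigenvalue \eqn{\lambda_N}.
#' @export
largest_eigenvalue <- function(nd) {
  D <- if (inherits(nd, "NormalizedDifference")) nd$d_matrix else
    as_values(nd)
  if (!all(is.finite(D))) {
    stop("matrix must be finite", call. = FALSE)
  }
  n <- nrow(D)
  max(eigen(D / sqrt(n), symmetric = TRUE, only.values = TRUE)$values)
}

#' Normalized largest-eigenvalue statistic
#'
#' \eqn{\theta_N = N^{2/3} (\lambda_N - 2)}, the centred and scaled largest
#' eigenvalue whose null distribution is Tracy-Widom \eqn{\beta = 1}.
#'
#' @param lambda_n largest eigenvalue of \eqn{D/\sqrt{N}}.
#' @param n_bins matrix dimension `N`.
#' @return The test statistic \eqn{\theta_N}.
#' @export
theta_statistic <- function(lambda_n, n_bins) {
  n_bins^(2 / 3) * (lambda_n - 2)
}

#' Configuration for the TAD reorganization test
#'
#' @param alpha significance level for calling a TAD reorganized
#'   (default 0.05, applied to BH-adjusted P values in
#'   [run_genomewide()]).
#' @param min_bins minimal TAD width in bins for the Tracy-Widom
#'   approximation to be trusted; smaller TADs are skipped (default 10).
#' @param adjust_method multiple-testing correction: `"BH"` (default),
#'   `"holm"` or `"bonferroni"`.
#' @param per_chromosome adjust P values within each chromosome instead of
#'   genome-wide (default `FALSE`).
#' @param imputation an [imputation_config()].
#' @param goe_diag see [stratified_standardize()].
#' @return A list of class `tad_test_config`.
#' @export
tad_test_config <- function(alpha = 0.05, min_bins = 10L,
                            adjust_method = c("BH", "holm", "bonferroni"),
                            per_chromosome = FALSE,
                            imputation = imputation_config(),
                            goe_diag = TRUE) {
  stopifnot(alpha > 0, alpha < 1, min_bins >= 3)
  structure(list(alpha = alpha, min_bins = as.integer(min_bins),
                 adjust_method = match.arg(adjust_method),
                 per_chromosome = isTRUE(per_chromosome),
                 imputation = imputation, goe_diag = isTRUE(goe_diag)),
            class = "tad_test_config")
}

#' Test one TAD for structural reorganization
#'
#' Runs the full per-TAD pipeline: joint imputation of the two condition
#' matrices, log-ratio difference, distance-stratified standardization,
#' largest eigenvalue of \eqn{D/\sqrt{N}}, and the one-sided Tracy-Widom
#' P value for \eqn{\theta_N}. TADs narrower than `min_bins` (before
#' imputation) are skipped, as are TADs left degenerate by imputation.
#'
#' @param A1,A2 the TAD's contact matrices in conditions 1 and 2
#'   (matrices or `ContactMatrix` objects, identical dimension).
#' @param config a [tad_test_config()].
#' @return A list with `n_bins` (input width), `n_bins_tested` (width
#'   after bin removal), `lambda_n`, `theta`, `pvalue` and `status`
#'   (`"tested"`, `"skipped_too_small"` or `"skipped_degenerate"`).
#' @export
test_tad <- function(A1, A2, config = tad_test_config()) {
  A1 <- as_values(A1); A2 <- as_values(A2)
  n <- nrow(A1)
  res <- list(n_bins = n, n_bins_tested = NA_integer_,
              lambda_n = NA_real_, theta = NA_real_, pvalue = NA_real_,
              status = "tested")
  if (n < config$min_bins) {
    res$status <- "skipped_too_small"
    return(res)
  }
  out <- tryCatch({
    imp <- impute_pair(A1, A2, config$imputation)
    nt <- nrow(imp$A1)
    if (nt < config$min_bins) {
      res$status <- "skipped_too_small"
      res$n_bins_tested <- nt
      return(res)
    }
    D <- log_difference(imp$A1, imp$A2)
    nd <- stratified_standardize(D, goe_diag = config$goe_diag)
    lam <- largest_eigenvalue(nd)
    th <- theta_statistic(lam, nt)
    res$n_bins_tested <- nt
    res$lambda_n <- lam
    res$theta <- th
    res$pvalue <- tw1_sf(th)
    res
  }, tadshift_degenerate_error = function(e) {
    res$status <- "skipped_degenerate"
    res
  })
  out
}

#' Adjust P values for multiple testing
#'
#' Step-up Benjamini-Hochberg by default. `NA` entries (skipped TADs) are
#' excluded from the number of comparisons and stay `NA`.
#'
#' @param pvalues numeric vector in `[0, 1]` (`NA` allowed).
#' @param method `"BH"`, `"holm"` or `"bonferroni"`.
#' @return Adjusted P values, same length and order as the input.
#' @export
adjust_pvalues <- function(pvalues, method = c("BH", "holm",
                                               "bonferroni")) {
  method <- match.arg(method)
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("P values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- p.adjust(pvalues[ok], method = method)
  out
}

#' Genome-wide TAD reorganization testing
#'
#' Extracts the per-TAD submatrices from two genome-wide (or per-region)
#' contact matrices, tests every TAD with [test_tad()], and adjusts the
#' P values across all tested TADs.
#'
#' @param mats1,mats2 a `ContactMatrix` or a named list of
#'   `ContactMatrix` objects keyed by chromosome, one per condition; the
#'   two conditions must share chromosomes and resolution.
#' @param tads a [tad_set()] called in condition 1.
#' @param config a [tad_test_config()].
#' @return A data frame with one row per TAD: `chrom`, `start`, `end`,
#'   `n_bins`, `lambda_n`, `theta`, `pvalue`, `qvalue`, `significant`,
#'   `subtype`, `direction`, `status`. Subtype and direction are filled by
#'   [classify_results()].
#' @export
run_genomewide <- function(mats1, mats2, tads,
                           config = tad_test_config()) {
  as_list <- function(m) {
    if (inherits(m, "ContactMatrix")) setNames(list(m), m$chrom) else m
  }
  mats1 <- as_list(mats1); mats2 <- as_list(mats2)
  rows <- vector("list", nrow(tads))
  for (i in seq_len(nrow(tads))) {
    chrom <- tads$chrom[i]
    row <- data.frame(chrom = chrom, start = tads$start[i],
                      end = tads$end[i], n_bins = NA_integer_,
                      lambda_n = NA_real_, theta = NA_real_,
                      pvalue = NA_real_, qvalue = NA_real_,
                      significant = NA, subtype = NA_character_,
                      direction = NA_character_, status = "skipped_degenerate",
                      stringsAsFactors = FALSE)
    if (!is.null(mats1[[chrom]]) && !is.null(mats2[[chrom]])) {
      m1 <- mats1[[chrom]]; m2 <- mats2[[chrom]]
      stopifnot(m1$resolution_bp == m2$resolution_bp)
      sub1 <- try(suppressWarnings(
        extract_submatrix(m1, tads$start[i], tads$end[i])), silent = TRUE)
      sub2 <- try(suppressWarnings(
        extract_submatrix(m2, tads$start[i], tads$end[i])), silent = TRUE)
      if (!inherits(sub1, "try-error") && !inherits(sub2, "try-error")) {
        tt <- test_tad(sub1, sub2, config)
        row$n_bins <- tt$n_bins
        row$lambda_n <- tt$lambda_n
        row$theta <- tt$theta
        row$pvalue <- tt$pvalue
        row$status <- tt$status
      }
    }
    rows[[i]] <- row
  }
  res <- do.call(rbind, rows)
  if (!any(res$status == "tested")) {
    warning("no testable TADs", call. = FALSE)
    return(res)
  }
  if (config$per_chromosome) {
    for (ch in unique(res$chrom)) {
      sel <- res$chrom == ch
      res$qvalue[sel] <- adjust_pvalues(res$pvalue[sel],
                                        config$adjust_method)
    }
  } else {
    res$qvalue <- adjust_pvalues(res$pvalue, config$adjust_method)
  }
  res$significant <- !is.na(res$qvalue) & res$qvalue <= config$alpha
  res$significant[is.na(res$qvalue)] <- NA
  res
}

#' Write a results table as TSV
#'
#' @param results data frame from [run_genomewide()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  for (col in c("start", "end")) {
    if (col %in% names(results)) {
      results[[col]] <- format(results[[col]], scientific = FALSE,
                               trim = TRUE)
    }
  }
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
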