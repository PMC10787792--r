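#' Construct a ContactMatrix
#'
#' A `ContactMatrix` holds a dense symmetric matrix of non-negative (or
#' missing) balanced contact frequencies anchored to a genomic window at a
#' fixed bin resolution. Bin `i` (1-based row/column) covers
#' `[start_bp + (i-1)*resolution_bp, start_bp + i*resolution_bp)`.
#'
#' @param values square numeric matrix; `NA` marks unobserved bin pairs.
#' @param chrom chromosome name.
#' @param start_bp 0-based genomic start of the window in bp; must be a
#'   multiple of `resolution_bp`.
#' @param resolution_bp bin size in bp.
#' @return An object of class `ContactMatrix`.
#' @export
contact_matrix <- function(values, chrom = "chr1", start_bp = 0,
                           resolution_bp = 1L) {
  values <- as.matrix(values)
  dimnames(values) <- NULL
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values)) {
    stop("contact matrix must be square", call. = FALSE)
  }
  obs <- !is.na(values)
  if (any(values[obs] < 0)) {
    stop("contact frequencies must be non-negative", call. = FALSE)
  }
  both <- obs & t(obs)
  if (any(abs(values[both] - t(values)[both]) >
            1e-8 * (1 + abs(values[both])))) {
    stop("contact matrix is not symmetric", call. = FALSE)
  }
  if (start_bp %% resolution_bp != 0) {
    stop("start_bp must be aligned to resolution_bp", call. = FALSE)
  }
  structure(
    list(values = values, chrom = as.character(chrom),
         start_bp = as.numeric(start_bp),
         resolution_bp = as.numeric(resolution_bp),
         n_bins = nrow(values)),
    class = "ContactMatrix"
  )
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %s:%d-%d, %d bins @ %d bp, %d missing entries\n",
              x$chrom, x$start_bp,
              x$start_bp + x$n_bins * x$resolution_bp,
              x$n_bins, as.integer(x$resolution_bp),
              sum(is.na(x$values))))
  invisible(x)
}

# snap a bp interval outward to bin boundaries; warn when it moves
snap_window <- function(start_bp, end_bp, resolution_bp, what = "window") {
  b0 <- floor(start_bp / resolution_bp)
  b1 <- ceiling(end_bp / resolution_bp)
  if (b0 * resolution_bp != start_bp || b1 * resolution_bp != end_bp) {
    warning(sprintf(
      "%s [%s, %s) not aligned to %d bp; snapped outward to [%s, %s)",
      what, format(start_bp, scientific = FALSE),
      format(end_bp, scientific = FALSE), as.integer(resolution_bp),
      format(b0 * resolution_bp, scientific = FALSE),
      format(b1 * resolution_bp, scientific = FALSE)), call. = FALSE)
  }
  c(bin_start = b0, bin_end = b1)
}

#' Read a Hi-C contact matrix
#'
#' Reads a dense whitespace/tab-delimited square matrix or a sparse
#' three-column triplet file (`bin1 bin2 value`, 0-based chromosome-wide bin
#' indices) into a [contact_matrix()]. Matrices are assumed to be balanced
#' already (e.g. KR); explicit zeros are kept as zeros and unobserved bin
#' pairs of a triplet file are returned as missing (`NA`). Binary cooler /
#' hic containers are not supported; export the region of interest as text.
#'
#' @param path file to read.
#' @param chrom chromosome name attached to the result.
#' @param start_bp,end_bp genomic window (0-based, half-open). Unaligned
#'   windows are snapped outward with a warning. When `NULL`, the full
#'   extent of the file is used.
#' @param resolution_bp bin size in bp.
#' @param format `"auto"` (by content: exactly 3 columns on every line is a
#'   triplet file), `"dense"` or `"triplet"`.
#' @return A `ContactMatrix` covering the requested window.
#' @export
read_contact_matrix <- function(path, chrom = "chr1", start_bp = NULL,
                                end_bp = NULL, resolution_bp,
                                format = c("auto", "dense", "triplet")) {
  format <- match.arg(format)
  if (grepl("\\.(cool|mcool|hic)$", path, ignore.case = TRUE)) {
    stop(sprintf(paste0(
      "'%s': binary cooler/hic containers are not supported; ",
      "export the matrix as dense or triplet text"), path),
      call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    colClasses = "numeric", na.strings = c("NA", "nan"))
  if (format == "auto") {
    format <- if (ncol(tab) == 3 && nrow(tab) != 3) "triplet" else "dense"
  }

  window_given <- !is.null(start_bp) && !is.null(end_bp)
  if (window_given) {
    w <- snap_window(start_bp, end_bp, resolution_bp, "region")
    b0 <- w[["bin_start"]]; b1 <- w[["bin_end"]]
  }

  if (format == "triplet") {
    bin1 <- as.integer(tab[[1]]); bin2 <- as.integer(tab[[2]])
    val <- as.numeric(tab[[3]])
    if (!window_given) {
      b0 <- 0; b1 <- max(bin1, bin2) + 1L
    }
    n <- b1 - b0
    keep <- bin1 >= b0 & bin1 < b1 & bin2 >= b0 & bin2 < b1
    m <- matrix(NA_real_, n, n)
    i <- bin1[keep] - b0 + 1L
    j <- bin2[keep] - b0 + 1L
    m[cbind(i, j)] <- val[keep]
    m[cbind(j, i)] <- val[keep]
  } else {
    m <- as.matrix(tab)
    if (nrow(m) != ncol(m)) {
      stop("dense matrix file is not square: ", path, call. = FALSE)
    }
    if (window_given) {
      n <- b1 - b0
      if (nrow(m) == n) {
        # file already holds exactly the requested window
      } else if (nrow(m) >= b1) {
        m <- m[(b0 + 1):b1, (b0 + 1):b1, drop = FALSE]
      } else {
        stop("requested window extends beyond the dense matrix in ", path,
             call. = FALSE)
      }
    } else {
      b0 <- 0
    }
  }
  contact_matrix(m, chrom = chrom, start_bp = b0 * resolution_bp,
                 resolution_bp = resolution_bp)
}

#' Write a contact matrix to text
#'
#' @param cm a `ContactMatrix`.
#' @param path output file.
#' @param format `"dense"` writes a tab-delimited square matrix;
#'   `"triplet"` writes the non-missing upper triangle (including the
#'   diagonal) as `bin1 bin2 value` with 0-based chromosome-wide bin
#'   indices.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(cm, path, format = c("dense", "triplet")) {
  stopifnot(inherits(cm, "ContactMatrix"))
  format <- match.arg(format)
  if (format == "dense") {
    write.table(cm$values, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    off <- cm$start_bp / cm$resolution_bp
    idx <- which(upper.tri(cm$values, diag = TRUE) & !is.na(cm$values),
                 arr.ind = TRUE)
    df <- data.frame(bin1 = idx[, 1] - 1 + off, bin2 = idx[, 2] - 1 + off,
                     value = cm$values[idx])
    df <- df[order(df$bin1, df$bin2), ]
    write.table(format(df, scientific = FALSE, trim = TRUE), path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Extract the submatrix covering a genomic interval
#'
#' Maps an interval to bin indices by floor division
#' (`bin = floor((pos - start_bp) / resolution_bp)`) and returns the
#' corresponding square block as a new `ContactMatrix`. Intervals not
#' aligned to the resolution are snapped outward with a warning, so a TAD
#' is never truncated.
#'
#' @param cm a `ContactMatrix`.
#' @param start_bp,end_bp interval to extract (0-based, half-open), inside
#'   the matrix window.
#' @param chrom optional chromosome check.
#' @return A `ContactMatrix` for the interval.
#' @export
extract_submatrix <- function(cm, start_bp, end_bp, chrom = NULL) {
  stopifnot(inherits(cm, "ContactMatrix"))
  if (!is.null(chrom) && !identical(as.character(chrom), cm$chrom)) {
    stop(sprintf("chromosome mismatch: requested %s, matrix holds %s",
                 chrom, cm$chrom), call. = FALSE)
  }
  w <- snap_window(start_bp, end_bp, cm$resolution_bp, "TAD")
  i0 <- w[["bin_start"]] - cm$start_bp / cm$resolution_bp
  i1 <- w[["bin_end"]] - cm$start_bp / cm$resolution_bp
  if (i0 < 0 || i1 > cm$n_bins || i1 <= i0) {
    stop(sprintf("interval [%s, %s) outside matrix window",
                 format(start_bp, scientific = FALSE),
                 format(end_bp, scientific = FALSE)), call. = FALSE)
  }
  contact_matrix(cm$values[(i0 + 1):i1, (i0 + 1):i1, drop = FALSE],
                 chrom = cm$chrom,
                 start_bp = w[["bin_start"]] * cm$resolution_bp,
                 resolution_bp = cm$resolution_bp)
}

# plain numeric matrix from ContactMatrix or matrix input
as_values <- function(x) {
  if (inherits(x, "ContactMatrix")) x$values else as.matrix(x)
}
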