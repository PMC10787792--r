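#' Construct a TAD set
#'
#' A `TADSet` is a data frame of 0-based half-open genomic intervals
#' (`chrom`, `start`, `end`), sorted by chromosome and start. Overlapping
#' intervals are permitted (TAD hierarchies).
#'
#' @param chrom,start,end interval columns (bp).
#' @param condition_label optional label for the biological condition.
#' @return A data frame with class `TADSet`.
#' @export
tad_set <- function(chrom, start, end, condition_label = NA_character_) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) {
    stop("all TADs must satisfy end > start", call. = FALSE)
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "condition_label") <- condition_label
  class(df) <- c("TADSet", "data.frame")
  df
}

#' Read a TAD list from a BED3+ file
#'
#' Only the first three columns (`chrom start end`) are used; extra columns
#' are ignored. Records with `start >= end` or non-numeric coordinates are
#' dropped with a warning. The result is sorted by `(chrom, start)`.
#'
#' @param path BED-like text file (tab or whitespace separated, `#`
#'   comments and `track`/`browser` lines skipped).
#' @param condition_label optional condition label stored as an attribute.
#' @return A [tad_set()] data frame.
#' @export
read_tads <- function(path, condition_label = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  fields <- strsplit(lines, "[\t ]+")
  ok <- vapply(fields, function(f) {
    length(f) >= 3 &&
      !is.na(suppressWarnings(as.numeric(f[2]))) &&
      !is.na(suppressWarnings(as.numeric(f[3]))) &&
      as.numeric(f[3]) > as.numeric(f[2])
  }, logical(1))
  if (any(!ok)) {
    warning(sprintf("dropped %d malformed TAD record(s) in %s",
                    sum(!ok), path), call. = FALSE)
  }
  fields <- fields[ok]
  if (length(fields) == 0) {
    return(tad_set(character(), numeric(), numeric(), condition_label))
  }
  tad_set(chrom = vapply(fields, `[`, character(1), 1),
          start = as.numeric(vapply(fields, `[`, character(1), 2)),
          end = as.numeric(vapply(fields, `[`, character(1), 3)),
          condition_label = condition_label)
}

#' Write a TAD set as BED3
#'
#' @param tads a [tad_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tads <- function(tads, path) {
  write.table(
    data.frame(tads$chrom, format(tads$start, scientific = FALSE,
                                  trim = TRUE),
               format(tads$end, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Width of a TAD in bins
#'
#' @param tads a `TADSet` (or any data frame with `start`/`end` in bp).
#' @param resolution_bp bin size.
#' @return Integer vector of bin counts after outward snapping.
#' @export
tad_n_bins <- function(tads, resolution_bp) {
  as.integer(ceiling(tads$end / resolution_bp) -
               floor(tads$start / resolution_bp))
}
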