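#' Interval relations between two TAD lists
#'
#' Two TADs are *identical* when both boundaries agree within
#' `boundary_tol_bins` bins (boundary calls jitter by about one bin
#' between Hi-C experiments), and *overlapping* when their intersection
#' has positive length and they are not identical. The relation graph also
#' records, per condition-1 TAD, its *siblings*: condition-1 TADs that are
#' adjacent (within tolerance) to or overlap it, which is the evidence
#' required by the merge subtype.
#'
#' @param tads1,tads2 [tad_set()] data frames for conditions 1 and 2.
#' @param resolution_bp bin size used to express the boundary tolerance.
#' @param boundary_tol_bins boundary-identity tolerance in bins
#'   (default 1).
#' @return A list of class `tad_relations` with per-TAD index sets
#'   `ident1`, `ovl1`, `ident2`, `ovl2`, `siblings1` and the inputs.
#' @export
build_relations <- function(tads1, tads2, resolution_bp,
                            boundary_tol_bins = 1L) {
  tol <- boundary_tol_bins * resolution_bp
  n1 <- nrow(tads1); n2 <- nrow(tads2)
  ident1 <- rep(list(integer(0)), n1); ovl1 <- rep(list(integer(0)), n1)
  ident2 <- rep(list(integer(0)), n2); ovl2 <- rep(list(integer(0)), n2)
  for (i in seq_len(n1)) {
    same <- which(tads2$chrom == tads1$chrom[i])
    for (j in same) {
      inter <- min(tads1$end[i], tads2$end[j]) -
        max(tads1$start[i], tads2$start[j])
      is_ident <- abs(tads1$start[i] - tads2$start[j]) <= tol &&
        abs(tads1$end[i] - tads2$end[j]) <= tol
      if (is_ident) {
        ident1[[i]] <- c(ident1[[i]], j)
        ident2[[j]] <- c(ident2[[j]], i)
      } else if (inter > 0) {
        ovl1[[i]] <- c(ovl1[[i]], j)
        ovl2[[j]] <- c(ovl2[[j]], i)
      }
    }
  }
  siblings1 <- rep(list(integer(0)), n1)
  for (i in seq_len(n1)) {
    same <- setdiff(which(tads1$chrom == tads1$chrom[i]), i)
    for (j in same) {
      inter <- min(tads1$end[i], tads1$end[j]) -
        max(tads1$start[i], tads1$start[j])
      if (inter > -tol) siblings1[[i]] <- c(siblings1[[i]], j)
    }
  }
  structure(list(ident1 = ident1, ovl1 = ovl1, ident2 = ident2,
                 ovl2 = ovl2, siblings1 = siblings1, tads1 = tads1,
                 tads2 = tads2, tol = tol),
            class = "tad_relations")
}

#' Reorganization subtype of one condition-1 TAD
#'
#' Assigns exactly one of six labels from the interval relations, checked
#' in the order loss, strength-change, merge, split, zoom, complex
#' (most specific first; merge precedes split because merge requires
#' sibling evidence that split lacks):
#' \describe{
#'   \item{loss}{no identical and no overlapping partner in condition 2.}
#'   \item{strength-change}{one-to-one identical partner and nothing
#'     else: same boundaries, altered contact intensity.}
#'   \item{merge}{the TAD and at least one adjacent/overlapping
#'     condition-1 sibling share a single condition-2 partner.}
#'   \item{split}{at least two partners, all of them contained in the TAD
#'     (within tolerance): the domain broke into pieces.}
#'   \item{zoom}{exactly one non-identical overlapping partner that maps
#'     one-to-one back: the boundaries expanded or shrank.}
#'   \item{complex}{any other configuration.}
#' }
#'
#' @param i index of the condition-1 TAD in the relation graph.
#' @param graph a [build_relations()] result built from the two full TAD
#'   lists (not only the significant TADs).
#' @return A single label.
#' @export
classify_subtype <- function(i, graph) {
  ident <- graph$ident1[[i]]
  ovl <- graph$ovl1[[i]]
  partners <- union(ident, ovl)
  if (length(partners) == 0) return("loss")
  if (length(ident) == 1 && length(ovl) == 0) return("strength-change")
  sibs <- graph$siblings1[[i]]
  if (length(sibs) > 0) {
    for (j in partners) {
      back <- union(graph$ident2[[j]], graph$ovl2[[j]])
      if (length(intersect(back, sibs)) > 0) return("merge")
    }
  }
  if (length(partners) >= 2) {
    contained <- vapply(partners, function(j) {
      graph$tads2$start[j] >= graph$tads1$start[i] - graph$tol &&
        graph$tads2$end[j] <= graph$tads1$end[i] + graph$tol
    }, logical(1))
    if (all(contained)) return("split")
    return("complex")
  }
  if (length(ident) == 0 && length(ovl) == 1) {
    back <- union(graph$ident2[[ovl]], graph$ovl2[[ovl]])
    if (setequal(back, i)) return("zoom")
  }
  "complex"
}

#' Direction of a strength-change TAD
#'
#' A strength-change TAD keeps its boundaries but gains or loses contact
#' intensity. With `m1`, `m2` the median balanced contact frequency within
#' the TAD region in each condition and `s1`, `s2` the total balanced
#' contacts summed over all TADs of each condition (normalizing away
#' sequencing-depth differences), the TAD is *up* when
#' `(m1/m2) * (s2/s1) >= 1` and *down* otherwise.
#'
#' @param m1,m2 within-TAD median contact frequency per condition.
#' @param s1,s2 total contact frequency over all TADs per condition.
#' @return `"up"`, `"down"`, or `NA` when a component is zero or
#'   undefined.
#' @export
strength_direction <- function(m1, m2, s1, s2) {
  vals <- c(m1, m2, s1, s2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    message("strength direction undefined: non-positive component")
    return(NA_character_)
  }
  if ((m1 / m2) * (s2 / s1) >= 1) "up" else "down"
}

# total balanced contacts over all TADs of one condition
total_tad_contacts <- function(mats, tads) {
  tot <- 0
  for (i in seq_len(nrow(tads))) {
    m <- mats[[tads$chrom[i]]]
    if (is.null(m)) next
    sub <- try(suppressWarnings(
      extract_submatrix(m, tads$start[i], tads$end[i])), silent = TRUE)
    if (!inherits(sub, "try-error")) {
      tot <- tot + sum(sub$values, na.rm = TRUE)
    }
  }
  tot
}

#' Classify significant TADs in a results table
#'
#' Builds the relation graph over the two full TAD lists, labels every
#' significantly reorganized TAD with its subtype, and, when the contact
#' matrices are supplied, splits strength-change TADs into up/down.
#'
#' @param results data frame from [run_genomewide()].
#' @param tads1,tads2 full TAD lists for conditions 1 and 2.
#' @param resolution_bp bin size.
#' @param mats1,mats2 optional `ContactMatrix` (or named lists keyed by
#'   chromosome) used for the strength-change direction; when omitted the
#'   direction is left `NA`.
#' @param boundary_tol_bins see [build_relations()].
#' @return `results` with `subtype` and `direction` filled for
#'   significant TADs.
#' @export
classify_results <- function(results, tads1, tads2, resolution_bp,
                             mats1 = NULL, mats2 = NULL,
                             boundary_tol_bins = 1L) {
  graph <- build_relations(tads1, tads2, resolution_bp, boundary_tol_bins)
  # map result rows onto tads1 rows by interval identity
  key <- paste(tads1$chrom, tads1$start, tads1$end)
  row_key <- paste(results$chrom, results$start, results$end)
  idx <- match(row_key, key)
  as_list <- function(m) {
    if (is.null(m)) NULL
    else if (inherits(m, "ContactMatrix")) setNames(list(m), m$chrom)
    else m
  }
  mats1 <- as_list(mats1); mats2 <- as_list(mats2)
  have_mats <- !is.null(mats1) && !is.null(mats2)
  if (have_mats) {
    s1 <- total_tad_contacts(mats1, tads1)
    s2 <- total_tad_contacts(mats2, tads2)
  }
  for (r in which(!is.na(results$significant) & results$significant)) {
    i <- idx[r]
    if (is.na(i)) next
    subtype <- classify_subtype(i, graph)
    results$subtype[r] <- subtype
    if (subtype == "strength-change" && have_mats) {
      m1mat <- mats1[[results$chrom[r]]]
      m2mat <- mats2[[results$chrom[r]]]
      if (!is.null(m1mat) && !is.null(m2mat)) {
        sub1 <- suppressWarnings(
          extract_submatrix(m1mat, results$start[r], results$end[r]))
        sub2 <- suppressWarnings(
          extract_submatrix(m2mat, results$start[r], results$end[r]))
        m1 <- median(sub1$values, na.rm = TRUE)
        m2 <- median(sub2$values, na.rm = TRUE)
        results$direction[r] <- suppressMessages(
          strength_direction(m1, m2, s1, s2))
      }
    }
  }
  results
}
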