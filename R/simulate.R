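#' Specification of a simulated Hi-C window pair
#'
#' Describes the expected contact surface of a genomic window containing a
#' TAD, plus an optional reorganization applied to condition 2. The
#' expected contact frequency decays as a power law of genomic distance,
#' `mu[i, j] = base_intensity * (|i - j| + 1)^(-decay_exponent)`, and is
#' multiplied by each TAD block's enrichment inside the block. Observed
#' matrices are `mu` times symmetric i.i.d. lognormal noise (log-SD
#' `noise_sigma`), drawn independently per condition, so that under the
#' null the standardized log-difference has exactly i.i.d. Gaussian
#' entries.
#'
#' The default geometry places one TAD with 2-fold enrichment on the
#' central 60 percent of the window. A reorganization that multiplied the
#' whole tested window uniformly would be removed by the distance
#' standardization (that invariance is the point of the normalization:
#' uniform rescaling is indistinguishable from a read-depth change), so a
#' detectable strength change must create contrast between the TAD body
#' and its surrounding background, which the interior block provides.
#'
#' @param n_bins window width in bins (default 40).
#' @param decay_exponent power-law decay exponent (default 1).
#' @param base_intensity expected contact frequency at distance 0
#'   (default 10).
#' @param tad_blocks list of `c(start_bin, end_bin, enrichment)` triples
#'   (1-based inclusive bins); `NULL` gives the default central block.
#' @param noise_sigma SD of the Gaussian log-noise (default 0.2).
#' @param reorganization a list with element `type` in `none`,
#'   `strength` (element `multiplier`, default 2), `loss`, `split`
#'   (element `cut_bin`, default block midpoint), `merge` (requires two
#'   blocks), `zoom` (elements `new_start`, `new_end`) or `complex`.
#' @param seed RNG seed used by [simulate_pair()] (set when given).
#' @return A list of class `SimulationSpec`.
#' @export
simulation_spec <- function(n_bins = 40, decay_exponent = 1,
                            base_intensity = 10, tad_blocks = NULL,
                            noise_sigma = 0.2,
                            reorganization = list(type = "none"),
                            seed = NULL) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 4, decay_exponent >= 0, base_intensity > 0,
            noise_sigma >= 0)
  if (is.null(tad_blocks)) {
    tad_blocks <- list(c(floor(0.2 * n_bins) + 1, floor(0.8 * n_bins), 2))
  }
  for (b in tad_blocks) {
    stopifnot(length(b) == 3, b[1] >= 1, b[2] <= n_bins, b[2] > b[1],
              b[3] > 0)
  }
  if (is.character(reorganization)) {
    reorganization <- list(type = reorganization)
  }
  stopifnot(reorganization$type %in% c("none", "strength", "loss",
                                       "split", "merge", "zoom",
                                       "complex"))
  structure(list(n_bins = n_bins, decay_exponent = decay_exponent,
                 base_intensity = base_intensity,
                 tad_blocks = tad_blocks, noise_sigma = noise_sigma,
                 reorganization = reorganization, seed = seed),
            class = "SimulationSpec")
}

# expected contact surface for a block list
expected_surface <- function(n, alpha, base, blocks) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- base * (d + 1)^(-alpha)
  for (b in blocks) {
    idx <- b[1]:b[2]
    mu[idx, idx] <- mu[idx, idx] * b[3]
  }
  mu
}

# condition-2 block list after applying the reorganization
reorganized_blocks <- function(spec) {
  blocks <- spec$tad_blocks
  re <- spec$reorganization
  b1 <- blocks[[1]]
  switch(re$type,
    none = blocks,
    strength = {
      mult <- if (is.null(re$multiplier)) 2 else re$multiplier
      lapply(blocks, function(b) c(b[1], b[2], b[3] * mult))
    },
    loss = blocks[-1],
    split = {
      cut <- if (is.null(re$cut_bin)) floor((b1[1] + b1[2]) / 2) else
        re$cut_bin
      if (cut <= b1[1] || cut >= b1[2]) {
        stop("split cut_bin must fall inside the first block",
             call. = FALSE)
      }
      c(list(c(b1[1], cut, b1[3]), c(cut + 1, b1[2], b1[3])), blocks[-1])
    },
    merge = {
      if (length(blocks) < 2) {
        stop("merge requires at least two blocks", call. = FALSE)
      }
      b2 <- blocks[[2]]
      c(list(c(min(b1[1], b2[1]), max(b1[2], b2[2]), b1[3])),
        blocks[-(1:2)])
    },
    zoom = {
      ns <- if (is.null(re$new_start)) max(1, b1[1] - 3) else re$new_start
      ne <- if (is.null(re$new_end)) min(spec$n_bins, b1[2] + 3) else
        re$new_end
      if (ne <= ns || ns < 1 || ne > spec$n_bins) {
        stop("invalid zoom bounds", call. = FALSE)
      }
      c(list(c(ns, ne, b1[3])), blocks[-1])
    },
    complex = {
      shift <- max(2, round((b1[2] - b1[1]) / 4))
      mid <- floor((b1[1] + b1[2]) / 2)
      c(list(c(max(1, b1[1] - shift), mid, b1[3] * 1.5),
             c(mid + 1, min(spec$n_bins, b1[2] + shift), b1[3] / 1.5)),
        blocks[-1])
    })
}

# symmetric lognormal noise factor
lognormal_noise <- function(n, sigma) {
  E <- matrix(rnorm(n * n, 0, sigma), n, n)
  E[lower.tri(E)] <- t(E)[lower.tri(E)]
  exp(E)
}

#' Simulate a pair of TAD-window contact matrices
#'
#' Builds the condition-1 and condition-2 expected surfaces from a
#' [simulation_spec()] (applying the reorganization to condition 2 before
#' noise) and multiplies each by independent symmetric lognormal noise.
#'
#' @param spec a [simulation_spec()].
#' @return A list with matrices `A1`, `A2` and a `truth` record
#'   (`is_reorganized`, `subtype`, `effect_size`).
#' @export
simulate_pair <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_bins
  mu1 <- expected_surface(n, spec$decay_exponent, spec$base_intensity,
                          spec$tad_blocks)
  mu2 <- expected_surface(n, spec$decay_exponent, spec$base_intensity,
                          reorganized_blocks(spec))
  A1 <- mu1 * lognormal_noise(n, spec$noise_sigma)
  A2 <- mu2 * lognormal_noise(n, spec$noise_sigma)
  re <- spec$reorganization
  effect <- if (re$type == "strength") {
    if (is.null(re$multiplier)) 2 else re$multiplier
  } else NA_real_
  list(A1 = A1, A2 = A2,
       truth = list(is_reorganized = re$type != "none",
                    subtype = re$type, effect_size = effect))
}

#' Simulate a generalized Wigner matrix
#'
#' Symmetric matrix with independent Gaussian entries scaled by
#' \eqn{1/\sqrt{N}}: off-diagonal variance 1 and diagonal variance 2, the
#' Gaussian Orthogonal Ensemble convention. Its largest eigenvalue
#' concentrates at 2 and its standardized fluctuation
#' \eqn{N^{2/3}(\lambda_N - 2)} follows the Tracy-Widom \eqn{\beta = 1}
#' law.
#'
#' @param n matrix dimension (`>= 2`).
#' @param seed RNG seed (set when given).
#' @return An `n x n` symmetric numeric matrix.
#' @export
simulate_wigner <- function(n, seed = NULL) {
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(rnorm(n * n), n, n)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  diag(W) <- rnorm(n, 0, sqrt(2))
  W / sqrt(n)
}

#' Simulate paired TAD lists with implanted reorganization subtypes
#'
#' Lays out one parent TAD (two for `merge`) per requested subtype along
#' a synthetic chromosome, separated by fixed gaps, and edits the
#' condition-2 list so that each implant produces the interval
#' configuration of its subtype: identical boundaries
#' (`none`/`strength-change`), removal (`loss`), two abutting halves
#' (`split`), a single covering interval (`merge`), a 3-bin boundary
#' extension (`zoom`), or two straddling intervals crossing the parent's
#' boundaries (`complex`).
#'
#' @param subtypes character vector over `none`, `strength-change`,
#'   `loss`, `split`, `merge`, `zoom`, `complex`; one implant per entry.
#' @param tad_bins parent TAD width in bins (default 20, even).
#' @param gap_bins gap between consecutive parents in bins (default 8;
#'   must be at least 7 so zoom/complex edits cannot collide).
#' @param resolution_bp bin size in bp (default 50000).
#' @param chrom chromosome name.
#' @return A list with `tads1`, `tads2` ([tad_set()]s) and `truth` (data
#'   frame with the implanted subtype per condition-1 TAD).
#' @export
simulate_tadsets <- function(subtypes, tad_bins = 20L, gap_bins = 8L,
                             resolution_bp = 50000, chrom = "chrS") {
  stopifnot(tad_bins >= 10, gap_bins >= 7)
  ok <- c("none", "strength-change", "loss", "split", "merge", "zoom",
          "complex")
  stopifnot(all(subtypes %in% ok))
  bp <- function(bins) bins * resolution_bp
  t1 <- list(); t2 <- list(); truth <- list()
  cursor <- gap_bins
  for (st in subtypes) {
    a <- cursor; b <- cursor + tad_bins
    add1 <- function(s, e) t1[[length(t1) + 1]] <<- c(s, e)
    add2 <- function(s, e) t2[[length(t2) + 1]] <<- c(s, e)
    if (st %in% c("none", "strength-change")) {
      add1(a, b); add2(a, b)
      truth[[length(truth) + 1]] <- c(a, b, st)
    } else if (st == "loss") {
      add1(a, b)
      truth[[length(truth) + 1]] <- c(a, b, st)
    } else if (st == "split") {
      add1(a, b)
      mid <- a + floor(tad_bins / 2)
      add2(a, mid); add2(mid, b)
      truth[[length(truth) + 1]] <- c(a, b, st)
    } else if (st == "merge") {
      b2 <- b + tad_bins
      add1(a, b); add1(b, b2)
      add2(a, b2)
      truth[[length(truth) + 1]] <- c(a, b, st)
      truth[[length(truth) + 1]] <- c(b, b2, st)
      b <- b2
    } else if (st == "zoom") {
      add1(a, b)
      add2(a, b + 3)
      truth[[length(truth) + 1]] <- c(a, b, st)
    } else if (st == "complex") {
      add1(a, b)
      mid <- a + floor(tad_bins / 2)
      add2(a - 3, mid); add2(mid, b + 3)
      truth[[length(truth) + 1]] <- c(a, b, st)
    }
    cursor <- b + gap_bins
  }
  mk <- function(lst) {
    tad_set(chrom = rep(chrom, length(lst)),
            start = bp(vapply(lst, `[`, numeric(1), 1)),
            end = bp(vapply(lst, `[`, numeric(1), 2)))
  }
  truth_df <- data.frame(
    chrom = chrom,
    start = bp(vapply(truth, function(x) as.numeric(x[1]), numeric(1))),
    end = bp(vapply(truth, function(x) as.numeric(x[2]), numeric(1))),
    subtype = vapply(truth, `[`, character(1), 3),
    stringsAsFactors = FALSE)
  truth_df$is_reorganized <- truth_df$subtype != "none"
  truth_df <- truth_df[order(truth_df$start), ]
  rownames(truth_df) <- NULL
  list(tads1 = mk(t1), tads2 = mk(t2), truth = truth_df)
}

#' Simulate sparse single-cell contact maps
#'
#' Each cell draws a fixed number of contacts from the multinomial
#' distribution over bin pairs proportional to the expected surface `mu`
#' (upper triangle including the diagonal), emulating shallow single-cell
#' Hi-C at a chosen depth.
#'
#' @param mu expected contact surface (symmetric non-negative matrix).
#' @param n_cells number of cells.
#' @param contacts_per_cell contacts drawn per cell.
#' @param seed RNG seed (set when given).
#' @param chrom,start_bp,resolution_bp window anchoring.
#' @param cell_type optional label stored for every cell.
#' @return A [cell_map_collection()].
#' @export
simulate_cells <- function(mu, n_cells, contacts_per_cell, seed = NULL,
                           chrom = "chr1", start_bp = 0,
                           resolution_bp = 1L, cell_type = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(mu)
  ut <- which(upper.tri(mu, diag = TRUE), arr.ind = TRUE)
  p <- mu[ut]
  p <- p / sum(p)
  cells <- vector("list", n_cells)
  for (cidx in seq_len(n_cells)) {
    counts <- as.vector(rmultinom(1, contacts_per_cell, p))
    nz <- counts > 0
    cells[[cidx]] <- data.frame(bin1 = ut[nz, 1] - 1L,
                                bin2 = ut[nz, 2] - 1L,
                                count = counts[nz])
  }
  cell_map_collection(cells, n_bins = n, chrom = chrom,
                      start_bp = start_bp, resolution_bp = resolution_bp,
                      cell_ids = paste0(
                        if (is.null(cell_type)) "cell" else cell_type,
                        seq_len(n_cells)),
                      cell_types = if (is.null(cell_type)) NULL else
                        rep(cell_type, n_cells))
}
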