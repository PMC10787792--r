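toy_collection <- function() {
  cells <- list(
    data.frame(bin1 = 0L, bin2 = 1L, count = 1L),
    data.frame(bin1 = 2L, bin2 = 3L, count = 1L))
  cell_map_collection(cells, n_bins = 4, resolution_bp = 1000)
}

test_that("pseudobulk is additive and deterministic", {
  coll <- toy_collection()
  pb <- pseudobulk(coll)
  expect_equal(pb$values[1, 2], 1)
  expect_equal(pb$values[2, 1], 1)
  expect_equal(pb$values[3, 4], 1)
  expect_equal(sum(pb$values), 4)  # two contacts, mirrored
  expect_identical(pseudobulk(coll, k = 1, seed = 3)$values,
                   pseudobulk(coll, k = 1, seed = 3)$values)
  expect_error(pseudobulk(coll, k = 0), "positive")
  expect_error(pseudobulk(coll, k = 5), "exceeds")
})

test_that("pseudobulk is permutation invariant and additive over subsets", {
  set.seed(1)
  mu <- expected <- matrix(1, 12, 12)
  coll <- simulate_cells(mu, n_cells = 6, contacts_per_cell = 50,
                         seed = 2, resolution_bp = 1000)
  rev_coll <- cell_map_collection(rev(coll$cells), 12,
                                  resolution_bp = 1000)
  expect_equal(pseudobulk(coll)$values, pseudobulk(rev_coll)$values)
  sub1 <- cell_map_collection(coll$cells[1:2], 12, resolution_bp = 1000)
  sub2 <- cell_map_collection(coll$cells[3:6], 12, resolution_bp = 1000)
  expect_equal(pseudobulk(sub1)$values + pseudobulk(sub2)$values,
               pseudobulk(coll)$values)
})

test_that("sampled pseudobulk counts have the k/n expectation", {
  mu <- matrix(1, 10, 10)
  coll <- simulate_cells(mu, n_cells = 20, contacts_per_cell = 200,
                         seed = 4, resolution_bp = 1000)
  total <- pseudobulk(coll)$values
  k <- 5
  acc <- matrix(0, 10, 10)
  for (r in 1:200) acc <- acc + pseudobulk(coll, k, seed = 100 + r)$values
  avg <- acc / 200
  # elementwise expectation k/n * total; compare in aggregate
  expect_equal(sum(avg), sum(total) * k / 20, tolerance = 0.02)
  expect_lt(max(abs(avg - total * k / 20)), 3)
})

test_that("jaccard index satisfies its definition", {
  expect_equal(jaccard_index(1:5, 1:5), 1)
  expect_equal(jaccard_index(1:3, 4:6), 0)
  expect_equal(jaccard_index(1:100, 51:150), 1 / 3)
  expect_message(j <- jaccard_index(integer(0), integer(0)), "empty")
  expect_equal(j, 1)
  expect_equal(jaccard_index(1:4, 3:6), jaccard_index(3:6, 1:4))
})

test_that("reproducibility at full sampling agrees with the reference", {
  g <- make_genome_pair(n_tads = 6, implant = c(2, 5), effect = 4,
                        bins_per_tad = 40, gap_bins = 6, seed = 5)
  collA <- simulate_cells(g$mu1, 30, 20000, seed = 6, chrom = "chrS",
                          resolution_bp = 50000)
  collB <- simulate_cells(g$mu2, 30, 20000, seed = 7, chrom = "chrS",
                          resolution_bp = 50000)
  curve <- reproducibility_curve(collA, collB, g$tads, k_grid = NA,
                                 n_repeats = 2, seed = 8)
  expect_equal(nrow(curve), 2)
  expect_true(all(curve$n_significant >= 1))  # implants are detectable
  expect_equal(curve$jaccard, c(1, 1))  # all cells: identical set
  expect_warning(
    reproducibility_curve(collA, collB, g$tads, k_grid = 40,
                          n_repeats = 1, seed = 9), "clipped")
})

test_that("cell-to-population flags planted high-variability TADs", {
  set.seed(10)
  g <- make_genome_pair(n_tads = 12, implant = integer(0),
                        bins_per_tad = 40, gap_bins = 8, sigma = 0.15,
                        seed = 10)
  bulk <- g$m1
  n_cells <- 8
  # three variability tiers by construction, matching the three classes
  # the clustering is asked to find
  high_tads <- c(3, 6, 9)
  mild_tads <- c(1, 5, 11)
  noise <- function(n, s) {
    E <- matrix(rnorm(n * n, 0, s), n, n)
    E[lower.tri(E)] <- t(E)[lower.tri(E)]
    exp(E)
  }
  res_bp <- 50000
  perturb <- function(mu, t, fold) {
    # per-cell random boundary-anchored sub-block perturbation inside the
    # TAD (anchored blocks carry the strongest eigenvalue signal)
    b0 <- g$tads$start[t] / res_bp
    off <- sample(c(0:3, 13:16), 1)
    idx <- (b0 + off + 1):(b0 + off + 24)
    mu[idx, idx] <- mu[idx, idx] * sample(c(1 / fold, fold), 1)
    mu
  }
  cell_maps <- lapply(seq_len(n_cells), function(cc) {
    mu <- g$mu1
    for (t in high_tads) mu <- perturb(mu, t, 8)
    for (t in mild_tads) mu <- perturb(mu, t, 1.3)
    contact_matrix(mu * noise(nrow(mu), 0.15), chrom = "chrS",
                   resolution_bp = res_bp)
  })
  vp <- cell_to_population(g$tads, cell_maps, bulk)
  expect_equal(length(vp$labels), length(vp$tads))
  expect_true(all(vp$labels %in% c("high", "median", "low")))
  got_high <- vp$tads[vp$labels == "high"]
  expect_gte(length(intersect(got_high, high_tads)) /
               length(high_tads), 0.8)
  # strongly perturbed TADs never pass as stable
  expect_false(any(vp$labels[match(high_tads, vp$tads)] == "low"))
})

test_that("cell-to-cell comparison and its baseline are consistent", {
  g <- make_genome_pair(n_tads = 6, implant = integer(0),
                        bins_per_tad = 40, gap_bins = 8, sigma = 0.15,
                        seed = 11)
  res_bp <- 50000
  mk_maps <- function(mu, n, seed) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
      E <- matrix(rnorm(nrow(mu)^2, 0, 0.15), nrow(mu), nrow(mu))
      E[lower.tri(E)] <- t(E)[lower.tri(E)]
      contact_matrix(mu * exp(E), chrom = "chrS",
                     resolution_bp = res_bp)
    })
  }
  # identical expected maps in both groups: nothing is reorganized ...
  mapsA <- mk_maps(g$mu1, 3, 12)
  same <- cell_to_cell(mapsA, mapsA, g$tads)
  expect_true(all(same$proportion < 0.2))
  # ... and one TAD perturbed in every B cell shows up in every pair
  mu_b <- g$mu1
  idx <- (g$tads$start[2] / res_bp + 9):(g$tads$start[2] / res_bp + 32)
  mu_b[idx, idx] <- mu_b[idx, idx] * 4
  mapsB <- mk_maps(mu_b, 3, 13)
  out <- cell_to_cell(mapsA, mapsB, g$tads, seed = 14)
  expect_equal(dim(out$proportion), c(3, 3))
  expect_true(all(out$counts[2, ] == 3))
  # baseline preserves each A cell's total number of significant calls
  expect_equal(colSums(out$baseline_counts), colSums(out$counts))
})
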