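test_that("log_difference obeys the log identities", {
  A <- random_contact_values(6, seed = 1)
  expect_equal(log_difference(A, A), matrix(0, 6, 6))
  expect_equal(log_difference(3 * A, A), matrix(log(3), 6, 6))
  # hand-evaluated 2x2 case
  A1 <- matrix(c(exp(2), exp(1), exp(1), exp(2)), 2, 2)
  A2 <- matrix(exp(1), 2, 2)
  expect_equal(log_difference(A1, A2), matrix(c(1, 0, 0, 1), 2, 2))
  expect_error(log_difference(matrix(1, 2, 2), matrix(1, 3, 3)),
               "identical dimensions")
})

test_that("zero entries are masked and median-filled by distance", {
  A1 <- random_contact_values(8, seed = 2)
  A2 <- random_contact_values(8, seed = 3)
  A2[2, 5] <- 0; A2[5, 2] <- 0  # log undefined there
  D_open <- log_difference(A1, A2, fill = FALSE)
  expect_true(is.na(D_open[2, 5]))
  D <- log_difference(A1, A2)
  peers <- D_open[cbind(1:5, 4:8)]
  expect_equal(D[2, 5], median(peers, na.rm = TRUE))
  expect_false(anyNA(D))
})

test_that("stratified standardization centres and scales each diagonal", {
  n <- 12
  D <- random_contact_values(n, seed = 4)
  nd <- stratified_standardize(D)
  Z <- nd$d_matrix
  expect_identical(Z, t(Z))
  for (k in 0:(n - 2)) {
    v <- Z[cbind(1:(n - k), (1 + k):n)]
    expect_lt(abs(mean(v)), 1e-10)
    expected_sd <- if (k == 0) sqrt(2) else 1  # GOE diagonal convention
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - expected_sd), 1e-10)
  }
  expect_equal(Z[1, n], 0)  # corner diagonals zeroed
  expect_equal(Z[n, 1], 0)
})

test_that("a hand-standardized diagonal comes out right", {
  # 4x4 with k = 1 diagonal {1, 2, 3}: population SD sqrt(2/3)
  D <- matrix(0, 4, 4)
  D[cbind(1:3, 2:4)] <- c(1, 2, 3)
  D <- D + t(D)
  D[cbind(1:2, 3:4)] <- c(2, 7); D[cbind(3:4, 1:2)] <- c(2, 7)
  diag(D) <- c(1, 4, 2, 3)
  Z <- stratified_standardize(D)$d_matrix
  expect_equal(Z[cbind(1:3, 2:4)],
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
})

test_that("standardization is shift and scale invariant per input", {
  D <- random_contact_values(10, seed = 5)
  base <- stratified_standardize(D)$d_matrix
  expect_equal(stratified_standardize(D + 3.7)$d_matrix, base)
  expect_equal(stratified_standardize(D * 0.25)$d_matrix, base)
  # idempotent (without the diagonal rescaling convention)
  Z <- stratified_standardize(D, goe_diag = FALSE)$d_matrix
  expect_equal(stratified_standardize(Z, goe_diag = FALSE)$d_matrix, Z,
               tolerance = 1e-10)
})

test_that("degenerate standardization inputs are handled", {
  expect_error(stratified_standardize(matrix(1, 2, 2)),
               class = "tadshift_degenerate_error")
  # constant diagonals are zeroed, not dropped
  Z <- stratified_standardize(matrix(5, 6, 6))$d_matrix
  expect_equal(Z, matrix(0, 6, 6))
})

test_that("largest eigenvalue and theta behave on known matrices", {
  expect_equal(largest_eigenvalue(matrix(0, 9, 9)), 0)
  expect_equal(largest_eigenvalue(sqrt(16) * diag(16)), 1)
  expect_equal(theta_statistic(2, 555), 0)
  expect_equal(theta_statistic(2.1, 1000), 10)
  expect_equal(theta_statistic(1, 8), -4)
})

test_that("the test is invariant to read depth and log base", {
  set.seed(6)
  for (r in 1:20) {
    p <- simulate_pair(simulation_spec(n_bins = 20))
    t0 <- test_tad(p$A1, p$A2)
    t_up <- test_tad(p$A1 * 1000, p$A2)
    t_dn <- test_tad(p$A1, p$A2 * 1000)
    expect_lt(abs(t0$theta - t_up$theta), 1e-10)
    expect_lt(abs(t0$theta - t_dn$theta), 1e-10)
    # log base: log2 difference is a uniform rescale of the natural-log one
    D2 <- (log2(p$A1) - log2(p$A2))
    Dn <- log_difference(p$A1, p$A2)
    expect_equal(stratified_standardize(D2)$d_matrix,
                 stratified_standardize(Dn)$d_matrix, tolerance = 1e-10)
  }
})

test_that("identical matrices give a null verdict, small TADs are skipped", {
  A <- random_contact_values(16, seed = 7)
  tt <- test_tad(A, A)
  expect_equal(tt$lambda_n, 0)
  expect_equal(tt$theta, -2 * 16^(2 / 3))
  expect_gt(tt$pvalue, 1 - 1e-6)
  expect_equal(tt$status, "tested")

  small <- random_contact_values(8, seed = 8)
  ts <- test_tad(small, small)
  expect_equal(ts$status, "skipped_too_small")
  expect_true(is.na(ts$pvalue))
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  set.seed(9)
  p <- runif(50)
  q <- adjust_pvalues(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # skipped TADs excluded from the number of comparisons
  expect_equal(adjust_pvalues(c(0.05, NA)), c(0.05, NA))
  expect_error(adjust_pvalues(c(0.5, 1.7)), "0, 1")
})

test_that("genome-wide run recovers implanted reorganizations", {
  g <- make_genome_pair(n_tads = 20, implant = c(2, 5, 9, 14, 17),
                        effect = 3, seed = 10)
  res <- run_genomewide(g$m1, g$m2, g$tads)
  expect_equal(nrow(res), 20)
  expect_true(all(res$status == "tested"))
  expect_true(all(res$qvalue >= res$pvalue, na.rm = TRUE))
  called <- which(res$significant)
  expect_gte(jaccard_index(called, which(g$truth)), 0.8)
})

test_that("results are written deterministically", {
  g <- make_genome_pair(n_tads = 6, implant = 2, seed = 11)
  res <- run_genomewide(g$m1, g$m2, g$tads)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_results(res, f1)
  write_results(run_genomewide(g$m1, g$m2, g$tads), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_match(readLines(f1)[1],
               "chrom\tstart\tend\tn_bins\tlambda_n\ttheta\tpvalue")
})
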