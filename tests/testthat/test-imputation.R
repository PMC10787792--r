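# brute-force reference: every diagonal-anchored all-missing square
brute_sv_blocks <- function(A, min_side) {
  n <- nrow(A)
  hits <- list()
  for (i in seq_len(n)) for (m in min_side:n) {
    if (i + m - 1 > n) next
    if (all(is.na(A[i:(i + m - 1), i:(i + m - 1)]))) {
      hits[[length(hits) + 1]] <- c(i, i + m - 1)
    }
  }
  hits
}

test_that("find_sv_blocks reports maximal all-missing diagonal squares", {
  A <- random_contact_values(20, seed = 2)
  A[5:8, 5:8] <- NA
  b <- find_sv_blocks(A)
  expect_equal(nrow(b), 1)
  expect_equal(b$start_bin, 5)
  expect_equal(b$side, 4)

  expect_equal(nrow(find_sv_blocks(random_contact_values(10, seed = 3))),
               0)
})

test_that("block detection agrees with a brute-force scan", {
  A <- random_contact_values(20, seed = 4)
  A[2:4, 2:4] <- NA      # side 3: reported
  A[10:12, 10:12] <- NA  # side 3: reported
  A[16:17, 16:17] <- NA  # side 2: below the default minimum
  b <- find_sv_blocks(A)
  expect_equal(b$start_bin, c(2, 10))
  expect_equal(b$side, c(3, 3))
  # every reported block is indeed all-missing and maximal per brute force
  ref <- brute_sv_blocks(A, 3)
  ref_max <- Filter(function(h) {
    !any(vapply(ref, function(g) {
      g[1] <= h[1] && g[2] >= h[2] && (g[2] - g[1]) > (h[2] - h[1])
    }, logical(1)))
  }, ref)
  expect_equal(lapply(seq_len(nrow(b)),
                      function(i) c(b$start_bin[i], b$end_bin[i])),
               ref_max)
})

test_that("SV blocks are filled with the configured constant", {
  A1 <- random_contact_values(20, seed = 5)
  A2 <- random_contact_values(20, seed = 6)
  A2[8:11, 8:11] <- NA
  out <- impute_pair(A1, A2)
  expect_equal(out$A2[8:11, 8:11], matrix(1, 4, 4))
  expect_equal(out$kept_bins, 1:20)
  out2 <- impute_pair(A1, A2,
                      imputation_config(sv_fill = 7, sv_mode = TRUE))
  expect_equal(out2$A2[8:11, 8:11], matrix(7, 4, 4))
  # sv_mode off: the block is dissolved by row removal / median fill
  out3 <- impute_pair(A1, A2, imputation_config(sv_mode = FALSE))
  expect_false(anyNA(out3$A2))
})

test_that("complete matrices pass through unchanged (idempotence)", {
  A1 <- random_contact_values(12, seed = 7)
  A2 <- random_contact_values(12, seed = 8)
  out <- impute_pair(A1, A2)
  expect_identical(out$A1, A1)
  expect_identical(out$A2, A2)
  expect_equal(out$kept_bins, 1:12)

  A2[3, 7] <- NA; A2[7, 3] <- NA
  once <- impute_pair(A1, A2)
  twice <- impute_pair(once$A1, once$A2)
  expect_identical(twice$A1, once$A1)
  expect_identical(twice$A2, once$A2)
})

test_that("isolated missing entries get the same-distance median", {
  A1 <- random_contact_values(8, seed = 9)
  A2 <- matrix(0, 8, 8)
  # distance-2 entries of A2: set known values, one of them missing
  A2[cbind(1:6, 3:8)] <- c(1, 3, 5, 1, 3, 5)
  A2 <- A2 + t(A2)
  diag(A2) <- 2
  A2[cbind(1:7, 2:8)] <- 4; A2[cbind(2:8, 1:7)] <- 4
  A2[cbind(1:5, 4:8)] <- 6; A2[cbind(4:8, 1:5)] <- 6
  A2[1, 3] <- NA; A2[3, 1] <- NA  # peers at distance 2: {3,5,1,3,5}
  out <- impute_pair(A1, A2, imputation_config(sv_mode = FALSE))
  expect_equal(out$A2[1, 3], 3)  # median by enumeration
  expect_equal(out$A2[3, 1], 3)
})

test_that("rows are removed when either matrix exceeds the threshold", {
  n <- 20
  A1 <- random_contact_values(n, seed = 10)
  A2 <- random_contact_values(n, seed = 11)
  A2[4, ] <- NA; A2[, 4] <- NA   # fully missing row in A2 only
  out <- impute_pair(A1, A2)
  expect_equal(out$kept_bins, setdiff(1:n, 4))
  expect_equal(dim(out$A1), c(n - 1, n - 1))
  expect_false(anyNA(out$A1))
  expect_false(anyNA(out$A2))
  expect_identical(out$A2, t(out$A2))
})

test_that("row retention boundary sits exactly at the threshold", {
  n <- 20
  # sweep the missing fraction of row 1; strictly-greater removal rule
  for (frac in seq(0.05, 0.95, by = 0.10)) {
    A1 <- random_contact_values(n, seed = 12)
    A2 <- random_contact_values(n, seed = 13)
    k <- round(frac * (n - 1))  # row 1 has n-1 countable entries
    if (k >= 1) {
      cols <- 1 + seq_len(k)    # skip the corner [1, n] when k < n-1
      A2[1, cols] <- NA; A2[cols, 1] <- NA
    }
    out <- impute_pair(A1, A2)
    retained <- 1 %in% out$kept_bins
    expect_equal(retained, k / (n - 1) <= 0.5,
                 info = sprintf("frac = %.2f", frac))
  }
})

test_that("degenerate inputs raise a typed error", {
  A <- matrix(NA_real_, 6, 6)
  expect_error(impute_pair(A, A, imputation_config(sv_mode = FALSE)),
               class = "tadshift_degenerate_error")
  expect_error(impute_pair(matrix(1, 3, 3), matrix(1, 4, 4)),
               "identical dimensions")
})
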