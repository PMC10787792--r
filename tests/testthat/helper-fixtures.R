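# shared fixture builders; everything is generated in code, nothing stored

# random symmetric positive matrix, optionally with a symmetric NA pattern
random_contact_values <- function(n, na_frac = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rlnorm(n * n, 0, 0.5), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  if (na_frac > 0) {
    idx <- which(upper.tri(m, diag = TRUE))
    drop <- sample(idx, round(na_frac * length(idx)))
    m[drop] <- NA
    m <- ifelse(is.na(m) | is.na(t(m)), NA, m)
  }
  m
}

# genome-wide pair of contact matrices with TAD blocks; implanted TADs get
# their inner core (central 60%) multiplied by `effect` in condition 2, so
# a strength change creates within-TAD contrast rather than a uniform
# (and hence normalization-invisible) rescaling. TADs default to 40 bins:
# block-contrast changes are statistically invisible to the eigenvalue
# test below roughly 28 bins, so recovery fixtures use amply sized TADs.
make_genome_pair <- function(n_tads = 10, implant = integer(0),
                             effect = 3, bins_per_tad = 40, gap_bins = 10,
                             sigma = 0.2, resolution_bp = 50000,
                             base = 10, decay = 1, enrichment = 2,
                             seed = NULL, chrom = "chrS") {
  if (!is.null(seed)) set.seed(seed)
  n <- n_tads * (bins_per_tad + gap_bins)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- base * (d + 1)^(-decay)
  starts <- (seq_len(n_tads) - 1) * (bins_per_tad + gap_bins) + gap_bins / 2
  mu2 <- mu
  for (t in seq_len(n_tads)) {
    idx <- (starts[t] + 1):(starts[t] + bins_per_tad)
    mu[idx, idx] <- mu[idx, idx] * enrichment
    mu2[idx, idx] <- mu2[idx, idx] * enrichment
    if (t %in% implant) {
      pad <- floor(0.2 * bins_per_tad)
      core <- idx[(pad + 1):(bins_per_tad - pad)]
      mu2[core, core] <- mu2[core, core] * effect
    }
  }
  noise <- function(sig) {
    E <- matrix(rnorm(n * n, 0, sig), n, n)
    E[lower.tri(E)] <- t(E)[lower.tri(E)]
    exp(E)
  }
  tads <- tad_set(chrom = rep(chrom, n_tads),
                  start = starts * resolution_bp,
                  end = (starts + bins_per_tad) * resolution_bp)
  list(m1 = contact_matrix(mu * noise(sigma), chrom = chrom,
                           resolution_bp = resolution_bp),
       m2 = contact_matrix(mu2 * noise(sigma), chrom = chrom,
                           resolution_bp = resolution_bp),
       mu1 = mu, mu2 = mu2, tads = tads,
       truth = seq_len(n_tads) %in% implant)
}
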