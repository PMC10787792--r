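---
title: "Detecting reorganized TADs with a Tracy-Widom eigenvalue test"
author: "tadshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting reorganized TADs with a Tracy-Widom eigenvalue test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadshift)
```

## The problem

Topologically associating domains (TADs) are the megabase-scale blocks of
enriched self-contact that tile mammalian Hi-C maps. Between two
biological conditions — cell types, disease states, perturbations — a TAD
can keep its boundaries yet change its internal contact structure, or it
can dissolve, split, merge, or shift. Boundary-based comparisons miss the
first kind entirely, and ad-hoc similarity scores lack a calibrated null
distribution. `tadshift` tests each TAD called in condition 1 for
structural reorganization in condition 2 and attaches a P value with a
known asymptotic null law.

## The model

For a TAD spanning $N$ bins, let $A_1$ and $A_2$ be the $N \times N$
balanced (e.g. KR-normalized) contact submatrices from the two
conditions. The pipeline computes

$$D = \log A_1 - \log A_2,$$

then standardizes each off-diagonal stratum: for $k = 0, \dots, N-2$,
the entries at genomic distance $k$ bins are centred by their sample
mean $\hat\mu_k$ and scaled by their sample standard deviation
$\hat\sigma_k$. The log transform turns the roughly multiplicative
distance decay of Hi-C signal into an additive offset per stratum, and
the per-stratum standardization removes it along with any global
read-depth ratio between the two experiments — multiplying either input
matrix by a constant provably leaves the statistic unchanged, and the
test suite checks this to $10^{-10}$.

Under the null hypothesis that the TAD is not reorganized, the
standardized $D$ has exchangeable, approximately standard-Gaussian
entries, so $D/\sqrt{N}$ behaves like a generalized Wigner matrix. Its
largest eigenvalue $\lambda_N$ concentrates at 2, and

$$\theta_N = N^{2/3}(\lambda_N - 2)$$

converges in distribution to the Tracy-Widom law for the orthogonal
class, $TW_1$. A one-sided P value $P(TW_1 \ge \theta_N)$ is therefore
large when $D$ looks like white noise and small when any coherent
structure — a gained loop, a shifted boundary, a strength change —
inflates the top eigenvalue. Across a TAD list, P values are adjusted by
Benjamini-Hochberg (the default; Holm and Bonferroni are available) and
significance is declared at $\alpha = 0.05$.

```{r example, eval = FALSE}
spec <- simulation_spec(reorganization = list(type = "strength",
                                              multiplier = 2), seed = 1)
pair <- simulate_pair(spec)
test_tad(pair$A1, pair$A2)
```

## Numerical choices

**Tracy-Widom evaluation.** No installed R package provides $TW_1$, so
the package ships a plain-text table of its CDF on $[-10, 6]$ at step
0.01, evaluated with monotone cubic interpolation (absolute accuracy
better than $10^{-4}$, ample for decisions at $\alpha = 0.05$). The
table is generated by `tools/make_tw1_table.R`, which integrates the
Hastings-McLeod solution of the Painlevé II equation
$q'' = sq + 2q^3$ downward from the Airy initial condition and assembles
$F_1(s) = \exp(-\tfrac12\int_s^\infty q)\,F_2(s)^{1/2}$. Downward
integration loses the separatrix near $s \approx -7.7$, where
$F_1 \sim 10^{-13}$; below $-7.4$ the table uses the left-tail
asymptotic $\log F_1 \sim -|s|^3/24$ anchored continuously. Beyond the
grid, `tw1_cdf` uses the standard tail asymptotics
($\log(1 - F_1) \sim -\tfrac23 x^{3/2}$ on the right). The generated
table reproduces the literature mean $-1.2065336$ and variance
$1.6077810$ of $TW_1$ to six digits, and the test suite cross-checks
fixed quantiles against an independent Painlevé integration.

**Standard deviation divisor.** $\hat\sigma_k$ uses the population
($1/n$) divisor, so every standardized stratum has exactly unit
variance, matching the null model in which entries are standard
Gaussian. With the $1/(n-1)$ divisor the short strata near the matrix
corner are shrunk by $\sqrt{(n-1)/n}$ — down to $1/\sqrt2$ for the
two-entry stratum — which at TAD sizes ($N \approx 10$–$40$)
measurably thickens the left side of the null $\theta_N$ distribution
and further depresses the rejection rate.

**Main diagonal.** After standardization the main diagonal is rescaled
to variance 2 (`goe_diag = TRUE`), the Gaussian Orthogonal Ensemble
convention. The asymptotic law is insensitive to the diagonal's
variance, but the finite-$N$ agreement with $TW_1$ is markedly better
under the GOE convention: in our simulations the Kolmogorov-Smirnov
distance between $\theta_N$ at $N = 200$ and $TW_1$ drops from about
0.07 (unit-variance diagonal) to about 0.015. `simulate_wigner` uses
the same convention (off-diagonal variance 1, diagonal variance 2).

**Corner and degenerate strata.** The single-entry corner diagonals
($|k| = N-1$) are outside the standardized range and set to 0.
Constant strata ($\hat\sigma_k = 0$) are set to 0 rather than dropped,
keeping the matrix square. TADs below `min_bins = 10` bins are skipped:
the $TW_1$ approximation is trusted from roughly $N = 10$ upward, and
at common resolutions 10 bins is well below the median TAD size.

**Zeros.** Balanced matrices contain structural and sampling zeros whose
log-ratio is undefined. Zeros are kept as zeros by the readers; at
testing time an entry that is zero or missing in either matrix is masked
and filled with the median of the observed log-ratio values at the same
distance. A pseudocount is deliberately not used: it would inject a
distance-dependent bias into exactly the strata the test standardizes.

## Missing-value imputation

Three stages run jointly on the matrix pair before testing, in this
order:

1. **SV blocks** (`sv_mode`, default on): a maximal all-missing square
   block of side at least 3 anchored on the diagonal — the footprint of
   a deletion or duplication — is filled with the constant 1 (so its
   log-ratio is driven by the other condition).
2. **Sparse bins**: a bin whose row is more than 50% missing in either
   matrix is removed from both, keeping the pair aligned. Removal uses
   a strict inequality, and the proportion is computed over the row's
   non-corner entries including the diagonal.
3. **Distance medians**: every remaining missing entry is filled with
   the median of the observed entries at the same distance in the same
   matrix; a distance with no observed entries falls back to the global
   median (logged).

The procedure is idempotent, preserves symmetry, and never leaves
missing values; a pair whose bins are all removed raises a typed
degenerate-input error and the TAD is reported as skipped, not dropped.

## Subtype classification

Significant TADs are classified from interval relations between the two
conditions' full TAD lists. Two TADs are *identical* when both
boundaries agree within one bin (boundary calls jitter; the tolerance is
configurable) and *overlapping* when they intersect without being
identical. Labels are assigned most-specific-first: **loss** (no
partner), **strength-change** (one-to-one identical), **merge** (the TAD
and an adjacent or overlapping condition-1 sibling share a single
condition-2 partner — checked before split because merge requires
sibling evidence that split lacks), **split** (at least two partners,
all contained in the TAD within tolerance), **zoom** (a single
non-identical partner mapping one-to-one back), and **complex**
(anything else, e.g. partners straddling the TAD's boundaries).
Requiring containment for split and reverse-uniqueness for zoom is what
keeps the complex class non-empty; without these refinements every
multi-partner configuration would be absorbed by split.

Strength-change TADs are further split by
$(m_1/m_2)\,(s_2/s_1) \ge 1 \Rightarrow$ *up*, else *down*, where $m_c$
is the median balanced contact within the TAD in condition $c$ and $s_c$
the total over all TADs of that condition (a depth normalization). The
formula is implemented exactly as stated; note that its polarity ties
"up" to the condition-1 side once depth is normalized away, so users
comparing conditions in the opposite orientation should swap inputs
rather than relabel.

## Single-cell Hi-C

Pseudo-bulk maps are raw count sums over sampled cells (sums, not
means — the test's scale invariance makes the choice immaterial).
`reproducibility_curve` resamples `k` cells per condition, reruns the
genome-wide test, and reports the Jaccard agreement of each significant
set with the all-cell reference. `cell_to_population` tests every
(TAD, cell) pair against the pseudo-bulk, then clusters the rows of the
$-\log_{10} P$ matrix (capped at 16, Ward linkage, Euclidean distance,
three classes per the analysis design) and labels the classes high /
median / low variability by ascending mean P. `cell_to_cell` runs all
cross pairs between two cell groups with per-pair BH adjustment and
builds a permutation baseline that redistributes each pair's significant
calls uniformly over the tested TADs, preserving per-pair totals while
destroying TAD identity.

Dedicated single-cell imputation methods are out of scope;
`impute_cell_map` provides a deliberately simple library-size +
Gaussian-smoothing imputer so the analyses are testable end to end, and
any externally imputed dense per-cell maps can be supplied instead.

## What the generators emulate — and what they do not

`simulate_pair` draws $A_c = \mu_c \times$ symmetric lognormal noise,
with $\mu$ a power-law decay surface $(|i-j|+1)^{-\alpha}$,
$\alpha = 1$, carrying 2-fold TAD-block enrichment, noise
$\sigma = 0.2$ on the log scale, and $N = 40$ windows by default. Under
the null the standardized log-difference then has exactly i.i.d.
Gaussian entries — the cleanest possible realization of the model
assumptions — so simulation-based calibration results are about the
$TW_1$ approximation itself, not about model misfit. Real Hi-C data
differ in ways the generator deliberately omits: positive correlation
between nearby matrix entries (which inflates $\lambda_N$), balancing
artifacts, trans contacts, and ligation noise. Passing calibration
tests on synthetic data therefore bounds the method's behaviour under
its own assumptions and does not certify real-data error rates.

The default reorganization geometry places the TAD block on the central
60% of the simulated window. This is a substantive choice: a multiplier
applied to the whole tested matrix is *removed* by the per-stratum
standardization (that invariance is the point — uniform rescaling is
indistinguishable from a read-depth change), so a detectable strength
change must create contrast within the window. Two empirical properties
of the statistic are worth knowing when designing studies or fixtures:
block-contrast changes are essentially undetectable below roughly 28
bins (the whitening caps the structured signal and the $N^{2/3}$
scaling is small), and boundary-anchored sub-blocks carry a
substantially stronger eigenvalue signal than centred ones of the same
size and fold.

## Calibration, honestly

The suite measures the empirical type-I error of the full pipeline on
2,000 exact-null pairs at $N = 40$ and the agreement of simulated
Wigner $\theta_N$ with $TW_1$. At $N = 40$ the test is conservative:
the measured rejection rate at $\alpha = 0.05$ is about 0.02, not
0.05. Two effects combine: finite-$N$ left bias of the raw
Tracy-Widom approximation (even a true GOE draw at $N = 40$ rejects at
only about 0.035), and the per-stratum mean/SD constraints, which
remove exactly the fluctuation modes that drive upward excursions of
$\lambda_N$. The value is pivotal — independent of noise level, decay,
and depth — so no study-condition choice moves it. The practical
consequence is a valid but conservative test at small $N$; FDR control
over the significant set is unaffected.

## Problem sizes

The shipped test suite and acceptance script use: 2,000 null pairs at
$N = 40$; 500 Wigner draws at $N = 500$ and 2,000 at $N = 200$; 500
power replicates at $N = 40$; genome fixtures of 10-20 TADs of 40 bins;
and single-cell collections of 150 cells at 20,000 contacts per cell
over a 600-bin window with reproducibility grids
$k \in \{25, 50, 100, \text{all}\}$ — sizes at which every simulated
quantity is stable enough for its stated tolerance while the whole
suite completes in a few minutes.

## Known limitations

- Conservative at small $N$ (above); TADs under 10 bins are not tested
  at all.
- TAD hierarchies are classified from interval relations only; nested
  dependency between a TAD and its sub-TADs is not modelled.
- Binary cooler/hic containers are not read; export regions as dense or
  triplet text first.
- The cell-to-population classes are exactly three by design; data with
  a continuum of variability will be discretized accordingly.
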