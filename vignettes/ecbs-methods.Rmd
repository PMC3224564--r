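---
title: "Model-based circular binary segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based circular binary segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecbs)
```

## The problem

Array comparative genomic hybridization (aCGH) measures DNA copy number as
log2 ratios of test versus reference signal at ordered genomic probes.
Regions of copy-number gain or loss appear as shifts in the mean log2 ratio,
and segmentation — partitioning each chromosome into regions of constant
mean — is the step that turns probe-level noise into discrete copy-number
calls.

Circular binary segmentation (CBS) detects change-points recursively.  For a
series $r_1, \dots, r_N$ the two ends are joined into a circle, and every
arc is compared with its complement by the two-sample t-like statistic

$$
T_{ij} = \frac{S_{ij}/k \;-\; (S_N - S_{ij})/(N-k)}
              {s\,\sqrt{1/k + 1/(N-k)}},
\qquad S_{ij} = \sum_{l=i+1}^{j} r_l,\quad k = j - i,
$$

with $s$ the sample standard deviation of the whole series.  The maximal
statistic $T_{\max} = \max_{i<j} |T_{ij}|$ and its arg-max $(i_c, j_c)$ are
the candidate change-points; if $T_{\max}$ is significant, the series is cut
at the surviving boundaries (a ternary split in general) and the procedure
recurses on each piece.

The expensive part of classical CBS is deciding significance: the null
distribution of $T_{\max}$ is approximated by permuting the series and
re-scanning, thousands of times, at every recursion node.  This package
replaces that with a **precomputed extreme-value model**: the null
distribution of $T_{\max}$ is simulated once, offline, over a grid of series
lengths and noise shapes, fitted by the generalized extreme value (GEV)
distribution, and stored as lookup tables.  At segmentation time a p-value
costs one table lookup, $1 - F_{\mathrm{GEV}}(T_{\max})$, in constant time.
Permutation is kept for short segments and as an internal validation oracle.

## The null model

### Pearson-system noise

Real array noise is frequently non-normal — skewed, heavy-tailed, or both —
and the null distribution of $T_{\max}$ is sensitive to tail weight.  Null
series are therefore simulated from the Pearson distribution system, the
family of densities solving

$$
\frac{p'(x)}{p(x)} = \frac{x - a}{b_2 x^2 + b_1 x + b_0},
$$

which can match any feasible (mean, variance, skewness, kurtosis)
quadruple.  With mean 0 and variance $\theta_2$, skewness $\beta_1$ and
(non-excess) kurtosis $\beta_2$, the coefficients are

$$
b_0 = -\tfrac{\theta_2(4\beta_2 - 3\beta_1^2)}{A},\quad
b_1 = a = -\tfrac{\sqrt{\theta_2}\,\beta_1(\beta_2+3)}{A},\quad
b_2 = -\tfrac{2\beta_2 - 3\beta_1^2 - 6}{A},
$$

with $A = 10\beta_2 - 12\beta_1^2 - 18$.  `rpearson()` classifies the type
from the denominator quadratic and samples each type exactly:

* **types I/II** (real roots straddling 0): a four-parameter Beta;
* **type III** ($b_2 = 0$): a standardized Gamma;
* **type VII** (symmetric, heavy tails): a rescaled Student $t$;
* **type VI** (real roots of one sign): a shifted Beta-prime (Gamma ratio);
* **type IV** (complex roots): see below;
* **type V** (double root): a measure-zero boundary curve, handled by an
  infinitesimal kurtosis perturbation ($10^{-7}$).

Two numerical points are worth recording.  First, the classification and
sampling work with the *unnormalized* coefficients $(A b_0, A b_1, A b_2)$:
the normalized triple degenerates where $A = 0$ (which happens inside the
simulation grid, at skewness $\pm 1$, kurtosis $3.0$) while the distribution
itself is perfectly regular there.  `pearson_coeffs()` reports the
degeneracy as an error, as a coefficient query must, but sampling covers the
whole grid.  Second, the type IV density has no standard-library sampler.
Substituting $\phi = \arctan((x-\lambda)/\alpha)$ maps it to
$g(\phi) \propto \cos^{2m-2}(\phi)\, e^{-\nu\phi}$ on the compact interval
$(-\pi/2, \pi/2)$, whose log is strictly concave.  We sample it by rejection
from the piecewise-exponential upper hull formed by tangents at 31 fixed
knots (valid globally by concavity), then apply $x = \lambda + \alpha
\tan\phi$.  The sampler is exact — no truncation or discretization — and
its acceptance rate is high because the hull is tight; the unit tests
verify third and fourth sample moments against their targets in every type
branch, within Monte-Carlo error.

### GEV fitting of the maximal-t null

For each grid cell $(N, sk, ku)$, `build_model()` simulates `replicates`
null series, computes $|T_{\max}|$ for each by exhaustive scan, and fits the
three-parameter GEV distribution

$$
F(t) = \exp\!\left\{-\left[1 + \gamma\,\tfrac{t-\mu}{\sigma}\right]^{-1/\gamma}\right\}
$$

by maximum likelihood.  $T_{ij}$ over the $(i,j)$ plane is a dependent
random field rather than an i.i.d. sequence, so the classical extreme-value
limit does not apply verbatim; the GEV family is used as a flexible
three-parameter model for the maximum, and its adequacy is checked
empirically — the acceptance suite requires the Kolmogorov–Smirnov distance
between $10^4$ simulated $|T_{\max}|$ values at $N = 250$ and the fitted CDF
to be below 0.02 (observed: about 0.004).

The fit starts from probability-weighted-moment estimates (Hosking's
estimators, with the sign convention $\gamma = -k$), refines by Nelder–Mead
on $(\gamma, \log\sigma, \mu)$, and treats support violations with a
log-likelihood barrier rather than clipping, so the optimum stays interior.
Up to five jittered restarts are attempted on non-convergence; a cell that
still fails is flagged and fails the build unless `allow_flagged = TRUE`.
Shapes with $|\gamma| < 10^{-6}$ are evaluated on the Gumbel branch to avoid
catastrophic cancellation; the CDF is continuous in $\gamma$ at 0 to within
$10^{-6}$ by test.

### The lookup tables

The reference grid (`full_grid()`) spans $N$ from 10 to 10,000 (steps of 10
up to 100, 100 up to 1,000, 1,000 up to 10,000), skewness $-1$ to $1$ in
steps of 0.1, and kurtosis 2.6 to 5.6 in steps of 0.2 — 9,408 cells, a
batch job best run once and saved with `save_model()`.  `desk_grid()` is a
coarsened preset for workstation builds covering the regimes exercised by
the validation simulations.  Queries between grid points are answered by
trilinear interpolation from the eight surrounding cells, each parameter
independently; the interpolation is linear in $N$ itself (the grid is
already refined at small $N$, where curvature is largest).  Queries outside
the axes are clamped to the boundary with a warning — the model deliberately
does not extrapolate.  Interpolated values are convex combinations, hence
bounded by their neighboring cells, and on-grid queries return stored values
bit-exactly; both properties are tested.

Interpolation presumes the tables vary smoothly.  The test suite checks
this on the built model: the relative jump of $\sigma$ and $\mu$ between
adjacent cells must stay below 25%.  The shape $\gamma$ is excluded from
the *relative* gate because its magnitude is near zero, where a ratio is
not meaningful at desk replicate counts; its sampling noise is already
controlled by the parameter-recovery and KS checks.

## Significance evaluation and the permutation fallback

`evaluate_significance()` routes a segment of $n$ probes to the table
lookup when $n \ge$ `gev_min_probes` (default 100, boundary inclusive) and
to permutation below that.  The short-segment fallback is a plain
permutation test with early stopping: the series values are shuffled
uniformly, $|T_{\max}|$ is recomputed per shuffle, and the add-one estimator
$(1 + \#\text{exceedances})/(1 + \#\text{permutations})$ is returned.  With
early stopping, permutation halts as soon as the exceedance count alone
guarantees the final p-value would exceed `alpha` — the rule
$e > \alpha(1+n_{\mathrm{perm}}) - 1$ — so stopping can never flip a
decision at level `alpha`; the returned estimate is conservative.  This
fallback is intentionally exact rather than fast: at small $n$ permutation
is cheap anyway.

A subtlety worth making explicit: a permutation test is *conditional* on
the observed values — its null distribution shifts with the sample's
empirical shape (at $N = 250$, sample kurtosis scatters with standard error
$\approx 0.3$ between series).  The lookup test tracks this by design: it
is indexed by the skewness and kurtosis estimated from the data whose
permutation test it replaces.  With that indexing, table p-values and
$10^3$-permutation p-values on common null series agree to Spearman
$\rho \approx 0.997$ and mean $|\Delta p| \approx 0.013$ on
$p \in [0.001, 0.2]$; indexing at the fixed population moments instead
leaves an irreducible $\rho \approx 0.985$, a floor shared by the exact
unconditional null CDF itself.

The test level defaults to $\alpha = 0.01$, a conventional choice for
CBS-style segmentation; it is configuration-exposed, as are the permutation
budget and the 100-probe routing threshold.

## Noise-moment estimation (pre-segmentation)

The tables are indexed by the *noise* skewness and kurtosis, but tumor
arrays always contain copy-number alterations, whose mean shifts bias raw
moment estimates (a 300-probe, $+3\sigma$ amplification in a 2,000-probe
arm moves naive skewness to about 0.77 and kurtosis to about 3.5).
`estimate_noise_moments()` therefore:

1. runs a coarse, permutation-free segmentation of each chromosome:
   recursive maximal-t splits accepted against a fixed conservative
   threshold (a Bonferroni bound over the $\sim N^2/2$ arcs at family-wise
   level `preseg_alpha` = 0.001 under a normal reference), with no edge
   correction and a 100-probe recursion floor;
2. discards segments shorter than `small_segment` (default 15 probes — the
   width scale of the aberrations in the power simulations);
3. subtracts each remaining segment's mean;
4. pools the residuals across chromosomes and computes moment-based
   skewness and kurtosis, clamped to the grid ranges.

The threshold-based pre-segmentation is this package's concrete realization
of a "quick, lower-resolution, permutation-free" pre-pass; it is
deliberately conservative — it only needs to remove shifts large enough to
distort fourth moments, and a missed borderline segment matters far less
here than a spurious cut.  Arrays with fewer than 200 probes total, or
arrays where discarding leaves (nearly) nothing, fall back to direct
moments of median-centered values, with a warning.  Note the segmentation
statistic itself is always computed from the original data; only the moment
estimation looks at residuals.

## The segmentation engine

`find_change_points()` recurses on one chromosome: scan, test, edge-correct,
split into up to three subsegments, repeat.  Design choices:

* **Index convention.** Pairs $(i, j)$ with $0 \le i < j \le N$ denote the
  half-open arc $(i, j]$; $i = 0$ is allowed so a single change-point is
  representable as $(0, j)$ or $(i, N)$.  Over this index set every split
  of the circle into two arcs appears (which is why $|T_{\max}|$ is
  invariant under circular shifts — a tested property).
* **Exhaustive scan.** The $O(N^2)$ scan is exact, implemented in C with
  per-width constants hoisted (about $3\times10^8$ candidate arcs per
  second); the method's speed comes from significance evaluation, not from
  approximating the arg-max.  Ties in $|T|$ break toward the
  lexicographically smallest $(i, j)$ for cross-platform determinism.
* **Minimum arc width** of 2 probes per side, so both arcs contribute
  variance.
* **Re-standardization.** Each recursion node recomputes $s$ within its
  own segment, matching the recursive semantics of CBS.
* **Edge correction.** Circular joining can propose a boundary between
  equal-mean regions.  Each proposed cut is re-tested by a Welch t-test on
  the `edge_window` = 25 probes on either side (capped at the adjacent
  proposed subsegment lengths) at `edge_alpha` = 0.01; failing cuts are
  dropped, and if all fail the split is rejected.  Zero-variance windows
  (noise-free data) are decided by exact mean comparison, where a t
  statistic is undefined.
* **Terminal segments.** A segment whose test is not significant, whose
  split was vetoed, that is shorter than $2\times$`min_width`, or that has
  zero variance is emitted as a leaf.  Each emitted segment carries the
  p-value of the split that created its boundaries; a chromosome that was
  never split reports `NA`.
* **Kurtosis convention** is non-excess throughout (normal = 3), matching
  the grid.
* Chromosomes are segmented independently; genomic positions affect only
  reporting, never the statistic.

## Validation simulations

`sim_model1()` builds a 150-probe chromosome with change-points at probes
50, 70, 80, 100 and segment means $(0, cv, -cv, cv, 0)$ under normal noise
of standard deviation $v$; $c \in \{2, 3, 4\}$ are the reference
amplitudes.  `sim_model2()` builds a 1,500-probe chromosome with a single
$k$-probe aberration of height $cv$ after position $l$ ($l = 0$: edge
aberration, the ROC design; $l = (N-k)/2$: two change-points in the
center), with Pearson-system noise of selectable skewness and kurtosis.
Defaults: $v = 0.2$, a typical post-normalization aCGH noise level; since
the statistic is scale invariant, only $c$ (the signal-to-noise ratio)
matters for detection.  Because amplitudes are parameterized as $c\,v$, a
literal "noise-free limit" $v = 0$ also zeroes the signal; tests that need
the deterministic profile isolate it by differencing two same-seed
simulations ($c$ vs $c = 0$).

`roc_study()` compares the table-lookup path against the permutation path
on identical seeded data: per replicate, one aberration-bearing and one
null series, each scanned once and assigned one p-value per method.  The
protocol evaluates the chromosome-level maximal-t test (the first split),
which is the decision that detects the single embedded aberration; a
replicate counts as detectable only when the scanned boundaries match the
true cut points within ±2 probes.  Sweeping the level $\alpha$ gives the
sensitivity/specificity table; the area under the curve is computed by the
rank (Mann–Whitney) construction on the paired p-values, equivalent to
sweeping $\alpha$ over $[0, 1]$ without discretizing a grid.  Detection
counts as successful only if *all* true cut points are matched within ±2
probes — strict, but achievable and configuration-exposed.

## What the generator does and does not emulate

The synthetic data reproduce the study conditions: i.i.d. noise of
controlled skewness/kurtosis plus piecewise-constant mean shifts, at the
published sizes (150- and 1,500-probe chromosomes, 15-probe aberrations,
amplitudes $c \le 4$).  They do **not** emulate spatial autocorrelation
("waves"), GC-content trends, probe-specific variances, or outlier probes
beyond what heavy-tailed marginals produce.  Passing tests therefore show
correctness of the statistic, the null model, and the calibration under
the stated noise classes — not robustness to wave artifacts, which
practitioners should remove upstream (as in standard aCGH preprocessing).

## Problem sizes used by the checks

The test and acceptance runs use desk-scale builds chosen once as
study-faithful reductions: lookup models of $4\times5\times4$ cells
($N \in \{100, 150, 250, 1000\}$, skewness $[-0.4, 0.4]$, kurtosis
$[2.6, 3.8]$) at 2,000–4,000 replicates per cell, plus a single-$N$ model
at $N = 1{,}500$ around the severely skewed operating point
(sk 0.5, ku 4.0); calibration checks use 1,000–2,000 null replicates per
series length, concordance 300–500 series at $10^3$ permutations, and ROC
parity 250–500 paired replicates at $10^2$ permutations.  The reference
design (9,408 cells at $10^4$ replicates) is available unchanged through
`build_model(full_grid(), replicates = 10000)`.

## Known limitations

* The model does not extrapolate beyond its axes; queries clamp to the
  boundary.  Series longer than the largest built $N$ get the boundary
  cell's null, which is anti-conservative — build a grid that covers your
  platform.
* Below 100 probes the GEV approximation is not trusted at all
  (permutation takes over); between 100 and ~150 probes the tables are
  usable but the fit quality degrades gradually.
* Noise-moment estimation assumes most probes are unaltered; arrays that
  are mostly aberrant can bias the profile despite pre-segmentation.
* Merging of adjacent segments ("undo" heuristics), gain/loss state
  calling, multi-sample joint segmentation and wave correction are out of
  scope.
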