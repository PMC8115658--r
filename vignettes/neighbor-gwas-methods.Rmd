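---
title: "Neighbor GWAS: model, estimation, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighbor GWAS: model, estimation, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbgwas)
```

## The model and its assumptions

`nbgwas` tests whether an individual's phenotype depends on the genotypic
identity between that individual and its spatial neighbors. With alleles
coded $x \in \{-1, +1\}$ (homozygous reference $\to -1$; the package
targets inbred panels and rejects heterozygous calls, since no dominance
weighting is defined for the neighbor product), the model at spatial
scale $s$ is

$$y_i = \beta_0 + \beta_1 x_i + \frac{\beta_2}{L_i}
\sum_{j \in N_s(i)} x_i x_j + u_i + e_i,$$

$$u \sim \mathrm{N}(0,\; \sigma_1^2 K_1 + \sigma_2^2 K_2), \qquad
e \sim \mathrm{N}(0,\; \sigma_e^2 I).$$

The neighbor covariate is the mean allele product over the $L_i$
neighbors within scale $s$: $+1$ when every neighbor shares the focal
allele, $-1$ when every neighbor differs, $0$ when they balance. The
structure is that of a two-dimensional Ising model — individuals are
spins, $\beta_2$ maps to the negative interaction energy and $\beta_1$ to
the negative external field — fitted as an inverse problem: arrangement
and genotypes are observed, coefficients are estimated. Setting $s = 0$
and $\sigma_2^2 = 0$ recovers a standard single-kinship mixed-model GWAS
exactly; the test suite verifies per-marker p-value agreement with an
independent dense-GLS implementation to $10^{-6}$.

Assumptions worth keeping in mind: effects are single-locus and additive
(no epistasis); neighbor influence is isotropic and depends only on
distance shell; individuals occupy fixed positions in a plane; the
phenotype is Gaussian after covariate adjustment.

### Kinship matrices

$K_1 = X_1 X_1^{\mathrm T}/(q-1)$ from the $n \times q$ matrix of
$\pm 1$ codes, rescaled entrywise to $(k+1)/2$ so entries read as the
proportion of shared loci (diagonal $\approx 1$). $K_2$ (and $K_{12}$ for
the asymmetric covariate $X_{12} = X_1 \odot X_2$) use the same
cross-product form without the rescaling, since their covariates are not
$\pm 1$. Note the $n \times n$ orientation: it is the only shape
consistent with an individual-level random effect.

### Neighborhoods

Shells are half-open distance bands $d \in (\delta_{s-1}, \delta_s]$ with
$\delta_0 = 0$; cumulative neighborhoods are therefore nested by
construction. On a checkered lattice with unit spacing (occupied cells
have even coordinate sum) the thresholds $\delta_s = s\sqrt{2}(1 +
10^{-6})$ give interior individuals exactly $L = 4$ at $s = 1$ and
$L = 12$ at $s = 2$; the $10^{-6}$ inflation keeps boundary distances
float-safe. Edge individuals keep their true, smaller $L$ — the model
scales by the actual neighbor count. Individuals with no neighbors get a
zero covariate row and a logged warning rather than exclusion, keeping
$n$ stable.

## Variance partitioning and the effective scale

Collinearity between the self genotype and the neighbor covariate (severe
at low MAF, and total as the neighborhood spans the field, where
$X_2 \to x_i \bar{x}$) makes naive variance attribution misleading. The
package therefore reports three PVE flavors per scale, all from AI-REML
fits of nested models with the same fixed design:

* *single* PVE — one random component at a time,
  $\sigma_1^2/(\sigma_1^2 + \sigma_e^2)$ (self) or the $K_2$ analogue;
  these systematically **overstate** under collinearity and are reported
  for diagnosis only;
* *partial* PVE — both components jointly,
  $\sigma_m^2/(\sigma_1^2 + \sigma_2^2 + \sigma_e^2)$;
* *net* PVE\_nei $=$ (partial self $+$ partial nei) $-$ single self: the
  gain of the two-component model over the self-only model, and the
  recommended conservative summary. Under self-only simulations its
  median magnitude stays below 0.05 while the single neighbor PVE
  inflates past 0.1 (both properties are asserted in the test suite).

Component significance uses likelihood ratios between nested REML fits on
one degree of freedom, reported as plain $\chi^2_1$ tail probabilities. A
50:50 boundary-mixture option exists (`boundary = TRUE`) but is off by
default, matching the plain-$\chi^2_1$ reporting convention the package
standardizes on; with it on, p-values halve.

The effective spatial range is estimated from the increments
$\Delta\mathrm{PVE}_{nei}(s) = \mathrm{PVE}_{nei}(s) -
\mathrm{PVE}_{nei}(s-1)$ (the $s = 0$ value is 0, since no neighbor model
exists there), as $\hat{s} = \arg\max_s \Delta\mathrm{PVE}_{nei}(s)$,
ties broken toward the smallest scale. In the package's own simulations
this recovers $\hat{s} = 1$ essentially always under strong decay
($\alpha = 3$). Under near-zero decay ($\alpha = 0.01$) the partial
neighbor PVE keeps rising with $s$ — correctly signaling a range beyond
the nearest neighbors — but the *increment* profile saturates one scale
early: cumulative neighbor kinships are nested and heavily overlapping,
so $K_2(2)$ already captures most of the variance structured by
$K_2(3)$, and the argmax typically lands at $s = 2$ rather than the
generative maximum. We verified this is not a sample-size artifact (it
persists at $n = 1296$ on the full 36 × 72 layout). Practical reading:
treat $\hat{s} = 1$ as evidence of short range, and a non-decreasing
profile with $\hat{s} > 1$ as evidence of broad range, rather than
expecting $\hat{s}$ to pin the exact generative horizon.

## Estimation

### AI-REML

Variance components are estimated by average-information REML, written
directly in the package (the algorithm is standard; the implementation is
cross-checked in the tests against a brute-force grid/`optim` evaluation
of the closed-form restricted likelihood, agreeing to $10^{-4}$ in
log-likelihood). Numerical choices, all tunable:

* start from an equal split of the OLS residual variance across
  components;
* propose an AI step; if it leaves the parameter space or fails to
  improve the restricted likelihood, halve the step (up to 8 times), then
  fall back to an EM-REML update, which is always ascent-safe;
* box-constrain variances at 0 (the null-boundary behavior is real: under
  pure-noise phenotypes a sizable fraction of fits end exactly at 0, and
  a test asserts this);
* declare convergence when the restricted log-likelihood moves by less
  than $10^{-6}$, cap at 100 iterations, and flag non-convergence in the
  result (propagated as a warning by `pve_partition`).

### The plug-in scan

Per-marker testing re-estimates nothing: variance components come from
the no-marker model once, the combined matrix
$(\hat\sigma_1^2 K_1 + \hat\sigma_2^2 K_2)/\hat\sigma_e^2$ is
eigendecomposed once, and every marker model becomes a weighted least
squares fit in the rotated basis with the overall scale profiled by
maximum likelihood — $O(n)$ per marker after one $O(n^3)$
decomposition. The forward-selection order is what keeps neighbor tests
honest under collinearity:

1. null likelihood under the $K_1$-only covariance (no marker);
2. test $\beta_1$ by LRT against that null;
3. recompute the self-likelihood under the two-component covariance with
   the self marker included;
4. test $\beta_2$ against the self-likelihood (and optionally
   $\beta_{12}$, one more df, on top).

A marker whose only signal is self-genotypic therefore gains no small
neighbor p-value (planted-simulation test: median $p_{nei} > 0.1$ at the
self-causal markers while all $p_{self} < 10^{-4}$). Markers collinear
with the design after rotation (detected by rank deficiency in the QR
fit) and monomorphic markers are reported with $p = 1$ and a flag rather
than dropped. An exact per-marker re-estimation mode exists
(`reestimate = TRUE`) for validation; a test confirms the plug-in and
exact scans agree on the top marker.

## The simulator

The generative model extends the fitting model with exponential distance
decay $w(s, \alpha) = e^{-\alpha(s-1)}$ over shells $1..s_{max}$
(default 3), an asymmetric interaction term
$\beta_{12}\, x_i \cdot (\text{neighbor covariate})$, and a three-part
random effect $u \sim \mathrm{N}(0, \sigma_1^2 K_1 + \sigma_2^2 K_2 +
\sigma_{12}^2 K_{12})$. The fit deliberately uses the unweighted,
symmetric covariate — the mis-specification is part of what the power
studies measure. Marker columns are standardized before effect
construction, and causal coefficients are drawn as independent
$\pm 1$ signs over four classes (self+neighbor+asymmetric / self+neighbor
/ self-only / neighbor-only at 15/15/35/35%, largest-remainder rounding
with ties to the earlier class, so truth tables are reproducible).

Design choices that were genuinely open:

* **What the ratio scales.** The `ratio` triple (e.g. 8:1:1) sets the
  relative importance of self, neighbor, and self×neighbor effects. It is
  applied to the random components
  ($\sigma_1^2 : \sigma_2^2 : \sigma_{12}^2$) *and* to the fixed blocks,
  each variance-normalized and reweighted so realized block variances are
  proportional to the ratio. Scaling only the random part would leave the
  fixed neighbor block at about 1% of the self block's variance (the
  cumulative-$L$ denominator dilutes decayed shells), contradicting both
  the intended meaning of a 1:8:1 condition and the requirement that a
  1:0:0 phenotype contain no neighbor contribution at all.
* **Cumulative $L$.** The generative covariate is scaled by the
  cumulative neighbor count across shells $1..s_{max}$, consistent with
  the fitting model's scale-dependent $L$.
* **Exact variance budget.** The phenotype is assembled as
  $y = a f + b u + e$ with two scalar gains calibrated by 1-D
  optimization so the realized fixed fraction hits `pve_beta` and the
  random fraction `pve_total - pve_beta` (residual takes the rest).
  Because $u$ is built from the same covariates as $f$, the two can be
  substantially correlated in finite samples, which makes the fractions
  non-identifiable (and the calibration divergent); $u$ is therefore
  residualized on $f$, and $e$ on both, so the decomposition is exact.
  Realized fractions land within $\pm 0.02$ of target. The raw phenotype
  is recorded on the scale where fixed coefficients equal the block
  gains, so true coefficients are recovered as
  $\hat\beta \times \mathrm{sd}(y_{raw})$; the returned $y$ is
  standardized to mean 0, variance 1.
* **Synthetic genotypes.** A Balding–Nichols-style draw (ancestral
  frequency uniform on `(maf_min, 1 - maf_min)`, Beta-perturbed
  subpopulation frequencies, inbred $\pm 1$ individuals, redraw of
  markers violating the MAF floor). Defaults `n_subpop = 3`,
  `fst = 0.3`, `maf_min = 0.1` give element-wise $K_1$–$K_2$ overlap in
  a realistic range for structured plant panels while staying well short
  of the near-total collinearity that makes neighbor effects
  unidentifiable. What this generator does **not** emulate: linkage
  disequilibrium along chromosomes, realistic MAF spectra skewed toward
  rare alleles, and isolation-by-distance placement (genotypes are
  arranged on the field at random). Power numbers from these simulations
  therefore speak to the method's behavior under clean population
  structure, not to any particular species' genome.

## Arrangement optimization

Once $\hat\beta_1, \hat\beta_2$ are estimated for a locus, the forward
Ising machinery searches for allele arrangements extremizing the
population sum $\sum_i y_i = \beta_1 \sum_i x_i + \beta_2 \sum_i x_i
h_i$ (each unordered neighbor pair counted from both members). Simulated
annealing uses Metropolis single-spin flips from a uniform random start
with geometric cooling, by default from $T = 10$ to $T = 0.01$ over
`n_iter = 1000` sweeps. One "iteration" is interpreted as a sweep — one
proposed flip per site — which both lattice graphs admit efficiently
because they are bipartite (full grids by rook adjacency, checkered grids
by diagonal adjacency): each sweep updates the two color classes
alternately, and simultaneous flips within a class never interact. One
subtlety: zero-gain flips are accepted with probability 1/2 rather than
always, since deterministic acceptance makes simultaneous updates cycle
between mirror states (observable already on a 2 × 2 lattice). The
best-visited state is returned, its best-so-far trace is monotone, and on
lattices up to 3 × 3 the annealer reaches the enumerated global optimum
in ≥ 95% of seeded runs. A swap mode (`dynamics = "swap"`) conserves
allele counts for settings where the planting stock is fixed.

The sign phases behave as the ferromagnet analogy predicts and as the
tests assert: $\beta_2 > 0$ drives mixed (checkerboard-like) optima with
neighbor agreement below 0.5, $\beta_2 < 0$ drives clustered optima, and
$\beta_1$ tilts the allele balance; with both coefficients zero the sum
is identically 0 and the state stays random.

## Degenerate inputs and numerical conventions

* Monomorphic markers: flagged at load (MAF = 0 warning), reported with
  $p = 1$ in scans, `NA` in collinearity diagnostics.
* LD pruning is adjacent-only in position order within chromosome
  (each candidate compared to the last kept marker), not windowed; it is
  idempotent.
* ROC AUC uses the Mann–Whitney rank form with midranks for ties;
  sensitivity at FPR 0.05 evaluates the ROC step function at the largest
  empirical FPR not exceeding the target (no interpolation).
* LRT statistics are clamped at 0 when numerical noise makes the full
  model's likelihood infinitesimally smaller than the null's.
* Kinship PSD is enforced only up to tolerance ($\lambda_{min} \ge
  -10^{-8}\,\mathrm{tr}(K)/n$); eigendecompositions clip tiny negative
  eigenvalues at 0.

## Problem sizes used by the test suite

The validation studies are sized to run comfortably on a laptop: power
and null-calibration studies use $n = 400$, $q = 1000$, 10 replicates on
a 20 × 40 checkered field; REML recovery uses $n = 400$, 60 replicates;
effective-scale recovery uses $n = 400$, $q = 400$, 5 replicates per
decay regime; oracle comparisons use $n = 30$–$120$ where dense
$O(n^3)$ references are cheap. These sizes are the package's choices for
its own regression tests; the estimators themselves have no such limits
beyond the dense $O(n^3)$ REML and eigendecomposition cost.

## Known limitations

* Rare variants: low MAF drives self–neighbor collinearity, misclassifying
  true neighbor signals as self effects (the reverse direction is
  suppressed by the forward-selection order). There is no fix within a
  single-locus linear model; interpret low-MAF neighbor hits cautiously.
* The effective-scale argmax saturates under very broad neighbor ranges
  (see above).
* Heterozygotes are rejected, not down-weighted; dosage data and 3-D or
  toroidal geometries are out of scope.
* The scan's plug-in approximation shares the usual property of
  EMMAX-style methods: p-values are slightly conservative for markers
  with large effects, since components are not re-estimated per marker.
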