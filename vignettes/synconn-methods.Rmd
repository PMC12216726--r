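---
title: "Synaptic density connectomes and causal covariance networks: methods"
author: "synconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synaptic density connectomes and causal covariance networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synconn)
```

# The problem

SV2A PET imaging gives an in-vivo proxy of synaptic density: the
standardized uptake value (SUV) of an SV2A-binding radioligand in a brain
region tracks the density of synaptic vesicle glycoprotein 2A. In a
neurodegenerative disease such as ALS, two questions follow naturally:

1. **Connectivity**: do the *distributions* of synaptic density across
   regions co-vary less in patients than in controls — that is, does the
   synaptic density *network* degrade?
2. **Ordering**: when several regions lose synapses, is there a
   recoverable ordering — does loss in one structure precede and predict
   loss in others?

`synconn` implements an individual-level similarity connectome for the
first question and a stage-sequenced causal covariance analysis for the
second, together with a synthetic cohort generator that plants a known
degeneration process so every stage of the pipeline can be validated
against ground truth.

# The similarity connectome (KLSE)

For one subject, every atlas region contributes the sample of its
in-mask voxel SUVs. After proportional scaling (division by the in-mask
global mean, which removes individual differences in global tracer
uptake), each region's sample is turned into a probability density by
Gaussian-kernel KDE with Silverman's rule-of-thumb bandwidth, evaluated
on one shared grid of `n_points` equally spaced points spanning the
subject's full in-mask SUV range. Densities are floored at `1e-12` and
renormalized so no zero ever enters a logarithm.

For two regional densities $P$ and $Q$ on that grid the symmetric
Kullback–Leibler divergence is

$$D(P,Q) = \sum_{i=1}^{n} P_i \ln \frac{P_i}{Q_i} + Q_i \ln \frac{Q_i}{P_i},$$

and the connectome entry is the similarity score $KLS = e^{-D} \in (0,1]$.
The result is a symmetric region-by-region matrix with unit diagonal —
high values mean two regions share a similar uptake distribution.

Numerical choices worth stating:

* **Natural logarithm** throughout, so $e^{-D}$ is the exact inverse map.
* **One shared grid per subject** rather than per-pair grids: all pairwise
  comparisons then live on common support, the matrix is built with one
  density evaluation per region, and similarity is transitive in the
  sense that identical samples always give $KLS = 1$.
* **Exact evaluation** of the KDE (no FFT binning), so the estimate is
  deterministic and reproducible to the last bit; `stats::density()`
  agrees closely but interpolates from a binned grid.
* **Zero-variance samples** (possible in noise-free simulations) fall
  back to a bandwidth of $10^{-3}\times$ the grid span.
* The cross-entropy matrix is symmetrized as `C + t(C)` before use, so
  the matrix is symmetric to the last bit and the class validity check
  can demand exact symmetry.

Nodal degree summarizes the graph: at a connection density $d$ the top
$d$ fraction of edges by weight is retained (ties broken by weight, then
by region-pair index, so results are deterministic) and surviving edges
per node are counted; in significance mode a binary matrix of
significant group-difference edges is counted directly. Because the
choice of $n$ (KDE sampling points) and $d$ is conventional, the package
ships a sweep (`sweepParameters()`) that recomputes the case–control
edgewise t-pattern over $n \in \{2^8 \ldots 2^{11}\}$ and
$d \in \{0.5 \ldots 1.0\}$ and reports all pairwise pattern
correlations; stable results show correlations near 1.

# Group inference

Edgewise and regional comparisons use Welch's two-sample t-test — the
paper-standard "two-sample t-test" is not specific about equal-variance
assumptions, and Welch is the safer default. All upper-triangle edges
form a single Benjamini–Hochberg FDR family (default q < 0.01 for edges,
q < 0.05 for regional mean SUV). Edges with zero standard error are
reported as `NA` and leave the family. Demographics use the three
conventional tests: Welch t (age), chi-square independence (sex), and
Mann–Whitney (education). The chi-square uses **no Yates continuity
correction** by default: for a 13/8 vs 13/12 male/female split this
convention reproduces the reference p = 0.500 at printed precision;
a toggle is provided.

# Causal synaptic covariance networks (cSCN)

Cross-sectional volumes carry no time axis. The cSCN idea is to impose a
pseudo-temporal one: ALS subjects are ordered by King's clinical stage
(1–5 with a/b sub-stages), so the sequence of volumes traces the disease
trajectory from early to late. On this ordered axis, signed-path
Granger causality asks whether the seed region's (standardized) SUV
series predicts another series one step ahead, beyond that series' own
lag:

$$y_t = \beta_0 + \alpha_1\, y_{t-1} + \beta_1\, x_{t-1} + \epsilon_t,$$

with $\beta_1$ (for order 1; the sum of x-lag coefficients for higher
orders) reported as the signed path coefficient. Both series are
standardized to mean 0, SD 1 before fitting; an intercept is always
included; constant or collinear series return 0 with a degeneracy flag
rather than NaN so maps and matrices stay well formed.

* **Voxelwise**: the seed's mean-SUV series is the source; every in-mask
  voxel is a target; only the seed-to-voxel direction is computed. The
  GC map is z-transformed (mean 0, SD 1 over non-degenerate in-mask
  voxels — an affine map, so invariant to common rescaling of the GC
  values), two-tailed normal p-values are BH-adjusted at q < 0.01.
* **ROI-to-ROI**: every ordered region pair is fitted; the matrix is
  binarized at GC > 0.82 and summarized by binary out-/in-degrees. A
  high out-degree marks a Granger-causal source. Directed pathways of
  length one and two from the seed (`extractPathways()`) render the
  result as schematic routes (e.g. seed → striatum → neocortex and
  seed → neocortex).

Model order 1 is the default and a configuration knob: with ~21 ordered
subjects, higher orders spend degrees of freedom quickly. Within-stage
ordering is a convention (stage, a/b sub-stage, then disease duration
ascending, ALSFRS-R descending, then subject id — stable and
documented); `tieOrderingAudit()` re-runs the ROI network over random
permutations of tied subjects and reports the stability of the seed's
out-/in-degree. No covariate residualization is applied by default; the
sequencing key itself is the only clinical input.

# The synthetic cohort and its ground truth

No public SV2A PET cohort accompanies this method, so the package makes
its study conditions explicit in a generator whose defaults describe the
emulated cohort: 21 ALS / 25 HC; a 96-region atlas (90 AAL-style
cerebral regions + 6 brainstem regions) tiled as disjoint 5³-voxel
blocks on a 37×25×25 grid of 2 mm voxels; King's stage composition
\{I: 2, IIa: 2, IIb: 9, III: 6, IVa: 1, IVb: 1\}; demographics drawn to
match the reference cohort's printed means and spreads (age 52.5 ± 11.0
vs 51.4 ± 8.5, education 9.0 ± 4.3 vs 9.9 ± 3.0, duration ~19 ± 15
months); ALSFRS-R generated as 48 − 5·stage + noise, a documented
convenience that reproduces the observed stage–disability correlation.

The planted disease process has three channels, all fractions of a
region's baseline mean:

1. **Stage-graded trend** — the seed region (right medulla oblongata)
   loses `delta` per stage; a region with lag $L$ loses
   `delta * max(0, stage - L)`. Striatum lags the seed by 1 stage,
   the affected neocortex group by 2. In noise-free mode this channel
   is exact, which the tests exploit.
2. **Severity propagation** — each subject carries a seed-severity
   innovation $u_t \sim N(0, \texttt{propagation\_sd}^2)$ along the
   stage-ordered sequence; downstream regions express $u_{t-1}$ (and the
   neocortex additionally $u_{t-2}$, weighting both the direct and the
   striatum-mediated route). This is the generative counterpart of what
   signed-path GC measures: a purely stage-graded trend contains no
   lag-specific innovation for an order-1 model to detect, because each
   region's own lag is then as informative as the seed's. Treating the
   stage axis as pseudo-time and propagating severity along it is
   exactly the process the cSCN model assumes.
3. **Dispersion inflation** — an affected region's voxel-noise SD is
   multiplied by `1 + dispersion_shift * max(0, stage - L)`, which
   widens its intensity distribution and lowers its KLS similarity to
   unaffected partners.

Members of an affected group share a common baseline mean, so a shared
loss factor transforms their distributions identically and within-group
edges stay null. A per-subject global uptake factor (log-SD 0.1) is
planted and exactly removed by proportional scaling. Setting
`delta = 0` disables the whole disease process, giving an exchangeable
null cohort.

**Ground truth.** Which pairs should *lose* similarity is not obvious
from the region list alone: a mean reduction can move one region's
distribution toward a partner's and increase similarity, and regions
sharing a severity innovation can co-vary into higher similarity — both
effects are real and are also visible in case–control studies as
"increased connectivity" edges. The generator therefore computes, for
every pair, the expected KLS under controls and under the ALS
stage/severity mixture from the closed-form symmetric KL between normal
densities (with the Silverman-bandwidth variance inflation included),
by fixed-seed Monte Carlo over the mixture. Pairs whose expected
similarity loss exceeds `kls_margin` (default 0.2 KLS units — a
substantial, meaningfully testable loss at n = 21 + 25) form
`decreased_pairs`; the full per-pair expectation is kept so tests can
distinguish "planted decrease", "planted increase", and "untouched".

**Effect-size defaults.** The reference study reports no effect sizes,
so the defaults were chosen once, by a power analysis at the study's
sample size, to give comfortable recovery margins: `delta = 0.10`
(≈ 10 % SUV loss per stage in the seed, i.e. ≈ 40 % at stage IV —
consistent in magnitude with reported late-stage synaptic loss),
`noise_sd = 0.10`, `dispersion_shift = 0.4`, `propagation_sd = 0.06`,
propagation weights 0.6. They are synthetic conventions, not claims
about ALS.

**What the generator does not emulate**: scanner point-spread and
partial-volume effects, anatomically shaped regions, spatial noise
correlation, registration error, or any real biological heterogeneity
beyond the planted channels. Passing tests demonstrate that the
implementation recovers what it plants under these idealized conditions;
they are not evidence about real PET data.

# Problem sizes used by the validation suite

The test suite validates at the study's default conditions: the
edgewise/regional recovery and the parameter sweep run on the full
21 + 25 cohort with 96 regions of 125 voxels; causal-direction recovery
uses 50 replicate cohorts (21 ALS with a minimal control arm, which the
ROI network does not use); type-I error control uses 200 null cohorts at
a reduced 16-region, 10 + 10 geometry, where the BH family is smaller
but the error-control property is the same. These sizes keep the whole
suite comfortably reproducible on a single CPU.

# Degenerate inputs and edge policies

* Regions with fewer than 2 usable voxels are dropped with a warning and
  the connectome shrinks; the dropped ids are reported.
* Zero-variance edges yield `NA` t-statistics and leave the FDR family.
* Constant series in GC fits return 0 with a degeneracy flag; degenerate
  voxels are excluded from the z-normalization.
* Smoothing uses reflective padding by default (configurable to zero
  padding); the kernel is truncated at 4σ and renormalized.
* Atlas construction rejects grids too small to host the requested
  number of ≥27-voxel blocks, and parcellation validity rejects atlases
  with empty regions.

# Known limitations

* The KLS connectome compares *distributions*, not spatial patterns: two
  regions with identical histograms are maximally similar wherever their
  voxels sit.
* Granger causality on stage-ordered cross-sections is an ordering
  heuristic, not a causal identification: it inherits all caveats of
  pseudo-time analysis, and the package's recovery guarantees hold for
  the planted generative process only.
* The GC binarization threshold (0.82) is a convention carried from the
  method's reference use; with other data scales it should be
  recalibrated against the voxelwise FDR-controlled map.
* With ~500 truly altered edges in a 4560-edge family, BH at q < 0.01
  admits a small number of null edges by construction (the FDR is a
  *rate*); exact-zero false-positive counts should not be expected.
* The two-sample t-test is applied to raw KLS values, following the
  method's reference convention. KLS is bounded and strongly non-linear
  in the underlying mean gap: for a given null pair, the group whose
  regions happen to sit slightly farther apart has both a lower mean and
  a lower variance of KLS, which makes the t statistic heavy-tailed.
  In simulation this shows up as occasional "bursts" of spuriously
  significant edges concentrated on one region whose control- or
  case-arm means drew a collective deviation; a variance-stabilizing
  transform (e.g. testing log(-log KLS) or the divergence itself) would
  tame this, at the cost of departing from the reference analysis.
* The expected-KLS bookkeeping in the synthetic ground truth uses the
  closed-form divergence between normal densities; in the low-similarity
  saturation regime the discrete floored estimator departs from it, so
  the ground truth certifies *decreased* pairs only with a large margin
  and certifies *null* pairs only structurally (pairs touching no
  affected region).
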