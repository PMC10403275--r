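---
title: "Network segregation and language production: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network segregation and language production: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segconn)
```

## The scientific question

Spoken language production tends to decline across adulthood, while many
comprehension-side abilities are preserved. One candidate neural correlate is
the *segregation* of resting-state functional networks: how much more
strongly a network's regions talk to each other than to the rest of the
brain. segconn implements a complete analysis path from node time series to
the statistical claim "higher segregation predicts better production, but
only below some age" — and a synthetic-cohort generator that plants exactly
that structure, so every stage can be verified against ground truth.

## Network model

A subject's resting state is summarized by node time series $x_i(t)$,
$i = 1..n$ (here $n = 231$ spherical nodes of radius 5 mm on the MNI152 2 mm
reference grid, partitioned into 14 networks including a left-language
network and its right-hemisphere homologue). The processing chain is:

1. Pearson cross-correlation of every node pair, $r_{ij}$.
2. Fisher transform $z_{ij} = \tfrac12 \log\frac{1 + r_{ij}}{1 - r_{ij}}$.
3. Thresholding: the diagonal and all negative $z_{ij}$ are set to exactly
   zero, giving the subject's weighted $n \times n$ $Z$-matrix. Negative
   edges are removed because their physiological meaning in denoised
   resting-state data is contested; the zeros they leave behind remain
   *entries* of the matrix and stay in every subsequent mean (see "Numerical
   choices" for the alternative).
4. For each network $k$ with node set $N_k$:
   within-network connectivity $\bar W_k$ is the mean of $z_{ij}$ over
   unordered pairs inside $N_k$; between-network connectivity $\bar B_k$
   is the mean over all pairs linking $N_k$ to its complement; and
   $$S_k = \frac{\bar W_k - \bar B_k}{\bar W_k}.$$
   $S_k = 1$ means the network shares no positive connectivity with the
   rest of the brain; $S_k = 0$ means no differentiation. $S_k$ requires
   $\bar W_k > 0$ and at least two nodes per network.
5. The whole-brain value is the *unweighted* mean of $S_k$ across networks,
   so small networks count as much as large ones.

Assumptions worth keeping in mind: time series are taken as already
preprocessed (motion-corrected, denoised, filtered) — nothing here scrubs or
filters; Pearson correlation only captures linear coupling; and the
segregation index inherits any bias in $\bar W_k$ from network size and
thresholding.

## Moderated regression and the Johnson-Neyman region

Production ability is summarized by a composite: the sum of cohort z-scores
of four measures — verbal fluency total, picture-naming reaction time
(reverse-coded by negating its z-score), mean length of utterance (MLU), and
moving-average type-token ratio (MATTR, window 50). All z-scores use the
sample SD ($n-1$).

The focal model is

$$y = b_0 + b_1\,\mathrm{seg} + b_2\,\mathrm{age} +
      b_3\,(\mathrm{seg}\times\mathrm{age}) + \gamma^\top c + \varepsilon,$$

with all predictors standardized before fitting and the interaction formed
as the product of the standardized columns. Head motion is the default
covariate; gray-matter volume is added in sensitivity refits. The
conditional slope of segregation at standardized age $m$ is
$\theta(m) = b_1 + b_3 m$ with variance
$V(m) = \mathrm{Var}(b_1) + 2m\,\mathrm{Cov}(b_1, b_3) + m^2\,\mathrm{Var}(b_3)$.
The Johnson-Neyman boundaries solve $|\theta(m)|/\sqrt{V(m)} = t_c$, i.e.
the quadratic
$(b_3^2 - t_c^2 V_{33})m^2 + 2(b_1 b_3 - t_c^2 V_{13})m + (b_1^2 - t_c^2 V_{11}) = 0$,
with $t_c$ the two-sided critical $t$ at the residual df (covariates
included in the df). Boundaries are computed in standardized units and
reported in years via the stored (mean, SD) of age. Zero, one or two real
roots can occur; the significant side is classified by evaluating
$\theta/\sqrt{V}$ at region midpoints, and the observed age range is always
attached so a reader can see which boundaries matter.

Before any model is fit, influence screening runs once on the simple
age-on-composite regression: subjects with Cook's distance above $4/n$ are
removed, and the retained set feeds *all* analyses. Screening is
deliberately not iterated — re-screening after removal would change $n$ and
the threshold, and invites silent over-pruning. The screening model is
configurable, but age-on-composite is the default because the screen is
meant to catch aberrant behavioral measurements before they propagate.

Tests are two-sided at $\alpha = 0.05$ throughout, with no multiple-testing
correction; the JN $\alpha$ is likewise unadjusted by default (an adjusted
level can be passed explicitly).

## What the synthetic cohort emulates

`cohortSpec()` fixes the study conditions: 90 subjects aged 22–78, 180 time
points per subject, 231 nodes in 14 networks. Each subject gets a two-level
block correlation matrix: within-network correlation `rWithin = 0.30`, and a
subject-specific between-network coupling

$$b_i = \mathrm{clamp}\big(r_B + \beta_{\mathrm{age}}\,\mathrm{age}_z +
  \eta_i,\; 0,\; r_W\big), \qquad \eta_i \sim N(0, 0.05),$$

with `rBetween = 0.08` and `segAgeSlope = 0.03` per SD of age, so networks
de-differentiate with age. The subject jitter $\eta_i$ is essential, not
cosmetic: without variance in segregation beyond age, the age and
segregation predictors would be exactly collinear and the moderated model
unidentifiable. A single-subject call standardizes age by the uniform
moments of the age range (midpoint, range$/\sqrt{12}$) so no cohort context
is needed. Time series are multivariate normal draws from the block matrix;
if eigenvalue rounding ever leaves the matrix indefinite it is repaired by
clipping eigenvalues at zero and re-normalizing the diagonal (the repair and
its worst entry change are reported; for the two-level family used here the
matrix is PSD by construction whenever $0 \le b \le r_W < 1$).

The analytic whole-brain segregation of the noiseless matrix,
$(z(r_W) - z(b_i))/z(r_W)$, is recorded as ground truth, and the behavioral
model is planted on it:

$$\mathrm{latent}_i = b_{\mathrm{age}}\,\mathrm{age}_z + b_{\mathrm{seg}}\,\mathrm{seg}_z
  + b_{\mathrm{int}}\,\mathrm{age}_z\,\mathrm{seg}_z + N(0, \sigma).$$

The four observed measures are monotone transforms of the latent score plus
independent noise: a fluency count (linear, rounded, floored at 0, emitted
as coded response tokens across the five categories), naming RT
(reverse-signed linear transform floored at 200 ms, emitted as per-trial
RTs), and a transcript whose shifted-Poisson utterance lengths and Zipf-like
vocabulary size scale with the latent score so that MLU and MATTR track it.
Only the monotone coupling is contracted — the Poisson/Zipf link functions
are convenient stand-ins, and their location/scale constants follow typical
adult norms for these tasks (fluency about 88 ± 15 responses, naming about
1050 ± 130 ms, MLU about 9.4, MATTR about 0.66 at window 50).

The default planted coefficients, `b_age = -0.30`, `b_seg = 0.20`,
`b_int = -0.40`, `noise_sd = 0.7` (latent scale), were chosen once so that a
90-subject cohort analyzed end to end shows the pattern the method is
designed to detect at realistic strength: a clearly significant negative age
effect on the composite, a *borderline* significant negative
age-by-segregation interaction, and — when the interaction is significant —
a JN region confined to ages below roughly the middle of the range. Effect
magnitudes on the raw segregation scale are free parameters of the
generator; these defaults make the planted effect neither trivially strong
nor undetectable.

What the generator does *not* emulate: hemodynamics and autocorrelated BOLD
noise (draws are i.i.d. across time), realistic motion artifacts (motion is
just a covariate correlated with age), spatial structure within networks,
and network-specific aging. That last one matters for interpretation: the
generator applies one age slope to *all* between-network couplings, so
synthetic language-network segregation declines with age along with the
whole brain, whereas empirically the language network appears age-stable.
Passing tests therefore show the machinery is correct, not that real
language networks behave like the synthetic ones.

## Numerical choices

* **Thresholded zeros** default to being *included* in within/between means
  (a removed negative edge contributes zero weight); `zeroPolicy =
  "exclude"` treats them as missing instead. The two readings can differ
  noticeably in sparse matrices, which is why both are exposed.
* **Perfect correlations** ($|r| = 1$) are an error, not clipped: at 180
  time points they indicate duplicated or degenerate input.
* **Sphere membership** uses voxel-center distance, Euclidean in mm space,
  inclusive ($\le$ radius), so anisotropic grids (e.g. the 3×3×4 mm
  functional grid) need no special casing. A 5 mm sphere on the 2 mm grid
  centered on a voxel center covers exactly 81 voxels.
* **Localizer assignment** relabels a node on ≥ 1 shared voxel with a
  localizer mask; a node overlapping both the left-language and
  right-homologue masks is an error rather than a silent tie-break
  (geometrically it should not happen; if it does, the node table deserves
  inspection).
* **MATTR below the window length** falls back to whole-text TTR with a
  warning; tokens are lowercased and stripped of leading/trailing
  punctuation before comparison. Fluency repetition detection uses the same
  normalization; morphological variants count as distinct unless the coder
  flags them.
* **JN roots**: the quadratic is solved in standardized units; $|A| <
  10^{-14}$ is treated as the linear case. Tangent (discriminant ≈ 0)
  regions are reported as two equal boundaries.
* **Cook's distance on an exact fit** (zero residual variance) is defined
  as zero for every point rather than 0/0.
* **Seeds**: every stochastic stage takes a seed fanned out from one master
  seed by a counter scheme (`fanSeed`), so stages and subjects are
  independently reproducible and re-running a config reproduces outputs
  bit-identically.

## What the tests establish, and at what scale

The suite verifies each stage against an independent oracle: segregation
profiles against exhaustive pair enumeration (100 random 20-node,
3-network matrices, agreement to $10^{-12}$); JN boundaries against a
$10^5$-point grid scan of the conditional-slope t-statistic (200 random
fits, agreement within one grid step); Cook's distances against
leave-one-out refits (50 random datasets, $10^{-8}$); sphere voxelization
against brute-force lattice enumeration; MATTR/MLU against hand-enumerated
windows and ratios. Statistical behavior is checked by parameter recovery
(100 cohorts of 200 subjects; each planted coefficient inside its 95% CI in
≥ 90 runs) and null calibration (1000 cohorts of 100 subjects with
`b_int = 0`; interaction rejection rate within 5% ± 2%). Recovery and
calibration are run on the planted latent outcome — the observed four-measure
composite is a monotone, attenuated transform whose coefficients live on a
different scale, so CI coverage of the planted values is only meaningful on
the latent scale; the transform path is covered by its own monotonicity
tests. These problem sizes keep the full suite under about a minute while
leaving each check statistically sharp.

## Known limitations

* Whole-brain segregation is an unweighted mean over networks; a different
  (node-weighted) convention would give different values.
* The generator's i.i.d.-in-time draws make connectivity estimates slightly
  less variable than real BOLD with autocorrelation; empirical segregation
  from 180 volumes is correspondingly optimistic.
* Listwise deletion is the only missing-data strategy.
* No multiple-testing correction is applied anywhere, matching the analysis
  convention the package implements; users running many per-measure models
  should correct externally.
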