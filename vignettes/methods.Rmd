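---
title: "Radial-tangential displays and their inference pipeline: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial-tangential displays and their inference pipeline: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numaniso)
```

## The scientific problem

Peripheral vision is anisotropic: items arranged along the line from
fixation to an item (radially) interfere with each other far more than
items arranged perpendicular to it (tangentially). This is the classical
radial-tangential anisotropy of crowding and of redundancy masking. If
such local interactions feed into numerosity estimation, displays whose
discs predominantly neighbor each other radially should be reported as
*less numerous* than property-matched displays whose discs neighbor each
other tangentially.

`numaniso` implements the full machinery needed to study that question
offline: a display generator that packs discs under eccentricity-scaled
"interference zone" constraints and then flanks them radially or
tangentially; property computation and radial-tangential matching; a
synthetic observer that replaces human participants; and the
mixed-model inference chain (deviation scores, +/-0.5 contrast coding,
random slopes, likelihood-ratio interaction tests, simulation-based
power).

## Display construction

### Interference zones

Every base disc at eccentricity $e$ (degrees of visual angle from
fixation) owns two concentric elliptical zones: a radial zone whose
major axis lies along the fixation-disc axis, and the same ellipse
rotated 90 degrees (the tangential zone). The package uses
**semi-axes** $a = 0.25\,e$ and $b = 0.1\,e$.

This reading was calibrated rather than assumed. Reading the two factors
as *full* axis lengths (semi-axes $0.125\,e$, $0.05\,e$) lets roughly
four times as many base discs into the field as the design's numerosity
grids imply (the small 21.5 x 13.5 degree field would saturate near 80
bases rather than about 20); the semi-axis reading reproduces the
intended base-count regime in both field sizes. The acceptance suite
pins the semi-axes exactly and checks the saturated small-field count
distribution.

### Packing

Base discs (radius 0.36 degrees) are placed by uniform rejection
sampling over the field rectangle. A candidate is accepted iff

1. its whole disc lies inside the field and wholly outside the 4-degree
   fixation exclusion circle;
2. neither of its zones overlaps any zone (of either kind) of an already
   accepted base — ellipse overlap is decided by a separating-axis test
   on 64-vertex inscribed polygons (see *Numerical choices*);
3. both sides of its *designated* zone (radial zone for radial displays,
   tangential for tangential) contain at least one legal flanker
   position: inside the half-zone, outside the central lens where the
   two zones intersect, at least one disc diameter from the base, wholly
   in the field and outside the exclusion circle. Feasibility is probed
   on a fixed 10 x 9 grid over the half-zone.

Constraint 3 is a package design decision. Without it, bases near the
field edge or the exclusion ring cannot host the flankers their role
requires, so mixture displays would silently miss their target
numerosity and all-triplet displays could never realize numerosity
$3B$. With it, flanker demotions are zero across all seeds the test
suite exercises, and the numerosity identities ($2B$ for mixtures, $3B$
for all-triplet displays) hold exactly.

"Until no more discs fit" is operationalized as
`max_consecutive_failures = 3000` consecutive rejected candidates; true
saturation is undecidable by sampling, and the proxy is part of the
configuration. An optional `n_bases` target stops packing early, which
is how displays for a fixed numerosity grid are produced (the original
design selected displays by numerosity from large pools; a stopping
target is the generative equivalent).

### Configurations, flankers, polarity

With `percent_pairs` $= p$, a fraction $p$ of bases receive one flanker
(pairs) and the remainder is split exactly in half between triplets
(two flankers) and singles (none), so total flankers $= B$ and
numerosity $= 2B$ for every $p$. When the rounded pair count leaves an
odd remainder it is moved one step (up for $p \ge 50$, down otherwise,
reversing direction at the boundaries), the minimal deterministic fix
that preserves the even split. In all-triplet mode every base gets two
flankers ($N = 3B$).

Flanker positions are sampled uniformly in the designated half-zone
(side chosen uniformly for pairs; both sides for triplets) and accepted
under the same legality rules as in constraint 3 plus pairwise
disc-disc clearance of one diameter. If uniform sampling fails 3000
times, the sampler retries from the packer's probe grid with growing
jitter; only if that also fails is the base demoted
(triplet to pair to single) and the demotion counted in the display
metadata.

Polarity: `uniform_dark` (all black), `uniform_light` (all white), or
`mixed` (black bases, white flankers). Rendering uses the gray
`#B6B6B6` background, `#000000`/`#FFFFFF` discs, and 0.04 degrees per
pixel, with anti-aliasing off so color assertions are exact.

## Display properties and matching

Five covariates are computed per display: mean center eccentricity;
mean spacing (mean nearest-neighbor center distance — the standard
spacing statistic; an all-pairs variant is provided and clearly named);
convex-hull area of the centers (shoelace on the hull); occupancy area
(union of disks of radius `occ_radius` around the centers, rasterized
at `grid_step`); and density (numerosity / hull area). The occupancy
radius defaults to 1 degree and the grid to 0.02 degrees; the exact
parameters of the original occupancy statistic are not published, so
the value is configurable and should be reported with any occupancy
number.

Matching pairs each radial display greedily (in id order, ties broken
by lower id) with the unused tangential display of identical numerosity
nearest in z-scored property space, z-scores taken from the pooled
distribution. A pair whose standardized mean difference exceeds
`max_smd` (default 0.2 SD, a conventional balance tolerance) on any
single property is rejected. Greedy matching is verified against
exhaustive search on small pools; optimal assignment at
thousands-of-displays scale is out of scope because the matching is
tolerance-style, not cost-minimizing.

## The synthetic observer

The observer is deliberately the analysis model run forward, not a
perceptual theory. For a main trial with true numerosity $N$ in a block
with mean numerosity $\bar N$:

$$
\text{response} = \max\!\Big(1,\ \mathrm{round}\big(N + \beta_0
 + \beta_{arr} X_{arr} + \beta_{pol} X_{pol} + \beta_{num} X_{num}
 + \beta_{arr \times pol} X_{arr} X_{pol}
 + u_{0j} + u_{1j} X_{arr}
 + w(\bar N - N) + \varepsilon\big)\Big)
$$

with $X$ the +/-0.5 contrast codes (tangential, uniform, large = +0.5),
$u_{0j} \sim \mathcal N(0, \sigma_0^2)$ and
$u_{1j} \sim \mathcal N(0, \sigma_1^2)$ per participant,
$\varepsilon \sim \mathcal N(0, \sigma_\varepsilon^2)$ per trial, and
round-half-up rounding. Control (subitizing) trials are answered
correctly with probability $1 - $ `subitizing_error_rate`, otherwise
off by one; any response is replaced by an invalid marker with
probability `invalid_rate`.

Defaults and rationale:

| parameter | default | why |
|---|---|---|
| `beta_arr` | 0.89 items | the small-range headline arrangement effect used as recovery ground truth |
| `beta_pol` | 1.64 items | the printed within-subjects polarity effect (uniform minus mixed) |
| `beta_num` | 1.08 items | the printed (non-significant) numerosity-range effect |
| `beta0` | -4 items | overall underestimation of the small-range sessions |
| `sd_intercept`, `sd_arr_slope`, `resid_sd` | 2, 1, 4 items | package choices: no variance components are printed; these put simulated *t* statistics in the reported order of magnitude |
| `regression_weight` | 0.3 | a moderate central-tendency pull toward the block mean, the documented response-bias phenomenon; it does not bias the arrangement contrast |
| `subitizing_error_rate`, `invalid_rate` | 0.02, 0.01 | produce realistic exclusion counts (a few participants per 40) |

What a green test does and does not establish: the generator reproduces
the *statistical structure the analysis assumes* (balanced contrasts,
participant heterogeneity in baseline and arrangement effect, additive
Gaussian trial noise, occasional invalid and control-error responses).
It does not emulate Weber-like multiplicative noise, sequential/order
effects, response-grid quantization beyond rounding, or any mechanistic
crowding or redundancy-masking process — so recovery tests certify the
inference chain, not any perceptual theory.

## Inference chain

* **Screening** (strict boundaries, in order): incomplete sessions;
  more than 5% invalid responses over the session (exactly 5% is
  kept); control-trial accuracy below 90%, i.e. 10% or more incorrect
  (exactly 90% correct is excluded; invalid control responses count as
  incorrect). Screening is idempotent.
* **Deviation score**: DV = response - true numerosity; negative means
  underestimation. Accuracy analyses use |DV|.
* **Models**: `lme4::lmer` with the contrast-coded fixed effects and a
  participant-level random intercept and arrangement slope by default;
  a crossed numerosity intercept and the simpler cross-experiment
  structure (intercept by participant plus intercept by
  participant-within-arrangement) are exposed through `random_spec`
  because the original random structures are abbreviated and ambiguous
  between crossed and nested readings. REML for reported estimates, ML
  for any model entering a likelihood-ratio comparison.
* **Degrees of freedom**: the environment provides no Satterthwaite
  implementation, so *t*-test df use the between-within fallback
  (participants - 1), recorded in every `FitResult`. At the simulated
  scales this is anticonservative by a negligible amount; the type-I
  acceptance test checks the realized error rate directly.
* **LRT**: $\chi^2 = \max(0, 2(\ell_{full} - \ell_{reduced}))$, df =
  difference in fixed-term counts, upper-tail chi-square $p$; REML
  inputs and non-nested models are rejected.
* **Power**: simulate, refit, count arrangement terms with $p < \alpha$;
  exact binomial CI. No multiplicity adjustment is applied anywhere by
  default.

## Numerical choices

* Ellipse overlap uses 64-vertex inscribed polygons and the
  separating-axis theorem (exact for convex polygons). Because the
  parameterization places vertices exactly at the major-axis tips,
  co-axial hairline overlaps are still detected. The test suite
  compares against a 0.005-degree rasterization oracle and skips only
  pairs whose outcome flips under a +/-0.5% size perturbation (both
  methods are at their resolution limit there).
* Orientations are stored mod $\pi$; a zone is symmetric under
  180-degree rotation.
* Round-half-up (`floor(x + 0.5)`) everywhere a printed rule implies
  deterministic rounding (reference numerosities, pair-count
  allocation, simulated responses); responses are floored at 1.
* All randomness flows through R's RNG (the C++ packer uses `R::runif`),
  so every artifact is a pure function of its seed; child seeds are
  derived with a fixed 32-bit LCG step (`derive_seed`).
* Display JSON stores coordinates with 17 significant digits, the
  minimum that round-trips IEEE doubles bit-exactly.

## Known limitations

* Radial small-field packing saturates around 16-21 bases under the
  flanker-room constraint; radial all-triplet displays therefore cannot
  reach the largest printed small-field numerosity (72 = 3 x 24). The
  original pipeline generated 5000 displays per condition and selected
  by numerosity, which this package mirrors with the `n_bases` target
  rather than brute-force selection.
* The saturation proxy (3000 consecutive failures) and the probe-grid
  flanker-room certificate are package operationalizations; the
  original stopping and feasibility rules are unpublished.
* Human data are not packaged with the study, so printed estimates are
  used as simulation ground truths for recovery, never as values to be
  reproduced from data.
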