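---
title: "Adaptive versus fixed bandwidths for spatial relative risk surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive versus fixed bandwidths for spatial relative risk surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(srrf)
```

## The problem

Cancer registries and other surveillance systems need to locate small areas
of elevated disease risk from individual case coordinates. A standard tool is
the spatial relative risk function (sRRF): the log ratio of two bivariate
kernel density estimates, one for the cases and one for a spatial sample of
controls representing the disease-free population. The decisive tuning
parameter is the kernel bandwidth. A single fixed bandwidth treats the dense
city centre and the empty countryside identically: it oversmooths where the
population is dense (hiding compact urban risk areas) and undersmooths where
it is sparse (conjuring spurious rural ones). The adaptive (Abramson) scheme
counters this by giving every observation its own bandwidth, inversely
proportional to the square root of a pilot density.

`srrf` implements both estimators together with an evaluation harness in
which the *true* risk areas are known, so sensitivity and specificity of the
two smoothing regimes can be measured rather than argued.

## The estimators

Both estimators share the kernel form

$$\hat f(x) = \frac1n \sum_{i=1}^n h_i^{-2} K\!\left(\frac{x - X_i}{h_i}\right),$$

with $K$ the radially symmetric bivariate Gaussian density.

**Fixed.** $h_i \equiv h_{\mathrm{fix}}$, chosen by Terrell's maximal
smoothing (oversmoothing, OS) principle on the pooled case+control
coordinates: $h = (2500/(3072\,n))^{1/6}\,\hat\sigma$ for bivariate data with
a Gaussian kernel, where $\hat\sigma$ is the root of the mean of the two
marginal sample variances and $n$ the *effective* sample size. For the fixed
estimator $n_{\mathrm{eff}} = n_f + n_g$. OS is deliberately conservative —
the largest bandwidth compatible with the scale of the data — which buys
first-order bias cancellation where case and control densities agree.

**Adaptive.** $h_i = h_0\, f(X_i)^{-1/2}/\gamma$, where the pilot $f$ is a
fixed-bandwidth KDE whose bandwidth is selected by least-squares
cross-validation (LSCV) *separately* for cases and controls (separate pilots
preserve each pattern's own heterogeneity), $\gamma$ is the geometric mean of
the $f(X_i)^{-1/2}$ terms — so $\mathrm{GM}(h_i) = h_0$ exactly, an invariant
the tests enforce to $10^{-6}$ — and the global bandwidth $h_0$ is the OS
bandwidth with $n_{\mathrm{eff}} = \sqrt{n_f n_g}$. With equal sample sizes
the two conventions differ by a factor 2, hence $h_0 = 2^{1/6} h_{\mathrm{fix}}$:
the package reproduces the published pooled bandwidth pairs from this ratio
alone.

**LSCV.** $\mathrm{LSCV}(h) = \int \hat f_h^2 - \frac2n \sum_i
\hat f_{h,-i}(X_i)$ has a closed form for Gaussian kernels in terms of the
pairwise squared distances; the package scans a log-spaced grid (61 points by
default) over $[\hat\sigma n^{-1/2},\, 3 h_{OS}]$, refines every grid-local
minimum by golden-section search, reports all minima, and breaks ties among
global minima towards the *largest* bandwidth. LSCV is notoriously prone to
multiple minima and a degenerate $h \to 0$ solution when points are
(near-)duplicated; a minimum on the lower search boundary is flagged
`degenerate` and duplicated points raise a warning.

**Edge correction.** Each kernel's contribution is divided by its mass inside
the rectangular window (the product of two univariate normal interval
probabilities), evaluated at the data point with that point's own bandwidth —
Diggle's correction, generalised per-point for the adaptive estimator. The
corrected density then integrates to 1 over the window up to grid
discretisation; the tests assert 2 %. Kernels are evaluated exactly (no
truncation radius): on the grids used here the dense evaluation is cheap, and
exactness keeps the adaptive-equals-fixed reduction invariant bitwise.

## The significance test

Elevated risk is flagged pointwise by
$z(x) = \hat r(x)/\sqrt{\hat V(x)} \sim N(0,1)$ with the plug-in asymptotic
variance

$$\hat V(x) = R(K)\left[\frac{1}{n_f h_f(x)^2 \hat f(x)} +
\frac{1}{n_g h_g(x)^2 \hat g(x)}\right], \qquad R(K) = \tfrac{1}{4\pi}.$$

For the fixed estimator $h_f = h_g = h_{\mathrm{fix}}$; for the adaptive
estimator the local bandwidth surface is interpolated from the per-point
$h_i$ by inverse-distance weighting over the 8 nearest sample points. This
plug-in form is our interpretation of the asymptotic-normality test — the
exact variance expressions used by the original software release are not
public — and it is therefore guarded by a Monte-Carlo calibration property:
under the null (cases and controls drawn from the same surface, n = 500 each,
200 replicates, fixed OS bandwidth) the pointwise exceedance of
$z > 1.6449$ at interior cells must stay within $[0.01, 0.12]$; observed
$\approx 0.048$ at nominal 0.05. The test is one-sided (elevated risk only),
with no multiple-testing adjustment across cells — tolerance contours are
pointwise by construction, a documented property rather than a defect to
correct. Both densities are floored at $10^{-12}\,\mathrm{m}^{-2}$ before the
ratio; cells where *both* sit at the floor carry no information and are
masked from testing.

Tolerance contours are traced by marching squares on the p-surface at level
$\alpha$; all area bookkeeping, however, uses the rasterized set
$\{x: p(x) < \alpha\}$ under the cell-centre rule, so the overlay is
deterministic and exactly consistent with the mask invariant.

## The synthetic study region

The generator rebuilds, at desk scale, an evaluation design in which risk
areas are *manufactured* from a known bias rather than assumed: population
counts available per community are disaggregated onto a 20 m grid
proportionally to remote-sensed surface sealing. Sealing is blind to building
height, so the estimate misses the vertical population of urban cores —
the deliberate bias source. The true population weights cells by
sealing × height; the biased estimate by sealing alone. Both are
mass-preserving per community (tested to rounding tolerance). Census-tract
relative errors $RE_b = 100(\hat y_b - y_b)/y_b$ (tracts with $y_b = 0$ are
excluded as undefined) select the "true risk areas": tracts with
$RE_b < -50\,\%$, buffered by 500 m. A quantile mode (default the 0.75
quantile of the ascending RE distribution) is available because a fixed
percent cutoff and a quartile need not coincide on generated data.

Default geometry (all configurable via `region_config()`):

- 19.2 km × 19.2 km window; 36 communities of 3.2 km, each split into
  4 × 4 tracts of 800 m; population grid 20 m; analysis/KDE grid 200 m.
  The analysis grid is decoupled from the population grid to bound memory;
  200 m keeps a 20-seed replicate study inside a few minutes of CPU.
- 3 urban cores of radius 500 m with a *plateau* (super-Gaussian, power 4)
  sealing/height profile — city cores have roughly uniform building height
  with a sharp falloff, and the plateau keeps core tracts deeply
  underestimated however the core sits in the tract grid. Core centres snap
  to tract centres, reflecting that census tracts are drawn around
  settlement cores rather than at random relative to them. Height multiplier
  peaks at 6.
- 40 secondary towns (radius 150–350 m, sealed but single-story): they
  cluster the settlement pattern — both observed patterns have
  nearest-neighbour ratios ≈ 0.8, cases more clustered than controls, the
  qualitative signature of the real registry patterns — without adding any
  height bias of their own.
- Rural background sealing 2 % (lognormal heterogeneity), as for open
  farmland.
- Total population 200,000; community counts proportional to built mass with
  15 % lognormal noise.

Cases (default $n_f = 1000$) are sampled from the true population surface —
constant individual risk makes the case density mirror the truth — and
controls ($n_g = n_f$, the 1:1 design) from the biased grid; cells are drawn
with replacement proportionally to their weight and points placed uniformly
within the cell. Sample-cell frequencies converge to the normalized weights
(total-variation < 0.01 at $n = 10^5$, tested).

**What the generator does and does not emulate.** It reproduces the bias
*mechanism* (dasymetric height blindness), the smallness of urban risk areas
relative to the OS bandwidth (here $h_{\mathrm{fix}} \approx 1.4$ km against
500 m cores, the same ~3× oversmoothing ratio as the original study), the
1:1 case–control design, and clustered point patterns. It does not emulate
cancer-specific spatial processes (screening participation, occupational
exposures), irregular administrative boundaries (communities and tracts are
rectangles; the window is rectangular), spatially autocorrelated rural
sealing, or geodetic coordinates (everything is planar metres). Passing tests
therefore support the *methodological* comparison of the estimators, not any
epidemiological claim about real registries.

## Scenario analyses

`scale_bandwidths()` implements the sensitivity scenarios: S1 halves the
pilot and global (and fixed) bandwidths, S4 doubles them, S2 halves the
pilots while doubling the global bandwidth, S3 the reverse (S2/S3 leave the
fixed bandwidth unchanged — they exist to separate the two adaptive tuning
knobs).

A finding worth stating plainly: in this scaled-down study (n = 1000 per
pattern) halving the adaptive bandwidths (S1) **raises specificity but
lowers sensitivity** across 20 replicates, whereas the original evaluation —
at twenty times the sample size — reported a simultaneous improvement. The
mechanism is visible in the variance formula: $\hat V \propto 1/(n h^2 \hat f)$
quadruples when $h$ halves, so at moderate $n$ the tolerance contours
contract faster than the sharpened urban peaks can compensate
(variance-limited regime). At registry-scale $n$ the variance term is
negligible and halving only sharpens the peaks (bias-limited regime). We
verified that raising $n$ to 2000–3000 does not reach that regime here — it
instead saturates detection for both estimators — so the corresponding
acceptance property is reported honestly as unmet at the study's scale.

## Numerical choices

- Rasters are row-major from the top row; cells are half-open
  $[x, x+\Delta) \times [y-\Delta, y)$; points on the top/right window edge
  clamp into the outermost cells. Densities are evaluated at cell centres.
- Terrell constant for $d = 2$, Gaussian kernel: $(2500/3072)^{1/6}$.
- LSCV tie-break: largest $h$ among global-minimum ties (conservative
  smoothing); boundary minima flagged rather than silently accepted.
- Pilot density floored at $10^{-12}\,\mathrm{m}^{-2}$ before the $-1/2$
  power (stray points would otherwise get infinite bandwidths); flooring is
  reported via a warning.
- Overlay on the analysis raster by cell-centre membership, not polygon
  arithmetic: deterministic, and its resolution error is controlled by the
  cell size (tested against the closed-form Minkowski area of a buffered
  square to 1 % at 5 m cells).
- Sensitivity is `NA`, not 0, when a replicate's truth mask is empty (0/0);
  replicate summaries skip such replicates.
- The nearest-neighbour ratio uses the plain Clark–Evans CSR expectation
  $1/(2\sqrt{\lambda})$ without edge correction; on a 10⁴-point CSR pattern
  it calibrates to 1 within 3 %.
- One-sided $\alpha = 0.05$ threshold on $z$ is 1.6449.

## A short tour

```{r example, eval = FALSE}
st <- run_study(study_config(scenarios = c("none", "S1")), seed = 42)
tidy(st) # one confusion row per estimator x scenario
glance(st) # bandwidth report + risk-area size
autoplot(st$region) # sealing map with core markers
autoplot(st$surfaces$adaptive_none) # log-RR with tolerance contours
res <- purrr::map_dfr(1:20, \(s) tidy(run_study(study_config(), seed = s)))
replicate_summary(res)
```

## Known limitations

- The plug-in variance (and hence the tolerance contours) is an
  interpretation validated by calibration, not a reproduction of a published
  formula; Monte-Carlo randomization tests are intentionally out of scope.
- Only elevated risk is tested; significantly *decreased* risk is not
  extracted.
- Windows are rectangular; polygonal study regions would need the edge
  factor computed by quadrature over a window mask.
- No age/sex stratification of the synthetic population.
- LSCV pilots inherit all known LSCV pathologies on tied data; the package
  flags rather than repairs them.
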