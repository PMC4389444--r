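# srrf — spatial relative risk surfaces with fixed and adaptive kernel bandwidths

`srrf` is an R package for **spatial disease surveillance with case–control
point data**. It estimates the spatial relative risk function (sRRF) — the log
ratio of the case and control kernel density surfaces over a planar study
window — flags regions of significantly elevated risk with asymptotic
tolerance contours, and scores how well an estimator detects *known* risk
areas by area overlay. Its core question is methodological: how does a
**fixed-bandwidth** kernel estimator compare with an **adaptive
(Abramson) bandwidth** estimator when the true risk areas are compact urban
zones?

## The model

For case locations `X_1, …, X_n` the bivariate kernel density estimate at a
location `x` is

    f̂(x) = (1/n) Σ_i h_i⁻² K((x − X_i)/h_i),

with `K` the radially symmetric bivariate Gaussian kernel. The *fixed*
estimator uses one bandwidth `h_i = h_fix` for all points, selected by
Terrell's oversmoothing (OS) principle on the pooled case+control pattern
with `n_eff = n_f + n_g`. The *adaptive* estimator uses Abramson bandwidths

    h_i = h₀ · f(X_i)^(−1/2) / γ,

where `f(X_i)` is a pilot density (fixed-bandwidth KDE with a least-squares
cross-validation bandwidth, selected separately for cases and controls), `γ`
is the geometric mean of the `f(X_i)^(−1/2)` terms (so the geometric mean of
the `h_i` equals the global bandwidth `h₀`), and `h₀` is the OS bandwidth
with the effective sample size `√(n_f·n_g)`. Edge effects are removed by
Diggle's correction (each kernel divided by its in-window mass).

The sRRF is `r̂(x) = log(f̂(x)/ĝ(x))`. Significance of elevated risk
(`H₁: r(x) > 0`) is assessed pointwise with the plug-in asymptotic variance

    V̂(x) = R(K) · [1/(n_f h_f(x)² f̂(x)) + 1/(n_g h_g(x)² ĝ(x))],  R(K) = 1/(4π),

and `z(x) = r̂(x)/√V̂(x) ~ N(0,1)` under the null; tolerance contours trace
`p(x) = α` (one-sided, default α = 0.05).

Detection skill against a boolean truth mask is summarised by area overlay:
sensitivity `Se = TP/(TP+FN)`, specificity `Sp = TN/(FP+TN)` and the positive
likelihood ratio `LR+ = Se/(1−Sp)`.

## The synthetic study

Because registry case coordinates are confidential, the package ships a
generator that reproduces the *design* of the real evaluation: population
counts known per community are disaggregated onto a 20 m grid proportionally
to surface sealing (imperviousness). Sealing cannot see building height, so
high-rise urban cores are **underestimated** and rural areas overestimated.
Census tracts whose relative error `RE_b = 100·(ŷ_b − y_b)/y_b` falls below
−50 % are the "true risk areas" (buffered by 500 m). Controls are sampled
from the biased grid, cases from the true population — so case excess appears
exactly over the underestimated urban cores. Everything (window, cores,
towns, counts, thresholds) is configurable; see `?region_config` and
`?study_config`.

## Worked example

```r
library(srrf)

st <- run_study(study_config(), seed = 42)
st
#> <rr_study> seed 42; 2 estimator x scenario runs
#> # A tibble: 2 × 5
#>   estimator scenario    se    sp lr_plus
#>   <chr>     <chr>    <dbl> <dbl>   <dbl>
#> 1 fixed     none     0.675 0.914    7.81
#> 2 adaptive  none     0.879 0.827    5.07

st$bandwidths
#> # A tibble: 1 × 6
#>     n_f   n_g os_h_pooled lscv_h_f lscv_h_g os_prime_h_pooled
#>   <int> <int>       <dbl>    <dbl>    <dbl>             <dbl>
#> 1  1000  1000       1456.     184.     219.             1634.

st$nn
#> # A tibble: 2 × 5
#>       n mean_nn_distance expected_csr_distance nn_ratio pattern
#>   <int>            <dbl>                 <dbl>    <dbl> <chr>
#> 1  1000             240.                  304.    0.790 cases
#> 2  1000             252.                  304.    0.830 controls
```

Reading the output: of the 11.6 km² of true (urban) risk area, the adaptive
estimator recovers 88 % but accepts more false positives (Sp 0.83), while the
fixed estimator — whose single 1.46 km bandwidth oversmooths the compact
cores — recovers only 68 % at higher specificity (0.91) and a higher LR+.
Both point patterns are clustered (NN ratio < 1), the cases more strongly
than the controls. `autoplot(st)` shows the Se/Sp bars;
`autoplot(st$surfaces$adaptive_none)` maps the log-RR surface with its
significant tolerance contours.

Replication over seeds and bandwidth scenarios:

```r
res <- purrr::map_dfr(1:20, \(s)
  tidy(run_study(study_config(scenarios = c("none", "S1")), seed = s)))
replicate_summary(res)
```

## Package layout

- `simulate_region()`, `disaggregate_population()`, `make_true_population()`,
  `relative_error()`, `derive_risk_areas()`, `sample_point_pattern()` — the
  synthetic study region.
- `os_bandwidth()`, `lscv_bandwidth()`, `effective_sample_size()`,
  `select_bandwidths()`, `scale_bandwidths()` — bandwidth selection and the
  S1–S4 scenario scalings.
- `fixed_kde()`, `adaptive_kde()`, `adaptive_bandwidths()`,
  `edge_correct_factor()` — kernel density estimation.
- `log_relative_risk()`, `asymptotic_z()`, `p_surface()`,
  `tolerance_contours()`, `risk_surface()` — the risk surface and its test.
- `overlay_confusion()`, `positive_likelihood_ratio()`, `nn_ratio()` —
  evaluation.
- `run_study()`, `replicate_summary()`, `study_config()` — orchestration.
- I/O: CSV point patterns, Esri ASCII grids, GeoJSON tract/contour export,
  YAML configs. `tidy()`/`glance()`/`autoplot()` methods throughout.

The methods vignette (`vignettes/adaptive-vs-fixed-srrf.Rmd`) documents the
model, the generator's assumptions and the numerical choices in detail.
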