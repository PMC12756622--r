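---
title: "Models and methods behind emwsoil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind emwsoil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emwsoil)
```

`emwsoil` analyzes how rock amendments (crushed basalt, lime) to tilled
cropland affect soil structure and organic-carbon (OC) stabilization. This
vignette explains the models it implements, the choices made where the
methodology left them open, and what the synthetic-data tests do and do not
demonstrate.

## The bimodal Kosugi soil-hydraulic model

Water retention in a structured soil reflects two superposed pore systems:
*textural* pores between primary particles and *structural* pores created by
aggregation, biota, and tillage. The Kosugi model describes each system as a
lognormal distribution of pore capillary sizes; the bimodal variant mixes
the two with weight `w`:

$$\theta(h) = \theta_r + (\theta_s-\theta_r)\left[
  w\,\tfrac12\mathrm{erfc}\frac{\ln(h/h_{m1})}{\sigma_1\sqrt2} +
  (1-w)\,\tfrac12\mathrm{erfc}\frac{\ln(h/h_{m2})}{\sigma_2\sqrt2}\right]$$

`h` is the suction head (cm of water, positive magnitude; pF = log₁₀ h),
`hm` the median head and `σ` the spread of each domain. The package stores
domain 1 as the coarser one (`hm1 ≤ hm2`, enforced after fitting — the
mixture is otherwise invariant to label switching). Some presentations of
this model describe `hm` as a median pore *radius*; it enters the retention
function as a head and maps to a radius only through the Young–Laplace
relation below, which is how `emwsoil` treats it.

The associated Mualem-type conductivity curve is

$$K(h) = K_s S_e^{\tau}\,
 \frac{\left[a\,\mathrm{erfc}\!\left(\tfrac{\sigma_1}{\sqrt2}+\mathrm{erfc}^{-1}(2S_{e1})\right)
 + b\,\mathrm{erfc}\!\left(\tfrac{\sigma_2}{\sqrt2}+\mathrm{erfc}^{-1}(2S_{e2})\right)\right]^2}
 {4\,(a+b)^2},\qquad
 a = \frac{w}{h_{m1}}e^{\sigma_1^2/2},\;
 b = \frac{1-w}{h_{m2}}e^{\sigma_2^2/2},$$

where $S_e$ is overall effective saturation and $S_{ei}$ the per-domain
saturations. For lognormal domains
$\mathrm{erfc}^{-1}(2S_{ei}) = \ln(h/h_{mi})/(\sigma_i\sqrt2)$ exactly,
which the implementation uses instead of a numerical inverse — it is both
faster and immune to inverse-erfc precision loss near saturation. At
saturation both erfc terms tend to 2 and `K → Ks`; in the dry limit `K → 0`.
`K(h)` is monotone non-increasing for `τ ≥ 0`; strongly negative `τ` can
lift the dry end, which is a property of the Mualem form itself, not an
implementation artifact.

### Fitting

Laboratory data are drying-curve points (h, θ) from the evaporation method
(near-saturation to about pF 3.5) merged with dewpoint dry-range points
(toward pF 4.2), plus optional (h, K) pairs. `fit_kosugi_bimodal()`
minimizes

$$\sum_i (\theta_i - \hat\theta_i)^2 \;+\;
  \lambda \sum_j (\log_{10}K_j - \log_{10}\hat K_j)^2 .$$

Choices, each exposed in `fit_config()`:

* **Objective weighting** `λ = n_θ/n_K` by default, so both residual blocks
  carry comparable leverage regardless of how many points each instrument
  produced. Commercial fitting software does not disclose its weighting, so
  parameter values fitted to the same cores by other tools may differ; the
  fitted *curves* are the robust quantity.
* **Optimizer**: bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) from 16
  starts — one data-driven heuristic plus 15 Latin-hypercube draws
  (`lhs`, fixed seed 42, recorded in the result). Fits are deterministic
  given data, bounds, and seed.
* **Bounds** span published mineral-soil ranges: θr ∈ [0, 0.25],
  θs ∈ [0.25, 0.65], w ∈ [0.01, 0.99], hm ∈ [1, 10⁵] cm and
  Ks ∈ [10⁻³, 10⁴] cm/d (both searched on log₁₀ scale), σ ∈ [0.1, 3.5],
  τ ∈ [−2, 3].
* **Identifiability**: without conductivity data, `Ks` and `τ` do not enter
  the objective and are reported as `NA` rather than at some arbitrary
  bound. Saturated conductivity is treated purely as a fitting parameter.
* **Guards**: at least 9 retention points spanning ≥ 2 decades of head;
  non-convergence of every start raises an error rather than returning a
  silent best-effort.

Water points follow the convention: field capacity at pF 1.8, permanent
wilting point at pF 4.2 (both vol-%), plant-available water their
difference, porosity `1 − BD/ρs` with particle density ρs = 2.65 g/cm³ by
default (standard mineral-soil value, overridable).

## The Kullback–Leibler structure index

The index scores how far a soil's pore-size distribution (PSD) has developed
away from that of a hypothetical *reference* soil of identical texture but
no structure — loose single-grain packing.

**Structured PSD.** Young–Laplace capillarity links pore radius and head:
`r [cm] = 0.149/h`, i.e. `r [µm] = 1490/h [cm]` (h = 1 cm ↔ 1490 µm; the
wilting point ↔ 0.1 µm). Note the inverse form: radius and suction are
reciprocal — a relation sometimes typeset as a product, which the anchor
radii above rule out. Under this transform the bimodal Kosugi curve becomes
a two-component lognormal mixture in `r` with medians `1490/hm_i` and
spreads `σ_i`. The package uses the effective-saturation density dSe/dr — a
proper probability density independent of the (θs−θr) scaling — truncated
and renormalized on the integration bounds. A water-content-weighted
alternative would multiply KLD contributions by (θs−θr) ratios; with both
PSDs normalized (the convention here) the index compares *shapes*, which is
the interpretation "structural development" calls for.

**Reference PSD.** From the cumulative particle-size distribution:
equivalent pore radius = `packing_factor` × particle radius (default 0.3, of
the order of pore-throat to grain-size ratios in dense random sphere
packings), cumulative mass fraction → water content on
[θr, θs,ref = 0.30], and the same bimodal lognormal form refit to these
pairs with θr fixed to the structured soil's fitted value (residual water is
texture-bound, not structural). **This pore-equivalent mapping is the
module's largest approximation**: `packing_factor` shifts the reference
median multiplicatively and therefore the index's absolute level. Hold it
fixed across any samples you compare; only relative comparisons under a
common configuration are meaningful. Sparse class data (a sand/silt/clay
triplet gives 4 cumulative points) are densified by monotone linear
interpolation on the log-size axis before fitting.

**The index.**
$$D_{KL}(p\|q) = \int_{0.1\,\mu m}^{1490\,\mu m} p(r)\ln\frac{p(r)}{q(r)}\,dr$$
computed by adaptive quadrature on the ln r axis (absolute tolerance 10⁻⁸;
tightening it tenfold moves results by < 10⁻⁵ in the test suite). The lower
bound is the equivalent radius at the wilting point, taken as unaffected by
structure; the upper bound corresponds to h = 1 cm. Results are clamped at
zero against truncation round-off; a negative integral beyond −10⁻⁸, or a
reference density underflowing where `p` carries mass, is an error, not a
silent floor.

## Aggregate OC accounting

Wet sieving over a 500/250/53 µm tower yields four water-stable classes.
Because loose primary sand grains are not aggregates, class masses are
sand-corrected (subtraction) before normalizing to mass fractions; the
<53 µm class has no sand measurement and carries zero correction. Replicate
sieving runs are averaged *after* sand correction, so per-run input-mass
differences cancel. Enrichment factors E_OC = OC_class/OC_bulk use the raw
measured class concentrations (a sand-corrected variant would need
per-class sand OC, which the protocol does not measure). The mass-weighted
sum of per-class OC contributions is checked against measured bulk OC: a
deviation beyond 15% sets a diagnostic flag (sieving loss or measurement
inconsistency) without erroring.

## Rock dilution mass balance

Applied rock accumulates in the plow layer (18 cm here) and dilutes
elemental concentrations of everything the rock is poor in. With areal soil
mass `BD × depth × 100` t/ha, the rock mass fraction is
`B = ΣM_rock/(M_soil + ΣM_rock)`; all applications are summed undepleted —
no weathering decay is subtracted, consistent with slow basalt dissolution
over the trial's six years. The default correction is the first-order form
`Ĉ = C(1+B)`; exact de-mixing `C/(1−B)` is available behind a flag, and the
two differ at O(B²) (at B = 0.1: 16.5 vs 16.67 on C = 15). The built-in
field schedule (4 × 50 t/ha + 2 × 40 t/ha) uses the published rock
grain-size data; one rock's printed fractions sum to 99% and are
renormalized. Per-class allocation maps rock sieve classes onto aggregate
classes (>600→>500, 250–600→250–500, 75–250→53–250, <75→<53 µm); the
75 vs 53 µm mismatch at the fine end is equalized exactly as the sieving
protocol forces, and flagged in the output metadata as added uncertainty.
The bulk density feeding the balance is configurable (profile mean by
default); the layer's own mean is the defensible choice since the balance
concerns the mixed plow layer, not a single sampling depth.

## Texture and statistics

The 12-class FAO/USDA triangle is implemented as a fixed decision cascade
with half-open boundaries (lower bounds inclusive), making the partition
total and non-overlapping — property-tested on a 1% simplex grid. Triplets
off the 100% simplex by ≤ 0.5 points are renormalized with a message.

Group statistics are orchestration over base R: Shapiro–Wilk screening
(logged, not gating), Kruskal–Wallis, and — only when the omnibus test is
significant at α = 0.05 — Dunn's post hoc z tests on mean ranks with the
standard tie correction, Holm-adjusted by default. The adjustment method is
configurable because reported analyses often leave it unstated; this is a
genuine reproducibility caveat when comparing significance letters across
studies. Eq.-style z-score normalization uses the sample (n−1) standard
deviation, and PCA on the standardized table is exactly correlation-matrix
PCA (verified against a direct eigendecomposition in the tests).

## The synthetic trial

`simulate_trial()` emulates the field design: 3 treatments × 3 blocks ×
2 depths, one hydraulic sample each. Defaults encode a tilled silt loam:

* θs 0.50 (surface) / 0.45 (deep), matching silt-loam porosities; BD 1.31 /
  1.42 g/cm³ with depth stratification.
* Textural pore domain at hm₂ = 600–700 cm, σ₂ = 1.6. The equivalent pore
  radius (~2 µm) is consistent with the pores the generator's own silt-loam
  texture implies under the 0.3 packing factor — a coherence requirement:
  a synthetic soil whose textural pores contradict its texture would make
  the structure index respond to that artifact rather than to structure.
* Structural domain at hm₁ = 30 cm with weight 0.25 at the surface,
  shrinking to 0.15 at depth (compaction). Treatments enhance it: lime
  strongest (w + 0.08, hm₁ × 0.7), basalt weaker and surface-only
  (w + 0.04, hm₁ × 0.85), reflecting fast calcite dissolution versus slow
  basalt weathering.
* Chemistry shifts at field magnitude (pH +1.1 basalt / +0.6 lime, available
  Ca +563 / +514 mg/kg); OC cv 5%, chemistry cv 10%.
* Aggregate OC depth gradient: the S+C (<53 µm) class depleted at the
  surface (E_OC ≈ 0.86) and enriched at depth (≈ 1.12). The source analyses
  state this pattern with the depth labels swapped in one place and in this
  orientation in another; the generator follows the orientation tied to the
  tillage mechanism (accelerated surface mineralization depletes the fine
  fraction at 1–6 cm).
* Texture noise sd 2 percentage points around (24, 65, 11). This represents
  a pedologically uniform field; real trials report apparent texture sds of
  4–11 points (partly measurement noise). At such heterogeneity, chance
  texture offsets between 3-block treatment groups can rival the built-in
  structural effect in the index — so the passing directional tests
  demonstrate detectability under homogeneous texture, **not** at
  real-field heterogeneity with n = 3.
* Noise models: additive Gaussian for θ (sd 0.003, the evaporation-method
  scale), multiplicative lognormal for K, cv-based lognormal for
  concentrations. All generators are pure functions of (parameters, seed);
  per-sample sub-seeds are derived arithmetically and stay below 2³¹.

What the generator does **not** emulate: hysteresis and air entrapment,
tensiometer measurement structure (correlated residuals within a drying
run), spatial autocorrelation between blocks, carbonate interference in OC
measurement, and any mechanistic weathering. Parameter-recovery results on
synthetic data therefore bound what laboratory data can give from below in
noise realism.

## Problem sizes and numerical choices

The analysis drivers use 60 retention + 20 conductivity points per sample
and 12 multistarts; the acceptance script uses the laboratory-like 100
points and 20 replicate fits; tests use 12–100 points as each property
needs. Levenberg–Marquardt tolerances are set near machine precision
(ftol = ptol = 10⁻¹⁵) so noiseless recovery is exact to ~10⁻⁴ relative or
better; quadrature tolerance 10⁻⁸; effective saturations are clamped to
[0, 1] with a warning only beyond 10⁻¹⁰ excursions. Ties in the reference
PSD fit are broken by ordering the coarse mode first, as for the structured
soil.

## Known limitations

* The reference-soil construction (packing factor, mass→saturation mapping)
  is the dominant systematic in the structure index; indices are comparable
  only within a fixed configuration.
* Without conductivity data, `Ks`/`τ` are unidentified; with sparse noisy
  dry-range data, `θr` and `σ₂` are weakly identified (their Monte-Carlo
  recovery spread is an order larger than the well-identified parameters).
* The dilution correction assumes chemically inert rock mass; elements the
  rock supplies need the full geochemical budget, which is out of scope.
* Significance letters depend on the post hoc adjustment method; Holm is
  the default but not a universal convention.
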