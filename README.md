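# emwsoil

Soil structure and carbon accounting for rock-amended field trials.

Enhanced mineral weathering (EMW) spreads crushed silicate rock — typically
basalt — on cropland so that carbonic-acid weathering exports alkalinity and
removes CO₂. Whether years of heavy rock additions also change the soil's
physical quality and its capacity to stabilize organic carbon is a question
for soil physicists and biogeochemists running EMW field trials. `emwsoil`
implements the analysis chain such a trial needs, end to end and testable
without any field data (a synthetic-trial generator stands in for the
laboratory measurements).

## What it computes

**Bimodal Kosugi soil hydraulics.** The water retention curve θ(h) is a
two-domain lognormal (Kosugi) model,

θ(h) = θr + w(θs−θr)·½erfc[ln(h/hm₁)/(σ₁√2)] + (1−w)(θs−θr)·½erfc[ln(h/hm₂)/(σ₂√2)],

with the matching Mualem-type conductivity curve

K(h) = Ks·Seᵗ·[a·erfc(σ₁/√2 + erfc⁻¹(2Se₁)) + b·erfc(σ₂/√2 + erfc⁻¹(2Se₂))]² / (4(a+b)²),

a = (w/hm₁)·exp(σ₁²/2), b = ((1−w)/hm₂)·exp(σ₂²/2). `fit_kosugi_bimodal()`
estimates the nine parameters by bounded Levenberg–Marquardt least squares
with a seeded Latin-hypercube multistart, jointly over θ and log₁₀K
residuals. `water_points()` reads field capacity (pF 1.8), permanent wilting
point (pF 4.2), plant-available water, and porosity off the fit.

**Kullback–Leibler structure index.** The fitted retention curve maps to a
pore-size density p(r) through the Young–Laplace capillary relation
r [cm] = 0.149/h (so r = 1490/h in µm), and a structureless *reference*
density q(r) is built from the sample's own particle-size distribution
(pore radius ∝ particle radius, cumulative mass → saturation, the same
bimodal lognormal form refit with θs = 0.30). The index

D(p‖q) = ∫ p(r) ln[p(r)/q(r)] dr over r ∈ [0.1, 1490] µm

is larger the further the soil's pore system has developed beyond
single-grain packing of its texture.

**Aggregate OC bookkeeping.** Sand-corrected aggregate size-class
distributions (>500, 250–500, 53–250, <53 µm), per-class OC contributions,
and relative enrichment factors E_OC = OC_class/OC_bulk.

**Rock dilution mass balance.** B = ΣM_rock/(M_soil + ΣM_rock) over the
incorporation layer, per-aggregate-class allocation from the rock's
grain-size distribution, and dilution-corrected concentrations
Ĉ = C·(1+B) (exact de-mixing C/(1−B) behind a flag).

**Plus**: FAO/USDA texture-triangle classification, z-score normalization,
Kruskal–Wallis/Dunn group tests with compact letters, correlation-matrix
PCA, and the seeded synthetic-trial generator.

## Worked example

```r
library(emwsoil)

truth <- kosugi_params(theta_r = 0.05, theta_s = 0.50, w = 0.7,
                       hm1 = 50, sigma1 = 0.8, hm2 = 2000, sigma2 = 1.2)
sim <- simulate_retention_dataset(truth, n_points = 100, noise_sd = 0.003,
                                  seed = 1)
fit <- fit_kosugi_bimodal(sim$retention)
fit
#> Bimodal Kosugi fit (100 theta points, 0 K points)
#> Bimodal Kosugi parameters
#>   theta_r = 0.0432, theta_s = 0.5004, w = 0.6868
#>   domain 1: hm = 49.92 cm, sigma = 0.8052
#>   domain 2: hm = 2176 cm, sigma = 1.2958
#>   Ks, tau: not identified (no conductivity data)
#>   RMSE theta = 0.00261
#>   converged: TRUE (16 starts, seed 42)

water_points(fit$params, bd = 1.32)
#> Fc = 30.7 vol-%, PWP = 5.2 vol-%, Wa = 25.5 vol-%, phi = 0.50

spec <- reference_soil_spec(texture_to_cumulative(24, 65, 11),
                            theta_r_fixed = fit$params$theta_r)
kl_divergence(psd_from_retention(fit$params), reference_psd(spec))
#> [1] 0.5194164

basalt_contribution(energy_farm_schedule(bulk_density = 1.4))
#> [1] 0.1
dilution_correct(15, 0.1)   # SOC of 15 mg/g corrected for 10% rock mass
#> [1] 16.5
classify_texture(24, 65, 11)
#> [1] "SiL"
```

The fit reproduces the generating curve (water-content RMSE 0.0026, well
below the 0.01 laboratory benchmark); the structure index of 0.52 says this
core's pore system diverges substantially from single-grain silt-loam
packing; six annual rock applications (4 × 50 + 2 × 40 t/ha) into an
18 cm plow layer at bulk density 1.4 g/cm³ make up 10% of the layer's mass,
so a measured 15 mg/g SOC corresponds to 16.5 mg/g of original soil.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on a simulated
trial, writing tables to `results/`:

```sh
Rscript analysis/01_simulate.R            # trial inputs (CSV bundle)
Rscript analysis/02_fit_hydraulics.R      # per-sample fits + water points
Rscript analysis/03_structure_index.R     # KL divergence per sample
Rscript analysis/04_aggregates_dilution.R # E_OC + rock mass balance
Rscript analysis/05_stats.R               # group tests + PCA
```

`run_pipeline()` chains the same stages programmatically over any input
directory with a `pipeline_config()`.

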