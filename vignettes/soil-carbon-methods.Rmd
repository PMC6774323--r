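---
title: "Soil carbon accounting for grassland-to-Miscanthus conversion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soil carbon accounting for grassland-to-Miscanthus conversion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miscsoc)
```

# Scope

`miscsoc` quantifies what happens to soil organic carbon (SOC, 0--30 cm)
when a temperate agricultural grassland is converted to the perennial C4
bioenergy grass *Miscanthus*, and what that change costs in greenhouse-gas
terms per unit of harvested feedstock energy. It chains four methods that
are usually applied separately:

1. **Core-based SOC stocks** by the fixed-depth and equivalent-soil-mass
   (ESM) methods (`compute_core_stocks()`).
2. **Two-pool delta-13C partitioning** of SOC into crop-derived (C4) and
   pre-existing (C3) carbon (`partition_cores()`).
3. **A five-pool monthly turnover simulation** of a continued-grassland
   counterfactual and a conversion scenario (`run_scenario()`).
4. **GWP/LCA arithmetic** turning SOC differences and soil N2O totals into
   g CO2-eq per MJ (`miscanthus_lca()`).

A synthetic field-trial generator (`generate_trial()`) reproduces the
statistical structure of a replicated hybrid trial with exported ground
truth, so every stage is testable end to end without any field data.

# SOC stocks

Each soil core layer carries a dried sample mass $M_{sample}$ (g) over the
corer cross-section $A_{sample}$ (mm^2^). Carbonates are removed by acid
washing before combustion analysis, which also removes mass, so the
measured carbon percentage of the washed sample ($POC$) is rescaled:

$$SOC\,(\%) = POC \times ODW_{acid} / ODW_{initial}.$$

The areal soil mass of the layer is $M_{soil} = M_{sample}/A_{sample}
\times 10^4$ (Mg/ha) and its stock is $M_{soil} \times SOC_{cont}/1000$
(Mg C/ha) with $SOC_{cont}$ in kg C per Mg soil.

Fixed-depth stocks are sensitive to bulk-density change: compaction pulls
more soil (and carbon) into a fixed sampling depth. The ESM method removes
this artefact by comparing stocks over a fixed cumulative *soil mass*. A
natural cubic spline is fitted through the origin and the cumulative
(soil mass, SOC stock) knots of the profile, and cumulative SOC is read off
at a reference mass (default 3000 Mg/ha, roughly the 0--30 cm profile of
this soil). Numerical choices:

* The spline is *natural* (zero curvature at the ends); with two layers
  plus the origin this is the standard three-knot ESM fit.
* The fitted cumulative curve must be non-decreasing and non-negative; on
  the rare irregular profile where the natural fit undershoots, a monotone
  (Hyman-filtered) spline is substituted with a warning rather than
  returning a physically impossible negative stock.
* Evaluation beyond the sampled profile mass is an explicit error unless
  `extrapolate = TRUE`; silent extrapolation is never performed.
* The spline is fitted per core by default. Fitting on the plot-mean
  profile (`esm_per_core = FALSE`) is also available; with one core per
  position the two coincide, and on noiseless synthetic data they agree to
  machine precision.

Core positions sample very different microsites under a row crop, so
plot-level stocks are an area-weighted mean over plant centre, plant edge
and inter-row cores. The default weights are ground-cover survey fractions
(9.82 / 53.39 / 36.79 % twelve years after planting; 8.1 / 24.5 / 67.4 %
at year six), exposed via `area_weights()`.

Bulk density is reported per layer as sample mass over (area x thickness)
for the density summary table only; it never enters the ESM path.

# Isotope partitioning

C3 vegetation (temperate grassland) fixes carbon near -28 permil delta-13C
and C4 vegetation (*Miscanthus*) near -12 permil, measured against the Pee
Dee Belemnite standard ratio 0.0112372:

$$\delta^{13}C = \left(\frac{^{13}C/^{12}C}{(^{13}C/^{12}C)_{PDB}} - 1\right)
\times 1000.$$

After conversion the soil signature drifts from the C3 end-member toward
the C4 end-member in proportion to the crop-derived carbon fraction:

$$C_{mis} = \frac{\delta_n - \delta_0}{\delta_r - \delta_0},$$

where $\delta_0$ is the pre-conversion (T0) soil signature, $\delta_r$ the
below-ground biomass signature at the sampling time and $\delta_n$ the
measured soil signature. Design choices:

* $\delta_0$ is the T0 plot-level mean per depth layer. Pre-conversion
  coring covered only two plots per block, so plots without a T0 core fall
  back to the block mean, then the trial mean.
* $\delta_r$ is the same core's below-ground-biomass measurement when
  available, else a trial-wide mean, else a configurable default.
* Measurement noise can push raw fractions slightly outside [0, 1]; they
  are clamped, and the unclamped value plus an `out_of_range` flag are kept
  in audit columns.
* End-member separations below 5 permil (configurable) make the mixing
  model ill-conditioned; such results are flagged and a warning raised.
* Fractions are computed per core and then averaged by default; mixing
  stratum-mean deltas first (`per_core = FALSE`) is provided as an
  alternative ordering, and the two agree exactly in the noise-free limit.

With instrument-level noise (0.2 permil sd) and the 16 permil end-member
separation of this system, the stratum-mean fraction from 12 cores has a
Monte-Carlo mean absolute error below 0.005 -- an order of magnitude inside
the 0.03 the pipeline's tests demand.

# Five-pool turnover simulation

The scenario model is a RothC-lineage five-pool monthly model:
decomposable plant material (DPM), resistant plant material (RPM),
microbial biomass (BIO), humified matter (HUM) and inert organic matter
(IOM). Each active pool decays as $e^{-k\,a\,b\,c\,\Delta t}$ with rate
constants $k$ = 10, 0.3, 0.66 and 0.02 yr^-1^. Decomposed carbon splits
between CO2 and retained carbon by the clay-dependent ratio
$CO_2/(BIO+HUM) = 1.67\,(1.85 + 1.60\,e^{-0.0786\,clay})$, the retained
part going 46:54 to BIO and HUM. Fresh inputs enter DPM and RPM in a
land-use-specific ratio (default 1.44 for both land uses, the
agricultural/improved-grassland convention; the ratio is config-exposed
because it is land-use-specific in principle).

Rate modifiers:

* temperature $a = 47.91 / (1 + \exp(106.06/(T + 18.27)))$, zero at and
  below -18.27 degC;
* moisture $b$: 1 until the accumulated topsoil moisture deficit passes
  0.444 of its clay-derived maximum
  $(20 + 1.3\,clay - 0.01\,clay^2) \times 30/23$ mm (scaled from the 23 cm
  reference depth to the simulated 30 cm), then linear down to 0.2; the
  deficit accumulates as $0.75\,PET - P$ clamped to $[0, max]$;
* cover $c$ = 0.6 under vegetation, 1.0 bare. Both land uses are treated
  as vegetated year-round except the conversion winter (November--March
  after the herbicide kill), the only bare period.

Potential evapotranspiration uses the Thornthwaite formulation
(temperature and latitude only, which is all the configuration carries),
with mid-month day lengths from solar declination.

**Initialization.** IOM is estimated by the Falloon form
$0.049\,SOC^{1.139}$. The remaining carbon is placed at the analytic
steady state of the monthly linear system under long-term mean modifiers
-- steady-state *proportions* are independent of input magnitude for a
linear model -- and scaled so pools sum exactly to the configured total.
The annual input that would hold that state stationary is returned as
`equilibrium_input`; under it and the initialization climate the 50-year
drift is far below 0.5%. Under a realistic seasonal climate the same
initialization drifts by about 1.5% over 16 years (Jensen-inequality
effects of averaging the modifiers), which is small against the
scenario signals of interest.

**Scenarios.** The continued-grassland counterfactual starts at 77 Mg C/ha
with a constant 8 Mg DM/ha annual yield. The conversion scenario starts at
78.8 Mg C/ha (including the herbicide-killed pasture input), applies a
land-use-change event in the planting spring -- a fraction (default 0.15,
config-exposed) of HUM is released to DPM/RPM, representing the
de-protection of soil organic matter by cultivation -- adds 1.5 Mg DM/ha of
killed-pasture residue in the conversion year, and follows the yield
trial's NPP schedule (1.9 Mg DM/ha in 2005 rising to the low twenties,
then 16 Mg DM/ha projected after 2016). Miscanthus NPP is defined from the
spring-harvested yield plus 33% over-winter ripening loss plus 20%
below-ground gain; the `npp_from_spring_yield()` entry point applies these
multiplicatively (the literal reading), and `npp_from_peak_yield()` covers
the peak-yield-plus-20% convention; the published NPP table itself is the
canonical input series and is accepted as given.

**Inputs to soil.** Annual NPP becomes soil carbon as
$NPP \times soil\_input\_fraction \times 0.45$ (45% C in dry matter,
conventional), spread evenly over April--October. The soil-input fraction
is the share of NPP not exported at harvest: 0.5 for a cut/grazed sward;
for Miscanthus the litter-drop share implied by the NPP definition is
$0.33/(1.33 \times 1.20) \approx 0.21$, and the default of 0.25 adds a
modest root/rhizome-turnover allowance, calibrated once so that the default
scenarios reproduce the site's observed trajectory (continued-grassland
loss near 7 Mg C/ha over 15 years, conversion loss near 12--13, end-of-life
difference near 4). These anchors are qualitative calibration targets, not
test assertions; what the tests assert are the structural properties below.

**Structural guarantees** (all enforced by tests):

* exact mass balance every month: change in total SOC equals inputs minus
  CO2 efflux, to 1e-9 Mg C/ha;
* pools stay non-negative (exponential decay by construction);
* with constant modifiers the multi-pool trajectory equals the matrix
  closed form to 1e-8, and a DPM-only state is a pure exponential;
* the land-use-change event conserves carbon exactly;
* monthly vs half-monthly stepping changes the 16-year endpoint by
  less than 0.5%;
* annual CO2 efflux increases with temperature, all else fixed.

The model deliberately has no nitrogen cycle, no water-table/anoxia
response (the 3 m water-table depth is recorded but inert) and a single
0--30 cm layer; N2O costs enter the LCA as measured constants instead.

# GWP / LCA arithmetic

The end-of-life SOC difference between the two scenarios converts as
$C \times 44/12$ to CO2 equivalents; soil N2O totals convert as
$N \times 44/28 \times GWP_{100}/1000$ with $GWP_{100} = 298$ -- the only
standard 100-year factor that jointly reproduces both published conversion
pairs (8.83 kg N2O-N/ha -> 4.13 Mg CO2-eq/ha and 7.29 -> 3.41), which the
tests verify against the alternatives 265, 296 and 310. Per-MJ intensities
divide by the lifetime feedstock energy, 180 Mg DM/ha x 17.95 GJ/Mg over
15 years; the per-Mg-DM headline multiplies the per-MJ total by the 18
GJ/Mg higher heating value. Both energy bases are explicit configuration
fields because they intentionally differ.

The summary table keeps full precision internally and also emits
display values rounded half-away-from-zero to integers, matching how such
tables are printed. Two derived quantities follow the displayed (not raw)
values because that is how the printed arithmetic works: the percentage
increase over the production chain, $(9-4)/4 = 125\%$ (the unrounded ratio
would be 103%), and the headline intensity, the displayed sum through
establishment N2O (10 g CO2-eq/MJ) times the HHV giving 180 kg CO2-eq/Mg
DM. The production-chain figure (4.4 g CO2-eq/MJ) and the fossil
comparators (59 and 121 g CO2-eq/MJ) are imported literature constants,
never computed here.

# Model evaluation statistics

For paired observed/simulated series, `rmse_percent()` and
`relative_error_percent()` express root-mean-square error and signed bias
as percentages of the observed mean; RMSE% always dominates |RE%|, and
both are scale- and permutation-invariant (property-tested over 1000
random series). The 95% confidence interval for the within/outside
verdict is t-based on measurement replicates, expressed as a percentage of
the replicate mean -- a documented convention choice, swappable, since the
field literature rarely prints the exact formula it used.

# The synthetic generator

`generate_trial()` emulates: 4 blocks x 5 hybrids x 3 core positions x 2
depth layers at three time points, with T0 coring restricted to two plots
per block (five cores each) as in the real pre-conversion campaign. Ground
truth per stratum: the C4 fraction follows
$f(t) = f_{max}(1 - e^{-rt})$ with position-specific rates (centre >
edge > inter-row) so the crop's carbon spreads outward and the positions
converge by year 12; bulk densities are the published per-layer,
per-time-point values; sample masses equal bulk density x layer volume for
an 8.5 cm corer (3% CV); delta-13C is drawn from the exact two-pool mixture
plus 0.2 permil noise; %C has a 5% CV; and below-ground biomass is
baseline + slope x f + noise in the top layer, reproducing the observed
positive biomass--C~mis~ correlation by construction. All randomness flows
through deterministic per-stratum substreams of one seed, so regeneration
is byte-identical and adding strata never perturbs existing draws.

What the generator does *not* emulate: within-plot spatial
autocorrelation beyond the three named positions, weather-driven yield
variation, depth-varying end-members, or temporal change in true SOC
concentration. Passing recovery tests therefore demonstrate the
correctness of the estimators under the stated noise model, not robustness
to every field artefact.

The climate generator produces a sinusoidal temperature cycle (exact
6.7 degC annual mean when noise is off) and monthly precipitation with a
mild winter surplus summing to 1074 mm/yr -- the cool, wet maritime
climatology of the trial site.

# Problem sizes and determinism

The test suite runs the full 16-year monthly simulations (192 steps), a
1000-year convergence loop for the fixed-point oracle, 200-seed
Monte-Carlo recovery checks and 1000-case property sweeps; everything is
seeded and completes in about a minute on one CPU. The acceptance script
(`scripts/acceptance.R`) recomputes the LCA chain, both default scenarios
and the isotope-recovery error from scratch at any seed.

# Known limitations

* The turnover parameterization is RothC-lineage, not a recalibration of
  the original site model; trajectory anchors are matched to within a few
  Mg C/ha, not digit-for-digit.
* ESM evaluation at a reference mass close to the profile's total mass
  relies on the outermost spline segment, where natural-spline curvature
  is least constrained; per-core fitting keeps this local.
* The LCA stage is a single-table arithmetic, not a full supply-chain
  model; everything upstream of the field enters through one production
  constant.
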