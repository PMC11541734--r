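---
title: "Attributing the GPP data-model discrepancy: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing the GPP data-model discrepancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gppattrib)
```

## The problem

Bottom-up ("biometric") estimates of tropical-forest gross primary
productivity (GPP) - sums of independently measured carbon-budget
components such as litterfall-derived canopy productivity, stem
respiration and fine-root productivity - can exceed satellite GPP
products and vegetation-model output by tens of percent, with West
African forests a prominent example. `gppattrib` implements a
transparent way to ask *why*: it runs one minimal light-use-efficiency
(LUE) photosynthesis model repeatedly, swapping each of its inputs
between a field-measured and a model/satellite version, so that every
increment of the data-model gap can be attributed to exactly one input.

All GPP calculations share the identity

$$\mathrm{GPP} = \mathrm{fAPAR} \times \mathrm{LUE} \times \mathrm{PPFD},$$

evaluated monthly, summed to calendar-year totals, averaged over the
study years, and reported in MgC ha^-1 yr^-1 (gC m^-2 yr^-1 times the
exact factor 0.01).

## The optimality photosynthesis model

LUE is predicted from Farquhar-von Caemmerer-Berry (FvCB) biochemistry
combined with two optimality principles.

**Least-cost ci/ca.** The ratio $\chi = c_i/c_a$ of leaf-internal to
ambient CO2 balances the unit costs of maintaining carboxylation and
transpiration capacity:

$$\xi = \sqrt{\frac{\beta\,(K + \Gamma^*)}{1.6\,\eta^*}}, \qquad
\chi = \frac{\Gamma^*}{c_a} +
\left(1 - \frac{\Gamma^*}{c_a}\right)\frac{\xi}{\xi + \sqrt{D}},$$

with $D$ the vapour pressure deficit (Pa), $K$ the effective
Michaelis-Menten coefficient, $\Gamma^*$ the photorespiratory
compensation point and $\eta^*$ the viscosity of water relative to
25 degC. At $D = 0$, $\chi = 1$ exactly (enforced explicitly so the
identity is not lost to floating-point rounding).

**Coordination.** The Rubisco-limited rate $A_C = V_{cmax}\,m_c$ and the
electron-transport-limited rate $A_J = \phi_0 I_{abs}\, m_j$ (with
$m_c = (c_i-\Gamma^*)/(c_i+K)$ and $m_j = (c_i-\Gamma^*)/(c_i+2\Gamma^*)$)
are equal under typical daytime conditions, which yields the acclimated
$V_{cmax} = \phi_0 I_{abs}\, m_j / m_c$. Accounting for the cost of
maintaining $J_{max}$ replaces $m_j$ by
$m' = m_j\sqrt{1 - (c^*/m_j)^{2/3}}$, and

$$\mathrm{LUE} = \phi_0\, m'\, M_C \quad (\mathrm{gC\ mol^{-1}\ photons}).$$

Electron transport saturates as
$J = 4\phi_0 I_{abs}\big/\sqrt{1 + (4\phi_0 I_{abs}/J_{max})^2}$ and
$A_J = (J/4)\,m_j$. This one saturating form is used *everywhere* -
forward LUE, the optimality-implied $J_{max}$, and the gas-exchange
inversion - so forward and inverse calculations are algebraically
consistent and round trips are exact.

### Parameters and defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `phi0`  | 0.05  | mol C mol^-1 photons | intrinsic quantum yield (realised, canopy scale) |
| `beta`  | 146   | -  | unit-cost ratio in the least-cost $\chi$ |
| `cstar` | 0.41  | -  | Jmax-limitation cost parameter |
| `o2_frac` | 0.20946 | - | atmospheric O2 mole fraction |
| $\Gamma^*_{25}$ | 4.332 | Pa | compensation point at 25 degC, standard pressure |
| $K_{c,25}$, $K_{o,25}$ | 39.97, 27480 | Pa | Michaelis constants at 25 degC |
| $H_a(\Gamma^*, K_c, K_o)$ | 37830, 79430, 36380 | J mol^-1 | Arrhenius activation energies |
| $H_a(V_{cmax}, J_{max}, R_d)$ | 65330, 43900, 46390 | J mol^-1 | trait temperature normalisation |

The kinetic constants live in a versioned JSON table
(`inst/extdata/kinetics.json`) and can be swapped wholesale. `phi0` is
fixed by default; `photo_params(phi0_tdep = TRUE)` enables a quadratic
temperature modulation normalised to 1 at 25 degC, for users who prefer
a temperature-dependent quantum yield. Both modes are tested; the fixed
mode is the default because it corresponds to the simplest published
calibration of this model family and the analyses here do not depend on
the distinction.

$\eta^*$ uses the Vogel pure-water viscosity correlation
$\eta = A\,10^{B/(T-C)}$ normalised at 25 degC; only the ratio enters
the model, the normalisation point is exact by construction, and the
pressure dependence of liquid viscosity is negligible over the surface
range.

**Which Vcmax does `vcmax_optimal()` return?** The default
(`method = "simple"`) is $\phi_0 I_{abs} m_j/m_c$, the coordination
value without the Jmax cost; `method = "jmax_limited"` uses $m'$
instead. The second form is the one consistent with the
Jmax-limitation-adjusted LUE, and it is the form used when constructing
"optimality-implied traits" - only with that variant do the trait-based
and optimality LUE paths coincide exactly (a property the test suite
asserts to 1e-6 relative). Both variants satisfy an exact $A_C = A_J$
coordination identity against their matching electron-transport rate
(unlimited $J$ for "simple", the implied $J_{max}$ for
"jmax_limited").

Sub-compensation conditions ($c_i \le \Gamma^*$) clamp the limitation
factors to zero rather than erroring, so cold or extremely dry months
contribute zero GPP and annual sums stay defined.

## Trait mode: from Asat/Amax to Vcmax/Jmax

Field campaigns at these sites measure two points per leaf with a gas
analyser at 2000 umol m^-2 s^-1 PPFD and 30 degC block temperature:
net assimilation at 400 umol mol^-1 CO2 (`asat`) and at
2000 umol mol^-1 CO2 (`amax`). The inversion assumes:

* `asat` is Rubisco-limited:
  $V_{cmax} = (A_{sat}+R_d)(c_i+K)/(c_i-\Gamma^*)$. With the
  respiration policy $R_d = r\,V_{cmax}$ (default $r$ = 0.015) this
  solves in closed form as $V_{cmax} = A_{sat}/(m_c - r)$.
* `amax` is electron-transport-limited; $A_J = (J/4)m_j = A_{max}+R_d$
  is solved for $J$ and the saturating form inverted for $J_{max}$.
  If the required $J$ reaches the light-limited asymptote
  $4\phi_0 I_{abs}$ the record has no solution and is flagged.
* Chamber $c_i$ is not usually printed with these two-point protocols,
  so defaults of $c_i = 0.7\,c_a$ at 400 ppm and $0.9\,c_a$ at 2000 ppm
  are used (stomatal limitation weakens at saturating CO2); measured
  `ci_sat`/`ci_max` columns override the defaults when present.
* A post-hoc check flags records whose fitted traits imply
  $A_C > A_J$ at the `asat` conditions (the Rubisco-limitation
  assumption would then have been wrong).

Rates are normalised between temperatures by Arrhenius scaling with
trait-specific activation energies; "growth temperature" is defined as
the mean temperature of the site forcing series. The community mean is
the basal-area-weighted arithmetic mean over *sun leaves only*, with
weights renormalised over the sampled species (which cover roughly 80%
of plot basal area in the emulated protocol); flagged records are
excluded and counted.

`lue_from_traits()` then evaluates $\min(A_C, A_J)/I_{abs}\times M_C$
with the measured capacities but the *optimality* $\chi$ - the same
$\chi$ in both LUE paths is what makes the trait term of the
attribution a pure capacity effect.

## Isotope-derived ci/ca

Leaf $\delta^{13}$C gives discrimination
$\Delta^{13}C = (\delta_{air}-\delta_{leaf})/(1+\delta_{leaf}/1000)$
and the simple mixing model $\Delta = a + (b-a)\chi$ inverts to
$\chi = (\Delta-a)/(b-a)$ with $a$ = 4.4 permil (diffusion) and $b$ =
27 permil (carboxylation) by default. Values outside (0, 1) are clamped
and flagged, never silently dropped. Atmospheric $\delta^{13}$C
defaults to -8 permil; a per-row column overrides it. This channel is
diagnostic (compare to `chi_optimal()`); it does not feed the GPP
experiments.

## fAPAR and cloud filtering

Satellite fAPAR retrievals carry a two-bit cloud state
(`00` clear, `01` significant cloud, `10` mixed cloud, `11` unset).
Three policies are provided: `all`, `exclude_significant` (drop `01`;
the practical product filter, since requiring `00` leaves almost no wet
season data), and `clear_only`. The retained sets are nested, so
record counts are monotone across policies for any input.

Climatologies are means per calendar month across years; missing months
stay `NA` in the climatology and are *reported*. Annual means average
the available months - deliberately no gap-filling, because at cloudy
sites gap-filling would be dominated by the dry season and hide the
bias this module exists to expose. Within the GPP experiments a missing
climatology month receives the annual mean of the available months, and
the imputation count is visible through the climatology itself. The
percent bias is
$100\,(\overline{f}_{insitu}-\overline{f}_{sat})/\overline{f}_{insitu}$
per site, averaged over sites with equal weight (per-plot weighting
would be an alternative; both conventions can be computed from the
per-site table the report returns).

## Biometric GPP

Plot GPP is the sum of its components; uncertainty propagates in
quadrature under independent errors (an optional covariance matrix
generalises this). Site GPP is the unweighted mean across plots, and
the reported site uncertainty is the mean of the plot measurement
errors - a measurement uncertainty, deliberately *not* a spatial
standard error, because plot-to-plot spread at these sites reflects
real heterogeneity rather than error in the site value.

## The attribution ledger

Five numbers per site - biometric GPP, the three model experiments
`Pmodel_PfL` (trait LUE + field fAPAR + field PPFD), `Pmodel_Pf`
(optimality LUE + field fAPAR + field PPFD), `Pmodel_P` (optimality
LUE + filtered satellite fAPAR + field PPFD) and a product GPP - give
four telescoping terms:

| term | definition | reads as |
|---|---|---|
| unresolved   | biometric - PfL | what field inputs cannot explain |
| traits       | PfL - Pf        | resolved by measured capacity |
| fapar        | Pf - P          | resolved by fAPAR source |
| optimisation | P - product     | resolved by optimality vs lookup LUE |

The terms sum to biometric - product by construction; the suite asserts
the identity to 1e-12 for random quintuples. Because every experiment
runs through one code path with only the bindings changed, swapping a
single input moves only its own term (also asserted). `Pmodel_null`
(product PPFD instead of field PPFD) is reported alongside so the PPFD
contribution is visible separately rather than folded into the
optimisation term. The product value may come from the built-in
lookup emulator or be supplied as an external site scalar (replication
mode); the ledger records which.

The lookup emulator computes
$\mathrm{LUE} = \varepsilon_{max}\cdot r(T_{min})\cdot r(D)$ with
linear ramps clamped to [0, 1], defaulting to the published
evergreen-broadleaf row of the MOD17 biome-properties table
(1.268 gC MJ^-1, converted at 4.6 mol photons MJ^-1 PAR). One honest
consequence of the conservative `phi0 = 0.05` calibration: at humid
sites the VPD ramp barely bites and the lookup LUE ceiling
(~0.28 gC mol^-1) can exceed the optimality LUE (~0.2 gC mol^-1), so
the optimisation term of the *synthetic* study can be negative. The
sign of that term is a function of the quantum-yield calibration and
site VPD, not of the code; with a higher calibrated `phi0` (~0.08) the
optimality LUE sits above the lookup value. The attribution machinery
is indifferent to the sign, and the end-to-end tests compare against
the generator's own designed truth.

## The synthetic-data generator

`generate_site()` fabricates everything the pipeline consumes for one
site, deterministically per seed. The default templates emulate a
wet-to-dry West African forest gradient: mean annual precipitation
2050/1500/1200 mm with 3/6/5 one-hectare plots; dense canopies with
weak fAPAR seasonality (means 0.96/0.94/0.92); a cloudy season with
significant-cloud probability peaking at 0.9 in August-September;
higher photosynthetic capacity at the drier sites (community Vcmax25
34/42/45 umol m^-2 s^-1, Jmax25/Vcmax25 = 1.8); monthly photon totals
around 1000-1080 mol m^-2 (roughly 33-35 mol m^-2 d^-1, a realistic
humid-tropical insolation), with photon supply scaled by month length
and reduced in cloudy months. With these conditions the designed
biometric GPP lands in the mid-30s to ~40 MgC ha^-1 yr^-1, the
magnitude reported for such forests.

Designed perturbations, all independently switchable: a clear-sky
satellite fAPAR bias (default 0.34 of truth); additional
significant-cloud contamination drawing flagged retrievals down by a
Beta(2,3) factor (mixed-cloud retrievals carry only the clear-sky
bias, so the `exclude_significant` filter recovers exactly the designed
clear-sky bias in expectation); community traits at the template level
rather than the optimality-implied level; a lookup-LUE product; and an
unresolved offset added to biometric truth (largest, 7.5 MgC ha^-1
yr^-1, at the wet template, where field studies leave the biggest
unexplained residual).

Noise model (scaled by a single `noise` multiplier): lognormal
multiplicative errors on GPP components (sdlog 0.05) with sigma set to
8% of the component value; additive normal errors on `asat`/`amax`
(sd 0.35/0.55 umol m^-2 s^-1); normal errors on in-situ fAPAR
(sd 0.012); small lognormal jitter on satellite retrievals. Species
traits scatter lognormally (sd 0.12) around the template community
mean; the generator's *truth* community mean is the realised
basal-area-weighted mean of the sampled species - the pipeline measures
those same species, so ground truth is the community that actually
exists in the data, not the target the species were drawn around.

Two deliberate idealisations matter when interpreting green tests:

* The generator knows nothing about orbital sampling, compositing
  windows, sensor degradation, or the radiative-transfer pathway from
  canopy structure to retrieved fAPAR; its "contamination" is a
  statistical stand-in. Passing tests show the *pipeline arithmetic and
  filtering logic* recover designed biases; they say nothing about how
  faithful any particular satellite product is.
* The zero-perturbation identity check (every ledger term exactly zero)
  uses a constant-climate configuration. With seasonally varying
  forcing a *fixed* community trait cannot reproduce the month-varying
  optimality LUE exactly, so the traits term would be small but
  non-zero - that residual is physically real and belongs in the trait
  term, not a numerical defect. Holding the climate constant (including
  CO2, and with photon supply proportional to month length so the
  per-second flux is month-invariant) makes the implied traits constant
  and the identity exact.

## Numerical choices

* Tolerances: algebraic identities are asserted at 1e-6 relative
  (coordination, round trips, two-path LUE) or 1e-12 absolute
  (telescoping, isotope inversion); stochastic recoveries at 5% of
  biometric GPP (ledger) or ~2 percentage points (fAPAR bias).
* Problem sizes: the study runs 3 sites x 6 years x 12 months; identity
  checks use 1000 random forcings, a 20 x 20 trait grid, 1e4 random
  ledger quintuples and a 1e5-draw Monte Carlo for the error
  propagation - sizes at which every check completes in seconds.
* Degenerate inputs: sub-compensation clamps to zero; `mj <= cstar`
  gives `mprime = 0` and hence zero LUE; Jmax inversion at the
  asymptote flags rather than extrapolates; all-missing climatologies
  error; fAPAR outside [0, 1] and malformed cloud codes are rejected at
  read time with line numbers.
* Ties/edge conventions: `amax < asat` flags the record
  (measurement-noise artefact); weights renormalise over retained
  records only; the `11` (unset) cloud state survives every policy
  except `clear_only`.

## Known limitations

Monthly time step only (no diurnal cycle, no sun/shade canopy
partitioning beyond the big-leaf absorption); no soil-moisture stress
factor; C3 physiology only; no mesophyll conductance in the inversion;
no post-photosynthetic isotope fractionation; the product emulator is a
two-ramp caricature of a satellite GPP algorithm, adequate for
factorial attribution but not for product evaluation.
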