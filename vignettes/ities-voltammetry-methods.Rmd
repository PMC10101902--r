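---
title: "Models and methods: ion-transfer voltammetry of ionizable drugs at liquid-liquid interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ion-transfer voltammetry of ionizable drugs at liquid-liquid interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itieskit)
```

`itieskit` implements the full analysis chain used to characterize and
quantify ionizable drugs — the worked examples here use nitrazepam (NIT) and
its metabolite 7-aminonitrazepam (7a-NIT) — by ion-transfer voltammetry (ITV)
at the electrified interface between two immiscible electrolyte solutions
(ITIES).  At an ITIES the "electrode reaction" is an ion crossing the
water/1,2-dichloroethane junction under an applied Galvani potential
difference, so everything measurable is controlled by the analyte's acid-base
speciation, its partitioning, and ordinary diffusion.  This vignette explains
each model, its assumptions, the tunable parameters, and the numerical
choices, in the order the pipeline uses them.

## Acid-base speciation

An ionizable drug with pKa ladder $\mathrm{p}K_{a,1} < \dots <
\mathrm{p}K_{a,n}$ has $n+1$ species, from the most protonated to the least,
adjacent species differing by one proton (charge step $-1$).  The fraction of
species $i$ at a given pH is

$$x_i = \frac{10^{L_i}}{\sum_j 10^{L_j}}, \qquad
  L_i = \sum_{k \le i} (\mathrm{pH} - \mathrm{p}K_{a,k}),\; L_0 = 0 .$$

The cumulative exponents are shifted by their maximum before exponentiation,
so fractions remain exact to machine precision even 40 pH units away from the
ladder — naive evaluation overflows beyond roughly $|\mathrm{pH} -
\mathrm{p}K_a| > 15$.  The test suite cross-checks this closed form against a
brute-force mass-balance equilibrium solver to $10^{-9}$.

```{r}
anit <- protolytic_system("7a-NIT", pka = c(2.5, 4.6, 13.1),
                          charges = c(2, 1, 0, -1))
species_fractions(anit, ph = 2)
dominance_ranges(anit)
```

The default ladders shipped in `inst/extdata/benzodiazepines.yml` use
pKa = 3.2/10.8 for nitrazepam and 2.5/4.6/13.1 for 7-aminonitrazepam.
Literature sources occasionally quote 10.6 for nitrazepam's azomethine step
and 4.8 for the metabolite's amine step; we treat those variants as rounding
or transcription noise, and in any case nothing is hard-coded — pKa values
are always user-supplied data.  Activity corrections, ionic-strength and
temperature dependence of pKa are out of scope.

## Ion partition diagrams, KD fitting and logP

The apparent (boundary) transfer potential of the protonated drug as a
function of pH follows

$$\Delta\phi(\mathrm{pH}) = \Delta\phi' + \frac{RT}{F}
  \ln\!\left[1 + 10^{\mathrm{pH}-\mathrm{p}K_a}\,(1 + K_D)\right],$$

flat at the formal transfer potential $\Delta\phi'$ below the pKa (simple
transfer of the drug cation) and rising by $\ln(10)RT/F \approx 58$ mV per pH
unit above it, where the measured current is a proton transfer facilitated by
the neutral drug partitioned into the organic phase.  The crossover condition
$10^{\mathrm{pH}-\mathrm{p}K_a}(1+K_D) = 1$ is what `mechanism_at()` reports;
a point exactly on the boundary is classified as facilitated.

Two conventions deserve a note:

* **The logarithm.**  Dimensional analysis forces the natural logarithm of
  the concentration ratio; the implementation uses `log1p` so alkaline pH
  cannot overflow.
* **KD orientation.**  $K_D$ is the distribution constant of the *neutral*
  form, taken here as organic/aqueous, so a larger $K_D$ means a more
  lipophilic neutral species (nitrazepam $K_D \approx 10$ is more lipophilic
  than 7-aminonitrazepam $K_D \approx 0.1$).  The convention is stated in the
  documentation rather than guessed at runtime.

`fit_partition_model()` fits $K_D$ (and optionally $\Delta\phi'$) to measured
(pH, potential) points by least squares.  $K_D$ is parameterized as
$\log_{10} K_D$ to keep it positive and well-scaled; for any candidate
$K_D$ the optimal $\Delta\phi'$ is the analytic mean offset, so the fit
reduces to a one-dimensional minimization solved by `optimize()` on
$\log_{10} K_D \in [-8, 8]$ to a tolerance of $10^{-10}$ — no starting values,
no convergence tuning.  Standard errors come from the Gauss-Newton
approximation at the optimum.  Fitting $\Delta\phi'$ requires at least one
point below the pKa to pin the plateau; the fit refuses to run otherwise.

The formal transfer potential maps onto lipophilicity:

$$\log P = -\frac{z F \,\Delta\phi'}{\ln(10)\,RT}.$$

```{r}
logp_from_potential(0.150, 1)  # 7a-NIT cation
logp_from_potential(0.242, 1)  # NIT cation
```

**Temperature.**  The package default is 293.15 K (20 °C).  It is the unique
temperature at which the formal potentials of 150 and 242 mV map onto logP
values of −2.58 and −4.16 simultaneously (298.15 K would give −2.54/−4.09),
and it is an ordinary lab temperature.  Temperature is a field of
`ities_conditions()` and is carried, never assumed, across modules.

## Transport: Randles-Ševčík and Saito inversions

For a reversible diffusion-limited transfer under linear diffusion the peak
current is $I_p = 0.4463\, zFAC \sqrt{zFvD/RT}$ (the 0.4463 prefactor is the
standard reversible value).  `diffusion_from_scan_rate_series()` regresses
peak current on $\sqrt{v}$ with a free intercept and inverts the slope for
$D$; the intercept is reported as a diagnostic only, since experimental
series routinely carry capacitive offsets.

At a disc-shaped micro-interface of radius $r$ the steady-state limiting
current is $I_{ss} = 4zFDCr$ (Saito), and `saito_radius()` is its exact
algebraic inverse — the capillary quality-control step that turns a measured
plateau current into a pore radius.

This module speaks CGS-molar units (cm, cm², cm² s⁻¹, mol cm⁻³, V s⁻¹, A)
because that is how diffusion coefficients and the two equations are
conventionally written; µM/µA conversions live at the I/O boundary
(`uM_to_M()`, `M_to_mol_cm3()`, …), never inside formulas.  One relevant
quirk: published area-normalized sensitivities for micro cells are sometimes
computed from inconsistent radii (a "12.5·10⁻⁶ cm" radius for a 25 µm
capillary), so `normalize_sensitivity()` always takes an explicit,
user-supplied geometry and never silently "fixes" a radius.

## Voltammogram processing

* **Segmentation** splits a triangular sweep at its potential extremum; a
  multi-cycle program uses the first cycle with a warning, and a monotone
  ramp is an error.
* **Peak extraction** subtracts a straight-line baseline fitted to (up to)
  30% of the segment immediately preceding the search window, and accepts an
  extremum only if it exceeds 3× the local noise SD.  Noise is estimated as
  the median absolute deviation (scaled by 1.4826) of the detrended baseline
  region, robust to residual slope.  Choose windows that open ~150 mV before
  the expected transfer potential: a linear baseline fitted right under the
  exponential foot of a peak extrapolates badly.
* **Wave extraction** measures the steady-state current of a micro-interface
  wave as the mean baseline-corrected current over a plateau window.  The
  baseline region is the forward segment up to 150 mV (≈ 6 RT/F) before the
  raw half-wave crossing — located on a lightly smoothed trace so noise
  cannot truncate it — where a reversible wave contributes < 0.3% of the
  plateau.  A window still sloping by more than 10% of $I_{ss}$ per 100 mV
  (or a non-positive plateau) raises a not-a-plateau error.
* **Reference correction** shifts the potential axis so the measured midpoint
  of an internal reference ion (TMA⁺ or TPrA⁺) lands on its assigned formal
  potential; currents are untouched and the shift is recorded in metadata.
* **Window width** is the largest contiguous forward-sweep interval with
  |current| below a threshold — the usable range before supporting-electrolyte
  transfer dominates (≈ 0.8 V in clean electrolyte, shrinking to ≈ 0.6 V in
  urine- or blood-like matrices).
* **Presence calls** (`detect_analyte()`) subtract a blank resampled onto the
  sample grid and call 1 when the difference within an expected-potential
  window exceeds 3× the blank's local noise SD.  This is a screening
  heuristic for qualitative matrix work, not a validated classifier; with
  independent (unpaired) noise in sample and blank its false-positive rate is
  that of a 3σ rule on the *difference* trace, so paired blanks are
  preferred.
* **Smoothing** is an optional 5-point adjacent average, off by default for
  macroscopic data.

## Calibration, LOD, standard addition

`fit_calibration()` is plain OLS; σ in the 3σ/a detection limit is the
standard error of the fitted intercept (LOQ uses 10σ/a).  No weighting, no
outlier removal — replicates are aggregated by mean with RSD reported.  The
test suite pins the whole object against a closed-form normal-equations
oracle, and pins the Monte-Carlo mean of the LOD against its exact
expectation $3\,c_4\,\mathrm{SE}(b)/a$, where $c_4$ is the small-sample mean
of the residual-SD estimator — at 8 calibration points the estimated LOD runs
about 4% below the known-σ value, which matters when validating against
simulations.

`standard_addition()` extrapolates the response line to its x-axis crossing;
$|b/a|$ is the analyte concentration in the measured solution, and the
dilution chain (dilution factor × stock volume × molar mass) converts it to
sample content.  With `volume_correction = TRUE` the cumulative addition
volumes (default 10 µL initial + 2.5 µL per addition) rescale both the added
concentrations and the signals so the x-intercept reads the undiluted sample
concentration exactly; the correction is off when reproducing a published
fit taken as given.  Worked example: the fit $y = 0.0128x + 0.1941$ has
x-intercept 15.16 µM; through a 50× dilution, 25 mL stock and M = 281.27
g/mol this is 5.33 mg of analyte.  Published contents computed from the same
intercept can differ by a few percent depending on unstated addition-volume
accounting — both conventions are available precisely for that reason.

## The synthetic voltammogram generator

The simulator replaces the potentiostat so every stage is testable offline.

**Macroscopic cell** (`simulate_macro_itv()`): one-dimensional semi-infinite
diffusion in both phases, explicit FTCS finite differences, with the
interfacial Nernst partition condition
$c_{org}(0)/c_{aq}(0) = \exp[zF(\Delta\phi - \Delta\phi')/RT]$ and flux
continuity solved at each step.  Defaults: 400 space nodes per phase,
stability number $\lambda = D\Delta t/\Delta x^2 = 0.45$ (the scheme refuses
$\lambda > 0.5$ before computing anything), domain length
$6\sqrt{D t_{total}}$ so the far field stays at bulk concentration.  The
reported current uses a three-point one-sided flux derivative (second-order
in $\Delta x$); with the default grid the simulated peak current sits within
0.1% of the Randles-Ševčík value and the peak separation within 1 mV of the
reversible $2.218\,RT/F$.  Mass across both phases is conserved to well
below 0.1% over a cycle.  Equal aqueous/organic diffusion coefficients are
the default (experimentally they differ by < 10%); per-phase values are
supported.

**Micro-interface** (`simulate_micro_itv()`): the aqueous side of the pore
mouth is modeled as a steady-state hemispherical supply with mass-transfer
coefficient $m = 4D/(\pi r)$ — whose limiting current is exactly the Saito
value — coupled through the same Nernst condition to explicit 1-D diffusion
along the capillary interior, closed at 10 pore diameters.  This single
boundary condition yields both halves of the characteristic asymmetry: a
semi-sigmoidal forward wave approaching the Saito plateau (with a half-wave
potential a few tens of mV above the formal potential, as expected when
transfer feeds a confined organic volume), and a backward linear-diffusion
peak releasing the charge accumulated in-pore.  It is an acknowledged
simplification of the true pore/bulk geometry: no 3-D bulk diffusion, no
adsorption, no uncompensated resistance.

**Background and noise**: exponential potential-window walls
$\pm A_w \exp(\pm(\Delta\phi - \phi_{wall})/\beta)$ with β = 25 mV, a
capacitive offset $\mathrm{sign}(d\Delta\phi/dt)\,C_{dl}\,v\,A$, and Gaussian
current noise.  The wall model is purely phenomenological.  Published traces
do not state noise magnitudes; the defaults used in the test suite (0.05 µA
macro, 5 pA micro) were chosen once to look like figure-scale traces and are
configuration, not claims.  Every stochastic output takes a seed and is
exactly reproducible from it; seeding is scoped, so simulations do not
disturb the caller's RNG stream.

**pH series** (`simulate_ph_series()`): apparent potentials are generated
from the boundary equation (plus optional potential noise), the transferring
cation's concentration is scaled by its speciation fraction, and points whose
boundary potential exceeds a positive window wall are marked undetectable —
reproducing the loss of the drug signal at high pH when the boundary line
runs into the background wall.

**What passing tests do and do not show.**  The generator emulates
reversible, diffusion-controlled transfer with additive Gaussian noise and
smooth backgrounds.  Real matrices add adsorption, ion pairing,
quasi-reversibility, drifting baselines and correlated noise, none of which
are modeled; parameter-recovery results on synthetic data are therefore
statements about the estimators under the stated model, not about accuracy in
blood or urine.

## Problem sizes and test design

The test suite runs the macroscopic simulator at 150–600 space nodes
(roughly 2,500–22,000 time steps) and the pore simulator at 120–150 nodes,
sizes at which the grid-convergence checks (peak current stable to 0.5% on
grid doubling, separation converging to $2.218\,RT/F$) already hold
comfortably; Monte-Carlo recovery studies use 50 replicates for the
distribution constant (2 mV potential noise, recovery within 20%), 100 for
the diffusion coefficient (2% current noise, within 5%), and 500–3,000 for
the LOD calibration studies.  All stochastic tests fix their seeds.

## Known limitations

* Reversible transfer only: no quasi-reversible or irreversible peak-shape
  corrections, no iR drop, no migration/convection.
* The binary presence caller is a stated 3σ heuristic.
* The partition module covers the cation/neutral branch of the partition
  diagram (the branch these drugs exercise); anionic branches are not
  implemented.
* Uncertainty propagation stops at the intercept standard error; no weighted
  or robust regression.
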