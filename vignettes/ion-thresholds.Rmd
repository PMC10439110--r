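---
title: "Ion thresholds for phage infection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ion thresholds for phage infection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageion)
```

# The scientific problem

Many lytic phages cannot bind or inject into their hosts unless the medium
supplies enough dissolved cations: divalent Ca²⁺/Mg²⁺ and monovalent
Na⁺/K⁺ neutralize membrane and virion charge, stabilize tail fibers and
packaged DNA, and induce receptor expression. The practical question for
terrestrial microbial ecology is quantitative: *at what ion concentration
does infection become possible, and which environments reach it?*
`phageion` answers it in four linked steps — threshold estimation from
plate assays, conversion to ionic strength, comparison against
environmental ion profiles, and mechanistic "hot spot" models of when thin
freshwaters transiently exceed the thresholds — plus an analysis track for
phage-cocktail effects on a nitrate-respiring community.

# Dose-response model

## The 4PL curve and what IC50/EC50 mean here

Normalized endpoint growth (or ammonium) $y$ against ion concentration $c$
(mM) is modeled with the four-parameter logistic

$$y(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + (c/c_{50})^{h}},$$

with hill slope $h > 0$ and half-maximal concentration $c_{50}$. In a
series measured **without** phage, $c_{50}$ is the ion's direct toxicity
threshold (IC₅₀). In a series measured **with** phage in an ion-depleted
medium (where phage cannot infect the control wells), growth suppression
appears as soon as the ion permits infection, so $c_{50}$ is the effective
concentration for lytic infection (EC₅₀). The curve family is symmetric on
the log-concentration axis; no asymmetry parameter is fitted. A 4PL rather
than a 3PL is used so that partially suppressed plateaus (bottom > 0) and
partial stimulation are representable; the choice matters little for
half-max recovery but avoids biased fits when suppression is incomplete.

Responses are first normalized by the mean of the zero-ion, no-phage
control wells (`normalize_responses()`), so 1 means control-like growth.
Zero-concentration wells never enter the regression — they only define the
normalization and the control level for the flatness rule below.

## Fitting: numerical choices

`fit_4pl()` minimizes the residual sum of squares on the
$x = \log_{10} c$ scale. Two choices make the fit fast and robust enough to
be run tens of thousands of times inside bootstrap and simulation loops:

* **Inner linearisation.** With $e = \log_{10} c_{50}$ and $h$ fixed, the
  model is linear in (bottom, top − bottom) through the basis function
  $f(x) = 1/(1 + 10^{h(x-e)})$, so the two asymptotes are profiled out by
  ordinary least squares and the nonlinear search runs over $(e, h)$ only.
* **Grid then refine.** A coarse grid (9 values of $e$ spanning the tested
  concentrations × hill ∈ {0.3, 0.5, 1, 2, 4, 8}) seeds a box-constrained
  L-BFGS-B refinement with tight tolerances (`factr = 10`,
  finite-difference step 10⁻⁷), which makes noiseless data recover the
  truth to ~10⁻⁶ relative and keeps refits deterministic.

Bounds: hill ∈ [0.2, 10]; $e$ within one decade of the tested range, so a
fitted half-max can never wander more than 10× beyond the data. Because the
grid is anchored on the data quantiles, rescaling all concentrations by $k$
rescales the fitted half-max by exactly $k$ (scale equivariance, tested).

**Direction handling.** The sign of the profiled linear slope distinguishes
inhibition (response falls with concentration) from stimulation (response
rises — the pattern seen when phage protect cells from a toxic metal such
as Al³⁺). A single optimisation therefore covers both directions and
automatically keeps the better-fitting one; `direction` is reported on the
fit.

**Degenerate series.** If all responses are equal, or the fitted dynamic
range |top − bottom| is below 20% of the control level
(`flat_threshold = 0.2`), the series is reported as `no_inhibition` with
`half_max = NA` instead of an extrapolated threshold: a half-max outside
the tested range is not an estimate, it is an artifact. Fewer than four
distinct nonzero concentrations is an error, not a sentinel. The 20% cut
is a reporting convention on normalized units — large enough to ignore
plate noise, small enough that any biologically meaningful suppression
still yields a threshold.

## Uncertainty and the shift test

`bootstrap_ci()` case-resamples the (concentration, response) points,
refits, and takes the percentile interval of the refitted half-max values
(default `n_boot = 1000`, α = 0.05; a seed is required, and the caller's
RNG stream is never disturbed). Resamples with fewer than four distinct
concentrations, failed refits, or refits that collapse below the flatness
rule count as failures; more than 50% failures aborts with an
"unstable fit" error rather than returning a meaningless interval.

`call_threshold()` compares the paired fits: the shift is *significant*
when the two percentile intervals are disjoint. This is deliberately
conservative (disjoint 95% intervals imply a far smaller pairwise error
rate) and was chosen because the assay design gives no replicate-level
pairing to support a sharper test. Classification follows:

| −phage curve | +phage curve | intervals | call |
|---|---|---|---|
| inhibits | inhibits, EC₅₀ < IC₅₀ | disjoint | `enables_infection` |
| inhibits | inhibits, EC₅₀ > IC₅₀ | disjoint | `protective` |
| inhibits | inhibits | overlap | `toxic_only` |
| flat | inhibits | — | `enables_infection` |
| inhibits | flat | — | `protective` |
| flat | flat | — | `no_inhibition` |

The two "flat on one side" rows are a design decision: a flat toxicity
curve with a clear +phage threshold is exactly the signature of an ion
that is harmless alone but required for infection, and calling it
`no_inhibition` because the −phage curve is flat would discard the most
interesting class in the screen. Under this rule `shifted` is true exactly
for the `enables_infection` and `protective` calls.

# Ionic strength

`ionic_strength()` implements the concentration-based
$I = \tfrac12 \sum_i c_i z_i^2$ in mM. Activity coefficients are **not**
applied: at the 1–700 mM range involved the concentration scale is the one
on which thresholds are compared in this field, and applying Davies/Debye–
Hückel corrections would change the numbers without changing any verdict.
Dosed cations are assumed to be chloride salts unless an explicit
`ion_species()` says otherwise (the two salts named in standard assay
protocols are chlorides); full dissociation is assumed. The ~30 mM Na⁺
background of an ion-depleted assay medium is *not* added to reported
threshold ionic strengths by default — it is a constant offset shared by
all ions, and `ec50_to_ionic_strength(..., background = )` adds it
explicitly when wanted.

# Environment comparison

`classify_environment()` is a per-ion comparison: an environment is
*permissive* for a (phage, ion) pair when its concentration is at or above
the threshold, else *limiting* with `fold_deficit = threshold /
concentration`. Equality counts as permissive because an EC₅₀ is a
half-maximal point, not a hard floor. No mixture synergy is assumed — ions
are judged one at a time, and one permissive ion suffices for the
environment-level flag (`any_permissive_ion`), since any single enabling
cation at sufficient concentration supports infection. Summaries are
ordered category-then-name so reports are reproducible.

The bundled profiles pin the two literature constants used throughout
(cytoplasmic Na⁺ 212, K⁺ 38, Ca²⁺ 0.5, Mg²⁺ 1 mM; global mean freshwater
Ca²⁺ 0.1 mM) and place the other compartments in their documented regimes;
the gut and springwater compositions are explicitly illustrative and
should be replaced by measured profiles for site-specific work.

# Hot-spot models

**Lysed-cell dilution.** A cell is a sphere of radius $r_0$ (default 1 µm)
whose cytoplasmic ions spread *evenly* through a sphere of radius $r$:
$C(r) = C_{cyto}(r_0/r)^3$. This is a mass-conservation argument, not a
Fickian steady state; it asks "out to what distance could the released
ions, however mixed, still exceed the threshold?" and therefore gives an
upper bound on the infective halo. The crossing distance has the closed
form $r_0 (C_{cyto}/T)^{1/3}$ for threshold $T < C_{cyto}$ (else $r_0$),
and the implementation is cross-checked against bisection and dense-grid
oracles to 10⁻⁹ in the tests. With cytoplasmic Na⁺ of 212 mM and a 100 mM
requirement this is ≈ 1.29 µm — phage blooms in biofilms are a
nearest-neighbour phenomenon.

**Evaporative concentration.** During drying, the concentration factor
$cf$ is the ratio of initial to remaining water volume. Conservative ions
(Na⁺, K⁺) scale as $c_0 \cdot cf$; Ca²⁺ and Mg²⁺ are capped at fixed
solubility ceilings (defaults 0.5 and 1 mM) standing in for calcium
carbonate and magnesium silicate equilibria. Fixed caps rather than full
$K_{sp}$/activity speciation are a deliberate simplification: the
controlling phases are known but their effective equilibrium constants are
water-specific, and the cap reproduces the qualitative behaviour that
matters — divalent ions stall while monovalent ions keep climbing.
Crossing factors are again closed-form ($T/c_0$ for conservative ions; 1
if already above; `NA` when the ceiling is below the threshold) and
oracle-checked. A dilute springwater with 0.1–0.3 mM Na⁺ therefore needs a
333–1000-fold concentration to reach a 100 mM Na⁺ requirement. The default
springwater composition (`na0 = 0.13` mM etc.) is an illustrative member
of the dilute granitic class, exposed as four required parameters.

# Community-function analysis

`phage_effect_by_carbon()` contrasts ammonium in minus- vs plus-cocktail
samples per carbon source with a **Welch two-sample t-test**. A per-carbon
one-way layout (rather than a pooled ANOVA) matches how each shaded
contrast is read in practice, and Welch avoids assuming equal variances
between conditions that differ in biomass. No multiple-testing correction
is applied by default (each carbon source is reported as its own
contrast); Benjamini–Hochberg is available via `p_adjust = "BH"`. The
dominant taxon is the argmax of mean minus-condition abundance with
lexicographic tie-breaking. `dnra_potential()` is the abundance-weighted
indicator of taxa carrying *both* the nitrate→nitrite and
nitrite→ammonium capabilities — by construction invariant under merging
taxa with identical flags. `nitrogen_assimilated()` converts OD600 to
biomass nitrogen with 0.3 g/L dry weight per OD unit × 12% N by weight
(= 0.036 g/L at OD 1, ≈ 2.57 mM N), for an optional total-N correction of
measured ammonium. `cocktail_ion_dose_response()` reuses the 4PL machinery
verbatim with ammonium as the response, so cocktail EC₅₀s inherit every
property established for the growth fits.

# Synthetic-data generators: what they emulate, and what not

The generators are first-class, tested code; every statistical guarantee
of the package is calibrated on them.

* `simulate_plate()` draws responses from the true 4PL curve plus Gaussian
  noise (sd = `noise_sd` × dynamic range, default 0.05) truncated at zero,
  over a 10-step 2-fold serial dilution with 2 replicates — the design
  used for all recovery and coverage simulations. Controls sit at the
  uninhibited level in *both* conditions, reflecting an ion-depleted
  medium in which phage cannot infect. Determinism is strict: one seed,
  one byte-identical table.
* `simulate_community()` depletes phage-target taxa by a survival factor
  (default 0.1) in plus-cocktail samples, computes ammonium from the
  yield-weighted *pre-renormalization* biomass (lysed cells do not produce
  ammonium, but the surviving community still renormalizes to 1 in the
  abundance table), then adds multiplicative lognormal noise to abundances
  and Gaussian noise to ammonium. Four replicates per group is the
  default, a realistic plate-experiment size.
* `environment_profiles()` and `springwater_scenario()` bundle the
  reference compartments and the evaporation scenario described above.

Not emulated: plate position effects (edge evaporation), growth kinetics
(only the endpoint is modeled), phage replication dynamics (MOI is a
label, not a simulated process), sequencing noise or compositional zeros
beyond what the lognormal perturbation produces, and real water-chemistry
covariance between ions. Passing tests on this synthetic family therefore
demonstrate correctness of the estimators under their stated noise model —
not robustness to every artifact of real plates or real 16S tables.

# Simulation sizes and test calibration

The package's own verification suite uses: 200 simulated series across the
EC₅₀ ∈ {0.1, 1, 10, 100} mM × noise ∈ {0, 0.05, 0.1} grid for half-max
recovery (median |relative bias| < 10%); 200 series × 500 bootstrap
resamples for interval coverage (target 95% ± 5); 100 random geometries
per crossing-solver-vs-brute-force check (10⁴-point log grids); 100 seeded
community runs for cocktail-effect detection and 1000 for the null
size of the Welch flag (≤ 7.5% at nominal 5%). These sizes were chosen to
make Monte Carlo error comfortably smaller than the tolerance being
checked while keeping the default test run quick.

# Known limitations

* Thresholds are single-salt; interactions between ions (synergy,
  antagonism, common-ion effects with the chloride counter-ion) are out of
  scope.
* The disjoint-CI shift test trades power for simplicity; with replicate
  pairing a permutation test would detect smaller shifts.
* The evaporation model has no pH evolution, nucleation kinetics or
  activity corrections, and the lysis model has no transport timescale —
  both are bounding geometries, not process models.
* Capability flags are inputs; the package does not call DNRA genes from
  genomes or process 16S reads.
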