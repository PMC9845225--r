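---
title: "Methods: models, estimators and design choices in oxmembrane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in oxmembrane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxmembrane)
```

`oxmembrane` quantifies how lipid peroxidation changes membrane
microviscosity, lamellar order and lateral organization. This vignette
documents the models behind each module, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and the
numerical choices made where the design was genuinely open. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

# TCSPC decay fitting and the rotor calibration

A time-correlated single-photon-counting trace is modelled as

$$\mu_k = b + s \,\big[\mathrm{IRF}(\cdot - \delta) \ast
  \textstyle\sum_i a_i e^{-t/\tau_i}\big]_k,$$

a background plus the instrument response function (IRF) convolved with a
mono- or bi-exponential decay. `fit_decay()` fits all parameters jointly:

* **Objective.** Poisson negative log-likelihood by default
  (`method = "poisson_mle"`), correct at the low counts of FLIM pixels;
  Neyman-weighted least squares (`"lsq"`) as the high-count alternative.
  On synthetic traces at 10^4 peak counts the two agree within one
  standard error (tested).
* **IRF shift** $\delta$ is a free parameter bounded to ±3 channels,
  implemented by fractional-channel linear interpolation of the measured
  IRF. Instruments drift; fixing the shift to zero biases lifetimes.
* **Fit window** starts 10 channels before the peak, so the rise carries
  information about the shift without the far pre-peak region (pure
  background) diluting the likelihood.
* **Uncertainties** come from the inverse numerical Hessian of the
  objective at the optimum (local curvature); lifetimes are reported with
  delta-method standard errors. Non-convergence and active bounds are
  flagged, never silent.

Lifetimes are mapped to microviscosity through a Förster–Hoffmann power
law $\tau = c\,\eta^{x}$ (`lifetime_to_viscosity()`, exact inverse
`viscosity_to_lifetime()`). The constants of the original published rotor
calibration are not redistributed here; the shipped
`default_calibration()` is a two-point power law anchored at
1.8 ns ↔ 159 cP and 2.1 ns ↔ 241 cP, the pure-POPC and fully peroxidized
endpoints, and `calibrate_from_pairs()` accepts any user calibration. The
anchored fit reproduces both pairs to 10⁻¹⁰ (exact two-point fit, tested).

For bi-exponential dyes the *longer* component reports on the membrane
(`select_reported_lifetime(fit, "bi_long")`); the short component tracks
the aqueous fraction of the dye. Both components float here; whether the
original instrument software fixed the short one is unknown, so a fixed
mode is deliberately not emulated.

`fit_flim_stack()` applies the same fit per pixel after square binning
((2b+1)² neighbourhood) and masks pixels whose post-binning peak count is
below `min_peak_counts` (200 for mono-, 500 for bi-exponential dyes by
convention). Binning then thresholding is equivalent to fitting pre-summed
decays (tested to 10⁻⁸ ns). Heterogeneity of the resulting lifetime
distribution is scored by `histogram_heterogeneity()`: moments plus
$\Delta\mathrm{BIC} = \mathrm{BIC}_1 - \mathrm{BIC}_2$ of one- versus
two-component Gaussian mixtures (mclust); positive values favour two
populations, the FLIM signature of coexisting membrane domains. A dip
test is not provided; the mixture score was chosen for its sensitivity at
the ~10³-pixel scale of a single vesicle rim. `map_morans_i()` adds a
rook-adjacency Moran's I with a permutation null to distinguish spatial
domains from pixel-level photon noise.

# Laurdan GP, spectral decomposition, breakpoints

`compute_gp()` integrates the spectrum over a blue and a red window
(defaults 430–450 and 480–500 nm; trapezoid rule) and reports
$(I_B - I_R)/(I_B + I_R)$. Absolute GP values depend on the band
convention in use, so the windows are arguments and are echoed in the
result. GP is scale-invariant to 10⁻¹²
(tested).

`decompose_lognormal3()` fits three Siano–Metzler asymmetric lognormal
bands — apolar (~425 nm), polar-aprotic (~450–470 nm) and polar-protic
(~480–510 nm) probe environments — by bounded Levenberg–Marquardt
(minpack.lm) with ≥ 7 jittered multistarts. Two numerical choices matter:

* **Shared asymmetry.** With three strongly overlapping bands a per-band
  asymmetry is practically unidentifiable: under 1% multiplicative noise
  it trades against the centers and moves them by 4–10 nm. One shared
  asymmetry (default; `shared_asym = FALSE` restores per-band) brings
  center errors to ~1–2 nm while leaving the noiseless fit exact.
* **Weighting.** Emission-spectrum noise is predominantly multiplicative,
  so residuals are weighted by inverse intensity, floored at 20% of the
  peak so that near-zero tails cannot dominate.

Area fractions are trapezoid integrals of the fitted bands; they conserve
the total spectral area within 1% (tested). A single-band fit that matches
the three-band residual raises a degeneracy warning.

`find_breakpoint()` detects a change of slope in GP- or intensity-versus-
temperature series — the phase-separation signature near ~50 °C — with a
continuous two-segment ("hinge") model, because the physical claim is a
gradient change, not a jump. The breakpoint is found by exhaustive search
over the data abscissae (two edge points per side excluded), compared to a
single line by an F statistic (2 extra parameters); below `alpha` the
series is declared linear and the breakpoint is `NA`. The confidence
interval is a seeded residual bootstrap and narrows with sample size
(tested).

# SAXS / WAXS

`find_bragg_peaks()` detects local maxima above a running-median baseline
(prominence ≥ 5 noise SDs), assigns integer Bragg orders relative to the
first peak, and refines each on a ±3×FWHM window with a pseudo-Voigt plus
linear local background. The repeat distance is $d = 2\pi/q_1$; higher
orders are cross-checked against $2\pi n/q_n$ and a >2% mismatch is
flagged. Full Caillé lineshape fitting is out of scope; the slope of FWHM
versus $n^2$ is reported instead as the rigidity-trend readout — in
smectic fluctuation theory stronger broadening of higher orders means
larger stack fluctuations and a softer membrane. The pseudo-Voigt was
chosen for the SAXS peaks because instrument smearing is unknown; the
WAXS chain-packing peak is fitted as a pure Lorentzian
(`fit_waxs()`, quadratic background, chain spacing $2\pi/q_c$), and a
clearly better Gaussian fit flags the residuals as non-Lorentzian.
`compare_series()` tabulates d-spacing, widths and WAXS parameters across
compositions with bootstrap SEs over replicates.

# Bilayer trajectory metrics

All pairwise computations use minimum-image distances in x, y (z is not
periodic) and are invariant under periodic translation (tested to 10⁻¹²).

* **Thickness** is the frame-averaged difference of mean phosphate z
  between leaflets. **Density profiles** are midplane-centred z histograms
  normalized per area and bin width; the integral times the box area
  returns the particle count exactly.
* **Order parameter.** $S_{cd} = \tfrac12\langle 3\cos^2\theta - 1\rangle$
  per chain-site index, θ against the bilayer normal, using consecutive
  chain-site vectors as the C–H proxy. Analytic limits (1, −0.5, 0) are
  hit exactly or within sampling error (tested).
* **Area per lipid.** Periodic 2-D Voronoi tessellation seeded at
  phosphate (x, y): each cell is built by half-plane clipping against the
  bisectors to all seeds and their 8 periodic images, nearest first, with
  a distance-based early exit. The cells tile the torus, so areas sum to
  $L_x L_y$ (machine precision; the test bound is 10⁻⁶ relative).
  Duplicate seeds are jittered by 10⁻⁶ Å with a warning.
  `apl_distribution()` scores bimodality with the same ΔBIC convention as
  the FLIM histograms.
* **Enrichment.** $E_{ij} = C_{j,\mathrm{local}}/C_{j,\mathrm{bulk}}$
  with an in-plane 12 Å neighbourhood, evaluated per leaflet and averaged
  (the `three_d` mode pools leaflets); the SE is a seeded block bootstrap
  over frames. The central molecule is excluded from its own local count,
  and for the same-species pair also from the bulk count
  ($C_{i,\mathrm{bulk}} = (N_i-1)/L_xL_y$): with the naive bulk, ideal
  mixing converges to $(N-1)/N$ rather than 1, a finite-size bias that a
  seed-averaged test reliably detects. With this pair normalization the
  ideal-mixing expectation is exactly 1, and the implementation agrees
  with a brute-force O(n²) counting oracle to 10⁻¹² (tested).
* **Snorkelling.** Fraction of peroxide proxies with
  $|z| > t \cdot (\text{thickness}/2)$, strict inequality, default
  threshold $t = 0.6$ — the value is a convention, chosen midway between
  the generator's buried (0.15) and interfacial (0.85) states; the
  measured fraction, per-molecule occupancies and mean dwell times are
  reported.
* **Diffusion.** Time- and ensemble-averaged 2-D MSD on unwrapped
  coordinates (steps ≥ box/2 are refused as wrap-ambiguous). D is
  slope/4 on lags 10–50% of the evaluated lag range, via a through-origin
  fit weighted by the inverse TAMSD sampling variance
  ($\propto \mathrm{lag}^3/(T-\mathrm{lag})$ for Brownian motion) — an
  unweighted intercept fit over the same window is dominated by the long,
  strongly correlated lags and mis-recovers planted coefficients by up to
  ~7%, versus ≤ 2.5% for the weighted form (property-tested at 5%).
  A log–log slope far from 1 flags non-diffusive motion (a ballistic
  control is tested). Note the through-origin form assumes no
  localization-noise offset, which holds for simulated coordinates; for
  offset-bearing data, fit the attached MSD curve directly.
* **Saffman–Delbrück.** $D = \frac{k_BT}{4\pi\eta_m h}
  \big(\ln(L_{sd}/r) - \gamma\big)$, $L_{sd} = \eta_m h/(2\eta_w)$, valid
  for $r < L_{sd}$. The inverse (`sd_membrane_viscosity()`) bisects on the
  physical, strictly decreasing large-viscosity branch — D(η) has a
  maximum at $L_{sd} = r\,e^{1+\gamma}$, below which no physical solution
  exists. Roundtrip identity holds to 10⁻⁸ (tested).

# The synthetic-data generators

The generators define the study conditions under which everything is
tested; their defaults are fixed, not tuning knobs.

**Decays and FLIM stacks.** Poisson counts around the IRF-convolved model,
scaled so the expected peak equals `peak_counts` (10⁴ for cuvette traces,
the usual acquisition target). The IRF is a Gaussian parameterized by
center and FWHM (0.2 ns default) — a measured IRF has no published
functional form, and a Gaussian is the standard stand-in; FWHM = 0 gives a
delta IRF for analytic tests. `gen_flim_stack()` paints angular sectors of
a vesicle rim with different lifetimes; the rim geometry is invented
plumbing for testing per-pixel fitting, not an optical model.

**Spectra.** Sums of Siano–Metzler lognormal bands (three by default at
425/460/495 nm) with multiplicative Gaussian noise.

**Scattering.** Gaussian Bragg peaks at $2\pi n/d$ with FWHM growing with
$n^2$ at a configurable rate (the Caillé-like signature), $1/n^2$
intensity decay, optional Lorentzian WAXS peak, polynomial background.

**Bilayer trajectories.** Overdamped 2-D Brownian dynamics per leaflet
(default 200 lipids per leaflet, equimolar POPC / POPC-OOH at ~63 Å² per
lipid, dt = 1 ns, 500 frames; the frame interval and length are the
package's choice — no canonical values exist — and give ≥10⁵ displacement
samples per species for diffusion tests). With `attraction_eps = 0` every
move is accepted and the planted diffusion coefficients (defaults 1.0 and
0.8 Å²/ns, a 20% decrease for the oxidized species) are exact by
construction. Interacting runs add a Metropolis acceptance on a
same-species square well (range 10 Å) *plus a soft-core exclusion for all
pairs* (diameter 7 Å ≈ the mean lipid spacing, 2 kT overlap penalty).
The exclusion is essential, not cosmetic: attracting point particles
condense but do not deplete the other species from their clusters, so
cross-enrichment would fluctuate around 1; with excluded area the dense
clusters expel the other species and $E_{ij} < 1$ robustly, which is the
physics the enrichment analysis is meant to detect. Metropolis rejection
necessarily lowers the effective D of interacting runs below the planted
values; D-recovery claims therefore apply to the non-interacting case.

Snorkelling is a two-state Markov chain in z (buried 0.15 / interfacial
0.85 of the half-thickness) with slow default rates (total 0.01 ns⁻¹)
whose stationary up-fraction equals `snorkel_fraction` (default 0.4);
the initial up-count is planted exactly (random assignment) so a single
run recovers the planted fraction within ±0.03. Chain vectors are drawn
i.i.d. per frame from an aligned/isotropic (or in-plane/isotropic, for
negative targets) mixture whose mean order parameter equals the target —
there is no intramolecular dynamics. Phosphates sit at ±thickness/2 with
1 Å thermal jitter. Units everywhere: Å, ns, cP, kT.

**What the generators do not emulate** — and hence what passing tests do
not show about real data: atomistic packing and force fields, solvent,
leaflet coupling and flip-flop, curvature, instrument afterpulsing or
detector nonlinearity in TCSPC, spectral baselines, and SAXS instrument
smearing. The generators validate the estimators, not the biology.

# Problem sizes and runtime

The shipped tests and the acceptance script run at deliberately modest
scale: 100-seed lifetime-recovery ensembles at 10⁴ peak counts, 500-frame
trajectories with 200–1000 lipids, 150-frame interacting runs with 200
lipids, ~30-pixel-wide FLIM rims. The full test suite completes in well
under a minute on one core; `scripts/acceptance.R` in a few seconds.

# Known limitations

* The Poisson MLE treats channels independently (no dead-time or
  afterpulsing model).
* The hinge breakpoint assumes one gradient change; multiple transitions
  require segmentation the package does not provide.
* Voronoi areas are assigned per leaflet from phosphate positions only;
  chain splay is not reflected in the tessellation.
* `compare_series()` bootstraps over replicate fits, not over raw
  profiles; with a single profile per composition it reports no SE.
* The Saffman–Delbrück bridge assumes a cylindrical inclusion in an
  infinite flat membrane; it is not valid near or beyond $r \ge L_{sd}$,
  where the function errors rather than extrapolating.
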