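# oxmembrane

Quantitative analysis of how lipid peroxidation remodels membranes.

Peroxidation of unsaturated phospholipids (e.g. POPC → POPC-OOH) pushes the
polar -OOH group of the oxidized acyl chain toward the water interface
("snorkelling"). Counter-intuitively this *raises* membrane microviscosity
and lateral ordering while *lowering* the stack rigidity of lamellar phases,
and it drives lateral clustering of the oxidized species even in otherwise
single-component bilayers. `oxmembrane` implements the full analysis chain
used to quantify these effects from four kinds of data, plus a synthetic-data
generator that emulates each modality with known ground truth so every stage
is testable without instrument files:

* **FLIM / TCSPC** — iterative-reconvolution fitting of photon-count decays
  (Poisson MLE or weighted least squares), per-pixel lifetime maps with
  binning and peak-count thresholds, molecular-rotor lifetime → viscosity
  conversion, and lifetime-histogram heterogeneity statistics (skewness,
  kurtosis, Gaussian-mixture ΔBIC, Moran's I).
* **Emission spectra** — Laurdan generalized polarization
  `GP = (I_B − I_R)/(I_B + I_R)`, three-lognormal (Siano–Metzler) band
  decomposition, and temperature-series breakpoint (hinge) detection.
* **X-ray scattering** — lamellar Bragg-peak analysis (`d = 2πn/q_n`,
  pseudo-Voigt refinement, order-dependent broadening as the Caillé-type
  rigidity readout) and Lorentzian WAXS chain-packing fits.
* **Bilayer trajectories** — electron-density profiles, phosphate–phosphate
  thickness, chain order parameter `S_cd = ½⟨3cos²θ − 1⟩`, periodic Voronoi
  area-per-lipid maps and bimodality, fractional enrichment
  `E_ij = C_j,local / C_j,bulk` within a 12 Å neighbourhood, snorkelling
  fraction, MSD-based lateral diffusion, and the Saffman–Delbrück bridge
  `D = k_BT/(4πη_m h)·(ln(L_sd/r) − γ)` between microviscosity and
  diffusion.

The rotor calibration follows the Förster–Hoffmann power law
`τ = c·η^x`; the shipped default is anchored so that 1.8 ns ↔ 159 cP and
2.1 ns ↔ 241 cP (pure POPC and fully peroxidized membranes respectively).

## Worked example

Fit a synthetic cuvette decay recorded to 10⁴ peak counts, convert the
lifetime to microviscosity, bridge to a diffusion coefficient, and measure
lateral clustering in an interacting two-species bilayer simulation:

```r
library(oxmembrane)

trace <- gen_decay(decay_sim_spec(lifetimes = 2.1, peak_counts = 10000,
                                  seed = 42))
fit <- fit_decay(trace, n_components = 1)
fit
#> lifetime_fit (poisson_mle, 1 component)
#>   tau1 = 2.0929 +/- 0.0038 ns (a = 1.000)
#>   shift 0.0004 ns, background 0.00, reduced chi2 0.919

tau <- select_reported_lifetime(fit, "mono")
eta <- lifetime_to_viscosity(tau, default_calibration())
sprintf("microviscosity: %.0f cP", eta)
#> "microviscosity: 239 cP"

saffman_delbruck(eta_m = eta, h = 3.24, probe_radius = 0.45)$D_um2_s
#> 2.634968   # um^2/s

traj <- gen_bilayer_traj(bilayer_sim_spec(n_per_leaflet = 100,
                                          n_frames = 150,
                                          attraction_eps = 1.2,
                                          n_chain_sites = 0, seed = 42))
en <- enrichment(traj, radius = 12, frames = seq(50, 150, by = 5),
                 n_boot = 0)
round(en$E, 2)
#>          POPC POPC-OOH
#> POPC     1.43     0.67
#> POPC-OOH 0.67     1.35
```

The fitted 2.09 ± 0.004 ns lifetime recovers the planted 2.1 ns within the
photon-noise limit; 239 cP is the corresponding microviscosity on the
anchored calibration; and the enrichment matrix shows the signature of
lateral demixing — same-species enrichment above 1, cross-species below 1.

`run_pipeline(list(seed = 1))` runs a demo over all four modalities and
returns a tidy metric table with a config hash for provenance; YAML configs
are accepted (`run_pipeline("config.yml")`).

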