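# dceflow

Absolute perfusion quantification for dynamic contrast-enhanced MRI
(DCE-MRI) with an intravascular (blood-pool) contrast agent, aimed at
low-perfused tissue such as skeletal muscle, breast, or prostate. Because a
blood-pool agent stays intravascular in healthy tissue, the tissue signal
needs no leakage term and the kinetic model reduces to flow, transit, and
vascular transport — which is what makes absolute quantification of flows
of a few mL/(min·100 cm³) feasible at all.

The package covers the whole chain from raw spoiled gradient-echo (SPGR)
signals to organ-level flow:

* **Relaxometry** — variable-flip-angle baseline mapping of `R10`/`M0`
  (`fit_vfa()`), frame-by-frame SPGR inversion of the dynamic series into
  relaxation-rate-change maps (`dynamic_delta_r1()`), optional conversion
  to concentration via the agent's relaxivity (`concentration()`, default
  19 L mmol⁻¹ s⁻¹).
* **Arterial input** — extraction from aortic voxels (`extract_aif()`),
  deterministic bolus-arrival detection (`detect_arrival()`),
  delay/dispersion correction with an exponential vascular transport
  kernel (`correct_aif()`), and the steady-state plateau statistic
  (`plateau_stat()`).
* **Kinetics** — the core estimator `dce_fit()`: one- and two-compartment
  exponential-residue models

  `Cb(t) = Σᵢ Fⁱ (CAⁱ ⊗ Hⁱ)(t)`, `Hⁱ(t) = exp(−t/Tⁱ)`,
  `CAⁱ(t) = (CA(·−Δtⁱ) ⊗ βⁱe^{−βⁱt})(t)`,

  fitted by bounded multi-start Levenberg–Marquardt least squares with
  the flows profiled out exactly (variable projection), the physical
  ordering constraint `Δtᵃ ≤ Δtᶜ`, `1/βᵃ ≤ 1/βᶜ` built into the
  parameterization, and nested-model selection by F-test
  (`f_test_select()`). `dce_fit` returns a classed object with `print`,
  `summary`, `coef`, `predict`, `plot`, `residuals`, and `simulate`
  methods; `vb = F·T` per compartment by the central volume theorem.
* **Flow integration** — per-segment perfusion × volume summed into total
  flow (`total_flow()`), inter-measurement normalization by the arterial
  plateau (`normalize_flows()`, `cₙ = wₙ/W`), validation regression
  against reference flows (`regress_validation()`), and capillary versus
  arteriolar flow attribution (`compartment_attribution()`).
* **Synthetic data** — `synth_study()` generates complete multi-subject
  studies (heterogeneous segment responsiveness, arteriolar-dominated
  flow increases, arterial plateau jitter, realistic noise), and
  `synth_phantom_4d()` renders a measurement as 4D SPGR image volumes
  (NIfTI-1 readable/writable) so the relaxometry path is testable end to
  end with no image data shipped.
* **Pipeline** — `run_measurement()` / `run_study()` orchestrate
  everything with a validated configuration (`study_config()`) and write
  deterministic CSV/JSON outputs; `inst/scripts/dceflow.R` is a thin
  command-line wrapper with `simulate` / `fit` / `study` / `all`
  subcommands.

## Worked example

Fit a noisy synthetic muscle curve with a strong, fast arteriolar
component against its arterial input:

```r
library(dceflow)

aif <- synth_aif(noise_sd = 0, seed = 1)            # ground-truth AIF
comps <- list(
  compartment_params(8.3e-4, 14, delay_s = 3,   dispersion_s = 1.5, label = "capillary"),
  compartment_params(6.67e-3, 2.5, delay_s = 0.8, dispersion_s = 0.2, label = "arteriolar"))
tissue <- synth_tissue(aif, comps, noise_sd = 0.04, seed = 21)

fit <- dce_fit(tissue, aif)    # fits 1C and 2C, F-test decides
fit
#> 2-compartment kinetic fit (41 frames, window 60 s)
#>   capillary  F =   2.01 mL/(min 100cm^3), T = 34.80 s, vb = 0.0117, delay = 8.37 s, 1/beta = 0.05 s
#>   arteriolar F =  37.03 mL/(min 100cm^3), T =  3.40 s, vb = 0.0210, delay = 0.85 s, 1/beta = 0.05 s
#>   total perfusion 39.04 mL/(min 100cm^3), rss = 0.05642
#> F-test model selection: F(4, 33) = 13.6, p = 1.2e-06 -> 2C model (alpha = 0.05)
```

The generating truth was 5 + 40 = 45 mL/(min·100 cm³) with the flow in
the fast arteriolar compartment; the F-test correctly promotes the
two-compartment model and attributes the flow to it. `plot(fit)` overlays
data, total fit, and per-compartment contributions; `summary(fit)`
tabulates per-compartment flow, transit time, blood volume, delay, and
dispersion.

A whole study, from simulation to validation statistics:

```r
study  <- synth_study(seed = 1)                      # 7 subjects, 20 measurements
result <- run_study(study, study_config(verbose = FALSE))
result$stats$corrected$pearson_r
#> [1] 0.9138917
```

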