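---
title: "Tracer-kinetic perfusion quantification with a blood-pool contrast agent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracer-kinetic perfusion quantification with a blood-pool contrast agent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(dceflow)
```

## The measurement problem

Dynamic contrast-enhanced MRI (DCE-MRI) with an intravascular ("blood-pool")
contrast agent allows absolute quantification of tissue blood flow in
low-perfused organs such as skeletal muscle, breast, or prostate. Because a
blood-pool agent does not extravasate in healthy tissue, no leakage or
permeability terms are needed: the tissue signal is purely intravascular,
and the kinetic model reduces to flow, transit, and vascular transport.

`dceflow` implements the full analysis chain:

1. **Relaxometry.** Multi-flip-angle spoiled gradient-echo (SPGR) baselines
   give voxelwise maps of the baseline relaxation rate $R_{10}$ and
   equilibrium magnetization $M_0$; the dynamic series is then inverted
   frame by frame into relaxation-rate-change maps $\Delta R_1(t)$, which
   are proportional to tracer concentration,
   $C(t) = \Delta R_1(t) / r_1$ with relaxivity
   $r_1 = 19\ \mathrm{L\,mmol^{-1}\,s^{-1}}$ for gadofosveset at 1.5 T.
   Because the proportionality is a single global scale shared by tissue
   and artery, all kinetic fitting can run directly on $\Delta R_1$ curves;
   converting both curves to concentration changes no fitted parameter
   (this is asserted by a test).
2. **Arterial input.** The arterial input function (AIF) is the mean
   $\Delta R_1$ curve over voxels fully inside the abdominal aorta. Bolus
   arrival is detected by a deterministic threshold rule; the steady-state
   plateau statistic $w_n$ (mean over 20 s starting 60 s after arrival)
   summarizes each measurement's arterial level.
3. **Kinetics.** Tissue curves are fitted with one- and two-compartment
   exponential-residue models whose per-compartment inputs are
   delay- and dispersion-corrected copies of the measured AIF; an F-test
   decides per region whether the second compartment is justified.
4. **Flow integration.** Fitted perfusion ($\mathrm{mL\,min^{-1}}$ per
   $100\ \mathrm{cm^3}$) is multiplied with segment volumes and summed into
   total flow; flows are normalized across measurements by the arterial
   plateau statistics; estimates are validated against reference flows by
   ordinary least-squares regression and Pearson correlation.

## The kinetic model

For compartment $i$ (capillary $c$, arteriolar $a$) with perfusion $F^i$
(in $\mathrm{s^{-1}}$, i.e. mL blood per mL tissue per second), mean
transit time $T^i$, bolus delay $\Delta t^i$ and dispersion time
$1/\beta^i$, the modeled tissue curve is

$$
C_b(t) \;=\; \sum_i F^i \, \big(C_A^i \otimes H^i\big)(t),
\qquad
H^i(t) = e^{-t/T^i},
$$

where each compartment input is the measured aortic curve corrected for
vascular transport,

$$
C_A^i(t) \;=\; \big(C_A^{\mathrm{est}}(\,\cdot - \Delta t^i)
  \otimes h^i\big)(t),
\qquad
h^i(t) = \beta^i e^{-\beta^i t}.
$$

The measured curve is shifted to *later* times by $\Delta t^i \ge 0$: the
muscle vasculature lies downstream of the aortic measurement site. The
fractional blood volume of each compartment follows from the central
volume theorem, $v_b^i = F^i\,T^i$, so the two-compartment tissue curve is
the volume-weighted sum of per-compartment concentrations; writing the
model directly in terms of $F^i$ avoids double-counting volume.

**Constraints.** Physically the arterioles feed the capillary bed and lie
closer to the aorta, so the arteriolar delay and dispersion can never
exceed the capillary ones. The fit enforces this by construction
(capillary delay and dispersion are parameterized as the arteriolar values
plus nonnegative increments).

## Fitting

* Curves are used as acquired at the frame interval (1.5 s); the first
  60 s of each curve enter the fit. Both curves are linearly interpolated
  once onto a 0.1 s grid, the model is evaluated on that grid, and the
  residual sum of squares is computed **at the acquired frame times only**
  (about 41 frames). Interpolated samples carry no information; counting
  them would wildly inflate the F-test's degrees of freedom.
* Estimation is bounded Levenberg-Marquardt least squares. The flows
  enter the model linearly and are profiled out exactly at every shape
  evaluation (variable projection with a tiny nonnegative least-squares
  subproblem). This removes the flow/shape trade-off directions from the
  nonlinear search, makes the one-compartment solution an exact subset of
  the two-compartment start set (guaranteeing
  $\mathrm{rss}_{2C} \le \mathrm{rss}_{1C}$), and substantially improves
  the basin structure.
* Multi-start: five deterministic Latin-hypercube points over the shape
  box (fixed seed), a deterministic transit-time ladder for the
  one-compartment model, and, for the two-compartment model, seeds derived
  from the one-compartment solution plus a seed obtained by fitting an
  exponential-residue basis to the *residual* of the one-compartment fit —
  whatever bolus the first compartment could not explain is the natural
  starting guess for the fast second compartment. The winner receives two
  polishing restarts. Identical inputs and seed give bitwise-identical
  fits.
* Model selection: $F = \frac{(\mathrm{rss}_1 - \mathrm{rss}_2)/(p_2-p_1)}
  {\mathrm{rss}_2/(n-p_2)}$ with $(p_1, p_2) = (4, 8)$ parameters and $n$
  the acquired frames in the window, order 2 chosen iff $p < 0.05$ (the
  study's general significance convention) and the rss actually improved.

### Parameter bounds and identifiability

Bounds: $F \in [0, 8.3\times10^{-2}]\ \mathrm{s^{-1}}$ (≈ 500
$\mathrm{mL\,min^{-1}(100\,cm^3)^{-1}}$, above the literature maximum for
exercising muscle), $T \in [1.5, 60]$ s, $\Delta t \in [0, 10]$ s,
$1/\beta \in [0.05, 3]$ s.

Two bounds are deliberately tighter than a naive reading of physiology
would suggest, for an identifiability reason that shapes this whole model
family. The exponential transport and residue filters *commute*, so a
compartment curve is exactly invariant under exchanging $T$ and $1/\beta$
while rescaling the flow by their ratio: $(F, T, 1/\beta)$ and
$(F\,T\beta,\ 1/\beta,\ T)$ produce the same data. The package resolves
the labeling by canonical relabeling (the larger time constant is the
transit time — residence in the tissue is slow, vascular transport fast),
which is exact and curve-preserving. Beyond the discrete swap there is a
continuous near-degeneracy: a very short transit time with heavy
dispersion mimics a long transit time at the same blood volume
$v_b = F\,T$ while the flow $v_b/T$ changes by orders of magnitude.
Admitting dispersion times of many seconds or transit times below the
frame interval therefore invites mirror solutions that reproduce the curve
but corrupt the flow. The transit-time floor of 1.5 s (one frame interval;
vascular transit through a perfused compartment is not faster) and the
dispersion cap of 3 s (transport times from the aorta to a limb inlet are
short compared with the 1.5 s frame interval) cut these mirror families
off. Even so, weak-bolus segments retain shallow local minima; the test
suite documents that a small fraction of noiseless segment fits (about
5%) lands a few percent off truth rather than at numerical zero error.
This is an identifiability property of exponential-residue deconvolution
at 1.5 s sampling, not an optimizer defect: the competing solutions differ
from truth by residuals of order $10^{-5}$ of the curve amplitude.

## Numerical choices

* **Convolution.** The exposed kernel convolution (`conv_causal`) is
  trapezoidal and second-order accurate; the exponential transport kernel
  is renormalized so that its *trapezoidal* mass is exactly 1, making
  transport mass-preserving in the same quadrature the convolution uses.
  On the fitting hot path the exponential convolutions are evaluated by an
  exact $O(n)$ recursion (`y_i = a y_{i-1} + (1-a)(x_i + x_{i-1})/2`,
  $a = e^{-\beta\,\mathrm{d}t}$, first sample exactly 0) whose DC gain is
  exactly 1 for any rate; it equals the kernel path up to the kernel's
  $e^{-8}$ truncation tail. The recursion kernels are implemented in C++
  for speed; a forced multi-start nonlinear fit per region times at about
  0.4 s.
* **Interpolation.** Linear, applied once per curve before any transport
  or fitting; fractional delays use linear interpolation between grid
  samples (implemented so that shifting and convolution commute to
  machine precision).
* **Relaxometry.** The variable-flip-angle fit is seeded by the exact
  linearization ($S/\sin\alpha$ on $S/\tan\alpha$) and refined by
  vectorized Gauss-Newton steps; degenerate voxels are masked invalid, and
  dynamic frames whose SPGR inversion is undefined
  ($S \ge M_0\sin\alpha$, or $E_1$ outside $(10^{-9}, 1-10^{-9})$) are
  masked and counted, never clipped into the curve.
* **Tie-breaks.** Multi-start winners are decided by strict rss
  improvement beyond $10^{-15}$, so ties resolve to the earlier
  (deterministic) start.

## The synthetic-study generator

No image data ship with the package; `synth_study()` generates complete
studies with the statistical structure the analysis assumes, and
`synth_phantom_4d()` renders single measurements as 4D SPGR image data for
the relaxometry path. Defaults encode the study conditions the pipeline is
designed for, chosen once:

* 7 subjects contributing up to 3 stable flow states each (20
  measurements), 8 segments with volumes summing to 5500 cm³ (the scale
  implied by a whole-limb offset perfusion of 4.7
  $\mathrm{mL\,min^{-1}(100\,cm^3)^{-1}}$ equalling 259 mL/min).
* Target total flows drawn uniformly in 142–941 mL/min (the reference
  flow-probe range), distributed over segments with heterogeneous
  responsiveness: some segments do not respond to vasodilation at all, the
  lower leg always responds most strongly, and non-muscle segments (bone,
  skin, fat) respond weakly — the increase above baseline is assigned to
  the arteriolar compartment, emulating vasodilation acting through
  fast arteriovenous shunt pathways.
* AIF: gamma-variate first pass with FWHM 10 s and peak amplitude
  60 s⁻¹ (about two orders of magnitude above the tissue curves), plus a
  recirculation plateau at 0.3 of the peak decaying with a 10 min
  half-life (a blood-pool agent persists in blood). With arterial noise
  SD 0.25 s⁻¹ this reproduces an arterial contrast-to-noise ratio of
  order 70.
* Noise: Gaussian, tissue SD 0.04 s⁻¹ and arterial SD 0.25 s⁻¹; the
  default muscle curves then carry a contrast-to-noise ratio near 9.
* Kinetics: capillary $T \sim U[8, 15]$ s, arteriolar $T \sim U[2, 3.5]$ s
  (fast shunt-like transit; this is also the regime in which the
  arteriolar bolus contribution is most distinguishable from the capillary
  response at 1.5 s sampling), capillary delays 1.5–3.5 s and dispersion
  times 0.5–1.5 s ("small compared with the temporal resolution"), with
  arteriolar values a fixed random fraction (0.25–0.7) of the capillary
  ones so the ordering constraint holds by construction.
* A per-measurement lognormal scale factor (SD 0.15 on the log scale)
  multiplies the *measured* AIF but not the tissue curves, emulating
  coil-profile and shimming differences in the arterial signal between
  measurements — exactly the artifact the plateau normalization
  ($w_n$, $W$, $c_n = w_n/W$) corrects.
* The measured AIF is emitted on the dense generation grid by default, so
  that the pipeline sees the full bolus shape and noiseless parameter
  recovery is a true round trip. `aif_sampling = "frames"` resamples it at
  the 1.5 s frame interval first, reproducing the first-pass peak
  flattening of a view-shared (k-space-sharing) acquisition — with it, the
  known upward flow bias of such acquisitions appears. The 4D phantom path
  necessarily samples the AIF at the frame rate, so its end-to-end
  recovery is tested against the looser, bias-aware tolerance.

What the generator does *not* emulate: k-space sampling and reconstruction
(only the optional frame-rate AIF resampling mimics its dominant effect),
$T_2^*$ and water-exchange effects, $B_1$/flip-angle errors, motion, or
partial-volume contamination of the arterial voxels. Passing tests
demonstrate correct recovery of the model the generator shares with the
fitter under realistic noise — they do not certify accuracy under these
additional real-data error sources.

## Problem sizes used in the shipped checks

The packaged tests fit single curves (41 frames in the window), small
noiseless studies (2–4 measurements × 3–4 segments), one full
20-measurement study at the default noise levels, and 200-replicate null
and power calibrations of the F-test; the 4D phantom is rendered at
10×10×4 voxels. These sizes make every scientific claim in the test suite
reproducible in minutes on a single core while keeping each check at the
study's stated conditions.

## Known limitations

* Flow in a compartment is identified as $v_b/T$; whenever the data
  constrain the transit time weakly (weak bolus, heavy smoothing), flow
  estimates inherit that uncertainty multiplicatively. Blood volume
  $v_b$ is far more robust than flow.
* The F-test is a global-trend tool; near the detection threshold its
  per-region decisions are noisy, and a one-compartment fit of a truly
  two-compartment region underestimates flow.
* The arrival detector assumes a quiet pre-bolus baseline; strong baseline
  drift would need a different rule.
* Voxelwise parameter maps are out of scope; the package fits
  segment-averaged curves.
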