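---
title: "Characterizing radiation damage with burn/collect experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing radiation damage with burn/collect experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaburn)
```

## The model

Global radiation damage at 100 K is well summarized by a single number: the
overall isotropic B-factor grows linearly with absorbed dose,
$B(D) = B_0 + \beta D$, so shell-mean diffracted intensities are attenuated
by $\exp(-2\,\beta D\, s^2)$ with $s = \sin\theta/\lambda = 1/(2d)$. The
decay rate $\beta$ (Å² MGy⁻¹) is close to 1 for typical protein crystals;
apparent departures from that value more often reflect beam-size or flux
mis-calibration than genuine chemistry. `betaburn` measures $\beta$ by a
*burn/collect* experiment: eleven narrow data wedges collected at
increasing accumulated dose, with deliberate "burn" irradiations between
them, followed by relative scaling and a straight-line fit of the per-wedge
B-factors against nominal dose. The linearity of that fit (its $r^2$) is
itself the main quality diagnostic.

Assumptions worth keeping in mind: isotropic decay (a single scalar $B$ per
wedge), acentric Wilson statistics within resolution shells, a dose rate
that is constant over the narrow (3–5°) rotation range, and damage
determined by accumulated dose alone (no dose-rate effects).

## Dose model

The absorbed dose rate is the power deposited in the illuminated crystal
volume divided by its mass. Deposited power is the intercepted photon flux
times the photon energy times $1 - e^{-\mu t}$ along the beam path $t$; the
linear energy-absorption coefficient $\mu$ sums, over the elements present,
photoelectric cross sections (tabulated for 20 biologically relevant
elements on a 5–25 keV grid at 0.25 keV spacing, interpolated log–log —
between absorption edges the cross sections are close to power laws in
energy, so this reproduces a much finer grid to better than 0.1%) and a
Klein–Nishina free-electron Compton energy-transfer term evaluated by
numeric angular integration. Against standard tabulations for liquid water
the model is accurate to about 4% in 10–15 keV, well within the 10%
fidelity the application needs. Fluorescence escape, near-edge structure
and depth-resolved dose fields are deliberately out of scope; photon
energies are assumed to sit away from the edges of the elements present,
as is standard practice (experiments near the Co and Se edges are run
10 eV below them).

Two beam profiles are supported. The default is a gaussian with the stated
FWHMs truncated at $\pm 3\sigma$, with the dose averaged over the
illuminated footprint (beam extent clipped by the crystal face). A uniform
top-hat of the stated sizes is selectable; it is the appropriate choice
when comparing against dose rates computed by the classic planning tools,
which modelled the beam as a top-hat — a gaussian averaged over its full
$\pm 3\sigma$ footprint spreads the same power over a much larger area and
reports a 2–3× lower *mean* rate for crystals larger than the beam. With
the top-hat profile the model reproduces published beamline dose rates for
six test-crystal setups to within 13%.

The default composition is the *average protein crystal*: 47% solvent,
0.05 sulfur atoms per amino-acid residue, 300 mM sulfur in the buffer. The
protein fraction uses a fixed average-residue stoichiometry
(C₄.₉H₇.₈N₁.₄O₁.₅ at 1.35 g/cm³); any standard average is acceptable here
because the composition correction only ever uses *ratios* of dose rates:
$\beta_{\mathrm{corrected}} = \beta / r$ with
$r = \dot D(\text{true comp}) / \dot D(\text{default comp})$. A crystal
that absorbs more than the default (bound heavy atoms, selenomethionine)
has $r > 1$ and a correspondingly smaller corrected sensitivity.

## Protocol generation

The generator takes the characterization results (dose rate, a Wilson
model $\{B_0, \text{scale}\}$ of the scattering power, detector noise
calibration, mosaicity, diffractometer limits) and emits the full cycle
sequence. The governing choices:

* **Collection dose** ≤ 0.1 MGy per cycle (default exactly 0.1), so each
  wedge perturbs the crystal negligibly relative to the burns.
* **Resolution limit**: the finest $d_{\min}$ whose predicted last-shell
  $\langle J\rangle/\langle\sigma_J\rangle$ reaches 5 within the cycle
  dose, never finer than 2.0 Å. Strong diffractors are held at 2.0 Å and
  simply enjoy higher signal-to-noise; weak ones get a coarser limit. The
  predictor evaluates the Wilson mean at the midpoint of the last shell of
  the grid that would be used at that resolution, which keeps it consistent
  with the statistic later measured on the data. If even the coarsest
  limit considered (8 Å) cannot reach the target, the protocol is declared
  infeasible rather than silently degraded.
* **Total dose**: chosen so the last resolution shell decays by a factor
  of 3 at the assumed sensitivity (default $\beta = 1$):
  $D_{\mathrm{tot}} = \ln 3 / (2\beta s_{\min}^2)$, i.e. ≈ 8.8 MGy at
  2.0 Å — one third of the Garman limit — and proportionally more for
  coarser limits (≈ 19.8 MGy at 3.0 Å). The burn dose is split into 10
  equal burns; the total is specified by the design rule, and an even
  split gives evenly spaced dose points for the linear fit.
* **Rotation**: one range (default 4°, the midpoint of the sensible 3–5°
  window) centred on the characterization angle and reused for burns, so
  the same crystal volume is damaged that is measured.
* **Frame width**: the largest divisor of the rotation range not exceeding
  $\min(1°, \max(0.1°, 1.5° - \text{mosaicity}))$ — wider mosaic spread
  leaves less angular room before neighbouring reflections overlap within
  a frame.
* **Exposure/transmission**: transmission is maximal subject to the
  per-frame minimum exposure and maximum rotation speed; when full
  transmission would overdose within those limits it is reduced, and the
  planned dose never changes with the dose rate — only exposure times and
  attenuation do.

Nominal dose stamps are assigned at the midpoint of each collecting cycle
(unbiased for a linear model); collect and burn doses both accumulate.

The schedule tolerates a misjudged sensitivity: for true $\beta$ anywhere
in $[1/3, 3] \times$ assumed, the simulated series remains monotone and
fittable ($r^2 > 0.9$ noiseless), which is the design intent behind the
factor-3 rule.

## Simulator

The simulator stands in for the beamline. It emulates: exponential
(acentric Wilson) intensities with shell means
$\mathrm{scale}_0 \exp(-2 B_0 s^2)$ on 10 equal-$s^2$ shells between 20 Å
and $d_{\min}$; deterministic decay of the *same* underlying reflection set
across wedges by $(1 + \text{drift}\cdot D)\exp(-2\beta_{\mathrm{true}} D s^2)$;
and counting noise with variance $(J g + v_b)/g^2$ for gain $g$ and
background variance $v_b$, with $\sigma_J$ set to the model standard
deviation. The gain is calibrated on expectation so the first wedge's
last-shell $\langle J\rangle/\langle\sigma_J\rangle$ hits the planning
target of 5 (closed form when $v_b = 0$; realized values fluctuate by
$\sim 1/\sqrt{n}$ per shell). Default 200 reflections per shell, the order
of a real 4° wedge of 2 Å data.

What it does *not* emulate — and therefore what passing tests cannot
certify about real data: image-level effects (spot overlap, mosaicity,
integration errors), anisotropic decay, specific chemical damage,
non-exponential intensity distributions from twinning or
pseudo-symmetry, and variations of illuminated volume with rotation.
Synthetic reflections carry sequential ids and sit at their shell's
midpoint $s^2$; since the estimator uses shell means only, within-shell
positions are immaterial, and the midpoint convention makes the
closed-form oracles exact.

## Scaling and fitting

Each wedge is reduced to shell means. Against a reference curve, the
log-ratio is linear in $s^2$:
$\ln(\bar J_w / \bar J_r) = \ln k - 2\,\Delta B\, s^2$, fitted by weighted
least squares with weights $1/\mathrm{relvar}$, where the relative variance
of a Wilson shell mean is $(1 + (\bar\sigma/\bar J)^2)/n$ summed over wedge
and reference. The reference itself is built iteratively as the
count-weighted average of all wedges brought onto a common scale, and the
per-wedge $(k_i, B_i)$ are refit until the largest $B$ change falls below
$10^{-8}$ Å² (typically 2–3 iterations). The gauge is fixed with $B_1 = 0$
and $\max_i k_i = 1$: B-factors are *relative* to the first wedge (so the
fitted intercept estimates 0, not $B_0$) and scales are normalized to
their maximum, the convention used in decay plots. Shells with
non-positive means (possible at high dose and noise) are excluded from the
log fit with a warning; the last-shell signal-to-noise is still reported
from the raw means. Two aligned positive shells are the minimum for a fit;
fewer is a degenerate-fit error.

$\beta$ is then the slope of $B_i$ versus nominal dose, by inverse-variance
weighted least squares when standard errors are available (ordinary
otherwise — the estimates agree closely since the per-wedge errors are
nearly homoscedastic). Per-position summaries report the mean and the
*population* standard deviation (divisor $n$, the convention for repeated
measurements on one sample); for a single position the spread is flagged
as undefined. Report tables round to two decimals, half away from zero.

## Numerical choices and edge cases

* Binning: wedges sharing a reflection set inherit the simulation's shell
  grid; raw tables with at most as many distinct $s^2$ values as requested
  shells are grouped by value (equal-width bins would split a discrete
  grid unevenly and bias the fit); otherwise equal-width $s^2$ bins over a
  common range, with empty bins merged into a neighbour and flagged.
* Noiseless pipelines are exact: the scaling recovers
  $B_i = \beta_{\mathrm{true}}(D_i - D_1)$ and the dose fit gives
  $r^2 = 1$ to machine precision, which the test suite uses as an oracle.
* Determinism: every stochastic step takes a seed and restores the RNG
  state; identical seeds give bit-identical outputs, including the
  serialized wedge files (17-significant-digit text).
* Simulation sizes in the shipped tests (200 reflections per shell,
  10 shells, 11 wedges; 50-seed recovery runs) were chosen to put the
  Monte-Carlo error of a recovered $\beta$ near 2% per experiment, far
  inside the 5% recovery tolerance, while keeping a full suite run in
  about a minute.

## Known limitations

The dose model reports a single volume-averaged rate (no depth resolution,
no photoelectron escape, no fluorescence escape), so very small crystals
in larger beams and strongly absorbing samples inherit the corresponding
systematic uncertainty; published dose rates are matched within tens of
percent, not exactly, and the package treats absolute dose calibration as
the beamline's job. The scaling model is isotropic: crystals with strongly
anisotropic diffraction will show systematically different last-shell
statistics depending on orientation. The estimator is a weighted
log-linear shell regression — the maximum-likelihood analogue of the
classical scaling target with the same estimand, chosen because it is
testable against closed forms; it does not implement per-reflection
outlier rejection.
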