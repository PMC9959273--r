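---
title: "Methods: DLVO force-curve analysis and chiral-nematic optics for CNC suspensions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DLVO force-curve analysis and chiral-nematic optics for CNC suspensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiralloid)
```

## The problem

Cellulose nanocrystals (CNCs) are charged, rod-like colloids that
self-assemble into cholesteric (chiral nematic) liquid crystals. In a dried
film the helix pitch $P$ sets the selectively reflected wavelength — the
film's structural colour. Oppositely charged additives (an anionic
polyelectrolyte such as sodium polyacrylate, PAAS, or a cationic
oligosaccharide such as chitosan oligosaccharide, COS) shift that colour by
changing the electrostatics between particles, and at high loading suppress
it entirely by gelling the suspension before chiral order can develop.

This package implements the quantitative chain connecting those
observations: colloid-probe AFM force curves are fitted with sphere-plate
DLVO theory to extract the Debye parameter $\kappa$, the electrostatic
interaction constant $Z$ and a *limit distance* (the separation at which
the net force profile flattens, proxying the equilibrium interparticle
spacing); QCM-D traces quantify additive adsorption via the Sauerbrey
relation; pitch/stacking relations translate interparticle geometry into
photonic-bandgap wavelengths; and phase-separation plus rheology
classification decides whether a formulation phase-separates into a chiral
phase or arrests kinetically. A seeded synthetic-data module emulates every
instrument, so the whole pipeline is exercised offline.

## The force model

For a sphere of radius $r$ against a plate at surface separation $D$ the
net DLVO force is

$$F_\mathrm{DLVO}(D) = \kappa\, r\, Z\, e^{-\kappa D}
  \;-\; \frac{A_H\, r}{6 D^2},$$

repulsion positive. The first term is the screened double-layer repulsion;
the second the non-retarded van der Waals attraction with Hamaker constant
$A_H$. Supporting relations:

* $\kappa = \sqrt{2 F^2 c_0 / (\varepsilon \varepsilon_0 R T)}$ links the
  Debye parameter to the electrolyte concentration $c_0$ (mol/m³);
* $Z = 64 \pi \varepsilon \varepsilon_0 (RT/F)^2
  \tanh^2\!\big(F \psi_\delta / 4RT\big)$ links the interaction constant to
  the Stern-layer potential $\psi_\delta$ (even in $\psi_\delta$, saturating
  for large potentials);
* $A_H$ can be estimated from the two-term Lifshitz expression over static
  dielectric constants and visible refractive indices
  (`hamaker_constant()`). The printed forms of this expression vary in
  typography across sources; the implementation follows the standard form
  whose symmetric-media reduction is
  $\frac{3}{4}kT\big(\frac{\varepsilon_1-\varepsilon_3}{\varepsilon_1+\varepsilon_3}\big)^2
  + \frac{3h\nu_e}{16\sqrt{2}}
  \frac{(n_1^2-n_3^2)^2}{(n_1^2+n_3^2)^{3/2}}$, and that reduction is
  asserted in the tests.

Conventions chosen where the field tolerates variation: $D$ is the
sphere-surface-to-plate-surface separation in nm; repulsive forces are
positive; public units are nm, nN, J, V, mol/m³, K. Defaults: $T = 298.15$
K, $\varepsilon = 78.5$ (water at 25 °C), $r = 5000$ nm (a 10 µm probe
sphere), $A_H = 3.6\times10^{-21}$ J (the literature value for cellulose
across water), $\nu_e = 3.0\times10^{15}$ Hz (a typical UV absorption
frequency; the dispersion term scales linearly with it, so it is exposed as
an input).

## Estimating $\kappa$ and $Z$ from a force curve

Over the large-distance tail the double-layer term dominates and
$\ln F$ is affine in $D$ with slope $-\kappa$ and intercept
$\ln(\kappa r Z)$. The pipeline (`loglinear_fit()`):

1. keeps the approach (extend) half of the measurement — the retract half
   carries adhesion hysteresis;
2. subtracts the *modelled* van der Waals force using the known $A_H$ and
   $r$, so the regressed quantity is the pure exponential. This matters
   quantitatively: the $D^{-2}$ attraction decays slower than the
   exponential, so its relative weight grows with distance and, left in
   place, biases the fitted $\kappa$ by 1–2% even on noiseless data. With
   `hamaker = 0` the uncorrected fit is available;
3. selects a contiguous tail: from $D \ge d_\mathrm{min}$ (default
   $2/\kappa_\mathrm{init}$, with $\kappa_\mathrm{init}$ a coarse two-point
   log-slope estimate anchored away from the noise floor) to the first
   force at or below `min_force` (default $10^{-3}$ nN). Contiguity keeps
   noise-induced sign flips from punching holes in the regression window;
4. regresses $\ln F$ on $D$: an ordinary least-squares pass followed by two
   inverse-variance reweighting iterations with weights equal to the
   squared fitted force. Additive force noise of sd $\sigma$ produces
   $\mathrm{var}(\ln F) \approx \sigma^2/F^2$, so equal weighting lets the
   noisiest far points dominate and biases $Z$ by up to ~10% at realistic
   noise; the weighted fit reduces the mean bias to a few tenths of a
   percent while remaining exact (weights inert) on noiseless data.

`refit_fixed_kappa()` repeats the intercept estimation with $\kappa$
imposed, the device used to compare $Z$ across samples measured in a common
medium. Note an imposed $\kappa$ folds each curve's $\kappa$ misfit into
the intercept (shifting $Z$ by $e^{(\kappa_\mathrm{fixed}-\kappa)\bar D}$,
roughly), so only well-separated $Z$ values keep their order under refit —
the extreme pairs do, adjacent middle pairs need not.

The *limit distance* is the largest $D$ at which $|dF/dD|$ equals a slope
threshold. The threshold default, $1.8\times10^{-3}$ nN/nm, was chosen by
evaluating the analytic slope of the published $(\kappa, Z)$ parameter sets
at their reported mean limit distances, which lands consistently in the
$1.6$–$1.9\times10^{-3}$ nN/nm range; it is a configuration parameter, not
physics. Analytic mode root-finds on the model derivative (outermost
crossing); empirical mode smooths the sampled curve with a Savitzky–Golay
filter (window 11, order 2 — unstated in the source protocols, chosen as
the mildest filter that stabilises a finite-difference slope) and scans
outward-in. Where the van der Waals slope is negligible the closed form
$D = \ln(\kappa^2 r Z / s)/\kappa$ holds and is used as the test oracle.

## Adsorption, phase behaviour, rheology

**Sauerbrey.** A rigid adsorbed film shifts a quartz crystal's resonance by
$\Delta f = -\Delta m\, n / C$ at overtone $n$; `sauerbrey_mass()` averages
$\Delta f$ over an equilibrium window (default: final 20% of the trace) and
inverts this. $C$ defaults to 17.7 ng/(cm²·Hz), the standard constant for
a 5 MHz AT-cut crystal. `specific_adsorption()` divides the areal mass by
the coating's areal mass; the default coating mass, 7.77 µg/cm², is
*inferred* by back-solving the published conversion (676 ng/cm² ↦ 87 mg/g)
and is flagged as such — it also reproduces the second published pair
(76 ng/cm² ↦ ≈10 mg/g) within rounding, which is the consistency check
available.

**Phase separation.** The anisotropic fraction is the height ratio of the
birefringent lower phase to the whole column. $C_a$ (appearance) and $C_i$
(completeness) are read off a concentration series with tolerance `tol`
(default 0.02 — appearance and completeness are judged by eye in the
laboratory protocol, so the tolerance is an operationalisation); when the
tested range does not bracket a transition the value is reported as a
one-sided bound rather than silently extrapolated.

**Rheology.** `classify_gel()` declares a gel when $G' > G''$ at every
sampled frequency, else reports the log-interpolated crossover.
`lc_viscosity_regions()` segments a steady-shear sweep into three log-log
linear pieces by exhaustive least-squares breakpoint search and labels the
slope pattern: middle slope above $-0.2$ with outer slopes below $-0.4$ is
the liquid-crystal three-region profile; a leading plateau with a thinning
final segment is Newtonian-then-thinning; otherwise simple shear thinning.
The two slope thresholds operationalise "very weak thinning" vs "shear
thinning" and are configurable; the segmentation is scale-invariant in
viscosity by construction. `kinetic_arrest_flag()` composes the
classifiers: a formulation whose lowest gel concentration is at or below
its $C_a$ arrests before chiral order can form, which is the
colour-suppression criterion.

## Optics

$\lambda = n P \sin\theta$ maps pitch to the photonic-bandgap wavelength
(defaults $n = 1.55$, $\theta = 90^\circ$: a standard CNC-film index and
normal incidence, the source protocols treating both as constant). The
stacking picture gives $P = (360/\alpha)\, d$ for cross angle $\alpha$
(degrees per adjacent layer) and centre-to-centre spacing $d$. Composing
the two yields the blue-shift contract — raising $\alpha$ or tightening $d$
can only lower $\lambda$ — which `blueshift_series()` exposes for
trajectories of $(\alpha, d)$ pairs. The dimer-scale numbers
($\alpha \approx 7^\circ$, $d \approx 3.8$ nm) give $P \approx 195$ nm,
roughly half the film-scale pitch inverted from the red film's 626 nm
reflection; the package treats this as a mechanism diagnostic, not a
film-pitch predictor, and no mapping from additive loading to $(\alpha, d)$
is attempted since none is established.

## The synthetic-data module

Generators stand in for the instruments and define the conditions under
which the pipeline is validated:

* `gen_force_curve()`: the forward model plus a short-range exponential
  contact artefact (amplitude 0.5 nN, decay 5 nm) emulating the
  steric/adsorption deviation real curves show near contact, plus additive
  Gaussian force noise (sd $2\times10^{-3}$ nN, typical colloid-probe
  scatter). The artefact is confined well below the fitted tail, and the
  tests verify it moves the fits by <0.5%.
* `gen_reference_suite()`: the seven-pair parameter table
  (`reference_pairs()`) replicated with per-curve seeds, emulating the
  100-repeats-at-10-locations protocol shape.
* `gen_qcm_trace()`: baseline → saturating adsorption → rinse →
  final plateau at `plateau_mass * (1 - rinse_drop_fraction)`, with
  $\Delta f$ noise sd 0.2 Hz.
* `gen_phase_series()`: fraction 0 below $C_a$, 1 at $C_i$, linear ramp
  between, starting at a small onset fraction (0.05) at $C_a$ itself so the
  transition is detectable on the tested grid.
* `gen_rheo_sweep()`: parametric power-law sweeps for each qualitative
  label (gel, liquid-like with crossover, three-region, simple power law)
  with mild log-normal amplitude noise.

All generators are bit-reproducible given their seed and restore the
caller's RNG state. What they deliberately do **not** emulate: instrument
drift, hysteresis, cantilever hydrodynamics, viscoelastic (non-Sauerbrey)
film response, vendor file formats, or any correlated-noise structure.
Passing tests therefore demonstrate correctness of the estimation machinery
under the stated noise model, not robustness to every artefact of real
instruments.

## Numerical choices and problem sizes

* Root finding for the limit distance brackets the outermost crossing on a
  4096-point log grid over [0.5, 2000] nm, then polishes with `uniroot` to
  $10^{-10}$; the no-crossing case names the searched interval.
* Duplicate distances on load are averaged; strictly descending traces are
  reversed; genuinely shuffled distances are an error naming the curve, on
  the grounds that shuffling indicates a parsing problem rather than an
  acquisition convention.
* Monte-Carlo checks run 100 replicates per pair; suite-scale rank checks
  use 100 curves per pair (the full protocol is 10×), sizes at which the
  standard error of the per-pair mean $\kappa$ is an order of magnitude
  below the smallest between-pair gap.
* Tolerances asserted in tests: noiseless parameter recovery to 0.1%,
  log-linear vs nonlinear least squares to 0.5%, noisy mean bias 2%
  ($\kappa$) and 5% ($Z$), Sauerbrey round trip ±1 ng/cm².

## Known limitations

Constant-potential/constant-charge boundary corrections, retarded dispersion
forces and non-DLVO short-range forces are out of scope — the short-range
regime is excluded by the tail policy, not modelled. The Hamaker calculator
implements the two-term Lifshitz estimate, not a full spectral integration,
and for cellulose–water–cellulose it lands within a factor of a few of the
literature constant used by the fitting default; the two are independent
inputs by design. $C_a$/$C_i$ are reported on the tested concentration
grid; no interpolation between tested concentrations is attempted.
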