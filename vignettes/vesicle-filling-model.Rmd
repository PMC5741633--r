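---
title: "Synaptic-vesicle filling and re-acidification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synaptic-vesicle filling and re-acidification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiclefill)
```

This vignette explains the science implemented by `vesiclefill`: how
bouton fluorescence traces are turned into kinetic and ionic quantities,
how the dual ratiometric chloride/pH sensor is calibrated and inverted,
and how the single-vesicle flux simulator is built and parameterised. It
also records the design decisions taken where the published record
leaves the design open, and the model's known limitations.

## 1. From fluorescence to luminal pH

A pHluorin-type reporter in the vesicle lumen titrates with a Hill-type
curve (pK~a~ 7.09, n~H~ 1.35). Normalizing a bouton trace so that the
resting baseline is 0 and the stimulation climax is 1 fixes the two
reference states — the resting lumen at pH 5.6 and surface reporter at
the bath pH 7.3 — and makes the normalized signal ΔF a closed-form
function of luminal pH (`deltaF_from_pH()`), with an exact algebraic
inverse (`pH_from_deltaF()`). The map is strictly increasing on pH
3–10, so the inversion is well defined; both directions are tested as a
round trip to 10^-9^.

One caveat is inherited from the underlying photophysics: at ΔF = 1/e
the printed titration parameters give pH 6.74, although the value
"about 6.4" circulates as a rule of thumb for the 1/e point. The
package follows the equations, not the rule of thumb.

A second caveat is numerical: near the basic end (pH ≳ 7.2) the
titration saturates, so small plateau-fluorescence errors translate
into large pH errors. Plateau-pH estimates for barely-recovering
boutons should be read as "no re-acidification" rather than as precise
pH values.

Re-acidification segments are fitted with a mono-exponential
`a + b exp(-t/tau)` by Levenberg–Marquardt least squares with an
analytic Jacobian; the plateau guess is the mean of the last 10% of the
segment and the initial rate comes from a log-linear regression.
Fits whose time constant exceeds three times the observed span are
reported as non-converged: a flat segment carries no identifiable decay,
and accepting such fits would turn noise into arbitrarily long time
constants. Traces with fewer than five post-stimulus frames are
rejected.

## 2. Wavelet bouton detection

Functional boutons are detected on the stimulation difference image
(mean of the last frames of the stimulation window minus the baseline
mean). The image is decomposed with the undecimated à trous B3-spline
wavelet (kernel `[1,4,6,4,1]/16`, dilation doubling per level, mirror
boundaries); the transform is exactly invertible, which the test suite
asserts on random images.

Detection thresholds each detail plane at `ld * 3 * sigma_j`. The noise
scale `sigma_j` is estimated once on the finest plane — by the median
absolute deviation, which is robust to the sparse signal there — and
propagated to coarser planes with the exact ℓ~2~ norms of the
equivalent wavelet filters (computed from the transform's impulse
response). Estimating noise per plane instead would fail on dense
bouton fields, where coarse planes are signal-dominated. The mask is
the support of the multiscale product of planes 2..k; the first plane
is noise-dominated and excluded, components smaller than 4 px
(sub-PSF) are discarded, and experiments with 50 or fewer active
boutons are rejected, matching standard practice for these recordings.
The exact thresholding rule behind the published "detection level
l~d~ = 1.0" is not reproduced in the accessible record; the MAD-scaled
multiscale product used here is a declared substitute with `ld` kept as
the user-facing scaling knob.

Per-bouton traces are component means minus the median of a local
background ring, which cancels any uniform offset (tested); components
touching the border are flagged, not dropped.

## 3. The ratiometric chloride/pH sensor

The sensor reports two excitation ratios: R~pH~ = F~488~/F~458~ (pH
arm) and R~Cl~ = F~458~/F~565~ (chloride arm). The pH arm follows a
sigmoid with limits R~A~, R~B~ and pK~a~ 7.49; the chloride arm is a
binding isotherm whose dissociation constant rises with pH (chloride
binds the protonated sensor only) and whose saturated ratio R~bound~
drifts linearly with pH with slope M = 0.061 per pH unit.

Only pK~a~, M and the ~88 mM 90%-saturation bound are published for
the vesicular sensor; the remaining constants (R~A~ = 0.4, R~B~ = 2.4,
R~free~ = 0.8, R~bound,pH0~ = 1.9, ¹K~d~^Cl^ = 9.7 mM) are synthetic
defaults chosen for simulation. ¹K~d~^Cl^ is set so that K~d~ at the
resting luminal pH 5.6 is ≈ 9.8 mM, placing 90% saturation at
≈ 88 mM — consistent with the published bound. The vesicular pH used
when inverting luminal R~Cl~ measurements is taken to be the resting
pH 5.6; this is an assumption, since the underlying pH distribution is
only reported as a histogram.

Calibration fitting is two-stage for identifiability: the pH sigmoid is
fitted on chloride-free rows first, then the chloride arm (R~free~,
R~bound,pH0~, M, ¹K~d~^Cl^) with pK~a~ fixed. Confidence intervals are
Wald intervals from the fit covariance under the multiplicative
per-ratio noise model used by the generator. One documented subtlety:
recovered [Cl⁻] at fixed R~Cl~ increases with pH only where the K~d~
growth dominates (pH ≳ 6.8 with these constants); below that, the
R~bound~ drift slightly outweighs it.

## 4. The single-vesicle flux model

The simulator integrates one newly endocytosed vesicle: a 20 × 10⁻²¹ l
lumen behind a 50 aF membrane carrying ~1.5 V-ATPase copies (≤ 200
H⁺ s⁻¹ each), ~10 VGLUT copies (≤ 20 glutamate s⁻¹ each, exporting
n~H~ = 1.5 H⁺ per glutamate, within the 1:1–1:2 coupling range) and a
channel-like anion conductance carried by the same transporter copies.

**State and fast equilibria.** The integrated state is three molecule
counts — total titratable protons, chloride, glutamate — plus
cumulative flux ledgers. Luminal buffers (engulfed HEPES pK~a~ 7.55,
histidine pK~a~ 6, TRIS pK~a~ 8.3, gluconate pK~a~ 3.7,
methanesulfonate pK~a~ −1.2, and the endogenous matrix: 13 mM histidine
pK~a~ 6 and 47 mM glutamate residues pK~a~ 4) are held at fast
equilibrium: at every derivative evaluation the pH is recovered from
the total proton content by a monotone bisection-safe root solve
(bracket pH 3–9.5, tolerance 10⁻¹⁰). Free protons are a continuous
fractional count — at pH 7.3 the lumen holds ~5 × 10⁻⁴ of one free
proton, so a discrete treatment would be meaningless. The matrix
histidine uses pK~a~ 6; attaching the glutamate-residue pK~a~ of 4 to
histidine instead would under-count the ~150 protons the stated buffer
mix binds between pH 7.3 and 6.4 (the package computes 156).

**Membrane potential.** ΔΨ is the running net charge (pumped protons −
exported protons − imported anions) times e/C. With 50 aF, one
elementary charge is worth ≈ 3.2 mV, so ~31 charges already polarise
the membrane by 100 mV: the vesicle is charge-pinned, and essentially
all transport must be electrically compensated.

**Pump.** The V-ATPase rate falls linearly to zero with a stall
variable `dpsi + 0.3 * Z * dpH` (Z the 59.2 mV Nernst slope), stalling
at 50 mV. The deliberate asymmetry — full weight on voltage, weight 0.3
on the pH gradient — is forced by the observations the model must
reproduce simultaneously: (i) under transport block at normal chloride,
the chloride-efflux potential (~+57 mV for 129.5/14 mM) must stall the
pump at neutral pH, so the voltage stall must sit below 57 mV; (ii) in
the control condition the pump must keep acidifying down to pH ≈ 5.5
under the residual ~18 mV left by the chloride equilibrium. An
equally-weighted proton-motive-force stall cannot satisfy both (57 mV
would be far below any pmf threshold consistent with pH 5.5), whereas a
voltage-dominated kinetic stall — consistent with the strong voltage
dependence of V-type pumps — satisfies both with v_stall = 50 mV and
weight 0.3.

**Exchanger.** Glutamate influx is the maximal rate times three
factors: a thermodynamic driving factor `1 − exp(ΔG/RT)` (clipped to
[0, 1]) for the full exchange cycle including both the chemical
gradients and the (1+n~H~)ΔΨ electrical term; the occupancy of a
luminal proton-binding site (pK~a~ 7.4) — the exchanger must load
luminal H⁺ to run, which prevents unphysical alkalinisation of a
neutral lumen; and an osmotic factor that ramps to zero over the last
5 mM as total luminal osmolyte anions approach the isosmotic ceiling
(1790 molecules ≈ 149 mM, within the published "up to 1800"). Setting
`n_h = 0` is allowed as a diagnostic limit (pure glutamate uniport).

**Channel.** Chloride moves down its electro-diffusive gradient with a
linear conductance–driving-force law. The conductance is inwardly
rectifying — influx into the lumen is conducted ~5× better than efflux
(ratio 0.19) — mirroring the inward rectification measured for the
plasma-membrane-targeted transporter, and transport block scales the
conductance by 0.8, reflecting the partial inhibition of the anion
current. Solute influx is subject to the same osmotic wall as the
exchanger; efflux is not.

**Integration.** `deSolve::lsoda` (rtol 10⁻⁸, atol 10⁻⁶) integrates
the three state counts and four cumulative ledgers. Charge and proton
mass balance are then algebraic identities audited by
`conservation_ledger()`; the tests require them to hold to 10⁻⁶ of one
molecule (they hold to ~10⁻¹⁰).

### Parameter provenance and calibration

Copy numbers, maximal rates, volume, capacitance, buffer lists and
solution compositions are published values. Five kinetic shape
parameters are not directly measured and were calibrated once, jointly,
so that the named scenarios reproduce the measured endpoints — control
τ ≈ 4.9 s, steady state pH ≈ 5.5 with ≈ 120 mM glutamate; uncoupled
τ ≈ 0.5 s — and were then frozen:

| parameter | default | role |
|---|---|---|
| `v_stall_mV` | 50 | pump stall voltage at zero ΔpH |
| `dph_weight` | 0.3 | ΔpH weight in the pump stall variable |
| `cl_permeability` | 1.4 ions s⁻¹ mV⁻¹ per copy | anion conductance, influx direction |
| `cl_rectification` | 0.19 | efflux/influx conductance ratio |
| `vglut_hill_pka` | 7.4 | luminal H⁺ site of the exchanger |

Auxiliary fixed choices: cytosolic pH 7.3, cytosolic chloride 14 mM
(the concentration used to mimic the cytosol in the whole-cell
measurement of the anion conductance), cytosolic glutamate 10 mM,
temperature 298 K.

With these values the control endpoint is largely *forced* by
conservation laws rather than by tuning: electroneutrality on a 50 aF
capacitance pins final glutamate at (chloride lost) + (protons
retained), and the proton retention at pH 5.5 with the stated buffers
is ≈ 19 mM — the simulator's ≈ 121 mM final glutamate for ≈ 102 mM
chloride lost is that identity in action.

### Scenarios

`flux_scenario()` provides: `control`; `rb` (transport block, normal
chloride — the lumen stays near pH 7.3 because chloride efflux clamps
ΔΨ above the pump stall); `uncoupled`/`rb_mes_hepes25` and
`rb_mes_hepes5` (block plus full methanesulfonate substitution — the
pump charges the buffers alone, an order of magnitude faster);
`gluc_hepes25/20/5` and `mes_hepes25` (substitution with active
transport); `ko` (no transporter); and the chloride titration
`cl100`–`cl10.5`. The gluconate/HEPES series is run *without* the
transport blocker, matching the buffering-capacity experiments it
represents. The end-of-run pH of that series falls monotonically as
HEPES drops from 25 to 20 to 5 mM, because the osmotic ceiling fixes
the importable charge and a smaller buffer pool then yields a lower
plateau pH.

The uncoupled scenario also closes the loop with the budget
calculators: protons bound down to the 1/e fluorescence point divided
by the maximal pump current (156/(1.5 × 200) ≈ 0.52 s) agrees with the
simulated fitted τ within 15%, and `infer_pump_rate(150, 0.5, 1.5)`
returns the ~200 s⁻¹ per-pump rate.

## 5. The synthetic-data generator

The generator emulates the features of these experiments that the
analysis depends on: a piecewise-linear fluorescence rise over the
stimulation train (200 action potentials at 20 Hz by default, i.e. a
10 s train) followed by single-exponential recovery toward a per-bouton
plateau; bouton classes (glutamatergic τ 4.9 s full recovery,
transport-inhibited plateau 0.985, GABAergic rendered on a
negative-going CypHer-like channel); rapid acid-quench masking of
surface reporter from the end of stimulation (the remaining signal
decays with the re-acidification constant above a small residual
floor); Gaussian spots (σ 1.5 px at the 2×2-binned scale) on a constant
background with Gaussian (default sd 2% of the response amplitude) or
Poisson noise; and sensor calibration tables generated from the forward
ratio model with multiplicative noise. Acquisition is at 0.5–5 Hz as in
the experiments; test fixtures use 2 Hz to keep them small.

Every artifact carries a ground-truth record (JSON-serialisable, tested
as a lossless round trip) and all randomness flows from explicit seed
arguments — identical seeds give bit-identical artifacts.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: optics beyond a Gaussian
PSF (no vignetting, bleaching, drift or chromatic offsets), camera gain
calibration, overlapping or moving boutons, endocytosis kinetics as a
separate process (rise and recovery are collapsed into the simplest
shape consistent with the measured traces), and the post-stimulus
cytosolic alkalinisation transient seen in inhibited boutons.

## 6. Known limitations

* **Slow coupled acidification under chloride substitution.** In the
  experiments, low-chloride conditions with active transport acidify
  much more slowly (τ ~ 18 s) than control, and transport block makes
  them *faster*. Reproducing that requires proton export to continue
  for tens of seconds at ~10 mM luminal chloride, which in any passive
  pump/exchanger/channel model with the published copy numbers would
  require importing several times more glutamate than the osmotic
  ceiling admits. The simulator therefore shows the opposite ordering
  (low-chloride coupled scenarios reach their endpoint faster than
  control). The plateau orderings, buffer-capacity monotonicity and the
  gluconate/methanesulfonate equivalence are reproduced; the sustained
  shunting phase is not. A transporter slip mode (proton efflux without
  net glutamate transport) could close the gap but has no published
  kinetics to constrain it.
* **Knockout re-acidification.** With the anion conductance carried by
  the transporter, deleting the transporter leaves no
  charge-compensation path and the model vesicle barely acidifies —
  unlike knockout boutons, whose fast re-acidification points to an
  additional, unidentified conductance. The `ko` scenario documents
  this honestly rather than papering over it.
* **No cation fluxes, no volume changes.** K⁺/Na⁺ movements and
  osmotic water flux are excluded by design; the osmotic ceiling is a
  hard cap rather than a swelling model.
* **Fractional copy numbers** (1.5 pumps) are deterministic rate
  scalings; the model is a mean-field description, not a stochastic
  single-molecule simulation.

## 7. Problem sizes used in the tests

The test suite runs entirely on synthetic data built at run time:
simulator scenarios of 15–60 s at 0.02–0.25 s sampling, image stacks up
to 120 × 120 px × ~100 frames with 40–55 boutons, trace populations of
100 boutons, and 10-replicate calibration refits. These sizes were
chosen so the full suite completes in well under a minute while leaving
the recovery statistics (binomial bands, CI coverage) meaningful.
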