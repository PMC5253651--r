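---
title: "Calorimetric enzyme kinetics and ITC binding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calorimetric enzyme kinetics and ITC binding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calokin)
```

`calokin` analyses two calorimetric experiment types on a product-inhibited
enzyme — here, human farnesyl pyrophosphate synthase (FPPS), which condenses
geranyl pyrophosphate (GPP) with isopentenyl pyrophosphate (IPP) to farnesyl
pyrophosphate (FPP) and is allosterically inhibited by that product. This
vignette records the models, the tunable parameters, what the simulator does
and does not emulate, and the numerical decisions a maintainer would want
explained.

## 1. From thermal power to reaction progress

A power-compensation calorimeter reports thermal power $dQ/dt$ (μcal s⁻¹).
For a reaction consuming a limiting substrate at concentration $[S]$ in a
cell of volume $V$, three relations carry the analysis:

$$\Delta H = \frac{Q_{\mathrm{total}}}{[S]_0\,V}, \qquad
[S](t) = [S]_0 - \frac{Q(t)}{\Delta H\,V}, \qquad
v(t) = \frac{1}{\Delta H\,V}\frac{dQ}{dt}.$$

Sign convention: exothermic reactions have negative $\Delta H$, negative
power excursions and negative $Q$; rates and concentrations then come out
positive with no special-casing.

**Instrument response.** The measured power is the true heat flow filtered
through a first-order response with time constant $\tau$:
$dP_{\mathrm{meas}}/dt = (P - P_{\mathrm{meas}})/\tau$. The correction
$P = P_{\mathrm{meas}} + \tau\,dP_{\mathrm{meas}}/dt$ is applied with the
derivative taken by central differences on a 5-point moving-average-smoothed
copy of the trace. Fourier deconvolution was rejected as over-engineering
for smooth enzyme-assay signals. The instrument's response time is not a
published constant for this machine class; the package default is
$\tau = 10$ s for both simulation and correction, configurable everywhere
it appears. Within roughly $2\tau$ of a sharp feature the discrete
inversion is still settling, which is why round-trip accuracy is stated
excluding the first $2\tau$.

**Baseline.** A constant offset estimated as the mean power over a stated
time window (`baseline_window`) is subtracted before integration. Drift
beyond a constant is out of scope; traces that start at the injection have
no pre-injection window and default to no correction.

**Induction period.** Data before steady-state behaviour are discarded.
Two rules are provided:

* `fixed` (default for single-run fitting): cutoff = injection end time
  + 30 s. The 30 s margin is a package choice; no numeric cutoff is
  standard.
* `auto`: the first time the smoothed power magnitude is within 2% of its
  monotone-decay trend (the running maximum taken from the right), i.e.
  the onset of post-peak decay, clamped to be no earlier than the
  injection end. The same-excess driver uses this rule because its paired
  runs differ several-fold in duration, and a fixed 30 s cutoff removes
  most of the informative substrate range of the faster run at the study
  concentrations (450 nM enzyme turns over 16 μM of substrate in about a
  minute).

**Clipping.** Noise can push the reconstructed $[S](t)$ slightly outside
$[0, [S]_0]$; values are clipped and the number of affected samples is
recorded rather than raised as an error, since noisy post-completion tails
would otherwise produce unphysical negative concentrations.

**Binning.** For display, consecutive groups of 5 points are replaced by
their means, the customary presentation for calorimetric rate data; the
trailing incomplete group is dropped. Fitting uses unbinned points: binning
is a display convention, and averaging (S, v) pairs across a curved rate
law introduces a small systematic (Jensen) bias that there is no reason to
feed into the regression.

## 2. The product-inhibition rate law

Steady-state competitive product inhibition:

$$v = \frac{V_{\max}\,[S]}{K_m\,(1 + [P]/K_p) + [S]}.$$

`fit_kinetics()` estimates $(K_m, V_{\max})$ with $K_p$ fixed at an
independently measured product dissociation constant (6 μM for FPP binding
to FPPS), reconstructing $[P] = [P]_0 + ([S]_0 - [S])$ from 1:1
stoichiometry. Fixing $K_p$ rather than fitting it is deliberate: a single
progress curve cannot usually separate $K_m$ from $K_p$, and the binding
assay measures $K_p$ directly. Fitting data generated with a finite $K_p$
under the plain Michaelis–Menten model inflates the apparent $K_m$ — a
directional bias the test suite asserts.

Numerical choices:

* unweighted least squares by default (inverse-variance weights may be
  supplied for replicate profiles);
* positivity via log-parameterization of both parameters;
  Levenberg–Marquardt refinement (`minpack.lm`);
* deterministic start: $V_{\max,0} = 1.05\,\max v$, $K_{m,0}$ = the $S$ at
  the point nearest half-maximal rate; on failure, restarts from 5
  log-spaced $K_{m,0}$ values;
* asymptotic standard errors from the Jacobian at the optimum (bootstrap
  intervals are out of scope);
* a narrow-coverage warning when the fitted $S$ values span less than 20%
  of $[S]_0$, where $K_m$ is poorly constrained;
* profiles flagged as excess-limiting-substrate designs are refused unless
  forced: high IPP binds the allylic site and acts as an apparent
  substrate inhibitor, and such data should not be regressed under this
  model. The simulator can reproduce that behaviour qualitatively by
  replacing the denominator $S$ with $S(1 + S/K_{si})$; no fitted
  $K_{si}$ exists, so the extension is simulation-only.

The turnover number is $k_{cat} = V_{\max}/[E]$ with $[E]$ in monomers,
matching the monomer convention used for the ITC cell concentrations; the
dimer's two active sites are treated as independent.

## 3. Same-excess reaction progress kinetic analysis

Two runs designed so that $[A]_0 - [B]_0$ (GPP minus IPP) is identical
traverse the same reaction coordinate: at equal remaining substrate they
differ only in accumulated product and in the number of turnovers the
catalyst has performed. If their rate-versus-substrate curves overlay,
neither product inhibition nor deactivation operates; if the later-entry
(higher-concentration) run traces lower, one of them does. A third run
spiked with the product the high run would have accumulated (defaulting to
the difference between the two substrate levels — the standard same-excess
control) discriminates: the spike restores overlay with the high run under
product inhibition but not under deactivation. `classify_inhibition()`
encodes exactly this decision table, and the simulator provides the
deactivation arm as first-order decay of $V_{\max}$ (default rate
2.5×10⁻³ s⁻¹, chosen once so a 40 μM run still approaches completion while
showing an unambiguous signature).

The absolute concentrations of the published same-excess experiment are
shown only graphically; the package defaults to $[B]_0$ = 16 and 40 μM
with excess = 24 μM, which makes the high run span the low run's full
range.

**The overlay metric.** The published judgement is visual; testing needs a
number. The metric had to satisfy two pulls: report an interpretable
relative deviation (a uniform 10% slowdown should read 0.1), yet remain
stable when rates approach zero and when profiles carry only the 50–250
one-second samples a fast reaction yields. The implementation:

* deviations $(v_2 - v_1)/v_1$ are weighted by $v_1^2$, making the rms
  exactly the relative L2 curve distance $\lVert v_2 - v_1\rVert /
  \lVert v_1\rVert$ — 0.1 for a uniform 10% offset, finite as $v \to 0$,
  and guaranteeing rms ≥ |signed mean|;
* points where the reference rate is below 20% of its in-overlap maximum
  are excluded: there the deviation is dominated by noise amplified
  through the time-constant correction (a factor of 2–3) and by the
  random-walk error that integrated power noise induces in $[S]$;
* dense profiles (≥ 20 distinct $S$ values) are represented by cubic
  smoothing splines at a deterministic, data-size-tied stiffness
  (df = n/10 clamped to [5, 8]) and compared on an even 101-point $S$
  grid inset 5% from the overlap edges, because spline estimates have
  inflated variance at their data boundary and chord interpolation of a
  concave rate law biases the comparison; sparse profiles (constructed
  examples, binned data) fall back to exact piecewise-linear
  interpolation onto the reference points;
* the verdict threshold is 0.05 rms relative deviation.

These constants were fixed from the noise budget of the simulated study
conditions (1% of peak power, 1 s sampling) and then frozen; they are all
exposed as arguments.

## 4. Single-site ITC binding

For each injection, total ligand $X$ and macromolecule $M$ in the cell
follow the standard fixed-volume perfusion bookkeeping
($M = M_0\,(1-\delta)/(1+\delta)$ and
$X = X_{syr}\,(\Delta V/V_0)/(1+\delta)$ with
$\delta = \Delta V/2V_0$); an explicit stepwise inject–mix–expel
simulation serves as the test oracle for these closed forms, not as the
production path. The bound fraction solves the Wiseman quadratic (physical
root in $[0,1]$, cross-checked against bisection on the free-ligand
equation to 10⁻⁸), cumulative heat is $n\,\Theta\,M\,\Delta H\,V_0$, and
per-injection heats include the volume-weighted displacement correction
for heat carried out with the expelled liquid.

`fit_binding()`:

* excludes the customary small first injection by default (its heat is
  corrupted by diffusion across the syringe tip during equilibration);
* starts from $\Delta H_0$ = first usable heat / moles injected,
  $K_{d,0} = M_0/10$, $n_0 = 1$; log-parameterized Levenberg–Marquardt;
* applies the low-c rule: when $c = n\,M_0/K_d < 5$ (or on request) the
  isotherm has too weak an inflection to constrain the stoichiometry, and
  $n$ is held at 1 while $(K_d, \Delta H)$ float. The threshold 5 is a
  package choice at the conservative end of the commonly quoted usable
  range; the motivating case is a weak binder at $c \approx 2.3$;
* derives $\Delta G = RT\ln K_d$ (standard state 1 mol L⁻¹,
  $R = 1.98720\times10^{-3}$ kcal mol⁻¹ K⁻¹, $K = {}^\circ C + 273.15$)
  and $T\Delta S = \Delta H - \Delta G$, which closes exactly by
  construction. Reported uncertainties are asymptotic standard errors;
  whether published ± values are s.d. or s.e.m. of triplicates is not
  modelled.

Inputs are already-integrated per-injection heats, as in the standard
instrument-software workflow; raw per-injection power peaks are not
modelled.

## 5. The synthetic-data generator

`simulate_assay()` integrates $dS/dt = -r(t)\,d(t)\,v(S, P)$ with `lsoda`
(relative tolerance 10⁻⁹, absolute tolerance $10^{-12} S_0$, maximum step
10 samples so the integrator does not overstep the sharp corner where the
substrate runs out), where $r(t)$ is a smoothstep mixing ramp over the
injection transient (default 20 s) and $d(t)$ an optional deactivation
decay. The ramp multiplies the *rate inside the ODE*, not the emitted
power: physically, catalysis begins as mixing completes, so all the
substrate still reacts and total heat equals $S_0 V \Delta H$ exactly —
a conservation the tests enforce at 0.5% — while still producing a
realistic induction period for the trimming rules to remove. Ideal power
$v\,V\,\Delta H$ is then passed through a discrete first-order filter
(exact exponential update with trapezoidal source) and additive Gaussian
power noise is applied. Sampling is 1 s by default, the fast-sampling
regime of this instrument class. Post-injection concentrations follow the
dilution by the combined volume, `injection_dilution()`; enzyme defaults
to 450 nM, the midpoint of the documented 400–500 nM range.

`simulate_titration()` emits Wiseman heats plus an optional constant
dilution offset and multiplicative heat noise, together with a paired
buffer blank for `subtract_dilution()`. Identical seeds give byte-identical
output files.

What the generator does **not** emulate: injection peak shapes and their
integration, baseline drift and thermal equilibration artefacts,
correlated (1/f) instrument noise, heat-capacity changes, stirring heat,
the two-substrate mass-action network of the full catalytic cycle (the
rate law treats the allylic substrate as saturating), and any Mg²⁺
dependence beyond distinct parameter sets. Passing recovery tests
therefore demonstrates the correctness of the analysis chain under the
stated noise model, not robustness to every artefact of real traces.

## 6. Problem sizes and determinism

The test suite runs the full pipeline at the study conditions (40 μM and
16/40 μM runs, 19-injection titrations), with seed-parameterized property
checks sized to keep the whole suite in the tens of seconds on one core:
20-seed overlay specificity, 40-seed mechanism-label recovery, 50-seed
parameter-recovery medians, 100-draw forward-model cross-checks. Every
stochastic path is seeded; generator outputs are reproducible
bit-for-bit.

## 7. Known limitations

* The kinetic model is the single-substrate reduction valid under
  saturating allylic substrate; different-excess (order-in-catalyst)
  analysis and bireactant rate laws are out of scope.
* $K_p$ is fixed, never fitted; joint fits across multiple progress
  curves are not implemented.
* The first-order instrument inversion assumes the vendor's response is
  well described by a single time constant.
* Multi-site, sequential and displacement ITC models are not provided.
* The classifier returns `"deactivation_or_mixed"` when the spiked
  control fails to restore overlay; it does not attempt to resolve
  mixtures of deactivation and product inhibition.
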