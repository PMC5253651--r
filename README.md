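# calokin

Calorimetric enzyme kinetics and isothermal titration binding analysis for
feedback-regulated enzymes, built around the experiments used to
characterize allosteric product inhibition of human farnesyl pyrophosphate
synthase (FPPS).

## What it is for

A power-compensation calorimeter (e.g. a MicroCal iTC200) can monitor an
enzyme reaction continuously: the thermal power it records is proportional
to the instantaneous reaction rate. `calokin` turns such single-injection
assay thermograms into rate-versus-substrate data and kinetic parameters,
and fits single-site binding thermodynamics from multi-injection ITC
titrations. It is aimed at anyone using reaction calorimetry to ask whether
an enzyme is inhibited by its own product.

The core relations, in the field's standard notation:

* **Thermogram conversion.** With total heat *Q* from a reaction that
  consumes limiting substrate *S*₀ in cell volume *V*, the molar reaction
  enthalpy is ΔH = *Q*/([*S*₀]·*V*). Then
  [*S*](t) = [*S*₀] − *Q*(t)/(ΔH·*V*) and the rate is
  *v*(t) = (d*Q*/dt)/(ΔH·*V*). Measured power is first deconvolved from
  the instrument's first-order response,
  *P*(t) = *P*meas(t) + τ·d*P*meas/dt, and the induction period after the
  injection is discarded.
* **Product-inhibition rate law.** Steady-state competitive product
  inhibition, *v* = *V*max·[S] / ( *K*m·(1 + [P]/*K*p) + [S] ), fitted for
  *K*m and *V*max (hence *k*cat = *V*max/[E]) with the product-affinity
  term *K*p held at an independently measured dissociation constant.
* **Same-excess reaction progress kinetic analysis.** Two runs sharing
  [A]₀ − [B]₀ traverse the same reaction coordinate; overlay of their rate
  curves excludes product inhibition and catalyst deactivation, divergence
  reveals one of them, and a product-spiked control discriminates the two.
* **Single-site ITC.** The Wiseman isotherm: the bound fraction Θ solves
  Θ² − Θ·(1 + X/(n·M) + *K*d/(n·M)) + X/(n·M) = 0, cumulative heat is
  n·Θ·M·ΔH·V₀, with the standard fixed-cell displacement bookkeeping.
  (n, *K*d, ΔH) are fitted; when c = n·M/*K*d is low the stoichiometry is
  held at 1. ΔG = RT·ln *K*d and TΔS = ΔH − ΔG are derived.

A seeded synthetic-data generator simulates both experiment types (progress
ODE + instrument response + noise; Wiseman forward model + dilution heats),
with ground-truth sidecars, so the whole pipeline is testable without
instrument files.

## Worked example

Simulate the excess-GPP single-injection assay (450 nM enzyme, 40 μM IPP
after injection, ΔH = −22.5 kcal mol⁻¹, τ = 10 s), process it, and fit the
product-inhibition model with *K*p fixed at 6 μM:

```r
library(calokin)

kin <- kinetic_params(kcat = 0.90, enzyme = 450e-9, Km = 1.1e-6,
                      Kp = 6e-6, dH_rxn = -22.5)
d   <- assay_design(enzyme = 450e-9, A0 = 400e-6, B0 = 40e-6,
                    label = "excess_GPP")
sim  <- simulate_assay(d, kin, tau = 10)
prof <- process_thermogram(sim$thermogram, tau = 10)
fit  <- fit_kinetics(prof, enzyme = 450e-9, Kp = 6e-6)
fit
#> Product-inhibition kinetic fit (Kp fixed)
#>   Km   = 1.1 +/- 3e-05 uM
#>   Vmax = 0.405 +/- 3.8e-06 uM/s
#>   kcat = 0.9 /s  ([E] = 450 nM)
#>   Kp   = 6 uM (fixed); RSS = 5.345e-20 over 445 points
```

The fitted Michaelis constant (1.1 μM) and turnover number (0.90 s⁻¹) are
the generator's ground truth, recovered through the full thermogram
pipeline. An ITC titration (1 μl + 18 × 2 μl into 204.1 μl of 100 μM
enzyme) with 2% heat noise:

```r
b    <- binding_params(n = 1.12, Kd = 5.3e-6, dH = -5.5, temp_C = 30)
titr <- simulate_titration(titration_schedule(M0 = 100e-6, X_syr = 1.5e-3),
                           b, noise = noise_model(heat_frac = 0.02, seed = 11))
fit_binding(titr$titration)
#> Single-site ITC binding fit
#>   n  = 1.133 +/- 0.007
#>   Kd = 4.86 +/- 0.28 uM
#>   dH = -5.38 +/- 0.049 kcal/mol
#>   dG = -7.37  TdS = 1.99 kcal/mol  (T = 303.15 K)
#>   c = 23.3; RSS = 0.4598 ucal^2 over 18 injections
```

Kd, ΔH and the derived ΔG/TΔS come back within the scatter expected at
this noise level; `c = 23` marks a well-conditioned titration (the fitter
automatically holds n = 1 when c < 5).

Same-excess analysis with `analyze_same_excess()` classifies simulated
mechanisms (`"none"`, `"product_inhibition"`, `"deactivation_or_mixed"`)
from the overlay of the paired rate curves and the product-spiked control.

## Command line

A thin CLI over the same functions lives at `inst/cli/calokin.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","calokin.R",package="calokin"))')" \
  simulate --out.dir runs --seed 1
```

Subcommands: `simulate`, `fit-kinetics`, `fit-binding`, `rpka`, `thermo`;
flat `key = value` config files plus `--key value` overrides
(`--show-config` prints the resolved configuration). Exit codes: 0 success,
2 validation error, 3 fit failure.

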