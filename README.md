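# mpbpk

A minimal physiologically based pharmacokinetic (mPBPK) model in R for
monoclonal antibodies and antibody fragments, for modellers who want to ask:
*given a molecule's molecular weight, net surface charge, FcRn affinity and
target affinity, what plasma and tissue kinetics should we expect?*

The body is reduced to plasma (with a nested endosomal space for the
systemic endothelium), lymph, and two lumped tissues — **tight** (brain,
muscle, skin, adipose) and **leaky** (everything else) — each split into
vascular, endosomal and interstitial sub-spaces. On top of this geometry the
model couples:

* **size** — two-pore transcapillary transport: per pore class *k* with
  relative solute size λ = a_e/r_k, steric partition Φ = (1−λ)²,
  reflection coefficient σ_k = (1−Φ)², Renkin-hindered permeability PS_k,
  and the Patlak flux J_k(1−σ_k)(C_v − C_is e^(−Pe_k))/(1 − e^(−Pe_k));
  plus size-based renal clearance CL_renal = GFR·θ(a_e) with a logistic
  sieving curve θ;
* **charge** — net charge z maps to an interstitial distribution factor
  K_p(z) (quadratic, K_p(0) = 1), a pinocytosis scaling S_pino(z), and a
  non-specific membrane binding affinity K_D,NSB(z) (monotone logistic),
  with non-specifically bound antibody internalized at S_pino·k_up;
* **FcRn** — pinocytic uptake k_up·V_e into endosomes, pH-6 FcRn binding,
  recycling CL_rec = V_e/τ of bound species, lysosomal degradation k_deg of
  the unbound;
* **target** — soluble and membrane-bound antigen with synthesis =
  baseline × degradation rate, competitive binding, and complex
  internalization (TMDD).

Reported observables are plasma concentration and volume-weighted
tight/leaky totals, C_total = (C_e·V_e + C_v·V_v + C_is·V_is)/(V_e+V_v+V_is).
The package also provides local sensitivity analysis (ΔAUC% for +20%
perturbations), multi-start nonlinear least squares with Latin-hypercube
starts minimizing the mean-normalized SSE, and a synthetic-data generator
for testing every fitting pathway. The ODE right-hand side is compiled C
(deSolve), with an identical R reference implementation cross-checked in
the tests.

## Worked example

```r
library(mpbpk)

# wild-type mouse, 150 kDa IgG, 8 mg/kg IV bolus
sc <- scenario_wildtype_mouse(dose_mg_per_kg = 8)
prof <- simulate_scenario(sc, n = 200)
prof
#> mPBPK profile: mouse / IgG-wt, 200 time points over 504 h
#>   C_plasma: 766.5 -> 200.8 nM

tc <- terminal_clearance(prof)
cat(sprintf("terminal half-life: %.0f h, clearance: %.3g L/h\n",
            log(2) / tc$kel, tc$CL))
#> terminal half-life: 309 h, clearance: 2.12e-06 L/h

c(plasma = auc(prof, "plasma"), tight = auc(prof, "tight_total"),
  leaky = auc(prof, "leaky_total"))
#> AUC plasma: 1.91e+05 nM h, tight: 3.53e+04, leaky: 7.71e+04
```

The first line of the profile is the post-bolus plasma concentration (the
1.49 nmol dose in 0.944 mL plasma, already partly mixed into tissue
vasculature on the dense grid); over 21 days the IgG falls to ~200 nM with
a terminal half-life of ~13 days, dominated by pinocytic uptake discounted
by FcRn salvage. Tissue exposures are far below plasma exposure because the
fitted reflection coefficients (σ₁ = 0.9, σ₂ = 0.86) reject most convective
transport.

Charge relations are one call:

```r
c(K_p = kp_from_charge(-4), K_D_NSB = kdnsb_from_charge(-4))
#> charge -4: K_p = 0.918, K_D_NSB = 14.64 nM
```

and a full recovery experiment (synthetic noiseless data at the calibrated
operating point, refit from 10 Latin-hypercube starts) runs in seconds:

```r
rec <- recovery_experiment("fcrn_ko", seed = 1)
rec$fit
#> mPBPK multi-start fit (10 starts, seed 1)
#>   best normalized SSE = 1.827e-14 (start 5)
#>   k_up       = 0.15  [0.001, 3]
```

With FcRn knocked out, the pinocytosis rate recalibrated to 0.15 1/h is
recovered exactly from the synthetic curves.

A thin command-line front end wraps the same functions:

```sh
exec/mpbpk two-pore --mw 150000
exec/mpbpk charge --z -4
exec/mpbpk simulate --scenario wildtype_mouse --out profile.csv
```

## Package layout

* `R/physiology.R`, `inst/extdata/*_tissues.csv` — species physiology and
  tissue lumping (editable config, not hard-coded).
* `R/compound.R` — antibody/target descriptors, Stokes radius, dose/unit
  conversions.
* `R/two_pore.R`, `inst/extdata/synthetic_glomerular_sieving.csv` —
  two-pore transport and renal sieving.
* `R/charge.R` — charge-to-parameter relations.
* `R/params.R`, `R/ode.R`, `src/mpbpk.c` — resolved parameters, state
  layout and the ODE right-hand side (R reference + compiled C).
* `R/simulate.R`, `R/scenarios.R` — solver orchestration, PK metrics,
  packaged case-study scenarios.
* `R/estimation.R`, `R/recovery.R`, `R/synthetic.R` — sensitivity,
  multi-start fitting, recovery experiments, synthetic datasets.
* `vignettes/mpbpk-methods.Rmd` — the model, assumptions, numerical
  choices and limitations in detail.
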