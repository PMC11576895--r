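---
title: "Methods: a minimal PBPK model linking antibody size, charge and binding to PK"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a minimal PBPK model linking antibody size, charge and binding to PK}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`mpbpk` implements a minimal physiologically based pharmacokinetic (mPBPK)
model for monoclonal antibodies and antibody fragments. The body is reduced
to plasma, lymph and two lumped tissues: a *tight* compartment (brain,
muscle, skin, adipose — tissues whose capillary pores exclude large
proteins) and a *leaky* compartment (all remaining tissues). Each lumped
tissue is subdivided into vascular, endosomal and interstitial sub-spaces,
and the plasma compartment carries a nested endosomal sub-space representing
the endothelium of the systemic vasculature. The state vector tracks 39
concentrations: free antibody, free soluble antigen and their complex in
plasma, lymph and tissue sub-spaces; membrane antigen and its complex, and
the non-specifically bound membrane complex, in tissue vascular spaces; and
free/FcRn-bound species in the three endosomal pools (see `state_names()`).

Processes, all first-order or mass-action:

* **Circulation.** Plasma flow `Q_i` carries antibody into each tissue
  vascular space; venous return is `Q_i - L_i`; interstitial fluid drains to
  lymph at `L_i (1 - sigma_L)` and lymph returns to plasma at `L_total`.
* **Transcapillary transport.** Vascular-to-interstitial antibody movement
  follows the two-pore formalism: convection and hindered diffusion through
  small (4.44 nm) and large (22.85 nm) pores, combined with the Patlak
  expression per pore class. The interstitial distribution volume is scaled
  by the charge-dependent factor `K_p`.
* **Pinocytosis and recycling.** Fluid-phase uptake into tissue endosomes is
  the clearance `S_pino,i * k_up * V_e,i` (endosomal-volume basis, matching
  the convention in which a literature pinocytosis rate of 0.0366 1/h is
  expressed), drawn equally from the vascular and interstitial faces of the
  endothelium; the plasma nested endosome takes up `k_up_p * V_ep` from
  plasma. At endosomal pH 6 the antibody binds FcRn (`k1on`, `k1off`);
  FcRn-bound antibody and complex are recycled with clearance
  `CL_rec = V_e / tau` (transit time `tau` = 8 min), split between the
  vascular and interstitial side by `f_rec_v`; free endosomal antibody is
  degraded at `k_deg` and free endosomal antigen/complex are catabolized
  with clearance `CL_cat`.
* **Target binding.** Soluble antigen is synthesized in plasma and tissue
  vascular spaces and eliminated first order; membrane antigen is
  synthesized in tissue vascular spaces at `T_m0 * k_p_Tm` and degraded at
  `k_p_Tm`; the membrane complex internalizes at `k_int`. Binding uses
  (`kon`, `koff`) at pH 7.4 and (`keon`, `keoff`) at pH 6. Endosomal pH is
  not a state; pH dependence enters only through which rate-constant pair a
  compartment uses.
* **Charge effects.** Net surface charge `z` maps to three parameters:
  `K_p(z)` (interpolating quadratic constrained to `K_p(0) = 1`),
  `S_pino(z)` (1 in tight tissue and for non-positive charge; linear above
  zero in leaky tissue) and the non-specific-binding dissociation constant
  `K_D,NSB(z)`. Non-specific binding to a fixed membrane pool `Rm_total`
  uses an association rate pinned to the FcRn association rate; the bound
  complex is internalized at `S_pino,i * k_up`, which is the charge-driven
  elimination route.
* **Size effects.** The Stokes radius follows the globular power law
  `a_e = 0.0483 MW^0.386`; pore-level hindrance factors, reflection
  coefficients and permeability-surface area products derive from
  `lambda = a_e / r_pore`; renal clearance is `GFR * theta(a_e)` with a
  logistic sieving curve, applied in the leaky vascular space only.

Lumped observables are volume-weighted means of the sub-space total-antibody
concentrations (endosomal, vascular, interstitial over their physical
volumes); interstitial amounts are computed with the accessible volume
`K_p * V_is` so mass is conserved when `K_p < 1`.

## Parameters, defaults, and why

Physiology ships as editable per-tissue tables (`inst/extdata/*.csv`,
compiled from standard antibody-PBPK physiology sources) that
`lump_tissues()` reduces to the two-compartment geometry; nothing numeric is
hard-coded in the model functions. Defaults chosen where the configuration
is genuinely open:

* `sigma_L = 0.2` — the common mPBPK convention for the lymphatic
  reflection coefficient.
* Endosomal volumes are 1% of tissue volume and the plasma nested endosome
  is `V_ep = 1.2e-4` L in the mouse (0.30 L in the human table). These give
  a wild-type mouse IgG terminal half-life of a few hundred hours, a
  knockout half-life an order of magnitude shorter, and a human IgG
  clearance near 0.01 L/h — the right regimes for every case study.
* `FcRn_total = 3000` nM with pH-6 affinity `K_D ~ 700` nM
  (`k1on = 0.0806` 1/nM/h, `k1off = 56.4` 1/h): endosomal FcRn is in
  excess, most uptaken antibody is salvaged, and occupancy stays below
  0.1% at the case-study doses, keeping the non-target model effectively
  linear in dose.
* `k_deg = 30` 1/h and `CL_cat = V_e / tau`: unsalvaged endosomal contents
  turn over on the endosomal transit time scale.
* `f_rec_v = 0.5`: recycling is directed to both the vascular and the
  interstitial space; no split is stated in the source literature, so an
  even split is used and exposed as a parameter. The uptake side split
  `f_up_v` is handled identically.
* Pore radii 4.44/22.85 nm with `alpha_large = 0.042`. (The radii sometimes
  quoted as "40 nm/220 nm" are inconsistent with a ~4.8 nm IgG being almost
  completely excluded by small pores; the Å-scale values standard in the
  two-pore literature are used.) Pore areas per unit path derive from the
  hydraulic conductance `LpS = L_i / dP` (net filtration pressure
  `dP = 6 mmHg` by default) split by fractional conductance and Poiseuille
  scaling `alpha_k / r_k^2`; free diffusivity is Stokes–Einstein at 310 K.
  The isogravimetric circular flow defaults to 0, so per-class fluid flows
  are `alpha_k L_i` and always sum to `L_i`.
* Calibrated operating points shipped with the scenarios: wild-type mouse
  `k_up = 0.0276`, `k_up_p = 0.05`, `sigma_1 = 0.9`, `sigma_2 = 0.86`;
  knockout `k_up = 0.15`; charge variants `Rm_total = 71.86` nM with
  `K_D,NSB` = 16.22/8.35/1.21 nM and `K_p` = 0.62/1/0.8 at z = -8/0/+5,
  `S_pino,leaky(+5) = 2.99`; anti-CEA `k_int = 0.015` 1/h with an 80 nM
  membrane baseline and 36 h half-life; human anti-TNF with a 0.276 pM
  soluble baseline and 8.316 L/h target clearance. User-supplied effective
  reflection coefficients take precedence over two-pore-derived values
  (they are what the tissue data identify); when supplied, transport runs
  through a single effective pathway with `J = L_i` and the summed
  permeability.

### The K_D,NSB(z) functional form

An exact quadratic through the three charge anchors becomes negative just
above z = +5, and a quadratic in log space loses monotonicity below
z ≈ -6, so neither satisfies "positive and strictly decreasing over
[-10, +10]". The packaged form is a three-parameter logistic
`K_max / (1 + exp(p (z - z0)))` solved exactly through the anchors: it
plateaus at weak binding for strongly negative charge (electrostatic
repulsion saturates) and decays towards zero for strongly positive charge.
Charges outside [-10, +10] are clamped with a warning rather than
extrapolated. The form is swappable: `fit_charge_relations()` accepts any
anchor set.

### The sieving curve

The glomerular sieving coefficient is a logistic in Stokes radius,
`theta = 1 / (1 + exp((a_e - a0) / w))`, fitted to the packaged
size-selectivity table by linear regression on the logit scale (the fit is
therefore exact least squares, with no iterative optimizer). The packaged
table is a synthetic stand-in emulating published Ficoll/protein sieving
measurements — steep cutoff near 3 nm, `theta < 1e-3` above 4 nm — and is
clearly labelled as such; users with real sieving data can refit with
`fit_sieving_curve()`.

## Numerical choices

* Stiff integration with `deSolve::lsoda`, `rtol = 1e-8`, `atol = 1e-10`
  nM (both exposed). The right-hand side is compiled C; an identical R
  reference implementation (`ode_rhs()`) is kept in the package and the two
  are compared term-by-term in the tests.
* The Patlak flux uses its analytic diffusion limit for `|Pe| < 1e-8` and
  saturated convection branches for `|Pe| > 500`; no division by
  `1 - exp(-Pe)` near zero.
* IV boluses are instantaneous increments of plasma concentration applied
  through solver events; doses at t = 0 are folded into the initial state.
* The drug-free system starts at steady state by construction: antigen
  synthesis balances *all* baseline loss routes (first-order elimination
  plus pinocytic uptake), and endosomal antigen starts at its fixed point
  (uptake inflow over catabolic clearance). Synthesis rates are always
  derived as baseline × degradation rate, never stored.
* Non-negativity is monitored against the solver tolerance (warning beyond
  `1e4 * atol`), never enforced by clipping. Free membrane receptors are
  algebraic (`Rm_total - ARm`), so the membrane pool is conserved exactly.

## Estimation

`multistart_fit()` minimizes the mean-normalized SSE — per observable, the
squared-residual sum divided by the mean of that observable's data, summed
over observables — as a weighted least-squares problem: residuals
`(pred - obs) / sqrt(mean(obs))` go to a bounded Levenberg–Marquardt
optimizer from each of `n_starts` (default 10) Latin-hypercube starting
points; parameters whose bounds span ≥ 2 decades are searched in log space.
Joint uptake/reflection fits have a shallow, curved valley (tissue and
plasma uptake rates trade off against each other), so the argmin is refined
by two Nelder–Mead + Levenberg–Marquardt cycles; on noiseless
self-generated data this reaches the generating parameters to ~1e-4%
rather than stalling at ~10% valley error. Everything is deterministic
given the seed. Default bounds span two decades around the literature
values for rates and [0.5, 0.999] for reflection coefficients; fitting is
on the linear concentration scale, matching the objective definition.

`local_sensitivity()` perturbs one parameter at a time by +20% and reports
the relative change in plasma/tight/leaky AUC. Parameters with a physical
upper limit of 1 (reflection coefficients, fractions, `K_p`) are clamped at
that limit after perturbation. The exposure window defaults to four times
the scenario horizon so that AUC approximates total exposure for
long-half-life antibodies; with the 21-day window alone, every clearance
parameter's sensitivity is flattened by the undecayed tail. The "sensitive
set" is defined by screening: parameters whose largest |ΔAUC| over the
three observables reaches 5%.

## The synthetic-data generator

`generate_pk_dataset()` samples the lumped observables at stated times and
applies, optionally, multiplicative log-normal noise with the median
preserved (`sd_log = sqrt(log(1 + cv^2))`, default cv = 0.15, typical
preclinical assay variability) and LLOQ flagging (values below the limit
are flagged, never silently dropped). It emulates noiseless or log-normally
noisy model output only: real tissue PK data additionally carry digitization
error, inter-animal variability, sparse and irregular sampling, and model
misspecification. Passing recovery tests therefore demonstrates that the
estimation machinery is correct and the parameters identifiable under the
stated designs — not that the model is validated against any animal data.

Recovery experiments (`recovery_experiment()`) use 12 log-spaced sampling
times from 0.25 h to 21 days across the three observables (36 records), 10
Latin-hypercube starts and noiseless data; each runs in a few seconds.
These problem sizes are the package's test design choices; all of them are
arguments.

## Known limitations

* Tissue-level resolution stops at the tight/leaky lumps; individual-organ
  concentrations are out of reach by design.
* IV bolus only; no subcutaneous absorption, no pharmacodynamics, no
  downstream cellular processing of internalized complexes (internalized
  and catabolized species simply leave the tracked system).
* Charge relations are calibrated from three variants of one IgG and are
  clamped outside net charge [-10, +10]; the human charge sweep is
  qualitative (direction, not magnitude).
* Glomerular sieving depends on size only; no charge-selective filtration.
* The shipped physiology tables are literature-style defaults, not
  measurements for any specific study animal; recovery experiments are
  self-consistent by construction and do not validate these tables.
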