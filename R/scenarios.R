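# Packaged ready-to-run scenario configurations for the case studies the
# model covers: wild-type and FcRn-knockout mouse IgG, size variants,
# charge variants, a membrane-target (anti-CEA) TMDD case and the human
# (adalimumab-like anti-TNF) case.

# Assemble a scenario container.
new_scenario <- function(name, params, dose_mg_per_kg, t_end,
                         schedule = NULL) {
  if (is.null(schedule)) {
    amount <- dose_to_amount(dose_mg_per_kg, params$physiology$body_weight_kg,
                             params$antibody$MW)
    schedule <- dose_schedule(0, amount)
  }
  structure(list(name = name, params = params, schedule = schedule,
                 dose_mg_per_kg = dose_mg_per_kg, t_end = t_end),
            class = "mpbpk_scenario")
}

#' @export
print.mpbpk_scenario <- function(x, ...) {
  cat(sprintf("mPBPK scenario '%s': %s, %g mg/kg, %g h\n", x$name,
              x$params$physiology$species_name, x$dose_mg_per_kg, x$t_end))
  invisible(x)
}

#' Simulate a packaged scenario
#'
#' @param scenario an `mpbpk_scenario`.
#' @param n number of output points (dense grid over `[0, t_end]`).
#' @param times optional explicit time grid.
#' @param ... passed to [simulate_pk()].
#' @return an `mpbpk_profile`.
#' @export
simulate_scenario <- function(scenario, n = 200, times = NULL, ...) {
  if (is.null(times)) times <- seq(0, scenario$t_end, length.out = n)
  simulate_pk(scenario$params, scenario$schedule, times, ...)
}

#' Wild-type mouse IgG scenario
#'
#' Non-specific FcRn-binding 150 kDa IgG in the wild-type mouse at the
#' calibrated operating point: `k_up = 0.0276` 1/h, `k_up_p = 0.05` 1/h and
#' fitted effective reflection coefficients `sigma_1 = 0.9`,
#' `sigma_2 = 0.86`; no antigen, no non-specific binding.
#'
#' @param dose_mg_per_kg IV bolus dose (default 8 mg/kg).
#' @param k_up,k_up_p,sigma_1,sigma_2 operating-point overrides.
#' @param ... further overrides passed to [model_params()].
#' @return an `mpbpk_scenario`.
#' @export
scenario_wildtype_mouse <- function(dose_mg_per_kg = 8, k_up = 0.0276,
                                    k_up_p = 0.05, sigma_1 = 0.9,
                                    sigma_2 = 0.86, ...) {
  phys <- mouse_physiology()
  ab <- antibody_descriptor("IgG-wt", MW = 150000, net_charge = 0)
  params <- model_params(phys, ab, k_up = k_up, k_up_p = k_up_p,
                         sigma_1 = sigma_1, sigma_2 = sigma_2, ...)
  new_scenario("wildtype_mouse", params, dose_mg_per_kg, t_end = 504)
}

#' FcRn-knockout mouse scenario
#'
#' As [scenario_wildtype_mouse()] but with endosomal FcRn set to zero and
#' the pinocytosis rate recalibrated to `k_up = 0.15` 1/h (pinocytic uptake
#' is the rate-limiting elimination step once recycling is absent).
#'
#' @param dose_mg_per_kg IV bolus dose (default 8 mg/kg).
#' @param k_up recalibrated pinocytosis rate.
#' @param ... further overrides passed to [model_params()].
#' @return an `mpbpk_scenario`.
#' @export
scenario_fcrn_ko_mouse <- function(dose_mg_per_kg = 8, k_up = 0.15, ...) {
  phys <- mouse_physiology(FcRn_total = 0)
  ab <- antibody_descriptor("IgG-FcRnKO", MW = 150000, net_charge = 0)
  params <- model_params(phys, ab, k_up = k_up, k_up_p = 0.05,
                         sigma_1 = 0.9, sigma_2 = 0.86, ...)
  new_scenario("fcrn_ko_mouse", params, dose_mg_per_kg, t_end = 504)
}

#' Size-variant scenario (50/100/150 kDa)
#'
#' Transport and renal clearance are fully derived from molecular weight via
#' the two-pore equations and the sieving curve (no fitted reflection
#' coefficients).  The 50 kDa fragment has no Fc and does not bind FcRn.
#'
#' @param MW molecular weight in Da (one of the case-study sizes or any
#'   value in the supported 50-150 kDa range).
#' @param dose_mg_per_kg IV bolus dose (default 5 mg/kg).
#' @param fcrn_binding default: `MW >= 100000` (Fc-containing formats).
#' @param ... further overrides passed to [model_params()].
#' @return an `mpbpk_scenario`.
#' @export
scenario_size_variant <- function(MW, dose_mg_per_kg = 5,
                                  fcrn_binding = MW >= 100000, ...) {
  phys <- mouse_physiology()
  ab <- antibody_descriptor(sprintf("IgG-%.0fkDa", MW / 1000), MW = MW,
                            net_charge = 0, fcrn_binding = fcrn_binding)
  params <- model_params(phys, ab, ...)
  new_scenario(sprintf("size_%.0fkDa", MW / 1000), params, dose_mg_per_kg,
               t_end = 504)
}

#' Charge-variant scenario (net charge -8, 0, +5, ...)
#'
#' 150 kDa IgG with non-specific membrane binding active
#' (`Rm_total = 71.86` nM); `K_p`, `S_pino` and `K_D_NSB` follow the
#' packaged charge relations for the requested net charge unless overridden.
#'
#' @param z net surface charge.
#' @param dose_mg_per_kg IV bolus dose (default 10 mg/kg).
#' @param Rm_total total membrane NSB receptor concentration (nM).
#' @param ... further overrides passed to [model_params()] (e.g. explicit
#'   `K_D_NSB`, `K_p`, `S_pino_2`).
#' @return an `mpbpk_scenario`.
#' @export
scenario_charge_variant <- function(z, dose_mg_per_kg = 10, Rm_total = 71.86, ...) {
  phys <- mouse_physiology()
  ab <- antibody_descriptor(sprintf("IgG-z%+g", z), MW = 150000, net_charge = z)
  params <- model_params(phys, ab, Rm_total = Rm_total,
                         sigma_1 = 0.9, sigma_2 = 0.86, ...)
  new_scenario(sprintf("charge_z%+g", z), params, dose_mg_per_kg, t_end = 504)
}

#' Anti-CEA TMDD scenario in mice
#'
#' Membrane-bound CEA at 80 nM baseline with a 36 h half-life
#' (`k_p_Tm = ln 2 / 36` 1/h), complex internalization `k_int = 0.015` 1/h,
#' and soluble CEA at 2 ng/mL (target MW 180 kDa) with a 2 h half-life.
#' Antibody-antigen binding is the same at both pH values.
#'
#' @param dose_mg_per_kg IV bolus dose (case-study doses 1, 10, 25 mg/kg).
#' @param k_int,k_p_Tm TMDD kinetic parameters.
#' @param ... further overrides passed to [model_params()].
#' @return an `mpbpk_scenario`.
#' @export
scenario_anti_cea_mouse <- function(dose_mg_per_kg = 1, k_int = 0.015,
                                    k_p_Tm = log(2) / 36, ...) {
  phys <- mouse_physiology()
  ab <- antibody_descriptor("anti-CEA-IgG", MW = 150000, net_charge = 0,
                            kon = 0.36, koff = 0.36, keon = 0.36, keoff = 0.36)
  tgt <- target_descriptor("CEA", T_s0 = ngml_to_nM(2, 180000), T_m0 = 80,
                           soluble_halflife = 2, k_p_Tm = k_p_Tm,
                           k_int = k_int, MW_target = 180000)
  params <- model_params(phys, ab, target = tgt,
                         sigma_1 = 0.9, sigma_2 = 0.86, ...)
  new_scenario("anti_cea_mouse", params, dose_mg_per_kg, t_end = 504)
}

#' Human anti-TNF (adalimumab-like) scenario
#'
#' Human physiology with a soluble TNF target at 0.276 pM baseline and a
#' soluble-target clearance of 8.316 L/h.
#'
#' @param dose_mg_per_kg IV bolus dose (case-study doses 1, 3, 5 mg/kg).
#' @param net_charge optional net charge (activates the charge relations).
#' @param Rm_total membrane NSB pool; enabled when simulating charge
#'   variants in humans.
#' @param ... further overrides passed to [model_params()].
#' @return an `mpbpk_scenario`.
#' @export
scenario_human_adalimumab <- function(dose_mg_per_kg = 1, net_charge = 0,
                                      Rm_total = 0, ...) {
  phys <- human_physiology()
  ab <- antibody_descriptor("adalimumab", MW = 148000, net_charge = net_charge,
                            kon = 0.36, koff = 0.036, keon = 0.36, keoff = 0.036)
  tgt <- target_descriptor("TNF-alpha", T_s0 = 2.76e-4, CL_pT = 8.316,
                           MW_target = 17000)
  params <- model_params(phys, ab, target = tgt, Rm_total = Rm_total, ...)
  new_scenario("human_adalimumab", params, dose_mg_per_kg, t_end = 700)
}

#' Human charge-sweep scenario
#'
#' The human configuration used for the charge-versus-clearance sweep:
#' non-specific membrane binding active, charge parameters from the
#' packaged relations.
#'
#' @param z net surface charge.
#' @param dose_mg_per_kg IV bolus dose.
#' @param ... further overrides.
#' @return an `mpbpk_scenario`.
#' @export
scenario_human_charge <- function(z, dose_mg_per_kg = 1, ...) {
  scenario_human_adalimumab(dose_mg_per_kg = dose_mg_per_kg, net_charge = z,
                            Rm_total = 71.86, ...)
}

#' All packaged scenario fixtures
#'
#' Ready-to-run configurations for every case study: wild-type mouse IgG at
#' 8 mg/kg, FcRn-knockout mouse, 50/100/150 kDa size variants at 5 mg/kg,
#' charge variants -8/0/+5 at 10 mg/kg, anti-CEA at 1/10/25 mg/kg and the
#' human anti-TNF case at 1/3/5 mg/kg.
#'
#' @return named list of `mpbpk_scenario` objects.
#' @export
scenario_fixtures <- function() {
  out <- list(
    wildtype_mouse = scenario_wildtype_mouse(8),
    fcrn_ko_mouse = scenario_fcrn_ko_mouse(8),
    size_50kDa = scenario_size_variant(50000, 5),
    size_100kDa = scenario_size_variant(100000, 5),
    size_150kDa = scenario_size_variant(150000, 5),
    charge_neg8 = scenario_charge_variant(-8, 10),
    charge_neutral = scenario_charge_variant(0, 10),
    charge_pos5 = scenario_charge_variant(5, 10),
    anti_cea_1mgkg = scenario_anti_cea_mouse(1),
    anti_cea_10mgkg = scenario_anti_cea_mouse(10),
    anti_cea_25mgkg = scenario_anti_cea_mouse(25),
    human_adalimumab_1mgkg = scenario_human_adalimumab(1),
    human_adalimumab_3mgkg = scenario_human_adalimumab(3),
    human_adalimumab_5mgkg = scenario_human_adalimumab(5))
  out
}
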