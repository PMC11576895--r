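# Self-consistency (parameter-recovery) experiments: synthetic noiseless
# data are generated at a scenario's calibrated operating point, the
# calibrated parameters are re-estimated from Latin-hypercube multi-starts,
# and the recovered values are compared with the generating truth.

#' Parameter-recovery experiment at a calibrated operating point
#'
#' Generates a noiseless synthetic dataset (plasma, tight and leaky totals
#' at 12 log-spaced time points over 21 days) from one of the packaged
#' calibration scenarios, then refits the scenario's calibrated parameters
#' with [multistart_fit()] (10 Latin-hypercube starts by default).
#'
#' Cases:
#' * `"wildtype"`: wild-type mouse IgG, 8 mg/kg; jointly refit
#'   `k_up` (0.0276 1/h), `k_up_p` (0.05 1/h), `sigma_1` (0.9),
#'   `sigma_2` (0.86).
#' * `"fcrn_ko"`: FcRn-knockout mouse, 8 mg/kg; refit `k_up` (0.15 1/h).
#' * `"charge_neutral"`: neutral IgG, 10 mg/kg; jointly refit
#'   `K_D_NSB` (8.35 nM) and `Rm_total` (71.86 nM).
#' * `"charge_pos"`: +5 variant, 10 mg/kg; refit `K_p` (0.8) with
#'   `S_pino_2` and `K_D_NSB` fixed at their generating values.
#' * `"charge_neg"`: -8 variant, 10 mg/kg; jointly refit `K_D_NSB`
#'   (16.22 nM) and `K_p` (0.62).
#' * `"tmdd"`: anti-CEA, 1 mg/kg, membrane target 80 nM with 36 h
#'   half-life; jointly refit `k_int` (0.015 1/h) and `k_p_Tm`
#'   (ln 2 / 36 1/h).
#'
#' @param case experiment name (see above).
#' @param seed seed for the Latin hypercube.
#' @param n_starts number of starts (default 10).
#' @param times_h sampling schedule (h).
#' @return list with elements `fit` (an `mpbpk_fit`), `truth` (named
#'   generating values), `scenario` and `dataset`.
#' @export
recovery_experiment <- function(case = c("wildtype", "fcrn_ko",
                                         "charge_neutral", "charge_pos",
                                         "charge_neg", "tmdd"),
                                seed = 1L, n_starts = 10,
                                times_h = round(exp(seq(log(0.25), log(504),
                                                        length.out = 12)), 3)) {
  case <- match.arg(case)
  spec <- switch(case,
    wildtype = list(
      scenario = scenario_wildtype_mouse(8),
      free = list(k_up = c(1e-3, 1), k_up_p = c(1e-3, 1),
                  sigma_1 = c(0.5, 0.999), sigma_2 = c(0.5, 0.999)),
      truth = c(k_up = 0.0276, k_up_p = 0.05, sigma_1 = 0.9, sigma_2 = 0.86)),
    fcrn_ko = list(
      scenario = scenario_fcrn_ko_mouse(8),
      free = list(k_up = c(1e-3, 3)),
      truth = c(k_up = 0.15)),
    charge_neutral = list(
      scenario = scenario_charge_variant(0, 10),
      free = list(K_D_NSB = c(0.1, 1000), Rm_total = c(1, 5000)),
      truth = c(K_D_NSB = 8.35, Rm_total = 71.86)),
    charge_pos = list(
      scenario = scenario_charge_variant(5, 10),
      free = list(K_p = c(0.2, 1)),
      truth = c(K_p = 0.8)),
    charge_neg = list(
      scenario = scenario_charge_variant(-8, 10),
      free = list(K_D_NSB = c(0.1, 1000), K_p = c(0.2, 1)),
      truth = c(K_D_NSB = 16.22, K_p = 0.62)),
    tmdd = list(
      scenario = scenario_anti_cea_mouse(1),
      free = list(k_int = c(1e-4, 1), k_p_Tm = c(1e-3, 0.2)),
      truth = c(k_int = 0.015, k_p_Tm = log(2) / 36)))
  dataset <- generate_pk_dataset(spec$scenario$params, spec$scenario$schedule,
                                 times_h)
  fit <- multistart_fit(spec$scenario, dataset, spec$free,
                        n_starts = n_starts, seed = seed)
  list(fit = fit, truth = spec$truth, scenario = spec$scenario,
       dataset = dataset)
}
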