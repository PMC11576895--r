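# Antibody/antigen descriptors, size derivation and dose conversions.

#' Stokes radius from molecular weight
#'
#' Globular-protein power law `a_e = 0.0483 * MW^0.386` (MW in Da, result in
#' nm), the relationship used throughout the two-pore transport literature.
#' A full-length IgG (150 kDa) maps to about 4.8 nm, a 50 kDa fragment to
#' about 3.15 nm.
#'
#' @param MW molecular weight in Da.
#' @return Stokes radius in nm.
#' @export
stokes_radius_from_mw <- function(MW) {
  if (!is.numeric(MW) || any(!is.finite(MW)) || any(MW <= 0))
    stop("'MW' must be positive", call. = FALSE)
  0.0483 * MW^0.386
}

#' Antibody descriptor
#'
#' Collects the compound-specific inputs of the mPBPK model: molecular
#' weight, Stokes radius (derived from MW unless supplied, since engineered
#' fragments can deviate from globular scaling), net surface charge, and the
#' binding rate constants for FcRn (endosomal pH 6), antigen at plasma pH 7.4
#' (`kon`/`koff`) and antigen at endosomal pH 6 (`keon`/`keoff`).
#'
#' `fcrn_binding = FALSE` (Fc-less fragments, or FcRn-knockout scenarios
#' handled at the physiology level) forces `k1on = 0`.
#'
#' @param name label.
#' @param MW molecular weight (Da).
#' @param net_charge signed net surface charge (elementary-charge units);
#'   charge relations are valid on `[-10, 10]`.
#' @param a_e Stokes radius in nm; default derived from `MW` via
#'   [stokes_radius_from_mw()].
#' @param fcrn_binding logical; whether the molecule binds FcRn.
#' @param k1on,k1off FcRn association (1/nM/h) and dissociation (1/h) rate
#'   constants at pH 6.
#' @param kon,koff antigen association/dissociation at pH 7.4.
#' @param keon,keoff antigen association/dissociation at pH 6.
#' @return an object of class `mpbpk_antibody`.
#' @export
antibody_descriptor <- function(name, MW, net_charge = 0, a_e = NULL,
                                fcrn_binding = TRUE,
                                k1on = 0.0806, k1off = 56.4,
                                kon = 0, koff = 0, keon = 0, keoff = 0) {
  if (!is.numeric(MW) || length(MW) != 1L || !is.finite(MW) || MW <= 0)
    stop("'MW' must be a single positive number", call. = FALSE)
  if (is.null(a_e)) a_e <- stokes_radius_from_mw(MW)
  if (a_e <= 0) stop("'a_e' must be positive", call. = FALSE)
  rates <- c(k1on = k1on, k1off = k1off, kon = kon, koff = koff,
             keon = keon, keoff = keoff)
  if (any(rates < 0) || any(!is.finite(rates)))
    stop("all rate constants must be finite and non-negative", call. = FALSE)
  if (!isTRUE(fcrn_binding)) k1on <- 0
  structure(list(name = name, MW = MW, a_e = a_e, net_charge = net_charge,
                 fcrn_binding = isTRUE(fcrn_binding),
                 k1on = k1on, k1off = k1off, kon = kon, koff = koff,
                 keon = keon, keoff = keoff),
            class = "mpbpk_antibody")
}

#' @export
print.mpbpk_antibody <- function(x, ...) {
  cat(sprintf("mPBPK antibody: %s\n  MW = %.4g Da, a_e = %.3g nm, charge = %+g, FcRn binding: %s\n",
              x$name, x$MW, x$a_e, x$net_charge, x$fcrn_binding))
  cat(sprintf("  FcRn pH6: k1on = %.3g 1/nM/h, k1off = %.3g 1/h\n", x$k1on, x$k1off))
  cat(sprintf("  antigen pH7.4: kon = %.3g, koff = %.3g; pH6: keon = %.3g, keoff = %.3g\n",
              x$kon, x$koff, x$keon, x$keoff))
  invisible(x)
}

#' Target (antigen) descriptor
#'
#' Soluble and/or membrane-bound antigen properties.  Soluble-target
#' elimination may be given either as a half-life (h) or as a clearance
#' (L/h); it is normalised internally to a first-order rate using the
#' synthesis-site volume.  Synthesis rates are always derived as
#' baseline x degradation rate, never stored.
#'
#' @param name label.
#' @param T_s0 soluble-target baseline concentration (nM); use
#'   [ngml_to_nM()] to convert mass-based baselines.
#' @param T_m0 membrane-target baseline concentration (nM) in tissue
#'   vascular space.
#' @param soluble_halflife soluble-target half-life (h); mutually exclusive
#'   with `CL_pT`.
#' @param CL_pT soluble-target clearance (L/h), converted to a rate with the
#'   plasma volume of the physiology in use.
#' @param k_p_Tm membrane-target degradation rate (1/h).
#' @param k_int internalization rate of the membrane antibody-antigen
#'   complex (1/h).
#' @param MW_target target molecular weight (Da), used only for mass/molar
#'   unit conversions.
#' @return an object of class `mpbpk_target`.
#' @export
target_descriptor <- function(name, T_s0 = 0, T_m0 = 0,
                              soluble_halflife = NULL, CL_pT = NULL,
                              k_p_Tm = 0, k_int = 0, MW_target = NA_real_) {
  if (T_s0 < 0 || T_m0 < 0 || k_p_Tm < 0 || k_int < 0)
    stop("target baselines and rates must be non-negative", call. = FALSE)
  if (!is.null(soluble_halflife) && !is.null(CL_pT))
    stop("give either 'soluble_halflife' or 'CL_pT', not both", call. = FALSE)
  structure(list(name = name, T_s0 = T_s0, T_m0 = T_m0,
                 soluble_halflife = soluble_halflife, CL_pT = CL_pT,
                 k_p_Tm = k_p_Tm, k_int = k_int, MW_target = MW_target),
            class = "mpbpk_target")
}

# First-order soluble-target elimination rate (1/h) for a given site volume.
soluble_target_rate <- function(target, V_site) {
  if (is.null(target)) return(0)
  if (!is.null(target$soluble_halflife)) {
    if (target$soluble_halflife <= 0) stop("soluble half-life must be positive", call. = FALSE)
    return(log(2) / target$soluble_halflife)
  }
  if (!is.null(target$CL_pT)) return(target$CL_pT / V_site)
  0
}

#' Convert an IV dose in mg/kg to an amount in nmol
#'
#' `amount_nmol = dose_mg_per_kg * body_weight_kg / MW * 1e6` (mg / (g/mol)
#' = mmol scaled to nmol).
#'
#' @param dose_mg_per_kg dose (mg/kg); 0 allowed.
#' @param body_weight_kg body weight (kg).
#' @param MW molecular weight (Da).
#' @return amount in nmol.
#' @export
dose_to_amount <- function(dose_mg_per_kg, body_weight_kg, MW) {
  if (any(dose_mg_per_kg < 0)) stop("'dose_mg_per_kg' must be non-negative", call. = FALSE)
  if (body_weight_kg <= 0 || MW <= 0)
    stop("'body_weight_kg' and 'MW' must be positive", call. = FALSE)
  dose_mg_per_kg * body_weight_kg / MW * 1e6
}

#' Mass/molar concentration conversions
#'
#' `ngml_to_nM()` converts ng/mL to nM given the molecular weight;
#' `nM_to_ngml()` is its inverse, and `nM_to_ugml()` converts nM to
#' micrograms/mL (the unit most PK figures use).
#'
#' @param x concentration value(s).
#' @param MW molecular weight (Da).
#' @return converted concentration.
#' @export
ngml_to_nM <- function(x, MW) {
  if (MW <= 0) stop("'MW' must be positive", call. = FALSE)
  x / MW * 1e3
}

#' @rdname ngml_to_nM
#' @export
nM_to_ngml <- function(x, MW) {
  if (MW <= 0) stop("'MW' must be positive", call. = FALSE)
  x * MW / 1e3
}

#' @rdname ngml_to_nM
#' @export
nM_to_ugml <- function(x, MW) nM_to_ngml(x, MW) / 1e3

#' Read / write a compound configuration
#'
#' YAML serialization of an [antibody_descriptor()] (charge as signed number,
#' FcRn binding as boolean).
#'
#' @param ab an `mpbpk_antibody`.
#' @param path file path.
#' @export
write_compound_config <- function(ab, path) {
  stopifnot(inherits(ab, "mpbpk_antibody"))
  writeLines(yaml::as.yaml(unclass(ab), precision = 17L), path)
  invisible(path)
}

#' @rdname write_compound_config
#' @export
read_compound_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  antibody_descriptor(name = cfg$name, MW = cfg$MW, net_charge = cfg$net_charge,
                      a_e = cfg$a_e, fcrn_binding = cfg$fcrn_binding,
                      k1on = cfg$k1on, k1off = cfg$k1off, kon = cfg$kon,
                      koff = cfg$koff, keon = cfg$keon, keoff = cfg$keoff)
}
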