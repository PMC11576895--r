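# Assembly of fully resolved model parameters and the ODE state layout.

#' State layout of the mPBPK model
#'
#' 39 concentration states (nM): plasma (antibody `A_p`, soluble target
#' `Ts_p`, complex `ATs_p`), the plasma nested endosome at pH 6 (`A_ep`,
#' `Ts_ep`, `ATs_ep`, free FcRn `F_ep`, `AF_ep`, `ATF_ep`), lymph (`A_L`,
#' `ATs_L`) and, per lumped tissue (1 = tight, 2 = leaky): vascular
#' (`A_v`, `Ts_v`, `ATs_v`, membrane target `Tm_v`, `ATm_v`, non-specific
#' membrane complex `ARm_v`), endosomal (`A_e`, `Ts_e`, `ATs_e`, `F_e`,
#' `AF_e`, `ATF_e`) and interstitial (`A_is`, `ATs_is`) sub-spaces.
#' Free membrane NSB receptor is algebraic: `Rm = Rm_total - ARm`.
#'
#' @return character vector of the 39 state names, in ODE order.
#' @export
state_names <- function() {
  tissue <- function(i) paste0(
    c("A_v", "Ts_v", "ATs_v", "Tm_v", "ATm_v", "ARm_v",
      "A_e", "Ts_e", "ATs_e", "F_e", "AF_e", "ATF_e",
      "A_is", "ATs_is"), i)
  c("A_p", "Ts_p", "ATs_p",
    "A_ep", "Ts_ep", "ATs_ep", "F_ep", "AF_ep", "ATF_ep",
    "A_L", "ATs_L", tissue(1), tissue(2))
}

# Layout of the packed numeric parameter vector shared with the C
# right-hand side (order must match src/mpbpk.c).
pvec_names <- function() c(
  "V_p", "V_ep", "V_L",
  "V_v1", "V_e1", "V_is1", "Q1", "L1",
  "V_v2", "V_e2", "V_is2", "Q2", "L2",
  "L_total", "sigma_L",
  "k_up", "k_up_p", "S_pino1", "S_pino2", "f_up_v",
  "CL_rec_p", "CL_rec1", "CL_rec2", "f_rec_v",
  "k_deg", "CL_cat_p", "CL_cat1", "CL_cat2",
  "FcRn_total", "k1on", "k1off",
  "kon", "koff", "keon", "keoff",
  "K_p", "kon_NSB", "koff_NSB", "Rm_total",
  "CL_renal",
  "T_s0", "k_Ts", "T_m0", "k_p_Tm", "k_int",
  "Js1", "Jl1", "sig_s1", "sig_l1", "PS_s1", "PS_l1",
  "Js2", "Jl2", "sig_s2", "sig_l2", "PS_s2", "PS_l2",
  "has_Ts", "has_Tm", "has_NSB")

#' Resolve a full mPBPK parameter set
#'
#' Combines a species physiology, an antibody descriptor, an optional
#' target descriptor and the charge relations into the fully resolved rate
#' and transport parameters of one simulation.
#'
#' Charge-dependent parameters (`K_p`, `S_pino` per tissue, `K_D_NSB`) are
#' evaluated from the antibody's net charge via the packaged charge
#' relations, unless overridden explicitly.  Non-specific membrane binding
#' is active only when `Rm_total > 0`; its association rate equals the
#' FcRn association rate `k1on` and its dissociation rate is
#' `K_D_NSB * kon_NSB`.  Transcapillary transport uses the two-pore derived
#' per-pore-class parameters unless explicit effective reflection
#' coefficients `sigma_1`/`sigma_2` are supplied, in which case a single
#' effective pathway with `J = L_i`, the supplied sigma and the summed
#' two-pore permeability is used (fitted sigmas take precedence over
#' derived ones).  Renal clearance defaults to `GFR * theta(a_e)` from the
#' fitted sieving curve and acts on the leaky vascular space only.
#'
#' @param physiology an `mpbpk_physiology`.
#' @param antibody an `mpbpk_antibody`.
#' @param target an `mpbpk_target` or `NULL`.
#' @param k_up,k_up_p tissue and plasma-endosome pinocytosis rates (1/h);
#'   uptake clearance is `S_pino * k_up * V_e` (endosomal-volume basis).
#' @param sigma_1,sigma_2 optional effective vascular reflection
#'   coefficients overriding the two-pore derived values.
#' @param K_p,S_pino_1,S_pino_2,K_D_NSB optional explicit charge parameters.
#' @param Rm_total total membrane NSB receptor concentration (nM); 0
#'   disables non-specific binding.
#' @param k_deg lysosomal degradation rate of free endosomal antibody (1/h).
#' @param cat_rate endosomal catabolism rate (1/h) applied to free antigen
#'   and antibody-antigen complex; catabolic clearance is
#'   `cat_rate * V_e` per endosome.
#' @param f_rec_v fraction of tissue endosomal recycling directed to the
#'   vascular space (the rest goes to the interstitium).
#' @param f_up_v fraction of tissue endosomal uptake drawn from the
#'   vascular side (the rest from the interstitium).
#' @param CL_renal optional explicit renal clearance (L/h).
#' @param geometry a [two_pore_geometry()].
#' @param charge_relations an `mpbpk_charge_relations`.
#' @return an object of class `mpbpk_params`.
#' @export
model_params <- function(physiology, antibody, target = NULL,
                         k_up = 0.0276, k_up_p = 0.05,
                         sigma_1 = NULL, sigma_2 = NULL,
                         K_p = NULL, S_pino_1 = NULL, S_pino_2 = NULL,
                         K_D_NSB = NULL, Rm_total = 0,
                         k_deg = 30, cat_rate = NULL,
                         f_rec_v = 0.5, f_up_v = 0.5,
                         CL_renal = NULL,
                         geometry = two_pore_geometry(),
                         charge_relations = default_charge_relations()) {
  stopifnot(inherits(physiology, "mpbpk_physiology"), inherits(antibody, "mpbpk_antibody"))
  if (!is.null(target)) stopifnot(inherits(target, "mpbpk_target"))
  if (f_rec_v < 0 || f_rec_v > 1 || f_up_v < 0 || f_up_v > 1)
    stop("'f_rec_v' and 'f_up_v' must lie in [0, 1]", call. = FALSE)
  if (k_up < 0 || k_up_p < 0 || k_deg < 0) stop("rates must be non-negative", call. = FALSE)
  z <- antibody$net_charge
  if (is.null(K_p)) K_p <- if (z == 0) 1 else kp_from_charge(z, charge_relations)
  if (is.null(S_pino_1)) S_pino_1 <- spino_from_charge(z, "tight", charge_relations)
  if (is.null(S_pino_2)) S_pino_2 <- spino_from_charge(z, "leaky", charge_relations)
  if (is.null(K_D_NSB)) K_D_NSB <- kdnsb_from_charge(z, charge_relations)
  if (K_p <= 0 || K_p > 1) stop("'K_p' must lie in (0, 1]", call. = FALSE)
  tau <- physiology$endosomal_transit_time
  if (is.null(cat_rate)) cat_rate <- 1 / tau
  # per-tissue transcapillary parameters
  tp <- list(two_pore_params(antibody$a_e, physiology$tight$L, geometry),
             two_pore_params(antibody$a_e, physiology$leaky$L, geometry))
  sig_user <- list(sigma_1, sigma_2)
  slots <- vector("list", 2)
  for (i in 1:2) {
    if (!is.null(sig_user[[i]])) {
      s <- sig_user[[i]]
      if (s < 0 || s > 1) stop("sigma must lie in [0, 1]", call. = FALSE)
      L_i <- if (i == 1) physiology$tight$L else physiology$leaky$L
      slots[[i]] <- list(Js = L_i, Jl = 0, sig_s = s, sig_l = 1,
                         PS_s = sum(tp[[i]]$PS), PS_l = 0, sigma_eff = s)
    } else {
      slots[[i]] <- list(Js = tp[[i]]$J[["small"]], Jl = tp[[i]]$J[["large"]],
                         sig_s = tp[[i]]$sigma[["small"]], sig_l = tp[[i]]$sigma[["large"]],
                         PS_s = tp[[i]]$PS[["small"]], PS_l = tp[[i]]$PS[["large"]],
                         sigma_eff = tp[[i]]$sigma_eff)
    }
  }
  if (is.null(CL_renal))
    CL_renal <- renal_clearance(physiology$GFR, sieving_coefficient(antibody$a_e))
  has_Ts <- !is.null(target) && target$T_s0 > 0
  has_Tm <- !is.null(target) && target$T_m0 > 0
  has_NSB <- Rm_total > 0
  k_Ts <- if (has_Ts) soluble_target_rate(target, physiology$V_p) else 0
  kon_NSB <- antibody$k1on   # NSB association pinned to the FcRn association rate
  p <- c(
    V_p = physiology$V_p, V_ep = physiology$V_ep, V_L = physiology$V_lymph,
    V_v1 = physiology$tight$V_v, V_e1 = physiology$tight$V_e,
    V_is1 = physiology$tight$V_is, Q1 = physiology$tight$Q, L1 = physiology$tight$L,
    V_v2 = physiology$leaky$V_v, V_e2 = physiology$leaky$V_e,
    V_is2 = physiology$leaky$V_is, Q2 = physiology$leaky$Q, L2 = physiology$leaky$L,
    L_total = physiology$L_total, sigma_L = physiology$sigma_L,
    k_up = k_up, k_up_p = k_up_p, S_pino1 = S_pino_1, S_pino2 = S_pino_2,
    f_up_v = f_up_v,
    CL_rec_p = recycling_clearance(physiology$V_ep, tau),
    CL_rec1 = recycling_clearance(physiology$tight$V_e, tau),
    CL_rec2 = recycling_clearance(physiology$leaky$V_e, tau),
    f_rec_v = f_rec_v,
    k_deg = k_deg,
    CL_cat_p = cat_rate * physiology$V_ep,
    CL_cat1 = cat_rate * physiology$tight$V_e,
    CL_cat2 = cat_rate * physiology$leaky$V_e,
    FcRn_total = physiology$FcRn_total,
    k1on = antibody$k1on, k1off = antibody$k1off,
    kon = antibody$kon, koff = antibody$koff,
    keon = antibody$keon, keoff = antibody$keoff,
    K_p = K_p, kon_NSB = kon_NSB, koff_NSB = K_D_NSB * kon_NSB,
    Rm_total = Rm_total,
    CL_renal = CL_renal,
    T_s0 = if (has_Ts) target$T_s0 else 0,
    k_Ts = k_Ts,
    T_m0 = if (has_Tm) target$T_m0 else 0,
    k_p_Tm = if (has_Tm) target$k_p_Tm else 0,
    k_int = if (has_Tm) target$k_int else 0,
    Js1 = slots[[1]]$Js, Jl1 = slots[[1]]$Jl,
    sig_s1 = slots[[1]]$sig_s, sig_l1 = slots[[1]]$sig_l,
    PS_s1 = slots[[1]]$PS_s, PS_l1 = slots[[1]]$PS_l,
    Js2 = slots[[2]]$Js, Jl2 = slots[[2]]$Jl,
    sig_s2 = slots[[2]]$sig_s, sig_l2 = slots[[2]]$sig_l,
    PS_s2 = slots[[2]]$PS_s, PS_l2 = slots[[2]]$PS_l,
    has_Ts = as.numeric(has_Ts), has_Tm = as.numeric(has_Tm),
    has_NSB = as.numeric(has_NSB))
  stopifnot(identical(names(p), pvec_names()))
  # remember resolved arguments so parameters can be rebuilt with changes
  args <- list(k_up = k_up, k_up_p = k_up_p, sigma_1 = sigma_1,
               sigma_2 = sigma_2, K_p = K_p, S_pino_1 = S_pino_1,
               S_pino_2 = S_pino_2, K_D_NSB = K_D_NSB, Rm_total = Rm_total,
               k_deg = k_deg, cat_rate = cat_rate, f_rec_v = f_rec_v,
               f_up_v = f_up_v, CL_renal = CL_renal, geometry = geometry,
               charge_relations = charge_relations)
  structure(list(pvec = p, physiology = physiology, antibody = antibody,
                 target = target, K_D_NSB = K_D_NSB,
                 sigma_eff = c(tight = slots[[1]]$sigma_eff,
                               leaky = slots[[2]]$sigma_eff),
                 args = args),
            class = "mpbpk_params")
}

#' @export
print.mpbpk_params <- function(x, ...) {
  cat("mPBPK resolved parameters:", x$physiology$species_name, "/", x$antibody$name, "\n")
  p <- x$pvec
  cat(sprintf("  k_up = %.4g 1/h, k_up_p = %.4g 1/h, sigma = (%.3g, %.3g)\n",
              p["k_up"], p["k_up_p"], x$sigma_eff[1], x$sigma_eff[2]))
  cat(sprintf("  K_p = %.3g, S_pino = (%.3g, %.3g), K_D_NSB = %.4g nM, Rm_total = %.4g nM\n",
              p["K_p"], p["S_pino1"], p["S_pino2"], x$K_D_NSB, p["Rm_total"]))
  cat(sprintf("  CL_renal = %.4g L/h, k_deg = %.3g 1/h, FcRn = %.4g nM\n",
              p["CL_renal"], p["k_deg"], p["FcRn_total"]))
  cat(sprintf("  targets: soluble %s, membrane %s, NSB %s\n",
              p["has_Ts"] == 1, p["has_Tm"] == 1, p["has_NSB"] == 1))
  invisible(x)
}

#' Initial ODE state for an IV bolus
#'
#' Antibody appears in plasma at `dose_amount / V_p`; soluble target starts
#' at its baseline in plasma and tissue vascular spaces and at its drug-free
#' fixed point in the endosomes (pinocytic inflow balanced by catabolism);
#' membrane target starts at its baseline; FcRn is fully free; all complexes
#' are zero, so the drug-free system is at steady state.
#'
#' @param params an `mpbpk_params`.
#' @param dose_amount dose in nmol (`>= 0`).
#' @return named numeric state vector (see [state_names()]).
#' @export
initial_state <- function(params, dose_amount = 0) {
  if (dose_amount < 0) stop("'dose_amount' must be non-negative", call. = FALSE)
  p <- params$pvec
  y <- setNames(numeric(39), state_names())
  y["A_p"] <- dose_amount / p[["V_p"]]
  y["F_ep"] <- y["F_e1"] <- y["F_e2"] <- p[["FcRn_total"]]
  if (p[["has_Ts"]] == 1) {
    Ts0 <- p[["T_s0"]]
    y["Ts_p"] <- y["Ts_v1"] <- y["Ts_v2"] <- Ts0
    CLup_p <- p[["k_up_p"]] * p[["V_ep"]]
    y["Ts_ep"] <- if (p[["CL_cat_p"]] > 0) CLup_p * Ts0 / p[["CL_cat_p"]] else 0
    for (i in 1:2) {
      CLup <- p[[paste0("S_pino", i)]] * p[["k_up"]] * p[[paste0("V_e", i)]]
      CLcat <- p[[paste0("CL_cat", i)]]
      y[paste0("Ts_e", i)] <- if (CLcat > 0) p[["f_up_v"]] * CLup * Ts0 / CLcat else 0
    }
  }
  if (p[["has_Tm"]] == 1) y["Tm_v1"] <- y["Tm_v2"] <- p[["T_m0"]]
  y
}
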