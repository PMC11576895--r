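# Reference R implementation of the mPBPK right-hand side.  The compiled C
# version in src/mpbpk.c is the one used by the solver by default; the two
# are cross-checked in the test suite.

#' mPBPK ODE right-hand side
#'
#' Time derivative of the 39-state concentration vector (nM/h).  Fluxes:
#' plasma/tissue-vascular plasma-flow exchange with venous return `Q - L`;
#' two-pore transcapillary transport of antibody and soluble complex into an
#' interstitium of accessible volume `K_p * V_is`; interstitial lymph
#' drainage `L_i (1 - sigma_L)` returning via the lymph compartment at
#' `L_total`; pinocytic uptake `S_pino,i * k_up * V_e,i` split between the
#' vascular and interstitial faces of the tissue endothelium (and
#' `k_up_p * V_ep` from plasma into the nested endosome); pH-6 endosomal
#' FcRn and antigen binding; FcRn-complex recycling `CL_rec` split
#' `f_rec_v` to the vascular side; lysosomal degradation of free endosomal
#' antibody (`k_deg`) and catabolism of free endosomal antigen and complex
#' (`CL_cat`); pH-7.4 binding to soluble/membrane antigen and the
#' non-specific membrane pool in vascular spaces; antigen synthesis at
#' baseline x elimination rate; internalization of membrane complexes; and
#' renal clearance from the leaky vascular space.
#'
#' @param t time (h); the system is autonomous, `t` is unused.
#' @param state named or unnamed numeric vector of the 39 states, order of
#'   [state_names()].
#' @param params an `mpbpk_params` object (or its packed numeric `pvec`).
#' @return list whose first element is the derivative vector, as expected
#'   by [deSolve::lsoda()].
#' @export
ode_rhs <- function(t, state, params) {
  p <- if (inherits(params, "mpbpk_params")) params$pvec else params
  if (length(state) != 39) stop("state must have 39 elements", call. = FALSE)
  bad <- which(!is.finite(state))
  if (length(bad))
    stop("non-finite state at index ", paste(bad, collapse = ", "), call. = FALSE)
  y <- unname(state)
  g <- function(nm) p[[nm]]
  hTs <- g("has_Ts"); hTm <- g("has_Tm"); hN <- g("has_NSB")
  V_p <- g("V_p"); V_ep <- g("V_ep"); V_L <- g("V_L")
  sigma_L <- g("sigma_L"); L_total <- g("L_total")
  k1on <- g("k1on"); k1off <- g("k1off")
  kon <- g("kon"); koff <- g("koff"); keon <- g("keon"); keoff <- g("keoff")
  k_deg <- g("k_deg"); K_p <- g("K_p")
  konN <- g("kon_NSB"); koffN <- g("koff_NSB"); Rm_tot <- g("Rm_total")
  T_s0 <- g("T_s0"); k_Ts <- g("k_Ts")
  CLup_p <- g("k_up_p") * V_ep
  # plasma, plasma endosome, lymph states
  A_p <- y[1]; Ts_p <- y[2]; ATs_p <- y[3]
  A_ep <- y[4]; Ts_ep <- y[5]; ATs_ep <- y[6]; F_ep <- y[7]; AF_ep <- y[8]; ATF_ep <- y[9]
  A_L <- y[10]; ATs_L <- y[11]
  d <- numeric(39)
  # accumulators for plasma-side sums over tissues
  sumQ <- 0; ven_A <- 0; ven_ATs <- 0; QTs <- 0; lym_A <- 0; lym_ATs <- 0
  for (i in 1:2) {
    o <- 11 + (i - 1) * 14
    A_v <- y[o + 1]; Ts_v <- y[o + 2]; ATs_v <- y[o + 3]
    Tm_v <- y[o + 4]; ATm_v <- y[o + 5]; ARm_v <- y[o + 6]
    A_e <- y[o + 7]; Ts_e <- y[o + 8]; ATs_e <- y[o + 9]
    F_e <- y[o + 10]; AF_e <- y[o + 11]; ATF_e <- y[o + 12]
    A_is <- y[o + 13]; ATs_is <- y[o + 14]
    V_v <- g(paste0("V_v", i)); V_e <- g(paste0("V_e", i)); V_is <- g(paste0("V_is", i))
    Q <- g(paste0("Q", i)); L <- g(paste0("L", i))
    CLup <- g(paste0("S_pino", i)) * g("k_up") * V_e
    CLrec <- g(paste0("CL_rec", i)); CLcat <- g(paste0("CL_cat", i))
    f_v <- g("f_up_v"); f_rv <- g("f_rec_v")
    renal <- if (i == 2) g("CL_renal") else 0
    Js <- g(paste0("Js", i)); Jl <- g(paste0("Jl", i))
    ss <- g(paste0("sig_s", i)); sl <- g(paste0("sig_l", i))
    PSs <- g(paste0("PS_s", i)); PSl <- g(paste0("PS_l", i))
    TPA <- patlak_flux(A_v, A_is, Js, ss, PSs) + patlak_flux(A_v, A_is, Jl, sl, PSl)
    TPATs <- patlak_flux(ATs_v, ATs_is, Js, ss, PSs) + patlak_flux(ATs_v, ATs_is, Jl, sl, PSl)
    V_is_eff <- K_p * V_is
    ksyn <- T_s0 * (k_Ts + f_v * CLup / V_v)
    d[o + 1] <- (Q * A_p - (Q - L) * A_v - TPA - f_v * CLup * A_v +
                   f_rv * CLrec * AF_e - renal * A_v) / V_v -
      hTs * (kon * A_v * Ts_v - koff * ATs_v) -
      hTm * (kon * A_v * Tm_v - koff * ATm_v) -
      hN * (konN * A_v * (Rm_tot - ARm_v) - koffN * ARm_v)
    d[o + 2] <- hTs * ((Q * (Ts_p - Ts_v) - f_v * CLup * Ts_v) / V_v +
                         ksyn - k_Ts * Ts_v - kon * A_v * Ts_v + koff * ATs_v)
    d[o + 3] <- hTs * ((Q * ATs_p - (Q - L) * ATs_v - TPATs - f_v * CLup * ATs_v +
                          f_rv * CLrec * ATF_e - renal * ATs_v) / V_v +
                         kon * A_v * Ts_v - koff * ATs_v)
    d[o + 4] <- hTm * (g("T_m0") * g("k_p_Tm") - g("k_p_Tm") * Tm_v -
                         kon * A_v * Tm_v + koff * ATm_v)
    d[o + 5] <- hTm * (kon * A_v * Tm_v - koff * ATm_v - g("k_int") * ATm_v)
    d[o + 6] <- hN * (konN * A_v * (Rm_tot - ARm_v) - koffN * ARm_v -
                        g(paste0("S_pino", i)) * g("k_up") * ARm_v)
    d[o + 7] <- CLup * (f_v * A_v + (1 - f_v) * A_is) / V_e - k_deg * A_e -
      k1on * A_e * F_e + k1off * AF_e - hTs * (keon * A_e * Ts_e - keoff * ATs_e)
    d[o + 8] <- hTs * (f_v * CLup * Ts_v / V_e - CLcat * Ts_e / V_e -
                         keon * A_e * Ts_e + keoff * ATs_e)
    d[o + 9] <- hTs * (CLup * (f_v * ATs_v + (1 - f_v) * ATs_is) / V_e +
                         keon * A_e * Ts_e - keoff * ATs_e -
                         k1on * ATs_e * F_e + k1off * ATF_e - CLcat * ATs_e / V_e)
    d[o + 10] <- -k1on * A_e * F_e + k1off * AF_e + CLrec * AF_e / V_e +
      hTs * (-k1on * ATs_e * F_e + k1off * ATF_e + CLrec * ATF_e / V_e)
    d[o + 11] <- k1on * A_e * F_e - k1off * AF_e - CLrec * AF_e / V_e
    d[o + 12] <- hTs * (k1on * ATs_e * F_e - k1off * ATF_e - CLrec * ATF_e / V_e)
    d[o + 13] <- (TPA - L * (1 - sigma_L) * A_is - (1 - f_v) * CLup * A_is +
                    (1 - f_rv) * CLrec * AF_e) / V_is_eff
    d[o + 14] <- hTs * (TPATs - L * (1 - sigma_L) * ATs_is - (1 - f_v) * CLup * ATs_is +
                          (1 - f_rv) * CLrec * ATF_e) / V_is_eff
    sumQ <- sumQ + Q
    ven_A <- ven_A + (Q - L) * A_v
    ven_ATs <- ven_ATs + (Q - L) * ATs_v
    QTs <- QTs + Q * (Ts_v - Ts_p)
    lym_A <- lym_A + L * (1 - sigma_L) * A_is
    lym_ATs <- lym_ATs + L * (1 - sigma_L) * ATs_is
  }
  ksyn_p <- T_s0 * (k_Ts + CLup_p / V_p)
  d[1] <- (-sumQ * A_p + ven_A + L_total * A_L - CLup_p * A_p +
             g("CL_rec_p") * AF_ep) / V_p - hTs * (kon * A_p * Ts_p - koff * ATs_p)
  d[2] <- hTs * ((QTs - CLup_p * Ts_p) / V_p + ksyn_p - k_Ts * Ts_p -
                   kon * A_p * Ts_p + koff * ATs_p)
  d[3] <- hTs * ((-sumQ * ATs_p + ven_ATs + L_total * ATs_L - CLup_p * ATs_p +
                    g("CL_rec_p") * ATF_ep) / V_p + kon * A_p * Ts_p - koff * ATs_p)
  CLrec_p <- g("CL_rec_p"); CLcat_p <- g("CL_cat_p")
  d[4] <- CLup_p * A_p / V_ep - k_deg * A_ep - k1on * A_ep * F_ep + k1off * AF_ep -
    hTs * (keon * A_ep * Ts_ep - keoff * ATs_ep)
  d[5] <- hTs * (CLup_p * Ts_p / V_ep - CLcat_p * Ts_ep / V_ep -
                   keon * A_ep * Ts_ep + keoff * ATs_ep)
  d[6] <- hTs * (CLup_p * ATs_p / V_ep + keon * A_ep * Ts_ep - keoff * ATs_ep -
                   k1on * ATs_ep * F_ep + k1off * ATF_ep - CLcat_p * ATs_ep / V_ep)
  d[7] <- -k1on * A_ep * F_ep + k1off * AF_ep + CLrec_p * AF_ep / V_ep +
    hTs * (-k1on * ATs_ep * F_ep + k1off * ATF_ep + CLrec_p * ATF_ep / V_ep)
  d[8] <- k1on * A_ep * F_ep - k1off * AF_ep - CLrec_p * AF_ep / V_ep
  d[9] <- hTs * (k1on * ATs_ep * F_ep - k1off * ATF_ep - CLrec_p * ATF_ep / V_ep)
  d[10] <- (lym_A - L_total * A_L) / V_L
  d[11] <- hTs * (lym_ATs - L_total * ATs_L) / V_L
  list(d)
}

#' Volume-weighted lumped-tissue concentration
#'
#' `(C_e V_e + C_v V_v + C_is V_is) / (V_e + V_v + V_is)`: the total
#' lumped-tissue concentration from per-sub-space total-antibody
#' concentrations and physical sub-space volumes.
#'
#' @param C_e,C_v,C_is total antibody concentration in the endosomal,
#'   vascular and interstitial sub-space (per physical sub-space volume).
#' @param V_e,V_v,V_is sub-space volumes (`> 0`).
#' @return lumped concentration.
#' @export
lumped_tissue_concentration <- function(C_e, C_v, C_is, V_e, V_v, V_is) {
  if (any(c(V_e, V_v, V_is) <= 0)) stop("volumes must be positive", call. = FALSE)
  (C_e * V_e + C_v * V_v + C_is * V_is) / (V_e + V_v + V_is)
}

#' Lump observed per-tissue amounts into a compartment concentration
#'
#' `sum(amounts in lump) / sum(volumes in lump)` -- the construction used to
#' compare lumped model output against per-tissue measurements (e.g. total
#' tight tissue concentration = summed amount in brain, muscle, skin and fat
#' divided by total tight tissue volume).
#'
#' @param amounts named numeric vector of drug amounts per tissue.
#' @param volumes named numeric vector of tissue volumes (same units base).
#' @param lump character vector of tissue names to pool.
#' @return pooled concentration (amount / volume).
#' @export
observed_lumping <- function(amounts, volumes, lump) {
  missing_t <- setdiff(lump, intersect(names(amounts), names(volumes)))
  if (length(missing_t))
    stop("tissue(s) missing from amounts/volumes: ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  sum(amounts[lump]) / sum(volumes[lump])
}

# Total antibody concentration per sub-space and the lumped observables
# (plasma, tight_total, leaky_total), given a state matrix (rows = times).
profile_observables <- function(state, params) {
  p <- params$pvec
  cn <- colnames(state)
  col <- function(nm) if (nm %in% cn) state[, nm] else 0
  plasma <- col("A_p") + col("ATs_p")
  out <- list(plasma = plasma)
  for (i in 1:2) {
    C_e <- col(paste0("A_e", i)) + col(paste0("ATs_e", i)) +
      col(paste0("AF_e", i)) + col(paste0("ATF_e", i))
    C_v <- col(paste0("A_v", i)) + col(paste0("ATs_v", i)) +
      col(paste0("ATm_v", i)) + col(paste0("ARm_v", i))
    # interstitial antibody is distributed in K_p * V_is; express per
    # physical interstitial volume so amounts stay consistent
    C_is <- (col(paste0("A_is", i)) + col(paste0("ATs_is", i))) * p[["K_p"]]
    out[[c("tight_total", "leaky_total")[i]]] <- lumped_tissue_concentration(
      C_e, C_v, C_is,
      p[[paste0("V_e", i)]], p[[paste0("V_v", i)]], p[[paste0("V_is", i)]])
  }
  out
}

# Total antibody amount in the system (nmol), for mass-balance checks.
total_antibody_amount <- function(state, params) {
  p <- params$pvec
  cn <- colnames(state)
  col <- function(nm) if (nm %in% cn) state[, nm] else 0
  amt <- (col("A_p") + col("ATs_p")) * p[["V_p"]] +
    (col("A_ep") + col("ATs_ep") + col("AF_ep") + col("ATF_ep")) * p[["V_ep"]] +
    (col("A_L") + col("ATs_L")) * p[["V_L"]]
  for (i in 1:2) {
    amt <- amt +
      (col(paste0("A_v", i)) + col(paste0("ATs_v", i)) +
         col(paste0("ATm_v", i)) + col(paste0("ARm_v", i))) * p[[paste0("V_v", i)]] +
      (col(paste0("A_e", i)) + col(paste0("ATs_e", i)) +
         col(paste0("AF_e", i)) + col(paste0("ATF_e", i))) * p[[paste0("V_e", i)]] +
      (col(paste0("A_is", i)) + col(paste0("ATs_is", i))) *
        p[["K_p"]] * p[[paste0("V_is", i)]]
  }
  amt
}
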