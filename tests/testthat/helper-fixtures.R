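# Shared small fixtures and a lazy cache for the expensive recovery fits so
# several test blocks can reuse one computation.

toy_tissue_table <- function() {
  data.frame(
    tissue = c("brain", "muscle", "skin", "adipose", "liver"),
    V_v_L = c(1, 2, 3, 4, 5) * 1e-5,
    V_e_L = c(1, 2, 3, 4, 5) * 1e-6,
    V_is_L = c(1, 2, 3, 4, 5) * 1e-4,
    Q_L_per_h = c(1, 2, 3, 4, 5) * 1e-2,
    L_L_per_h = c(1, 2, 3, 4, 5) * 1e-5)
}

toy_physiology <- function(tab = toy_tissue_table(), ...) {
  lump_tissues(tab, species_name = "toy", body_weight_kg = 0.028,
               V_p = 9.4e-4, V_lymph = 1e-4, V_ep = 3e-5,
               FcRn_total = 3000, GFR = 0.0167, ...)
}

.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fit_cache[[key]])) .fit_cache[[key]] <- builder()
  .fit_cache[[key]]
}

cached_recovery <- function(case, seed = 101L) {
  cached(paste0("recovery_", case), function() recovery_experiment(case, seed = seed))
}

# Independent reduced model: antibody-only system with no FcRn (all
# endosomal uptake is degraded or recycled is impossible without FcRn, so
# uptaken antibody is simply degraded at k_deg after entering the
# endosome).  9 states: plasma, plasma endosome, lymph, and per tissue
# vascular/endosome/interstitium.
reduced_no_fcrn_rhs <- function(t, y, p) {
  with(as.list(p), {
    A_p <- y[1]; A_ep <- y[2]; A_L <- y[3]
    d <- numeric(9)
    sumQ <- 0; ven <- 0; lym <- 0
    for (i in 1:2) {
      o <- 3 + (i - 1) * 3
      A_v <- y[o + 1]; A_e <- y[o + 2]; A_is <- y[o + 3]
      V_v <- get(paste0("V_v", i)); V_e <- get(paste0("V_e", i))
      V_is <- get(paste0("V_is", i))
      Q <- get(paste0("Q", i)); L <- get(paste0("L", i))
      CLup <- k_up * V_e
      Js <- get(paste0("Js", i)); sig <- get(paste0("sig", i))
      PS <- get(paste0("PS", i))
      TPA <- {
        conv <- Js * (1 - sig)
        Pe <- conv / PS
        conv * (A_v - A_is * exp(-Pe)) / (1 - exp(-Pe))
      }
      renal <- if (i == 2) CL_renal else 0
      d[o + 1] <- (Q * A_p - (Q - L) * A_v - TPA - 0.5 * CLup * A_v - renal * A_v) / V_v
      d[o + 2] <- CLup * (0.5 * A_v + 0.5 * A_is) / V_e - k_deg * A_e
      d[o + 3] <- (TPA - L * (1 - sigma_L) * A_is - 0.5 * CLup * A_is) / V_is
      sumQ <- sumQ + Q; ven <- ven + (Q - L) * A_v
      lym <- lym + L * (1 - sigma_L) * A_is
    }
    CLup_p <- k_up_p * V_ep
    d[1] <- (-sumQ * A_p + ven + L_total * A_L - CLup_p * A_p) / V_p
    d[2] <- CLup_p * A_p / V_ep - k_deg * A_ep
    d[3] <- (lym - L_total * A_L) / V_L
    list(d)
  })
}
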