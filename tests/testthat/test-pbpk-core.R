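test_that("compiled and reference right-hand sides agree exactly", {
  set.seed(11)
  cases <- list(
    scenario_wildtype_mouse(8)$params,
    scenario_charge_variant(5, 10)$params,
    scenario_anti_cea_mouse(1)$params,
    scenario_human_adalimumab(3)$params)
  for (p in cases) {
    for (rep in 1:5) {
      y <- runif(39, 0, 200)
      dR <- ode_rhs(0, y, p)[[1]]
      dC <- deSolve::DLLfunc(y = y, dllname = "mpbpk", func = "mpbpk_derivs",
                             initfunc = "mpbpk_initmod",
                             parms = unname(p$pvec), times = 0)$dy
      expect_equal(unname(dC), dR, tolerance = 1e-14)
    }
  }
})

test_that("initial state puts the dose in plasma and targets at steady state", {
  sc <- scenario_anti_cea_mouse(1)
  y0 <- initial_state(sc$params, 0.5)
  expect_equal(unname(y0["A_p"]), 0.5 / sc$params$pvec[["V_p"]])
  expect_equal(unname(y0["Tm_v1"]), 80)
  expect_equal(unname(y0["Ts_p"]), ngml_to_nM(2, 180000))
  expect_equal(unname(y0["F_ep"]), sc$params$pvec[["FcRn_total"]])
  expect_error(initial_state(sc$params, -1), "non-negative")
  # drug-free simulation stays at baseline for 1000 h
  pr <- simulate_pk(sc$params, dose_schedule(0, 0), seq(0, 1000, length.out = 21))
  expect_lt(max(abs(pr$state[, "Ts_p"] - y0[["Ts_p"]])), 1e-8 * y0[["Ts_p"]])
  expect_lt(max(abs(pr$state[, "Tm_v1"] - 80)), 1e-6)
  expect_lt(max(abs(pr$state[, "Ts_e2"] - y0[["Ts_e2"]])), 1e-8 * y0[["Ts_e2"]])
  expect_true(all(abs(pr$observables$plasma) < 1e-12))
})

test_that("antibody mass is conserved when all elimination routes are off", {
  sc <- scenario_wildtype_mouse(8)
  p0 <- rebuild_params(sc$params, list(k_deg = 0, CL_renal = 0))
  pr <- simulate_pk(p0, sc$schedule, seq(0, 2000, length.out = 41))
  amt <- mpbpk:::total_antibody_amount(pr$state, p0)
  expect_lt(max(abs(amt - amt[1]) / amt[1]), 1e-6)
})

test_that("FcRn is conserved in every endosome along a TMDD simulation", {
  sc <- scenario_anti_cea_mouse(10)
  pr <- simulate_scenario(sc, n = 80)
  Ftot <- sc$params$pvec[["FcRn_total"]]
  for (e in c("ep", "e1", "e2")) {
    tot <- pr$state[, paste0("F_", e)] + pr$state[, paste0("AF_", e)] +
      pr$state[, paste0("ATF_", e)]
    expect_lt(max(abs(tot - Ftot)) / Ftot, 1e-8)
  }
})

test_that("membrane NSB pool is conserved and complexes stay within it", {
  sc <- scenario_charge_variant(5, 10)
  pr <- simulate_scenario(sc, n = 80)
  Rm <- sc$params$pvec[["Rm_total"]]
  # ARm <= Rm_total; free receptor is Rm_total - ARm by construction
  expect_true(all(pr$state[, "ARm_v1"] <= Rm * (1 + 1e-10)))
  expect_true(all(pr$state[, "ARm_v2"] <= Rm * (1 + 1e-10)))
  expect_true(all(pr$state[, c("ARm_v1", "ARm_v2")] >= -1e-10))
})

test_that("FcRn removal reduces to an independent antibody-only model", {
  # reduced oracle: no FcRn, no targets, no NSB, explicit sigma slots
  sc <- scenario_wildtype_mouse(8)
  p <- rebuild_params(sc$params, list(FcRn_total = 0))
  pv <- p$pvec
  red_par <- c(V_p = pv[["V_p"]], V_ep = pv[["V_ep"]], V_L = pv[["V_L"]],
               V_v1 = pv[["V_v1"]], V_e1 = pv[["V_e1"]],
               V_is1 = pv[["K_p"]] * pv[["V_is1"]],
               V_v2 = pv[["V_v2"]], V_e2 = pv[["V_e2"]],
               V_is2 = pv[["K_p"]] * pv[["V_is2"]],
               Q1 = pv[["Q1"]], Q2 = pv[["Q2"]], L1 = pv[["L1"]], L2 = pv[["L2"]],
               L_total = pv[["L_total"]], sigma_L = pv[["sigma_L"]],
               k_up = pv[["k_up"]], k_up_p = pv[["k_up_p"]],
               k_deg = pv[["k_deg"]], CL_renal = pv[["CL_renal"]],
               Js1 = pv[["Js1"]], sig1 = pv[["sig_s1"]], PS1 = pv[["PS_s1"]],
               Js2 = pv[["Js2"]], sig2 = pv[["sig_s2"]], PS2 = pv[["PS_s2"]])
  dose <- sum(sc$schedule$amount_nmol)
  y0 <- c(dose / pv[["V_p"]], rep(0, 8))
  times <- seq(0, 300, length.out = 31)
  red <- deSolve::lsoda(y0, times, reduced_no_fcrn_rhs, red_par,
                        rtol = 1e-10, atol = 1e-12)
  full <- simulate_pk(p, sc$schedule, times, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(full$observables$plasma), unname(red[, 2]),
               tolerance = 1e-6)
  expect_equal(unname(full$state[, "A_is2"]), unname(red[, 10]),
               tolerance = 1e-5)
})

test_that("renal elimination acts only on the leaky vascular space", {
  sc <- scenario_size_variant(50000, 5)  # small fragment, active renal route
  expect_gt(sc$params$pvec[["CL_renal"]], 1e-4)
  times <- seq(0, 100, length.out = 21)
  base <- simulate_scenario(sc, times = times)
  # removing renal clearance must raise exposure; removing it from a model
  # whose leaky vascular antibody is zeroed must not change anything else
  norenal <- rebuild_params(sc$params, list(CL_renal = 0))
  pr2 <- simulate_pk(norenal, sc$schedule, times)
  expect_gt(auc(pr2), auc(base))
  # flux check at a state with antibody only in tight vascular space:
  # derivative difference appears nowhere (renal term touches A_v2/ATs_v2 only)
  y <- setNames(numeric(39), state_names()); y["A_v1"] <- 50
  d_with <- ode_rhs(0, y, sc$params)[[1]]
  d_without <- ode_rhs(0, y, norenal)[[1]]
  expect_equal(d_with, d_without)
  y["A_v2"] <- 50
  d2_with <- ode_rhs(0, y, sc$params)[[1]]
  d2_without <- ode_rhs(0, y, norenal)[[1]]
  i_Av2 <- match("A_v2", state_names())
  expect_lt(d2_with[i_Av2], d2_without[i_Av2])
  expect_equal(d2_with[-i_Av2], d2_without[-i_Av2])
})

test_that("lumped concentrations are volume-weighted means", {
  expect_equal(lumped_tissue_concentration(3, 3, 3, 1, 2, 7), 3)
  expect_equal(lumped_tissue_concentration(0, 10, 0, 1, 2, 7), 2)
  set.seed(5)
  for (i in 1:10) {
    C <- runif(3, 0, 100); V <- runif(3, 0.1, 5)
    expect_equal(lumped_tissue_concentration(C[1], C[2], C[3], V[1], V[2], V[3]),
                 sum(C * V) / sum(V))
  }
  expect_error(lumped_tissue_concentration(1, 1, 1, 0, 1, 1), "positive")
})

test_that("observed lumping pools amounts over volumes", {
  amounts <- c(brain = 2, muscle = 8, skin = 6, adipose = 4, liver = 10)
  volumes <- c(brain = 0.5, muscle = 11, skin = 5, adipose = 2, liver = 2)
  tight <- c("brain", "muscle", "skin", "adipose")
  expect_equal(observed_lumping(amounts, volumes, tight),
               sum(amounts[tight]) / sum(volumes[tight]))
  expect_equal(observed_lumping(amounts, volumes, "liver"), 5)
  eq <- c(a = 3, b = 3, c = 3, d = 3); vv <- c(a = 2, b = 2, c = 2, d = 2)
  expect_equal(observed_lumping(eq, vv, names(eq)), 1.5)
  expect_error(observed_lumping(amounts, volumes, c("brain", "bone")), "bone")
})

test_that("membrane-target degradation from a 36 h half-life is 0.019 1/h", {
  sc <- scenario_anti_cea_mouse(1)
  expect_equal(signif(sc$params$pvec[["k_p_Tm"]], 2), 0.019)
})
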