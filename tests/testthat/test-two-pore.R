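test_that("hindrance factors match independent closed-form evaluation", {
  # lambda = 0.5 oracle, evaluated by direct arithmetic
  h <- hindrance_and_reflection(2.22, 4.44)
  expect_equal(h$lambda, 0.5)
  expect_equal(h$partition, 0.25)
  expect_equal(h$diffusive_hindrance,
               0.25 * (1 - 2.104 * 0.5 + 2.09 * 0.125 - 0.95 * 0.03125),
               tolerance = 1e-12)
  expect_equal(h$sigma_pore, (1 - 0.25)^2)
  # point solute and steric exclusion limits
  h0 <- hindrance_and_reflection(0, 4.44)
  expect_equal(h0$sigma_pore, 0)
  expect_equal(h0$partition, 1)
  h1 <- hindrance_and_reflection(5, 4.44)
  expect_equal(h1$sigma_pore, 1)
  expect_equal(h1$diffusive_hindrance, 0)
  # a 150 kDa IgG is fully excluded from the small pores
  expect_equal(hindrance_and_reflection(stokes_radius_from_mw(150000), 4.44)$sigma_pore, 1)
  expect_error(hindrance_and_reflection(-1, 4), "non-negative")
})

test_that("sigma_pore is strictly increasing in lambda and bounded", {
  lam <- seq(0.001, 0.999, length.out = 400)
  s <- hindrance_and_reflection(lam, 1)$sigma_pore
  expect_true(all(diff(s) > 0))
  expect_true(all(s >= 0 & s <= 1))
  H <- hindrance_and_reflection(lam, 1)$diffusive_hindrance
  expect_true(all(H >= 0 & H <= 1))
})

test_that("two-pore parameters satisfy flow balance and Peclet definitions", {
  for (a_e in c(1, 3.15, 4.8)) {
    p <- two_pore_params(a_e, 1e-4)
    expect_equal(sum(p$J), 1e-4)
    expect_equal(sum(p$alpha), 1)
    expect_gte(p$sigma[["small"]], p$sigma[["large"]])
    for (k in c("small", "large"))
      if (is.finite(p$Pe[[k]]))
        expect_equal(p$Pe[[k]], p$J[[k]] * (1 - p$sigma[[k]]) / p$PS[[k]])
    expect_equal(p$sigma_eff, sum(p$alpha * p$sigma))
  }
  # small solutes approach free fluid movement
  expect_lt(two_pore_params(0.01, 1e-4)$sigma_eff, 1e-3)
  # IgG-sized solutes are strongly reflected (same magnitude as the
  # fitted effective coefficients around 0.86-0.9)
  s_igg <- two_pore_params(stokes_radius_from_mw(150000), 1e-4)$sigma_eff
  expect_gt(s_igg, 0.8)
  expect_lte(s_igg, 1)
  expect_error(two_pore_params(4.8, 0), "positive")
})

test_that("transcapillary flux obeys the Patlak limits", {
  p <- two_pore_params(3.15, 1e-4)
  expect_equal(transcapillary_flux(0, 0, p), 0)
  # diffusion limit: construct a pure-diffusion parameter set (J = 0)
  pd <- p; pd$J[] <- 0
  expect_equal(transcapillary_flux(10, 0, pd), sum(pd$PS) * 10, tolerance = 1e-12)
  expect_equal(transcapillary_flux(7, 7, pd), 0, tolerance = 1e-12)
  # at equal concentrations convection remains: sum J_k (1 - sigma_k) C
  C <- 5
  expect_equal(transcapillary_flux(C, C, p),
               sum(p$J * (1 - p$sigma)) * C, tolerance = 1e-10)
  # continuity at small Pe: analytic limit equals evaluation at Pe +/- eps
  for (eps in c(1e-10, 1e-12)) {
    f <- mpbpk:::patlak_flux(8, 3, eps, 0, 1e-5)
    expect_equal(f, 1e-5 * (8 - 3), tolerance = 1e-4)
  }
  # generic continuity: flux is continuous in J around any point
  f0 <- mpbpk:::patlak_flux(8, 3, 2e-5, 0.4, 1e-5)
  f1 <- mpbpk:::patlak_flux(8, 3, 2e-5 * (1 + 1e-8), 0.4, 1e-5)
  expect_equal(f0, f1, tolerance = 1e-6)
})

test_that("sieving curve is monotone, near-total above 4 nm, and refittable", {
  sv <- default_sieving_curve()
  a <- seq(0.2, 6, length.out = 300)
  th <- sieving_coefficient(a, sv)
  expect_true(all(diff(th) < 0))
  expect_true(all(th >= 0 & th <= 1))
  expect_gt(sieving_coefficient(0.05, sv), 0.999)
  expect_lt(sieving_coefficient(4, sv), 1e-3)
  expect_lt(sieving_coefficient(stokes_radius_from_mw(150000), sv), 1e-3)
  # refit oracle: refitting the packaged fixture reproduces the curve
  refit <- fit_sieving_curve(read_sieving_table())
  expect_equal(sieving_coefficient(3.15, refit),
               sieving_coefficient(3.15, sv), tolerance = 1e-10)
  expect_error(sieving_coefficient(3, list(a0 = NULL)), "required")
})

test_that("renal clearance is GFR times theta with domain checks", {
  expect_equal(renal_clearance(0.0167, 0), 0)
  expect_equal(renal_clearance(0.0167, 1), 0.0167)
  expect_equal(renal_clearance(0.01668, 0.05), 8.34e-4, tolerance = 1e-12)
  expect_error(renal_clearance(0.0167, 1.2), "0, 1")
  expect_error(renal_clearance(0, 0.5), "positive")
})
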