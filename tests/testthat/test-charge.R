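test_that("K_p quadratic passes exactly through the calibration anchors", {
  rel <- default_charge_relations()
  expect_equal(kp_from_charge(0, rel), 1)
  expect_equal(kp_from_charge(5, rel), 0.8, tolerance = 1e-10)
  expect_equal(kp_from_charge(-8, rel), 0.62, tolerance = 1e-10)
  # coefficients equal the solution of the 3x3 interpolation system
  # (oracle: base solve() on the Vandermonde system)
  V <- rbind(c(64, -8, 1), c(0, 0, 1), c(25, 5, 1))
  abc <- solve(V, c(0.62, 1, 0.8))
  expect_equal(unname(rel$kp_coeffs), unname(abc), tolerance = 1e-10)
  expect_equal(unname(rel$kp_coeffs["a"]), -0.006731, tolerance = 1e-3)
  expect_equal(unname(rel$kp_coeffs["b"]), -0.006346, tolerance = 1e-3)
})

test_that("K_D,NSB curve hits the anchors, stays positive and decreases", {
  rel <- default_charge_relations()
  expect_equal(kdnsb_from_charge(0, rel), 8.35, tolerance = 1e-4)
  expect_equal(kdnsb_from_charge(5, rel), 1.21, tolerance = 1e-4)
  expect_equal(kdnsb_from_charge(-8, rel), 16.22, tolerance = 1e-4)
  z <- seq(-10, 10, length.out = 300)
  kd <- kdnsb_from_charge(z, rel)
  expect_true(all(kd > 0))
  expect_true(all(diff(kd) < 0))
})

test_that("S_pino is 1 except for positive charge in leaky tissue", {
  rel <- default_charge_relations()
  expect_equal(spino_from_charge(0, "leaky", rel), 1)
  expect_equal(spino_from_charge(5, "leaky", rel), 2.99, tolerance = 1e-10)
  expect_equal(spino_from_charge(-8, "leaky", rel), 1)
  expect_equal(spino_from_charge(-8, "tight", rel), 1)
  expect_equal(spino_from_charge(5, "tight", rel), 1)
  z <- seq(-10, 10, by = 0.5)
  expect_true(all(spino_from_charge(z, "leaky", rel) >= 1))
  expect_error(spino_from_charge(2, "kidney"), "arg")
})

test_that("charge outside the valid range is clamped with a warning", {
  rel <- default_charge_relations()
  expect_warning(v <- kp_from_charge(12, rel), "clamped")
  expect_equal(v, kp_from_charge(10, rel))
  expect_warning(kdnsb_from_charge(-15, rel), "clamped")
})

test_that("refitting reproduces anchors and responds locally to perturbation", {
  anchors <- default_charge_anchors()
  rel <- fit_charge_relations(anchors)
  for (r in seq_len(nrow(anchors))) {
    expect_equal(kp_from_charge(anchors$z[r], rel), anchors$K_p[r],
                 tolerance = 0.01)
    expect_equal(kdnsb_from_charge(anchors$z[r], rel), anchors$K_D_NSB[r],
                 tolerance = 0.01)
  }
  # anchors already on a quadratic -> exact coefficient recovery
  quad <- data.frame(z = c(-6, 0, 4), K_p = c(-0.002 * 36 + 0.01 * -6 + 1,
                                              1, -0.002 * 16 + 0.01 * 4 + 1),
                     K_D_NSB = c(20, 10, 2), S_pino = c(1, 1, 2))
  relq <- fit_charge_relations(quad)
  expect_equal(unname(relq$kp_coeffs[c("a", "b")]), c(-0.002, 0.01),
               tolerance = 1e-8)
  # +10% on the negative K_D anchor: curve still monotone, positive anchors
  # nearly unchanged
  pert <- anchors; pert$K_D_NSB[1] <- pert$K_D_NSB[1] * 1.1
  relp <- fit_charge_relations(pert)
  z <- seq(-10, 10, length.out = 200)
  expect_true(all(diff(kdnsb_from_charge(z, relp)) < 0))
  expect_equal(kdnsb_from_charge(5, relp), 1.21, tolerance = 0.05)
  expect_error(fit_charge_relations(anchors[1:2, ]), "3 anchors")
})

test_that("NSB association rate is pinned to the FcRn association rate", {
  phys <- toy_physiology()
  ab <- antibody_descriptor("igg", MW = 150000, net_charge = 5, k1on = 0.123)
  p <- model_params(phys, ab, Rm_total = 71.86)
  expect_equal(unname(p$pvec[["kon_NSB"]]), 0.123)
  expect_equal(unname(p$pvec[["koff_NSB"]]), 0.123 * p$K_D_NSB)
})
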