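test_that("normalized SSE matches brute-force recomputation", {
  expect_equal(normalized_sse(c(1, 2, 3), c(1, 2, 3)), 0)
  # single point, pred - obs = 2, observed mean 4 -> 4/4 = 1
  expect_equal(normalized_sse(6, 4), 1)
  set.seed(3)
  ds <- data.frame(time_h = rep(1:5, 2),
                   observable = rep(c("plasma", "tight_total"), each = 5),
                   value = runif(10, 1, 10))
  pred <- ds; pred$value <- ds$value + rnorm(10)
  # brute force: per-observable SSE over per-observable mean, summed
  brute <- 0
  for (g in unique(ds$observable)) {
    i <- ds$observable == g
    brute <- brute + sum((pred$value[i] - ds$value[i])^2) / mean(ds$value[i])
  }
  expect_equal(normalized_sse(pred, ds), brute)
  expect_error(normalized_sse(numeric(0), numeric(0)), "non-empty")
  expect_error(normalized_sse(1, 0), "zero")
})

test_that("rebuild and getters round-trip model parameters", {
  sc <- scenario_anti_cea_mouse(1)
  p2 <- rebuild_params(sc$params, list(k_up = 0.1, sigma_1 = 0.7,
                                       k_int = 0.03, L_2 = 1e-3,
                                       FcRn_total = 500))
  expect_equal(get_model_param(p2, "k_up"), 0.1)
  expect_equal(get_model_param(p2, "sigma_1"), 0.7)
  expect_equal(get_model_param(p2, "k_int"), 0.03)
  expect_equal(get_model_param(p2, "L_2"), 1e-3)
  expect_equal(p2$pvec[["FcRn_total"]], 500)
  # lymph totals re-derived from the lump flows
  expect_equal(p2$pvec[["L_total"]], p2$physiology$tight$L + 1e-3)
  expect_error(rebuild_params(sc$params, list(nonsense = 1)), "unknown")
})

test_that("sensitivity is zero for parameters absent from active fluxes", {
  sc <- scenario_wildtype_mouse(8)   # no target configured
  sens <- local_sensitivity(sc, parameters = c("k_int", "k_p_Tm", "k_up"),
                            n = 60, t_end_mult = 1)
  zeroed <- sens[sens$parameter %in% c("k_int", "k_p_Tm"), "dAUC_pct"]
  expect_true(all(zeroed == 0))
  expect_true(all(sens[sens$parameter == "k_up", "dAUC_pct"] != 0))
})

test_that("a parameter that doubles exposure reports +100%", {
  sc <- scenario_wildtype_mouse(8)
  sens <- local_sensitivity(sc, parameters = "k_deg", perturbation = 0.2,
                            n = 80, t_end_mult = 1)
  base <- simulate_pk(sc$params, sc$schedule, seq(0, sc$t_end, length.out = 80))
  pert <- simulate_pk(rebuild_params(sc$params, list(k_deg = sc$params$args$k_deg * 1.2)),
                      sc$schedule, seq(0, sc$t_end, length.out = 80))
  manual <- (auc(pert) - auc(base)) / auc(base) * 100
  expect_equal(sens$dAUC_pct[sens$observable == "plasma"], manual,
               tolerance = 1e-8)
})

test_that("multistart fitting is deterministic and converges from truth", {
  sc <- scenario_fcrn_ko_mouse(8)
  times <- c(1, 6, 24, 72, 168, 336)
  ds <- generate_pk_dataset(sc$params, sc$schedule, times)
  free <- list(k_up = c(0.15, 0.1501))  # one start essentially at truth
  f1 <- multistart_fit(sc, ds, free, n_starts = 1, seed = 4, polish = 0)
  expect_lt(f1$sse, 1e-8)
  expect_equal(unname(f1$estimates["k_up"]), 0.15, tolerance = 1e-4)
  # identical seeds give identical per-start tables
  free2 <- list(k_up = c(0.01, 1))
  f2 <- multistart_fit(sc, ds, free2, n_starts = 3, seed = 9, polish = 0)
  f3 <- multistart_fit(sc, ds, free2, n_starts = 3, seed = 9, polish = 0)
  expect_identical(f2$starts, f3$starts)
  expect_error(multistart_fit(sc, ds[0, ], free2), "empty")
  expect_error(multistart_fit(sc, ds, list()), "free")
})

test_that("noiseless self-generated data are recovered to within 2%", {
  rec <- cached_recovery("fcrn_ko")
  expect_lt(abs(rec$fit$estimates[["k_up"]] - rec$truth[["k_up"]]) /
              rec$truth[["k_up"]], 0.02)
  expect_lt(rec$fit$sse, 1e-6)
})
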