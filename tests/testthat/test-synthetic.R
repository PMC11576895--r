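test_that("noiseless datasets equal model output at the sample times", {
  sc <- scenario_wildtype_mouse(8)
  times <- c(1, 24, 168, 504)
  ds <- generate_pk_dataset(sc$params, sc$schedule, times)
  pr <- simulate_pk(sc$params, sc$schedule, times)
  idx <- match(times, pr$time_h)
  for (obs in c("plasma", "tight_total", "leaky_total"))
    expect_equal(ds$value[ds$observable == obs], pr$observables[[obs]][idx])
  expect_true(all(!ds$below_lloq))
})

test_that("noisy generation is seed-reproducible and median-preserving", {
  sc <- scenario_wildtype_mouse(8)
  times <- c(1, 24, 168)
  nm <- noise_model("lognormal", cv = 0.15, seed = 77)
  a <- generate_pk_dataset(sc$params, sc$schedule, times, nm)
  b <- generate_pk_dataset(sc$params, sc$schedule, times, nm)
  expect_identical(a$value, b$value)
  c2 <- generate_pk_dataset(sc$params, sc$schedule, times,
                            noise_model("lognormal", cv = 0.15, seed = 78))
  expect_false(identical(a$value, c2$value))
})

test_that("log-normal noise has the nominal log-scale spread", {
  # distributional oracle: sd(log(noisy/clean)) ~ sqrt(log(1 + cv^2))
  sc <- scenario_wildtype_mouse(8)
  times <- seq(1, 500, length.out = 334)  # ~1000 points over 3 observables
  clean <- generate_pk_dataset(sc$params, sc$schedule, times)
  noisy <- generate_pk_dataset(sc$params, sc$schedule, times,
                               noise_model("lognormal", cv = 0.15, seed = 5))
  eps <- log(noisy$value / clean$value)
  expect_equal(mean(eps), 0, tolerance = 0.02)
  expect_equal(sd(eps), sqrt(log(1 + 0.15^2)), tolerance = 0.1 * sqrt(log(1 + 0.15^2)))
})

test_that("values below the LLOQ are flagged, not removed", {
  sc <- scenario_fcrn_ko_mouse(8)
  times <- c(1, 100, 300, 504)
  ds <- generate_pk_dataset(sc$params, sc$schedule, times,
                            noise_model("none", lloq = 1))
  expect_equal(nrow(ds), 12)
  expect_true(any(ds$below_lloq))
  expect_true(all(ds$value[ds$below_lloq] < 1))
})

test_that("datasets round-trip through the CSV schema", {
  sc <- scenario_wildtype_mouse(8)
  ds <- generate_pk_dataset(sc$params, sc$schedule, c(1, 24))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(ds, path)
  back <- read_pk_dataset(path)
  expect_equal(back$value, ds$value)
  expect_setequal(names(back), c("time_h", "observable", "value", "unit"))
})

test_that("scenario fixtures carry the case-study doses", {
  fx <- scenario_fixtures()
  expect_equal(fx$size_50kDa$dose_mg_per_kg, 5)
  expect_equal(fx$size_150kDa$dose_mg_per_kg, 5)
  expect_equal(fx$charge_pos5$dose_mg_per_kg, 10)
  expect_equal(fx$charge_neg8$dose_mg_per_kg, 10)
  expect_equal(unname(sapply(fx[c("anti_cea_1mgkg", "anti_cea_10mgkg",
                                  "anti_cea_25mgkg")], `[[`, "dose_mg_per_kg")),
               c(1, 10, 25))
  expect_equal(fx$wildtype_mouse$dose_mg_per_kg, 8)
  # the 50 kDa fragment does not bind FcRn; full IgG does
  expect_false(fx$size_50kDa$params$antibody$fcrn_binding)
  expect_true(fx$size_150kDa$params$antibody$fcrn_binding)
})
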