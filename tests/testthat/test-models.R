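test_that("presets carry the estimated mouse demographic parameters", {
  fl <- preset_model("florida")
  expect_equal(fl$demography$N_anc, 2482)
  expect_equal(fl$demography$f, 0.001)
  expect_equal(fl$demography$c_recovery, 0.413)
  expect_equal(fl$demography$d, 1.225)
  nb <- preset_model("nebraska")
  expect_equal(nb$demography$N_anc, 53080)
  expect_equal(nb$demography$f, 0.004)
  expect_equal(nb$demography$c_recovery, 0.662)
  expect_equal(nb$demography$d, 0.067)
  # rounded power-study variants
  expect_equal(preset_model("florida-table2")$demography$N_anc, 2500)
  expect_equal(preset_model("nebraska-table2")$demography$N_anc, 50000)
  # shared region conventions
  expect_equal(fl$region$L, 180000)
  expect_equal(fl$region$n, 40L)
  expect_equal(fl$region$mu, 3.7e-8)
  expect_equal(fl$region$r, 5.6e-7)
})

test_that("unknown presets raise an error naming the valid choices", {
  expect_error(preset_model("oldfield"), "valid presets")
})

test_that("theta_per_site is 4 N mu", {
  fl <- preset_model("florida")
  expect_equal(theta_per_site(fl$demography, fl$region), 4 * 2482 * 3.7e-8)
  # agreement with the published estimate to rounding
  expect_equal(theta_per_site(fl$demography, fl$region), 3.672e-4,
               tolerance = 5e-4)
  nb <- preset_model("nebraska")
  expect_equal(theta_per_site(nb$demography, nb$region), 7.856e-3,
               tolerance = 1e-4)
})

test_that("model invariants are enforced", {
  expect_error(demographic_model(1, 0.1, 0.5, 1, 0.1), "N_anc")
  expect_error(demographic_model(100, 0, 0.5, 1, 0.1), "severity")
  expect_error(demographic_model(100, 1.5, 0.5, 1, 0.1), "severity")
  expect_warning(demographic_model(100, 0.1, 1.5, 1, 0.1), "exceeds")
  expect_error(demographic_model(100, 0.1, 0.5, 1, 1.2), "t_r < d")
  expect_error(sweep_model(-0.1, 0.1), "positive")
  expect_error(region_config(n = 1), "n")
  expect_error(study_config(alpha_level = 1.2), "alpha_level")
})

test_that("time conversions work both ways and into ms units", {
  m <- preset_model("florida")$demography
  expect_equal(time_to_generations(1.225, m), 1.225 * 2 * 2482)
  expect_equal(generations_to_time(time_to_generations(0.3, m), m), 0.3)
  # ms scales time by 4N, so our 2N-based times halve
  expect_equal(time_to_ms_units(0.2), 0.1)
})

test_that("preset configurations round-trip through the plain-text format", {
  p <- preset_model("nebraska")
  cfg <- list(demography = p$demography, region = p$region,
              sweep = sweep_model(0.01, 0.02, 90000),
              study = study_config(n_replicates = 7, seed = 3L))
  path <- tempfile(fileext = ".cfg")
  write_model_config(cfg, path)
  back <- read_model_config(path)
  expect_equal(back$demography, p$demography)
  expect_equal(back$region, p$region)
  expect_equal(back$sweep$s, 0.01)
  expect_equal(back$study$n_replicates, 7L)
})

test_that("derived seeds are valid and distinct across counters", {
  s <- vapply(0:99, function(i) derive_seed(42L, i), integer(1))
  expect_true(all(s > 0))
  expect_equal(length(unique(s)), 100L)
})

test_that("the sweep-footprint approximation follows 0.01 s / r", {
  expect_equal(expected_sweep_width(0.1, 5.6e-7), 0.001 / 5.6e-7)
  expect_equal(expected_sweep_width(0.1, 5.6e-7), 1786, tolerance = 1e-3)
  expect_equal(expected_sweep_width(0.001, 5.6e-7), 17.9, tolerance = 1e-2)
  expect_error(expected_sweep_width(0.1, 0), "zero")
})
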