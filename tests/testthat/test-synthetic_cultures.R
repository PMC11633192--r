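test_that("latent state conserves nitrogen exactly at every time point", {
  for (sub in c("NO3", "NO2")) {
    cfg <- culture_config(sub)
    lat <- simulate_culture(cfg)$latent
    total <- lat$no3 + lat$no2 + lat$nh4 + lat$n2o_n + lat$other
    expect_lt(max(abs(total - cfg$conc_mM)) / cfg$conc_mM, 1e-6)
  }
})

test_that("zero N2O yield produces no N2O at any time", {
  cfg <- culture_config("NO3", y_n2o = 0)
  ts <- simulate_culture(cfg)
  expect_true(all(ts$data$n2o_total == 0))
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- culture_config("NO3")
  a <- simulate_culture(cfg, seed = 4, measurement_noise = TRUE)
  b <- simulate_culture(cfg, seed = 4, measurement_noise = TRUE)
  expect_identical(a$data, b$data)
  c <- simulate_culture(cfg, seed = 5, measurement_noise = TRUE)
  expect_false(identical(a$data, c$data))

  ia <- simulate_isotopes(cfg, seed = 4)
  ib <- simulate_isotopes(cfg, seed = 4)
  expect_identical(ia, ib)
})

test_that("default NO3 run reproduces the expected end-stage structure", {
  cfg <- culture_config("NO3")
  ts <- simulate_culture(cfg)
  comp <- end_stage_composition(ts)
  expect_lt(comp$NO3, 0.01) # substrate fully consumed
  expect_gt(comp$NH4, 0.6) # ammonium is the main product
  expect_true(comp$NO2 >= 0.03 && comp$NO2 <= 0.20) # residual nitrite band
  ratio <- conversion_ratio(ts, "N2O")
  expect_lt(abs(ratio - cfg$y_n2o), 0.002)
  # transient accumulation: the NO2 peak exceeds its final value
  expect_gt(max(ts$data$no2), utils::tail(ts$data$no2, 1) * 1.5)
})

test_that("configured yields are recovered exactly from a nitrite-fed run", {
  cfg <- culture_config("NO2", y_nh4 = 0.65, y_n2o = 0.01)
  ts <- simulate_culture(cfg)
  expect_equal(conversion_ratio(ts, "NH4"), 0.65, tolerance = 1e-9)
  expect_equal(conversion_ratio(ts, "N2O"), 0.01, tolerance = 1e-9)
})

test_that("N2O production tracks nitrite accumulation in accumulating cultures", {
  # weak-nitrite-reducer phenotype: NO2 builds up, no ammonium
  cfg <- culture_config("NO3", y_nh4 = 0, y_n2o = 0.02,
                        k_consume = 0.06, k_nitrite = 0.015)
  fit <- production_association(simulate_culture(cfg))
  expect_gte(fit$r_squared, 0.7)
  expect_gt(fit$slope, 0)
})

test_that("unstable integration is caught rather than silently clamped", {
  cfg <- culture_config("NO3", k_consume = 2000, dt = 0.1)
  expect_error(simulate_culture(cfg), "smaller dt")
})

test_that("isotope tables honour the configured pathway mixture", {
  # pure DNRA with all randomness off gives the endmember exactly
  pure <- culture_config("NO3", f_dnra = 1, sp_dnra_sd = 0, sp_cnor_sd = 0,
                         eps15n_sd = 0, eps18o_sd = 0,
                         noise = list(d15n_bulk = 0, sp = 0, d18o = 0,
                                      conc_rel = 0))
  tab <- simulate_isotopes(pure, seed = 1)
  expect_true(all(tab$SP == 46.2))

  # 90:10 mixture of the two endmembers
  mix <- culture_config("NO3", f_dnra = 0.9, sp_dnra_sd = 0, sp_cnor_sd = 0,
                        eps15n_sd = 0, eps18o_sd = 0,
                        noise = list(d15n_bulk = 0, sp = 0, d18o = 0,
                                     conc_rel = 0))
  tab_mix <- simulate_isotopes(mix, seed = 1)
  expect_equal(unique(tab_mix$SP), 0.9 * 46.2 + 0.1 * -5.9, tolerance = 1e-12)

  # raw-scale deltas sit at substrate composition plus the configured offsets
  expect_equal(unique(tab$d15N_bulk), 2.4 - 24.6, tolerance = 1e-12)
  expect_equal(unique(tab$d18O), 17.9 + 23.6, tolerance = 1e-12)
})

test_that("generated tables satisfy the isotopocule identities by construction", {
  cfg <- culture_config("NO2", n_replicates = 4)
  tab <- simulate_isotopes(cfg, seed = 8)
  expect_equal(nrow(tab), 8) # 4 replicates x 2 days
  out <- complete_isotopocule(tab)
  expect_true(all(out$consistent))
  expect_lt(max(out$residual), 1e-9)
})

test_that("config invariants are enforced", {
  expect_error(culture_config("NO3", y_nh4 = 0.9, y_n2o = 0.2))
  expect_error(culture_config("NO3", f_dnra = 1.2))
  expect_error(culture_config("NO3", dt = 0.5))
})
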