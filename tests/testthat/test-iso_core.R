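test_that("completion fills the missing 15N quantities from any sufficient pair", {
  cases <- list(
    # (given fields) -> expected completed record
    list(given = list(d15N_bulk = 0, d15N_alpha = 0),
         want = c(d15N_alpha = 0, d15N_beta = 0, d15N_bulk = 0, SP = 0)),
    list(given = list(d15N_bulk = 10, d15N_alpha = 30),
         want = c(d15N_alpha = 30, d15N_beta = -10, d15N_bulk = 10, SP = 40)),
    list(given = list(d15N_bulk = -39.8, SP = 46.5),
         want = c(d15N_alpha = -16.55, d15N_beta = -63.05,
                  d15N_bulk = -39.8, SP = 46.5)),
    list(given = list(d15N_alpha = 5, d15N_beta = -3),
         want = c(d15N_alpha = 5, d15N_beta = -3, d15N_bulk = 1, SP = 8)),
    list(given = list(d15N_beta = -63.05, SP = 46.5),
         want = c(d15N_alpha = -16.55, d15N_beta = -63.05,
                  d15N_bulk = -39.8, SP = 46.5))
  )
  for (cs in cases) {
    m <- do.call(isotope_measurement, c(list(sample_id = "x"), cs$given))
    out <- complete_isotopocule(m)
    expect_equal(unlist(out[1, names(cs$want)]), cs$want, tolerance = 1e-12)
    expect_true(out$consistent[1])
  }
})

test_that("under-determined and inconsistent inputs are rejected with diagnostics", {
  only_sp <- isotope_measurement("x", SP = 46.5)
  expect_error(complete_isotopocule(only_sp), "under-determined")

  # alpha/beta/bulk mutually inconsistent by 1 permil
  bad <- isotope_measurement("x", d15N_alpha = 10, d15N_beta = 0, d15N_bulk = 6)
  expect_error(complete_isotopocule(bad), "residual")
  flagged <- complete_isotopocule(bad, on_inconsistent = "flag")
  expect_false(flagged$consistent[1])
  expect_gt(flagged$residual[1], 0.01)

  # inconsistency below tolerance passes
  near <- isotope_measurement("x", d15N_alpha = 10, d15N_beta = 0, d15N_bulk = 5.004)
  expect_true(complete_isotopocule(near)$consistent[1])
})

test_that("dropping any one field of a consistent record is recoverable", {
  withr::with_seed(42, {
    for (i in 1:20) {
      rec <- complete_isotopocule(random_consistent_record())
      for (col in c("d15N_alpha", "d15N_beta", "d15N_bulk", "SP")) {
        partial <- rec
        partial[[col]] <- NA_real_
        refilled <- complete_isotopocule(partial)
        expect_equal(refilled[[col]], rec[[col]], tolerance = 1e-9)
      }
    }
  })
})

test_that("substrate referencing subtracts the substrate composition and leaves SP alone", {
  m <- complete_isotopocule(
    isotope_measurement("red32_no3_3d", substrate = "NO3",
                        d15N_bulk = -37.4, SP = 46.5, d18O = 34.1)
  )
  ref <- substrate_reference(m, "NO3")
  expect_equal(ref$d15N_bulk, -37.4 - 2.4) # -39.8
  expect_equal(ref$d18O, 34.1 - 17.9)
  expect_equal(ref$SP, 46.5) # reference-frame invariant
  expect_true(ref$referenced)

  # value equal to the substrate maps to zero
  z <- substrate_reference(
    isotope_measurement("z", substrate = "NO3", d15N_bulk = 2.4,
                        SP = 0, d18O = 17.9), "NO3")
  expect_equal(z$d15N_bulk, 0)
  expect_equal(z$d18O, 0)

  expect_error(substrate_reference(ref, "NO3"), "double-reference")
  back <- substrate_unreference(ref, "NO3")
  expect_equal(back$d15N_bulk, m$d15N_bulk, tolerance = 1e-12)
  expect_equal(back$d18O, m$d18O, tolerance = 1e-12)
  expect_false(back$referenced)
})

test_that("referencing keeps completed records internally consistent", {
  withr::with_seed(7, {
    rec <- complete_isotopocule(random_consistent_record())
    ref <- substrate_reference(rec, "NO2")
    expect_equal(ref$SP, ref$d15N_alpha - ref$d15N_beta, tolerance = 1e-12)
    expect_equal(ref$d15N_bulk, (ref$d15N_alpha + ref$d15N_beta) / 2,
                 tolerance = 1e-12)
  })
})

test_that("every biotic reference row passes consistency completion", {
  tab <- load_reference_isotopes()
  biotic <- tab[tab$biotic, ]
  m <- isotope_measurement(
    sample_id = paste(biotic$strain, biotic$substrate, biotic$day),
    strain = biotic$strain, substrate = biotic$substrate, day = biotic$day,
    d15N_bulk = biotic$d15N_bulk, SP = biotic$SP, d18O = biotic$d18O,
    referenced = TRUE
  )
  expect_no_error(out <- complete_isotopocule(m))
  expect_true(all(out$consistent))
  expect_equal(nrow(out), 22)
})

test_that("shipped substrate references carry the measured compositions", {
  no3 <- substrate_reference_values("NO3")
  no2 <- substrate_reference_values("NO2")
  expect_equal(c(no3$d15N, no3$d18O), c(2.4, 17.9))
  expect_equal(c(no2$d15N, no2$d18O), c(-1.8, 3.7))
  expect_true(all(c(no3$d15N_sd, no3$d18O_sd, no2$d15N_sd, no2$d18O_sd) >= 0))
})
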