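ref_point <- function(sp = NA, d15n = NA, d18o = NA) {
  tibble::tibble(SP = sp, d15N_bulk = d15n, d18O = d18o, referenced = TRUE)
}

test_that("zone membership uses closed intervals over the defined axes", {
  dn <- dnra_zone()
  # a nitrite-fed culture observation sits in the DNRA box
  expect_equal(classify_zones(ref_point(46.8, -23.7, 27.8), dn)[[1]], "DN")
  # the abiotic observation is far below the SP range
  expect_equal(classify_zones(ref_point(20.0, -28.8, 20.1), dn)[[1]], character(0))
  # boundary points match (closed intervals)
  expect_equal(classify_zones(ref_point(43.0, -39.9, 30.5), dn)[[1]], "DN")
  # empty library matches nothing
  expect_equal(classify_zones(ref_point(46.8, -23.7, 27.8), list())[[1]],
               character(0))
})

test_that("a zone constraining an absent axis is a warned non-match", {
  dn <- dnra_zone()
  expect_warning(res <- classify_zones(ref_point(46.8, -23.7, NA), dn),
                 "absent")
  expect_equal(res[[1]], character(0))
  # a zone without the d18O constraint still matches
  sp_only <- endmember_zone("SPonly", sp_range = c(43, 49.9))
  expect_equal(classify_zones(ref_point(46.8, NA, NA), sp_only)[[1]], "SPonly")
})

test_that("enlarging a zone range never removes a match", {
  withr::with_seed(21, {
    for (i in 1:20) {
      p <- ref_point(stats::runif(1, 0, 60), stats::runif(1, -50, 0),
                     stats::runif(1, 0, 40))
      z <- endmember_zone("z", sp_range = sort(stats::runif(2, 0, 60)),
                          d15n_range = sort(stats::runif(2, -50, 0)))
      grown <- endmember_zone("z", sp_range = z$sp_range + c(-5, 5),
                              d15n_range = z$d15n_range + c(-5, 5))
      if (length(classify_zones(p, z)[[1]]) == 1) {
        expect_length(classify_zones(p, grown)[[1]], 1)
      }
    }
  })
})

test_that("reduction displacement follows the vector slopes and composes", {
  p0 <- ref_point(0, 0, 0)
  p1 <- apply_reduction(p0, 10)
  expect_equal(c(p1$SP, p1$d15N_bulk, p1$d18O), c(9.6, 10, 22.1))
  expect_equal(apply_reduction(p0, 0), p0)
  # composition: two steps equal one combined step
  expect_equal(apply_reduction(apply_reduction(p0, 4), 6),
               apply_reduction(p0, 10))
  expect_error(apply_reduction(ref_point(5, NA, 5), 1), "d15N_bulk")
})

test_that("alpha and beta stay consistent after displacement", {
  m <- complete_isotopocule(
    isotope_measurement("x", d15N_bulk = -20, SP = 46, d18O = 25,
                        referenced = TRUE))
  shifted <- apply_reduction(m, 5)
  expect_equal(shifted$SP, shifted$d15N_alpha - shifted$d15N_beta,
               tolerance = 1e-12)
  expect_equal(shifted$d15N_bulk, (shifted$d15N_alpha + shifted$d15N_beta) / 2,
               tolerance = 1e-12)
})

test_that("back-projection solves per-axis delta intervals", {
  dn <- dnra_zone()
  inside <- ref_point(46, -20, 25)
  r <- reachable_zones(inside, dn, delta_range = c(0, 30))
  expect_true(r$reachable)
  expect_equal(r$delta_min, 0) # already inside at delta = 0

  # SP five permil above the zone maximum, other axes staying in range
  above <- ref_point(49.9 + 5, -20, 25)
  r2 <- reachable_zones(above, endmember_zone("SPonly", sp_range = c(43, 49.9)),
                        delta_range = c(0, 30))
  expect_equal(r2$delta_min, 5 / 0.96, tolerance = 1e-9)

  # a zone displaced off the line in d18O is unreachable
  off <- endmember_zone("off", sp_range = c(43, 49.9), d18o_range = c(200, 210))
  r3 <- reachable_zones(ref_point(52, -20, 25), off, delta_range = c(0, 30))
  expect_false(r3$reachable)

  # zero-width delta range reduces to plain classification
  zones <- list(dn, endmember_zone("SPonly", sp_range = c(0, 10)))
  pt <- ref_point(46, -20, 25)
  r4 <- reachable_zones(pt, zones, delta_range = c(0, 0))
  expect_equal(r4$zone[r4$reachable], unlist(classify_zones(pt, zones)))
})

test_that("the shipped zone library round-trips through YAML", {
  lib <- read_zone_library(system.file("extdata", "endmember_zones.yaml",
                                       package = "isoN2O"))
  dn <- lib$zones[[which(vapply(lib$zones, `[[`, "", "name") == "DN")]]
  expect_equal(dn$sp_range, dnra_zone()$sp_range)
  expect_equal(dn$d15n_range, dnra_zone()$d15n_range)
  expect_equal(dn$d18o_range, dnra_zone()$d18o_range)
  cnor <- lib$endmembers[[1]]
  expect_equal(c(cnor$sp, cnor$sp_sd), c(-5.9, 2.1))
  expect_equal(lib$vector$slope_sp_d15n, 0.96)
  expect_equal(lib$vector$slope_d18o_d15n, 2.21)
})

test_that("the printed SP/d18O slope is selectable for the reduction line", {
  v <- reduction_vector(use_printed_sp_d18o = TRUE)
  p <- apply_reduction(ref_point(0, 0, 0), 10, v)
  expect_equal(p$d18O, 10 * 0.96 / 0.45, tolerance = 1e-12)
  expect_error(reduction_vector(slope_sp_d15n = 0), "nonzero")
})
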