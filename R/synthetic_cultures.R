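# Seeded generator of DNRA batch-culture time series and replicate-level
# isotope tables with the statistical structure the analysis assumes.

#' Configure a synthetic DNRA culture
#'
#' Collects the kinetic, yield, isotopic and noise parameters of the
#' simulator. Defaults emulate the reference experiments: 8 mM NO3- or 2 mM
#' NO2- in 20 mL medium under 30 mL headspace; first-order substrate
#' consumption scaled by logistic biomass with transient NO2- accumulation;
#' product yields of reduced NO2--N of 0.65 to NH4+ and 0.01 (NO3- runs) or
#' 0.02 (NO2- runs) to N2O-N; SP drawn around the DNRA (46.2 +/- 1.5 permil)
#' and cNor (-5.9 +/- 2.1 permil) pathway endmembers mixed at `f_dnra`; net
#' 15N/18O fractionation of the product relative to the substrate of
#' -24.6 +/- 6.0 and 23.6 +/- 6.3 permil; instrument SDs 0.2 permil
#' (d15N_alpha), 0.1 permil (d15N_bulk, d18O) and, by propagation through
#' `beta = 2 bulk - alpha`, sqrt(0.2^2 + (2*0.1)^2) = 0.283 permil for SP.
#'
#' @param substrate `"NO3"` (8 mM) or `"NO2"` (2 mM); override the starting
#'   concentration with `conc_mM`.
#' @param conc_mM Initial substrate concentration, mM.
#' @param geometry A [vessel_geometry()].
#' @param k_consume First-order substrate consumption rate constant per unit
#'   biomass, 1/(h OD600).
#' @param k_nitrite Onward NO2- reduction rate constant, 1/(h OD600).
#' @param y_nh4 Fraction of reduced NO2--N routed to NH4+.
#' @param y_n2o Fraction of reduced NO2--N routed to N2O-N; default 0.01 for
#'   NO3- runs and 0.02 for NO2- runs. `y_nh4 + y_n2o <= 1`; the remainder
#'   goes to an unmeasured pool so the latent budget closes exactly.
#' @param growth List `r` (1/h), `K` (OD600 carrying capacity), `od0`
#'   (inoculum OD600) of the logistic biomass model.
#' @param f_dnra Fraction of N2O from the DNRA pathway, in `[0, 1]`; the
#'   complement comes from the cNor endmember.
#' @param sp_dnra,sp_dnra_sd,sp_cnor,sp_cnor_sd Pathway SP endmembers,
#'   per-mil (mean, 1 SD).
#' @param eps15n,eps15n_sd,eps18o,eps18o_sd Net product-substrate isotope
#'   offsets, per-mil (mean, 1 SD).
#' @param noise List of instrument 1-SD noise terms in per-mil (`d15n_bulk`,
#'   `sp`, `d18o`) plus `conc_rel`, the relative SD applied to sampled
#'   concentrations when measurement noise is on.
#' @param n_replicates Replicate bottles per condition.
#' @param t_end Simulation horizon, h.
#' @param dt Euler step, h (<= 0.1).
#' @param sample_every Sampling interval, h.
#' @return An object of class `culture_config`.
#' @export
culture_config <- function(substrate = c("NO3", "NO2"), conc_mM = NULL,
                           geometry = vessel_geometry(),
                           k_consume = 0.5, k_nitrite = 0.11,
                           y_nh4 = 0.65, y_n2o = NULL,
                           growth = list(r = 0.06, K = 0.20, od0 = 0.02),
                           f_dnra = 1,
                           sp_dnra = 46.2, sp_dnra_sd = 1.5,
                           sp_cnor = -5.9, sp_cnor_sd = 2.1,
                           eps15n = -24.6, eps15n_sd = 6.0,
                           eps18o = 23.6, eps18o_sd = 6.3,
                           noise = list(d15n_bulk = 0.1,
                                        sp = sqrt(0.2^2 + (2 * 0.1)^2),
                                        d18o = 0.1, conc_rel = 0.02),
                           n_replicates = 3, t_end = 168, dt = 0.05,
                           sample_every = 12) {
  substrate <- match.arg(substrate)
  if (is.null(conc_mM)) conc_mM <- if (substrate == "NO3") 8 else 2
  if (is.null(y_n2o)) y_n2o <- if (substrate == "NO3") 0.01 else 0.02
  stopifnot(
    conc_mM > 0, k_consume >= 0, k_nitrite >= 0,
    y_nh4 >= 0, y_n2o >= 0, y_nh4 + y_n2o <= 1,
    f_dnra >= 0, f_dnra <= 1,
    sp_dnra_sd >= 0, sp_cnor_sd >= 0, eps15n_sd >= 0, eps18o_sd >= 0,
    growth$r >= 0, growth$K > 0, growth$od0 > 0,
    dt > 0, dt <= 0.1, t_end > 0, sample_every > 0, n_replicates >= 1
  )
  structure(
    list(substrate = substrate, conc_mM = conc_mM, geometry = geometry,
         k_consume = k_consume, k_nitrite = k_nitrite,
         y_nh4 = y_nh4, y_n2o = y_n2o, growth = growth,
         f_dnra = f_dnra, sp_dnra = sp_dnra, sp_dnra_sd = sp_dnra_sd,
         sp_cnor = sp_cnor, sp_cnor_sd = sp_cnor_sd,
         eps15n = eps15n, eps15n_sd = eps15n_sd,
         eps18o = eps18o, eps18o_sd = eps18o_sd,
         noise = noise, n_replicates = n_replicates,
         t_end = t_end, dt = dt, sample_every = sample_every),
    class = "culture_config"
  )
}

#' Simulate one culture bottle
#'
#' Deterministic forward-Euler integration (step `cfg$dt` <= 0.1 h) of
#' logistic biomass, first-order substrate consumption (NO3- -> NO2-) and
#' onward NO2- reduction partitioned into NH4+, N2O-N and an unmeasured
#' remainder, all scaled by biomass. The latent (noise-free) state conserves
#' nitrogen exactly; optional Gaussian measurement noise is applied to the
#' sampled concentrations only. N2O is reported as whole-bottle umol
#' (`mM-N2O-N equivalent * v_liquid / 2`).
#'
#' @param cfg A [culture_config()].
#' @param seed Integer seed (used only when `measurement_noise = TRUE`).
#' @param measurement_noise Add relative Gaussian noise (`cfg$noise$conc_rel`)
#'   to the sampled observations?
#' @param bottle_id Identifier for the generated bottle.
#' @param strain Strain label carried on the series.
#' @return A [culture_timeseries()] whose `latent` field holds the exact
#'   state (including the unmeasured pool) at the sampled times.
#' @export
simulate_culture <- function(cfg, seed = 1L, measurement_noise = FALSE,
                             bottle_id = "synthetic-1", strain = "synthetic") {
  g <- cfg$growth
  times <- seq(0, cfg$t_end, by = cfg$dt)
  sample_times <- seq(0, cfg$t_end, by = cfg$sample_every)
  n_keep <- length(sample_times)

  B <- g$od0
  sub <- cfg$conc_mM # NO3 for NO3 runs, NO2 for NO2 runs (mM)
  no3 <- if (cfg$substrate == "NO3") sub else 0
  no2 <- if (cfg$substrate == "NO2") sub else 0
  nh4 <- 0; n2o_n <- 0; other <- 0 # mM-N equivalents

  keep <- matrix(NA_real_, n_keep, 7,
                 dimnames = list(NULL, c("time", "od600", "no3", "no2",
                                         "nh4", "n2o_n", "other")))
  ki <- 1
  record <- function(t) {
    keep[ki, ] <<- c(t, B, no3, no2, nh4, n2o_n, other)
    ki <<- ki + 1
  }
  record(0)
  next_sample <- if (n_keep > 1) sample_times[2] else Inf

  for (t in times[-1]) {
    dB <- g$r * B * (1 - B / g$K) * cfg$dt
    d_no3 <- if (cfg$substrate == "NO3") cfg$k_consume * B * no3 * cfg$dt else 0
    d_no2_red <- cfg$k_nitrite * B * no2 * cfg$dt
    B <- B + dB
    no3 <- no3 - d_no3
    no2 <- no2 + d_no3 - d_no2_red
    nh4 <- nh4 + cfg$y_nh4 * d_no2_red
    n2o_n <- n2o_n + cfg$y_n2o * d_no2_red
    other <- other + (1 - cfg$y_nh4 - cfg$y_n2o) * d_no2_red
    if (min(no3, no2, nh4, n2o_n, other) < -1e-9) {
      stop("integration unstable (pool went negative); use a smaller dt",
           call. = FALSE)
    }
    if (t >= next_sample - cfg$dt / 2) {
      record(sample_times[ki])
      next_sample <- if (ki <= n_keep) sample_times[ki] else Inf
    }
  }

  latent <- tibble::tibble(
    time = keep[, "time"], od600 = keep[, "od600"],
    no3 = keep[, "no3"], no2 = keep[, "no2"], nh4 = keep[, "nh4"],
    n2o_n = keep[, "n2o_n"], other = keep[, "other"]
  )
  obs <- latent
  if (measurement_noise) {
    obs <- withr::with_seed(seed, {
      noisy <- latent
      rel <- cfg$noise$conc_rel
      for (col in c("od600", "no3", "no2", "nh4", "n2o_n")) {
        n <- nrow(noisy)
        noisy[[col]] <- pmax(0, noisy[[col]] *
                               (1 + stats::rnorm(n, 0, rel)))
      }
      noisy
    })
  }
  v <- cfg$geometry$v_liquid
  culture_timeseries(
    bottle_id = bottle_id, strain = strain, substrate = cfg$substrate,
    time = obs$time, od600 = obs$od600,
    no3 = obs$no3, no2 = obs$no2, nh4 = obs$nh4,
    n2o_total = obs$n2o_n * v / 2, # mM-N equivalent -> umol N2O per bottle
    geometry = cfg$geometry, latent = latent
  )
}

#' Simulate a replicate-level isotope table
#'
#' Draws per-replicate, per-day N2O isotopocule observations consistent with
#' the configured pathway mixture. Per observation: each pathway SP is drawn
#' around its endmember, mixed linearly at `f_dnra`; raw d15N_bulk and d18O
#' are the substrate composition plus a drawn net offset; instrument noise
#' is then added to (d15N_bulk, SP, d18O) and d15N_alpha/beta are derived
#' exactly so the completion identities hold by construction.
#'
#' @param cfg A [culture_config()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @param days Sampling days (incubation time).
#' @param strain Strain label.
#' @return Raw-scale (`referenced = FALSE`) isotopocule tibble with one row
#'   per replicate and day.
#' @export
simulate_isotopes <- function(cfg, seed = 1L, days = c(3, 7),
                              strain = "synthetic") {
  ref <- substrate_reference_values(cfg$substrate)
  grid <- expand.grid(replicate = seq_len(cfg$n_replicates), day = days)
  n <- nrow(grid)
  withr::with_seed(seed, {
    sp_path_a <- stats::rnorm(n, cfg$sp_dnra, cfg$sp_dnra_sd)
    sp_path_b <- stats::rnorm(n, cfg$sp_cnor, cfg$sp_cnor_sd)
    sp_true <- cfg$f_dnra * sp_path_a + (1 - cfg$f_dnra) * sp_path_b
    bulk_raw <- ref$d15N + stats::rnorm(n, cfg$eps15n, cfg$eps15n_sd)
    d18o_raw <- ref$d18O + stats::rnorm(n, cfg$eps18o, cfg$eps18o_sd)
    bulk <- bulk_raw + stats::rnorm(n, 0, cfg$noise$d15n_bulk)
    sp <- sp_true + stats::rnorm(n, 0, cfg$noise$sp)
    d18o <- d18o_raw + stats::rnorm(n, 0, cfg$noise$d18o)
    isotope_measurement(
      sample_id = sprintf("%s_%s_d%g_r%d", strain, cfg$substrate,
                          grid$day, grid$replicate),
      strain = strain, substrate = cfg$substrate,
      day = grid$day, replicate = grid$replicate,
      d15N_alpha = bulk + sp / 2, d15N_beta = bulk - sp / 2,
      d15N_bulk = bulk, d18O = d18o, SP = sp, referenced = FALSE
    )
  })
}
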