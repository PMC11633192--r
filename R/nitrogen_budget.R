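# Per-bottle nitrogen accounting for DNRA batch cultures: amounts as N,
# conversion ratios, end-stage composition and the N2O-nitrite association.

#' Construct a culture time series
#'
#' One bottle's time course of biomass and nitrogen species. Ion
#' concentrations are bulk-liquid mM; N2O is the whole-bottle amount in umol
#' (headspace + dissolved, see [total_n2o()]).
#'
#' @param bottle_id Bottle identifier.
#' @param strain Strain label.
#' @param substrate Initial substrate, `"NO3"` or `"NO2"`.
#' @param time Sampling times, h; strictly increasing, first row defines the
#'   initial substrate amount.
#' @param od600 Optical density at 600 nm (>= 0).
#' @param no3,no2,nh4 Concentrations, mM (>= 0).
#' @param n2o_total Whole-bottle N2O, umol (>= 0).
#' @param geometry A [vessel_geometry()] (needed to turn mM into umol).
#' @param latent Optional tibble of the noise-free simulator state (internal).
#' @return An object of class `culture_timeseries`.
#' @export
culture_timeseries <- function(bottle_id, strain = NA_character_,
                               substrate = c("NO3", "NO2"),
                               time, od600, no3, no2, nh4, n2o_total,
                               geometry = vessel_geometry(),
                               latent = NULL) {
  substrate <- match.arg(substrate)
  data <- tibble::tibble(
    time = as.numeric(time), od600 = as.numeric(od600),
    no3 = as.numeric(no3), no2 = as.numeric(no2), nh4 = as.numeric(nh4),
    n2o_total = as.numeric(n2o_total)
  )
  if (any(diff(data$time) <= 0)) {
    stop(sprintf("bottle '%s': time must be strictly increasing", bottle_id),
         call. = FALSE)
  }
  conc <- as.matrix(data[, c("od600", "no3", "no2", "nh4", "n2o_total")])
  if (any(conc < 0, na.rm = TRUE)) {
    stop(sprintf("bottle '%s': negative concentration/amount", bottle_id),
         call. = FALSE)
  }
  structure(
    list(bottle_id = as.character(bottle_id), strain = as.character(strain),
         substrate = substrate, data = data, geometry = geometry,
         latent = latent),
    class = "culture_timeseries"
  )
}

#' @export
print.culture_timeseries <- function(x, ...) {
  cat(sprintf("<culture_timeseries> bottle %s (%s, substrate %s): %d time points, %g-%g h\n",
              x$bottle_id, x$strain, x$substrate, nrow(x$data),
              min(x$data$time), max(x$data$time)))
  invisible(x)
}

#' Nitrogen amounts per species and time point
#'
#' Converts the time series to umol N per bottle: `mM * v_liquid(mL) = umol`
#' for the ions, and `umol N2O * 2 = umol N` for the doubly nitrogenous N2O.
#'
#' @param ts A [culture_timeseries()].
#' @return Tibble with columns `time`, `no3_N`, `no2_N`, `nh4_N`, `n2o_N`.
#' @export
amounts_as_N <- function(ts) {
  if (is.null(ts$geometry)) stop("time series has no vessel geometry", call. = FALSE)
  v <- ts$geometry$v_liquid
  tibble::tibble(
    time = ts$data$time,
    no3_N = ts$data$no3 * v,
    no2_N = ts$data$no2 * v,
    nh4_N = ts$data$nh4 * v,
    n2o_N = ts$data$n2o_total * 2
  )
}

species_col <- function(species) {
  switch(toupper(species),
    "NO3" = "no3_N", "NO2" = "no2_N", "NH4" = "nh4_N", "N2O" = "n2o_N",
    stop("unknown nitrogen species: ", species, call. = FALSE)
  )
}

#' Conversion ratio of consumed substrate-N into a product
#'
#' Product-N produced over `[t0, t_end]` divided by substrate-N consumed over
#' the same interval, both in umol N.
#'
#' @param ts A [culture_timeseries()].
#' @param product `"NH4"`, `"N2O"` or `"NO2"`.
#' @param t_end End of the interval, h; defaults to the last time point.
#' @return A single fraction.
#' @export
conversion_ratio <- function(ts, product = c("NH4", "N2O", "NO2"),
                             t_end = NULL) {
  product <- match.arg(product)
  n <- amounts_as_N(ts)
  if (is.null(t_end)) t_end <- max(n$time)
  i_end <- max(which(n$time <= t_end))
  if (i_end < 2) stop("t_end precedes the second time point; no interval", call. = FALSE)
  sub_col <- species_col(ts$substrate)
  consumed <- n[[sub_col]][1] - n[[sub_col]][i_end]
  if (consumed <= 0) {
    stop("no substrate consumption over the interval; conversion ratio undefined",
         call. = FALSE)
  }
  produced <- n[[species_col(product)]][i_end] - n[[species_col(product)]][1]
  produced / consumed
}

#' End-stage nitrogen composition of a culture
#'
#' Each pool's N at the final (or given) time divided by the initial
#' substrate-N. The remainder is reported as `unrecovered`; it may be
#' negative if the measured pools over-close the budget and is never
#' clipped. Fractions sum to 1 exactly.
#'
#' @param ts A [culture_timeseries()].
#' @param t_end Evaluation time, h; defaults to the last time point (the
#'   final reaction stage).
#' @return Tibble with one row: `NO3`, `NO2`, `NH4`, `N2O_N`, `unrecovered`.
#' @export
end_stage_composition <- function(ts, t_end = NULL) {
  n <- amounts_as_N(ts)
  if (is.null(t_end)) t_end <- max(n$time)
  i <- max(which(n$time <= t_end))
  n0 <- n[[species_col(ts$substrate)]][1]
  if (n0 <= 0) stop("initial substrate amount is zero", call. = FALSE)
  f <- c(NO3 = n$no3_N[i], NO2 = n$no2_N[i], NH4 = n$nh4_N[i],
         N2O_N = n$n2o_N[i]) / n0
  tibble::tibble(
    NO3 = f[["NO3"]], NO2 = f[["NO2"]], NH4 = f[["NH4"]], N2O_N = f[["N2O_N"]],
    unrecovered = 1 - sum(f)
  )
}

#' Linear association between product accumulations
#'
#' Ordinary least squares of cumulative product-N (default N2O) on cumulative
#' substrate-intermediate accumulation (default NO2-). "Accumulation" of the
#' x species is its max-to-date net increase above the initial amount, which
#' is monotone even after the intermediate starts being consumed;
#' `x_mode = "instantaneous"` uses the raw net change instead.
#'
#' @param ts A [culture_timeseries()].
#' @param x,y Nitrogen species for predictor and response.
#' @param x_mode `"max_to_date"` (default) or `"instantaneous"`.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value` (two-sided
#'   test of zero slope).
#' @export
production_association <- function(ts, x = "NO2", y = "N2O",
                                   x_mode = c("max_to_date", "instantaneous")) {
  x_mode <- match.arg(x_mode)
  n <- amounts_as_N(ts)
  if (nrow(n) < 3) stop("need at least 3 time points", call. = FALSE)
  xv <- n[[species_col(x)]] - n[[species_col(x)]][1]
  if (x_mode == "max_to_date") xv <- cummax(xv)
  yv <- n[[species_col(y)]] - n[[species_col(y)]][1]
  if (isTRUE(all.equal(stats::var(xv), 0)) || stats::var(xv) == 0) {
    stop("predictor species shows no variation; degenerate fit", call. = FALSE)
  }
  fit <- stats::lm(yv ~ xv)
  s <- summary(fit)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = s$r.squared,
    p_value = unname(s$coefficients[2, 4])
  )
}
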