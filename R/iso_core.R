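# Isotopocule calculus for N2O: delta-15N-alpha (central N), delta-15N-beta
# (terminal N), delta-15N-bulk, delta-18O and site preference SP.
#
# All per-mil values are stored as plain numbers on the per-mil scale
# (46.5 means 46.5 permil); every relation used here is linear in per-mil,
# so no ratio-space conversion is performed.

#' Column schema of an isotopocule table
#'
#' Isotopocule measurements are kept in ordinary tibbles with one row per
#' observation. These are the columns the package reads and writes.
#'
#' @return Character vector of required column names.
#' @export
isotope_columns <- function() {
  c("sample_id", "strain", "substrate", "day", "replicate",
    "d15N_alpha", "d15N_beta", "d15N_bulk", "d18O", "SP")
}

#' Construct an isotopocule measurement table
#'
#' Builds a validated tibble of N2O isotopocule observations. Any subset of
#' the four 15N-related quantities (`d15N_alpha`, `d15N_beta`, `d15N_bulk`,
#' `SP`) may be supplied; use [complete_isotopocule()] to fill the rest.
#'
#' @param sample_id Sample identifiers.
#' @param strain Strain labels.
#' @param substrate One of `"NO3"`, `"NO2"`, `"NO_donor"`, `"abiotic"`.
#' @param day Incubation time in days (> 0).
#' @param replicate Replicate index (>= 1).
#' @param d15N_alpha,d15N_beta,d15N_bulk Per-mil vs air-N2 (may be `NA`).
#' @param d18O Per-mil vs VSMOW (may be `NA`).
#' @param SP Site preference `d15N_alpha - d15N_beta`, per-mil (may be `NA`).
#' @param referenced Logical; `TRUE` once delta values are expressed relative
#'   to the substrate (see [substrate_reference()]).
#' @return A tibble with the columns of [isotope_columns()] plus `referenced`.
#' @export
isotope_measurement <- function(sample_id, strain = NA_character_,
                                substrate = c("NO3", "NO2", "NO_donor", "abiotic"),
                                day = 1, replicate = 1L,
                                d15N_alpha = NA_real_, d15N_beta = NA_real_,
                                d15N_bulk = NA_real_, d18O = NA_real_,
                                SP = NA_real_, referenced = FALSE) {
  if (missing(substrate)) substrate <- "NO3"
  ok <- substrate %in% c("NO3", "NO2", "NO_donor", "abiotic")
  if (!all(ok)) {
    stop("unknown substrate value(s): ",
         paste(unique(substrate[!ok]), collapse = ", "), call. = FALSE)
  }
  x <- tibble::tibble(
    sample_id = as.character(sample_id), strain = as.character(strain),
    substrate = substrate, day = as.numeric(day),
    replicate = as.integer(replicate),
    d15N_alpha = as.numeric(d15N_alpha), d15N_beta = as.numeric(d15N_beta),
    d15N_bulk = as.numeric(d15N_bulk), d18O = as.numeric(d18O),
    SP = as.numeric(SP), referenced = as.logical(referenced)
  )
  validate_isotope_table(x)
  x
}

validate_isotope_table <- function(x) {
  if (any(!is.na(x$day) & x$day <= 0)) {
    stop("incubation day must be > 0", call. = FALSE)
  }
  if (any(!is.na(x$replicate) & x$replicate < 1)) {
    stop("replicate index must be >= 1", call. = FALSE)
  }
  invisible(x)
}

# Design matrix rows mapping the unknowns (alpha, beta) to each observable.
.iso_design <- rbind(
  d15N_alpha = c(1, 0),
  d15N_beta  = c(0, 1),
  d15N_bulk  = c(0.5, 0.5),
  SP         = c(1, -1)
)

#' Complete the 15N isotopocule quantities of a measurement
#'
#' The four 15N-related observables of an N2O molecule obey
#' `SP = d15N_alpha - d15N_beta` and `d15N_bulk = (d15N_alpha + d15N_beta)/2`
#' (equivalently `d15N_beta = 2 d15N_bulk - d15N_alpha`). Any two of the four
#' determine the other two; this function fills every missing one and checks
#' over-determined rows for internal consistency.
#'
#' @param x An isotopocule tibble (see [isotope_measurement()]).
#' @param tol Consistency tolerance in per-mil. The default 0.01 is one
#'   decimal beyond the usual 0.1-permil reporting precision.
#' @param on_inconsistent `"error"` (default) raises a validation error
#'   carrying the residual; `"flag"` keeps the row and records the residual.
#' @return `x` with all four 15N columns filled and two extra columns:
#'   `consistent` (logical) and `residual` (max absolute misfit, per-mil).
#' @examples
#' m <- isotope_measurement("s1", d15N_bulk = 10, d15N_alpha = 30)
#' complete_isotopocule(m)[, c("d15N_beta", "SP")] # -10, 40
#' @export
complete_isotopocule <- function(x, tol = 0.01,
                                 on_inconsistent = c("error", "flag")) {
  on_inconsistent <- match.arg(on_inconsistent)
  obs <- as.matrix(x[, rownames(.iso_design)])
  out <- matrix(NA_real_, nrow(x), 4, dimnames = list(NULL, rownames(.iso_design)))
  residual <- rep(NA_real_, nrow(x))
  for (i in seq_len(nrow(x))) {
    known <- which(!is.na(obs[i, ]))
    if (length(known) < 2) {
      stop(sprintf(
        "row %d: under-determined isotopocule (need two of alpha/beta/bulk/SP, have %d)",
        i, length(known)
      ), call. = FALSE)
    }
    A <- .iso_design[known, , drop = FALSE]
    v <- obs[i, known]
    ab <- qr.solve(crossprod(A), crossprod(A, v)) # least squares for (alpha, beta)
    fit <- drop(.iso_design %*% ab)
    residual[i] <- max(abs(fit[known] - v))
    # keep observed values verbatim; derive only the missing ones
    out[i, ] <- obs[i, ]
    out[i, -known] <- fit[-known]
  }
  bad <- residual > tol
  if (any(bad) && on_inconsistent == "error") {
    stop(sprintf(
      "inconsistent isotopocule row(s) %s: max residual %.4g permil exceeds tolerance %g",
      paste(which(bad), collapse = ", "), max(residual[bad]), tol
    ), call. = FALSE)
  }
  x$d15N_alpha <- unname(out[, "d15N_alpha"])
  x$d15N_beta <- unname(out[, "d15N_beta"])
  x$d15N_bulk <- unname(out[, "d15N_bulk"])
  x$SP <- unname(out[, "SP"])
  x$consistent <- !bad
  x$residual <- residual
  x
}

#' Substrate isotope reference values
#'
#' Shipped reference composition of the growth substrates, measured by the
#' denitrifier (NO3-) and azide (NO2-) methods: d15N vs air-N2 and d18O vs
#' VSMOW, each with 1-SD uncertainty.
#'
#' @param species `"NO3"` or `"NO2"`; omit for the full table.
#' @return A one-row list for a single species, else a tibble.
#' @export
substrate_reference_values <- function(species = NULL) {
  tab <- tibble::tibble(
    species = c("NO3", "NO2"),
    d15N = c(2.4, -1.8), d15N_sd = c(0.1, 0.3),
    d18O = c(17.9, 3.7), d18O_sd = c(0.3, 0.2)
  )
  if (is.null(species)) return(tab)
  species <- match.arg(species, tab$species)
  as.list(tab[tab$species == species, ])
}

#' Express product N2O deltas relative to the substrate
#'
#' Replaces `d15N_bulk` (and, to keep the completion identities intact,
#' `d15N_alpha` and `d15N_beta`) by product-minus-substrate differences and
#' does the same for `d18O`. SP is a difference of two 15N positions of the
#' same molecule, hence invariant under this reference-frame shift; it is
#' left untouched.
#'
#' @param x Isotopocule tibble on the raw calibrated scale
#'   (`referenced = FALSE`).
#' @param ref A substrate reference: `"NO3"`, `"NO2"`, or a list with
#'   elements `d15N` and `d18O` (see [substrate_reference_values()]).
#' @return `x` with shifted delta columns and `referenced = TRUE`.
#' @export
substrate_reference <- function(x, ref = substrate_reference_values("NO3")) {
  if (is.character(ref)) ref <- substrate_reference_values(ref)
  if (any(isTRUE(x$referenced) | x$referenced %in% TRUE)) {
    stop("table is already substrate-referenced; refusing to double-reference",
         call. = FALSE)
  }
  shift_deltas(x, -ref$d15N, -ref$d18O, referenced = TRUE)
}

#' Undo substrate referencing
#'
#' Exact inverse of [substrate_reference()]: adds the substrate values back.
#'
#' @inheritParams substrate_reference
#' @export
substrate_unreference <- function(x, ref = substrate_reference_values("NO3")) {
  if (is.character(ref)) ref <- substrate_reference_values(ref)
  if (any(!(x$referenced %in% TRUE))) {
    stop("table is not substrate-referenced", call. = FALSE)
  }
  shift_deltas(x, ref$d15N, ref$d18O, referenced = FALSE)
}

shift_deltas <- function(x, d15N_shift, d18O_shift, referenced) {
  for (col in c("d15N_alpha", "d15N_beta", "d15N_bulk")) {
    if (col %in% names(x)) x[[col]] <- x[[col]] + d15N_shift
  }
  if ("d18O" %in% names(x)) x$d18O <- x$d18O + d18O_shift
  x$referenced <- referenced
  x
}
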