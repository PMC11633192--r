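# CSV readers/writers, zone-library config parsing and shipped datasets.
# Dialect: RFC 4180 CSV, UTF-8, '.' decimal, '#' comment lines for
# provenance headers; per-mil columns carry no unit suffix.

required_isotope_cols <- c("sample_id", "strain", "substrate", "day",
                           "replicate", "d15N_alpha", "d15N_bulk", "d18O", "SP")

#' Read an isotopocule measurement table
#'
#' Reads the standard isotope CSV schema (columns `sample_id, strain,
#' substrate, day, replicate, d15N_alpha, d15N_bulk, d18O, SP`; blank cells
#' are treated as absent; `d15N_beta` and `referenced` optional). Rows whose
#' 15N quantities are mutually sufficient are completed; rows inconsistent
#' beyond `tol` are flagged via the `consistent` column, not dropped.
#'
#' @param path CSV file path.
#' @param tol Consistency tolerance passed to [complete_isotopocule()].
#' @param complete Complete/validate the 15N quantities? Set `FALSE` to read
#'   the table verbatim.
#' @return Isotopocule tibble.
#' @export
read_isotope_table <- function(path, tol = 0.01, complete = TRUE) {
  raw <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                         colClasses = "character", blank.lines.skip = TRUE)
  missing_cols <- setdiff(required_isotope_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("isotope table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("day", "replicate", "d15N_alpha", "d15N_beta", "d15N_bulk",
                "d18O", "SP")
  x <- tibble::as_tibble(raw)
  for (col in intersect(num_cols, names(x))) {
    v <- trimws(x[[col]])
    v[v == ""] <- NA
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in column '%s' at data line %d of %s",
                   v[bad[1]], col, bad[1], path), call. = FALSE)
    }
    x[[col]] <- parsed
  }
  if (!"d15N_beta" %in% names(x)) x$d15N_beta <- NA_real_
  if (!"referenced" %in% names(x)) {
    x$referenced <- FALSE
  } else {
    x$referenced <- as.logical(x$referenced)
  }
  x$replicate <- as.integer(x$replicate)
  x <- x[, c(required_isotope_cols[1:5], "d15N_alpha", "d15N_beta",
             "d15N_bulk", "d18O", "SP", "referenced")]
  validate_isotope_table(x)
  if (complete && nrow(x) > 0) {
    x <- complete_isotopocule(x, tol = tol, on_inconsistent = "flag")
  }
  x
}

#' Write an isotopocule table
#'
#' Writes the CSV schema of [read_isotope_table()] with a provenance header
#' (tool version, seed, config hash) as `#` comment lines.
#'
#' @param x Isotopocule tibble.
#' @param path Output path.
#' @param seed Seed recorded in the provenance header (optional).
#' @param config Configuration object hashed into the provenance header
#'   (optional).
#' @export
write_isotope_table <- function(x, path, seed = NULL, config = NULL) {
  write_with_provenance(x, path, seed, config)
}

#' Read culture time series tables
#'
#' Reads a long-format CSV with columns `bottle_id, strain, substrate, time,
#' od600, no3, no2, nh4, n2o_total` and splits it into one
#' [culture_timeseries()] per bottle. Times must be strictly increasing
#' within each bottle.
#'
#' @param path CSV file path.
#' @param geometry [vessel_geometry()] attached to every series.
#' @return Named list of [culture_timeseries()] objects, keyed by bottle.
#' @export
read_timeseries_table <- function(path, geometry = vessel_geometry()) {
  cols <- c("bottle_id", "strain", "substrate", "time", "od600", "no3",
            "no2", "nh4", "n2o_total")
  raw <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("time-series table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(raw, raw$bottle_id), function(d) {
    culture_timeseries(
      bottle_id = d$bottle_id[1], strain = d$strain[1],
      substrate = d$substrate[1], time = d$time, od600 = d$od600,
      no3 = d$no3, no2 = d$no2, nh4 = d$nh4, n2o_total = d$n2o_total,
      geometry = geometry
    )
  })
  out[unique(raw$bottle_id)]
}

#' Write culture time series
#'
#' Long-format counterpart of [read_timeseries_table()]; write-then-read
#' round-trips to equal records.
#'
#' @param ts A [culture_timeseries()] or list of them.
#' @inheritParams write_isotope_table
#' @export
write_timeseries_table <- function(ts, path, seed = NULL, config = NULL) {
  if (inherits(ts, "culture_timeseries")) ts <- list(ts)
  rows <- lapply(ts, function(s) {
    tibble::tibble(bottle_id = s$bottle_id, strain = s$strain,
                   substrate = s$substrate, s$data)
  })
  write_with_provenance(do.call(rbind, rows), path, seed, config)
}

write_with_provenance <- function(x, path, seed = NULL, config = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(seed, config), con)
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

provenance_header <- function(seed = NULL, config = NULL) {
  ver <- as.character(utils::packageVersion("isoN2O"))
  lines <- sprintf("# isoN2O %s", ver)
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed=%d", as.integer(seed)))
  if (!is.null(config)) {
    tf <- tempfile()
    on.exit(unlink(tf), add = TRUE)
    writeLines(yaml::as.yaml(unclass_recursive(config)), tf)
    lines <- c(lines, sprintf("# config_md5=%s", unname(tools::md5sum(tf))))
  }
  lines
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else unclass(x)
}

#' Read an endmember-zone library from YAML
#'
#' Parses a declarative zone config (see the shipped
#' `extdata/endmember_zones.yaml`): a `zones` sequence of maps with `name`,
#' optional `sp_range`/`d15n_range`/`d18o_range` pairs and a `source`
#' citation string; optional `endmembers` (name, sp, sp_sd) and
#' `reduction_vector` blocks.
#'
#' @param path YAML file path.
#' @return List with elements `zones` (list of [endmember_zone()]),
#'   `endmembers` (list of [point_endmember()]) and `vector`
#'   (a [reduction_vector()] or `NULL`).
#' @export
read_zone_library <- function(path) {
  cfg <- yaml::read_yaml(path)
  zones <- lapply(cfg$zones, function(z) {
    endmember_zone(z$name,
                   sp_range = unlist(z$sp_range),
                   d15n_range = unlist(z$d15n_range),
                   d18o_range = unlist(z$d18o_range),
                   source = z$source %||% "")
  })
  endmembers <- lapply(cfg$endmembers, function(e) {
    point_endmember(e$name, e$sp, e$sp_sd %||% 0)
  })
  vec <- if (!is.null(cfg$reduction_vector)) {
    reduction_vector(cfg$reduction_vector$slope_sp_d15n,
                     cfg$reduction_vector$slope_sp_d18o,
                     cfg$reduction_vector$slope_d18o_d15n)
  }
  list(zones = zones, endmembers = endmembers, vector = vec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The shipped endmember-zone library
#'
#' @return The `zones` element of the packaged zone config (currently the
#'   DNRA zone; other process zones are left for the user to fill in from a
#'   literature compilation — see the comments in the shipped YAML).
#' @export
default_zone_library <- function() {
  read_zone_library(system.file("extdata", "endmember_zones.yaml",
                                package = "isoN2O", mustWork = TRUE))$zones
}

#' Reference N2O isotopocule dataset
#'
#' Strain-mean isotopocule signatures (with replicate SDs) of N2O produced
#' from NO3- (8 mM) and NO2- (2 mM) reduction by nine Geobacteraceae
#' nitrate/nitrite-ammonifying strains, plus one abiotic (acidified,
#' bacteria-free) control. `d15N_bulk` and `d18O` are substrate-referenced
#' (product minus substrate); SP is frame-free. The two `NO3`/7-day rows of
#' strains Red69 and Red111 carry lowered SP from mixed production
#' processes and are excluded from the DNRA signature range.
#'
#' @return Tibble with columns `substrate, strain, genus, day, d18O,
#'   d18O_sd, d15N_bulk, d15N_bulk_sd, SP, SP_sd, biotic`.
#' @export
load_reference_isotopes <- function() {
  path <- system.file("extdata", "reference_isotopocules.csv",
                      package = "isoN2O", mustWork = TRUE)
  tab <- tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                           check.names = FALSE))
  tab$biotic <- as.logical(tab$biotic)
  tab
}
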