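# Group summaries and nonparametric comparisons of isotopocule values.

#' Round half away from zero
#'
#' Reported per-mil values follow the one-decimal convention with ties
#' rounded away from zero (46.35 -> 46.4), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  z <- abs(x) * p
  # relative guard against binary representation of exact halves
  # (e.g. (46.3 + 46.4)/2 stored fractionally below 46.35)
  sign(x) * floor(z + 0.5 + z * 1e-12) / p
}

#' Per-group medians of isotopocule values
#'
#' Standard medians (mean of the central pair for even n) per group, with
#' both the raw value and the one-decimal reported value
#' (half-away-from-zero, see [round_half_away()]).
#'
#' @param groups Named list of numeric vectors, e.g. SP values keyed by
#'   substrate, genus, strain or day. Every group must be nonempty.
#' @return Tibble with columns `group`, `n`, `median_raw`, `median_reported`.
#' @examples
#' group_medians(list(NO3 = c(46.3, 46.4), NO2 = c(46.1, 46.3)))
#' @export
group_medians <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a named list of numeric vectors", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes == 0)) {
    stop("empty group(s): ", paste(names(groups)[sizes == 0], collapse = ", "),
         call. = FALSE)
  }
  med <- vapply(groups, stats::median, numeric(1))
  tibble::tibble(
    group = names(groups), n = as.integer(sizes),
    median_raw = unname(med),
    median_reported = round_half_away(unname(med), 1)
  )
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two groups, delegated to [stats::wilcox.test()]:
#' exact permutation p-value when the smaller group has at most
#' `exact_max` observations and there are no ties, else the normal
#' approximation with tie correction.
#'
#' @param a,b Numeric vectors (each nonempty).
#' @param exact_max Largest `min(n_a, n_b)` for which the exact distribution
#'   is used (default 8).
#' @return List with `U`, `p_two_sided`, and `method` (`"exact"` or
#'   `"normal_approx"`).
#' @export
mann_whitney <- function(a, b, exact_max = 8) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- !has_ties && min(length(a), length(b)) <= exact_max
  w <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact,
                       alternative = "two.sided")
  )
  list(U = unname(w$statistic), p_two_sided = w$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Kruskal-Wallis H test
#'
#' Rank-based comparison of three or more groups, delegated to
#' [stats::kruskal.test()] (tie-corrected H, chi-square p with k - 1 df).
#'
#' @param groups List of at least three nonempty numeric vectors.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3) {
    stop("need at least 3 groups; use mann_whitney() for two-group comparisons",
         call. = FALSE)
  }
  if (any(lengths(groups) == 0)) stop("empty group(s)", call. = FALSE)
  if (length(unique(unlist(groups))) == 1) {
    # every observation tied: no rank variation, H is 0 by convention
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  k <- stats::kruskal.test(groups)
  list(H = unname(k$statistic), df = unname(k$parameter), p = k$p.value)
}

#' Substrate-wise SP groups from the reference isotopocule table
#'
#' Convenience splitter used by the substrate/genus comparisons: groups the
#' strain-mean SP values of [load_reference_isotopes()] by a metadata column.
#' By default the two nitrite-only strains (DSM 16622, JCM 30203), which have
#' no nitrate arm, and the abiotic control are excluded from substrate
#' comparisons; set `include_nitrite_only = TRUE` to keep them.
#'
#' @param tab A reference isotopocule table ([load_reference_isotopes()]).
#' @param by Grouping column: `"substrate"`, `"genus"`, `"strain"` or `"day"`.
#' @param metric Value column, default `"SP"`.
#' @param include_nitrite_only Logical, see above.
#' @return Named list of numeric vectors suitable for [group_medians()],
#'   [mann_whitney()] or [kruskal_wallis()].
#' @export
sp_groups <- function(tab, by = c("substrate", "genus", "strain", "day"),
                      metric = "SP", include_nitrite_only = FALSE) {
  by <- match.arg(by)
  tab <- tab[tab$biotic %in% TRUE, ]
  if (!include_nitrite_only) {
    nitrite_only <- grepl("DSM 16622|JCM 30203", tab$strain)
    tab <- tab[!nitrite_only, ]
  }
  split(tab[[metric]], tab[[by]])
}
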