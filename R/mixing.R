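# Two-endmember isotope mass balance on site preference:
#   SP_mix = f * SP_a + (1 - f) * SP_b
# with Monte Carlo propagation of endmember and mixture uncertainty.

#' Define a point endmember
#'
#' A source process's characteristic SP value with a 1-SD uncertainty, e.g.
#' the cNor-driven denitrification endmember SP = -5.9 +/- 2.1 permil.
#'
#' @param name Endmember label.
#' @param sp Site preference, per-mil.
#' @param sp_sd 1-SD uncertainty, per-mil (>= 0).
#' @return An object of class `point_endmember`.
#' @export
point_endmember <- function(name, sp, sp_sd = 0) {
  stopifnot(is.numeric(sp), length(sp) == 1, sp_sd >= 0)
  structure(list(name = as.character(name), sp = sp, sp_sd = sp_sd),
            class = "point_endmember")
}

#' @export
print.point_endmember <- function(x, ...) {
  cat(sprintf("<point_endmember> %s: SP = %.4g +/- %.4g permil\n",
              x$name, x$sp, x$sp_sd))
  invisible(x)
}

# condition class distinguishing estimation failures (CLI exit code 3)
# from ordinary validation errors (exit code 2)
estimation_error <- function(msg) {
  structure(class = c("estimation_error", "error", "condition"),
            list(message = msg, call = NULL))
}

as_endmember <- function(x, default_name = "endmember") {
  if (inherits(x, "point_endmember")) return(x)
  if (is.numeric(x) && length(x) == 1) return(point_endmember(default_name, x))
  stop("expected a point_endmember or a single SP value", call. = FALSE)
}

#' Solve the two-endmember mixing fraction
#'
#' Closed-form inversion of `sp_mix = f * a + (1 - f) * b`:
#' `f = (sp_mix - b) / (a - b)`, the fraction attributed to endmember `a`.
#' The result is not clipped; values outside `[0, 1]` indicate that the
#' mixture lies outside the endmember span (a warning is raised).
#'
#' @param sp_mix Measured mixture SP, per-mil. Vectorised.
#' @param a,b Endmembers ([point_endmember()] or plain SP values); `f` is the
#'   fraction of `a`.
#' @return Fraction(s) of endmember `a`.
#' @examples
#' solve_fraction(41.9, 45.5, -5.9) # 0.930
#' @export
solve_fraction <- function(sp_mix, a, b) {
  a <- as_endmember(a, "a"); b <- as_endmember(b, "b")
  if (a$sp == b$sp) {
    stop("degenerate endmembers: identical SP values, fraction unidentifiable",
         call. = FALSE)
  }
  f <- (sp_mix - b$sp) / (a$sp - b$sp)
  out <- f[!is.na(f)]
  if (any(out < 0 | out > 1)) {
    warning("mixing fraction outside [0, 1]: mixture lies outside the endmember span",
            call. = FALSE)
  }
  f
}

#' Forward two-endmember mixture
#'
#' `f * a + (1 - f) * b`; exact inverse of [solve_fraction()]. `f` outside
#' `[0, 1]` is allowed (extrapolation).
#'
#' @param f Fraction of endmember `a`. Vectorised.
#' @inheritParams solve_fraction
#' @return Mixture SP, per-mil.
#' @export
predict_mixture <- function(f, a, b) {
  a <- as_endmember(a, "a"); b <- as_endmember(b, "b")
  f * a$sp + (1 - f) * b$sp
}

#' Monte Carlo uncertainty on the mixing fraction
#'
#' Draws the mixture SP and both endmember SPs independently from normal
#' distributions (the +/- values are read as 1 SD), solves the closed form
#' per draw, and summarises. Draws whose endmembers come within 1e-6 permil
#' of each other are rejected and resampled (their count is reported).
#' Out-of-`[0, 1]` draws are retained in the statistics — truncation would
#' bias `f` near the boundaries — and their share is reported.
#'
#' @param sp_mix Measured mixture SP, per-mil.
#' @param sp_mix_sd 1-SD uncertainty of `sp_mix`, per-mil (>= 0).
#' @param a,b Endmembers ([point_endmember()]); their `sp_sd` fields are used.
#' @param n_draws Number of Monte Carlo draws (>= 1).
#' @param seed Integer seed; the result is reproducible for a fixed seed.
#' @param ci Two-sided central interval coverage (default 0.95).
#' @return An object of class `mixing_result`: `f_point` (closed form at the
#'   means), `f_mean`, `f_sd`, `ci_low`, `ci_high`, `n_draws`, `seed`,
#'   `clipped_share`, `n_resampled`, and the draw vector in `draws`.
#' @export
mc_fraction <- function(sp_mix, sp_mix_sd = 0, a, b, n_draws = 10000L,
                        seed = 1L, ci = 0.95) {
  a <- as_endmember(a, "a"); b <- as_endmember(b, "b")
  stopifnot(n_draws >= 1, sp_mix_sd >= 0, a$sp_sd >= 0, b$sp_sd >= 0)
  f_point <- solve_fraction(sp_mix, a, b)
  if (a$sp == b$sp || (a$sp_sd == 0 && b$sp_sd == 0 && abs(a$sp - b$sp) < 1e-6)) {
    stop(estimation_error("all draws degenerate: endmembers cannot be separated"))
  }
  res <- withr::with_seed(seed, {
    mix <- stats::rnorm(n_draws, sp_mix, sp_mix_sd)
    ea <- stats::rnorm(n_draws, a$sp, a$sp_sd)
    eb <- stats::rnorm(n_draws, b$sp, b$sp_sd)
    n_resampled <- 0L
    repeat {
      degen <- which(abs(ea - eb) < 1e-6)
      if (length(degen) == 0) break
      n_resampled <- n_resampled + length(degen)
      if (n_resampled > 1000L * n_draws) {
        stop(estimation_error("endmember draws persistently degenerate"))
      }
      ea[degen] <- stats::rnorm(length(degen), a$sp, a$sp_sd)
      eb[degen] <- stats::rnorm(length(degen), b$sp, b$sp_sd)
    }
    list(draws = (mix - eb) / (ea - eb), n_resampled = n_resampled)
  })
  draws <- res$draws
  q <- stats::quantile(draws, c((1 - ci) / 2, 1 - (1 - ci) / 2), names = FALSE)
  structure(
    list(
      f_point = f_point,
      f_mean = mean(draws),
      f_sd = if (n_draws > 1) stats::sd(draws) else 0,
      ci_low = q[1], ci_high = q[2], ci = ci,
      n_draws = as.integer(n_draws), seed = as.integer(seed),
      clipped_share = mean(draws < 0 | draws > 1),
      n_resampled = res$n_resampled,
      draws = draws
    ),
    class = "mixing_result"
  )
}

#' @export
print.mixing_result <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<mixing_result> f = %.*f (closed form), MC mean %.*f +/- %.*f, %g%% CI [%.*f, %.*f]\n",
    digits, x$f_point, digits, x$f_mean, digits, x$f_sd,
    100 * x$ci, digits, x$ci_low, digits, x$ci_high
  ))
  cat(sprintf("  n_draws = %d, seed = %d, share outside [0,1] = %.3g, resampled = %d\n",
              x$n_draws, x$seed, x$clipped_share, x$n_resampled))
  invisible(x)
}
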