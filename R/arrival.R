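#' Logistic law of the arrival time of type-n cells
#'
#' For small mutation rates the arrival time `tau_n` of the first type-n cell
#' is approximately logistic,
#' `P(tau_n > t) = 1 / (1 + exp(lambda_1 * (t - t_half)))`,
#' with scale `1 / lambda_1` (so the variance is always `pi^2 / (3 lambda_1^2)`
#' whatever the path) and median
#' `t_half = (1 / delta_{n-1}) * log( delta_{n-1} /
#'   (omega_{n-1} * nu_{n-1} * (log(1/nu_{n-1}) / delta_{n-1})^(r_{n-1} - 1)) )`.
#'
#' `median_arrival()` evaluates the median directly from the scale parameter
#' `omega_{n-1}`; [median_recursion()] reaches the same medians through the
#' per-step increment recursion, and the two agree to floating-point accuracy.
#'
#' If the mutation rates are not small enough for the asymptotic law the
#' median formula produces a non-positive time; this is reported as a regime
#' error rather than clamped.
#'
#' @param profile A [fitness_profile()].
#' @param path The [mutation_path()] the profile was built from.
#' @param n Target type index, `2 <= n <= N`.
#' @return An object of class `arrival_law` with elements `n`, `median`, and
#'   `scale`.
#' @examples
#' path <- mutation_path(alpha = c(1, 1), beta = c(0.3, 0.3), nu = c(0.01, 0))
#' prof <- fitness_profile(path)
#' law <- median_arrival(prof, path, 2)
#' law$median  # log(0.7^2 / (1 * 0.01)) / 0.7
#' @export
median_arrival <- function(profile, path, n) {
  stopifnot(inherits(profile, "fitness_profile"))
  if (n < 2L || n > path$n_types) {
    stop("'n' must satisfy 2 <= n <= number of types")
  }
  m <- n - 1L
  nu <- path$nu[m]
  if (nu >= 1) {
    stop(sprintf("regime error: nu[%d] >= 1, log(1/nu) <= 0; the asymptotic arrival law requires small mutation rates", m))
  }
  dm <- profile$delta[m]
  med <- (log(dm) - profile$log_omega[m] - log(nu) -
            (profile$r[m] - 1L) * (log(log(1 / nu)) - log(dm))) / dm
  if (!is.finite(med) || med <= 0) {
    stop(sprintf(
      "regime error: the asymptotic median arrival time of type %d is not positive (%.4g); the mutation rates are not small enough for the limit law",
      n, med))
  }
  structure(list(n = n, median = med, scale = 1 / profile$lam[1L]),
            class = "arrival_law")
}

#' @export
print.arrival_law <- function(x, ...) {
  cat(sprintf(
    "Logistic arrival law for type %d: median %.6g, scale %.6g (variance %.6g)\n",
    x$n, x$median, x$scale, pi^2 / 3 * x$scale^2))
  invisible(x)
}

#' Median arrival times via the per-step increment recursion
#'
#' An independent route to the medians of [median_arrival()]: starting from
#' `t_half(2) = (1 / delta_1) * log(delta_1^2 / (alpha_1 * nu_1))`, each new
#' type adds an increment whose form depends on how `lambda_n` compares with
#' the previous running max `delta_{n-1}`:
#'
#' * below the max: `(1/delta_n) * log( (delta_n - lambda_n) / nu_n *
#'   (log(1/nu_{n-1}) / log(1/nu_n))^(r_n - 1) )`;
#' * equal to the max: `(1/delta_n) * log( r_{n-1} * delta_n / nu_n *
#'   log(1/nu_{n-1})^(r_n - 2) / log(1/nu_n)^(r_n - 1) )`;
#' * above the max (a fitness increase): `(1/delta_n) * log(delta_n / nu_n *
#'   (delta_n / log(1/nu_n))^(r_n - 1)) -
#'   (1/delta_{n-1}) * log(delta_{n-1}^(r_{n-1}) * kappa_{n-1})`.
#'
#' To leading order each increment is `log(1/nu_n) / delta_n`: the time an
#' exponential clone at rate `delta_n` needs to grow from one cell to the
#' `1/nu_n` cells at which the next mutant appears.
#'
#' Because the final mutation rate enters through an ordered small-rate limit,
#' its `log log` correction is privileged; alternative limit orders could
#' alter those corrections (see the methods vignette).
#'
#' @inheritParams median_arrival
#' @return Numeric vector of medians for types `2, ..., N`, named by type.
#' @export
median_recursion <- function(profile, path) {
  stopifnot(inherits(profile, "fitness_profile"))
  N <- path$n_types
  if (N < 2L) stop("the path must reach at least type 2")
  nu <- path$nu
  if (any(nu[seq_len(N - 1L)] >= 1)) {
    stop("regime error: all mutation rates must be < 1 for the asymptotic arrival law")
  }
  lnu <- log(1 / nu[seq_len(N - 1L)])  # log(nu^-1) per step
  d <- profile$delta
  r <- profile$r
  med <- numeric(N - 1L)
  med[1L] <- (2 * log(d[1L]) - log(path$alpha[1L]) - log(nu[1L])) / d[1L]
  if (N > 2L) {
    for (n in 2L:(N - 1L)) {
      # increment from t_half(n) to t_half(n+1); case of lambda_n vs delta_{n-1}
      inc <- switch(profile$case[n - 1L],
        stay = (log(d[n] - profile$lam[n]) - log(nu[n]) +
                  (r[n] - 1L) * (log(lnu[n - 1L]) - log(lnu[n]))) / d[n],
        equal = (log(r[n - 1L]) + log(d[n]) - log(nu[n]) +
                   (r[n] - 2L) * log(lnu[n - 1L]) -
                   (r[n] - 1L) * log(lnu[n])) / d[n],
        increase = (log(d[n]) - log(nu[n]) +
                      (r[n] - 1L) * (log(d[n]) - log(lnu[n]))) / d[n] -
          (r[n - 1L] * log(d[n - 1L]) + profile$log_kappa[n - 1L]) / d[n - 1L]
      )
      med[n] <- med[n - 1L] + inc
    }
  }
  if (any(!is.finite(med) | med <= 0)) {
    stop("regime error: a median arrival time is not positive; the mutation rates are not small enough for the limit law")
  }
  names(med) <- paste0("type", 2L:N)
  med
}

#' Arrival-time distribution functions
#'
#' Density, distribution function, random generation, and survival for the
#' logistic arrival law of an [median_arrival()] object. `rarrival()` draws
#' logistic variates; negative draws are possible in the limit law (they
#' correspond to the regime where the asymptotics are inaccurate) and are
#' returned as-is.
#'
#' @param law An `arrival_law`.
#' @param t Time(s).
#' @param n Number of samples.
#' @param lower.tail If `FALSE`, `parrival()` returns the survival
#'   `P(tau > t)`.
#' @name arrival_distribution
NULL

#' @rdname arrival_distribution
#' @export
parrival <- function(t, law, lower.tail = TRUE) {
  stats::plogis(t, location = law$median, scale = law$scale,
                lower.tail = lower.tail)
}

#' @rdname arrival_distribution
#' @export
darrival <- function(t, law) {
  stats::dlogis(t, location = law$median, scale = law$scale)
}

#' @rdname arrival_distribution
#' @export
qarrival <- function(p, law) {
  stats::qlogis(p, location = law$median, scale = law$scale)
}

#' @rdname arrival_distribution
#' @export
rarrival <- function(n, law) {
  stats::rlogis(n, location = law$median, scale = law$scale)
}

#' Rank evolutionary paths by median arrival time
#'
#' Compares several linear mutational paths to the same target type by the
#' median arrival time of that type, the natural summary when asking which of
#' two mutational routes (say, a high-mutation-rate/low-fitness "mini-driver"
#' route versus a low-rate/high-fitness "major-driver" route) produces the
#' first target cell sooner. Ties are reported through the `rank` column
#' (minimum rank), so tied paths share a rank.
#'
#' @param paths A list of [mutation_path()] objects (optionally named).
#' @param n Target type index, applied to every path.
#' @param tie_tol Passed to [fitness_profile()].
#' @return A data frame with one row per path: `path`, `median`, `scale`, and
#'   `rank`, ordered fastest first. Regime errors in any single path
#'   propagate.
#' @export
compare_paths <- function(paths, n, tie_tol = 1e-9) {
  stopifnot(is.list(paths), length(paths) >= 1L)
  nm <- names(paths)
  if (is.null(nm) || any(nm == "")) nm <- paste0("path", seq_along(paths))
  res <- lapply(paths, function(p) {
    prof <- fitness_profile(p, tie_tol = tie_tol)
    median_arrival(prof, p, n)
  })
  out <- data.frame(
    path = nm,
    median = vapply(res, `[[`, numeric(1), "median"),
    scale = vapply(res, `[[`, numeric(1), "scale")
  )
  out$rank <- rank(out$median, ties.method = "min")
  out[order(out$median), , drop = FALSE]
}
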