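#' Two-parameter Mittag-Leffler function
#'
#' Evaluates `E_{a,b}(z) = sum_k z^k / Gamma(a k + b)` for real `z` and
#' `0 < a <= 1`, the parameter range the cell-number laws use (the random
#' amplitude density is `x^(g-1) * E_{g,g}(-x^g)` with tail parameter
#' `g in (0, 1]`).
#'
#' Three evaluation regimes are combined: the truncated power series where it
#' is numerically safe (small `|z|`, or any positive `z`, where there is no
#' cancellation), a branch-cut (Hankel-contour) integral representation for
#' moderate negative `z`, and the algebraic asymptotic expansion
#' `-sum_{k>=1} z^-k / Gamma(b - a k)` for large negative `z`. The crossovers
#' are chosen so that cancellation in the alternating series never exceeds a
#' few digits. For `b >= a + 1` on the integral branch the index is first
#' reduced with `E_{a,b}(z) = (E_{a,b-a}(z) - 1/Gamma(b - a)) / z`.
#'
#' @param a First parameter, `0 < a <= 1`.
#' @param b Second parameter (default 1).
#' @param z Real argument(s); negative arguments are the main use.
#' @return `E_{a,b}(z)`, vectorized over `z`.
#' @examples
#' mittag_leffler(1, 1, -2)       # exp(-2)
#' mittag_leffler(0.5, 1, -1.5)   # exp(1.5^2) * erfc(1.5)
#' @export
mittag_leffler <- function(a, b = 1, z) {
  if (!is.numeric(a) || length(a) != 1L || a <= 0 || a > 1) {
    stop("'a' must be a scalar in (0, 1]")
  }
  if (!is.numeric(b) || length(b) != 1L) stop("'b' must be a numeric scalar")
  vapply(z, function(zz) ml_scalar(a, b, zz), numeric(1))
}

ml_scalar <- function(a, b, z) {
  if (!is.finite(z)) {
    if (is.na(z)) return(NA_real_)
    if (z < 0) return(0)
    stop("z = +Inf is outside the supported domain")
  }
  if (z >= 0) return(ml_series(a, b, z))
  az <- -z
  if (a == 1) {
    if (b == 1) return(exp(z))
    if (az <= 30) return(ml_series(a, b, z))
    return(ml_asymptotic(a, b, z))
  }
  # negative argument, 0 < a < 1: pick route by cancellation / accuracy
  if (az^(1 / a) <= 6) return(ml_series(a, b, z))
  if (az >= 1e4) return(ml_asymptotic(a, b, z))
  ml_branch_cut(a, b, z)
}

ml_series <- function(a, b, z, kmax = 2000L, tol = 1e-16) {
  total <- term <- 1 / gamma(b)
  k <- 1L
  zk <- 1
  repeat {
    zk <- zk * z
    g <- a * k + b
    term <- if (g > 0 || g != floor(g)) zk / gamma(g) else 0
    total <- total + term
    if (abs(term) < tol * max(abs(total), 1e-300) && k > 3L) break
    k <- k + 1L
    if (k > kmax) break
  }
  total
}

# Asymptotic expansion for z -> -Inf: -sum_{k>=1} z^-k / Gamma(b - a k),
# truncated at the smallest (nonzero) term.
ml_asymptotic <- function(a, b, z, kmax = 200L) {
  total <- 0
  prev <- Inf
  zk <- 1
  for (k in seq_len(kmax)) {
    zk <- zk * z
    g <- b - a * k
    if (g <= 0 && g == floor(g)) next  # 1/Gamma at a pole: term vanishes
    term <- -1 / (zk * gamma(g))
    if (abs(term) > prev) break  # asymptotic series started diverging
    total <- total + term
    prev <- abs(term)
    if (prev < 1e-17 * max(abs(total), 1e-300)) break
  }
  total
}

# Branch-cut (Hankel) integral for 0 < a < 1, z < 0 (no pole on the
# principal branch):
# E_{a,b}(z) = (1/pi) * Int_0^Inf exp(-r) r^(a-b) *
#   [r^a sin(pi b) + z sin(pi (a - b))] /
#   (r^(2a) - 2 r^a z cos(pi a) + z^2) dr,
# integrable at 0 when b < a + 1; otherwise reduce b first with
# E_{a,b}(z) = (E_{a,b-a}(z) - 1/Gamma(b - a)) / z.
ml_branch_cut <- function(a, b, z) {
  if (b >= a + 1) {
    return((ml_branch_cut(a, b - a, z) - 1 / gamma(b - a)) / z)
  }
  s1 <- sinpi(b)
  s2 <- sinpi(a - b)
  c1 <- cospi(a)
  # substitution r = u^p with p = 1/(a - b + 1) removes the r^(a-b)
  # endpoint singularity exactly
  p <- 1 / (a - b + 1)
  integrand <- function(u) {
    r <- u^p
    ra <- r^a
    p * exp(-r) * (ra * s1 + z * s2) / (ra^2 - 2 * ra * z * c1 + z^2)
  }
  val <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-11,
                          abs.tol = 1e-14, subdivisions = 1000L)
  val$value / pi
}

#' Mittag-Leffler distribution of the random amplitude
#'
#' The positive law with Laplace transform `(1 + (scale * theta)^tail)^-1`,
#' `tail in (0, 1]`. For `tail == 1` this is the exponential distribution with
#' mean `scale`; for `tail < 1` the density has an `x^(tail - 1)` singularity
#' at the origin and an `x^(-tail - 1)` power-law tail, so the mean is
#' infinite. The density at unit scale is
#' `f(x) = x^(tail - 1) * E_{tail,tail}(-x^tail)` and the survival function is
#' `E_{tail,1}(-x^tail)`, both evaluated through [mittag_leffler()]; the
#' equivalent completely-monotone spectral representation
#' `f(x) = (sin(pi g) / pi) * Int_0^Inf u^g e^{-u x} /
#'   (u^{2g} + 2 u^g cos(pi g) + 1) du`
#' is kept internally as an independent cross-check.
#'
#' `rml()` samples exactly via the product representation
#' `scale * E^{1/tail} * S`, where `E` is unit exponential and `S` is a
#' one-sided `tail`-stable variate from the Kanter (Chambers-Mallows-Stuck
#' type) trigonometric construction.
#'
#' @param x,q Positive quantiles.
#' @param p Probabilities.
#' @param n Number of samples.
#' @param tail Tail parameter in (0, 1].
#' @param scale Scale parameter (> 0).
#' @param lower.tail If `FALSE`, `pml()` returns the survival function.
#' @param log If `TRUE`, `dml()` returns the log density.
#' @name mittag_leffler_distribution
#' @examples
#' dml(1, tail = 1)          # exp(-1)
#' pml(2, tail = 0.5)        # P(X <= 2)
#' set.seed(1); mean(rml(1e4, tail = 1, scale = 2))  # about 2
NULL

ml_check_par <- function(tail, scale) {
  if (!is.numeric(tail) || length(tail) != 1L || tail <= 0 || tail > 1) {
    stop("'tail' must be a scalar in (0, 1]")
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("'scale' must be a positive scalar")
  }
}

#' @rdname mittag_leffler_distribution
#' @export
dml <- function(x, tail, scale = 1, log = FALSE) {
  ml_check_par(tail, scale)
  out <- vapply(x, function(xx) {
    if (is.na(xx)) return(NA_real_)
    if (xx < 0) return(0)
    y <- xx / scale
    if (tail == 1) return(exp(-y) / scale)
    if (y == 0) return(Inf)  # x^(tail-1) singularity
    y^(tail - 1) * ml_scalar(tail, tail, -y^tail) / scale
  }, numeric(1))
  if (log) base::log(out) else out
}

#' @rdname mittag_leffler_distribution
#' @export
pml <- function(q, tail, scale = 1, lower.tail = TRUE) {
  ml_check_par(tail, scale)
  sf <- vapply(q, function(qq) {
    if (is.na(qq)) return(NA_real_)
    if (qq <= 0) return(1)
    y <- qq / scale
    if (tail == 1) return(exp(-y))
    ml_scalar(tail, 1, -y^tail)
  }, numeric(1))
  if (lower.tail) 1 - sf else sf
}

# Spectral (completely monotone) representation, rescaled so the quadrature
# is uniformly stable in x. With w = (u x)^g and Q(v) = v^2 + 2 v cos(pi g) + 1:
#   survival: S(x) = (sin(pi g)/(pi g)) x^-g    Int e^{-w^(1/g)} / Q(w x^-g) dw
#   density:  f(x) = (sin(pi g)/(pi g)) x^-(g+1) Int w^(1/g) e^{-w^(1/g)} / Q(w x^-g) dw
ml_spectral <- function(x, g, moment) {
  cg <- cospi(g)
  if (x > 1) {
    # scaled form: the e^{-w^(1/g)} factor pins the quadrature feature at O(1)
    xg <- x^(-g)
    f <- function(w) {
      u <- w^(1 / g)
      v <- w * xg
      out <- exp(-u) / (v^2 + 2 * v * cg + 1)
      if (moment == 1) out * u else out
    }
    val <- stats::integrate(f, 0, Inf, rel.tol = 1e-11, abs.tol = 1e-300,
                            subdivisions = 1000L)$value
    return(sinpi(g) / (pi * g) * val * xg / if (moment == 1) x else 1)
  }
  # unscaled form (v = u^g), stable for small x
  f <- function(v) {
    u <- v^(1 / g)
    out <- exp(-u * x) / (v^2 + 2 * v * cg + 1)
    if (moment == 1) out * u else out
  }
  val <- stats::integrate(f, 0, Inf, rel.tol = 1e-11, abs.tol = 1e-300,
                          subdivisions = 1000L)$value
  sinpi(g) / (pi * g) * val
}

#' @rdname mittag_leffler_distribution
#' @export
qml <- function(p, tail, scale = 1) {
  ml_check_par(tail, scale)
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_real_)
    if (pp < 0 || pp > 1) stop("'p' must be in [0, 1]")
    if (pp == 0) return(0)
    if (pp == 1) return(Inf)
    if (tail == 1) return(stats::qexp(pp) * scale)
    f <- function(lx) pml(exp(lx), tail, scale) - pp
    lo <- log(scale) - 5
    hi <- log(scale) + 5
    while (f(lo) > 0) lo <- lo - 5
    while (f(hi) < 0) hi <- hi + 5
    exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
  }, numeric(1))
}

#' @rdname mittag_leffler_distribution
#' @export
rml <- function(n, tail, scale = 1) {
  ml_check_par(tail, scale)
  e <- stats::rexp(n)
  if (tail == 1) return(scale * e)
  scale * e^(1 / tail) * rstable_onesided(n, tail)
}

# One-sided (totally skewed) stable variate with Laplace transform
# exp(-theta^g), by the Kanter construction.
rstable_onesided <- function(n, g) {
  u <- pi * stats::runif(n)
  w <- stats::rexp(n)
  (sin((1 - g) * u) / w)^((1 - g) / g) * sin(g * u) / sin(u)^(1 / g)
}

#' Mittag-Leffler amplitude law of the type-n cell number
#'
#' Packages the limiting law of the random amplitude `V_n` in
#' `Z_n(t) ~ V_n * t^(r_n - 1) * exp(delta_n * t)`: Mittag-Leffler with tail
#' `lambda_1 / delta_n` and scale `omega_n`. Use [dml()]/[pml()]/[qml()]/
#' [rml()] with the returned `tail` and `scale`, or the [prob_exceed()]
#' helper.
#'
#' @param profile A [fitness_profile()].
#' @param n Type index.
#' @return An object of class `amplitude_law` with elements `n`, `tail`, and
#'   `scale`.
#' @export
amplitude_law <- function(profile, n) {
  stopifnot(inherits(profile, "fitness_profile"))
  if (n < 1L || n > profile$n_types) stop("'n' out of range")
  tail <- profile$lam[1L] / profile$delta[n]
  if (tail > 1) tail <- 1  # delta_n >= lambda_1 always; guard rounding
  structure(list(n = n, tail = tail, scale = profile$omega[n],
                 log_scale = profile$log_omega[n]),
            class = "amplitude_law")
}

#' @export
print.amplitude_law <- function(x, ...) {
  cat(sprintf(
    "Mittag-Leffler amplitude law for type %d: tail %.6g, scale %.6g%s\n",
    x$n, x$tail, x$scale,
    if (x$tail == 1) " (exponential)" else " (heavy-tailed, infinite mean)"))
  invisible(x)
}

#' Mean of the random amplitude
#'
#' Defined only in the exponential case `tail == 1` (the running-max fitness
#' never exceeded `lambda_1`); for `tail < 1` the Mittag-Leffler law has a
#' power-law tail with infinite mean, and this function refuses rather than
#' silently returning `Inf`.
#'
#' @param law An [amplitude_law()].
#' @return The mean, `scale`, when `tail == 1`.
#' @export
amplitude_mean <- function(law) {
  stopifnot(inherits(law, "amplitude_law"))
  if (law$tail < 1) {
    stop(sprintf(
      "the amplitude of type %d has tail parameter %.4g < 1: its Mittag-Leffler law has an x^(-tail-1) power-law tail and infinite mean",
      law$n, law$tail))
  }
  law$scale
}

#' Probability that the type-n population exceeds a size threshold
#'
#' At large times the event `Z_n(t) > k` reduces to a tail probability of the
#' random amplitude: `P(Z_n(t) > k) ~ P(V_n > k * t^(1 - r_n) * exp(-delta_n
#' t))`. The threshold is computed in log space so that very large `t` cannot
#' underflow prematurely.
#'
#' @param profile A [fitness_profile()].
#' @param n Type index.
#' @param t Time (scalar or vector).
#' @param k Size threshold (scalar or vector, recycled against `t`).
#' @return `P(Z_n(t) > k)` under the limit law.
#' @export
prob_exceed <- function(profile, n, t, k) {
  law <- amplitude_law(profile, n)
  ans <- mapply(function(tt, kk) {
    if (kk <= 0) return(1)
    lx <- log(kk) + (1 - profile$r[n]) * log(tt) - profile$delta[n] * tt
    pml(exp(lx), tail = law$tail, scale = law$scale, lower.tail = FALSE)
  }, t, k)
  as.numeric(ans)
}
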