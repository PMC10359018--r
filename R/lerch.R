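#' Lerch transcendent on the real domain of the transform chain
#'
#' Evaluates `Phi(z, s, a) = sum_{k>=0} z^k / (k + a)^s` for `z <= 0`,
#' positive integer `s`, and `a in (0, 1]` -- the domain in which the
#' transcendent appears inside the per-step Laplace-transform map of the
#' fitness-increase case.
#'
#' The direct series is used for `|z| <= 0.5`; for more negative `z` the
#' integral representation
#' `Phi(z, s, a) = (1/Gamma(s)) * Int_0^Inf t^(s-1) e^(-a t) / (1 - z e^(-t)) dt`
#' is evaluated by adaptive quadrature, split at `log(-z)` where the integrand
#' peaks. As `z -> -Inf`,
#' `Phi(z, s, a) ~ (pi / sin(pi a)) * (-z)^(-a) * log(-z)^(s-1) / (s-1)!`;
#' that asymptotic is used as an independent check in the test-suite, never in
#' production evaluation.
#'
#' @param z Real argument(s), `z <= 0`.
#' @param s Positive integer parameter.
#' @param a Parameter in (0, 1].
#' @param method `"auto"` (default), or force `"series"` / `"integral"`.
#' @return `Phi(z, s, a)`, vectorized over `z`.
#' @examples
#' lerch_phi(0, 2, 0.4)    # a^(-s) = 0.4^-2
#' lerch_phi(-5, 1, 0.5)
#' @export
lerch_phi <- function(z, s, a, method = c("auto", "series", "integral")) {
  method <- match.arg(method)
  if (!is.numeric(s) || length(s) != 1L || s < 1 || s != floor(s)) {
    stop("'s' must be a positive integer")
  }
  if (!is.numeric(a) || length(a) != 1L || a <= 0 || a > 1) {
    stop("'a' must be a scalar in (0, 1]")
  }
  vapply(z, function(zz) {
    if (is.na(zz)) return(NA_real_)
    if (zz > 0) stop("lerch_phi() is implemented for z <= 0 only")
    use <- if (method == "auto") {
      if (abs(zz) <= 0.5) "series" else "integral"
    } else method
    if (use == "series") {
      if (abs(zz) >= 1) stop("the series representation requires |z| < 1")
      lerch_series(zz, s, a)
    } else {
      lerch_integral(zz, s, a)
    }
  }, numeric(1))
}

lerch_series <- function(z, s, a, kmax = 100000L, tol = 1e-16) {
  total <- a^(-s)
  zk <- 1
  for (k in seq_len(kmax)) {
    zk <- zk * z
    term <- zk / (k + a)^s
    total <- total + term
    if (abs(term) < tol * max(abs(total), 1e-300)) return(total)
  }
  total
}

lerch_integral <- function(z, s, a) {
  f <- function(t) t^(s - 1) * exp(-a * t) / (1 - z * exp(-t))
  # integrand peaks near log(-z) when z << -1; split there for the quadrature
  split <- max(1, if (z < -1) log(-z) else 1)
  v1 <- stats::integrate(f, 0, split, rel.tol = 1e-12, abs.tol = 0,
                         subdivisions = 400L)$value
  v2 <- stats::integrate(f, split, Inf, rel.tol = 1e-12, abs.tol = 1e-300,
                         subdivisions = 400L)$value
  (v1 + v2) / gamma(s)
}
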