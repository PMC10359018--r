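#' Fitness bookkeeping for a mutational path
#'
#' Computes every derived parameter the limit laws need from the raw rate
#' triples of a [mutation_path()]:
#'
#' * `lam`: net growth rates `lambda_n = alpha_n - beta_n`;
#' * `delta`: running-max fitness `delta_n = max(lambda_1, ..., lambda_n)`,
#'   the asymptotic exponential growth rate of the type-n population;
#' * `r`: attainment counts `r_n = #\{i <= n : lambda_i = delta_n\}`, which set
#'   the polynomial correction `t^(r_n - 1)` in the cell-number law;
#' * `case`: per-step classification of `lambda_{n+1}` against `delta_n`
#'   (`"stay"` below the running max, `"equal"` to it, `"increase"` above it);
#' * `gamma`: `delta_n / delta_{n+1}`;
#' * `phi`: lineage survival probabilities `lambda_{n+1} / alpha_{n+1}`;
#' * `kappa` (with `log_kappa`): the per-step constant entering the scale
#'   recursion; in the fitness-increase branch it equals the constant `c_n`
#'   multiplying the logistic/Mittag-Leffler scale,
#'   `pi * (alpha_{n+1}/lambda_{n+1})^gamma_n /
#'    (alpha_{n+1} * delta_n^(r_n - 1) * sin(pi * gamma_n))`,
#'   computed in log-space to avoid overflow;
#' * `omega` (with `log_omega`): the Mittag-Leffler scale parameters from
#'   [omega_recursion()].
#'
#' Whether `lambda_{n+1}` ties the running max is decided with a relative
#' tolerance `tie_tol` because the case structure is discontinuous. Mildly
#' deleterious steps (`0 < delta_n - lambda_{n+1} < warn_margin * delta_n`)
#' make the scale parameter large and the large-time approximation poor, so
#' they raise a warning.
#'
#' Only the founding type must be supercritical; intermediate types may be
#' critical or subcritical.
#'
#' @param path A [mutation_path()].
#' @param tie_tol Relative tolerance for classifying `lambda_{n+1} == delta_n`.
#' @param warn_margin Relative margin below the running max within which a
#'   deleterious step triggers the "mildly deleterious" warning.
#' @return An object of class `fitness_profile`.
#' @examples
#' path <- mutation_path(c(1.1, 1, 1.1), c(0.8, 0.9, 0.5), c(0.01, 0.01, 0))
#' fitness_profile(path)
#' @export
fitness_profile <- function(path, tie_tol = 1e-9, warn_margin = 0.05) {
  stopifnot(inherits(path, "mutation_path"))
  if (!is.null(attr(path, "tie_tol")) && missing(tie_tol)) {
    tie_tol <- attr(path, "tie_tol")
  }
  n <- path$n_types
  lam <- path$alpha - path$beta
  if (lam[1L] <= 0) stop("supercriticality violation: lambda[1] must be > 0")

  delta <- numeric(n)
  r <- integer(n)
  delta[1L] <- lam[1L]
  r[1L] <- 1L
  case <- character(max(n - 1L, 0L))
  mild <- logical(max(n - 1L, 0L))
  for (i in seq_len(n - 1L)) {
    gap <- lam[i + 1L] - delta[i]
    tol <- tie_tol * abs(delta[i])
    if (abs(gap) <= tol) {
      case[i] <- "equal"
      delta[i + 1L] <- delta[i]
      r[i + 1L] <- r[i] + 1L
    } else if (gap > 0) {
      case[i] <- "increase"
      delta[i + 1L] <- lam[i + 1L]
      r[i + 1L] <- 1L
    } else {
      case[i] <- "stay"
      delta[i + 1L] <- delta[i]
      r[i + 1L] <- r[i]
      mild[i] <- (-gap) < warn_margin * delta[i]
    }
  }
  if (any(mild)) {
    warning(warningCondition(
      sprintf(paste(
        "mildly deleterious step(s) %s: 0 < delta_n - lambda_{n+1} <",
        "%g * delta_n, so the scale parameter is large and the large-time",
        "approximation may be poor"),
        paste(which(mild), collapse = ", "), warn_margin),
      class = "seqmut_mildly_deleterious"
    ))
  }

  gamma <- phi <- kappa <- log_kappa <- rep(NA_real_, max(n - 1L, 0L))
  for (i in seq_len(n - 1L)) {
    gamma[i] <- delta[i] / delta[i + 1L]
    phi[i] <- if (path$alpha[i + 1L] > 0) lam[i + 1L] / path$alpha[i + 1L] else NA_real_
    log_kappa[i] <- switch(case[i],
      stay = -log(delta[i] - lam[i + 1L]),
      equal = -log(r[i]),
      increase = {
        # c_n in log space; gamma_i in (0,1) strictly here so sin() > 0
        log(pi) + gamma[i] * (log(path$alpha[i + 1L]) - log(lam[i + 1L])) -
          log(path$alpha[i + 1L]) - (r[i] - 1L) * log(delta[i]) -
          log(sin(pi * gamma[i]))
      }
    )
    kappa[i] <- exp(log_kappa[i])
  }

  profile <- structure(
    list(lam = lam, delta = delta, r = r, case = case, gamma = gamma,
         phi = phi, kappa = kappa, log_kappa = log_kappa,
         mildly_deleterious = mild, tie_tol = tie_tol,
         n_types = n, path = path),
    class = "fitness_profile"
  )
  om <- omega_recursion(profile, path)
  profile$omega <- om
  profile$log_omega <- attr(om, "log_omega")
  profile
}

#' Scale-parameter recursion for the random amplitudes
#'
#' The random amplitude `V_n` of the type-n cell number,
#' `Z_n(t) ~ V_n * t^(r_n - 1) * exp(delta_n * t)`, is Mittag-Leffler
#' distributed with tail `lambda_1 / delta_n` and scale `omega_n`. Starting
#' from `omega_1 = alpha_1 / lambda_1`, each step multiplies (or, on a fitness
#' increase, power-transforms) the scale:
#'
#' * `delta_n > lambda_{n+1}` ("stay"):
#'   `omega_{n+1} = nu_n / (delta_n - lambda_{n+1}) * omega_n`;
#' * `delta_n == lambda_{n+1}` ("equal"):
#'   `omega_{n+1} = nu_n / r_n * omega_n`;
#' * `delta_n < lambda_{n+1}` ("increase"):
#'   `omega_{n+1} = (kappa_n * nu_n * log(1/nu_n)^(r_n - 1) *
#'                   omega_n)^(lambda_{n+1} / delta_n)`,
#'   which requires `nu_n < 1` (the small-mutation regime).
#'
#' The recursion is carried in log-space so that large exponents
#' `lambda_{n+1} / delta_n` cannot overflow.
#'
#' @param profile A [fitness_profile()] (its `omega` element is ignored here).
#' @param path The [mutation_path()] the profile was built from.
#' @return Numeric vector of scale parameters `omega_1, ..., omega_N`, with
#'   attribute `log_omega`.
#' @export
omega_recursion <- function(profile, path) {
  stopifnot(inherits(profile, "fitness_profile"))
  n <- path$n_types
  log_omega <- numeric(n)
  log_omega[1L] <- log(path$alpha[1L]) - log(profile$lam[1L])
  for (i in seq_len(n - 1L)) {
    nu <- path$nu[i]
    log_omega[i + 1L] <- switch(profile$case[i],
      stay = log(nu) + profile$log_kappa[i] + log_omega[i],
      equal = log(nu) + profile$log_kappa[i] + log_omega[i],
      increase = {
        if (nu >= 1) {
          stop(sprintf(
            "invalid regime at step %d: nu[%d] >= 1, so log(1/nu) <= 0 and the fitness-increase scale recursion does not apply",
            i, i))
        }
        (profile$lam[i + 1L] / profile$delta[i]) *
          (log(nu) + (profile$r[i] - 1L) * log(log(1 / nu)) +
             profile$log_kappa[i] + log_omega[i])
      }
    )
  }
  omega <- exp(log_omega)
  attr(omega, "log_omega") <- log_omega
  omega
}

#' @export
print.fitness_profile <- function(x, ...) {
  cat(sprintf("Fitness profile for %d type(s)\n", x$n_types))
  df <- data.frame(
    type = seq_len(x$n_types),
    lambda = x$lam,
    delta = x$delta,
    r = x$r,
    tail = pmin(1, x$lam[1L] / x$delta),
    omega = x$omega
  )
  print(df, row.names = FALSE)
  if (x$n_types > 1L) {
    cat("Step classification (lambda_{n+1} vs delta_n):",
        paste(x$case, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert a fitness profile to a data frame
#'
#' One row per type with the derived sequences; step-level quantities
#' (`case`, `gamma`, `phi`, `kappa`) are attached to the row of the type the
#' step leads *from* and are `NA` for the final type.
#'
#' @param x A [fitness_profile()].
#' @param ... Unused.
#' @export
as.data.frame.fitness_profile <- function(x, ...) {
  n <- x$n_types
  pad <- function(v) c(v, rep(NA, n - length(v)))
  data.frame(
    type = seq_len(n),
    alpha = x$path$alpha,
    beta = x$path$beta,
    nu = x$path$nu,
    lambda = x$lam,
    delta = x$delta,
    r = x$r,
    tail = pmin(1, x$lam[1L] / x$delta),
    omega = x$omega,
    case = pad(x$case),
    gamma = pad(x$gamma),
    phi = pad(x$phi),
    kappa = pad(x$kappa)
  )
}
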