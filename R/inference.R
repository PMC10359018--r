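#' Fluctuation-assay data
#'
#' Container for the outcome of an n-mutation fluctuation assay: replicate
#' cultures grown from single sensitive cells for time `t`, then selected so
#' that only resistant cells (type `n_target`) survive and are counted.
#'
#' The inference in this module follows the neutral assay model: all types
#' share the net growth rate `lambda1` and all mutation steps share the
#' unknown rate `nu`. Note the indexing: when `k` mutations are required for
#' resistance the resistant type is `n_target = k + 1` (type 1 is the
#' unmutated founder). `alpha1` and `lambda1` are required, externally
#' measured inputs (e.g. from growth-curve assays); they are never
#' co-estimated.
#'
#' @param counts Nonnegative integer vector of per-replicate mutant counts.
#' @param t Growth time before selection (> 0).
#' @param n_target Resistant type index (>= 2).
#' @param alpha1 Division rate of the founding type.
#' @param lambda1 Net growth rate (shared across types under neutrality).
#' @param seed,mode Optional provenance from [simulate_assay()].
#' @return An object of class `assay_data`.
#' @export
assay_data <- function(counts, t, n_target, alpha1, lambda1,
                       seed = NULL, mode = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L || any(!is.finite(counts)) || any(counts < 0)) {
    stop("'counts' must be a nonempty vector of nonnegative mutant counts")
  }
  stopifnot(t > 0, n_target >= 2, alpha1 > 0, lambda1 > 0)
  structure(
    list(counts = counts, t = t, n_target = as.integer(n_target),
         alpha1 = alpha1, lambda1 = lambda1, seed = seed, mode = mode),
    class = "assay_data"
  )
}

#' @export
print.assay_data <- function(x, ...) {
  k <- length(x$counts)
  nz <- sum(x$counts == 0)
  cat(sprintf(
    "Fluctuation assay: %d replicate(s), t = %g, resistant type %d (%d mutation(s))\n",
    k, x$t, x$n_target, x$n_target - 1L))
  cat(sprintf("replicates without resistance: %d (%.1f%%)\n", nz, 100 * nz / k))
  cat(sprintf("positive counts: median %g, max %g\n",
              stats::median(x$counts[x$counts > 0]), max(x$counts)))
  invisible(x)
}

# Neutral-path median arrival time of the resistant type n for mutation
# rate nu: t_half(n) = (1/lambda1) * log( lambda1^2 (n-2)! /
#   (alpha1 * (log(1/nu)/lambda1)^(n-2) * nu^(n-1)) ).
neutral_median <- function(nu, n, alpha1, lambda1) {
  if (any(nu <= 0 | nu >= 1)) {
    stop("the neutral arrival law requires 0 < nu < 1")
  }
  m <- n - 2L
  (2 * log(lambda1) + lgamma(m + 1) - log(alpha1) -
      m * (log(log(1 / nu)) - log(lambda1)) - (n - 1L) * log(nu)) / lambda1
}

# Neutral amplitude scale omega_n = (alpha1/lambda1) nu^(n-1) / (n-1)!
# (log scale, used for the mutant-count mean).
neutral_log_omega <- function(nu, n, alpha1, lambda1) {
  log(alpha1) - log(lambda1) + (n - 1L) * log(nu) - lgamma(n)
}

# P(no resistant cell at time t) under the logistic arrival law.
p0_prob <- function(nu, data) {
  m <- neutral_median(nu, data$n_target, data$alpha1, data$lambda1)
  stats::plogis(data$t, location = m, scale = 1 / data$lambda1,
                lower.tail = FALSE)
}

#' Log-likelihood of the zero-replicate count (p0 method)
#'
#' The number of replicates without resistance is binomial with success
#' probability equal to the logistic no-arrival probability
#' `P(tau_{n} > t)` evaluated at the neutral-path median. This is the
#' n-mutation generalization of the classical p0 method of fluctuation
#' analysis.
#'
#' @param data An [assay_data()].
#' @param nu Mutation rate(s) at which to evaluate.
#' @return Log-likelihood value(s).
#' @export
p0_loglik <- function(data, nu) {
  stopifnot(inherits(data, "assay_data"))
  y <- sum(data$counts == 0)
  k <- length(data$counts)
  vapply(nu, function(v) {
    stats::dbinom(y, k, p0_prob(v, data), log = TRUE)
  }, numeric(1))
}

#' Log-likelihood of the mutant counts
#'
#' At long times the resistant-cell number is `Z_n(t) ~ V_n t^(n-1)
#' exp(lambda1 t)` with `V_n` exponential with mean `omega_n(nu) =
#' (alpha1/lambda1) nu^(n-1)/(n-1)!` on the neutral path, so positive counts
#' are modeled as exponential with mean `omega_n(nu) t^(n-1) exp(lambda1 t)`.
#' Replicates with zero mutants are handled according to `zero_handling`:
#'
#' * `"mixture"` (default): zeros contribute the logistic no-arrival
#'   probability and positives the complementary mass times the exponential
#'   density;
#' * `"condition"`: the likelihood conditions on positivity and zeros are
#'   dropped.
#'
#' @inheritParams p0_loglik
#' @param zero_handling How replicates with zero mutants enter the likelihood.
#' @export
count_loglik <- function(data, nu,
                         zero_handling = c("mixture", "condition")) {
  stopifnot(inherits(data, "assay_data"))
  zero_handling <- match.arg(zero_handling)
  pos <- data$counts[data$counts > 0]
  y <- sum(data$counts == 0)
  vapply(nu, function(v) {
    log_mean <- neutral_log_omega(v, data$n_target, data$alpha1, data$lambda1) +
      (data$n_target - 1L) * log(data$t) + data$lambda1 * data$t
    ll <- sum(-log_mean - pos * exp(-log_mean))
    if (zero_handling == "mixture") {
      p0 <- p0_prob(v, data)
      ll <- ll + y * log(p0) + length(pos) * log1p(-p0)
    }
    ll
  }, numeric(1))
}

# Shared machinery: maximize a log-likelihood over log10(nu) on a bracket and
# return a profile-likelihood confidence interval (drop of
# qchisq(conf, 1) / 2 ~ 1.92 log-units at 95%).
profile_mle <- function(ll_fun, bracket, conf_level) {
  f <- function(x) ll_fun(10^x)
  opt <- stats::optimize(f, interval = bracket, maximum = TRUE, tol = 1e-8)
  xhat <- opt$maximum
  llmax <- opt$objective
  # an optimum within tolerance of the bracket edge is treated as boundary
  at_lower <- xhat - bracket[1L] < 1e-4
  at_upper <- bracket[2L] - xhat < 1e-4
  drop <- stats::qchisq(conf_level, df = 1) / 2
  g <- function(x) f(x) - (llmax - drop)
  lo <- if (g(bracket[1L]) > 0 || at_lower) bracket[1L] else {
    stats::uniroot(g, c(bracket[1L], xhat), tol = 1e-8)$root
  }
  hi <- if (g(bracket[2L]) > 0 || at_upper) bracket[2L] else {
    stats::uniroot(g, c(xhat, bracket[2L]), tol = 1e-8)$root
  }
  list(log10_estimate = xhat, loglik = llmax, log10_ci = c(lo, hi),
       at_boundary = c(lower = at_lower, upper = at_upper),
       one_sided = c(lower = g(bracket[1L]) > 0, upper = g(bracket[2L]) > 0))
}

new_nu_estimate <- function(fit, method, conf_level, data, notes) {
  structure(
    list(estimate = 10^fit$log10_estimate,
         log10_estimate = fit$log10_estimate,
         ci = 10^fit$log10_ci,
         log10_ci = fit$log10_ci,
         method = method,
         loglik = fit$loglik,
         conf_level = conf_level,
         diagnostics = list(
           frac_zero = mean(data$counts == 0),
           n_replicates = length(data$counts),
           one_sided = fit$one_sided,
           at_boundary = fit$at_boundary,
           notes = notes
         )),
    class = "nu_estimate"
  )
}

#' @export
print.nu_estimate <- function(x, ...) {
  cat(sprintf("Mutation-rate estimate (%s method)\n", x$method))
  cat(sprintf("  nu = %.4g  (log10 nu = %.3f)\n", x$estimate, x$log10_estimate))
  cat(sprintf("  %d%% profile CI: [%.4g, %.4g]\n", round(100 * x$conf_level),
              x$ci[1L], x$ci[2L]))
  cat(sprintf("  log-likelihood %.3f; %.0f%% of replicates without resistance\n",
              x$loglik, 100 * x$diagnostics$frac_zero))
  for (msg in x$diagnostics$notes) cat("  note:", msg, "\n")
  invisible(x)
}

#' Estimate the mutation rate from the zero-replicate fraction (p0 method)
#'
#' Maximizes [p0_loglik()] over `log10(nu)` and reports a profile-likelihood
#' confidence interval. With every replicate resistant the zero count carries
#' only limited information and the estimate degenerates to a one-sided bound
#' (a warning is raised); with every replicate sensitive only an upper bound
#' on `nu` is available.
#'
#' @param data An [assay_data()].
#' @param bracket Search bracket on `log10(nu)`.
#' @param conf_level Confidence level of the profile interval.
#' @return A `nu_estimate`.
#' @export
p0_estimate <- function(data, bracket = c(-8, -0.5), conf_level = 0.95) {
  stopifnot(inherits(data, "assay_data"))
  y <- sum(data$counts == 0)
  k <- length(data$counts)
  notes <- character(0)
  if (y == 0L) {
    warning(warningCondition(
      "p0 uninformative: every replicate has resistant cells, so only a lower bound on nu is available",
      class = "seqmut_p0_uninformative"))
    notes <- "all replicates resistant: one-sided lower bound"
  } else if (y == k) {
    notes <- "no replicate resistant: one-sided upper bound on nu"
  }
  fit <- profile_mle(function(v) p0_loglik(data, v), bracket, conf_level)
  new_nu_estimate(fit, "p0", conf_level, data, notes)
}

#' Estimate the mutation rate from the mutant counts
#'
#' Maximizes [count_loglik()] over `log10(nu)` with a profile-likelihood
#' confidence interval. This estimator relies on the long-time exponential
#' amplitude law, so it is accurate when the growth time is well past the
#' median arrival time of the resistant type (all replicates carry sizeable
#' mutant numbers); near the median arrival time it is biased and the p0
#' method should be preferred (see [method_advisor()]).
#'
#' @inheritParams p0_estimate
#' @param zero_handling Passed to [count_loglik()].
#' @return A `nu_estimate`.
#' @export
count_mle <- function(data, bracket = c(-8, -0.5), conf_level = 0.95,
                      zero_handling = c("mixture", "condition")) {
  stopifnot(inherits(data, "assay_data"))
  zero_handling <- match.arg(zero_handling)
  notes <- character(0)
  if (all(data$counts == 0)) {
    warning(warningCondition(
      "all replicates have zero mutants: the count likelihood is degenerate; reporting the p0 upper bound",
      class = "seqmut_counts_degenerate"))
    fit <- profile_mle(function(v) p0_loglik(data, v), bracket, conf_level)
    return(new_nu_estimate(fit, "counts",
                           conf_level, data,
                           "degenerate all-zero data: p0 upper bound"))
  }
  fit <- profile_mle(function(v) count_loglik(data, v, zero_handling),
                     bracket, conf_level)
  new_nu_estimate(fit, "counts", conf_level, data, notes)
}

#' Recommend an inference method for an assay
#'
#' If an appreciable fraction of replicates shows no resistance the zero
#' count is informative and the p0 method is preferred; if essentially all
#' replicates carry sizeable mutant numbers the long-time count law applies
#' and the mutant-count MLE is advisable.
#'
#' @param data An [assay_data()].
#' @param zero_threshold Zero-replicate fraction above which p0 is
#'   recommended.
#' @return A list with `method` (`"p0"` or `"counts"`) and `rationale`.
#' @export
method_advisor <- function(data, zero_threshold = 0.1) {
  stopifnot(inherits(data, "assay_data"))
  frac <- mean(data$counts == 0)
  if (frac == 1) {
    list(method = "p0",
         rationale = "every replicate is without resistance: only a p0 upper bound on nu is available")
  } else if (frac > zero_threshold) {
    list(method = "p0",
         rationale = sprintf(
           "%.0f%% of replicates are without resistance (> %.0f%%): the zero count is informative and the count law may not yet apply",
           100 * frac, 100 * zero_threshold))
  } else {
    list(method = "counts",
         rationale = sprintf(
           "only %.0f%% of replicates are without resistance (<= %.0f%%): the zero count carries little information; use the mutant-count MLE",
           100 * frac, 100 * zero_threshold))
  }
}

#' Estimate the mutation rate, choosing the method automatically
#'
#' @param data An [assay_data()].
#' @param method `"auto"` (use [method_advisor()]), `"p0"`, or `"counts"`.
#' @param ... Passed to [p0_estimate()] or [count_mle()].
#' @return A `nu_estimate`; with `method = "auto"` the advisor's rationale is
#'   appended to the diagnostics notes.
#' @export
estimate_mutation_rate <- function(data, method = c("auto", "p0", "counts"),
                                   ...) {
  method <- match.arg(method)
  if (method == "auto") {
    adv <- method_advisor(data)
    est <- if (adv$method == "p0") p0_estimate(data, ...) else count_mle(data, ...)
    est$diagnostics$notes <- c(est$diagnostics$notes, adv$rationale)
    est
  } else if (method == "p0") {
    p0_estimate(data, ...)
  } else {
    count_mle(data, ...)
  }
}
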