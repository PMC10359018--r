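#' @name simulators
#' @title Stochastic simulation of the multitype branching process
#'
#' @description
#' Three simulators share one interface. [simulate_exact()] is the
#' event-driven (Gillespie) simulation of the branching process itself: a
#' type-n cell waits an exponential time with rate
#' `alpha_n + beta_n + nu_n` and then divides, dies, or mutates; a mutation
#' leaves the parent in place and adds one cell of type n+1.
#' [simulate_hybrid()] runs the exact simulation while every type's count is
#' below `switch_threshold` and then switches to tau-leaping, where each
#' type's count is advanced over a step by the exact birth-death transition
#' law (binomial survivors plus a negative-binomial offspring excess, so the
#' per-step growth is unbiased) and mutant seeding is Poisson with a
#' trapezoidal intensity. [sample_limit_model()] draws from the approximate
#' (Poisson-seeding) model that underlies the limit laws.
#'
#' All simulators are bit-reproducible given `seed`.
NULL

# internal: one realization; exact phase followed (optionally) by tau-leaping
sim_engine <- function(path, t_end, grid, stop_at_type = NULL,
                       threshold = Inf, step_frac = 0.05,
                       max_events = 5e6) {
  N <- path$n_types
  alpha <- path$alpha
  beta <- path$beta
  nu <- path$nu
  nu[N] <- 0  # nu[N] is unused: there is no type N + 1
  trc <- alpha + beta + nu

  z <- numeric(N)
  z[1L] <- 1
  t <- 0
  arr <- rep(Inf, N)
  arr[1L] <- 0
  extinct1 <- FALSE
  stopped <- FALSE

  nG <- length(grid)
  gi <- 1L
  rec_t <- numeric(nG + N + 1L)
  rec_z <- matrix(0, nrow = nG + N + 1L, ncol = N)
  ri <- 0L
  push <- function(tt, zz) {
    ri <<- ri + 1L
    rec_t[ri] <<- tt
    rec_z[ri, ] <<- zz
  }

  # ---- exact (event-driven) phase ----
  events <- 0L
  repeat {
    if (any(z >= threshold)) break
    R <- sum(z * trc)
    if (R <= 0) {  # nothing can happen any more
      while (gi <= nG) { push(grid[gi], z); gi <- gi + 1L }
      t <- t_end
      break
    }
    tn <- t + stats::rexp(1L, R)
    while (gi <= nG && grid[gi] < tn) {
      push(grid[gi], z)
      gi <- gi + 1L
    }
    if (tn > t_end) { t <- t_end; break }
    events <- events + 1L
    if (events > max_events) {
      stop(sprintf(
        "event budget exceeded (%g events before t = %.3g of %.3g): population too large for exact simulation; use simulate_hybrid()",
        max_events, tn, t_end))
    }
    u <- stats::runif(1L) * R
    cs <- cumsum(c(z * alpha, z * beta, z * nu))
    j <- findInterval(u, cs) + 1L
    type <- (j - 1L) %% N + 1L
    kind <- (j - 1L) %/% N + 1L
    t <- tn
    if (kind == 1L) {
      z[type] <- z[type] + 1
    } else if (kind == 2L) {
      z[type] <- z[type] - 1
      if (type == 1L && z[1L] == 0) extinct1 <- TRUE
    } else {
      z[type + 1L] <- z[type + 1L] + 1
      if (is.infinite(arr[type + 1L])) {
        arr[type + 1L] <- t
        push(t, z)
        if (!is.null(stop_at_type) && type + 1L == stop_at_type) {
          stopped <- TRUE
        }
      }
    }
    if (stopped) break
  }

  # ---- tau-leaping phase ----
  if (!stopped && t < t_end && any(z >= threshold)) {
    dt0 <- step_frac / max(trc)
    cache <- bd_step_params(alpha, beta, dt0)
    mut_idx <- seq_len(N - 1L)
    while (t < t_end - 1e-12) {
      while (gi <= nG && grid[gi] <= t + 1e-12) {  # flush due grid points
        push(grid[gi], z)
        gi <- gi + 1L
      }
      dtg <- if (gi <= nG) grid[gi] - t else Inf
      dt <- min(dt0, dtg, t_end - t)
      par <- if (dt == dt0) cache else bd_step_params(alpha, beta, dt)
      m <- rbinom_safe(z, par$psurv)
      znew <- m + rnbinom_safe(m, par$one_minus_q)
      if (N > 1L) {
        lam_mut <- nu[mut_idx] * dt * (z[mut_idx] + znew[mut_idx]) / 2
        muts <- rpois_safe(lam_mut)
        znew[mut_idx + 1L] <- znew[mut_idx + 1L] + muts
      }
      z <- znew
      t <- t + dt
      if (z[1L] == 0 && !extinct1) extinct1 <- TRUE
      new_arr <- which(is.infinite(arr) & z > 0)
      for (k in new_arr) {
        arr[k] <- t
        push(t, z)
        if (!is.null(stop_at_type) && k == stop_at_type) stopped <- TRUE
      }
      if (stopped) break
    }
    while (!stopped && gi <= nG && grid[gi] <= t + 1e-12) {
      push(grid[gi], z)
      gi <- gi + 1L
    }
  }

  keep <- seq_len(ri)
  ord <- order(rec_t[keep])
  list(times = rec_t[keep][ord],
       counts = rec_z[keep, , drop = FALSE][ord, , drop = FALSE],
       arrivals = arr, final = z, t = t, extinct1 = extinct1,
       stopped = stopped, events = events)
}

# Exact birth-death transition over a step of length dt, per type:
# a cell alive at the start leaves a surviving lineage with probability
# psurv; each surviving lineage has size 1 + Geom(one_minus_q). Hence
# z' = Binom(z, psurv) + NegBinom(size = survivors, prob = one_minus_q),
# with E[z'] = z * exp(lambda * dt) exactly.
bd_step_params <- function(alpha, beta, dt) {
  N <- length(alpha)
  psurv <- one_minus_q <- numeric(N)
  for (i in seq_len(N)) {
    a <- alpha[i]; b <- beta[i]; lam <- a - b
    if (a == 0) {            # pure death
      psurv[i] <- exp(-b * dt)
      one_minus_q[i] <- 1
    } else if (abs(lam) < 1e-12 * a) {  # critical
      psurv[i] <- one_minus_q[i] <- 1 / (1 + a * dt)
    } else if (lam > 0) {
      em <- exp(-lam * dt)   # a - b*em = e^{-lam dt} * D, all O(1)
      psurv[i] <- lam / (a - b * em)
      one_minus_q[i] <- lam * em / (a - b * em)
    } else {
      el <- exp(lam * dt)
      D <- a * el - b
      psurv[i] <- lam * el / D
      one_minus_q[i] <- lam / D
    }
  }
  list(psurv = psurv, one_minus_q = one_minus_q)
}

# Samplers that fall back to a normal approximation far beyond the range
# where the discreteness could matter (guards integer overflow in rbinom/
# rpois/rnbinom).
rbinom_safe <- function(size, prob) {
  out <- numeric(length(size))
  big <- size > 2^30
  if (any(!big)) out[!big] <- stats::rbinom(sum(!big), size[!big], prob[!big])
  if (any(big)) {
    mu <- size[big] * prob[big]
    out[big] <- pmax(0, round(stats::rnorm(sum(big), mu,
                                           sqrt(mu * (1 - prob[big])))))
  }
  out
}

rnbinom_safe <- function(size, prob) {
  out <- numeric(length(size))
  pos <- size > 0 & prob < 1
  if (any(pos)) {
    mu <- size[pos] * (1 - prob[pos]) / prob[pos]
    big <- mu > 1e8
    i <- which(pos)
    if (any(!big)) {
      out[i[!big]] <- stats::rnbinom(sum(!big), size = size[i[!big]],
                                     prob = prob[i[!big]])
    }
    if (any(big)) {
      ib <- i[big]
      v <- size[ib] * (1 - prob[ib]) / prob[ib]^2
      out[ib] <- pmax(0, round(stats::rnorm(length(ib), mu[big], sqrt(v))))
    }
  }
  out
}

rpois_safe <- function(lambda) {
  out <- numeric(length(lambda))
  big <- lambda > 1e8
  if (any(!big)) out[!big] <- stats::rpois(sum(!big), lambda[!big])
  if (any(big)) {
    out[big] <- pmax(0, round(stats::rnorm(sum(big), lambda[big],
                                           sqrt(lambda[big]))))
  }
  out
}

new_trajectory <- function(run, path, grid, mode, seed, n_rejected) {
  structure(
    list(times = run$times, counts = run$counts, arrivals = run$arrivals,
         final = run$final, t_end = run$t, labels = path$labels,
         mode = mode, seed = seed, n_rejected = n_rejected,
         n_events_exact = run$events, path = path),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory (%s simulation) of %d type(s) to t = %.4g\n",
              x$mode, length(x$final), x$t_end))
  cat("final counts:", paste(format(x$final), collapse = ", "), "\n")
  cat("arrival times:",
      paste(format(signif(x$arrivals, 4)), collapse = ", "), "\n")
  if (x$n_rejected > 0) {
    cat(sprintf("(%d realization(s) rejected for type-1 extinction)\n",
                x$n_rejected))
  }
  invisible(x)
}

#' Long-format view of a trajectory
#'
#' @param x A trajectory from [simulate_exact()] or [simulate_hybrid()].
#' @param ... Unused.
#' @return A data frame with columns `time`, `type`, `count`.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  N <- ncol(x$counts)
  data.frame(
    time = rep(x$times, times = N),
    type = rep(seq_len(N), each = length(x$times)),
    count = as.vector(x$counts)
  )
}

run_conditioned <- function(path, t_end, grid, stop_at_type, threshold,
                            step_frac, max_events, condition,
                            max_rejections = 10000L) {
  n_rejected <- 0L
  repeat {
    run <- sim_engine(path, t_end, grid, stop_at_type, threshold, step_frac,
                      max_events)
    if (!condition || !run$extinct1) return(c(run, list(rejected = n_rejected)))
    n_rejected <- n_rejected + 1L
    if (n_rejected > max_rejections) {
      stop("rejection budget exceeded while conditioning on type-1 survival")
    }
  }
}

default_grid <- function(t_end, record_grid) {
  if (is.null(record_grid)) seq(0, t_end, length.out = 200L)
  else sort(unique(as.numeric(record_grid)))
}

#' @rdname simulators
#' @param path A [mutation_path()].
#' @param t_end Time horizon (> 0).
#' @param seed Integer seed for reproducibility (`NULL` leaves the RNG state
#'   alone).
#' @param condition_on_type1_survival If `TRUE`, realizations in which the
#'   type-1 population dies out before `t_end` (or before the stopping time)
#'   are rejected and redrawn; the number of rejections is recorded. This
#'   approximates the limit laws' conditioning on the founding population
#'   surviving forever with a residual bias of order `exp(-lambda_1 t_end)`.
#' @param record_grid Observation times; `NULL` gives 200 equally spaced
#'   times. First-arrival times are always added as extra records.
#' @param stop_at_type Stop the realization as soon as this type arrives
#'   (records are truncated at the stopping time).
#' @param max_events Event budget for the exact phase; exceeding it raises an
#'   error suggesting the hybrid simulator.
#' @return A `trajectory` object: observation `times`, a `counts` matrix (one
#'   column per type), per-type first-arrival times `arrivals` (`Inf` if the
#'   type never arose), the final state, and provenance (mode, seed,
#'   rejection count).
#' @export
simulate_exact <- function(path, t_end, seed = NULL,
                           condition_on_type1_survival = FALSE,
                           record_grid = NULL, stop_at_type = NULL,
                           max_events = 5e6) {
  stopifnot(inherits(path, "mutation_path"), t_end > 0)
  if (!is.null(seed)) set.seed(seed)
  grid <- default_grid(t_end, record_grid)
  run <- run_conditioned(path, t_end, grid, stop_at_type, Inf, 0.05,
                         max_events, condition_on_type1_survival)
  new_trajectory(run, path, grid, "exact", seed, run$rejected)
}

#' @rdname simulators
#' @param switch_threshold Population size per type above which the engine
#'   switches from event-driven simulation to tau-leaping. `Inf` reproduces
#'   [simulate_exact()] path-for-path under the same seed.
#' @param step_frac Tau-leap step is `step_frac / max(alpha + beta + nu)`, so
#'   the expected per-type relative change per step is at most about
#'   `step_frac`.
#' @export
simulate_hybrid <- function(path, t_end, seed = NULL,
                            switch_threshold = 1000,
                            condition_on_type1_survival = FALSE,
                            record_grid = NULL, stop_at_type = NULL,
                            step_frac = 0.05, max_events = 5e6) {
  stopifnot(inherits(path, "mutation_path"), t_end > 0, switch_threshold >= 1)
  if (is.infinite(switch_threshold)) {
    return(simulate_exact(path, t_end, seed, condition_on_type1_survival,
                          record_grid, stop_at_type, max_events))
  }
  if (!is.null(seed)) set.seed(seed)
  grid <- default_grid(t_end, record_grid)
  run <- run_conditioned(path, t_end, grid, stop_at_type, switch_threshold,
                         step_frac, max_events, condition_on_type1_survival)
  new_trajectory(run, path, grid, "hybrid", seed, run$rejected)
}

#' @rdname simulators
#' @param n Target type whose population size is sampled.
#' @param t Observation time.
#' @param n_samples Number of independent samples.
#' @param profile Optional precomputed [fitness_profile()].
#' @param max_expected_clones Guard on the expected number of seeded clones
#'   per sample (checked in log space).
#' @details
#' `sample_limit_model()` draws `V_1` exponential with mean
#' `alpha_1 / lambda_1` (the amplitude of the surviving founding population),
#' seeds each subsequent type by a Poisson process with intensity
#' `nu_n * V_n * s^(r_n - 1) * exp(delta_n * s)`, and grows each seeded clone
#' for its remaining time by the closed-form linear birth-death law (extinct
#' with the classical probability, geometric size otherwise). For
#' intermediate types the amplitude passed to the next seeding step is the
#' scaled population size at the horizon, `exp(-delta t) t^{-(r-1)} Z(t)`.
#' @export
sample_limit_model <- function(path, n, t, n_samples, seed = NULL,
                               profile = NULL, max_expected_clones = 1e7) {
  stopifnot(inherits(path, "mutation_path"), t > 0, n_samples >= 1)
  if (n < 1L || n > path$n_types) stop("'n' out of range")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(profile)) {
    profile <- suppressWarnings(fitness_profile(path))
  }
  lam1 <- profile$lam[1L]
  v <- stats::rexp(n_samples, rate = lam1 / path$alpha[1L])
  if (n == 1L) return(v * exp(lam1 * t))

  for (i in seq_len(n - 1L)) {
    d <- profile$delta[i]
    r <- profile$r[i]
    nu <- path$nu[i]
    # log of I = Int_0^t s^(r-1) exp(d s) ds, overflow-safe
    log_I <- if (r == 1L) {
      d * t + log(-expm1(-d * t)) - log(d)
    } else {
      val <- stats::integrate(function(s) s^(r - 1) * exp(d * (s - t)),
                              0, t, rel.tol = 1e-10)$value
      d * t + log(val)
    }
    log_lambda_pois <- log(nu) + log(v) + log_I
    if (any(log_lambda_pois > log(max_expected_clones))) {
      stop("expected clone count overflows the budget; reduce t or the rates")
    }
    a2 <- path$alpha[i + 1L]
    b2 <- path$beta[i + 1L]
    z_next <- vapply(exp(log_lambda_pois), function(lp) {
      k <- rpois_safe(lp)
      if (k == 0) return(0)
      s <- sample_seed_times(k, r, d, t)
      sum(rbd_clone(t - s, a2, b2))
    }, numeric(1))
    if (i + 1L < n) {
      v <- z_next * exp(-profile$delta[i + 1L] * t) * t^(-(profile$r[i + 1L] - 1L))
    }
  }
  z_next
}

# k draws from the density proportional to s^(r-1) exp(d s) on [0, t]:
# inverse-CDF for the exponential envelope, thinning for the polynomial part
sample_seed_times <- function(k, r, d, t) {
  out <- numeric(0)
  while (length(out) < k) {
    m <- k - length(out)
    u <- stats::runif(m)
    s <- t + log(u + (1 - u) * exp(-d * t)) / d
    if (r > 1L) s <- s[stats::runif(m) < (s / t)^(r - 1)]
    out <- c(out, s)
  }
  out[seq_len(k)]
}

# Size of a clone grown from one cell for time u under a linear birth-death
# process: 0 with the classical extinction probability, else 1 + geometric.
# Vectorized over u; the geometric is drawn via logs so that near-one
# success probabilities (huge clones) cannot overflow integer ranges.
rbd_clone <- function(u, alpha, beta) {
  k <- length(u)
  if (k == 0L) return(numeric(0))
  if (alpha == 0) return(as.numeric(stats::runif(k) < exp(-beta * u)))
  lam <- alpha - beta
  if (abs(lam) < 1e-12 * alpha) {
    au <- alpha * u
    p0 <- au / (1 + au)
    omq <- 1 / (1 + au)
  } else if (lam > 0) {
    em <- exp(-lam * u)
    denom <- alpha - beta * em
    p0 <- beta * (1 - em) / denom
    omq <- lam * em / denom
  } else {
    el <- exp(lam * u)
    denom <- alpha * el - beta
    p0 <- beta * (el - 1) / denom  # el < 1, denom < 0: ratio positive
    omq <- lam / denom
  }
  y <- numeric(k)
  alive <- stats::runif(k) >= p0
  if (any(alive)) {
    lq <- log1p(-omq[alive])
    lu <- log(stats::runif(sum(alive)))
    y[alive] <- ifelse(lq == 0, 1, 1 + floor(lu / lq))
  }
  y
}

#' Simulate an n-mutation fluctuation assay
#'
#' Runs `n_replicates` independent growth experiments from a single type-1
#' cell to time `t_growth` and records the number of resistant cells (cells of
#' `n_target`, i.e. carrying `n_target - 1` mutations) in each replicate --
#' the observable of a fluctuation assay after selection kills the
#' non-resistant types.
#'
#' @param path A [mutation_path()] (must reach `n_target`).
#' @param t_growth Growth time before selection.
#' @param n_target Resistant type index.
#' @param n_replicates Number of replicate cultures.
#' @param seed Integer seed.
#' @param mode `"hybrid"` (default), `"exact"`, or `"limit"`.
#' @param switch_threshold,step_frac Passed to [simulate_hybrid()].
#' @param condition_on_type1_survival Passed to the simulators.
#' @return An [assay_data()] object whose `counts` are the per-replicate
#'   mutant numbers.
#' @export
simulate_assay <- function(path, t_growth, n_target, n_replicates,
                           seed = NULL, mode = c("hybrid", "exact", "limit"),
                           switch_threshold = 500, step_frac = 0.05,
                           condition_on_type1_survival = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(path, "mutation_path"), t_growth > 0, n_replicates >= 1)
  if (n_target < 2L || n_target > path$n_types) {
    stop("'n_target' must be a reachable type index (2..N)")
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- if (mode == "limit") {
    sample_limit_model(path, n_target, t_growth, n_replicates)
  } else {
    vapply(seq_len(n_replicates), function(i) {
      run <- if (mode == "exact") {
        simulate_exact(path, t_growth,
                       condition_on_type1_survival = condition_on_type1_survival,
                       record_grid = t_growth)
      } else {
        simulate_hybrid(path, t_growth,
                        switch_threshold = switch_threshold,
                        step_frac = step_frac,
                        condition_on_type1_survival = condition_on_type1_survival,
                        record_grid = t_growth)
      }
      run$final[n_target]
    }, numeric(1))
  }
  assay_data(counts = counts, t = t_growth, n_target = n_target,
             alpha1 = path$alpha[1L],
             lambda1 = path$alpha[1L] - path$beta[1L],
             seed = seed, mode = mode)
}
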