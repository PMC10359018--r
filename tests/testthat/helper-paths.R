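# Shared fixtures: the printed parameter sets used across the suite.

# Three-type path with net growth rates 0.3, 0.1, 0.6 (running max 0.3, 0.3, 0.6)
three_type_path <- function() {
  mutation_path(alpha = c(1.1, 1, 1.1), beta = c(0.8, 0.9, 0.5),
                nu = c(0.01, 0.01, 0))
}

# Two-type amplitude benchmark family: alpha_1 = 1.2, beta_1 = 0.2,
# nu_1 = 0.01, beta_2 = 0.3; alpha_2 and the horizon vary to set the tail
# parameter lambda_1 / delta_2.
amplitude_sim_path <- function(alpha2) {
  mutation_path(alpha = c(1.2, alpha2), beta = c(0.2, 0.3), nu = c(0.01, 0))
}
amplitude_sim_settings <- list(
  list(alpha2 = 4.3, t = 5, tail = 0.25),
  list(alpha2 = 2.3, t = 7, tail = 0.5),
  list(alpha2 = 1.0, t = 12, tail = 1.0)
)

# Three-type arrival benchmark (growth rate up then down):
# lambda = (0.7, 1.1, -0.5), all mutation rates 0.01
arrival_sim_path <- function() {
  mutation_path(alpha = c(1, 1.4, 1), beta = c(0.3, 0.3, 1.5),
                nu = c(0.01, 0.01, 0))
}

# Neutral fluctuation-assay path: k + 1 types, no death, unit division rate
neutral_assay_path <- function(nu, k_mutations = 2) {
  n <- k_mutations + 1L
  mutation_path(alpha = rep(1, n), beta = rep(0, n),
                nu = c(rep(nu, n - 1L), 0))
}

# Random valid path whose asymptotic laws exist (regime errors rejected).
# Ties are injected with probability ~1/3 per step so the "equal" branch is
# exercised.
random_valid_path <- function(max_types = 5L) {
  repeat {
    n <- sample(2:max_types, 1L)
    alpha <- stats::runif(n, 0.5, 3)
    lam <- stats::runif(n, -0.5, 2)
    lam[1L] <- stats::runif(1L, 0.2, 1.5)
    for (i in seq_len(n - 1L)) {
      if (stats::runif(1L) < 1 / 3) lam[i + 1L] <- max(lam[seq_len(i)])
    }
    beta <- alpha - lam
    if (any(beta < 0)) next
    nu <- c(10^stats::runif(n - 1L, -6, -2.5), 0)
    path <- mutation_path(alpha, beta, nu)
    prof <- tryCatch(suppressWarnings(fitness_profile(path)),
                     error = function(e) NULL)
    if (is.null(prof)) next
    med <- tryCatch(median_recursion(prof, path), error = function(e) NULL)
    if (is.null(med)) next
    return(list(path = path, profile = prof))
  }
}

# Per-replicate final counts (and optionally arrivals) from the hybrid
# simulator, conditioned on type-1 survival -- the protocol under which the
# limit laws are stated.
replicate_final_counts <- function(path, t, n_reps, switch_threshold = 300) {
  vapply(seq_len(n_reps), function(i) {
    simulate_hybrid(path, t, switch_threshold = switch_threshold,
                    record_grid = t,
                    condition_on_type1_survival = TRUE)$final
  }, numeric(path$n_types))
}

replicate_arrival <- function(path, type, t_max, n_reps,
                              switch_threshold = 500) {
  vapply(seq_len(n_reps), function(i) {
    simulate_hybrid(path, t_max, switch_threshold = switch_threshold,
                    record_grid = t_max, stop_at_type = type,
                    condition_on_type1_survival = TRUE)$arrivals[type]
  }, numeric(1))
}
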