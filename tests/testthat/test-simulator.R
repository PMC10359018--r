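
test_that("exact simulation reproduces the pure-birth mean and growth curve", {
  p <- mutation_path(1, 0)
  set.seed(11)
  t <- 3
  n <- 400
  z <- vapply(seq_len(n), function(i) {
    simulate_exact(p, t, record_grid = t)$final
  }, numeric(1))
  se <- sqrt((exp(2 * t) - exp(t)) / n)   # Yule variance
  expect_lt(abs(mean(z) - exp(t)), 3 * se)
  expect_true(all(z >= 1))                # pure birth never dies
})

test_that("extinction probability matches the classical beta/alpha limit", {
  p <- mutation_path(1, 0.4)
  set.seed(12)
  n <- 800
  extinct <- vapply(seq_len(n), function(i) {
    simulate_exact(p, 15, record_grid = 15)$final == 0
  }, logical(1))
  se <- sqrt(0.4 * 0.6 / n)
  expect_lt(abs(mean(extinct) - 0.4), 3.5 * se)
})

test_that("mutation retains the parent cell", {
  # if mutation removed the parent, E[Z_1(t)] would be exp((lambda - nu) t);
  # with the parent retained it is exp(lambda t) for any nu
  p <- mutation_path(c(1, 1), c(0, 0.5), c(2, 0))
  set.seed(13)
  t <- 2
  n <- 600
  z1 <- vapply(seq_len(n), function(i) {
    simulate_exact(p, t, record_grid = t)$final[1]
  }, numeric(1))
  se <- stats::sd(z1) / sqrt(n)
  expect_lt(abs(mean(z1) - exp(t)), 3.5 * se)
  expect_gt(mean(z1), exp((1 - 2) * t) * 3)  # rules out the parent-loss model
})

test_that("hybrid with infinite threshold reproduces exact path-for-path", {
  p <- three_type_path()
  a <- simulate_exact(p, 8, seed = 99, condition_on_type1_survival = TRUE)
  b <- simulate_hybrid(p, 8, seed = 99, switch_threshold = Inf,
                       condition_on_type1_survival = TRUE)
  expect_identical(a$counts, b$counts)
  expect_identical(a$arrivals, b$arrivals)
  expect_identical(a$times, b$times)
})

test_that("a fixed seed makes both simulators bit-reproducible", {
  p <- three_type_path()
  a <- simulate_hybrid(p, 8, seed = 7, switch_threshold = 50)
  b <- simulate_hybrid(p, 8, seed = 7, switch_threshold = 50)
  expect_identical(a$counts, b$counts)
  expect_identical(a$final, b$final)
})

test_that("hybrid and exact final counts are statistically indistinguishable", {
  p <- amplitude_sim_path(1.0)
  t <- 6
  set.seed(21)
  n <- 400
  z_ex <- vapply(seq_len(n), function(i) {
    simulate_exact(p, t, record_grid = t,
                   condition_on_type1_survival = TRUE)$final[1]
  }, numeric(1))
  z_hy <- vapply(seq_len(n), function(i) {
    simulate_hybrid(p, t, record_grid = t, switch_threshold = 50,
                    condition_on_type1_survival = TRUE)$final[1]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(z_ex, z_hy))
  expect_gt(ks$p.value, 0.01)
  # and the tau-leap phase does not bias the mean growth
  se <- sqrt(stats::var(z_ex) / n + stats::var(z_hy) / n)
  expect_lt(abs(mean(z_hy) - mean(z_ex)), 3.5 * se)
})

test_that("neutral second-type mean follows nu * t * exp(lambda t)", {
  p <- mutation_path(c(1, 1), c(0, 0), c(0.01, 0))
  t <- 5
  set.seed(22)
  n <- 500
  z2 <- vapply(seq_len(n), function(i) {
    simulate_hybrid(p, t, record_grid = t, switch_threshold = 100)$final[2]
  }, numeric(1))
  expected <- 0.01 * t * exp(t)
  se <- stats::sd(z2) / sqrt(n)
  expect_lt(abs(mean(z2) - expected), 3.5 * se)
})

test_that("trajectories are internally consistent", {
  p <- three_type_path()
  run <- simulate_hybrid(p, 10, seed = 31, switch_threshold = 100,
                         condition_on_type1_survival = TRUE)
  # arrivals are ordered along the path and counts are zero before arrival
  arr <- run$arrivals
  expect_equal(arr[1], 0)
  finite <- which(is.finite(arr))
  expect_true(all(diff(arr[finite]) >= 0))
  for (k in seq_len(p$n_types)) {
    before <- run$times < arr[k] - 1e-12
    expect_true(all(run$counts[before, k] == 0))
  }
  # long-format conversion carries the same information
  df <- as.data.frame(run)
  expect_equal(sort(unique(df$time)), sort(unique(run$times)))
  expect_equal(nrow(df), length(run$times) * p$n_types)
  # a type that never arrived is reported as Inf
  run2 <- simulate_exact(mutation_path(c(1, 5), c(0.3, 0.2), c(1e-9, 0)),
                         1, seed = 32)
  expect_equal(run2$arrivals[2], Inf)
  expect_equal(run2$final[2], 0)
})

test_that("stop_at_type truncates the run at the arrival", {
  p <- arrival_sim_path()
  run <- simulate_hybrid(p, 30, seed = 41, switch_threshold = 200,
                         stop_at_type = 3,
                         condition_on_type1_survival = TRUE)
  expect_true(is.finite(run$arrivals[3]))
  expect_lte(run$t_end, 30)
  expect_equal(run$t_end, run$arrivals[3])
  expect_true(all(run$times <= run$arrivals[3] + 1e-12))
})

test_that("the exact event budget fails loudly and points to the hybrid", {
  p <- mutation_path(1, 0)
  expect_error(simulate_exact(p, 25, seed = 51, max_events = 1000),
               "hybrid")
})

test_that("limit-model founder samples are exponential on the growth scale", {
  p <- mutation_path(1.2, 0.2)
  t <- 9
  set.seed(61)
  v <- sample_limit_model(p, 1, t, 2000) * exp(-1 * t)
  ks <- stats::ks.test(v, stats::pexp, rate = 1 / 1.2)
  expect_gt(ks$p.value, 0.01)
})

test_that("limit-model mutant amplitudes follow the Mittag-Leffler law", {
  # scaled mutant size e^{-delta t} t^{1-r} Z_2(t) / omega_2, conditioned on
  # at least one surviving mutant cell, against the limit law conditioned
  # above the one-cell threshold
  s <- amplitude_sim_settings[[2]]      # tail 0.5
  p <- amplitude_sim_path(s$alpha2)
  prof <- fitness_profile(p)
  set.seed(62)
  z <- sample_limit_model(p, 2, s$t, 3000, profile = prof)
  w <- z * exp(-prof$delta[2] * s$t) / prof$omega[2]
  cmin <- exp(-prof$delta[2] * s$t) / prof$omega[2]   # one-cell threshold
  w <- w[w > 0]
  f0 <- pml(cmin / 2, s$tail)
  emp <- stats::ecdf(w)
  grid <- stats::quantile(w, seq(0.02, 0.98, by = 0.02))
  theo <- (pml(grid, s$tail) - f0) / (1 - f0)
  expect_lt(max(abs(emp(grid) - theo)), 0.05)
})

test_that("fluctuation assays return the mutant counts of the target type", {
  p <- neutral_assay_path(1e-2)
  a <- simulate_assay(p, t_growth = 6, n_target = 3, n_replicates = 30,
                      seed = 71, switch_threshold = 200)
  expect_s3_class(a, "assay_data")
  expect_length(a$counts, 30)
  expect_equal(a$n_target, 3L)
  expect_equal(a$t, 6)
  expect_true(all(a$counts >= 0))

  # with a negligible mutation rate every replicate is mutant-free
  p0 <- neutral_assay_path(1e-12)
  a0 <- simulate_assay(p0, t_growth = 4, n_target = 3, n_replicates = 10,
                       seed = 72)
  expect_true(all(a0$counts == 0))

  # limit mode produces counts on the same scale as the hybrid mode
  set.seed(73)
  al <- simulate_assay(p, 6, 3, 200, mode = "limit")
  ah <- simulate_assay(p, 6, 3, 200, seed = 74, switch_threshold = 200,
                       condition_on_type1_survival = TRUE)
  expect_lt(abs(log(mean(al$counts) + 1) - log(mean(ah$counts) + 1)), 0.5)
})
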