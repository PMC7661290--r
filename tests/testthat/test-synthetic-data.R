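test_that("cohort timestamps satisfy the stage ordering and commit definition", {
  env <- test_env(n_days = 30)
  tr <- simulation_truth(beta_find = c(temperature = 0.3, diel = 1.5,
                                       count = 0.4),
                         commit_coeffs = c(intercept = qlogis(0.43),
                                           temperature = -0.3),
                         arrival_total = 300, p_missing = 0.05, seed = 7)
  coh <- simulate_cohort(tr, env)
  ok <- !is.na(coh$t_tailrace_entry) & !is.na(coh$t_first_fishway_entry)
  expect_true(all(coh$t_tailrace_entry[ok] <= coh$t_first_fishway_entry[ok]))
  ok2 <- !is.na(coh$t_first_fishway_entry) & !is.na(coh$t_last_fishway_entry)
  expect_true(all(coh$t_first_fishway_entry[ok2] <=
                    coh$t_last_fishway_entry[ok2]))
  ok3 <- !is.na(coh$t_last_fishway_entry) & !is.na(coh$t_fishway_exit)
  expect_true(all(coh$t_last_fishway_entry[ok3] <= coh$t_fishway_exit[ok3]))
  # committed on first attempt iff first entry equals last entry
  expect_equal(coh$committed_first_attempt[ok2],
               coh$t_first_fishway_entry[ok2] ==
                 coh$t_last_fishway_entry[ok2])
  # stage durations add up to total passage duration
  full <- ok & ok2 & ok3
  tot <- coh$t_fishway_exit[full] - coh$t_tailrace_entry[full]
  stages <- (coh$t_first_fishway_entry - coh$t_tailrace_entry) +
    (coh$t_last_fishway_entry - coh$t_first_fishway_entry) +
    (coh$t_fishway_exit - coh$t_last_fishway_entry)
  expect_equal(stages[full], tot)
  # determinism
  expect_identical(as.data.frame(simulate_cohort(tr, env)),
                   as.data.frame(simulate_cohort(tr, env)))
})

test_that("finding times are exponential when beta = 0 with a constant baseline", {
  env <- simulate_environment(n_days = 400, temp_noise_sd = 0, seed = 1)
  # long flat season so nearly no fish is censored at the boundary
  tr <- simulation_truth(beta_find = c(temperature = 0), find_rate = 0.2,
                         arrival_total = 2000, arrival_sd = 30,
                         arrival_peak = 100, seed = 11)
  coh <- simulate_cohort(tr, env)
  tt <- coh$t_first_fishway_entry - coh$t_tailrace_entry
  tt <- tt[!is.na(tt)]
  expect_gt(length(tt), 1900)
  se <- (1 / 0.2) / sqrt(length(tt))
  expect_lt(abs(mean(tt) - 1 / 0.2), 3 * se)
})

test_that("doubling the hazard halves finding times (PH scaling)", {
  env <- simulate_environment(n_days = 60, seed = 2)
  base <- simulation_truth(beta_find = c(temperature = 0), find_rate = 0.1,
                           arrival_total = 1200, seed = 3)
  fast <- simulation_truth(beta_find = c(temperature = 0), find_rate = 0.2,
                           arrival_total = 1200, seed = 3)
  t1 <- with(simulate_cohort(base, env),
             t_first_fishway_entry - t_tailrace_entry)
  t2 <- with(simulate_cohort(fast, env),
             t_first_fishway_entry - t_tailrace_entry)
  r <- median(t2, na.rm = TRUE) / median(t1, na.rm = TRUE)
  expect_lt(abs(r - 0.5), 0.07)
})

test_that("default commit intercept yields the 43% baseline commit rate", {
  expect_equal(plogis(simulation_truth()$commit_coeffs[["intercept"]]), 0.43)
  env <- simulate_environment(n_days = 60, seed = 4)
  tr <- simulation_truth(arrival_total = 1500, seed = 5)  # intercept-only
  coh <- simulate_cohort(tr, env)
  p_hat <- mean(coh$committed_first_attempt, na.rm = TRUE)
  n <- sum(!is.na(coh$committed_first_attempt))
  expect_lt(abs(p_hat - 0.43), 3 * sqrt(0.43 * 0.57 / n))
})

test_that("derived counts conserve fish, shift with lag, and validate input", {
  env <- test_env(n_days = 10)
  expect_equal(sum(derive_daily_counts(empty <- simulate_cohort(
    simulation_truth(arrival_total = 0), env), n_days = 10)$count), 0)

  tr <- test_truth()
  coh <- simulate_cohort(tr, test_env(n_days = 30))
  c0 <- derive_daily_counts(coh, lag = 0, noise = 0, n_days = 30)
  expect_equal(sum(c0$count), sum(!is.na(coh$t_fishway_exit)))
  expect_error(derive_daily_counts(coh, lag = -1), ">= 0")
})

test_that("a 24 h lag shifts the count series by exactly one day", {
  coh <- simulate_cohort(test_truth(), test_env(n_days = 30))
  c0 <- derive_daily_counts(coh, lag = 0, noise = 0, n_days = 40)
  c24 <- derive_daily_counts(coh, lag = 24, noise = 0, n_days = 40)
  m <- max(c0$day)
  expect_equal(c24$count[match(1:m, c24$day)], c0$count[match(0:(m - 1),
                                                              c0$day)])
  # conservation with one-day-on-one-day exits
  one <- coh[rep(which(!is.na(coh$t_fishway_exit))[1], 5), ]
  one$t_fishway_exit <- 26  # all on day 1
  cs <- derive_daily_counts(one, n_days = 3)
  expect_equal(cs$count, c(0L, 5L, 0L))
})

test_that("mean finding time falls as run intensity rises under a latent density effect", {
  env <- simulate_environment(n_days = 30, seed = 6)
  means <- sapply(c(60, 180, 540), function(total) {
    reps <- sapply(1:10, function(r) {
      tr <- simulation_truth(
        beta_find = c(temperature = 0.2, density = 0.5),
        arrival_total = total, density_mode = "latent",
        seed = 1000 + total + r)
      coh <- simulate_cohort(tr, env)
      mean(coh$t_first_fishway_entry - coh$t_tailrace_entry, na.rm = TRUE)
    })
    mean(reps)
  })
  expect_true(all(diff(means) < 0))
})
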