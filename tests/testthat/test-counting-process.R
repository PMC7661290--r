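test_that("exposure is split at covariate boundaries and conserved", {
  env <- test_env(n_days = 10)
  fish <- data.frame(fish_id = "f1", species = "chinook", run = "none",
                     dam = "TD", fishway = "east",
                     t_tailrace_entry = 20, t_first_fishway_entry = 50,
                     t_last_fishway_entry = 50, t_fishway_exit = 52,
                     committed_first_attempt = TRUE)
  rs <- build_counting_process(fish, env, "finding",
                               c("temperature", "diel", "count"))
  # 30 h spanning midnight: at least 2 intervals, exposure exactly 30 h
  expect_gte(nrow(rs), 2)
  expect_equal(sum(rs$stop - rs$start), 30)
  expect_equal(rs$start[1], 0)
  expect_equal(sum(rs$event), 1)
  expect_equal(rs$event[nrow(rs)], 1L)
  # diel-only covariate set still splits at the day-window transitions
  rs2 <- build_counting_process(fish, env, "finding", "diel")
  expect_equal(sum(rs2$stop - rs2$start), 30)
  expect_true(all(rs2$diel %in% c(0, 1)))
  # fishway stage uses last entry -> exit
  rs3 <- build_counting_process(fish, env, "fishway", "temperature")
  expect_equal(sum(rs3$stop - rs3$start), 2)
})

test_that("count threshold indicator switches exactly at the cut", {
  env <- simulate_environment(n_days = 2, seed = 1)
  env <- attach_counts(env, data.frame(day = 0:1, dam = "TD",
                                       species = "chinook",
                                       count = c(150L, 151L)))
  fish <- data.frame(fish_id = "f1", species = "chinook", run = "none",
                     dam = "TD", fishway = "east",
                     t_tailrace_entry = 1, t_first_fishway_entry = 40,
                     t_last_fishway_entry = 40, t_fishway_exit = 41,
                     committed_first_attempt = TRUE)
  rs <- build_counting_process(fish, env, "finding", c("count"),
                               count_threshold = 150)
  expect_equal(unique(rs$count_low[rs$count == 150]), 1)
  expect_equal(unique(rs$count_low[rs$count == 151]), 0)
})

test_that("missing timestamps are excluded with a count, and bad exposure errors name the fish", {
  env <- test_env(n_days = 10)
  fish <- data.frame(fish_id = c("a", "b"), species = "chinook",
                     run = "none", dam = "TD", fishway = "east",
                     t_tailrace_entry = c(5, NA),
                     t_first_fishway_entry = c(10, 20),
                     t_last_fishway_entry = c(10, 20),
                     t_fishway_exit = c(12, 22),
                     committed_first_attempt = TRUE)
  rs <- build_counting_process(fish, env, "finding", "temperature")
  expect_equal(length(unique(rs$id)), 1)
  expect_equal(unname(attr(rs, "excluded")["missing_timestamp"]), 1)
  fish$t_tailrace_entry[2] <- 5
  fish$t_first_fishway_entry[2] <- 24 * 10 + 5  # beyond coverage
  expect_error(build_counting_process(fish, env, "finding", "temperature"),
               "b")
  # zero fish: empty risk set, no error
  rs0 <- build_counting_process(fish[0, ], env, "finding", "temperature")
  expect_equal(nrow(rs0), 0)
})

test_that("standardization is exposure-weighted, idempotent and leaves binaries alone", {
  rs <- data.frame(id = c("a", "a", "b"), start = c(0, 1, 0),
                   stop = c(1, 2, 2), event = c(0, 1, 1),
                   x = c(0, 10, 10), diel = c(0, 1, 1))
  # exposure weights 1,1,2 -> values 0 (w 1) and 10 (w 3): not the 2x2 case
  rs22 <- rs; rs22$stop <- c(1, 2, 1); rs22$x <- c(0, 0, 10)
  # equal-weight {0, 10}: w for x=0 is 2, x=10 is... build explicit equal case
  eq <- data.frame(id = c("a", "b"), start = 0, stop = 1, event = 1,
                   x = c(0, 10))
  out <- standardize_covariates(eq, "x")
  expect_equal(out$x, c(-1, 1))
  sc <- attr(out, "scaling")
  expect_equal(sc$mean[sc$covariate == "x"], 5)
  expect_equal(sc$sd[sc$covariate == "x"], 5)
  # idempotence
  twice <- standardize_covariates(out, "x")
  expect_equal(twice$x, out$x, tolerance = 1e-12)
  # binary untouched
  out2 <- standardize_covariates(rs, c("x", "diel"))
  expect_equal(out2$diel, rs$diel)
  expect_true(attr(out2, "scaling")$binary[2])
  # zero-variance continuous covariate errors
  zv <- eq; zv$x <- c(3, 3)
  expect_error(standardize_covariates(zv, "x"), "zero exposure-weighted")
})

test_that("exposure totals are invariant under boundary splitting", {
  env <- test_env(n_days = 25)
  coh <- simulate_cohort(test_truth(), env)
  keep <- !is.na(coh$t_first_fishway_entry)
  durations <- coh$t_first_fishway_entry[keep] - coh$t_tailrace_entry[keep]
  for (covs in list("temperature", c("temperature", "diel", "count"))) {
    rs <- build_counting_process(coh, env, "finding", covs)
    expect_equal(sum(rs$stop - rs$start), sum(durations))
  }
})
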