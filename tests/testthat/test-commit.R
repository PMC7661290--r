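test_that("commit table encodes the first-attempt definition and exclusions", {
  env <- test_env(n_days = 10)
  fish <- data.frame(fish_id = c("a", "b", "c"), species = "chinook",
                     run = "none", dam = "TD", fishway = "east",
                     t_tailrace_entry = c(1, 1, 1),
                     t_first_fishway_entry = c(10, 10, NA),
                     t_last_fishway_entry = c(10, 30, NA),
                     t_fishway_exit = c(12, 33, NA),
                     committed_first_attempt = c(TRUE, FALSE, NA))
  tab <- build_commit_table(fish, env)
  expect_equal(tab$committed, c(1L, 0L))
  expect_equal(unname(attr(tab, "excluded")["missing_timestamp"]), 1)
  expect_equal(nrow(build_commit_table(fish[0, ], env)), 0)
  # covariates evaluated on the day/hour of first entry
  expect_equal(tab$temperature, rep(env$daily$temperature[1], 2))
})

test_that("grouped 2x2 data reproduce the closed-form logistic solution", {
  tab <- data.frame(id = as.character(1:200),
                    committed = c(rep(1, 30), rep(0, 70),
                                  rep(1, 60), rep(0, 40)),
                    x = rep(c(0, 1), each = 100))
  fit <- fit_commit(tab, "x", standardize = FALSE)
  expect_equal(unname(fit$beta["(Intercept)"]), log(30 / 70),
               tolerance = 1e-8)
  expect_equal(unname(fit$beta["x"]), log((60 / 40) / (30 / 70)),
               tolerance = 1e-8)
})

test_that("intercept-only fit is the sample commit fraction and probabilities average right", {
  set.seed(5)
  tab <- data.frame(id = as.character(1:150),
                    committed = rbinom(150, 1, 0.4),
                    x = rnorm(150))
  f0 <- fit_commit(tab, character(0))
  expect_equal(plogis(unname(f0$beta[1])), mean(tab$committed))
  f1 <- fit_commit(tab, "x")
  expect_equal(mean(fishpass:::commit_probs(f1, tab)), mean(tab$committed))
})

test_that("slope is null-distributed when the covariate is permuted", {
  set.seed(6)
  inside <- replicate(40, {
    y <- rbinom(250, 1, 0.45)
    tab <- data.frame(id = as.character(1:250), committed = y,
                      x = rnorm(250))
    f <- fit_commit(tab, "x")
    abs(f$beta["x"]) < 3 * sqrt(diag(f$vcov))["x"]
  })
  expect_gte(sum(inside), 34)  # ~99.7% nominal; allow binomial slack
})

test_that("degenerate commit designs error", {
  tab <- data.frame(id = as.character(1:10), committed = rep(1L, 10),
                    x = rnorm(10))
  expect_error(fit_commit(tab, "x"), class = "fp_fit_error")
  sep <- data.frame(id = as.character(1:20),
                    committed = rep(c(0L, 1L), each = 10),
                    x = c(rnorm(10, -3), rnorm(10, 3)))
  expect_error(suppressWarnings(fit_commit(sep, "x", standardize = FALSE)),
               class = "fp_fit_error")
})

test_that("known commit model is recovered on synthetic cohorts", {
  # true slope 0.7 per SD; mean estimate near truth across replicates
  set.seed(7)
  est <- replicate(15, {
    x <- rnorm(900)
    y <- rbinom(900, 1, plogis(-0.3 + 0.7 * x))
    tab <- data.frame(id = as.character(1:900), committed = y, x = x)
    unname(fit_commit(tab, "x")$beta["x"])
  })
  expect_lt(abs(mean(est) - 0.7), 0.1)
})

test_that("scenario prediction is identity at factor 1 and monotone in density", {
  env <- test_env(n_days = 25)
  tr <- simulation_truth(beta_find = c(temperature = 0.3, diel = 1.2,
                                       count = 0.3),
                         commit_coeffs = c(intercept = qlogis(0.43),
                                           count = 0.6),
                         arrival_total = 800, seed = 8)
  coh <- simulate_cohort(tr, env)
  tab <- build_commit_table(coh, env, c("temperature", "count"))
  fit <- fit_commit(tab, c("temperature", "count"))
  expect_equal(predict_commit_rate(fit, tab, 1),
               mean(fishpass:::commit_probs(fit, tab)))
  rates <- vapply(c(0, 0.5, 1, 1.5, 2), function(f)
    predict_commit_rate(fit, tab, f), numeric(1))
  if (fit$beta[["count"]] > 0) expect_true(all(diff(rates) > 0))
  expect_error(predict_commit_rate(fit, tab, -0.5), ">= 0")
  # generator oracle: predictions at factor 2 track the generating model
  sc <- attr(coh, "generator_scaling")$count
  z2 <- (2 * tab$count - sc[["mean"]]) / sc[["sd"]]
  truth_rate <- mean(plogis(qlogis(0.43) + 0.6 * z2))
  expect_lt(abs(predict_commit_rate(fit, tab, 2) - truth_rate), 0.1)
})
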