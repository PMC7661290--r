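test_that("Breslow baseline reduces to Nelson-Aalen without covariates", {
  # events at t = 1, 2 with risk sets of sizes 3, 2
  rs <- data.frame(id = c("a", "b", "c"), start = 0, stop = c(1, 2, 2),
                   event = c(1, 1, 0))
  fit <- fit_ph(rs, character(0))
  base <- breslow_baseline(fit, rs)
  expect_equal(base$times, c(1, 2))
  expect_equal(base$increments, c(1 / 3, 1 / 2))
  expect_equal(cumhaz(base, 2), 5 / 6, tolerance = 1e-12)
  expect_equal(unname(cumhaz(base, 0)), 0)
  expect_true(all(diff(cumhaz(base, seq(0, 3, 0.1))) >= 0))
})

test_that("doubling every subject's exp(X beta) halves every increment", {
  rs <- flat_riskset(time = c(1, 2, 3), x = c(0.5, -0.2, 1))
  fit <- make_fit(c(x = 0.4))
  b1 <- breslow_baseline(fit, rs)
  rs2 <- rs
  rs2$x <- rs$x + log(2) / 0.4   # exp(x beta) doubles for every subject
  b2 <- breslow_baseline(fit, rs2)
  expect_equal(b2$increments, b1$increments / 2, tolerance = 1e-12)
})

test_that("no events give an identically-zero cumulative hazard", {
  rs <- flat_riskset(time = c(1, 2), x = c(0, 1), event = 0L)
  base <- breslow_baseline(make_fit(c(x = 0.3)), rs)
  expect_equal(length(base$times), 0)
  expect_equal(cumhaz(base, c(0, 5, 100)), c(0, 0, 0))
})

test_that("simulated times under a constant unit hazard are exponential(1)", {
  tpl <- flat_riskset(time = rep(1e6, 5000), x = 0,
                      id = sprintf("s%04d", 1:5000))
  fit <- make_fit(c(x = 0))
  sim <- simulate_event_times(fit, piecewise_baseline(0, 1), tpl, seed = 5)
  expect_true(all(sim$resolved))
  ks <- suppressWarnings(stats::ks.test(sim$time, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("relative risk 2 halves the median simulated time", {
  tpl <- flat_riskset(time = rep(1e6, 4000), x = rep(c(0, 1), each = 2000),
                      id = sprintf("s%04d", 1:4000))
  fit <- make_fit(c(x = log(2)))
  sim <- simulate_event_times(fit, piecewise_baseline(0, 0.3), tpl,
                              seed = 6)
  med <- tapply(sim$time, tpl$x[match(sim$id, tpl$id)], median)
  expect_lt(abs(med[["1"]] / med[["0"]] - 0.5), 0.06)
})

test_that("a two-piece covariate path reproduces the piecewise-exponential law", {
  # rate r1 = 2 on (0, 1], then r2 = 0.5: via a covariate step, constant
  # baseline 1
  n <- 4000
  tpl <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(id = sprintf("s%04d", i), start = c(0, 1),
               stop = c(1, 1e6), event = c(0L, 1L),
               x = c(log(2), log(0.5)))
  }))
  fit <- make_fit(c(x = 1))
  sim <- simulate_event_times(fit, piecewise_baseline(0, 1), tpl, seed = 7)
  S <- function(t) exp(-(2 * pmin(t, 1) + 0.5 * pmax(0, t - 1)))
  for (t0 in c(0.5, 1, 2, 4)) {
    p_hat <- mean(sim$time > t0)
    se <- sqrt(S(t0) * (1 - S(t0)) / n)
    expect_lt(abs(p_hat - S(t0)), 4 * se + 1e-3)
  }
})

test_that("zero tail hazard leaves unspent draws unresolved", {
  tpl <- flat_riskset(time = rep(1, 200), x = 0,
                      id = sprintf("s%03d", 1:200))
  # baseline vanishes after t = 0.5: some draws cannot be spent
  base <- piecewise_baseline(c(0, 0.5), c(1, 0))
  sim <- simulate_event_times(make_fit(c(x = 0)), base, tpl, seed = 8)
  expect_true(any(!sim$resolved))
  expect_true(all(is.na(sim$time[!sim$resolved])))
  expect_true(all(sim$time[sim$resolved] <= 0.5))
})

test_that("simulate/refit round trip recovers the generating coefficients", {
  env <- test_env(n_days = 30)
  coh <- simulate_cohort(simulation_truth(
    beta_find = c(temperature = 0.3, diel = 1.5, count = 0.4),
    arrival_total = 300, seed = 31), env)
  rs <- build_counting_process(coh, env, "finding",
                               c("temperature", "diel", "count"))
  fit <- fit_ph(rs, c("temperature", "diel", "count"))
  base <- breslow_baseline(fit, rs)
  set.seed(32)
  betas <- replicate(15, {
    sim <- simulate_event_times(fit, base, rs)
    fit_ph(fishpass:::riskset_with_times(rs, sim),
           c("temperature", "diel", "count"))$beta
  })
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(rowMeans(betas) - fit$beta) < 3 * se / sqrt(15) +
                    0.05))
})

test_that("assumption check is calibrated-ish under PH and flags strong non-PH", {
  set.seed(41)
  # under the PH model the trend p-value should not be tiny systematically
  tpl <- flat_riskset(time = rexp(150), x = rnorm(150),
                      id = sprintf("s%03d", 1:150))
  fit <- fit_ph(tpl, "x", standardize = FALSE)
  chk <- ph_assumption_check(fit, tpl, B = 99, seed = 1)
  expect_true(is.finite(chk$p_value))
  expect_false(attr(chk, "skipped"))
  # a strongly time-increasing effect is detected
  n <- 300
  x <- rnorm(n)
  u <- runif(n)
  # hazard exp(beta(t) x) with beta rising: early events ~ x irrelevant,
  # late events strongly x-driven -> simulate via two epochs
  t1 <- rexp(n, exp(-1 * x))      # effect -1 early
  t2 <- 1 + rexp(n, exp(2 * x))   # effect +2 late
  tt <- ifelse(t1 < 1, t1, t2)
  tv <- flat_riskset(time = tt, x = x, id = sprintf("s%03d", 1:n))
  fit2 <- fit_ph(tv, "x", standardize = FALSE)
  chk2 <- ph_assumption_check(fit2, tv, B = 199, seed = 2)
  expect_lt(chk2$p_value, 0.05)
  # degenerate: fewer than 10 events
  few <- flat_riskset(time = 1:5, x = c(1, -1, 0.5, -0.5, 0))
  f1 <- fit_ph(few, "x", standardize = FALSE)
  expect_warning(chk3 <- ph_assumption_check(f1, few, B = 19),
                 "skipped")
  expect_true(attr(chk3, "skipped"))
})
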