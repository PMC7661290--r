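# shared fixture builders and independent oracles

# single-interval risk set: one row per subject, event at `time`
flat_riskset <- function(time, x = NULL, event = 1L, id = NULL) {
  n <- length(time)
  out <- data.frame(id = id %||% sprintf("s%03d", seq_len(n)),
                    start = 0, stop = time,
                    event = rep_len(event, n), stringsAsFactors = FALSE)
  if (!is.null(x)) out$x <- x
  class(out) <- c("fp_riskset", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built PH fit object with prescribed coefficients (no scaling)
make_fit <- function(beta, covariates = names(beta)) {
  structure(list(beta = setNames(beta, covariates),
                 vcov = diag(length(beta), length(beta)),
                 covariates = covariates, scaling = NULL,
                 ties = "breslow", n_events = NA_integer_),
            class = "fp_ph_fit")
}

# independent oracle: enumerate the Breslow log partial likelihood for
# single-interval data (start = 0), all subjects at risk until their stop
enum_ph_loglik <- function(beta, time, x, event = rep(1, length(time))) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# small standard environment used across tests
test_env <- function(n_days = 20, seed = 1, counts = TRUE) {
  env <- simulate_environment(n_days = n_days, seed = seed)
  if (counts) env <- simulate_run_counts(env, seed = seed + 1)
  env
}

# quick exogenous-mode truth
test_truth <- function(...) {
  simulation_truth(beta_find = c(temperature = 0.3, diel = 1.5),
                   arrival_total = 150, seed = 1, ...)
}
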