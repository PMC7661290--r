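#' Breslow estimate of the cumulative baseline hazard
#'
#' After fitting \eqn{\lambda(t|X)=\lambda_0(t)\exp(X\beta)}, the Breslow
#' increment of the cumulative baseline hazard at event time \eqn{t} is
#' \eqn{d(t) / \sum_{j \in R(t)} \exp(X_j\hat\beta)}, with \eqn{d(t)} the
#' number of events at \eqn{t} and \eqn{R(t)} the risk set. With no
#' covariates this is exactly the Nelson--Aalen estimator. For simulation
#' beyond the last observed event time, the hazard is extrapolated as a
#' constant equal to the mean baseline rate over the final quartile of event
#' times.
#'
#' @param fit an `fp_ph_fit` produced from `data`.
#' @param data the same risk-set data the model was fitted on (raw scale;
#'   the fit's scaling record is applied internally).
#' @return object of class `fp_baseline`: list with `type = "step"`, `times`
#'   (ordered unique event times), `increments` (positive Breslow steps),
#'   `tail_rate`, and `n_events`. `cumhaz(base, t)` evaluates the implied
#'   step function.
#' @export
breslow_baseline <- function(fit, data) {
  stopifnot(inherits(fit, "fp_ph_fit"))
  check_riskset(data)
  if (!is.null(fit$scaling)) data <- apply_scaling(data, fit$scaling)
  X <- as.matrix(data[fit$covariates])
  storage.mode(X) <- "double"
  q <- ph_quantities(data$start, data$stop, data$event, X, fit$beta,
                     fit$ties)
  times <- q$ut
  inc <- if (length(times)) q$d / q$S0 else numeric(0)
  structure(list(type = "step", times = times, increments = inc,
                 tail_rate = tail_rate(times, inc),
                 n_events = sum(q$d)),
            class = "fp_baseline")
}

# mean baseline rate over the final quartile of event times
tail_rate <- function(times, inc) {
  if (!length(times)) return(0)
  H <- cumsum(inc)
  t75 <- unname(quantile(times, 0.75, type = 1))
  lo <- max(which(times <= t75))
  if (times[length(times)] > times[lo]) {
    (H[length(H)] - H[lo]) / (times[length(times)] - times[lo])
  } else {
    H[length(H)] / times[length(times)]
  }
}

#' Piecewise-constant parametric baseline hazard
#'
#' Constructs a baseline hazard directly from rates, mostly for simulation
#' and testing: `rates[k]` applies on `(breaks[k], breaks[k+1]]` with the
#' last rate extended indefinitely.
#'
#' @param breaks ascending break points starting at 0 (hours).
#' @param rates non-negative rates (events/hour), same length as `breaks`.
#' @return object of class `fp_baseline` with `type = "rate"`.
#' @export
piecewise_baseline <- function(breaks = 0, rates = 1) {
  spec <- as_pc_rate(list(breaks = breaks, rates = rates), "baseline")
  structure(list(type = "rate", breaks = spec$breaks, rates = spec$rates,
                 tail_rate = spec$rates[length(spec$rates)]),
            class = "fp_baseline")
}

#' Evaluate the cumulative baseline hazard
#'
#' @param base an `fp_baseline`.
#' @param t vector of times (hours, >= 0).
#' @return \eqn{\Lambda_0(t)}, using the tail extrapolation beyond support.
#' @export
cumhaz <- function(base, t) {
  stopifnot(inherits(base, "fp_baseline"))
  pc <- baseline_to_rates(base)
  Hk <- c(0, cumsum(pc$rates[-length(pc$rates)] * diff(pc$knots)))
  j <- findInterval(t, pc$knots)
  j[j == 0] <- 1L
  Hk[j] + pc$rates[j] * pmax(t - pc$knots[j], 0)
}

# Unified piecewise-constant-rate view of a baseline. Breslow steps are
# linearly interpolated between event times (the step atoms are spread over
# the preceding inter-event gap), which avoids massive ties when simulating.
baseline_to_rates <- function(base) {
  if (base$type == "rate") {
    return(list(knots = base$breaks, rates = base$rates))
  }
  if (!length(base$times)) {
    return(list(knots = 0, rates = base$tail_rate))
  }
  knots <- c(0, base$times)
  rates <- c(base$increments / diff(knots), base$tail_rate)
  list(knots = knots, rates = rates)
}

#' @export
print.fp_baseline <- function(x, ...) {
  if (x$type == "rate") {
    cat("<fp_baseline> piecewise-constant rate,", length(x$rates),
        "segment(s)\n")
  } else {
    cat(sprintf("<fp_baseline> Breslow steps at %d event times (tail rate %.4g/h)\n",
                length(x$times), x$tail_rate))
  }
  invisible(x)
}

#' Simulate event times from a fitted proportional-hazards model
#'
#' Draws one event time per subject by inverting the subject-specific
#' cumulative hazard \eqn{\Lambda_i(t) = \int_0^t \exp(X_i(u)\hat\beta)\,
#' d\Lambda_0(u)} at an independent standard-exponential draw. Piecewise
#' constant covariate paths are handled exactly; the Breslow baseline is
#' linearly interpolated between event times and extended beyond its support
#' at the tail rate, with the subject's last covariate values carried
#' forward. Subjects whose exponential draw is never spent (zero tail
#' hazard) are flagged unresolved.
#'
#' @param fit an `fp_ph_fit`.
#' @param base an `fp_baseline` (Breslow or parametric).
#' @param template risk-set data supplying each subject's covariate path, on
#'   the raw scale (the fit's scaling record is applied internally).
#' @param seed optional integer seed.
#' @return data.frame with one row per subject: `id`, `time` (hours; `NA`
#'   if unresolved), `resolved`, `extrapolated` (event drawn beyond the
#'   subject's observed path).
#' @export
simulate_event_times <- function(fit, base, template, seed = NULL) {
  stopifnot(inherits(fit, "fp_ph_fit"), inherits(base, "fp_baseline"))
  check_riskset(template)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(fit$scaling)) template <- apply_scaling(template, fit$scaling)
  X <- as.matrix(template[fit$covariates])
  storage.mode(X) <- "double"
  eta <- if (length(fit$beta)) drop(X %*% fit$beta) else
    numeric(nrow(template))
  pc <- baseline_to_rates(base)
  K <- length(pc$knots)
  Hk <- c(0, cumsum(pc$rates[-K] * diff(pc$knots)))
  L0 <- function(t) {  # cumulative baseline hazard (tail rate beyond support)
    j <- pmax(findInterval(t, pc$knots), 1L)
    Hk[j] + pc$rates[j] * pmax(t - pc$knots[j], 0)
  }
  L0inv <- function(h) {  # rightmost inverse; Inf when the tail rate is 0
    j <- pmax(findInterval(h, Hk), 1L)
    dh <- h - Hk[j]
    pc$knots[j] + ifelse(dh <= 0, 0, dh / pc$rates[j])
  }

  ids <- unique(template$id)
  grp <- match(template$id, ids)
  ord <- order(grp, template$start)
  template <- template[ord, , drop = FALSE]
  eta <- eta[ord]; grp <- grp[ord]
  w <- exp(eta)

  # per-row hazard mass and within-subject cumulative mass
  m <- w * (L0(template$stop) - L0(template$start))
  cm <- cumsum(m)
  first <- !duplicated(grp)
  before <- rep(cm[first] - m[first], times = tabulate(grp))
  Hend <- cm - before
  Hstart <- Hend - m

  E <- rexp(length(ids))
  Er <- E[grp]
  hit <- Hstart < Er & Er <= Hend
  time <- rep(NA_real_, length(ids))
  time[grp[hit]] <- L0inv(L0(template$start[hit]) +
                            (Er[hit] - Hstart[hit]) / w[hit])

  # draws not spent on the observed path: last covariates carried forward
  last <- !duplicated(grp, fromLast = TRUE)
  last_stop <- template$stop[last]
  spill <- which(is.na(time))
  if (length(spill)) {
    le <- w[last][spill]
    time[spill] <- L0inv(L0(last_stop[spill]) +
                           (E[spill] - Hend[last][spill]) / le)
  }
  data.frame(id = ids, time = ifelse(is.finite(time), time, NA_real_),
             resolved = is.finite(time),
             extrapolated = is.finite(time) & time > last_stop,
             stringsAsFactors = FALSE)
}

#' Advisory proportional-hazards assumption check
#'
#' Computes, per covariate, the correlation between Schoenfeld residuals and
#' event-time rank (a score-process trend statistic) with a permutation
#' p-value: under proportional hazards the residuals show no trend in time.
#' Advisory only -- it never gates the pipeline. Requires at least 10
#' events; otherwise it warns and returns a skipped result.
#'
#' @param fit an `fp_ph_fit` with at least one covariate.
#' @param data the risk-set data the model was fitted on (raw scale).
#' @param B number of permutations.
#' @param seed optional seed.
#' @return data.frame with `covariate`, `trend`, `p_value`, plus attribute
#'   `"skipped"`.
#' @export
ph_assumption_check <- function(fit, data, B = 199, seed = NULL) {
  stopifnot(inherits(fit, "fp_ph_fit"))
  if (length(fit$beta) == 0) stop("fit has no covariates", call. = FALSE)
  if (fit$n_events < 10) {
    warning("fewer than 10 events; PH assumption check skipped")
    out <- data.frame(covariate = fit$covariates, trend = NA_real_,
                      p_value = NA_real_)
    attr(out, "skipped") <- TRUE
    return(out)
  }
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(fit$scaling)) data <- apply_scaling(data, fit$scaling)
  X <- as.matrix(data[fit$covariates])
  storage.mode(X) <- "double"
  q <- ph_quantities(data$start, data$stop, data$event, X, fit$beta,
                     fit$ties)
  ev <- which(data$event == 1)
  ev <- ev[order(data$stop[ev])]
  jj <- match(data$stop[ev], q$ut)
  resid <- X[ev, , drop = FALSE] - q$S1[jj, , drop = FALSE] / q$S0[jj]
  rk <- rank(data$stop[ev])
  n <- length(ev)
  stat <- suppressWarnings(apply(resid, 2, cor, y = rk))
  perm <- matrix(NA_real_, B, length(stat))
  for (b in seq_len(B)) {
    perm[b, ] <- suppressWarnings(apply(resid, 2, cor, y = sample(rk)))
  }
  p <- vapply(seq_along(stat), function(k) {
    if (!is.finite(stat[k])) return(NA_real_)
    (1 + sum(abs(perm[, k]) >= abs(stat[k]), na.rm = TRUE)) / (B + 1)
  }, numeric(1))
  out <- data.frame(covariate = fit$covariates, trend = unname(stat),
                    p_value = p)
  attr(out, "skipped") <- FALSE
  out
}
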