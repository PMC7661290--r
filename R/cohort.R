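#' Simulate a telemetered cohort from known ground truth
#'
#' Draws one cohort of radio-tagged fish for a single dam and species from
#' the generating model in a [simulation_truth()]: arrivals from an
#' inhomogeneous Poisson process with a Gaussian run-timing intensity,
#' finding times from the proportional-hazards model
#' \eqn{\lambda(t|X) = \lambda_0(t)\exp(X\beta)} with the cohort's
#' time-varying covariates handled exactly (piecewise-exponential inversion
#' of the cumulative hazard), a Bernoulli first-attempt commit outcome from
#' the logistic model, and a fishway transit time from a second
#' proportional-hazards model.
#'
#' In `density_mode = "latent"` the finding hazard (and commit decision)
#' responds to the instantaneous number of cohort fish currently searching
#' the tailrace, simulated with an exact event-driven (Gillespie) scheme:
#' the causal density variable is then *not* observable by the analysis,
#' which sees only daily counts derived from passage events via
#' [derive_daily_counts()]. In `"exogenous"` mode the `count` covariate is
#' the run-count series attached to the environment, shared by generator and
#' analysis.
#'
#' @param truth an `fp_truth` object.
#' @param env an `fp_covariates` object covering the season. If `count`
#'   appears in `beta_find`/`beta_fishway`/`commit_coeffs`, a count series
#'   for `dam`/`species` must be attached.
#' @param dam,species,run cohort labels.
#' @param fishways character vector of fishway labels assigned uniformly at
#'   random per fish.
#' @param seed optional seed overriding `truth$seed`.
#' @return data.frame of class `fp_cohort` with columns `fish_id`, `species`,
#'   `run`, `dam`, `fishway`, `t_tailrace_entry`, `t_first_fishway_entry`,
#'   `t_last_fishway_entry`, `t_fishway_exit` (hours from the season origin;
#'   possibly `NA`), and `committed_first_attempt`. The generator's covariate
#'   standardization is attached as attribute `"generator_scaling"`.
#' @export
simulate_cohort <- function(truth, env, dam = "TD", species = "chinook",
                            run = "none", fishways = c("east", "north"),
                            seed = NULL) {
  stopifnot(inherits(truth, "fp_truth"), inherits(env, "fp_covariates"))
  seed <- if (is.null(seed)) truth$seed else seed
  if (!is.null(seed)) set.seed(seed)
  # observation ends with the season: fish not resolved by then are missing
  season_end <- 24 * env$n_days
  horizon <- season_end

  if ("density" %in% names(truth$beta_fishway)) {
    stop("latent `density` is not supported in the fishway-stage hazard",
         call. = FALSE)
  }
  needs_count <- "count" %in% c(names(truth$beta_find),
                                names(truth$beta_fishway),
                                names(truth$commit_coeffs))
  if (needs_count) covariate_at(env, 0, dam, species)  # validates coverage

  # arrivals: inhomogeneous Poisson over days, uniform within day
  peak <- if (is.null(truth$arrival_peak)) env$n_days / 2 else truth$arrival_peak
  sdd <- if (is.null(truth$arrival_sd)) env$n_days / 6 else truth$arrival_sd
  w <- exp(-0.5 * ((env$daily$day - peak) / sdd)^2)
  lam <- truth$arrival_total * w / sum(w)
  n_day <- rpois(env$n_days, lam)
  n <- sum(n_day)
  if (n == 0) {
    return(empty_cohort(dam, species, run))
  }
  arrive <- sort(24 * rep(env$daily$day, n_day) + runif(n, 0, 24))

  scaling <- generator_scaling(env, truth, dam,
                               if (needs_count) species else NULL)

  # stage 1: finding
  if (truth$density_mode == "latent" &&
      "density" %in% names(truth$beta_find)) {
    find <- latent_finding_times(truth, env, arrive, scaling, dam, species,
                                 horizon, needs_count)
    t_first <- find$t_first
    occupancy <- find$occupancy_at_exit
  } else {
    beta <- truth$beta_find[setdiff(names(truth$beta_find), "density")]
    t_first <- vapply(arrive, function(a) {
      a + draw_pc_event(truth$find_rate, beta, env, a, horizon, scaling,
                        dam, species)
    }, numeric(1))
    t_first[t_first > horizon] <- NA_real_
    # occupancy = fish that had arrived and not yet found at the exit moment
    occupancy <- rep(NA_real_, n)
    for (i in which(!is.na(t_first))) {
      occupancy[i] <- sum(arrive <= t_first[i] &
                            (is.na(t_first) | t_first >= t_first[i]))
    }
  }

  # stage 2: commit (logistic at the moment of first fishway entry)
  p_commit <- rep(NA_real_, n)
  ok <- !is.na(t_first)
  if (any(ok)) {
    z <- commit_linear_predictor(truth$commit_coeffs, env,
                                 pmin(t_first[ok], season_end - 1e-9),
                                 scaling, dam, species,
                                 occupancy[ok])
    p_commit[ok] <- plogis(z)
  }
  committed <- rep(NA, n)
  committed[ok] <- runif(sum(ok)) < p_commit[ok]
  t_last <- ifelse(ok & committed, t_first,
                   t_first + rexp(n, truth$reattempt_rate))
  t_last[!ok] <- NA_real_

  # stage 3: fishway transit
  t_exit <- rep(NA_real_, n)
  ok2 <- !is.na(t_last) & t_last < horizon
  if (any(ok2)) {
    t_exit[ok2] <- vapply(which(ok2), function(i) {
      t_last[i] + draw_pc_event(truth$fishway_rate, truth$beta_fishway, env,
                                t_last[i], horizon, scaling, dam, species)
    }, numeric(1))
    t_exit[t_exit > horizon] <- NA_real_
  }

  out <- data.frame(
    fish_id = sprintf("%s_%s_%04d", dam, substr(species, 1, 4), seq_len(n)),
    species = species, run = run, dam = dam,
    fishway = sample(fishways, n, replace = TRUE),
    t_tailrace_entry = arrive,
    t_first_fishway_entry = t_first,
    t_last_fishway_entry = t_last,
    t_fishway_exit = t_exit,
    committed_first_attempt = committed,
    stringsAsFactors = FALSE
  )
  if (truth$p_missing > 0) {
    for (col in c("t_tailrace_entry", "t_first_fishway_entry",
                  "t_last_fishway_entry", "t_fishway_exit")) {
      drop <- runif(n) < truth$p_missing
      out[[col]][drop] <- NA_real_
    }
  }
  attr(out, "generator_scaling") <- scaling
  class(out) <- c("fp_cohort", "data.frame")
  out
}

empty_cohort <- function(dam, species, run) {
  out <- data.frame(
    fish_id = character(), species = character(), run = character(),
    dam = character(), fishway = character(),
    t_tailrace_entry = numeric(), t_first_fishway_entry = numeric(),
    t_last_fishway_entry = numeric(), t_fishway_exit = numeric(),
    committed_first_attempt = logical(), stringsAsFactors = FALSE
  )
  class(out) <- c("fp_cohort", "data.frame")
  out
}

# Arrival-weighted seasonal mean/sd per continuous covariate. Weighting by
# the run-timing curve approximates the exposure-weighted standardization the
# analysis applies, so generator-scale and analysis-scale coefficients agree
# closely. `diel` is binary and enters unscaled; latent density uses the
# configured centre/scale.
generator_scaling <- function(env, truth, dam, species) {
  peak <- if (is.null(truth$arrival_peak)) env$n_days / 2 else truth$arrival_peak
  sdd <- if (is.null(truth$arrival_sd)) env$n_days / 6 else truth$arrival_sd
  w <- exp(-0.5 * ((env$daily$day - peak) / sdd)^2)
  w <- w / sum(w)
  wstat <- function(x) {
    m <- sum(w * x)
    c(mean = m, sd = sqrt(sum(w * (x - m)^2)))
  }
  sc <- list(temperature = wstat(env$daily$temperature),
             spill = wstat(env$daily$spill),
             diel = c(mean = 0, sd = 1),
             density = c(mean = truth$latent_center, sd = truth$latent_scale))
  if (!is.null(species)) {
    sel <- env$counts$dam == dam & env$counts$species == species
    if (any(sel)) {
      cs <- env$counts[sel, ]
      sc$count <- wstat(cs$count[match(env$daily$day, cs$day)])
    }
  }
  sc
}

# environmental linear predictor (excluding latent density) at calendar hours
env_linear_predictor <- function(beta, env, hours, scaling, dam, species) {
  if (length(beta) == 0) return(numeric(length(hours)))
  needs_count <- "count" %in% names(beta)
  cv <- covariate_at(env, pmin(hours, 24 * env$n_days - 1e-9),
                     dam = if (needs_count) dam else NULL,
                     species = if (needs_count) species else NULL)
  lp <- numeric(length(hours))
  for (nm in names(beta)) {
    s <- scaling[[nm]]
    if (is.null(s)) stop("no generator scaling for covariate ", nm,
                         call. = FALSE)
    lp <- lp + beta[[nm]] * (cv[[nm]] - s[["mean"]]) / s[["sd"]]
  }
  lp
}

commit_linear_predictor <- function(coeffs, env, hours, scaling, dam, species,
                                    occupancy) {
  beta <- coeffs[setdiff(names(coeffs), c("intercept", "density"))]
  lp <- coeffs[["intercept"]] +
    env_linear_predictor(beta, env, hours, scaling, dam, species)
  if ("density" %in% names(coeffs)) {
    s <- scaling$density
    lp <- lp + coeffs[["density"]] * (occupancy - s[["mean"]]) / s[["sd"]]
  }
  lp
}

# Draw one event waiting time (hours since `entry`) under a piecewise-constant
# baseline (subject time) and piecewise-constant covariates (calendar time),
# by exact inversion of the cumulative hazard at an Exp(1) draw. Returns a
# value > horizon - entry when the draw is not spent by the horizon.
draw_pc_event <- function(rate_spec, beta, env, entry, horizon, scaling,
                          dam, species) {
  span <- horizon - entry
  cb <- covariate_boundaries(env, entry, min(24 * env$n_days, horizon)) - entry
  knots <- sort(unique(c(0, rate_spec$breaks, cb)))
  knots <- knots[knots < span]
  base <- rate_spec$rates[findInterval(knots, rate_spec$breaks)]
  lp <- env_linear_predictor(beta, env, entry + knots, scaling, dam, species)
  rates <- base * exp(lp)
  invert_pc_hazard(knots, rates, rexp(1))
}

# Invert a piecewise-constant hazard: rates[k] applies on
# (knots[k], knots[k+1]] with the last rate extended to infinity. Returns the
# time at which the cumulative hazard reaches E (Inf if it never does).
invert_pc_hazard <- function(knots, rates, E) {
  M <- length(knots)
  Hk <- c(0, cumsum(rates[-M] * diff(knots)))  # cumulative hazard at knots
  j <- sum(Hk < E)
  if (j == 0L) j <- 1L
  if (rates[j] <= 0) return(Inf)
  knots[j] + (E - Hk[j]) / rates[j]
}

# Event-driven simulation of the finding stage when the hazard depends on the
# latent instantaneous tailrace occupancy. Between state changes (arrivals,
# departures, covariate boundaries, baseline breaks) every present fish has a
# constant rate, so the scheme is exact.
latent_finding_times <- function(truth, env, arrive, scaling, dam, species,
                                 horizon, needs_count) {
  n <- length(arrive)
  beta_env <- truth$beta_find[setdiff(names(truth$beta_find), "density")]
  beta_d <- truth$beta_find[["density"]]
  sd_ <- scaling$density
  season_end <- 24 * env$n_days

  bounds <- covariate_boundaries(env, arrive[1], min(season_end, horizon))
  brks <- truth$find_rate$breaks[-1]
  if (length(brks)) bounds <- sort(c(bounds, rep(arrive, each = length(brks)) +
                                       brks))
  events <- sort(unique(c(arrive, bounds)))
  events <- events[events <= horizon]

  t_first <- rep(NA_real_, n)
  occ_at_exit <- rep(NA_real_, n)
  present <- integer(0)
  t <- arrive[1]
  next_arr <- 1L
  ei <- match(TRUE, events > t, nomatch = length(events) + 1L)

  rate_of <- function(ids, tt, n_present) {
    if (!length(ids)) return(numeric(0))
    base <- truth$find_rate$rates[findInterval(tt - arrive[ids],
                                               truth$find_rate$breaks)]
    lp <- env_linear_predictor(beta_env, env, rep(tt, length(ids)), scaling,
                               dam, species)
    zd <- (n_present - sd_[["mean"]]) / sd_[["sd"]]
    base * exp(lp + beta_d * zd)
  }

  while (t < horizon && (length(present) || next_arr <= n)) {
    while (next_arr <= n && arrive[next_arr] <= t) {
      present <- c(present, next_arr)
      next_arr <- next_arr + 1L
    }
    t_next <- min(if (ei <= length(events)) events[ei] else horizon, horizon)
    r <- rate_of(present, t, length(present))
    R <- sum(r)
    dt <- if (R > 0) rexp(1, R) else Inf
    if (t + dt < t_next) {
      t <- t + dt
      i <- present[sample.int(length(present), 1L, prob = r)]
      t_first[i] <- t
      occ_at_exit[i] <- length(present)
      present <- setdiff(present, i)
    } else {
      t <- t_next
      if (ei <= length(events)) ei <- ei + 1L else break
    }
  }
  list(t_first = t_first, occupancy_at_exit = occ_at_exit)
}
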