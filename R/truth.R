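#' Ground-truth parameter set for the synthetic telemetry generator
#'
#' Collects every parameter of the generating model: log-hazard-ratio
#' coefficients for the finding and fishway stages (on the generator's
#' standardized covariate scale), logistic coefficients for the first-attempt
#' commit decision, piecewise-constant baseline hazard rates, the seasonal
#' arrival process, and the observer-count process (lag and overdispersion).
#' A cohort simulated from a `simulation_truth` obeys the proportional-hazards
#' model \eqn{\lambda(t|X) = \lambda_0(t)\exp(X\beta)} exactly, so fitted
#' coefficients can be compared against `beta_find` / `beta_fishway` in
#' recovery and calibration studies.
#'
#' Covariates available to the coefficients: `temperature`, `spill`, `diel`
#' (binary day indicator, entered unscaled), `count` (daily count series,
#' requires one attached to the environment) and `density` (the *latent*
#' instantaneous number of fish in the tailrace; only meaningful for the
#' finding stage and the commit decision). The generator standardizes
#' `temperature`, `spill` and `count` by their arrival-weighted seasonal mean
#' and SD, and `density` by `(D - latent_center) / latent_scale`, before
#' applying the coefficients, so all coefficients are per-SD effects.
#'
#' @param beta_find named coefficient vector for the finding-stage hazard.
#' @param beta_fishway named coefficient vector for the fishway-stage hazard.
#' @param commit_coeffs named logistic coefficients for the commit decision;
#'   must include `intercept`. The default intercept `qlogis(0.43)` puts the
#'   commit probability at 43% when all covariates sit at their seasonal
#'   means.
#' @param find_rate,fishway_rate baseline hazards (events/hour) for the two
#'   stages: either a single constant rate or a list
#'   `list(breaks = c(0, ...), rates = c(...))` giving a piecewise-constant
#'   rate on `(breaks[k], breaks[k+1]]` in hours since stage entry, with the
#'   last rate extended indefinitely.
#' @param arrival_total expected number of arrivals over the season.
#' @param arrival_peak,arrival_sd centre and SD (days) of the Gaussian
#'   run-timing arrival intensity; defaults mid-season and `n_days / 6`
#'   (resolved at simulation time).
#' @param count_lag delay (hours, >= 0) between a fish passing the telemetry
#'   exit antenna and being counted by observers mid-ladder.
#' @param count_window_offset hours between the mid-ladder count window and
#'   the fishway exit (subtracted from the exit time).
#' @param count_noise negative-binomial overdispersion of derived counts
#'   (0 = exact tally).
#' @param density_mode `"exogenous"`: the count covariate driving the hazard
#'   is an exogenous run-count series attached to the environment (tagged
#'   fish are a negligible part of the run). `"latent"`: the finding hazard
#'   and commit decision respond to the latent instantaneous tailrace
#'   occupancy of the simulated cohort itself, which the analysis never sees
#'   -- it sees only counts derived from passage events.
#' @param latent_center,latent_scale standardization of the latent occupancy.
#' @param reattempt_rate rate (per hour) of the exponential delay between the
#'   first and last fishway entry for fish that do not commit.
#' @param p_missing probability each recorded timestamp is missing completely
#'   at random.
#' @param seed integer seed; fixed seed implies identical output.
#' @return an object of class `fp_truth`.
#' @export
simulation_truth <- function(beta_find = c(temperature = 0.3, diel = 1.5),
                             beta_fishway = c(temperature = 0.2, diel = 2.0),
                             commit_coeffs = c(intercept = qlogis(0.43)),
                             find_rate = 0.10,
                             fishway_rate = 0.5,
                             arrival_total = 500,
                             arrival_peak = NULL,
                             arrival_sd = NULL,
                             count_lag = 0,
                             count_window_offset = 0,
                             count_noise = 0,
                             density_mode = c("exogenous", "latent"),
                             latent_center = 4,
                             latent_scale = 2.5,
                             reattempt_rate = 0.25,
                             p_missing = 0,
                             seed = NULL) {
  density_mode <- match.arg(density_mode)
  find_rate <- as_pc_rate(find_rate, "find_rate")
  fishway_rate <- as_pc_rate(fishway_rate, "fishway_rate")
  if (arrival_total < 0) stop("`arrival_total` must be >= 0", call. = FALSE)
  if (count_lag < 0) stop("`count_lag` must be >= 0", call. = FALSE)
  if (count_noise < 0) stop("`count_noise` must be >= 0", call. = FALSE)
  if (!("intercept" %in% names(commit_coeffs))) {
    stop("`commit_coeffs` must contain an `intercept` term", call. = FALSE)
  }
  if (p_missing < 0 || p_missing >= 1) {
    stop("`p_missing` must be in [0, 1)", call. = FALSE)
  }
  structure(list(
    beta_find = beta_find, beta_fishway = beta_fishway,
    commit_coeffs = commit_coeffs,
    find_rate = find_rate, fishway_rate = fishway_rate,
    arrival_total = arrival_total, arrival_peak = arrival_peak,
    arrival_sd = arrival_sd,
    count_lag = count_lag, count_window_offset = count_window_offset,
    count_noise = count_noise,
    density_mode = density_mode,
    latent_center = latent_center, latent_scale = latent_scale,
    reattempt_rate = reattempt_rate, p_missing = p_missing,
    seed = seed
  ), class = "fp_truth")
}

# validate / normalize a piecewise-constant rate spec
as_pc_rate <- function(x, what) {
  if (is.numeric(x) && length(x) == 1L) x <- list(breaks = 0, rates = x)
  if (!is.list(x) || !all(c("breaks", "rates") %in% names(x)) ||
      length(x$breaks) != length(x$rates)) {
    stop("`", what, "` must be a rate or list(breaks=, rates=) of equal length",
         call. = FALSE)
  }
  if (x$breaks[1] != 0 || is.unsorted(x$breaks, strictly = TRUE)) {
    stop("`", what, "` breaks must be strictly increasing and start at 0",
         call. = FALSE)
  }
  if (any(x$rates < 0)) stop("`", what, "` rates must be >= 0", call. = FALSE)
  x
}

#' @export
print.fp_truth <- function(x, ...) {
  cat("<fp_truth>", x$density_mode, "density mode\n")
  cat("  beta_find:   ", paste(names(x$beta_find), round(x$beta_find, 3),
                               sep = "=", collapse = ", "), "\n")
  cat("  beta_fishway:", paste(names(x$beta_fishway), round(x$beta_fishway, 3),
                               sep = "=", collapse = ", "), "\n")
  cat("  commit:      ", paste(names(x$commit_coeffs),
                               round(x$commit_coeffs, 3),
                               sep = "=", collapse = ", "), "\n")
  cat(sprintf("  arrivals ~%g over season; count lag %gh, noise %g\n",
              x$arrival_total, x$count_lag, x$count_noise))
  invisible(x)
}
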