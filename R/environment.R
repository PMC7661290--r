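#' Simulate an environmental covariate series for one run season
#'
#' Generates the time-varying covariates the passage models condition on:
#' daily water temperature (seasonal sinusoid plus AR(1) noise), daily
#' spillway discharge (declining seasonal trend with multiplicative AR(1)
#' noise) and an hourly binary diel (daytime) indicator. Temperature and
#' discharge are piecewise constant over calendar days; the diel indicator is
#' piecewise constant over hours. All times are hours from the season origin
#' (hour 0 = midnight starting day 0); intervals are half-open `(t, t+1]` with
#' left-continuous covariate values.
#'
#' @param n_days season length in days (> 0).
#' @param temp_mean,temp_amplitude seasonal temperature sinusoid: level at
#'   day 0 and seasonal rise in degrees C. The deterministic component is
#'   `temp_mean + temp_amplitude * sin(pi * day / (2 * n_days))`, the rising
#'   quarter-wave of a seasonal sinusoid -- water warms monotonically over a
#'   late-spring/summer run season.
#' @param temp_ar,temp_noise_sd AR(1) coefficient and innovation SD of the
#'   daily temperature noise (degrees C). `temp_noise_sd = 0` gives the exact
#'   sinusoid.
#' @param spill_base baseline spillway discharge (arbitrary flow units, kcfs
#'   scale) at day 0.
#' @param spill_decay exponential decay rate of discharge over the season
#'   (per season).
#' @param spill_ar,spill_noise_sd AR(1) coefficient and innovation SD of the
#'   log-discharge noise.
#' @param day_window numeric length-2, local hours `[start, end)` of the
#'   daytime window for the diel indicator. Default 06:00--18:00.
#' @param origin ISO date of day 0, recorded for file output only.
#' @param seed optional integer seed; a fixed seed reproduces the series
#'   exactly.
#'
#' @return An object of class `fp_covariates`: a list with elements
#'   `n_days`, `daily` (data.frame `day`, `temperature`, `spill`),
#'   `day_window`, `counts` (data.frame `day`, `dam`, `species`, `count`;
#'   initially empty) and `origin`.
#' @seealso [simulate_run_counts()], [attach_counts()], [covariate_at()]
#' @export
simulate_environment <- function(n_days = 60,
                                 temp_mean = 16, temp_amplitude = 4,
                                 temp_ar = 0.6, temp_noise_sd = 1.0,
                                 spill_base = 150, spill_decay = 1.2,
                                 spill_ar = 0.7, spill_noise_sd = 0.15,
                                 day_window = c(6, 18),
                                 origin = "2013-06-01",
                                 seed = NULL) {
  if (!is.numeric(n_days) || length(n_days) != 1L || n_days <= 0) {
    stop("`n_days` must be a positive number", call. = FALSE)
  }
  n_days <- as.integer(n_days)
  if (length(day_window) != 2L || day_window[1] >= day_window[2] ||
      day_window[1] < 0 || day_window[2] > 24) {
    stop("`day_window` must be increasing hours within [0, 24]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  day <- seq_len(n_days) - 1L
  temp_det <- temp_mean + temp_amplitude * sin(pi * day / (2 * n_days))
  temp_eps <- ar1_noise(n_days, temp_ar, temp_noise_sd)
  spill_det <- spill_base * exp(-spill_decay * day / n_days)
  spill_eps <- ar1_noise(n_days, spill_ar, spill_noise_sd)

  env <- list(
    n_days = n_days,
    daily = data.frame(
      day = day,
      temperature = temp_det + temp_eps,
      spill = spill_det * exp(spill_eps)
    ),
    day_window = as.numeric(day_window),
    counts = data.frame(day = integer(), dam = character(),
                        species = character(), count = integer()),
    origin = origin
  )
  class(env) <- "fp_covariates"
  env
}

# stationary AR(1) noise of length n (zero-mean)
ar1_noise <- function(n, ar, sd) {
  if (sd == 0) return(numeric(n))
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd / sqrt(max(1 - ar^2, 1e-12)))
  if (n > 1) for (i in 2:n) e[i] <- ar * e[i - 1] + rnorm(1, 0, sd)
  e
}

#' @export
print.fp_covariates <- function(x, ...) {
  cat(sprintf("<fp_covariates> %d days from %s; day window %02.0f:00-%02.0f:00\n",
              x$n_days, x$origin, x$day_window[1], x$day_window[2]))
  cat(sprintf("  temperature %.1f-%.1f C, spill %.0f-%.0f, counts for %d dam/species series\n",
              min(x$daily$temperature), max(x$daily$temperature),
              min(x$daily$spill), max(x$daily$spill),
              nrow(unique(x$counts[c("dam", "species")]))))
  invisible(x)
}

#' Simulate an exogenous daily run-count series
#'
#' Generates a daily observer-count series for one dam and species from a
#' Gaussian-shaped run-timing curve with negative-binomial observation noise.
#' This emulates counts of the *whole run* (of which any telemetered cohort
#' is a small subsample), so the series can be used both as the density
#' covariate driving a simulated cohort's hazard and as the covariate seen by
#' the analysis, with no feedback from the tagged fish. For the
#' reverse-causal alternative -- counts computed from simulated passage
#' events -- see [derive_daily_counts()].
#'
#' @param env an `fp_covariates` object.
#' @param dam,species series labels.
#' @param total expected total count over the season (fish).
#' @param peak_day,sd_days centre and width (days) of the run-timing curve;
#'   defaults mid-season and `n_days / 6`.
#' @param noise negative-binomial overdispersion `phi >= 0`: daily variance
#'   is approximately `mu * (1 + phi)`. `0` means deterministic rounding of
#'   the expected curve.
#' @param seed optional integer seed.
#' @return the `fp_covariates` object with the series appended to `counts`.
#' @export
simulate_run_counts <- function(env, dam = "TD", species = "chinook",
                                total = 60000, peak_day = NULL, sd_days = NULL,
                                noise = 0.2, seed = NULL) {
  stopifnot(inherits(env, "fp_covariates"))
  if (noise < 0) stop("`noise` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(peak_day)) peak_day <- env$n_days / 2
  if (is.null(sd_days)) sd_days <- env$n_days / 6
  day <- env$daily$day
  w <- exp(-0.5 * ((day - peak_day) / sd_days)^2)
  mu <- total * w / sum(w)
  count <- if (noise == 0) round(mu) else
    rnbinom(length(mu), mu = mu, size = pmax(mu, 1) / noise)
  attach_counts(env, data.frame(day = day, dam = dam, species = species,
                                count = as.integer(count)))
}

#' Attach a daily count series to a covariate series
#'
#' @param env an `fp_covariates` object.
#' @param counts data.frame with columns `day`, `dam`, `species`, `count`
#'   (non-negative integers, one row per day/dam/species).
#' @return the updated `fp_covariates` object.
#' @export
attach_counts <- function(env, counts) {
  stopifnot(inherits(env, "fp_covariates"))
  need <- c("day", "dam", "species", "count")
  if (!all(need %in% names(counts))) {
    stop("`counts` needs columns day, dam, species, count", call. = FALSE)
  }
  if (any(counts$count < 0)) stop("counts must be non-negative", call. = FALSE)
  keep <- !(paste(env$counts$dam, env$counts$species) %in%
              unique(paste(counts$dam, counts$species)))
  env$counts <- rbind(env$counts[keep, , drop = FALSE], counts[need])
  rownames(env$counts) <- NULL
  env
}

#' Look up covariate values at calendar hours
#'
#' Evaluates the environmental covariates (and, if attached, the daily count
#' for one dam/species) at a vector of calendar hours from the season origin.
#' Values are left-continuous over `(t, t+1]` intervals: the value on an
#' interval is the value at its start.
#'
#' @param env an `fp_covariates` object.
#' @param hours numeric vector of hours from origin, within `[0, 24 * n_days)`.
#' @param dam,species optional labels selecting a count series; if `NULL` the
#'   `count` column is omitted.
#' @return data.frame with columns `temperature`, `spill`, `diel` and
#'   (optionally) `count`, one row per element of `hours`.
#' @export
covariate_at <- function(env, hours, dam = NULL, species = NULL) {
  stopifnot(inherits(env, "fp_covariates"))
  if (any(hours < 0 | hours >= 24 * env$n_days)) {
    stop("hours outside covariate coverage [0, ", 24 * env$n_days, ")",
         call. = FALSE)
  }
  day <- pmin(floor(hours / 24), env$n_days - 1L)
  hod <- hours - 24 * day
  out <- data.frame(
    temperature = env$daily$temperature[day + 1L],
    spill = env$daily$spill[day + 1L],
    diel = as.numeric(hod >= env$day_window[1] & hod < env$day_window[2])
  )
  if (!is.null(dam) && !is.null(species)) {
    sel <- env$counts$dam == dam & env$counts$species == species
    if (!any(sel)) {
      stop("no count series for dam=", dam, " species=", species,
           call. = FALSE)
    }
    cs <- env$counts[sel, ]
    idx <- match(day, cs$day)
    if (anyNA(idx)) {
      stop("count series for dam=", dam, " species=", species,
           " does not cover all requested days", call. = FALSE)
    }
    out$count <- cs$count[idx]
  }
  out
}

# calendar hours (within (from, to)) at which any covariate changes value:
# day boundaries plus diel transitions
covariate_boundaries <- function(env, from, to) {
  days <- seq(floor(from / 24), ceiling(to / 24))
  b <- sort(unique(c(days * 24,
                     days * 24 + env$day_window[1],
                     days * 24 + env$day_window[2])))
  b[b > from & b < to]
}
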