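#' Build counting-process (start, stop] data for one passage stage
#'
#' Expands each fish's exposure during one stage into contiguous
#' `(start, stop]` intervals on the *subject* time scale (hours since the
#' fish's own stage entry), split at every calendar boundary where a
#' covariate changes value: daily boundaries for temperature, spillway
#' discharge and count, and the day-window transitions for the diel
#' indicator. Covariates are piecewise constant and left-continuous: the
#' value on an interval is the value prevailing at its start. The event flag
#' is set on the final interval. Fish with a missing stage timestamp are
#' excluded (not censored); exclusion counts are attached as an attribute.
#'
#' @param fish an `fp_cohort` (or compatible data.frame).
#' @param env an `fp_covariates` covering every fish's exposure window; a
#'   count series must be attached when `"count"` is requested.
#' @param stage `"finding"` (tailrace entry to first fishway entry) or
#'   `"fishway"` (last fishway entry to exit).
#' @param covariates covariate columns to evaluate; any of `"temperature"`,
#'   `"spill"`, `"diel"`, `"count"`.
#' @param count_threshold optional numeric: adds a binary column `count_low`
#'   equal to 1 when `count <= count_threshold` (the threshold density
#'   effect; the conventional cut is 150 fish/day).
#' @return data.frame of class `fp_riskset` with columns `id`, `start`,
#'   `stop`, `event`, the covariate columns, and the grouping labels
#'   `dam`, `species`, `run`, `fishway`. Attributes: `stage`, `excluded`
#'   (named count of dropped fish), `count_threshold`.
#' @export
build_counting_process <- function(fish, env,
                                   stage = c("finding", "fishway"),
                                   covariates = c("temperature", "diel",
                                                  "count"),
                                   count_threshold = NULL) {
  stage <- match.arg(stage)
  stopifnot(inherits(env, "fp_covariates"))
  bad <- setdiff(covariates, c("temperature", "spill", "diel", "count"))
  if (length(bad)) stop("unknown covariates: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  origin_col <- if (stage == "finding") "t_tailrace_entry" else
    "t_last_fishway_entry"
  end_col <- if (stage == "finding") "t_first_fishway_entry" else
    "t_fishway_exit"

  keep <- !is.na(fish[[origin_col]]) & !is.na(fish[[end_col]])
  excluded <- c(missing_timestamp = sum(!keep))
  f <- fish[keep, , drop = FALSE]
  out <- empty_riskset(covariates, !is.null(count_threshold))
  if (nrow(f) > 0) {
    end_cov <- 24 * env$n_days
    if (any(f[[origin_col]] < 0 | f[[end_col]] > end_cov)) {
      bad_id <- f$fish_id[f[[origin_col]] < 0 | f[[end_col]] > end_cov][1]
      stop("fish ", bad_id, " has exposure outside covariate coverage",
           call. = FALSE)
    }
    if (any(f[[end_col]] <= f[[origin_col]])) {
      bad_id <- f$fish_id[f[[end_col]] <= f[[origin_col]]][1]
      stop("fish ", bad_id, " has non-positive stage duration", call. = FALSE)
    }
    needs_count <- "count" %in% covariates
    rows <- vector("list", nrow(f))
    for (i in seq_len(nrow(f))) {
      a <- f[[origin_col]][i]; b <- f[[end_col]][i]
      knots <- c(a, covariate_boundaries(env, a, b), b)
      nseg <- length(knots) - 1L
      cv <- covariate_at(env, knots[-length(knots)],
                         dam = if (needs_count) f$dam[i] else NULL,
                         species = if (needs_count) f$species[i] else NULL)
      seg <- data.frame(id = f$fish_id[i],
                        start = knots[-length(knots)] - a,
                        stop = knots[-1] - a,
                        event = c(rep(0L, nseg - 1L), 1L),
                        stringsAsFactors = FALSE)
      for (nm in covariates) seg[[nm]] <- cv[[nm]]
      seg$dam <- f$dam[i]; seg$species <- f$species[i]
      seg$run <- f$run[i]; seg$fishway <- f$fishway[i]
      rows[[i]] <- seg
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    if (!is.null(count_threshold)) {
      if (!needs_count) stop("`count_threshold` requires the count covariate",
                             call. = FALSE)
      out$count_low <- as.numeric(out$count <= count_threshold)
    }
  }
  structure(out, stage = stage, excluded = excluded,
            count_threshold = count_threshold,
            class = c("fp_riskset", "data.frame"))
}

empty_riskset <- function(covariates, threshold) {
  out <- data.frame(id = character(), start = numeric(), stop = numeric(),
                    event = integer(), stringsAsFactors = FALSE)
  for (nm in covariates) out[[nm]] <- numeric()
  out$dam <- character(); out$species <- character()
  out$run <- character(); out$fishway <- character()
  if (threshold) out$count_low <- numeric()
  out
}

#' Standardize continuous covariates of a risk-set table
#'
#' Transforms each continuous covariate to exposure-weighted mean 0 and SD 1
#' (weights are interval lengths `stop - start`, so fish contribute in
#' proportion to their time at risk). Binary covariates (all values in
#' \{0, 1\}) are left untouched and flagged. The scaling record needed to
#' invert the transform (and to re-standardize rescaled scenario covariates)
#' is attached as attribute `"scaling"`.
#'
#' @param data an `fp_riskset` (or any data.frame with `start`, `stop` and
#'   the covariate columns).
#' @param covariates columns to consider; default every covariate column
#'   present.
#' @return the data with transformed columns, plus attribute `"scaling"`: a
#'   data.frame with `covariate`, `mean`, `sd`, `binary`.
#' @export
standardize_covariates <- function(data, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- intersect(c("temperature", "spill", "diel", "count",
                              "count_low"), names(data))
  }
  w <- data$stop - data$start
  sc <- data.frame(covariate = character(), mean = numeric(), sd = numeric(),
                   binary = logical(), stringsAsFactors = FALSE)
  for (nm in covariates) {
    x <- data[[nm]]
    is_bin <- all(x %in% c(0, 1))
    if (is_bin) {
      sc <- rbind(sc, data.frame(covariate = nm, mean = 0, sd = 1,
                                 binary = TRUE))
      next
    }
    if (nrow(data) == 0) {
      m <- 0; s <- 1
    } else {
      m <- sum(w * x) / sum(w)
      s <- sqrt(sum(w * (x - m)^2) / sum(w))
    }
    if (s <= 0 || !is.finite(s)) {
      stop("covariate `", nm, "` has zero exposure-weighted variance",
           call. = FALSE)
    }
    data[[nm]] <- (x - m) / s
    sc <- rbind(sc, data.frame(covariate = nm, mean = m, sd = s,
                               binary = FALSE))
  }
  attr(data, "scaling") <- sc
  data
}

# apply a previously stored scaling record to (raw) covariate columns
apply_scaling <- function(data, scaling) {
  for (k in seq_len(nrow(scaling))) {
    nm <- scaling$covariate[k]
    if (scaling$binary[k] || !nm %in% names(data)) next
    data[[nm]] <- (data[[nm]] - scaling$mean[k]) / scaling$sd[k]
  }
  data
}
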