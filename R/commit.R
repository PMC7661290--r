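#' Build the first-attempt commit table
#'
#' One row per fish with a recorded first fishway entry: the binary outcome
#' is 1 when the fish passed fully through the fishway on its first attempt
#' (first entry equals last entry), and the covariates are evaluated on the
#' day/hour of the first fishway entry -- the moment of the commit decision.
#'
#' @param fish an `fp_cohort` (or compatible data.frame).
#' @param env an `fp_covariates`; a count series must be attached when
#'   `"count"` is requested.
#' @param covariates any of `"temperature"`, `"spill"`, `"diel"`, `"count"`.
#' @param count_threshold optional: adds binary `count_low`
#'   (`count <= count_threshold`).
#' @return data.frame of class `fp_commit_table` with `id`, `committed`,
#'   the covariates, and grouping labels; attribute `"excluded"` counts
#'   dropped fish.
#' @export
build_commit_table <- function(fish, env,
                               covariates = c("temperature", "diel", "count"),
                               count_threshold = NULL) {
  stopifnot(inherits(env, "fp_covariates"))
  keep <- !is.na(fish$t_first_fishway_entry) &
    !is.na(fish$t_last_fishway_entry)
  excluded <- c(missing_timestamp = sum(!keep))
  f <- fish[keep, , drop = FALSE]
  if (nrow(f) == 0) {
    out <- data.frame(id = character(), committed = integer(),
                      stringsAsFactors = FALSE)
    for (nm in covariates) out[[nm]] <- numeric()
    out$dam <- character(); out$species <- character()
    out$run <- character(); out$fishway <- character()
    if (!is.null(count_threshold)) out$count_low <- numeric()
    return(structure(out, excluded = excluded,
                     count_threshold = count_threshold,
                     class = c("fp_commit_table", "data.frame")))
  }
  needs_count <- "count" %in% covariates
  hrs <- pmin(f$t_first_fishway_entry, 24 * env$n_days - 1e-9)
  if (any(hrs < 0)) stop("first fishway entry before covariate coverage",
                         call. = FALSE)
  cv <- if (needs_count) {
    rows <- lapply(seq_len(nrow(f)), function(i)
      covariate_at(env, hrs[i], f$dam[i], f$species[i]))
    do.call(rbind, rows)
  } else covariate_at(env, hrs)
  out <- data.frame(
    id = f$fish_id,
    committed = as.integer(f$t_first_fishway_entry ==
                             f$t_last_fishway_entry),
    stringsAsFactors = FALSE
  )
  for (nm in covariates) out[[nm]] <- cv[[nm]]
  out$dam <- f$dam; out$species <- f$species
  out$run <- f$run; out$fishway <- f$fishway
  if (!is.null(count_threshold)) {
    if (!needs_count) stop("`count_threshold` requires the count covariate",
                           call. = FALSE)
    out$count_low <- as.numeric(out$count <= count_threshold)
  }
  structure(out, excluded = excluded, count_threshold = count_threshold,
            class = c("fp_commit_table", "data.frame"))
}

#' Fit the logistic commit model
#'
#' Maximum-likelihood logistic regression of the first-attempt commit
#' outcome on covariates evaluated at the commit decision, via iteratively
#' reweighted least squares, with the gradient max-norm verified below
#' `1e-8`. Continuous covariates are standardized (unweighted mean 0, SD 1
#' across fish) so coefficients are per-SD log odds ratios; an intercept is
#' always included.
#'
#' @param table an `fp_commit_table`.
#' @param covariates covariate columns (may be empty: intercept-only).
#' @param standardize standardize continuous covariates first.
#' @return object of class `fp_commit_fit`: list with `beta` (including
#'   `(Intercept)`), `vcov`, `loglik`, `aicc`, `n`, `scaling`, `covariates`,
#'   `converged`.
#' @export
fit_commit <- function(table, covariates, standardize = TRUE) {
  if (!"committed" %in% names(table)) {
    stop("`table` must have a `committed` column", call. = FALSE)
  }
  y <- table$committed
  if (length(unique(y)) < 2) {
    stop_fit("both commit outcomes must be present")
  }
  scaling <- NULL
  if (standardize && length(covariates)) {
    tb <- table
    tb$start <- 0; tb$stop <- 1  # equal weights
    tb <- standardize_covariates(tb, covariates)
    scaling <- attr(tb, "scaling")
    table <- tb
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(table[covariates]))
  storage.mode(X) <- "double"
  if (qr(X)$rank < ncol(X)) {
    stop_fit("rank-deficient design in commit model")
  }
  fit <- glm.fit(X, y, family = binomial(),
                 control = list(epsilon = 1e-12, maxit = 100))
  beta <- coef(fit)
  if (any(abs(beta[-1]) > 20) || !fit$converged) {
    stop_fit("commit model did not converge (possible complete separation)")
  }
  p_hat <- fit$fitted.values
  grad <- drop(crossprod(X, y - p_hat))
  if (max(abs(grad)) > 1e-8) {
    stop_fit(sprintf("gradient max-norm %.2e exceeds 1e-8", max(abs(grad))))
  }
  W <- p_hat * (1 - p_hat)
  info <- crossprod(X, X * W)
  vcov <- solve(info)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  ll <- sum(dbinom(y, 1, p_hat, log = TRUE))
  k <- ncol(X); n <- length(y)
  aicc <- -2 * ll + 2 * k +
    if (n > k + 1) 2 * k * (k + 1) / (n - k - 1) else Inf
  structure(list(beta = beta, vcov = vcov, loglik = ll, aicc = aicc,
                 n = n, scaling = scaling, covariates = covariates,
                 converged = TRUE),
            class = "fp_commit_fit")
}

#' @export
print.fp_commit_fit <- function(x, ...) {
  cat(sprintf("<fp_commit_fit> n = %d\n", x$n))
  print(data.frame(beta = round(x$beta, 4),
                   se = round(sqrt(diag(x$vcov)), 4)))
  cat(sprintf("  log-likelihood %.3f, AICc %.2f\n", x$loglik, x$aicc))
  invisible(x)
}

# fitted commit probabilities for a (raw-scale) table
commit_probs <- function(fit, table) {
  if (!is.null(fit$scaling)) table <- apply_scaling(table, fit$scaling)
  X <- cbind(1, as.matrix(table[fit$covariates]))
  storage.mode(X) <- "double"
  plogis(drop(X %*% fit$beta))
}

#' Predict the commit rate under a density scenario
#'
#' Multiplies the raw count covariate by `density_factor`, recomputes the
#' threshold indicator if one is attached, re-standardizes with the fit's
#' stored scaling record, and averages the fitted commit probabilities over
#' the supplied rows. `density_factor = 1` reproduces the in-sample mean
#' fitted probability.
#'
#' @param fit an `fp_commit_fit`.
#' @param table an `fp_commit_table` on the raw scale.
#' @param density_factor non-negative multiplier on the count covariate.
#' @return mean predicted commit probability (scalar).
#' @export
predict_commit_rate <- function(fit, table, density_factor = 1) {
  if (density_factor < 0) stop("`density_factor` must be >= 0", call. = FALSE)
  if ("count" %in% names(table)) {
    table$count <- table$count * density_factor
    thr <- attr(table, "count_threshold")
    if (!is.null(thr) && "count_low" %in% names(table)) {
      table$count_low <- as.numeric(table$count <= thr)
      if (all(table$count_low == 1)) {
        warning("density factor ", density_factor, " puts every day under ",
                "the count threshold; predictions are unreliable")
      }
    }
  }
  mean(commit_probs(fit, table))
}
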