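#' Fit a proportional-hazards model on counting-process data
#'
#' Maximizes the Cox partial likelihood with the Breslow approximation for
#' ties (Efron available) over risk sets defined by `(start, stop]`
#' intervals, by Newton--Raphson with step-halving. Convergence requires the
#' score vector's max-norm below `1e-6` and a relative log-likelihood change
#' below `1e-10`. The covariance matrix is the inverse observed information;
#' AICc uses the number of events as the effective sample size,
#' \eqn{AICc = -2\ell + 2k + 2k(k+1)/(n_{ev} - k - 1)}.
#'
#' Continuous covariates are standardized to exposure-weighted mean 0, SD 1
#' before fitting (see [standardize_covariates()]); coefficients are
#' per-SD log hazard ratios so their magnitudes are comparable across
#' covariates. Monotone likelihoods (separation) and rank-deficient designs
#' raise errors of class `fp_fit_error`.
#'
#' @param data an `fp_riskset` (or data.frame with `id`, `start`, `stop`,
#'   `event` and covariate columns).
#' @param covariates character vector of covariate columns; may be empty for
#'   a baseline-only model.
#' @param standardize standardize continuous covariates before fitting
#'   (default `TRUE`). Set `FALSE` when the columns are already on the scale
#'   the coefficients should refer to.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param max_iter Newton--Raphson iteration cap.
#' @return object of class `fp_ph_fit`: list with `beta`, `vcov`, `loglik`,
#'   `loglik_null`, `aicc`, `n_subjects`, `n_events`, `scaling`,
#'   `covariates`, `ties`, `iterations`, `score_norm`, `converged`.
#' @export
fit_ph <- function(data, covariates, standardize = TRUE,
                   ties = c("breslow", "efron"), max_iter = 30) {
  ties <- match.arg(ties)
  check_riskset(data)
  if (sum(data$event) < 1) {
    stop_fit("at least one event is required to fit a PH model")
  }
  scaling <- NULL
  if (standardize && length(covariates)) {
    data <- standardize_covariates(data, covariates)
    scaling <- attr(data, "scaling")
  }
  X <- as.matrix(data[covariates])
  storage.mode(X) <- "double"
  p <- length(covariates)
  if (p > 0) {
    qx <- qr(X)
    if (qx$rank < p) {
      dropped <- covariates[qx$pivot[(qx$rank + 1):p]]
      stop_fit(paste0("rank-deficient design; collinear covariate(s): ",
                      paste(dropped, collapse = ", ")))
    }
  }

  beta <- rep(0, p)
  q <- ph_quantities(data$start, data$stop, data$event, X, beta, ties)
  loglik_null <- q$loglik
  iter <- 0L; converged <- p == 0L || max(abs(q$score)) < 1e-6
  while (p > 0 && !converged && iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(q$info, q$score), error = function(e)
      stop_fit("singular information matrix (possible separation)"))
    new_beta <- beta + step
    halved <- 0L
    q_new <- ph_quantities(data$start, data$stop, data$event, X, new_beta,
                           ties)
    # non-strict acceptance: near the optimum the Newton step may change
    # the log likelihood by less than machine precision
    while ((!is.finite(q_new$loglik) ||
            q_new$loglik < q$loglik - 1e-12) && halved < 20L) {
      halved <- halved + 1L
      new_beta <- beta + step / 2^halved
      q_new <- ph_quantities(data$start, data$stop, data$event, X, new_beta,
                             ties)
    }
    if (any(abs(new_beta) > 20)) {
      stop_fit(paste0("coefficient diverging (|beta| > 20) -- monotone ",
                      "partial likelihood / separation; covariates: ",
                      paste(covariates, collapse = ", ")))
    }
    rel <- abs(q_new$loglik - q$loglik) /
      max(abs(q$loglik), .Machine$double.eps)
    beta <- new_beta; q <- q_new
    converged <- max(abs(q$score)) < 1e-6 &&
      (rel < 1e-10 || halved == 0L)
  }
  if (!converged) {
    stop_fit(sprintf("Newton-Raphson did not converge in %d iterations (score max-norm %.2e)",
                     max_iter, if (p > 0) max(abs(q$score)) else 0))
  }
  vcov <- if (p > 0) solve(q$info) else matrix(0, 0, 0)
  dimnames(vcov) <- list(covariates, covariates)
  n_events <- sum(data$event)
  aicc <- -2 * q$loglik + 2 * p +
    if (n_events > p + 1) 2 * p * (p + 1) / (n_events - p - 1) else Inf
  structure(list(
    beta = setNames(beta, covariates), vcov = vcov,
    loglik = q$loglik, loglik_null = loglik_null, aicc = aicc,
    n_subjects = length(unique(data$id)), n_events = n_events,
    scaling = scaling, covariates = covariates, ties = ties,
    iterations = iter,
    score_norm = if (p > 0) max(abs(q$score)) else 0,
    converged = converged
  ), class = "fp_ph_fit")
}

stop_fit <- function(msg) {
  stop(structure(class = c("fp_fit_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

check_riskset <- function(data) {
  need <- c("id", "start", "stop", "event")
  if (!all(need %in% names(data))) {
    stop("risk-set data needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(data$start >= data$stop)) {
    stop("risk-set intervals must have start < stop", call. = FALSE)
  }
  invisible(data)
}

#' @export
print.fp_ph_fit <- function(x, ...) {
  cat(sprintf("<fp_ph_fit> %d subjects, %d events, %s ties\n",
              x$n_subjects, x$n_events, x$ties))
  if (length(x$beta)) {
    se <- sqrt(diag(x$vcov))
    tab <- data.frame(beta = round(x$beta, 4), se = round(se, 4))
    print(tab)
  } else cat("  (baseline-only model)\n")
  cat(sprintf("  log partial likelihood %.3f, AICc %.2f\n", x$loglik, x$aicc))
  invisible(x)
}

# Partial-likelihood value, score, observed information and per-event-time
# risk sums for counting-process data. Risk set at event time t: rows with
# start < t <= stop. Vectorized via range scatter-adds over the sorted
# unique event times.
ph_quantities <- function(start, stop, event, X, beta, ties = "breslow") {
  et <- stop[event == 1]
  ut <- sort(unique(et))
  J <- length(ut)
  d <- tabulate(match(et, ut), J)
  p <- ncol(X)
  eta <- if (p > 0) drop(X %*% beta) else numeric(length(start))
  w <- exp(eta)
  a <- findInterval(start, ut)   # at risk for event-time indices (a, b]
  b <- findInterval(stop, ut)

  # one matrix scatter-add for S0, all S1 columns and the upper triangle of S2
  ii <- unlist(lapply(seq_len(p), function(i) i:p))
  jj <- rep(seq_len(p), times = rev(seq_len(max(p, 1)))[seq_len(p)])
  V <- cbind(w, if (p > 0) w * X,
             if (p > 0) w * X[, jj, drop = FALSE] * X[, ii, drop = FALSE])
  S <- range_sums_mat(a, b, V, J)
  S0 <- S[, 1]
  S1 <- S[, 1 + seq_len(p), drop = FALSE]

  ev <- event == 1
  if (ties == "breslow" || all(d == 1)) {
    loglik <- sum(eta[ev]) - sum(d * log(S0))
    if (p == 0) {
      return(list(loglik = loglik, score = numeric(0),
                  info = matrix(0, 0, 0), ut = ut, d = d, S0 = S0, S1 = S1))
    }
    xbar <- S1 / S0
    score <- colSums(X[ev, , drop = FALSE]) - colSums(d * xbar)
    info <- matrix(0, p, p)
    S2 <- S[, 1 + p + seq_along(ii), drop = FALSE]
    for (k in seq_along(ii)) {
      v <- sum(d * (S2[, k] / S0 - xbar[, ii[k]] * xbar[, jj[k]]))
      info[ii[k], jj[k]] <- v; info[jj[k], ii[k]] <- v
    }
    return(list(loglik = loglik, score = score, info = info,
                ut = ut, d = d, S0 = S0, S1 = S1))
  }
  efron_quantities(start, stop, event, X, beta, ut, d, eta, w, a, b, S0, S1)
}

# Efron tie correction: within a group of d tied events the l-th denominator
# subtracts (l-1)/d of the tied subjects' own risk contributions.
efron_quantities <- function(start, stop, event, X, beta, ut, d, eta, w,
                             a, b, S0, S1) {
  p <- ncol(X)
  J <- length(ut)
  loglik <- sum(eta[event == 1])
  score <- if (p > 0) colSums(X[event == 1, , drop = FALSE]) else numeric(0)
  info <- matrix(0, p, p)
  S2 <- array(0, c(J, p, p))
  rsum <- function(v) range_sums(a, b, v, J)
  if (p > 0) for (i in seq_len(p)) for (j in i:p) {
    S2[, i, j] <- S2[, j, i] <- rsum(w * X[, i] * X[, j])
  }
  for (jj in seq_len(J)) {
    tied <- which(event == 1 & stop == ut[jj])
    W0 <- sum(w[tied])
    W1 <- if (p > 0) colSums(w[tied] * X[tied, , drop = FALSE]) else numeric(0)
    W2 <- matrix(0, p, p)
    if (p > 0) for (i in seq_len(p)) for (k in i:p) {
      W2[i, k] <- W2[k, i] <- sum(w[tied] * X[tied, i] * X[tied, k])
    }
    for (l in seq_len(d[jj])) {
      f <- (l - 1) / d[jj]
      D0 <- S0[jj] - f * W0
      loglik <- loglik - log(D0)
      if (p > 0) {
        D1 <- S1[jj, ] - f * W1
        score <- score - D1 / D0
        D2 <- S2[jj, , ] - f * W2
        info <- info + D2 / D0 - tcrossprod(D1 / D0)
      }
    }
  }
  list(loglik = loglik, score = score, info = info,
       ut = ut, d = d, S0 = S0, S1 = S1)
}

# sum of v over rows covering each index j in (a, b], via difference array
range_sums <- function(a, b, v, J) {
  drop(range_sums_mat(a, b, matrix(v, ncol = 1), J))
}

# column-wise version: V is rows x m; result J x m
range_sums_mat <- function(a, b, V, J) {
  keep <- b > a
  m <- ncol(V)
  if (!any(keep) || J == 0) return(matrix(0, J, m))
  A <- matrix(0, J + 1L, m)
  add <- rowsum(V[keep, , drop = FALSE], a[keep] + 1L)
  A[as.integer(rownames(add)), ] <- add
  sub <- rowsum(V[keep, , drop = FALSE], b[keep] + 1L)
  idx <- as.integer(rownames(sub))
  A[idx, ] <- A[idx, , drop = FALSE] - sub
  apply(A, 2, cumsum)[seq_len(J), , drop = FALSE]
}
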