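#' Read and write the standard input tables
#'
#' Plain-CSV interchange for the three input tables. Times are hours from
#' the season origin; dates are day indices from the origin. Each writer
#' documents the layout in `#`-prefixed header lines, which the readers
#' skip.
#'
#' @param x the object to write.
#' @param path file path.
#' @name fp_io
NULL

#' @rdname fp_io
#' @export
write_cohort_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# telemetry event table: one row per fish",
               "# t_* columns are hours from the season origin (NA = missing)"),
             con)
  write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname fp_io
#' @export
read_cohort_csv <- function(path) {
  out <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("fish_id", "species", "run", "dam", "fishway",
            "t_tailrace_entry", "t_first_fishway_entry",
            "t_last_fishway_entry", "t_fishway_exit")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("cohort file ", path, " missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- with(out, which(
    (!is.na(t_tailrace_entry) & !is.na(t_first_fishway_entry) &
       t_tailrace_entry > t_first_fishway_entry) |
      (!is.na(t_first_fishway_entry) & !is.na(t_last_fishway_entry) &
         t_first_fishway_entry > t_last_fishway_entry) |
      (!is.na(t_last_fishway_entry) & !is.na(t_fishway_exit) &
         t_last_fishway_entry > t_fishway_exit)))
  if (length(bad)) {
    stop("cohort file ", path, ": timestamps out of order at data row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  class(out) <- c("fp_cohort", "data.frame")
  out
}

#' @rdname fp_io
#' @export
write_counts_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# daily observer counts: day is days from the season origin",
             con)
  write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' @rdname fp_io
#' @export
read_counts_csv <- function(path) {
  out <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("day", "dam", "species", "count")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("count file ", path, " missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(out$count < 0)) stop("count file ", path,
                               ": negative counts", call. = FALSE)
  out
}

#' @rdname fp_io
#' @export
write_covariates_csv <- function(x, path) {
  stopifnot(inherits(x, "fp_covariates"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# daily environmental covariates; day is days from origin",
               sprintf("# origin=%s n_days=%d day_window=%g-%g",
                       x$origin, x$n_days, x$day_window[1], x$day_window[2])),
             con)
  write.csv(x$daily, con, row.names = FALSE)
  invisible(path)
}

#' @rdname fp_io
#' @export
read_covariates_csv <- function(path) {
  hdr <- readLines(path, n = 5)
  meta <- grep("origin=", hdr, value = TRUE)
  m <- regmatches(meta, regexec(
    "origin=(\\S+) n_days=(\\d+) day_window=([0-9.]+)-([0-9.]+)", meta))[[1]]
  if (length(m) != 5) stop("covariate file ", path,
                           " missing metadata header", call. = FALSE)
  daily <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  env <- list(n_days = as.integer(m[3]), daily = daily,
              day_window = as.numeric(m[4:5]),
              counts = data.frame(day = integer(), dam = character(),
                                  species = character(), count = integer()),
              origin = m[2])
  class(env) <- "fp_covariates"
  env
}

#' @rdname fp_io
#' @export
write_riskset_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# counting-process intervals: (start, stop] hours since each subject's stage entry",
               sprintf("# stage=%s", attr(x, "stage") %||% "unknown")), con)
  write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname fp_io
#' @export
read_riskset_csv <- function(path) {
  out <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  check_riskset(out)
  class(out) <- c("fp_riskset", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a fitted model to JSON
#'
#' Writes coefficients on both the standardized scale (per SD, as fitted)
#' and the natural scale (per raw covariate unit), with the scaling record
#' embedded so either can be reconstructed.
#'
#' @param fit an `fp_ph_fit` or `fp_commit_fit`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  beta <- fit$beta
  nat <- beta
  if (!is.null(fit$scaling)) {
    for (k in seq_len(nrow(fit$scaling))) {
      nm <- fit$scaling$covariate[k]
      if (!fit$scaling$binary[k] && nm %in% names(nat)) {
        nat[nm] <- beta[nm] / fit$scaling$sd[k]
      }
    }
  }
  obj <- list(
    class = class(fit),
    coefficients_standardized = as.list(beta),
    coefficients_natural = as.list(nat),
    se = as.list(setNames(sqrt(diag(fit$vcov)), colnames(fit$vcov))),
    loglik = fit$loglik, aicc = fit$aicc,
    n_events = fit$n_events %||% NULL, n = fit$n %||% NULL,
    scaling = fit$scaling
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Serialize the generator ground truth to JSON
#'
#' Sidecar recording every generating parameter, for recovery tests against
#' simulated datasets.
#'
#' @param truth an `fp_truth`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- lapply(unclass(truth), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Serialize a bootstrap result
#'
#' Full draw vectors included; written gzip-compressed when `path` ends in
#' `.gz`, plain JSON otherwise.
#'
#' @param x an `fp_bootstrap_result` or `fp_bootstrap_ci`.
#' @param path output path.
#' @export
write_bootstrap_json <- function(x, path) {
  obj <- unclass(x)
  obj$full_fit <- NULL
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(txt, con)
  invisible(path)
}
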