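#' Define the analysis configuration
#'
#' A configuration is a list of model definitions plus global settings. Each
#' model definition is a list with fields:
#' \describe{
#'   \item{name}{unique label.}
#'   \item{species, process}{required; `process` is `"finding"`,
#'     `"fishway"` or `"commit"`.}
#'   \item{dam, run, fishway}{optional subset filters (`NULL` = pooled).}
#'   \item{covariates}{full-model covariate set; must contain the count
#'     covariate.}
#'   \item{null_candidates}{list of candidate null covariate sets; default
#'     the single set `covariates` minus the count covariate. Their union
#'     plus the count covariate must equal `covariates`.}
#'   \item{count_threshold}{optional threshold (e.g. 150) adding the binary
#'     `count_low` covariate, conventionally part of the null model.}
#'   \item{scenarios}{logical: run density scenarios for this model.}
#' }
#'
#' @param models list of model definitions.
#' @param B_null,B_ci bootstrap replicate counts (2000 at report scale);
#'   `B_ci = 0` skips confidence intervals.
#' @param min_cohort minimum fish per model; smaller cohorts are dropped
#'   with a notice (default 100 -- comfortably above the conventional
#'   discard, below any fitted model's size).
#' @param scenario_factors density factors for flagged models.
#' @param n_scenario_rep simulated cohorts per scenario (192 at report
#'   scale).
#' @param count_name name of the density covariate.
#' @param seed master seed for the pipeline.
#' @return object of class `fp_config`.
#' @export
analysis_config <- function(models, B_null = 2000, B_ci = 2000,
                            min_cohort = 100,
                            scenario_factors = c(0, 0.5, 1, 1.5, 2),
                            n_scenario_rep = 192,
                            count_name = "count", seed = 1L) {
  stopifnot(is.list(models), length(models) > 0)
  nms <- vapply(models, function(m) m$name %||% "", "")
  if (anyDuplicated(nms) || any(nms == "")) {
    stop("every model needs a unique `name`", call. = FALSE)
  }
  for (m in models) {
    if (is.null(m$species) || is.null(m$process) ||
        !m$process %in% c("finding", "fishway", "commit")) {
      stop("model `", m$name, "`: `species` and a valid `process` required",
           call. = FALSE)
    }
    if (is.null(m$covariates) || !count_name %in% m$covariates) {
      stop("model `", m$name, "`: `covariates` must contain `", count_name,
           "`", call. = FALSE)
    }
    cand <- m$null_candidates %||%
      list(setdiff(m$covariates, count_name))
    un <- sort(unique(unlist(c(cand, count_name))))
    if (!identical(un, sort(unique(m$covariates)))) {
      stop("model `", m$name, "`: union of null candidates plus `",
           count_name, "` must equal the full covariate set", call. = FALSE)
    }
  }
  structure(list(models = models, B_null = B_null, B_ci = B_ci,
                 min_cohort = min_cohort,
                 scenario_factors = scenario_factors,
                 n_scenario_rep = n_scenario_rep,
                 count_name = count_name, seed = seed),
            class = "fp_config")
}

model_filter <- function(fish, m) {
  sel <- fish$species == m$species
  for (f in c("dam", "run", "fishway")) {
    if (!is.null(m[[f]])) sel <- sel & fish[[f]] == m[[f]]
  }
  sel & !is.na(sel)
}

#' Split the cohort into per-model subsets
#'
#' Assigns fish to each configured model by dam / species / run / fishway
#' labels, verifies that subsets are disjoint within each species-process
#' family (structurally identical models on disjoint data), and drops
#' cohorts below the configured minimum size with a logged notice.
#'
#' @param fish an `fp_cohort`.
#' @param config an `fp_config`.
#' @return named list of per-model cohorts; attribute `"dropped"` is a
#'   data.frame of dropped models and their sizes.
#' @export
split_models <- function(fish, config) {
  stopifnot(inherits(config, "fp_config"))
  sel <- lapply(config$models, model_filter, fish = fish)
  names(sel) <- vapply(config$models, `[[`, "", "name")
  fam <- vapply(config$models, function(m) paste(m$species, m$process), "")
  for (f in unique(fam)) {
    grp <- which(fam == f)
    if (length(grp) > 1) {
      hits <- Reduce(`+`, lapply(sel[grp], as.integer))
      if (any(hits > 1)) {
        stop("overlapping subset filters within family `", f, "`",
             call. = FALSE)
      }
    }
  }
  cohorts <- lapply(sel, function(s) {
    out <- fish[s, , drop = FALSE]
    class(out) <- c("fp_cohort", "data.frame")
    out
  })
  sizes <- vapply(cohorts, nrow, integer(1))
  drop <- sizes < config$min_cohort
  if (any(drop)) {
    for (nm in names(cohorts)[drop]) {
      message("model `", nm, "` dropped: n = ", sizes[nm], " < minimum ",
              config$min_cohort)
    }
  }
  out <- cohorts[!drop]
  attr(out, "dropped") <- data.frame(model = names(cohorts)[drop],
                                     n = unname(sizes[drop]))
  out
}

#' Run the full analysis pipeline
#'
#' For every configured model: build the stage data (risk sets or commit
#' table), select the null model by AICc among the candidate covariate
#' sets, fit the full model, run the parametric-bootstrap null test and the
#' full-model bootstrap confidence interval, and (for flagged models)
#' density scenarios. A failure in one model is isolated: the report
#' records the error and the remaining models still run. Deterministic
#' given the configuration seed.
#'
#' @param fish an `fp_cohort`.
#' @param env an `fp_covariates` with the needed count series attached.
#' @param config an `fp_config`.
#' @return object of class `fp_report`: list with `models` (per-model
#'   results), `table` (one row per fitted model: species, process, dam,
#'   subset, n, p-value, CI), `dropped`, `excluded`, and `meta`.
#' @export
run_pipeline <- function(fish, env, config) {
  stopifnot(inherits(config, "fp_config"))
  set.seed(config$seed)
  cohorts <- split_models(fish, config)
  keep <- vapply(config$models, function(m) m$name %in% names(cohorts),
                 logical(1))
  models <- config$models[keep]
  results <- list()
  rows <- list()
  for (m in models) {
    seed_m <- sample.int(2^31 - 2, 1)
    res <- tryCatch(
      run_one_model(cohorts[[m$name]], env, m, config, seed_m),
      error = function(e) list(error = conditionMessage(e))
    )
    results[[m$name]] <- res
    rows[[m$name]] <- data.frame(
      model = m$name, species = m$species, process = m$process,
      dam = m$dam %||% ".", subset = m$run %||% m$fishway %||% ".",
      n = if (is.null(res$n)) NA_integer_ else res$n,
      observed = res$test$observed_coefficient %||% NA_real_,
      p_value = res$test$p_value %||% NA_real_,
      ci_lower = res$ci$lower %||% NA_real_,
      ci_upper = res$ci$upper %||% NA_real_,
      unreliable = res$test$unreliable %||% NA,
      error = res$error %||% "",
      stringsAsFactors = FALSE
    )
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(
    models = results, table = table,
    dropped = attr(cohorts, "dropped"),
    meta = list(seed = config$seed, B_null = config$B_null,
                B_ci = config$B_ci, n_input = nrow(fish),
                n_tests = nrow(table),
                package_version = as.character(utils::packageVersion("fishpass")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), class = "fp_report")
}

run_one_model <- function(cohort, env, m, config, seed) {
  count_name <- config$count_name
  if (m$process == "commit") {
    covs <- setdiff(unique(unlist(c(m$null_candidates, m$covariates))),
                    "count_low")
    data <- build_commit_table(cohort, env, covariates = covs,
                               count_threshold = m$count_threshold)
  } else {
    stage <- if (m$process == "finding") "finding" else "fishway"
    covs <- setdiff(unique(unlist(c(m$null_candidates, m$covariates))),
                    "count_low")
    data <- build_counting_process(cohort, env, stage = stage,
                                   covariates = covs,
                                   count_threshold = m$count_threshold)
  }
  cand <- m$null_candidates %||% list(setdiff(m$covariates, count_name))
  null <- select_null_model(data, cand, count_name = count_name)
  test <- null_bootstrap_test(null$fit, m$covariates, data,
                              B = config$B_null, seed = seed,
                              count_name = count_name)
  ci <- if (config$B_ci >= 199) {
    full_model_bootstrap_ci(test$full_fit, data, B = config$B_ci,
                            seed = seed + 1L, count_name = count_name)
  }
  scen <- NULL
  if (isTRUE(m$scenarios)) {
    if (m$process == "commit") {
      scen <- commit_scenarios(test$full_fit, data,
                               factors = config$scenario_factors)
    } else {
      base <- breslow_baseline(test$full_fit, data)
      scen <- lapply(config$scenario_factors, function(f) {
        run_density_scenario(test$full_fit, base, data, factor = f,
                             n_rep = config$n_scenario_rep,
                             seed = seed + 2L)
      })
    }
  }
  n <- if (m$process == "commit") nrow(data) else length(unique(data$id))
  list(n = n, null = null, test = test, ci = ci, scenarios = scen,
       excluded = attr(data, "excluded"))
}

#' @export
print.fp_report <- function(x, ...) {
  cat(sprintf("<fp_report> %d models (%d tests, p-values not corrected for multiplicity)\n",
              length(x$models), x$meta$n_tests))
  print(x$table[c("model", "species", "process", "dam", "subset", "n",
                  "p_value", "ci_lower", "ci_upper")])
  if (nrow(x$dropped)) {
    cat("dropped (below minimum size):",
        paste(x$dropped$model, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read an analysis report
#'
#' The JSON report round-trips: reading it back yields an equal summary
#' table. Full per-model objects (draw vectors, fits) are summarized, not
#' embedded.
#'
#' @param report an `fp_report`.
#' @param path JSON file path.
#' @export
write_report <- function(report, path) {
  obj <- list(table = report$table, dropped = report$dropped,
              meta = report$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$table <- as.data.frame(obj$table, stringsAsFactors = FALSE)
  if (is.null(obj$table$error)) obj$table$error <- ""
  obj$table$error[is.na(obj$table$error)] <- ""
  obj
}
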