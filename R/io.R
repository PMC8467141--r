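# CSV + config loading and the end-to-end run pipeline behind the
# command-line interface (inst/cli/gphurdle.R).

#' Build a run configuration
#'
#' @param input path to the input CSV (header row required).
#' @param response name of the count response column.
#' @param count_columns covariate columns for the count part; default: all
#'   non-response columns.
#' @param zero_columns covariate columns for the zero part; default: same as
#'   `count_columns` (the two parts may share covariates).
#' @param coding named list mapping categorical columns to explicit
#'   level-to-number maps, e.g.
#'   `list(frequency = c(Often = 1, Occas = 2))`. Coding is never inferred:
#'   fitted coefficients depend on it, so it must be stated.
#' @param model `"gphr"`, `"ph"` or `"gp"`.
#' @param estimator `"ml"` or `"gmm"` (GMM is initialized at the ML
#'   estimate).
#' @param weight_strategy GMM weight strategy, see [gmm_spec()].
#' @param bootstrap_B bootstrap replicates for standard errors; 0 disables
#'   bootstrap inference (ML then falls back to observed-information SEs).
#' @param seed integer seed for the bootstrap.
#' @param level Wald significance level.
#' @param nm an [nm_config()].
#' @param output path prefix for the report files (`<output>.txt`,
#'   `<output>.json`); `NULL` writes no files.
#' @return a list of class `run_config`.
#' @export
run_config <- function(input, response, count_columns = NULL,
                       zero_columns = NULL, coding = list(),
                       model = c("gphr", "ph", "gp"),
                       estimator = c("ml", "gmm"),
                       weight_strategy = "identity",
                       bootstrap_B = 50, seed = 1L, level = 0.05,
                       nm = nm_config(), output = NULL) {
  model <- match.arg(model)
  estimator <- match.arg(estimator)
  structure(list(input = input, response = response,
                 count_columns = count_columns,
                 zero_columns = zero_columns, coding = coding,
                 model = model, estimator = estimator,
                 weight_strategy = weight_strategy,
                 bootstrap_B = bootstrap_B, seed = as.integer(seed),
                 level = level, nm = nm, output = output),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Accepts the same keys as [run_config()]; `coding` is a nested map, and
#' `nm` may override individual [nm_config()] fields.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  # keep YAML-1.1 single-letter booleans (y/n) as strings: "y" is a common
  # column name, while true/false still parse as logicals
  raw <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x)
      if (tolower(x) %in% c("true", "yes", "on")) TRUE else x,
    "bool#no" = function(x)
      if (tolower(x) %in% c("false", "no", "off")) FALSE else x))
  nm <- do.call(nm_config, raw$nm %||% list())
  coding <- lapply(raw$coding %||% list(), unlist)
  run_config(input = raw$input, response = raw$response,
             count_columns = raw$count_columns,
             zero_columns = raw$zero_columns, coding = coding,
             model = raw$model %||% "gphr",
             estimator = raw$estimator %||% "ml",
             weight_strategy = raw$weight_strategy %||% "identity",
             bootstrap_B = raw$bootstrap_B %||% 50,
             seed = raw$seed %||% 1L, level = raw$level %||% 0.05,
             nm = nm, output = raw$output)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a CSV into a count dataset
#'
#' Validates the response (finite non-negative integers; offending rows are
#' named in the error), applies the explicit categorical coding map, builds
#' intercept-first design matrices for both model parts, and logs the
#' summary quantities (n, zero count and share, mean, variance) as a
#' message.
#'
#' @param path CSV path.
#' @param config a [run_config()] (its `input` field is ignored in favour of
#'   `path`).
#' @return a [count_dataset()].
#' @export
load_dataset <- function(path, config) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- unique(c(config$response, config$count_columns,
                   config$zero_columns, names(config$coding)))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  y_raw <- df[[config$response]]
  y_num <- suppressWarnings(as.numeric(y_raw))
  bad <- which(!is.finite(y_num) | y_num < 0 | y_num != floor(y_num))
  if (length(bad))
    stop("response '", config$response, "' must be a non-negative integer; ",
         "offending row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  for (col in names(config$coding)) {
    map <- config$coding[[col]]
    lv <- as.character(df[[col]])
    unmapped <- setdiff(unique(lv), names(map))
    if (length(unmapped))
      stop("column '", col, "' has unmapped level(s): ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    df[[col]] <- unname(map[lv])
  }
  xcols <- config$count_columns %||% setdiff(names(df), config$response)
  zcols <- config$zero_columns %||% xcols
  X <- cbind(1, as.matrix(df[, xcols, drop = FALSE]))
  Z <- cbind(1, as.matrix(df[, zcols, drop = FALSE]))
  colnames(X) <- c("(intercept)", xcols)
  colnames(Z) <- c("(intercept)", zcols)
  ds <- count_dataset(y_num, X, Z)
  message(sprintf(
    "loaded %s: n = %d, zeros = %d (%.1f%%), mean = %.4g, variance = %.4g",
    basename(path), ds$n, sum(ds$y == 0), 100 * mean(ds$y == 0),
    mean(ds$y), var(ds$y)))
  ds
}

#' Run a configured fit end to end
#'
#' Loads the data, fits the requested model and estimator (GMM starts from
#' the ML estimate), attaches bootstrap or observed-information inference,
#' and optionally writes a plain-text table plus a JSON report embedding the
#' full configuration and seed, so a run can be reproduced bit-identically.
#'
#' @param config a [run_config()].
#' @param dataset optional pre-loaded [count_dataset()]; skips the CSV load.
#' @return list with `fit`, `dataset`, `report` (the JSON-ready list).
#' @export
run_fit <- function(config, dataset = NULL) {
  if (is.null(dataset)) dataset <- load_dataset(config$input, config)
  fit <- if (config$estimator == "gmm") {
    if (config$model != "gphr")
      stop("GMM estimation is implemented for the GPHR model only",
           call. = FALSE)
    fit_gmm(dataset, spec = gmm_spec(weight_strategy = config$weight_strategy))
  } else {
    fit_ml(config$model, dataset, nm = config$nm)
  }
  if (config$bootstrap_B >= 2) {
    fit <- add_bootstrap_inference(fit, dataset, B = config$bootstrap_B,
                                   seed = config$seed, level = config$level)
  } else if (config$estimator == "ml") {
    se <- ml_observed_info_se(fit, dataset)
    wi <- wald_inference(unname(fit$theta), se, config$level)
    fit$se <- se; fit$ci_low <- wi$ci_low; fit$ci_high <- wi$ci_high
    fit$p_values <- wi$p_values
  }
  report <- list(
    config = config[c("input", "response", "count_columns", "zero_columns",
                      "model", "estimator", "weight_strategy",
                      "bootstrap_B", "seed", "level")],
    n = dataset$n,
    zeros = sum(dataset$y == 0),
    coefficients = as.list(fit$theta),
    se = fit$se, ci_low = fit$ci_low, ci_high = fit$ci_high,
    p_values = fit$p_values,
    loglik = fit$loglik, aic = fit$aic, n_params = fit$n_params,
    converged = fit$converged)
  if (!is.null(config$output)) {
    jsonlite::write_json(report, paste0(config$output, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    writeLines(format_fit_table(fit), paste0(config$output, ".txt"))
  }
  list(fit = fit, dataset = dataset, report = report)
}

#' Render a fit as a plain-text coefficient table
#'
#' One row per coefficient: estimate with Wald interval, standard error with
#' p-value, followed by the log-likelihood and AIC lines.
#'
#' @param fit a `gphr_fit`.
#' @return character vector of lines.
#' @export
format_fit_table <- function(fit) {
  nm <- names(fit$theta)
  lines <- c(sprintf("model: %s   estimator: %s", toupper(fit$model),
                     toupper(fit$estimator)),
             sprintf("%-10s %-22s %s", "term", "coefficient (95% CI)",
                     "SE (p-value)"))
  for (i in seq_along(nm)) {
    ci <- if (!is.null(fit$se))
      sprintf("%.2f (%.2f, %.2f)", fit$theta[i], fit$ci_low[i],
              fit$ci_high[i])
    else sprintf("%.2f", fit$theta[i])
    sep <- if (!is.null(fit$se))
      sprintf("%.2f (%.3g)", fit$se[i], fit$p_values[i])
    else ""
    lines <- c(lines, sprintf("%-10s %-22s %s", nm[i], ci, sep))
  }
  c(lines,
    sprintf("loglik: %.4f", fit$loglik),
    sprintf("AIC: %.2f%s", fit$aic,
            if (identical(fit$aic_type, "quasi")) " (quasi, at GMM estimate)"
            else ""))
}
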