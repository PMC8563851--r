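#' Read and write transient / estimate tables
#'
#' CSV (comma-separated, dot decimal, header row) is the exchange format:
#' ROI-level two-wavelength recordings are naturally tabular.  Numbers are
#' written with 17 significant digits so write-then-read round-trips are
#' exact.
#'
#' @name fura-io
NULL

stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("fura_parse_error", "error")))
}

TRANSIENT_COLS <- c("time", "adu340", "adu340_bg", "adu380", "adu380_bg")

parse_numeric_column <- function(df, col, path) {
  v <- trimws(as.character(df[[col]]))
  num <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(num) & !(v %in% c("NA", "")))
  if (length(bad))
    stop_parse("non-numeric value '", v[bad[1L]], "' in column '", col,
               "', line ", bad[1L] + 1L, " of ", path)
  num
}

#' @rdname fura-io
#' @param path file path.
#' @return `read_transient_csv()`: a [transient_series()].
#' @export
read_transient_csv <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(TRANSIENT_COLS, names(df))
  if (length(missing_cols))
    stop_parse("missing column(s) in ", path, ": ",
               paste(missing_cols, collapse = ", "))
  cols <- lapply(TRANSIENT_COLS, function(cl) parse_numeric_column(df, cl, path))
  names(cols) <- TRANSIENT_COLS
  tm <- cols$time
  if (length(tm) > 1L) {
    i <- which(diff(tm) <= 0)
    if (length(i))
      stop_parse("time not strictly increasing at line ", i[1L] + 2L,
                 " of ", path)
  }
  transient_series(tm, cols$adu340, cols$adu340_bg,
                   cols$adu380, cols$adu380_bg)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (!is.finite(v)) "" else formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}

write_csv_full <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
    if (is.logical(out[[nm]])) out[[nm]] <- tolower(as.character(out[[nm]]))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = ",", row.names = FALSE,
                       quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(errorCondition(paste0("cannot write ", path, ": ",
                               conditionMessage(ok)),
                        class = c("fura_io_error", "error")))
  invisible(path)
}

#' @rdname fura-io
#' @param sim a list with `series` and `true_ca`, as returned by
#'   [simulate_transient()]; `true_ca` is written as an extra column.
#' @export
write_transient_csv <- function(sim, path) {
  df <- as.data.frame(sim$series)
  if (!is.null(sim$true_ca)) df$true_ca <- sim$true_ca
  write_csv_full(df, path)
}

#' @rdname fura-io
#' @param estimates a `fura_estimates` data frame from
#'   [estimate_transient()]; rows are written in time order, invalid points
#'   with `valid=false` and empty estimate fields.
#' @export
write_estimates_csv <- function(estimates, path) {
  if (nrow(estimates) == 0L) stop_invalid("empty estimates")
  df <- as.data.frame(estimates)[order(estimates$time), , drop = FALSE]
  df[!df$valid, c("ca", "se_delta", "se_mc")] <- NA_real_
  write_csv_full(df, path)
}

#' @rdname fura-io
#' @export
read_estimates_csv <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("valid" %in% names(df) && !is.logical(df$valid))
    df$valid <- tolower(as.character(df$valid)) == "true"
  structure(df, class = c("fura_estimates", "data.frame"))
}

config_keys <- function() {
  c(names(FURA_DEFAULTS), "k_draws", "seed", "method", "grid")
}

config_defaults <- function() {
  c(FURA_DEFAULTS,
    list(k_draws = 10000L, seed = 1L, method = "both",
         grid = list(span = 30, by = 0.15)))
}

#' Load a run configuration
#'
#' Reads a JSON (or YAML, when the `yaml` package is installed)
#' configuration with flat keys `r_min`, `r_max`, `k_eff`, `k_fura`,
#' `fura_total_phi`, `t_340`, `t_380`, `p_roi`, `p_bg`, `gain`,
#' `readout_variance`, `f340_bg`, `f380_bg`, `t0`, `ca0`, `delta`, `tau`,
#' `k_draws`, `seed`, `method` and `grid` (`span`/`by`, or explicit
#' `times`).  Unset keys fall back to the packaged defaults
#' ([fura_default_params()]); every defaulted key is reported via
#' `message()`.  Unknown keys produce a warning, not an error.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file, or `NULL` for the
#'   pure defaults.
#' @return a list of class `fura_config` with elements `acquisition`,
#'   `illumination`, `decay`, `k_draws`, `seed`, `method`, `grid`, `times`.
#' @export
load_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config("config file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    raw <- if (ext %in% c("yaml", "yml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop_config("YAML config requires the 'yaml' package; ",
                    "use JSON instead")
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    if (!is.list(raw)) stop_config("config must be a mapping/object")
  }
  unknown <- setdiff(names(raw), config_keys())
  if (length(unknown))
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "))
  cfg <- config_defaults()
  known <- intersect(names(raw), config_keys())
  cfg[known] <- raw[known]
  defaulted <- setdiff(config_keys(), known)
  if (length(defaulted))
    message("config: using packaged defaults for ",
            paste(defaulted, collapse = ", "))
  if (!cfg$method %in% c("delta", "mc", "both"))
    stop_config("method must be one of delta, mc, both (key 'method')")
  if (!is.numeric(cfg$k_draws) || cfg$k_draws < 2)
    stop_config("k_draws must be >= 2 (key 'k_draws')")
  parts <- tryCatch(list(
    acquisition = acquisition_params(
      calibration = calibration_params(cfg$r_min, cfg$r_max, cfg$k_eff,
                                       cfg$k_fura),
      ccd = ccd_params(cfg$gain, cfg$readout_variance),
      p_roi = cfg$p_roi, p_bg = cfg$p_bg,
      t_340 = cfg$t_340, t_380 = cfg$t_380),
    illumination = illumination_model(cfg$fura_total_phi, cfg$f340_bg,
                                      cfg$f380_bg),
    decay = decay_params(cfg$t0, cfg$ca0, cfg$delta, cfg$tau)
  ), fura_invalid_input = function(e)
    stop_config("invalid config value: ", conditionMessage(e)))
  times <- if (!is.null(cfg$grid$times)) as.numeric(cfg$grid$times) else
    decay_grid(parts$decay,
               span = if (is.null(cfg$grid$span)) 30 else cfg$grid$span,
               by = if (is.null(cfg$grid$by)) 0.15 else cfg$grid$by)
  structure(c(parts, list(
    k_draws = as.integer(cfg$k_draws), seed = as.integer(cfg$seed),
    method = cfg$method, grid = cfg$grid, times = times
  )), class = "fura_config")
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("fura_config_error", "error")))
}

#' Write a validation report as JSON (plus the residuals as CSV)
#'
#' @param report a `fura_validation` object from [run_validation()].
#' @param path output JSON path; the residuals go to the same path with a
#'   `_residuals.csv` suffix.
#' @return invisibly, the JSON path.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "fura_validation"))
  out <- list(
    n_points = report$n_points, seed = report$seed, k = report$k,
    se_method = report$se_method,
    residual_mean = report$mean, residual_sd = report$sd,
    sw_w = report$sw_w, sw_p = report$sw_p,
    band_95_ok = report$band_95_ok, band_99_ok = report$band_99_ok,
    bands = lapply(unname(report$bands), function(b)
      b[c("alpha", "inside", "max_deviation", "half_width", "band_method")])
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  res_path <- sub("\\.json$", "", path)
  write_csv_full(data.frame(time = report$estimates$time[report$estimates$valid],
                            residual = report$residuals),
                 paste0(res_path, "_residuals.csv"))
  invisible(path)
}
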