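#' Read and write growth-curve CSV files
#'
#' The interchange format is comma-delimited UTF-8 with a header row and
#' columns `condition, time_days, pd` (decimal point, times in days).
#' Rows are grouped by condition; within each condition times must be
#' strictly increasing.  Parse problems are reported with the offending
#' row number.
#'
#' @param path file path.
#' @return `read_growth_csv()`: named list of [growth_curve()] objects.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_growth_csv(list(growth_curve("a", 0:3, c(0, 1, 2, 3))), f)
#' read_growth_csv(f)
#' @export
read_growth_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "time_days", "pd")
  if (!all(need %in% names(df))) {
    stop("growth CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("time_days", "pd")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      stop(sprintf("non-numeric %s in row %d", col, bad[1] + 1),
           call. = FALSE)
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  out <- list()
  for (cond in unique(df$condition)) {
    sub <- df[df$condition == cond, ]
    d <- diff(sub$time_days)
    if (any(d <= 0)) {
      row_global <- which(df$condition == cond)[which(d <= 0)[1] + 1]
      stop(sprintf(
        "times not strictly increasing for condition '%s' at row %d",
        cond, row_global + 1), call. = FALSE)
    }
    out[[cond]] <- growth_curve(cond, sub$time_days, sub$pd)
  }
  out
}

#' @rdname read_growth_csv
#' @param curves list of [growth_curve()] objects.
#' @export
write_growth_csv <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(condition = cv$condition, time_days = cv$times, pd = cv$pd)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write marker-series CSV files
#'
#' Columns `marker, time_days, fraction_positive, n_counted`; one series
#' per marker, fractions validated to `[0, 1]`.
#'
#' @param path file path.
#' @return `read_marker_csv()`: named list of [marker_series()] objects.
#' @export
read_marker_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("marker", "time_days", "fraction_positive", "n_counted")
  if (!all(need %in% names(df))) {
    stop("marker CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (col in need[-1]) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      stop(sprintf("non-numeric %s in row %d", col, bad[1] + 1),
           call. = FALSE)
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  bad <- which(df$fraction_positive < 0 | df$fraction_positive > 1)
  if (length(bad)) {
    stop(sprintf("fraction_positive outside [0, 1] in row %d", bad[1] + 1),
         call. = FALSE)
  }
  out <- list()
  for (mk in unique(df$marker)) {
    sub <- df[df$marker == mk, ]
    out[[mk]] <- marker_series(mk, sub$time_days, sub$fraction_positive,
                               n_counted = sub$n_counted)
  }
  out
}

#' @rdname read_marker_csv
#' @param markers list of [marker_series()] objects.
#' @export
write_marker_csv <- function(markers, path) {
  df <- do.call(rbind, lapply(markers, function(m) {
    data.frame(marker = m$marker, time_days = m$times,
               fraction_positive = m$fraction_positive,
               n_counted = if (length(m$n_counted) == 1) {
                 rep(m$n_counted, length(m$times))
               } else m$n_counted)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- run configuration -------------------------------------------------

run_config_defaults <- function() {
  list(
    parameters = list(r = 0.5, f1 = 0, f2 = 0, f3 = 0, K = 1,
                      a = 39.6, b = 20, c = 1),
    protocol = list(kind = "none", gamma = 0, start = 1, duration = 0,
                    alpha = 0, beta = 0),
    initial = list(P = 1e5, C = 0, S = 0, F = 0),
    solver = list(t_end = 14, step = 0.5, rtol = 1e-8, atol = 1e-10,
                  extinction = TRUE, extinction_threshold = 1),
    fit = list(mode = "constant", n_starts = 16, seed = 1,
               r_fixed = 0.70, f2_fixed = 1, alpha = 0, beta = 0,
               what = "rates"),
    noise = list(pd_sd = 0.25, n_counted = 100, n_replicates = 3)
  )
}

#' Read a run configuration file
#'
#' A single YAML file with sections `parameters`, `protocol`, `initial`,
#' `solver`, `fit`, `noise`; unknown sections or keys are rejected with a
#' clear error, missing keys take package defaults.  Every CLI run echoes
#' the fully resolved configuration into its output directory for
#' provenance.
#'
#' @param path YAML file path (or `NULL` for pure defaults).
#' @return The resolved configuration (class `run_config`).
#' @export
read_run_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    for (sec in names(user)) {
      if (!sec %in% names(cfg)) {
        stop("unknown config section: ", sec, call. = FALSE)
      }
      for (key in names(user[[sec]])) {
        if (!key %in% names(cfg[[sec]])) {
          stop(sprintf("unknown config key: %s.%s", sec, key), call. = FALSE)
        }
        cfg[[sec]][[key]] <- user[[sec]][[key]]
      }
    }
  }
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param cfg a `run_config` object.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_params <- function(cfg) do.call(pcs_params, cfg$parameters)

config_protocol <- function(cfg) {
  p <- cfg$protocol
  switch(p$kind,
    none = stress_none(),
    pulse = stress_pulse(p$gamma, p$start, p$duration),
    constant = stress_constant(p$gamma),
    linear = stress_linear(p$alpha, p$beta),
    stop("unknown protocol kind: ", p$kind, call. = FALSE))
}

config_initial <- function(cfg) do.call(cell_state, cfg$initial)
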