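#' Write a tracer time course to CSV
#'
#' Fixed CSV dialect: comma-separated, `.` decimal separator, LF line
#' endings, UTF-8, with a provenance block of `#`-prefixed comment lines
#' (package version and, when available, the generating seed) ahead of the
#' header. Columns: `time_min, channel, protocol, replicate,
#' value_pct_of_added[, counts_bq]`.
#'
#' @param tc A `tracer_timecourse` or compatible data frame.
#' @param path Output file path.
#' @param seed Optional seed to record in the provenance block.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path, seed = NULL) {
  stopifnot(is.data.frame(tc))
  cols <- c("time_min", "channel", "protocol", "replicate",
            "value_pct_of_added")
  if (!all(cols %in% names(tc)))
    .stopf("missing column(s): %s",
           paste(setdiff(cols, names(tc)), collapse = ", "))
  if ("counts_bq" %in% names(tc)) cols <- c(cols, "counts_bq")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# periphos %s tracer time course",
            as.character(utils::packageVersion("periphos"))),
    if (!is.null(seed)) sprintf("# seed: %s", format(seed)),
    sprintf("# records: %d", nrow(tc))), con)
  utils::write.csv(as.data.frame(tc)[, cols], con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a tracer time course from CSV
#'
#' Counterpart of [write_timecourse()]; `write` then `read` round-trips a
#' generated table. Schema violations raise informative errors: a missing
#' column is named; non-numeric or negative values are reported with their
#' row numbers.
#'
#' @param path CSV file path (comment lines starting `#` are ignored).
#' @return A `tracer_timecourse` data frame.
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character")
  req <- c("time_min", "channel", "protocol", "replicate",
           "value_pct_of_added")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    .stopf("schema error: missing column '%s'", miss[1])
  num_cols <- c("time_min", "replicate", "value_pct_of_added",
                intersect("counts_bq", names(df)))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & !(df[[cl]] %in% c("NA", "")))
    if (length(bad) > 0)
      .stopf("non-numeric '%s' value in row(s) %s", cl,
             paste(utils::head(bad, 5), collapse = ", "))
    df[[cl]] <- v
  }
  if (!all(df$channel %in% .channels))
    .stopf("unknown channel value(s): %s",
           paste(unique(setdiff(df$channel, .channels)), collapse = ", "))
  if (!all(df$protocol %in% .protocols))
    .stopf("unknown protocol value(s): %s",
           paste(unique(setdiff(df$protocol, .protocols)), collapse = ", "))
  neg <- which(df$value_pct_of_added < 0)
  if (length(neg) > 0)
    .stopf("validation error: negative value_pct_of_added in row(s) %s",
           paste(utils::head(neg, 5), collapse = ", "))
  dup <- duplicated(df[, c("time_min", "channel", "protocol", "replicate")])
  if (any(dup))
    .stopf("validation error: duplicated (time, channel, protocol, replicate) in row(s) %s",
           paste(utils::head(which(dup), 5), collapse = ", "))
  structure(df, class = c("tracer_timecourse", "data.frame"))
}

#' Read a run configuration file
#'
#' Reads a YAML (or JSON-compatible) key-value file with optional sections
#' `geometry`, `kinetics`, `design` and `noise`, and validates each through
#' the corresponding constructor. Times are minutes, concentrations mol/l,
#' per-cell amounts molecules throughout — no unit auto-detection.
#'
#' Within `design`, `additions` (and `inhibitor_events`, if present) are
#' lists of records that are bound into data frames.
#'
#' @param path Path to the configuration file.
#' @return A list of class `run_config` with validated components (absent
#'   sections are `NULL`).
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    .stopf("the 'yaml' package is required to read configuration files")
  if (!file.exists(path)) .stopf("file not found: %s", path)
  raw <- yaml::read_yaml(path)
  out <- list(geometry = NULL, kinetics = NULL, design = NULL, noise = NULL)
  if (!is.null(raw$geometry))
    out$geometry <- do.call(cell_geometry, raw$geometry)
  if (!is.null(raw$kinetics))
    out$kinetics <- do.call(kinetic_parameters, raw$kinetics)
  if (!is.null(raw$design)) {
    d <- raw$design
    d$additions <- do.call(rbind, lapply(d$additions, as.data.frame))
    if (!is.null(d$inhibitor_events))
      d$inhibitor_events <- do.call(rbind, lapply(d$inhibitor_events,
                                                  as.data.frame))
    d$sampling_times <- as.numeric(unlist(d$sampling_times))
    d$protocols <- as.character(unlist(d$protocols))
    out$design <- do.call(experiment_design, d)
  }
  if (!is.null(raw$noise))
    out$noise <- do.call(noise_model, raw$noise)
  class(out) <- "run_config"
  out
}
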