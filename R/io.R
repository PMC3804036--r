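#' Write a recording to a plain-text file
#'
#' Columnar text format with a commented key=value header:
#' \preformatted{
#' # format_version = 1
#' # fs_hz = 200
#' # protocol = cetm
#' # velocity_mm_s = 0.09
#' # channel_count = 1
#' # units = mmHg
#' time_s	pressure_mmHg
#' 0	0.123...
#' }
#' Samples are written at full double precision (17 significant
#' digits), so `read_recording(write_recording(r))` round-trips
#' bit-exactly.
#'
#' @param recording a [tonometry_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "tonometry_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    "# format_version = 1",
    sprintf("# fs_hz = %.17g", recording$fs_hz),
    sprintf("# protocol = %s", recording$protocol),
    if (is.finite(recording$velocity_mm_s)) {
      sprintf("# velocity_mm_s = %.17g", recording$velocity_mm_s)
    },
    "# channel_count = 1",
    "# units = mmHg"
  )
  for (key in names(recording$meta)) {
    val <- recording$meta[[key]]
    hdr <- c(hdr, sprintf("# %s = %s", key,
                          paste(sprintf("%.17g", val), collapse = ",")))
  }
  writeLines(hdr, con)
  writeLines("time_s\tpressure_mmHg", con)
  writeLines(sprintf("%.17g\t%.17g", recording$time_s,
                     recording$pressure_mmHg), con)
  invisible(path)
}

#' Read a recording from a plain-text file
#'
#' Parses the format written by [write_recording()]. The header keys
#' `fs_hz` and `protocol` are mandatory, and `velocity_mm_s` is
#' mandatory when `protocol = cetm`; sample spacing is validated
#' against `fs_hz` (tolerance 1e-6 s) and NaN samples are rejected.
#'
#' @param path input file path.
#' @return a [tonometry_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  header <- list()
  for (h in hdr_lines) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3) header[[m[2]]] <- m[3]
  }
  for (key in c("fs_hz", "protocol")) {
    if (is.null(header[[key]])) {
      stop(sprintf("parse error: mandatory header key '%s' missing", key))
    }
  }
  fs <- as.numeric(header$fs_hz)
  protocol <- header$protocol
  if (protocol == "cetm" && is.null(header$velocity_mm_s)) {
    stop("parse error: header key 'velocity_mm_s' is mandatory for protocol 'cetm'")
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)][-1]  # drop column header
  parts <- strsplit(body, "\t", fixed = TRUE)
  time_s <- as.numeric(vapply(parts, `[[`, "", 1))
  pressure <- as.numeric(vapply(parts, `[[`, "", 2))
  if (any(is.na(pressure)) || any(is.na(time_s))) {
    stop("parse error: NaN or unparseable samples in body")
  }
  if (any(abs(diff(time_s) - 1 / fs) > 1e-6)) {
    stop("parse error: non-uniform sampling (spacing deviates from 1/fs_hz by > 1e-6 s)")
  }
  known <- c("format_version", "fs_hz", "protocol", "velocity_mm_s",
             "channel_count", "units")
  meta <- lapply(header[setdiff(names(header), known)], function(v) {
    as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
  })
  tonometry_recording(
    pressure, fs, protocol = protocol,
    velocity_mm_s = if (!is.null(header$velocity_mm_s)) as.numeric(header$velocity_mm_s),
    meta = meta
  )
}

#' Write simulation ground truth as a key=value sidecar
#'
#' @param truth the `truth` element of a `sim_result`.
#' @param path output file path (conventionally `<recording>.truth`).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  put <- function(key, val) {
    writeLines(sprintf("%s = %s", key,
                       paste(sprintf("%.17g", val), collapse = ",")), con)
  }
  scalars <- intersect(names(truth),
                       c("true_pdi_mm", "true_contact_time_s",
                         "true_step_sd_mm", "true_step_amplitudes_mmHg"))
  for (key in scalars) put(key, truth[[key]])
  put("true_onset_times_s", truth$true_onset_times_s)
  if (!is.null(truth$config)) {
    for (key in setdiff(names(truth$config), character(0))) {
      put(paste0("config.", key), truth$config[[key]])
    }
  }
  invisible(path)
}

#' Write / read the cohort index table
#'
#' Tab-separated columnar text with a header row; the standard exchange
#' format of the cohort statistics.
#'
#' @param table cohort data frame (see [cohort_table()]).
#' @param path file path.
#' @return `write_cohort_table`: `path` invisibly;
#'   `read_cohort_table`: the data frame.
#' @export
write_cohort_table <- function(table, path) {
  write.table(format(table, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a flat key-value index report
#'
#' @param fit a `depth_assessment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path) {
  stopifnot(inherits(fit, "depth_assessment"))
  ind <- fit$indices
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("protocol = %s", fit$recording$protocol), con)
  for (key in c("ocp_mmHg", "cfs_ocp", "cfs_pad", "pdi_mm",
                "sd_contact_mm", "sd_optimal_mm",
                "h_shallow_mmHg", "h_deep_mmHg")) {
    val <- ind[[key]]
    writeLines(sprintf("%s = %s", key,
                       if (is.na(val)) "not-applicable" else sprintf("%.6g", val)),
               con)
  }
  invisible(path)
}
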