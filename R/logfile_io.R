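# Trajectory-log data model and portable on-disk container.
#
# A trajectory log is the analysis unit: one delivered VMAT field, sampled on
# a uniform 20 ms grid, holding planned and actual values for every machine
# axis (gantry angle, 120 MLC leaves, cumulative MU) plus the actual dose
# rate. MLC bank A is stored sign-flipped so that the leaf-pair gap is always
# gap(p) = B_p - A_p >= 0 (collision invariant is sign-stable).

LOG_FORMAT_VERSION <- 1L
SITE_LEVELS <- c("prostate", "spine", "thorax", "other")

#' Construct a trajectory log
#'
#' Builds the in-memory representation of one VMAT field's trajectory log:
#' time-sampled planned and actual machine axes on a uniform grid
#' (20 ms by default, the TrueBeam logging interval).
#'
#' @param sampling_interval Sampling interval in seconds (default 0.020).
#' @param gantry_planned,gantry_actual Gantry angle in degrees, length N.
#' @param mlc_planned,mlc_actual N x 120 matrices of leaf positions in
#'   millimetres at the isocentre plane; columns are bank A leaves 1-60 then
#'   bank B leaves 1-60. Bank A uses the flipped sign convention so that
#'   `mlc[, 60 + p] - mlc[, p]` is the (non-negative) gap of pair `p`.
#' @param mu_planned,mu_actual Cumulative monitor units, non-decreasing,
#'   length N.
#' @param dose_rate_actual Actual dose rate in MU/min, length N.
#' @param site_label One of `"prostate"`, `"spine"`, `"thorax"`, `"other"`.
#' @param field_id Free-text field identifier.
#' @param num_arcs Positive integer number of arcs the MU belongs to.
#' @param source `"synthetic"` or `"imported"`.
#' @param validate If `TRUE` (default), stop when [validate_log()] reports
#'   issues.
#'
#' @return An object of class `trajectory_log`.
#' @seealso [validate_log()], [write_log()], [read_log()]
#' @export
trajectory_log <- function(sampling_interval = 0.020,
                           gantry_planned, gantry_actual,
                           mlc_planned, mlc_actual,
                           mu_planned, mu_actual,
                           dose_rate_actual,
                           site_label = "other", field_id = "field",
                           num_arcs = 1L, source = "synthetic",
                           validate = TRUE) {
  mlc_planned <- as.matrix(mlc_planned)
  mlc_actual <- as.matrix(mlc_actual)
  colnames(mlc_planned) <- colnames(mlc_actual) <- leaf_names()
  log <- structure(list(
    sampling_interval = as.numeric(sampling_interval),
    gantry = list(planned = as.numeric(gantry_planned),
                  actual = as.numeric(gantry_actual)),
    mlc = list(planned = mlc_planned, actual = mlc_actual),
    mu = list(planned = as.numeric(mu_planned),
              actual = as.numeric(mu_actual)),
    dose_rate_actual = as.numeric(dose_rate_actual),
    meta = list(site_label = site_label, field_id = field_id,
                num_arcs = as.integer(num_arcs), source = source)
  ), class = "trajectory_log")
  if (validate) {
    issues <- validate_log(log)
    if (nrow(issues) > 0) {
      stop("invalid trajectory log: ",
           paste(unique(issues$invariant), collapse = "; "), call. = FALSE)
    }
  }
  log
}

leaf_names <- function() {
  c(sprintf("A%02d", 1:60), sprintf("B%02d", 1:60))
}

#' Number of time samples in a trajectory log
#' @param log A `trajectory_log`.
#' @return Integer sample count.
#' @export
n_samples <- function(log) length(log$gantry$planned)

#' Leaf-pair gap series of a trajectory log
#'
#' @param log A `trajectory_log`.
#' @param which `"planned"` or `"actual"`.
#' @return N x 60 matrix of pair gaps (mm), `gap = B - A`.
#' @export
leaf_gaps <- function(log, which = c("planned", "actual")) {
  which <- match.arg(which)
  m <- log$mlc[[which]]
  m[, 61:120, drop = FALSE] - m[, 1:60, drop = FALSE]
}

#' @export
print.trajectory_log <- function(x, ...) {
  cat(sprintf(
    "<trajectory_log> %s/%s: %d samples @ %.0f ms, gantry %.1f..%.1f deg, %.1f MU, %d arc(s)\n",
    x$meta$site_label, x$meta$field_id, n_samples(x),
    x$sampling_interval * 1000,
    x$gantry$planned[1], x$gantry$planned[n_samples(x)],
    max(x$mu$planned), x$meta$num_arcs))
  invisible(x)
}

issue_df <- function(invariant = character(), axis = character(),
                     index = integer(), message = character()) {
  data.frame(invariant = invariant, axis = axis, index = index,
             message = message, stringsAsFactors = FALSE)
}

#' Validate a trajectory log
#'
#' Runs every structural invariant of the trajectory-log model and returns
#' diagnostics. Never raises on a structurally readable log: use it to triage
#' before analysis.
#'
#' Checked invariants: all axis series share one length N >= 2; no NaN/Inf
#' anywhere; `sampling_interval > 0`; planned and actual cumulative MU
#' non-decreasing; leaf-pair gap `B - A >= 0` at every sample (no collision);
#' exactly 120 leaf series; known site label; positive `num_arcs`.
#'
#' @param log A `trajectory_log` (or structurally similar list).
#' @return A data frame of issues with columns `invariant`, `axis`, `index`
#'   (first offending sample, `NA` when not sample-specific) and `message`.
#'   Zero rows iff the log is valid.
#' @export
validate_log <- function(log) {
  iss <- issue_df()
  add <- function(invariant, axis, index, message) {
    iss <<- rbind(iss, issue_df(invariant, axis, as.integer(index), message))
  }
  n <- length(log$gantry$planned)
  if (!is.numeric(log$sampling_interval) || length(log$sampling_interval) != 1 ||
      !is.finite(log$sampling_interval) || log$sampling_interval <= 0) {
    add("sampling interval", "sampling_interval", NA,
        "sampling_interval must be a single positive number")
  }
  if (n < 2) add("length", "gantry", NA, "need at least 2 samples")

  lens <- c(gantry_planned = length(log$gantry$planned),
            gantry_actual = length(log$gantry$actual),
            mu_planned = length(log$mu$planned),
            mu_actual = length(log$mu$actual),
            dose_rate_actual = length(log$dose_rate_actual),
            mlc_planned = nrow(log$mlc$planned),
            mlc_actual = nrow(log$mlc$actual))
  bad <- names(lens)[lens != n]
  for (b in bad) add("length mismatch", b, NA,
                     sprintf("%s has length %d, expected %d", b, lens[[b]], n))

  for (bank in c("planned", "actual")) {
    if (ncol(log$mlc[[bank]]) != N_LEAVES) {
      add("leaf count", paste0("mlc_", bank), NA,
          sprintf("expected %d leaf series, found %d", N_LEAVES,
                  ncol(log$mlc[[bank]])))
    }
  }

  finite_check <- list(gantry_planned = log$gantry$planned,
                       gantry_actual = log$gantry$actual,
                       mu_planned = log$mu$planned,
                       mu_actual = log$mu$actual,
                       dose_rate_actual = log$dose_rate_actual,
                       mlc_planned = log$mlc$planned,
                       mlc_actual = log$mlc$actual)
  for (nm in names(finite_check)) {
    v <- finite_check[[nm]]
    if (length(v) && !all(is.finite(v))) {
      idx <- which(!is.finite(v))[1]
      if (is.matrix(v)) idx <- ((idx - 1) %% nrow(v)) + 1
      add("finite values", nm, idx, "NaN/Inf value present")
    }
  }

  for (nm in c("planned", "actual")) {
    muv <- log$mu[[nm]]
    if (length(muv) >= 2 && all(is.finite(muv))) {
      d <- diff(muv)
      if (any(d < -1e-9)) {
        add("mu monotonicity", paste0("mu_", nm), which(d < -1e-9)[1] + 1L,
            sprintf("cumulative %s MU decreases", nm))
      }
    }
  }

  if (all(lens == n) && ncol(log$mlc$planned) == N_LEAVES &&
      ncol(log$mlc$actual) == N_LEAVES) {
    for (bank in c("planned", "actual")) {
      g <- log$mlc[[bank]][, 61:120, drop = FALSE] -
        log$mlc[[bank]][, 1:60, drop = FALSE]
      neg <- which(g < -1e-9, arr.ind = TRUE)
      if (nrow(neg)) {
        add("leaf gap", sprintf("%s pair %d", bank, neg[1, 2]), neg[1, 1],
            sprintf("negative gap (%.4f mm) at pair %d, sample %d",
                    g[neg[1, 1], neg[1, 2]], neg[1, 2], neg[1, 1]))
      }
    }
  }

  if (!isTRUE(log$meta$site_label %in% SITE_LEVELS)) {
    add("site label", "meta", NA,
        sprintf("site_label must be one of %s",
                paste(SITE_LEVELS, collapse = ", ")))
  }
  if (!isTRUE(is.finite(log$meta$num_arcs) && log$meta$num_arcs >= 1)) {
    add("num arcs", "meta", NA, "num_arcs must be a positive integer")
  }
  iss
}

#' Write a trajectory log to the portable container format
#'
#' The container is a single text file: a `key=value` header block
#' (`format_version`, `sampling_interval_s`, `n_samples`, `n_leaves`,
#' `site_label`, `field_id`, `num_arcs`, `source`) terminated by a blank
#' line, followed by a CSV payload with one row per 20 ms sample and columns
#' `t_s`, `gantry_planned_deg`, `gantry_actual_deg`, `mu_planned`,
#' `mu_actual`, `dose_rate_actual`, then interleaved
#' `leafA01_planned_mm`, `leafA01_actual_mm`, ... `leafB60_actual_mm`.
#' Numbers are written with 17 significant digits so the round trip is exact
#' at 64-bit precision.
#'
#' @param log A valid `trajectory_log`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_log <- function(log, path) {
  issues <- validate_log(log)
  if (nrow(issues) > 0) {
    stop("cannot write invalid log: ",
         paste(unique(issues$invariant), collapse = "; "), call. = FALSE)
  }
  n <- n_samples(log)
  header <- c(
    sprintf("format_version=%d", LOG_FORMAT_VERSION),
    sprintf("sampling_interval_s=%.17g", log$sampling_interval),
    sprintf("n_samples=%d", n),
    sprintf("n_leaves=%d", N_LEAVES),
    sprintf("site_label=%s", log$meta$site_label),
    sprintf("field_id=%s", log$meta$field_id),
    sprintf("num_arcs=%d", log$meta$num_arcs),
    sprintf("source=%s", log$meta$source),
    "")
  leaf_cols <- matrix(NA_real_, n, 2L * N_LEAVES)
  leaf_cols[, seq(1, 240, by = 2)] <- log$mlc$planned
  leaf_cols[, seq(2, 240, by = 2)] <- log$mlc$actual
  payload <- cbind(
    (seq_len(n) - 1) * log$sampling_interval,
    log$gantry$planned, log$gantry$actual,
    log$mu$planned, log$mu$actual, log$dose_rate_actual,
    leaf_cols)
  ln <- leaf_names()
  pa <- as.vector(rbind(paste0("leaf", ln, "_planned_mm"),
                        paste0("leaf", ln, "_actual_mm")))
  cols <- c("t_s", "gantry_planned_deg", "gantry_actual_deg",
            "mu_planned", "mu_actual", "dose_rate_actual", pa)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(cols, collapse = ","), con)
  body <- do.call(paste, c(lapply(seq_len(ncol(payload)), function(j)
    sprintf("%.17g", payload[, j])), sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a trajectory log from the portable container format
#'
#' Inverse of [write_log()]. Fails with a format error (reporting the header
#' key or payload shape at fault) on truncated or malformed files; never
#' returns a partially populated log.
#'
#' @param path Path to a file written by [write_log()].
#' @return A validated `trajectory_log`.
#' @export
read_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 64L, warn = FALSE)
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop("format error: missing blank line terminating header",
                         call. = FALSE)
  hdr_lines <- lines[seq_len(blank - 1)]
  kv <- strsplit(hdr_lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) {
    stop(sprintf("format error: malformed header at line %d",
                 which(lengths(kv) != 2)[1]), call. = FALSE)
  }
  hdr <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  need <- c("format_version", "sampling_interval_s", "n_samples", "n_leaves",
            "site_label", "field_id", "num_arcs", "source")
  missing_keys <- setdiff(need, names(hdr))
  if (length(missing_keys)) {
    stop("format error: missing header key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  if (as.integer(hdr[["format_version"]]) != LOG_FORMAT_VERSION) {
    stop("unsupported format version: ", hdr[["format_version"]],
         call. = FALSE)
  }
  if (as.integer(hdr[["n_leaves"]]) != N_LEAVES) {
    stop(sprintf("format error: leaf count %s, expected %d",
                 hdr[["n_leaves"]], N_LEAVES), call. = FALSE)
  }
  n <- as.integer(hdr[["n_samples"]])

  tab <- data.table::fread(path, skip = blank, header = TRUE, sep = ",",
                           data.table = FALSE, showProgress = FALSE,
                           fill = TRUE)
  n_expected_cols <- 6L + 2L * N_LEAVES
  if (ncol(tab) != n_expected_cols) {
    stop(sprintf("format error: payload has %d columns, expected %d",
                 ncol(tab), n_expected_cols), call. = FALSE)
  }
  if (nrow(tab) != n) {
    stop(sprintf(
      "format error: payload truncated or padded at row %d (expected %d rows)",
      nrow(tab), n), call. = FALSE)
  }
  if (!all(vapply(tab, is.numeric, TRUE))) {
    stop("format error: non-numeric payload value", call. = FALSE)
  }
  m <- as.matrix(tab)
  mlc_planned <- m[, 6L + seq(1, 240, by = 2), drop = FALSE]
  mlc_actual <- m[, 6L + seq(2, 240, by = 2), drop = FALSE]
  log <- trajectory_log(
    sampling_interval = as.numeric(hdr[["sampling_interval_s"]]),
    gantry_planned = m[, 2], gantry_actual = m[, 3],
    mlc_planned = mlc_planned, mlc_actual = mlc_actual,
    mu_planned = m[, 4], mu_actual = m[, 5],
    dose_rate_actual = m[, 6],
    site_label = hdr[["site_label"]], field_id = hdr[["field_id"]],
    num_arcs = as.integer(hdr[["num_arcs"]]), source = hdr[["source"]],
    validate = FALSE)
  issues <- validate_log(log)
  if (nrow(issues) > 0) {
    stop("file decodes to an invalid log: ",
         paste(unique(issues$invariant), collapse = "; "), call. = FALSE)
  }
  log
}

#' Test two trajectory logs for exact equality
#' @param a,b `trajectory_log` objects.
#' @return `TRUE` iff every field and array is identical (bitwise for doubles).
#' @export
logs_identical <- function(a, b) {
  identical(a$sampling_interval, b$sampling_interval) &&
    identical(a$gantry, b$gantry) &&
    identical(unname(a$mlc$planned), unname(b$mlc$planned)) &&
    identical(unname(a$mlc$actual), unname(b$mlc$actual)) &&
    identical(a$mu, b$mu) &&
    identical(a$dose_rate_actual, b$dose_rate_actual) &&
    identical(a$meta, b$meta)
}
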