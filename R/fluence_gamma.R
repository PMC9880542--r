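# Idealised fluence engine and global gamma-index analysis: the in-repo
# stand-in for portal dosimetry. The planned-vs-actual fluence comparison
# preserves the causal chain delivery error -> dose-image discrepancy ->
# gamma passing rate; absolute EPID dosimetry is out of scope.

#' The four default gamma criteria
#' @return List of `c(dose_percent, distance_mm)` pairs: 2/2, 2/1, 1/2, 1/1.
#' @export
default_gamma_criteria <- function() {
  list(c(2, 2), c(2, 1), c(1, 2), c(1, 1))
}

criterion_name <- function(crit) sprintf("gpr_%g_%g", crit[1], crit[2])

#' Construct a fluence map object
#'
#' @param values Matrix of non-negative relative fluence (rows = y, cols = x).
#' @param pixel_spacing_mm Pixel pitch in mm (> 0).
#' @param origin_mm `c(x, y)` of the grid corner (first row/col centre), mm.
#' @return A `fluence_map` object.
#' @export
fluence_map <- function(values, pixel_spacing_mm, origin_mm) {
  stopifnot(is.matrix(values), all(values >= 0), pixel_spacing_mm > 0)
  structure(list(values = values, pixel_spacing_mm = pixel_spacing_mm,
                 origin_mm = origin_mm, shape = dim(values)),
            class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("<fluence_map> %d x %d px @ %.2f mm, max %.3f\n",
              x$shape[1], x$shape[2], x$pixel_spacing_mm, max(x$values)))
  invisible(x)
}

#' Compute an idealised fluence map from a trajectory log
#'
#' For each beam-on sample the delivered MU increment is deposited into
#' every pixel covered by the open aperture (between each pair's leaf tips,
#' within the pair's width band), with fractional area weighting at the
#' aperture boundary; unit transmission, no penumnbra or scatter. The map is
#' normalised to a maximum of 100 (relative %).
#'
#' @param log A valid `trajectory_log`.
#' @param which `"planned"` or `"actual"` trajectory (MU weights follow the
#'   same choice).
#' @param pixel_spacing_mm Pixel pitch, in (0.1, 5] mm (default 1).
#' @param extent_mm Square grid extent centred on the isocentre (default
#'   200 mm). Apertures opening outside the extent raise an error naming the
#'   sample.
#' @param normalize If `TRUE` (default) scale the map to a maximum of 100
#'   (relative %). [label_log()] uses `normalize = FALSE` for both maps so
#'   the comparison stays in absolute (MU-proportional) dose, as a global
#'   absolute-dose gamma requires; a delivery hot spot then fails locally
#'   instead of silently rescaling the whole evaluated map.
#' @return A [fluence_map()].
#' @export
compute_fluence <- function(log, which = c("planned", "actual"),
                            pixel_spacing_mm = 1, extent_mm = 200,
                            normalize = TRUE) {
  which <- match.arg(which)
  stopifnot(pixel_spacing_mm > 0.1, pixel_spacing_mm <= 5, extent_mm > 0)
  M <- log$mlc[[which]]
  d <- mu_increments(log$mu[[which]])
  vals <- .fluence_accumulate(M[, 1:60, drop = FALSE],
                              M[, 61:120, drop = FALSE],
                              d, leaf_pair_edges(),
                              extent_mm / 2, pixel_spacing_mm,
                              CLOSED_GAP_TOL)
  mx <- max(vals)
  if (normalize && mx > 0) vals <- vals * (100 / mx)
  fluence_map(vals, pixel_spacing_mm,
              origin_mm = c(-extent_mm / 2, -extent_mm / 2))
}

#' Global gamma-index comparison of two fluence maps
#'
#' For each reference pixel at or above the low-dose threshold, the gamma
#' index is the minimum over candidate displacements (within
#' `search_radius_mm`, on a sub-pixel grid of step at most `distance_mm/10`
#' that always contains the pixel centres) of
#' `sqrt((dose diff / dose tolerance)^2 + (displacement / distance_mm)^2)`,
#' with the evaluated map bilinearly interpolated. The dose tolerance is
#' global: `dose_percent`% of the reference maximum. Pixels below the
#' threshold are excluded from the mask and the passing rate.
#'
#' @param reference,evaluated [fluence_map()]s on the same grid.
#' @param dose_percent Dose-difference criterion in % of the global
#'   reference maximum (> 0).
#' @param distance_mm Distance-to-agreement criterion in mm (> 0).
#' @param low_dose_threshold_frac Mask threshold as a fraction of the
#'   reference maximum (default 0.10).
#' @param search_radius_mm Search radius (default `3 * distance_mm`); must
#'   be at least `distance_mm`.
#' @param step_mm Sub-pixel search step; the default
#'   `min(distance_mm, pixel spacing) / 10` is criterion-independent, so the
#'   candidate set of a looser criterion contains that of a tighter one and
#'   per-log GPR is exactly monotone across criteria.
#' @return A `gamma_result`: `gamma_map` (NA outside the mask), `criterion`,
#'   `low_dose_threshold_frac`, `gpr_percent` (percentage of in-mask pixels
#'   with gamma <= 1) and `n_evaluated`.
#' @export
gamma_index <- function(reference, evaluated, dose_percent, distance_mm,
                        low_dose_threshold_frac = 0.10,
                        search_radius_mm = 3 * distance_mm,
                        step_mm = min(distance_mm,
                                      reference$pixel_spacing_mm) / 10) {
  stopifnot(inherits(reference, "fluence_map"),
            inherits(evaluated, "fluence_map"),
            dose_percent > 0, distance_mm > 0)
  if (!identical(reference$shape, evaluated$shape) ||
      reference$pixel_spacing_mm != evaluated$pixel_spacing_mm) {
    stop("gamma_index: reference and evaluated grids differ", call. = FALSE)
  }
  if (search_radius_mm < distance_mm) {
    stop("gamma_index: search_radius_mm must be >= distance_mm",
         call. = FALSE)
  }
  ref_max <- max(reference$values)
  if (ref_max <= 0) stop("gamma_index: empty reference map", call. = FALSE)
  gm <- .gamma_search(reference$values, evaluated$values,
                      reference$pixel_spacing_mm,
                      dose_percent / 100 * ref_max, distance_mm,
                      low_dose_threshold_frac * ref_max,
                      search_radius_mm, step_mm)
  n_eval <- sum(!is.na(gm))
  gpr <- if (n_eval > 0) 100 * sum(gm <= 1 + 1e-9, na.rm = TRUE) / n_eval
         else NA_real_
  structure(list(gamma_map = gm,
                 criterion = c(dose_percent = dose_percent,
                               distance_mm = distance_mm),
                 low_dose_threshold_frac = low_dose_threshold_frac,
                 gpr_percent = gpr, n_evaluated = n_eval),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%gmm: GPR %.2f%% (%d pixels)\n",
              x$criterion[1], x$criterion[2], x$gpr_percent, x$n_evaluated))
  invisible(x)
}

#' Gamma-passing-rate labels for one trajectory log
#'
#' Computes the planned (reference) and actual (evaluated) fluence maps once
#' and runs the global gamma analysis at each criterion — the field-by-field
#' QA label used as the regression target.
#'
#' @param log A valid `trajectory_log`.
#' @param criteria List of `c(dose_percent, distance_mm)` pairs (default the
#'   four standard criteria).
#' @param low_dose_threshold_frac Low-dose mask threshold (default 0.10).
#' @param pixel_spacing_mm,extent_mm Fluence grid settings
#'   (see [compute_fluence()]).
#' @return Named numeric vector of GPR percentages, names `gpr_<dose>_<dist>`.
#' @export
label_log <- function(log, criteria = default_gamma_criteria(),
                      low_dose_threshold_frac = 0.10,
                      pixel_spacing_mm = 1, extent_mm = 200) {
  # raw (un-normalised) maps: dose tolerance and threshold scale with the
  # reference maximum, so this is the global absolute-dose convention
  ref <- compute_fluence(log, "planned", pixel_spacing_mm, extent_mm,
                         normalize = FALSE)
  ev <- compute_fluence(log, "actual", pixel_spacing_mm, extent_mm,
                        normalize = FALSE)
  out <- vapply(criteria, function(crit) {
    gamma_index(ref, ev, crit[1], crit[2], low_dose_threshold_frac)$gpr_percent
  }, numeric(1))
  names(out) <- vapply(criteria, criterion_name, character(1))
  out
}

#' Label a list of logs
#'
#' @inheritParams label_log
#' @param logs List of `trajectory_log`s.
#' @return Data frame with `field_id`, `site` and one GPR column per
#'   criterion.
#' @export
label_cohort <- function(logs, criteria = default_gamma_criteria(), ...) {
  rows <- lapply(logs, function(log) {
    data.frame(field_id = log$meta$field_id, site = log$meta$site_label,
               as.list(label_log(log, criteria = criteria, ...)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Composite (plan-level) GPR by summing per-field fluences
#'
#' Sums the planned and the actual fluence maps over all fields of a plan
#' before the gamma comparison — the composite analog of the field-by-field
#' [label_log()]. Off the main analysis path (the per-field GPR is the
#' modelling unit); provided for plan-level reporting.
#'
#' @inheritParams label_log
#' @param logs List of `trajectory_log`s belonging to one plan.
#' @return Named numeric vector of composite GPR percentages.
#' @export
label_composite <- function(logs, criteria = default_gamma_criteria(),
                            low_dose_threshold_frac = 0.10,
                            pixel_spacing_mm = 1, extent_mm = 200) {
  stopifnot(length(logs) >= 1)
  acc <- function(which) {
    maps <- lapply(logs, compute_fluence, which = which,
                   pixel_spacing_mm = pixel_spacing_mm,
                   extent_mm = extent_mm, normalize = FALSE)
    vals <- Reduce(`+`, lapply(maps, `[[`, "values"))
    fluence_map(vals, pixel_spacing_mm,
                origin_mm = c(-extent_mm / 2, -extent_mm / 2))
  }
  ref <- acc("planned")
  ev <- acc("actual")
  out <- vapply(criteria, function(crit) {
    gamma_index(ref, ev, crit[1], crit[2], low_dose_threshold_frac)$gpr_percent
  }, numeric(1))
  names(out) <- vapply(criteria, criterion_name, character(1))
  out
}

#' Write a fluence map as a plain text grid
#' @param map A [fluence_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fluence <- function(map, path) {
  utils::write.table(map$values, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
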