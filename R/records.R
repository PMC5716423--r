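#' Planned arc and delivery-record containers
#'
#' An `arc_plan` holds the ordered control points of one VMAT arc: cumulative
#' monitor units (the progress coordinate), gantry angle, the 80 MLC leaf
#' positions (two banks of 40) and the 4 jaw positions at each control point.
#' A `delivery_record` holds the machine-reported snapshot captured at each
#' control-point boundary of one delivered fraction, with the same per-row
#' layout. Both store leaves/jaws in mm at isocenter and gantry angles in
#' degrees on the IEC 61217 circle `[0, 360)`.
#'
#' The leaf sign convention is that bank A positions never exceed the opposing
#' bank B positions; a closed pair has `bank_a == bank_b`. Jaws are ordered
#' `x1 <= x2` (leaf-travel direction) and `y1 <= y2` (transverse direction);
#' leaf pairs whose transverse extent does not overlap the open `(y1, y2)`
#' interval are shielded by the jaws.
#'
#' @param patient_id,field_id Identifier strings.
#' @param cumulative_mu Non-decreasing numeric vector of cumulative monitor
#'   units, one per control point / snapshot.
#' @param gantry_deg Gantry angles in `[0, 360)`, one per row.
#' @param bank_a,bank_b Numeric matrices, one row per control point and one
#'   column per leaf (40 each), mm at isocenter.
#' @param jaws Numeric matrix with columns `x1, x2, y1, y2`, mm at isocenter.
#' @param collimator_deg Static collimator angle, degrees (metadata).
#' @param rotation_sense `+1` (clockwise, increasing IEC angle) or `-1`
#'   (counter-clockwise). If `NULL` it is inferred from the gantry sequence.
#' @param geometry A [machine_geometry()].
#' @return A validated `arc_plan`.
#' @seealso [read_plan()], [generate_plan()], [interpolate_plan()]
#' @export
arc_plan <- function(patient_id, field_id, cumulative_mu, gantry_deg,
                     bank_a, bank_b, jaws,
                     collimator_deg = 45, rotation_sense = NULL,
                     geometry = machine_geometry()) {
  bank_a <- as.matrix(bank_a); bank_b <- as.matrix(bank_b)
  jaws <- as.matrix(jaws)
  colnames(jaws) <- c("x1", "x2", "y1", "y2")
  if (is.null(rotation_sense))
    rotation_sense <- infer_rotation_sense(gantry_deg)
  plan <- structure(
    list(
      patient_id = as.character(patient_id),
      field_id = as.character(field_id),
      collimator_deg = as.numeric(collimator_deg),
      rotation_sense = as.integer(rotation_sense),
      cumulative_mu = as.numeric(cumulative_mu),
      gantry_deg = as.numeric(gantry_deg),
      gantry_unwrapped_deg = NULL,  # filled by validate_arc_plan
      bank_a = bank_a,
      bank_b = bank_b,
      jaws = jaws
    ),
    class = "arc_plan"
  )
  validate_arc_plan(plan, geometry)
}

#' Validate an arc plan against its structural invariants
#'
#' Checks cardinalities (40 leaves per bank, 4 jaws), non-decreasing
#' cumulative MU, non-crossing leaf pairs and jaws, and that the gantry
#' sequence unwraps monotonically along `rotation_sense`. Recomputes and
#' caches the unwrapped gantry coordinate.
#'
#' @param plan An `arc_plan`.
#' @param geometry A [machine_geometry()].
#' @return The plan, invisibly usable, with `gantry_unwrapped_deg` populated.
#' @export
validate_arc_plan <- function(plan, geometry = machine_geometry()) {
  n <- length(plan$cumulative_mu)
  if (n < 2L)
    arcv_stop("an arc plan needs at least 2 control points",
              "arcv_validation_error")
  check_row_shapes(plan, n, geometry)
  if (any(diff(plan$cumulative_mu) < 0))
    arcv_stop("cumulative_mu must be non-decreasing across control points",
              "arcv_validation_error")
  if (any(plan$cumulative_mu < 0))
    arcv_stop("cumulative_mu must be non-negative", "arcv_validation_error")
  if (!plan$rotation_sense %in% c(-1L, 1L))
    arcv_stop("rotation_sense must be +1 or -1", "arcv_validation_error")
  if (any(plan$bank_a > plan$bank_b + 1e-9))
    arcv_stop("opposing leaves overlap: bank A must not pass bank B",
              "arcv_validation_error")
  if (any(plan$jaws[, "x1"] > plan$jaws[, "x2"]) ||
      any(plan$jaws[, "y1"] > plan$jaws[, "y2"]))
    arcv_stop("jaw pairs cross: require x1 <= x2 and y1 <= y2",
              "arcv_validation_error")
  u <- unwrap_gantry(plan$gantry_deg, plan$rotation_sense)
  if (any(plan$rotation_sense * diff(u) < 0))
    arcv_stop("gantry sequence is not monotone along rotation_sense",
              "arcv_validation_error")
  plan$gantry_unwrapped_deg <- u
  plan
}

#' Machine-reported delivery record for one fraction
#'
#' @inheritParams arc_plan
#' @param fraction_date Date of the delivered fraction (`Date` or
#'   `"YYYY-MM-DD"` string).
#' @param timestamp Optional per-snapshot timestamps (character).
#' @return A validated `delivery_record`.
#' @export
delivery_record <- function(patient_id, field_id, fraction_date,
                            cumulative_mu, gantry_deg, bank_a, bank_b, jaws,
                            timestamp = NULL,
                            geometry = machine_geometry()) {
  bank_a <- as.matrix(bank_a); bank_b <- as.matrix(bank_b)
  jaws <- as.matrix(jaws)
  colnames(jaws) <- c("x1", "x2", "y1", "y2")
  rec <- structure(
    list(
      patient_id = as.character(patient_id),
      field_id = as.character(field_id),
      fraction_date = format(as.Date(fraction_date)),
      cumulative_mu = as.numeric(cumulative_mu),
      gantry_deg = as.numeric(gantry_deg),
      bank_a = bank_a,
      bank_b = bank_b,
      jaws = jaws,
      timestamp = timestamp
    ),
    class = "delivery_record"
  )
  validate_delivery_record(rec, geometry)
}

#' @rdname delivery_record
#' @param record A `delivery_record`.
#' @export
validate_delivery_record <- function(record, geometry = machine_geometry()) {
  n <- length(record$cumulative_mu)
  if (n < 1L)
    arcv_stop("delivery record has no snapshots", "arcv_validation_error")
  check_row_shapes(record, n, geometry)
  if (any(diff(record$cumulative_mu) < 0))
    arcv_stop("cumulative_mu must be non-decreasing across snapshots",
              "arcv_validation_error")
  record
}

check_row_shapes <- function(x, n, geometry) {
  np <- geometry$n_leaf_pairs
  bad <- !is.matrix(x$bank_a) || !is.matrix(x$bank_b) ||
    nrow(x$bank_a) != n || nrow(x$bank_b) != n ||
    ncol(x$bank_a) != np || ncol(x$bank_b) != np ||
    !is.matrix(x$jaws) || nrow(x$jaws) != n || ncol(x$jaws) != 4L ||
    length(x$gantry_deg) != n
  if (bad)
    arcv_stop(sprintf(
      "inconsistent shapes: need %d rows with %d leaves per bank, 4 jaws and 1 gantry angle each",
      n, np), "arcv_validation_error")
  if (any(!is.finite(x$bank_a)) || any(!is.finite(x$bank_b)) ||
      any(!is.finite(x$jaws)) || any(!is.finite(x$gantry_deg)) ||
      any(!is.finite(x$cumulative_mu)))
    arcv_stop("non-finite values in positions or monitor units",
              "arcv_validation_error")
  if (any(x$gantry_deg < 0 | x$gantry_deg >= 360))
    arcv_stop("gantry angles must lie in [0, 360)", "arcv_validation_error")
  invisible(x)
}

# Sense of travel from the sum of shortest-path steps. Ties default to -1
# (counter-clockwise), the usual single-arc start direction.
infer_rotation_sense <- function(gantry_deg) {
  d <- diff(gantry_deg) %% 360
  d[d > 180] <- d[d > 180] - 360
  s <- sum(d)
  if (s > 0) 1L else -1L
}

#' @export
print.arc_plan <- function(x, ...) {
  cat(sprintf(
    "<arc_plan> patient %s field %s: %d control points, %.1f MU, gantry %.1f -> %.1f deg (sense %+d)\n",
    x$patient_id, x$field_id, length(x$cumulative_mu),
    max(x$cumulative_mu), x$gantry_deg[1L],
    x$gantry_deg[length(x$gantry_deg)], x$rotation_sense))
  invisible(x)
}

#' @export
print.delivery_record <- function(x, ...) {
  cat(sprintf(
    "<delivery_record> patient %s field %s on %s: %d snapshots, %.1f MU\n",
    x$patient_id, x$field_id, x$fraction_date,
    length(x$cumulative_mu), max(x$cumulative_mu)))
  invisible(x)
}

#' Turn a plan into an error-free delivery record
#'
#' Samples the plan exactly at its own control points, producing the record a
#' perfect machine would report. Useful as the identity case in testing and
#' commissioning.
#'
#' @param plan An `arc_plan`.
#' @param fraction_date Date tag for the synthetic fraction.
#' @return A `delivery_record` whose snapshots equal the plan's control points.
#' @export
sample_plan_as_record <- function(plan, fraction_date = "2026-01-01") {
  delivery_record(
    patient_id = plan$patient_id, field_id = plan$field_id,
    fraction_date = fraction_date,
    cumulative_mu = plan$cumulative_mu, gantry_deg = plan$gantry_deg,
    bank_a = plan$bank_a, bank_b = plan$bank_b, jaws = plan$jaws
  )
}

#' Tolerance configuration for error tabulation
#'
#' Headline tolerances follow standard VMAT delivery-verification practice:
#' MLC leaves within 3 mm, gantry within 2 degrees, jaws within 3 mm, plus a
#' sweep of levels for the tabulated percent-within-tolerance table.
#'
#' @param mlc_mm MLC leaf tolerance, mm.
#' @param gantry_deg Gantry tolerance, degrees.
#' @param jaw_mm Jaw tolerance, mm.
#' @param sweep Tolerance levels (mm or deg) for the tabulation sweep.
#' @return A `tolerance_config`.
#' @export
tolerance_config <- function(mlc_mm = 3, gantry_deg = 2, jaw_mm = 3,
                             sweep = c(1, 2, 3, 5)) {
  for (v in list(mlc_mm = mlc_mm, gantry_deg = gantry_deg, jaw_mm = jaw_mm)) {
    stopifnot_scalar_num(v, "tolerance", positive = TRUE)
  }
  if (!is.numeric(sweep) || length(sweep) < 1L || any(sweep <= 0))
    arcv_stop("'sweep' tolerances must be positive", "arcv_validation_error")
  structure(
    list(mlc_mm = mlc_mm, gantry_deg = gantry_deg, jaw_mm = jaw_mm,
         sweep = sort(unique(as.numeric(sweep)))),
    class = "tolerance_config"
  )
}

leaf_ids <- function(np = 40L) {
  c(sprintf("a%02d", seq_len(np)), sprintf("b%02d", seq_len(np)))
}
jaw_ids <- function() c("x1", "x2", "y1", "y2")
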