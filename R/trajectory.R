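# Reduce onto [0, 360); plain `x %% 360` can round to exactly 360 for tiny
# negative inputs, which would violate the angle invariant downstream.
wrap360 <- function(x) {
  y <- x %% 360
  y[y >= 360] <- 0
  y
}

#' Unwrap gantry angles along a rotation sense
#'
#' Single VMAT arcs commonly start at 175 degrees and rotate counter-clockwise
#' through 0/360 to 185 degrees, so any interpolation on the raw IEC angle
#' would jump at the wrap. This maps an ordered sequence of raw angles in
#' `[0, 360)` to a cumulative signed coordinate that is continuous along the
#' direction of travel: each step takes the shortest path consistent with
#' `rotation_sense`, and the first element is returned unchanged.
#'
#' @param angles Ordered gantry angles in `[0, 360)`.
#' @param rotation_sense `+1` for clockwise (increasing IEC angle), `-1` for
#'   counter-clockwise.
#' @return Numeric vector of unwrapped angles; `unwrapped %% 360` equals the
#'   input.
#' @details A raw step of exactly 180 degrees is ambiguous (it cannot be
#'   attributed to either direction) and raises a trajectory error.
#' @examples
#' unwrap_gantry(c(2, 358), -1)   # c(2, -2): wrap through zero
#' unwrap_gantry(c(358, 2), +1)   # c(358, 362)
#' @export
unwrap_gantry <- function(angles, rotation_sense) {
  if (!rotation_sense %in% c(-1, 1))
    arcv_stop("rotation_sense must be +1 or -1", "arcv_validation_error")
  n <- length(angles)
  if (n == 0L) return(numeric(0))
  if (any(angles < 0 | angles >= 360))
    arcv_stop("angles must lie in [0, 360)", "arcv_validation_error")
  if (n == 1L) return(as.numeric(angles))
  s <- rotation_sense
  delta <- (s * diff(angles)) %% 360       # in [0, 360)
  if (any(delta == 180))
    arcv_stop("ambiguous 180-degree gantry step: cannot unwrap",
              "arcv_trajectory_error")
  step <- ifelse(delta < 180, s * delta, s * (delta - 360))
  as.numeric(angles[1L]) + c(0, cumsum(step))
}

#' Signed shortest angular difference
#'
#' Reduces `reported - planned` modulo 360 into `(-180, 180]`; the antipodal
#' tie at 180 degrees resolves to `+180`.
#'
#' @param reported_deg,planned_deg Angles in `[0, 360)` (vectorized).
#' @return Signed difference in degrees, `(-180, 180]`.
#' @export
angular_error <- function(reported_deg, planned_deg) {
  d <- (reported_deg - planned_deg) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Planned machine state at arbitrary cumulative MU
#'
#' Reconstructs the planned gantry angle, leaf and jaw positions at any
#' cumulative-monitor-unit value by linear interpolation between the
#' bracketing control-point pair, the standard reconstruction for comparing
#' reported VMAT snapshots against the plan. The gantry is interpolated on
#' its unwrapped coordinate, so arcs crossing 0/360 interpolate correctly.
#'
#' With bracketing control points `k, k+1` and
#' `t = (mu - mu_k) / (mu_{k+1} - mu_k)`, every parameter equals
#' `(1 - t) * value_k + t * value_{k+1}`. A zero-MU segment
#' (`mu_{k+1} == mu_k`) resolves to the earlier control point (`t = 0`), as
#' does a query exactly on a repeated MU knot. Interpolation is exact (bit
#' for bit) at control points.
#'
#' @param plan A validated `arc_plan`.
#' @param mu Cumulative MU value(s) at which to evaluate.
#' @param clamp If `TRUE`, out-of-range `mu` are mapped to the nearest arc
#'   endpoint and flagged in the result; if `FALSE` (default) they raise a
#'   range error.
#' @return A `planned_state` list with elements `cumulative_mu`, `gantry_deg`
#'   (wrapped to `[0, 360)`), `gantry_unwrapped_deg`, `bank_a`, `bank_b`
#'   (matrices, one row per query), `jaws`, `segment_index` and `clamped`.
#' @export
interpolate_plan <- function(plan, mu, clamp = FALSE) {
  pm <- plan$cumulative_mu
  n <- length(pm)
  if (is.null(plan$gantry_unwrapped_deg))
    plan <- validate_arc_plan(plan)
  mu <- as.numeric(mu)
  below <- mu < pm[1L]; above <- mu > pm[n]
  clamped <- below | above
  if (any(clamped) && !clamp)
    arcv_stop(sprintf("mu out of plan range [%g, %g] (use clamp = TRUE)",
                      pm[1L], pm[n]), "arcv_range_error")
  mu[below] <- pm[1L]; mu[above] <- pm[n]

  k <- findInterval(mu, pm)
  # exact hits on a knot resolve to the first control point carrying that MU
  first_occ <- match(pm, pm)
  hit <- mu == pm[k]
  k[hit] <- first_occ[k[hit]]
  seg <- pmin(k, n - 1L)
  denom <- pm[seg + 1L] - pm[seg]
  t <- ifelse(denom > 0, (mu - pm[seg]) / denom, 0)

  lerp_vec <- function(v) (1 - t) * v[seg] + t * v[seg + 1L]
  lerp_mat <- function(m) (1 - t) * m[seg, , drop = FALSE] +
    t * m[seg + 1L, , drop = FALSE]

  gu <- lerp_vec(plan$gantry_unwrapped_deg)
  structure(
    list(
      cumulative_mu = mu,
      gantry_deg = wrap360(gu),
      gantry_unwrapped_deg = gu,
      bank_a = lerp_mat(plan$bank_a),
      bank_b = lerp_mat(plan$bank_b),
      jaws = lerp_mat(plan$jaws),
      segment_index = seg,
      clamped = clamped
    ),
    class = "planned_state"
  )
}

#' Is a leaf pair shielded by the jaws?
#'
#' A pair is blocked when its transverse extent
#' `[edge_i, edge_{i+1}]` has zero-length intersection with the open Y-jaw
#' interval `(y1, y2)`: leaves that merely touch a jaw edge contribute no
#' open aperture and are excluded from positional analysis.
#'
#' @param pair_index Leaf-pair index (1-based, vectorized).
#' @param jaws Numeric vector of 4 jaw positions `x1, x2, y1, y2` in mm.
#' @param geometry A [machine_geometry()].
#' @return Logical vector, `TRUE` where the pair is blocked.
#' @details An intersection shorter than 1e-9 mm counts as zero length, so
#'   the common exactly-touching configuration (jaw edge on a leaf-pair
#'   boundary) classifies stably even after the jaw position has passed
#'   through floating-point interpolation.
#' @export
leaf_blocked <- function(pair_index, jaws, geometry = machine_geometry()) {
  if (any(pair_index < 1L | pair_index > geometry$n_leaf_pairs))
    arcv_stop("pair_index out of range", "arcv_validation_error")
  eps <- 1e-9
  ext <- pair_extents_mm(geometry)
  lo <- ext["lo", pair_index]; hi <- ext["hi", pair_index]
  y1 <- jaws[3L]; y2 <- jaws[4L]
  unname(hi <= y1 + eps | lo >= y2 - eps)
}

# Blocked mask for all pairs over several jaw rows: n x n_pairs logical.
blocked_matrix <- function(jaws, geometry) {
  t(apply(jaws, 1L, function(j) leaf_blocked(seq_len(geometry$n_leaf_pairs),
                                             j, geometry)))
}

#' Compare a delivery record against its plan
#'
#' For every reported snapshot, the planned state is reconstructed with
#' [interpolate_plan()] at the snapshot's reported cumulative MU, and signed
#' errors (reported minus planned) are computed for each of the 80 leaves,
#' the 4 jaws and the gantry angle (shortest signed angular difference).
#' Leaves belonging to pairs shielded by the planned (interpolated) Y jaws
#' are flagged as excluded but their errors are retained, so metrics can be
#' recomputed under different exclusion rules.
#'
#' Reported MU slightly outside the planned range is clamped to the nearest
#' arc endpoint with a warning rather than rejected.
#'
#' @param plan A validated `arc_plan`.
#' @param record A `delivery_record` for the same patient and field.
#' @param geometry A [machine_geometry()].
#' @return An `error_log` with matrices `leaf_errors` (snapshots x 80, bank A
#'   columns then bank B), `leaf_excluded`, `jaw_errors` (x 4), vector
#'   `gantry_errors`, and the planned/reported values they derive from.
#' @export
compute_errors <- function(plan, record, geometry = machine_geometry()) {
  if (!identical(plan$patient_id, record$patient_id) ||
      !identical(plan$field_id, record$field_id))
    arcv_stop(sprintf(
      "plan (%s/%s) and record (%s/%s) identify different fields",
      plan$patient_id, plan$field_id, record$patient_id, record$field_id),
      "arcv_pairing_error")
  plan <- validate_arc_plan(plan, geometry)
  record <- validate_delivery_record(record, geometry)

  st <- interpolate_plan(plan, record$cumulative_mu, clamp = TRUE)
  if (any(st$clamped))
    arcv_warn(sprintf(
      "%d snapshot(s) report cumulative MU outside the planned range; clamped to the arc endpoints",
      sum(st$clamped)), "arcv_clamp_warning")

  np <- geometry$n_leaf_pairs
  leaf_planned <- cbind(st$bank_a, st$bank_b)
  leaf_reported <- cbind(record$bank_a, record$bank_b)
  colnames(leaf_planned) <- colnames(leaf_reported) <- leaf_ids(np)
  excl_pairs <- blocked_matrix(st$jaws, geometry)
  leaf_excluded <- cbind(excl_pairs, excl_pairs)
  colnames(leaf_excluded) <- leaf_ids(np)
  jaw_planned <- st$jaws
  jaw_reported <- record$jaws
  colnames(jaw_planned) <- colnames(jaw_reported) <- jaw_ids()

  structure(
    list(
      patient_id = plan$patient_id,
      field_id = plan$field_id,
      fraction_date = record$fraction_date,
      cumulative_mu = record$cumulative_mu,
      leaf_planned = leaf_planned,
      leaf_reported = leaf_reported,
      leaf_errors = leaf_reported - leaf_planned,
      leaf_excluded = leaf_excluded,
      gantry_planned = st$gantry_deg,
      gantry_reported = record$gantry_deg,
      gantry_errors = angular_error(record$gantry_deg, st$gantry_deg),
      jaw_planned = jaw_planned,
      jaw_reported = jaw_reported,
      jaw_errors = jaw_reported - jaw_planned
    ),
    class = "error_log"
  )
}

#' @export
print.error_log <- function(x, ...) {
  n <- nrow(x$leaf_errors)
  cat(sprintf(
    "<error_log> patient %s field %s on %s: %d snapshots, %d leaf samples (%d excluded)\n",
    x$patient_id, x$field_id, x$fraction_date, n,
    length(x$leaf_errors), sum(x$leaf_excluded)))
  invisible(x)
}

validate_error_log <- function(log) {
  n <- nrow(x = log$leaf_errors)
  nl <- ncol(log$leaf_errors)
  ok <- n >= 1L &&
    identical(dim(log$leaf_errors), dim(log$leaf_excluded)) &&
    identical(dim(log$leaf_errors), dim(log$leaf_planned)) &&
    identical(dim(log$leaf_errors), dim(log$leaf_reported)) &&
    length(log$gantry_errors) == n &&
    nrow(log$jaw_errors) == n && ncol(log$jaw_errors) == 4L &&
    length(log$cumulative_mu) == n && nl %% 2L == 0L
  if (!ok)
    arcv_stop("error log has inconsistent shapes", "arcv_validation_error")
  invisible(log)
}
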