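#' Machine geometry of the treatment head
#'
#' Describes the multileaf collimator (MLC) and delivery hardware assumed by
#' the verification pipeline: an 80-leaf MLC arranged as 40 opposing pairs of
#' 1 cm projected width at isocenter, discretely variable dose rates, and a
#' maximum planned leaf travel per degree of gantry rotation.
#'
#' Leaf pair `i` occupies the transverse (Y) interval
#' `[leaf_pair_y_edges[i], leaf_pair_y_edges[i + 1]]`, in cm at the isocenter
#' plane. Leaf and jaw *positions* along the travel direction are expressed in
#' mm at isocenter throughout the package; only the leaf-bank geometry is kept
#' in cm (the unit leaf widths are quoted in).
#'
#' @param n_leaf_pairs Number of opposing leaf pairs (default 40, i.e. 80
#'   leaves).
#' @param leaf_width_iso Projected leaf width at isocenter, cm (default 1.0).
#' @param leaf_pair_y_edges Strictly increasing vector of `n_leaf_pairs + 1`
#'   pair-boundary coordinates, cm at isocenter. Defaults to a contiguous bank
#'   centered on the beam axis.
#' @param dose_rates Nominal dose rates available to the control system,
#'   MU/min. All positive.
#' @param max_leaf_speed Maximum planned leaf travel per degree of gantry
#'   rotation, mm/deg (default 4).
#' @return An object of class `machine_geometry`.
#' @export
machine_geometry <- function(n_leaf_pairs = 40L,
                             leaf_width_iso = 1.0,
                             leaf_pair_y_edges = NULL,
                             dose_rates = c(500, 250, 125, 63, 37),
                             max_leaf_speed = 4.0) {
  n_leaf_pairs <- as.integer(n_leaf_pairs)
  if (is.na(n_leaf_pairs) || n_leaf_pairs < 1L)
    arcv_stop("'n_leaf_pairs' must be a positive integer",
              "arcv_validation_error")
  stopifnot_scalar_num(leaf_width_iso, "leaf_width_iso", positive = TRUE)
  if (is.null(leaf_pair_y_edges)) {
    leaf_pair_y_edges <-
      seq(-n_leaf_pairs / 2, n_leaf_pairs / 2) * leaf_width_iso
  }
  if (length(leaf_pair_y_edges) != n_leaf_pairs + 1L)
    arcv_stop(sprintf("'leaf_pair_y_edges' must have %d values (n_leaf_pairs + 1)",
                      n_leaf_pairs + 1L), "arcv_validation_error")
  if (any(diff(leaf_pair_y_edges) <= 0))
    arcv_stop("'leaf_pair_y_edges' must be strictly increasing",
              "arcv_validation_error")
  if (!is.numeric(dose_rates) || length(dose_rates) < 1L ||
      any(!is.finite(dose_rates)) || any(dose_rates <= 0))
    arcv_stop("'dose_rates' must be positive", "arcv_validation_error")
  stopifnot_scalar_num(max_leaf_speed, "max_leaf_speed", positive = TRUE)

  structure(
    list(
      n_leaf_pairs = n_leaf_pairs,
      leaf_width_iso = leaf_width_iso,
      leaf_pair_y_edges = as.numeric(leaf_pair_y_edges),
      dose_rates = as.numeric(dose_rates),
      max_leaf_speed = max_leaf_speed
    ),
    class = "machine_geometry"
  )
}

#' @export
print.machine_geometry <- function(x, ...) {
  cat(sprintf(
    "<machine_geometry> %d leaf pairs (%g cm width), dose rates %s MU/min, max leaf speed %g mm/deg\n",
    x$n_leaf_pairs, x$leaf_width_iso,
    paste(x$dose_rates, collapse = "/"), x$max_leaf_speed))
  invisible(x)
}

n_leaves <- function(geometry) 2L * geometry$n_leaf_pairs

# Leaf-pair transverse extents in mm at isocenter (rows: lo, hi).
pair_extents_mm <- function(geometry) {
  e <- geometry$leaf_pair_y_edges * 10
  rbind(lo = e[-length(e)], hi = e[-1L])
}
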