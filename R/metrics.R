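#' Percentage of samples within tolerance
#'
#' `100 * #(|error| <= tolerance) / #included`, the headline daily QA metric
#' (e.g. P3mm for MLC leaves, P2deg for the gantry). The comparison is
#' inclusive at the boundary. Samples flagged excluded (jaw-blocked leaves)
#' are removed before counting.
#'
#' @param errors Numeric vector or matrix of signed errors.
#' @param tolerance Positive tolerance in the same unit as `errors`.
#' @param excluded Optional logical mask of the same shape; `TRUE` entries
#'   are dropped.
#' @return Percentage in `[0, 100]`.
#' @export
percent_within <- function(errors, tolerance, excluded = NULL) {
  stopifnot_scalar_num(tolerance, "tolerance", positive = TRUE)
  e <- as.numeric(errors)
  if (!is.null(excluded)) {
    if (length(excluded) != length(e))
      arcv_stop("'excluded' mask does not match 'errors'",
                "arcv_validation_error")
    e <- e[!excluded]
  }
  if (length(e) == 0L)
    arcv_stop("no included samples: percent-within-tolerance is undefined",
              "arcv_undefined_metric")
  100 * mean(abs(e) <= tolerance)
}

# Histogram with bins of width `bin_width` centered on zero (one bin center
# at 0), covering the data range. Counts sum to length(x).
error_histogram <- function(x, bin_width) {
  x <- as.numeric(x)
  if (length(x) == 0L) {
    return(list(breaks = c(-bin_width / 2, bin_width / 2),
                counts = 0L, bin_width = bin_width))
  }
  m <- max(ceiling((max(abs(x)) - bin_width / 2) / bin_width), 0) + 1L
  breaks <- seq(-(m - 0.5) * bin_width, (m - 0.5) * bin_width,
                by = bin_width)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  list(breaks = breaks, counts = counts, bin_width = bin_width)
}

metric_name <- function(kind, tol, unit) {
  sprintf("P%g%s_%s", tol, unit, kind)
}

#' Summarize one fraction's error log
#'
#' Aggregates an [compute_errors()] log into the per-fraction statistics a
#' daily report is built from: percent-within-tolerance for MLC leaves,
#' gantry and jaws at the headline tolerances and across the tabulation
#' sweep, per-leaf RMS error (over included samples only), zero-centered
#' error histograms, and sample counts.
#'
#' @param log An `error_log`.
#' @param config A [tolerance_config()].
#' @param bin_width_mm Histogram bin width for leaf and jaw errors, mm.
#' @param bin_width_deg Histogram bin width for gantry errors, degrees.
#' @return A `fraction_summary` with elements `headline` (named metrics such
#'   as `P3mm_mlc`, `P2deg_gantry`, `P3mm_jaw`), `p_within` (data frame
#'   `kind, tolerance, percent`), `rms_per_leaf` (`NA` for leaves excluded at
#'   every snapshot), `histograms` and counts.
#' @details A leaf shielded by the jaws throughout the fraction has no
#'   included samples; its RMS is reported as `NA` rather than 0 so it cannot
#'   be mistaken for a perfectly tracking leaf.
#' @export
summarize_fraction <- function(log, config = tolerance_config(),
                               bin_width_mm = 0.5, bin_width_deg = 0.5) {
  validate_error_log(log)
  inc <- !log$leaf_excluded
  leaf_inc <- log$leaf_errors[inc]

  sweep_rows <- function(kind, errors, excluded, tols) {
    data.frame(
      kind = kind, tolerance = tols,
      percent = vapply(tols, function(tl)
        percent_within(errors, tl, excluded), 0.0)
    )
  }
  tol_mlc <- sort(unique(c(config$sweep, config$mlc_mm)))
  tol_gan <- sort(unique(c(config$sweep, config$gantry_deg)))
  tol_jaw <- sort(unique(c(config$sweep, config$jaw_mm)))
  p_within <- rbind(
    sweep_rows("mlc", log$leaf_errors, log$leaf_excluded, tol_mlc),
    sweep_rows("gantry", log$gantry_errors, NULL, tol_gan),
    sweep_rows("jaw", log$jaw_errors, NULL, tol_jaw)
  )
  lookup <- function(kind, tol)
    p_within$percent[p_within$kind == kind & p_within$tolerance == tol]
  headline <- stats::setNames(
    c(lookup("mlc", config$mlc_mm),
      lookup("gantry", config$gantry_deg),
      lookup("jaw", config$jaw_mm)),
    c(metric_name("mlc", config$mlc_mm, "mm"),
      metric_name("gantry", config$gantry_deg, "deg"),
      metric_name("jaw", config$jaw_mm, "mm"))
  )

  sq <- log$leaf_errors^2
  sq[!inc] <- NA
  n_inc_leaf <- colSums(inc)
  rms <- sqrt(colMeans(sq, na.rm = TRUE))
  rms[n_inc_leaf == 0L] <- NA_real_

  structure(
    list(
      patient_id = log$patient_id,
      field_id = log$field_id,
      fraction_date = log$fraction_date,
      headline = headline,
      p_within = p_within,
      rms_per_leaf = rms,
      histograms = list(
        mlc = error_histogram(leaf_inc, bin_width_mm),
        gantry = error_histogram(log$gantry_errors, bin_width_deg),
        jaw = error_histogram(log$jaw_errors, bin_width_mm)
      ),
      n_included_leaf = sum(inc),
      n_excluded_leaf = sum(!inc),
      n_gantry = length(log$gantry_errors),
      n_jaw = length(log$jaw_errors)
    ),
    class = "fraction_summary"
  )
}

#' @export
print.fraction_summary <- function(x, ...) {
  cat(sprintf("<fraction_summary> patient %s field %s on %s\n",
              x$patient_id, x$field_id, x$fraction_date))
  for (nm in names(x$headline))
    cat(sprintf("  %-14s %6.2f %%\n", nm, x$headline[[nm]]))
  cat(sprintf("  leaf samples: %d included, %d excluded\n",
              x$n_included_leaf, x$n_excluded_leaf))
  invisible(x)
}

#' Planned leaf-motion statistics of an arc
#'
#' Leaf speed is expressed in mm of leaf travel per degree of gantry
#' rotation, the natural complexity scale for VMAT: for each control-point
#' segment and each leaf, `|leaf_{k+1} - leaf_k| / |gantry_{k+1} - gantry_k|`
#' on the unwrapped gantry coordinate. The fraction of leaf movements
#' requiring more than 1 mm/deg (strict) is a per-plan complexity index that
#' correlates negatively with delivery accuracy.
#'
#' @param plan A validated `arc_plan`.
#' @param bin_width Histogram bin width for speeds, mm/deg.
#' @return A `plan_motion_summary` with the `(segments x 80)` speed matrix,
#'   `frac_gt_1mm_per_deg`, mean speed and a speed histogram.
#' @export
plan_motion_summary <- function(plan, bin_width = 0.25) {
  plan <- validate_arc_plan(plan)
  du <- diff(plan$gantry_unwrapped_deg)
  if (any(du == 0))
    arcv_stop(sprintf("segment %d has zero gantry travel: leaf speed undefined",
                      which(du == 0)[1L]), "arcv_degenerate_segment")
  leaves <- cbind(plan$bank_a, plan$bank_b)
  colnames(leaves) <- leaf_ids(ncol(plan$bank_a))
  speeds <- abs(apply(leaves, 2L, diff)) / abs(du)
  if (is.null(dim(speeds))) speeds <- matrix(speeds, nrow = 1L,
                                             dimnames = list(NULL, colnames(leaves)))
  hist_breaks <- seq(0, max(ceiling(max(speeds) / bin_width), 1L) * bin_width,
                     by = bin_width)
  structure(
    list(
      patient_id = plan$patient_id,
      field_id = plan$field_id,
      leaf_speeds = speeds,
      mean_speed = mean(speeds),
      frac_gt_1mm_per_deg = 100 * mean(speeds > 1),
      speed_histogram = list(
        breaks = hist_breaks,
        counts = tabulate(findInterval(speeds, hist_breaks,
                                       rightmost.closed = TRUE),
                          nbins = length(hist_breaks) - 1L),
        bin_width = bin_width
      )
    ),
    class = "plan_motion_summary"
  )
}

#' Aggregate fraction summaries into a trend table
#'
#' Builds the multi-fraction history a trend chart and drift alerts work
#' from: a date-ordered per-fraction table of the headline metrics, overall
#' mean and SD per metric, and per-patient mean, SD and 2*SD across each
#' patient's fractions (the per-patient reproducibility figure), plus the
#' average over patients of the per-patient SDs.
#'
#' A patient (or metric) with a single fraction has SD 0 by convention: one
#' observation shows no spread.
#'
#' @param summaries List of `fraction_summary` objects.
#' @return A `trend_table` with `fractions`, `overall`, `per_patient` data
#'   frames and `mean_patient_sd`.
#' @export
aggregate_history <- function(summaries) {
  if (length(summaries) == 0L)
    arcv_stop("no fraction summaries to aggregate", "arcv_validation_error")
  metrics <- names(summaries[[1L]]$headline)
  rows <- lapply(summaries, function(s) {
    vals <- s$headline[metrics]
    if (anyNA(vals))
      arcv_stop("fraction summaries report different headline metrics",
                "arcv_validation_error")
    cbind(data.frame(patient_id = s$patient_id, field_id = s$field_id,
                     fraction_date = s$fraction_date,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)))
  })
  frac <- do.call(rbind, rows)
  metrics <- setdiff(names(frac), c("patient_id", "field_id", "fraction_date"))
  frac <- frac[order(frac$fraction_date, frac$patient_id, frac$field_id), ,
               drop = FALSE]
  rownames(frac) <- NULL

  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  overall <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(frac[[m]]), 0.0),
    sd = vapply(metrics, function(m) sd0(frac[[m]]), 0.0),
    row.names = NULL
  )
  pp <- do.call(rbind, lapply(split(frac, frac$patient_id), function(d) {
    data.frame(
      patient_id = d$patient_id[1L],
      metric = metrics,
      n_fractions = nrow(d),
      mean = vapply(metrics, function(m) mean(d[[m]]), 0.0),
      sd = vapply(metrics, function(m) sd0(d[[m]]), 0.0),
      sd2 = vapply(metrics, function(m) 2 * sd0(d[[m]]), 0.0),
      row.names = NULL
    )
  }))
  rownames(pp) <- NULL
  mean_psd <- vapply(metrics, function(m)
    mean(pp$sd[pp$metric == m]), 0.0)

  structure(
    list(fractions = frac, overall = overall, per_patient = pp,
         mean_patient_sd = mean_psd, metrics = metrics),
    class = "trend_table"
  )
}

#' @export
print.trend_table <- function(x, ...) {
  cat(sprintf("<trend_table> %d fractions, %d patients\n",
              nrow(x$fractions), length(unique(x$fractions$patient_id))))
  print(x$overall)
  invisible(x)
}

#' Pearson product-moment correlation coefficient
#'
#' Direct evaluation of `sum((x - mx)(y - my)) / sqrt(sum((x - mx)^2)
#' sum((y - my)^2))`, used to assess linear dependence between two error
#' series (e.g. verification-system vs control-system leaf errors).
#'
#' @param x,y Numeric vectors of equal length, at least 3, neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    arcv_stop("'x' and 'y' must have equal length", "arcv_validation_error")
  if (length(x) < 3L)
    arcv_stop("need at least 3 paired samples", "arcv_validation_error")
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sum(xc^2); sy <- sum(yc^2)
  if (sx == 0 || sy == 0)
    arcv_stop("correlation undefined for a constant series",
              "arcv_undefined_metric")
  r <- sum(xc * yc) / sqrt(sx * sy)
  max(-1, min(1, r))
}

#' Pair plan complexity with delivered accuracy
#'
#' Matches per-fraction planned-motion summaries to their fraction summaries
#' and returns the paired series (percentage of leaf movements over 1 mm/deg,
#' headline MLC percent-within-tolerance) for plotting or correlation: the
#' complexity-accuracy relationship.
#'
#' @param plan_summaries Named list of [plan_motion_summary()] results, keyed
#'   by fraction.
#' @param fraction_summaries Named list of [summarize_fraction()] results
#'   with identical keys.
#' @return Data frame `key, frac_gt_1mm_per_deg, p_mlc` in the key order of
#'   `plan_summaries`.
#' @export
speed_error_relation <- function(plan_summaries, fraction_summaries) {
  kp <- names(plan_summaries); kf <- names(fraction_summaries)
  if (is.null(kp) || is.null(kf) || !setequal(kp, kf) ||
      length(kp) != length(kf))
    arcv_stop("plan and fraction summaries must share the same keys",
              "arcv_pairing_error")
  data.frame(
    key = kp,
    frac_gt_1mm_per_deg = vapply(plan_summaries, function(s)
      s$frac_gt_1mm_per_deg, 0.0),
    p_mlc = vapply(kp, function(k)
      fraction_summaries[[k]]$headline[[1L]], 0.0),
    row.names = NULL
  )
}
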