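#' Declarative alert rule over fraction metrics
#'
#' Formalizes "notify when predefined tolerance values are exceeded" as a
#' rule on a summary metric: a fraction-scoped rule fires on every fraction
#' whose metric violates the comparator; a window-scoped rule fires on every
#' trailing window (over the date-ordered fraction series) whose mean
#' violates it, which is how slow calibration drift is caught.
#'
#' @param metric Metric name, e.g. `"P3mm_mlc"`, `"P2deg_gantry"`,
#'   `"P3mm_jaw"`.
#' @param comparator `"below"` (fires when observed < threshold) or
#'   `"above"` (observed > threshold).
#' @param threshold Finite scalar.
#' @param scope `"fraction"` or `"window"`.
#' @param window Trailing-window length in fractions (window scope only).
#' @return An `alert_rule`.
#' @export
alert_rule <- function(metric, comparator = c("below", "above"), threshold,
                       scope = c("fraction", "window"), window = 1L) {
  comparator <- match.arg(comparator)
  scope <- match.arg(scope)
  stopifnot_scalar_num(threshold, "threshold")
  window <- as.integer(window)
  if (scope == "window" && window < 1L)
    arcv_stop("'window' must be >= 1 for window-scoped rules",
              "arcv_config_error")
  structure(
    list(metric = metric, comparator = comparator, threshold = threshold,
         scope = scope, window = window),
    class = "alert_rule"
  )
}

rule_violated <- function(rule, observed) {
  if (rule$comparator == "below") observed < rule$threshold
  else observed > rule$threshold
}

#' Evaluate alert rules against fraction summaries
#'
#' @param summaries List of `fraction_summary` objects.
#' @param rules List of [alert_rule()]s.
#' @return List of `alert_event`s, ordered by fraction date then rule;
#'   each carries the rule, the patient/date keys, the observed value and a
#'   rendered message. Empty list when nothing fires.
#' @export
evaluate_alerts <- function(summaries, rules) {
  if (length(rules) == 0L) return(list())
  trend <- aggregate_history(summaries)
  frac <- trend$fractions
  for (rule in rules) {
    if (!rule$metric %in% trend$metrics)
      arcv_stop(sprintf("alert rule references unknown metric '%s' (have: %s)",
                        rule$metric, paste(trend$metrics, collapse = ", ")),
                "arcv_config_error")
  }
  events <- list()
  for (ri in seq_along(rules)) {
    rule <- rules[[ri]]
    vals <- frac[[rule$metric]]
    if (rule$scope == "fraction") {
      hits <- which(rule_violated(rule, vals))
      for (i in hits) {
        events[[length(events) + 1L]] <- alert_event(
          rule, ri, frac$patient_id[i], frac$fraction_date[i], vals[i],
          sprintf("%s = %.2f %s threshold %.2f for patient %s on %s",
                  rule$metric, vals[i], rule$comparator, rule$threshold,
                  frac$patient_id[i], frac$fraction_date[i]))
      }
    } else {
      w <- rule$window
      if (length(vals) >= w) {
        for (i in w:length(vals)) {
          m <- mean(vals[(i - w + 1L):i])
          if (rule_violated(rule, m)) {
            events[[length(events) + 1L]] <- alert_event(
              rule, ri, NA_character_, frac$fraction_date[i], m,
              sprintf("trailing %d-fraction mean %s = %.2f %s threshold %.2f (window ending %s)",
                      w, rule$metric, m, rule$comparator, rule$threshold,
                      frac$fraction_date[i]))
          }
        }
      }
    }
  }
  ord <- order(vapply(events, `[[`, "", "fraction_date"),
               vapply(events, `[[`, 0L, "rule_index"))
  events[ord]
}

alert_event <- function(rule, rule_index, patient_id, fraction_date,
                        observed, message) {
  structure(
    list(rule = rule, rule_index = rule_index, patient_id = patient_id,
         fraction_date = fraction_date, observed = observed,
         message = message),
    class = "alert_event"
  )
}

#' @export
print.alert_event <- function(x, ...) {
  cat("<alert_event>", x$message, "\n")
  invisible(x)
}

#' Notification sinks
#'
#' Transport for alert messages is pluggable: a sink is a list with a
#' `deliver(text, event)` function. `file_sink()` writes one numbered text
#' file per message into a directory (the scheduler-friendly stand-in for
#' email); `list_sink()` collects messages in memory for inspection and
#' testing.
#'
#' @param dir Output directory (created if missing).
#' @return A sink object.
#' @export
file_sink <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  count <- new.env(parent = emptyenv()); count$n <- 0L
  structure(
    list(deliver = function(text, event) {
      count$n <- count$n + 1L
      path <- file.path(dir, sprintf("alert-%03d.txt", count$n))
      writeLines(text, path)
      path
    }),
    class = "arcv_sink"
  )
}

#' @rdname file_sink
#' @export
list_sink <- function() {
  store <- new.env(parent = emptyenv()); store$messages <- character(0)
  structure(
    list(deliver = function(text, event) {
      store$messages <- c(store$messages, text)
      length(store$messages)
    },
    messages = function() store$messages),
    class = "arcv_sink"
  )
}

#' Deliver alert events through a sink
#'
#' Each event is serialized to one message and handed to the sink. A sink
#' failure never loses an event: failed deliveries are returned in the
#' `undelivered` queue alongside per-event receipts.
#'
#' @param events List of `alert_event`s.
#' @param sink A sink from [file_sink()] or [list_sink()].
#' @return A list with `receipts` (data frame: message, delivered, detail)
#'   and `undelivered` (the failed events).
#' @export
notify <- function(events, sink) {
  if (!inherits(sink, "arcv_sink"))
    arcv_stop("'sink' must be an arcv_sink", "arcv_config_error")
  receipts <- data.frame(message = character(0), delivered = logical(0),
                         detail = character(0))
  undelivered <- list()
  for (ev in events) {
    res <- tryCatch(sink$deliver(ev$message, ev), error = function(e) e)
    ok <- !inherits(res, "error")
    if (!ok) undelivered[[length(undelivered) + 1L]] <- ev
    receipts <- rbind(receipts, data.frame(
      message = ev$message, delivered = ok,
      detail = if (ok) as.character(res) else conditionMessage(res)))
  }
  list(receipts = receipts, undelivered = undelivered)
}

#' Render a machine-readable per-fraction report
#'
#' Produces the single-fraction analysis artifact: headline percentages, the
#' tolerance-sweep table, histogram data and per-leaf RMS, as a versioned
#' JSON-serializable list (schema `arcverify-report/1`). Rendering is
#' lossless: numbers survive a write/re-parse round trip exactly. With
#' `figures = TRUE` a four-panel PDF (leaf, gantry and jaw error histograms
#' plus per-leaf RMS) is drawn next to the JSON.
#'
#' @param summary A `fraction_summary`.
#' @param log Optional `error_log` the summary derives from (used only for
#'   figures).
#' @param path Optional output path for the JSON document.
#' @param figures If `TRUE`, also render the four-panel figure.
#' @param figure_path Path of the PDF (defaults next to `path`).
#' @return The report list, invisibly when written to `path`.
#' @export
render_fraction_report <- function(summary, log = NULL, path = NULL,
                                   figures = FALSE, figure_path = NULL) {
  report <- list(
    schema = "arcverify-report/1",
    kind = "fraction",
    patient_id = summary$patient_id,
    field_id = summary$field_id,
    fraction_date = summary$fraction_date,
    headline = as.list(summary$headline),
    tolerance_sweep = summary$p_within,
    rms_per_leaf = summary$rms_per_leaf,
    histograms = summary$histograms,
    counts = list(
      n_included_leaf = summary$n_included_leaf,
      n_excluded_leaf = summary$n_excluded_leaf,
      n_gantry = summary$n_gantry,
      n_jaw = summary$n_jaw
    )
  )
  if (!is.null(path)) write_report_json(report, path)
  if (figures) {
    if (is.null(figure_path))
      figure_path <- if (!is.null(path))
        sub("\\.json$", ".pdf", path) else
          arcv_stop("figures = TRUE needs 'path' or 'figure_path'",
                    "arcv_config_error")
    plot_fraction_panels(summary, figure_path)
  }
  if (is.null(path)) report else invisible(report)
}

plot_fraction_panels <- function(summary, figure_path) {
  grDevices::pdf(figure_path, width = 9, height = 7)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(op), add = TRUE)
  hp <- function(h, main, xlab) {
    mids <- (h$breaks[-1L] + h$breaks[-length(h$breaks)]) / 2
    graphics::barplot(h$counts, names.arg = sprintf("%.2g", mids),
                      main = main, xlab = xlab, ylab = "count",
                      border = NA, col = "grey40", las = 2,
                      cex.names = 0.6)
  }
  hp(summary$histograms$mlc, "MLC leaf errors", "error (mm)")
  hp(summary$histograms$gantry, "Gantry errors", "error (deg)")
  hp(summary$histograms$jaw, "Jaw errors", "error (mm)")
  graphics::plot(seq_along(summary$rms_per_leaf), summary$rms_per_leaf,
                 type = "h", lwd = 2, col = "grey40",
                 main = "Per-leaf RMS error", xlab = "leaf",
                 ylab = "RMS (mm)")
  invisible(figure_path)
}

#' Render the historical trend report
#'
#' Per-metric, date-ordered series of the headline metrics across fractions
#' with overall mean and SD, per-patient variability, and annotation hooks
#' for dated machine events (e.g. servo calibration adjustments) so trend
#' charts can mark when the machine was touched.
#'
#' @param trend A `trend_table` from [aggregate_history()].
#' @param annotations Optional data frame with columns `date`, `label`.
#' @param path Optional JSON output path.
#' @return The report list, invisibly when written.
#' @export
render_history_report <- function(trend, annotations = NULL, path = NULL) {
  report <- list(
    schema = "arcverify-report/1",
    kind = "history",
    series = trend$fractions,
    overall = trend$overall,
    per_patient = trend$per_patient,
    mean_patient_sd = as.list(trend$mean_patient_sd),
    annotations = annotations
  )
  if (!is.null(path)) write_report_json(report, path)
  if (is.null(path)) report else invisible(report)
}

write_report_json <- function(report, path) {
  # I(17) = 17 *significant* digits: doubles survive write/re-parse exactly
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", dataframe = "columns")
  invisible(path)
}

#' Read configuration (tolerances, binning, alert rules)
#'
#' JSON natively; YAML when the `yaml` package is installed and the file
#' extension is `.yaml`/`.yml`. Recognized top-level keys: `tolerances`
#' (mlc_mm, gantry_deg, jaw_mm, sweep), `bin_width_mm`, `bin_width_deg`, and
#' `alerts` (array of rule objects with metric, comparator, threshold,
#' scope, window).
#'
#' @param path Config file path.
#' @return List with `tolerances` ([tolerance_config()]), `bin_width_mm`,
#'   `bin_width_deg` and `rules`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    arcv_stop(sprintf("config not found: %s", path), "arcv_io_error")
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      arcv_stop("YAML config requires the 'yaml' package", "arcv_config_error")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  tol <- raw$tolerances %||% list()
  rules <- list()
  if (!is.null(raw$alerts)) {
    alerts <- raw$alerts
    if (is.data.frame(alerts))
      alerts <- lapply(seq_len(nrow(alerts)), function(i)
        as.list(alerts[i, , drop = FALSE]))
    rules <- lapply(alerts, function(a)
      alert_rule(metric = a$metric,
                 comparator = a$comparator %||% "below",
                 threshold = a$threshold,
                 scope = a$scope %||% "fraction",
                 window = a$window %||% 1L))
  }
  list(
    tolerances = tolerance_config(
      mlc_mm = tol$mlc_mm %||% 3, gantry_deg = tol$gantry_deg %||% 2,
      jaw_mm = tol$jaw_mm %||% 3, sweep = unlist(tol$sweep) %||% c(1, 2, 3, 5)),
    bin_width_mm = raw$bin_width_mm %||% 0.5,
    bin_width_deg = raw$bin_width_deg %||% 0.5,
    rules = rules
  )
}
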