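#' File dialects for plans, delivery records and error logs
#'
#' Plain-text formats carry everything the pipeline exchanges, replacing a
#' record-and-verify database with files any scheduler can move around:
#'
#' * **Plan** (`# arcverify-plan v1`): CSV, metadata lines
#'   (`patient_id`, `field_id`, `collimator_deg`, `rotation_sense`) then one
#'   row per control point:
#'   `index, cumulative_mu, gantry_deg, a01..a40, b01..b40, x1, x2, y1, y2`.
#' * **Record** (`# arcverify-record v1`): same column layout plus a
#'   `fraction_date` metadata line; one row per reported snapshot.
#' * **Error log** (`# arcverify-errorlog v1`): TSV, one row per
#'   (snapshot, parameter) with columns
#'   `boundary_index, param_kind, param_id, planned, reported, error,
#'   excluded` — 80 leaf rows, 4 jaw rows and 1 gantry row per snapshot.
#'   Excluded leaves are serialized with `excluded = 1`, never dropped.
#'
#' All units are stated in the header line: mm at isocenter, degrees, MU.
#' Numbers are written with 17 significant digits so write-then-read is the
#' identity on IEEE doubles.
#'
#' @name arcverify-io
NULL

FMT <- "%.17g"
fmt_num <- function(x) sprintf(FMT, x)

plan_columns <- function(np = 40L) {
  c("index", "cumulative_mu", "gantry_deg", leaf_ids(np), jaw_ids())
}

write_meta <- function(keys) {
  vapply(names(keys), function(k) sprintf("# %s=%s", k, keys[[k]]), "")
}

parse_meta <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines, regexec("^#\\s*([A-Za-z_]+)=(.*)$", meta_lines))
  kv <- Filter(function(m) length(m) == 3L, kv)
  stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L))
}

parse_numeric_rows <- function(lines, line_no, n_cols, sep, path) {
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(parts) != n_cols)
  if (length(bad))
    arcv_stop(sprintf("%s line %d: expected %d fields, found %d",
                      path, line_no[bad[1L]], n_cols,
                      lengths(parts)[bad[1L]]), "arcv_format_error")
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              nrow = length(lines), ncol = n_cols, byrow = TRUE)
  if (anyNA(m)) {
    bad_row <- which(apply(is.na(m), 1L, any))[1L]
    arcv_stop(sprintf("%s line %d: non-numeric value", path,
                      line_no[bad_row]), "arcv_format_error")
  }
  m
}

read_dialect_table <- function(path, magic, sep = ",") {
  if (!file.exists(path))
    arcv_stop(sprintf("file not found: %s", path), "arcv_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || !startsWith(lines[1L], paste0("# ", magic)))
    arcv_stop(sprintf("%s: missing '%s' header line", path, magic),
              "arcv_format_error")
  meta <- parse_meta(lines)
  body_idx <- which(!startsWith(lines, "#"))
  if (length(body_idx) < 2L)
    arcv_stop(sprintf("%s: no data rows", path), "arcv_format_error")
  header <- strsplit(lines[body_idx[1L]], sep, fixed = TRUE)[[1L]]
  data_idx <- body_idx[-1L]
  list(meta = meta, header = trimws(header),
       rows = lines[data_idx], row_lines = data_idx)
}

split_columns <- function(m, header, np, path) {
  want <- plan_columns(np)
  if (!identical(header, want)) {
    missing <- setdiff(want, header)
    msg <- if (length(missing))
      sprintf("%s: missing column(s): %s", path,
              paste(utils::head(missing, 5L), collapse = ", "))
    else sprintf("%s: unexpected column layout (%d columns, need %d)",
                 path, length(header), length(want))
    arcv_stop(msg, "arcv_format_error")
  }
  list(
    cumulative_mu = m[, 2L],
    gantry_deg = m[, 3L],
    bank_a = m[, 3L + seq_len(np), drop = FALSE],
    bank_b = m[, 3L + np + seq_len(np), drop = FALSE],
    jaws = m[, 3L + 2L * np + 1:4, drop = FALSE]
  )
}

#' Read a planned arc from the plan dialect
#'
#' @param path Path to a `# arcverify-plan v1` CSV file.
#' @param geometry A [machine_geometry()].
#' @return A validated [arc_plan()]; `rotation_sense` is inferred from the
#'   unwrapped gantry sequence when the metadata line is absent.
#' @export
read_plan <- function(path, geometry = machine_geometry()) {
  tab <- read_dialect_table(path, "arcverify-plan v1")
  np <- geometry$n_leaf_pairs
  m <- parse_numeric_rows(tab$rows, tab$row_lines,
                          length(plan_columns(np)), ",", path)
  cols <- split_columns(m, tab$header, np, path)
  sense <- if (!is.null(tab$meta$rotation_sense))
    as.integer(tab$meta$rotation_sense) else NULL
  arc_plan(
    patient_id = tab$meta$patient_id %||% "unknown",
    field_id = tab$meta$field_id %||% "unknown",
    collimator_deg = as.numeric(tab$meta$collimator_deg %||% 45),
    rotation_sense = sense,
    cumulative_mu = cols$cumulative_mu, gantry_deg = cols$gantry_deg,
    bank_a = cols$bank_a, bank_b = cols$bank_b, jaws = cols$jaws,
    geometry = geometry
  )
}

#' Write a planned arc in the plan dialect
#'
#' @param plan An `arc_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  np <- ncol(plan$bank_a)
  header <- c(
    "# arcverify-plan v1; units=mm,deg,MU",
    write_meta(list(patient_id = plan$patient_id,
                    field_id = plan$field_id,
                    collimator_deg = fmt_num(plan$collimator_deg),
                    rotation_sense = plan$rotation_sense)),
    paste(plan_columns(np), collapse = ",")
  )
  body <- row_lines(plan, np, ",")
  write_lines_checked(c(header, body), path)
}

#' Read a delivery record from the record dialect
#'
#' @inheritParams read_plan
#' @return A validated [delivery_record()].
#' @export
read_record <- function(path, geometry = machine_geometry()) {
  tab <- read_dialect_table(path, "arcverify-record v1")
  np <- geometry$n_leaf_pairs
  m <- parse_numeric_rows(tab$rows, tab$row_lines,
                          length(plan_columns(np)), ",", path)
  cols <- split_columns(m, tab$header, np, path)
  delivery_record(
    patient_id = tab$meta$patient_id %||% "unknown",
    field_id = tab$meta$field_id %||% "unknown",
    fraction_date = tab$meta$fraction_date %||% NA,
    cumulative_mu = cols$cumulative_mu, gantry_deg = cols$gantry_deg,
    bank_a = cols$bank_a, bank_b = cols$bank_b, jaws = cols$jaws,
    geometry = geometry
  )
}

#' Write a delivery record in the record dialect
#'
#' @param record A `delivery_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  np <- ncol(record$bank_a)
  header <- c(
    "# arcverify-record v1; units=mm,deg,MU",
    write_meta(list(patient_id = record$patient_id,
                    field_id = record$field_id,
                    fraction_date = record$fraction_date)),
    paste(plan_columns(np), collapse = ",")
  )
  body <- row_lines(record, np, ",")
  write_lines_checked(c(header, body), path)
}

row_lines <- function(x, np, sep) {
  n <- length(x$cumulative_mu)
  m <- cbind(seq_len(n), x$cumulative_mu, x$gantry_deg,
             x$bank_a, x$bank_b, x$jaws)
  apply(m, 1L, function(r) paste(c(sprintf("%d", as.integer(r[1L])),
                                   fmt_num(r[-1L])), collapse = sep))
}

#' Write an error log as tab-separated text
#'
#' Emits one row per (snapshot, parameter): 80 leaf rows, 4 jaw rows and one
#' gantry row per snapshot, each with planned, reported and signed error
#' values and an explicit excluded flag (leaves only).
#'
#' @param log An `error_log` from [compute_errors()] or [read_error_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_error_log <- function(log, path) {
  validate_error_log(log)
  n <- nrow(log$leaf_errors)
  lids <- colnames(log$leaf_errors)
  jids <- jaw_ids()
  header <- c(
    "# arcverify-errorlog v1; units=mm,deg,MU",
    write_meta(list(patient_id = log$patient_id,
                    field_id = log$field_id,
                    fraction_date = log$fraction_date,
                    cumulative_mu = paste(fmt_num(log$cumulative_mu),
                                          collapse = ","))),
    paste(c("boundary_index", "param_kind", "param_id",
            "planned", "reported", "error", "excluded"), collapse = "\t")
  )
  rows <- character(0)
  for (i in seq_len(n)) {
    leaf <- sprintf("%d\tleaf\t%s\t%s\t%s\t%s\t%d",
                    i, lids,
                    fmt_num(log$leaf_planned[i, ]),
                    fmt_num(log$leaf_reported[i, ]),
                    fmt_num(log$leaf_errors[i, ]),
                    as.integer(log$leaf_excluded[i, ]))
    jaw <- sprintf("%d\tjaw\t%s\t%s\t%s\t%s\t0",
                   i, jids,
                   fmt_num(log$jaw_planned[i, ]),
                   fmt_num(log$jaw_reported[i, ]),
                   fmt_num(log$jaw_errors[i, ]))
    gantry <- sprintf("%d\tgantry\tgantry\t%s\t%s\t%s\t0",
                      i,
                      fmt_num(log$gantry_planned[i]),
                      fmt_num(log$gantry_reported[i]),
                      fmt_num(log$gantry_errors[i]))
    rows <- c(rows, leaf, jaw, gantry)
  }
  write_lines_checked(c(header, rows), path)
}

#' Read an error log written by [write_error_log()]
#'
#' @param path Path to a `# arcverify-errorlog v1` TSV file.
#' @return An `error_log`.
#' @export
read_error_log <- function(path) {
  tab <- read_dialect_table(path, "arcverify-errorlog v1", sep = "\t")
  parts <- strsplit(tab$rows, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 7L)
  if (length(bad))
    arcv_stop(sprintf("%s line %d: expected 7 fields", path,
                      tab$row_lines[bad[1L]]), "arcv_format_error")
  df <- data.frame(
    boundary_index = as.integer(vapply(parts, `[`, "", 1L)),
    param_kind = vapply(parts, `[`, "", 2L),
    param_id = vapply(parts, `[`, "", 3L),
    planned = as.numeric(vapply(parts, `[`, "", 4L)),
    reported = as.numeric(vapply(parts, `[`, "", 5L)),
    error = as.numeric(vapply(parts, `[`, "", 6L)),
    excluded = as.integer(vapply(parts, `[`, "", 7L))
  )
  if (anyNA(df$boundary_index) || anyNA(df$error))
    arcv_stop(sprintf("%s: non-numeric value in error-log body", path),
              "arcv_format_error")
  snaps <- sort(unique(df$boundary_index))
  if (!identical(snaps, seq_along(snaps)))
    arcv_stop(sprintf("%s: boundary indices are not 1..n", path),
              "arcv_format_error")
  leaf <- df[df$param_kind == "leaf", ]
  jaw <- df[df$param_kind == "jaw", ]
  gan <- df[df$param_kind == "gantry", ]
  n <- length(snaps)
  lids <- unique(leaf$param_id[leaf$boundary_index == 1L])
  if (nrow(leaf) != n * length(lids) || nrow(jaw) != n * 4L ||
      nrow(gan) != n)
    arcv_stop(sprintf("%s: inconsistent per-snapshot row counts", path),
              "arcv_format_error")
  to_mat <- function(d, ids) {
    m <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
    m[cbind(d$boundary_index, match(d$param_id, ids))] <- d$value
    m
  }
  mats <- function(d, ids) {
    list(planned = to_mat(transform(d, value = d$planned), ids),
         reported = to_mat(transform(d, value = d$reported), ids),
         error = to_mat(transform(d, value = d$error), ids),
         excluded = to_mat(transform(d, value = as.numeric(d$excluded)), ids))
  }
  lm <- mats(leaf, lids)
  jm <- mats(jaw, jaw_ids())
  mu <- as.numeric(strsplit(tab$meta$cumulative_mu %||% "",
                            ",", fixed = TRUE)[[1L]])
  if (length(mu) != n) mu <- rep(NA_real_, n)
  gord <- order(gan$boundary_index)
  log <- structure(
    list(
      patient_id = tab$meta$patient_id %||% "unknown",
      field_id = tab$meta$field_id %||% "unknown",
      fraction_date = tab$meta$fraction_date %||% NA_character_,
      cumulative_mu = mu,
      leaf_planned = lm$planned, leaf_reported = lm$reported,
      leaf_errors = lm$error,
      leaf_excluded = lm$excluded == 1,
      gantry_planned = gan$planned[gord],
      gantry_reported = gan$reported[gord],
      gantry_errors = gan$error[gord],
      jaw_planned = jm$planned, jaw_reported = jm$reported,
      jaw_errors = jm$error
    ),
    class = "error_log"
  )
  validate_error_log(log)
  log
}

write_lines_checked <- function(lines, path) {
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    arcv_stop(sprintf("cannot write '%s': %s", path,
                      conditionMessage(ok)), "arcv_io_error")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
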