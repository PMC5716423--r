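mk_summary <- function(pid, date, p3, p2g = 95, p3j = 99) {
  s <- list(patient_id = pid, field_id = "F", fraction_date = date,
            headline = c(P3mm_mlc = p3, P2deg_gantry = p2g, P3mm_jaw = p3j))
  class(s) <- "fraction_summary"
  s
}

test_that("fraction-scoped rules fire exactly on violating fractions", {
  sums <- list(mk_summary("A", "2026-01-01", 92),
               mk_summary("A", "2026-01-02", 84),
               mk_summary("A", "2026-01-03", 88))
  rule <- alert_rule("P3mm_mlc", "below", 85)
  ev <- evaluate_alerts(sums, list(rule))
  expect_length(ev, 1)
  expect_equal(ev[[1]]$observed, 84)
  expect_equal(ev[[1]]$fraction_date, "2026-01-02")

  expect_length(evaluate_alerts(sums, list()), 0)
  expect_error(
    evaluate_alerts(sums, list(alert_rule("NoSuchMetric", "below", 1))),
    class = "arcv_config_error")
})

test_that("windowed rules fire on trailing-window means", {
  sums <- list(mk_summary("A", "2026-01-01", 95),
               mk_summary("A", "2026-01-02", 88),
               mk_summary("A", "2026-01-03", 85),
               mk_summary("A", "2026-01-04", 92))
  rule <- alert_rule("P3mm_mlc", "below", 90, scope = "window", window = 3)
  ev <- evaluate_alerts(sums, list(rule))
  # windows: (95,88,85) = 89.33 and (88,85,92) = 88.33 both violate
  expect_length(ev, 2)
  expect_equal(ev[[1]]$fraction_date, "2026-01-03")
  expect_equal(ev[[1]]$observed, mean(c(95, 88, 85)))
  expect_equal(ev[[2]]$observed, mean(c(88, 85, 92)))
})

test_that("emitted events equal a brute-force scan over randomized rules", {
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    sums <- lapply(seq_len(n), function(i)
      mk_summary(sample(c("A", "B"), 1),
                 sprintf("2026-02-%02d", i),
                 runif(1, 70, 100), runif(1, 85, 100), runif(1, 95, 100)))
    rules <- lapply(seq_len(sample(1:4, 1)), function(j)
      alert_rule(sample(c("P3mm_mlc", "P2deg_gantry", "P3mm_jaw"), 1),
                 sample(c("below", "above"), 1),
                 runif(1, 80, 99)))
    ev <- evaluate_alerts(sums, rules)
    # brute force: loop every (rule, fraction)
    expected <- 0
    for (r in rules) for (s in sums) {
      v <- s$headline[[r$metric]]
      hit <- if (r$comparator == "below") v < r$threshold else v > r$threshold
      expected <- expected + hit
    }
    expect_length(ev, expected)
    for (e in ev) {
      r <- e$rule
      hit <- if (r$comparator == "below") e$observed < r$threshold
      else e$observed > r$threshold
      expect_true(hit)
    }
  }
})

test_that("fraction reports are lossless and ordered", {
  plan <- generate_plan(plan_generator_config(seed = 61, complexity = 0.5))
  log <- compute_errors(plan, simulate_delivery(plan, error_model(seed = 62)))
  s <- summarize_fraction(log)
  path <- withr::local_tempfile(fileext = ".json")
  render_fraction_report(s, log, path = path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)

  expect_identical(back$schema, "arcverify-report/1")
  expect_identical(unlist(back$headline), s$headline)
  expect_identical(back$tolerance_sweep$percent, s$p_within$percent)
  expect_identical(back$rms_per_leaf, unname(s$rms_per_leaf))
  expect_identical(back$histograms$mlc$counts, s$histograms$mlc$counts)
  expect_identical(back$counts$n_included_leaf, s$n_included_leaf)

  # sweep rows non-decreasing left to right
  sw <- back$tolerance_sweep
  for (kind in unique(sw$kind))
    expect_true(all(diff(sw$percent[sw$kind == kind][
      order(sw$tolerance[sw$kind == kind])]) >= 0))

  # deterministic rendering
  path2 <- withr::local_tempfile(fileext = ".json")
  render_fraction_report(s, log, path = path2)
  expect_identical(readLines(path), readLines(path2))

  # identity delivery reports all-100 headlines
  ident <- summarize_fraction(compute_errors(plan,
                                             sample_plan_as_record(plan)))
  rep0 <- render_fraction_report(ident)
  expect_true(all(unlist(rep0$headline) == 100))
})

test_that("figure rendering writes a non-empty document", {
  plan <- generate_plan(plan_generator_config(seed = 63, complexity = 0.5))
  log <- compute_errors(plan, simulate_delivery(plan, error_model(seed = 64)))
  s <- summarize_fraction(log)
  jpath <- withr::local_tempfile(fileext = ".json")
  render_fraction_report(s, log, path = jpath, figures = TRUE)
  fig <- sub("\\.json$", ".pdf", jpath)
  expect_true(file.exists(fig))
  expect_gt(file.size(fig), 1000)
})

test_that("history report carries dated series, aggregates and annotations", {
  sums <- lapply(1:5, function(i)
    mk_summary("A", sprintf("2026-03-%02d", i), 90 + i))
  tr <- aggregate_history(sums)
  rep <- render_history_report(
    tr, annotations = data.frame(date = "2026-03-03",
                                 label = "gantry servo adjustment"))
  expect_equal(nrow(rep$series), 5)
  expect_equal(rep$annotations$label, "gantry servo adjustment")

  const <- aggregate_history(lapply(1:4, function(i)
    mk_summary("A", sprintf("2026-03-%02d", i), 91)))
  expect_equal(const$overall$sd, rep(0, 3))

  # locality: dropping one fraction changes only that entry and aggregates
  tr4 <- aggregate_history(sums[-3])
  expect_equal(tr4$fractions,
               tr$fractions[tr$fractions$fraction_date != "2026-03-03", ],
               ignore_attr = TRUE)
})

test_that("notify delivers through sinks and never loses events", {
  sums <- list(mk_summary("A", "2026-01-01", 80),
               mk_summary("A", "2026-01-02", 82))
  ev <- evaluate_alerts(sums, list(alert_rule("P3mm_mlc", "below", 85)))
  expect_length(ev, 2)

  dir <- withr::local_tempdir()
  res <- notify(ev, file_sink(dir))
  expect_length(list.files(dir, pattern = "^alert-"), 2)
  expect_true(all(res$receipts$delivered))
  expect_length(res$undelivered, 0)

  expect_equal(nrow(notify(list(), file_sink(withr::local_tempdir()))$receipts), 0)

  broken <- structure(list(deliver = function(text, event)
    stop("smtp down")), class = "arcv_sink")
  res2 <- notify(ev, broken)
  expect_false(any(res2$receipts$delivered))
  expect_length(res2$undelivered, 2)
})

test_that("config files round through JSON (and YAML when available)", {
  cfgj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    tolerances = list(mlc_mm = 2.5, sweep = c(1, 2, 3, 5)),
    bin_width_mm = 0.25,
    alerts = list(list(metric = "P2.5mm_mlc", comparator = "below",
                       threshold = 90))
  ), cfgj, auto_unbox = TRUE)
  cfg <- read_config(cfgj)
  expect_equal(cfg$tolerances$mlc_mm, 2.5)
  expect_equal(cfg$bin_width_mm, 0.25)
  expect_length(cfg$rules, 1)
  expect_equal(cfg$rules[[1]]$threshold, 90)

  if (requireNamespace("yaml", quietly = TRUE)) {
    cfgy <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("tolerances:", "  gantry_deg: 1.5", "bin_width_deg: 0.2"),
               cfgy)
    cy <- read_config(cfgy)
    expect_equal(cy$tolerances$gantry_deg, 1.5)
    expect_equal(cy$bin_width_deg, 0.2)
  }
})
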