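test_that("percent_within counts inclusively over included samples", {
  expect_equal(percent_within(c(0.5, 2.9, 3.0, 3.1, -4.0), 3), 60.0)
  expect_equal(percent_within(rep(0, 7), 0.1), 100.0)
  expect_error(percent_within(c(5, -5), 3, excluded = c(TRUE, TRUE)),
               class = "arcv_undefined_metric")

  # brute-force equivalence on simulator output
  plan <- generate_plan(plan_generator_config(seed = 21, complexity = 0.5))
  log <- compute_errors(plan, simulate_delivery(plan, error_model(seed = 22)))
  for (tol in c(1, 2, 3, 5)) {
    expect_equal(percent_within(log$leaf_errors, tol, log$leaf_excluded),
                 brute_percent(log$leaf_errors, log$leaf_excluded, tol))
  }
})

test_that("fraction summaries reproduce hand-computable cases", {
  plan <- tiny_plan(mu = c(0, 50, 100), gantry = c(175, 173, 171))
  log <- compute_errors(plan, sample_plan_as_record(plan))
  s <- summarize_fraction(log)
  expect_true(all(s$p_within$percent == 100))
  expect_equal(unname(s$rms_per_leaf), rep(0, 80))
  expect_equal(s$n_excluded_leaf, 0)

  # constant +2 mm on every leaf
  log2 <- log
  log2$leaf_reported <- log2$leaf_planned + 2
  log2$leaf_errors <- log2$leaf_reported - log2$leaf_planned
  s2 <- summarize_fraction(log2)
  expect_equal(unname(s2$rms_per_leaf), rep(2, 80))
  expect_equal(s2$p_within$percent[s2$p_within$kind == "mlc" &
                                     s2$p_within$tolerance == 1], 0)
  expect_equal(s2$headline[["P3mm_mlc"]], 100)
})

test_that("histograms are zero-centered and conserve counts", {
  set.seed(23)
  plan <- generate_plan(plan_generator_config(seed = 23, complexity = 0.7))
  log <- compute_errors(plan, simulate_delivery(plan, error_model(seed = 24)))
  s <- summarize_fraction(log)
  h <- s$histograms$mlc
  expect_equal(sum(h$counts), s$n_included_leaf)
  expect_equal(sum(s$histograms$gantry$counts), s$n_gantry)
  # bins symmetric about zero with one bin centered on 0
  expect_equal(h$breaks, -rev(h$breaks))
  expect_true(any(abs(h$breaks + h$bin_width / 2) < 1e-12))
})

test_that("per-leaf RMS bounds |mean| and marks fully excluded leaves NA", {
  plan <- generate_plan(plan_generator_config(seed = 25, complexity = 0.5))
  log <- compute_errors(plan, simulate_delivery(plan, error_model(seed = 26)))
  s <- summarize_fraction(log)
  inc <- !log$leaf_excluded
  all_excluded <- colSums(inc) == 0
  expect_true(any(all_excluded))  # parked pairs exist in generated plans
  expect_true(all(is.na(s$rms_per_leaf[all_excluded])))
  for (l in which(!all_excluded)) {
    m <- mean(log$leaf_errors[inc[, l], l])
    expect_gte(s$rms_per_leaf[l] + 1e-12, abs(m))
  }
})

test_that("plan motion summary measures mm per degree of gantry rotation", {
  # 4-degree segment, one leaf travels 8 mm -> 2 mm/deg, 1/80 movements > 1
  plan <- tiny_plan(mu = c(0, 10), gantry = c(175, 171))
  plan$bank_b[2, 1] <- plan$bank_b[1, 1] + 8
  plan <- validate_arc_plan(plan)
  pm <- plan_motion_summary(plan)
  expect_equal(unname(pm$leaf_speeds[1, "b01"]), 2.0)
  expect_equal(pm$frac_gt_1mm_per_deg, 100 / 80)

  static <- tiny_plan(mu = c(0, 10), gantry = c(175, 171))
  pm0 <- plan_motion_summary(static)
  expect_true(all(pm0$leaf_speeds == 0))
  expect_equal(pm0$frac_gt_1mm_per_deg, 0)

  degen <- tiny_plan(mu = c(0, 10), gantry = c(175, 175))
  expect_error(plan_motion_summary(degen),
               class = "arcv_degenerate_segment")
})

test_that("generated plans respect the 4 mm/deg leaf-speed constraint", {
  for (seed in 1:8) {
    plan <- generate_plan(plan_generator_config(seed = seed,
                                                complexity = runif(1)))
    pm <- plan_motion_summary(plan)
    expect_lte(max(pm$leaf_speeds), 4.0 + 1e-9)
  }
})

test_that("history aggregation matches hand-computed patient variability", {
  mk <- function(pid, date, p3) {
    s <- list(patient_id = pid, field_id = "F", fraction_date = date,
              headline = c(P3mm_mlc = p3, P2deg_gantry = 95, P3mm_jaw = 99))
    class(s) <- "fraction_summary"
    s
  }
  one <- aggregate_history(list(mk("A", "2026-01-01", 90)))
  expect_equal(one$overall$mean[one$overall$metric == "P3mm_mlc"], 90)
  expect_equal(one$overall$sd, rep(0, 3))

  sums <- list(mk("A", "2026-01-01", 90), mk("A", "2026-01-02", 94),
               mk("B", "2026-01-01", 80), mk("B", "2026-01-02", 88))
  tr <- aggregate_history(sums)
  pp <- tr$per_patient[tr$per_patient$metric == "P3mm_mlc", ]
  expect_equal(pp$sd[pp$patient_id == "A"], sd(c(90, 94)))
  expect_equal(pp$sd[pp$patient_id == "B"], sd(c(80, 88)))
  expect_equal(pp$sd2, 2 * pp$sd)
  expect_equal(unname(tr$mean_patient_sd["P3mm_mlc"]),
               mean(c(sd(c(90, 94)), sd(c(80, 88)))))
  expect_equal(unname(tr$mean_patient_sd["P3mm_mlc"]), 4.242640687, tolerance = 1e-8)

  # permutation invariance
  tr2 <- aggregate_history(sums[c(3, 1, 4, 2)])
  expect_equal(tr2$overall, tr$overall)
  expect_equal(tr2$per_patient, tr$per_patient)
  expect_equal(tr2$fractions, tr$fractions)
})

test_that("pearson_r evaluates the product-moment formula", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)),
               class = "arcv_undefined_metric")
  expect_error(pearson_r(1:2, 1:2), class = "arcv_validation_error")
  # independent route: stats::cor on random data
  set.seed(27)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(20) + 0.5 * x
    expect_equal(pearson_r(x, y), stats::cor(x, y), tolerance = 1e-12)
  }
})

test_that("speed_error_relation pairs fractions by key", {
  plan <- generate_plan(plan_generator_config(seed = 31, complexity = 0.4))
  pm <- plan_motion_summary(plan)
  log <- compute_errors(plan, simulate_delivery(plan, error_model(seed = 32)))
  fs <- summarize_fraction(log)
  plans <- list(f1 = pm, f2 = pm, f3 = pm)
  fracs <- list(f1 = fs, f2 = fs, f3 = fs)
  rel <- speed_error_relation(plans, fracs)
  expect_equal(rel$key, c("f1", "f2", "f3"))
  expect_equal(rel$p_mlc, rep(fs$headline[["P3mm_mlc"]], 3))
  expect_error(speed_error_relation(plans, fracs[c("f1", "f2")]),
               class = "arcv_pairing_error")
})

test_that("percent-within is non-decreasing in tolerance on simulated fractions", {
  for (seed in c(41, 42, 43)) {
    plan <- generate_plan(plan_generator_config(seed = seed,
                                                complexity = runif(1)))
    log <- compute_errors(plan,
                          simulate_delivery(plan, error_model(seed = seed + 50)))
    s <- summarize_fraction(log)
    for (kind in unique(s$p_within$kind)) {
      rows <- s$p_within[s$p_within$kind == kind, ]
      rows <- rows[order(rows$tolerance), ]
      expect_true(all(diff(rows$percent) >= 0))
    }
  }
})
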