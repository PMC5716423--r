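test_that("gantry unwrapping follows the rotation sense through the wrap", {
  expect_equal(unwrap_gantry(c(175, 171, 167), -1), c(175, 171, 167))
  expect_equal(unwrap_gantry(c(2, 358), -1), c(2, -2))
  expect_equal(unwrap_gantry(c(358, 2), +1), c(358, 362))
  expect_error(unwrap_gantry(c(0, 180), -1), class = "arcv_trajectory_error")

  # property: value mod 360 reproduces the input; first element unchanged
  set.seed(1)
  for (i in 1:25) {
    sense <- sample(c(-1, 1), 1)
    raw <- (100 + sense * cumsum(c(0, runif(20, 0, 170)))) %% 360
    u <- unwrap_gantry(raw, sense)
    expect_equal(u %% 360, raw)
    expect_identical(u[1], raw[1])
    expect_true(all(sense * diff(u) >= 0))
  }
})

test_that("angular error is the signed shortest difference", {
  expect_equal(angular_error(359.5, 0.5), -1.0)
  expect_equal(angular_error(10, 10), 0)
  expect_equal(angular_error(190, 10), 180)  # antipodal tie -> +180
  set.seed(2)
  r <- runif(200, 0, 360); p <- runif(200, 0, 360)
  e <- angular_error(r, p)
  expect_true(all(e > -180 & e <= 180))
  expect_equal((p + e) %% 360, r %% 360)
})

test_that("interpolation reproduces the spec'd hand cases", {
  p <- tiny_plan(mu = c(0, 10), gantry = c(175, 171))
  expect_equal(interpolate_plan(p, 5)$gantry_deg, 173)

  p2 <- tiny_plan(mu = c(0, 10), gantry = c(175, 171))
  p2$bank_a[, 1] <- c(-20, -12)
  p2 <- validate_arc_plan(p2)
  expect_equal(interpolate_plan(p2, 2.5)$bank_a[1, 1], -18)

  # wrap-aware midpoint: gantry 2 -> 358 counter-clockwise passes through 0
  p3 <- tiny_plan(mu = c(0, 10), gantry = c(2, 358), sense = -1L)
  expect_equal(interpolate_plan(p3, 5)$gantry_deg, 0)

  expect_error(interpolate_plan(p, 11), class = "arcv_range_error")
  st <- interpolate_plan(p, c(-1, 11), clamp = TRUE)
  expect_equal(st$cumulative_mu, c(0, 10))
  expect_identical(st$clamped, c(TRUE, TRUE))
})

test_that("interpolation is exact on control points and handles zero-MU segments", {
  set.seed(3)
  plan <- random_plan(8, dup_knot = TRUE)
  for (k in seq_along(plan$cumulative_mu)) {
    mu_k <- plan$cumulative_mu[k]
    k_first <- match(mu_k, plan$cumulative_mu)  # duplicated knot -> earlier CP
    st <- interpolate_plan(plan, mu_k)
    expect_identical(st$bank_a[1, ], plan$bank_a[k_first, ])
    expect_identical(st$bank_b[1, ], plan$bank_b[k_first, ])
    expect_identical(unname(st$jaws[1, ]), unname(plan$jaws[k_first, ]))
    expect_identical(st$gantry_unwrapped_deg,
                     plan$gantry_unwrapped_deg[k_first])
  }
})

test_that("interpolation agrees with the brute-force evaluator on random plans", {
  set.seed(4)
  for (rep in 1:5) {
    plan <- random_plan(10, wrap = TRUE, dup_knot = rep %% 2 == 0)
    mu <- runif(200, 0, max(plan$cumulative_mu))
    st <- interpolate_plan(plan, mu)
    for (j in seq_along(mu)) {
      ref <- brute_interp(plan, mu[j])
      expect_equal(st$gantry_unwrapped_deg[j], ref$gantry_unwrapped,
                   tolerance = 1e-12)
      expect_equal(st$bank_a[j, ], ref$bank_a, tolerance = 1e-12)
      expect_equal(st$bank_b[j, ], ref$bank_b, tolerance = 1e-12)
      expect_equal(unname(st$jaws[j, ]), unname(ref$jaws), tolerance = 1e-12)
    }
  }
})

test_that("jaw blocking matches its interval definition", {
  geom <- machine_geometry()
  # pair extent [50, 60] mm is pair 26 with default edges
  expect_true(leaf_blocked(26, c(-100, 100, -50, 50), geom))
  # pair extent [-10, 0] mm is pair 20
  expect_false(leaf_blocked(20, c(-100, 100, -50, 50), geom))
  expect_false(any(leaf_blocked(1:40, c(-100, 100, -200, 200), geom)))

  set.seed(5)
  for (i in 1:50) {
    y <- sort(runif(2, -210, 210))
    jaws <- c(-100, 100, y)
    got <- leaf_blocked(1:40, jaws, geom)
    ref <- vapply(1:40, function(k) brute_blocked(k, jaws, geom), TRUE)
    expect_identical(got, ref)
  }
})

test_that("widening the Y jaws never increases the blocked count", {
  geom <- machine_geometry()
  set.seed(6)
  for (i in 1:25) {
    y <- sort(runif(2, -150, 150))
    widen <- runif(1, 0, 60)
    n1 <- sum(leaf_blocked(1:40, c(-100, 100, y), geom))
    n2 <- sum(leaf_blocked(1:40, c(-100, 100, y[1] - widen, y[2] + widen),
                           geom))
    expect_lte(n2, n1)
  }
})

test_that("identity deliveries produce all-zero errors", {
  plan <- tiny_plan(mu = c(0, 50, 100), gantry = c(175, 173, 171))
  log <- compute_errors(plan, sample_plan_as_record(plan))
  expect_true(all(log$leaf_errors == 0))
  expect_true(all(log$jaw_errors == 0))
  expect_true(all(log$gantry_errors == 0))
  expect_false(any(log$leaf_excluded))  # jaws wide open in tiny_plan
})

test_that("errors follow reported minus MU-interpolated planned positions", {
  plan <- tiny_plan(mu = c(0, 10), gantry = c(175, 171))
  plan$bank_a[] <- rep(c(-20, -12), 40)  # each leaf moves -20 -> -12
  plan$bank_b[] <- rep(c(10, 18), 40)
  plan <- validate_arc_plan(plan)
  # snapshot at midpoint MU: planned bank_a = -16, bank_b = 14 (hand oracle);
  # report every leaf 1.2 mm beyond its planned position
  rec <- delivery_record(
    "PT1", "F1", "2026-01-01", cumulative_mu = 5, gantry_deg = 173,
    bank_a = matrix(-16 + 1.2, 1, 40), bank_b = matrix(14 + 1.2, 1, 40),
    jaws = matrix(c(-100, 100, -200, 200), 1, 4))
  log <- compute_errors(plan, rec)
  expect_equal(unname(log$leaf_errors), matrix(1.2, 1, 80))
  expect_equal(log$gantry_errors, 0)
})

test_that("gantry errors wrap: reported 359.5 vs planned 0.5 is -1 degree", {
  plan <- tiny_plan(mu = c(0, 10), gantry = c(2, 359), sense = -1L)
  # midpoint MU -> planned gantry 0.5
  rec <- sample_plan_as_record(plan)
  rec$cumulative_mu <- c(0, 5)
  rec$gantry_deg <- c(2, 359.5)
  log <- compute_errors(plan, rec)
  expect_equal(log$gantry_errors[2], -1.0)
})

test_that("field mismatch raises a pairing error; stray MU only warns", {
  plan <- tiny_plan()
  rec <- sample_plan_as_record(plan)
  rec$patient_id <- "OTHER"
  expect_error(compute_errors(plan, rec), class = "arcv_pairing_error")

  rec2 <- sample_plan_as_record(plan)
  rec2$cumulative_mu[2] <- max(plan$cumulative_mu) + 0.5
  expect_warning(log <- compute_errors(plan, rec2),
                 class = "arcv_clamp_warning")
  expect_true(all(log$leaf_errors == 0))
})

test_that("rotating the whole geometry leaves gantry errors unchanged", {
  set.seed(7)
  plan <- generate_plan(plan_generator_config(seed = 70, complexity = 0.4))
  rec <- simulate_delivery(plan, error_model(seed = 71))
  base <- suppressWarnings(compute_errors(plan, rec))
  for (shift in c(37.25, 180, 271)) {
    p2 <- plan; r2 <- rec
    p2$gantry_deg <- (plan$gantry_deg + shift) %% 360
    p2 <- validate_arc_plan(p2)
    r2$gantry_deg <- (rec$gantry_deg + shift) %% 360
    shifted <- suppressWarnings(compute_errors(p2, r2))
    expect_equal(shifted$gantry_errors, base$gantry_errors,
                 tolerance = 1e-9)
  }
})
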