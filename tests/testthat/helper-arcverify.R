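# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive scalar code, independent of the package's vectorized paths.

# A small hand-specified plan: open jaws, two moving leaves.
tiny_plan <- function(mu = c(0, 100), gantry = c(175, 171),
                      leaf_a = -10, leaf_b = 10,
                      jaws = c(-100, 100, -200, 200),
                      sense = NULL) {
  n <- length(mu)
  arc_plan(
    patient_id = "PT1", field_id = "F1",
    cumulative_mu = mu, gantry_deg = gantry,
    bank_a = matrix(leaf_a, n, 40), bank_b = matrix(leaf_b, n, 40),
    jaws = matrix(rep(jaws, each = n), n, 4),
    rotation_sense = sense
  )
}

# Random structurally valid plan built directly (not via the generator),
# optionally crossing the 0/360 wrap like a 175 -> 185 counter-clockwise arc.
random_plan <- function(n_cp = 10, wrap = TRUE, dup_knot = FALSE) {
  mu <- sort(runif(n_cp, 0, 200))
  mu[1] <- 0
  if (dup_knot && n_cp >= 4) mu[3] <- mu[2]  # zero-MU segment
  start <- if (wrap) 175 else runif(1, 200, 300)
  u <- start - cumsum(c(0, runif(n_cp - 1, 1, 350 / n_cp)))
  gantry <- u %% 360
  a <- matrix(runif(n_cp * 40, -60, 0), n_cp, 40)
  b <- a + matrix(runif(n_cp * 40, 0, 60), n_cp, 40)
  arc_plan("PTR", "FR", mu, gantry, a, b,
           jaws = matrix(rep(c(-80, 80, -120, 120), each = n_cp), n_cp, 4),
           rotation_sense = -1L)
}

# Brute-force piecewise-linear evaluator: scalar loop over segments.
brute_interp <- function(plan, mu) {
  pm <- plan$cumulative_mu
  n <- length(pm)
  u <- unwrap_gantry(plan$gantry_deg, plan$rotation_sense)
  k <- 1
  for (j in seq_len(n - 1)) {
    if (mu >= pm[j] && (mu < pm[j + 1] || j == n - 1)) { k <- j; break }
  }
  # exact knot hits resolve to the first control point at that MU
  for (j in seq_len(n)) if (pm[j] == mu) { k <- min(j, n - 1); break }
  t <- if (pm[k + 1] > pm[k]) (mu - pm[k]) / (pm[k + 1] - pm[k]) else 0
  lerp <- function(v0, v1) (1 - t) * v0 + t * v1
  list(
    gantry_unwrapped = lerp(u[k], u[k + 1]),
    bank_a = lerp(plan$bank_a[k, ], plan$bank_a[k + 1, ]),
    bank_b = lerp(plan$bank_b[k, ], plan$bank_b[k + 1, ]),
    jaws = lerp(plan$jaws[k, ], plan$jaws[k + 1, ])
  )
}

# Brute-force jaw blocking via explicit interval intersection length.
brute_blocked <- function(pair, jaws, geometry) {
  e <- geometry$leaf_pair_y_edges * 10
  lo <- e[pair]; hi <- e[pair + 1]
  inter <- min(hi, jaws[4]) - max(lo, jaws[3])
  inter <= 1e-9
}

# Brute-force percent-within over a raw error log.
brute_percent <- function(errors, excluded, tol) {
  n_in <- 0; n_ok <- 0
  e <- as.numeric(errors)
  x <- if (is.null(excluded)) rep(FALSE, length(e)) else as.logical(excluded)
  for (i in seq_along(e)) {
    if (!x[i]) {
      n_in <- n_in + 1
      if (abs(e[i]) <= tol) n_ok <- n_ok + 1
    }
  }
  100 * n_ok / n_in
}

expect_plan_equal <- function(p, q) {
  expect_identical(p$patient_id, q$patient_id)
  expect_identical(p$field_id, q$field_id)
  expect_identical(p$rotation_sense, q$rotation_sense)
  expect_identical(p$cumulative_mu, q$cumulative_mu)
  expect_identical(p$gantry_deg, q$gantry_deg)
  expect_identical(unname(p$bank_a), unname(q$bank_a))
  expect_identical(unname(p$bank_b), unname(q$bank_b))
  expect_identical(unname(p$jaws), unname(q$jaws))
}
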