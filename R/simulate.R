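#' Configuration for the synthetic arc-plan generator
#'
#' Defaults reproduce the planning constraints of a typical single-arc VMAT
#' protocol: the arc begins at 175 degrees and rotates counter-clockwise
#' through 0/360 to 185 degrees, control points are placed at a final gantry
#' spacing of 4 degrees, leaf motion is clipped to at most 4 mm per degree of
#' gantry rotation, and each arc is planned for delivery within 90 seconds.
#'
#' `complexity` in `[0, 1]` scales the requested leaf motion: 0 produces a
#' static aperture (prostate-like plans sit near the low end, chest-wall-like
#' plans near the high end). It is purely a motion scale; no anatomical
#' content is implied.
#'
#' @param n_arcs 1 or 2 (a second arc returns clockwise).
#' @param arc_start_deg,arc_stop_deg Arc endpoints, degrees in `[0, 360)`.
#' @param rotation_sense Travel direction of the first arc (`-1` =
#'   counter-clockwise).
#' @param gantry_spacing_deg Nominal control-point spacing, degrees; the
#'   realized spacing divides the span exactly (within one control point of
#'   the nominal count).
#' @param total_mu Total monitor units for the arc (default 500 MU, a
#'   typical 2 Gy arc).
#' @param max_leaf_speed Leaf-motion clip, mm/deg.
#' @param aperture_profile List with `center_drift` (mm, amplitude of the
#'   shared aperture drift), `width_max` (mm, widest base aperture), and
#'   `motion_amp` (mm, per-leaf smooth motion amplitude at complexity 1).
#' @param complexity Motion scale in `[0, 1]`.
#' @param n_active_pairs Number of central leaf pairs inside the Y jaws;
#'   remaining pairs are parked closed behind the jaws.
#' @param max_delivery_time_s Planned delivery time cap, seconds (metadata).
#' @param seed Optional integer seed; fixed seeds give bit-identical plans.
#' @return A `plan_generator_config`.
#' @export
plan_generator_config <- function(n_arcs = 1L,
                                  arc_start_deg = 175,
                                  arc_stop_deg = 185,
                                  rotation_sense = -1L,
                                  gantry_spacing_deg = 4,
                                  total_mu = 500,
                                  max_leaf_speed = 4,
                                  aperture_profile = list(center_drift = 8,
                                                          width_max = 60,
                                                          motion_amp = 12),
                                  complexity = 0.3,
                                  n_active_pairs = 16L,
                                  max_delivery_time_s = 90,
                                  seed = NULL) {
  if (!n_arcs %in% c(1L, 2L))
    arcv_stop("'n_arcs' must be 1 or 2", "arcv_config_error")
  stopifnot_scalar_num(total_mu, "total_mu")
  if (total_mu <= 0)
    arcv_stop("'total_mu' must be positive", "arcv_config_error")
  stopifnot_scalar_num(gantry_spacing_deg, "gantry_spacing_deg",
                       positive = TRUE)
  stopifnot_scalar_num(max_leaf_speed, "max_leaf_speed", positive = TRUE)
  if (!is.numeric(complexity) || complexity < 0 || complexity > 1)
    arcv_stop("'complexity' must lie in [0, 1]", "arcv_config_error")
  structure(
    list(n_arcs = as.integer(n_arcs),
         arc_start_deg = arc_start_deg, arc_stop_deg = arc_stop_deg,
         rotation_sense = as.integer(rotation_sense),
         gantry_spacing_deg = gantry_spacing_deg,
         total_mu = total_mu, max_leaf_speed = max_leaf_speed,
         aperture_profile = aperture_profile, complexity = complexity,
         n_active_pairs = as.integer(n_active_pairs),
         max_delivery_time_s = max_delivery_time_s, seed = seed),
    class = "plan_generator_config"
  )
}

#' Parameters of the simulated delivery-error model
#'
#' The dominant structured effect in reported VMAT snapshots is a latency
#' lag: parameters are sampled into control-system memory at different rates
#' (MU every 20 ms, MLC positions every 40 ms), so a snapshot's reported leaf
#' position trails the moving planned position by an amount proportional to
#' how fast that leaf travels. The simulator models this in the gantry-angle
#' domain: reported leaf error contains `-lag_coeff * v` where `v` is the
#' signed planned leaf speed (mm/deg) in the segment preceding the snapshot.
#' On top of the lag sit independent Gaussian noise terms per parameter, an
#' optional constant leaf bias (miscalibration), and Gaussian jitter on the
#' reported cumulative MU.
#'
#' Default magnitudes are calibrated once against the error regime clinical
#' delivery verification reports: with the default generator, low-motion
#' (complexity ~0.15) plans land near 0.4 mm mean absolute leaf error and
#' high-motion (~0.9) plans near 1.5 mm with tails of several mm, gantry
#' noise puts roughly 96% of angles within 2 degrees, and jaw noise puts
#' over 99% of jaw positions within 3 mm.
#'
#' @param lag_coeff mm of lag per (mm/deg) of planned leaf speed.
#' @param leaf_noise_sd,jaw_noise_sd Gaussian position noise, mm.
#' @param gantry_noise_sd Gaussian gantry noise, degrees.
#' @param mu_jitter_sd Gaussian jitter on reported cumulative MU, MU.
#' @param leaf_bias Constant leaf offset, mm.
#' @param seed Optional integer seed.
#' @return An `error_model`.
#' @export
error_model <- function(lag_coeff = 0.7, leaf_noise_sd = 0.35,
                        gantry_noise_sd = 0.9, jaw_noise_sd = 0.8,
                        mu_jitter_sd = 0.2, leaf_bias = 0, seed = NULL) {
  sds <- c(leaf_noise_sd, gantry_noise_sd, jaw_noise_sd, mu_jitter_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    arcv_stop("noise standard deviations must be non-negative",
              "arcv_config_error")
  structure(
    list(lag_coeff = lag_coeff, leaf_noise_sd = leaf_noise_sd,
         gantry_noise_sd = gantry_noise_sd, jaw_noise_sd = jaw_noise_sd,
         mu_jitter_sd = mu_jitter_sd, leaf_bias = leaf_bias, seed = seed),
    class = "error_model"
  )
}

# Smooth unit-variance noise along the control-point axis: moving average of
# white noise (window 3), restandardized. Step sd ~ 0.8, so motion_amp maps
# almost directly to typical per-segment travel.
smooth_noise <- function(n) {
  z <- stats::rnorm(n + 2L)
  s <- (z[1:n] + z[2:(n + 1L)] + z[3:(n + 2L)]) / sqrt(3)
  s
}

#' Generate a synthetic VMAT arc plan
#'
#' Builds an arc honoring the generator constraints: control points at the
#' configured gantry spacing along the arc, cumulative MU apportioned
#' uniformly across segments, smoothly varying random apertures whose
#' per-segment leaf travel is clipped to `max_leaf_speed`, and static jaws
#' framing the active leaf pairs (pairs outside the Y jaws are parked closed
#' and end up excluded from error analysis, as on a real delivery).
#'
#' @param config A [plan_generator_config()].
#' @param geometry A [machine_geometry()].
#' @param patient_id,field_id Identifiers for the generated plan.
#' @param arc Which arc of `n_arcs` to generate (arc 2 reverses the sense).
#' @return A validated [arc_plan()].
#' @export
generate_plan <- function(config = plan_generator_config(),
                          geometry = machine_geometry(),
                          patient_id = "SYN001", field_id = "ARC1",
                          arc = 1L) {
  if (arc > config$n_arcs)
    arcv_stop("'arc' exceeds n_arcs", "arcv_config_error")
  with_seed(config$seed, {
    sense <- if (arc == 1L) config$rotation_sense else -config$rotation_sense
    start <- if (arc == 1L) config$arc_start_deg else config$arc_stop_deg
    stop_ <- if (arc == 1L) config$arc_stop_deg else config$arc_start_deg
    span <- ((sense * (stop_ - start)) %% 360)
    if (span == 0) span <- 360
    n_cp <- max(2L, floor(span / config$gantry_spacing_deg) + 1L)
    u <- start + sense * seq(0, span, length.out = n_cp)
    gantry <- wrap360(u)
    mu <- seq(0, config$total_mu, length.out = n_cp)

    np <- geometry$n_leaf_pairs
    n_active <- min(config$n_active_pairs, np)
    first_active <- (np - n_active) %/% 2L + 1L
    active <- seq(first_active, first_active + n_active - 1L)
    edges_mm <- geometry$leaf_pair_y_edges * 10

    prof <- config$aperture_profile
    cx <- config$complexity
    # elliptic base aperture across active pairs, >= 10 mm wide
    rel <- (active - mean(active)) / (n_active / 2 + 0.5)
    w_base <- pmax(prof$width_max * sqrt(pmax(1 - rel^2, 0)), 10)
    drift <- cx * prof$center_drift * smooth_noise(n_cp)
    amp <- cx * prof$motion_amp

    bank_a <- matrix(0, n_cp, np)
    bank_b <- matrix(0, n_cp, np)
    for (j in seq_along(active)) {
      i <- active[j]
      a_t <- drift - w_base[j] / 2 + amp * smooth_noise(n_cp)
      b_t <- drift + w_base[j] / 2 + amp * smooth_noise(n_cp)
      clipped <- clip_leaf_pair(a_t, b_t, abs(diff(u)) *
                                  config$max_leaf_speed)
      bank_a[, i] <- clipped$a
      bank_b[, i] <- clipped$b
    }

    jaws <- matrix(rep(c(
      x1 = floor(min(bank_a[, active]) - 5),
      x2 = ceiling(max(bank_b[, active]) + 5),
      y1 = edges_mm[active[1L]],
      y2 = edges_mm[active[n_active] + 1L]
    ), each = n_cp), n_cp, 4L)

    arc_plan(
      patient_id = patient_id, field_id = field_id,
      cumulative_mu = mu, gantry_deg = gantry,
      bank_a = bank_a, bank_b = bank_b, jaws = jaws,
      collimator_deg = 45, rotation_sense = sense,
      geometry = geometry
    )
  })
}

# Sequentially clip a leaf pair's target trajectory to the per-segment travel
# budget, collapsing to the midpoint when clipping would cross the banks
# (midpoints stay within the travel budget of both previous positions).
clip_leaf_pair <- function(a_t, b_t, max_move) {
  n <- length(a_t)
  a <- a_t; b <- pmax(b_t, a_t)
  b[1L] <- max(b[1L], a[1L])
  for (k in 2:n) {
    m <- max_move[k - 1L]
    a[k] <- a[k - 1L] + max(min(a_t[k] - a[k - 1L], m), -m)
    b[k] <- b[k - 1L] + max(min(b_t[k] - b[k - 1L], m), -m)
    if (b[k] < a[k]) a[k] <- b[k] <- (a[k] + b[k]) / 2
  }
  list(a = a, b = b)
}

#' Simulate the machine-reported delivery of a plan
#'
#' Emits one snapshot per control-point boundary. The reported cumulative MU
#' is the planned MU plus Gaussian jitter (monotonicity restored by a running
#' maximum and clamped to the planned range); reported leaf positions are the
#' planned positions at the jittered MU minus `lag_coeff` times each leaf's
#' signed planned speed in the preceding segment, plus constant bias and
#' Gaussian noise; gantry and jaws get additive Gaussian noise (gantry
#' wrapped back onto `[0, 360)`).
#'
#' With an all-zero [error_model()] the record equals sampling the plan at
#' its own control points and [compute_errors()] returns all zeros.
#'
#' @param plan A validated `arc_plan`.
#' @param model An [error_model()].
#' @param fraction_date Date tag for the simulated fraction.
#' @return A `delivery_record`.
#' @export
simulate_delivery <- function(plan, model = error_model(),
                              fraction_date = "2026-01-01") {
  plan <- validate_arc_plan(plan)
  with_seed(model$seed, {
    n <- length(plan$cumulative_mu)
    np <- ncol(plan$bank_a)

    mu <- plan$cumulative_mu +
      stats::rnorm(n, 0, model$mu_jitter_sd)
    mu <- cummax(mu)
    mu <- pmin(pmax(mu, plan$cumulative_mu[1L]),
               plan$cumulative_mu[n])

    st <- interpolate_plan(plan, mu)

    du <- abs(diff(plan$gantry_unwrapped_deg))
    speed_a <- rbind(0, diff(plan$bank_a) / du)
    speed_b <- rbind(0, diff(plan$bank_b) / du)

    noise <- function(sd, rows, cols) {
      if (cols == 1L) stats::rnorm(rows, 0, sd)
      else matrix(stats::rnorm(rows * cols, 0, sd), rows, cols)
    }
    bank_a <- st$bank_a - model$lag_coeff * speed_a + model$leaf_bias +
      noise(model$leaf_noise_sd, n, np)
    bank_b <- st$bank_b - model$lag_coeff * speed_b + model$leaf_bias +
      noise(model$leaf_noise_sd, n, np)
    gantry <- wrap360(st$gantry_deg + noise(model$gantry_noise_sd, n, 1L))
    jaws <- st$jaws + noise(model$jaw_noise_sd, n, 4L)

    delivery_record(
      patient_id = plan$patient_id, field_id = plan$field_id,
      fraction_date = fraction_date,
      cumulative_mu = mu, gantry_deg = gantry,
      bank_a = bank_a, bank_b = bank_b, jaws = jaws
    )
  })
}

#' Generate a reproducible multi-patient cohort
#'
#' Assigns each synthetic patient a plan complexity drawn from `site_mix`,
#' generates one arc plan per patient, and simulates `fractions_per_patient`
#' deliveries per patient under `model`, with deterministic per-patient and
#' per-fraction sub-seeds so the whole cohort is a pure function of `seed`.
#'
#' @param n_patients Number of patients.
#' @param site_mix Named numeric vector: names are complexity levels in
#'   `[0, 1]` (e.g. `c("0.15" = 0.5, "0.9" = 0.5)` for a prostate-like /
#'   chest-wall-like split), values are proportions summing to 1.
#' @param fractions_per_patient Fractions simulated per patient.
#' @param model An [error_model()] (its `seed` field is ignored; sub-seeds
#'   derive from `seed`).
#' @param seed Integer master seed.
#' @param config Base [plan_generator_config()]; complexity and seed are
#'   overridden per patient.
#' @param start_date First fraction date; fractions advance one day at a
#'   time.
#' @return A `cohort`: named list (keys `P01`, ...) of entries with
#'   `patient_id`, `complexity`, `plan` and `records` (one per fraction,
#'   named by date).
#' @export
generate_cohort <- function(n_patients, site_mix = c("0.15" = 0.5,
                                                     "0.9" = 0.5),
                            fractions_per_patient = 1L,
                            model = error_model(), seed = 1L,
                            config = plan_generator_config(),
                            start_date = "2026-01-05") {
  props <- as.numeric(site_mix)
  levels <- as.numeric(names(site_mix))
  if (anyNA(levels) || anyNA(props) || abs(sum(props) - 1) > 1e-8)
    arcv_stop("'site_mix' must map complexity levels to proportions summing to 1",
              "arcv_config_error")
  counts <- diff(round(cumsum(c(0, props)) * n_patients))
  complexities <- rep(levels, counts)
  if (length(complexities) < n_patients)
    complexities <- c(complexities,
                      rep(levels[length(levels)],
                          n_patients - length(complexities)))
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L,
                            n_patients * (fractions_per_patient + 1L))
    dates <- format(as.Date(start_date) + seq_len(fractions_per_patient) - 1L)
    cohort <- lapply(seq_len(n_patients), function(p) {
      pid <- sprintf("P%02d", p)
      base <- (p - 1L) * (fractions_per_patient + 1L)
      cfg <- config
      cfg$complexity <- complexities[p]
      cfg$seed <- sub_seeds[base + 1L]
      plan <- generate_plan(cfg, patient_id = pid, field_id = "ARC1")
      records <- lapply(seq_len(fractions_per_patient), function(f) {
        m <- model
        m$seed <- sub_seeds[base + 1L + f]
        simulate_delivery(plan, m, fraction_date = dates[f])
      })
      names(records) <- dates
      list(patient_id = pid, complexity = complexities[p],
           plan = plan, records = records)
    })
    names(cohort) <- vapply(cohort, `[[`, "", "patient_id")
    structure(cohort, class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  nf <- sum(vapply(x, function(e) length(e$records), 0L))
  cat(sprintf("<cohort> %d patients, %d fractions, complexities %s\n",
              length(x), nf,
              paste(sort(unique(vapply(x, `[[`, 0.0, "complexity"))),
                    collapse = "/")))
  invisible(x)
}
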