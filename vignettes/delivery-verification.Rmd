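---
title: "Verifying VMAT deliveries from control-point snapshots: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying VMAT deliveries from control-point snapshots: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcverify)
```

## The verification model

A VMAT arc is planned as an ordered sequence of control points, each
carrying a gantry angle, an MLC shape (40 opposing leaf pairs, 80 leaves of
1 cm projected width), four jaw positions and a cumulative monitor-unit
(MU) value. Between control points the machine moves continuously; the
control system samples the delivered state at every control-point boundary
and reports it to the record-and-verify system. Because the snapshot is
taken at a *reported MU*, not at a planned index, the planned state it must
be compared against is reconstructed by linear interpolation on cumulative
MU: with bracketing control points $k, k{+}1$ and
$t = (m - \mu_k)/(\mu_{k+1} - \mu_k)$, every planned parameter is
$(1-t)\,x_k + t\,x_{k+1}$.

Three conventions make this well defined on real arcs:

* **Gantry unwrapping.** Single arcs conventionally start at 175° and
  rotate counter-clockwise through 0°/360° to 185°, so interpolation runs
  on an unwrapped coordinate (each step takes the shortest path consistent
  with the rotation sense; a 180° raw step is ambiguous and is refused).
  Gantry *errors* are signed shortest angular differences in
  $(-180°, 180°]$, with the antipodal tie resolved to $+180°$.
* **Interpolation abscissa.** The snapshot's *reported* cumulative MU is
  the only per-snapshot abscissa available, so it is what the planned state
  is evaluated at. Reported MU slightly beyond the planned total (which
  happens on real machines) is clamped to the arc endpoint with a warning
  rather than rejected.
* **Degenerate segments.** A zero-MU segment ($\mu_{k+1} = \mu_k$) resolves
  to the earlier control point ($t = 0$), and a query exactly on a repeated
  MU knot resolves the same way. Interpolation is exact — bit for bit — at
  control points, because the convex form $(1-t)x_k + t\,x_{k+1}$ returns
  $x_k$ at $t=0$ and $x_{k+1}$ at $t=1$ without rounding.

Errors are stored signed, `reported − planned`, per leaf (mm at isocenter),
per jaw (mm) and for the gantry (degrees). Leaf pairs shielded by the jaws
carry no dosimetric information, so they are flagged excluded: a pair is
blocked when its transverse extent $[e_i, e_{i+1}]$ has zero-length
intersection with the *open* Y-jaw interval $(y_1, y_2)$, evaluated on the
planned (interpolated) jaws so the exclusion mask is independent of
delivery noise. Excluded errors are retained and serialized with an
explicit flag — never deleted — so metrics can be recomputed under a
different exclusion rule later.

## Metrics

* **Percent within tolerance**, $100\cdot\#(|e|\le\tau)/\#\text{included}$,
  with an *inclusive* boundary (a 3.000 mm error counts as within 3 mm).
  Headlines are `P3mm` for leaves, `P2deg` for the gantry, `P3mm` for jaws;
  the tabulation sweeps 1/2/3/5 (mm or degrees), and is non-decreasing in
  tolerance by construction.
* **Per-leaf RMS** over included samples only; a leaf excluded at every
  snapshot reports `NA`, not 0, so it cannot masquerade as perfect.
* **Histograms** use 0.5 mm (leaves, jaws) and 0.5° (gantry) bins by
  default, centered on zero (one bin center at 0); counts always sum to
  the number of included samples.
* **Planned leaf speed** is leaf travel per degree of gantry rotation,
  $|\Delta x|/|\Delta\theta|$ per segment on the unwrapped gantry; the
  percentage of movements strictly greater than 1 mm/deg is the per-plan
  complexity index. Speeds are computed for all 80 leaves, including
  jaw-blocked ones: planned motion exists regardless of blocking.
* **Multi-fraction variability** reports per-patient mean, SD and 2·SD of
  each headline metric (single-observation SD is 0 by convention), plus the
  average over patients of the per-patient SDs.
* **Pearson's $r$** is evaluated directly from the product-moment formula
  (length ≥ 3, non-constant series required).

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| MLC tolerance | 3 | mm | standard daily-QA headline for leaf position |
| Gantry tolerance | 2 | deg | standard headline for gantry angle |
| Jaw tolerance | 3 | mm | standard headline for jaws |
| Sweep levels | 1, 2, 3, 5 | mm / deg | tabulation grid around the headlines |
| Histogram bins | 0.5 | mm / deg | resolves sub-tolerance structure without noise |
| Max leaf speed | 4 | mm/deg | planning constraint of the emulated protocol |
| Control-point spacing | 4 | deg | final gantry spacing of the emulated protocol |
| Total MU | 500 | MU | typical single 2 Gy arc; also consistent with a 90 s arc at the 500 MU/min top dose rate |

## The synthetic world

The generator emulates the arc protocol the verification system was built
around: one (or two, the second returning clockwise) 175° → 185°
counter-clockwise arcs, control points every ~4°, MU apportioned uniformly
across segments, static jaws framing a central block of active leaf pairs,
and leaf trajectories built from smooth random aperture drift and per-leaf
width modulation, sequentially clipped to the 4 mm/deg budget (a pair whose
clipped banks would cross collapses to their midpoint, which is always
within the travel budget). `complexity` $\in [0,1]$ scales requested
motion: 0 is a static aperture; ~0.15 produces active-leaf mean speeds near
0.35 mm/deg (a low-motion, prostate-like regime) and ~0.9 near 2 mm/deg
with frequent clipping (a high-motion, chest-wall-like regime). The labels
are purely motion scales — no anatomical content is claimed.

The delivery simulator emits one snapshot per control-point boundary. Its
dominant structured effect is a **latency lag**: the control system samples
MU and MLC positions into memory at different rates (20 ms vs 40 ms), so a
snapshot's reported leaf position trails a fast-moving leaf. The pipeline
has no time axis, so the lag is modeled in the gantry-angle domain:
reported leaf error contains $-\kappa v$, where $v$ is the leaf's signed
planned speed (mm/deg) in the segment preceding the boundary and $\kappa$
(mm per mm/deg) is a free parameter. On top sit independent Gaussian noise
per parameter, an optional constant leaf bias, and Gaussian jitter on
reported MU (monotonicity restored by a running maximum, clamped to the
planned range).

Defaults were fixed once, against the error magnitudes clinical delivery
verification reports — low-motion plans around 0.4 mm mean absolute leaf
error and nearly all samples within 3 mm; high-motion plans around 1.5 mm
with tails of several mm; ~96% of gantry angles within 2°; >99% of jaws
within 3 mm: $\kappa = 0.7$, $\sigma_\text{leaf} = 0.35$ mm,
$\sigma_\text{gantry} = 0.9°$, $\sigma_\text{jaw} = 0.8$ mm,
$\sigma_\text{MU} = 0.2$ MU. They were not adjusted afterwards.

What a green test does — and does not — establish: the simulator produces
smooth, speed-limited, seeded-reproducible trajectories with a *known*
error law, which is exactly what property tests need (identity deliveries,
closed-form Gaussian coverage, recoverable $\kappa$, a negative
complexity-accuracy relationship). Real treatment logs additionally contain
servo transients, dose-rate switching artifacts, asymmetric and
non-Gaussian error tails, occasional communication dropouts, and plan
populations whose complexity drifts over months. Green tests here certify
the pipeline's arithmetic and plumbing, not the clinical error
distribution.

```{r complexity, eval = FALSE}
# the qualitative complexity-accuracy ordering, at desk scale
cohort <- generate_cohort(8, c("0.15" = 0.5, "0.9" = 0.5), 1, seed = 1)
sapply(cohort, function(e) {
  s <- summarize_fraction(compute_errors(e$plan, e$records[[1]]))
  c(complexity = e$complexity, P3mm = unname(s$headline["P3mm_mlc"]))
})
```

## Numerical choices

* File dialects write doubles with 17 significant digits (`%.17g`), and
  JSON reports with 17 significant digits, so write-then-read is the
  identity on IEEE doubles; round-trip tests assert bit identity.
* `leaf_blocked` treats an intersection shorter than $10^{-9}$ mm as zero.
  Exact comparison made the common touching configuration (jaw edge
  exactly on a leaf-pair boundary) flip with the 1-ulp wiggle that linear
  interpolation introduces even into constant jaw positions.
* Angle reduction uses a guarded modulo: `x %% 360` in R can round to
  exactly 360 for tiny negative `x`, which would violate the
  $[0°, 360°)$ invariant.
* Alert comparators are strict (`below` fires on `observed < threshold`);
  windowed rules evaluate trailing means over the date-ordered fraction
  series and fire on every violating window.
* `aggregate_history` defines the SD of a single observation as 0 rather
  than `NA`, so one-fraction patients aggregate cleanly.

## Open design points resolved here

* **Jaw count.** Four reported jaw positions per snapshot (two orthogonal
  pairs); consistent with reported jaw/gantry sample-count ratios of ~4 on
  the emulated platform. Recorded as an inference, not a vendor claim.
* **Leaf sign convention.** Bank A ≤ bank B defines the open aperture
  along leaf travel; a closed pair has zero gap. Validated on ingestion.
* **Database replacement.** The record-and-verify SQL query stage is
  replaced by documented plain-text dialects plus a CLI whose exit code
  counts fired alerts, so any scheduler can drive nightly verification.
  Email is abstracted behind a sink interface; a file sink ships for tests
  and batch use.
* **DICOM import** is a convenience reader covering uncompressed
  explicit-VR little-endian RT Plans with one dynamic MLC beam; everything
  else raises an unsupported-content error. The CSV dialect remains the
  normative interface.

## Known limitations

* The latency model is first-order and angle-domain; it does not model
  dose-rate switching, servo dynamics, or time-domain sampling explicitly.
* Jaws are static in generated plans (tracking jaws are not emulated).
* Only IEC-style angles in $[0°, 360°)$ are supported on input.
* The DICOM reader does not parse RT Treatment Records or vendor binary
  log formats.
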