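# Shared fixtures and independent oracles. Everything is generated in code
# at test time; expensive objects are memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

# Reduced panel covering the same 409.6 mm physical extent as the full
# 512 x 0.8 mm detector, for fast image synthesis in tests.
tiny_geometry <- function(n = 32L) {
  panel_geometry(n_pixels = n, pixel_pitch_panel_mm = 0.8 * 512 / n)
}

small_config <- function() {
  run_config(seed = 42L, n_segments = 60L, geometry = tiny_geometry(32L),
             noise = noise_model(rampup_segments = 6L))
}

# Six-patient cohort (3 varied + 3 fixed menus) at reduced scale, simulated
# once per test run.
small_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- simulate_cohort(small_config())
  .fixture_env$cohort
}

# ---- synthetic traces (no images) ----------------------------------------

# Wrap a sections x 4 matrix of metric values as a metric_trace.
synth_trace <- function(M, start = 19L, n_segments = start + nrow(M) - 1L,
                        patient_id = "S", error = error_spec("NONE")) {
  df <- data.frame(section_index = start:(start + nrow(M) - 1L),
                   cas = M[, 1], miv = M[, 2], mdm = M[, 3], mdl = M[, 4])
  as_metric_trace(df, n_segments = n_segments, patient_id = patient_id,
                  error = error)
}

# Trace-only cohort with seeded noise normals and step-elevated error
# cases: patient-varying baseline, error cases jump at a magnitude-
# dependent section. Used for optimiser mechanics.
synth_cohort <- function(seed = 7L, n_varied = 3L, n_fixed = 3L,
                         n_sections = 50L, start = 19L) {
  set.seed(seed)
  mk_patient <- function(id, varied) {
    base <- runif(4, 0.05, 0.15)
    noise_mat <- function() {
      M <- matrix(abs(rep(base, each = n_sections) +
                        rnorm(4 * n_sections, 0, 0.02)),
                  n_sections, 4)
      M
    }
    normal <- synth_trace(noise_mat(), start, patient_id = id)
    mags <- if (varied) seq(2, 10, 2) else 4
    cases <- list()
    for (fam in c("MU_SCALE", "LEAF_RETRACT", "LEAF_SHIFT", "AIR_CAVITY")) {
      for (mg in mags) {
        M <- noise_mat()
        onset <- max(1L, n_sections - 2L * mg)
        M[onset:n_sections, ] <- M[onset:n_sections, ] + 0.1 * mg
        cases[[length(cases) + 1L]] <-
          synth_trace(M, start, patient_id = id, error = error_spec(fam, mg))
      }
    }
    pd_patient(id, varied, normal, cases)
  }
  ids <- sprintf("T%02d", seq_len(n_varied + n_fixed))
  pd_cohort(lapply(seq_along(ids), function(i)
    mk_patient(ids[i], i <= n_varied)))
}

# Cohort realising the premise of the composite metric: several metrics
# rise together to 60% of their thresholds, none crossing alone. Normals
# have one metric at a time elevated (uncorrelated); the single error case
# elevates CAS/MIV/MDM simultaneously from `onset` on.
correlated_cohort <- function(seed = 11L, n_sections = 62L, start = 19L,
                              onset_section = 40L) {
  set.seed(seed)
  n_pat <- 4L
  mk_normal <- function(id) {
    M <- matrix(runif(n_sections * 4, 0.01, 0.03), n_sections, 4)
    for (s in seq_len(n_sections))
      M[s, (s %% 4L) + 1L] <- runif(1, 0.15, 0.2)
    synth_trace(M, start, patient_id = id)
  }
  ids <- sprintf("C%02d", seq_len(n_pat))
  normals <- lapply(ids, mk_normal)
  thr <- build_thresholds(normals)
  M <- matrix(runif(n_sections * 4, 0.01, 0.03), n_sections, 4)
  rows <- (onset_section - start + 1L):n_sections
  for (i in 1:3) M[rows, i] <- 0.6 * thr$metrics[i]
  case <- synth_trace(M, start, patient_id = ids[1],
                      error = error_spec("LEAF_SHIFT", 2))
  pats <- lapply(seq_len(n_pat), function(i) {
    pd_patient(ids[i], varied = i == 1L, normal = normals[[i]],
               cases = if (i == 1L) list(case) else list())
  })
  list(cohort = pd_cohort(pats),
       fold = list(optimisation_ids = ids, test_ids = character(0)),
       thresholds = thr, onset = onset_section)
}

# ---- independent oracles --------------------------------------------------

# Brute-force ray-marching radiological path (water minus cavity), step in
# mm along the ray.
raymarch_path <- function(ph, gantry_deg, u, y = 0, step = 0.05) {
  th <- gantry_deg * pi / 180
  d <- c(-sin(th), -cos(th))
  p <- c(cos(th), -sin(th))
  s <- seq(-400, 400, by = step)
  x <- u * p[1] + s * d[1]
  z <- u * p[2] + s * d[2]
  if (abs(y) > ph$length_gt_mm / 2) return(0)
  eps <- 1e-9  # keep grazing rays on closed faces (floating-point jitter)
  inside <- abs(x) <= ph$width_ab_mm / 2 + eps & abs(z) <= ph$height_mm / 2 + eps
  cav <- ph$cavity
  if (!is.null(cav) && abs(y - cav$centre_offset_mm[2]) <= cav$length_gt_mm / 2) {
    in_cav <- abs(x - cav$centre_offset_mm[1]) <= cav$width_lr_mm / 2 + eps &
      abs(z - cav$centre_offset_mm[3]) <= cav$height_ap_mm / 2 + eps
    inside <- inside & !in_cav
  }
  sum(inside) * step
}

# Naive per-pixel metric computation with explicit loops over the mask.
naive_metrics <- function(pred, meas, fraction = 0.1) {
  n <- nrow(pred)
  mx <- max(pred)
  ctr <- c(n %/% 2L, n %/% 2L + 1L)
  cas <- abs(mean(meas[ctr, ctr]) - mean(pred[ctr, ctr]))
  svals <- sdiff <- srel <- 0; cnt <- 0L; smeas <- spred <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (pred[i, j] > fraction * mx) {
      cnt <- cnt + 1L
      smeas <- smeas + meas[i, j]; spred <- spred + pred[i, j]
      sdiff <- sdiff + abs(meas[i, j] - pred[i, j])
      srel <- srel + abs(meas[i, j] - pred[i, j]) / pred[i, j]
    }
  }
  c(cas = cas, miv = abs(smeas / cnt - spred / cnt),
    mdm = 100 * (sdiff / cnt) / mx, mdl = 100 * srel / cnt)
}
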