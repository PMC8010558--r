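# Analytic EPID forward model: aperture projection, exponential attenuation
# through the phantom (parallel-beam approximation), couch attenuation,
# uniform out-of-field scatter level, two-Gaussian panel scatter, and
# sinusoidal panel sag. Also the "measured" delivery simulator (forward
# model + output/noise/ramp-up perturbations).

#' Panel geometry of the portal imager
#'
#' Defaults describe a 512 x 512 amorphous-silicon panel with 0.8 mm pixels
#' at a source-panel distance of 1600 mm and source-axis distance 1000 mm,
#' giving 0.5 mm pixels at the isocentre plane, plus a 4 mm peak-to-peak
#' sinusoidal longitudinal sag.
#'
#' @param n_pixels Number of pixels along each side (even integer).
#' @param pixel_pitch_panel_mm Pixel pitch at the panel plane, mm.
#' @param sdd_mm Source-panel distance, mm.
#' @param sad_mm Source-axis distance, mm.
#' @param sag_peak_to_peak_mm Peak-to-peak longitudinal panel sag, mm.
#' @param sag_phase_deg Phase of the sag sinusoid, degrees.
#' @return An object of class `panel_geometry`.
#' @export
panel_geometry <- function(n_pixels = 512L, pixel_pitch_panel_mm = 0.8,
                           sdd_mm = 1600, sad_mm = 1000,
                           sag_peak_to_peak_mm = 4, sag_phase_deg = 0) {
  n_pixels <- as.integer(n_pixels)
  stop_if(n_pixels < 2L || n_pixels %% 2L != 0L, "n_pixels must be even")
  stop_if(!(sdd_mm >= sad_mm) || sad_mm <= 0,
          "require sdd_mm >= sad_mm > 0")
  structure(list(n_pixels = n_pixels,
                 pixel_pitch_panel_mm = pixel_pitch_panel_mm,
                 sdd_mm = sdd_mm, sad_mm = sad_mm,
                 sag_peak_to_peak_mm = sag_peak_to_peak_mm,
                 sag_phase_deg = sag_phase_deg),
            class = "panel_geometry")
}

#' Forward-model parameters
#'
#' @param mu_water_per_mm Linear attenuation coefficient used for the
#'   in-field exponential attenuation, per mm.
#' @param couch_path_mm Base additional water-equivalent path through the
#'   couch at gantry 0, mm. Divided by cos(gantry) inside the couch window.
#' @param couch_window_deg Length-2 vector `c(from, to)`; the couch lies in
#'   the beam for gantry angles from `from` through 0 to `to` (default
#'   300 through 60), edges included.
#' @param scatter_sigmas_mm Standard deviations (narrow, broad) of the two
#'   Gaussian panel-scatter kernels, mm at the panel plane.
#' @param scatter_weight Mixture weight of the narrow kernel, in \[0, 1\].
#' @param out_of_field_coeff Scalar linking open aperture area (per
#'   10^4 mm^2) and attenuation along the mean in-field path to the uniform
#'   out-of-field level.
#' @param oof_mu_per_mm Attenuation coefficient applied to the mean path in
#'   the out-of-field scatter term, per mm.
#' @param intensity_scale Maps raw attenuated fluence per MU into the
#'   working 0-100 intensity range (plays the role of the detector gain
#'   and the 1e-4 rescale applied to real images).
#' @return An object of class `forward_params`.
#' @export
forward_params <- function(mu_water_per_mm = 0.0049, couch_path_mm = 8,
                           couch_window_deg = c(300, 60),
                           scatter_sigmas_mm = c(2, 20),
                           scatter_weight = 0.9,
                           out_of_field_coeff = 0.03,
                           oof_mu_per_mm = mu_water_per_mm,
                           intensity_scale = 10) {
  stop_if(couch_path_mm < 0, "couch_path_mm must be >= 0")
  stop_if(scatter_weight < 0 || scatter_weight > 1,
          "scatter_weight must be in [0, 1]")
  stop_if(any(scatter_sigmas_mm <= 0), "scatter sigmas must be positive")
  structure(list(mu_water_per_mm = mu_water_per_mm,
                 couch_path_mm = couch_path_mm,
                 couch_window_deg = couch_window_deg,
                 scatter_sigmas_mm = scatter_sigmas_mm,
                 scatter_weight = scatter_weight,
                 out_of_field_coeff = out_of_field_coeff,
                 oof_mu_per_mm = oof_mu_per_mm,
                 intensity_scale = intensity_scale),
            class = "forward_params")
}

#' Additional radiological path through the couch
#'
#' Returns `couch_path_mm / cos(gantry)` for gantry angles inside the couch
#' window (default 300 degrees through 0 to 60, edges included) and 0
#' elsewhere. At gantry 60 the default path is therefore 16 mm.
#'
#' @param gantry_deg Gantry angle(s), degrees in \[0, 360). Vectorised.
#' @param params A [forward_params()].
#' @return Water-equivalent path in mm, same length as `gantry_deg`.
#' @export
couch_extra_path <- function(gantry_deg, params = forward_params()) {
  g <- gantry_deg %% 360
  w <- params$couch_window_deg
  inside <- (g >= w[1]) | (g <= w[2])
  out <- numeric(length(g))
  out[inside] <- params$couch_path_mm / cos(g[inside] * pi / 180)
  out
}

#' Longitudinal panel sag shift
#'
#' Sinusoidal gravity-induced longitudinal displacement of the panel image:
#' `(peak_to_peak / 2) * sin(gantry + phase)`. Applied identically when
#' synthesising predicted and measured images.
#'
#' @param gantry_deg Gantry angle(s), degrees. Vectorised.
#' @param geometry A [panel_geometry()].
#' @return Shift in mm at the panel plane.
#' @export
panel_sag_shift <- function(gantry_deg, geometry = panel_geometry()) {
  (geometry$sag_peak_to_peak_mm / 2) *
    sin((gantry_deg + geometry$sag_phase_deg) * pi / 180)
}

#' Pixel pitch at the isocentre plane
#'
#' `pixel_pitch_panel_mm * sad_mm / sdd_mm`; 0.5 mm for the default panel.
#'
#' @param geometry A [panel_geometry()].
#' @return Pitch in mm.
#' @export
isocentre_pixel_pitch <- function(geometry = panel_geometry()) {
  geometry$pixel_pitch_panel_mm * geometry$sad_mm / geometry$sdd_mm
}

# Chord length of the line through (u * p + s * d) across an axis-aligned
# rectangle centred at (cx, cz) with half-sizes (hx, hz), where the ray
# direction d and lateral unit vector p follow the gantry angle. Vectorised
# over the lateral offset u. Parallel-beam approximation.
rect_chord <- function(hx, hz, gantry_deg, u, cx = 0, cz = 0) {
  th <- gantry_deg * pi / 180
  dx <- -sin(th); dz <- -cos(th)     # ray direction (towards the panel)
  px <- cos(th);  pz <- -sin(th)     # lateral (crossplane) unit vector
  x0 <- u * px - cx
  z0 <- u * pz - cz
  lo <- rep(-Inf, length(u)); hi <- rep(Inf, length(u))
  clip <- function(p0, dir, h, lo, hi) {
    if (abs(dir) < 1e-12) {
      miss <- abs(p0) > h
      lo[miss] <- Inf; hi[miss] <- -Inf
    } else {
      s1 <- (-h - p0) / dir; s2 <- (h - p0) / dir
      lo <- pmax(lo, pmin(s1, s2)); hi <- pmin(hi, pmax(s1, s2))
    }
    list(lo = lo, hi = hi)
  }
  cl <- clip(x0, dx, hx, lo, hi)
  cl <- clip(z0, dz, hz, cl$lo, cl$hi)
  pmax(0, cl$hi - cl$lo)
}

#' Water-equivalent radiological path through the phantom
#'
#' Chord length of the parallel ray at the given lateral (crossplane)
#' offset through the phantom cross-section, minus any chord through the
#' air cavity, under a parallel-beam approximation with the ray direction
#' set by the gantry angle. Rays missing the phantom return 0.
#'
#' @param ph A [phantom()].
#' @param gantry_deg Gantry angle, degrees.
#' @param lateral_offset_mm Crossplane offset(s) of the ray at the
#'   isocentre plane, mm. Vectorised.
#' @param longitudinal_offset_mm Gun-target offset of the ray, mm (scalar);
#'   rays beyond the phantom's G-T extent return 0 and the cavity is only
#'   traversed within its G-T length.
#' @return Water-equivalent path(s) in mm.
#' @export
radiological_path <- function(ph, gantry_deg, lateral_offset_mm,
                              longitudinal_offset_mm = 0) {
  stop_if(!inherits(ph, "phantom"), "ph must be a phantom")
  u <- lateral_offset_mm
  y <- longitudinal_offset_mm
  if (abs(y) > ph$length_gt_mm / 2) return(numeric(length(u)))
  p <- rect_chord(ph$width_ab_mm / 2, ph$height_mm / 2, gantry_deg, u)
  cav <- ph$cavity
  if (!is.null(cav) &&
      abs(y - cav$centre_offset_mm[2]) <= cav$length_gt_mm / 2) {
    p <- p - rect_chord(cav$width_lr_mm / 2, cav$height_ap_mm / 2,
                        gantry_deg, u,
                        cx = cav$centre_offset_mm[1],
                        cz = cav$centre_offset_mm[3])
  }
  pmax(p, 0)
}

# ---- panel scatter: cached separable Gaussian band matrices ---------------

.blur_cache <- new.env(parent = emptyenv())

# n x n symmetric Toeplitz matrix of a discrete Gaussian (sigma in mm,
# pixels of `pitch` mm), truncated at 4 sigma and normalised so the full
# kernel sums to one (energy-preserving on interior-supported images).
gauss_band_matrix <- function(n, pitch, sigma) {
  key <- sprintf("%d_%.8g_%.8g", n, pitch, sigma)
  hit <- .blur_cache[[key]]
  if (!is.null(hit)) return(hit)
  K <- max(1L, ceiling(4 * sigma / pitch))
  g <- stats::dnorm((-K:K) * pitch, 0, sigma)
  g <- g / sum(g)
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  B <- matrix(0, n, n)
  idx <- D <= K
  B[idx] <- g[D[idx] + K + 1L]
  .blur_cache[[key]] <- B
  B
}

# Two-Gaussian panel scatter: w * G(sigma1) + (1 - w) * G(sigma2), applied
# separably along rows and columns via band-matrix products.
panel_scatter <- function(img, geometry, params) {
  n <- nrow(img); pitch <- geometry$pixel_pitch_panel_mm
  s <- params$scatter_sigmas_mm; w <- params$scatter_weight
  B1 <- gauss_band_matrix(n, pitch, s[1])
  B2 <- gauss_band_matrix(n, pitch, s[2])
  w * (B1 %*% img %*% B1) + (1 - w) * (B2 %*% img %*% B2)
}

# Shift image rows (longitudinal axis) by a sub-pixel amount with linear
# interpolation, zero padding at the edges.
shift_rows <- function(img, shift_px) {
  if (abs(shift_px) < 1e-12) return(img)
  n <- nrow(img)
  r0 <- floor(shift_px); f <- shift_px - r0
  src1 <- seq_len(n) - r0
  src2 <- src1 - 1L
  pick <- function(src) {
    out <- matrix(0, n, ncol(img))
    ok <- src >= 1L & src <= n
    out[ok, ] <- img[src[ok], ]
    out
  }
  (1 - f) * pick(src1) + f * pick(src2)
}

# ---- portal images and stacks --------------------------------------------

new_portal_image <- function(pixels, segment_index, gantry_deg, role) {
  structure(list(pixels = pixels, segment_index = segment_index,
                 gantry_deg = gantry_deg, role = role),
            class = "portal_image")
}

#' @export
print.portal_image <- function(x, ...) {
  cat(sprintf("<portal_image> segment %d, gantry %.1f deg, %s, %dx%d, max %.3g\n",
              x$segment_index, x$gantry_deg, x$role,
              nrow(x$pixels), ncol(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Predict the portal image of one segment
#'
#' The forward model: (1) the MLC aperture is rendered at isocentre-plane
#' pixel pitch (one panel pixel per isocentre-plane sample, i.e. a single
#' SDD/SAD magnification); (2) the in-field signal is
#' `mu * intensity_scale * exp(-mu_water * (radiological_path + couch_path))`;
#' (3) the out-of-field signal is a uniform level proportional to the open
#' aperture area and attenuated along the mean in-field path; (4) the union
#' of both regions is convolved with the two-Gaussian panel-scatter kernel;
#' (5) the sinusoidal sag shift is applied. The image is linear in the
#' segment's MU.
#'
#' @param segment A segment as returned by [plan_segment()].
#' @param ph A [phantom()].
#' @param geometry A [panel_geometry()].
#' @param params A [forward_params()].
#' @return A `portal_image` with non-negative pixels on the working scale.
#' @export
predict_image <- function(segment, ph, geometry = panel_geometry(),
                          params = forward_params()) {
  n <- geometry$n_pixels
  pitch_iso <- isocentre_pixel_pitch(geometry)
  u <- (seq_len(n) - (n + 1) / 2) * pitch_iso   # crossplane, columns
  v <- (seq_len(n) - (n + 1) / 2) * pitch_iso   # longitudinal, rows

  # Aperture mask: leaf pairs stack along the longitudinal axis.
  np <- length(segment$bank_a)
  lp <- segment$leaf_pitch_mm
  k <- floor(v / lp + np / 2) + 1L
  valid <- k >= 1L & k <= np
  a_row <- b_row <- rep(NA_real_, n)
  a_row[valid] <- segment$bank_a[k[valid]]
  b_row[valid] <- segment$bank_b[k[valid]]
  U <- matrix(u, n, n, byrow = TRUE)
  mask <- !is.na(a_row) & (U > a_row) & (U < b_row)

  # Radiological path matrix (rows share the same crossplane chord profile).
  g <- segment$gantry_deg
  chord_u <- rect_chord(ph$width_ab_mm / 2, ph$height_mm / 2, g, u)
  in_gt <- as.numeric(abs(v) <= ph$length_gt_mm / 2)
  P <- in_gt %o% chord_u
  cav <- ph$cavity
  if (!is.null(cav)) {
    cav_u <- rect_chord(cav$width_lr_mm / 2, cav$height_ap_mm / 2, g, u,
                        cx = cav$centre_offset_mm[1],
                        cz = cav$centre_offset_mm[3])
    in_cav <- as.numeric(abs(v - cav$centre_offset_mm[2]) <=
                           cav$length_gt_mm / 2)
    P <- pmax(P - in_cav %o% cav_u, 0)
  }

  couch <- couch_extra_path(g, params)
  infield <- segment$mu * params$intensity_scale *
    exp(-params$mu_water_per_mm * (P + couch))

  area_mm2 <- lp * sum(pmax(segment$bank_b - segment$bank_a, 0))
  if (any(mask)) {
    mean_path <- mean(P[mask]) + couch
  } else {
    mean_path <- couch
  }
  oof <- segment$mu * params$intensity_scale * params$out_of_field_coeff *
    (area_mm2 / 1e4) * exp(-params$oof_mu_per_mm * mean_path)

  img <- matrix(oof, n, n)
  img[mask] <- infield[mask]
  img <- panel_scatter(img, geometry, params)
  sag_px <- panel_sag_shift(g, geometry) / geometry$pixel_pitch_panel_mm
  img <- shift_rows(img, sag_px)
  new_portal_image(pmax(img, 0), segment$index, g, "predicted")
}

new_portal_stack <- function(pixels, gantry_deg, role, patient_id,
                             provenance = list()) {
  structure(list(pixels = pixels, gantry_deg = gantry_deg, role = role,
                 patient_id = patient_id, provenance = provenance),
            class = "portal_stack")
}

#' @export
print.portal_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<portal_stack> %s: %d frames of %dx%d (%s)\n",
              x$patient_id, d[3], d[1], d[2], x$role))
  invisible(x)
}

#' Predict the full portal-image stack of a plan
#'
#' Applies [predict_image()] to every segment.
#'
#' @param plan A `vmat_plan`.
#' @param ph A [phantom()].
#' @param geometry A [panel_geometry()].
#' @param params A [forward_params()].
#' @return A `portal_stack` with role `"predicted"`.
#' @export
predict_stack <- function(plan, ph, geometry = panel_geometry(),
                          params = forward_params()) {
  n <- geometry$n_pixels
  ns <- n_segments(plan)
  px <- array(0, c(n, n, ns))
  for (j in seq_len(ns))
    px[, , j] <- predict_image(plan_segment(plan, j), ph, geometry, params)$pixels
  new_portal_stack(px, plan$gantry_deg, "predicted", plan$patient_id)
}

#' Measurement noise and instability model
#'
#' A per-delivery multiplicative output factor (SD `global_output_sd`),
#' additive per-pixel Gaussian noise on the working intensity scale, and an
#' optional early-delivery signal instability: the first `rampup_segments`
#' frames are scaled by a deficit ramping linearly from
#' `1 - rampup_amplitude` back to 1.
#'
#' @param global_output_sd SD of the per-delivery output factor. Default 0.01.
#' @param pixel_noise_sd SD of the additive per-pixel noise (working
#'   scale). Default 0.2.
#' @param rampup_segments Number of initial unstable segments. Default 18
#'   (the first 10% of a 180-segment arc).
#' @param rampup_amplitude Fractional signal deficit at the first segment.
#'   Default 0.05.
#' @param seed Integer RNG seed for the delivery.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(global_output_sd = 0.01, pixel_noise_sd = 0.2,
                        rampup_segments = 18L, rampup_amplitude = 0.05,
                        seed = 1L) {
  stop_if(global_output_sd < 0 || pixel_noise_sd < 0 || rampup_amplitude < 0,
          "noise SDs and ramp amplitude must be >= 0")
  structure(list(global_output_sd = global_output_sd,
                 pixel_noise_sd = pixel_noise_sd,
                 rampup_segments = as.integer(rampup_segments),
                 rampup_amplitude = rampup_amplitude,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Noise-free measurement model
#'
#' Convenience constructor: no output variation, no pixel noise, no ramp-up.
#' With this model a simulated measured stack of an unmodified plan equals
#' the predicted stack exactly.
#'
#' @param seed Seed (kept for interface symmetry; unused randomness).
#' @return A `noise_model`.
#' @export
zero_noise <- function(seed = 1L) {
  noise_model(0, 0, 0L, 0, seed)
}

#' Simulate the measured portal-image stack of a delivery
#'
#' Applies the forward model to the (possibly error-injected) plan and
#' phantom, then multiplies by a per-delivery output factor, applies the
#' early-segment instability ramp, and adds per-pixel Gaussian noise
#' (clipped at zero). Deterministic for a fixed noise seed.
#'
#' @param plan A `vmat_plan` (possibly after [inject_error()]).
#' @param ph A [phantom()] (possibly carrying an air cavity).
#' @param geometry A [panel_geometry()].
#' @param params A [forward_params()].
#' @param noise A [noise_model()].
#' @param provenance Optional list stored with the stack (e.g. the
#'   [error_spec()]).
#' @return A `portal_stack` with role `"measured"`.
#' @export
simulate_measured_stack <- function(plan, ph, geometry = panel_geometry(),
                                    params = forward_params(),
                                    noise = noise_model(),
                                    provenance = list()) {
  n <- geometry$n_pixels
  ns <- n_segments(plan)
  px <- array(0, c(n, n, ns))
  with_seed(noise$seed, {
    fac <- max(1 + stats::rnorm(1) * noise$global_output_sd, 0)
    for (j in seq_len(ns)) {
      pred <- predict_image(plan_segment(plan, j), ph, geometry, params)$pixels
      ramp <- 1
      if (noise$rampup_segments > 0L && j <= noise$rampup_segments) {
        ramp <- 1 - noise$rampup_amplitude *
          (1 - (j - 1) / noise$rampup_segments)
      }
      frame <- pred * fac * ramp
      if (noise$pixel_noise_sd > 0)
        frame <- frame + stats::rnorm(n * n) * noise$pixel_noise_sd
      px[, , j] <- pmax(frame, 0)
    }
  })
  prov <- c(provenance, list(noise_seed = noise$seed))
  new_portal_stack(px, plan$gantry_deg, "measured", plan$patient_id, prov)
}
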