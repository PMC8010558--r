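# Synthetic VMAT plans, the water-equivalent phantom, and deliberate
# delivery errors.
#
# Geometry conventions (used consistently by the forward model):
#   x = crossplane / left-right (A-B) direction, mm at the isocentre plane
#   y = longitudinal / gun-target (G-T) direction, mm
#   z = anteroposterior direction, mm; +z towards the source at gantry 0
# Gantry angles are IEC-style degrees in [0, 360): 0 = source above the
# couch; the couch sits between isocentre and panel for gantry angles in
# [300, 60] through 0. Segment indices are 1-based.

#' Construct a water-equivalent phantom
#'
#' A rectangular water-equivalent box centred on the isocentre, optionally
#' containing a rectangular air cavity. Default dimensions are 300 mm long
#' (G-T) x 300 mm wide (A-B) x 200 mm high.
#'
#' @param length_gt_mm Box length in the gun-target direction (mm).
#' @param width_ab_mm Box width in the left-right direction (mm).
#' @param height_mm Box height in the anteroposterior direction (mm).
#' @param mu_water_per_mm Linear attenuation coefficient of water for the
#'   beam quality, per mm. Default 0.0049 (6 MV-like).
#' @param cavity Optional [air_cavity()].
#' @return An object of class `phantom`.
#' @export
phantom <- function(length_gt_mm = 300, width_ab_mm = 300, height_mm = 200,
                    mu_water_per_mm = 0.0049, cavity = NULL) {
  stop_if(!all(vapply(list(length_gt_mm, width_ab_mm, height_mm, mu_water_per_mm),
                      is_scalar_number, logical(1))) ||
            length_gt_mm <= 0 || width_ab_mm <= 0 || height_mm <= 0 ||
            mu_water_per_mm <= 0,
          "phantom dimensions and mu_water_per_mm must be positive numbers")
  ph <- structure(
    list(length_gt_mm = length_gt_mm, width_ab_mm = width_ab_mm,
         height_mm = height_mm, mu_water_per_mm = mu_water_per_mm,
         cavity = NULL),
    class = "phantom")
  if (!is.null(cavity)) ph <- set_cavity(ph, cavity)
  ph
}

#' Construct an air cavity
#'
#' A rectangular air volume placed inside the phantom, used to emulate
#' rectal gas: `width_lr_mm` wide (left-right) x 50 mm high
#' (anteroposterior) by default, centred 40 mm posterior of the isocentre.
#'
#' @param width_lr_mm Cavity width in the left-right direction (mm).
#' @param height_ap_mm Cavity height in the anteroposterior direction (mm).
#' @param length_gt_mm Cavity length in the gun-target direction (mm).
#' @param centre_offset_mm Numeric length-3 offset (x, y, z) of the cavity
#'   centre from the isocentre, mm. Negative z is posterior.
#' @return An object of class `air_cavity`.
#' @export
air_cavity <- function(width_lr_mm, height_ap_mm = 50, length_gt_mm = 50,
                       centre_offset_mm = c(0, 0, -40)) {
  stop_if(!is_scalar_number(width_lr_mm) || width_lr_mm <= 0 ||
            !is_scalar_number(height_ap_mm) || height_ap_mm <= 0 ||
            !is_scalar_number(length_gt_mm) || length_gt_mm <= 0,
          "air cavity dimensions must be positive")
  stop_if(!is.numeric(centre_offset_mm) || length(centre_offset_mm) != 3L,
          "centre_offset_mm must be a numeric 3-vector (x, y, z)")
  structure(
    list(width_lr_mm = width_lr_mm, height_ap_mm = height_ap_mm,
         length_gt_mm = length_gt_mm,
         centre_offset_mm = as.numeric(centre_offset_mm)),
    class = "air_cavity")
}

#' Place an air cavity inside a phantom
#'
#' Validates that the cavity lies fully inside the phantom box.
#'
#' @param ph A [phantom()].
#' @param cavity An [air_cavity()].
#' @return The phantom with the cavity set.
#' @export
set_cavity <- function(ph, cavity) {
  stop_if(!inherits(ph, "phantom"), "ph must be a phantom")
  stop_if(!inherits(cavity, "air_cavity"), "cavity must be an air_cavity")
  off <- cavity$centre_offset_mm
  half <- c(cavity$width_lr_mm, cavity$length_gt_mm, cavity$height_ap_mm) / 2
  lim <- c(ph$width_ab_mm, ph$length_gt_mm, ph$height_mm) / 2
  stop_if(any(abs(off) + half > lim + 1e-9),
          "air cavity extends outside the phantom box")
  ph$cavity <- cavity
  ph
}

#' Construct a VMAT plan object
#'
#' Low-level constructor; most users will call [generate_plan()]. Leaf bank
#' positions are stored as segment x leaf-pair matrices in mm at the
#' isocentre plane, with `bank_a[j, k] <= bank_b[j, k]` defining the open
#' interval of pair `k` in segment `j`.
#'
#' @param patient_id Character identifier.
#' @param gantry_deg Numeric vector of per-segment gantry angles, degrees
#'   in \[0, 360).
#' @param mu Numeric vector of per-segment monitor units (>= 0).
#' @param bank_a,bank_b Numeric matrices (n_segments x n_leaf_pairs) of
#'   leaf positions, mm at isocentre.
#' @param collimator_deg Collimator angle, degrees.
#' @param leaf_pitch_mm Leaf width at the isocentre plane, mm.
#' @param arc_span_deg Total gantry arc, degrees.
#' @return An object of class `vmat_plan`.
#' @export
vmat_plan <- function(patient_id, gantry_deg, mu, bank_a, bank_b,
                      collimator_deg = 2, leaf_pitch_mm = 5,
                      arc_span_deg = 358) {
  n <- length(gantry_deg)
  stop_if(n < 1L, "plan needs at least one segment")
  stop_if(length(mu) != n, "mu must have one value per segment")
  stop_if(!is.matrix(bank_a) || !is.matrix(bank_b) ||
            nrow(bank_a) != n || !identical(dim(bank_a), dim(bank_b)),
          "bank_a and bank_b must be n_segments x n_leaf_pairs matrices")
  stop_if(any(!is.finite(mu)) || any(mu < 0), "mu must be finite and >= 0")
  stop_if(any(bank_a > bank_b + 1e-9),
          "bank_a must not exceed bank_b for any leaf pair")
  structure(
    list(patient_id = as.character(patient_id),
         gantry_deg = as.numeric(gantry_deg) %% 360,
         mu = as.numeric(mu),
         bank_a = bank_a, bank_b = bank_b,
         collimator_deg = collimator_deg,
         leaf_pitch_mm = leaf_pitch_mm,
         arc_span_deg = arc_span_deg),
    class = "vmat_plan")
}

#' @export
print.vmat_plan <- function(x, ...) {
  cat(sprintf("<vmat_plan> %s: %d segments, %.0f deg arc, %d leaf pairs, total MU %.1f\n",
              x$patient_id, n_segments(x), x$arc_span_deg,
              ncol(x$bank_a), sum(x$mu)))
  invisible(x)
}

#' Number of segments of a plan or image stack
#' @param x A `vmat_plan` or `portal_stack`.
#' @return Integer count of segments.
#' @export
n_segments <- function(x) {
  if (inherits(x, "vmat_plan")) return(length(x$gantry_deg))
  if (inherits(x, "portal_stack")) return(dim(x$pixels)[3])
  stop("n_segments: unsupported object", call. = FALSE)
}

#' Extract one segment from a plan
#'
#' @param plan A `vmat_plan`.
#' @param j 1-based segment index.
#' @return A list with fields `index`, `gantry_deg`, `mu`, `bank_a`,
#'   `bank_b`, `collimator_deg`, `leaf_pitch_mm`.
#' @export
plan_segment <- function(plan, j) {
  stop_if(!inherits(plan, "vmat_plan"), "plan must be a vmat_plan")
  j <- as.integer(j)
  stop_if(j < 1L || j > n_segments(plan), "segment index out of range")
  list(index = j, gantry_deg = plan$gantry_deg[j], mu = plan$mu[j],
       bank_a = plan$bank_a[j, ], bank_b = plan$bank_b[j, ],
       collimator_deg = plan$collimator_deg,
       leaf_pitch_mm = plan$leaf_pitch_mm)
}

#' Per-segment aperture area
#'
#' Open aperture area of every segment, computed from the leaf positions as
#' `leaf_pitch * sum(bank_b - bank_a)` at the isocentre plane.
#'
#' @param plan A `vmat_plan`.
#' @return Numeric vector of areas in mm^2, one per segment.
#' @export
aperture_area <- function(plan) {
  stop_if(!inherits(plan, "vmat_plan"), "plan must be a vmat_plan")
  plan$leaf_pitch_mm * rowSums(pmax(plan$bank_b - plan$bank_a, 0))
}

#' Generate a synthetic prostate-like VMAT arc plan
#'
#' Produces a single-arc plan with evenly spaced gantry angles spanning
#' `arc_span_deg` (spacing `arc_span_deg / (n_segments - 1)`), approximately
#' even monitor-unit weighting, and smoothly modulated rounded apertures of
#' prostate-like extent (about 50-100 mm). Apertures are sampled as an
#' elliptical target outline whose half-widths are modulated per segment
#' and per leaf pair by low-frequency sinusoids with seeded random phases,
#' standing in for inverse-planned apertures.
#'
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @param n_segments Number of segments (>= 20). Default 180.
#' @param arc_span_deg Total arc span, degrees (<= 360). Default 358.
#' @param mean_mu Mean monitor units per segment (> 0). Default 2.
#' @param n_leaf_pairs Number of MLC leaf pairs. Default 40.
#' @param leaf_pitch_mm Leaf width at isocentre, mm. Default 5.
#' @param start_gantry_deg Gantry angle of the first segment. Default 181.
#' @param mu_spread Half-width of the uniform relative MU variation about
#'   `mean_mu` ("approximately even weighting"). Default 0.08.
#' @param patient_id Identifier stored in the plan.
#' @return A `vmat_plan`.
#' @export
generate_plan <- function(seed, n_segments = 180L, arc_span_deg = 358,
                          mean_mu = 2, n_leaf_pairs = 40L, leaf_pitch_mm = 5,
                          start_gantry_deg = 181, mu_spread = 0.08,
                          patient_id = sprintf("SYN%03d", as.integer(seed))) {
  stop_if(!is_scalar_number(n_segments) || n_segments < 20,
          "n_segments must be a number >= 20")
  stop_if(!is_scalar_number(arc_span_deg) || arc_span_deg <= 0 ||
            arc_span_deg > 360, "arc_span_deg must be in (0, 360]")
  stop_if(!is_scalar_number(mean_mu) || mean_mu <= 0,
          "mean_mu must be positive")
  n <- as.integer(n_segments)
  np <- as.integer(n_leaf_pairs)
  spacing <- arc_span_deg / (n - 1L)
  gantry <- (start_gantry_deg + (seq_len(n) - 1L) * spacing) %% 360

  with_seed(seed, {
    # Elliptical target outline: semi-axes in mm, prostate-like extent.
    semi_x <- stats::runif(1, 32, 42)   # crossplane half-width
    semi_y <- stats::runif(1, 28, 38)   # longitudinal half-extent
    y_k <- (seq_len(np) - (np + 1) / 2) * leaf_pitch_mm
    base_half <- semi_x * sqrt(pmax(0, 1 - (y_k / semi_y)^2))

    # Smooth per-segment modulation of the overall opening (arc harmonics).
    ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
    t <- 2 * pi * (seq_len(n) - 1L) / n
    seg_mod <- 1 + 0.15 * sin(2 * t + ph1) + 0.10 * sin(5 * t + ph2)

    # Smooth per-bank perturbation, low-rank in (segment, leaf pair).
    bank_pert <- function() {
      p <- matrix(0, n, np)
      for (h in 1:3) {
        amp <- stats::runif(1, 0.8, 2.0)
        pa <- stats::runif(1, 0, 2 * pi); pb <- stats::runif(1, 0, 2 * pi)
        fy <- stats::runif(1, 0.5, 2.0)
        p <- p + amp * outer(sin(h * t + pa), sin(fy * pi * y_k / (semi_y + 1) + pb))
      }
      p
    }
    half <- outer(seg_mod, base_half)          # n x np half-widths
    bank_a <- -half + bank_pert()
    bank_b <- half + bank_pert()
    # Closed pairs (outside the outline) park at the midline; never invert.
    mid <- (bank_a + bank_b) / 2
    closed <- half <= 0 | bank_a > bank_b
    bank_a[closed] <- mid[closed]
    bank_b[closed] <- mid[closed]

    mu <- mean_mu * (1 + stats::runif(n, -mu_spread, mu_spread))
    vmat_plan(patient_id, gantry, mu, bank_a, bank_b,
              leaf_pitch_mm = leaf_pitch_mm, arc_span_deg = arc_span_deg)
  })
}

# ---- deliberate delivery errors ------------------------------------------

error_families <- function() {
  c("NONE", "MU_SCALE", "LEAF_RETRACT", "LEAF_SHIFT", "AIR_CAVITY")
}

#' Specify a deliberate delivery error
#'
#' The four deliberate error families: monitor-unit increase (percent),
#' retraction of all MLC leaves (mm, each bank retreats from the aperture
#' centre by the magnitude, so each opening widens by twice the magnitude),
#' shift of all MLC leaves (mm, both banks move the same way), and an air
#' cavity introduced into the phantom (cavity width in mm).
#'
#' @param family One of `"NONE"`, `"MU_SCALE"`, `"LEAF_RETRACT"`,
#'   `"LEAF_SHIFT"`, `"AIR_CAVITY"`.
#' @param magnitude Percent for `MU_SCALE`, mm otherwise; must be 0 for
#'   `NONE`.
#' @return An object of class `error_spec`.
#' @export
error_spec <- function(family, magnitude = 0) {
  family <- match.arg(family, error_families())
  stop_if(!is_scalar_number(magnitude) || magnitude < 0,
          "magnitude must be a non-negative number")
  stop_if(family == "NONE" && magnitude != 0,
          "NONE errors must have magnitude 0")
  structure(list(family = family, magnitude = magnitude),
            class = "error_spec")
}

#' @export
format.error_spec <- function(x, ...) {
  if (x$family == "NONE") return("no error")
  unit <- if (x$family == "MU_SCALE") "%" else " mm"
  sprintf("%s %+g%s", x$family, x$magnitude, unit)
}

#' @export
print.error_spec <- function(x, ...) {
  cat("<error_spec>", format(x), "\n"); invisible(x)
}

#' The menu of deliberate errors
#'
#' `varied = FALSE` gives the four fixed-magnitude errors (4% MU increase,
#' 4 mm leaf retraction, 4 mm leaf shift, 20 mm air cavity). `varied = TRUE`
#' gives all four families at five magnitudes each: 2-10% in 2% steps,
#' 2-10 mm in 2 mm steps (both leaf families) and 10-50 mm cavity width in
#' 10 mm steps.
#'
#' @param varied Logical; varied-magnitude menu or fixed menu.
#' @return List of [error_spec()] objects (length 4 or 20).
#' @export
error_menu <- function(varied = FALSE) {
  fam <- c("MU_SCALE", "LEAF_RETRACT", "LEAF_SHIFT", "AIR_CAVITY")
  if (!varied) {
    mags <- list(4, 4, 4, 20)
  } else {
    mags <- list(seq(2, 10, 2), seq(2, 10, 2), seq(2, 10, 2), seq(10, 50, 10))
  }
  out <- list()
  for (i in seq_along(fam))
    for (m in mags[[i]])
      out[[length(out) + 1L]] <- error_spec(fam[i], m)
  out
}

#' Inject a deliberate error into a plan/phantom pair
#'
#' Pure function: inputs are never modified. `MU_SCALE` multiplies every
#' segment's MU by `1 + magnitude/100`; `LEAF_RETRACT` moves every `bank_a`
#' leaf by `-magnitude` and every `bank_b` leaf by `+magnitude` (every
#' opening widens by `2 * magnitude`); `LEAF_SHIFT` moves both banks by
#' `+magnitude`; `AIR_CAVITY` leaves the plan unchanged and returns a
#' phantom carrying an air cavity of the given width (x 50 mm height);
#' `NONE` is the identity.
#'
#' @param plan A `vmat_plan`.
#' @param ph A [phantom()].
#' @param spec An [error_spec()].
#' @param cavity_template Optional [air_cavity()] whose height/length/offset
#'   are reused with the spec's width (for `AIR_CAVITY`).
#' @return List with elements `plan` and `phantom`.
#' @export
inject_error <- function(plan, ph, spec, cavity_template = NULL) {
  stop_if(!inherits(plan, "vmat_plan"), "plan must be a vmat_plan")
  stop_if(!inherits(ph, "phantom"), "ph must be a phantom")
  stop_if(!inherits(spec, "error_spec"), "spec must be an error_spec")
  mag <- spec$magnitude
  if (spec$family == "NONE" || mag == 0)
    return(list(plan = plan, phantom = ph))
  switch(spec$family,
    MU_SCALE = {
      plan$mu <- plan$mu * (1 + mag / 100)
      list(plan = plan, phantom = ph)
    },
    LEAF_RETRACT = {
      plan$bank_a <- plan$bank_a - mag
      plan$bank_b <- plan$bank_b + mag
      list(plan = plan, phantom = ph)
    },
    LEAF_SHIFT = {
      plan$bank_a <- plan$bank_a + mag
      plan$bank_b <- plan$bank_b + mag
      list(plan = plan, phantom = ph)
    },
    AIR_CAVITY = {
      cav <- if (is.null(cavity_template)) air_cavity(width_lr_mm = mag) else {
        air_cavity(width_lr_mm = mag,
                   height_ap_mm = cavity_template$height_ap_mm,
                   length_gt_mm = cavity_template$length_gt_mm,
                   centre_offset_mm = cavity_template$centre_offset_mm)
      }
      list(plan = plan, phantom = set_cavity(ph, cav))
    })
}

# ---- plain-text plan serialisation ---------------------------------------

#' Write a plan to a plain-text tabular file
#'
#' One row per segment: index, gantry angle, MU, collimator angle, then the
#' leaf positions of bank A and bank B. Plan-level fields are stored in
#' `#key=value` header lines. Numbers are written with full precision so
#' the round-trip through [read_plan()] is exact.
#'
#' @param plan A `vmat_plan`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  stop_if(!inherits(plan, "vmat_plan"), "plan must be a vmat_plan")
  np <- ncol(plan$bank_a)
  hdr <- c(sprintf("#patient_id=%s", plan$patient_id),
           sprintf("#leaf_pitch_mm=%.17g", plan$leaf_pitch_mm),
           sprintf("#arc_span_deg=%.17g", plan$arc_span_deg),
           sprintf("#collimator_deg=%.17g", plan$collimator_deg),
           sprintf("#n_leaf_pairs=%d", np))
  tab <- cbind(index = seq_len(n_segments(plan)),
               gantry_deg = plan$gantry_deg, mu = plan$mu,
               plan$bank_a, plan$bank_b)
  colnames(tab) <- c("index", "gantry_deg", "mu",
                     paste0("a_", seq_len(np)), paste0("b_", seq_len(np)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  body <- apply(tab, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a plan written by [write_plan()]
#'
#' @param path File path.
#' @return A `vmat_plan`.
#' @export
read_plan <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#", "", hdr), "=", fixed = TRUE))
  meta <- stats::setNames(as.list(kv[, 2]), kv[, 1])
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t")
  np <- as.integer(meta$n_leaf_pairs)
  vmat_plan(meta$patient_id,
            gantry_deg = tab$gantry_deg, mu = tab$mu,
            bank_a = unname(as.matrix(tab[, paste0("a_", seq_len(np))])),
            bank_b = unname(as.matrix(tab[, paste0("b_", seq_len(np))])),
            collimator_deg = as.numeric(meta$collimator_deg),
            leaf_pitch_mm = as.numeric(meta$leaf_pitch_mm),
            arc_span_deg = as.numeric(meta$arc_span_deg))
}
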