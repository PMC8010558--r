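# The four per-section difference metrics (CAS, MIV, MDM, MDL), running
# 10-segment section images, and the composite difference metric (CDM),
# a weighted power sum of the individual metrics.

#' First section index entering the analysis
#'
#' The first 10% of segments are excluded (signal instability during beam
#' ramp-up), and a section needs a full running window behind it; the first
#' evaluated section index is the smaller of the two constraints' upper
#' bound: the smallest `s` with `s > floor(exclusion_fraction * n_segments)`
#' and `s >= window`. For 180 segments this is 19.
#'
#' @param n_segments Total number of segments (>= `window`).
#' @param exclusion_fraction Fraction of initial segments excluded.
#'   Default 0.10.
#' @param window Running-window length in segments. Default 10.
#' @return Integer section index.
#' @export
evaluation_start_index <- function(n_segments, exclusion_fraction = 0.10,
                                   window = 10L) {
  stop_if(!is_scalar_number(n_segments) || n_segments < window,
          "n_segments must be >= the window length")
  max(floor(exclusion_fraction * n_segments) + 1L, as.integer(window))
}

#' Section image: running sum of the last `window` frames
#'
#' The section image at segment `s` is the pixelwise sum of frames
#' `s - window + 1` to `s`.
#'
#' @param stack A `portal_stack`.
#' @param s Section (segment) index, `window <= s <= n_segments`.
#' @param window Window length. Default 10.
#' @return Numeric matrix.
#' @export
section_image <- function(stack, s, window = 10L) {
  stop_if(!inherits(stack, "portal_stack"), "stack must be a portal_stack")
  ns <- n_segments(stack)
  stop_if(s < window || s > ns, "section index out of range")
  idx <- (s - window + 1L):s
  rowSums(stack$pixels[, , idx, drop = FALSE], dims = 2L)
}

#' In-field mask from a predicted section image
#'
#' Pixels whose predicted intensity exceeds `fraction` of the image
#' maximum (default 10%).
#'
#' @param predicted_section Numeric matrix with a positive maximum.
#' @param fraction Mask threshold as a fraction of the maximum.
#' @return Logical matrix.
#' @export
in_field_mask <- function(predicted_section, fraction = 0.10) {
  m <- max(predicted_section)
  stop_if(!is.finite(m) || m <= 0,
          "predicted section must have a positive maximum")
  predicted_section > fraction * m
}

#' Compute the four difference metrics for one section
#'
#' * CAS: absolute difference of the mean central 2 x 2 pixel block
#'   (working-scale intensity);
#' * MIV: absolute difference of the mean over the in-field mask
#'   (working-scale intensity);
#' * MDM: mean absolute difference over the mask as a percentage of the
#'   maximum predicted intensity;
#' * MDL: mean absolute difference over the mask as a percentage of the
#'   local predicted intensity.
#'
#' The mask contains pixels above 10% of the predicted maximum, so the MDL
#' denominator is bounded away from zero (an epsilon clamp guards it
#' regardless).
#'
#' @param pred_section,meas_section Same-shaped numeric matrices (predicted
#'   and measured section images).
#' @param mask_fraction Mask threshold fraction. Default 0.10.
#' @param absolute Use absolute CAS/MIV differences (default). `FALSE`
#'   keeps the signed values.
#' @param eps Denominator clamp for MDL.
#' @return Named numeric vector `c(cas, miv, mdm, mdl)`.
#' @export
compute_metrics <- function(pred_section, meas_section, mask_fraction = 0.10,
                            absolute = TRUE, eps = 1e-6) {
  stop_if(!identical(dim(pred_section), dim(meas_section)),
          "predicted and measured sections must have the same shape")
  mask <- in_field_mask(pred_section, mask_fraction)
  n <- nrow(pred_section)
  ctr <- c(n %/% 2L, n %/% 2L + 1L)
  cas <- mean(meas_section[ctr, ctr]) - mean(pred_section[ctr, ctr])
  miv <- mean(meas_section[mask]) - mean(pred_section[mask])
  if (absolute) { cas <- abs(cas); miv <- abs(miv) }
  d <- abs(meas_section[mask] - pred_section[mask])
  mdm <- 100 * mean(d) / max(pred_section)
  mdl <- 100 * mean(d / pmax(pred_section[mask], eps))
  c(cas = cas, miv = miv, mdm = mdm, mdl = mdl)
}

#' Composite difference metric (weighted power sum)
#'
#' `CDM = sum_i w_i * m_i ^ w_i` over the four metrics, with the convention
#' that a zero weight contributes exactly zero (covering both `0 * m^0` and
#' `m = 0`). With weights below one each term rises steeply at small metric
#' values and then plateaus, so the composite responds most strongly when
#' several metrics are slightly elevated together.
#'
#' @param m Numeric vector of four non-negative metric values (order
#'   CAS, MIV, MDM, MDL), or an n x 4 matrix of metric rows.
#' @param w Numeric weight vector of length four, each in \[0, 1\].
#' @return A single CDM value, or a vector of n values for matrix input.
#' @export
cdm <- function(m, w) {
  stop_if(length(w) != 4L || any(w < 0) || any(w > 1),
          "w must be four weights in [0, 1]")
  if (is.matrix(m)) {
    stop_if(ncol(m) != 4L, "metric matrix must have four columns")
    stop_if(any(m < 0), "metric values must be >= 0")
    out <- numeric(nrow(m))
    for (i in 1:4) if (w[i] > 0) out <- out + w[i] * m[, i]^w[i]
    return(out)
  }
  stop_if(length(m) != 4L, "m must have four values")
  stop_if(any(m < 0), "metric values must be >= 0")
  s <- 0
  for (i in 1:4) if (w[i] > 0) s <- s + w[i] * m[i]^w[i]
  s
}

# ---- metric traces --------------------------------------------------------

new_metric_trace <- function(df, n_segments, window, start_index,
                             patient_id = "unknown",
                             error = error_spec("NONE")) {
  structure(df,
            class = c("metric_trace", "data.frame"),
            n_segments = n_segments, window = window,
            start_index = start_index, patient_id = patient_id,
            error = error)
}

#' Build a metric trace from a data frame of section values
#'
#' Used when reconstructing traces from tidy CSV files and when composing
#' synthetic traces directly (without images).
#'
#' @param df Data frame with columns `section_index`, `cas`, `miv`, `mdm`,
#'   `mdl`, contiguous section indices.
#' @param n_segments Number of segments of the underlying delivery
#'   (defaults to the last section index).
#' @param patient_id Identifier.
#' @param error [error_spec()] provenance of the measured delivery.
#' @param window Window length used. Default 10.
#' @return A `metric_trace`.
#' @export
as_metric_trace <- function(df, n_segments = max(df$section_index),
                            patient_id = "unknown",
                            error = error_spec("NONE"), window = 10L) {
  need <- c("section_index", metric_names())
  stop_if(!all(need %in% names(df)), "missing trace columns")
  df <- as.data.frame(df)[, need]
  stop_if(nrow(df) == 0L, "empty trace")
  stop_if(any(diff(df$section_index) != 1L),
          "section indices must be contiguous")
  new_metric_trace(df, n_segments = n_segments, window = window,
                   start_index = df$section_index[1L],
                   patient_id = patient_id, error = error)
}

#' @export
print.metric_trace <- function(x, ...) {
  cat(sprintf("<metric_trace> %s (%s): sections %d-%d\n",
              attr(x, "patient_id"), format(attr(x, "error")),
              x$section_index[1L], x$section_index[nrow(x)]))
  invisible(x)
}

# Metric columns of a trace as a matrix (sections x 4).
trace_matrix <- function(trace) {
  as.matrix(as.data.frame(trace)[, metric_names()])
}

#' Compute the metric trace of a delivery
#'
#' Evaluates [compute_metrics()] on the running section images of the
#' predicted and measured stacks at every section index from
#' [evaluation_start_index()] to the last segment. Section sums are updated
#' incrementally (telescoping), so the cost is linear in the number of
#' segments.
#'
#' @param pred_stack Predicted `portal_stack`.
#' @param meas_stack Measured `portal_stack` of the same patient/geometry.
#' @param window Running-window length. Default 10.
#' @param exclusion_fraction Initial exclusion fraction. Default 0.10.
#' @param mask_fraction In-field mask fraction. Default 0.10.
#' @param absolute Absolute-valued CAS/MIV (default).
#' @return A `metric_trace` (data frame of section metric values).
#' @export
metric_trace <- function(pred_stack, meas_stack, window = 10L,
                         exclusion_fraction = 0.10, mask_fraction = 0.10,
                         absolute = TRUE) {
  stop_if(!inherits(pred_stack, "portal_stack") ||
            !inherits(meas_stack, "portal_stack"),
          "inputs must be portal_stacks")
  stop_if(!identical(dim(pred_stack$pixels), dim(meas_stack$pixels)),
          "stacks are misaligned (different shapes)")
  stop_if(max(abs(pred_stack$gantry_deg - meas_stack$gantry_deg)) > 1e-9,
          "stacks are misaligned (different gantry angles)")
  ns <- n_segments(pred_stack)
  start <- evaluation_start_index(ns, exclusion_fraction, window)
  psec <- section_image(pred_stack, start, window)
  msec <- section_image(meas_stack, start, window)
  rows <- matrix(0, ns - start + 1L, 4L,
                 dimnames = list(NULL, metric_names()))
  rows[1L, ] <- compute_metrics(psec, msec, mask_fraction, absolute)
  if (start < ns) {
    for (s in (start + 1L):ns) {
      psec <- psec + pred_stack$pixels[, , s] - pred_stack$pixels[, , s - window]
      msec <- msec + meas_stack$pixels[, , s] - meas_stack$pixels[, , s - window]
      rows[s - start + 1L, ] <- compute_metrics(psec, msec, mask_fraction,
                                                absolute)
    }
  }
  err <- meas_stack$provenance$error
  if (is.null(err)) err <- error_spec("NONE")
  df <- data.frame(section_index = start:ns, rows)
  new_metric_trace(df, n_segments = ns, window = window, start_index = start,
                   patient_id = meas_stack$patient_id, error = err)
}
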