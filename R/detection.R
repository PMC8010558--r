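# Threshold setting from error-free deliveries, the three detection
# scenarios, false-positive counting, and the traffic-light status stream.

#' Median-plus-range threshold rule
#'
#' Given the maximum metric value observed in the error-free delivery of
#' each reference patient, the detection threshold is the median of those
#' maxima plus their range (max - min). The rule places the threshold at
#' the upper extreme of the implied distribution of error-free maxima, so
#' no reference patient can exceed it (median >= min implies
#' median + range >= max).
#'
#' @param per_patient_maxima Numeric vector of per-patient maxima
#'   (length >= 1, finite).
#' @return The threshold value.
#' @export
threshold_from_maxima <- function(per_patient_maxima) {
  x <- per_patient_maxima
  stop_if(length(x) < 1L || any(!is.finite(x)),
          "need at least one finite maximum")
  stats::median(x) + (max(x) - min(x))
}

#' Build the threshold set from error-free traces
#'
#' For each individual metric, each reference patient contributes the
#' maximum of that metric over their error-free trace; the threshold is the
#' median plus range of those maxima. If a weight vector is supplied, the
#' CDM trace of every patient is computed under those weights and the CDM
#' threshold is derived by the same rule. Because the CDM value depends on
#' its weights, the CDM threshold is bound to the weight vector it was
#' computed under and must be recomputed whenever the weights change.
#'
#' @param normal_traces List of `metric_trace` objects, one error-free
#'   delivery per reference patient.
#' @param weights Optional CDM weight vector (length 4, each in \[0, 1\]).
#' @return An object of class `threshold_set`: `$metrics` (named vector of
#'   four thresholds), `$cdm` (CDM threshold or `NA`), `$weights`.
#' @export
build_thresholds <- function(normal_traces, weights = NULL) {
  stop_if(length(normal_traces) < 1L, "need at least one normal trace")
  stop_if(!all(vapply(normal_traces, inherits, logical(1), "metric_trace")),
          "normal_traces must be metric_trace objects")
  mats <- lapply(normal_traces, trace_matrix)
  t_m <- vapply(seq_len(4L), function(i) {
    threshold_from_maxima(vapply(mats, function(M) max(M[, i]), numeric(1)))
  }, numeric(1))
  names(t_m) <- metric_names()
  t_cdm <- NA_real_
  if (!is.null(weights)) {
    t_cdm <- threshold_from_maxima(
      vapply(mats, function(M) max(cdm(M, weights)), numeric(1)))
  }
  structure(list(metrics = t_m, cdm = t_cdm, weights = weights),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set>\n")
  for (i in 1:4)
    cat(sprintf("  %s: %.4g\n", metric_labels()[i], x$metrics[i]))
  if (!is.na(x$cdm))
    cat(sprintf("  CDM: %.4g (w = %s)\n", x$cdm,
                paste(format(x$weights), collapse = ", ")))
  invisible(x)
}

#' Sentinel index for undetected deliveries
#'
#' One past the last segment (`n_segments + 1`), so that means over mixed
#' detected/undetected cases remain well defined.
#'
#' @param n_segments Number of segments.
#' @return Integer sentinel.
#' @export
not_detected <- function(n_segments) as.integer(n_segments) + 1L

#' First section index at which an error is detected
#'
#' Scans the sections of a trace in order and reports the first index at
#' which the active metric set strictly exceeds its threshold(s):
#' * scenario 1 - a single chosen metric against its own threshold;
#' * scenario 2 - any of the four individual metrics (the usual clinical
#'   arrangement);
#' * scenario 3 - any of the four individual metrics or the CDM.
#'
#' Ties do not trigger: a metric exactly at its threshold is not a
#' detection, which keeps an all-zero weight vector inert.
#'
#' @param trace A `metric_trace`.
#' @param thresholds A [build_thresholds()] result; scenario 3 requires a
#'   CDM threshold (and carries the weights it was computed under).
#' @param scenario 1, 2 or 3.
#' @param metric For scenario 1, one of `"cas"`, `"miv"`, `"mdm"`, `"mdl"`.
#' @return An object of class `detection_outcome` with fields `scenario`,
#'   `metric`, `first_index` (sentinel `n_segments + 1` if never),
#'   `detected`, `patient_id`, `error`.
#' @export
first_detection_index <- function(trace, thresholds, scenario = 2L,
                                  metric = NULL) {
  stop_if(!inherits(trace, "metric_trace"), "trace must be a metric_trace")
  stop_if(!inherits(thresholds, "threshold_set"),
          "thresholds must be a threshold_set")
  scenario <- as.integer(scenario)
  stop_if(!scenario %in% 1:3, "scenario must be 1, 2 or 3")
  M <- trace_matrix(trace)
  t_m <- thresholds$metrics
  if (scenario == 1L) {
    stop_if(is.null(metric), "scenario 1 requires a metric name")
    metric <- match.arg(metric, metric_names())
    hit <- M[, metric] > t_m[metric]
  } else {
    hit <- (M[, 1] > t_m[1]) | (M[, 2] > t_m[2]) |
      (M[, 3] > t_m[3]) | (M[, 4] > t_m[4])
    if (scenario == 3L) {
      stop_if(is.na(thresholds$cdm) || is.null(thresholds$weights),
              "scenario 3 requires a CDM threshold bound to weights")
      hit <- hit | (cdm(M, thresholds$weights) > thresholds$cdm)
    }
  }
  ns <- attr(trace, "n_segments")
  pos <- which(hit)
  first <- if (length(pos)) trace$section_index[pos[1L]] else not_detected(ns)
  structure(list(scenario = scenario, metric = metric,
                 first_index = as.integer(first),
                 detected = length(pos) > 0L,
                 patient_id = attr(trace, "patient_id"),
                 error = attr(trace, "error")),
            class = "detection_outcome")
}

#' @export
print.detection_outcome <- function(x, ...) {
  what <- if (x$scenario == 1L) sprintf("scenario 1 (%s)", toupper(x$metric))
          else sprintf("scenario %d", x$scenario)
  cat(sprintf("<detection_outcome> %s, %s: %s\n", x$patient_id, what,
              if (x$detected) sprintf("first detected at section %d",
                                      x$first_index)
              else "not detected"))
  invisible(x)
}

#' Count false positives among error-free test deliveries
#'
#' Number of test patients whose error-free delivery triggers a detection
#' under the given thresholds and scenario.
#'
#' @param normal_traces List of error-free `metric_trace` objects.
#' @param thresholds A `threshold_set`.
#' @param scenario 1, 2 or 3.
#' @param metric Metric name for scenario 1.
#' @return Integer count.
#' @export
count_false_positives <- function(normal_traces, thresholds, scenario = 2L,
                                  metric = NULL) {
  sum(vapply(normal_traces, function(tr) {
    first_detection_index(tr, thresholds, scenario, metric)$detected
  }, logical(1)))
}

#' Traffic-light status stream for one delivery
#'
#' Per-section status: red if any active metric strictly exceeds its
#' threshold; orange (near miss) if not red and some active metric exceeds
#' `near_miss_fraction` of its threshold; green otherwise. The active set
#' is the four individual metrics, plus the CDM when the threshold set
#' carries one.
#'
#' @param trace A `metric_trace`.
#' @param thresholds A `threshold_set`.
#' @param near_miss_fraction Fraction of the threshold at which the status
#'   turns orange. Default 0.8.
#' @return Data frame with columns `section_index`, `status` (factor
#'   green/orange/red) and `trigger` (the metric furthest above its
#'   threshold fraction, `NA` when green).
#' @export
traffic_light_stream <- function(trace, thresholds, near_miss_fraction = 0.8) {
  stop_if(!inherits(trace, "metric_trace"), "trace must be a metric_trace")
  M <- trace_matrix(trace)
  vals <- M
  lims <- thresholds$metrics
  labs <- metric_labels()
  if (!is.na(thresholds$cdm) && !is.null(thresholds$weights)) {
    vals <- cbind(vals, cdm(M, thresholds$weights))
    lims <- c(lims, thresholds$cdm)
    labs <- c(labs, "CDM")
  }
  over <- sweep(vals, 2L, lims, ">")
  near <- sweep(vals, 2L, near_miss_fraction * lims, ">")
  red <- apply(over, 1L, any)
  orange <- !red & apply(near, 1L, any)
  status <- factor(ifelse(red, "red", ifelse(orange, "orange", "green")),
                   levels = c("green", "orange", "red"))
  # Trigger: largest excess relative to threshold (safe when thresholds
  # are zero: comparisons above are on raw values, trigger only reported
  # for non-green sections).
  rel <- sweep(vals, 2L, pmax(lims, 1e-12), "/")
  trig <- labs[max.col(rel, ties.method = "first")]
  trig[status == "green"] <- NA_character_
  data.frame(section_index = trace$section_index, status = status,
             trigger = trig)
}
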