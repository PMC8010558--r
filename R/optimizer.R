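# Exhaustive search of the CDM weight grid under leave-pair-out
# cross-validation. The optimiser consumes metric traces only (never
# images): traces are computed once per delivery, the grid search operates
# on cached per-power transforms of the trace matrices.

#' Assemble a patient's trace data
#'
#' @param patient_id Identifier.
#' @param varied Logical: does this patient carry the varied-magnitude
#'   error menu (TRUE) or the fixed menu (FALSE)?
#' @param normal Error-free `metric_trace`.
#' @param cases List of error-case `metric_trace` objects (each carrying
#'   its [error_spec()] provenance).
#' @return An object of class `pd_patient`.
#' @export
pd_patient <- function(patient_id, varied, normal, cases) {
  stop_if(!inherits(normal, "metric_trace"), "normal must be a metric_trace")
  stop_if(!all(vapply(cases, inherits, logical(1), "metric_trace")),
          "cases must be metric_trace objects")
  structure(list(patient_id = as.character(patient_id),
                 varied = isTRUE(varied), normal = normal, cases = cases),
            class = "pd_patient")
}

#' Assemble a cohort of patients
#'
#' The study cohort is six patients, three carrying the varied-magnitude
#' error menu (20 cases) and three the fixed menu (4 cases).
#'
#' @param patients List of [pd_patient()] objects.
#' @return An object of class `pd_cohort`.
#' @export
pd_cohort <- function(patients) {
  stop_if(!all(vapply(patients, inherits, logical(1), "pd_patient")),
          "patients must be pd_patient objects")
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  stop_if(anyDuplicated(ids) > 0L, "duplicate patient ids")
  structure(list(patients = stats::setNames(patients, ids)),
            class = "pd_cohort")
}

#' @export
print.pd_cohort <- function(x, ...) {
  v <- vapply(x$patients, function(p) p$varied, logical(1))
  cat(sprintf("<pd_cohort> %d patients (%d varied, %d fixed)\n",
              length(v), sum(v), sum(!v)))
  invisible(x)
}

cohort_ids <- function(cohort, varied = NULL) {
  ids <- names(cohort$patients)
  if (is.null(varied)) return(ids)
  keep <- vapply(cohort$patients, function(p) p$varied == varied, logical(1))
  ids[keep]
}

#' The exhaustive weight grid
#'
#' Full Cartesian product of the four weight axes over
#' `seq(0, 1, by = step)`, in deterministic order (the CAS weight varies
#' fastest, the MDL weight slowest). The default step 0.05 gives 21 values
#' per axis and 194,481 vectors.
#'
#' @param step Grid step; must divide 1 exactly on the decimal grid.
#' @return Numeric matrix with columns `cas`, `miv`, `mdm`, `mdl`.
#' @export
weight_grid <- function(step = 0.05) {
  k <- 1 / step
  stop_if(abs(k - round(k)) > 1e-9, "step must divide 1 exactly")
  vals <- round(seq(0, 1, length.out = round(k) + 1L), 10)
  g <- as.matrix(expand.grid(cas = vals, miv = vals, mdm = vals, mdl = vals,
                             KEEP.OUT.ATTRS = FALSE))
  dimnames(g) <- list(NULL, metric_names())
  g
}

#' Leave-pair-out folds
#'
#' Every combination of one held-out varied-menu patient and one held-out
#' fixed-menu patient forms the test set; the remaining patients (two
#' varied, two fixed for the default 3 + 3 cohort) form the optimisation
#' set. A 3 + 3 cohort yields nine folds, and each patient appears in
#' exactly three test sets.
#'
#' @param cohort A [pd_cohort()].
#' @param require_3x3 Enforce the 3 varied + 3 fixed study layout
#'   (default). Set `FALSE` to allow any m x n split.
#' @return List of folds, each a list with `optimisation_ids` and
#'   `test_ids`.
#' @export
leave_pair_out_folds <- function(cohort, require_3x3 = TRUE) {
  stop_if(!inherits(cohort, "pd_cohort"), "cohort must be a pd_cohort")
  v_ids <- cohort_ids(cohort, varied = TRUE)
  f_ids <- cohort_ids(cohort, varied = FALSE)
  stop_if(require_3x3 && !(length(v_ids) == 3L && length(f_ids) == 3L),
          "cohort must contain 3 varied and 3 fixed patients")
  stop_if(length(v_ids) < 2L || length(f_ids) < 2L,
          "need at least two patients of each kind")
  folds <- list()
  for (v in v_ids) for (f in f_ids) {
    folds[[length(folds) + 1L]] <- list(
      optimisation_ids = c(setdiff(v_ids, v), setdiff(f_ids, f)),
      test_ids = c(v, f))
  }
  folds
}

# ---- objective (reference implementation) --------------------------------

#' Mean first-detection index under a weight vector
#'
#' The optimisation objective: individual-metric thresholds are built from
#' the error-free deliveries of the optimisation patients, the CDM
#' threshold is rebuilt for the supplied weights from the same deliveries,
#' and the scenario-3 first-detection index is averaged over every
#' (patient, error case) of the optimisation set. Undetected cases enter
#' the mean at the `n_segments + 1` sentinel.
#'
#' This is the plain reference implementation; [optimize_weights()]
#' evaluates the same quantity with per-power memoisation across the grid.
#'
#' @param weights Length-4 weight vector.
#' @param cohort A [pd_cohort()].
#' @param optimisation_ids Patient ids of the optimisation set.
#' @return The mean first-detection index.
#' @export
cdm_objective <- function(weights, cohort, optimisation_ids) {
  pats <- cohort$patients[optimisation_ids]
  thr <- build_thresholds(lapply(pats, function(p) p$normal), weights)
  idx <- unlist(lapply(pats, function(p) {
    vapply(p$cases, function(tr) {
      first_detection_index(tr, thr, scenario = 3L)$first_index
    }, numeric(1))
  }), use.names = FALSE)
  mean(idx)
}

# ---- fast exhaustive search ----------------------------------------------

# Column-wise first index holding TRUE, NA when a column has none.
first_true_per_column <- function(L) {
  idx <- max.col(t(L) * 1, ties.method = "first")
  idx[colSums(L) == 0L] <- NA_integer_
  idx
}

#' Exhaustive CDM weight optimisation for one fold
#'
#' Evaluates the objective for every vector of the weight grid and returns
#' the minimiser (the first vector in grid order on ties), its thresholds
#' and its objective value. Individual-metric thresholds and the
#' scenario-2 component of detection are computed once per fold; the CDM
#' contribution is assembled from per-power transforms of the cached trace
#' matrices, and the CDM threshold is recomputed for every weight vector
#' from the optimisation patients' error-free deliveries.
#'
#' @param cohort A [pd_cohort()].
#' @param fold One fold from [leave_pair_out_folds()] (any list with an
#'   `optimisation_ids` field).
#' @param step Weight-grid step. Default 0.05.
#' @param return_surface Also return the full objective vector over the
#'   grid (in [weight_grid()] order).
#' @return An object of class `cdm_fit`: `best_weights`, `objective`,
#'   `thresholds` (with the CDM threshold bound to the best weights),
#'   `step`, `fold`, `n_evaluated`, and optionally `surface`.
#' @export
optimize_weights <- function(cohort, fold, step = 0.05,
                             return_surface = FALSE) {
  stop_if(!inherits(cohort, "pd_cohort"), "cohort must be a pd_cohort")
  opt_ids <- fold$optimisation_ids
  stop_if(is.null(opt_ids) || !all(opt_ids %in% names(cohort$patients)),
          "fold does not match the cohort")
  pats <- cohort$patients[opt_ids]

  normals <- lapply(pats, function(p) p$normal)
  thr_ind <- build_thresholds(normals)
  t_m <- thr_ind$metrics

  # Stack the optimisation set: one column per error-free delivery (for
  # the CDM threshold) and one per error case (for detection).
  N <- lapply(1:4, function(i)
    vapply(normals, function(tr) trace_matrix(tr)[, i], numeric(nrow(normals[[1]]))))
  case_traces <- unlist(lapply(pats, function(p) p$cases), recursive = FALSE)
  n_sec <- nrow(trace_matrix(case_traces[[1]]))
  C <- lapply(1:4, function(i)
    vapply(case_traces, function(tr) trace_matrix(tr)[, i], numeric(n_sec)))
  sec_index <- case_traces[[1]]$section_index
  ns_total <- attr(case_traces[[1]], "n_segments")
  sentinel <- not_detected(ns_total)

  # Scenario-2 first-detection index per case (fixed across the grid).
  hit2 <- (C[[1]] > t_m[1]) | (C[[2]] > t_m[2]) |
    (C[[3]] > t_m[3]) | (C[[4]] > t_m[4])
  p2 <- first_true_per_column(hit2)
  s2_idx <- ifelse(is.na(p2), sentinel, sec_index[p2])

  vals <- round(seq(0, 1, by = step), 10)
  nv <- length(vals)
  # Per-power transforms, memoised once: index [[metric]][[power level]].
  powN <- lapply(1:4, function(i)
    lapply(seq_len(nv), function(k) if (vals[k] > 0) vals[k] * N[[i]]^vals[k]))
  powC <- lapply(1:4, function(i)
    lapply(seq_len(nv), function(k) if (vals[k] > 0) vals[k] * C[[i]]^vals[k]))

  zeroN <- N[[1]] * 0; zeroC <- C[[1]] * 0
  best_obj <- Inf; best_w <- NULL
  surface <- if (return_surface) numeric(nv^4) else NULL
  pos <- 0L
  # Loop nesting mirrors weight_grid() order: w1 (CAS) varies fastest.
  for (i4 in seq_len(nv)) {
    n4 <- if (vals[i4] > 0) powN[[4]][[i4]] else zeroN
    c4 <- if (vals[i4] > 0) powC[[4]][[i4]] else zeroC
    for (i3 in seq_len(nv)) {
      n34 <- if (vals[i3] > 0) n4 + powN[[3]][[i3]] else n4
      c34 <- if (vals[i3] > 0) c4 + powC[[3]][[i3]] else c4
      for (i2 in seq_len(nv)) {
        n234 <- if (vals[i2] > 0) n34 + powN[[2]][[i2]] else n34
        c234 <- if (vals[i2] > 0) c34 + powC[[2]][[i2]] else c34
        for (i1 in seq_len(nv)) {
          cdmN <- if (vals[i1] > 0) n234 + powN[[1]][[i1]] else n234
          cdmC <- if (vals[i1] > 0) c234 + powC[[1]][[i1]] else c234
          t_cdm <- threshold_from_maxima(apply(cdmN, 2L, max))
          p3 <- first_true_per_column(cdmC > t_cdm)
          cdm_idx <- ifelse(is.na(p3), sentinel, sec_index[p3])
          obj <- mean(pmin(s2_idx, cdm_idx))
          pos <- pos + 1L
          if (return_surface) surface[pos] <- obj
          if (obj < best_obj) {
            best_obj <- obj
            best_w <- c(vals[i1], vals[i2], vals[i3], vals[i4])
          }
        }
      }
    }
  }
  names(best_w) <- metric_names()
  thr <- build_thresholds(normals, best_w)
  structure(list(best_weights = best_w, objective = best_obj,
                 thresholds = thr, step = step, fold = fold,
                 n_evaluated = pos, surface = surface),
            class = "cdm_fit")
}

#' @export
print.cdm_fit <- function(x, ...) {
  cat(sprintf("<cdm_fit> best weights (%s) = (%s), objective %.2f over %d vectors\n",
              paste(metric_labels(), collapse = ", "),
              paste(format(x$best_weights), collapse = ", "),
              x$objective, x$n_evaluated))
  invisible(x)
}

# ---- fold evaluation and summaries ---------------------------------------

#' Evaluate frozen thresholds and weights on test patients
#'
#' Applies a threshold set (individual metrics plus the CDM bound to its
#' weights) to the held-out patients of a fold: mean first-detection index
#' over their error cases for each scenario (per metric for scenario 1),
#' and false-positive counts on their error-free deliveries.
#'
#' @param cohort A [pd_cohort()].
#' @param test_ids Patient ids of the test set.
#' @param thresholds A `threshold_set` carrying a CDM threshold.
#' @return List with `mean_index` (named vector: cas, miv, mdm, mdl,
#'   scenario2, scenario3), `false_positives` (same structure) and
#'   `n_cases`.
#' @export
evaluate_detection <- function(cohort, test_ids, thresholds) {
  pats <- cohort$patients[test_ids]
  cases <- unlist(lapply(pats, function(p) p$cases), recursive = FALSE)
  normals <- lapply(pats, function(p) p$normal)
  one <- function(scenario, metric = NULL) {
    mean(vapply(cases, function(tr)
      first_detection_index(tr, thresholds, scenario, metric)$first_index,
      numeric(1)))
  }
  fp <- function(scenario, metric = NULL)
    count_false_positives(normals, thresholds, scenario, metric)
  mi <- c(vapply(metric_names(), function(m) one(1L, m), numeric(1)),
          scenario2 = one(2L), scenario3 = one(3L))
  fps <- c(vapply(metric_names(), function(m) fp(1L, m), numeric(1)),
           scenario2 = fp(2L), scenario3 = fp(3L))
  list(mean_index = mi, false_positives = fps, n_cases = length(cases))
}

#' Run the full leave-pair-out optimisation
#'
#' For every fold: optimise the CDM weights on the optimisation set, then
#' evaluate the frozen thresholds and weights on the held-out pair.
#'
#' @param cohort A [pd_cohort()] (3 varied + 3 fixed patients).
#' @param step Weight-grid step. Default 0.05.
#' @param require_3x3 Passed to [leave_pair_out_folds()].
#' @param verbose Print one progress line per fold.
#' @return An object of class `loo_result`: a list of per-fold entries
#'   (`fit`, `test`) plus the fold definitions.
#' @export
run_loo_optimisation <- function(cohort, step = 0.05, require_3x3 = TRUE,
                                 verbose = FALSE) {
  folds <- leave_pair_out_folds(cohort, require_3x3)
  res <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    fit <- optimize_weights(cohort, folds[[i]], step)
    test <- evaluate_detection(cohort, folds[[i]]$test_ids, fit$thresholds)
    if (verbose)
      message(sprintf("fold %d/%d: w = (%s), objective %.2f, test s3 %.2f",
                      i, length(folds),
                      paste(format(fit$best_weights), collapse = ", "),
                      fit$objective, test$mean_index[["scenario3"]]))
    res[[i]] <- list(fit = fit, test = test)
  }
  structure(list(folds = folds, results = res, step = step),
            class = "loo_result")
}

#' Summarise leave-pair-out results
#'
#' Median and range summaries across folds, in the shape of the study's
#' reporting: the optimal weight of each constituent metric; the mean
#' first-detection index of each scenario (per metric, multiple separate
#' metrics, and multiple separate metrics plus CDM); the per-fold benefit
#' ratio (scenario-3 mean over scenario-2 mean); and false-positive totals.
#'
#' @param loo A [run_loo_optimisation()] result.
#' @return List of data frames: `weights`, `detection`, `benefit_ratio`,
#'   `false_positives`.
#' @export
summarize_folds <- function(loo) {
  stop_if(!inherits(loo, "loo_result"), "loo must be a loo_result")
  res <- loo$results
  stop_if(length(res) < 1L, "no folds to summarise")
  med_range <- function(x) c(median = stats::median(x), min = min(x), max = max(x))
  W <- t(vapply(res, function(r) r$fit$best_weights, numeric(4)))
  weights <- data.frame(metric = metric_labels(),
                        t(apply(W, 2L, med_range)))
  MI <- t(vapply(res, function(r) r$test$mean_index, numeric(6)))
  det_labels <- c(metric_labels(), "Multiple separate metrics",
                  "Multiple separate metrics + CDM")
  detection <- data.frame(detector = det_labels, t(apply(MI, 2L, med_range)))
  ratio <- MI[, "scenario3"] / MI[, "scenario2"]
  benefit <- data.frame(t(med_range(ratio)))
  FP <- t(vapply(res, function(r) r$test$false_positives, numeric(6)))
  fps <- data.frame(detector = det_labels, total = colSums(FP))
  list(weights = weights, detection = detection, benefit_ratio = benefit,
       false_positives = fps)
}
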