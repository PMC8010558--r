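# Run configuration, cohort simulation, tidy trace persistence, and the
# command surface (simulate / optimize / report) tying the pipeline
# together. A thin command-line wrapper over these functions is installed
# at inst/cli/portalcdm.R.

#' Default run configuration
#'
#' All tunable parameters of the pipeline in one (YAML-serialisable) list.
#' Defaults describe the study conditions: six patients (three with the
#' varied-magnitude error menu, three with the fixed menu), a 358 degree
#' arc of 180 segments, the 300 x 300 x 200 mm water-equivalent phantom,
#' and the 512 x 512 / 0.8 mm panel. One global seed fans out
#' deterministically to per-patient plan seeds and per-delivery noise
#' seeds (`plan seed = seed + 1000 * patient`, `delivery seed =
#' plan seed + case index`), so any single stack is reproducible in
#' isolation.
#'
#' @param seed Global integer seed.
#' @param ... Overrides of any top-level field (e.g. `n_segments = 60`,
#'   `geometry = panel_geometry(n_pixels = 64, pixel_pitch_panel_mm = 6.4)`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_patients = 6L,
    n_varied = 3L,
    n_segments = 180L,
    arc_span_deg = 358,
    mean_mu = 2,
    n_leaf_pairs = 40L,
    leaf_pitch_mm = 5,
    phantom = phantom(),
    geometry = panel_geometry(),
    params = forward_params(),
    noise = noise_model(),
    window = 10L,
    exclusion_fraction = 0.10,
    mask_fraction = 0.10,
    grid_step = 0.05,
    near_miss_fraction = 0.8,
    save_stacks = FALSE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  stop_if(length(unknown) > 0L,
          "unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stop_if(cfg$n_varied > cfg$n_patients, "n_varied exceeds n_patients")
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' Structured objects (phantom, geometry, model, noise) are flattened to
#' plain key-value maps; [read_config()] restores them, so the round-trip
#' is lossless.
#'
#' @param config A [run_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stop_if(!inherits(config, "run_config"), "config must be a run_config")
  plain <- lapply(unclass(config), function(x) {
    if (is.object(x)) lapply(unclass(x), function(f)
      if (is.null(f)) NULL else f) else x
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a run configuration written by [write_config()]
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rebuild <- function(x, ctor) do.call(ctor, x[!vapply(x, is.null, logical(1))])
  args <- raw
  args$phantom <- rebuild(raw$phantom, phantom)
  args$geometry <- rebuild(raw$geometry, panel_geometry)
  args$params <- rebuild(raw$params, forward_params)
  args$noise <- rebuild(raw$noise, noise_model)
  seed <- args$seed; args$seed <- NULL
  do.call(run_config, c(list(seed = seed), args))
}

# Per-patient and per-delivery seeds derived from the global seed.
patient_seed <- function(config, p) config$seed + 1000L * as.integer(p)
delivery_seed <- function(config, p, case) patient_seed(config, p) + as.integer(case)

# Simulate one patient: plan, predicted stack, normal measured stack, one
# measured stack per error of the patient's menu; return traces (and
# optionally the stacks).
simulate_patient <- function(config, p, varied, keep_stacks = FALSE) {
  plan <- generate_plan(patient_seed(config, p),
                        n_segments = config$n_segments,
                        arc_span_deg = config$arc_span_deg,
                        mean_mu = config$mean_mu,
                        n_leaf_pairs = config$n_leaf_pairs,
                        leaf_pitch_mm = config$leaf_pitch_mm,
                        patient_id = sprintf("P%02d", p))
  ph <- config$phantom
  pred <- predict_stack(plan, ph, config$geometry, config$params)
  tracer <- function(meas) {
    metric_trace(pred, meas, window = config$window,
                 exclusion_fraction = config$exclusion_fraction,
                 mask_fraction = config$mask_fraction)
  }
  noise_for <- function(case) {
    nm <- config$noise
    noise_model(nm$global_output_sd, nm$pixel_noise_sd, nm$rampup_segments,
                nm$rampup_amplitude, seed = delivery_seed(config, p, case))
  }
  normal <- simulate_measured_stack(plan, ph, config$geometry, config$params,
                                    noise_for(0L),
                                    provenance = list(error = error_spec("NONE")))
  menu <- error_menu(varied)
  cases <- vector("list", length(menu))
  case_stacks <- if (keep_stacks) vector("list", length(menu)) else NULL
  for (k in seq_along(menu)) {
    inj <- inject_error(plan, ph, menu[[k]])
    meas <- simulate_measured_stack(inj$plan, inj$phantom, config$geometry,
                                    config$params, noise_for(k),
                                    provenance = list(error = menu[[k]]))
    cases[[k]] <- tracer(meas)
    if (keep_stacks) case_stacks[[k]] <- meas
  }
  patient <- pd_patient(plan$patient_id, varied, tracer(normal), cases)
  out <- list(patient = patient, plan = plan)
  if (keep_stacks) {
    out$predicted <- pred; out$normal <- normal; out$case_stacks <- case_stacks
  }
  out
}

#' Simulate the full synthetic cohort
#'
#' Generates each patient's plan, predicted stack, error-free measured
#' delivery and one measured delivery per error of the patient's menu, and
#' reduces every delivery to its metric trace. The first `n_varied`
#' patients carry the varied-magnitude menu.
#'
#' @param config A [run_config()].
#' @param verbose Print one line per patient.
#' @return A [pd_cohort()] of metric traces.
#' @export
simulate_cohort <- function(config, verbose = FALSE) {
  stop_if(!inherits(config, "run_config"), "config must be a run_config")
  pats <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    varied <- p <= config$n_varied
    if (verbose)
      message(sprintf("simulating patient %d/%d (%s menu)", p,
                      config$n_patients, if (varied) "varied" else "fixed"))
    pats[[p]] <- simulate_patient(config, p, varied)$patient
  }
  pd_cohort(pats)
}

# ---- tidy trace persistence ----------------------------------------------

#' Flatten a cohort's traces to a tidy data frame
#'
#' One row per (patient, delivery, section): `patient_id`, `varied`,
#' `family`, `magnitude`, `n_segments`, `section_index`, `cas`, `miv`,
#' `mdm`, `mdl`. The error-free delivery appears with family `"NONE"`.
#'
#' @param cohort A [pd_cohort()].
#' @return A data frame.
#' @export
traces_to_df <- function(cohort) {
  stop_if(!inherits(cohort, "pd_cohort"), "cohort must be a pd_cohort")
  one <- function(tr, varied) {
    err <- attr(tr, "error")
    data.frame(patient_id = attr(tr, "patient_id"), varied = varied,
               family = err$family, magnitude = err$magnitude,
               n_segments = attr(tr, "n_segments"),
               as.data.frame(tr))
  }
  do.call(rbind, unlist(lapply(cohort$patients, function(p) {
    c(list(one(p$normal, p$varied)),
      lapply(p$cases, one, varied = p$varied))
  }), recursive = FALSE))
}

#' Rebuild a cohort from a tidy trace data frame
#'
#' Inverse of [traces_to_df()].
#'
#' @param df Data frame in the [traces_to_df()] layout.
#' @return A [pd_cohort()].
#' @export
cohort_from_df <- function(df) {
  need <- c("patient_id", "varied", "family", "magnitude", "n_segments",
            "section_index", metric_names())
  stop_if(!all(need %in% names(df)), "missing trace columns")
  pats <- lapply(split(df, df$patient_id), function(dp) {
    normal <- NULL; cases <- list()
    for (dd in split(dp, paste(dp$family, dp$magnitude))) {
      dd <- dd[order(dd$section_index), ]
      tr <- as_metric_trace(dd, n_segments = dd$n_segments[1L],
                            patient_id = dd$patient_id[1L],
                            error = error_spec(dd$family[1L], dd$magnitude[1L]))
      if (dd$family[1L] == "NONE") normal <- tr
      else cases[[length(cases) + 1L]] <- tr
    }
    stop_if(is.null(normal), "patient without an error-free trace: ",
            dp$patient_id[1L])
    pd_patient(dp$patient_id[1L], dp$varied[1L], normal, cases)
  })
  pd_cohort(unname(pats[order(names(pats))]))
}

#' Write cohort traces to a tidy CSV
#' @param cohort A [pd_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_traces <- function(cohort, path) {
  utils::write.csv(traces_to_df(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Read cohort traces from a tidy CSV
#' @param path CSV written by [write_metric_traces()].
#' @return A [pd_cohort()].
#' @export
read_metric_traces <- function(path) {
  cohort_from_df(utils::read.csv(path))
}

# ---- command surface ------------------------------------------------------

#' Simulate the cohort and persist traces (and optionally stacks)
#'
#' Writes `traces.csv` (tidy metric traces of every delivery), `config.yaml`
#' and `manifest.json` (seeds, per-patient menus, stack counts) under
#' `out_dir`. With `config$save_stacks = TRUE`, every predicted and
#' measured stack is also written to `stacks/` in the native container.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Print progress lines.
#' @return The [pd_cohort()], invisibly.
#' @export
cmd_simulate <- function(config, out_dir, verbose = FALSE) {
  stop_if(!inherits(config, "run_config"), "config must be a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stop_if(!dir.exists(out_dir), "cannot create output directory: ", out_dir)
  pats <- vector("list", config$n_patients)
  stack_counts <- integer(config$n_patients)
  if (config$save_stacks)
    dir.create(file.path(out_dir, "stacks"), showWarnings = FALSE)
  for (p in seq_len(config$n_patients)) {
    varied <- p <= config$n_varied
    if (verbose)
      message(sprintf("simulating patient %d/%d (%s menu)", p,
                      config$n_patients, if (varied) "varied" else "fixed"))
    sim <- simulate_patient(config, p, varied,
                            keep_stacks = config$save_stacks)
    pats[[p]] <- sim$patient
    stack_counts[p] <- 2L + length(sim$patient$cases)
    if (config$save_stacks) {
      sdir <- file.path(out_dir, "stacks")
      id <- sim$patient$patient_id
      write_stack(sim$predicted, file.path(sdir, paste0(id, "_predicted.pds")))
      write_stack(sim$normal, file.path(sdir, paste0(id, "_normal.pds")))
      for (k in seq_along(sim$case_stacks))
        write_stack(sim$case_stacks[[k]],
                    file.path(sdir, sprintf("%s_case%02d.pds", id, k)))
    }
  }
  cohort <- pd_cohort(pats)
  write_metric_traces(cohort, file.path(out_dir, "traces.csv"))
  write_config(config, file.path(out_dir, "config.yaml"))
  manifest <- list(
    seed = config$seed,
    patients = lapply(seq_len(config$n_patients), function(p) list(
      patient_id = pats[[p]]$patient_id,
      varied = pats[[p]]$varied,
      plan_seed = patient_seed(config, p),
      n_error_cases = length(pats[[p]]$cases),
      n_stacks = stack_counts[p])),
    total_stacks = sum(stack_counts),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cohort)
}

#' Optimise CDM weights over the leave-pair-out folds
#'
#' Reads the traces (unless a cohort is supplied), runs
#' [run_loo_optimisation()] and writes `folds.json` (per-fold best weights,
#' objectives and test summaries) plus `weights_summary.csv` and
#' `detection_summary.csv` under `out_dir`.
#'
#' @param config A [run_config()] (supplies the grid step).
#' @param traces Path to a `traces.csv` file, or a [pd_cohort()].
#' @param out_dir Output directory.
#' @param verbose Print per-fold progress.
#' @return The `loo_result`, invisibly.
#' @export
cmd_optimize <- function(config, traces, out_dir, verbose = FALSE) {
  stop_if(!inherits(config, "run_config"), "config must be a run_config")
  cohort <- if (inherits(traces, "pd_cohort")) traces else {
    stop_if(!file.exists(traces), "trace file not found: ", traces)
    read_metric_traces(traces)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  loo <- run_loo_optimisation(cohort, step = config$grid_step,
                              verbose = verbose)
  summ <- summarize_folds(loo)
  fold_entries <- lapply(seq_along(loo$results), function(i) {
    r <- loo$results[[i]]
    list(fold = i,
         optimisation_ids = loo$folds[[i]]$optimisation_ids,
         test_ids = loo$folds[[i]]$test_ids,
         best_weights = as.list(r$fit$best_weights),
         objective = r$fit$objective,
         thresholds = c(as.list(r$fit$thresholds$metrics),
                        list(cdm = r$fit$thresholds$cdm)),
         test_mean_index = as.list(r$test$mean_index),
         test_false_positives = as.list(r$test$false_positives))
  })
  jsonlite::write_json(list(grid_step = loo$step, folds = fold_entries),
                       file.path(out_dir, "folds.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(summ$weights, file.path(out_dir, "weights_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(summ$detection,
                   file.path(out_dir, "detection_summary.csv"),
                   row.names = FALSE)
  invisible(loo)
}

#' Render the human-readable report
#'
#' Formats the leave-pair-out summaries as text tables (median and range
#' of the optimal weight per constituent metric; median and range of the
#' mean first-detection index per detector; benefit ratio; false-positive
#' totals) and writes `report.txt`. Regeneration from the same results is
#' idempotent.
#'
#' @param results A `loo_result`, or the path to a directory containing
#'   `folds.json` (then the summaries are recomputed from the JSON).
#' @param out_dir Output directory.
#' @return The report lines, invisibly.
#' @export
cmd_report <- function(results, out_dir) {
  if (inherits(results, "loo_result")) {
    summ <- summarize_folds(results)
  } else {
    path <- if (dir.exists(results)) file.path(results, "folds.json") else results
    stop_if(!file.exists(path), "results JSON not found: ", path)
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    med_range <- function(x) c(median = stats::median(x), min = min(x), max = max(x))
    W <- t(vapply(raw$folds, function(f) unlist(f$best_weights), numeric(4)))
    MI <- t(vapply(raw$folds, function(f) unlist(f$test_mean_index), numeric(6)))
    FP <- t(vapply(raw$folds, function(f) unlist(f$test_false_positives),
                   numeric(6)))
    det_labels <- c(metric_labels(), "Multiple separate metrics",
                    "Multiple separate metrics + CDM")
    summ <- list(
      weights = data.frame(metric = metric_labels(), t(apply(W, 2L, med_range))),
      detection = data.frame(detector = det_labels, t(apply(MI, 2L, med_range))),
      benefit_ratio = data.frame(t(med_range(MI[, 6] / MI[, 5]))),
      false_positives = data.frame(detector = det_labels, total = colSums(FP)))
  }
  fmt_row <- function(label, m, lo, hi)
    sprintf("  %-34s %6.2f (%.2f-%.2f)", label, m, lo, hi)
  lines <- c(
    "Composite difference metric: leave-pair-out summary",
    "",
    "Optimal weights (median and range over folds):",
    mapply(fmt_row, summ$weights$metric, summ$weights$median,
           summ$weights$min, summ$weights$max),
    "",
    "Mean segment index of first detection (median and range over folds):",
    mapply(fmt_row, summ$detection$detector, summ$detection$median,
           summ$detection$min, summ$detection$max),
    "",
    sprintf("Benefit ratio (scenario 3 / scenario 2): %.2f (%.2f-%.2f)",
            summ$benefit_ratio$median, summ$benefit_ratio$min,
            summ$benefit_ratio$max),
    "",
    "False positives on held-out error-free deliveries (total over folds):",
    sprintf("  %-34s %d", summ$false_positives$detector,
            as.integer(summ$false_positives$total)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(lines)
}

#' Run the full pipeline: simulate, optimise, report
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param verbose Print progress lines.
#' @return List with the cohort, the `loo_result` and the summaries,
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  cohort <- cmd_simulate(config, out_dir, verbose = verbose)
  loo <- cmd_optimize(config, cohort, out_dir, verbose = verbose)
  cmd_report(loo, out_dir)
  invisible(list(cohort = cohort, loo = loo, summary = summarize_folds(loo)))
}
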