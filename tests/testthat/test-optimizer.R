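test_that("the weight grid is the full Cartesian product in fixed order", {
  g <- weight_grid(0.05)
  expect_equal(nrow(g), 194481L)           # 21^4
  expect_equal(length(unique(g[, 1])), 21L)
  expect_equal(nrow(weight_grid(0.5)), 81L)
  # CAS weight varies fastest
  expect_equal(g[1:3, 1], c(0, 0.05, 0.10))
  expect_equal(g[1:3, 4], c(0, 0, 0))
  expect_error(weight_grid(0.3), "divide")
})

test_that("leave-pair-out folds pair one varied with one fixed patient", {
  cohort <- synth_cohort()
  folds <- leave_pair_out_folds(cohort)
  expect_length(folds, 9L)
  keys <- vapply(folds, function(f) paste(sort(f$test_ids), collapse = "+"),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  all_ids <- names(cohort$patients)
  appearances <- table(unlist(lapply(folds, function(f) f$test_ids)))
  expect_true(all(appearances == 3L))
  for (f in folds) {
    expect_length(f$optimisation_ids, 4L)
    expect_equal(sort(c(f$optimisation_ids, f$test_ids)), sort(all_ids))
  }
  # a 2 + 2 cohort is rejected under the study layout but allowed generally
  small <- pd_cohort(cohort$patients[c(1, 2, 4, 5)])
  expect_error(leave_pair_out_folds(small), "3 varied")
  expect_length(leave_pair_out_folds(small, require_3x3 = FALSE), 4L)
})

test_that("the objective reduces to the scenario-2 mean when the CDM is inert", {
  cohort <- synth_cohort()
  fold <- leave_pair_out_folds(cohort)[[1]]
  pats <- cohort$patients[fold$optimisation_ids]
  thr <- build_thresholds(lapply(pats, function(p) p$normal))
  s2 <- mean(unlist(lapply(pats, function(p)
    vapply(p$cases, function(tr)
      first_detection_index(tr, thr, 2)$first_index, numeric(1)))))
  expect_equal(cdm_objective(c(0, 0, 0, 0), cohort, fold$optimisation_ids), s2)
  # scenario nesting: no weight vector can do worse than scenario 2
  set.seed(8)
  for (k in 1:10) {
    w <- round(runif(4, 0, 1), 2)
    expect_lte(cdm_objective(w, cohort, fold$optimisation_ids), s2)
  }
})

test_that("the grid search equals an independent brute-force oracle", {
  cohort <- synth_cohort()
  fold <- leave_pair_out_folds(cohort)[[2]]
  fit <- optimize_weights(cohort, fold, step = 0.5, return_surface = TRUE)
  g <- weight_grid(0.5)
  oracle <- vapply(seq_len(nrow(g)), function(i)
    cdm_objective(g[i, ], cohort, fold$optimisation_ids), numeric(1))
  expect_equal(fit$surface, oracle)
  expect_equal(fit$objective, min(oracle))
  expect_equal(unname(fit$best_weights), unname(g[which.min(oracle), ]))
  expect_equal(fit$n_evaluated, 81L)
  # thresholds returned are bound to the winning weights
  expect_equal(fit$thresholds$weights, fit$best_weights)
  expect_false(is.na(fit$thresholds$cdm))
})

test_that("a grid restricted to the zero vector reproduces scenario 2", {
  cohort <- synth_cohort()
  fold <- leave_pair_out_folds(cohort)[[1]]
  fit <- optimize_weights(cohort, fold, step = 1)  # grid {0, 1}^4
  expect_equal(fit$n_evaluated, 16L)
  expect_lte(fit$objective,
             cdm_objective(c(0, 0, 0, 0), cohort, fold$optimisation_ids))
})

test_that("the objective is invariant to patient and case enumeration order", {
  cohort <- synth_cohort()
  fold <- leave_pair_out_folds(cohort)[[1]]
  w <- c(0.5, 0.25, 0.75, 0)
  base <- cdm_objective(w, cohort, fold$optimisation_ids)
  expect_equal(cdm_objective(w, cohort, rev(fold$optimisation_ids)), base)
  shuffled <- cohort
  shuffled$patients <- lapply(shuffled$patients, function(p) {
    p$cases <- rev(p$cases); p
  })
  expect_equal(cdm_objective(w, shuffled, fold$optimisation_ids), base)
})

test_that("correlated sub-threshold elevations are caught only by the composite", {
  cc <- correlated_cohort()
  fold <- cc$fold
  pats <- cc$cohort$patients[fold$optimisation_ids]
  s2 <- cdm_objective(c(0, 0, 0, 0), cc$cohort, fold$optimisation_ids)
  # no individual metric ever crosses: scenario 2 never detects
  case <- pats[[1]]$cases[[1]]
  expect_false(first_detection_index(case, cc$thresholds, 2)$detected)
  fit <- optimize_weights(cc$cohort, fold, step = 0.25)
  expect_lt(fit$objective, s2)
  out <- first_detection_index(case, fit$thresholds, 3)
  expect_true(out$detected)
  expect_equal(out$first_index, cc$onset)
})

test_that("an informative single metric receives nonzero weight when it helps", {
  # all error signal lives in MDM, at sub-threshold level
  set.seed(12)
  n_sec <- 40L
  normals <- lapply(1:4, function(i)
    synth_trace(matrix(runif(n_sec * 4, 0.05, 0.1), n_sec, 4),
                patient_id = paste0("R", i)))
  thr <- build_thresholds(normals)
  M <- matrix(runif(n_sec * 4, 0.05, 0.1), n_sec, 4)
  M[20:n_sec, 3] <- 0.95 * thr$metrics[3]
  pats <- lapply(1:4, function(i)
    pd_patient(paste0("R", i), i == 1, normals[[i]],
               if (i == 1) list(synth_trace(M, patient_id = "R1",
                                            error = error_spec("MU_SCALE", 2)))
               else list()))
  cohort <- pd_cohort(pats)
  fold <- list(optimisation_ids = paste0("R", 1:4))
  fit <- optimize_weights(cohort, fold, step = 0.25)
  s2 <- cdm_objective(c(0, 0, 0, 0), cohort, fold$optimisation_ids)
  expect_lte(fit$objective, s2)
  if (fit$objective < s2)
    expect_gt(fit$best_weights[["mdm"]], 0)
})

test_that("fold evaluation and summaries follow order statistics and nesting", {
  cohort <- synth_cohort()
  loo <- run_loo_optimisation(cohort, step = 0.5)
  summ <- summarize_folds(loo)
  expect_equal(summ$weights$metric, c("CAS", "MIV", "MDM", "MDL"))
  expect_equal(nrow(summ$detection), 6L)

  # per-fold benefit ratio never exceeds one (scenario nesting)
  MI <- t(vapply(loo$results, function(r) r$test$mean_index, numeric(6)))
  ratio <- MI[, "scenario3"] / MI[, "scenario2"]
  expect_true(all(ratio <= 1 + 1e-12))
  expect_equal(summ$benefit_ratio$median, stats::median(ratio))
  expect_equal(c(summ$benefit_ratio$min, summ$benefit_ratio$max),
               range(ratio))

  # median/range agree with direct order statistics on the weights
  W <- t(vapply(loo$results, function(r) r$fit$best_weights, numeric(4)))
  expect_equal(summ$weights$median, apply(W, 2, stats::median),
               ignore_attr = TRUE)
  expect_equal(summ$weights$min, apply(W, 2, min), ignore_attr = TRUE)

  # identical folds collapse the range to a point
  one <- structure(list(folds = loo$folds[c(1, 1)],
                        results = loo$results[c(1, 1)], step = 0.5),
                   class = "loo_result")
  s1 <- summarize_folds(one)
  expect_equal(s1$weights$min, s1$weights$max)
})

test_that("per-power memoisation agrees with direct composite evaluation", {
  set.seed(13)
  M <- matrix(runif(30 * 4, 0, 3), 30, 4)
  vals <- seq(0, 1, 0.25)
  for (w1 in vals) for (w3 in vals) {
    w <- c(w1, 0.5, w3, 0.75)
    pieces <- lapply(1:4, function(i) if (w[i] > 0) w[i] * M[, i]^w[i] else 0)
    expect_equal(Reduce(`+`, pieces), cdm(M, w), tolerance = 1e-12)
  }
})
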