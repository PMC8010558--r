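test_that("the median-plus-range rule sits at or above every reference maximum", {
  expect_equal(threshold_from_maxima(c(1, 2, 3, 4)), 5.5)
  expect_equal(threshold_from_maxima(7.3), 7.3)
  set.seed(4)
  for (k in 1:20) {
    x <- runif(sample(1:8, 1), 0, 10)
    expect_gte(threshold_from_maxima(x), max(x))
  }
  expect_error(threshold_from_maxima(numeric(0)), "at least one")
})

test_that("threshold sets are built per metric from error-free maxima", {
  M <- matrix(runif(40 * 4, 0, 2), 40, 4)
  tr <- synth_trace(M)
  # four identical normal traces: threshold equals the common maximum
  thr <- build_thresholds(list(tr, tr, tr, tr))
  expect_equal(unname(thr$metrics), apply(M, 2, max))

  # homogeneity: scaling every trace scales every threshold
  traces <- lapply(1:4, function(i) synth_trace(M * i))
  thr1 <- build_thresholds(traces)
  thr3 <- build_thresholds(lapply(1:4, function(i) synth_trace(3 * M * i)))
  expect_equal(thr3$metrics, 3 * thr1$metrics)

  # a zero weight vector yields a CDM threshold of zero that is never
  # strictly exceeded
  thr0 <- build_thresholds(traces, weights = c(0, 0, 0, 0))
  expect_equal(thr0$cdm, 0)
  out <- first_detection_index(traces[[1]], thr0, scenario = 3)
  out2 <- first_detection_index(traces[[1]], thr0, scenario = 2)
  expect_equal(out$first_index, out2$first_index)
})

test_that("first detection scans sections in order with a sentinel fallback", {
  zeroes <- synth_trace(matrix(0, 60, 4), start = 19, n_segments = 78)
  thr <- build_thresholds(list(zeroes))
  out <- first_detection_index(zeroes, thr, scenario = 2)
  expect_false(out$detected)
  expect_equal(out$first_index, not_detected(78))
  expect_equal(not_detected(180), 181L)

  # only MDM crosses, first at section 40
  M <- matrix(0.1, 60, 4)
  M[(40 - 19 + 1):60, 3] <- 5
  tr <- synth_trace(M, start = 19)
  thr <- build_thresholds(list(synth_trace(matrix(0.2, 60, 4), start = 19)))
  out <- first_detection_index(tr, thr, scenario = 2)
  expect_true(out$detected)
  expect_equal(out$first_index, 40L)
  expect_equal(first_detection_index(tr, thr, 1, metric = "mdm")$first_index, 40L)
  expect_false(first_detection_index(tr, thr, 1, metric = "cas")$detected)
  expect_error(first_detection_index(tr, thr, 1), "metric")

  # exact ties do not trigger
  tie <- synth_trace(matrix(0.2, 60, 4), start = 19)
  expect_false(first_detection_index(tie, thr, scenario = 2)$detected)
})

test_that("detection scenarios are nested: 3 detects no later than 2, 2 than 1", {
  set.seed(6)
  normals <- lapply(1:4, function(i)
    synth_trace(matrix(runif(50 * 4, 0, 0.5), 50, 4), patient_id = paste0("N", i)))
  thr <- build_thresholds(normals, weights = c(0.15, 0.10, 0.15, 0))
  for (k in 1:25) {
    M <- matrix(runif(50 * 4, 0, 0.6), 50, 4)
    if (k %% 2 == 0) M[sample(10:50, 1):50, sample(1:4, 2)] <- runif(1, 0.5, 2)
    tr <- synth_trace(M)
    i3 <- first_detection_index(tr, thr, 3)$first_index
    i2 <- first_detection_index(tr, thr, 2)$first_index
    expect_lte(i3, i2)
    for (m in c("cas", "miv", "mdm", "mdl"))
      expect_lte(i2, first_detection_index(tr, thr, 1, m)$first_index)
  }
})

test_that("false positives are counted per patient and nested across scenarios", {
  set.seed(7)
  normals <- lapply(1:4, function(i)
    synth_trace(matrix(runif(40 * 4, 0, 1), 40, 4), patient_id = paste0("N", i)))
  thr <- build_thresholds(normals, weights = c(0.5, 0.5, 0.5, 0.5))
  # thresholds were built from these very deliveries: zero false positives
  expect_equal(count_false_positives(normals, thr, 2), 0L)
  expect_equal(count_false_positives(normals, thr, 3), 0L)

  inflated <- normals
  M2 <- as.matrix(as.data.frame(normals[[2]])[, c("cas", "miv", "mdm", "mdl")])
  inflated[[2]] <- synth_trace(10 * M2)
  expect_equal(count_false_positives(inflated, thr, 2), 1L)
  expect_gte(count_false_positives(inflated, thr, 3),
             count_false_positives(inflated, thr, 2))
})

test_that("the traffic-light stream flags near misses and errors", {
  thr <- build_thresholds(list(synth_trace(matrix(1, 30, 4))))  # all t = 1
  green <- traffic_light_stream(synth_trace(matrix(0, 30, 4)), thr)
  expect_true(all(green$status == "green"))
  expect_true(all(is.na(green$trigger)))

  M <- matrix(0.1, 30, 4)
  M[10, 2] <- 1.5   # red: above threshold
  M[20, 3] <- 0.9   # orange: above 0.8 * threshold
  tl <- traffic_light_stream(synth_trace(M), thr)
  expect_equal(as.character(tl$status[10]), "red")
  expect_equal(tl$trigger[10], "MIV")
  expect_equal(as.character(tl$status[20]), "orange")
  expect_equal(tl$trigger[20], "MDM")
  expect_equal(as.character(tl$status[1]), "green")
})
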