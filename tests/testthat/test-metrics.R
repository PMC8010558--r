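test_that("evaluation start index excludes the first 10% and honours the window", {
  expect_equal(evaluation_start_index(180), 19L)
  expect_equal(evaluation_start_index(100), 11L)
  expect_equal(evaluation_start_index(50), 10L)
  expect_error(evaluation_start_index(8), "window")
})

test_that("section images are running 10-frame sums with the telescoping identity", {
  set.seed(1)
  px <- array(runif(8 * 8 * 15), c(8, 8, 15))
  stack <- portalcdm:::new_portal_stack(px, seq_len(15), "measured", "X")

  const <- portalcdm:::new_portal_stack(array(3, c(4, 4, 12)), 1:12,
                                        "measured", "X")
  expect_equal(section_image(const, 10), matrix(30, 4, 4))

  expect_equal(section_image(stack, 10), rowSums(px[, , 1:10], dims = 2))
  for (s in 11:15) {
    expect_equal(section_image(stack, s) - section_image(stack, s - 1),
                 px[, , s] - px[, , s - 10])
  }
  expect_error(section_image(stack, 9), "out of range")
})

test_that("the in-field mask keeps pixels above 10% of the predicted maximum", {
  expect_true(all(in_field_mask(matrix(5, 4, 4))))
  two <- matrix(c(100, 5, 100, 5), 2, 2)
  expect_equal(in_field_mask(two), two == 100)
  img <- matrix(runif(100, 0, 10), 10, 10)
  for (f in c(0.05, 0.1, 0.3, 0.6))
    expect_gte(sum(in_field_mask(img, f)), sum(in_field_mask(img, f + 0.05)))
  expect_error(in_field_mask(matrix(0, 3, 3)), "positive maximum")
})

test_that("the four metrics match their definitions and a naive oracle", {
  set.seed(2)
  pred <- matrix(runif(16 * 16, 1, 10), 16, 16)
  expect_equal(compute_metrics(pred, pred),
               c(cas = 0, miv = 0, mdm = 0, mdl = 0))

  up <- compute_metrics(pred, 1.04 * pred)
  expect_equal(up[["mdl"]], 4)
  mask <- in_field_mask(pred)
  expect_equal(up[["mdm"]], 4 * mean(pred[mask]) / max(pred))

  for (k in 1:5) {
    pred <- matrix(runif(12 * 12, 0.5, 8), 12, 12)
    meas <- pred + matrix(rnorm(12 * 12, 0, 0.5), 12, 12)
    meas <- pmax(meas, 0)
    expect_equal(compute_metrics(pred, meas), naive_metrics(pred, meas),
                 tolerance = 1e-12)
  }
  expect_error(compute_metrics(matrix(1, 2, 2), matrix(1, 3, 3)),
               "same shape")
})

test_that("the composite metric obeys its algebraic identities", {
  m <- c(1.3, 0.4, 2.2, 5.1)
  expect_equal(cdm(m, c(1, 0, 0, 0)), m[1])
  expect_equal(cdm(m, c(0, 0, 0, 0)), 0)
  expect_equal(cdm(c(4, 4, 4, 4), c(0.5, 0.5, 0.5, 0.5)), 4)
  # with 0/1 weights the CDM is a plain sum of the selected metrics
  expect_equal(cdm(m, c(1, 0, 1, 1)), m[1] + m[3] + m[4])
  # matrix form agrees with row-wise evaluation
  set.seed(3)
  M <- matrix(runif(40, 0, 5), 10, 4)
  w <- c(0.25, 0.9, 0, 0.55)
  expect_equal(cdm(M, w),
               apply(M, 1, cdm, w = w))
  expect_error(cdm(c(-1, 0, 0, 0), w), ">= 0")
})

test_that("the composite metric is monotone in each metric and concave below unit weight", {
  w <- c(0.3, 0.7, 0.5, 0.15)
  grid <- seq(0.01, 6, length.out = 120)
  for (i in 1:4) {
    m <- matrix(1, length(grid), 4)
    m[, i] <- grid
    v <- cdm(m, w)
    expect_true(all(diff(v) > 0))          # monotone increasing
    expect_true(all(diff(diff(v)) < 1e-9)) # concave (plateauing) for w < 1
  }
})

test_that("metric traces cover the right sections and scale as expected", {
  geom <- tiny_geometry(32)
  plan <- generate_plan(seed = 8, n_segments = 30, arc_span_deg = 58)
  ph <- phantom()
  pred <- predict_stack(plan, ph, geom)

  tr0 <- metric_trace(pred, pred)
  expect_equal(nrow(tr0), 30 - 10 + 1)
  expect_equal(tr0$section_index, 10:30)
  expect_true(all(as.matrix(tr0[, c("cas", "miv", "mdm", "mdl")]) == 0))

  meas <- simulate_measured_stack(plan, ph, geom,
                                  noise = noise_model(seed = 5L,
                                                      rampup_segments = 3L))
  tr <- metric_trace(pred, meas)
  # a common positive rescale of both stacks leaves the ratio metrics alone
  k <- 3.7
  pred_k <- pred; pred_k$pixels <- k * pred$pixels
  meas_k <- meas; meas_k$pixels <- k * meas$pixels
  tr_k <- metric_trace(pred_k, meas_k)
  expect_equal(tr_k$mdm, tr$mdm)
  expect_equal(tr_k$mdl, tr$mdl)
  expect_equal(tr_k$cas, k * tr$cas)

  # trace length for a 180-segment arc is 162 sections (start index 19)
  expect_equal(180L - evaluation_start_index(180L) + 1L, 162L)

  bad <- meas; bad$gantry_deg <- meas$gantry_deg + 1
  expect_error(metric_trace(pred, bad), "misaligned")
})
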