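test_that("couch attenuation path follows the cosine model in its window", {
  expect_equal(couch_extra_path(0), 8)
  expect_equal(couch_extra_path(60), 16)
  expect_equal(couch_extra_path(300), 16)
  expect_equal(couch_extra_path(90), 0)
  expect_equal(couch_extra_path(180), 0)
  # window symmetry about gantry zero
  th <- seq(0, 359.5, by = 0.5)
  expect_equal(couch_extra_path(th), couch_extra_path((360 - th) %% 360))
})

test_that("panel sag is a 4 mm peak-to-peak sinusoid", {
  g <- panel_geometry()
  th <- seq(0, 359.9, by = 0.1)
  s <- panel_sag_shift(th, g)
  expect_equal(max(s) - min(s), 4, tolerance = 1e-6)
  expect_equal(panel_sag_shift(0, g), 0)
  expect_equal(panel_sag_shift(th, g), -panel_sag_shift(360 - th, g))
})

test_that("pixel pitch projects to the isocentre plane by SAD/SDD", {
  expect_equal(isocentre_pixel_pitch(panel_geometry()), 0.5)
  expect_equal(isocentre_pixel_pitch(panel_geometry(sdd_mm = 1000, sad_mm = 1000)),
               0.8)
  expect_equal(isocentre_pixel_pitch(
    panel_geometry(pixel_pitch_panel_mm = 1, sdd_mm = 2000, sad_mm = 1000)), 0.5)
})

test_that("radiological path matches a brute-force ray-marching integrator", {
  ph <- phantom()
  expect_equal(radiological_path(ph, 0, 0), 200)
  expect_equal(radiological_path(ph, 90, 0), 300)
  # cavity centred on the central axis removes its full A-P height
  ph_cav <- set_cavity(ph, air_cavity(20, centre_offset_mm = c(0, 0, 0)))
  expect_equal(radiological_path(ph_cav, 0, 0), 150)
  # rays beyond the panel-projected phantom edge miss entirely
  expect_equal(radiological_path(ph, 0, 200), 0)
  expect_equal(radiological_path(ph, 0, 0, longitudinal_offset_mm = 160), 0)

  ph_off <- set_cavity(ph, air_cavity(30, centre_offset_mm = c(10, 0, -40)))
  for (g in c(0, 37, 90, 213, 300)) {
    for (u in c(-120, -40, 0, 12, 35, 100)) {
      expect_equal(radiological_path(ph_off, g, u),
                   raymarch_path(ph_off, g, u),
                   tolerance = 0.01,
                   label = sprintf("gantry %g offset %g", g, u))
    }
  }
})

test_that("predicted images are linear in MU and monotone in aperture", {
  geom <- tiny_geometry(32)
  plan <- generate_plan(seed = 4, n_segments = 20, arc_span_deg = 38)
  ph <- phantom()
  seg <- plan_segment(plan, 7)
  img <- predict_image(seg, ph, geom)

  seg2 <- seg; seg2$mu <- 2 * seg$mu
  img2 <- predict_image(seg2, ph, geom)
  expect_equal(img2$pixels, 2 * img$pixels)

  wide <- seg; wide$bank_a <- seg$bank_a - 3; wide$bank_b <- seg$bank_b + 3
  expect_gt(sum(predict_image(wide, ph, geom)$pixels), sum(img$pixels))

  closed <- seg; closed$bank_a[] <- 0; closed$bank_b[] <- 0
  cimg <- predict_image(closed, ph, geom)$pixels
  interior <- cimg[8:24, 8:24]
  expect_lt(stats::sd(interior), 1e-12 * (mean(interior) + 1e-12))
})

test_that("in-field signal attenuates with path and rises over an air cavity", {
  geom <- tiny_geometry(32)
  params <- forward_params()
  plan <- generate_plan(seed = 4, n_segments = 20, arc_span_deg = 38)
  seg <- plan_segment(plan, 7)
  thin <- predict_image(seg, phantom(height_mm = 150), geom, params)$pixels
  thick <- predict_image(seg, phantom(height_mm = 250), geom, params)$pixels
  expect_true(all(thin >= thick))
  expect_gt(mean(thin), mean(thick))

  ph <- phantom()
  ph_cav <- set_cavity(ph, air_cavity(40, centre_offset_mm = c(0, 0, 0)))
  plain <- predict_image(seg, ph, geom, params)$pixels
  cavd <- predict_image(seg, ph_cav, geom, params)$pixels
  expect_gt(max(cavd - plain), 0)
  expect_gt(sum(cavd), sum(plain))
})

test_that("two-Gaussian panel scatter preserves energy on interior images", {
  geom <- tiny_geometry(64)
  params <- forward_params()
  img <- matrix(0, 64, 64)
  img[28:36, 28:36] <- 5
  blurred <- portalcdm:::panel_scatter(img, geom, params)
  expect_equal(sum(blurred), sum(img), tolerance = 1e-3)
  expect_true(all(blurred >= 0))
})

test_that("measured simulation is deterministic and exact without noise", {
  geom <- tiny_geometry(32)
  plan <- generate_plan(seed = 6, n_segments = 20, arc_span_deg = 38)
  ph <- phantom()
  pred <- predict_stack(plan, ph, geom)

  meas0 <- simulate_measured_stack(plan, ph, geom, noise = zero_noise())
  expect_equal(meas0$pixels, pred$pixels)

  inj <- inject_error(plan, ph, error_spec("MU_SCALE", 4))
  meas4 <- simulate_measured_stack(inj$plan, inj$phantom, geom,
                                   noise = zero_noise())
  expect_equal(meas4$pixels, 1.04 * pred$pixels)

  nm <- noise_model(seed = 99L)
  a <- simulate_measured_stack(plan, ph, geom, noise = nm)
  b <- simulate_measured_stack(plan, ph, geom, noise = nm)
  expect_identical(a$pixels, b$pixels)
  expect_true(all(a$pixels >= 0))
})
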