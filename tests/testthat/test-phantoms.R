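test_that("gamma variate peaks at c0 at the peak time and vanishes at t = 0", {
  expect_equal(gamma_variate(20, 20, 11, 1), 1.0)
  expect_equal(gamma_variate(0, 20, 11, 1), 0.0)
  expect_equal(gamma_variate(10, 10, 5, 3.7), 3.7)
  expect_error(gamma_variate(1, 1, alpha_gamma = 0), "alpha")
  expect_error(gamma_variate(1, 0, 11), "peak_time")
})

test_that("gamma variate is unimodal around the peak for any positive alpha", {
  tau <- seq(0.02, 3, by = 0.02)
  for (a in c(0.5, 2, 11, 25)) {
    v <- gamma_variate(tau, 1, a)
    d <- diff(v)
    expect_true(all(d[tau[-1] <= 1] > 0), info = paste("alpha", a))
    expect_true(all(d[tau[-length(tau)] >= 1] < 0), info = paste("alpha", a))
  }
})

test_that("continuous FWHM of the alpha = 11 bolus matches the bisection oracle", {
  # frozen from the oracle; ~0.7125 of the peak time
  expect_equal(gamma_fwhm_tau(11), 0.7124931, tolerance = 1e-6)
  # sampled-curve FWHM (2 s frames, peak 20 s) within 10% of continuous
  tt <- (1:27) * 2
  curve <- time_density_curve(gamma_variate(tt, 20, 11, 1), 2)
  expect_equal(curve_fwhm(curve), 20 * 0.7124931, tolerance = 0.1)
})

test_that("rasterized disks have near-analytic area", {
  # 10 mm vessel at 0.75 mm pixels ~ 13.3 px diameter
  img <- disk_image(1, 5, 128, 0.75)
  expect_equal(sum(img) * 0.75^2, pi * 25, tolerance = 0.02)
})

test_that("rendering is deterministic and static when c0 = 0", {
  spec <- forbild_head_spec(image_size = 128, pixel_spacing = 3, c0 = 0)
  a <- render_dynamic_phantom(spec)
  b <- render_dynamic_phantom(spec)
  expect_identical(a$data, b$data)
  for (f in 2:spec$n_frames)
    expect_equal(a$data[, , f], a$data[, , 1])
  expect_true(all(a$data >= 0))
})

test_that("vessel ROI means reproduce the gamma-variate curve on rendered frames", {
  spec <- forbild_head_spec(image_size = 256, pixel_spacing = 1.5)
  ser <- render_dynamic_phantom(spec)
  v <- spec$vessels[[1]]
  roi <- roi_circle(mm_to_pixel(v$center, 256, 1.5), v$diameter / 2 / 1.5 - 1)
  tdc <- extract_tdc(ser, roi, baseline_frames = 2)
  model <- gamma_variate((1:27) * 2, 20, 11, 1)
  expect_lt(sqrt(mean((tdc$values / v$c0 - model)^2)), 0.005)
  expect_equal(which.max(tdc$values), 10L)
})

test_that("phantom spec rejects vessels outside the field of view", {
  expect_error(
    phantom_spec(list(), list(vessel_dynamics(c(90, 0), 10, 0.02, 0.01)),
                 image_size = 64, pixel_spacing = 1),
    "field of view")
})

test_that("rod phantom encodes the indicator-dilution model", {
  spec <- rod_phantom_spec(image_size = 96, pixel_spacing = 2)
  aif <- gamma_variate((0:26) * 2, 14, 11, 0.02)
  expect_error(render_perfusion_rod_phantom(aif, 50, "exponential", mtt = 0,
                                            spec), "mtt")

  # zero flow: tissue rods stay flat
  ser0 <- render_perfusion_rod_phantom(aif, 0, "exponential", mtt = 4, spec)
  troi <- roi_circle(mm_to_pixel(c(0, 30), 96, 2), 3)
  expect_equal(extract_tdc(ser0, troi, baseline_frames = 1)$values,
               rep(0, 27), tolerance = 1e-12)

  # box residue with mtt of one frame: tissue curve proportional to the AIF
  ser1 <- render_perfusion_rod_phantom(aif, 60, "box", mtt = 2, spec)
  tcurve <- extract_tdc(ser1, troi, baseline_frames = 1)$values
  acurve <- extract_tdc(ser1, roi_circle(mm_to_pixel(c(-30, 0), 96, 2), 2),
                        baseline_frames = 1)$values
  fit <- lm(tcurve ~ acurve - 1)
  expect_gt(summary(fit)$r.squared, 0.999)
})
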