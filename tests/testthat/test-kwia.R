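test_that("ring arithmetic reproduces the reference radii", {
  expect_equal(nyquist_radius(576), 576 / pi)
  expect_equal(nyquist_radius(pi), 1)
  expect_equal(nyquist_radius(1152), 2 * nyquist_radius(576))

  # Ring-1 radii for the four shipped dose configurations
  expect_identical(ring1_radius(576, sqrt(0.5)), 130)
  expect_identical(ring1_radius(576, 0.5), 92)
  expect_identical(ring1_radius(576, sqrt(0.6)), 142)
  expect_identical(ring1_radius(576, sqrt(0.3)), 100)
  expect_error(ring1_radius(576, 1.2), "relative_snr")
  expect_error(ring1_radius(3, 0.5), "smaller")

  # outer rings by linear interpolation, intermediates unrounded
  expect_identical(ring_radii(576 / pi * 0.5, 728, 4), c(92, 182, 273, 364))
  expect_identical(ring_radii(130, 728, 2), c(130, 364))
  expect_identical(ring_radii(91.7, 728, 1), 364)
  for (r1 in c(70.2, 100.5, 180.9))
    expect_identical(ring_radii(r1, 728, 2),
                     c(floor(r1 + 0.5), 364))
})

test_that("ring presets carry the shipped radii and window sizes", {
  p <- ring_preset("kwia25-4ring")
  expect_equal(p$radii, c(92L, 182L, 273L, 364L))
  expect_equal(p$window_sizes, c(1L, 2L, 4L, 8L))
  expect_equal(ring_preset("kwia50-3ring")$radii, c(130L, 234L, 364L))
  expect_equal(ring_preset("kwia30-4ring")$radii, c(100L, 190L, 280L, 368L))
  expect_error(ring_preset("nope"), "available")
  expect_error(ring_spec(c(10, 20), window_sizes = c(2, 4)), "never averaged")
})

test_that("radial k-space obeys the central slice theorem basics", {
  g <- projection_geometry("parallel", 64, 1, 80)
  ones <- sinogram(matrix(1, 40, 64), g)
  ks <- projections_to_radial_kspace(ones)
  dc_col <- 33
  expect_equal(Re(ks$samples[, dc_col]), rep(64, 40))   # mass * spacing
  off <- Mod(ks$samples[, -dc_col])
  expect_lt(max(off), 1e-9)

  # every view's DC sample equals the same total mass
  set.seed(2)
  img <- disk_image(0.02, 20, 64, 1)
  s <- forward_project_parallel(img, 1, g)
  ks2 <- projections_to_radial_kspace(s)
  dc <- Re(ks2$samples[, dc_col])
  expect_lt(max(abs(dc - mean(dc))) / mean(dc), 1e-3)

  # real projections give Hermitian spokes
  sym <- ks2$samples[, dc_col + (1:31)] - Conj(ks2$samples[, dc_col - (1:31)])
  expect_lt(max(Mod(sym)), 1e-9 * max(Mod(ks2$samples)))

  gf <- projection_geometry("fan", 64, 1, 80, source_to_detector = 700,
                            source_to_isocenter = 400)
  expect_error(projections_to_radial_kspace(
    sinogram(matrix(0, 80, 64), gf)), "rebin")
})

test_that("radial spokes of a disk match the analytic transform", {
  g <- projection_geometry("parallel", 192, 1, 404)
  s <- disk_sinogram(0.02, 40, g)
  ks <- projections_to_radial_kspace(s)
  r <- (1:60)          # lower half of k-range
  k <- r * ks$dk
  analytic <- 0.02 * 40 * besselJ(2 * pi * k * 40, 1) / k
  measured <- Re(ks$samples[1, 97 + r])
  expect_lt(max(abs(measured - analytic)) / Re(ks$samples[1, 97]), 0.01)
})

test_that("view-shared averaging honors ring membership and window placement", {
  nv <- 16; nr <- 32; T <- 10
  rings <- ring_spec(c(4, 9, 16), c(1, 2, 4))
  # frame-coded series: sample value = frame index everywhere
  ser <- array(rep(seq_len(T), each = nv * nr) + 0i, c(nv, nr, T))
  out <- kwia_combine(ser, rings, 5)
  rr <- abs(seq_len(nr) - 1 - nr %/% 2)
  expect_true(all(Re(out[, rr <= 4]) == 5))            # ring 1 untouched
  expect_true(all(Re(out[, rr > 4 & rr <= 9]) == 5.5)) # frames {5,6}
  expect_true(all(Re(out[, rr > 9]) == 5.5))           # frames {4,5,6,7}
  # sliding (not shrinking) windows at the series ends
  expect_true(all(Re(kwia_combine(ser, rings, 1)[, rr > 9]) == 2.5))  # {1..4}
  expect_true(all(Re(kwia_combine(ser, rings, T)[, rr > 9]) == 8.5))  # {7..10}

  # constant series: every ring passes through unchanged
  serc <- array(1.7 + 0.3i, c(nv, nr, 4))
  expect_equal(kwia_combine(serc, rings, 2), serc[, , 2])

  # Ring 1 of the combined frame is bit-identical to the input frame
  set.seed(7)
  sern <- array(complex(real = rnorm(nv * nr * 8),
                        imaginary = rnorm(nv * nr * 8)), c(nv, nr, 8))
  out2 <- kwia_combine(sern, rings, 4)
  expect_identical(out2[, rr <= 4], sern[, rr <= 4, 4])

  expect_error(kwia_combine(sern[, , 1:3], rings, 2), "shorter")
})

test_that("view sharing reduces i.i.d. noise variance by the window size", {
  nv <- 48; nr <- 64; T <- 16
  set.seed(31)
  ser <- array(complex(real = rnorm(nv * nr * T),
                       imaginary = rnorm(nv * nr * T)), c(nv, nr, T))
  rings <- ring_spec(c(8, 20, 32), c(1, 2, 4))
  out <- kwia_combine(ser, rings, 8)
  rr <- abs(seq_len(nr) - 1 - nr %/% 2)
  v1 <- var(as.vector(Re(out[, rr <= 8])))
  v2 <- var(as.vector(Re(out[, rr > 8 & rr <= 20])))
  v3 <- var(as.vector(Re(out[, rr > 20])))
  expect_equal(v1, 1, tolerance = 0.1)
  expect_equal(v2, 1 / 2, tolerance = 0.1)
  expect_equal(v3, 1 / 4, tolerance = 0.1)
})

test_that("density weights are the ramp of radial sampling and tile the disk", {
  w <- voronoi_weights(128, 100)
  rr <- abs(seq_len(128) - 1 - 64)
  interior <- rr >= 1 & rr <= 62
  expect_equal(w[1, interior] / (pi / 100 * rr[interior]),
               rep(1, sum(interior)), tolerance = 0.02)
  expect_equal(sum(w), pi * 64^2, tolerance = 0.01 * pi * 64^2)
  w2 <- voronoi_weights(128, 200)
  expect_equal(w2[1, interior] / w[1, interior],
               rep(0.5, sum(interior)), tolerance = 1e-12)
  expect_error(voronoi_weights(16, 2), "3 views")
})

test_that("gridding a DC impulse yields a flat deapodized image", {
  nv <- 60; nr <- 64
  S <- matrix(0 + 0i, nv, nr); S[, 33] <- 1
  ang <- (seq_len(nv) - 1) * pi / nv
  # synthetic impulse, not a contained projection: no radial refinement
  cart <- regrid_to_cartesian(S, angles = ang, dk = 1 / 64,
                              radial_refine = 1)
  img <- inverse_fft_and_deapodize(cart, final_size = 40)
  central <- img[11:30, 11:30]
  expect_lt((max(central) - min(central)) / max(abs(central)), 1e-3)
})

test_that("kernel defaults match the reference regridding configuration", {
  k <- kernel_spec()
  expect_equal(k$kb_beta, 16.25)
  expect_equal(k$width, 7)
  expect_equal(k$oversampling, 2)
})

test_that("regridding matches brute-force nonuniform DFT within 1%", {
  n <- 64; h <- 1; mu <- 0.02; r0 <- 20
  g <- projection_geometry("parallel", 64, h, 204)
  img <- disk_image(mu, r0, n, h)
  s <- forward_project_parallel(img, h, g)
  ks <- projections_to_radial_kspace(s)

  rec <- inverse_fft_and_deapodize(
    regrid_to_cartesian(ks), kernel_spec(), final_size = n)

  Sref <- kwia:::refine_spokes(ks$samples, 2)
  wref <- voronoi_weights(ncol(Sref), nrow(Sref))
  oracle <- ndft_reconstruct(Sref, wref, ks$angles, ks$dk / 2, n, h)
  expect_lt(sqrt(sum((rec - oracle)^2) / sum(oracle^2)), 0.01)
})

test_that("reconstruction is linear and approximately energy preserving", {
  g <- projection_geometry("parallel", 96, 1, 204)
  # smooth Gaussian blob: analytic projections, well-convergent quadrature
  sig <- 8; A <- 0.02
  tj <- (seq_len(96) - 1 - 48) * 1
  prj <- A * sqrt(2 * pi) * sig * exp(-tj^2 / (2 * sig^2))
  s <- sinogram(matrix(rep(prj, each = 102), 102, 96), g)
  ks <- projections_to_radial_kspace(s)
  cart <- regrid_to_cartesian(ks)
  r1 <- inverse_fft_and_deapodize(cart, final_size = 96)
  r3 <- inverse_fft_and_deapodize(regrid_to_cartesian(
    structure(list(samples = 3 * ks$samples, angles = ks$angles,
                   n_radial = 96, dk = ks$dk), class = "radial_kspace")),
    final_size = 96)
  expect_equal(r3, 3 * r1, tolerance = 1e-10)

  # Parseval: weighted k-space energy vs image-domain energy
  Sref <- kwia:::refine_spokes(ks$samples, 2)
  wref <- voronoi_weights(ncol(Sref), nrow(Sref)) * (ks$dk / 2)^2
  ek <- sum(wref * Mod(Sref)^2)
  full <- inverse_fft_and_deapodize(cart, final_size = 192)
  ei <- sum(full^2) * 1^2
  expect_equal(ei / ek, 1, tolerance = 0.02)
})

test_that("noiseless disk reconstruction error stays below 2% of contrast", {
  h <- 0.75; n <- 256; mu <- 0.02; r0 <- 60
  g <- projection_geometry("parallel", 360, h, 1152)
  img <- disk_image(mu, r0, n, h)
  s <- forward_project_parallel(img, h, g)
  rec <- regrid_reconstruct(s, final_size = n)
  expect_lt(sqrt(mean((rec - img)^2)) / mu, 0.02)
})

test_that("a single ring makes KWIA identical to plain regridding", {
  g <- projection_geometry("parallel", 48, 1, 60)
  set.seed(13)
  arr <- array(abs(rnorm(30 * 48 * 5, 0.5, 0.1)), c(30, 48, 5))
  ss <- sinogram_series(arr, g, 2)
  plain <- regrid_reconstruct_series(ss, final_size = 48)
  one <- reconstruct_kwia_series(ss, ring_spec(24), final_size = 48)
  expect_equal(one$data, plain$data, tolerance = 1e-12)

  # time-constant series: KWIA with rings equals plain reconstruction
  arrc <- array(rep(arr[, , 1], 5), c(30, 48, 5))
  ssc <- sinogram_series(arrc, g, 2)
  kw <- reconstruct_kwia_series(ssc, ring_spec(c(8, 16, 24), c(1, 2, 4)),
                                final_size = 48)
  pl <- regrid_reconstruct_series(ssc, final_size = 48)
  expect_lt(max(abs(kw$data - pl$data)) / max(abs(pl$data)), 1e-6)
})
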