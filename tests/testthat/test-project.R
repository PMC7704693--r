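geom64 <- projection_geometry("parallel", 96, 1, 200)

test_that("projection of a zero image is zero and the operator is linear", {
  z <- matrix(0, 64, 64)
  expect_equal(forward_project_parallel(z, 1, geom64)$values,
               matrix(0, 100, 96))

  set.seed(5)
  i1 <- matrix(runif(64^2), 64)
  i2 <- matrix(runif(64^2), 64)
  p1 <- forward_project_parallel(i1, 1, geom64)$values
  p2 <- forward_project_parallel(i2, 1, geom64)$values
  p12 <- forward_project_parallel(2 * i1 + 0.5 * i2, 1, geom64)$values
  expect_equal(p12, 2 * p1 + 0.5 * p2, tolerance = 1e-12)
})

test_that("central ray through a centered disk integrates to the chord 2*mu*r", {
  mu <- 0.02; r0 <- 20
  img <- disk_image(mu, r0, 64, 1)
  s <- forward_project_parallel(img, 1, geom64)
  central <- s$values[, 49]   # detector offset 0
  expect_equal(central, rep(2 * mu * r0, 100), tolerance = 0.005)
})

test_that("total mass is conserved across view angles for a contained object", {
  set.seed(11)
  img <- disk_image(0.015, 18, 64, 1) +
    disk_image(0.01, 8, 64, 1)   # off-center content via asymmetric sum
  img[20:30, 35:45] <- img[20:30, 35:45] + 0.005
  s <- forward_project_parallel(img, 1, geom64)
  mass <- rowSums(s$values) * 1
  expect_lt((max(mass) - min(mass)) / mean(mass), 0.01)
})

test_that("Joseph projector matches a 0.1-pixel ray-marching oracle", {
  # small head-like frame: skull ring + brain + one vessel
  spec <- phantom_spec(
    list(list(shape = "ellipse", center = c(0, 0), axes = c(24, 28),
              value = 0.044),
         list(shape = "ellipse", center = c(0, 0), axes = c(20, 24),
              value = 0.0208),
         list(shape = "disk", center = c(-8, -6), axes = 3, value = 0.021)),
    image_size = 64, pixel_spacing = 1, n_frames = 1)
  img <- render_dynamic_phantom(spec)$data[, , 1]
  g <- projection_geometry("parallel", 96, 1, 60)
  fast <- forward_project_parallel(img, 1, g)$values
  slow <- raymarch_project(img, 1, parallel_view_angles(g), 96, 1)
  expect_lt(sqrt(sum((fast - slow)^2) / sum(slow^2)), 0.005)
})

test_that("fan-beam rebinning recovers the direct parallel projection of a disk", {
  mu <- 0.02; r0 <- 30
  sid <- 400; sdd <- 700
  nfan <- 720; ndet <- 128
  gf <- projection_geometry("fan", ndet, detector_spacing = 1.2,
                            n_views_per_rotation = nfan,
                            source_to_detector = sdd,
                            source_to_isocenter = sid)
  th <- (seq_len(nfan) - 1) * 2 * pi / nfan
  gam <- (seq_len(ndet) - 1 - ndet %/% 2) * gf$detector_spacing / sdd
  # analytic fan sinogram of the centered disk: ray distance = sid * sin(gamma)
  tdist <- sid * sin(gam)
  ch <- numeric(ndet); inside <- abs(tdist) < r0
  ch[inside] <- 2 * mu * sqrt(r0^2 - tdist[inside]^2)
  fan <- sinogram(matrix(rep(ch, each = nfan), nfan, ndet), gf, th)

  par <- rebin_fan_to_parallel(fan)
  expect_equal(par$geometry$beam_type, "parallel")
  expect_equal(nrow(par$values), nfan / 2)   # 1152-style halving of views

  ref <- disk_sinogram(mu, r0, par$geometry)
  num <- sqrt(mean((par$values - ref$values)^2))
  expect_lt(num / max(ref$values), 0.01)
})

test_that("rebinning rejects partial rotations and non-fan input", {
  gf <- projection_geometry("fan", 32, 1, 360, source_to_detector = 700,
                            source_to_isocenter = 400)
  half <- sinogram(matrix(0, 180, 32), gf,
                   view_angles = (seq_len(180) - 1) * pi / 180)
  expect_error(rebin_fan_to_parallel(half), "full rotation")
  gp <- projection_geometry("parallel", 32, 1, 64)
  expect_error(rebin_fan_to_parallel(sinogram(matrix(0, 32, 32), gp)),
               "fan")
})
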