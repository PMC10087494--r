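test_that("gantry angle law matches the frame-number formula", {
  a <- gantry_angles(660, frame_rate = 11, rotation_speed = 6)
  expect_equal(a[1], 0)
  expect_equal(a[12], 6.0)                 # frame 12: (1/11)*6*11
  expect_equal(a[660], (1 / 11) * 6 * 659) # 359.4545...
  expect_error(gantry_angles(10, frame_rate = 0), "positive")
})

test_that("forward projector is linear with an exact adjoint (dense oracle)", {
  set.seed(11)
  dp <- fix_dense_projector()
  vol <- new_volume(array(rnorm(8^3), rep(8, 3)), rep(6, 3))

  # zero volume projects to zero
  z <- forward_project(new_volume(array(0, rep(8, 3)), rep(6, 3)), dp$geom,
                       dp$angles)
  expect_true(all(z$images == 0))

  # forward agrees with the dense operator (columns = projected unit voxels);
  # linearity follows
  px <- forward_project(vol, dp$geom, dp$angles)
  expect_equal(as.numeric(px$images),
               as.numeric(dp$A %*% as.numeric(vol$data)), tolerance = 1e-12)

  # adjoint identity <Ax, y> = <x, A^T y> and dense-transpose equivalence
  set.seed(12)
  y <- array(rnorm(10 * 10 * 2), c(10, 10, 2))
  ps <- px; ps$images <- y
  aty <- backproject(ps, vol)
  lhs <- sum(px$images * y); rhs <- sum(vol$data * aty$data)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-4)
  expect_equal(as.numeric(aty$data),
               as.numeric(crossprod(dp$A, as.numeric(y))), tolerance = 1e-10)
})

test_that("central ray integral equals attenuation times chord length", {
  mu <- 0.02
  cube <- new_volume(array(mu, rep(8, 3)), rep(6, 3))  # 48 mm cube
  geom <- scan_geometry(det_shape = c(16, 16), det_pitch = c(9, 9),
                        n_frames = 1)
  p <- forward_project(cube, geom, 0)
  # near-central pixels: ray crosses the full 48 mm thickness
  centre <- p$images[8:9, 8:9, 1]
  expect_equal(mean(centre), mu * 48, tolerance = 0.02)
})

test_that("single-view backprojection is confined to the ray corridor", {
  geom <- scan_geometry(det_shape = c(16, 16), det_pitch = c(12, 12),
                        n_frames = 1)
  img <- array(0, c(16, 16, 1)); img[8, 8, 1] <- 1
  tmpl <- new_volume(array(0, rep(16, 3)), rep(6, 3))
  ps <- forward_project(tmpl, geom, 0); ps$images <- img
  bp <- backproject(ps, tmpl)
  expect_true(sum(bp$data != 0) > 0)
  # the impulse ray at angle 0 runs along y at the detector-u offset:
  # nonzero voxels stay within a thin x/z corridor
  nz <- which(bp$data != 0, arr.ind = TRUE)
  expect_lt(diff(range(nz[, 1])), 5)
  expect_lt(diff(range(nz[, 3])), 5)
  z <- backproject(new_projection_set(img * 0, 0, 0, 1L, geom), tmpl)
  expect_true(all(z$data == 0))
})

test_that("FDK reconstructs the static phantom and degrades with limited angles", {
  fd <- fix_fdk_static()
  anat <- fd$anat
  expect_lte(fd$re_full, 0.15)

  # projections of a zero volume reconstruct to (numerical) zero
  zero <- fd$pset
  zero$images <- zero$images * 0
  rec0 <- fdk_reconstruct(subset_projections(zero, 1:64), anat$volume)
  expect_lt(max(abs(rec0$data)), 1e-6)

  # a 60-degree subset is strictly worse
  expect_gt(fd$re_sub, fd$re_full)

  # view-count consistency: error non-increasing over {16, 32, 64} views
  res <- vapply(c(16, 32, 64), function(nv) {
    idx <- round(seq(1, 660, length.out = nv))
    relative_error(fdk_reconstruct(subset_projections(fd$pset, idx),
                                   anat$volume), anat$volume)
  }, numeric(1))
  expect_true(all(diff(res) <= 1e-6))
})

test_that("Poisson projection noise is seeded, unbiased and vanishes at high dose", {
  fx <- fix_phantom32()
  anat <- build_reference_anatomy(fx$params)
  geom <- scaled_scan_geometry(det_n = 32, n_frames = 2)
  pset <- forward_project(anat$volume, geom)

  n1 <- add_poisson_noise(pset, 1e4, seed = 3)
  n2 <- add_poisson_noise(pset, 1e4, seed = 3)
  expect_identical(n1$images, n2$images)
  expect_error(add_poisson_noise(pset, -1), "positive")

  nh <- add_poisson_noise(pset, 1e9, seed = 3)
  expect_lt(max(abs(nh$images - pset$images)), 1e-2)

  # Monte-Carlo mean of one mid-object pixel matches the clean value
  clean <- pset$images[16, 16, 1]
  draws <- vapply(seq_len(1000), function(s) {
    add_poisson_noise(subset_projections(pset, 1), 1e4, seed = s)$images[16, 16, 1]
  }, numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - clean), 3 * se + 1e-4)
})

test_that("projection sets round-trip through TIFF + YAML", {
  fx <- fix_phantom32()
  anat <- build_reference_anatomy(fx$params)
  geom <- scaled_scan_geometry(det_n = 32, n_frames = 3)
  pset <- forward_project(anat$volume, geom)
  path <- file.path(tempdir(), "proj_roundtrip")
  write_projections(pset, path)
  back <- read_projections(path)
  expect_equal(back$angles_deg, pset$angles_deg)
  expect_equal(back$images, pset$images, tolerance = 1e-5)  # 32-bit storage
  expect_equal(back$geometry$sid, pset$geometry$sid)
})
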