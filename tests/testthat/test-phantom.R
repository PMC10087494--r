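test_that("reference anatomy voxelises the tumor at the expected size", {
  # 15 mm sphere at 3 mm spacing: ~(4/3) pi 5^3 = 524 voxels
  params <- anatomy_params(grid_shape = c(64, 64, 64))
  anat <- build_reference_anatomy(params)
  expect_equal(sum(anat$masks$tumor), 4 / 3 * pi * 5^3, tolerance = 0.10)

  # halved diameter (S7-style) scales the mask volume by ~1/8
  params_s7 <- anatomy_params(grid_shape = c(64, 64, 64), tumor_radius = 7.5)
  anat_s7 <- build_reference_anatomy(params_s7)
  expect_equal(sum(anat_s7$masks$tumor) / sum(anat$masks$tumor), 1 / 8,
               tolerance = 0.15)

  # air outside the body carries zero attenuation
  expect_true(all(anat$volume$data[!anat$masks$body] == 0))

  # attenuations stay inside the display range
  expect_true(all(anat$volume$data >= 0 & anat$volume$data <= 0.05))

  # deterministic
  anat2 <- build_reference_anatomy(params)
  expect_identical(anat$volume$data, anat2$volume$data)
})

test_that("a tumor outside the lung is rejected", {
  params <- anatomy_params(grid_shape = c(32, 32, 32),
                           tumor_center = c(0, 0, 0))
  expect_error(build_reference_anatomy(params), "inside a lung")
})

test_that("breathing tracks start at end-expiration and follow their closed forms", {
  for (sc in c("baseline", paste0("S", c(1, 3:6)))) {
    tr <- breathing_track(sc, n_frames = 660, frame_rate = 11)
    expect_equal(tr$signal_mm[1], 0, info = sc)
    expect_equal(nrow(tr), 660)
  }

  # the unmodified track is 5 s-periodic on the frame grid (55 frames/cycle)
  tr <- breathing_track("baseline", n_frames = 660, frame_rate = 11)
  expect_equal(tr$signal_mm[1:(660 - 55)], tr$signal_mm[56:660],
               tolerance = 1e-12)
  # surrogate is affine in c1
  expect_equal(tr$signal_mm, 12 * tr$c1)

  # the non-periodic scenario is a monotone excursion
  s6 <- breathing_track("S6", n_frames = 660, frame_rate = 11)
  expect_true(all(diff(s6$signal_mm) >= -1e-12))

  # baseline shifts step at mid-scan by their nominal size
  s1 <- breathing_track("S1", n_frames = 660, frame_rate = 11)
  base <- breathing_track("baseline", n_frames = 660, frame_rate = 11)
  expect_equal(s1$signal_mm[660] - base$signal_mm[660], 3)
  s2 <- breathing_track("S2", n_frames = 660, frame_rate = 11)
  expect_equal(s2$signal_mm[660] - base$signal_mm[660], 8)

  expect_error(breathing_track("S99"), "unknown scenario")
})

test_that("frame rendering matches direct warp oracles", {
  fx <- fix_phantom32()
  anat <- build_reference_anatomy(fx$params)

  # zero coefficients: identity warp
  fr0 <- render_frame(anat$volume, fx$basis, c(0, 0, 0), anat$masks$tumor)
  expect_equal(fr0$volume$data, anat$volume$data)
  expect_identical(fr0$tumor_mask, anat$masks$tumor)

  # pure SI translation of 9 mm = exactly 1.5 voxels at 6 mm spacing:
  # use a constant-field basis so the warp is a pure shift
  dims <- fx$params$grid_shape
  const_field <- array(0, c(dims, 3))
  const_field[, , , 3] <- 9
  tbasis <- structure(list(fields = list(const_field),
                           support = array(TRUE, dims), amplitudes = 9),
                      class = "motion_basis")
  fr <- render_frame(anat$volume, tbasis, 1, anat$masks$tumor)
  c0 <- mask_centroid_mm(anat$masks$tumor, fx$params$spacing)
  c1 <- mask_centroid_mm(fr$tumor_mask, fx$params$spacing)
  expect_equal(unname(abs(c1[3] - c0[3])), 9, tolerance = 0.15)
  expect_equal(c1[1:2], c0[1:2], tolerance = 1e-6)

  # two basis fields with disjoint supports compose like individual warps
  f1 <- array(0, c(dims, 3)); f1[1:12, , , 3] <- 6
  f2 <- array(0, c(dims, 3)); f2[20:32, , , 1] <- 6
  b2 <- structure(list(fields = list(f1, f2), support = array(TRUE, dims),
                       amplitudes = c(6, 6)), class = "motion_basis")
  both <- render_frame(anat$volume, b2, c(1, 1))$volume$data
  direct <- cpp_warp(anat$volume$data, dims, fx$params$spacing, f1 + f2)
  expect_equal(both, direct)
})

test_that("prior 4D set has the EE reference, peak-inhale ordering and in-span DVFs", {
  fx <- fix_phantom32()
  prior <- fx$prior
  expect_identical(prior$phases[[1]]$data, prior$reference$data)
  expect_equal(which.max(abs(prior$signal_mm)), 6)   # mid-cycle peak inhale

  # every inter-phase DVF is an exact linear combination of the basis fields
  for (p in c(1, 5, 9)) {
    cf <- prior$coeffs[p + 1, ]
    expected <- compose_basis_dvf(fx$basis, cf)
    expect_equal(prior$dvfs[[p]], expected)
  }
})

test_that("dynamic sequences follow the scan clock and scenario anatomy changes", {
  geom <- scan_geometry()
  expect_equal(geom$n_frames, 660)
  expect_equal(frame_times(geom$n_frames, geom$frame_rate)[2], 1 / 11)

  fx <- fix_phantom32()
  sc <- fix_scan_s1()
  expect_length(sc$seq_gt$frames, sc$geom$n_frames)
  # first frame (zero baseline, EE) equals the onboard reference
  expect_equal(sc$seq_gt$frames[[1]]$volume$data, sc$seq_gt$reference$data)

  # S8: onboard tumor shifted 6 mm per axis from the prior position
  geom_small <- scaled_scan_geometry(det_n = 16, n_frames = 4)
  s8 <- generate_dynamic_sequence("S8", fx$params, fx$basis, geom_small)
  prior_anat <- build_reference_anatomy(fx$params)
  d <- mask_centroid_mm(s8$tumor_mask, fx$params$spacing) -
    mask_centroid_mm(prior_anat$masks$tumor, fx$params$spacing)
  expect_true(all(abs(d - 6) <= fx$params$spacing))
})

test_that("ground-truth motion is low-rank and mask volume is conserved", {
  sc <- fix_scan_s1()
  idx <- seq(1, 110, by = 10)
  D <- vapply(sc$seq_gt$frames[idx],
              function(f) as.numeric(f$dvf), numeric(32^3 * 3))
  sv <- svd(D, nu = 0, nv = 0)$d
  expect_lt(sum(sv[-(1:3)]^2) / sum(sv^2), 1e-20)

  vols <- vapply(sc$seq_gt$frames[idx], function(f) sum(f$tumor_mask),
                 numeric(1))
  ref_vol <- sum(sc$seq_gt$tumor_mask)
  expect_true(all(abs(vols / ref_vol - 1) <= 0.2))
})
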