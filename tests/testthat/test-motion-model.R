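test_that("bypass registration returns the ground-truth fields", {
  fx <- fix_phantom32()
  dvfs <- register_phases(fx$prior$reference, fx$prior$phases[-1],
                          method = "bypass", gt_dvfs = fx$prior$dvfs,
                          perturb_sd = 0)
  expect_identical(dvfs, fx$prior$dvfs)

  # seeded perturbation is reproducible and bounded
  d1 <- register_phases(fx$prior$reference, fx$prior$phases[-1],
                        method = "bypass", gt_dvfs = fx$prior$dvfs,
                        perturb_sd = 0.5, seed = 2)
  d2 <- register_phases(fx$prior$reference, fx$prior$phases[-1],
                        method = "bypass", gt_dvfs = fx$prior$dvfs,
                        perturb_sd = 0.5, seed = 2)
  expect_identical(d1, d2)
  expect_false(identical(d1, fx$prior$dvfs))
})

test_that("demons registration recovers small known displacements", {
  # a smooth blob, registered to itself: negligible displacement
  vol <- smooth_random_volume(16, seed = 21)
  d_self <- register_phases(vol, list(vol), method = "demons",
                            iterations = 15)[[1]]
  expect_lt(max(abs(d_self)), 0.1 * min(vol$spacing))

  # a known 2-voxel SI translation is recovered within half a voxel where
  # the image has gradient support
  sp <- vol$spacing
  shift <- array(0, c(dim(vol$data), 3)); shift[, , , 3] <- 2 * sp[3]
  moved <- warp_volume(vol, shift)
  d_hat <- register_phases(vol, list(moved), method = "demons",
                           iterations = 40)[[1]]
  g <- abs(vol$data - mean(vol$data)) > stats::sd(vol$data)
  core <- array(FALSE, dim(vol$data)); core[4:13, 4:13, 4:13] <- TRUE
  sel <- g & core
  expect_lt(abs(mean(d_hat[, , , 3][sel]) - 2 * sp[3]), 0.5 * sp[3])
})

test_that("the PCA model reproduces its defining identities", {
  fx <- fix_phantom32()
  model <- fix_model32()

  # the DC component is the arithmetic mean of the training fields
  manual_mean <- Reduce(`+`, fx$prior$dvfs) / length(fx$prior$dvfs)
  expect_equal(array(model$pc0, c(model$dims, 3)), manual_mean)

  # rank-3 planted motion: top-3 explained variance per direction
  expect_true(all(model$explained_variance[, 3] >= 0.999))
  # explained variance is monotone in the number of components
  expect_true(all(diff(t(model$explained_variance)) >= -1e-12))

  # orthogonality of the per-direction components (before/after scaling)
  for (dim_i in 1:3) {
    P <- model$pcs[, dim_i, ]
    G <- crossprod(P)
    offdiag <- G - diag(diag(G))
    expect_lt(max(abs(offdiag)), 1e-9 * max(diag(G)))
  }

  expect_error(build_pca_model(fx$prior$dvfs[1:3], n_comp = 3), "at least")
})

test_that("composition and projection invert each other on in-span fields", {
  fx <- fix_phantom32()
  model <- fix_model32()

  # zero weights give the mean field
  expect_equal(compose_dvf(model, rep(0, 9)),
               array(model$pc0, c(model$dims, 3)))

  # linearity: compose(w1) + compose(w2) - PC0 = compose(w1 + w2)
  set.seed(8)
  w1 <- rnorm(9); w2 <- rnorm(9)
  lhs <- compose_dvf(model, w1) + compose_dvf(model, w2) -
    array(model$pc0, c(model$dims, 3))
  expect_equal(lhs, compose_dvf(model, w1 + w2), tolerance = 1e-12)

  # sign-flip invariance: flipping one component and its weight is a no-op
  m2 <- model
  m2$pcs[, 3, 1] <- -m2$pcs[, 3, 1]
  wf <- w1; wf[7] <- -wf[7]
  expect_equal(compose_dvf(m2, wf), compose_dvf(model, w1), tolerance = 1e-12)

  # projection closed forms
  expect_equal(project_dvf_to_weights(model, array(model$pc0,
                                                   c(model$dims, 3))),
               rep(0, 9))
  planted <- array(model$pc0, c(model$dims, 3))
  planted[, , , 3] <- planted[, , , 3] + 2 * array(model$pcs[, 3, 1], model$dims)
  wp <- project_dvf_to_weights(model, planted)
  expect_equal(wp[7], 2, tolerance = 1e-9)
  expect_equal(wp[-7], rep(0, 8), tolerance = 1e-9)

  # idempotence and training-field round trip
  d <- fx$prior$dvfs[[6]]
  w <- project_dvf_to_weights(model, d)
  expect_equal(project_dvf_to_weights(model, compose_dvf(model, w)), w,
               tolerance = 1e-9)
  rel <- sqrt(sum((compose_dvf(model, w) - d)^2) / sum(d^2))
  expect_lte(rel, 1e-3)
})

test_that("ground-truth per-frame weights exist for rank-covered scan motion", {
  # the premise that makes joint reconstruction well-posed: every intra-scan
  # deformation is exactly representable by the prior-built model
  model <- fix_model32()
  sc <- fix_scan_s1()
  for (i in c(5, 40, 87)) {
    d <- sc$seq_gt$frames[[i]]$dvf
    w <- project_dvf_to_weights(model, d)
    rms_mm <- sqrt(mean((compose_dvf(model, w) - d)^2))
    expect_lt(rms_mm, 1e-8)
  }
})

test_that("motion models survive disk round trips and resampling", {
  model <- fix_model32()
  dir <- file.path(tempdir(), "mm_roundtrip")
  write_motion_model(model, dir)
  back <- read_motion_model(dir)
  expect_equal(back$pc0, model$pc0, tolerance = 1e-6)
  expect_equal(back$pcs, model$pcs, tolerance = 1e-6)

  small <- resample_motion_model(model, c(16, 16, 16))
  expect_equal(small$dims, c(16L, 16L, 16L))
  # resampling preserves the large-scale structure of the mean field
  big_again <- resample_motion_model(small, c(32, 32, 32))
  expect_gt(cor(big_again$pc0[, 3], model$pc0[, 3]), 0.97)
})
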