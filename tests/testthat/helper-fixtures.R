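# Shared fixtures, built once per test session and memoised. All fixtures are
# generated in code; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 32^3 thorax phantom with motion basis and prior 4D set
fix_phantom32 <- function() {
  memo("phantom32", function() {
    params <- anatomy_params(grid_shape = c(32, 32, 32))
    basis <- motion_basis(params)
    prior <- generate_prior_4dct(params, basis)
    list(params = params, basis = basis, prior = prior)
  })
}

# bypass-registration PCA motion model on the 32^3 grid
fix_model32 <- function() {
  memo("model32", function() {
    fx <- fix_phantom32()
    dvfs <- register_phases(fx$prior$reference, fx$prior$phases[-1],
                            method = "bypass", gt_dvfs = fx$prior$dvfs)
    build_pca_model(dvfs, n_comp = 3, spacing = fx$params$spacing,
                    signal = fx$prior$signal_mm[-1])
  })
}

# scaled S1 dynamic scan (110 frames over a full rotation) + projections
fix_scan_s1 <- function() {
  memo("scan_s1", function() {
    fx <- fix_phantom32()
    geom <- scaled_scan_geometry(det_n = 64, n_frames = 110)
    seq_gt <- generate_dynamic_sequence("S1", fx$params, fx$basis, geom)
    pset <- project_dynamic_sequence(seq_gt, geom)
    list(geom = geom, seq_gt = seq_gt, pset = pset)
  })
}

# dense matrix of the projector on an 8^3 grid (columns = projected unit
# voxels), shared by the operator-oracle tests
fix_dense_projector <- function() {
  memo("dense_projector", function() {
    geom <- scan_geometry(det_shape = c(10, 10), det_pitch = c(14, 14),
                          n_frames = 2)
    angles <- c(33, 208)
    nvox <- 8^3
    A <- matrix(0, 10 * 10 * 2, nvox)
    for (i in seq_len(nvox)) {
      e <- array(0, rep(8, 3)); e[i] <- 1
      A[, i] <- as.numeric(forward_project(new_volume(e, rep(6, 3)), geom,
                                           angles)$images)
    }
    list(A = A, geom = geom, angles = angles)
  })
}

# static-phantom full-scan projections + full/limited-angle FDK errors,
# shared by the geometry tests and the acceptance suite
fix_fdk_static <- function() {
  memo("fdk_static", function() {
    fx <- fix_phantom32()
    anat <- build_reference_anatomy(fx$params)
    geom <- scaled_scan_geometry(det_n = 128, n_frames = 660)
    pset <- forward_project(anat$volume, geom)
    rec_full <- fdk_reconstruct(pset, anat$volume)
    sub <- subset_projections(pset, which(pset$angles_deg <= 60))
    rec_sub <- fdk_reconstruct(sub, anat$volume)
    list(anat = anat, pset = pset,
         re_full = relative_error(rec_full, anat$volume),
         re_sub = relative_error(rec_sub, anat$volume))
  })
}

# a small smooth random volume for capacity tests
smooth_random_volume <- function(n = 16, seed = 4) {
  set.seed(seed)
  arr <- array(rnorm(n^3), rep(n, 3))
  arr <- cpp_gauss_smooth(arr, rep(n, 3), rep(2, 3))
  new_volume(arr / max(abs(arr)) * 0.02, rep(96 / n, 3))
}
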