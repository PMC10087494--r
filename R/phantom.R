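#' Parametric thorax anatomy parameters
#'
#' Describes the synthetic thorax used by the dynamic-scan simulator: a body
#' ellipsoid of soft tissue, two lung ellipsoids, a spherical tumor inside the
#' right lung, a bony spine cylinder and a heart ellipsoid. Attenuations are
#' chosen inside the conventional CBCT display range [0, 0.05] mm^-1:
#' air 0, lung 0.005, soft tissue 0.020, tumor 0.028, bone 0.045.
#'
#' @param grid_shape voxels per axis (default 64^3).
#' @param spacing mm per voxel; defaults to a 192 mm field of view
#'   (`192 / grid_shape`), i.e. 3 mm at 64^3.
#' @param tumor_center mm, world coordinates (must place the sphere strictly
#'   inside a lung).
#' @param tumor_radius mm (default 15, a 30 mm diameter lesion).
#' @param attenuation named attenuation table (mm^-1).
#' @return An `anatomy_params` list.
#' @export
anatomy_params <- function(grid_shape = c(64, 64, 64), spacing = NULL,
                           tumor_center = c(45, 0, -15), tumor_radius = 15,
                           attenuation = c(air = 0, lung = 0.005,
                                           soft = 0.020, tumor = 0.028,
                                           bone = 0.045)) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(all(grid_shape > 0))
  if (is.null(spacing)) spacing <- 192 / grid_shape
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(all(spacing > 0), tumor_radius > 0, all(attenuation >= 0),
            all(attenuation <= 0.05))
  structure(
    list(grid_shape = grid_shape, spacing = as.numeric(spacing),
         tumor_center = as.numeric(tumor_center), tumor_radius = tumor_radius,
         attenuation = attenuation,
         body = list(center = c(0, 0, 0), semi = c(85, 70, 92)),
         lungs = list(
           right = list(center = c(42, 0, 10), semi = c(30, 38, 55)),
           left  = list(center = c(-42, 0, 10), semi = c(30, 38, 55))
         ),
         heart = list(center = c(-12, 8, 10), semi = c(26, 26, 32)),
         spine = list(center_xy = c(0, 48), radius = 13)),
    class = "anatomy_params"
  )
}

inside_ellipsoid <- function(xyz, center, semi) {
  rowSums(sweep(sweep(xyz, 2, center, "-"), 2, semi, "/")^2) <= 1
}

#' Build the reference thorax anatomy
#'
#' Voxelises the parametric thorax into an attenuation volume plus per-tissue
#' boolean masks. Deterministic given the parameters. The tumor sphere must be
#' strictly inside a lung ellipsoid.
#'
#' @param params an [anatomy_params()] list.
#' @return A list with `volume` (a `stinr_volume`) and `masks` (logical arrays
#'   `body`, `lung`, `heart`, `spine`, `tumor`).
#' @export
build_reference_anatomy <- function(params) {
  # analytic containment check: sample the tumor sphere surface
  th <- seq(0, pi, length.out = 13); ph <- seq(0, 2 * pi, length.out = 25)
  sph <- as.matrix(expand.grid(th = th, ph = ph))
  surf <- cbind(sin(sph[, 1]) * cos(sph[, 2]),
                sin(sph[, 1]) * sin(sph[, 2]),
                cos(sph[, 1])) * params$tumor_radius
  surf <- sweep(surf, 2, params$tumor_center, "+")
  in_lung <- inside_ellipsoid(surf, params$lungs$right$center, params$lungs$right$semi) |
    inside_ellipsoid(surf, params$lungs$left$center, params$lungs$left$semi)
  if (!all(in_lung)) stop("tumor sphere is not strictly inside a lung")

  vol <- new_volume(array(0, params$grid_shape), params$spacing)
  xyz <- voxel_coordinates(vol)
  att <- params$attenuation
  body <- inside_ellipsoid(xyz, params$body$center, params$body$semi)
  lung <- (inside_ellipsoid(xyz, params$lungs$right$center, params$lungs$right$semi) |
           inside_ellipsoid(xyz, params$lungs$left$center, params$lungs$left$semi)) & body
  heart <- inside_ellipsoid(xyz, params$heart$center, params$heart$semi) & body
  spine <- (rowSums(sweep(xyz[, 1:2, drop = FALSE], 2,
                          params$spine$center_xy, "-")^2) <=
            params$spine$radius^2) & body
  tumor <- rowSums(sweep(xyz, 2, params$tumor_center, "-")^2) <=
    params$tumor_radius^2

  a <- numeric(nrow(xyz))
  a[body] <- att[["soft"]]
  a[lung] <- att[["lung"]]
  a[heart & !lung] <- att[["soft"]]
  a[spine] <- att[["bone"]]
  a[tumor] <- att[["tumor"]]
  vol$data <- array(a, params$grid_shape)
  shape <- function(m) array(m, params$grid_shape)
  list(volume = vol,
       masks = list(body = shape(body), lung = shape(lung & !tumor),
                    heart = shape(heart), spine = shape(spine),
                    tumor = shape(tumor)))
}

#' Low-rank respiratory motion basis
#'
#' Three smooth, linearly independent displacement basis fields (mm) on the
#' reference grid. The dominant field is a superior-inferior diaphragm-driven
#' displacement (12 mm at its peak); the second is a smaller anterior-posterior
#' chest-wall expansion; the third a weaker secondary mode with a different
#' spatial envelope. All fields vanish on the spine and outside the body, so
#' the bony anatomy stays static. Every simulated deformation is a linear
#' combination `D(x, t) = sum_k c_k(t) b_k(x)`, so ground-truth motion is
#' rank-3 by construction and exactly representable by a 3-component PCA
#' motion model.
#'
#' @param params an [anatomy_params()] list.
#' @param amplitudes mm peak amplitude of each basis field.
#' @return A `motion_basis` object: list of fields (each an array
#'   `c(grid_shape, 3)`, mm) plus the support mask.
#' @export
motion_basis <- function(params, amplitudes = c(12, 3, 2)) {
  vol <- new_volume(array(0, params$grid_shape), params$spacing)
  xyz <- voxel_coordinates(vol)
  body <- inside_ellipsoid(xyz, params$body$center, params$body$semi * 0.98)
  spine <- rowSums(sweep(xyz[, 1:2, drop = FALSE], 2,
                         params$spine$center_xy, "-")^2) <=
    (params$spine$radius + 6)^2
  support <- body & !spine

  env1 <- exp(-(xyz[, 1] / 75)^2 - (xyz[, 2] / 70)^2 - ((xyz[, 3] + 35) / 60)^2)
  env2 <- exp(-(xyz[, 1] / 70)^2 - ((xyz[, 2] + 20) / 55)^2 - (xyz[, 3] / 70)^2)
  env3 <- exp(-((xyz[, 1] - 25) / 55)^2 - (xyz[, 2] / 60)^2 - ((xyz[, 3] - 10) / 80)^2)

  n <- nrow(xyz)
  field <- function(ex, ey, ez) {
    f <- cbind(ex, ey, ez) * support
    array(f, c(params$grid_shape, 3))
  }
  b1 <- field(numeric(n), numeric(n), amplitudes[1] * env1)
  b2 <- field(0.3 * amplitudes[2] * env2, amplitudes[2] * env2, numeric(n))
  b3 <- field(0.4 * amplitudes[3] * env3, numeric(n), amplitudes[3] * env3)
  structure(list(fields = list(b1, b2, b3), support = array(support, params$grid_shape),
                 amplitudes = amplitudes),
            class = "motion_basis")
}

#' Scenario breathing coefficient tracks
#'
#' Closed-form coefficient tracks `c_k(t)` for the motion basis, sampled on the
#' projection frame grid. The baseline pattern is a 5 s-period breathing cycle
#' `c1 = (1 - cos(2 pi t / 5)) / 2` starting at end-expiration (c1(0) = 0); the
#' second and third coefficients are phase-lagged and second-harmonic
#' companions so the three tracks are linearly independent. Scenario variants:
#'
#' * `S1`: +3 mm superior baseline step at mid-scan.
#' * `S2`: +8 mm baseline step at mid-scan.
#' * `S3`: breathing period changed from 5 s (prior) to 3.5 s.
#' * `S4`: amplitude modulated +/-30 % plus a 3 mm linear baseline drift.
#' * `S5`: simultaneous amplitude (+/-30 %) and period (5 +/- 1 s) modulation.
#' * `S6`: a single slow monotone excursion (non-periodic motion).
#' * `S7`, `S8`: the S1 track (the anatomy, not the motion, changes).
#'
#' The scalar surrogate `signal_mm` is the peak diaphragm SI displacement,
#' affine in `c1` (12 mm per unit).
#'
#' @param scenario one of `"S1" ... "S8"` (or `"baseline"` for the unmodified
#'   periodic track).
#' @param n_frames number of frames.
#' @param frame_rate frames/s (frame spacing `1/frame_rate` s).
#' @param si_amplitude_mm mm of diaphragm displacement per unit `c1`.
#' @return A tibble with columns `frame`, `time_s`, `c1`, `c2`, `c3`,
#'   `signal_mm`, `scenario`.
#' @export
breathing_track <- function(scenario = "S1", n_frames = 660, frame_rate = 11,
                            si_amplitude_mm = 12) {
  scenarios <- c("baseline", paste0("S", 1:8))
  if (!scenario %in% scenarios) {
    stop("unknown scenario id: ", scenario)
  }
  stopifnot(n_frames >= 1)
  t <- (seq_len(n_frames) - 1) / frame_rate
  dur <- max(t[n_frames], 1)
  amp <- rep(1, n_frames)
  drift <- rep(0, n_frames)
  theta <- 2 * pi * t / 5
  if (scenario == "S3") theta <- 2 * pi * t / 3.5
  if (scenario %in% c("S1", "S7", "S8")) drift <- ifelse(t >= dur / 2, 3 / si_amplitude_mm, 0)
  if (scenario == "S2") drift <- ifelse(t >= dur / 2, 8 / si_amplitude_mm, 0)
  if (scenario == "S4") {
    amp <- 1 + 0.3 * sin(2 * pi * t / dur)
    drift <- (3 / si_amplitude_mm) * t / dur
  }
  if (scenario == "S5") {
    amp <- 1 + 0.3 * sin(2 * pi * t / dur)
    period <- 5 + sin(2 * pi * t / dur)          # 5 +/- 1 s
    inst_freq <- 1 / period
    dt <- c(0, diff(t))
    theta <- 2 * pi * cumsum(inst_freq * dt)
  }
  if (scenario == "S6") theta <- pi * t / dur
  g <- function(th) (1 - cos(th)) / 2
  scale6 <- if (scenario == "S6") 0.8 else 1
  c1 <- scale6 * amp * g(theta) + drift
  c2 <- 0.5 * amp * (g(theta - 0.6) - g(-0.6))
  c3 <- 0.2 * amp * sin(theta)^2
  tibble::tibble(
    frame = seq_len(n_frames), time_s = t,
    c1 = c1, c2 = c2, c3 = c3,
    signal_mm = si_amplitude_mm * c1,
    scenario = scenario
  )
}

compose_basis_dvf <- function(basis, coeffs) {
  stopifnot(length(coeffs) == length(basis$fields))
  d <- basis$fields[[1]] * coeffs[1]
  for (k in seq_along(basis$fields)[-1]) d <- d + basis$fields[[k]] * coeffs[k]
  d
}

warp_mask <- function(mask, spacing, dvf) {
  ind <- cpp_warp(array(as.numeric(mask), dim(mask)), dim(mask), spacing, dvf)
  array(ind >= 0.5, dim(mask))
}

#' Render one ground-truth dynamic frame
#'
#' Backward-warps the reference anatomy by `D(x) = sum_k c_k b_k(x)` (pull-back
#' convention: the frame at `x` samples the reference at `x + D(x)` by
#' trilinear interpolation) and propagates the tumor mask the same way.
#'
#' @param reference a `stinr_volume` reference anatomy.
#' @param basis a [motion_basis()].
#' @param coeffs numeric coefficients, one per basis field.
#' @param tumor_mask logical array on the reference grid.
#' @param time_s frame timestamp.
#' @return A `gt_frame` list: `volume`, `dvf` (array `c(dims, 3)`, mm),
#'   `tumor_mask`, `time_s`.
#' @export
render_frame <- function(reference, basis, coeffs, tumor_mask = NULL,
                         time_s = NA_real_) {
  dvf <- compose_basis_dvf(basis, coeffs)
  arr <- cpp_warp(reference$data, dim(reference$data), reference$spacing, dvf)
  out <- list(volume = new_volume(arr, reference$spacing, reference$origin),
              dvf = dvf, time_s = time_s)
  if (!is.null(tumor_mask)) {
    out$tumor_mask <- warp_mask(tumor_mask, reference$spacing, dvf)
    if (!any(out$tumor_mask)) stop("propagated tumor mask is empty")
  }
  structure(out, class = "gt_frame")
}

#' Generate the prior 10-phase 4D volume set
#'
#' Samples the baseline 5 s breathing cycle at 10 equispaced phase points.
#' Phase 1 (end-expiration, all coefficients zero) equals the reference
#' anatomy; the 9 inter-phase deformation fields map the EE phase to each other
#' phase and lie exactly in the span of the motion basis.
#'
#' @param params an [anatomy_params()].
#' @param basis a [motion_basis()].
#' @param si_amplitude_mm surrogate scaling (mm per unit `c1`).
#' @return A list: `phases` (10 `stinr_volume`s), `dvfs` (9 arrays, EE to each
#'   non-EE phase), `coeffs` (10 x 3 matrix), `signal_mm` (length 10),
#'   `reference`, `tumor_mask`, `masks`.
#' @export
generate_prior_4dct <- function(params, basis, si_amplitude_mm = 12) {
  anat <- build_reference_anatomy(params)
  ph <- (0:9) / 10
  theta <- 2 * pi * ph
  g <- function(th) (1 - cos(th)) / 2
  coeffs <- cbind(c1 = g(theta),
                  c2 = 0.5 * (g(theta - 0.6) - g(-0.6)),
                  c3 = 0.2 * sin(theta)^2)
  phases <- vector("list", 10)
  dvfs <- vector("list", 9)
  phases[[1]] <- anat$volume
  for (p in 2:10) {
    fr <- render_frame(anat$volume, basis, coeffs[p, ])
    phases[[p]] <- fr$volume
    dvfs[[p - 1]] <- fr$dvf
  }
  list(phases = phases, dvfs = dvfs, coeffs = coeffs,
       signal_mm = si_amplitude_mm * coeffs[, 1],
       reference = anat$volume, tumor_mask = anat$masks$tumor,
       masks = anat$masks)
}

scenario_params <- function(params, scenario) {
  if (scenario == "S7") params$tumor_radius <- params$tumor_radius / 2
  if (scenario == "S8") params$tumor_center <- params$tumor_center + c(6, 6, 6)
  params
}

#' Generate the ground-truth dynamic scan sequence
#'
#' One ground-truth frame per projection time: the onboard reference anatomy
#' (equal to the prior anatomy except for the inter-scan changes of scenarios
#' S7/S8) warped by the scenario's coefficient track. Each frame carries its
#' volume, its pull-back deformation field, the propagated tumor mask and its
#' timestamp.
#'
#' @param scenario scenario id (`"S1" ... "S8"`).
#' @param params prior [anatomy_params()].
#' @param basis a [motion_basis()].
#' @param geometry a `stinr_geometry` (frame count/rate taken from it).
#' @param si_amplitude_mm surrogate scaling.
#' @return A list: `frames` (list of `gt_frame`), `track` (tibble),
#'   `reference` (onboard reference `stinr_volume`), `tumor_mask` (onboard
#'   reference tumor mask), `masks`, `params_onboard`.
#' @export
generate_dynamic_sequence <- function(scenario, params, basis, geometry,
                                      si_amplitude_mm = 12) {
  track <- breathing_track(scenario, geometry$n_frames, geometry$frame_rate,
                           si_amplitude_mm)
  params_ob <- scenario_params(params, scenario)
  anat <- build_reference_anatomy(params_ob)
  cm <- as.matrix(track[, c("c1", "c2", "c3")])
  frames <- lapply(seq_len(nrow(cm)), function(i) {
    render_frame(anat$volume, basis, cm[i, ], anat$masks$tumor,
                 time_s = track$time_s[i])
  })
  list(frames = frames, track = track, reference = anat$volume,
       tumor_mask = anat$masks$tumor, masks = anat$masks,
       params_onboard = params_ob)
}

#' Forward-project a ground-truth dynamic sequence
#'
#' Simulates the cone-beam scan of a moving anatomy: frame `N` of the sequence
#' is projected at gantry angle `alpha_N` only, producing one projection per
#' frame.
#'
#' @param seq_gt result of [generate_dynamic_sequence()].
#' @param geometry a `stinr_geometry`.
#' @param step ray sampling step (mm).
#' @return A `stinr_projections` with one view per frame.
#' @export
project_dynamic_sequence <- function(seq_gt, geometry, step = NULL) {
  angles <- gantry_angles(geometry$n_frames, geometry$frame_rate,
                          geometry$rotation_speed)
  vol1 <- seq_gt$frames[[1]]$volume
  if (is.null(step)) step <- default_ray_step(vol1)
  imgs <- array(0, c(geometry$det_shape, geometry$n_frames))
  for (i in seq_len(geometry$n_frames)) {
    p <- cpp_forward_project(seq_gt$frames[[i]]$volume$data, dim(vol1$data),
                             vol1$spacing, vol1$origin, angles[i] * pi / 180,
                             geometry$det_shape[1], geometry$det_shape[2],
                             geometry$det_pitch[1], geometry$det_pitch[2],
                             geometry$sid, geometry$sdd, step)
    imgs[, , i] <- p[, , 1]
  }
  new_projection_set(imgs, angles, seq_gt$track$time_s,
                     seq_len(geometry$n_frames), geometry)
}
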