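#' Cone-beam scan geometry
#'
#' Full-fan circular cone-beam geometry rotating about the superior-inferior
#' axis. Defaults follow a standard clinical thorax protocol: 1000 mm
#' source-to-isocentre, 1500 mm source-to-detector, a 512 x 512 flat panel with
#' 1.17 mm pixels, 6 deg/s rotation at 11 frames/s, 660 projections over 360
#' degrees (a 60 s scan).
#'
#' @param sid source-to-isocentre distance (mm).
#' @param sdd source-to-detector distance (mm).
#' @param det_shape detector pixels `c(nu, nv)`; `u` is in the rotation plane,
#'   `v` along the rotation axis.
#' @param det_pitch pixel pitch `c(pu, pv)` in mm.
#' @param rotation_speed gantry speed (deg/s).
#' @param frame_rate projection frame rate (frames/s).
#' @param n_frames number of projections in the scan.
#' @return A `stinr_geometry` list.
#' @export
scan_geometry <- function(sid = 1000, sdd = 1500,
                          det_shape = c(512, 512), det_pitch = c(1.17, 1.17),
                          rotation_speed = 6, frame_rate = 11, n_frames = 660) {
  stopifnot(sdd > sid, sid > 0, all(det_pitch > 0), all(det_shape >= 1))
  if (rotation_speed <= 0 || frame_rate <= 0) {
    stop("rotation_speed and frame_rate must be positive")
  }
  structure(
    list(sid = sid, sdd = sdd,
         det_shape = as.integer(det_shape), det_pitch = as.numeric(det_pitch),
         rotation_speed = rotation_speed, frame_rate = frame_rate,
         n_frames = as.integer(n_frames)),
    class = "stinr_geometry"
  )
}

#' Desk-scale scan geometry
#'
#' A scaled-down full-rotation scan: the scan still covers 360 degrees in 60 s
#' at 6 deg/s, but with fewer frames (lower frame rate) and a coarser detector.
#' The panel is sized to the simulated 192 mm field of view (300 mm wide, which
#' covers the magnified thorax with margin) rather than to a full clinical
#' panel, so detector sampling stays commensurate with the voxel grid.
#'
#' @param det_n detector pixels per side.
#' @param n_frames number of projections over the 60 s scan.
#' @param panel_mm physical panel width (mm); pitch is `panel_mm / det_n`.
#' @inheritParams scan_geometry
#' @return A `stinr_geometry`.
#' @export
scaled_scan_geometry <- function(det_n = 64, n_frames = 220,
                                 rotation_speed = 6, panel_mm = 300) {
  duration <- 360 / rotation_speed
  scan_geometry(det_shape = c(det_n, det_n),
                det_pitch = rep(panel_mm / det_n, 2),
                rotation_speed = rotation_speed,
                frame_rate = n_frames / duration,
                n_frames = n_frames)
}

#' Gantry angle of each projection frame
#'
#' The angle of frame `N` is `(rotation_speed / frame_rate) * (N - 1)` degrees:
#' the gantry rotates continuously while projections are read out at a fixed
#' frame rate, and the first frame is acquired at 0 degrees.
#'
#' @param n_frames number of frames.
#' @param frame_rate frames/s.
#' @param rotation_speed deg/s.
#' @return Numeric vector of angles in degrees.
#' @export
gantry_angles <- function(n_frames, frame_rate = 11, rotation_speed = 6) {
  stopifnot(n_frames >= 1)
  if (frame_rate <= 0 || rotation_speed <= 0) {
    stop("frame_rate and rotation_speed must be positive")
  }
  (1 / frame_rate) * rotation_speed * (seq_len(n_frames) - 1)
}

#' Projection-frame timestamps
#' @inheritParams gantry_angles
#' @return Numeric vector of acquisition times (s), starting at 0.
#' @export
frame_times <- function(n_frames, frame_rate = 11) {
  (seq_len(n_frames) - 1) / frame_rate
}

new_projection_set <- function(images, angles_deg, times_s, frame_index, geometry) {
  structure(
    list(images = images, angles_deg = angles_deg, times_s = times_s,
         frame_index = as.integer(frame_index), geometry = geometry),
    class = "stinr_projections"
  )
}

#' @export
print.stinr_projections <- function(x, ...) {
  cat("<stinr_projections> ", dim(x$images)[3], " views of ",
      dim(x$images)[1], " x ", dim(x$images)[2], " pixels, angles [",
      signif(min(x$angles_deg), 4), ", ", signif(max(x$angles_deg), 4),
      "] deg\n", sep = "")
  invisible(x)
}

default_ray_step <- function(vol) min(vol$spacing) / 2

#' Forward projection (cone-beam line integrals)
#'
#' Ray-driven projector: each detector pixel value is the line integral of the
#' attenuation along the source-to-pixel ray (units mm^-1 * mm), computed by
#' trilinear sampling at a fixed step of half the smallest voxel spacing. The
#' operator is linear in the volume and `backproject()` is its exact adjoint.
#'
#' @param vol a `stinr_volume`.
#' @param geometry a `stinr_geometry`.
#' @param angles_deg gantry angles (degrees); defaults to the geometry's frame
#'   schedule.
#' @param times_s,frame_index optional per-view metadata.
#' @param step ray sampling step (mm).
#' @return A `stinr_projections` object.
#' @export
forward_project <- function(vol, geometry, angles_deg = NULL,
                            times_s = NULL, frame_index = NULL, step = NULL) {
  if (is.null(angles_deg)) {
    angles_deg <- gantry_angles(geometry$n_frames, geometry$frame_rate,
                                geometry$rotation_speed)
  }
  stopifnot(all(is.finite(angles_deg)))
  if (is.null(step)) step <- default_ray_step(vol)
  half_extent <- max(abs(c(vol$origin, vol$origin + (dim(vol$data) - 1) * vol$spacing)))
  fov <- geometry$sid * geometry$det_shape[1] * geometry$det_pitch[1] /
    (2 * geometry$sdd)
  if (half_extent > fov * 1.5) {
    warning("volume extends well beyond the reconstructible field of view")
  }
  imgs <- cpp_forward_project(vol$data, dim(vol$data), vol$spacing, vol$origin,
                              angles_deg * pi / 180,
                              geometry$det_shape[1], geometry$det_shape[2],
                              geometry$det_pitch[1], geometry$det_pitch[2],
                              geometry$sid, geometry$sdd, step)
  if (is.null(times_s)) times_s <- frame_times(length(angles_deg), geometry$frame_rate)
  if (is.null(frame_index)) frame_index <- seq_along(angles_deg)
  new_projection_set(imgs, angles_deg, times_s, frame_index, geometry)
}

#' Adjoint of the forward projector
#'
#' The exact transpose of `forward_project()` on the same discretisation (same
#' ray traversal with gather replaced by scatter), as required for algebraic
#' reconstruction and gradient-based fitting.
#'
#' @param pset a `stinr_projections` object (or a plain image array with
#'   matching geometry passed via `geometry`/`angles_deg`).
#' @param template a `stinr_volume` defining the target grid.
#' @param step ray sampling step (mm); must match the forward pass for a true
#'   adjoint pair.
#' @return A `stinr_volume`.
#' @export
backproject <- function(pset, template, step = NULL) {
  g <- pset$geometry
  if (any(dim(pset$images)[1:2] != g$det_shape)) {
    stop("projection images do not match the stated detector shape")
  }
  if (is.null(step)) step <- default_ray_step(template)
  arr <- cpp_backproject(pset$images, dim(template$data), template$spacing,
                         template$origin, pset$angles_deg * pi / 180,
                         g$det_shape[1], g$det_shape[2],
                         g$det_pitch[1], g$det_pitch[2], g$sid, g$sdd, step)
  new_volume(arr, template$spacing, template$origin)
}

ramp_filter_response <- function(nfft, pitch) {
  # spatial-domain band-limited ramp kernel (Kak & Slaney), FFT'd to get the
  # exact discrete frequency response, then apodised with a raised cosine
  h <- numeric(nfft)
  k <- c(0:(nfft / 2 - 1), -(nfft / 2):-1)
  h[k == 0] <- 1 / (4 * pitch^2)
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi * k[odd] * pitch)^2
  H <- Re(stats::fft(h))
  f <- seq(0, nfft - 1) / nfft
  f <- ifelse(f > 0.5, 1 - f, f)        # cycles/sample, folded
  window <- 0.5 * (1 + cos(pi * f / 0.5))
  H * window
}

#' FDK reconstruction
#'
#' Feldkamp-Davis-Kress filtered backprojection for a circular full-fan scan:
#' cosine weighting, ramp filtering along the detector rows (raised-cosine
#' apodisation), and distance-weighted voxel-driven backprojection. Full-scan
#' (360 degree) weighting is assumed.
#'
#' @param pset a `stinr_projections` object with at least 2 views.
#' @param template a `stinr_volume` defining the reconstruction grid.
#' @return A `stinr_volume` of attenuation coefficients (mm^-1).
#' @export
fdk_reconstruct <- function(pset, template) {
  g <- pset$geometry
  nview <- dim(pset$images)[3]
  if (is.null(nview) || nview < 2) stop("FDK needs at least 2 views")
  nu <- g$det_shape[1]; nv <- g$det_shape[2]
  mag <- g$sid / g$sdd
  pu <- g$det_pitch[1] * mag; pv <- g$det_pitch[2] * mag  # virtual detector at iso
  u <- (seq_len(nu) - (nu + 1) / 2) * pu
  v <- (seq_len(nv) - (nv + 1) / 2) * pv
  cosw <- g$sid / sqrt(g$sid^2 + outer(u^2, v^2, "+"))
  nfft <- 2^ceiling(log2(2 * nu))
  H <- ramp_filter_response(nfft, pu)
  q <- array(0, dim(pset$images))
  for (a in seq_len(nview)) {
    pw <- pset$images[, , a] * cosw
    padded <- matrix(0, nfft, nv)
    padded[seq_len(nu), ] <- pw
    filt <- Re(stats::mvfft(stats::mvfft(padded) * H, inverse = TRUE)) / nfft
    q[, , a] <- filt[seq_len(nu), ] * pu
  }
  dbeta <- 2 * pi / nview   # full-scan average angular increment
  arr <- cpp_fdk_backproject(q, dim(template$data), template$spacing,
                             template$origin, pset$angles_deg * pi / 180,
                             nu, nv, pu, pv, g$sid)
  new_volume(arr * 0.5 * dbeta, template$spacing, template$origin)
}

#' Add Poisson counting noise to projections
#'
#' Converts line integrals to expected photon counts `I0 * exp(-p)`, draws
#' Poisson counts, and converts back with a one-count floor to avoid infinite
#' line integrals.
#'
#' @param pset a `stinr_projections` object.
#' @param I0 unattenuated photon count per pixel (must be positive).
#' @param seed RNG seed for reproducibility.
#' @return A `stinr_projections` with noisy images.
#' @export
add_poisson_noise <- function(pset, I0, seed = 1L) {
  if (I0 <= 0) stop("I0 must be positive")
  imgs <- pset$images
  set.seed(seed)
  n <- stats::rpois(length(imgs), I0 * exp(-as.numeric(imgs)))
  n <- pmax(n, 1)
  noisy <- array(-log(n / I0), dim(imgs))
  out <- pset
  out$images <- noisy
  out
}

#' Write projections as multi-page TIFF + YAML sidecar
#'
#' @param pset a `stinr_projections`.
#' @param path base path; writes `<path>.tif` (32-bit float pages) and
#'   `<path>.yaml` (angles, times, frame indices, geometry).
#' @return `path`, invisibly.
#' @export
write_projections <- function(pset, path) {
  # TIFF float storage is defined on [0, 1]: store normalised images and
  # record the scale in the sidecar
  lo <- min(pset$images, 0)
  scale <- max(pset$images - lo, 1e-12)
  pages <- lapply(seq_len(dim(pset$images)[3]),
                  function(a) (pset$images[, , a] - lo) / scale)
  tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 32L)
  meta <- list(
    intensity_offset = lo, intensity_scale = scale,
    angles_deg = as.numeric(pset$angles_deg),
    times_s = as.numeric(pset$times_s),
    frame_index = as.integer(pset$frame_index),
    geometry = unclass(pset$geometry)
  )
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read projections written by [write_projections()]
#' @param path base path used at write time.
#' @return A `stinr_projections`.
#' @export
read_projections <- function(path) {
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  g <- do.call(scan_geometry, meta$geometry[c("sid", "sdd", "det_shape",
                                              "det_pitch", "rotation_speed",
                                              "frame_rate", "n_frames")])
  imgs <- array(0, c(dim(pages[[1]]), length(pages)))
  off <- meta$intensity_offset %||% 0
  sc <- meta$intensity_scale %||% 1
  for (a in seq_along(pages)) imgs[, , a] <- pages[[a]] * sc + off
  new_projection_set(imgs, meta$angles_deg, meta$times_s, meta$frame_index, g)
}
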