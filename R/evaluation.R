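#' DICE overlap coefficient
#'
#' `2 |A n B| / (|A| + |B|)` between two binary masks on the same grid.
#'
#' @param mask_recon,mask_gt logical arrays of equal shape.
#' @return A scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(mask_recon, mask_gt) {
  stopifnot(all(dim(mask_recon) == dim(mask_gt)))
  a <- sum(mask_recon); b <- sum(mask_gt)
  if (a + b == 0) stop("both masks are empty")
  2 * sum(mask_recon & mask_gt) / (a + b)
}

mask_centroid_mm <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  colMeans(idx) * spacing
}

#' Center-of-mass error between two masks
#'
#' Euclidean distance (mm) between the centroids of two masks, the standard
#' target-localisation metric for image-guided radiotherapy.
#'
#' @param mask_recon,mask_gt logical arrays on the same grid (non-empty).
#' @param spacing voxel spacing (mm).
#' @return Distance in mm.
#' @export
center_of_mass_error <- function(mask_recon, mask_gt, spacing) {
  stopifnot(all(dim(mask_recon) == dim(mask_gt)), length(spacing) == 3)
  sqrt(sum((mask_centroid_mm(mask_recon, spacing) -
              mask_centroid_mm(mask_gt, spacing))^2))
}

#' Intensity-threshold tumor segmentation
#'
#' All voxels above `tau`, labelled by 6-connectivity; returns the connected
#' component with the largest overlap with the seed region (a ball around
#' `seed_center_mm`), restricted to that ball. Selecting
#' by seed overlap (rather than total component size) keeps a small
#' high-contrast lesion from being out-competed by large organs that also
#' exceed the threshold. Used to segment the tumor out of reconstructed
#' reference volumes.
#'
#' @param vol a `stinr_volume`.
#' @param tau intensity threshold (mm^-1).
#' @param seed_center_mm world coordinate the component must be near.
#' @param seed_radius_mm radius of the seed region (mm).
#' @return Logical mask array.
#' @export
threshold_segment <- function(vol, tau, seed_center_mm, seed_radius_mm = 25) {
  above <- vol$data > tau
  if (!any(above)) stop("no voxels above the threshold")
  lab <- cpp_label_components(above, dim(vol$data))
  xyz <- voxel_coordinates(vol)
  d2 <- rowSums(sweep(xyz, 2, seed_center_mm, "-")^2)
  near <- d2 <= seed_radius_mm^2
  cand <- unique(lab[near & as.vector(above)])
  cand <- cand[cand > 0]
  if (length(cand) == 0) stop("no component intersects the seed region")
  overlap <- vapply(cand, function(k) sum(lab[near] == k), numeric(1))
  sel <- lab == cand[which.max(overlap)]
  # keep only the component's voxels inside the seed ball: interpolation
  # blur can bridge a small lesion into adjacent large organs, and the ball
  # is chosen so it contains no other above-threshold tissue
  sel[d2 > seed_radius_mm^2] <- FALSE
  array(sel, dim(vol$data))
}

#' Propagate a mask through a deformation field
#'
#' Backward-warps the mask indicator by trilinear interpolation and
#' re-binarises at 0.5, matching how volumes are deformed.
#'
#' @param reference_mask logical array on the reference grid.
#' @param dvf pull-back displacement array `c(dims, 3)` (mm) on the target
#'   grid.
#' @param spacing voxel spacing (mm).
#' @return Logical mask array.
#' @export
propagate_mask <- function(reference_mask, dvf, spacing) {
  stopifnot(all(dim(dvf)[1:3] == dim(reference_mask)))
  warp_mask(reference_mask, spacing, dvf)
}

#' Evaluate a reconstructed dynamic sequence
#'
#' Per-frame relative error of the reconstructed volumes, and DICE / tumor
#' center-of-mass error of the propagated tumor mask against the ground-truth
#' per-frame masks, plus SI centroid trajectories for motion plots.
#'
#' @param recon_volumes list of reconstructed `stinr_volume`s (or `NULL` to
#'   skip the intensity metric).
#' @param recon_dvfs list of solved pull-back DVF arrays, one per frame.
#' @param reference_mask tumor mask on the reconstruction reference grid.
#' @param gt_frames list of `gt_frame`s (with `volume` and `tumor_mask`).
#' @param spacing voxel spacing (mm).
#' @param method label recorded in the report.
#' @return A `stinr_report`: `per_frame` tibble (`frame`, `re`, `dice`,
#'   `come_mm`, SI centroids), `summary` tibble (mean/sd per metric), and the
#'   method label.
#' @export
evaluate_sequence <- function(recon_volumes, recon_dvfs, reference_mask,
                              gt_frames, spacing, method = "method") {
  n <- length(gt_frames)
  if (length(recon_dvfs) != n) stop("frame count mismatch")
  if (!is.null(recon_volumes) && length(recon_volumes) != n) {
    stop("frame count mismatch")
  }
  re <- dice <- come <- si_rec <- si_gt <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    gt <- gt_frames[[i]]
    if (!is.null(recon_volumes)) re[i] <- relative_error(recon_volumes[[i]], gt$volume)
    m <- propagate_mask(reference_mask, recon_dvfs[[i]], spacing)
    if (any(m)) {
      dice[i] <- dice_coefficient(m, gt$tumor_mask)
      come[i] <- center_of_mass_error(m, gt$tumor_mask, spacing)
      si_rec[i] <- mask_centroid_mm(m, spacing)[3]
    } else {
      # a deformation that annihilates the contour is a tracking failure,
      # reported as zero overlap with an undefined centroid
      dice[i] <- 0
    }
    si_gt[i] <- mask_centroid_mm(gt$tumor_mask, spacing)[3]
  }
  per_frame <- tibble::tibble(
    frame = seq_len(n),
    time_s = vapply(gt_frames, function(f) f$time_s, numeric(1)),
    re = re, dice = dice, come_mm = come,
    si_recon_mm = si_rec, si_gt_mm = si_gt
  )
  summary <- tibble::tibble(
    method = method,
    metric = c("re", "dice", "come_mm"),
    mean = c(mean(re), mean(dice), mean(come, na.rm = TRUE)),
    sd = c(stats::sd(re), stats::sd(dice), stats::sd(come, na.rm = TRUE))
  )
  structure(list(per_frame = per_frame, summary = summary, method = method),
            class = "stinr_report")
}

#' @export
print.stinr_report <- function(x, ...) {
  cat("<stinr_report> ", x$method, ", ", nrow(x$per_frame), " frames\n", sep = "")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Tracked SI tumor trajectory plot
#'
#' Reconstructed versus ground-truth superior-inferior tumor centroid over the
#' scan, the standard visual check of solved respiratory motion.
#'
#' @param report a `stinr_report` from [evaluate_sequence()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(report) {
  pf <- report$per_frame
  df <- rbind(
    data.frame(time_s = pf$time_s, si_mm = pf$si_gt_mm, curve = "ground truth"),
    data.frame(time_s = pf$time_s, si_mm = pf$si_recon_mm, curve = report$method)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$si_mm,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "SI tumor centroid (mm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write a report to CSV (per-frame) + JSON (aggregates)
#' @param report a `stinr_report`.
#' @param path base path; writes `<path>_frames.csv` and `<path>_summary.json`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report$per_frame, paste0(path, "_frames.csv"),
                   row.names = FALSE)
  agg <- stats::setNames(as.list(report$summary$mean), report$summary$metric)
  agg$sd <- stats::setNames(as.list(report$summary$sd), report$summary$metric)
  agg$method <- report$method
  jsonlite::write_json(agg, paste0(path, "_summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
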