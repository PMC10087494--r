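#' Voxel volume container
#'
#' A minimal attenuation-volume container: a 3-D numeric array together with
#' voxel spacing (mm) and the world coordinate of the first voxel centre (mm).
#' The world frame is centred at the scanner isocentre with `x` lateral,
#' `y` anterior-posterior and `z` superior-inferior (the gantry rotation axis).
#'
#' @param data numeric 3-D array of attenuation coefficients (mm^-1).
#' @param spacing numeric length-3, mm per voxel along each axis.
#' @param origin numeric length-3, mm coordinate of the centre of voxel
#'   `[1,1,1]`. Defaults to a grid centred on the isocentre.
#' @return An object of class `stinr_volume`.
#' @export
new_volume <- function(data, spacing, origin = NULL) {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3, all(spacing > 0))
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * spacing
  structure(
    list(data = data, spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "stinr_volume"
  )
}

#' @export
print.stinr_volume <- function(x, ...) {
  cat("<stinr_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "), " mm\n",
      "  range [", signif(min(x$data), 4), ", ", signif(max(x$data), 4), "] mm^-1\n",
      sep = "")
  invisible(x)
}

#' @export
dim.stinr_volume <- function(x) dim(x$data)

#' @export
as.array.stinr_volume <- function(x, ...) x$data

is_volume <- function(x) inherits(x, "stinr_volume")

#' World coordinates of all voxel centres
#'
#' @param vol a `stinr_volume`.
#' @return An `n x 3` matrix of mm coordinates in array (column-major) order.
#' @export
voxel_coordinates <- function(vol) {
  d <- dim(vol$data)
  g <- expand.grid(
    x = vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
    y = vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
    z = vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  )
  as.matrix(g)
}

#' Normalised [-1, 1] coordinates of all voxel centres
#'
#' Coordinates are normalised per axis by the half-extent of the grid, the
#' convention used for the spatial coordinate MLP input.
#' @param vol a `stinr_volume`.
#' @return An `n x 3` matrix with entries in `[-1, 1]`.
#' @export
normalized_coordinates <- function(vol) {
  d <- dim(vol$data)
  half <- (d - 1) / 2 * vol$spacing
  centre <- vol$origin + half
  xyz <- voxel_coordinates(vol)
  sweep(sweep(xyz, 2, centre, "-"), 2, pmax(half, 1e-9), "/")
}

#' Resample a volume onto a new grid
#'
#' Trilinear, world-aligned resampling with clamp-to-edge boundary handling.
#'
#' @param vol a `stinr_volume`.
#' @param dims integer length-3 target grid shape.
#' @param spacing target spacing (mm); defaults to preserving the physical
#'   extent of `vol`.
#' @param origin target origin (mm); defaults to a grid centred like `vol`.
#' @return A `stinr_volume` on the new grid.
#' @export
resample_volume <- function(vol, dims, spacing = NULL, origin = NULL) {
  dims <- as.integer(dims)
  if (is.null(spacing)) spacing <- dim(vol$data) * vol$spacing / dims
  if (is.null(origin)) {
    centre <- vol$origin + (dim(vol$data) - 1) / 2 * vol$spacing
    origin <- centre - (dims - 1) / 2 * spacing
  }
  arr <- cpp_resample(vol$data, dim(vol$data), vol$spacing, vol$origin,
                      dims, spacing, origin)
  new_volume(arr, spacing, origin)
}

#' Write a volume to NIfTI
#'
#' @param vol a `stinr_volume` (or a logical mask array with the same metadata,
#'   written as uint8).
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data, pixdim = vol$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file path.
#' @param origin optional origin override (mm).
#' @return A `stinr_volume`.
#' @export
read_volume <- function(path, origin = NULL) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  new_volume(array(as.numeric(img), dim = dim(img)), sp, origin)
}

#' Relative error between two volumes
#'
#' `sqrt(sum((recon - truth)^2) / sum(truth^2))`, the standard normalised
#' root-sum-of-squares reconstruction error.
#'
#' @param recon,truth `stinr_volume`s or numeric arrays on the same grid.
#' @return A non-negative scalar.
#' @export
relative_error <- function(recon, truth) {
  a <- if (is_volume(recon)) recon$data else recon
  b <- if (is_volume(truth)) truth$data else truth
  stopifnot(all(dim(a) == dim(b)))
  denom <- sum(b^2)
  if (denom == 0) stop("ground truth volume is identically zero")
  sqrt(sum((a - b)^2) / denom)
}
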