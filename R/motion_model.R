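#' Inter-phase deformable registration
#'
#' Estimates pull-back deformation fields mapping the end-expiration (EE)
#' reference phase to each other phase of a prior 4D set. Two modes:
#'
#' * `"demons"` — a lightweight multi-resolution demons-style registration
#'   (gradient-force updates with Gaussian field smoothing, 3 levels).
#' * `"bypass"` — return the simulator's ground-truth fields (optionally with
#'   seeded Gaussian perturbation), which isolates downstream motion-model and
#'   reconstruction tests from registration error.
#'
#' @param reference the EE-phase `stinr_volume`.
#' @param phases list of the other phase `stinr_volume`s.
#' @param method `"bypass"` or `"demons"`.
#' @param gt_dvfs list of ground-truth fields (required for `"bypass"`).
#' @param perturb_sd mm standard deviation of smoothed Gaussian perturbation
#'   added in bypass mode (0 = exact).
#' @param seed RNG seed for the perturbation.
#' @param iterations demons iterations per resolution level.
#' @param smooth_sigma Gaussian field smoothing (voxels) per level.
#' @return List of pull-back DVF arrays `c(dims, 3)` (mm), one per phase.
#' @export
register_phases <- function(reference, phases, method = c("bypass", "demons"),
                            gt_dvfs = NULL, perturb_sd = 0, seed = 1L,
                            iterations = 30, smooth_sigma = 1) {
  method <- match.arg(method)
  if (method == "bypass") {
    stopifnot(!is.null(gt_dvfs), length(gt_dvfs) == length(phases))
    if (perturb_sd > 0) {
      set.seed(seed)
      gt_dvfs <- lapply(gt_dvfs, function(d) {
        noise <- array(stats::rnorm(length(d), sd = perturb_sd), dim(d))
        for (k in 1:3) {
          noise[, , , k] <- cpp_gauss_smooth(noise[, , , k], dim(d)[1:3], rep(2, 3))
        }
        d + noise
      })
    }
    return(gt_dvfs)
  }
  lapply(phases, function(ph) {
    if (!all(dim(ph$data) == dim(reference$data))) stop("phase/reference shape mismatch")
    demons_register(reference, ph, iterations, smooth_sigma)
  })
}

# multi-resolution demons: solves frame(x) = ref(x + D(x)) for the pull-back
# field D, i.e. registers the reference (moving) onto each phase (fixed).
demons_register <- function(reference, fixed, iterations = 30, smooth_sigma = 1) {
  levels <- c(4, 2, 1)
  dims_full <- dim(reference$data)
  dvf <- NULL
  for (lv in levels) {
    dims <- pmax(dims_full %/% lv, 8L)
    ref_l <- resample_volume(reference, dims)
    fix_l <- resample_volume(fixed, dims)
    if (is.null(dvf)) {
      dvf <- array(0, c(dims, 3))
    } else {
      dvf_new <- array(0, c(dims, 3))
      prev_vol <- new_volume(array(0, dim(dvf)[1:3]), dim(reference$data) *
                               reference$spacing / dim(dvf)[1:3])
      for (k in 1:3) {
        comp <- new_volume(dvf[, , , k], prev_vol$spacing)
        dvf_new[, , , k] <- resample_volume(comp, dims)$data
      }
      dvf <- dvf_new
    }
    sp <- dims_full * reference$spacing / dims
    sp2 <- mean(sp)^2
    for (it in seq_len(iterations)) {
      warped <- cpp_warp(ref_l$data, dims, sp, dvf)
      diff <- fix_l$data - warped
      g <- array(0, c(dims, 3))
      # central-difference gradient of the warped moving image, per mm
      for (k in 1:3) {
        idx1 <- idx2 <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
        idx1[[k]] <- pmin(idx1[[k]] + 1, dims[k])
        idx2[[k]] <- pmax(idx2[[k]] - 1, 1)
        g[, , , k] <- (warped[idx1[[1]], idx1[[2]], idx1[[3]]] -
                         warped[idx2[[1]], idx2[[2]], idx2[[3]]]) / (2 * sp[k])
      }
      gn2 <- g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2
      # classic demons force with spacing-normalised stabiliser: steps are
      # bounded by ~half a voxel per iteration
      denom <- gn2 + diff^2 / sp2
      denom[denom < 1e-18] <- 1e-18
      for (k in 1:3) {
        upd <- diff * g[, , , k] / denom
        dvf[, , , k] <- cpp_gauss_smooth(dvf[, , , k] + upd, dims,
                                         rep(smooth_sigma, 3))
      }
    }
  }
  if (!all(dim(dvf)[1:3] == dims_full)) {
    out <- array(0, c(dims_full, 3))
    sp_l <- dims_full * reference$spacing / dim(dvf)[1:3]
    for (k in 1:3) {
      comp <- new_volume(dvf[, , , k], sp_l)
      out[, , , k] <- resample_volume(comp, dims_full)$data
    }
    dvf <- out
  }
  dvf
}

#' Build the PCA respiratory motion model
#'
#' For each Cartesian direction independently: flatten the corresponding
#' component of the inter-phase DVFs into an `m x n_vox` matrix, mean-centre
#' it, and take the top `n_comp` right singular vectors as spatial principal
#' components, each scaled by `singular value / sqrt(m - 1)` (one standard
#' deviation of the training coefficient), so that unit temporal weights
#' correspond to typical training motion and MLP outputs stay O(1). The mean
#' field over the training DVFs is the model's DC component. Component signs
#' are fixed so each training weight track correlates positively with the
#' provided surrogate (or has a positive dominant entry when no surrogate is
#' given).
#'
#' @param dvfs list of >= `n_comp + 1` pull-back DVF arrays `c(dims, 3)` (mm).
#' @param n_comp number of principal components per direction (default 3).
#' @param spacing voxel spacing of the model grid (mm).
#' @param signal optional per-DVF surrogate values used for the sign
#'   convention.
#' @return A `motion_model` object: `pc0` (`n_vox x 3` mean field), `pcs`
#'   (array `n_vox x 3 x n_comp`, scaled), `scales` (`3 x n_comp`),
#'   `explained_variance` (`3 x n_comp`, cumulative fraction), grid metadata,
#'   and `train_weights` (`m x 9`).
#' @export
build_pca_model <- function(dvfs, n_comp = 3, spacing = NULL, signal = NULL) {
  m <- length(dvfs)
  if (m < n_comp + 1) stop("need at least n_comp + 1 DVFs")
  dims <- dim(dvfs[[1]])[1:3]
  nvox <- prod(dims)
  pc0 <- matrix(0, nvox, 3)
  pcs <- array(0, c(nvox, 3, n_comp))
  scales <- matrix(0, 3, n_comp)
  ev <- matrix(0, 3, n_comp)
  train_w <- matrix(0, m, 3 * n_comp)
  for (dim_i in 1:3) {
    X <- t(vapply(dvfs, function(d) as.numeric(d[, , , dim_i]), numeric(nvox)))
    mu <- colMeans(X)
    pc0[, dim_i] <- mu
    Xc <- sweep(X, 2, mu, "-")
    sv <- svd(Xc, nu = n_comp, nv = n_comp)
    tot <- sum(sv$d^2)
    for (k in seq_len(n_comp)) {
      sc <- sv$d[k] / sqrt(m - 1)
      vk <- sv$v[, k]
      alpha <- drop(Xc %*% vk)             # training coefficients (mm scale)
      flip <- if (!is.null(signal) && stats::sd(alpha) > 1e-12 &&
                  stats::sd(signal) > 1e-12 &&
                  abs(stats::cor(alpha, signal)) > 1e-6) {
        sign(stats::cor(alpha, signal))
      } else {
        s <- sign(vk[which.max(abs(vk))])
        if (s == 0) 1 else s
      }
      pcs[, dim_i, k] <- flip * vk * sc
      scales[dim_i, k] <- sc
      train_w[, (dim_i - 1) * n_comp + k] <- if (sc > 1e-12) flip * alpha / sc else 0
      ev[dim_i, k] <- sum(sv$d[seq_len(k)]^2) / max(tot, 1e-300)
    }
  }
  structure(list(pc0 = pc0, pcs = pcs, scales = scales,
                 explained_variance = ev, dims = dims,
                 spacing = if (is.null(spacing)) rep(NA_real_, 3) else as.numeric(spacing),
                 n_comp = n_comp, train_weights = train_w),
            class = "motion_model")
}

#' @export
print.motion_model <- function(x, ...) {
  cat("<motion_model> ", paste(x$dims, collapse = " x "), " grid, ",
      x$n_comp, " components/direction\n", sep = "")
  cat("  cumulative explained variance (x/y/z):\n")
  print(round(x$explained_variance, 5))
  invisible(x)
}

#' Compose a deformation field from model weights
#'
#' `D = PC0 + sum_dim sum_n w[dim, n] * PC[dim, n]`: the mean field plus the
#' weighted scaled principal components, assembled into one 3-vector field.
#'
#' @param model a [build_pca_model()] result.
#' @param w numeric 9-vector, ordered `(x1, x2, x3, y1, y2, y3, z1, z2, z3)`.
#' @return A DVF array `c(dims, 3)` in mm.
#' @export
compose_dvf <- function(model, w) {
  stopifnot(length(w) == 3 * model$n_comp, all(is.finite(w)))
  d <- model$pc0
  for (dim_i in 1:3) {
    for (k in seq_len(model$n_comp)) {
      wk <- w[(dim_i - 1) * model$n_comp + k]
      if (wk != 0) d[, dim_i] <- d[, dim_i] + wk * model$pcs[, dim_i, k]
    }
  }
  array(d, c(model$dims, 3))
}

#' Project a deformation field onto model weights
#'
#' Least-squares inverse of [compose_dvf()]: the weight vector minimising
#' `|| compose(w) - dvf ||_2`, solved per direction via the (diagonal, since
#' the scaled components are orthogonal) normal equations.
#'
#' @param model a motion model.
#' @param dvf array `c(dims, 3)` on the model grid.
#' @return Numeric 9-vector of weights.
#' @export
project_dvf_to_weights <- function(model, dvf) {
  stopifnot(all(dim(dvf)[1:3] == model$dims))
  if (all(abs(model$scales) < 1e-12)) {
    stop("degenerate motion model (all components have zero scale)")
  }
  w <- numeric(3 * model$n_comp)
  ref_scale <- max(abs(model$scales))
  for (dim_i in 1:3) {
    resid <- as.numeric(dvf[, , , dim_i]) - model$pc0[, dim_i]
    for (k in seq_len(model$n_comp)) {
      # scaled components are mutually orthogonal within a direction, so the
      # normal equations are diagonal; components with (numerically) zero
      # scale contribute nothing and get weight 0
      p <- model$pcs[, dim_i, k]
      nrm2 <- sum(p^2)
      w[(dim_i - 1) * model$n_comp + k] <-
        if (model$scales[dim_i, k] > 1e-9 * ref_scale) sum(p * resid) / nrm2 else 0
    }
  }
  w
}

# (3 * nvox) x 9 design matrix and mean vector, for fast repeated composition
model_matrix <- function(model) {
  nvox <- prod(model$dims)
  P <- matrix(0, 3 * nvox, 3 * model$n_comp)
  for (dim_i in 1:3) {
    rows <- (dim_i - 1) * nvox + seq_len(nvox)
    for (k in seq_len(model$n_comp)) {
      P[rows, (dim_i - 1) * model$n_comp + k] <- model$pcs[, dim_i, k]
    }
  }
  list(P = P, pc0 = as.numeric(model$pc0), dims = model$dims)
}

#' Resample a motion model onto a new grid
#'
#' Trilinear, world-aligned resampling of the mean field and every scaled
#' component, preserving mm units.
#'
#' @param model a motion model with known `spacing`.
#' @param dims target grid shape.
#' @param spacing,origin target grid metadata (defaults preserve extent).
#' @return A `motion_model` on the new grid.
#' @export
resample_motion_model <- function(model, dims, spacing = NULL, origin = NULL) {
  dims <- as.integer(dims)
  if (all(dims == model$dims)) return(model)
  if (any(is.na(model$spacing))) stop("model has no spacing metadata")
  res_field <- function(vals) {
    v <- new_volume(array(vals, model$dims), model$spacing)
    as.numeric(resample_volume(v, dims, spacing, origin)$data)
  }
  nvox <- prod(dims)
  pc0 <- matrix(0, nvox, 3)
  pcs <- array(0, c(nvox, 3, model$n_comp))
  for (dim_i in 1:3) {
    pc0[, dim_i] <- res_field(model$pc0[, dim_i])
    for (k in seq_len(model$n_comp)) {
      pcs[, dim_i, k] <- res_field(model$pcs[, dim_i, k])
    }
  }
  out <- model
  out$pc0 <- pc0; out$pcs <- pcs; out$dims <- dims
  out$spacing <- if (is.null(spacing)) model$dims * model$spacing / dims else spacing
  out
}

#' Write a motion model to a directory (NIfTI components + YAML metadata)
#' @param model a motion model.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_motion_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- if (any(is.na(model$spacing))) rep(1, 3) else model$spacing
  for (dim_i in 1:3) {
    write_volume(new_volume(array(model$pc0[, dim_i], model$dims), sp),
                 file.path(dir, sprintf("pc0_dim%d.nii.gz", dim_i)))
    for (k in seq_len(model$n_comp)) {
      write_volume(new_volume(array(model$pcs[, dim_i, k], model$dims), sp),
                   file.path(dir, sprintf("pc_dim%d_n%d.nii.gz", dim_i, k)))
    }
  }
  yaml::write_yaml(list(dims = model$dims, spacing = model$spacing,
                        n_comp = model$n_comp, scales = as.numeric(model$scales),
                        explained_variance = as.numeric(model$explained_variance)),
                   file.path(dir, "model.yaml"))
  invisible(dir)
}

#' Read a motion model written by [write_motion_model()]
#' @param dir model directory.
#' @return A `motion_model`.
#' @export
read_motion_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  dims <- as.integer(meta$dims)
  nvox <- prod(dims)
  pc0 <- matrix(0, nvox, 3)
  pcs <- array(0, c(nvox, 3, meta$n_comp))
  for (dim_i in 1:3) {
    pc0[, dim_i] <- as.numeric(read_volume(
      file.path(dir, sprintf("pc0_dim%d.nii.gz", dim_i)))$data)
    for (k in seq_len(meta$n_comp)) {
      pcs[, dim_i, k] <- as.numeric(read_volume(
        file.path(dir, sprintf("pc_dim%d_n%d.nii.gz", dim_i, k)))$data)
    }
  }
  structure(list(pc0 = pc0, pcs = pcs,
                 scales = matrix(meta$scales, 3, meta$n_comp),
                 explained_variance = matrix(meta$explained_variance, 3, meta$n_comp),
                 dims = dims, spacing = as.numeric(meta$spacing),
                 n_comp = meta$n_comp, train_weights = NULL),
            class = "motion_model")
}
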