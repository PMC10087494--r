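## Reconstruction methods: the three-stage spatiotemporal INR fit, the
## per-projection PCA-weight comparator, ART+TV, and the polynomial temporal
## baseline. All share the single-view projector/adjoint and the
## differentiable warp.

project_single_view <- function(vol_arr, grid, geom, angle_rad, step) {
  cpp_forward_project(vol_arr, grid$dims, grid$spacing, grid$origin, angle_rad,
                      geom$det_shape[1], geom$det_shape[2],
                      geom$det_pitch[1], geom$det_pitch[2],
                      geom$sid, geom$sdd, step)
}

backproject_single_view <- function(img, grid, geom, angle_rad, step) {
  cpp_backproject(img, grid$dims, grid$spacing, grid$origin, angle_rad,
                  geom$det_shape[1], geom$det_shape[2],
                  geom$det_pitch[1], geom$det_pitch[2],
                  geom$sid, geom$sdd, step)
}

grid_info <- function(template) {
  list(dims = dim(template$data), spacing = template$spacing,
       origin = template$origin)
}

#' Subset a projection set by frame indices
#' @param pset a `stinr_projections`.
#' @param idx frame indices to keep.
#' @return A `stinr_projections` with the selected views.
#' @export
subset_projections <- function(pset, idx) {
  new_projection_set(pset$images[, , idx, drop = FALSE],
                     pset$angles_deg[idx], pset$times_s[idx],
                     pset$frame_index[idx], pset$geometry)
}

#' Extract the end-expiration projection subset
#'
#' Selects the frames whose respiratory surrogate lies in the lowest
#' `fraction` quantile — the quasi-static end-expiration phase used to
#' pre-condition the reference-volume reconstruction.
#'
#' @param pset a `stinr_projections`.
#' @param signal surrogate value per frame (same length as the scan).
#' @param fraction quantile fraction in (0, 1].
#' @return A `stinr_projections` subset (angles/timestamps preserved).
#' @export
extract_ee_projections <- function(pset, signal, fraction = 0.1) {
  n <- dim(pset$images)[3]
  if (length(signal) != n) stop("signal length must match frame count")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (stats::sd(signal) < 1e-12) {
    warning("constant surrogate signal: all frames selected")
    return(pset)
  }
  thr <- stats::quantile(signal, fraction, names = FALSE)
  idx <- which(signal <= thr)
  if (length(idx) == 0) stop("empty end-expiration selection")
  subset_projections(pset, idx)
}

#' Configuration for the spatiotemporal INR fit
#'
#' Defaults follow the reference three-stage schedule: 500 iterations of
#' voxel-domain pre-conditioning on an end-expiration FDK volume, 500
#' iterations of projection-domain fine-tuning on the end-expiration subset,
#' and 4000 joint spatiotemporal iterations on all projections, all with
#' learning rate 0.002. Stage 3 samples `batch_frames` random frames per
#' iteration.
#'
#' @param iters integer length-3 stage iteration counts.
#' @param lr initial Adam learning rate (all INRs).
#' @param lr_decay final learning-rate fraction per stage (1 = constant rate;
#'   values below 1 decay exponentially over each stage). The default keeps
#'   the rate constant; late-stage minibatch noise is handled by tail
#'   averaging instead (see `stinr_fit()`).
#' @param batch_frames projection minibatch size for stages 2-3.
#' @param ee_fraction quantile fraction for end-expiration extraction.
#' @param w_bound box bound on the scaled component weights. Scaled weights
#'   are standard deviations of training motion, so real trajectories stay
#'   well inside a few units; the bound keeps weakly-projecting (and hence
#'   weakly-constrained) components from drifting under adaptive-moment
#'   updates.
#' @param preset an [inr_preset()] architecture.
#' @param seed seed controlling encoder matrices, weight init and minibatch
#'   order.
#' @return A `stinr_config` list.
#' @export
stinr_config <- function(iters = c(500L, 500L, 4000L), lr = 0.002,
                         lr_decay = 1, batch_frames = 8L,
                         ee_fraction = 0.1, w_bound = 4,
                         preset = inr_preset("scaled"), seed = 1L) {
  stopifnot(length(iters) == 3, all(iters >= 0), lr > 0, batch_frames >= 1,
            lr_decay > 0, lr_decay <= 1, w_bound > 0)
  structure(list(iters = as.integer(iters), lr = lr, lr_decay = lr_decay,
                 batch_frames = as.integer(batch_frames),
                 ee_fraction = ee_fraction, w_bound = w_bound,
                 preset = preset, seed = as.integer(seed)),
            class = "stinr_config")
}

# running mean of MLP parameters: avg + (net - avg) / n
net_running_mean <- function(avg, net, n) {
  for (l in seq_along(net$layers)) {
    avg$layers[[l]]$W <- avg$layers[[l]]$W +
      (net$layers[[l]]$W - avg$layers[[l]]$W) / n
    avg$layers[[l]]$b <- avg$layers[[l]]$b +
      (net$layers[[l]]$b - avg$layers[[l]]$b) / n
  }
  avg
}

# exponential learning-rate schedule from lr to lr * decay over n iterations
lr_schedule <- function(lr, decay, n) {
  if (n <= 1) return(rep(lr, max(n, 0)))
  lr * decay^((seq_len(n) - 1) / (n - 1))
}

# one Adam fit of the spatial net to a target volume (stage 1), in the
# network's internal attenuation units; the loss trace is per-voxel MSE
fit_spatial_to_volume <- function(sinr, target_vec, enc_grid, iters, lr,
                                  lr_decay = 1, seed = 1L) {
  s <- sinr$att_scale %||% 1
  target <- target_vec / s
  st <- adam_init(sinr$net)
  trace <- numeric(iters)
  n <- length(target)
  ws <- mlp_ws_new(enc_grid)
  lrs <- lr_schedule(lr, lr_decay, iters)
  for (it in seq_len(iters)) {
    r <- mlp_ws_forward(ws, sinr$net) - target
    trace[it] <- mean(r^2)
    grads <- mlp_ws_backward(ws, sinr$net, 2 * r / n)
    upd <- adam_step(sinr$net, grads, st, lrs[it])
    sinr$net <- upd$net; st <- upd$state
  }
  list(sinr = sinr, trace = trace)
}

# projection-domain stage: returns loss over a frame minibatch and the
# gradient wrt the rendered volume (plus optional motion machinery)
stage_projection_pass <- function(V, grid, geom, pset, frames, step,
                                  dvfs = NULL) {
  g_V <- numeric(length(V))
  g_D <- if (!is.null(dvfs)) vector("list", length(frames)) else NULL
  loss <- 0
  for (j in seq_along(frames)) {
    fidx <- frames[j]
    ang <- pset$angles_deg[fidx] * pi / 180
    if (is.null(dvfs)) {
      Vt <- V
    } else {
      Vt <- cpp_warp(V, grid$dims, grid$spacing, dvfs[[j]])
    }
    drr <- project_single_view(Vt, grid, geom, ang, step)
    r <- drr - pset$images[, , fidx, drop = FALSE]
    loss <- loss + sum(r^2)
    g_vt <- backproject_single_view(2 * r, grid, geom, ang, step)
    if (is.null(dvfs)) {
      g_V <- g_V + as.numeric(g_vt)
    } else {
      g_V <- g_V + as.numeric(cpp_warp_adjoint(g_vt, grid$dims, grid$spacing,
                                               dvfs[[j]]))
      g_D[[j]] <- cpp_warp_grad_dvf(V, grid$dims, grid$spacing, dvfs[[j]],
                                    g_vt)
    }
  }
  list(loss = loss, g_V = g_V, g_D = g_D)
}

#' Three-stage spatiotemporal INR reconstruction
#'
#' Jointly reconstructs a reference attenuation volume (spatial coordinate
#' MLP) and the time-varying weights of a PCA motion model (nine temporal
#' MLPs) from a single dynamic cone-beam scan, by minimising the squared
#' mismatch between forward projections of the warped reference and the
#' acquired projections:
#'
#' 1. *Stage 1*: the spatial MLP is fitted voxelwise to an FDK reconstruction
#'    of the end-expiration projection subset.
#' 2. *Stage 2*: the spatial MLP is fine-tuned directly against the
#'    end-expiration projections (no motion model).
#' 3. *Stage 3*: spatial and temporal MLPs are optimised jointly on all
#'    projections; each frame's deformation is the model mean plus the
#'    MLP-weighted scaled principal components.
#'
#' @param pset the full dynamic `stinr_projections`.
#' @param model a [build_pca_model()] motion model (resampled to the
#'   optimisation grid if needed).
#' @param template a `stinr_volume` defining the optimisation grid.
#' @param signal respiratory surrogate per frame (for end-expiration
#'   extraction).
#' @param config a [stinr_config()].
#' @return A `stinr_fit` object: fitted `spatial`/`temporal` INRs, the
#'   (resampled) motion model, grid and normalisation metadata, per-stage loss
#'   traces, and the end-expiration frame indices.
#' @export
stinr_fit <- function(pset, model, template, signal, config = stinr_config()) {
  grid <- grid_info(template)
  if (!all(model$dims == grid$dims)) {
    model <- resample_motion_model(model, grid$dims, grid$spacing)
  }
  model$spacing <- grid$spacing
  geom <- pset$geometry
  step <- min(grid$spacing) / 2
  n_frames <- dim(pset$images)[3]

  ee <- extract_ee_projections(pset, signal, config$ee_fraction)
  ee_idx <- match(ee$frame_index, pset$frame_index)
  fdk_ee <- fdk_reconstruct(ee, template)

  sinr <- spatial_inr(config$preset, seed = config$seed)
  tinr <- temporal_inr(config$preset, n_sub = 3L * model$n_comp,
                       seed = config$seed + 100L)
  coords <- normalized_coordinates(template)
  enc_grid <- grff_encode(sinr$encoder, coords)

  ## stage 1: voxel-domain pre-conditioning on the EE FDK volume. The target
  ## is clipped at zero: a sparse-view FDK carries strong negative streak
  ## artifacts that the network would otherwise spend its capacity fitting,
  ## and attenuation is physically non-negative.
  s1 <- fit_spatial_to_volume(sinr, pmax(as.numeric(fdk_ee$data), 0),
                              enc_grid, config$iters[1], config$lr,
                              config$lr_decay, seed = config$seed + 1L)
  sinr <- s1$sinr

  t_norm <- (pset$times_s - pset$times_s[1]) /
    max(pset$times_s[n_frames] - pset$times_s[1], 1e-12)
  enc_t <- grff_encode(tinr$encoder, matrix(t_norm, ncol = 1))
  mm <- model_matrix(model)

  ws <- mlp_ws_new(enc_grid)
  s_att <- sinr$att_scale %||% 1
  st_theta <- adam_init(sinr$net)
  trace2 <- numeric(config$iters[2])
  lrs2 <- lr_schedule(config$lr, config$lr_decay, config$iters[2])
  set.seed(config$seed + 2L)
  ## stage 2: projection-domain fine-tuning on the EE subset
  for (it in seq_len(config$iters[2])) {
    V <- mlp_ws_forward(ws, sinr$net) * s_att
    frames <- ee_idx[sample.int(length(ee_idx),
                                min(config$batch_frames, length(ee_idx)))]
    pass <- stage_projection_pass(V, grid, geom, pset, frames, step)
    trace2[it] <- pass$loss
    if (!is.finite(pass$loss)) stop("stage 2 diverged (non-finite loss)")
    grads <- mlp_ws_backward(ws, sinr$net, pass$g_V * s_att)
    upd <- adam_step(sinr$net, grads, st_theta, lrs2[it])
    sinr$net <- upd$net; st_theta <- upd$state
  }

  ## stage 3: joint spatiotemporal optimisation on all projections.
  ## The temporal output biases start at the weights that cancel the model
  ## mean, so the initial deformation state is the static end-expiration
  ## anatomy (D ~ 0) rather than the mean-displaced state; and the spatial
  ## parameters are held for a short warm-up while the temporal weights
  ## catch up with the intra-scan motion, so the reference does not absorb
  ## motion artifacts it would later have to unlearn.
  w_ee <- project_dvf_to_weights(model,
                                 array(0, c(grid$dims, 3)))   # solves D ~ 0
  for (k in seq_len(length(tinr$nets))) {
    L <- length(tinr$nets[[k]]$layers)
    tinr$nets[[k]]$layers[[L]]$b <- tinr$nets[[k]]$layers[[L]]$b + w_ee[k]
  }
  st_theta <- adam_init(sinr$net)
  st_phi <- lapply(tinr$nets, adam_init)
  trace3 <- numeric(config$iters[3])
  lrs3 <- lr_schedule(config$lr, config$lr_decay, config$iters[3])
  n_sub <- length(tinr$nets)
  warmup <- floor(config$iters[3] / 10)
  set.seed(config$seed + 3L)
  nb <- min(config$batch_frames, n_frames)
  ## tail averaging (Polyak-Ruppert): parameters are averaged over the final
  ## quarter of stage 3, removing the stationary minibatch-noise walk from
  ## the returned fit without slowing convergence
  avg_from <- config$iters[3] - floor(config$iters[3] / 4) + 1L
  avg_n <- 0L
  sinr_avg <- NULL; tinr_avg <- NULL
  for (it in seq_len(config$iters[3])) {
    V <- mlp_ws_forward(ws, sinr$net) * s_att
    frames <- sample.int(n_frames, nb)
    enc_b <- enc_t[frames, , drop = FALSE]
    tfw <- lapply(tinr$nets, function(net) mlp_forward_train(net, enc_b))
    W <- vapply(tfw, function(f) drop(f$out), numeric(length(frames)))
    W <- matrix(W, nrow = length(frames))
    clamped <- abs(W) > config$w_bound
    Wc <- pmin(pmax(W, -config$w_bound), config$w_bound)
    dvfs <- lapply(seq_along(frames), function(j) {
      array(mm$pc0 + mm$P %*% Wc[j, ], c(grid$dims, 3))
    })
    pass <- stage_projection_pass(V, grid, geom, pset, frames, step, dvfs)
    trace3[it] <- pass$loss
    if (!is.finite(pass$loss)) stop("stage 3 diverged (non-finite loss)")
    ## temporal gradients: dL/dw[j, k] = PC_k . g_D[j]
    gW <- matrix(0, length(frames), n_sub)
    for (j in seq_along(frames)) {
      gW[j, ] <- drop(crossprod(mm$P, as.numeric(pass$g_D[[j]])))
    }
    gW[clamped] <- 0                       # box-bound subgradient
    for (k in seq_len(n_sub)) {
      gk <- mlp_backward(tinr$nets[[k]], tfw[[k]]$cache,
                         matrix(gW[, k], ncol = 1))
      upd <- adam_step(tinr$nets[[k]], gk, st_phi[[k]], lrs3[it])
      tinr$nets[[k]] <- upd$net; st_phi[[k]] <- upd$state
    }
    if (it > warmup) {
      grads <- mlp_ws_backward(ws, sinr$net, pass$g_V * s_att)
      upd <- adam_step(sinr$net, grads, st_theta, lrs3[it])
      sinr$net <- upd$net; st_theta <- upd$state
    }
    if (it >= avg_from) {
      avg_n <- avg_n + 1L
      if (is.null(sinr_avg)) {
        sinr_avg <- sinr$net
        tinr_avg <- tinr$nets
      } else {
        sinr_avg <- net_running_mean(sinr_avg, sinr$net, avg_n)
        for (k in seq_len(n_sub)) {
          tinr_avg[[k]] <- net_running_mean(tinr_avg[[k]], tinr$nets[[k]],
                                            avg_n)
        }
      }
    }
  }
  if (!is.null(sinr_avg)) {
    sinr$net <- sinr_avg
    tinr$nets <- tinr_avg
  }

  structure(list(spatial = sinr, temporal = tinr, model = model,
                 grid = grid, config = config, w_bound = config$w_bound,
                 t_range = range(pset$times_s),
                 traces = list(stage1 = s1$trace, stage2 = trace2,
                               stage3 = trace3),
                 ee_frame_index = ee$frame_index,
                 fdk_ee = fdk_ee),
            class = "stinr_fit")
}

#' @export
print.stinr_fit <- function(x, ...) {
  cat("<stinr_fit> grid ", paste(x$grid$dims, collapse = " x "),
      ", stages ", paste(x$config$iters, collapse = "/"), " iterations\n",
      sep = "")
  for (s in names(x$traces)) {
    tr <- x$traces[[s]]
    if (length(tr)) {
      cat("  ", s, ": loss ", signif(tr[1], 4), " -> ",
          signif(tr[length(tr)], 4), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Render the fitted reference volume on an arbitrary grid
#'
#' @param fit a `stinr_fit`.
#' @param grid_template optional `stinr_volume` defining the output grid
#'   (defaults to the optimisation grid). Coordinates are normalised by the
#'   optimisation grid's extent, so finer grids query the same continuous
#'   representation.
#' @param clip clip negative attenuations to zero (export convention).
#' @return A `stinr_volume`.
#' @export
stinr_reference <- function(fit, grid_template = NULL, clip = TRUE) {
  if (is.null(grid_template)) {
    grid_template <- new_volume(array(0, fit$grid$dims), fit$grid$spacing,
                                fit$grid$origin)
  }
  half <- (fit$grid$dims - 1) / 2 * fit$grid$spacing
  centre <- fit$grid$origin + half
  xyz <- voxel_coordinates(grid_template)
  coords <- sweep(sweep(xyz, 2, centre, "-"), 2, pmax(half, 1e-9), "/")
  vals <- spatial_inr_eval(fit$spatial, coords)
  if (clip) vals <- pmax(vals, 0)
  new_volume(array(vals, dim(grid_template$data)), grid_template$spacing,
             grid_template$origin)
}

#' Inference: dynamic volumes from a fitted spatiotemporal model
#'
#' Evaluates the temporal MLPs at the requested times, composes the
#' deformation fields, and warps the rendered reference volume. Any output
#' grid is allowed; the motion model is resampled to it.
#'
#' @param fit a `stinr_fit`.
#' @param times_s times within the scan window (default: all training times
#'   cannot be reconstructed here, pass explicitly).
#' @param grid_template optional output-grid `stinr_volume`.
#' @param clip clip negative attenuations to zero.
#' @return A list: `volumes` (list of `stinr_volume`), `dvfs` (list of
#'   arrays), `weights` (tibble with `time_s` and `w1..w9`), `reference`.
#' @export
stinr_infer <- function(fit, times_s, grid_template = NULL, clip = TRUE) {
  if (any(times_s < fit$t_range[1] - 1e-9 | times_s > fit$t_range[2] + 1e-9)) {
    stop("times outside the scan window")
  }
  t_norm <- (times_s - fit$t_range[1]) /
    max(diff(fit$t_range), 1e-12)
  W <- temporal_inr_eval(fit$temporal, t_norm)
  if (!is.null(fit$w_bound)) {
    W <- pmin(pmax(W, -fit$w_bound), fit$w_bound)
  }
  ref <- stinr_reference(fit, grid_template, clip = clip)
  model <- fit$model
  if (!all(dim(ref$data) == model$dims)) {
    model <- resample_motion_model(model, dim(ref$data), ref$spacing)
  }
  mm <- model_matrix(model)
  vols <- vector("list", length(times_s))
  dvfs <- vector("list", length(times_s))
  for (i in seq_along(times_s)) {
    d <- array(mm$pc0 + mm$P %*% W[i, ], c(dim(ref$data), 3))
    dvfs[[i]] <- d
    vols[[i]] <- warp_volume(ref, d)
  }
  wtb <- tibble::as_tibble(stats::setNames(as.data.frame(W), paste0("w", 1:ncol(W))))
  wtb <- tibble::add_column(wtb, time_s = times_s, .before = 1)
  list(volumes = vols, dvfs = dvfs, weights = wtb, reference = ref)
}

#' Save / load a fitted spatiotemporal model
#'
#' Checkpoints carry the spatial and temporal MLP parameters, the frozen
#' encoder seeds and shapes, the motion model and the grid/normalisation
#' metadata, so inference can be reproduced bit-identically in a new session.
#'
#' @param fit a `stinr_fit`.
#' @param path checkpoint file path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_stinr_fit <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_stinr_fit
#' @export
load_stinr_fit <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "stinr_fit"))
  fit
}

#' ART + total-variation reconstruction configuration
#' @param lambda ART relaxation factor, in (0, 2).
#' @param n_alt number of ART/TV alternations.
#' @param tv_steps TV descent steps per alternation.
#' @param tv_scale TV step length as a fraction of the preceding ART update
#'   norm.
#' @param nonneg clip negative attenuation after each sweep.
#' @return An `art_tv_config` list.
#' @export
art_tv_config <- function(lambda = 0.4, n_alt = 20L, tv_steps = 10L,
                          tv_scale = 0.1, nonneg = TRUE) {
  if (lambda <= 0 || lambda >= 2) stop("lambda must be in (0, 2)")
  structure(list(lambda = lambda, n_alt = as.integer(n_alt),
                 tv_steps = as.integer(tv_steps), tv_scale = tv_scale,
                 nonneg = nonneg),
            class = "art_tv_config")
}

tv_gradient <- function(arr, eps = 1e-8) {
  d <- dim(arr)
  shift <- function(a, k, by) {
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[k]] <- pmin(pmax(idx[[k]] + by, 1), d[k])
    a[idx[[1]], idx[[2]], idx[[3]]]
  }
  gx <- shift(arr, 1, 1) - arr
  gy <- shift(arr, 2, 1) - arr
  gz <- shift(arr, 3, 1) - arr
  nrm <- sqrt(gx^2 + gy^2 + gz^2 + eps)
  div <- (gx + gy + gz) / nrm -
    (shift(gx / nrm, 1, -1) + shift(gy / nrm, 2, -1) + shift(gz / nrm, 3, -1))
  -div
}

#' Algebraic reconstruction with total-variation regularisation
#'
#' Alternates relaxed algebraic update sweeps (simultaneous over each view's
#' rays, normalised by ray and voxel weight sums) with steepest-descent steps
#' on the smoothed isotropic TV norm, the classic regularised algebraic
#' scheme used to reconstruct a reference volume from a sparse projection
#' subset.
#'
#' @param pset a `stinr_projections` (>= 1 view).
#' @param template reconstruction-grid `stinr_volume`.
#' @param config an [art_tv_config()].
#' @return A `stinr_volume`.
#' @export
art_tv_reconstruct <- function(pset, template, config = art_tv_config()) {
  grid <- grid_info(template)
  geom <- pset$geometry
  nview <- dim(pset$images)[3]
  if (nview < 1) stop("need at least one view")
  step <- min(grid$spacing) / 2
  mu <- array(0, grid$dims)
  ones_vol <- array(1, grid$dims)
  npix <- prod(geom$det_shape)
  row_sums <- vector("list", nview)
  for (a in seq_len(nview)) {
    row_sums[[a]] <- project_single_view(ones_vol, grid, geom,
                                         pset$angles_deg[a] * pi / 180, step)
  }
  for (alt in seq_len(config$n_alt)) {
    mu_before <- mu
    for (a in seq_len(nview)) {
      ang <- pset$angles_deg[a] * pi / 180
      r <- pset$images[, , a, drop = FALSE] -
        project_single_view(mu, grid, geom, ang, step)
      r <- r / (row_sums[[a]] + 1e-9)
      num <- backproject_single_view(r, grid, geom, ang, step)
      den <- backproject_single_view(array(1, dim(r)), grid, geom, ang, step)
      mu <- mu + config$lambda * num / (den + 1e-9)
      if (config$nonneg) mu[mu < 0] <- 0
    }
    du <- sqrt(sum((mu - mu_before)^2))
    if (du < 1e-14) break
    for (s in seq_len(config$tv_steps)) {
      g <- tv_gradient(mu)
      gn <- sqrt(sum(g^2))
      if (gn < 1e-14) break
      mu <- mu - config$tv_scale * du / gn * g
      if (config$nonneg) mu[mu < 0] <- 0
    }
  }
  new_volume(mu, grid$spacing, grid$origin)
}

#' Per-projection PCA-weight fitting (conventional PCA method)
#'
#' The single-projection-driven comparator: with a fixed reference volume and
#' the same PCA motion model, the 9 component weights of each frame are fitted
#' independently by minimising the squared mismatch between the projected
#' warped reference and that frame's measured projection, using
#' Polak-Ribiere nonlinear conjugate gradient with an Armijo line search and
#' warm starts from the previous frame.
#'
#' @param pset the dynamic `stinr_projections`.
#' @param model the motion model on the reference grid.
#' @param mu reference `stinr_volume` (e.g. an ART+TV reconstruction of the
#'   end-expiration subset).
#' @param max_iter NLCG iterations per frame.
#' @param w_bound box bound on the scaled weights.
#' @param g_tol gradient-norm stopping tolerance.
#' @return A list: `weights` (frames x 9 matrix), `flags` (frames where the
#'   line search failed and the previous frame's weights were kept),
#'   `objective` (final per-frame loss).
#' @export
pca_cv_fit <- function(pset, model, mu, max_iter = 60L, w_bound = 4,
                       g_tol = 1e-10) {
  grid <- grid_info(mu)
  if (!all(model$dims == grid$dims)) {
    model <- resample_motion_model(model, grid$dims, grid$spacing)
  }
  geom <- pset$geometry
  step <- min(grid$spacing) / 2
  mm <- model_matrix(model)
  n_frames <- dim(pset$images)[3]
  nw <- ncol(mm$P)
  V <- mu$data
  clamp <- function(w) pmin(pmax(w, -w_bound), w_bound)

  fg <- function(w, fidx) {
    ang <- pset$angles_deg[fidx] * pi / 180
    d <- array(mm$pc0 + mm$P %*% w, c(grid$dims, 3))
    Vt <- cpp_warp(V, grid$dims, grid$spacing, d)
    drr <- project_single_view(Vt, grid, geom, ang, step)
    r <- drr - pset$images[, , fidx, drop = FALSE]
    g_vt <- backproject_single_view(2 * r, grid, geom, ang, step)
    gD <- cpp_warp_grad_dvf(V, grid$dims, grid$spacing, d, g_vt)
    list(f = sum(r^2), g = drop(crossprod(mm$P, as.numeric(gD))))
  }

  weights <- matrix(0, n_frames, nw)
  flags <- logical(n_frames)
  objective <- numeric(n_frames)
  w <- numeric(nw)
  for (fidx in seq_len(n_frames)) {
    eval0 <- fg(w, fidx)
    f <- eval0$f; g <- eval0$g
    d <- -g
    alpha <- 1 / max(sqrt(sum(g^2)), 1e-12)
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      gg <- sum(g^2)
      if (gg < g_tol) { ok <- TRUE; break }
      ## Armijo backtracking along d
      slope <- sum(g * d)
      if (slope >= 0) { d <- -g; slope <- -gg }
      accepted <- FALSE
      a <- alpha
      for (ls in 1:20) {
        w_new <- clamp(w + a * d)
        ev <- fg(w_new, fidx)
        if (ev$f <= f + 1e-4 * a * slope) { accepted <- TRUE; break }
        a <- a / 2
      }
      if (!accepted) break
      ok <- TRUE
      alpha <- a * 2
      beta <- max(0, sum(ev$g * (ev$g - g)) / max(sum(g^2), 1e-300))
      d <- -ev$g + beta * d
      w <- w_new; f <- ev$f; g <- ev$g
    }
    if (!ok && fidx > 1) {
      w <- weights[fidx - 1, ]
      flags[fidx] <- TRUE
      f <- fg(w, fidx)$f
    }
    weights[fidx, ] <- w
    objective[fidx] <- f
  }
  list(weights = weights, flags = flags, objective = objective,
       model = model)
}

#' Polynomial-in-time motion configuration for the temporal baseline
#' @param order polynomial order `p >= 1`.
#' @param iters Adam iterations.
#' @param lr learning rate.
#' @param batch_frames frames per iteration.
#' @param preset spatial INR architecture.
#' @param seed RNG seed.
#' @return A `poly_motion_config` list.
#' @export
poly_motion_config <- function(order = 3L, iters = 2000L, lr = 0.002,
                               lr_decay = 1, batch_frames = 8L,
                               preset = inr_preset("scaled"), seed = 1L) {
  if (order < 1) stop("polynomial order must be >= 1")
  structure(list(order = as.integer(order), iters = as.integer(iters),
                 lr = lr, lr_decay = lr_decay,
                 batch_frames = as.integer(batch_frames),
                 preset = preset, seed = as.integer(seed)),
            class = "poly_motion_config")
}

#' Spatial INR with polynomial temporal motion (baseline)
#'
#' The prior-free baseline: a spatial coordinate MLP for the reference volume
#' plus per-voxel motion-coefficient grids weighted by temporal polynomials,
#' `D(x, t) = sum_{k=1..p} t^k M_k(x)`, optimised jointly under the same
#' projection loss. Without a motion prior, high-frequency periodic motion is
#' outside the model class — the known failure mode this baseline exists to
#' demonstrate.
#'
#' @param pset the dynamic `stinr_projections`.
#' @param template optimisation-grid `stinr_volume`.
#' @param config a [poly_motion_config()].
#' @return A `inr_poly_fit` object: `spatial`, `M` (array
#'   `nvox x 3 x order`, mm), `grid`, `t_range`, `trace`.
#' @export
inr_poly_fit <- function(pset, template, config = poly_motion_config()) {
  grid <- grid_info(template)
  geom <- pset$geometry
  step <- min(grid$spacing) / 2
  n_frames <- dim(pset$images)[3]
  nvox <- prod(grid$dims)
  p <- config$order

  sinr <- spatial_inr(config$preset, seed = config$seed)
  coords <- normalized_coordinates(template)
  enc_grid <- grff_encode(sinr$encoder, coords)
  ## warm start the reference on a plain FDK of all frames (motion-blurred)
  fdk_all <- fdk_reconstruct(pset, template)
  s1 <- fit_spatial_to_volume(sinr, as.numeric(fdk_all$data), enc_grid,
                              300L, config$lr)
  sinr <- s1$sinr

  t_norm <- (pset$times_s - pset$times_s[1]) /
    max(pset$times_s[n_frames] - pset$times_s[1], 1e-12)
  tpow <- outer(t_norm, seq_len(p), "^")     # n_frames x p

  M <- array(0, c(nvox, 3, p))
  mM <- array(0, dim(M)); vM <- array(0, dim(M))
  st_theta <- adam_init(sinr$net)
  trace <- numeric(config$iters)
  set.seed(config$seed + 1L)
  b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8
  ws <- mlp_ws_new(enc_grid)
  s_att <- sinr$att_scale %||% 1
  lrs <- lr_schedule(config$lr, config$lr_decay %||% 1, config$iters)
  for (it in seq_len(config$iters)) {
    V <- mlp_ws_forward(ws, sinr$net) * s_att
    frames <- sample.int(n_frames, min(config$batch_frames, n_frames))
    dvfs <- lapply(frames, function(fidx) {
      d <- matrix(0, nvox, 3)
      for (k in seq_len(p)) d <- d + tpow[fidx, k] * M[, , k]
      array(d, c(grid$dims, 3))
    })
    pass <- stage_projection_pass(V, grid, geom, pset, frames, step, dvfs)
    trace[it] <- pass$loss
    if (!is.finite(pass$loss)) stop("polynomial-motion fit diverged")
    gM <- array(0, dim(M))
    for (j in seq_along(frames)) {
      gd <- pass$g_D[[j]]
      for (k in seq_len(p)) {
        gM[, , k] <- gM[, , k] + tpow[frames[j], k] * gd
      }
    }
    ## Adam on the coefficient grids
    mM <- b1 * mM + (1 - b1) * gM
    vM <- b2 * vM + (1 - b2) * gM^2
    bc1 <- 1 - b1^it; bc2 <- 1 - b2^it
    M <- M - lrs[it] * (mM / bc1) / (sqrt(vM / bc2) + epsa)
    grads <- mlp_ws_backward(ws, sinr$net, pass$g_V * s_att)
    upd <- adam_step(sinr$net, grads, st_theta, lrs[it])
    sinr$net <- upd$net; st_theta <- upd$state
  }
  structure(list(spatial = sinr, M = M, grid = grid,
                 t_range = range(pset$times_s), order = p,
                 config = config, trace = trace),
            class = "inr_poly_fit")
}

#' Deformation fields of a fitted polynomial-motion baseline
#' @param fit an `inr_poly_fit`.
#' @param times_s query times within the scan window.
#' @return List of DVF arrays `c(dims, 3)` (mm).
#' @export
inr_poly_dvfs <- function(fit, times_s) {
  t_norm <- (times_s - fit$t_range[1]) / max(diff(fit$t_range), 1e-12)
  nvox <- prod(fit$grid$dims)
  lapply(t_norm, function(tn) {
    d <- matrix(0, nvox, 3)
    for (k in seq_len(fit$order)) d <- d + tn^k * fit$M[, , k]
    array(d, c(fit$grid$dims, 3))
  })
}
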