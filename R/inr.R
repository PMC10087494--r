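#' Swish activation
#'
#' `swish(y) = y * sigmoid(y) = y / (1 + exp(-y))`, the smooth self-gated
#' activation used throughout the coordinate MLPs.
#'
#' @param y numeric vector/matrix.
#' @return Elementwise swish of `y`.
#' @export
swish <- function(y) y / (1 + exp(-y))

swish_grad <- function(y) {
  s <- 1 / (1 + exp(-y))
  s * (1 + y * (1 - s))
}

#' Gaussian random Fourier feature encoder
#'
#' Frozen random projection matrix `B` with i.i.d. `N(0, sigma^2)` entries;
#' coordinates are encoded as `gamma(x) = [sin(2 pi B x), cos(2 pi B x)]`.
#' Spatial coordinates are expected in `[-1, 1]^3` and temporal coordinates in
#' `[0, 1]`. The encoder is fixed after initialisation; only its seed and shape
#' need to be stored to reproduce it.
#'
#' @param in_dim input dimensionality (3 spatial, 1 temporal).
#' @param n_features number of Fourier features (output dim is `2 * n_features`).
#' @param sigma Gaussian width of `B`. Presets: 2.5 (digital-phantom studies)
#'   and 4 (patient studies).
#' @param seed RNG seed for `B`.
#' @return A `grff_encoder` object.
#' @export
grff_encoder <- function(in_dim, n_features = 128, sigma = 2.5, seed = 1L) {
  set.seed(seed)
  B <- matrix(stats::rnorm(n_features * in_dim, sd = sigma), n_features, in_dim)
  structure(list(B = B, in_dim = in_dim, n_features = n_features,
                 sigma = sigma, seed = seed),
            class = "grff_encoder")
}

#' Encode coordinates with a GRFF encoder
#'
#' @param encoder a [grff_encoder()].
#' @param coords numeric matrix `n x in_dim` (a vector is treated as one
#'   column for `in_dim = 1`).
#' @return `n x (2 * n_features)` matrix `[sin block, cos block]`, all entries
#'   in `[-1, 1]`.
#' @export
grff_encode <- function(encoder, coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = encoder$in_dim)
  stopifnot(ncol(coords) == encoder$in_dim)
  proj <- 2 * pi * coords %*% t(encoder$B)
  cbind(sin(proj), cos(proj))
}

## ---- dense MLP with hand-rolled backprop -------------------------------

mlp_init <- function(sizes, seed = 1L, out_scale = 1) {
  # sizes: c(in, hidden..., out); Xavier-uniform weights, zero biases
  set.seed(seed)
  layers <- vector("list", length(sizes) - 1)
  for (l in seq_along(layers)) {
    fi <- sizes[l]; fo <- sizes[l + 1]
    lim <- sqrt(6 / (fi + fo))
    W <- matrix(stats::runif(fi * fo, -lim, lim), fi, fo)
    if (l == length(layers)) W <- W * out_scale
    layers[[l]] <- list(W = W, b = numeric(fo))
  }
  structure(list(layers = layers, sizes = sizes), class = "stinr_mlp")
}

net_Ws <- function(net) lapply(net$layers, `[[`, "W")
net_bs <- function(net) lapply(net$layers, function(l) matrix(l$b, nrow = 1))

mlp_forward <- function(net, X) {
  list(out = cpp_mlp_forward(net_Ws(net), net_bs(net), X))
}

# forward pass that caches inputs, pre-activations and sigmoids for backprop
mlp_forward_train <- function(net, X) {
  fw <- cpp_mlp_forward_train(net_Ws(net), net_bs(net), X)
  list(out = fw$out, cache = fw)
}

mlp_backward <- function(net, cache, g_out) {
  # per-layer gradients; g_out is dLoss/d(output), n x out
  g <- cpp_mlp_backward(net_Ws(net), cache$A_in, cache$Z, cache$S, g_out)
  lapply(seq_along(net$layers), function(l) {
    list(W = g$W[[l]], b = drop(g$b[[l]]))
  })
}

# workspace variants: the encoding matrix and all layer caches live in C++
# memory across iterations (scalar-output nets only)
mlp_ws_new <- function(X) cpp_mlp_ws_new(X)

mlp_ws_forward <- function(ws, net) {
  drop(cpp_mlp_ws_fwd(ws, net_Ws(net), net_bs(net)))
}

mlp_ws_backward <- function(ws, net, g_vec) {
  g <- cpp_mlp_ws_bwd(ws, net_Ws(net), g_vec)
  lapply(seq_along(net$layers), function(l) {
    list(W = g$W[[l]], b = drop(g$b[[l]]))
  })
}

## ---- Adam ---------------------------------------------------------------

adam_init <- function(net) {
  state <- lapply(net$layers, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
  list(t = 0, layers = state)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$layers)) {
    s <- state$layers[[l]]
    g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    net$layers[[l]]$W <- net$layers[[l]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state$layers[[l]] <- s
  }
  list(net = net, state = state)
}

## ---- spatial / temporal INRs --------------------------------------------

#' Architecture presets for the implicit representations
#'
#' `"full"` matches the reference architecture: 128 Fourier features
#' (sigma 2.5), a 4-layer 256-neuron spatial MLP and nine 3-layer
#' (256, 100, 100) temporal sub-MLPs. `"scaled"` is a CPU-friendly preset
#' (64 spatial / 32 temporal features, 64-neuron spatial layers,
#' (64, 32, 32) temporal layers) used for desk-scale studies.
#'
#' @param name `"full"` or `"scaled"`.
#' @param sigma_spatial GRFF width for spatial coordinates (preset 2.5; use 4
#'   for patient-like data).
#' @return A list of architecture settings.
#' @export
inr_preset <- function(name = c("scaled", "full"), sigma_spatial = 2.5) {
  name <- match.arg(name)
  if (name == "full") {
    list(n_features = 128L, n_features_temporal = 128L,
         sigma_spatial = sigma_spatial, sigma_temporal = 2.5,
         spatial_hidden = c(256L, 256L, 256L),
         temporal_hidden = c(256L, 100L, 100L), att_scale = 0.02)
  } else {
    # the reduced temporal encoder (32 features) is deliberately band-limited:
    # each frame's weight is informed by a single projection, and the
    # restricted encoder band acts as a temporal smoothness prior on the
    # per-frame weight estimates
    list(n_features = 64L, n_features_temporal = 32L,
         sigma_spatial = sigma_spatial, sigma_temporal = 2.5,
         spatial_hidden = c(64L, 64L, 64L),
         temporal_hidden = c(64L, 32L, 32L), att_scale = 0.02)
  }
}

#' Initialise a spatial implicit representation
#'
#' A coordinate MLP mapping GRFF-encoded normalised 3-D coordinates to a scalar
#' attenuation value. Internally the network works in units of `att_scale`
#' mm^-1 (0.02, a soft-tissue attenuation) so that activations, gradients and
#' the loss are O(1); outputs are rescaled to mm^-1. The output layer is
#' linear (no non-negativity activation); negative attenuations are clipped
#' only at export.
#'
#' @param preset an [inr_preset()] list.
#' @param seed seed controlling both the encoder matrix and the weight init.
#' @return A `spatial_inr` object.
#' @export
spatial_inr <- function(preset = inr_preset(), seed = 1L) {
  enc <- grff_encoder(3L, preset$n_features, preset$sigma_spatial, seed)
  net <- mlp_init(c(2L * preset$n_features, preset$spatial_hidden, 1L),
                  seed = seed + 1L, out_scale = 0.1)
  structure(list(encoder = enc, net = net, preset = preset, seed = seed,
                 att_scale = preset$att_scale %||% 1),
            class = "spatial_inr")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a spatial INR at arbitrary coordinates
#'
#' Grid-free: any set of normalised coordinates may be queried, which is how
#' volumes of arbitrary resolution are rendered at inference time.
#'
#' @param model a [spatial_inr()].
#' @param coords_norm `n x 3` matrix in `[-1, 1]^3`.
#' @return Numeric vector of `n` attenuation values.
#' @export
spatial_inr_eval <- function(model, coords_norm) {
  if (any(!is.finite(coords_norm))) stop("non-finite query coordinates")
  enc <- grff_encode(model$encoder, coords_norm)
  drop(mlp_forward(model$net, enc)$out) * (model$att_scale %||% 1)
}

#' Initialise the temporal implicit representations
#'
#' Nine independent sub-MLPs, one per (Cartesian direction, principal
#' component) pair, each mapping the GRFF-encoded normalised timestamp to one
#' unbounded scalar weight. The output layers start near zero so the initial
#' deformation state is the motion-model mean.
#'
#' @param preset an [inr_preset()].
#' @param n_sub number of sub-MLPs (3 directions x 3 components).
#' @param seed base seed; sub-MLP `k` uses `seed + k`.
#' @return A `temporal_inr` object.
#' @export
temporal_inr <- function(preset = inr_preset(), n_sub = 9L, seed = 100L) {
  nf <- preset$n_features_temporal %||% preset$n_features
  enc <- grff_encoder(1L, nf, preset$sigma_temporal, seed)
  nets <- lapply(seq_len(n_sub), function(k) {
    mlp_init(c(2L * nf, preset$temporal_hidden, 1L),
             seed = seed + k, out_scale = 0.01)
  })
  structure(list(encoder = enc, nets = nets, preset = preset, seed = seed),
            class = "temporal_inr")
}

#' Evaluate the temporal INRs
#'
#' @param model a [temporal_inr()].
#' @param times numeric vector of normalised times in `[0, 1]`.
#' @return An `n x 9` matrix of weights; column `(dim - 1) * 3 + n` is the
#'   weight of component `n` along direction `dim` (x, y, z = SI).
#' @export
temporal_inr_eval <- function(model, times) {
  if (any(times < -1e-9 | times > 1 + 1e-9)) {
    stop("times must be normalised to [0, 1]")
  }
  enc <- grff_encode(model$encoder, matrix(times, ncol = 1))
  do.call(cbind, lapply(model$nets, function(net) drop(mlp_forward(net, enc)$out)))
}

#' Backward-warp a volume by a displacement field
#'
#' `out(x) = in(x + D(x))` by trilinear interpolation with clamp-to-edge
#' boundary handling (no NaNs). Differentiable with respect to both the volume
#' (the adjoint is the transpose scatter) and the displacement field.
#'
#' @param vol a `stinr_volume`.
#' @param dvf displacement array `c(dim(vol), 3)` in mm, on the output grid,
#'   pointing from output coordinates into input coordinates.
#' @return A `stinr_volume`.
#' @export
warp_volume <- function(vol, dvf) {
  stopifnot(all(dim(dvf) == c(dim(vol$data), 3)))
  arr <- cpp_warp(vol$data, dim(vol$data), vol$spacing, dvf)
  new_volume(arr, vol$spacing, vol$origin)
}
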