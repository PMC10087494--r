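test_that("swish matches its closed form and limits", {
  expect_equal(swish(0), 0)
  expect_equal(swish(1), 1 / (1 + exp(-1)))
  expect_equal(swish(50) / 50, 1, tolerance = 1e-9)
  expect_equal(swish(c(-2, 3)), c(-2, 3) * stats::plogis(c(-2, 3)))
})

test_that("random Fourier encoding is frozen, bounded and correct at zero", {
  enc <- grff_encoder(3, n_features = 16, sigma = 2.5, seed = 5)
  enc2 <- grff_encoder(3, n_features = 16, sigma = 2.5, seed = 5)
  expect_identical(enc$B, enc2$B)

  z <- grff_encode(enc, matrix(0, 1, 3))
  expect_equal(z[1, 1:16], rep(0, 16))       # sin block
  expect_equal(z[1, 17:32], rep(1, 16))      # cos block

  set.seed(6)
  x <- matrix(runif(300, -1, 1), 100, 3)
  g <- grff_encode(enc, x)
  expect_true(all(g >= -1 & g <= 1))
  expect_equal(dim(g), c(100, 32))
  expect_identical(g, grff_encode(enc2, x))
})

test_that("spatial INR is deterministic, differentiable and has fitting capacity", {
  preset <- inr_preset("scaled")
  m <- spatial_inr(preset, seed = 3)
  x <- matrix(c(0.1, -0.4, 0.7, 0.1, -0.4, 0.7), 2, 3, byrow = TRUE)
  v <- spatial_inr_eval(m, x)
  expect_equal(v[1], v[2])
  expect_error(spatial_inr_eval(m, matrix(NaN, 1, 3)), "coordinates")

  # overfitting capacity: SSD on a smooth 16^3 volume drops >= 10x in 500 steps
  vol <- smooth_random_volume(16)
  target <- as.numeric(vol$data)
  enc <- grff_encode(m$encoder, normalized_coordinates(vol))
  ssd0 <- sum((drop(mlp_forward(m$net, enc)$out) * m$att_scale - target)^2)
  fit <- fit_spatial_to_volume(m, target, enc, 500L, 0.002)
  ssd1 <- sum((drop(mlp_forward(fit$sinr$net, enc)$out) * m$att_scale -
                 target)^2)
  expect_lt(ssd1, ssd0 / 10)

  # analytic gradients agree with finite differences through the full stack
  ws <- mlp_ws_new(enc[1:500, , drop = FALSE])
  f <- function(net) sum(mlp_ws_forward(ws, net)^2)
  g <- mlp_ws_backward(ws, m$net, 2 * mlp_ws_forward(ws, m$net))
  for (probe in list(c(1, 2, 3), c(3, 10, 1))) {
    l <- probe[1]
    net2 <- m$net
    eps <- 1e-6
    net2$layers[[l]]$W[probe[2], probe[3]] <-
      net2$layers[[l]]$W[probe[2], probe[3]] + eps
    num <- (f(net2) - f(m$net)) / eps
    expect_equal(g[[l]]$W[probe[2], probe[3]], num, tolerance = 1e-3)
  }
})

test_that("rendered volumes are resolution-consistent (grid-free queries)", {
  vol <- smooth_random_volume(16)
  m <- spatial_inr(inr_preset("scaled"), seed = 3)
  enc <- grff_encode(m$encoder, normalized_coordinates(vol))
  fit <- fit_spatial_to_volume(m, as.numeric(vol$data), enc, 400L, 0.01)
  # query at 32^3 over the same extent, downsample back to 16^3
  hi <- new_volume(array(0, rep(32, 3)), rep(96 / 32, 3))
  v_hi <- spatial_inr_eval(fit$sinr, normalized_coordinates(hi))
  hi$data <- array(v_hi, rep(32, 3))
  down <- resample_volume(hi, rep(16, 3))
  lo <- array(spatial_inr_eval(fit$sinr, normalized_coordinates(vol)),
              rep(16, 3))
  # interior agreement within trilinear interpolation tolerance
  core <- 3:14
  expect_equal(down$data[core, core, core], lo[core, core, core],
               tolerance = 0.15)
})

test_that("temporal INRs are independent sub-networks with 1-D fitting capacity", {
  tm <- temporal_inr(inr_preset("scaled"), seed = 11)
  w <- temporal_inr_eval(tm, c(0.3, 0.3))
  expect_equal(w[1, ], w[2, ])
  expect_equal(dim(w), c(2, 9))
  expect_error(temporal_inr_eval(tm, 1.5), "normalised")

  # perturbing one sub-MLP leaves the others unchanged
  tm2 <- tm
  tm2$nets[[4]]$layers[[1]]$W <- tm2$nets[[4]]$layers[[1]]$W + 0.5
  w2 <- temporal_inr_eval(tm2, c(0.3, 0.3))
  expect_equal(w2[, -4], w[, -4])
  expect_false(isTRUE(all.equal(w2[, 4], w[, 4])))

  # regression capacity: fit one sub-MLP to a sinusoid, r >= 0.99
  t_tr <- seq(0, 1, length.out = 120)
  target <- sin(2 * pi * 3 * t_tr) * 1.5
  enc <- grff_encode(tm$encoder, matrix(t_tr, ncol = 1))
  net <- tm$nets[[1]]
  st <- adam_init(net)
  for (it in 1:500) {
    fw <- mlp_forward_train(net, enc)
    r <- drop(fw$out) - target
    g <- mlp_backward(net, fw$cache, matrix(2 * r / length(r), ncol = 1))
    upd <- adam_step(net, g, st, 0.01)
    net <- upd$net; st <- upd$state
  }
  pred <- drop(mlp_forward(net, enc)$out)
  expect_gte(cor(pred, target), 0.99)
})

test_that("warp is exact on oracles and clamps at the boundary", {
  vol <- smooth_random_volume(16)
  dims <- dim(vol$data)
  d0 <- array(0, c(dims, 3))
  expect_equal(warp_volume(vol, d0)$data, vol$data)

  # constant one-voxel SI displacement: interior equals a direct index shift
  d1 <- d0; d1[, , , 3] <- vol$spacing[3]
  w <- warp_volume(vol, d1)
  expect_equal(w$data[, , 1:15], vol$data[, , 2:16])

  # far out-of-bounds displacements clamp to edge values, never NaN
  d2 <- d0; d2[, , , 1] <- 1e4
  w2 <- warp_volume(vol, d2)
  expect_true(all(is.finite(w2$data)))
  expect_equal(w2$data[5, , ], vol$data[16, , ])

  # adjoint identity for the warp pair
  set.seed(3)
  g_out <- array(rnorm(prod(dims)), dims)
  dr <- d0; dr[, , , ] <- rnorm(length(dr), sd = 4)
  lhs <- sum(cpp_warp(vol$data, dims, vol$spacing, dr) * g_out)
  rhs <- sum(vol$data * cpp_warp_adjoint(g_out, dims, vol$spacing, dr))
  expect_equal(lhs, rhs, tolerance = 1e-10)

  # displacement gradient matches finite differences
  gd <- cpp_warp_grad_dvf(vol$data, dims, vol$spacing, dr, g_out)
  i <- 1000
  for (k in 1:3) {
    dp <- dr; dp[, , , k][i] <- dp[, , , k][i] + 1e-5
    num <- (sum(cpp_warp(vol$data, dims, vol$spacing, dp) * g_out) - lhs) / 1e-5
    expect_equal(gd[i, k], num, tolerance = 1e-3)
  }
})
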