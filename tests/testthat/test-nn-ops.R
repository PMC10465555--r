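# The conv/pool/resize kernels are validated against independent plain-R
# oracles on tiny tensors, and their backward passes against the adjoint
# identity <A x, y> = <x, A' y>.

test_that("conv3d forward matches the direct-loop oracle", {
  em <- asNamespace("emphysemap")
  set.seed(12)
  cases <- list(list(xd = c(5, 4, 6, 2), k = 3, cout = 3, s = 1, p = 1),
                list(xd = c(6, 6, 6, 1), k = 3, cout = 2, s = 2, p = 1),
                list(xd = c(7, 6, 5, 2), k = 1, cout = 4, s = 1, p = 0),
                list(xd = c(8, 8, 8, 1), k = 7, cout = 2, s = 2, p = 3))
  for (cs in cases) {
    x <- array(rnorm(prod(cs$xd)), cs$xd)
    w <- array(rnorm(cs$k^3 * cs$xd[4] * cs$cout),
               c(cs$k, cs$k, cs$k, cs$xd[4], cs$cout))
    b <- rnorm(cs$cout)
    y <- em$cpp_conv3d_fwd(x, dim(x), w,
                           as.integer(c(cs$k, cs$k, cs$k, cs$xd[4],
                                        cs$cout)), cs$s, cs$p, b, NULL)
    expect_equal(y, naive_conv3d(x, w, cs$s, cs$p, b), tolerance = 1e-5)
  }
})

test_that("conv3d backward satisfies the adjoint identity and dW oracle", {
  em <- asNamespace("emphysemap")
  set.seed(13)
  xd <- c(5, 5, 6, 2); k <- 3L; cout <- 3L
  kd <- as.integer(c(k, k, k, 2, cout))
  x <- array(rnorm(prod(xd)), xd)
  w <- array(rnorm(k^3 * 2 * cout), c(k, k, k, 2, cout))
  y <- em$cpp_conv3d_fwd(x, dim(x), w, kd, 1L, 1L, NULL, NULL)
  dy <- array(rnorm(length(y)), dim(y))
  g <- em$cpp_conv3d_bwd(x, dim(x), w, kd, dy, 1L, 1L, FALSE, TRUE, NULL)
  # adjoint identity: <conv(x), dy> == <x, conv'(dy)> for the linear map
  expect_equal(sum(y * dy), sum(x * g$dx), tolerance = 1e-4)
  # weight gradient via finite differences on a few entries
  # the map is linear in w, so a large step is exact and averages away the
  # single-precision noise of the forward pass
  for (i in sample(length(w), 5)) {
    wp <- w; wp[i] <- wp[i] + 0.05
    wm <- w; wm[i] <- wm[i] - 0.05
    fd <- (sum(em$cpp_conv3d_fwd(x, dim(x), wp, kd, 1L, 1L, NULL, NULL) * dy) -
           sum(em$cpp_conv3d_fwd(x, dim(x), wm, kd, 1L, 1L, NULL, NULL) * dy)) /
          0.1
    expect_equal(g$dw[i], fd, tolerance = 0.01)
  }
})

test_that("maxpool matches a direct oracle and routes gradients correctly", {
  em <- asNamespace("emphysemap")
  set.seed(14)
  x <- array(rnorm(6 * 6 * 6 * 2), c(6, 6, 6, 2))
  r <- em$cpp_maxpool3d_fwd(x, dim(x), 3L, 2L, 1L)
  # oracle: brute-force max within each padded window
  d <- dim(r$y)
  for (ci in 1:2) for (ow in 1:d[3]) for (oh in 1:d[2]) for (od in 1:d[1]) {
    ids <- function(o, n) max(1, (o - 1) * 2 - 1 + 1):min(n, (o - 1) * 2 + 2)
    win <- x[ids(od, 6), ids(oh, 6), ids(ow, 6), ci]
    expect_equal(r$y[od, oh, ow, ci], max(win))
  }
  dy <- array(rnorm(prod(d)), d)
  dx <- em$cpp_maxpool3d_bwd(r$idx, dy, dim(x))
  expect_equal(sum(dx), sum(dy))  # gradient mass is preserved
  expect_true(all(dx[setdiff(seq_along(x), r$idx + 1)] == 0))
})

test_that("trilinear resize is exact on identity and linear ramps", {
  em <- asNamespace("emphysemap")
  x <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  expect_identical(resize3d(x, c(4, 5, 6)), x)
  # a linear ramp resampled at half-pixel centres stays linear (interior)
  ramp <- array(rep(seq_len(16), 8 * 8), c(16, 8, 8))
  up <- resize3d(ramp, c(32, 8, 8))
  expect_equal(diff(up[3:30, 4, 4]), rep(0.5, 27), tolerance = 1e-12)
  # constant fields are preserved exactly under any resize
  cst <- array(3.7, c(5, 6, 7))
  expect_equal(resize3d(cst, c(9, 4, 11)), array(3.7, c(9, 4, 11)))
})

test_that("resize adjoint satisfies the inner-product identity", {
  em <- asNamespace("emphysemap")
  set.seed(15)
  xd <- c(5L, 6L, 7L, 2L); od <- c(9L, 4L, 13L, 2L)
  x <- array(rnorm(prod(xd)), xd)
  y <- array(rnorm(prod(od)), od)
  Ax <- em$cpp_resize3d(x, xd, od)
  Aty <- em$cpp_resize3d_adjoint(y, od, xd)
  expect_equal(sum(Ax * y), sum(x * Aty), tolerance = 1e-10)
})

test_that("euclidean distance transform matches brute force on a blob", {
  em <- asNamespace("emphysemap")
  m <- array(0, c(8, 9, 7)); m[3:6, 3:7, 2:6] <- 1
  d <- em$cpp_edt3d(as.numeric(m), dim(m))
  zeros <- which(m == 0, arr.ind = TRUE)
  ones <- which(m == 1, arr.ind = TRUE)
  for (r in sample(nrow(ones), 10)) {
    v <- ones[r, ]
    bf <- sqrt(min(colSums((t(zeros) - v)^2)))
    # border voxels also count as background
    edge <- min(v, dim(m) - v + 1)
    expect_equal(d[v[1], v[2], v[3]], min(bf, edge))
  }
  expect_true(all(d[m == 0] == 0))
})

test_that("network autodiff agrees with finite differences", {
  # single-precision conv kernels: FD agreement is checked at a float32
  # tolerance; the loss-level gradients are validated at 1e-4 elsewhere
  em <- asNamespace("emphysemap")
  net <- tiny_net(seed = 5)
  set.seed(16)
  x <- array(runif(16 * 16 * 24), c(16, 16, 24))
  md <- array(1, c(8, 8, 12))
  td <- array(rbinom(8 * 8 * 12, 1, 0.2), c(8, 8, 12))
  ivc <- score_to_interval("cle", 2)
  ivp <- score_to_interval("pse", 1)
  cfg <- loss_config()
  loss_of <- function() {
    cache <- em$nn_forward(net, x, train = TRUE)
    za <- get("head_cle", cache); zb <- get("head_pse", cache)
    a <- em$sigmoid(za); b <- em$sigmoid(zb)
    dim(a) <- dim(a)[1:3]; dim(b) <- dim(b)[1:3]
    em$regression_loss_grads(a, b, md, td, ivc, ivp, cfg)
  }
  base <- loss_of()
  cache <- em$nn_forward(net, x, train = TRUE)
  za <- get("head_cle", cache); zb <- get("head_pse", cache)
  a <- em$sigmoid(za); b <- em$sigmoid(zb)
  dim(a) <- dim(a)[1:3]; dim(b) <- dim(b)[1:3]
  lg <- em$regression_loss_grads(a, b, md, td, ivc, ivp, cfg)
  dza <- lg$da * a * (1 - a); dzb <- lg$db * b * (1 - b)
  dim(dza) <- dim(za); dim(dzb) <- dim(zb)
  grads <- em$nn_backward(net, cache, list(head_cle = dza, head_pse = dzb))
  set.seed(17)
  for (nm in c("stem.conv.W", "layer2.block1.a.conv.W", "recon2b.conv.W",
               "recon1a.bn.gamma", "head_cle.b")) {
    w <- get(nm, net$params)
    for (i in sample(length(w), min(2, length(w)))) {
      w0 <- w[i]
      w[i] <- w0 + 1e-3; assign(nm, w, net$params); lp <- loss_of()$total
      w[i] <- w0 - 1e-3; assign(nm, w, net$params); lm <- loss_of()$total
      w[i] <- w0; assign(nm, w, net$params)
      fd <- (lp - lm) / 2e-3
      an <- get(nm, grads)[i]
      expect_equal(an, fd, tolerance = 0.05)
    }
  }
})
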