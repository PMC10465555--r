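# Shared fixtures, built in code. Heavier objects are memoised per session.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = fixture_env, inherits = FALSE))
    assign(name, force(expr), envir = fixture_env)
  get(name, envir = fixture_env)
}

# small phantom with both subtypes present
small_phantom <- function() {
  memo("small_phantom", generate_phantom(phantom_spec(
    shape = c(24L, 32L, 40L), seed = 7, target_cle_pct = 0.12,
    target_pse_pct = 0.03, tolerance = 0.02)))
}

# tiny trainable regression network + matching sample (fast per-epoch)
tiny_net <- function(head = "regression", seed = 3) {
  build_network(network_config("resnet18", head,
                               input_shape = c(16L, 16L, 24L),
                               width_mult = 1 / 32, seed = seed))
}

tiny_sample <- function(seed = 1, cle = 2L, pse = 1L) {
  ph <- generate_phantom(phantom_spec(
    shape = c(16L, 16L, 24L), seed = seed,
    target_cle_pct = c(0, 0.02, 0.07, 0.15, 0.25, 0.35)[cle + 1L],
    target_pse_pct = c(0, 0.02, 0.07)[pse + 1L],
    radius_range = c(1L, 2L), margin = 2L, tolerance = 0.02))
  prepare_sample(ph$ct, ph$mask, ph$truth$scores$cle, ph$truth$scores$pse,
                 input_shape = c(16L, 16L, 24L),
                 truth = list(cle_pct = ph$truth$achieved_cle_pct,
                              pse_pct = ph$truth$achieved_pse_pct))
}

# reference trilinear-convolution oracle: direct 6-nested loops, double
naive_conv3d <- function(x, w, stride, pad, bias = NULL) {
  xd <- dim(x); kd <- dim(w)
  odim <- function(n, k) (n + 2 * pad - k) %/% stride + 1L
  Do <- odim(xd[1], kd[1]); Ho <- odim(xd[2], kd[2]); Wo <- odim(xd[3], kd[3])
  y <- array(0, c(Do, Ho, Wo, kd[5]))
  for (co in seq_len(kd[5]))
    for (ow in seq_len(Wo)) for (oh in seq_len(Ho)) for (od in seq_len(Do)) {
      acc <- if (is.null(bias)) 0 else bias[co]
      for (ci in seq_len(kd[4]))
        for (c3 in seq_len(kd[3])) for (c2 in seq_len(kd[2]))
          for (c1 in seq_len(kd[1])) {
            id <- (od - 1) * stride - pad + c1
            ih <- (oh - 1) * stride - pad + c2
            iw <- (ow - 1) * stride - pad + c3
            if (id >= 1 && id <= xd[1] && ih >= 1 && ih <= xd[2] &&
                iw >= 1 && iw <= xd[3])
              acc <- acc + x[id, ih, iw, ci] * w[c1, c2, c3, ci, co]
          }
      y[od, oh, ow, co] <- acc
    }
  y
}

# central finite differences of f at x (vectorized over elements of x)
num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# absolute-tolerance comparison against printed (2 d.p.) reference values
expect_within <- function(actual, expected, tol) {
  testthat::expect_lt(max(abs(actual - expected)), tol)
}

# mean voxel-wise product of the two subtype maps over the lung; the
# untrained baseline is measured with batch statistics, since a never-trained
# network's running statistics are placeholders
map_overlap <- function(net, samples, batch_stats = FALSE) {
  em <- asNamespace("emphysemap")
  mean(vapply(samples, function(s) {
    if (batch_stats) {
      cache <- em$nn_forward(net, s$pre$values, train = TRUE)
      a <- em$sigmoid(get("head_cle", cache))
      b <- em$sigmoid(get("head_pse", cache))
      dim(a) <- dim(a)[1:3]; dim(b) <- dim(b)[1:3]
    } else {
      fr <- forward_regress(net, s$pre)
      a <- fr$maps$cle; b <- fr$maps$pse
    }
    sum(a * b * s$mask_dense) / sum(s$mask_dense)
  }, numeric(1)))
}
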