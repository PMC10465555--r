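test_that("interval loss is zero inside the interval, quadratic outside", {
  iv <- list(r_l = 0.01, r_u = 0.05)
  expect_equal(interval_loss(0.03, iv), 0)
  expect_equal(interval_loss(0.05, iv), 0)   # boundary: (0.02)^2 - K = 0
  expect_equal(interval_loss(0.01, iv), 0)
  expect_equal(interval_loss(0.10, iv), 0.0045)  # (0.07)^2 - 4e-4
  # zero exactly iff inside the closed interval
  p <- seq(0, 1, by = 1e-3)
  lz <- vapply(p, interval_loss, numeric(1), interval = iv) < 1e-15
  expect_equal(lz, p >= 0.01 - 1e-9 & p <= 0.05 + 1e-9)
})

test_that("overlap loss is the soft Dice of the two maps", {
  one <- array(1, c(2, 2, 2))
  expect_equal(overlap_loss(one, one), 1)
  expect_equal(overlap_loss(c(1, 0), c(0, 1)), 0)
  expect_equal(overlap_loss(c(1, 0), c(1, 1)), 2 / 3)
  expect_equal(overlap_loss(one * 0, one * 0), 0)  # guarded denominator
  expect_error(overlap_loss(array(1, c(2, 2, 2)), array(1, c(2, 2, 3))),
               "shape")
  # symmetry and joint permutation invariance
  set.seed(8)
  a <- runif(60); b <- runif(60)
  expect_equal(overlap_loss(a, b), overlap_loss(b, a))
  perm <- sample(60)
  expect_equal(overlap_loss(a[perm], b[perm]), overlap_loss(a, b))
})

test_that("segmentation loss reproduces its closed-form unit cases", {
  cfg0 <- loss_config(epsilon = 0)
  t <- array(c(1, 0, 1, 0, 1, 0, 0, 0), c(2, 2, 2))
  # p == t exactly -> zero loss
  expect_equal(seg_loss(t, t * 0, t, cfg0), 0, tolerance = 1e-6)
  # p == 0.5 everywhere -> log 2 per voxel
  half <- t * 0 + 0.5
  expect_equal(seg_loss(half, half * 0, t, cfg0), log(2))
  # label smoothing: t = 1, p = 1 -> -log(0.95) per voxel
  ones <- array(1, c(2, 2, 2))
  expect_equal(seg_loss(ones, ones * 0, ones, loss_config(epsilon = 0.1)),
               -log(0.95), tolerance = 1e-5)
  # smoothness factor scales linearly
  expect_equal(seg_loss(half, half * 0, t, loss_config(epsilon = 0, s = 3)),
               3 * log(2))
  expect_error(seg_loss(t, array(0, c(2, 2, 3)), t), "shape")
})

test_that("segmentation loss with no smoothing equals mean binary CE", {
  set.seed(21)
  for (rep in 1:5) {
    a <- array(runif(125, 0.01, 0.6), c(5, 5, 5))
    b <- array(runif(125, 0.01, 0.39), c(5, 5, 5))
    t <- array(rbinom(125, 1, 0.3), c(5, 5, 5))
    p <- pmin(pmax(a + b, 0), 1)
    bce <- -mean(t * log(p) + (1 - t) * log(1 - p))  # independent oracle
    expect_equal(seg_loss(a, b, t, loss_config(epsilon = 0)), bce,
                 tolerance = 1e-10)
  }
})

test_that("total regression loss is the unweighted sum of its parts", {
  iv_cle <- list(r_l = 0.01, r_u = 0.05)
  iv_pse <- list(r_l = 0, r_u = 0.01)
  a <- array(0.2, c(2, 2, 2)); b <- array(0.1, c(2, 2, 2))
  t <- array(1, c(2, 2, 2))
  tot <- total_regression_loss(0.10, 0.005, iv_cle, iv_pse, a, b, t)
  expect_equal(tot$total, sum(tot$components))
  expect_equal(unname(tot$components["int_cle"]), 0.0045)
  expect_equal(unname(tot$components["int_pse"]), 0)
  expect_true(all(tot$total >= tot$components))
  # worked composite: components (0.0045, 0.2, 0.1) sum to 0.3045
  expect_equal(0.0045 + 0.2 + 0.1, 0.3045)
})

test_that("analytic loss gradients match finite differences to 1e-4", {
  set.seed(31)
  em <- asNamespace("emphysemap")
  a <- array(runif(27, 0.05, 0.6), c(3, 3, 3))
  b <- array(runif(27, 0.05, 0.35), c(3, 3, 3))
  t <- array(rbinom(27, 1, 0.4), c(3, 3, 3))
  md <- array(rbinom(27, 1, 0.8), c(3, 3, 3))
  iv <- list(r_l = 0.01, r_u = 0.05)
  cfg <- loss_config(epsilon = 0.1)
  rel_err <- function(gn, ga) {
    max(abs(gn - ga) / pmax(abs(gn), abs(ga), 1e-6))
  }
  # interval loss through the masked mean
  f_int <- function(m) interval_loss(sum(m * md) / sum(md), iv)
  g_an <- em$interval_loss_grad(sum(a * md) / sum(md), iv) * md / sum(md)
  expect_lt(rel_err(num_grad(f_int, a), g_an), 1e-4)
  # overlap loss, both arguments
  og <- em$overlap_loss_grad(a, b)
  expect_lt(rel_err(num_grad(function(m) overlap_loss(m, b), a), og$dC),
            1e-4)
  expect_lt(rel_err(num_grad(function(m) overlap_loss(a, m), b), og$dS),
            1e-4)
  # segmentation loss, both arguments
  sg <- em$seg_loss_impl(a, b, t, cfg, md, grads = TRUE)
  expect_lt(rel_err(num_grad(function(m) seg_loss(m, b, t, cfg, md), a),
                    sg$dC * (a + b > 0 & a + b < 1)), 1e-4)
  expect_lt(rel_err(num_grad(function(m) seg_loss(a, m, t, cfg, md), b),
                    sg$dS * (a + b > 0 & a + b < 1)), 1e-4)
})

test_that("class weights start at normalized inverse frequencies", {
  cw <- class_weights_init(c(10, 10, 10))
  expect_equal(cw$w, rep(1, 3))
  # evaluation-set centrilobular frequencies
  counts <- c(2499, 1322, 1409, 1049, 656, 208)
  cw2 <- class_weights_init(counts)
  raw <- c(2.86, 5.40, 5.07, 6.81, 10.89, 34.34)
  expect_equal(cw2$w, raw / mean(raw), tolerance = 1e-3)
  expect_equal(mean(cw2$w), 1)
  # an unobserved class inherits the maximum observed weight
  cw3 <- class_weights_init(c(5, 0, 20))
  expect_equal(cw3$w0[2], max(cw3$w0))
  expect_error(class_weights_init(c(0, 0)), "no labels")
})

test_that("per-class accuracy update rescales and renormalizes weights", {
  cw <- class_weights_init(c(100, 50, 25))
  up <- update_weights(cw, c(0.9, 0.5, 0.2), delta = 0.1)
  manual <- cw$w0 * (1 - c(0.9, 0.5, 0.2) + 0.1)
  expect_equal(up$w, manual / mean(manual))
  # perfect accuracy everywhere degenerates to the initial weights
  up2 <- update_weights(cw, c(1, 1, 1), delta = 0.1)
  expect_equal(up2$w, cw$w0)
  expect_length(up2$history, 2)
})

test_that("weighted cross-entropy scales the loss by the true-class weight", {
  logits <- c(2, 0, -1)
  cw <- class_weights_init(c(10, 20, 5))
  r <- weighted_ce(logits, 1L, cw)
  pr <- exp(logits) / sum(exp(logits))
  expect_equal(r$loss, -cw$w[2] * log(pr[2]))
  expect_equal(r$grad, cw$w[2] * (pr - c(0, 1, 0)))
  expect_equal(num_grad(function(z) weighted_ce(z, 1L, cw)$loss, logits),
               r$grad, tolerance = 1e-6)
  expect_error(weighted_ce(logits, 3L, cw), "out of range")
})
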