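test_that("network config validates its inputs", {
  expect_error(network_config(input_shape = c(30, 64, 80)), "divisible by 8")
  expect_error(network_config(width_mult = 1 / 3), "integer")
  expect_error(network_config("resnet99"), "arg")
  cfg <- network_config("resnet18", "classification", c(16, 16, 24), 1 / 32)
  expect_s3_class(cfg, "network_config")
})

test_that("dense maps sit at half the input resolution (stride arithmetic)", {
  net <- build_network(network_config("resnet18", "regression",
                                      input_shape = c(32L, 48L, 64L),
                                      width_mult = 1 / 8, seed = 1))
  cache <- emphysemap:::nn_forward(net, array(0.3, c(32, 48, 64)))
  expect_equal(dim(get("head_cle", cache)), c(16L, 24L, 32L, 1L))
  # backbone bottleneck at 1/8 of the input
  expect_equal(dim(get("layer4.block2.relu", cache))[1:3], c(4L, 6L, 8L))
})

test_that("classification softmax outputs normalize and pool constants", {
  net <- build_network(network_config("resnet18", "classification",
                                      input_shape = c(16L, 16L, 24L),
                                      width_mult = 1 / 32, seed = 2))
  fc <- forward_classify(net, array(0, c(16, 16, 24)))
  expect_equal(sum(fc$cle_probs), 1, tolerance = 1e-6)
  expect_equal(sum(fc$pse_probs), 1, tolerance = 1e-6)
  expect_length(fc$cle_probs, 6)
  expect_length(fc$pse_probs, 3)
  expect_equal(dim(fc$maps$cle)[4], 6L)
  expect_identical(fc$cle_score, which.max(fc$cle_probs) - 1L)
  # pooling a constant map makes the argmax the maximal channel
  d <- dim(fc$maps$cle)
  m <- fc$maps$cle * 0
  m[, , , 4] <- 1
  pool <- colMeans(matrix(m, prod(d[1:3]), d[4]))
  expect_identical(which.max(pool), 4L)
  expect_error(forward_regress(net, array(0, c(16, 16, 24))), "head")
})

test_that("regression pooling averages the sigmoid maps over the lung only", {
  s <- tiny_sample(seed = 9)
  net <- tiny_net(seed = 4)
  fr <- forward_regress(net, s$pre)
  md <- fr$mask_dense
  expect_equal(fr$p_cle, sum(fr$maps$cle * md) / sum(md))
  expect_true(fr$p_cle >= 0 && fr$p_cle <= 1)
  # the lung-wise mean ignores values outside the mask
  m2 <- fr$maps$cle
  m2[md == 0] <- 9
  expect_equal(sum(m2 * md) / sum(md), fr$p_cle)
  # masked-mean arithmetic: half-ones map pools to 0.5
  half <- md * 0
  half[which(md == 1)[seq_len(sum(md) / 2)]] <- 1
  expect_equal(sum(half * md) / sum(md), 0.5, tolerance = 1e-2)
  expect_error(forward_classify(net, s$pre), "head")
})

test_that("inputs differing only outside the lung give identical outputs", {
  s <- tiny_sample(seed = 10)
  net <- tiny_net(seed = 5)
  fr1 <- forward_regress(net, s$pre)
  pre2 <- s$pre
  # preprocessing zeroes outside the lung; verify the contract holds
  expect_true(all(pre2$values[pre2$mask == 0] == 0))
  fr2 <- forward_regress(net, pre2)
  expect_identical(fr1$p_cle, fr2$p_cle)
})

test_that("classification and regression variants share all non-head shapes", {
  a <- build_network(network_config("resnet18", "regression",
                                    c(16, 16, 24), 1 / 32, seed = 1))
  b <- build_network(network_config("resnet18", "classification",
                                    c(16, 16, 24), 1 / 32, seed = 1))
  na <- emphysemap:::nn_param_names(a)
  nb <- emphysemap:::nn_param_names(b)
  expect_setequal(na, nb)
  for (nm in setdiff(na, c("head_cle.W", "head_cle.b",
                           "head_pse.W", "head_pse.b")))
    expect_identical(dim(get(nm, a$params)), dim(get(nm, b$params)))
})
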