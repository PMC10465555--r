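#' Network configuration
#'
#' Defines the 3D ResNet backbone (18/34/50), the output head, the input grid
#' and an optional width multiplier for desk-scale experiments. The backbone
#' follows the standard design: a 7^3 stride-2 stem with 64 filters, a 3^3
#' stride-2 max-pool, then four ResNet layers with (2,2,2,2) blocks for
#' ResNet18 and (3,4,6,3) for ResNet34/50 (bottleneck blocks for ResNet50);
#' from layer 2 onward the first block doubles the channels, and only layer 2
#' downsamples, so backbone features sit at 1/8 of the input resolution. A
#' reconstruction network with two trilinear x2 upsampling stages - each
#' concatenating skip features from the matching backbone resolution (layer-1
#' output at 1/4, post-stem features at 1/2) before two 3^3 convolutions -
#' restores dense features at 1/2 resolution for the heads.
#'
#' The reconstruction channel widths (576->64->64 and 128->50->32 for
#' ResNet18/34; 2304->24->64 and 128->39->32 for ResNet50; head input 32) are
#' fixed by the published parameter budgets of the three variants: 34.48 M,
#' 64.79 M and 47.86 M trainable parameters at full width.
#'
#' @param variant `"resnet18"`, `"resnet34"` or `"resnet50"`.
#' @param head `"regression"` (two sigmoid dense maps, lung-wise mean pooled
#'   to per-subtype percentages) or `"classification"` (6+3 channel dense
#'   class activation maps, global-average pooled to softmax scores).
#' @param input_shape network input grid (axial, coronal, sagittal); each
#'   dimension must be divisible by 8. Default 128 x 224 x 288.
#' @param width_mult width multiplier; 1 is full width, 1/8 the desk scale.
#' @param seed RNG seed for weight initialization.
#' @return A `network_config` list.
#' @export
network_config <- function(variant = c("resnet34", "resnet18", "resnet50"),
                           head = c("regression", "classification"),
                           input_shape = c(128L, 224L, 288L),
                           width_mult = 1, seed = 1L) {
  variant <- match.arg(variant)
  head <- match.arg(head)
  input_shape <- as.integer(input_shape)
  if (any(input_shape %% 8L != 0L))
    stop("network_config: input_shape must be divisible by 8")
  base <- 64 * width_mult
  if (abs(base - round(base)) > 1e-9)
    stop("network_config: width_mult must make 64 * width_mult an integer")
  structure(list(variant = variant, head = head,
                 input_shape = input_shape, width_mult = width_mult,
                 seed = as.integer(seed)),
            class = "network_config")
}

# width scaling helper: full-width channels -> scaled, at least 1
scale_w <- function(w, mult) pmax(1L, as.integer(round(w * mult)))

#' Build a network from its configuration
#'
#' @param cfg a [network_config()].
#' @return An `emph_network` (environment with steps and parameters),
#'   initialized with He-normal weights under `cfg$seed`. The regression
#'   head biases start at -2 so the sigmoid maps begin near 0.12, close to
#'   the low emphysema fractions that dominate training.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  mult <- cfg$width_mult
  base <- scale_w(64L, mult)
  blocks <- switch(cfg$variant,
                   resnet18 = c(2L, 2L, 2L, 2L),
                   resnet34 = c(3L, 4L, 6L, 3L),
                   resnet50 = c(3L, 4L, 6L, 3L))
  bottleneck <- cfg$variant == "resnet50"
  recon_full <- if (bottleneck) c(24L, 64L, 39L, 32L)
                else c(64L, 64L, 50L, 32L)
  rw <- scale_w(recon_full, mult)

  steps <- list()
  add_step <- function(id, op, inp = character(), ...) {
    steps[[length(steps) + 1L]] <<- c(list(id = id, op = op, inp = inp),
                                      list(...))
    id
  }
  conv_bn <- function(prefix, inp, k, cin, cout, stride = 1L, pad = NULL,
                      relu = TRUE) {
    if (is.null(pad)) pad <- (k - 1L) %/% 2L
    cid <- add_step(paste0(prefix, ".conv"), "conv", inp, k = k, cin = cin,
                    cout = cout, stride = stride, pad = pad, bias = FALSE)
    bid <- add_step(paste0(prefix, ".bn"), "bn", cid, cout = cout)
    if (relu) add_step(paste0(prefix, ".relu"), "relu", bid) else bid
  }
  basic_block <- function(prefix, inp, cin, cout, stride) {
    a <- conv_bn(paste0(prefix, ".a"), inp, 3L, cin, cout, stride)
    b <- conv_bn(paste0(prefix, ".b"), a, 3L, cout, cout, relu = FALSE)
    sc <- if (stride != 1L || cin != cout)
      conv_bn(paste0(prefix, ".ds"), inp, 1L, cin, cout, stride,
              relu = FALSE) else inp
    s <- add_step(paste0(prefix, ".add"), "add", c(b, sc))
    add_step(paste0(prefix, ".relu"), "relu", s)
  }
  bottleneck_block <- function(prefix, inp, cin, w, stride) {
    cout <- 4L * w
    a <- conv_bn(paste0(prefix, ".a"), inp, 1L, cin, w)
    b <- conv_bn(paste0(prefix, ".b"), a, 3L, w, w, stride)
    c_ <- conv_bn(paste0(prefix, ".c"), b, 1L, w, cout, relu = FALSE)
    sc <- if (stride != 1L || cin != cout)
      conv_bn(paste0(prefix, ".ds"), inp, 1L, cin, cout, stride,
              relu = FALSE) else inp
    s <- add_step(paste0(prefix, ".add"), "add", c(c_, sc))
    add_step(paste0(prefix, ".relu"), "relu", s)
  }

  xin <- add_step("input", "input")
  stem <- conv_bn("stem", xin, 7L, 1L, base, stride = 2L, pad = 3L)
  cur <- add_step("pool", "maxpool", stem, k = 3L, stride = 2L, pad = 1L)
  cin <- base
  skip1 <- NULL
  for (l in 1:4) {
    w <- scale_w(64L * 2L^(l - 1L), mult)
    cout <- if (bottleneck) 4L * w else w
    for (b in seq_len(blocks[l])) {
      stride <- if (l == 2L && b == 1L) 2L else 1L
      prefix <- sprintf("layer%d.block%d", l, b)
      cur <- if (bottleneck) bottleneck_block(prefix, cur, cin, w, stride)
             else basic_block(prefix, cur, cin, cout, stride)
      cin <- cout
    }
    if (l == 1L) skip1 <- list(id = cur, ch = cout)
  }

  up1 <- add_step("up1", "upsample", cur)
  cat1 <- add_step("cat1", "concat", c(up1, skip1$id))
  r1a <- conv_bn("recon1a", cat1, 3L, cin + skip1$ch, rw[1])
  r1b <- conv_bn("recon1b", r1a, 3L, rw[1], rw[2])
  up2 <- add_step("up2", "upsample", r1b)
  cat2 <- add_step("cat2", "concat", c(up2, stem))
  r2a <- conv_bn("recon2a", cat2, 3L, rw[2] + base, rw[3])
  dense <- conv_bn("recon2b", r2a, 3L, rw[3], rw[4])

  head_ch <- if (cfg$head == "classification") c(6L, 3L) else c(1L, 1L)
  bias_init <- if (cfg$head == "regression") -2 else 0
  add_step("head_cle", "conv", dense, k = 1L, cin = rw[4],
           cout = head_ch[1], stride = 1L, pad = 0L, bias = TRUE,
           bias_init = bias_init)
  add_step("head_pse", "conv", dense, k = 1L, cin = rw[4],
           cout = head_ch[2], stride = 1L, pad = 0L, bias = TRUE,
           bias_init = bias_init)

  net <- nn_new(cfg, steps)
  nn_init_params(net, cfg$seed)
  net
}

#' Count trainable parameters
#'
#' Convolution weights and biases plus batch-norm scale/shift; running
#' statistics are not trainable and are excluded.
#'
#' @param net an `emph_network`.
#' @return Integer-valued count.
#' @export
count_params <- function(net) nn_param_count(net)

#' @export
print.emph_network <- function(x, ...) {
  cat(sprintf("emph_network: %s, %s head, input %s, width x%s, %.2f M params\n",
              x$cfg$variant, x$cfg$head,
              paste(x$cfg$input_shape, collapse = "x"),
              format(x$cfg$width_mult), count_params(x) / 1e6))
  invisible(x)
}

# transported lung mask at the dense-map grid (1/2 input resolution)
dense_mask <- function(pre) {
  d <- dim(pre$mask)
  (resize3d(pre$mask, d %/% 2L) >= 0.5) * 1
}

#' Classification forward pass
#'
#' Runs the network and applies whole-grid global average pooling to each
#' channel group of the dense class activation maps, then a per-subtype
#' softmax.
#'
#' @param net an `emph_network` with the classification head.
#' @param pre a [preprocess()] output (or bare 3D array in [0, 1]).
#' @return list with `cle_probs` (6), `pse_probs` (3), `cle_score`,
#'   `pse_score` (argmax, 0-based) and `maps` (pre-pooling dense class
#'   activation maps at 1/2 input resolution).
#' @export
forward_classify <- function(net, pre) {
  stopifnot(inherits(net, "emph_network"))
  if (net$cfg$head != "classification")
    stop("forward_classify: network has head '", net$cfg$head, "'")
  x <- if (inherits(pre, "preprocessed_volume")) pre$values else pre
  cache <- nn_forward(net, x, train = FALSE)
  mc <- get("head_cle", envir = cache)
  mp <- get("head_pse", envir = cache)
  pool <- function(m) {
    d <- dim(m); dim(m) <- c(prod(d[1:3]), d[4]); colMeans(m)
  }
  cle_probs <- softmax(pool(mc))
  pse_probs <- softmax(pool(mp))
  list(cle_probs = cle_probs, pse_probs = pse_probs,
       cle_score = which.max(cle_probs) - 1L,
       pse_score = which.max(pse_probs) - 1L,
       maps = list(cle = mc, pse = mp))
}

#' Regression forward pass
#'
#' Runs the network, applies the sigmoid to both single-channel dense maps,
#' and averages each map over the lung voxels (mask transported to the
#' dense-map grid) to produce the two per-lung emphysema percentages.
#'
#' @param net an `emph_network` with the regression head.
#' @param pre a [preprocess()] output.
#' @return list with `p_cle`, `p_pse` in [0, 1], `maps` (sigmoid dense
#'   regression activation maps), and `mask_dense`.
#' @export
forward_regress <- function(net, pre) {
  stopifnot(inherits(net, "emph_network"))
  if (net$cfg$head != "regression")
    stop("forward_regress: network has head '", net$cfg$head, "'")
  stopifnot(inherits(pre, "preprocessed_volume"))
  md <- dense_mask(pre)
  if (sum(md) == 0) stop("forward_regress: empty transported mask")
  cache <- nn_forward(net, pre$values, train = FALSE)
  a <- sigmoid(get("head_cle", envir = cache))
  b <- sigmoid(get("head_pse", envir = cache))
  dim(a) <- dim(a)[1:3]; dim(b) <- dim(b)[1:3]
  nl <- sum(md)
  list(p_cle = sum(a * md) / nl, p_pse = sum(b * md) / nl,
       maps = list(cle = a, pse = b), mask_dense = md)
}
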