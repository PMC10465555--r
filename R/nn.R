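# Minimal trainable 3D CNN engine.
#
# A network is an environment holding an ordered list of `steps` (a DAG in
# topological order; each step names its input step ids) plus an environment
# of parameter arrays. Forward caches every node value; backward walks the
# steps in reverse, accumulating gradients per node and per parameter.
# Heavy kernels (conv via im2col+GEMM, pooling, trilinear resize) live in C++;
# batch norm and activations are vectorized R.
#
# Tensors are R arrays with dim = (D, H, W, C). All computation is double
# precision and deterministic (single-threaded kernels, R RNG only).

nn_new <- function(cfg, steps) {
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$steps <- steps
  net$params <- new.env(parent = emptyenv())
  class(net) <- "emph_network"
  net
}

# He-normal weight init; BN gamma=1 beta=0; head biases from cfg
nn_init_params <- function(net, seed = 1L) {
  set.seed(seed)
  for (st in net$steps) {
    if (st$op == "conv") {
      fan_in <- st$k^3 * st$cin
      w <- array(rnorm(st$k^3 * st$cin * st$cout, 0, sqrt(2 / fan_in)),
                 dim = c(st$k, st$k, st$k, st$cin, st$cout))
      assign(paste0(st$id, ".W"), w, envir = net$params)
      if (isTRUE(st$bias))
        assign(paste0(st$id, ".b"),
               rep(st$bias_init %||% 0, st$cout), envir = net$params)
    } else if (st$op == "bn") {
      assign(paste0(st$id, ".gamma"), rep(1, st$cout), envir = net$params)
      assign(paste0(st$id, ".beta"), rep(0, st$cout), envir = net$params)
      assign(paste0(st$id, ".rmean"), rep(0, st$cout), envir = net$params)
      assign(paste0(st$id, ".rvar"), rep(1, st$cout), envir = net$params)
    }
  }
  invisible(net)
}

# trainable parameter names (BN running stats excluded)
nn_param_names <- function(net) {
  nm <- ls(net$params)
  nm[!grepl("\\.(rmean|rvar)$", nm)]
}

nn_param_count <- function(net) {
  sum(vapply(nn_param_names(net),
             function(nm) length(get(nm, envir = net$params)), numeric(1)))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

nn_forward <- function(net, x, train = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  cache <- new.env(parent = emptyenv())
  p <- net$params
  for (st in net$steps) {
    val <- switch(st$op,
      input = x,
      conv = {
        xin <- get(st$inp[1], envir = cache)
        b <- if (isTRUE(st$bias)) get(paste0(st$id, ".b"), envir = p) else NULL
        cpp_conv3d_fwd(xin, dim(xin), get(paste0(st$id, ".W"), envir = p),
                       c(st$k, st$k, st$k, st$cin, st$cout),
                       st$stride, st$pad, b,
                       if (train) st$id else NULL)
      },
      bn = {
        xin <- get(st$inp[1], envir = cache)
        d <- dim(xin); C <- d[4]
        g <- get(paste0(st$id, ".gamma"), envir = p)
        be <- get(paste0(st$id, ".beta"), envir = p)
        if (train) {
          stats <- cpp_bn_stats(xin, d)
          mu <- stats[1:C]; v <- stats[C + (1:C)]
          rm_ <- get(paste0(st$id, ".rmean"), envir = p)
          rv_ <- get(paste0(st$id, ".rvar"), envir = p)
          assign(paste0(st$id, ".rmean"),
                 (1 - BN_MOMENTUM) * rm_ + BN_MOMENTUM * mu, envir = p)
          assign(paste0(st$id, ".rvar"),
                 (1 - BN_MOMENTUM) * rv_ + BN_MOMENTUM * v, envir = p)
        } else {
          mu <- get(paste0(st$id, ".rmean"), envir = p)
          v <- get(paste0(st$id, ".rvar"), envir = p)
        }
        invstd <- 1 / sqrt(v + BN_EPS)
        r <- cpp_bn_fwd(xin, d, g, be, mu, invstd)
        assign(paste0(st$id, ".xhat"), r$xhat, envir = cache)
        assign(paste0(st$id, ".invstd"), invstd, envir = cache)
        r$y
      },
      relu = {
        xin <- get(st$inp[1], envir = cache)
        xin * (xin > 0)
      },
      maxpool = {
        xin <- get(st$inp[1], envir = cache)
        r <- cpp_maxpool3d_fwd(xin, dim(xin), st$k, st$stride, st$pad)
        assign(paste0(st$id, ".idx"), r$idx, envir = cache)
        assign(paste0(st$id, ".indim"), dim(xin), envir = cache)
        r$y
      },
      upsample = {
        xin <- get(st$inp[1], envir = cache)
        d <- dim(xin)
        cpp_resize3d(xin, d, c(2L * d[1:3], d[4]))
      },
      concat = {
        a <- get(st$inp[1], envir = cache)
        b <- get(st$inp[2], envir = cache)
        da <- dim(a); db <- dim(b)
        stopifnot(identical(da[1:3], db[1:3]))
        y <- c(a, b)
        dim(y) <- c(da[1:3], da[4] + db[4])
        y
      },
      add = {
        get(st$inp[1], envir = cache) + get(st$inp[2], envir = cache)
      },
      stop("unknown op ", st$op))
    assign(st$id, val, envir = cache)
  }
  cache
}

# grad_outputs: named list (step id -> gradient array). Returns environment
# of parameter gradients keyed like the parameters.
nn_backward <- function(net, cache, grad_outputs) {
  p <- net$params
  gval <- new.env(parent = emptyenv())   # per-node accumulated gradients
  gpar <- new.env(parent = emptyenv())   # per-parameter gradients
  for (nm in names(grad_outputs)) assign(nm, grad_outputs[[nm]], envir = gval)
  acc <- function(id, g) {
    if (exists(id, envir = gval, inherits = FALSE))
      assign(id, get(id, envir = gval) + g, envir = gval)
    else assign(id, g, envir = gval)
  }
  for (st in rev(net$steps)) {
    if (!exists(st$id, envir = gval, inherits = FALSE)) next
    dy <- get(st$id, envir = gval)
    switch(st$op,
      input = NULL,
      conv = {
        xin <- get(st$inp[1], envir = cache)
        need_dx <- !identical(st$inp[1], "input")
        r <- cpp_conv3d_bwd(xin, dim(xin),
                            get(paste0(st$id, ".W"), envir = p),
                            c(st$k, st$k, st$k, st$cin, st$cout),
                            dy, st$stride, st$pad, isTRUE(st$bias), need_dx,
                            st$id)
        assign(paste0(st$id, ".W"), r$dw, envir = gpar)
        if (isTRUE(st$bias)) assign(paste0(st$id, ".b"), r$db, envir = gpar)
        if (need_dx) acc(st$inp[1], r$dx)
      },
      bn = {
        d <- dim(get(st$inp[1], envir = cache))
        r <- cpp_bn_bwd(dy, get(paste0(st$id, ".xhat"), envir = cache), d,
                        get(paste0(st$id, ".gamma"), envir = p),
                        get(paste0(st$id, ".invstd"), envir = cache))
        assign(paste0(st$id, ".gamma"), r$dgamma, envir = gpar)
        assign(paste0(st$id, ".beta"), r$dbeta, envir = gpar)
        acc(st$inp[1], r$dx)
      },
      relu = {
        y <- get(st$id, envir = cache)
        acc(st$inp[1], dy * (y > 0))
      },
      maxpool = {
        idx <- get(paste0(st$id, ".idx"), envir = cache)
        indim <- get(paste0(st$id, ".indim"), envir = cache)
        acc(st$inp[1], cpp_maxpool3d_bwd(idx, dy, indim))
      },
      upsample = {
        indim <- dim(get(st$inp[1], envir = cache))
        acc(st$inp[1], cpp_resize3d_adjoint(dy, dim(dy), indim))
      },
      concat = {
        da <- dim(get(st$inp[1], envir = cache))
        db <- dim(get(st$inp[2], envir = cache))
        nsp <- prod(da[1:3])
        ga <- dy[seq_len(nsp * da[4])]
        gb <- dy[nsp * da[4] + seq_len(nsp * db[4])]
        dim(ga) <- da; dim(gb) <- db
        acc(st$inp[1], ga)
        acc(st$inp[2], gb)
      },
      add = {
        acc(st$inp[1], dy)
        acc(st$inp[2], dy)
      })
  }
  gpar
}

# ---- Adam ------------------------------------------------------------------

adam_new <- function(net, lr = 1e-5, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- new.env(parent = emptyenv())
  st$v <- new.env(parent = emptyenv())
  for (nm in nn_param_names(net)) {
    z <- get(nm, envir = net$params) * 0
    assign(nm, z, envir = st$m)
    assign(nm, z, envir = st$v)
  }
  st
}

adam_step <- function(net, grads, opt, lr = NULL) {
  if (is.null(lr)) lr <- opt$lr
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in ls(grads)) {
    g <- get(nm, envir = grads)
    m <- opt$beta1 * get(nm, envir = opt$m) + (1 - opt$beta1) * g
    v <- opt$beta2 * get(nm, envir = opt$v) + (1 - opt$beta2) * g * g
    assign(nm, m, envir = opt$m)
    assign(nm, v, envir = opt$v)
    w <- get(nm, envir = net$params)
    assign(nm, w - lr * (m / bc1) / (sqrt(v / bc2) + opt$eps),
           envir = net$params)
  }
  invisible(opt)
}

# accumulate gradients from b into a (both environments)
grads_accumulate <- function(a, b) {
  for (nm in ls(b)) {
    if (exists(nm, envir = a, inherits = FALSE))
      assign(nm, get(nm, envir = a) + get(nm, envir = b), envir = a)
    else assign(nm, get(nm, envir = b), envir = a)
  }
  invisible(a)
}

grads_scale <- function(a, s) {
  for (nm in ls(a)) assign(nm, get(nm, envir = a) * s, envir = a)
  invisible(a)
}

nn_params_snapshot <- function(net) as.list(net$params)

nn_params_restore <- function(net, snap) {
  for (nm in names(snap)) assign(nm, snap[[nm]], envir = net$params)
  invisible(net)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}
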