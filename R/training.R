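#' Training configuration
#'
#' Defaults follow the published schedule: Adam, initial learning rate 1e-5
#' with exponential decay 0.9 per epoch, batch size 4, at most 200 epochs,
#' early stopping after 10 epochs without validation improvement. Desk-scale
#' phantom experiments override `lr` (the full-scale rate is far too small to
#' move a width-reduced network within a few dozen epochs).
#'
#' @param max_epochs maximum number of epochs.
#' @param lr initial Adam learning rate.
#' @param lr_decay per-epoch exponential decay factor.
#' @param patience epochs without validation improvement before stopping.
#' @param batch_size gradient-accumulation batch size.
#' @param seed RNG seed for shuffling and augmentation.
#' @param augment an [augment_config()]; `NULL` disables augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 200L, lr = 1e-5, lr_decay = 0.9,
                         patience = 10L, batch_size = 4L, seed = 1L,
                         augment = augment_config()) {
  stopifnot(patience < max_epochs, lr > 0, batch_size >= 1)
  structure(list(max_epochs = as.integer(max_epochs), lr = lr,
                 lr_decay = lr_decay, patience = as.integer(patience),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 augment = augment),
            class = "train_config")
}

#' Augmentation configuration
#'
#' Each transform fires independently with its own probability; with all
#' probabilities zero, [augment()] is the identity. Spatial transforms use
#' trilinear interpolation, keep the grid shape, and are applied jointly to
#' the image and its mask (outside-lung voxels are re-zeroed afterwards).
#'
#' @param flip_prob probability of a sagittal flip.
#' @param rot_prob probability of an in-plane (coronal-sagittal) rotation,
#'   angle uniform in +/- `rot_max_deg` degrees.
#' @param rot_max_deg maximum rotation angle.
#' @param crop_prob probability of crop-and-resize; each axis keeps at least
#'   `1 - crop_frac` of its extent.
#' @param crop_frac maximum cropped-away fraction per axis.
#' @param smooth_prob probability of Gaussian smoothing, sigma uniform in
#'   (0, `smooth_sigma_max`] voxels.
#' @param smooth_sigma_max maximum smoothing sigma.
#' @param intensity_prob probability of an additive intensity shift, uniform
#'   in +/- `intensity_shift`.
#' @param intensity_shift maximum absolute shift (input is in [0, 1]).
#' @param contrast_prob probability of a contrast rescale about the in-lung
#'   mean, factor uniform in `contrast_range`.
#' @param contrast_range multiplicative contrast range.
#' @param noise_prob probability of additive Gaussian noise.
#' @param noise_sd noise standard deviation.
#' @return An `augment_config` list.
#' @export
augment_config <- function(flip_prob = 0.5, rot_prob = 0.25,
                           rot_max_deg = 10, crop_prob = 0.25,
                           crop_frac = 0.1, smooth_prob = 0.25,
                           smooth_sigma_max = 1, intensity_prob = 0.5,
                           intensity_shift = 0.05, contrast_prob = 0.5,
                           contrast_range = c(0.9, 1.1), noise_prob = 0.5,
                           noise_sd = 0.02) {
  structure(as.list(environment()), class = "augment_config")
}

# identity-configuration helper used in tests
augment_off <- function() {
  a <- augment_config()
  for (nm in grep("_prob$", names(a), value = TRUE)) a[[nm]] <- 0
  a
}

#' Randomly augment a preprocessed volume
#'
#' @param pre a [preprocess()] output (or any list with `values` and `mask`
#'   arrays of equal shape).
#' @param seed integer seed; the composition is deterministic given the seed.
#' @param cfg an [augment_config()].
#' @param label optional 0/1 grid (e.g. the LAA-950 pseudo-label on the input
#'   grid) carried through the same spatial transforms; intensity transforms
#'   leave it untouched. Returned as the `label` element.
#' @return The augmented `preprocessed_volume` (same shape; values in [0, 1],
#'   zero outside the transformed mask).
#' @export
augment <- function(pre, seed, cfg = augment_config(), label = NULL) {
  set.seed(seed)
  x <- pre$values
  m <- pre$mask
  lb <- label
  d <- dim(x)
  if (runif(1) < cfg$flip_prob) {
    x <- x[, , d[3]:1, drop = FALSE]
    m <- m[, , d[3]:1, drop = FALSE]
    if (!is.null(lb)) lb <- lb[, , d[3]:1, drop = FALSE]
  }
  if (runif(1) < cfg$rot_prob) {
    ang <- runif(1, -cfg$rot_max_deg, cfg$rot_max_deg) * pi / 180
    x <- rotate_axial(x, ang)
    m <- (rotate_axial(m, ang) >= 0.5) * 1
    if (!is.null(lb)) lb <- (rotate_axial(lb, ang) >= 0.5) * 1
  }
  if (runif(1) < cfg$crop_prob) {
    keep <- 1 - runif(3, 0, cfg$crop_frac)
    sz <- pmax(2L, as.integer(round(d * keep)))
    off <- vapply(seq_len(3), function(i)
      sample.int(d[i] - sz[i] + 1L, 1L), integer(1))
    idx <- lapply(seq_len(3), function(i) off[i]:(off[i] + sz[i] - 1L))
    x <- resize3d(x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], d)
    m <- (resize3d(m[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], d)
          >= 0.5) * 1
    if (!is.null(lb))
      lb <- (resize3d(lb[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], d)
             >= 0.5) * 1
  }
  if (runif(1) < cfg$smooth_prob) {
    x <- gaussian_smooth3d(x, runif(1, 1e-3, cfg$smooth_sigma_max))
  }
  if (runif(1) < cfg$intensity_prob) {
    x <- x + runif(1, -cfg$intensity_shift, cfg$intensity_shift)
  }
  if (runif(1) < cfg$contrast_prob) {
    f <- runif(1, cfg$contrast_range[1], cfg$contrast_range[2])
    mu <- sum(x * m) / max(sum(m), 1)
    x <- mu + (x - mu) * f
  }
  if (runif(1) < cfg$noise_prob) {
    x <- x + rnorm(length(x), 0, cfg$noise_sd)
  }
  x <- pmin(pmax(x, 0), 1) * m
  out <- pre
  out$values <- x
  out$mask <- m
  if (!is.null(label)) out$label <- lb
  out
}

# rotate each axial slice by `ang` about the slice centre (bilinear, clamped)
rotate_axial <- function(x, ang) {
  d <- dim(x)
  H <- d[2]; W <- d[3]
  ch <- (H + 1) / 2; cw <- (W + 1) / 2
  g <- expand.grid(h = seq_len(H), w = seq_len(W))
  hs <- ch + cos(ang) * (g$h - ch) - sin(ang) * (g$w - cw)
  ws <- cw + sin(ang) * (g$h - ch) + cos(ang) * (g$w - cw)
  hs <- pmin(pmax(hs, 1), H); ws <- pmin(pmax(ws, 1), W)
  h0 <- pmin(floor(hs), H - 1); w0 <- pmin(floor(ws), W - 1)
  fh <- hs - h0; fw <- ws - w0
  xm <- x; dim(xm) <- c(d[1], H * W)
  lin <- function(h, w) (w - 1) * H + h
  y <- t(t(xm[, lin(h0, w0)]) * ((1 - fh) * (1 - fw))) +
       t(t(xm[, lin(h0 + 1, w0)]) * (fh * (1 - fw))) +
       t(t(xm[, lin(h0, w0 + 1)]) * ((1 - fh) * fw)) +
       t(t(xm[, lin(h0 + 1, w0 + 1)]) * (fh * fw))
  dim(y) <- d
  y
}

# separable Gaussian smoothing via small dense band matrices per axis
gaussian_smooth3d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(x, axis) {
    d <- dim(x)
    n <- d[axis]
    Km <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmin(pmax(i + (-r:r), 1L), n)   # replicate padding
      for (t_ in seq_along(j)) Km[i, j[t_]] <- Km[i, j[t_]] + k[t_]
    }
    perm <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    dim(xp) <- c(dp[1], prod(dp[-1]))
    y <- Km %*% xp
    dim(y) <- dp
    aperm(y, order(perm))
  }
  for (ax in 1:3) x <- smooth_axis(x, ax)
  x
}

#' Prepare one training sample from a phantom (or CT + mask + scores)
#'
#' Runs [preprocess()], derives the LAA-950 pseudo-label, transports mask and
#' pseudo-label to the dense-map grid (1/2 input resolution), and attaches
#' the score-derived target intervals. Training uses only the score-derived
#' intervals - never the phantom's true percentages - mirroring the weak
#' supervision of the visual-score setting.
#'
#' @param ct a [ct_volume()].
#' @param mask a [lung_mask()].
#' @param cle_score,pse_score ordinal labels.
#' @param input_shape network input shape.
#' @param truth optional list of true percentages kept for evaluation.
#' @return A `training_sample` list.
#' @export
prepare_sample <- function(ct, mask, cle_score, pse_score,
                           input_shape = c(48L, 64L, 80L), truth = NULL) {
  pre <- preprocess(ct, mask, input_shape)
  dense_shape <- as.integer(input_shape %/% 2L)
  laa <- (ct$values < -950) * mask$values
  md <- dense_mask(pre)
  t_input <- transport_binary(laa, pre$provenance, input_shape) * pre$mask
  t_dense <- transport_binary(laa, pre$provenance, dense_shape) * md
  structure(list(
    pre = pre, t_input = t_input, mask_dense = md, t_dense = t_dense,
    cle_score = as.integer(cle_score), pse_score = as.integer(pse_score),
    interval_cle = score_to_interval("cle", cle_score),
    interval_pse = score_to_interval("pse", pse_score),
    truth = truth
  ), class = "training_sample")
}

#' Generate and prepare a phantom cohort for training
#'
#' Streams phantom generation so raw volumes are not retained.
#'
#' @inheritParams generate_cohort
#' @param input_shape network input shape.
#' @return list with `samples` (list of `training_sample`) and `labels`.
#' @export
prepare_cohort <- function(n, score_distribution = NULL, seed = 1L,
                           shape = c(48L, 64L, 80L),
                           input_shape = c(48L, 64L, 80L), ...) {
  plan <- sample_cohort_labels(n, score_distribution, seed)
  samples <- vector("list", n)
  labels <- data.frame(id = plan$id, cle_score = NA_integer_,
                       pse_score = NA_integer_, cle_pct = NA_real_,
                       pse_pct = NA_real_)
  for (i in seq_len(n)) {
    sp <- phantom_spec(shape = shape, seed = plan$seed[i],
                       target_cle_pct = plan$target_cle_pct[i],
                       target_pse_pct = plan$target_pse_pct[i], ...)
    ph <- generate_phantom(sp)
    tr <- ph$truth
    labels$cle_score[i] <- tr$scores$cle
    labels$pse_score[i] <- tr$scores$pse
    labels$cle_pct[i] <- tr$achieved_cle_pct
    labels$pse_pct[i] <- tr$achieved_pse_pct
    samples[[i]] <- prepare_sample(
      ph$ct, ph$mask, tr$scores$cle, tr$scores$pse, input_shape,
      truth = list(cle_pct = tr$achieved_cle_pct,
                   pse_pct = tr$achieved_pse_pct))
  }
  list(samples = samples, labels = labels)
}

# one forward/backward pass of a regression-head sample; returns loss pieces
# and parameter gradients
regression_sample_grads <- function(net, sample, cfg_loss, aug_seed = NULL,
                                    aug_cfg = NULL) {
  pre <- sample$pre
  md <- sample$mask_dense
  td <- sample$t_dense
  if (!is.null(aug_seed) && !is.null(aug_cfg)) {
    pre <- augment(pre, aug_seed, aug_cfg, label = sample$t_input)
    dense_shape <- dim(md)
    md2 <- (resize3d(pre$mask, dense_shape) >= 0.5) * 1
    if (sum(md2) > 0) {
      md <- md2
      td <- (resize3d(pre$label, dense_shape) >= 0.5) * md
    }
  }
  cache <- nn_forward(net, pre$values, train = TRUE)
  za <- get("head_cle", envir = cache)
  zb <- get("head_pse", envir = cache)
  dmap <- dim(za)
  a <- sigmoid(za); b <- sigmoid(zb)
  dim(a) <- dmap[1:3]; dim(b) <- dmap[1:3]
  lg <- regression_loss_grads(a, b, md, td, sample$interval_cle,
                              sample$interval_pse, cfg_loss)
  dza <- lg$da * a * (1 - a)
  dzb <- lg$db * b * (1 - b)
  dim(dza) <- dmap; dim(dzb) <- dmap
  grads <- nn_backward(net, cache, list(head_cle = dza, head_pse = dzb))
  list(loss = lg$total, components = lg$components, grads = grads,
       p_cle = lg$p_cle, p_pse = lg$p_pse)
}

# one forward/backward pass of a classification-head sample
classification_sample_grads <- function(net, sample, cw_cle, cw_pse,
                                        aug_seed = NULL, aug_cfg = NULL) {
  pre <- sample$pre
  if (!is.null(aug_seed) && !is.null(aug_cfg))
    pre <- augment(pre, aug_seed, aug_cfg)
  cache <- nn_forward(net, pre$values, train = TRUE)
  mc <- get("head_cle", envir = cache)
  mp <- get("head_pse", envir = cache)
  dmc <- dim(mc); dmp <- dim(mp)
  nvox <- prod(dmc[1:3])
  pool <- function(m) { dim(m) <- c(nvox, dim(m)[4]); colMeans(m) }
  lc <- weighted_ce(pool(mc), sample$cle_score, cw_cle)
  lp <- weighted_ce(pool(mp), sample$pse_score, cw_pse)
  gmc <- array(rep(lc$grad / nvox, each = nvox), dim = dmc)
  gmp <- array(rep(lp$grad / nvox, each = nvox), dim = dmp)
  grads <- nn_backward(net, cache, list(head_cle = gmc, head_pse = gmp))
  list(loss = lc$loss + lp$loss, grads = grads,
       pred_cle = which.max(pool(mc)) - 1L,
       pred_pse = which.max(pool(mp)) - 1L)
}

# validation pass: predictions, mean loss and the kappa-based metric
validate_epoch <- function(net, samples, cfg_loss) {
  n <- length(samples)
  pred_c <- integer(n); pred_p <- integer(n)
  true_c <- integer(n); true_p <- integer(n)
  loss <- 0
  for (i in seq_len(n)) {
    s <- samples[[i]]
    true_c[i] <- s$cle_score; true_p[i] <- s$pse_score
    if (net$cfg$head == "regression") {
      fr <- forward_regress(net, s$pre)
      pred_c[i] <- percent_to_score("cle", fr$p_cle)
      pred_p[i] <- percent_to_score("pse", fr$p_pse)
      loss <- loss + total_regression_loss(
        fr$p_cle, fr$p_pse, s$interval_cle, s$interval_pse,
        fr$maps$cle, fr$maps$pse, s$t_dense, cfg_loss,
        s$mask_dense)$total
    } else {
      fc <- forward_classify(net, s$pre)
      pred_c[i] <- fc$cle_score
      pred_p[i] <- fc$pse_score
      loss <- loss - log(max(fc$cle_probs[s$cle_score + 1], 1e-12)) -
                     log(max(fc$pse_probs[s$pse_score + 1], 1e-12))
    }
  }
  kap <- function(pred, true, K) {
    cm <- confusion(pred, true, K)
    k <- tryCatch(weighted_kappa(cm)$kappa, error = function(e) NA_real_)
    if (is.na(k)) 0 else k / 100
  }
  metric <- mean(c(kap(pred_c, true_c, 6L), kap(pred_p, true_p, 3L)))
  list(metric = metric, loss = loss / max(n, 1),
       pred_cle = pred_c, pred_pse = pred_p)
}

#' Train a network on prepared samples
#'
#' Adam with gradient accumulation over `batch_size` samples, exponential
#' learning-rate decay, and early stopping on the validation metric (mean of
#' the centrilobular and paraseptal linear weighted kappa against the labels;
#' ties broken by lower validation loss). The best-validation parameter
#' snapshot is restored before returning. For classification training the
#' per-class cross-entropy weights start at inverse frequencies and are
#' re-damped by per-class accuracy after each epoch. Validation volumes are
#' never augmented.
#'
#' @param net an `emph_network` from [build_network()].
#' @param train,val lists of `training_sample` objects ([prepare_sample()]).
#' @param cfg a [train_config()].
#' @param loss_cfg a [loss_config()].
#' @param verbose print one line per epoch.
#' @return list with `net` (trained, best weights), `history` (per-epoch
#'   data.frame) and `best_epoch`.
#' @export
fit <- function(net, train, val, cfg = train_config(),
                loss_cfg = loss_config(), verbose = FALSE) {
  if (length(train) == 0 || length(val) == 0)
    stop("fit: empty train or validation split")
  opt <- adam_new(net, cfg$lr)
  cw_cle <- cw_pse <- NULL
  if (net$cfg$head == "classification") {
    cw_cle <- class_weights_init(tabulate(
      vapply(train, `[[`, integer(1), "cle_score") + 1L, 6L))
    cw_pse <- class_weights_init(tabulate(
      vapply(train, `[[`, integer(1), "pse_score") + 1L, 3L))
  }
  hist <- data.frame()
  best_metric <- -Inf; best_loss <- Inf; best_epoch <- 0L
  best_snap <- nn_params_snapshot(net)
  wait <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    lr_e <- cfg$lr * cfg$lr_decay^(epoch - 1)
    set.seed(cfg$seed + 1000L * epoch)
    ord <- sample.int(length(train))
    aug_seeds <- sample.int(.Machine$integer.max, length(train))
    acc_grads <- NULL; in_batch <- 0L
    ep_loss <- 0
    correct_c <- rep(0, 6); total_c <- rep(0, 6)
    correct_p <- rep(0, 3); total_p <- rep(0, 3)
    for (j in seq_along(ord)) {
      s <- train[[ord[j]]]
      res <- if (net$cfg$head == "regression")
        regression_sample_grads(net, s, loss_cfg, aug_seeds[j], cfg$augment)
      else
        classification_sample_grads(net, s, cw_cle, cw_pse, aug_seeds[j],
                                    cfg$augment)
      if (!is.finite(res$loss))
        stop(sprintf("fit: non-finite loss at epoch %d sample %d",
                     epoch, j))
      ep_loss <- ep_loss + res$loss
      if (net$cfg$head == "classification") {
        tc <- s$cle_score + 1L; tp <- s$pse_score + 1L
        total_c[tc] <- total_c[tc] + 1
        total_p[tp] <- total_p[tp] + 1
        if (res$pred_cle == s$cle_score) correct_c[tc] <- correct_c[tc] + 1
        if (res$pred_pse == s$pse_score) correct_p[tp] <- correct_p[tp] + 1
      }
      if (is.null(acc_grads)) acc_grads <- res$grads
      else grads_accumulate(acc_grads, res$grads)
      in_batch <- in_batch + 1L
      if (in_batch == cfg$batch_size || j == length(ord)) {
        grads_scale(acc_grads, 1 / in_batch)
        adam_step(net, acc_grads, opt, lr_e)
        acc_grads <- NULL; in_batch <- 0L
      }
    }
    if (net$cfg$head == "classification") {
      acc_c <- ifelse(total_c > 0, correct_c / total_c, 1)
      acc_p <- ifelse(total_p > 0, correct_p / total_p, 1)
      cw_cle <- update_weights(cw_cle, acc_c, loss_cfg$delta)
      cw_pse <- update_weights(cw_pse, acc_p, loss_cfg$delta)
    }
    v <- validate_epoch(net, val, loss_cfg)
    hist <- rbind(hist, data.frame(
      epoch = epoch, lr = lr_e, train_loss = ep_loss / length(train),
      val_metric = v$metric, val_loss = v$loss))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val kappa %.3f  val loss %.4f",
                      epoch, ep_loss / length(train), v$metric, v$loss))
    improved <- v$metric > best_metric + 1e-12 ||
      (abs(v$metric - best_metric) <= 1e-12 && v$loss < best_loss)
    if (improved) {
      best_metric <- v$metric; best_loss <- v$loss; best_epoch <- epoch
      best_snap <- nn_params_snapshot(net)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  nn_params_restore(net, best_snap)
  list(net = net, history = hist, best_epoch = best_epoch,
       best_metric = best_metric)
}

#' Save / load a trained network checkpoint
#'
#' The checkpoint directory holds `config.yaml` (network + training
#' configuration) and `params.rds` (parameter arrays), plus the training
#' history as `history.csv`.
#'
#' @param fitres result of [fit()] (or a bare network).
#' @param dir checkpoint directory.
#' @return `dir` (save) or the restored `emph_network` (load).
#' @export
save_checkpoint <- function(fitres, dir) {
  net <- if (inherits(fitres, "emph_network")) fitres else fitres$net
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(net$cfg), file.path(dir, "config.yaml"))
  saveRDS(nn_params_snapshot(net), file.path(dir, "params.rds"))
  if (!inherits(fitres, "emph_network") && !is.null(fitres$history))
    write.csv(fitres$history, file.path(dir, "history.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- network_config(cfg$variant, cfg$head, unlist(cfg$input_shape),
                        cfg$width_mult, cfg$seed)
  net <- build_network(cfg)
  nn_params_restore(net, readRDS(file.path(dir, "params.rds")))
  net
}
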