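#' Loss configuration for regression training
#'
#' @param epsilon label-smoothing strength applied to the LAA-950
#'   pseudo-label: `t' = t * (1 - epsilon) + epsilon / 2`. Default 0.1.
#' @param s smoothness factor scaling the segmentation loss. Default 1.
#' @param delta damping constant of the dynamic class-weight update used in
#'   classification training. Default 0.1.
#' @return A `loss_config` list.
#' @export
loss_config <- function(epsilon = 0.1, s = 1, delta = 0.1) {
  stopifnot(epsilon >= 0, epsilon < 1, s > 0, delta >= 0)
  structure(list(epsilon = epsilon, s = s, delta = delta),
            class = "loss_config")
}

#' Interval regression loss
#'
#' Zero whenever the predicted fraction lies inside the closed target
#' interval, quadratic outside:
#' `L = max(0, (p - (r_l + r_u)/2)^2 - K)` with `K = (0.5 (r_l - r_u))^2`.
#'
#' @param p predicted emphysema fraction in [0, 1].
#' @param interval list with `r_l`, `r_u` (e.g. from [score_to_interval()]).
#' @return Non-negative scalar.
#' @export
interval_loss <- function(p, interval) {
  mid <- 0.5 * (interval$r_l + interval$r_u)
  K <- (0.5 * (interval$r_l - interval$r_u))^2
  max(0, (p - mid)^2 - K)
}

interval_loss_grad <- function(p, interval) {
  mid <- 0.5 * (interval$r_l + interval$r_u)
  K <- (0.5 * (interval$r_l - interval$r_u))^2
  if ((p - mid)^2 - K > 0) 2 * (p - mid) else 0
}

#' Overlapping (mutual-exclusion) loss
#'
#' Soft Dice coefficient between the two subtype probability maps,
#' `2 * sum(p_C p_S) / (sum p_C + sum p_S)`; minimizing it drives the
#' centrilobular and paraseptal activations apart so that each voxel is
#' assigned to at most one subtype. Defined as 0 when both maps are
#' identically zero.
#'
#' @param p_C,p_S arrays of identical shape with values in [0, 1].
#' @return Scalar in [0, 1].
#' @export
overlap_loss <- function(p_C, p_S) {
  if (!identical(dim(p_C), dim(p_S)))
    stop("overlap_loss: shape mismatch")
  den <- sum(p_C) + sum(p_S)
  if (den == 0) return(0)
  2 * sum(p_C * p_S) / den
}

overlap_loss_grad <- function(p_C, p_S) {
  den <- sum(p_C) + sum(p_S)
  if (den == 0) return(list(dC = p_C * 0, dS = p_S * 0))
  L <- 2 * sum(p_C * p_S) / den
  list(dC = (2 * p_S - L) / den, dS = (2 * p_C - L) / den)
}

#' Segmentation loss against the LAA-950 pseudo-label
#'
#' The joint emphysema probability `p = clamp(p_C + p_S, 0, 1)` is scored
#' against the smoothed pseudo-label `t' = t (1 - eps) + eps / 2` with a
#' binary cross-entropy `-s * log(p t' + (1 - p)(1 - t'))`, averaged over the
#' lung voxels of the dense grid (`p` is clipped to [1e-7, 1 - 1e-7] before
#' the log). With `eps = 0` this is exactly the mean binary cross-entropy
#' between `p` and `t`.
#'
#' @param p_C,p_S subtype probability maps on the dense grid.
#' @param t 0/1 pseudo-label on the same grid.
#' @param cfg a [loss_config()].
#' @param mask optional 0/1 lung mask on the same grid; defaults to all ones.
#' @return Non-negative scalar.
#' @export
seg_loss <- function(p_C, p_S, t, cfg = loss_config(), mask = NULL) {
  seg_loss_impl(p_C, p_S, t, cfg, mask, grads = FALSE)$loss
}

seg_loss_impl <- function(p_C, p_S, t, cfg, mask, grads) {
  if (!identical(dim(p_C), dim(p_S)))
    stop("seg_loss: shape mismatch between maps")
  tt <- if (is.list(t)) t$t else t
  if (!is.null(dim(p_C)) && !identical(dim(tt), dim(p_C)))
    stop("seg_loss: pseudo-label shape mismatch")
  if (is.null(mask)) mask <- rep(1, length(p_C))
  nl <- sum(mask)
  if (nl == 0) stop("seg_loss: empty mask")
  tp <- tt * (1 - cfg$epsilon) + cfg$epsilon / 2
  raw <- p_C + p_S
  p <- pmin(pmax(raw, 0), 1)
  pcl <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  q <- pcl * tp + (1 - pcl) * (1 - tp)
  loss <- -cfg$s * sum(mask * log(q)) / nl
  if (!grads) return(list(loss = loss))
  dp <- -cfg$s * (2 * tp - 1) / q * mask / nl
  dp <- dp * (raw > 0 & raw < 1)   # clamp subgradient
  list(loss = loss, dC = dp, dS = dp)
}

#' Total regression-training loss
#'
#' `L = L_INT(cle) + L_INT(pse) + L_OL + L_SEG`, the unweighted sum of the
#' two interval losses, the overlap loss and the segmentation loss.
#'
#' @param p_cle,p_pse predicted per-lung fractions (lung-wise means of the
#'   maps).
#' @param interval_cle,interval_pse target intervals from
#'   [score_to_interval()].
#' @param p_C,p_S dense regression activation maps.
#' @param t LAA-950 pseudo-label on the dense grid.
#' @param cfg a [loss_config()].
#' @param mask lung mask on the dense grid.
#' @return list with `total` and the components `int_cle`, `int_pse`, `ol`,
#'   `seg`.
#' @export
total_regression_loss <- function(p_cle, p_pse, interval_cle, interval_pse,
                                  p_C, p_S, t, cfg = loss_config(),
                                  mask = NULL) {
  comps <- c(int_cle = interval_loss(p_cle, interval_cle),
             int_pse = interval_loss(p_pse, interval_pse),
             ol = overlap_loss(p_C, p_S),
             seg = seg_loss(p_C, p_S, t, cfg, mask))
  list(total = sum(comps), components = comps)
}

# loss + gradients w.r.t. the sigmoid maps a (cle) and b (pse);
# p_* are the masked means, md the dense lung mask, t the pseudo-label
regression_loss_grads <- function(a, b, md, t, interval_cle, interval_pse,
                                  cfg) {
  nl <- sum(md)
  p_cle <- sum(a * md) / nl
  p_pse <- sum(b * md) / nl
  li_c <- interval_loss(p_cle, interval_cle)
  li_p <- interval_loss(p_pse, interval_pse)
  gi_c <- interval_loss_grad(p_cle, interval_cle)
  gi_p <- interval_loss_grad(p_pse, interval_pse)
  og <- overlap_loss_grad(a, b)
  lo <- overlap_loss(a, b)
  sg <- seg_loss_impl(a, b, t, cfg, md, grads = TRUE)
  da <- gi_c * md / nl + og$dC + sg$dC
  db <- gi_p * md / nl + og$dS + sg$dS
  list(total = li_c + li_p + lo + sg$loss,
       components = c(int_cle = li_c, int_pse = li_p, ol = lo,
                      seg = sg$loss),
       p_cle = p_cle, p_pse = p_pse, da = da, db = db)
}

#' Per-class weights for the weighted cross-entropy
#'
#' Initial weights are inverse class frequencies, normalized to mean 1; a
#' class absent from the training labels receives the maximum weight among
#' observed classes. At the end of each epoch [update_weights()] rescales the
#' initial weights by `(1 - accuracy_c + delta)` (and renormalizes), so
#' classes with low per-class accuracy are penalized more in the next epoch.
#'
#' @param counts integer vector of per-class label counts (length K).
#' @return A `class_weights` list with `w` (current weights), `w0` (initial
#'   inverse-frequency weights) and `history`.
#' @export
class_weights_init <- function(counts) {
  if (any(counts < 0)) stop("class_weights_init: negative counts")
  if (sum(counts) == 0) stop("class_weights_init: no labels")
  inv <- ifelse(counts > 0, sum(counts) / counts, NA_real_)
  inv[is.na(inv)] <- max(inv, na.rm = TRUE)
  w0 <- inv / mean(inv)
  structure(list(w = w0, w0 = w0, history = list(w0)),
            class = "class_weights")
}

#' @rdname class_weights_init
#' @param cw a `class_weights` object.
#' @param per_class_accuracy accuracies in [0, 1], length K.
#' @param delta damping constant (default from [loss_config()]).
#' @export
update_weights <- function(cw, per_class_accuracy, delta = 0.1) {
  stopifnot(inherits(cw, "class_weights"),
            all(per_class_accuracy >= 0), all(per_class_accuracy <= 1))
  w <- cw$w0 * (1 - per_class_accuracy + delta)
  w <- w / mean(w)
  cw$w <- w
  cw$history <- c(cw$history, list(w))
  cw
}

#' Weighted cross-entropy for one subtype head
#'
#' @param logits pre-softmax pooled logits (length K).
#' @param score true ordinal score (0-based).
#' @param cw a `class_weights` object (or bare weight vector).
#' @return list with `loss` and `grad` (d loss / d logits).
#' @export
weighted_ce <- function(logits, score, cw) {
  w <- if (inherits(cw, "class_weights")) cw$w else cw
  K <- length(logits)
  if (score < 0 || score >= K) stop("weighted_ce: score out of range")
  pr <- softmax(logits)
  one <- rep(0, K); one[score + 1] <- 1
  list(loss = -w[score + 1] * log(max(pr[score + 1], 1e-12)),
       grad = w[score + 1] * (pr - one))
}
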