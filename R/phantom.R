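#' Synthetic lung phantom specification
#'
#' Phantoms emulate the statistical structure the subtyping method relies on:
#' two ellipsoidal "lungs" filled with parenchyma-like noise around -850 HU,
#' into which spherical emphysema-like blobs below the -950 HU densitometric
#' threshold are placed with subtype-specific spatial priors - centrilobular
#' blobs scattered in the lung core (centre deeper than `margin` voxels from
#' the lung boundary) and paraseptal blobs hugging the pleural surface (centre
#' within `margin` voxels of the boundary). Blobs are added greedily until the
#' achieved per-lung LAA fraction of each subtype reaches its target within
#' `tolerance`. With parenchyma N(-850, 30) the probability of a non-blob
#' voxel falling below -950 HU is pnorm(-10/3), about 4e-4, so pseudo-labels
#' are essentially blob-driven.
#'
#' @param shape grid shape (axial, coronal, sagittal); default 48 x 64 x 80,
#'   the package's desk-scale reference resolution.
#' @param seed integer RNG seed; phantoms are bit-reproducible given the spec.
#' @param target_cle_pct,target_pse_pct target emphysema fractions of the lung
#'   per subtype; their sum must not exceed 0.9.
#' @param parenchyma_mean,parenchyma_sd HU distribution of normal parenchyma.
#' @param emphysema_mean,emphysema_sd HU distribution inside blobs.
#' @param radius_range inclusive range of blob radii in voxels (>= 1).
#' @param margin subpleural margin m in voxels separating the two priors.
#' @param tolerance acceptable shortfall of achieved vs target fraction.
#' @param max_blobs per-subtype cap on placement attempts.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(48L, 64L, 80L), seed = 1L,
                         target_cle_pct = 0, target_pse_pct = 0,
                         parenchyma_mean = -850, parenchyma_sd = 30,
                         emphysema_mean = -1000, emphysema_sd = 15,
                         radius_range = c(2L, 4L), margin = 4L,
                         tolerance = 0.01, max_blobs = 4000L) {
  if (target_cle_pct + target_pse_pct > 0.9)
    stop("phantom_spec: target_cle_pct + target_pse_pct must be <= 0.9")
  if (any(radius_range < 1)) stop("phantom_spec: radii must be >= 1")
  structure(list(shape = as.integer(shape), seed = as.integer(seed),
                 target_cle_pct = target_cle_pct,
                 target_pse_pct = target_pse_pct,
                 parenchyma_mean = parenchyma_mean,
                 parenchyma_sd = parenchyma_sd,
                 emphysema_mean = emphysema_mean,
                 emphysema_sd = emphysema_sd,
                 radius_range = as.integer(radius_range),
                 margin = margin, tolerance = tolerance,
                 max_blobs = as.integer(max_blobs)),
            class = "phantom_spec")
}

# two disjoint ellipsoids standing in for the left and right lung
phantom_lung_mask <- function(shape) {
  D <- shape[1]; H <- shape[2]; W <- shape[3]
  ax <- (seq_len(D) - (D + 1) / 2) / (0.42 * D)
  co <- (seq_len(H) - (H + 1) / 2) / (0.40 * H)
  sa <- seq_len(W)
  m <- array(0, shape)
  for (cw in c(0.30 * W, 0.70 * W)) {
    sg <- (sa - cw) / (0.16 * W)
    rho2 <- outer(outer(ax^2, co^2, `+`), sg^2, `+`)
    m[rho2 <= 1] <- 1
  }
  m
}

# integer offsets of a voxel ball of radius r
ball_offsets <- function(r) {
  s <- -r:r
  g <- expand.grid(d = s, h = s, w = s)
  g[g$d^2 + g$h^2 + g$w^2 <= r^2, , drop = FALSE]
}

# Greedily drop spherical blobs with centres drawn from cand_idx until the
# LAA fraction inside `own` reaches `target` (within tolerance). Blobs that
# would touch the other subtype's mask are rejected, keeping the masks
# mutually exclusive. Pure function: returns the updated state.
place_blobs <- function(hu, lung, own, other, target, cand_idx, spec,
                        nlung, offs) {
  cnt <- sum(own == 1L & hu < -950)   # maintained incrementally per blob
  achieved <- cnt / nlung
  attempts <- 0L
  shape <- spec$shape
  radii <- seq(spec$radius_range[1], spec$radius_range[2])
  while (achieved < target - spec$tolerance && attempts < spec$max_blobs &&
         length(cand_idx) > 0) {
    attempts <- attempts + 1L
    centre <- arrayInd(cand_idx[sample.int(length(cand_idx), 1L)], shape)
    r <- if (length(radii) == 1L) radii else sample(radii, 1L)
    off <- offs[[as.character(r)]]
    d <- centre[1] + off$d; h <- centre[2] + off$h; w <- centre[3] + off$w
    ok <- d >= 1 & d <= shape[1] & h >= 1 & h <= shape[2] &
          w >= 1 & w <= shape[3]
    lin <- d[ok] + shape[1] * (h[ok] - 1 + shape[2] * (w[ok] - 1))
    lin <- lin[lung[lin] == 1]
    if (length(lin) == 0) next
    if (any(other[lin] == 1L)) next
    c0 <- sum(own[lin] == 1L & hu[lin] < -950)
    hu[lin] <- rnorm(length(lin), spec$emphysema_mean, spec$emphysema_sd)
    own[lin] <- 1L
    cnt <- cnt + sum(hu[lin] < -950) - c0
    achieved <- cnt / nlung
  }
  list(hu = hu, own = own, achieved = achieved,
       converged = achieved >= target - spec$tolerance)
}

#' Generate one synthetic CT + lung mask + truth triplet
#'
#' @param spec a [phantom_spec()].
#' @return A list with `ct` ([ct_volume()]), `mask` ([lung_mask()]) and
#'   `truth`, which carries the achieved per-subtype fractions (lung voxels
#'   below -950 HU inside each subtype's blob mask, divided by lung voxels),
#'   the disjoint `cle_mask`/`pse_mask` grids, the ordinal `scores` implied by
#'   the achieved fractions via [percent_to_score()], and a `converged` flag
#'   (FALSE when a target was unreachable within the blob budget).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shape <- spec$shape
  lung <- phantom_lung_mask(shape)
  lung_idx <- which(lung == 1)
  nlung <- length(lung_idx)

  hu <- array(50, shape)  # soft tissue outside the lung
  hu[lung_idx] <- rnorm(nlung, spec$parenchyma_mean, spec$parenchyma_sd)

  dist <- cpp_edt3d(as.numeric(lung), shape)
  deep_idx <- lung_idx[dist[lung_idx] > spec$margin]
  rim_idx <- lung_idx[dist[lung_idx] <= spec$margin]

  radii <- seq(spec$radius_range[1], spec$radius_range[2])
  offs <- setNames(lapply(radii, ball_offsets), as.character(radii))

  cle_mask <- array(0L, shape)
  pse_mask <- array(0L, shape)
  converged <- TRUE

  if (spec$target_cle_pct > 0) {
    st <- place_blobs(hu, lung, cle_mask, pse_mask, spec$target_cle_pct,
                      deep_idx, spec, nlung, offs)
    hu <- st$hu; cle_mask <- st$own
    converged <- converged && st$converged
  }
  if (spec$target_pse_pct > 0) {
    st <- place_blobs(hu, lung, pse_mask, cle_mask, spec$target_pse_pct,
                      rim_idx, spec, nlung, offs)
    hu <- st$hu; pse_mask <- st$own
    converged <- converged && st$converged
  }
  if (!converged)
    warning(sprintf(
      "generate_phantom: target unreachable within %d blobs (seed %d)",
      spec$max_blobs, spec$seed))

  achieved_cle <- sum(cle_mask == 1L & hu < -950) / nlung
  achieved_pse <- sum(pse_mask == 1L & hu < -950) / nlung
  truth <- list(
    achieved_cle_pct = achieved_cle,
    achieved_pse_pct = achieved_pse,
    cle_mask = cle_mask, pse_mask = pse_mask,
    scores = list(cle = percent_to_score("cle", achieved_cle),
                  pse = percent_to_score("pse", achieved_pse)),
    converged = converged
  )
  list(ct = ct_volume(hu), mask = lung_mask(lung), truth = truth,
       spec = spec)
}

#' Sample per-phantom targets and seeds for a cohort
#'
#' Draws (centrilobular, paraseptal) score pairs from `score_distribution`,
#' then draws each phantom's target percentage uniformly inside the sampled
#' score's interval. Draws from the open-ended top intervals are capped at
#' 0.45 (centrilobular) and 0.20 (paraseptal) of the lung - realistic upper
#' bounds for severe disease that the spherical-blob model can attain; the
#' caps lie inside the top intervals, so achieved scores are unaffected.
#'
#' @param n cohort size (>= 1).
#' @param score_distribution data.frame with columns `cle`, `pse`, `prob`;
#'   default is independent uniform over the 6 x 3 score grid.
#' @param seed integer master seed; per-phantom seeds are derived from it.
#' @return data.frame: id, seed, cle_score, pse_score, target_cle_pct,
#'   target_pse_pct.
#' @export
sample_cohort_labels <- function(n, score_distribution = NULL, seed = 1L) {
  if (n < 1) stop("sample_cohort_labels: n must be >= 1")
  if (is.null(score_distribution)) {
    score_distribution <- expand.grid(cle = 0:5, pse = 0:2)
    score_distribution$prob <- 1 / nrow(score_distribution)
  }
  sd_ <- score_distribution
  if (nrow(sd_) == 0 || sum(sd_$prob) <= 0)
    stop("sample_cohort_labels: empty score distribution")
  set.seed(seed)
  pick <- sample.int(nrow(sd_), n, replace = TRUE, prob = sd_$prob)
  draw_target <- function(subtype, score, cap) {
    iv <- score_to_interval(subtype, score)
    if (score == 0) return(0)
    runif(1, iv$r_l, min(iv$r_u, cap))
  }
  out <- data.frame(id = sprintf("phantom_%04d", seq_len(n)),
                    seed = (seed + 9973L * seq_len(n)) %% .Machine$integer.max,
                    cle_score = sd_$cle[pick], pse_score = sd_$pse[pick])
  out$target_cle_pct <- mapply(function(s) draw_target("cle", s, 0.45),
                               out$cle_score)
  out$target_pse_pct <- mapply(function(s) draw_target("pse", s, 0.20),
                               out$pse_score)
  out
}

#' Generate a phantom cohort with its label table
#'
#' @inheritParams sample_cohort_labels
#' @param shape phantom grid shape.
#' @param out_dir if non-NULL, each phantom's CT and lung mask are written as
#'   NIfTI (`<id>_ct.nii.gz`, `<id>_mask.nii.gz`) together with `labels.csv`
#'   (id, cle_score, pse_score, cle_pct, pse_pct) and a `manifest.json`
#'   recording seeds and generator settings.
#' @param keep `"phantom"` returns the generated triplets in memory;
#'   `"none"` drops them (requires `out_dir`).
#' @param ... further arguments passed to [phantom_spec()].
#' @return list with `labels` (data.frame of achieved percentages and scores)
#'   and `phantoms` (list or NULL).
#' @export
generate_cohort <- function(n, score_distribution = NULL, seed = 1L,
                            shape = c(48L, 64L, 80L), out_dir = NULL,
                            keep = c("phantom", "none"), ...) {
  keep <- match.arg(keep)
  if (keep == "none" && is.null(out_dir))
    stop("generate_cohort: keep = 'none' requires out_dir")
  plan <- sample_cohort_labels(n, score_distribution, seed)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  phantoms <- if (keep == "phantom") vector("list", n) else NULL
  labels <- data.frame(id = plan$id, cle_score = NA_integer_,
                       pse_score = NA_integer_, cle_pct = NA_real_,
                       pse_pct = NA_real_)
  for (i in seq_len(n)) {
    sp <- phantom_spec(shape = shape, seed = plan$seed[i],
                       target_cle_pct = plan$target_cle_pct[i],
                       target_pse_pct = plan$target_pse_pct[i], ...)
    ph <- generate_phantom(sp)
    labels$cle_score[i] <- ph$truth$scores$cle
    labels$pse_score[i] <- ph$truth$scores$pse
    labels$cle_pct[i] <- ph$truth$achieved_cle_pct
    labels$pse_pct[i] <- ph$truth$achieved_pse_pct
    if (!is.null(out_dir)) {
      write_volume(ph$ct, file.path(out_dir,
                                    paste0(plan$id[i], "_ct.nii.gz")))
      write_volume(ct_volume(ph$mask$values),
                   file.path(out_dir, paste0(plan$id[i], "_mask.nii.gz")))
    }
    if (keep == "phantom") phantoms[[i]] <- ph
  }
  if (!is.null(out_dir)) {
    write.csv(labels, file.path(out_dir, "labels.csv"), row.names = FALSE)
    jsonlite::write_json(list(seed = seed, n = n, shape = shape,
                              plan = plan),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(labels = labels, phantoms = phantoms)
}
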