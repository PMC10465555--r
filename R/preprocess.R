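#' Preprocess a CT volume and lung mask for the network
#'
#' Applies the fixed preprocessing chain: clamp HU to [-1150, -300], rescale
#' linearly to [0, 1] (so -1150 maps to 0 and -300 to 1), crop to the tight
#' bounding box of the lung mask, resize with trilinear interpolation to
#' `out_shape`, and zero every voxel outside the (identically resized,
#' re-binarized) mask. The resulting grid is generally anisotropic; the crop
#' box and source geometry are recorded in `provenance` so dense maps can be
#' resampled back onto the original CT grid.
#'
#' @param ct a [ct_volume()].
#' @param mask a [lung_mask()] on the same grid.
#' @param out_shape integer length-3 network input shape (axial, coronal,
#'   sagittal); default 128 x 224 x 288.
#' @return An object of class `preprocessed_volume`: list with `values` (array
#'   in [0, 1], zero outside the lung), `mask` (0/1 array of the same shape)
#'   and `provenance` (source shape/spacing, crop box, output shape).
#' @export
preprocess <- function(ct, mask, out_shape = c(128L, 224L, 288L)) {
  stopifnot(inherits(ct, "ct_volume"))
  if (!inherits(mask, "lung_mask")) mask <- lung_mask(mask, ct)
  if (!identical(dim(ct$values), dim(mask$values)))
    stop("preprocess: ct and mask shapes differ")
  out_shape <- as.integer(out_shape)
  if (length(out_shape) != 3L || any(out_shape <= 0))
    stop("preprocess: out_shape must be 3 positive integers")
  if (sum(mask$values) == 0) stop("preprocess: empty mask")

  v <- rescale_hu(ct$values)
  bb <- mask_bbox(mask$values)
  vc <- v[bb[1]:bb[2], bb[3]:bb[4], bb[5]:bb[6], drop = FALSE]
  mc <- mask$values[bb[1]:bb[2], bb[3]:bb[4], bb[5]:bb[6], drop = FALSE]
  vr <- resize3d(vc, out_shape)
  mr <- resize3d(mc, out_shape)
  mr <- (mr >= 0.5) * 1
  vr <- vr * mr
  prov <- list(
    orig_shape = dim(ct$values),
    spacing = ct$spacing,
    origin = ct$origin,
    bbox = bb,
    crop_shape = dim(vc),
    out_shape = out_shape,
    zoom = out_shape / dim(vc)
  )
  structure(list(values = vr, mask = mr, provenance = prov),
            class = "preprocessed_volume")
}

# clamp to the emphysema window and map affinely onto [0, 1]
rescale_hu <- function(hu, lo = -1150, hi = -300) {
  (pmin(pmax(hu, lo), hi) - lo) / (hi - lo)
}

# tight 1-based bounding box of a 0/1 array: (d0,d1,h0,h1,w0,w1)
mask_bbox <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask_bbox: empty mask")
  as.integer(c(min(idx[, 1]), max(idx[, 1]),
               min(idx[, 2]), max(idx[, 2]),
               min(idx[, 3]), max(idx[, 3])))
}

#' Trilinear resize of a 3D array
#'
#' Half-pixel-centre (align-corners-false) trilinear interpolation, clamped at
#' the edges; the same sampling is used by the network's upsampling layers,
#' so a resize to the input's own shape is the identity.
#'
#' @param arr 3D numeric array.
#' @param out_shape integer length-3 target shape.
#' @return Resized 3D array.
#' @export
resize3d <- function(arr, out_shape) {
  d <- dim(arr)
  stopifnot(length(d) == 3L)
  out_shape <- as.integer(out_shape)
  if (identical(d, out_shape)) return(arr)
  y <- cpp_resize3d(as.numeric(arr), c(d, 1L), c(out_shape, 1L))
  dim(y) <- out_shape
  y
}

#' Derive the LAA-950 pseudo-label for weak segmentation supervision
#'
#' Low-attenuation areas are the lung voxels below -950 HU on the raw
#' (unclamped) CT; their fraction of the lung is the standard densitometric
#' emphysema surrogate. The binary map is transported onto the network grid
#' with the same crop box and trilinear zoom as [preprocess()], then
#' re-binarized at 0.5 and clipped to the transported lung mask.
#'
#' @param ct a [ct_volume()].
#' @param mask the paired [lung_mask()].
#' @param pre optionally, the [preprocess()] output for this scan; when given,
#'   the pseudo-label `t` is produced on the network grid.
#' @param threshold HU threshold, default -950.
#' @return An object of class `pseudo_label`: list with `fraction` (LAA voxels
#'   / lung voxels on the original grid), `t` (0/1 array on the network grid,
#'   `NULL` when `pre` is missing) and `threshold`.
#' @export
compute_laa950 <- function(ct, mask, pre = NULL, threshold = -950) {
  stopifnot(inherits(ct, "ct_volume"))
  if (!inherits(mask, "lung_mask")) mask <- lung_mask(mask, ct)
  if (!identical(dim(ct$values), dim(mask$values)))
    stop("compute_laa950: ct and mask shapes differ")
  laa <- (ct$values < threshold) * mask$values
  fraction <- sum(laa) / sum(mask$values)
  t_grid <- NULL
  if (!is.null(pre)) {
    if (!inherits(pre, "preprocessed_volume") || is.null(pre$provenance))
      stop("compute_laa950: pre must carry preprocessing provenance")
    bb <- pre$provenance$bbox
    tc <- laa[bb[1]:bb[2], bb[3]:bb[4], bb[5]:bb[6], drop = FALSE]
    tr <- resize3d(tc, pre$provenance$out_shape)
    t_grid <- (tr >= 0.5) * pre$mask
  }
  structure(list(fraction = fraction, t = t_grid, threshold = threshold),
            class = "pseudo_label")
}

# transport a 0/1 grid from the original CT grid to any target grid using the
# stored crop box, then re-binarize; used for masks and pseudo-labels at the
# dense-map resolution
transport_binary <- function(grid, provenance, target_shape) {
  bb <- provenance$bbox
  gc <- grid[bb[1]:bb[2], bb[3]:bb[4], bb[5]:bb[6], drop = FALSE]
  (resize3d(gc, target_shape) >= 0.5) * 1
}
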