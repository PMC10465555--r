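#' Predict severity scores and percentages for one scan
#'
#' Preprocesses the CT + lung mask to the network's input grid, runs the
#' forward pass, and decodes the head outputs: the regression head yields
#' per-lung emphysema percentages (lung-wise means of the dense regression
#' activation maps) which are mapped to ordinal scores with
#' [percent_to_score()]; the classification head yields per-subtype softmax
#' probabilities and argmax scores. Dense maps can be exported co-registered
#' with the source CT via [export_maps()].
#'
#' @param net a trained `emph_network`.
#' @param ct a [ct_volume()].
#' @param mask the paired [lung_mask()].
#' @param export_dir if non-NULL, dense activation maps are written there.
#' @param id scan identifier used in file names.
#' @return A `prediction` list: `cle_score`, `pse_score`; `cle_pct`,
#'   `pse_pct` (regression head); `cle_probs`, `pse_probs` (classification
#'   head); `maps` (dense maps on the network grid), `provenance` and
#'   `map_paths` (when exported).
#' @export
predict_scan <- function(net, ct, mask, export_dir = NULL, id = "scan") {
  stopifnot(inherits(net, "emph_network"))
  if (!inherits(mask, "lung_mask")) mask <- lung_mask(mask, ct)
  if (!identical(dim(ct$values), dim(mask$values)))
    stop("predict_scan: geometry mismatch between ct and mask")
  pre <- preprocess(ct, mask, net$cfg$input_shape)
  out <- if (net$cfg$head == "regression") {
    fr <- forward_regress(net, pre)
    list(cle_score = percent_to_score("cle", fr$p_cle),
         pse_score = percent_to_score("pse", fr$p_pse),
         cle_pct = fr$p_cle, pse_pct = fr$p_pse, maps = fr$maps)
  } else {
    fc <- forward_classify(net, pre)
    list(cle_score = fc$cle_score, pse_score = fc$pse_score,
         cle_probs = fc$cle_probs, pse_probs = fc$pse_probs,
         maps = fc$maps)
  }
  out$provenance <- pre$provenance
  out$id <- id
  if (!is.null(export_dir))
    out$map_paths <- export_maps(out$maps, pre$provenance, mask,
                                 ct$spacing, export_dir, id,
                                 head = net$cfg$head)
  structure(out, class = "prediction")
}

#' @export
print.prediction <- function(x, ...) {
  if (!is.null(x$cle_pct))
    cat(sprintf("%s: CLE score %d (%.2f%% of lung), PSE score %d (%.2f%%)\n",
                x$id, x$cle_score, 100 * x$cle_pct, x$pse_score,
                100 * x$pse_pct))
  else
    cat(sprintf("%s: CLE score %d, PSE score %d\n", x$id, x$cle_score,
                x$pse_score))
  invisible(x)
}

# resample a dense-grid map back onto the original CT grid: upsample to the
# network input grid, invert the crop-box resize, embed at the crop box, and
# zero outside the lung (the maps' training-time support)
map_to_original <- function(map_dense, provenance, lung) {
  up <- resize3d(map_dense, provenance$out_shape)
  back <- resize3d(up, provenance$crop_shape)
  out <- array(0, provenance$orig_shape)
  bb <- provenance$bbox
  out[bb[1]:bb[2], bb[3]:bb[4], bb[5]:bb[6]] <- back
  out * lung
}

#' Export dense activation maps co-registered with the source CT
#'
#' Regression maps produce one scalar NIfTI per subtype; classification maps
#' one per class channel (6 centrilobular + 3 paraseptal). Values are in
#' [0, 1] and zero outside the lung.
#'
#' @param maps `maps` element of a prediction (dense grid, 1/2 input
#'   resolution).
#' @param provenance preprocessing provenance of the scan.
#' @param mask the scan's [lung_mask()].
#' @param spacing voxel spacing of the source CT.
#' @param dir output directory.
#' @param id scan identifier.
#' @param head `"regression"` or `"classification"`.
#' @return Character vector of written file paths.
#' @export
export_maps <- function(maps, provenance, mask, spacing, dir, id = "scan",
                        head = "regression") {
  if (is.null(provenance)) stop("export_maps: missing provenance")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lung <- if (inherits(mask, "lung_mask")) mask$values else mask
  paths <- character()
  emit <- function(m, tag) {
    full <- map_to_original(m, provenance, lung)
    p <- file.path(dir, sprintf("%s_%s.nii.gz", id, tag))
    write_volume(ct_volume(full, spacing = spacing), p)
    paths <<- c(paths, p)
  }
  if (head == "regression") {
    emit(maps$cle, "cle_map")
    emit(maps$pse, "pse_map")
  } else {
    for (k in seq_len(dim(maps$cle)[4]))
      emit(maps$cle[, , , k], sprintf("cle_class%d", k - 1L))
    for (k in seq_len(dim(maps$pse)[4]))
      emit(maps$pse[, , , k], sprintf("pse_class%d", k - 1L))
  }
  paths
}
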