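#' CT volume container
#'
#' A `ct_volume` is a 3D scalar grid in Hounsfield units with its voxel
#' geometry. The array axis order is (axial, coronal, sagittal), matching the
#' D x H x W convention used for the network input.
#'
#' @param values 3D numeric array of HU values (finite).
#' @param spacing numeric length-3, mm per voxel along each axis (> 0).
#' @param origin numeric length-3, mm offset of the first voxel.
#' @return An object of class `ct_volume` with fields `values`, `spacing`,
#'   `origin`.
#' @export
ct_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("ct_volume: values must be a 3D array")
  if (!all(is.finite(values))) stop("ct_volume: values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("ct_volume: spacing must be 3 positive numbers")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("ct_volume %s, spacing %s mm, HU range [%.0f, %.0f]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Lung mask paired with a CT volume
#'
#' @param values 3D array of 0/1 values on the same grid as its CT volume.
#' @param ct optional `ct_volume` to validate the geometry against.
#' @return An object of class `lung_mask`.
#' @export
lung_mask <- function(values, ct = NULL) {
  if (length(dim(values)) != 3L) stop("lung_mask: values must be a 3D array")
  v <- unique(as.vector(values))
  if (!all(v %in% c(0, 1))) stop("lung_mask: values must be 0/1")
  if (!is.null(ct) && !identical(dim(values), dim(ct$values)))
    stop("lung_mask: shape does not match the paired ct_volume")
  if (sum(values) == 0) stop("lung_mask: mask is empty")
  structure(list(values = values), class = "lung_mask")
}

#' Read a CT volume or mask from disk
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) via RNifti and uncompressed MetaImage
#' (`.mha`, `.mhd` + `.raw`/`.zraw` is not supported compressed). Errors on
#' non-3D images.
#'
#' @param path file path.
#' @return A [ct_volume()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("load_volume: file not found: ", path)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3L)
      stop("load_volume: expected a 3D image, got ", length(dim(img)), "D")
    sp <- attr(img, "pixdim")
    if (is.null(sp)) sp <- RNifti::pixdim(img)
    hdr <- RNifti::niftiHeader(img)
    org <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
    ct_volume(unclass(img)[, , , drop = FALSE], spacing = sp[1:3],
              origin = org)
  } else if (grepl("\\.(mha|mhd)$", lp)) {
    read_metaimage(path)
  } else {
    stop("load_volume: unsupported format: ", path)
  }
}

#' Write a CT volume or scalar map to disk
#'
#' @param vol a [ct_volume()] or bare 3D array.
#' @param path output path ending in `.nii`, `.nii.gz` or `.mha`.
#' @param datatype on-disk element type for NIfTI (`"float"` or `"int16"`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "float") {
  if (!inherits(vol, "ct_volume")) vol <- ct_volume(vol)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    arr <- vol$values
    attr(arr, "pixdim") <- vol$spacing
    img <- RNifti::asNifti(arr, datatype = datatype)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mha$", lp)) {
    write_metaimage(vol, path)
  } else {
    stop("write_volume: unsupported format: ", path)
  }
  invisible(path)
}

# --- MetaImage (uncompressed, local or detached raw) ------------------------

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  data_file <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("read_metaimage: truncated header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("read_metaimage: malformed header line: ", line)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") { data_file <- val; break }
  }
  ndims <- as.integer(hdr[["NDims"]])
  if (is.na(ndims) || ndims != 3L)
    stop("read_metaimage: expected a 3D image, got NDims=", hdr[["NDims"]])
  if (identical(tolower(hdr[["CompressedData"]] %||% "false"), "true"))
    stop("read_metaimage: compressed MetaImage is not supported")
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1",
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr[["Offset"]] %||% "0 0 0", "\\s+")[[1]])
  et <- hdr[["ElementType"]] %||% "MET_FLOAT"
  type <- switch(et,
    MET_DOUBLE = list(what = "double", size = 8L),
    MET_FLOAT  = list(what = "double", size = 4L),
    MET_SHORT  = list(what = "integer", size = 2L),
    MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
    MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
    MET_CHAR   = list(what = "integer", size = 1L),
    stop("read_metaimage: unsupported ElementType ", et))
  n <- prod(dims)
  if (identical(data_file, "LOCAL")) {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), data_file)
    if (!file.exists(raw_path))
      stop("read_metaimage: data file not found: ", raw_path)
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  msb <- identical(tolower(hdr[["BinaryDataByteOrderMSB"]] %||% "false"),
                   "true")
  vals <- readBin(raw_con, what = type$what, n = n, size = type$size,
                  signed = type$signed %||% TRUE,
                  endian = if (msb) "big" else "little")
  if (length(vals) != n) stop("read_metaimage: short read")
  ct_volume(array(as.numeric(vals), dim = dims), spacing = spacing,
            origin = origin)
}

write_metaimage <- function(vol, path) {
  dims <- dim(vol$values)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %s", paste(dims, collapse = " ")),
    sprintf("ElementSpacing = %s", paste(vol$spacing, collapse = " ")),
    sprintf("Offset = %s", paste(vol$origin, collapse = " ")),
    "ElementType = MET_DOUBLE",
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  writeBin(as.vector(vol$values), con, size = 8L, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
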