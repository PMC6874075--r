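#' 3D voxel image container
#'
#' A `voxel_image` wraps a 3D numeric array with an isotropic voxel spacing
#' and a value kind. The axis convention is fixed throughout the package:
#' array dimensions are `[x, y, z]` with the z axis longitudinal and slice 1
#' the most proximal.
#'
#' @param data 3D numeric array.
#' @param spacing isotropic voxel spacing in micrometres (default 10.4, the
#'   in vivo scanning resolution the pipeline targets).
#' @param value_kind `"grey"` for raw scanner grey values or `"tmd"` for
#'   calibrated tissue mineral density in mg HA/cc.
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(data, spacing = 10.4, value_kind = c("grey", "tmd")) {
  value_kind <- match.arg(value_kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a single positive number (micrometres)")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, value_kind = value_kind),
            class = "voxel_image")
}

#' Binary bone mask
#'
#' Same grid conventions as [voxel_image()]; `data` holds 0/1 integers.
#' `provenance` records the threshold (or other rule) that produced the mask.
#'
#' @param data 3D array coercible to 0/1.
#' @param spacing voxel spacing, micrometres.
#' @param provenance free-form description of how the mask was obtained.
#' @return An object of class `bone_mask`.
#' @export
bone_mask <- function(data, spacing = 10.4, provenance = NA_character_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  d <- array(as.integer(data != 0), dim = dim(data))
  structure(list(data = d, spacing = spacing,
                 provenance = as.character(provenance)[1]),
            class = "bone_mask")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_image> %d x %d x %d voxels, %.4g um spacing, values: %s\n",
              d[1], d[2], d[3], x$spacing, x$value_kind))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.bone_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bone_mask> %d x %d x %d voxels, %.4g um spacing, %d bone voxels\n",
              d[1], d[2], d[3], x$spacing, sum(x$data)))
  if (!is.na(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.voxel_image <- function(x) dim(x$data)

#' @export
dim.bone_mask <- function(x) dim(x$data)

as_mask_array <- function(x) {
  if (inherits(x, "bone_mask")) x$data
  else if (inherits(x, "voxel_image")) array(as.integer(x$data != 0), dim(x$data))
  else if (is.array(x)) array(as.integer(x != 0), dim(x))
  else stop("expected a bone_mask, voxel_image or array")
}

#' Read a 3D image from disk
#'
#' Supported formats: a multi-page TIFF stack (`.tif`/`.tiff`), MetaImage
#' (`.mhd` header + raw data file) and NIfTI-1 (`.nii`/`.nii.gz`). Slices in
#' a TIFF stack are interpreted as successive z (longitudinal) planes,
#' slice 1 proximal.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"tiff"`, `"mhd"`, `"nifti"`.
#' @param spacing voxel spacing in micrometres; required for TIFF (the format
#'   carries no physical spacing), read from the header for MHD/NIfTI.
#' @param value_kind value kind to record on the returned image.
#' @return A [voxel_image()].
#' @export
read_image <- function(path, format = c("auto", "tiff", "mhd", "nifti"),
                       spacing = NULL, value_kind = "grey") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext,
      tif = , tiff = "tiff",
      mhd = "mhd",
      nii = "nifti",
      stop("cannot infer image format from extension: ", path))
  }
  if (format == "tiff") {
    if (is.null(spacing)) stop("TIFF stacks carry no spacing; supply `spacing`")
    sl <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(sl)) sl <- list(sl)
    nz <- length(sl)
    # readTIFF returns row-major matrices (rows = image y); store as [x, y, z]
    d0 <- dim(sl[[1]])
    arr <- array(0, dim = c(d0[2], d0[1], nz))
    for (k in seq_len(nz)) arr[, , k] <- t(sl[[k]])
    return(voxel_image(arr, spacing = spacing, value_kind = value_kind))
  }
  if (format == "mhd") {
    return(read_mhd(path, value_kind = value_kind))
  }
  # nifti
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)
  sp <- pix[1:3] * 1000 # NIfTI stores mm; package convention is um
  if (max(sp) - min(sp) > 1e-6 * max(sp))
    stop("anisotropic voxel spacing is not supported")
  arr <- array(as.numeric(img), dim = dim(img))
  voxel_image(arr, spacing = sp[1], value_kind = value_kind)
}

#' Write a 3D image to disk
#'
#' @param image a [voxel_image()] or [bone_mask()]. Masks are written as
#'   8-bit 0/1 data.
#' @param path output path; the extension selects the format
#'   (`.tif`, `.mhd`, `.nii`).
#' @param bits_per_sample TIFF bit depth (8, 16 or 32).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits_per_sample = 16L) {
  is_mask <- inherits(image, "bone_mask")
  arr <- image$data
  spacing <- image$spacing
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("tif", "tiff")) {
    if (is_mask) bits_per_sample <- 8L
    maxval <- 2^bits_per_sample - 1
    if (min(arr) < 0 || max(arr) > maxval)
      stop("values out of range for ", bits_per_sample, "-bit TIFF")
    sl <- lapply(seq_len(dim(arr)[3]),
                 function(k) t(arr[, , k]) / maxval)
    tiff::writeTIFF(sl, path, bits.per.sample = as.integer(bits_per_sample))
  } else if (ext == "mhd") {
    write_mhd(arr, spacing, path,
              type = if (is_mask) "MET_UCHAR" else "MET_DOUBLE")
  } else if (ext == "nii") {
    nim <- RNifti::asNifti(array(as.numeric(arr), dim = dim(arr)))
    RNifti::pixdim(nim) <- rep(spacing / 1000, 3)
    RNifti::writeNifti(nim, path)
  } else {
    stop("unsupported output format: .", ext)
  }
  invisible(path)
}

# -- MetaImage (MHD + RAW, little-endian) -----------------------------------

read_mhd <- function(path, value_kind = "grey") {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) >= 2)
      kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  dims <- as.integer(strsplit(kv[["DimSize"]], "\\s+")[[1]])
  sp <- as.numeric(strsplit(kv[["ElementSpacing"]], "\\s+")[[1]])
  if (max(sp) - min(sp) > 1e-9 * max(sp))
    stop("anisotropic voxel spacing is not supported")
  type <- kv[["ElementType"]]
  datafile <- kv[["ElementDataFile"]]
  raw_path <- file.path(dirname(path), datafile)
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- switch(type,
    MET_UCHAR = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    MET_SHORT = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                                   endian = "little")),
    MET_USHORT = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                                    endian = "little")),
    MET_FLOAT = readBin(con, "double", n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    stop("unsupported MetaImage ElementType: ", type))
  voxel_image(array(vals, dim = dims), spacing = sp[1], value_kind = value_kind)
}

write_mhd <- function(arr, spacing, path, type = "MET_DOUBLE") {
  raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  raw_path <- file.path(dirname(path), raw_name)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(arr), collapse = " ")),
           paste("ElementSpacing =", paste(rep(spacing, 3), collapse = " ")),
           paste("ElementType =", type),
           paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  if (type == "MET_UCHAR") {
    writeBin(as.integer(arr), con, size = 1)
  } else if (type == "MET_DOUBLE") {
    writeBin(as.numeric(arr), con, size = 8, endian = "little")
  } else if (type == "MET_FLOAT") {
    writeBin(as.numeric(arr), con, size = 4, endian = "little")
  } else stop("unsupported MetaImage ElementType: ", type)
  invisible(path)
}
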