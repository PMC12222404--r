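#' Construct a volumetric image
#'
#' A `volume3d` is a real-valued 3D grid with spacing and origin metadata, the
#' common carrier for SPECT count maps, absorbed-dose maps (Gy) and
#' attenuation-coefficient maps (mm^-1). World coordinates follow
#' `world = origin + index * spacing` with 0-based indices and an identity
#' direction matrix (RAS).
#'
#' @param values numeric 3D array; must be finite.
#' @param spacing numeric length-3, voxel size in mm (all > 0).
#' @param origin numeric length-3, world position of voxel (0,0,0) in mm.
#' @param unit optional unit label ("counts", "Gy", "mm^-1", ...).
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     unit = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("volume3d: `values` must be a 3D array", call. = FALSE)
  if (!all(is.finite(values)))
    stop("volume3d: values must be finite (no NaN/Inf)", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("volume3d: spacing must be three positive numbers", call. = FALSE)
  if (length(origin) != 3L) stop("volume3d: origin must have length 3", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin,
                 unit = unit),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s  %d x %d x %d voxels  spacing %.4g x %.4g x %.4g mm\n",
              x$unit %||% "", dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm  value range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$values)

#' Voxel volume in mm^3
#' @param image a `volume3d`.
#' @return scalar, mm^3.
#' @export
voxel_volume <- function(image) prod(image$spacing)

is_volume3d <- function(x) inherits(x, "volume3d")

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on a shared grid (dims/spacing/origin differ)", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Read a volumetric image
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`) through RNifti, or MetaImage
#' (`.mha`, `.mhd`) through a built-in reader. Spacing and origin are taken
#' from the file header; the value unit is left to the caller's context.
#'
#' @param path path to a `.nii`, `.nii.gz`, `.mha` or `.mhd` file.
#' @param unit optional unit label attached to the result.
#' @return a [volume3d].
#' @export
read_volume <- function(path, unit = NULL) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.(nii|nii\\.gz)$", lower)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
    if (length(dim(arr)) != 3L)
      stop("read_volume: expected a 3D payload, got ", length(dim(arr)),
           " dimensions", call. = FALSE)
    xf <- RNifti::xform(img)
    spacing <- RNifti::pixdim(img)[1:3]
    origin <- xf[1:3, 4]
    v <- array(as.numeric(arr), dim = dim(arr))
    if (!all(is.finite(v))) stop("read_volume: non-finite voxel values", call. = FALSE)
    return(volume3d(v, spacing = spacing, origin = origin, unit = unit))
  }
  if (grepl("\\.(mha|mhd)$", lower)) return(read_metaimage(path, unit = unit))
  stop("read_volume: unrecognised volumetric format: ", path, call. = FALSE)
}

#' Write a volumetric image
#'
#' NIfTI-1 output (`.nii`/`.nii.gz`, float64, RAS) or MetaImage (`.mha`).
#' A round trip through [read_volume()] reproduces values exactly (float64
#' payloads in both formats) and grid metadata within storage precision:
#' NIfTI-1 headers hold spacing/origin as 32-bit floats, while the
#' MetaImage text header keeps full double precision.
#'
#' @param image a [volume3d].
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(image, path) {
  stopifnot(is_volume3d(image))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("write_volume: directory does not exist: ", dir, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.(nii|nii\\.gz)$", lower)) {
    img <- RNifti::asNifti(image$values)
    aff <- diag(c(image$spacing, 1))
    aff[1:3, 4] <- image$origin
    RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
    RNifti::pixdim(img) <- image$spacing
    ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                   error = function(e) FALSE)
    if (!ok || !file.exists(path))
      stop("write_volume: failed to write ", path, call. = FALSE)
    return(invisible(path))
  }
  if (grepl("\\.(mha|mhd)$", lower)) return(write_metaimage(image, path))
  stop("write_volume: unrecognised output format: ", path, call. = FALSE)
}

# --- MetaImage (ITK .mha/.mhd) support -------------------------------------

metaimage_types <- c(MET_DOUBLE = "double", MET_FLOAT = "float",
                     MET_INT = "int", MET_UINT = "uint", MET_SHORT = "short",
                     MET_USHORT = "ushort", MET_CHAR = "char",
                     MET_UCHAR = "uchar")

read_metaimage <- function(path, unit = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop("read_volume: truncated MetaImage header", call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% "3")
  if (ndims != 3L)
    stop("read_volume: expected a 3D payload, got ", ndims, " dimensions", call. = FALSE)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% hdr$ElementSize %||% "1 1 1",
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset %||% hdr$Position %||% hdr$Origin %||% "0 0 0",
                                "\\s+")[[1]])
  etype <- hdr$ElementType %||% "MET_FLOAT"
  if (!etype %in% names(metaimage_types))
    stop("read_volume: unsupported MetaImage ElementType ", etype, call. = FALSE)
  if (tolower(hdr$CompressedData %||% "false") == "true")
    stop("read_volume: compressed MetaImage not supported", call. = FALSE)
  msb <- tolower(hdr$BinaryDataByteOrderMSB %||% hdr$ElementByteOrderMSB %||% "false") == "true"
  endian <- if (msb) "big" else "little"
  n <- prod(dims)
  datafile <- hdr$ElementDataFile
  if (identical(toupper(datafile), "LOCAL")) {
    raw_con <- con
  } else {
    raw_con <- file(file.path(dirname(path), datafile), "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  vals <- switch(metaimage_types[[etype]],
    double = readBin(raw_con, "double", n, size = 8, endian = endian),
    float  = readBin(raw_con, "double", n, size = 4, endian = endian),
    int    = readBin(raw_con, "integer", n, size = 4, endian = endian),
    uint   = readBin(raw_con, "integer", n, size = 4, endian = endian),
    short  = readBin(raw_con, "integer", n, size = 2, signed = TRUE, endian = endian),
    ushort = readBin(raw_con, "integer", n, size = 2, signed = FALSE, endian = endian),
    char   = readBin(raw_con, "integer", n, size = 1, signed = TRUE, endian = endian),
    uchar  = readBin(raw_con, "integer", n, size = 1, signed = FALSE, endian = endian))
  if (length(vals) != n) stop("read_volume: truncated MetaImage payload", call. = FALSE)
  volume3d(array(as.numeric(vals), dim = dims), spacing = spacing,
           origin = origin, unit = unit)
}

write_metaimage <- function(image, path) {
  d <- dim(image$values)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementSpacing = %.17g %.17g %.17g",
                   image$spacing[1], image$spacing[2], image$spacing[3]),
           sprintf("Offset = %.17g %.17g %.17g",
                   image$origin[1], image$origin[2], image$origin[3]),
           "ElementType = MET_DOUBLE",
           "ElementDataFile = LOCAL")
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("write_volume: cannot open ", path, " for writing", call. = FALSE))
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(image$values), con, size = 8, endian = "little")
  invisible(path)
}

# --- Resampling -------------------------------------------------------------

# Trilinear sample of array `a` at fractional 0-based index coordinates.
# Out-of-range queries are clamped to the boundary (replicate padding).
trilinear_sample <- function(a, xi, yi, zi) {
  d <- dim(a)
  xi <- pmin(pmax(xi, 0), d[1] - 1)
  yi <- pmin(pmax(yi, 0), d[2] - 1)
  zi <- pmin(pmax(zi, 0), d[3] - 1)
  x0 <- pmin(floor(xi), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(yi), d[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(zi), d[3] - 2); z0 <- pmax(z0, 0)
  if (d[1] == 1) x0 <- rep(0, length(xi))
  if (d[2] == 1) y0 <- rep(0, length(yi))
  if (d[3] == 1) z0 <- rep(0, length(zi))
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  at <- function(ix, iy, iz) {
    ix <- pmin(ix, d[1] - 1); iy <- pmin(iy, d[2] - 1); iz <- pmin(iz, d[3] - 1)
    a[1 + ix + d[1] * (iy + d[2] * iz)]
  }
  (1 - fx) * (1 - fy) * (1 - fz) * at(x0,     y0,     z0) +
       fx  * (1 - fy) * (1 - fz) * at(x0 + 1, y0,     z0) +
  (1 - fx) *      fy  * (1 - fz) * at(x0,     y0 + 1, z0) +
       fx  *      fy  * (1 - fz) * at(x0 + 1, y0 + 1, z0) +
  (1 - fx) * (1 - fy) *      fz  * at(x0,     y0,     z0 + 1) +
       fx  * (1 - fy) *      fz  * at(x0 + 1, y0,     z0 + 1) +
  (1 - fx) *      fy  *      fz  * at(x0,     y0 + 1, z0 + 1) +
       fx  *      fy  *      fz  * at(x0 + 1, y0 + 1, z0 + 1)
}

nearest_sample <- function(a, xi, yi, zi) {
  d <- dim(a)
  ix <- pmin(pmax(round(xi), 0), d[1] - 1)
  iy <- pmin(pmax(round(yi), 0), d[2] - 1)
  iz <- pmin(pmax(round(zi), 0), d[3] - 1)
  a[1 + ix + d[1] * (iy + d[2] * iz)]
}

#' Resample a volume onto a new grid
#'
#' Resamples to the requested spacing while covering the same physical
#' extent. `continuous` (trilinear) mode is for dose and count-concentration
#' maps; `nearest` for label volumes. By default values are treated as
#' intensive quantities (concentrations / Gy) and interpolated as-is; with
#' `extensive = TRUE` values are additionally multiplied by the voxel-volume
#' ratio so that the total (e.g. counts) is approximately preserved.
#'
#' @param image a [volume3d].
#' @param target_spacing numeric length-1 or -3, mm.
#' @param interpolation "continuous" or "nearest".
#' @param extensive logical; rescale by voxel-volume ratio (count-preserving).
#' @return a [volume3d] on the new grid.
#' @export
resample_to_grid <- function(image, target_spacing,
                             interpolation = c("continuous", "nearest"),
                             extensive = FALSE) {
  stopifnot(is_volume3d(image))
  interpolation <- match.arg(interpolation)
  if (length(target_spacing) == 1) target_spacing <- rep(target_spacing, 3)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3 || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("resample_to_grid: target spacing must be positive", call. = FALSE)
  d <- dim(image$values)
  if (all(abs(target_spacing - image$spacing) < 1e-12)) return(image)
  extent <- d * image$spacing
  nd <- pmax(1L, as.integer(round(extent / target_spacing)))
  # voxel-centre alignment: both grids span the same physical extent
  idx <- lapply(1:3, function(ax) {
    ((seq_len(nd[ax]) - 0.5) * target_spacing[ax]) / image$spacing[ax] - 0.5
  })
  g <- expand.grid(x = idx[[1]], y = idx[[2]], z = idx[[3]])
  vals <- if (interpolation == "continuous") {
    trilinear_sample(image$values, g$x, g$y, g$z)
  } else {
    nearest_sample(image$values, g$x, g$y, g$z)
  }
  out <- array(vals, dim = nd)
  if (extensive) out <- out * prod(target_spacing) / prod(image$spacing)
  new_origin <- image$origin - 0.5 * image$spacing + 0.5 * target_spacing
  volume3d(out, spacing = target_spacing, origin = new_origin, unit = image$unit)
}

#' Derive a body mask from image support
#'
#' Thresholds at `threshold_fraction` of a robust maximum (99.9th
#' percentile), keeps the largest 26-connected component, and applies one
#' morphological closing pass with a 1-voxel-radius ball. Used for background
#' removal outside the body contour.
#'
#' @param image a non-negative [volume3d].
#' @param threshold_fraction fraction of the robust maximum (default 0.01).
#' @return logical 3D array (the body mask).
#' @export
derive_body_mask <- function(image, threshold_fraction = 0.01) {
  stopifnot(is_volume3d(image))
  v <- image$values
  if (min(v) < 0) stop("derive_body_mask: image must be non-negative", call. = FALSE)
  robust_max <- as.numeric(quantile(v, 0.999, names = FALSE))
  if (robust_max <= 0) {
    warning("derive_body_mask: all-zero image, returning empty mask")
    return(array(FALSE, dim(v)))
  }
  fg <- v > threshold_fraction * robust_max
  if (!any(fg)) {
    warning("derive_body_mask: threshold removed all voxels, returning empty mask")
    return(array(FALSE, dim(v)))
  }
  lab <- label_components_26(fg)
  tab <- tabulate(lab[lab > 0L])
  keep <- which.max(tab)
  close6(lab == keep)
}

label_components_26 <- function(mask) {
  storage.mode(mask) <- "logical"
  array(cpp_label26(mask, dim(mask)), dim(mask))
}
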