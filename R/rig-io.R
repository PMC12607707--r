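## Calibration file and raster I/O. Rig calibration is a flat YAML mapping
## with blocks `nir` and `tir`, each holding kx, ky, u0, v0, width, height,
## R (9 values, row-major) and p (3 values, meters). Depth rasters are 16-bit
## single-channel millimeter-valued images (0 = no return).

#' Write a camera rig calibration file
#'
#' @param rig [CameraRig-class].
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
writeRig <- function(rig, path) {
  stopifnot(is(rig, "CameraRig"))
  blk <- function(intr, pose, size) list(
    kx = intr@kx, ky = intr@ky, u0 = intr@u0, v0 = intr@v0,
    width = size[1], height = size[2],
    R = as.numeric(t(pose@R)),           # row-major
    p = as.numeric(pose@p))
  yaml::write_yaml(list(nir = blk(rig@nirIntrinsics, rig@nirPose, rig@nirSize),
                        tir = blk(rig@tirIntrinsics, rig@tirPose, rig@tirSize)),
                   path, precision = 15L)   # keep rotations orthonormal to 1e-9
  invisible(path)
}

#' Read a camera rig calibration file
#'
#' @param path YAML file written by [writeRig()] (or hand-authored in the
#'   same layout).
#' @return A [CameraRig-class].
#' @export
readRig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!all(c("nir", "tir") %in% names(cfg)))
    stop("rig calibration must contain 'nir' and 'tir' blocks")
  get <- function(b) {
    need <- c("kx", "ky", "u0", "v0", "width", "height", "R", "p")
    if (!all(need %in% names(b)))
      stop("rig block missing fields: ", paste(setdiff(need, names(b)), collapse = ", "))
    list(intr = Intrinsics(b$kx, b$ky, b$u0, b$v0),
         pose = Pose(matrix(as.numeric(b$R), 3, 3, byrow = TRUE), as.numeric(b$p)),
         size = c(b$width, b$height))
  }
  n <- get(cfg$nir); t <- get(cfg$tir)
  CameraRig(n$intr, t$intr, n$pose, t$pose, n$size, t$size)
}

#' Read / write 16-bit depth rasters
#'
#' Depth is stored as 16-bit unsigned millimeters, 0 meaning no return.
#' `writeDepth()` emits single-channel 16-bit TIFF; `readDepth()` accepts
#' 16-bit TIFF or PNG.
#'
#' @param depthMm Integer-valued `height x width` matrix of millimeters
#'   in `[0, 65535]`.
#' @param path File path (`.tif`/`.tiff` for writing; reading also `.png`).
#' @return `readDepth()` returns the millimeter matrix; `writeDepth()` the
#'   path, invisibly.
#' @export
writeDepth <- function(depthMm, path) {
  stopifnot(is.matrix(depthMm))
  if (any(depthMm < 0 | depthMm > 65535))
    stop("depth values must lie in [0, 65535] mm")
  tiff::writeTIFF(depthMm / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname writeDepth
#' @export
readDepth <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  round(img * 65535)
}

#' Read / write 8-bit grayscale rasters
#'
#' Thin PNG wrappers used for the NIR/TIR/RGB modalities; values are 0-255.
#'
#' @param img `height x width` matrix (grayscale) or `height x width x 3`
#'   array (RGB), values in 0-255.
#' @param path PNG file path.
#' @return `readGray()` returns the 0-255 raster; `writeGray()` the path.
#' @export
writeGray <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @rdname writeGray
#' @export
readGray <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] > 3L) img <- img[, , 1:3]
  round(img * 255)
}
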