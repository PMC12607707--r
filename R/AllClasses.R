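#' @import methods
#' @importFrom stats median qt rnorm runif sd
#' @importFrom utils read.csv
NULL

## Rotation validity tolerance used throughout: max|R'R - I| <= 1e-9 and
## |det(R) - 1| <= 1e-9. Poses map world coordinates into the camera frame as
## camera = R %*% world + p.
.ROT_TOL <- 1e-9

#' Pinhole camera intrinsics
#'
#' Focal scales (`kx`, `ky`, pixels) and principal point (`u0`, `v0`, pixels)
#' of a distortion-free pinhole camera. Pixel coordinates are 0-based with
#' `u` the column and `v` the row, and pixel centers at integer coordinates.
#'
#' @slot kx,ky Focal scales along the horizontal / vertical axis (pixels).
#' @slot u0,v0 Principal point column / row (pixels).
#' @export
setClass("Intrinsics",
  representation(kx = "numeric", ky = "numeric", u0 = "numeric", v0 = "numeric"))

setValidity("Intrinsics", function(object) {
  v <- c(object@kx, object@ky, object@u0, object@v0)
  if (length(v) != 4L || any(!is.finite(v)))
    return("kx, ky, u0, v0 must be single finite numbers")
  if (object@kx <= 0 || object@ky <= 0)
    return("focal scales kx and ky must be positive")
  TRUE
})

#' Construct camera intrinsics
#'
#' @param kx,ky Focal scales (pixels); must be positive.
#' @param u0,v0 Principal point column / row (pixels).
#' @return An [Intrinsics-class] object.
#' @examples
#' Intrinsics(730, 730, 511.5, 383.5)
#' @export
Intrinsics <- function(kx, ky, u0, v0) {
  new("Intrinsics", kx = as.numeric(kx), ky = as.numeric(ky),
      u0 = as.numeric(u0), v0 = as.numeric(v0))
}

#' Rigid camera pose
#'
#' A world-to-camera rigid transform: `camera = R %*% world + p`. `R` must be
#' a proper rotation (orthonormal, determinant +1, both to 1e-9).
#'
#' @slot R 3x3 rotation matrix (unitless).
#' @slot p Translation vector (meters).
#' @export
setClass("Pose", representation(R = "matrix", p = "numeric"))

setValidity("Pose", function(object) {
  R <- object@R
  if (!is.numeric(R) || !identical(dim(R), c(3L, 3L)) || any(!is.finite(R)))
    return("R must be a finite 3x3 numeric matrix")
  if (max(abs(crossprod(R) - diag(3))) > .ROT_TOL)
    return("R is not orthonormal (tolerance 1e-9)")
  if (abs(det(R) - 1) > .ROT_TOL)
    return("R must have determinant +1 (tolerance 1e-9)")
  if (length(object@p) != 3L || any(!is.finite(object@p)))
    return("p must be a finite length-3 numeric vector")
  TRUE
})

#' Construct a camera pose
#'
#' @param R 3x3 proper rotation matrix mapping world into camera coordinates.
#' @param p Length-3 translation vector (meters).
#' @return A [Pose-class] object.
#' @examples
#' Pose()                      # identity pose
#' Pose(diag(3), c(0.02, 0, 0))
#' @export
Pose <- function(R = diag(3), p = c(0, 0, 0)) {
  new("Pose", R = R, p = as.numeric(p))
}

#' Calibrated two-camera rig
#'
#' Intrinsics and world poses of the NIR and TIR cameras, plus raster sizes.
#' Defaults match the deployed sensors: NIR/depth 1024x768, TIR 256x192.
#'
#' @slot nirIntrinsics,tirIntrinsics [Intrinsics-class] of each camera.
#' @slot nirPose,tirPose [Pose-class] of each camera (world to camera).
#' @slot nirSize,tirSize Integer `(width, height)` in pixels.
#' @export
setClass("CameraRig",
  representation(nirIntrinsics = "Intrinsics", tirIntrinsics = "Intrinsics",
                 nirPose = "Pose", tirPose = "Pose",
                 nirSize = "integer", tirSize = "integer"))

setValidity("CameraRig", function(object) {
  for (s in list(object@nirSize, object@tirSize))
    if (length(s) != 2L || any(!is.finite(s)) || any(s <= 0L))
      return("sizes must be positive integer (width, height) pairs")
  TRUE
})

#' Construct a camera rig
#'
#' @param nirIntrinsics,tirIntrinsics [Intrinsics-class] objects.
#' @param nirPose,tirPose [Pose-class] objects (world-to-camera).
#' @param nirSize,tirSize Raster `(width, height)` in pixels.
#' @return A [CameraRig-class] object.
#' @examples
#' rig <- CameraRig(Intrinsics(730, 730, 511.5, 383.5),
#'                  Intrinsics(240, 240, 127.5, 95.5))
#' @export
CameraRig <- function(nirIntrinsics, tirIntrinsics,
                      nirPose = Pose(), tirPose = Pose(),
                      nirSize = c(1024L, 768L), tirSize = c(256L, 192L)) {
  new("CameraRig", nirIntrinsics = nirIntrinsics, tirIntrinsics = tirIntrinsics,
      nirPose = nirPose, tirPose = tirPose,
      nirSize = as.integer(nirSize), tirSize = as.integer(tirSize))
}

#' Per-pixel NIR-to-TIR registration map
#'
#' For every NIR pixel, the continuous and rounded target TIR pixel (or `NA`
#' when the pixel has no depth return or falls outside the TIR frame), and on
#' the TIR grid the z-buffer of the winning (nearest) source depth together
#' with the linear index of the winning NIR pixel.
#'
#' Raster slots are stored as `height x width` matrices (row = `v + 1`,
#' column = `u + 1`).
#'
#' @slot targetU,targetV NIR-sized matrices of continuous target TIR
#'   coordinates (`NA` where invalid/out of view).
#' @slot zbuffer TIR-sized matrix of the winning depth in the TIR frame
#'   (meters; `NA` where no source landed).
#' @slot sourceIndex TIR-sized matrix of the winning NIR pixel's linear index.
#' @slot validMask TIR-sized logical matrix: `TRUE` where a source won.
#' @slot nirSize,tirSize `(width, height)` of the two grids.
#' @export
setClass("RegistrationMap",
  representation(targetU = "matrix", targetV = "matrix",
                 zbuffer = "matrix", sourceIndex = "matrix",
                 validMask = "matrix", nirSize = "integer", tirSize = "integer"))

setValidity("RegistrationMap", function(object) {
  hN <- object@nirSize[2]; wN <- object@nirSize[1]
  hT <- object@tirSize[2]; wT <- object@tirSize[1]
  if (!identical(dim(object@targetU), c(hN, wN)) ||
      !identical(dim(object@targetV), c(hN, wN)))
    return("targetU/targetV must be NIR-sized (height x width)")
  if (!identical(dim(object@zbuffer), c(hT, wT)) ||
      !identical(dim(object@sourceIndex), c(hT, wT)) ||
      !identical(dim(object@validMask), c(hT, wT)))
    return("zbuffer/sourceIndex/validMask must be TIR-sized (height x width)")
  u <- object@targetU[!is.na(object@targetU)]
  v <- object@targetV[!is.na(object@targetV)]
  if (length(u) && (any(u < -0.5) || any(u >= wT - 0.5) ||
                    any(v < -0.5) || any(v >= hT - 0.5)))
    return("valid targets must round into the TIR frame")
  TRUE
})

#' A registered and fused NIR-TIR frame
#'
#' TIR-sized raster stack: channel 1 the NIR intensity warped into the TIR
#' frame, channel 2 the TIR intensity, channel 3 their mean. Pixels that no
#' NIR sample reached are hole-filled and flagged `FALSE` in the mask.
#'
#' @slot nirReg,tir,fused TIR-sized `height x width` matrices (0-255).
#' @slot mask Logical matrix, `TRUE` where channel 1 holds a warped sample
#'   (not a hole-fill value).
#' @slot metadata List: provenance (rig/frame ids), fill policy, and the
#'   nominal TIR intensity-to-temperature mapping.
#' @export
setClass("FusedFrame",
  representation(nirReg = "matrix", tir = "matrix", fused = "matrix",
                 mask = "matrix", metadata = "list"))

setValidity("FusedFrame", function(object) {
  d <- dim(object@tir)
  if (!identical(dim(object@nirReg), d) || !identical(dim(object@fused), d) ||
      !identical(dim(object@mask), d))
    return("all channels and the mask must share the TIR dimensions")
  TRUE
})
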