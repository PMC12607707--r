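## Depth-assisted pinhole chain: NIR pixel -> NIR camera frame -> TIR camera
## frame -> TIR pixel. All point operations are vectorized over pixels;
## 3D points travel as n x 3 matrices with columns X, Y, Z (meters).

#' Round half away from zero
#'
#' Deterministic rounding used when a discrete target pixel is required:
#' `0.5 -> 1`, `-0.5 -> -1` (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @examples roundHalfAway(c(-1.5, -0.5, 0.5, 1.5))
#' @export
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Back-project NIR pixels to the NIR camera frame
#'
#' With a depth value for each pixel, a pixel `(u, v)` lifts to the 3D camera
#' point `X = (u - u0) Z / kx`, `Y = (v - v0) Z / ky`, `Z = depth`.
#'
#' @param u,v Pixel coordinates (0-based column / row; may be fractional).
#' @param depthM Depth along the optical axis (meters); must be positive.
#' @param intr NIR camera [Intrinsics-class].
#' @return An `n x 3` matrix with columns `X`, `Y`, `Z` (meters).
#' @examples
#' K <- Intrinsics(500, 500, 512, 384)
#' backprojectNir(612, 384, 0.5, K)   # (0.1, 0, 0.5)
#' @export
backprojectNir <- function(u, v, depthM, intr) {
  stopifnot(is(intr, "Intrinsics"))
  if (any(!is.finite(u)) || any(!is.finite(v)))
    stop("non-finite pixel coordinates")
  if (any(!is.finite(depthM)) || any(depthM <= 0))
    stop("invalid depth: depth must be finite and positive")
  X <- (u - intr@u0) * depthM / intr@kx
  Y <- (v - intr@v0) * depthM / intr@ky
  cbind(X = X, Y = Y, Z = depthM)
}

#' Transform points from the NIR to the TIR camera frame
#'
#' Composes the two world-to-camera poses: with `cam = R world + p` for each
#' camera, a point in the NIR frame maps to
#' `R_TIR R_NIR^-1 (x - p_NIR) + p_TIR` in the TIR frame.
#'
#' @param points `n x 3` matrix (or length-3 vector) of NIR-frame points (m).
#' @param nirPose,tirPose [Pose-class] of the two cameras.
#' @return `n x 3` matrix of TIR-frame points.
#' @export
transformNirToTir <- function(points, nirPose, tirPose) {
  stopifnot(is(nirPose, "Pose"), is(tirPose, "Pose"))
  p <- .asPoints(points)
  M <- tirPose@R %*% t(nirPose@R)          # R_NIR^-1 = t(R_NIR)
  out <- sweep(p, 2, nirPose@p) %*% t(M)
  sweep(out, 2, tirPose@p, `+`)
}

#' Project TIR-frame points to TIR pixel coordinates
#'
#' Pinhole projection `u = u0 + kx X / Z`, `v = v0 + ky Y / Z`. Points with
#' non-positive `Z` are behind the camera and raise an error.
#'
#' @param points `n x 3` matrix (or length-3 vector) of TIR-frame points (m).
#' @param intr TIR camera [Intrinsics-class].
#' @return `n x 2` matrix with columns `u`, `v` (continuous pixels).
#' @examples
#' projectToTir(c(0.1, 0, 0.5), Intrinsics(200, 200, 128, 96))  # (168, 96)
#' @export
projectToTir <- function(points, intr) {
  stopifnot(is(intr, "Intrinsics"))
  p <- .asPoints(points)
  if (any(p[, 3] <= 0))
    stop("behind-camera: point has non-positive Z in the TIR frame")
  cbind(u = intr@u0 + intr@kx * p[, 1] / p[, 3],
        v = intr@v0 + intr@ky * p[, 2] / p[, 3])
}

#' Map NIR pixels to TIR pixels through the depth-assisted chain
#'
#' Runs [backprojectNir()], [transformNirToTir()] and [projectToTir()] for
#' each pixel and rounds the result (half away from zero) to a discrete TIR
#' pixel. Pixels whose rounded target falls outside
#' `[0, tir_width) x [0, tir_height)`, or that land behind the TIR camera,
#' are flagged out of view rather than raising.
#'
#' @param u,v NIR pixel coordinates (0-based, vectorized).
#' @param depthM Depth (meters, positive) per pixel.
#' @param rig [CameraRig-class].
#' @return A data.frame with columns `u`, `v` (continuous TIR coordinates,
#'   `NA` behind camera), `col`, `row` (rounded integer TIR pixel, `NA` when
#'   out of view), `zTir` (depth in the TIR frame), and `inView`.
#' @export
mapNirPixelToTir <- function(u, v, depthM, rig) {
  stopifnot(is(rig, "CameraRig"))
  n <- max(length(u), length(v), length(depthM))
  u <- rep_len(u, n); v <- rep_len(v, n); depthM <- rep_len(depthM, n)
  pts <- backprojectNir(u, v, depthM, rig@nirIntrinsics)
  pts <- transformNirToTir(pts, rig@nirPose, rig@tirPose)
  zT <- pts[, 3]
  front <- zT > 0
  uT <- vT <- rep(NA_real_, n)
  if (any(front)) {
    px <- projectToTir(pts[front, , drop = FALSE], rig@tirIntrinsics)
    uT[front] <- px[, 1]
    vT[front] <- px[, 2]
  }
  colI <- roundHalfAway(uT)
  rowI <- roundHalfAway(vT)
  inView <- front & !is.na(colI) &
    colI >= 0 & colI < rig@tirSize[1] & rowI >= 0 & rowI < rig@tirSize[2]
  colI[!inView] <- NA_real_
  rowI[!inView] <- NA_real_
  data.frame(u = uT, v = vT, col = colI, row = rowI, zTir = zT, inView = inView)
}

.asPoints <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  if (any(!is.finite(points))) stop("non-finite 3D coordinates")
  points
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula; used to build calibration poses and synthetic rigs.
#'
#' @param axis Length-3 rotation axis (need not be normalized).
#' @param angleDeg Rotation angle in degrees.
#' @return A 3x3 proper rotation matrix.
#' @export
rotationAxisAngle <- function(axis, angleDeg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
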