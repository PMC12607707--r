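## Synthetic inputs with known ground truth: perturbed camera rigs,
## geometrically consistent NIR/TIR/depth scenes with live/dead rabbit
## phantoms rendered through the full perspective model of each camera, and
## environmental time series. All generators are pure functions of their
## spec and seed.

#' Generate a two-camera rig with a perturbed TIR pose
#'
#' The NIR camera sits at the world origin (identity pose); the TIR pose is
#' perturbed by a random-direction baseline translation and a
#' random-axis rotation of the stated magnitudes. Deterministic per seed.
#' Default intrinsics give fields of view close to the deployed LiDAR
#' camera (NIR) and thermal camera (TIR).
#'
#' @param seed Integer seed.
#' @param baselineMm Camera baseline (mm); short-baseline regime, <= 50.
#' @param rotationDeg Relative rotation (degrees); small-angle regime, <= 5.
#' @param nirSize,tirSize Raster sizes `(width, height)`.
#' @param nirFocal,tirFocal Focal scales (pixels).
#' @return A [CameraRig-class].
#' @export
synthRig <- function(seed = 1, baselineMm = 20, rotationDeg = 2,
                     nirSize = c(1024L, 768L), tirSize = c(256L, 192L),
                     nirFocal = 730, tirFocal = 240) {
  stopifnot(baselineMm >= 0, baselineMm <= 50,
            rotationDeg >= 0, rotationDeg <= 5)
  set.seed(as.integer(seed))
  nirIntr <- Intrinsics(nirFocal, nirFocal, (nirSize[1] - 1) / 2,
                        (nirSize[2] - 1) / 2)
  tirIntr <- Intrinsics(tirFocal, tirFocal, (tirSize[1] - 1) / 2,
                        (tirSize[2] - 1) / 2)
  if (baselineMm == 0 && rotationDeg == 0) {
    tirPose <- Pose()
  } else {
    dirT <- rnorm(3); dirT <- dirT / sqrt(sum(dirT^2))
    axis <- rnorm(3)
    R <- if (rotationDeg > 0) rotationAxisAngle(axis, rotationDeg) else diag(3)
    tirPose <- Pose(R, dirT * baselineMm / 1000)
  }
  CameraRig(nirIntr, tirIntr, Pose(), tirPose, nirSize, tirSize)
}

#' Specify a synthetic cage scene
#'
#' The scene is a flat cage plane at `planeDepth` below the cameras with
#' half-ellipsoid rabbit phantoms bulging toward them. Live phantoms are
#' body-warm in the TIR channel; dead phantoms sit at ambient (cold body =
#' mortality cue). Both NIR and TIR render bright animal contours against a
#' dark cage background.
#'
#' @param phantoms A data.frame with columns `x`, `y` (world position on
#'   the plane, m), `ax`, `ay`, `az` (semi-axes, m), `status` (`"live"` /
#'   `"dead"`).
#' @param planeDepth Cage plane depth below the camera (m); the deployed
#'   imaging distance is about 0.384 m.
#' @param ambient Background / dead-body TIR intensity (0-255).
#' @param bodyWarm Live-body TIR intensity (0-255).
#' @param phantomAlbedo,backgroundAlbedo NIR intensities (0-255).
#' @param noiseSd Gaussian intensity noise scale added to NIR and TIR.
#' @param seed Integer seed (noise only; geometry is deterministic).
#' @return A list of class `SceneSpec`.
#' @export
sceneSpec <- function(phantoms = NULL, planeDepth = 0.384, ambient = 80,
                      bodyWarm = 180, phantomAlbedo = 200,
                      backgroundAlbedo = 30, noiseSd = 0, seed = 1) {
  if (is.null(phantoms))
    phantoms <- data.frame(x = numeric(), y = numeric(), ax = numeric(),
                           ay = numeric(), az = numeric(),
                           status = character())
  stopifnot(all(c("x", "y", "ax", "ay", "az", "status") %in% names(phantoms)),
            planeDepth > 0,
            all(phantoms$status %in% c("live", "dead")),
            all(phantoms$ax > 0), all(phantoms$ay > 0), all(phantoms$az > 0),
            all(phantoms$az < planeDepth))
  structure(list(phantoms = phantoms, planeDepth = planeDepth,
                 ambient = ambient, bodyWarm = bodyWarm,
                 phantomAlbedo = phantomAlbedo,
                 backgroundAlbedo = backgroundAlbedo,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "SceneSpec")
}

#' Draw a random scene specification
#'
#' Places non-overlapping live and dead phantoms uniformly inside the region
#' of the cage plane seen by both cameras of a default-geometry rig.
#'
#' @param seed Integer seed.
#' @param nLive,nDead Phantom counts.
#' @param xRange,yRange Placement region on the plane (m).
#' @param ... Passed to [sceneSpec()] (e.g. `noiseSd`, `planeDepth`).
#' @return A `SceneSpec`.
#' @export
randomScene <- function(seed = 1, nLive = 2, nDead = 1,
                        xRange = c(-0.11, 0.11), yRange = c(-0.07, 0.07),
                        ...) {
  set.seed(as.integer(seed))
  n <- nLive + nDead
  x <- y <- ax <- ay <- numeric(n)
  for (k in seq_len(n)) {
    for (try in 1:200) {
      xk <- runif(1, xRange[1], xRange[2])
      yk <- runif(1, yRange[1], yRange[2])
      axk <- runif(1, 0.035, 0.055)
      ayk <- runif(1, 0.030, 0.045)
      prev <- seq_len(k - 1L)
      ## footprint-ellipse separation so phantom silhouettes never merge
      clear <- all(((x[prev] - xk) / (ax[prev] + axk))^2 +
                   ((y[prev] - yk) / (ay[prev] + ayk))^2 > 1.3)
      if (clear) break
    }
    x[k] <- xk; y[k] <- yk; ax[k] <- axk; ay[k] <- ayk
  }
  ph <- data.frame(x = x, y = y, ax = ax, ay = ay,
                   az = runif(n, 0.020, 0.040),
                   status = c(rep("live", nLive), rep("dead", nDead)))
  sceneSpec(phantoms = ph, seed = seed, ...)
}

## Ray-cast one camera: plane + ellipsoid intersection per pixel.
## Returns camera-frame depth (m) and the id of the nearest phantom hit.
.renderCamera <- function(spec, intr, pose, size) {
  w <- size[1]; h <- size[2]
  R <- pose@R; p <- pose@p
  o <- as.numeric(-crossprod(R, p))            # camera origin in world
  u <- rep(seq_len(w) - 1, each = h)
  v <- rep(seq_len(h) - 1, times = w)
  dx <- (u - intr@u0) / intr@kx                # ray direction, camera frame
  dy <- (v - intr@v0) / intr@ky
  ## world direction = t(R) %*% (dx, dy, 1)
  dwx <- R[1, 1] * dx + R[2, 1] * dy + R[3, 1]
  dwy <- R[1, 2] * dx + R[2, 2] * dy + R[3, 2]
  dwz <- R[1, 3] * dx + R[2, 3] * dy + R[3, 3]
  tBuf <- (spec$planeDepth - o[3]) / dwz       # cage plane hit
  id <- integer(length(tBuf))
  ph <- spec$phantoms
  for (k in seq_len(nrow(ph))) {
    cx <- ph$x[k]; cy <- ph$y[k]; cz <- spec$planeDepth
    ax <- ph$ax[k]; ay <- ph$ay[k]; az <- ph$az[k]
    ocx <- o[1] - cx; ocy <- o[2] - cy; ocz <- o[3] - cz
    A <- (dwx / ax)^2 + (dwy / ay)^2 + (dwz / az)^2
    B <- 2 * (ocx * dwx / ax^2 + ocy * dwy / ay^2 + ocz * dwz / az^2)
    C <- (ocx / ax)^2 + (ocy / ay)^2 + (ocz / az)^2 - 1
    disc <- B^2 - 4 * A * C
    hit <- disc > 0
    t <- rep(Inf, length(tBuf))
    t[hit] <- (-B[hit] - sqrt(disc[hit])) / (2 * A[hit])
    better <- hit & t > 0 & t < tBuf
    tBuf[better] <- t[better]
    id[better] <- k
  }
  ## camera-frame Z of the hit point: point_cam = t * (dx, dy, 1)
  list(Z = matrix(tBuf, h, w), id = matrix(id, h, w))
}

.clamp8 <- function(x) round(pmin(pmax(x, 0), 255))

.maskCentroid <- function(idMat, k) {
  idx <- which(idMat == k)
  if (!length(idx)) return(c(u = NA_real_, v = NA_real_, area = 0))
  h <- nrow(idMat)
  c(u = mean((idx - 1) %/% h), v = mean((idx - 1) %% h), area = length(idx))
}

#' Render a synthetic multi-modal frame set
#'
#' Ray-casts the scene through each camera's own pose and intrinsics, so the
#' cross-modal geometry is exactly consistent with the registration chain:
#' the depth raster holds the NIR camera-frame depth in millimeters, and
#' per-phantom ground-truth masks and centroids are emitted in both NIR and
#' TIR pixel coordinates. Identical spec and seed give bitwise-identical
#' rasters.
#'
#' @param spec A [sceneSpec()].
#' @param rig A [CameraRig-class].
#' @param renderRgb Also render the 1920x1080 RGB proxy (a grayscale render
#'   replicated to three channels; nothing downstream consumes its content).
#' @return A list of class `SynthFrameSet`: `nir`, `tir` (0-255 matrices),
#'   `depth` (mm matrix), optionally `rgb` (h x w x 3), `nirMask`,
#'   `tirMask` (phantom-id matrices), `gt` (data.frame: `id`, `status`,
#'   `nirU`, `nirV`, `nirArea`, `tirU`, `tirV`, `tirArea`), `contentTag`,
#'   `rig`, `spec`.
#' @export
renderScene <- function(spec, rig, renderRgb = TRUE) {
  stopifnot(inherits(spec, "SceneSpec"), is(rig, "CameraRig"))
  set.seed(spec$seed)
  ph <- spec$phantoms
  nPh <- nrow(ph)

  nirCam <- .renderCamera(spec, rig@nirIntrinsics, rig@nirPose, rig@nirSize)
  tirCam <- .renderCamera(spec, rig@tirIntrinsics, rig@tirPose, rig@tirSize)

  shade <- function(id, dark, bright) {
    out <- matrix(dark, nrow(id), ncol(id))
    out[id > 0] <- bright
    out
  }
  tirLevel <- function(id) {
    out <- matrix(spec$ambient, nrow(id), ncol(id))
    for (k in seq_len(nPh))
      if (ph$status[k] == "live") out[id == k] <- spec$bodyWarm
    out
  }
  noisy <- function(x) {
    if (spec$noiseSd > 0) x <- x + rnorm(length(x), 0, spec$noiseSd)
    .clamp8(x)
  }
  nir <- noisy(shade(nirCam$id, spec$backgroundAlbedo, spec$phantomAlbedo))
  tir <- noisy(tirLevel(tirCam$id))
  depth <- round(pmin(nirCam$Z * 1000, 65535))

  gt <- do.call(rbind, lapply(seq_len(nPh), function(k) {
    cN <- .maskCentroid(nirCam$id, k)
    cT <- .maskCentroid(tirCam$id, k)
    data.frame(id = k, status = ph$status[k],
               nirU = cN["u"], nirV = cN["v"], nirArea = cN["area"],
               tirU = cT["u"], tirV = cT["v"], tirArea = cT["area"],
               row.names = NULL)
  }))
  if (is.null(gt)) gt <- data.frame(id = integer(), status = character(),
                                    nirU = numeric(), nirV = numeric(),
                                    nirArea = numeric(), tirU = numeric(),
                                    tirV = numeric(), tirArea = numeric())
  skipped <- gt$nirArea == 0 & gt$tirArea == 0
  if (any(skipped)) {
    warning(sum(skipped), " phantom(s) outside both camera frusta; skipped")
    gt <- gt[!skipped, , drop = FALSE]
  }
  contentTag <- if (!nrow(gt)) "live-only"
    else if (all(gt$status == "dead")) "dead-only"
    else if (any(gt$status == "dead")) "mixed" else "live-only"

  out <- list(nir = nir, tir = tir, depth = depth,
              nirMask = nirCam$id, tirMask = tirCam$id,
              gt = gt, contentTag = contentTag, rig = rig, spec = spec)
  if (renderRgb) {
    rgbIntr <- Intrinsics(rig@nirIntrinsics@kx * 1920 / rig@nirSize[1],
                          rig@nirIntrinsics@ky * 1920 / rig@nirSize[1],
                          (1920 - 1) / 2, (1080 - 1) / 2)
    rgbCam <- .renderCamera(spec, rgbIntr, rig@nirPose, c(1920L, 1080L))
    g <- noisy(shade(rgbCam$id, spec$backgroundAlbedo, spec$phantomAlbedo))
    out$rgb <- array(g, c(1080L, 1920L, 3L))
  }
  structure(out, class = "SynthFrameSet")
}

#' @export
print.SynthFrameSet <- function(x, ...) {
  cat(sprintf("SynthFrameSet: %d phantom(s) [%s], plane %.3f m, seed %d\n",
              nrow(x$gt), x$contentTag, x$spec$planeDepth, x$spec$seed))
  invisible(x)
}

#' Synthesize an environmental telemetry series
#'
#' Draws each parameter independently from a normal distribution around its
#' mean. Defaults center on the conditions observed in a running rabbit
#' house: NH3 10-11 ppm, CO2 400-440 ppm, temperature 20-25 C, humidity
#' 50-55 %RH, wind 0.11-0.15 m/s, light 6-10 lux, pressure 970-1000 hPa.
#' Deterministic per seed.
#'
#' @param n Number of records.
#' @param means,spreads Named numeric vectors (`wind`, `pressure`, `nh3`,
#'   `co2`, `temperature`, `humidity`, `light`); spreads are normal SDs.
#' @param seed Integer seed.
#' @param startTime First record time, `MMDD-HH:MM:SS`.
#' @param stepS Seconds between records.
#' @param locations Location strings `"x-y"`, recycled to `n`.
#' @return A data.frame of [envRecord()] rows.
#' @export
synthEnvSeries <- function(n, means = c(wind = 0.13, pressure = 985,
                                        nh3 = 10.5, co2 = 420,
                                        temperature = 22.5, humidity = 52.5,
                                        light = 8),
                           spreads = c(wind = 0.01, pressure = 7.5,
                                       nh3 = 0.25, co2 = 10,
                                       temperature = 1.25, humidity = 1.25,
                                       light = 1),
                           seed = 1, startTime = "0604-10:53:45", stepS = 9,
                           locations = "1-1") {
  stopifnot(n >= 0)
  if (n == 0L) return(.emptyEnv())
  set.seed(as.integer(seed))
  draw <- function(nm) rnorm(n, means[[nm]], spreads[[nm]])
  mmdd <- sub("-.*", "", startTime)
  hms <- as.integer(strsplit(sub(".*-", "", startTime), ":")[[1]])
  secs <- (hms[1] * 3600 + hms[2] * 60 + hms[3] + (seq_len(n) - 1) * stepS) %%
    86400
  times <- sprintf("%s-%02d:%02d:%02d", mmdd, secs %/% 3600,
                   (secs %% 3600) %/% 60, secs %% 60)
  data.frame(time = times,
             wind = pmax(draw("wind"), 0),
             pressure = draw("pressure"),
             nh3 = pmax(draw("nh3"), 0),
             co2 = pmax(draw("co2"), 0),
             temperature = draw("temperature"),
             humidity = pmin(pmax(draw("humidity"), 0), 100),
             light = pmax(draw("light"), 0),
             location = rep_len(locations, n))
}

#' Provider factories for synthetic sessions
#'
#' Convenience closures plugging the synthetic generators into
#' [runSession()]: the scene provider renders one random scene per waypoint
#' (seeded by `seed + i`), the environment provider draws one telemetry row
#' per waypoint.
#'
#' @param rig A [CameraRig-class] (scene provider).
#' @param seed Integer base seed.
#' @param ... Passed to [randomScene()].
#' @return A `function(waypoint, i)` suitable for [runSession()].
#' @export
makeSceneProvider <- function(rig, seed = 1, ...) {
  force(rig); force(seed)
  function(waypoint, i) {
    fs <- renderScene(randomScene(seed = seed + i, ...), rig)
    list(rgb = fs$rgb, nir = fs$nir, depth = fs$depth, tir = fs$tir,
         contentTag = fs$contentTag)
  }
}

#' @rdname makeSceneProvider
#' @export
makeEnvProvider <- function(seed = 1) {
  force(seed)
  function(waypoint, i) synthEnvSeries(1, seed = seed + i)
}
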