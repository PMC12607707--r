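## Whole-image registration: the point chain applied to every NIR pixel with
## a depth return, with collisions on a TIR pixel resolved by keeping the
## nearest source (z-buffer), then forward-scattering NIR intensities into a
## TIR-sized raster and fusing with the TIR channel.

#' Build the z-buffered NIR-to-TIR registration map
#'
#' Applies [mapNirPixelToTir()] to every NIR pixel with a nonzero depth
#' return. When several NIR pixels round to the same TIR pixel, the one with
#' the smallest transformed (TIR-frame) depth wins.
#'
#' @param depthMm `height x width` matrix of 16-bit depth values
#'   (millimeters; 0 = no return), aligned to the NIR grid.
#' @param rig [CameraRig-class] whose `nirSize` matches `depthMm`.
#' @return A [RegistrationMap-class].
#' @export
buildRegistrationMap <- function(depthMm, rig) {
  stopifnot(is(rig, "CameraRig"), is.matrix(depthMm))
  wN <- rig@nirSize[1]; hN <- rig@nirSize[2]
  wT <- rig@tirSize[1]; hT <- rig@tirSize[2]
  if (!identical(dim(depthMm), c(hN, wN)))
    stop(sprintf("depth raster is %dx%d but rig expects %dx%d (height x width)",
                 nrow(depthMm), ncol(depthMm), hN, wN))

  targetU <- matrix(NA_real_, hN, wN)
  targetV <- matrix(NA_real_, hN, wN)
  zbuffer <- matrix(NA_real_, hT, wT)
  sourceIndex <- matrix(NA_integer_, hT, wT)
  validMask <- matrix(FALSE, hT, wT)

  sel <- which(depthMm > 0)                 # linear indices, column-major
  if (length(sel)) {
    rowN <- (sel - 1L) %% hN + 1L
    colN <- (sel - 1L) %/% hN + 1L
    m <- mapNirPixelToTir(colN - 1, rowN - 1, depthMm[sel] / 1000, rig)
    iv <- which(m$inView)
    if (length(iv)) {
      selIV <- sel[iv]
      targetU[selIV] <- m$u[iv]
      targetV[selIV] <- m$v[iv]
      tirIdx <- m$row[iv] + 1 + m$col[iv] * hT   # linear index on TIR grid
      z <- m$zTir[iv]
      ord <- order(z)                            # nearest depth wins
      keep <- ord[!duplicated(tirIdx[ord])]
      win <- tirIdx[keep]
      zbuffer[win] <- z[keep]
      sourceIndex[win] <- selIV[keep]
      validMask[win] <- TRUE
    }
  }
  new("RegistrationMap", targetU = targetU, targetV = targetV,
      zbuffer = zbuffer, sourceIndex = sourceIndex, validMask = validMask,
      nirSize = rig@nirSize, tirSize = rig@tirSize)
}

#' Warp an NIR image into the TIR frame and fuse the modalities
#'
#' Scatters NIR intensities through a [RegistrationMap-class] into a
#' TIR-sized raster. TIR pixels that no NIR sample reached are hole-filled
#' (default: median of valid 3x3 neighbors, iterated to closure) and flagged
#' `FALSE` in the mask. The fused stack holds the registered NIR, the TIR
#' raster, and their pixelwise mean.
#'
#' @param nir `height x width` 8-bit NIR raster matching the map's NIR size.
#' @param tir `height x width` 8-bit TIR raster matching the map's TIR size.
#' @param map [RegistrationMap-class].
#' @param fill Hole-fill policy: `"median3"` (iterated 3x3 median of valid
#'   neighbors) or `"none"` (holes left at `fillValue`).
#' @param fillValue Value used when a frame has no valid pixels at all, or
#'   with `fill = "none"`.
#' @param provenance Optional list recorded into the frame metadata.
#' @return A [FusedFrame-class].
#' @export
warpAndFuse <- function(nir, tir, map, fill = c("median3", "none"),
                        fillValue = 0, provenance = list()) {
  fill <- match.arg(fill)
  stopifnot(is(map, "RegistrationMap"))
  if (!identical(dim(nir), c(map@nirSize[2], map@nirSize[1])))
    stop("NIR raster dimensions do not match the registration map")
  if (!identical(dim(tir), c(map@tirSize[2], map@tirSize[1])))
    stop("TIR raster dimensions do not match the registration map")

  out <- matrix(NA_real_, nrow(tir), ncol(tir))
  valid <- map@validMask
  out[valid] <- nir[map@sourceIndex[valid]]
  if (fill == "median3" && any(valid)) {
    out <- .fillHolesMedian3(out)
  }
  out[is.na(out)] <- fillValue
  meta <- c(provenance,
            list(fill = fill,
                 holeCount = sum(!valid),
                 tirIntensityMap = c(intercept = 0, slope = 1)))
  new("FusedFrame", nirReg = out, tir = tir, fused = (out + tir) / 2,
      mask = valid, metadata = meta)
}

## Iterated 3x3 median over valid neighbors until every hole with a valid
## neighbor chain is closed. Deterministic: each pass fills from the previous
## pass's state only.
.fillHolesMedian3 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  repeat {
    holes <- which(is.na(x))
    if (!length(holes)) break
    prev <- x
    rr <- (holes - 1L) %% h + 1L
    cc <- (holes - 1L) %/% h + 1L
    nb <- matrix(NA_real_, length(holes), 8L)
    k <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      k <- k + 1L
      r2 <- rr + dr; c2 <- cc + dc
      ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
      nb[ok, k] <- prev[cbind(r2[ok], c2[ok])]
    }
    med <- apply(nb, 1L, median, na.rm = TRUE)   # NaN when all neighbors NA
    fillable <- is.finite(med)
    if (!any(fillable)) break                     # isolated region: give up
    x[holes[fillable]] <- med[fillable]
  }
  x
}

#' Write a fused frame as multi-channel TIFF with a JSON sidecar
#'
#' @param frame [FusedFrame-class].
#' @param path Output TIFF path; the sidecar is written next to it as
#'   `<path>.json` (mask statistics and provenance).
#' @return `path`, invisibly.
#' @export
writeFusedFrame <- function(frame, path) {
  stopifnot(is(frame, "FusedFrame"))
  arr <- array(0, c(nrow(frame@tir), ncol(frame@tir), 3L))
  arr[, , 1] <- frame@nirReg; arr[, , 2] <- frame@tir; arr[, , 3] <- frame@fused
  tiff::writeTIFF(arr / 255, path, compression = "none")
  side <- list(validFraction = mean(frame@mask),
               holeCount = sum(!frame@mask),
               metadata = frame@metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Screen a fused frame for cold-body candidates
#'
#' A deliberately simple mortality screen standing in for a learned detector:
#' pixels that are cold in the TIR channel (at or below ambient + offset) and
#' have NIR support (registered NIR at or above a floor, i.e. an animal
#' contour is present) are labelled into connected components; components
#' passing the area and mean-NIR filters are returned as candidate boxes.
#'
#' @param frame [FusedFrame-class].
#' @param ambient Ambient TIR intensity level; defaults to the frame's TIR
#'   median (robust background estimate).
#' @param offset Intensity offset above ambient still considered cold.
#' @param minArea Minimum component area (pixels).
#' @param nirFloor Minimum NIR intensity for a pixel (and component mean) to
#'   count as animal contour support.
#' @return A data.frame of boxes (half-open, 0-based TIR pixel coordinates)
#'   with columns `x0`, `y0`, `x1`, `y1`, `area`, `meanTir`, `meanNir`,
#'   `label`, sorted by area descending, ties by box origin (row, column).
#'   Empty (zero-row) when nothing qualifies.
#' @export
screenColdCandidates <- function(frame, ambient = NULL, offset = 20,
                                 minArea = 20, nirFloor = 100) {
  stopifnot(is(frame, "FusedFrame"))
  if (is.null(ambient)) ambient <- median(frame@tir)
  cold <- frame@tir <= ambient + offset
  support <- frame@nirReg >= nirFloor
  cand <- cold & support
  empty <- data.frame(x0 = integer(), y0 = integer(), x1 = integer(),
                      y1 = integer(), area = integer(), meanTir = numeric(),
                      meanNir = numeric(), label = character())
  if (!any(cand)) return(empty)
  lab <- EBImage::bwlabel(cand * 1)   # numeric 0/1 matrix for labelling
  ids <- seq_len(max(lab))
  rows <- lapply(ids, function(i) {
    idx <- which(lab == i)
    area <- length(idx)
    mNir <- mean(frame@nirReg[idx])
    if (area < minArea || mNir < nirFloor) return(NULL)
    r <- (idx - 1L) %% nrow(lab)          # 0-based row (v)
    cc <- (idx - 1L) %/% nrow(lab)        # 0-based col (u)
    data.frame(x0 = min(cc), y0 = min(r), x1 = max(cc) + 1L, y1 = max(r) + 1L,
               area = area, meanTir = mean(frame@tir[idx]), meanNir = mNir,
               label = "cold-candidate")
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(-out$area, out$y0, out$x0), , drop = FALSE]
}
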