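#' Accessors for rig, map and frame objects
#'
#' Slot access for the S4 containers: camera intrinsics, poses and raster
#' sizes of a [CameraRig-class]; validity mask of a [RegistrationMap-class] or
#' [FusedFrame-class]; channels of a [FusedFrame-class].
#'
#' @param x The object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nirIntrinsics", function(x) standardGeneric("nirIntrinsics"))
#' @rdname accessors
#' @export
setGeneric("tirIntrinsics", function(x) standardGeneric("tirIntrinsics"))
#' @rdname accessors
#' @export
setGeneric("nirPose", function(x) standardGeneric("nirPose"))
#' @rdname accessors
#' @export
setGeneric("tirPose", function(x) standardGeneric("tirPose"))
#' @rdname accessors
#' @export
setGeneric("nirSize", function(x) standardGeneric("nirSize"))
#' @rdname accessors
#' @export
setGeneric("tirSize", function(x) standardGeneric("tirSize"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("registeredNir", function(x) standardGeneric("registeredNir"))
#' @rdname accessors
#' @export
setGeneric("tirChannel", function(x) standardGeneric("tirChannel"))
#' @rdname accessors
#' @export
setGeneric("fusedChannel", function(x) standardGeneric("fusedChannel"))

#' @rdname accessors
setMethod("nirIntrinsics", "CameraRig", function(x) x@nirIntrinsics)
#' @rdname accessors
setMethod("tirIntrinsics", "CameraRig", function(x) x@tirIntrinsics)
#' @rdname accessors
setMethod("nirPose", "CameraRig", function(x) x@nirPose)
#' @rdname accessors
setMethod("tirPose", "CameraRig", function(x) x@tirPose)
#' @rdname accessors
setMethod("nirSize", "CameraRig", function(x) x@nirSize)
#' @rdname accessors
setMethod("tirSize", "CameraRig", function(x) x@tirSize)
#' @rdname accessors
setMethod("nirSize", "RegistrationMap", function(x) x@nirSize)
#' @rdname accessors
setMethod("tirSize", "RegistrationMap", function(x) x@tirSize)
#' @rdname accessors
setMethod("validMask", "RegistrationMap", function(x) x@validMask)
#' @rdname accessors
setMethod("validMask", "FusedFrame", function(x) x@mask)
#' @rdname accessors
setMethod("registeredNir", "FusedFrame", function(x) x@nirReg)
#' @rdname accessors
setMethod("tirChannel", "FusedFrame", function(x) x@tir)
#' @rdname accessors
setMethod("fusedChannel", "FusedFrame", function(x) x@fused)

setMethod("show", "Intrinsics", function(object) {
  cat(sprintf("Intrinsics: kx=%g ky=%g u0=%g v0=%g\n",
              object@kx, object@ky, object@u0, object@v0))
})

setMethod("show", "Pose", function(object) {
  cat("Pose (camera = R * world + p)\n")
  cat("  R:\n")
  print(round(object@R, 6))
  cat(sprintf("  p: [%s] m\n", paste(signif(object@p, 6), collapse = ", ")))
})

setMethod("show", "CameraRig", function(object) {
  cat("CameraRig\n")
  cat(sprintf("  NIR: %dx%d px, kx=%g ky=%g u0=%g v0=%g\n",
              object@nirSize[1], object@nirSize[2],
              object@nirIntrinsics@kx, object@nirIntrinsics@ky,
              object@nirIntrinsics@u0, object@nirIntrinsics@v0))
  cat(sprintf("  TIR: %dx%d px, kx=%g ky=%g u0=%g v0=%g\n",
              object@tirSize[1], object@tirSize[2],
              object@tirIntrinsics@kx, object@tirIntrinsics@ky,
              object@tirIntrinsics@u0, object@tirIntrinsics@v0))
  cat(sprintf("  baseline: %.1f mm\n",
              1000 * sqrt(sum((object@nirPose@p - object@tirPose@p)^2))))
})

setMethod("show", "RegistrationMap", function(object) {
  nValid <- sum(object@validMask)
  nMapped <- sum(!is.na(object@targetU))
  cat(sprintf("RegistrationMap: %dx%d NIR -> %dx%d TIR\n",
              object@nirSize[1], object@nirSize[2],
              object@tirSize[1], object@tirSize[2]))
  cat(sprintf("  %d NIR pixels mapped in view; %d/%d TIR pixels covered (%.1f%%)\n",
              nMapped, nValid, prod(object@tirSize),
              100 * nValid / prod(object@tirSize)))
})

setMethod("show", "FusedFrame", function(object) {
  d <- dim(object@tir)
  cat(sprintf("FusedFrame: %dx%d px, %.1f%% valid (%d hole-filled)\n",
              d[2], d[1], 100 * mean(object@mask), sum(!object@mask)))
})
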