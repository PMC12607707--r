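## Independent oracles for the registration chain: a single precomposed 4x4
## homogeneous matrix replacing the three-step chain, and brute-force rig
## generators built from QR-based random rotations.

randomRotationQR <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

randomTestRig <- function() {
  CameraRig(
    Intrinsics(runif(1, 300, 900), runif(1, 300, 900),
               runif(1, 400, 600), runif(1, 300, 450)),
    Intrinsics(runif(1, 150, 350), runif(1, 150, 350),
               runif(1, 100, 150), runif(1, 80, 110)),
    Pose(randomRotationQR(), rnorm(3, 0, 0.02)),
    Pose(randomRotationQR(), rnorm(3, 0, 0.02)))
}

## One 4x4 homogeneous transform NIR-frame -> TIR-frame, then pinhole at
## both ends. Continuous TIR pixel; NA if behind the TIR camera.
oracleNirToTirPixel <- function(rig, u, v, zM) {
  Kn <- nirIntrinsics(rig); Kt <- tirIntrinsics(rig)
  Rn <- nirPose(rig)@R; pn <- nirPose(rig)@p
  Rt <- tirPose(rig)@R; pt <- tirPose(rig)@p
  M <- Rt %*% solve(Rn)
  A <- rbind(cbind(M, pt - M %*% pn), c(0, 0, 0, 1))
  q <- A %*% c((u - Kn@u0) * zM / Kn@kx, (v - Kn@v0) * zM / Kn@ky, zM, 1)
  if (q[3] <= 0) return(c(NA_real_, NA_real_))
  c(Kt@u0 + Kt@kx * q[1] / q[3], Kt@v0 + Kt@ky * q[2] / q[3])
}

## An exact-identity rig: co-located cameras, equal intrinsics and sizes.
identityRig <- function(size = c(64L, 48L), focal = 120) {
  K <- Intrinsics(focal, focal, (size[1] - 1) / 2, (size[2] - 1) / 2)
  CameraRig(K, K, Pose(), Pose(), size, size)
}

## Centroids of bright connected components in a registered-NIR channel,
## matched to ground-truth TIR centroids; returns per-phantom errors (px).
registrationErrors <- function(frameSet, fused, bright = 150) {
  ch1 <- registeredNir(fused)
  lab <- EBImage::bwlabel((ch1 >= bright) * 1)
  h <- nrow(lab)
  cent <- t(vapply(seq_len(max(lab)), function(i) {
    idx <- which(lab == i)
    c(u = mean((idx - 1) %/% h), v = mean((idx - 1) %% h), n = length(idx))
  }, numeric(3)))
  cent <- cent[cent[, "n"] >= 20, , drop = FALSE]   # ignore speckle
  vapply(seq_len(nrow(frameSet$gt)), function(k) {
    d <- sqrt((cent[, "u"] - frameSet$gt$tirU[k])^2 +
              (cent[, "v"] - frameSet$gt$tirV[k])^2)
    min(d)
  }, numeric(1))
}
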