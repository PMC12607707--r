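test_that("identity-rig registration map is the identity on nonzero depth", {
  rig <- identityRig()
  depth <- matrix(400L, 48, 64)
  depth[1, 1] <- 0L                       # one invalid pixel
  map <- buildRegistrationMap(depth, rig)
  expect_equal(sum(validMask(map)), sum(depth > 0))
  idx <- which(validMask(map))
  expect_identical(map@sourceIndex[idx], idx)   # each pixel maps to itself
  expect_false(validMask(map)[1, 1])
  # conservation: valid entries bounded by sources and by the TIR grid
  expect_lte(sum(validMask(map)), sum(depth > 0))
  expect_lte(sum(validMask(map)), prod(tirSize(map)))
})

test_that("z-buffer keeps the nearest of two colliding sources", {
  # co-located cameras, TIR grid much coarser than NIR: many NIR pixels per
  # TIR pixel; give two of them different depths and check the near one wins
  Kn <- Intrinsics(120, 120, 31.5, 23.5)
  Kt <- Intrinsics(15, 15, 3.5, 2.5)
  rig <- CameraRig(Kn, Kt, Pose(), Pose(), c(64L, 48L), c(8L, 6L))
  depth <- matrix(0L, 48, 64)
  depth[24, 33] <- 500L                   # u = 32 -> TIR u 3.5625 -> 4
  depth[24, 34] <- 300L                   # u = 33 -> TIR u 3.6875 -> 4, nearer
  map <- buildRegistrationMap(depth, rig)
  expect_equal(sum(validMask(map)), 1L)
  win <- map@sourceIndex[which(validMask(map))]
  expect_equal(depth[win], 300L)
  expect_equal(map@zbuffer[which(validMask(map))], 0.3)
})

test_that("an all-zero depth raster yields an empty map and a flagged frame", {
  rig <- identityRig()
  map <- buildRegistrationMap(matrix(0L, 48, 64), rig)
  expect_equal(sum(validMask(map)), 0L)
  frame <- warpAndFuse(matrix(200, 48, 64), matrix(80, 48, 64), map,
                       fillValue = 0)
  expect_true(all(!validMask(frame)))
  expect_true(all(registeredNir(frame) == 0))
})

test_that("warping through an identity map reproduces the NIR raster and is idempotent", {
  rig <- identityRig()
  depth <- matrix(400L, 48, 64)
  map <- buildRegistrationMap(depth, rig)
  set.seed(31)
  nir <- matrix(sample(0:255, 48 * 64, replace = TRUE), 48, 64)
  tir <- matrix(sample(0:255, 48 * 64, replace = TRUE), 48, 64)
  f1 <- warpAndFuse(nir, tir, map)
  expect_identical(registeredNir(f1), nir + 0)
  expect_true(all(validMask(f1)))
  expect_equal(fusedChannel(f1), (nir + tir) / 2)
  # idempotence: warp the warped channel again
  f2 <- warpAndFuse(registeredNir(f1), tir, map)
  expect_identical(registeredNir(f2), registeredNir(f1))
  expect_error(warpAndFuse(nir[1:10, ], tir, map), "dimensions")
})

test_that("holes are closed by the iterated 3x3 median and stay flagged", {
  rig <- identityRig()
  depth <- matrix(400L, 48, 64)
  hole <- cbind(rep(20:26, each = 7), rep(30:36, times = 7))
  depth[hole] <- 0L
  map <- buildRegistrationMap(depth, rig)
  nir <- matrix(100, 48, 64)
  frame <- warpAndFuse(nir, matrix(80, 48, 64), map)
  # flat surround: every filled value equals the surround, mask records holes
  expect_true(all(registeredNir(frame) == 100))
  expect_identical(sum(!validMask(frame)), nrow(hole))
  expect_true(all(!validMask(frame)[hole]))
})

test_that("phantom centroids survive warping to within a TIR pixel", {
  # 20 seeded scenes: mean registration error < 1 TIR px, max < 2 px
  errs <- unlist(lapply(1:20, function(s) {
    rig <- synthRig(seed = s)
    fs <- renderScene(randomScene(seed = 100 + s, nLive = 1, nDead = 1),
                      rig, renderRgb = FALSE)
    fused <- warpAndFuse(fs$nir, fs$tir, buildRegistrationMap(fs$depth, rig))
    registrationErrors(fs, fused)
  }))
  expect_gt(length(errs), 30)
  expect_lt(mean(errs), 1)
  expect_lt(max(errs), 2)
})

test_that("cold-body screening finds dead phantoms and only dead phantoms", {
  # noiseless scenes: precision = recall = 1 over 20 seeded scenes
  tp <- fp <- fn <- 0
  for (s in 1:20) {
    rig <- synthRig(seed = 300 + s)
    fs <- renderScene(randomScene(seed = 400 + s, nLive = 2, nDead = 1),
                      rig, renderRgb = FALSE)
    fused <- warpAndFuse(fs$nir, fs$tir, buildRegistrationMap(fs$depth, rig))
    boxes <- screenColdCandidates(fused, ambient = fs$spec$ambient)
    dead <- fs$gt[fs$gt$status == "dead", ]
    hit <- logical(nrow(dead))
    for (b in seq_len(nrow(boxes))) {
      inDead <- dead$tirU >= boxes$x0[b] & dead$tirU < boxes$x1[b] &
                dead$tirV >= boxes$y0[b] & dead$tirV < boxes$y1[b]
      if (any(inDead)) { tp <- tp + 1; hit <- hit | inDead } else fp <- fp + 1
    }
    fn <- fn + sum(!hit)
  }
  expect_equal(fp, 0)
  expect_equal(fn, 0)
  expect_equal(tp, 20)
})

test_that("screening respects the area floor and returns sorted boxes", {
  # hand-built frame: two cold NIR-supported blobs and a warm blob
  tir <- matrix(200, 40, 60)
  nir <- matrix(0, 40, 60)
  tir[5:14, 5:14] <- 60;  nir[5:14, 5:14] <- 220     # 100 px cold candidate
  tir[30:32, 40:42] <- 60; nir[30:32, 40:42] <- 220  # 9 px cold candidate
  nir[20:28, 20:28] <- 220                           # warm: not a candidate
  frame <- new("FusedFrame", nirReg = nir, tir = tir, fused = (nir + tir) / 2,
               mask = matrix(TRUE, 40, 60), metadata = list())
  boxes <- screenColdCandidates(frame, ambient = 60, offset = 20,
                                minArea = 5, nirFloor = 100)
  expect_equal(nrow(boxes), 2L)
  expect_true(all(diff(boxes$area) <= 0))           # sorted by area desc
  # boundary of the area filter: 9-px component dropped at minArea = 10
  boxes10 <- screenColdCandidates(frame, ambient = 60, offset = 20,
                                  minArea = 10, nirFloor = 100)
  expect_equal(nrow(boxes10), 1L)
  expect_equal(boxes10$area, 100L)
  # nothing cold enough: empty result
  none <- screenColdCandidates(frame, ambient = 0, offset = 10)
  expect_equal(nrow(none), 0L)
})

test_that("fused frames persist as multi-channel TIFF with a JSON sidecar", {
  rig <- identityRig()
  map <- buildRegistrationMap(matrix(400L, 48, 64), rig)
  frame <- warpAndFuse(matrix(120, 48, 64), matrix(90, 48, 64), map,
                       provenance = list(rigId = "test-rig"))
  path <- withr::local_tempfile(fileext = ".tif")
  writeFusedFrame(frame, path)
  arr <- round(tiff::readTIFF(path) * 255)
  expect_equal(dim(arr), c(48, 64, 3))
  expect_true(all(arr[, , 1] == 120) && all(arr[, , 2] == 90))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$validFraction, 1)
  expect_equal(side$metadata$rigId, "test-rig")
})
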