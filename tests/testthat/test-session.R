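tablePath <- function(f) system.file("extdata", f, package = "GantryInspect")

test_that("image names follow the modality_date_time_x_y convention", {
  expect_identical(imageName("depth", "20240729", "1228", 5, 6),
                   "depth_20240729_1228_5_6")
  got <- parseImageName("depth_20240729_1228_5_6")
  expect_identical(got, list(modality = "depth", date = "20240729",
                             time = "1228", x = 5L, y = 6L))
  # extensions are tolerated on parse
  expect_equal(parseImageName("tir_20240729_1228_78_12.png")$x, 78L)
  # grid bounds: 78 x 12, 1-based
  expect_error(imageName("depth", "20240729", "1228", 79, 1), "grid")
  expect_error(imageName("depth", "20240729", "1228", 0, 1), "grid")
  expect_error(imageName("depth", "20240729", "1228", 5, 13), "grid")
  expect_error(parseImageName("depth_20240729_1228_79_1"), "grid")
  expect_error(parseImageName("not_an_image_name"), "parse")
  expect_error(imageName("xray", "20240729", "1228", 5, 6))
})

test_that("naming and parsing are mutual inverses over random valid records", {
  set.seed(14)
  for (i in 1:200) {
    rec <- list(modality = sample(c("rgb", "nir", "depth", "tir"), 1),
                date = sprintf("2024%02d%02d", sample(12, 1), sample(28, 1)),
                time = sprintf("%02d%02d", sample(0:23, 1), sample(0:59, 1)),
                x = sample(78, 1), y = sample(12, 1))
    back <- parseImageName(do.call(imageName, rec))
    expect_identical(back, c(rec[1:3], list(x = as.integer(rec$x),
                                            y = as.integer(rec$y))))
  }
})

test_that("routes resolve grid coordinates through the position tables", {
  # single waypoint
  r1 <- planRouteFromTables(tablePath("x_pst_table.csv"),
                            tablePath("y_pst_table.csv"),
                            data.frame(x = 5, y = 6))
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$x_mm, 500 + 4 * 730)
  expect_equal(r1$y_mm, 500 + 5 * 1150)
  expect_equal(r1$tier, "lower")
  # the ten-key-position fixture route
  ra <- planRouteFromTables(tablePath("x_pst_table.csv"),
                            tablePath("y_pst_table.csv"),
                            read.csv(tablePath("route_a.csv")))
  expect_equal(nrow(ra), 10L)
  # full-grid selection: 78 x 12 = 936 waypoints
  full <- expand.grid(x = 1:78, y = 1:12)
  rf <- planRouteFromTables(tablePath("x_pst_table.csv"),
                            tablePath("y_pst_table.csv"), full)
  expect_equal(nrow(rf), 936L)
  # missing index and non-monotone table
  xt <- read.csv(tablePath("x_pst_table.csv"))
  expect_error(planRouteFromTables(xt[xt$index != 5, ],
                                   tablePath("y_pst_table.csv"),
                                   data.frame(x = 5, y = 1)), "missing")
  xbad <- xt; xbad$position_mm[2] <- 1e6; xbad$position_mm[3] <- 100
  expect_warning(expect_error(
    planRouteFromTables(xbad, tablePath("y_pst_table.csv"),
                        data.frame(x = 2, y = 1)), "workspace"),
    "monotone")
})

test_that("a session emits 4 images and one env row per waypoint", {
  route <- planRouteFromTables(tablePath("x_pst_table.csv"),
                               tablePath("y_pst_table.csv"),
                               data.frame(x = c(3, 7, 11), y = c(1, 2, 3)))
  out <- withr::local_tempdir()
  # cheap flat-raster provider at the deployed resolutions
  scenes <- function(wp, i)
    list(rgb = array(120, c(1080, 1920, 3)), nir = matrix(100, 768, 1024),
         depth = matrix(384L, 768, 1024), tir = matrix(80, 192, 256),
         contentTag = "live-only")
  res <- runSession(route, scenes, makeEnvProvider(5), out)
  expect_equal(nrow(res$images), 12L)
  expect_equal(unname(unlist(res$completeness$perModality)), rep(3L, 4))
  expect_equal(res$completeness$namingAccuracy, 1)
  expect_equal(nrow(res$env), 3L)
  expect_equal(res$env$location, c("3-1", "7-2", "11-3"))
  expect_true(all(file.exists(file.path(out, res$images$filename))))
  expect_true(file.exists(file.path(out, "environment.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "completeness.json")))
  # every emitted filename parses back to its waypoint
  parsed <- lapply(res$images$filename, parseImageName)
  expect_equal(vapply(parsed, `[[`, integer(1), "x"), res$images$x)
})

test_that("an empty route emits nothing and still reports completeness", {
  route <- planRouteFromTables(tablePath("x_pst_table.csv"),
                               tablePath("y_pst_table.csv"),
                               data.frame(x = integer(), y = integer()))
  out <- withr::local_tempdir()
  res <- runSession(route, function(wp, i) stop("never called"),
                    makeEnvProvider(1), out)
  expect_equal(nrow(res$images), 0L)
  expect_equal(nrow(res$env), 0L)
  expect_equal(res$completeness$imagesExpected, 0L)
})

test_that("provider failures degrade completeness instead of aborting", {
  route <- planRouteFromTables(tablePath("x_pst_table.csv"),
                               tablePath("y_pst_table.csv"),
                               data.frame(x = c(1, 2, 3), y = 1))
  out <- withr::local_tempdir()
  flaky <- function(wp, i) {
    if (i == 2) stop("camera timeout")
    list(rgb = array(0, c(4, 4, 3)), nir = matrix(0, 4, 4),
         depth = matrix(1L, 4, 4), tir = matrix(0, 4, 4))
  }
  res <- runSession(route, flaky, makeEnvProvider(1), out)
  expect_equal(nrow(res$images), 8L)
  expect_equal(res$completeness$failures, 1L)
  expect_lt(res$completeness$completionRate, 1)
  expect_equal(res$failures$kind, "scene")
  expect_equal(nrow(res$env), 3L)   # env capture unaffected
})

test_that("manifest splits follow the seeded 70/15/15 floor rule", {
  manifest <- data.frame(setId = sprintf("s%03d", 1:100),
                         contentTag = "mixed")
  sp <- splitManifest(manifest, seed = 21)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 70L, val = 15L, test = 15L))
  # disjoint and exhaustive
  ids <- unlist(lapply(sp, `[[`, "setId"))
  expect_setequal(ids, manifest$setId)
  expect_equal(anyDuplicated(ids), 0L)
  # same seed, same membership; different seed differs
  sp2 <- splitManifest(manifest, seed = 21)
  expect_identical(lapply(sp, `[[`, "setId"), lapply(sp2, `[[`, "setId"))
  sp3 <- splitManifest(manifest, seed = 22)
  expect_false(identical(sp$train$setId, sp3$train$setId))
  # floor boundary: N = 1 goes entirely to test
  one <- splitManifest(manifest[1, , drop = FALSE], seed = 1)
  expect_equal(vapply(one, nrow, integer(1)),
               c(train = 0L, val = 0L, test = 1L))
  # empty manifest: three empty parts, no error
  empty <- splitManifest(manifest[0, , drop = FALSE], seed = 1)
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))
  # sizes follow the floor rule for arbitrary N
  for (n in c(2, 7, 19, 53)) {
    spN <- splitManifest(manifest[1:n, , drop = FALSE], seed = 3)
    expect_equal(unname(vapply(spN, nrow, integer(1))),
                 c(floor(0.7 * n), floor(0.15 * n),
                   n - floor(0.7 * n) - floor(0.15 * n)))
  }
  expect_error(splitManifest(manifest, fractions = c(0.5, 0.3, 0.1)), "sum")
})
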