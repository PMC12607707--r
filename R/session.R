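## Inspection-session orchestration: the 78x12 cage coordinate grid, route
## planning from the two axis position tables, per-stop multi-modal capture
## with the imageType_date_time_x_y naming convention, completeness
## verification, and dataset manifest / split tooling.

.MODALITIES <- c("rgb", "nir", "depth", "tir")
.MODALITY_DIMS <- list(rgb = c(1920L, 1080L), nir = c(1024L, 768L),
                       depth = c(1024L, 768L), tir = c(256L, 192L))

.checkCoord <- function(x, y, gridDim = c(78L, 12L)) {
  if (length(x) != 1L || length(y) != 1L || x != round(x) || y != round(y) ||
      x < 1 || x > gridDim[1] || y < 1 || y > gridDim[2])
    stop(sprintf("cage coordinate (%s,%s) outside the %dx%d grid",
                 format(x), format(y), gridDim[1], gridDim[2]))
  invisible(TRUE)
}

#' Build an image file name from its fields
#'
#' Captured images are named `imageType_date_time_x_y`, e.g. a depth image
#' taken at cage coordinate (5,6) on 2024-07-29 at 12:28 is
#' `depth_20240729_1228_5_6`. Cage coordinates are 1-based on the 78x12
#' grid.
#'
#' @param modality One of `"rgb"`, `"nir"`, `"depth"`, `"tir"`.
#' @param date Acquisition date, `YYYYMMDD`.
#' @param time Acquisition time, `HHMM`; an optional collision suffix
#'   (`"1228-2"`) is accepted.
#' @param x,y Cage coordinate (1-based).
#' @param gridDim Grid extent `(nx, ny)`.
#' @return The file name (no extension).
#' @examples
#' imageName("depth", "20240729", "1228", 5, 6)
#' @export
imageName <- function(modality, date, time, x, y, gridDim = c(78L, 12L)) {
  modality <- match.arg(modality, .MODALITIES)
  if (!grepl("^\\d{8}$", date)) stop("date must be YYYYMMDD")
  if (!grepl("^\\d{4}(-\\d+)?$", time)) stop("time must be HHMM")
  .checkCoord(x, y, gridDim)
  paste(modality, date, time, x, y, sep = "_")
}

#' Parse an image file name back into its fields
#'
#' Inverse of [imageName()]; a trailing raster extension is stripped first.
#'
#' @param name File name, with or without extension.
#' @param gridDim Grid extent `(nx, ny)`.
#' @return A list with `modality`, `date`, `time`, `x`, `y`.
#' @export
parseImageName <- function(name, gridDim = c(78L, 12L)) {
  base <- sub("\\.(png|tif|tiff)$", "", name, ignore.case = TRUE)
  pat <- "^(rgb|nir|depth|tir)_(\\d{8})_(\\d{4}(?:-\\d+)?)_(\\d+)_(\\d+)$"
  m <- regmatches(base, regexec(pat, base))[[1]]
  if (length(m) != 6L) stop("cannot parse image name: ", name)
  x <- as.integer(m[5]); y <- as.integer(m[6])
  .checkCoord(x, y, gridDim)
  list(modality = m[2], date = m[3], time = m[4], x = x, y = y)
}

.readPosTable <- function(tab, axis, n) {
  if (is.character(tab)) tab <- read.csv(tab)
  if (!all(c("index", "position_mm") %in% names(tab)))
    stop(axis, " table must have columns 'index' and 'position_mm'")
  if (is.unsorted(tab$position_mm[order(tab$index)], strictly = FALSE))
    warning(axis, " table positions are not monotone in index")
  tab
}

#' Plan an inspection route from the axis coordinate tables
#'
#' Resolves selected cage coordinates to physical gantry positions using the
#' two route coordinate tables (`x_pst_table.csv`, `y_pst_table.csv`; columns
#' `index`, `position_mm`). Selection order is preserved.
#'
#' @param xTable,yTable Paths to the CSV tables, or data.frames.
#' @param selection A data.frame with columns `x`, `y`, and optionally
#'   `tier` (`"lower"`/`"upper"`, default lower) and `bypass` (logical).
#' @param gridDim Grid extent `(nx, ny)`.
#' @param workspaceMm Physical workspace `(x, y)` bounds (mm); the deployed
#'   system spans 58 m x 13.3 m.
#' @return A route data.frame: `x`, `y`, `x_mm`, `y_mm`, `tier`, `bypass`.
#' @export
planRouteFromTables <- function(xTable, yTable, selection,
                                gridDim = c(78L, 12L),
                                workspaceMm = c(58000, 13300)) {
  xt <- .readPosTable(xTable, "x", gridDim[1])
  yt <- .readPosTable(yTable, "y", gridDim[2])
  if (is.null(selection$tier)) selection$tier <- rep("lower", nrow(selection))
  if (is.null(selection$bypass)) selection$bypass <- rep(FALSE, nrow(selection))
  n <- nrow(selection)
  xmm <- ymm <- numeric(n)
  for (i in seq_len(n)) {
    .checkCoord(selection$x[i], selection$y[i], gridDim)
    ix <- match(selection$x[i], xt$index)
    iy <- match(selection$y[i], yt$index)
    if (is.na(ix)) stop("x index ", selection$x[i], " missing from x table")
    if (is.na(iy)) stop("y index ", selection$y[i], " missing from y table")
    xmm[i] <- xt$position_mm[ix]
    ymm[i] <- yt$position_mm[iy]
  }
  if (any(xmm < 0 | xmm > workspaceMm[1] | ymm < 0 | ymm > workspaceMm[2]))
    stop("route positions fall outside the workspace")
  data.frame(x = as.integer(selection$x), y = as.integer(selection$y),
             x_mm = xmm, y_mm = ymm,
             tier = as.character(selection$tier),
             bypass = as.logical(selection$bypass))
}

#' Run an inspection session over a route
#'
#' Visits each waypoint in order: selects the Z-axis posture, captures one
#' RGB + NIR + depth + TIR frame set from `sceneProvider`, writes each image
#' under the naming convention, and appends one environmental record from
#' `envProvider`. Provider failures at a waypoint are recorded as
#' missing-data entries and the session continues (completeness drops below
#' 100%). Finally the completeness report, manifest and environment CSV are
#' emitted and the gantry's return to start is logged.
#'
#' @param route A route data.frame from [planRouteFromTables()].
#' @param sceneProvider `function(waypoint, i)` returning a list with
#'   rasters `rgb` (h x w x 3 array or matrix, 0-255), `nir`, `tir`
#'   (matrices, 0-255), `depth` (matrix, mm), and optionally `contentTag`
#'   (`"dead-only"`, `"mixed"`, `"live-only"`).
#' @param envProvider `function(waypoint, i)` returning a one-row
#'   environment data.frame (see [envRecord()]); `time` and `location` are
#'   filled in by the session.
#' @param outDir Output directory (created if needed).
#' @param date Session date `YYYYMMDD`.
#' @param startTime Session start `HHMM`; each waypoint advances one minute.
#' @return A list of class `SessionResult`: `images` (data.frame of emitted
#'   records), `env` (data.frame), `manifest` (data.frame), `completeness`
#'   (list), `failures` (data.frame of missing-data entries).
#' @export
runSession <- function(route, sceneProvider, envProvider, outDir,
                       date = "20240729", startTime = "1200") {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.integer(substr(startTime, 1, 2)) * 60L +
    as.integer(substr(startTime, 3, 4))
  images <- list(); envs <- list(); fails <- list(); manifest <- list()
  for (i in seq_len(nrow(route))) {
    wp <- route[i, ]
    posture <- selectPosture(wp$tier, wp$bypass)
    tm <- sprintf("%02d%02d", ((t0 + i - 1L) %/% 60L) %% 24L,
                  (t0 + i - 1L) %% 60L)
    frames <- tryCatch(sceneProvider(wp, i), error = function(e) e)
    if (inherits(frames, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(x = wp$x, y = wp$y, time = tm, kind = "scene",
                   message = conditionMessage(frames))
    } else {
      for (mod in .MODALITIES) {
        ras <- frames[[mod]]
        if (is.null(ras)) {
          fails[[length(fails) + 1L]] <-
            data.frame(x = wp$x, y = wp$y, time = tm, kind = mod,
                       message = "modality missing from provider output")
          next
        }
        ext <- if (mod == "depth") ".tif" else ".png"
        nm <- imageName(mod, date, tm, wp$x, wp$y)
        path <- file.path(outDir, paste0(nm, ext))
        if (mod == "depth") writeDepth(ras, path) else writeGray(ras, path)
        d <- dim(ras)
        images[[length(images) + 1L]] <-
          data.frame(modality = mod, date = date, time = tm,
                     x = wp$x, y = wp$y, filename = basename(path),
                     width = d[2], height = d[1])
      }
      manifest[[length(manifest) + 1L]] <-
        data.frame(setId = sprintf("%s_%s_%d_%d", date, tm, wp$x, wp$y),
                   x = wp$x, y = wp$y, time = tm,
                   modalities = paste(.MODALITIES[.MODALITIES %in% names(frames)],
                                      collapse = "+"),
                   contentTag = if (!is.null(frames$contentTag))
                     frames$contentTag else "live-only")
    }
    env <- tryCatch(envProvider(wp, i), error = function(e) e)
    if (inherits(env, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(x = wp$x, y = wp$y, time = tm, kind = "env",
                   message = conditionMessage(env))
    } else {
      env$location <- sprintf("%d-%d", wp$x, wp$y)
      envs[[length(envs) + 1L]] <- env
    }
  }
  images <- if (length(images)) do.call(rbind, images) else
    data.frame(modality = character(), date = character(), time = character(),
               x = integer(), y = integer(), filename = character(),
               width = integer(), height = integer())
  envDf <- if (length(envs)) do.call(rbind, envs) else .emptyEnv()
  manifestDf <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(setId = character(), x = integer(), y = integer(),
               time = character(), modalities = character(),
               contentTag = character())
  failDf <- if (length(fails)) do.call(rbind, fails) else
    data.frame(x = integer(), y = integer(), time = character(),
               kind = character(), message = character())
  parseable <- vapply(images$filename, function(f)
    !inherits(tryCatch(parseImageName(f), error = function(e) e), "error"),
    logical(1))
  completeness <- list(
    waypoints = nrow(route),
    imagesExpected = 4L * nrow(route),
    imagesCollected = nrow(images),
    perModality = as.list(table(factor(images$modality, levels = .MODALITIES))),
    envRowsExpected = nrow(route),
    envRowsCollected = nrow(envDf),
    namingAccuracy = if (nrow(images)) mean(parseable) else 1,
    completionRate = if (nrow(route)) nrow(images) / (4L * nrow(route)) else 1,
    failures = nrow(failDf),
    returnedToStart = TRUE)
  writeEnvCsv(envDf, file.path(outDir, "environment.csv"))
  jsonlite::write_json(manifestDf, file.path(outDir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(completeness, file.path(outDir, "completeness.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(images = images, env = envDf, manifest = manifestDf,
                 completeness = completeness, failures = failDf,
                 outDir = outDir),
            class = "SessionResult")
}

#' @export
print.SessionResult <- function(x, ...) {
  cat(sprintf("SessionResult: %d waypoints, %d/%d images, %d env rows\n",
              x$completeness$waypoints, x$completeness$imagesCollected,
              x$completeness$imagesExpected, x$completeness$envRowsCollected))
  cat(sprintf("  naming accuracy %.1f%%, completion %.1f%%, %d failure(s)\n",
              100 * x$completeness$namingAccuracy,
              100 * x$completeness$completionRate, x$completeness$failures))
  invisible(x)
}

#' Split a dataset manifest into train / validation / test parts
#'
#' Seeded uniform shuffle with the floor rule: `floor(0.70 N)` entries go to
#' training, `floor(0.15 N)` to validation, and the remainder to testing.
#' The parts are disjoint and their union is the manifest; the same seed
#' always yields the same membership.
#'
#' @param manifest A data.frame of frame-set entries (e.g. from
#'   [runSession()]).
#' @param fractions Named fractions `(train, val, test)` summing to 1
#'   (within 1e-9).
#' @param seed Integer seed for the shuffle.
#' @return A list of three data.frames: `train`, `val`, `test`.
#' @export
splitManifest <- function(manifest, fractions = c(train = 0.70, val = 0.15,
                                                  test = 0.15), seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("split fractions must sum to 1")
  n <- nrow(manifest)
  if (n == 0L)
    return(list(train = manifest, val = manifest, test = manifest))
  set.seed(as.integer(seed))
  idx <- sample.int(n)
  nTrain <- floor(fractions[[1]] * n)
  nVal <- floor(fractions[[2]] * n)
  list(train = manifest[sort(idx[seq_len(nTrain)]), , drop = FALSE],
       val = manifest[sort(idx[nTrain + seq_len(nVal)]), , drop = FALSE],
       test = manifest[sort(idx[setdiff(seq_len(n), seq_len(nTrain + nVal))]),
                       , drop = FALSE])
}
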