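#' @include AllClasses.R
NULL

.sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read and write height maps
#'
#' Two on-disk forms are supported, both with a JSON sidecar
#' (\code{<stem>.json}) holding \code{spacing_x_um}, \code{spacing_y_um},
#' \code{origin_x_um}, \code{origin_y_um}:
#' \itemize{
#'   \item \code{.csv}: a plain numeric grid (rows = y), heights in µm;
#'   \item \code{.tif}/\code{.tiff}: single-channel 32-bit float TIFF. The
#'     float samples are stored normalized to [0, 1]; the sidecar records
#'     \code{z_min_um}/\code{z_max_um} and reading restores micrometres.
#' }
#'
#' @param hm a [HeightMap-class] (write) .
#' @param path file path ending in .csv, .tif or .tiff.
#' @return \code{readHeightMap} returns a [HeightMap-class];
#'   \code{writeHeightMap} invisibly returns \code{path}.
#' @name heightmap-io
NULL

#' @rdname heightmap-io
#' @export
writeHeightMap <- function(hm, path) {
  validObject(hm)
  ext <- tolower(tools::file_ext(path))
  side <- list(spacing_x_um = hm@spacing[1], spacing_y_um = hm@spacing[2],
               origin_x_um = hm@origin[1], origin_y_um = hm@origin[2])
  if (ext == "csv") {
    utils::write.table(hm@heights, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (ext %in% c("tif", "tiff")) {
    z <- hm@heights
    zr <- range(z)
    side$z_min_um <- zr[1]; side$z_max_um <- zr[2]
    zn <- if (diff(zr) > 0) (z - zr[1]) / diff(zr) else z * 0
    tiff::writeTIFF(zn, path, bits.per.sample = 32L, reduce = FALSE)
  } else stop("unsupported height-map extension: ", ext, call. = FALSE)
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname heightmap-io
#' @export
readHeightMap <- function(path) {
  side <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    z <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
    dimnames(z) <- NULL
  } else if (ext %in% c("tif", "tiff")) {
    zn <- tiff::readTIFF(path)
    z <- if (!is.null(side$z_min_um) && side$z_max_um > side$z_min_um)
      side$z_min_um + zn * (side$z_max_um - side$z_min_um)
    else zn + (side$z_min_um %||% 0)
  } else stop("unsupported height-map extension: ", ext, call. = FALSE)
  heightMap(z, spacing = c(side$spacing_x_um, side$spacing_y_um),
            origin = c(side$origin_x_um, side$origin_y_um))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write nuclei point sets
#'
#' CSV with header \code{x_um,y_um[,label]}.
#'
#' @param points data.frame with columns \code{x}, \code{y} and optionally
#'   \code{label}.
#' @param path CSV file path.
#' @return \code{readPointSet} returns the data.frame (columns \code{x},
#'   \code{y}, optional \code{label}).
#' @name pointset-io
NULL

#' @rdname pointset-io
#' @export
writePointSet <- function(points, path) {
  df <- data.frame(x_um = points$x, y_um = points$y)
  if (!is.null(points$label)) df$label <- points$label
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pointset-io
#' @export
readPointSet <- function(path) {
  df <- utils::read.csv(path)
  out <- data.frame(x = df$x_um, y = df$y_um)
  if (!is.null(df$label)) out$label <- df$label
  out
}

#' Read and write time-lapse tracks
#'
#' CSV with header \code{track_id,t_min,x_um,y_um[,cx_um,cy_um]}; the
#' optional last two columns carry the paired cell-centroid position for
#' nucleus tracks.
#'
#' @param tracks data.frame with columns \code{track_id}, \code{t},
#'   \code{x}, \code{y} and optionally \code{cx}, \code{cy}.
#' @param path CSV file path.
#' @return \code{readTracks} returns the data.frame in internal column
#'   names.
#' @name tracks-io
NULL

#' @rdname tracks-io
#' @export
writeTracks <- function(tracks, path) {
  df <- data.frame(track_id = tracks$track_id, t_min = tracks$t,
                   x_um = tracks$x, y_um = tracks$y)
  if (!is.null(tracks$cx)) { df$cx_um <- tracks$cx; df$cy_um <- tracks$cy }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tracks-io
#' @export
readTracks <- function(path) {
  df <- utils::read.csv(path)
  out <- data.frame(track_id = df$track_id, t = df$t_min,
                    x = df$x_um, y = df$y_um)
  if (!is.null(df$cx_um)) { out$cx <- df$cx_um; out$cy <- df$cy_um }
  out
}

#' Read and write voxel masks
#'
#' Multi-page 8-bit TIFF stacks (one page per z slice, foreground > 0) with
#' a JSON sidecar \code{\{voxel_x_um, voxel_y_um, voxel_z_um\}}.
#'
#' @param mask a [VoxelMask-class].
#' @param path TIFF file path.
#' @return \code{readVoxelMask} returns a [VoxelMask-class].
#' @name voxelmask-io
NULL

#' @rdname voxelmask-io
#' @export
writeVoxelMask <- function(mask, path) {
  validObject(mask)
  m <- mask@mask != 0
  pages <- lapply(seq_len(dim(m)[3]), function(k)
    matrix(as.numeric(m[, , k]), dim(m)[1], dim(m)[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(list(voxel_x_um = mask@voxelSize[1],
                            voxel_y_um = mask@voxelSize[2],
                            voxel_z_um = mask@voxelSize[3]),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname voxelmask-io
#' @export
readVoxelMask <- function(path) {
  side <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  m <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) m[, , k] <- pages[[k]]
  voxelMask(m > 0.5, voxelSize = c(side$voxel_x_um, side$voxel_y_um,
                                   side$voxel_z_um))
}

#' Read a simulation configuration from JSON
#'
#' The JSON mirrors [simulationConfig()] arguments, with the landscape under
#' \code{spec} (\code{form}, \code{amplitude_um}, \code{period_um},
#' \code{phase_x}, \code{phase_y}, \code{z_offset_um}); absent fields take
#' the documented defaults.
#'
#' @param path JSON file path.
#' @return A [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- if (is.null(j$spec)) sinusoidSpec("sum", 2.5, 100) else
    sinusoidSpec(j$spec$form %||% "sum",
                 amplitude = j$spec$amplitude_um %||% 2.5,
                 period = j$spec$period_um %||% 100,
                 phaseX = j$spec$phase_x %||% 0,
                 phaseY = j$spec$phase_y %||% 0,
                 zOffset = j$spec$z_offset_um %||% 0)
  defaults <- formals(simulationConfig)
  args <- list(spec = spec)
  for (nm in c("nCells", "dt", "duration", "v0", "persistenceTau", "chi",
               "lambdaSpeed", "nucleusGain", "nucleusNoise", "cellRadius",
               "extent", "seed"))
    if (!is.null(j[[nm]])) args[[nm]] <- j[[nm]]
  do.call(simulationConfig, args)
}
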