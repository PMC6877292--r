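#' Read and write hyperstacks as multi-page TIFF with a JSON sidecar
#'
#' Hyperstacks are stored as 16-bit multi-page TIFF in T-major, Z-minor page
#' order (page `k` holds timepoint `floor((k-1)/Z) + 1`, plane
#' `(k-1) %% Z + 1`), with acquisition metadata in a `<path>.json` sidecar.
#' Writing quantizes intensities to the nearest integer in the 16-bit range;
#' integer-valued stacks round-trip bit-exactly, and metadata round-trips to
#' full precision.
#'
#' @param stack a [Hyperstack-class].
#' @param path TIFF file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `writeHyperstack` returns `path` invisibly; `readHyperstack`
#'   returns a [Hyperstack-class].
#' @export
writeHyperstack <- function(stack, path) {
  stopifnot(is(stack, "Hyperstack"))
  v <- voxels(stack)
  d <- dim(v)
  if (any(v > 65535))
    stop("intensities exceed the 16-bit range")
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    pages[[k]] <- round(v[t, z, , ]) / 65535
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(shape = d, pixel_size_um = stack@pixelSizeUm,
               z_step_um = stack@zStepUm,
               frame_interval_min = stack@frameIntervalMin,
               t0_min = stack@t0Min)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeHyperstack
#' @export
readHyperstack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("metadata sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("shape", "pixel_size_um", "z_step_um", "frame_interval_min",
              "t0_min"))
    if (is.null(meta[[f]]))
      stop("metadata field missing from sidecar: '", f, "'")
  d <- as.integer(meta$shape)
  if (length(d) != 4L) stop("metadata 'shape' must have 4 entries (T,Z,Y,X)")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != d[1] * d[2])
    stop(sprintf("shape error: file has %d pages but metadata declares T=%d, Z=%d (%d pages)",
                 length(pages), d[1], d[2], d[1] * d[2]))
  v <- array(0, dim = d)
  k <- 1L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    v[t, z, , ] <- round(pages[[k]] * 65535)
    k <- k + 1L
  }
  Hyperstack(v, pixelSizeUm = as.numeric(meta$pixel_size_um),
             zStepUm = as.numeric(meta$z_step_um),
             frameIntervalMin = as.numeric(meta$frame_interval_min),
             t0Min = as.numeric(meta$t0_min))
}

#' Write or read a vessel label volume as an integer TIFF
#'
#' Pages are Z-planes; pixel values are segment ids (0 = background).
#'
#' @param labels 3D integer array (Z, Y, X) of segment ids.
#' @param path TIFF file path.
#' @export
writeLabelVolume <- function(labels, path) {
  stopifnot(length(dim(labels)) == 3L)
  if (max(labels) > 65535) stop("more than 65535 segment ids")
  pages <- lapply(seq_len(dim(labels)[1]), function(z) labels[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeLabelVolume
#' @export
readLabelVolume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- as.integer(round(pages[[z]] * 65535))
  arr
}

#' Serialize a VesselTree (label TIFF + segments JSON)
#'
#' @param tree a [VesselTree-class].
#' @param dir output directory; writes `labels.tiff` and `segments.json`.
#' @export
writeVesselTree <- function(tree, dir) {
  stopifnot(is(tree, "VesselTree"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLabelVolume(labelVolume(tree), file.path(dir, "labels.tiff"))
  meta <- list(pixel_size_um = tree@pixelSizeUm, z_step_um = tree@zStepUm,
               segments = segments(tree))
  jsonlite::write_json(meta, file.path(dir, "segments.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @rdname writeVesselTree
#' @export
readVesselTree <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "segments.json"),
                              simplifyVector = TRUE)
  seg <- as.data.frame(meta$segments)
  if (nrow(seg) == 0) {
    seg <- data.frame(id = integer(), category = character(),
                      diameter_um = numeric(), length_um = numeric(),
                      orientation = character(), arterial = logical())
  } else {
    if (is.null(seg$arterial)) seg$arterial <- NA   # all-NA column elided
    seg$arterial <- as.logical(seg$arterial)
    seg$diameter_um <- as.numeric(seg$diameter_um)
    seg$length_um <- as.numeric(seg$length_um)
    seg$id <- as.integer(seg$id)
  }
  new("VesselTree", segments = seg,
      labels = readLabelVolume(file.path(dir, "labels.tiff")),
      pixelSizeUm = meta$pixel_size_um, zStepUm = meta$z_step_um)
}

#' Trace CSV I/O
#'
#' Traces are stored as CSV with columns `time_min,value,units,compartment`.
#'
#' @param trace an [IntensityTrace-class].
#' @param path CSV file path.
#' @export
writeTrace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  IntensityTrace(df$time_min, df$value, units = df$units[1],
                 compartment = df$compartment[1])
}

#' ROI set JSON I/O
#'
#' ROIs are serialized as a JSON list of `[row, col, height, width]` with
#' 0-based row-major corner coordinates (converted from the package's
#' internal 1-based representation).
#'
#' @param roiset a [RoiSet-class].
#' @param path JSON file path.
#' @export
writeRoiSet <- function(roiset, path) {
  r <- roiset@rois
  lst <- lapply(seq_len(nrow(r)), function(i)
    c(r$row[i] - 1L, r$col[i] - 1L, r$height[i], r$width[i]))
  jsonlite::write_json(
    list(compartment = roiset@compartment,
         grid_dim = roiset@gridDim, rois = lst),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRoiSet
#' @export
readRoiSet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- do.call(rbind, lapply(seq_len(nrow(obj$rois)), function(i) obj$rois[i, ]))
  if (is.list(obj$rois)) m <- do.call(rbind, obj$rois)
  else m <- obj$rois
  df <- data.frame(row = m[, 1] + 1L, col = m[, 2] + 1L,
                   height = m[, 3], width = m[, 4])
  new("RoiSet", rois = df, compartment = obj$compartment,
      gridDim = as.integer(obj$grid_dim))
}

#' Read a tracer injection schedule from JSON or YAML
#'
#' The file holds a list of tracer records with fields `name`, `mw_kda`,
#' `injection_time_min`, `window_start_min`, `window_end_min`, `leak_class`.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return schedule data.frame (see [tracerSchedule()]).
#' @export
readSchedule <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  df <- as.data.frame(do.call(rbind, lapply(raw, as.data.frame)))
  if (is.data.frame(raw)) df <- raw
  validateSchedule(df)
}
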