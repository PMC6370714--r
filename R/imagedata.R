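#' Multi-channel microscopy image
#'
#' Container for a set of co-registered 2D intensity planes keyed by stain
#' name (for example `DAPI`, `BSP`, `phalloidin`), sharing dimensions and an
#' optional pixel calibration. Intensities are stored as numeric matrices in
#' arbitrary units, exactly as read from disk: the package never rescales or
#' normalizes on load, and all quantification is performed on these raw
#' values.
#'
#' @param channels named list of numeric matrices, all of identical
#'   dimensions, with unique names. Values must be finite and non-negative.
#' @param pixel_size physical edge length of one pixel, in micrometers, or
#'   `NA` when the image is uncalibrated. Areas are always reported in
#'   pixels; calibrated areas are additionally derivable as
#'   `area_px * pixel_size^2`.
#'
#' @return an object of class `mcimage`: a list with elements `channels` and
#'   `pixel_size`.
#' @seealso [read_image()], [get_channel()], [region_properties()]
#' @export
multichannel_image <- function(channels, pixel_size = NA_real_) {
  if (!is.list(channels) || length(channels) < 1L)
    stop("`channels` must be a non-empty named list of matrices", call. = FALSE)
  nms <- names(channels)
  if (is.null(nms) || anyNA(nms) || any(nms == "") || anyDuplicated(nms))
    stop("channel names must be unique and non-empty", call. = FALSE)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("every channel must be a matrix", call. = FALSE)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must share the same dimensions", call. = FALSE)
  for (nm in nms) {
    v <- channels[[nm]]
    if (!all(is.finite(v)))
      stop("channel '", nm, "' contains non-finite values", call. = FALSE)
    if (any(v < 0))
      stop("channel '", nm, "' contains negative intensities", call. = FALSE)
    storage.mode(channels[[nm]]) <- "double"
  }
  if (!is.na(pixel_size) && pixel_size <= 0)
    stop("`pixel_size` must be positive when given", call. = FALSE)
  structure(list(channels = channels, pixel_size = as.numeric(pixel_size)),
            class = "mcimage")
}

#' @export
print.mcimage <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<mcimage> ", d[1], "x", d[2], " px, ", length(x$channels),
      " channel(s): ", paste(names(x$channels), collapse = ", "), "\n", sep = "")
  if (!is.na(x$pixel_size))
    cat("  pixel size: ", x$pixel_size, " um\n", sep = "")
  invisible(x)
}

#' Extract one channel of a multi-channel image
#'
#' @param image an [multichannel_image()] object.
#' @param channel channel name.
#' @return the numeric intensity matrix of that channel.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "mcimage"))
  if (!channel %in% names(image$channels))
    stop("channel '", channel, "' not present; available: ",
         paste(names(image$channels), collapse = ", "), call. = FALSE)
  image$channels[[channel]]
}

#' Dimensions of a multi-channel image
#' @param x an `mcimage`.
#' @export
dim.mcimage <- function(x) dim(x$channels[[1]])

#' Read a TIFF or PNG image into a multi-channel container
#'
#' Single- or multi-page TIFF files are read page-by-page; each page becomes
#' one channel, in file order, named by `channel_names`. PNG is accepted for
#' single-channel input (greyscale, or the first plane of an RGB file).
#' Integer pixel data are promoted to double without rescaling, so 8-bit
#' input yields values in 0..255 and 16-bit input values in 0..65535.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param channel_names character vector naming the channels; its length
#'   must equal the number of pages/planes in the file.
#' @param pixel_size optional pixel calibration in micrometers.
#' @return a [multichannel_image()].
#' @export
read_image <- function(path, channel_names, pixel_size = NA_real_) {
  if (!file.exists(path))
    stop("cannot read image: file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e)
                        stop("failed to read TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
    planes <- lapply(pages, .collapse_plane)
  } else if (ext == "png") {
    p <- tryCatch(png::readPNG(path),
                  error = function(e)
                    stop("failed to read PNG '", path, "': ",
                         conditionMessage(e), call. = FALSE))
    # png values are scaled to [0,1]; restore the stored integer range
    planes <- list(.collapse_plane(p) * 255)
  } else {
    stop("unsupported image format '.", ext, "' for ", path, call. = FALSE)
  }
  if (length(planes) != length(channel_names))
    stop("channel-count mismatch for '", path, "': file has ", length(planes),
         " page(s) but ", length(channel_names), " channel name(s) were given",
         call. = FALSE)
  names(planes) <- channel_names
  multichannel_image(planes, pixel_size = pixel_size)
}

# first plane of an RGB(A) array, or the matrix itself for greyscale
.collapse_plane <- function(p) {
  if (length(dim(p)) == 3L) p <- p[, , 1L]
  storage.mode(p) <- "double"
  p
}

#' Write a label map to a TIFF file
#'
#' Label maps are integer matrices with 0 meaning background and positive
#' values identifying ROIs. Written as a single-page 16-bit TIFF; when the
#' maximum label exceeds 65535 the file is automatically promoted to 32-bit
#' float storage (exact for labels below 2^23) rather than silently
#' truncated. [read_labelmap()] reproduces the labels exactly.
#'
#' @param labelmap integer matrix of non-negative labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(labelmap, path) {
  .check_labelmap(labelmap)
  k <- max(labelmap)
  if (k <= 65535) {
    tiff::writeTIFF(labelmap / 65535, path, bits.per.sample = 16L)
  } else {
    if (k >= 2^23)
      stop("label values above 2^23 are not exactly representable", call. = FALSE)
    tiff::writeTIFF(labelmap / 2^24, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a label map written by [write_labelmap()]
#' @param path path to the label TIFF.
#' @return integer matrix of labels.
#' @export
read_labelmap <- function(path) {
  if (!file.exists(path))
    stop("cannot read label map: file not found: ", path, call. = FALSE)
  x <- tiff::readTIFF(path, info = TRUE)
  bps <- attr(x, "bits.per.sample")
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  # 16-bit files come back in [0,1] scaled by 65535; 32-bit float by 2^24
  scale <- if (!is.null(bps) && bps == 32L) 2^24 else 65535
  matrix(as.integer(round(x * scale)), nrow(x), ncol(x))
}

.check_labelmap <- function(labelmap) {
  if (is.null(dim(labelmap)) || length(dim(labelmap)) != 2L)
    stop("a label map must be a 2D matrix", call. = FALSE)
  if (any(labelmap < 0) || any(labelmap != round(labelmap)))
    stop("labels must be non-negative integers", call. = FALSE)
  invisible(TRUE)
}

#' Per-ROI measurements of a label map over raw image channels
#'
#' Computes one record per positive label: pixel area, unweighted centroid,
#' and per-channel mean and summed intensity, measured on the raw stored
#' intensities of `image` (never on any filtered or contrast-adjusted
#' intermediate). This mirrors overlaying segmentation ROIs onto the
#' original file before measuring.
#'
#' Coordinates are 1-based `(row, col)` with pixel centers at integer
#' positions; the centroid is the plain mean of member pixel coordinates.
#'
#' @param labelmap integer label matrix, same dimensions as `image`.
#' @param image a [multichannel_image()], or a single numeric matrix (then
#'   reported as channel `"value"`).
#' @return a tibble with columns `label`, `area_px`, `centroid_row`,
#'   `centroid_col`, then `mean_<channel>` and `sum_<channel>` per channel,
#'   and a `zone` column initialized to `"ungated"` (see [assign_zones()]).
#'   An empty label map yields a zero-row table.
#' @export
region_properties <- function(labelmap, image) {
  .check_labelmap(labelmap)
  if (is.matrix(image)) image <- multichannel_image(list(value = image))
  stopifnot(inherits(image, "mcimage"))
  if (!identical(dim(labelmap), dim(image)))
    stop("labelmap and image dimensions differ", call. = FALSE)

  ids <- sort(unique(labelmap[labelmap > 0]))
  if (length(ids) == 0L) {
    out <- tibble::tibble(label = integer(), area_px = integer(),
                          centroid_row = numeric(), centroid_col = numeric())
    for (nm in names(image$channels)) {
      out[[paste0("mean_", nm)]] <- numeric()
      out[[paste0("sum_", nm)]] <- numeric()
    }
    out$zone <- character()
    return(out)
  }

  lab <- as.integer(labelmap)
  fg <- lab > 0L
  labf <- lab[fg]
  d <- dim(labelmap)
  rows <- rep.int(seq_len(d[1]), d[2])[fg]
  cols <- rep(seq_len(d[2]), each = d[1])[fg]

  area <- tabulate(labf)
  out <- tibble::tibble(
    label = ids,
    area_px = area[ids],
    centroid_row = unname((rowsum(rows, labf)[, 1])[as.character(ids)]) / area[ids],
    centroid_col = unname((rowsum(cols, labf)[, 1])[as.character(ids)]) / area[ids]
  )
  for (nm in names(image$channels)) {
    v <- image$channels[[nm]][fg]
    s <- (rowsum(v, labf)[, 1])[as.character(ids)]
    out[[paste0("sum_", nm)]] <- unname(s)
    out[[paste0("mean_", nm)]] <- unname(s) / out$area_px
  }
  # conventional column order: means before sums
  mcols <- paste0("mean_", names(image$channels))
  scols <- paste0("sum_", names(image$channels))
  out <- out[, c("label", "area_px", "centroid_row", "centroid_col", mcols, scols)]
  out$zone <- "ungated"
  out
}

#' Write a region table to CSV with a JSON provenance sidecar
#'
#' @param table a region table (tibble).
#' @param path output CSV path; a sidecar `<path>.json` records provenance.
#' @param provenance named list echoed into the sidecar (source file,
#'   parameters, seed, ...). Package version and timestamp-free metadata are
#'   added automatically so identical runs write identical files.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(table, path, provenance = list()) {
  readr::write_csv(table, path)
  prov <- c(list(package = "spheroidseg",
                 version = as.character(utils::packageVersion("spheroidseg"))),
            provenance)
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
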