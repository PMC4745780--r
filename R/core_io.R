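#' Image sequence container
#'
#' Ordered list of 2-D intensity frames from one channel of a time-lapse
#' acquisition. Frames are stored as numeric matrices (row = y, column = x,
#' origin top-left); intensities are kept as read, processing is done in
#' floating point.
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @param channel channel role: `"phase"`, `"fluor_green"` or `"fluor_red"`.
#' @param frame_interval time between frames in hours (live-cell capture
#'   here is one image per well per hour, so the default is 1).
#' @param pixel_size physical pixel size, or the string `"pixels"` when no
#'   calibration is available.
#' @return an object of class `ImageSequence`.
#' @export
image_sequence <- function(frames,
                           channel = c("phase", "fluor_green", "fluor_red"),
                           frame_interval = 1, pixel_size = "pixels") {
  channel <- match.arg(channel)
  if (!is.list(frames) || length(frames) < 1)
    stopf("`frames` must be a non-empty list of matrices")
  dims <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f))
      stopf("frame %d is not a matrix", i)
    if (!identical(dim(f), dims))
      stopf("frame %d has dimensions %dx%d, expected %dx%d",
            i, nrow(f), ncol(f), dims[1], dims[2])
    if (!all(is.finite(f)))
      stopf("frame %d contains non-finite intensities", i)
  }
  structure(list(frames = lapply(frames, function(f) {
    storage.mode(f) <- "double"; f
  }),
  channel = channel, frame_interval = frame_interval,
  pixel_size = pixel_size),
  class = "ImageSequence")
}

#' @export
print.ImageSequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("ImageSequence: %d frame(s) of %dx%d [%s], dt = %s h\n",
              length(x$frames), d[1], d[2], x$channel,
              format(x$frame_interval)))
  invisible(x)
}

#' @export
length.ImageSequence <- function(x) length(x$frames)

#' Binary mask sequence aligned to an image sequence
#'
#' @param frames list of binary (0/1) matrices.
#' @param source_channel channel the masks were derived from.
#' @param aligned_to identifier of the source [image_sequence()].
#' @return an object of class `MaskSequence`.
#' @export
mask_sequence <- function(frames, source_channel = "fluor_green",
                          aligned_to = "") {
  if (!is.list(frames) || length(frames) < 1)
    stopf("`frames` must be a non-empty list of matrices")
  dims <- dim(frames[[1]])
  frames <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    if (!identical(dim(f), dims))
      stopf("mask frame %d has inconsistent dimensions", i)
    f <- (f != 0) * 1L
    storage.mode(f) <- "integer"
    f
  })
  structure(list(frames = frames, source_channel = source_channel,
                 aligned_to = aligned_to),
            class = "MaskSequence")
}

#' Read an image sequence from disk
#'
#' Accepts a multi-page TIFF or a directory of single-frame TIFF/PNG files
#' taken in lexicographic name order. Integer intensities are preserved
#' without rescaling (8- and 16-bit TIFF both accepted).
#'
#' @param path file or directory path.
#' @inheritParams image_sequence
#' @return an [image_sequence()].
#' @export
read_sequence <- function(path,
                          channel = c("phase", "fluor_green", "fluor_red"),
                          frame_interval = 1) {
  channel <- match.arg(channel)
  read_one <- function(p) {
    if (grepl("\\.png$", p, ignore.case = TRUE)) {
      img <- png::readPNG(p)
      if (length(dim(img)) == 3) img <- img[, , 1]
      return(round(img * 255))
    }
    tiff::readTIFF(p, as.is = TRUE)
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stopf("no frame images found in '%s'", path)
    frames <- lapply(files, read_one)
  } else {
    if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
    frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(frames)) frames <- list(frames)
  }
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3) f <- f[, , 1]
    f
  })
  image_sequence(frames, channel = channel, frame_interval = frame_interval)
}

#' Write an image sequence as a multi-page TIFF
#'
#' Frames are quantized to the requested unsigned integer bit depth.
#' Writing integer-valued frames already within range and reading them back
#' with [read_sequence()] reproduces the pixel values exactly.
#'
#' @param seq an [image_sequence()] or list of matrices.
#' @param path output file path (`.tif`).
#' @param bits 8 or 16.
#' @export
write_sequence <- function(seq, path, bits = 16) {
  frames <- if (inherits(seq, "ImageSequence")) seq$frames else seq
  if (!bits %in% c(8, 16)) stopf("`bits` must be 8 or 16")
  mx <- 2^bits - 1
  scaled <- lapply(frames, function(f) {
    f <- pmin(pmax(f, 0), mx)
    f / mx
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = bits)
  invisible(path)
}

#' Write a metrics table as CSV
#'
#' @param records non-empty data frame of per-object or per-frame metrics.
#' @param path output CSV path.
#' @export
write_metrics_table <- function(records, path) {
  if (is.null(records) || nrow(as.data.frame(records)) == 0)
    stopf("`records` is empty; refusing to write an empty metrics table")
  write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Read a metrics table written by [write_metrics_table()]
#' @param path CSV path.
#' @return data frame.
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a QC overlay PNG
#'
#' Renders a grayscale image with up to three binary masks overlaid in
#' red, green and blue.
#'
#' @param img background intensity image.
#' @param masks list of binary matrices (1 to 3).
#' @param path output PNG path.
#' @export
write_overlay <- function(img, masks, path) {
  rng <- range(img)
  g <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  rgb <- array(rep(g, 3), c(nrow(img), ncol(img), 3))
  if (!is.list(masks)) masks <- list(masks)
  for (i in seq_along(masks)) {
    m <- masks[[i]] != 0
    ch <- ((i - 1) %% 3) + 1
    plane <- rgb[, , ch]
    plane[m] <- 1
    rgb[, , ch] <- plane
  }
  png::writePNG(rgb, path)
  invisible(path)
}
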