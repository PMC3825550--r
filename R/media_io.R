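#' Construct a calibrated frame stack
#'
#' A `frame_stack` holds a grayscale time-lapse video together with its
#' acquisition calibration: frame rate and pixel size. Frames are stored as a
#' numeric array of dimension `rows x cols x n_frames`, intensities on a
#' common `[0, 1]` scale (8/16-bit inputs are promoted on read).
#'
#' @param frames numeric array `rows x cols x n_frames` (a matrix is treated
#'   as a single frame and rejected: at least two frames are required).
#' @param fps frames per second (> 0).
#' @param pixel_size microns per pixel (> 0).
#' @param times_ms optional per-frame timestamps in milliseconds, strictly
#'   increasing; defaults to uniform timing `1000 * (index - 1) / fps`.
#' @return An object of class `frame_stack` with elements `frames`, `fps`,
#'   `pixel_size`, `times_ms`.
#' @export
frame_stack <- function(frames, fps, pixel_size, times_ms = NULL) {
  check_positive_scalar(fps, "fps")
  check_positive_scalar(pixel_size, "pixel_size")
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop_input("`frames` must be a rows x cols x n_frames numeric array")
  n <- dim(frames)[3L]
  if (n < 2L) stop_input("a frame stack needs at least 2 frames")
  if (is.null(times_ms)) times_ms <- 1000 * (seq_len(n) - 1) / fps
  if (length(times_ms) != n || any(diff(times_ms) <= 0))
    stop_input("`times_ms` must be strictly increasing, one per frame")
  structure(
    list(frames = frames, fps = fps, pixel_size = pixel_size,
         times_ms = as.numeric(times_ms)),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "frame_stack: %d frames of %d x %d px, %.3g fps, %.3g um/px (%.3g s)\n",
    d[3], d[1], d[2], x$fps, x$pixel_size, d[3] / x$fps))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3L]

get_frame <- function(stack, i) stack$frames[, , i]

#' Read a calibrated image stack
#'
#' Reads a grayscale video either from a multi-page TIFF file or from a
#' directory of lexically ordered single-page images (TIFF or PNG). 8- and
#' 16-bit integer data are promoted to doubles on `[0, 1]`.
#'
#' @param path multi-page TIFF file, or a directory of single-page images.
#' @param fps frames per second of the recording.
#' @param pixel_size microns per pixel.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, fps, pixel_size) {
  if (!file.exists(path)) stop_input("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L)
      stop_input("directory must contain at least 2 image files")
    pages <- lapply(files, read_gray_image)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, drop_to_gray)
    if (length(pages) < 2L) stop_input("stack must contain at least 2 frames")
  }
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop_input("inconsistent frame shapes across the stack: ",
               paste(unique(shapes), collapse = ", "))
  frames <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  frame_stack(frames, fps = fps, pixel_size = pixel_size)
}

read_gray_image <- function(f) {
  img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
         else tiff::readTIFF(f)
  drop_to_gray(img)
}

drop_to_gray <- function(img) {
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel of RGB(A)
  img
}

#' Write a frame stack as a 16-bit multi-page TIFF
#'
#' Intensities are clamped to `[0, 1]` and quantized to 16 bits; reading the
#' file back yields exactly the quantized values, so write/read round-trips
#' are bit-stable.
#'
#' @param stack a [frame_stack()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(seq_len(n_frames(stack)), function(i) {
    f <- pmax(pmin(get_frame(stack, i), 1), 0)
    round(f * 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read manually traced contours
#'
#' Reads per-frame closed polygons from a CSV with columns `frame,x,y`
#' (pixel coordinates, 0-based, vertices in tracing order; polygons are
#' closed implicitly). This supports the manual tracing workflow in which the
#' inner perimeter of the ventricle is outlined frame by frame.
#'
#' @param path CSV file path.
#' @return A `contour_set`: a named list of data frames with columns `x`,
#'   `y`, names being frame indices, plus attribute `frames`.
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  df <- tryCatch(read.csv(path), error = function(e)
    stop_input("cannot parse contour CSV: ", conditionMessage(e)))
  if (nrow(df) == 0L) stop_input("contour file is empty")
  need <- c("frame", "x", "y")
  if (!all(need %in% names(df)))
    stop_input("contour CSV must have columns frame,x,y")
  if (!all(vapply(df[need], is.numeric, TRUE)))
    stop_input("non-numeric values in contour CSV")
  polys <- split(df[, c("x", "y")], df$frame)
  bad <- names(polys)[vapply(polys, nrow, 0L) < 3L]
  if (length(bad))
    stop_input("contour with fewer than 3 vertices on frame(s): ",
               paste(bad, collapse = ", "))
  areas <- vapply(polys, function(p) polygon_moments(p$x, p$y)$area, 0)
  if (any(areas <= 0))
    stop_input("contour with non-positive area on frame(s): ",
               paste(names(polys)[areas <= 0], collapse = ", "))
  structure(polys, frames = as.integer(names(polys)), class = "contour_set")
}

#' Write a table of named metrics
#'
#' Writes a one-row-per-record table of numeric metrics as CSV or JSON.
#' Values round-trip losslessly at 12 significant digits; column order is
#' the order of first appearance and is preserved.
#'
#' @param records a data frame, or a named list/vector of scalars (treated
#'   as a one-row table).
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(records)) {
    if (length(records) == 0L || is.null(names(records)) ||
        any(names(records) == ""))
      stop_input("`records` must be non-empty and fully named")
    records <- as.data.frame(as.list(records))
  }
  if (nrow(records) == 0L || ncol(records) == 0L)
    stop_input("`records` must be non-empty")
  if (format == "csv") {
    out <- records
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], function(v) format(v, digits = 12,
                                                    scientific = FALSE))
    tryCatch(write.csv(out, path, row.names = FALSE, quote = FALSE),
             error = function(e) stop_input("cannot write ", path, ": ",
                                            conditionMessage(e)),
             warning = function(w) stop_input("cannot write ", path, ": ",
                                              conditionMessage(w)))
  } else {
    jsonlite::write_json(records, path, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' Read a metrics table written by [write_metrics()]
#' @param path CSV or JSON file path.
#' @return A data frame.
#' @export
read_metrics <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  else read.csv(path)
}
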