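#' Ellipsoid body volume from three linear measurements
#'
#' Treats length, width and height as the three full axis lengths of an
#' ellipsoid: `V = pi/6 * L * W * H`.  Vectorized over its arguments.
#'
#' @param length,width,height Positive measurements in mm (length and width
#'   from the dorsal view, height from the lateral view; head excluded).
#' @return Volume in mm^3.
#' @examples
#' ellipsoid_volume(2, 2, 2)  # sphere of radius 1: 4*pi/3
#' @export
ellipsoid_volume <- function(length, width, height) {
  if (any(!is.finite(c(length, width, height))) ||
      any(c(length, width, height) <= 0))
    tf_stop("all of length, width, height must be positive and finite")
  pi / 6 * length * width * height
}

#' Convert image intensity to the darkness channel
#'
#' Linearly rescales inverted intensity onto the integer darkness scale:
#' 0 = pure white (intensity 1), 222 = pure black (intensity 0).
#'
#' @param intensity Numeric matrix/vector of intensities in `[0, 1]`.
#' @return Integer darkness values in `{0, ..., 222}`.
#' @export
darkness_channel <- function(intensity) {
  if (any(intensity < -1e-9 | intensity > 1 + 1e-9, na.rm = TRUE))
    tf_stop("intensity values must lie in [0, 1] (white = 1)")
  d <- as.integer(round((1 - intensity) * DARKNESS_MAX))
  pmin(pmax(d, 0L), DARKNESS_MAX)
}

#' Median body darkness of a masked image region
#'
#' Bins the masked pixels' darkness-channel values into the integer
#' histogram 0..222 and returns the histogram median, using the
#' lower-median convention for even pixel counts (the value at rank
#' `ceiling(n/2)`), as integer-histogram tools do.
#'
#' @param image Grayscale intensity matrix in `[0, 1]` (white = 1).
#' @param mask Logical matrix of the same shape marking the body region
#'   (face/thorax/abdomen; wings and legs excluded).
#' @return Median darkness, an integer in `[0, 222]`.
#' @export
measure_darkness <- function(image, mask) {
  if (!identical(dim(image), dim(mask)))
    tf_stop("image and mask dimensions differ")
  vals <- darkness_channel(image[mask])
  n <- length(vals)
  if (n == 0L) tf_stop("measurement error: empty body mask")
  counts <- tabulate(vals + 1L, nbins = DARKNESS_MAX + 1L)
  rank <- ceiling(n / 2)
  as.integer(which(cumsum(counts) >= rank)[1L] - 1L)
}

# Axis-aligned pixel extents (x = columns, y = rows) of a logical mask.
mask_extent_px <- function(mask, view = "image") {
  hit <- which(mask, arr.ind = TRUE)
  if (!nrow(hit)) tf_stop("measurement error: empty body mask in %s view", view)
  c(x = diff(range(hit[, 2L])) + 1L, y = diff(range(hit[, 1L])) + 1L)
}

#' Extract linear body dimensions from a three-view image set
#'
#' Length and width are the horizontal and vertical extents of the dorsal
#' body mask, height the vertical extent of the lateral mask, each times
#' the pixel scale.  Head exclusion is a property of the masks.
#'
#' @param images A `specimen_images` object (see [render_specimen()] /
#'   [read_specimen_images()]).
#' @return Named numeric `c(length=, width=, height=)` in mm.
#' @export
extract_dimensions <- function(images) {
  if (!inherits(images, "specimen_images")) tf_stop("not a specimen_images object")
  s <- images$pixel_scale
  if (is.null(s) || s <= 0) tf_stop("pixel_scale must be > 0")
  d <- mask_extent_px(images$views$dorsal$mask, "dorsal")
  l <- mask_extent_px(images$views$lateral$mask, "lateral")
  c(length = unname(d["x"]) * s, width = unname(d["y"]) * s,
    height = unname(l["y"]) * s)
}

#' Measure one specimen from its three-view image set
#'
#' Composes [extract_dimensions()], [ellipsoid_volume()] and
#' [measure_darkness()] (darkness from the dorsal body mask by default).
#'
#' @param images A `specimen_images` object with dorsal, lateral and
#'   anterior views.
#' @param darkness_view View whose mask defines the darkness region.
#' @return Object of class `morph_measurement`: list with `length`,
#'   `width`, `height` (mm), `volume` (mm^3) and `darkness` (0-222).
#' @export
measure_specimen <- function(images, darkness_view = "dorsal") {
  if (!inherits(images, "specimen_images")) tf_stop("not a specimen_images object")
  missing_views <- setdiff(c("dorsal", "lateral", "anterior"),
                           names(images$views))
  if (length(missing_views))
    tf_stop("missing view(s): %s", paste(missing_views, collapse = ", "))
  dims <- extract_dimensions(images)
  dv <- images$views[[darkness_view]]
  if (is.null(dv)) tf_stop("unknown darkness view '%s'", darkness_view)
  structure(list(
    length = dims[["length"]], width = dims[["width"]],
    height = dims[["height"]],
    volume = ellipsoid_volume(dims[["length"]], dims[["width"]],
                              dims[["height"]]),
    darkness = measure_darkness(dv$image, dv$mask)
  ), class = "morph_measurement")
}

#' @export
print.morph_measurement <- function(x, ...) {
  cat(sprintf("specimen: L %.3f x W %.3f x H %.3f mm, volume %.2f mm^3, darkness %d\n",
              x$length, x$width, x$height, x$volume, x$darkness))
  invisible(x)
}
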