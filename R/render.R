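# Synthetic specimen imagery: each specimen is rendered as three grayscale
# views (dorsal, lateral, anterior) of an ellipsoid body on an 11%-gray
# background, with optional head/wing decorations that sit OUTSIDE the body
# mask -- mirroring how real measurements exclude head, wings and legs.

BACKGROUND_INTENSITY <- 0.89  # 11% neutral gray, white = 1

# Intensity (0 = black, 1 = white) encoding a darkness value on [0, 222].
darkness_to_intensity <- function(d) 1 - d / DARKNESS_MAX

# Rasterize a filled axis-aligned ellipse over pixel centers.
# dims in mm: c(x_extent, y_extent); returns logical matrix [rows = y].
ellipse_mask <- function(nrow_px, ncol_px, cx, cy, dx, dy, pixel_scale) {
  xs <- (seq_len(ncol_px) - 0.5) * pixel_scale
  ys <- (seq_len(nrow_px) - 0.5) * pixel_scale
  fx <- ((xs - cx) / (dx / 2))^2
  fy <- ((ys - cy) / (dy / 2))^2
  outer(fy, fx, `+`) <= 1
}

#' Render a specimen as three-view synthetic images
#'
#' Produces dorsal, lateral and anterior grayscale rasters for one specimen
#' record.  The body is an axis-aligned ellipse whose extents encode body
#' length and width (dorsal) or height (lateral/anterior) and whose fill
#' intensity encodes the record's darkness (0 = white fill, 222 = black
#' fill) on an 11%-gray background.  A head disc and wing ellipses are
#' rendered as decoration but excluded from the body mask, so mask-based
#' measurements automatically exclude them.
#'
#' Body dimensions are derived from the record's volume through the
#' ellipsoid relation `V = pi/6 L W H` and the `aspect` ratios
#' (length : width : height), unless explicit `dims` are given.
#'
#' @param record A one-row specimen record (needs `body_volume_mm3` and
#'   `darkness`), or a list with those elements.
#' @param dims Optional named numeric `c(length=, width=, height=)` in mm,
#'   overriding the volume-derived dimensions.
#' @param aspect Length:width:height ratios used when `dims` is `NULL`.
#' @param pixel_scale mm per pixel; default scales the longest axis to
#'   `target_px` pixels.
#' @param target_px Approximate pixel extent of the longest body axis.
#' @param decorations Render head and wings (outside the mask)?
#' @return Object of class `specimen_images`: list with `views` (each a
#'   list `image` (matrix in `[0,1]`, white = 1) and `mask` (logical)),
#'   `pixel_scale`, and `record`.
#' @examples
#' rec <- list(body_volume_mm3 = 200, darkness = 100)
#' img <- render_specimen(rec, target_px = 120)
#' measure_specimen(img)
#' @export
render_specimen <- function(record, dims = NULL,
                            aspect = c(length = 2, width = 1, height = 1),
                            pixel_scale = NULL, target_px = 256,
                            decorations = TRUE) {
  vol <- record$body_volume_mm3 %||% record$volume
  dark <- record$darkness
  if (is.null(dark) || dark < 0 || dark > DARKNESS_MAX)
    tf_stop("record darkness must lie in [0, %d]", DARKNESS_MAX)
  if (is.null(dims)) {
    if (is.null(vol) || vol <= 0) tf_stop("record body volume must be > 0")
    unit <- (6 * vol / (pi * prod(aspect)))^(1 / 3)
    dims <- c(length = unname(aspect[1] * unit),
              width = unname(aspect[2] * unit),
              height = unname(aspect[3] * unit))
  }
  if (any(dims <= 0)) tf_stop("specimen dimensions must be > 0")
  if (!is.null(pixel_scale) && pixel_scale <= 0)
    tf_stop("pixel_scale must be > 0")
  if (target_px <= 0) tf_stop("requested image size must be > 0")
  pixel_scale <- pixel_scale %||% (max(dims) / target_px)

  body_int <- darkness_to_intensity(dark)
  views <- list(
    dorsal = c(dims[["length"]], dims[["width"]]),
    lateral = c(dims[["length"]], dims[["height"]]),
    anterior = c(dims[["width"]], dims[["height"]])
  )

  out <- lapply(names(views), function(v) {
    d <- views[[v]]
    # margins leave room for decorations (head along -x, wings along y)
    wmm <- d[1] * 1.7
    hmm <- d[2] * 2.1
    ncol_px <- max(8L, ceiling(wmm / pixel_scale))
    nrow_px <- max(8L, ceiling(hmm / pixel_scale))
    cx <- wmm * 0.6
    cy <- hmm / 2
    img <- matrix(BACKGROUND_INTENSITY, nrow_px, ncol_px)
    body <- ellipse_mask(nrow_px, ncol_px, cx, cy, d[1], d[2], pixel_scale)
    if (decorations) {
      if (v %in% c("dorsal", "lateral")) {
        head_d <- 0.45 * d[2]
        head <- ellipse_mask(nrow_px, ncol_px, cx - d[1] / 2 - head_d / 2 - pixel_scale,
                             cy, head_d, head_d, pixel_scale)
        img[head & !body] <- body_int
      }
      if (v == "dorsal") {
        for (sgn in c(-1, 1)) {
          wing <- ellipse_mask(nrow_px, ncol_px, cx + d[1] * 0.1,
                               cy + sgn * (d[2] / 2 + 0.25 * d[2] + pixel_scale),
                               0.9 * d[1], 0.4 * d[2], pixel_scale)
          img[wing & !body] <- 0.55
        }
      }
    }
    img[body] <- body_int
    list(image = img, mask = body)
  })
  names(out) <- names(views)
  structure(list(views = out, pixel_scale = pixel_scale,
                 record = list(body_volume_mm3 = vol, darkness = dark,
                               dims = dims)),
            class = "specimen_images")
}

#' Write/read a rendered specimen image set as PNG files
#'
#' Images are written as 16-bit grayscale PNGs (`<view>.png`) with their
#' body masks as companion single-channel PNGs (`<view>_mask.png`).
#'
#' @param images A `specimen_images` object.
#' @param dir Output directory (created if missing).
#' @return `write_specimen_images`: the directory, invisibly.
#' @export
write_specimen_images <- function(images, dir) {
  if (!inherits(images, "specimen_images")) tf_stop("not a specimen_images object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in names(images$views)) {
    png::writePNG(images$views[[v]]$image, file.path(dir, paste0(v, ".png")))
    png::writePNG(images$views[[v]]$mask * 1,
                  file.path(dir, paste0(v, "_mask.png")))
  }
  meta <- list(pixel_scale = images$pixel_scale)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_specimen_images
#' @param pixel_scale mm per pixel; if `NULL`, read from the `meta.json`
#'   written alongside the images.
#' @return `read_specimen_images`: a `specimen_images` object (without the
#'   generating record).
#' @export
read_specimen_images <- function(dir, pixel_scale = NULL) {
  if (is.null(pixel_scale)) {
    mp <- file.path(dir, "meta.json")
    if (!file.exists(mp))
      tf_stop("pixel_scale not given and %s not found", mp)
    pixel_scale <- jsonlite::fromJSON(mp)$pixel_scale
  }
  views <- lapply(c(dorsal = "dorsal", lateral = "lateral",
                    anterior = "anterior"), function(v) {
    ip <- file.path(dir, paste0(v, ".png"))
    mp <- file.path(dir, paste0(v, "_mask.png"))
    if (!file.exists(ip) || !file.exists(mp))
      tf_stop("missing %s view (or its mask) under %s", v, dir)
    img <- png::readPNG(ip)
    msk <- png::readPNG(mp)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
    list(image = img, mask = msk > 0.5)
  })
  structure(list(views = views, pixel_scale = pixel_scale, record = NULL),
            class = "specimen_images")
}
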