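#' Convert a false-RGB image to grayscale
#'
#' Pixel-wise luminance weighting `0.2989 R + 0.5870 G + 0.1140 B`, the
#' standard ITU-R BT.601 weights. Output intensities stay real-valued; no
#' integer cast is performed.
#'
#' @param rgb an [rgb_image()] or a rows x cols x 3 numeric array.
#' @return an [image_grid()] on the same intensity scale as the input.
#' @examples
#' g <- to_grayscale(rgb_image(matrix(255, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2)))
#' g[1, 1]  # 76.2195
#' @export
to_grayscale <- function(rgb) {
  if (inherits(rgb, "image_grid")) return(rgb)
  a <- unclass(rgb)
  if (length(dim(a)) != 3L || dim(a)[3] < 3L)
    stop("expected a three-channel image")
  g <- 0.2989 * a[, , 1] + 0.5870 * a[, , 2] + 0.1140 * a[, , 3]
  image_grid(g, range = if (max(a) <= 1) c(0, 1) else c(0, 255))
}

#' Resize an image to a standard square side
#'
#' Bilinear resampling to `side x side`; pixel spacing, if present, is rescaled
#' per axis so physical extent is preserved.
#'
#' @param image an [image_grid()].
#' @param side output side in pixels (default 1024).
#' @return resized [image_grid()].
#' @export
resize_to_standard <- function(image, side = 1024L) {
  m <- grid_pixels(image)
  side <- as.integer(side)
  out <- if (nrow(m) == side && ncol(m) == side) m
         else EBImage::resize(m, w = side, h = side, filter = "bilinear")
  sp <- grid_spacing(image)
  if (!is.null(sp)) sp <- sp * c(nrow(m), ncol(m)) / side
  image_grid(out, spacing = sp, range = grid_range(image))
}

#' Linear intensity windowing (VOI-LUT style)
#'
#' Maps intensities through a linear window: values at or below
#' `center - width/2` go to 0, values at or above `center + width/2` go to the
#' top of the display range, linear in between. With `center`/`width` omitted,
#' a fallback window spans the 2nd-98th percentiles of the foreground
#' (pixels > 0); a degenerate window (zero width) returns the image unchanged.
#'
#' @param image an [image_grid()].
#' @param center,width window center and width on the image's intensity scale;
#'   `width` must be positive when given.
#' @return windowed [image_grid()] spanning its display range.
#' @export
voi_window <- function(image, center = NULL, width = NULL) {
  m <- grid_pixels(image)
  r <- grid_range(image)
  if (is.null(center) || is.null(width)) {
    fg <- m[m > 0]
    if (length(fg) == 0L) fg <- as.vector(m)
    q <- stats::quantile(fg, c(0.02, 0.98), names = FALSE, type = 7)
    center <- (q[1] + q[2]) / 2
    width <- q[2] - q[1]
    if (width <= 0) return(image)  # constant image: declared degenerate
  }
  if (width <= 0) stop("window width must be positive")
  lo <- center - width / 2
  u <- (m - lo) / width
  out <- pmin(pmax(u, 0), 1) * r[2]
  image_grid(out, spacing = grid_spacing(image), range = r)
}

#' Remove off-breast artifacts by largest-island selection
#'
#' Labels the 4-connected components of `{pixels > fg_threshold}`, keeps the
#' largest-area component (the breast), and zeroes every other component. Ties
#' on area go to the component whose first pixel comes earliest in raster
#' order (smallest label).
#'
#' @param image an [image_grid()].
#' @param fg_threshold foreground threshold; background after preprocessing is
#'   exact 0, so the default 0 keeps any positive pixel.
#' @return list with `image` (cleaned [image_grid()]) and `n_removed`, the
#'   count of discarded components.
#' @export
remove_artifacts <- function(image, fg_threshold = 0) {
  m <- grid_pixels(image)
  mask <- m > fg_threshold
  if (!any(mask)) stop("no foreground found above threshold (no breast)")
  lab <- label_components(mask, connectivity = 4L)
  areas <- tabulate(lab[lab > 0L])
  keep <- which.max(areas)  # ties -> smallest label, i.e. first in raster order
  m[lab != keep & lab > 0L] <- 0
  list(image = image_grid(m, spacing = grid_spacing(image),
                          range = grid_range(image)),
       n_removed = length(areas) - 1L)
}

#' Full preprocessing pipeline
#'
#' Normalizes a raw input into a uniform grid: grayscale conversion, then
#' largest-island artifact removal, then intensity windowing, then resizing --
#' in that order by default (the order of removal vs. windowing is
#' configurable).
#'
#' @param raw an [image_grid()], [rgb_image()], or path readable by
#'   [read_image()].
#' @param side output side (default 1024).
#' @param window `NULL` for the percentile fallback, `"identity"` to skip
#'   windowing, or a list `list(center =, width =)`.
#' @param artifact_removal logical; set `FALSE` to skip island removal.
#' @param window_first if `TRUE`, windowing precedes artifact removal.
#' @param fg_threshold passed to [remove_artifacts()].
#' @return preprocessed [image_grid()].
#' @export
preprocess_pipeline <- function(raw, side = 1024L, window = NULL,
                                artifact_removal = TRUE,
                                window_first = FALSE, fg_threshold = 0) {
  img <- if (is.character(raw)) read_image(raw) else raw
  if (inherits(img, "rgb_image")) img <- to_grayscale(img)
  if (!inherits(img, "image_grid")) img <- image_grid(img)
  do_window <- function(x) {
    if (identical(window, "identity")) x
    else if (is.null(window)) voi_window(x)
    else voi_window(x, center = window$center, width = window$width)
  }
  do_remove <- function(x) {
    if (artifact_removal) remove_artifacts(x, fg_threshold)$image else x
  }
  img <- if (window_first) do_remove(do_window(img)) else do_window(do_remove(img))
  resize_to_standard(img, side = side)
}
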