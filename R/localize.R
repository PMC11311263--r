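#' Disk-shaped structuring element
#'
#' The binary mask `{(dr, dc): dr^2 + dc^2 <= radius^2}`, symmetric under
#' 90-degree rotation, transpose, and flips, with the center pixel always
#' included.
#'
#' @param radius disk radius in pixels (>= 1).
#' @return a `structuring_element`: logical `(2r+1) x (2r+1)` mask with a
#'   `radius` attribute.
#' @export
disk_se <- function(radius) {
  if (radius < 1) stop("radius must be >= 1")
  r <- as.integer(radius)
  d <- -r:r
  mask <- outer(d^2, d^2, "+") <= radius^2
  structure(mask, radius = radius,
            class = c("structuring_element", "matrix", "array"))
}

# Offsets (dr, dc) of the true pixels of an SE, relative to its center.
se_offsets <- function(se) {
  r <- (nrow(se) - 1L) %/% 2L
  w <- which(unclass(se), arr.ind = TRUE)
  cbind(dr = w[, 1] - r - 1L, dc = w[, 2] - r - 1L)
}

# Grayscale erosion (op = pmin) or dilation (op = pmax) with edge replication:
# out(x) = min/max over SE offsets of img(clamp(x + off)).
morph_op <- function(image, se, op) {
  m <- grid_pixels(image)
  nr <- nrow(m); nc <- ncol(m)
  if (nrow(se) > nr || ncol(se) > nc) stop("structuring element larger than image")
  offs <- se_offsets(se)
  out <- NULL
  rs <- seq_len(nr); cs <- seq_len(nc)
  for (i in seq_len(nrow(offs))) {
    shifted <- m[pmin(pmax(rs + offs[i, 1], 1L), nr),
                 pmin(pmax(cs + offs[i, 2], 1L), nc)]
    out <- if (is.null(out)) shifted else op(out, shifted)
  }
  out
}

#' Grayscale morphological opening
#'
#' Erosion (minimum over the structuring element) followed by dilation
#' (maximum), both with edge replication at the borders. Opening is
#' anti-extensive (never exceeds the input) and idempotent; it removes bright
#' structures smaller than the structuring element.
#'
#' @param image an [image_grid()] or matrix.
#' @param se a [disk_se()] (or any logical SE mask).
#' @return opened image, same class as the input.
#' @export
open_image <- function(image, se) {
  er <- morph_op(image, se, pmin)
  op <- morph_op(er, se, pmax)
  if (inherits(image, "image_grid"))
    image_grid(op, spacing = grid_spacing(image), range = grid_range(image))
  else op
}

#' White top-hat transform
#'
#' The original image minus its morphological opening: non-negative, and
#' responding strongly exactly where bright structures smaller than the
#' structuring element sit -- the morphological signature of
#' microcalcifications.
#'
#' @inheritParams open_image
#' @return non-negative response matrix (class preserved).
#' @export
white_top_hat <- function(image, se) {
  m <- grid_pixels(image)
  op <- grid_pixels(open_image(m, se))
  th <- m - op
  if (inherits(image, "image_grid"))
    image_grid(th, spacing = grid_spacing(image), range = grid_range(image))
  else th
}

#' Extract candidate regions from a top-hat response
#'
#' Binarizes the response (adaptive default: mean + k*sd of the nonzero
#' responses; an absolute threshold is selectable), labels 8-connected
#' components, filters by area, and returns candidates sorted by descending
#' peak response.
#'
#' @param tophat_map non-negative response matrix from [white_top_hat()].
#' @param threshold `"adaptive"` (default) or a numeric absolute threshold.
#' @param k sigma multiplier for the adaptive threshold (default 3).
#' @param min_area,max_area inclusive area filter in pixels.
#' @return data.frame of class `region_candidates` with columns
#'   `id, row, col, r0, c0, r1, c1, area, mean_intensity, score` (centroids
#'   1-based; boxes 0-based half-open).
#' @export
candidate_regions <- function(tophat_map, threshold = "adaptive", k = 3,
                              min_area = 1L, max_area = Inf) {
  m <- grid_pixels(tophat_map)
  if (min(m) < -1e-9) stop("top-hat map must be non-negative")
  thr <- if (identical(threshold, "adaptive")) {
    nz <- m[m > 0]
    if (length(nz) == 0L) Inf else mean(nz) + k * stats::sd(nz)
  } else as.numeric(threshold)
  mask <- m > thr
  empty <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                      r0 = integer(0), c0 = integer(0),
                      r1 = integer(0), c1 = integer(0),
                      area = integer(0), mean_intensity = numeric(0),
                      score = numeric(0))
  class(empty) <- c("region_candidates", "data.frame")
  if (!any(mask) || max_area < min_area || max_area <= 0) return(empty)
  lab <- label_components(mask, connectivity = 8L)
  nlab <- max(lab)
  rows <- vector("list", nlab)
  nr <- nrow(m)
  for (l in seq_len(nlab)) {
    idx <- which(lab == l)
    area <- length(idx)
    if (area < min_area || area > max_area) next
    rr <- (idx - 1L) %% nr + 1L
    cc <- (idx - 1L) %/% nr + 1L
    rows[[l]] <- data.frame(
      id = l, row = mean(rr), col = mean(cc),
      r0 = min(rr) - 1L, c0 = min(cc) - 1L, r1 = max(rr), c1 = max(cc),
      area = area, mean_intensity = mean(m[idx]), score = max(m[idx]))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(empty)
  out <- out[order(-out$score), , drop = FALSE]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("region_candidates", "data.frame")
  out
}

#' Default structuring-element radius from pixel spacing
#'
#' Ties the SE to the largest clinically relevant deposit (1 mm):
#' `ceil(1.0 / spacing / 2) + 1` pixels, so every deposit up to 1 mm is
#' smaller than the element and survives into the top-hat response.
#'
#' @param pixel_spacing mm per pixel.
#' @return integer radius.
#' @export
default_se_radius <- function(pixel_spacing = 0.07) {
  as.integer(ceiling(1.0 / pixel_spacing / 2) + 1L)
}

#' Localization pipeline
#'
#' White top-hat of a preprocessed image with a disk structuring element,
#' followed by candidate-region extraction; also returns an overlay image
#' with candidate bounding boxes burned in at full intensity. By default the
#' response is restricted to the breast interior (foreground eroded by the
#' structuring-element radius): the skin line is a step edge that always
#' rings under the top-hat, and deposits of interest lie within the tissue.
#'
#' @param image preprocessed [image_grid()].
#' @param se_radius disk radius in pixels; default derived from the image's
#'   pixel spacing via [default_se_radius()] (falling back to spacing 0.07).
#' @param mask_foreground zero the top-hat response outside the eroded
#'   foreground (`pixels > 0`) before extracting candidates (default `TRUE`).
#' @param ... passed to [candidate_regions()].
#' @return list with `candidates` (a `region_candidates` data.frame),
#'   `tophat` (response [image_grid()]), and `overlay` ([image_grid()]).
#' @export
localize_pipeline <- function(image, se_radius = NULL, mask_foreground = TRUE,
                              ...) {
  if (is.null(se_radius)) {
    sp <- grid_spacing(image)
    se_radius <- default_se_radius(if (is.null(sp)) 0.07 else sp[1])
  }
  se <- disk_se(se_radius)
  th <- white_top_hat(image, se)
  if (mask_foreground) {
    fg <- grid_pixels(image) > 0
    interior <- !morph_op(!fg, se, pmax)  # binary erosion of the foreground
    thm <- grid_pixels(th)
    thm[!interior] <- 0
    th <- image_grid(thm, spacing = grid_spacing(image),
                     range = grid_range(image))
  }
  cand <- candidate_regions(th, ...)
  ov <- grid_pixels(image)
  hi <- grid_range(image)[2]
  if (nrow(cand)) {
    for (i in seq_len(nrow(cand))) {
      r0 <- cand$r0[i] + 1L; c0 <- cand$c0[i] + 1L
      r1 <- cand$r1[i]; c1 <- cand$c1[i]
      ov[r0, c0:c1] <- hi; ov[r1, c0:c1] <- hi
      ov[r0:r1, c0] <- hi; ov[r0:r1, c1] <- hi
    }
  }
  list(candidates = cand, tophat = th,
       overlay = image_grid(ov, spacing = grid_spacing(image),
                            range = grid_range(image)))
}

#' Write candidates to CSV
#' @param candidates a `region_candidates` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.csv(as.data.frame(candidates)[, c("id", "row", "col", "r0",
                                                 "c0", "r1", "c1", "area",
                                                 "score")],
                   path, row.names = FALSE)
  invisible(path)
}
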