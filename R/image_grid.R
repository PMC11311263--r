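#' Single-channel intensity grid
#'
#' The universal image currency of the package: a numeric matrix of pixel
#' intensities with optional physical pixel spacing and a tracked display
#' range. Intensities are held as reals end-to-end; quantization happens only
#' when a file is written.
#'
#' @param pixels numeric matrix (rows x cols), all values finite.
#' @param spacing pixel spacing in mm per pixel; either a single number or a
#'   `(row, col)` pair. `NULL` if unknown.
#' @param range display range tag, a length-2 numeric `(lo, hi)`; defaults to
#'   `c(0, 1)` if all pixels lie in `[0, 1]`, else `c(0, 255)`.
#' @return an object of class `image_grid`.
#' @examples
#' g <- image_grid(matrix(runif(16), 4), spacing = 0.07)
#' dim(g)
#' @export
image_grid <- function(pixels, spacing = NULL, range = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop("image intensities must all be finite")
  if (is.null(range)) {
    range <- if (max(pixels) <= 1 && min(pixels) >= 0) c(0, 1) else c(0, 255)
  }
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) == 1L) spacing <- c(spacing, spacing)
    stopifnot(length(spacing) == 2L, all(spacing > 0))
  }
  structure(pixels, spacing = spacing, range = as.numeric(range),
            class = c("image_grid", "matrix", "array"))
}

#' @export
as.matrix.image_grid <- function(x, ...) {
  attributes(x) <- list(dim = dim(x))
  x
}

grid_pixels <- function(x) {
  if (inherits(x, "image_grid")) as.matrix(x) else as.matrix(x)
}

grid_spacing <- function(x) attr(x, "spacing", exact = TRUE)

grid_range <- function(x) {
  r <- attr(x, "range", exact = TRUE)
  if (is.null(r)) {
    m <- grid_pixels(x)
    r <- if (max(m) <= 1 && min(m) >= 0) c(0, 1) else c(0, 255)
  }
  r
}

#' @export
print.image_grid <- function(x, ...) {
  sp <- grid_spacing(x)
  cat(sprintf("<image_grid %d x %d px", nrow(x), ncol(x)))
  if (!is.null(sp)) cat(sprintf(", %.4g x %.4g mm/px", sp[1], sp[2]))
  r <- grid_range(x)
  cat(sprintf(", range tag [%g, %g], values [%.4g, %.4g]>\n",
              r[1], r[2], min(x), max(x)))
  invisible(x)
}

#' Three-channel image
#'
#' A false-RGB image: three equally shaped channel grids. Mammograms exported
#' from viewers are often stored this way even when visually grayscale.
#'
#' @param r,g,b numeric matrices of identical shape.
#' @return object of class `rgb_image` (a rows x cols x 3 array).
#' @export
rgb_image <- function(r, g, b) {
  r <- as.matrix(r); g <- as.matrix(g); b <- as.matrix(b)
  if (!identical(dim(r), dim(g)) || !identical(dim(r), dim(b)))
    stop("RGB channels must have identical shapes")
  a <- array(c(r, g, b), dim = c(dim(r), 3L))
  if (!all(is.finite(a))) stop("channel intensities must be finite")
  structure(a, class = c("rgb_image", "array"))
}

# Run code with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Read an image file
#'
#' Reads PNG or TIFF (8/16-bit) into an [image_grid()] (grayscale input) or an
#' [rgb_image()] (color input). Intensities are returned on the file's native
#' scale: `[0, 255]` for 8-bit, `[0, 65535]` rescaled to `[0, 255]` for 16-bit,
#' so one display convention covers both depths.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param spacing optional pixel spacing (mm/px) to attach.
#' @return `image_grid` or `rgb_image`.
#' @export
read_image <- function(path, spacing = NULL) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  a <- a * 255  # readers return [0,1] regardless of stored depth
  if (length(dim(a)) == 2L) {
    image_grid(a, spacing = spacing, range = c(0, 255))
  } else {
    if (dim(a)[3] >= 3L) rgb_image(a[, , 1], a[, , 2], a[, , 3])
    else image_grid(a[, , 1], spacing = spacing, range = c(0, 255))
  }
}

#' Write an image grid to disk
#'
#' Writes 16-bit TIFF (default) or 8-bit PNG. Intensities are mapped from the
#' grid's range tag to the full file depth and rounded half-to-even at write
#' time only.
#'
#' @param image an [image_grid()].
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  m <- grid_pixels(image)
  r <- grid_range(image)
  span <- if (diff(r) > 0) diff(r) else 1
  u <- pmin(pmax((m - r[1]) / span, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(round(u * 255) / 255, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(round(u * 65535) / 65535, where = path,
                    bits.per.sample = 16L, compression = "none")
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

# Zero-padded 'same' cross-correlation (kernel NOT flipped) by shift-and-add.
# Returns the response matrix with a "valid" attribute marking interior pixels
# where no zero padding entered the sum.
xcorr2 <- function(image, kernel) {
  m <- grid_pixels(image)
  k <- as.matrix(kernel)
  kr <- nrow(k); kc <- ncol(k)
  if (nrow(m) < kr || ncol(m) < kc)
    stop(sprintf("image (%d x %d) smaller than kernel (%d x %d)",
                 nrow(m), ncol(m), kr, kc))
  cr <- (kr - 1L) %/% 2L; cc <- (kc - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    dr <- i - 1L - cr
    for (j in seq_len(kc)) {
      w <- k[i, j]
      if (w == 0) next
      dc <- j - 1L - cc
      # out[r, c] += w * m[r + dr, c + dc] for in-bounds source pixels
      rdst <- max(1L, 1L - dr):min(nr, nr - dr)
      cdst <- max(1L, 1L - dc):min(nc, nc - dc)
      out[rdst, cdst] <- out[rdst, cdst] + w * m[rdst + dr, cdst + dc]
    }
  }
  valid <- matrix(FALSE, nr, nc)
  valid[(1L + cr):(nr - (kr - 1L - cr)), (1L + cc):(nc - (kc - 1L - cc))] <- TRUE
  attr(out, "valid") <- valid
  out
}

# Connected-component labeling on a logical mask. connectivity 4 or 8.
# Vectorized frontier flood fill; labels assigned in raster order (row-major,
# origin top-left) of each component's first pixel, so label 1 is the first
# component encountered scanning row by row.
label_components <- function(mask, connectivity = 4L) {
  stopifnot(connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  fg <- fg[order((fg - 1L) %% nr, (fg - 1L) %/% nr)]  # row-major scan order
  offs <- if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  }
  unvisited <- mask
  nextlab <- 0L
  for (start in fg) {
    if (!unvisited[start]) next
    nextlab <- nextlab + 1L
    frontier <- start
    unvisited[start] <- FALSE
    lab[start] <- nextlab
    while (length(frontier) > 0L) {
      fr <- ((frontier - 1L) %% nr) + 1L
      fc <- ((frontier - 1L) %/% nr) + 1L
      nxt <- integer(0)
      for (o in offs) {
        rr <- fr + o[1]; cc <- fc + o[2]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (!any(ok)) next
        idx <- (cc[ok] - 1L) * nr + rr[ok]
        idx <- idx[unvisited[idx]]
        if (length(idx)) {
          unvisited[idx] <- FALSE
          lab[idx] <- nextlab
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}
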