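#' Specification of a synthetic mammographic phantom
#'
#' Defines the geometry, texture, and planted-lesion layout of a synthetic
#' mammogram-like image. Defaults emulate full-field digital mammography:
#' 0.07 mm/px spacing so the clinically relevant 0.1-1 mm deposit diameters map
#' to roughly 1.4-14 px.
#'
#' @param width,height image size in pixels.
#' @param pixel_spacing mm per pixel (default 0.07).
#' @param n_spots number of planted bright deposits (0 for a negative image).
#' @param spot_diameter_range deposit diameter range in mm, within
#'   `[0.05, 2.0]`; default `c(0.1, 1.0)`.
#' @param pattern spatial layout of the deposits: one of `"scattered"`,
#'   `"clustered"`, `"segmental"`, `"linear"`, `"regional"`.
#' @param spot_contrast fractional intensity lift of a deposit peak over its
#'   local background, as a fraction of the dynamic range; in `(0, 1]`.
#' @param tissue_texture_scale correlation length of the background tissue
#'   texture, in pixels.
#' @param add_artifacts if `TRUE`, bright annotation-like blobs are placed in
#'   the background outside the breast.
#' @param seed integer RNG seed; the same spec (including seed) always yields
#'   bit-identical output.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_dataset()]
#' @export
phantom_spec <- function(width = 256L, height = 256L, pixel_spacing = 0.07,
                         n_spots = 5L,
                         spot_diameter_range = c(0.1, 1.0),
                         pattern = c("scattered", "clustered", "segmental",
                                     "linear", "regional"),
                         spot_contrast = 0.5,
                         tissue_texture_scale = 24,
                         add_artifacts = FALSE,
                         seed = 1L) {
  pattern <- match.arg(pattern)
  width <- as.integer(width); height <- as.integer(height)
  n_spots <- as.integer(n_spots)
  if (width <= 0L || height <= 0L) stop("width and height must be positive")
  if (n_spots < 0L) stop("n_spots must be non-negative")
  sdr <- sort(as.numeric(spot_diameter_range))
  if (sdr[1] < 0.05 || sdr[2] > 2.0)
    stop("spot_diameter_range must lie within [0.05, 2.0] mm")
  if (!(spot_contrast > 0 && spot_contrast <= 1))
    stop("spot_contrast must be in (0, 1]")
  if (pixel_spacing <= 0) stop("pixel_spacing must be positive")
  if (tissue_texture_scale <= 0) stop("tissue_texture_scale must be positive")
  structure(list(width = width, height = height, pixel_spacing = pixel_spacing,
                 n_spots = n_spots, spot_diameter_range = sdr,
                 pattern = pattern, spot_contrast = spot_contrast,
                 tissue_texture_scale = tissue_texture_scale,
                 add_artifacts = isTRUE(add_artifacts),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec %d x %d px @ %.3g mm/px, %d %s spot(s), ",
                     "contrast %.2f, seed %d>\n"),
              x$width, x$height, x$pixel_spacing, x$n_spots, x$pattern,
              x$spot_contrast, x$seed))
  invisible(x)
}

# Gaussian low-pass via separable kernel; sigma in pixels.
smooth_noise <- function(nr, nc, sigma) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  # separable filtering with edge replication via padded index clamping
  idx <- function(n, d) pmin(pmax(seq_len(n) + d, 1L), n)
  acc <- matrix(0, nr, nc)
  for (i in seq_along(k)) acc <- acc + k[i] * z[idx(nr, i - half - 1L), ]
  z <- acc
  acc <- matrix(0, nr, nc)
  for (i in seq_along(k)) acc <- acc + k[i] * z[, idx(nc, i - half - 1L)]
  acc
}

# Half-elliptical breast mask flush with the left or right image edge.
breast_mask <- function(h, w, side = c("left", "right")) {
  side <- match.arg(side)
  cy <- (h + 1) / 2
  ry <- 0.46 * h
  rx <- 0.82 * w
  cx <- if (side == "left") 0.5 else w + 0.5
  r <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - cy) / ry)^2 + ((cc - cx) / rx)^2 <= 1
}

# Radially symmetric raised-cosine bump of peak `amp` and radius R px,
# stamped additively at (row, col). Avoids aliasing of hard disks at 1-14 px.
stamp_bump <- function(img, row, col, radius, amp) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1L, floor(row - radius)); r1 <- min(nr, ceiling(row + radius))
  c0 <- max(1L, floor(col - radius)); c1 <- min(nc, ceiling(col + radius))
  rr <- r0:r1; cc <- c0:c1
  d <- sqrt(outer((rr - row)^2, (cc - col)^2, "+"))
  bump <- ifelse(d <= radius, 0.5 * (1 + cos(pi * d / radius)), 0)
  img[rr, cc] <- img[rr, cc] + amp * bump
  img
}

# Sample spot centers for a layout pattern inside an eroded allowed mask.
# Returns a 2-col matrix (row, col) or signals an error after bounded retries.
sample_centers <- function(n, allowed, pattern, max_tries = 400L) {
  ok_idx <- which(allowed)
  if (length(ok_idx) == 0L) stop("spot placement failure: no interior room")
  nr <- nrow(allowed)
  pick_uniform <- function() {
    i <- sample(ok_idx, 1L)
    c((i - 1L) %% nr + 1L, (i - 1L) %/% nr + 1L)
  }
  inside <- function(p) {
    r <- round(p[1]); c <- round(p[2])
    r >= 1 && r <= nr && c >= 1 && c <= ncol(allowed) && allowed[r, c]
  }
  centers <- matrix(NA_real_, n, 2L)
  if (n == 0L) return(centers)
  if (pattern == "scattered") {
    for (i in seq_len(n)) centers[i, ] <- pick_uniform()
    return(centers)
  }
  disp <- 0.08 * min(dim(allowed))   # single dispersion radius parameter
  if (pattern %in% c("clustered", "regional")) {
    radius <- if (pattern == "clustered") disp else 2.5 * disp
    for (t in seq_len(max_tries)) {
      ctr <- pick_uniform()
      got <- 0L
      for (i in seq_len(n)) {
        for (u in seq_len(max_tries)) {
          p <- ctr + runif(2, -radius, radius)
          if (inside(p)) { centers[i, ] <- round(p); got <- got + 1L; break }
        }
      }
      if (got == n) return(centers)
    }
  } else if (pattern == "segmental") {
    # wedge fanning out from an apex
    for (t in seq_len(max_tries)) {
      apex <- pick_uniform()
      base_ang <- runif(1, 0, 2 * pi)
      got <- 0L
      for (i in seq_len(n)) {
        for (u in seq_len(max_tries)) {
          ang <- base_ang + runif(1, -pi / 12, pi / 12)
          rad <- runif(1, 0.2, 1) * 3 * disp
          p <- apex + rad * c(sin(ang), cos(ang))
          if (inside(p)) { centers[i, ] <- round(p); got <- got + 1L; break }
        }
      }
      if (got == n) return(centers)
    }
  } else if (pattern == "linear") {
    # points along a random chord with perpendicular jitter <= 1.5 px
    for (t in seq_len(max_tries)) {
      a <- pick_uniform()
      ang <- runif(1, 0, pi)
      dir <- c(sin(ang), cos(ang))
      perp <- c(-dir[2], dir[1])
      span <- 0.35 * min(dim(allowed))
      s <- sort(runif(n, -span / 2, span / 2))
      got <- 0L
      for (i in seq_len(n)) {
        p <- a + s[i] * dir + runif(1, -1.5, 1.5) * perp
        if (inside(p)) { centers[i, ] <- round(p); got <- got + 1L }
      }
      if (got == n) return(centers)
    }
  }
  stop(sprintf("spot placement failure: pattern '%s' infeasible for geometry",
               pattern))
}

#' Generate a synthetic mammographic phantom
#'
#' Builds a half-elliptical breast-shaped foreground of low-pass-filtered
#' tissue texture on a zero background and plants `n_spots` bright
#' raised-cosine deposits with known centers, diameters, and contrast. The
#' result is the ground-truth test bed for every downstream stage.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `image` (an [image_grid()] on the `[0, 1]`
#'   range) and `truth`, a `phantom_truth` list carrying `label`
#'   (`"positive"`/`"negative"`), `spots` (data.frame `row, col, diameter_px,
#'   contrast`), `artifact_boxes` (data.frame of half-open boxes `r0, c0, r1,
#'   c1`, 0-based), and the breast `mask`.
#' @examples
#' p <- generate_phantom(phantom_spec(n_spots = 3, seed = 42))
#' p$truth$spots
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    side <- if (runif(1) < 0.5) "left" else "right"
    mask <- breast_mask(h, w, side)
    tex <- smooth_noise(h, w, spec$tissue_texture_scale)
    s <- stats::sd(tex)
    if (s > 0) tex <- tex / s
    img <- matrix(0, h, w)
    img[mask] <- 0.45 + 0.08 * tex[mask]   # mid-gray tissue, mild texture
    img <- pmin(pmax(img, 0), 1)

    diam_px <- numeric(0)
    centers <- matrix(NA_real_, 0, 2)
    if (spec$n_spots > 0L) {
      diam_mm <- runif(spec$n_spots, spec$spot_diameter_range[1],
                       spec$spot_diameter_range[2])
      diam_px <- diam_mm / spec$pixel_spacing
      margin <- ceiling(max(diam_px) / 2) + 2L
      allowed <- erode_mask(mask, margin)
      centers <- sample_centers(spec$n_spots, allowed, spec$pattern)
      for (i in seq_len(spec$n_spots)) {
        img <- stamp_bump(img, centers[i, 1], centers[i, 2],
                          radius = diam_px[i] / 2, amp = spec$spot_contrast)
      }
      img <- pmin(img, 1)
    }

    boxes <- empty_boxes()
    if (spec$add_artifacts) {
      art <- place_artifacts(img, mask, seed = NULL)
      img <- art$image
      boxes <- art$boxes
    }

    truth <- structure(list(
      label = if (spec$n_spots > 0L) "positive" else "negative",
      spots = data.frame(row = centers[, 1], col = centers[, 2],
                         diameter_px = diam_px,
                         contrast = rep(spec$spot_contrast,
                                        length(diam_px))),
      artifact_boxes = boxes,
      mask = mask
    ), class = "phantom_truth")
    list(image = image_grid(img, spacing = spec$pixel_spacing,
                            range = c(0, 1)),
         truth = truth)
  })
}

# Binary erosion of a mask by a square margin (cheap, used only for placement).
erode_mask <- function(mask, margin) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- function(n, d) pmin(pmax(seq_len(n) + d, 1L), n)
  for (d in seq_len(margin)) {
    out <- out & mask[idx(nr, d), ] & mask[idx(nr, -d), ] &
           mask[, idx(nc, d)] & mask[, idx(nc, -d)]
  }
  # also blank the image border so bumps stay fully inside
  out[c(seq_len(margin), nr - seq_len(margin) + 1L), ] <- FALSE
  out[, c(seq_len(margin), nc - seq_len(margin) + 1L)] <- FALSE
  out
}

empty_boxes <- function() {
  data.frame(r0 = integer(0), c0 = integer(0),
             r1 = integer(0), c1 = integer(0))
}

# Shared artifact placer: 1-3 bright text-like blobs fully outside the breast.
place_artifacts_impl <- function(img, mask) {
  nr <- nrow(img); nc <- ncol(img)
  free <- !mask
  boxes <- empty_boxes()
  n_art <- sample(1:3, 1L)
  for (k in seq_len(n_art)) {
    bh <- sample(4:8, 1L); bw <- sample(10:20, 1L)
    for (t in 1:200) {
      r0 <- sample(seq_len(max(1L, nr - bh)), 1L)
      c0 <- sample(seq_len(max(1L, nc - bw)), 1L)
      rr <- r0:(r0 + bh - 1L); cc <- c0:(c0 + bw - 1L)
      if (max(rr) > nr || max(cc) > nc) next
      if (all(free[rr, cc])) {
        # dashed bright strokes, mimicking annotation text
        stroke <- matrix(runif(bh * bw) < 0.6, bh, bw)
        blk <- img[rr, cc]
        blk[stroke] <- 0.95
        img[rr, cc] <- blk
        boxes <- rbind(boxes, data.frame(r0 = r0 - 1L, c0 = c0 - 1L,
                                         r1 = r0 + bh - 1L,
                                         c1 = c0 + bw - 1L))
        break
      }
    }
  }
  list(image = img, boxes = boxes)
}

place_artifacts <- function(img, mask, seed) {
  if (is.null(seed)) place_artifacts_impl(img, mask)
  else with_seed(seed, place_artifacts_impl(img, mask))
}

#' Add annotation-like artifacts to an image
#'
#' Places 1-3 bright text-like blobs in background (zero-valued) regions
#' outside the breast foreground, emulating the scanner/annotation marks that
#' preprocessing must remove. A no-op returning zero boxes if there is no
#' background room.
#'
#' @param image an [image_grid()] whose background is (near-)zero.
#' @param seed integer seed; same seed, same boxes.
#' @param fg_threshold intensity above which a pixel counts as foreground when
#'   deriving the keep-out mask.
#' @return list with `image` (artifacts burned in) and `boxes` (data.frame of
#'   0-based half-open bounding boxes `r0, c0, r1, c1`).
#' @export
add_artifacts <- function(image, seed, fg_threshold = 0) {
  m <- grid_pixels(image)
  mask <- m > fg_threshold
  # keep-out margin of 2 px around the foreground
  grown <- mask
  idx <- function(n, d) pmin(pmax(seq_len(n) + d, 1L), n)
  for (d in 1:2) {
    grown <- grown | mask[idx(nrow(m), d), ] | mask[idx(nrow(m), -d), ] |
             mask[, idx(ncol(m), d)] | mask[, idx(ncol(m), -d)]
  }
  if (all(grown)) {
    return(list(image = image, boxes = empty_boxes()))
  }
  res <- place_artifacts(m, grown, seed = seed)
  list(image = image_grid(res$image, spacing = grid_spacing(image),
                          range = grid_range(image)),
       boxes = res$boxes)
}

#' Generate a labeled phantom dataset on disk
#'
#' Writes `n_pos` positive and `n_neg` negative phantoms as 16-bit TIFF images
#' with per-image JSON truth sidecars and a manifest CSV
#' (`path,label,seed,n_spots`). Per-image seeds are derived deterministically
#' from `seed`, so a rerun reproduces identical files.
#'
#' @param n_pos,n_neg class counts (each >= 0).
#' @param spec_template a [phantom_spec()] supplying everything but the label
#'   and per-image seed; negatives reuse it with `n_spots = 0`.
#' @param out_dir output directory (created if needed).
#' @param seed base integer seed.
#' @return the manifest as a data.frame (also written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
generate_dataset <- function(n_pos, n_neg, spec_template = phantom_spec(),
                             out_dir, seed = 1L) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- list()
  labels <- c(rep("positive", n_pos), rep("negative", n_neg))
  for (i in seq_along(labels)) {
    s <- spec_template
    s$seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    if (labels[i] == "negative") s$n_spots <- 0L
    ph <- generate_phantom(s)
    stem <- sprintf("phantom_%03d_%s", i, substr(labels[i], 1, 3))
    img_path <- file.path(out_dir, paste0(stem, ".tiff"))
    write_image(ph$image, img_path)
    truth <- ph$truth
    truth$mask <- NULL  # geometry recoverable from the spec; keep sidecars small
    jsonlite::write_json(unclass(truth), file.path(out_dir, paste0(stem, ".json")),
                         auto_unbox = TRUE, digits = NA)
    rows[[i]] <- data.frame(path = img_path, label = labels[i],
                            seed = s$seed, n_spots = s$n_spots)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(0), label = character(0),
               seed = integer(0), n_spots = integer(0))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
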