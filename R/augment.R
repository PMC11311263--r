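#' Geometric augmentation plan
#'
#' The default plan mirrors the augmentation recipe used for mammogram class
#' balancing: scale factors 0.8/1.0/1.2, right-angle rotations 90/180/270, and
#' both reflections. Each transform is applied to the original independently
#' (no compositions); the identity scale 1.0 emits nothing extra.
#'
#' @param scales positive scale factors.
#' @param angles rotation angles in degrees (multiples of 90 for exact mode).
#' @param reflections subset of `c("horizontal", "vertical")`.
#' @return object of class `augment_plan`.
#' @export
augment_plan <- function(scales = c(0.8, 1.0, 1.2),
                         angles = c(90, 180, 270),
                         reflections = c("horizontal", "vertical")) {
  if (any(scales <= 0)) stop("scale factors must be positive")
  if (length(reflections))
    reflections <- match.arg(reflections, c("horizontal", "vertical"),
                             several.ok = TRUE)
  structure(list(scales = scales, angles = angles, reflections = reflections),
            class = "augment_plan")
}

#' Scale an image about its center on a fixed canvas
#'
#' Bilinear scaling by `(sx, sy)` (columns, rows), then recentering on a
#' canvas of the original size with zero padding (or center cropping when the
#' factor exceeds 1), so downstream input shapes stay constant.
#'
#' @param image an [image_grid()].
#' @param sx,sy positive scale factors along x (columns) and y (rows).
#' @return scaled [image_grid()] of the original size.
#' @export
scale_image <- function(image, sx, sy = sx) {
  if (sx <= 0 || sy <= 0) stop("scale factors must be positive")
  m <- grid_pixels(image)
  nr <- nrow(m); nc <- ncol(m)
  nr2 <- max(1L, round(nr * sy)); nc2 <- max(1L, round(nc * sx))
  s <- if (nr2 == nr && nc2 == nc) m
       else EBImage::resize(m, w = nr2, h = nc2, filter = "bilinear")
  out <- matrix(0, nr, nc)
  # copy the centered overlap between scaled content and fixed canvas
  ro <- (nr - nr2) %/% 2L; co <- (nc - nc2) %/% 2L
  rdst <- max(1L, 1L + ro):min(nr, nr2 + ro)
  cdst <- max(1L, 1L + co):min(nc, nc2 + co)
  out[rdst, cdst] <- s[rdst - ro, cdst - co]
  image_grid(out, spacing = grid_spacing(image), range = grid_range(image))
}

rot90_ccw <- function(m) {
  t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
}

#' Rotate an image
#'
#' Right angles (90/180/270, counter-clockwise positive, about the image
#' center) are exact pixel permutations. Arbitrary angles fall back to
#' bilinear interpolation with the output center-cropped/padded to the input
#' size.
#'
#' @param image an [image_grid()] or plain matrix.
#' @param angle_degrees rotation angle.
#' @return rotated image of the same class and size (size preserved exactly
#'   for right angles on square images; for non-square inputs 90/270 swap the
#'   dimensions, as a pure permutation must).
#' @export
rotate_image <- function(image, angle_degrees) {
  m <- grid_pixels(image)
  a <- angle_degrees %% 360
  out <- if (a == 0) m
  else if (a == 90) rot90_ccw(m)
  else if (a == 180) rot90_ccw(rot90_ccw(m))
  else if (a == 270) rot90_ccw(rot90_ccw(rot90_ccw(m)))
  else {
    r <- EBImage::rotate(m, angle = -a, filter = "bilinear",
                         output.dim = dim(m), bg.col = 0)
    as.matrix(r)
  }
  if (inherits(image, "image_grid"))
    image_grid(out, spacing = grid_spacing(image), range = grid_range(image))
  else out
}

#' Reflect an image
#'
#' Exact pixel permutations: `"horizontal"` mirrors left-right (column flip,
#' `I'(x, y) = I(W - x, y)`); `"vertical"` mirrors top-bottom (row flip,
#' `I'(x, y) = I(x, H - y)`).
#'
#' @param image an [image_grid()] or matrix.
#' @param axis `"horizontal"` or `"vertical"`.
#' @return reflected image of the same class and size.
#' @export
reflect_image <- function(image, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  m <- grid_pixels(image)
  out <- if (axis == "horizontal") m[, rev(seq_len(ncol(m))), drop = FALSE]
         else m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (inherits(image, "image_grid"))
    image_grid(out, spacing = grid_spacing(image), range = grid_range(image))
  else out
}

#' Expand a manifest with augmented images
#'
#' Reads each manifest image, applies every transform in the plan to the
#' original independently, writes the results next to the originals (suffix
#' per transform), and returns a manifest with provenance columns
#' (`source_id`, `transform`). Labels are inherited.
#'
#' @param manifest data.frame with at least `path` and `label` columns (as
#'   written by [generate_dataset()]).
#' @param plan an [augment_plan()].
#' @param out_dir directory for augmented images; defaults to the source
#'   directory.
#' @return augmented manifest data.frame with columns
#'   `path,label,source_id,transform`.
#' @export
augment_set <- function(manifest, plan = augment_plan(), out_dir = NULL) {
  stopifnot(all(c("path", "label") %in% names(manifest)))
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    src <- manifest$path[i]
    if (!file.exists(src)) stop("unreadable image: ", src)
    img <- read_image(src)
    if (inherits(img, "rgb_image")) img <- to_grayscale(img)
    stem <- tools::file_path_sans_ext(src)
    ext <- tools::file_ext(src)
    dir <- if (is.null(out_dir)) dirname(src) else out_dir
    if (!is.null(out_dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    stem <- file.path(dir, basename(stem))
    emit <- function(im, tag) {
      p <- paste0(stem, "_", tag, ".", ext)
      write_image(im, p)
      data.frame(path = p, label = manifest$label[i],
                 source_id = i, transform = tag)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(path = src, label = manifest$label[i],
                 source_id = i, transform = "original")
    for (s in plan$scales) {
      if (s == 1.0) next  # identity scale emits nothing extra
      rows[[length(rows) + 1L]] <- emit(scale_image(img, s, s),
                                        sprintf("scale%0.2f", s))
    }
    for (a in plan$angles)
      rows[[length(rows) + 1L]] <- emit(rotate_image(img, a),
                                        sprintf("rot%03d", as.integer(a)))
    for (ax in plan$reflections)
      rows[[length(rows) + 1L]] <- emit(reflect_image(img, ax),
                                        paste0("flip_", substr(ax, 1, 1)))
  }
  do.call(rbind, rows)
}

round_half_up <- function(x) floor(x + 0.5)

#' Deterministic stratified train/validation/test split
#'
#' Per class, `train = round(n * 0.70)` and `val = round(n * 0.20)` under
#' round-half-up, with the remainder going to test -- the only rounding
#' convention consistent with a 70/20/10 split of 2748 positives into
#' 1924/550/274 and 2942 negatives into 2059/588/295. Assignment within a
#' class is a seeded shuffle sliced into the three blocks, so the same seed
#' always reproduces the same membership.
#'
#' @param n_per_class named integer vector of class sizes, or a manifest
#'   data.frame with a `label` column.
#' @param fractions `(train, val, test)` fractions summing to 1.
#' @param seed integer seed for the shuffles.
#' @return If given counts: a list with `counts` (classes x
#'   train/val/test matrix) and `assignment` (per class, a factor of
#'   `train/val/test` over that class's indices). If given a manifest: the
#'   manifest with a `split` column appended.
#' @examples
#' stratified_split(c(positive = 2748, negative = 2942), seed = 1)$counts
#' @export
stratified_split <- function(n_per_class, fractions = c(0.70, 0.20, 0.10),
                             seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0))
    stop("fractions must be non-negative and sum to 1")
  if (is.data.frame(n_per_class)) {
    manifest <- n_per_class
    stopifnot("label" %in% names(manifest))
    counts <- table(manifest$label)
    res <- stratified_split(stats::setNames(as.integer(counts), names(counts)),
                            fractions, seed)
    manifest$split <- NA_character_
    for (cl in names(res$assignment)) {
      idx <- which(manifest$label == cl)
      manifest$split[idx] <- as.character(res$assignment[[cl]])
    }
    return(manifest)
  }
  n_per_class <- stats::setNames(as.integer(n_per_class),
                                 names(n_per_class) %||%
                                   paste0("class", seq_along(n_per_class)))
  counts <- matrix(0L, length(n_per_class), 3L,
                   dimnames = list(names(n_per_class),
                                   c("train", "val", "test")))
  assignment <- list()
  for (k in seq_along(n_per_class)) {
    n <- n_per_class[k]
    tr <- as.integer(round_half_up(n * fractions[1]))
    va <- as.integer(round_half_up(n * fractions[2]))
    te <- n - tr - va
    if (n > 0L && te < 0L)
      stop("degenerate split: class too small for the requested fractions")
    if (n >= 1L && n < 3L && all(fractions > 0))
      stop("degenerate split: need at least 3 items per class")
    counts[k, ] <- c(tr, va, te)
    perm <- with_seed(seed + k - 1L, sample.int(n))
    splits <- rep(c("train", "val", "test"), times = c(tr, va, te))
    out <- character(n)
    out[perm] <- splits
    assignment[[names(n_per_class)[k]]] <-
      factor(out, levels = c("train", "val", "test"))
  }
  list(counts = counts, assignment = assignment)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
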