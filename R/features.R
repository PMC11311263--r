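#' Prewitt kernel pair
#'
#' The 3x3 horizontal- and vertical-gradient Prewitt kernels. Entries are in
#' `{-1, 0, 1}`; the x kernel differences columns (responds to horizontal
#' intensity change), the y kernel differences rows.
#'
#' @return list with matrices `prewitt_x` and `prewitt_y`.
#' @export
prewitt_kernels <- function() {
  list(
    prewitt_x = matrix(c(-1, 0, 1,
                         -1, 0, 1,
                         -1, 0, 1), 3, 3, byrow = TRUE),
    prewitt_y = matrix(c(-1, -1, -1,
                          0,  0,  0,
                          1,  1,  1), 3, 3, byrow = TRUE)
  )
}

# The five canonical 5x5 Gabor matrices, one per orientation. These printed
# matrices are treated as authoritative fixtures: they are not reproducible
# from the Gabor closed form with any single parameter setting (the 0-degree
# matrix is radially symmetric and the 180-degree one differs from it), so
# canonical mode ships them verbatim rather than regenerating them.
canonical_gabor <- function() {
  g0 <- matrix(c(
    0.1105, 0.2368, 0.2921, 0.2368, 0.1105,
    0.2368, 0.5101, 0.6291, 0.5101, 0.2368,
    0.2921, 0.6291, 0.7726, 0.6291, 0.2921,
    0.2368, 0.5101, 0.6291, 0.5101, 0.2368,
    0.1105, 0.2368, 0.2921, 0.2368, 0.1105), 5, 5, byrow = TRUE)
  g45 <- matrix(c(
    0.0000, 0.0000, 0.1105, 0.2368, 0.1105,
    0.0000, 0.0000, 0.2368, 0.5101, 0.2368,
    0.1105, 0.2368, 0.5101, 0.6291, 0.2921,
    0.2368, 0.5101, 0.6291, 0.5101, 0.2368,
    0.1105, 0.2368, 0.2921, 0.2368, 0.1105), 5, 5, byrow = TRUE)
  g90 <- matrix(c(
    -0.1105, -0.2368, 0.0000, 0.2368, 0.1105,
    -0.2368, -0.5101, 0.0000, 0.5101, 0.2368,
     0.0000,  0.0000, 0.0000, 0.0000, 0.0000,
     0.2368,  0.5101, 0.0000, 0.5101, 0.2368,
     0.1105,  0.2368, 0.0000, 0.2368, 0.1105), 5, 5, byrow = TRUE)
  g135 <- matrix(c(
     0.1105,  0.2368, 0.2921, 0.2368, 0.1105,
     0.2368,  0.5101, 0.6291, 0.5101, 0.2368,
     0.0000,  0.0000, 0.0000, 0.0000, 0.0000,
    -0.2368, -0.5101, 0.0000, 0.5101, 0.2368,
    -0.1105, -0.2368, 0.0000, 0.2368, 0.1105), 5, 5, byrow = TRUE)
  g180 <- matrix(c(
     0.1105,  0.2368, 0.2921, 0.2368, 0.1105,
     0.2368,  0.5101, 0.6291, 0.5101, 0.2368,
     0.1105,  0.2368, 0.2921, 0.2368, 0.1105,
     0.0000,  0.0000, 0.0000, 0.0000, 0.0000,
    -0.1105, -0.2368, 0.0000, 0.2368, 0.1105), 5, 5, byrow = TRUE)
  list(`0` = g0, `45` = g45, `90` = g90, `135` = g135, `180` = g180)
}

#' Build the Gabor filter bank
#'
#' `"canonical"` mode (the default) returns the five fixed 5x5 orientation
#' matrices (0, 45, 90, 135, 180 degrees) used throughout the pipeline.
#' `"parametric"` mode evaluates the Gabor closed form
#' `exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * cos(2 pi x' / lambda + psi)`
#' with `x' = x cos(theta) + y sin(theta)`, `y' = -x sin(theta) + y cos(theta)`
#' on the integer grid -2..2, at wavelength `lambda = 1/0.625` (a spatial
#' frequency of 0.625, matched to the ~1 mm deposit scale) and configurable
#' envelope; it is an approximate, exploratory alternative and does not
#' reproduce the canonical matrices.
#'
#' @param mode `"canonical"` or `"parametric"`.
#' @param sigma,gamma,psi parametric-mode Gaussian envelope width, aspect
#'   ratio, and phase offset.
#' @param frequency parametric-mode spatial frequency (`lambda = 1/frequency`).
#' @return a `kernel_bank`: list with `prewitt_x`, `prewitt_y`, `gabor` (five
#'   matrices keyed `"0", "45", "90", "135", "180"`), and `mode`.
#' @export
build_gabor_bank <- function(mode = c("canonical", "parametric"),
                             sigma = 2, gamma = 0.5, psi = 0,
                             frequency = 0.625) {
  mode <- match.arg(mode)
  pk <- prewitt_kernels()
  gab <- if (mode == "canonical") canonical_gabor() else {
    lambda <- 1 / frequency
    thetas <- c(0, 45, 90, 135, 180)
    out <- lapply(thetas, function(th) {
      t <- th * pi / 180
      x <- matrix(-2:2, 5, 5, byrow = TRUE)   # x: column offset
      y <- matrix(-2:2, 5, 5)                 # y: row offset
      xp <- x * cos(t) + y * sin(t)
      yp <- -x * sin(t) + y * cos(t)
      exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) *
        cos(2 * pi * xp / lambda + psi)
    })
    names(out) <- as.character(thetas)
    out
  }
  structure(list(prewitt_x = pk$prewitt_x, prewitt_y = pk$prewitt_y,
                 gabor = gab, mode = mode),
            class = "kernel_bank")
}

#' @export
print.kernel_bank <- function(x, ...) {
  cat(sprintf("<kernel_bank: Prewitt pair + %d Gabor orientations (%s mode)>\n",
              length(x$gabor), x$mode))
  invisible(x)
}

#' Save / load a kernel bank
#'
#' JSON serialization at full double precision, so the canonical bank
#' round-trips bit-exactly.
#'
#' @param bank a `kernel_bank`.
#' @param path file path.
#' @return `write_kernel_bank` returns `path` invisibly; `read_kernel_bank`
#'   returns the `kernel_bank`.
#' @export
write_kernel_bank <- function(bank, path) {
  payload <- list(mode = bank$mode,
                  prewitt_x = bank$prewitt_x, prewitt_y = bank$prewitt_y,
                  gabor = bank$gabor)
  jsonlite::write_json(payload, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_kernel_bank
#' @export
read_kernel_bank <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_dbl <- function(m) { m <- as.matrix(m); storage.mode(m) <- "double"; m }
  structure(list(prewitt_x = as_dbl(p$prewitt_x),
                 prewitt_y = as_dbl(p$prewitt_y),
                 gabor = lapply(p$gabor, as_dbl), mode = p$mode),
            class = "kernel_bank")
}

#' Prewitt edge responses
#'
#' Cross-correlation (filter convention, kernel not flipped) of the image with
#' the Prewitt pair; 'same'-size output via zero padding, with the border ring
#' flagged invalid in each map's `"valid"` attribute.
#'
#' @param image an [image_grid()] or matrix, at least 3x3.
#' @return list of matrices `map_x`, `map_y`, each with a logical `"valid"`
#'   attribute.
#' @export
prewitt_response <- function(image) {
  pk <- prewitt_kernels()
  list(map_x = xcorr2(image, pk$prewitt_x),
       map_y = xcorr2(image, pk$prewitt_y))
}

#' Gabor orientation responses
#'
#' Cross-correlates the image with each of the bank's five Gabor matrices;
#' 'same'-size zero-padded outputs ordered by ascending orientation.
#'
#' @param image an [image_grid()] or matrix, at least 5x5.
#' @param bank a `kernel_bank` from [build_gabor_bank()].
#' @return named list of five response matrices (`"0"` ... `"180"`).
#' @export
gabor_responses <- function(image, bank = build_gabor_bank()) {
  lapply(bank$gabor, function(k) xcorr2(image, k))
}

#' Gray-level co-occurrence matrix of a window
#'
#' Quantizes the window to `levels` gray levels by uniform binning over its
#' min-max span, then counts ordered pixel pairs at offset
#' `(dcol, drow) = d * (cos(theta), -sin(theta))` (rounded to integers), i.e.
#' theta = 0 pairs each pixel with its right neighbor and theta = 90 with the
#' pixel above.
#'
#' @param window numeric matrix.
#' @param levels number of gray levels G.
#' @param d pair distance (>= 1).
#' @param theta angle in degrees, one of 0, 45, 90, 135.
#' @param symmetric if `TRUE`, counts are symmetrized (pairs counted in both
#'   directions); off by default.
#' @return a `glcm` object: integer G x G `counts` matrix with attributes
#'   `levels`, `d`, `theta`, `offset`.
#' @export
glcm_compute <- function(window, levels = 8L, d = 1L, theta = 0,
                         symmetric = FALSE) {
  stopifnot(d >= 1, theta %in% c(0, 45, 90, 135))
  m <- grid_pixels(window)
  q <- quantize_levels(m, levels)
  dc <- as.integer(round(d * cos(theta * pi / 180)))
  dr <- as.integer(round(-d * sin(theta * pi / 180)))
  nr <- nrow(m); nc <- ncol(m)
  rsrc <- seq_len(nr); csrc <- seq_len(nc)
  rsrc <- rsrc[rsrc + dr >= 1L & rsrc + dr <= nr]
  csrc <- csrc[csrc + dc >= 1L & csrc + dc <= nc]
  if (length(rsrc) == 0L || length(csrc) == 0L)
    stop("window smaller than the requested offset")
  i <- q[rsrc, csrc, drop = FALSE]
  j <- q[rsrc + dr, csrc + dc, drop = FALSE]
  counts <- matrix(tabulate((i - 1L) * levels + j, nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  structure(counts, levels = as.integer(levels), d = as.integer(d),
            theta = theta, offset = c(dcol = dc, drow = dr),
            class = c("glcm", "matrix", "array"))
}

# Uniform quantization to 1..levels over the window's min-max span; a constant
# window maps entirely to bin 1.
quantize_levels <- function(m, levels) {
  lo <- min(m); hi <- max(m)
  if (hi <= lo) return(matrix(1L, nrow(m), ncol(m)))
  q <- floor((m - lo) / (hi - lo) * levels) + 1L
  q[q > levels] <- as.integer(levels)
  storage.mode(q) <- "integer"
  q
}

#' Haralick features of a GLCM
#'
#' Normalizes the counts to probabilities and evaluates the four standard
#' texture statistics: contrast `sum p (i-j)^2`, correlation
#' `sum p (i - mu_i)(j - mu_j) / (sigma_i sigma_j)` (defined as 0 when either
#' marginal variance is 0), energy `sum p^2`, homogeneity
#' `sum p / (1 + |i-j|)`.
#'
#' @param glcm a `glcm` from [glcm_compute()] or a plain non-negative counts
#'   matrix.
#' @return named list `contrast`, `correlation`, `energy`, `homogeneity`.
#' @export
glcm_features <- function(glcm) {
  counts <- unclass(glcm)
  attributes(counts) <- list(dim = dim(counts))
  tot <- sum(counts)
  if (tot <= 0) stop("GLCM has all-zero counts")
  p <- counts / tot
  g <- nrow(p)
  i <- matrix(seq_len(g), g, g)
  j <- matrix(seq_len(g), g, g, byrow = TRUE)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  var_i <- sum(p * (i - mu_i)^2); var_j <- sum(p * (j - mu_j)^2)
  corr <- if (var_i > 0 && var_j > 0)
    sum(p * (i - mu_i) * (j - mu_j)) / sqrt(var_i * var_j) else 0
  list(contrast = sum(p * (i - j)^2),
       correlation = corr,
       energy = sum(p^2),
       homogeneity = sum(p / (1 + abs(i - j))))
}

#' Sliding-window GLCM texture map
#'
#' Evaluates a windowed GLCM texture feature over the image: at each stride
#' position, counts are pooled over the four offsets (0, 45, 90, 135 degrees)
#' at distance `d` on an 8-level quantization of the window, the chosen
#' Haralick feature is computed, and the coarse feature grid is bilinearly
#' upsampled back to the image size.
#'
#' @param image an [image_grid()] or matrix.
#' @param window_side odd window side in pixels (default 17).
#' @param stride sampling stride in pixels (default 8).
#' @param feature one of `"contrast"`, `"correlation"`, `"energy"`,
#'   `"homogeneity"` (default contrast).
#' @param levels,d quantization levels and pair distance.
#' @return a matrix of the image's size.
#' @export
glcm_texture_map <- function(image, window_side = 17L, stride = 8L,
                             feature = c("contrast", "correlation", "energy",
                                         "homogeneity"),
                             levels = 8L, d = 1L) {
  feature <- match.arg(feature)
  m <- grid_pixels(image)
  ws <- as.integer(window_side)
  if (ws %% 2L == 0L) stop("window_side must be odd")
  if (ws > nrow(m) || ws > ncol(m)) stop("window larger than image")
  half <- ws %/% 2L
  rc <- seq(half + 1L, nrow(m) - half, by = stride)
  cc <- seq(half + 1L, ncol(m) - half, by = stride)
  coarse <- matrix(0, length(rc), length(cc))
  for (a in seq_along(rc)) {
    for (b in seq_along(cc)) {
      win <- m[(rc[a] - half):(rc[a] + half), (cc[b] - half):(cc[b] + half)]
      pooled <- matrix(0L, levels, levels)
      for (th in c(0, 45, 90, 135))
        pooled <- pooled + unclass(glcm_compute(win, levels = levels,
                                                d = d, theta = th))
      coarse[a, b] <- glcm_features(pooled)[[feature]]
    }
  }
  if (length(rc) == 1L && length(cc) == 1L)
    return(matrix(coarse[1, 1], nrow(m), ncol(m)))
  EBImage::resize(coarse, w = nrow(m), h = ncol(m), filter = "bilinear")
}

feature_channel_names <- function() {
  c("prewitt_x", "prewitt_y", "gabor_0", "gabor_45", "gabor_90",
    "gabor_135", "gabor_180", "glcm_texture")
}

#' Assemble the 8-channel classifier input
#'
#' Computes the hybrid descriptive stack at full resolution -- 2 Prewitt edge
#' maps, 5 Gabor orientation responses, 1 windowed GLCM texture map -- then
#' min-max normalizes each channel to `[0, 1]` (a constant channel maps to 0),
#' bilinearly downsamples each to `out_side`, and concatenates in the fixed
#' order `prewitt_x, prewitt_y, gabor_0, gabor_45, gabor_90, gabor_135,
#' gabor_180, glcm_texture`. The default `out_side = 508` pairs a 1024x1024
#' preprocessed image with the classifier's default 508x508x8 input.
#'
#' @param image a preprocessed [image_grid()] or matrix.
#' @param out_side output side per channel (default 508).
#' @param bank kernel bank (default canonical).
#' @param glcm_window,glcm_stride windowed-GLCM parameters.
#' @return a `feature_stack`: `out_side x out_side x 8` array with channel
#'   dimnames.
#' @export
assemble_feature_stack <- function(image, out_side = 508L,
                                   bank = build_gabor_bank(),
                                   glcm_window = 17L, glcm_stride = 8L) {
  m <- grid_pixels(image)
  pw <- prewitt_response(m)
  gb <- gabor_responses(m, bank)
  gl <- glcm_texture_map(m, window_side = glcm_window, stride = glcm_stride)
  chans <- c(list(pw$map_x, pw$map_y), unname(gb), list(gl))
  norm01 <- function(x) {
    x <- unclass(x); attributes(x) <- list(dim = dim(x))
    lo <- min(x); hi <- max(x)
    if (hi <= lo) return(matrix(0, nrow(x), ncol(x)))
    (x - lo) / (hi - lo)
  }
  out_side <- as.integer(out_side)
  stack <- array(0, dim = c(out_side, out_side, 8L),
                 dimnames = list(NULL, NULL, feature_channel_names()))
  for (k in seq_along(chans)) {
    ch <- norm01(chans[[k]])
    if (!(nrow(ch) == out_side && ncol(ch) == out_side))
      ch <- EBImage::resize(ch, w = out_side, h = out_side,
                            filter = "bilinear")
    stack[, , k] <- pmin(pmax(ch, 0), 1)
  }
  structure(stack, class = c("feature_stack", "array"))
}
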