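test_that("grayscale conversion applies the luminance weights exactly", {
  z <- matrix(0, 2, 2)
  black <- to_grayscale(rgb_image(z, z, z))
  expect_true(all(black == 0))

  red <- to_grayscale(rgb_image(matrix(255, 1, 1), matrix(0, 1, 1),
                                matrix(0, 1, 1)))
  expect_equal(red[1, 1], 76.2195)

  white <- to_grayscale(rgb_image(matrix(255, 1, 1), matrix(255, 1, 1),
                                  matrix(255, 1, 1)))
  expect_equal(white[1, 1], 254.9745)  # the three weights sum to 0.9999
})

test_that("grayscale conversion is linear in the input", {
  set.seed(42)
  r <- matrix(runif(64, 0, 255), 8); g <- matrix(runif(64, 0, 255), 8)
  b <- matrix(runif(64, 0, 255), 8)
  g1 <- as.matrix(to_grayscale(rgb_image(r, g, b)))
  g2 <- as.matrix(to_grayscale(rgb_image(0.5 * r, 0.5 * g, 0.5 * b)))
  expect_equal(g2, 0.5 * g1, tolerance = 1e-12)
  expect_error(to_grayscale(rgb_image(r, g, matrix(0, 4, 4))), "shape")
})

test_that("resizing preserves identity, constancy, and physical extent", {
  m <- image_grid(matrix(runif(32 * 32), 32), spacing = 0.1)
  same <- resize_to_standard(m, side = 32L)
  expect_equal(as.matrix(same), as.matrix(m))

  const <- resize_to_standard(image_grid(matrix(3.7, 40, 40),
                                         range = c(0, 255)), side = 20L)
  expect_equal(as.matrix(const), matrix(3.7, 20, 20), tolerance = 1e-9)

  up <- resize_to_standard(image_grid(matrix(runif(16 * 16), 16),
                                      spacing = 0.1), side = 32L)
  expect_equal(attr(up, "spacing"), c(0.05, 0.05))
})

test_that("intensity windowing is monotone and maps bounds to extremes", {
  img <- image_grid(matrix(seq(0, 255, length.out = 256), 16),
                    range = c(0, 255))
  w <- voi_window(img, center = 127.5, width = 255)
  expect_equal(min(w), 0)
  expect_equal(max(w), 255)
  v <- as.vector(as.matrix(w))[order(as.vector(as.matrix(img)))]
  expect_true(all(diff(v) >= -1e-9))
  # a value exactly at the center maps to half the range
  mid <- voi_window(image_grid(matrix(50, 1, 1), range = c(0, 255)),
                    center = 50, width = 20)
  expect_equal(mid[1, 1], 127.5)
  # out-of-window values clamp; the center maps to half range
  w2 <- voi_window(image_grid(matrix(c(0, 15, 20, 30), 2), range = c(0, 255)),
                   center = 15, width = 10)
  expect_equal(as.vector(as.matrix(w2)), c(0, 127.5, 255, 255))
})

test_that("windowing degenerate and error cases behave as declared", {
  const <- image_grid(matrix(5, 4, 4), range = c(0, 255))
  expect_identical(as.matrix(voi_window(const)), as.matrix(const))
  expect_error(voi_window(const, center = 10, width = 0), "width")
})

test_that("largest-island removal matches a flood-fill oracle incl. 4- vs 8-connectivity", {
  # two blobs of different areas: the small one goes
  m <- matrix(0, 12, 12)
  m[2:11, 2:11][matrix(runif(100) > 0.7, 10)] <- 0  # keep structured blobs
  m[2:6, 2:6] <- 1    # area 25
  m[9:10, 9:10] <- 1  # area 4
  res <- remove_artifacts(image_grid(m, range = c(0, 1)))
  expect_equal(res$n_removed, 1L)
  out <- as.matrix(res$image)
  expect_true(all(out[9:10, 9:10] == 0))
  expect_true(all(out[2:6, 2:6] == 1))

  # diagonal-touching pixels are NOT 4-connected: two components, one removed
  d <- matrix(0, 5, 5)
  d[2, 2] <- 1; d[3, 3] <- 1; d[3, 4] <- 1
  res2 <- remove_artifacts(image_grid(d, range = c(0, 1)))
  expect_equal(res2$n_removed, 1L)
  expect_equal(sum(as.matrix(res2$image) > 0), 2L)

  single <- remove_artifacts(image_grid(matrix(c(0, 1, 1, 1), 2),
                                        range = c(0, 1)))
  expect_equal(single$n_removed, 0L)
  expect_error(remove_artifacts(image_grid(matrix(0, 3, 3))), "foreground")
})

test_that("component labeling agrees with EBImage bwlabel on random masks", {
  set.seed(7)
  for (i in 1:20) {
    mask <- matrix(runif(64 * 64) < 0.35, 64)
    lab <- mammocalc:::label_components(mask, connectivity = 4L)
    ref <- EBImage::bwlabel(mask * 1)
    expect_equal(max(lab), max(ref))
    # same partition: component ids co-vary one-to-one
    expect_equal(length(unique(paste(lab[mask], ref[mask]))),
                 max(lab))
  }
})

test_that("removal output equals the largest component exactly on small grids", {
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(as.numeric(runif(24 * 24) < 0.4), 24)
    if (!any(m > 0)) next
    res <- remove_artifacts(image_grid(m, range = c(0, 1)))
    out <- as.matrix(res$image)
    expect_true(all(out[m == 0] == 0))          # foreground subset of input
    lab <- mammocalc:::label_components(out > 0, connectivity = 4L)
    expect_lte(max(lab), 1L)                    # a single surviving component
  }
})

test_that("the preprocessing pipeline yields one island and is idempotent", {
  ph <- small_phantom(n_spots = 3L, seed = 9L, side = 128L,
                      add_artifacts = TRUE)
  out <- preprocess_pipeline(ph$image, side = 128L, window = "identity")
  lab <- mammocalc:::label_components(as.matrix(out) > 0, connectivity = 4L)
  expect_equal(max(lab), 1L)
  again <- preprocess_pipeline(out, side = 128L, window = "identity")
  expect_equal(as.matrix(again), as.matrix(out), tolerance = 1e-12)
})

test_that("false-RGB input preprocesses identically to its grayscale content", {
  ph <- small_phantom(n_spots = 2L, seed = 12L, side = 64L)
  m <- as.matrix(ph$image)
  rgb <- rgb_image(m, m, m)
  a <- preprocess_pipeline(rgb, side = 64L, window = "identity",
                           artifact_removal = FALSE)
  b <- preprocess_pipeline(image_grid(0.9999 * m, range = c(0, 1)),
                           side = 64L, window = "identity",
                           artifact_removal = FALSE)
  # equal channels scale by the weight sum 0.9999
  expect_equal(as.matrix(a), as.matrix(b), tolerance = 1e-12)
})

test_that("image files round-trip through the writers", {
  ph <- small_phantom(n_spots = 2L, seed = 21L, side = 48L)
  p <- file.path(tempdir(), "rt.tiff")
  write_image(ph$image, p)
  back <- read_image(p)
  # 16-bit quantization: max error half a step on the 0-255 scale
  expect_lt(max(abs(as.matrix(back) / 255 - as.matrix(ph$image))), 1 / 65535)
  p2 <- file.path(tempdir(), "rt.png")
  write_image(ph$image, p2)
  back2 <- read_image(p2)
  expect_lt(max(abs(as.matrix(back2) / 255 - as.matrix(ph$image))), 1 / 255)
  unlink(c(p, p2))
})
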