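test_that("Prewitt responses obey ramp and step closed forms", {
  const <- matrix(5, 9, 9)
  pr <- prewitt_response(const)
  v <- attr(pr$map_x, "valid")
  expect_true(all(pr$map_x[v] == 0))
  expect_true(all(pr$map_y[v] == 0))
  expect_false(any(v[1, ]) || any(v[, 1]))

  ramp <- matrix(rep(1:9, each = 9), 9, 9)  # I(x, y) = x (column index)
  pr <- prewitt_response(ramp)
  expect_true(all(pr$map_x[attr(pr$map_x, "valid")] == 6))  # 3 * ((x+1)-(x-1))
  expect_true(all(pr$map_y[attr(pr$map_y, "valid")] == 0))

  h <- 2.5
  step <- rbind(matrix(0, 4, 9), matrix(h, 5, 9))  # vertical step between rows
  pr <- prewitt_response(step)
  expect_equal(max(pr$map_y[attr(pr$map_y, "valid")]), 3 * h)
  expect_error(prewitt_response(matrix(1, 2, 2)), "smaller")
})

test_that("filter responses are linear on interior pixels", {
  set.seed(11)
  x <- matrix(runif(144), 12); y <- matrix(runif(144), 12)
  bank <- build_gabor_bank()
  for (k in c(list(prewitt_kernels()$prewitt_x), bank$gabor["45"])) {
    rx <- mammocalc:::xcorr2(x, k[[1]] %||% k)
  }
  a <- 2.5; b <- -1.25
  k <- bank$gabor[["90"]]
  r1 <- mammocalc:::xcorr2(a * x + b * y, k)
  r2 <- a * mammocalc:::xcorr2(x, k) + b * mammocalc:::xcorr2(y, k)
  v <- attr(r1, "valid")
  expect_equal(r1[v], r2[v], tolerance = 1e-12)
})

test_that("the canonical Gabor bank matches its printed fixture", {
  bank <- build_gabor_bank("canonical")
  g0 <- bank$gabor[["0"]]
  expect_equal(max(g0), 0.7726)
  expect_identical(g0, t(g0))  # transpose-symmetric
  expect_identical(g0[1, ], c(0.1105, 0.2368, 0.2921, 0.2368, 0.1105))
  expect_identical(bank$gabor[["90"]][1, ],
                   c(-0.1105, -0.2368, 0.0000, 0.2368, 0.1105))
  expect_identical(bank$gabor[["180"]][3, ],
                   c(0.1105, 0.2368, 0.2921, 0.2368, 0.1105))
  expect_equal(names(bank$gabor), c("0", "45", "90", "135", "180"))
  expect_true(all(bank$prewitt_x %in% c(-1, 0, 1)))
})

test_that("the canonical bank round-trips through serialization bit-exactly", {
  bank <- build_gabor_bank()
  p <- file.path(tempdir(), "bank.json")
  write_kernel_bank(bank, p)
  back <- read_kernel_bank(p)
  expect_identical(back$gabor, bank$gabor)
  expect_identical(back$prewitt_x, bank$prewitt_x)
  unlink(p)
})

test_that("parametric mode collapses to all-ones in the degenerate limit", {
  bank <- build_gabor_bank("parametric", sigma = 1e8, psi = 0,
                          frequency = 1e-8)
  for (g in bank$gabor) expect_equal(g, matrix(1, 5, 5), tolerance = 1e-6)
  expect_error(build_gabor_bank("nonsense"))
})

test_that("Gabor responses: zero, constant, and impulse identities", {
  bank <- build_gabor_bank()
  zero <- gabor_responses(matrix(0, 8, 8), bank)
  for (g in zero) expect_true(all(g == 0))

  const <- gabor_responses(matrix(3, 9, 9), bank)
  for (nm in names(const)) {
    v <- attr(const[[nm]], "valid")
    expect_equal(unique(round(const[[nm]][v], 10)),
                 round(3 * sum(bank$gabor[[nm]]), 10))
  }

  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  resp <- gabor_responses(imp, bank)
  rot180 <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
  for (nm in names(resp))  # correlation: impulse stamps the reflected kernel
    expect_equal(resp[[nm]][4:8, 4:8], rot180(bank$gabor[[nm]]),
                 tolerance = 1e-12)
})

test_that("GLCM counts match hand enumeration and closed-form totals", {
  w <- matrix(c(0, 1, 0, 1), 2)  # rows: [0,0],[1,1]
  g <- glcm_compute(w, levels = 2L, d = 1L, theta = 0)
  expect_equal(unclass(g)[1:2, 1:2], matrix(c(1, 0, 0, 1), 2),
               ignore_attr = TRUE)

  const <- glcm_compute(matrix(7, 3, 4), levels = 4L, d = 1L, theta = 0)
  expect_equal(sum(unclass(const)), 3 * (4 - 1))
  expect_equal(unclass(const)[1, 1], 9)

  set.seed(13)
  for (i in 1:10) {
    R <- sample(4:9, 1); C <- sample(4:9, 1)
    win <- matrix(runif(R * C), R)
    for (th in c(0, 45, 90, 135)) {
      g <- glcm_compute(win, levels = 4L, d = 1L, theta = th)
      off <- attr(g, "offset")
      q <- mammocalc:::quantize_levels(win, 4L)
      expect_equal(unclass(g), oracle_glcm(q, 4L, off["drow"], off["dcol"]),
                   ignore_attr = TRUE)
    }
    g0 <- glcm_compute(win, levels = 4L, d = 1L, theta = 0)
    expect_equal(sum(unclass(g0)), R * (C - 1))
  }
  expect_error(glcm_compute(matrix(1, 1, 1), levels = 2L, d = 1L, theta = 0),
               "offset")
})

test_that("Haralick features follow their formulas on hand-checked matrices", {
  f <- glcm_features(matrix(c(1, 0, 0, 1), 2))
  expect_equal(f$contrast, 0)
  expect_equal(f$energy, 0.5)
  expect_equal(f$homogeneity, 1.0)
  expect_equal(f$correlation, 1.0)  # perfectly co-varying diagonal

  anti <- glcm_features(matrix(c(0, 1, 1, 0), 2))
  expect_equal(anti$contrast, 1.0)

  const <- glcm_features(glcm_compute(matrix(2, 4, 4), levels = 8L,
                                      d = 1L, theta = 0))
  expect_equal(const$energy, 1.0)
  expect_equal(const$contrast, 0)
  expect_equal(const$correlation, 0)  # zero marginal variance, flagged 0
  expect_error(glcm_features(matrix(0, 2, 2)), "zero")
})

test_that("Haralick features stay in their theoretical ranges", {
  set.seed(17)
  for (i in 1:50) {
    win <- matrix(runif(49), 7)
    g <- glcm_compute(win, levels = sample(2:8, 1), d = 1L,
                      theta = sample(c(0, 45, 90, 135), 1))
    f <- glcm_features(g)
    expect_gt(f$energy, 0); expect_lte(f$energy, 1)
    expect_gt(f$homogeneity, 0); expect_lte(f$homogeneity, 1)
    expect_gte(f$contrast, 0)
    expect_gte(f$correlation, -1 - 1e-12); expect_lte(f$correlation, 1 + 1e-12)
  }
})

test_that("the GLCM texture map distinguishes rough from smooth regions", {
  const <- glcm_texture_map(matrix(4, 32, 32), window_side = 9L, stride = 8L)
  expect_true(all(const == 0))

  set.seed(19)
  img <- matrix(0.5, 48, 48)
  chk <- outer(1:48, 1:24, function(i, j) (i + j) %% 2)
  img[, 25:48] <- chk  # right half checkerboard, left half smooth
  m <- glcm_texture_map(img, window_side = 9L, stride = 4L)
  expect_gt(mean(m[, 31:48]), mean(m[, 1:18]))

  # stride consistency: coarse and dense sampling agree at shared centers
  f1 <- glcm_texture_map(img, window_side = 9L, stride = 9L)
  f2 <- glcm_texture_map(img, window_side = 9L, stride = 1L)
  ctr <- seq(5, 40, by = 9)
  expect_equal(f1[ctr[2], ctr[2]], f2[ctr[2], ctr[2]], tolerance = 0.35)
})

test_that("the assembled stack has the contract shape, range, and order", {
  zero <- assemble_feature_stack(matrix(0, 64, 64), out_side = 32L,
                                 glcm_window = 9L, glcm_stride = 8L)
  expect_true(all(zero == 0))
  expect_identical(dim(zero), c(32L, 32L, 8L))

  ph <- small_phantom(n_spots = 1L, seed = 23L, side = 64L,
                      spot_diameter_range = c(0.8, 1.0), spot_contrast = 0.7)
  st <- assemble_feature_stack(ph$image, out_side = 64L, glcm_window = 9L,
                               glcm_stride = 8L)
  expect_identical(dim(st), c(64L, 64L, 8L))
  expect_identical(dimnames(st)[[3]],
                   c("prewitt_x", "prewitt_y", "gabor_0", "gabor_45",
                     "gabor_90", "gabor_135", "gabor_180", "glcm_texture"))
  expect_gte(min(st), 0); expect_lte(max(st), 1)

  # the planted spot ranks in the top 1% of at least one channel
  s <- ph$truth$spots
  r <- round(s$row[1]); c <- round(s$col[1])
  hit <- FALSE
  for (k in 1:8) {
    ch <- st[, , k]
    if (ch[r, c] >= stats::quantile(ch, 0.99)) hit <- TRUE
  }
  expect_true(hit)
})
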