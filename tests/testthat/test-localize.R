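test_that("disk structuring elements enumerate the right lattice points", {
  se1 <- disk_se(1)
  expect_equal(sum(se1), 5L)           # plus shape
  expect_true(se1[2, 2])               # center pixel
  se2 <- disk_se(2)
  expect_equal(sum(se2), 13L)
  for (se in list(se1, se2, disk_se(4))) {
    m <- unclass(se); attributes(m) <- list(dim = dim(m))
    expect_identical(m, t(m))
    expect_identical(m, m[rev(seq_len(nrow(m))), ])
    expect_identical(m, m[, rev(seq_len(ncol(m)))])
  }
  expect_error(disk_se(0), "radius")
})

test_that("opening and top-hat follow hand-worked examples", {
  const <- matrix(4.2, 8, 8)
  expect_equal(open_image(const, disk_se(2)), const)
  expect_true(all(white_top_hat(const, disk_se(2)) == 0))

  single <- matrix(0, 5, 5); single[3, 3] <- 7
  op <- open_image(single, disk_se(1))
  expect_true(all(op == 0))
  th <- white_top_hat(single, disk_se(1))
  expect_equal(th[3, 3], 7)
  expect_equal(sum(th), 7)

  # a plateau larger than the SE survives opening exactly
  plate <- matrix(0, 12, 12); plate[4:9, 4:9] <- 2
  op <- open_image(plate, disk_se(2))
  expect_equal(op[5:8, 5:8], plate[5:8, 5:8])
  expect_true(all(white_top_hat(plate, disk_se(2)) >= 0))
})

test_that("morphology agrees with the brute-force oracle on random grids", {
  set.seed(41)
  for (i in 1:6) {
    m <- matrix(runif(24 * 24), 24)
    se <- disk_se(sample(1:3, 1))
    expect_equal(open_image(m, se), oracle_open(m, se), tolerance = 1e-12)
    th <- white_top_hat(m, se)
    expect_equal(th, m - oracle_open(m, se), tolerance = 1e-12)
    # 0 <= tophat <= I - min(I); opening anti-extensive and idempotent
    expect_gte(min(th), 0)
    expect_true(all(th <= m - min(m) + 1e-12))
    op <- open_image(m, se)
    expect_true(all(op <= m + 1e-12))
    expect_equal(open_image(op, se), op, tolerance = 1e-12)
  }
})

test_that("an isolated bump's top-hat peak drops once the SE exceeds it", {
  img <- matrix(0.2, 40, 40)
  img <- mammocalc:::stamp_bump(img, 20, 20, radius = 5, amp = 0.6)
  peaks <- vapply(c(2L, 4L, 6L, 8L), function(r)
    max(white_top_hat(img, disk_se(r))), numeric(1))
  # response grows with SE radius until the bump no longer survives opening
  expect_true(all(diff(peaks) >= -1e-12))
  expect_lt(peaks[1], 0.9 * peaks[4])
})

test_that("candidate extraction honors thresholds, areas, and ordering", {
  expect_equal(nrow(candidate_regions(matrix(0, 10, 10))), 0L)
  m <- matrix(0, 20, 20)
  m[5:6, 5:6] <- 1      # area 4, score 1
  m[14, 14] <- 0.5      # area 1, score 0.5
  cand <- candidate_regions(m, threshold = 0.1)
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$score, c(1, 0.5))  # sorted descending
  expect_equal(cand$area, c(4L, 1L))
  expect_equal(cand$row[1], 5.5)
  expect_equal(unname(unlist(cand[1, c("r0", "c0", "r1", "c1")])),
               c(4, 4, 6, 6))  # 0-based half-open
  expect_equal(nrow(candidate_regions(m, threshold = 0.1, max_area = 0)), 0L)
  expect_equal(nrow(candidate_regions(m, threshold = 0.1, min_area = 2)), 1L)
  # 8-connectivity: diagonal pixels form one blob
  d <- matrix(0, 10, 10); d[3, 3] <- 1; d[4, 4] <- 1
  expect_equal(nrow(candidate_regions(d, threshold = 0.5)), 1L)
  expect_error(candidate_regions(matrix(-1, 3, 3)), "non-negative")
})

test_that("localization recovers planted deposits on positive phantoms", {
  hits <- 0L; total <- 0L; n_cand_pos <- c()
  for (seed in 1:8) {
    ph <- generate_phantom(phantom_spec(width = 192L, height = 192L,
                                        n_spots = 5L,
                                        spot_diameter_range = c(0.3, 1.0),
                                        spot_contrast = 0.6, seed = seed))
    loc <- localize_pipeline(ph$image)
    expect_gte(nrow(loc$candidates), 1L)
    sc <- localization_score(loc$candidates, ph$truth, match_radius_px = 3)
    hits <- hits + nrow(sc$matches)
    total <- total + nrow(ph$truth$spots)
    n_cand_pos <- c(n_cand_pos, nrow(loc$candidates))
  }
  expect_gte(hits / total, 0.8)
  # determinism of the full path
  ph <- generate_phantom(phantom_spec(width = 128L, height = 128L,
                                      n_spots = 4L, seed = 77L))
  l1 <- localize_pipeline(ph$image)
  l2 <- localize_pipeline(ph$image)
  expect_identical(l1$candidates, l2$candidates)
})

test_that("negative phantoms yield few, low-scoring candidates", {
  counts <- c(); maxscore <- c()
  for (seed in 1:10) {
    ph <- generate_phantom(phantom_spec(width = 192L, height = 192L,
                                        n_spots = 0L, seed = 1000L + seed))
    cand <- localize_pipeline(ph$image)$candidates
    counts <- c(counts, nrow(cand))
    if (nrow(cand)) maxscore <- c(maxscore, max(cand$score))
  }
  # adaptive mean+3*sd thresholding leaves a handful of texture-tail blobs
  expect_lte(stats::median(counts), 4)
  # and their responses sit far below a contrast-0.6 deposit's
  expect_lt(max(maxscore), 0.3)
})

test_that("candidate extraction is translation-equivariant for interior spots", {
  base <- matrix(0.2, 64, 64)
  base <- mammocalc:::stamp_bump(base, 25, 30, radius = 3, amp = 0.6)
  shift <- matrix(0.2, 64, 64)
  shift <- mammocalc:::stamp_bump(shift, 25 + 7, 30 + 5, radius = 3, amp = 0.6)
  se <- disk_se(5)
  c1 <- candidate_regions(white_top_hat(base, se),
                          threshold = 0.2)
  c2 <- candidate_regions(white_top_hat(shift, se),
                          threshold = 0.2)
  expect_equal(c2$row - c1$row, 7)
  expect_equal(c2$col - c1$col, 5)
})

test_that("the overlay marks every candidate box at full intensity", {
  ph <- generate_phantom(phantom_spec(width = 128L, height = 128L,
                                      n_spots = 3L, spot_contrast = 0.7,
                                      seed = 55L))
  loc <- localize_pipeline(ph$image)
  ov <- as.matrix(loc$overlay)
  for (i in seq_len(nrow(loc$candidates))) {
    r0 <- loc$candidates$r0[i] + 1L
    c0 <- loc$candidates$c0[i] + 1L
    expect_equal(ov[r0, c0], 1)
  }
})
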