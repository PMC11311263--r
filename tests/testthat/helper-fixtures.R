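# Shared in-code fixtures: small phantoms and stacks built at test time.

small_phantom <- function(n_spots = 5L, seed = 1L, side = 96L, ...) {
  generate_phantom(phantom_spec(width = side, height = side,
                                n_spots = n_spots, seed = seed, ...))
}

# A tiny classifier problem: feature stacks from miniature phantoms.
tiny_stack_set <- function(n_pos, n_neg, side = 64L, out_side = 24L,
                           seed = 1L, spot_contrast = 0.6) {
  bank <- build_gabor_bank()
  labs <- c(rep(1L, n_pos), rep(0L, n_neg))
  xs <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    ph <- generate_phantom(phantom_spec(
      width = side, height = side,
      n_spots = if (labs[i] == 1L) 4L else 0L,
      spot_diameter_range = c(0.3, 1.0), spot_contrast = spot_contrast,
      seed = seed + 37L * i))
    xs[[i]] <- assemble_feature_stack(ph$image, out_side = out_side,
                                      bank = bank, glcm_window = 9L,
                                      glcm_stride = 8L)
  }
  list(x = xs, y = labs)
}

tiny_cnn_config <- function(side = 24L, channels = 8L) {
  cnn_config(input_shape = c(side, side, channels),
             conv_blocks = list(c(4L, 3L, 2L), c(4L, 3L, 2L)),
             dense_units = 8L)
}

# Brute-force grayscale morphology oracle with edge replication: direct
# per-pixel min/max loops, independent of the shift-and-clamp implementation.
oracle_erode <- function(m, se) {
  r <- (nrow(se) - 1L) %/% 2L
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      if (!se[di + r + 1L, dj + r + 1L]) next
      ii <- min(max(i + di, 1L), nrow(m))
      jj <- min(max(j + dj, 1L), ncol(m))
      vals <- c(vals, m[ii, jj])
    }
    out[i, j] <- min(vals)
  }
  out
}

oracle_dilate <- function(m, se) {
  -oracle_erode(-m, se)
}

oracle_open <- function(m, se) oracle_dilate(oracle_erode(m, se), se)

# Exhaustive GLCM pair enumeration oracle.
oracle_glcm <- function(q, levels, dr, dc) {
  counts <- matrix(0L, levels, levels)
  for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
    ii <- i + dr; jj <- j + dc
    if (ii >= 1 && ii <= nrow(q) && jj >= 1 && jj <= ncol(q))
      counts[q[i, j], q[ii, jj]] <- counts[q[i, j], q[ii, jj]] + 1L
  }
  counts
}

# Spelled-out metric arithmetic oracle.
oracle_metrics <- function(TP, FP, FN, TN) {
  list(recall = TP / (TP + FN), specificity = TN / (TN + FP),
       precision = TP / (TP + FP), accuracy = (TP + TN) / (TP + FP + FN + TN),
       f1 = 2 * (TP / (TP + FP)) * (TP / (TP + FN)) /
         (TP / (TP + FP) + TP / (TP + FN)))
}

# Brute-force AUC: probability a random positive outscores a random negative,
# ties counting one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
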