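# Brute-force grayscale opening with a disc: erosion (min) then dilation
# (max) computed by explicit neighborhood loops. Independent of EBImage.
brute_opening <- function(img, radius) {
  off <- ciliaHTS:::disc_offsets(radius)
  nr <- nrow(img); nc <- ncol(img)
  run <- function(src, fun) {
    out <- matrix(NA_real_, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      rr <- r + off[, 1]; cc <- c + off[, 2]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      out[r, c] <- fun(src[cbind(rr[ok], cc[ok])])
    }
    out
  }
  run(run(img, min), max)
}

test_that("background subtraction handles constants, zeros and recovers puncta", {
  const <- matrix(7, 16, 16)
  expect_equal(subtract_background(const, "mode"), matrix(0, 16, 16))
  zero <- matrix(0, 16, 16)
  expect_equal(subtract_background(zero, "mode"), zero)
  expect_equal(subtract_background(zero, "rolling_ball", 5), zero)
  expect_error(subtract_background(matrix(c(1, NaN, 1, 1), 2)), "non-finite")

  # gradient + 5 bright puncta; rolling ball radius >> punctum radius
  set.seed(21)
  nr <- 48
  img <- outer(seq(0, 40, length.out = nr), seq(0, 25, length.out = nr), "+")
  amp <- c(500, 650, 800, 950, 1100)
  pos <- cbind(c(10, 10, 24, 38, 38), c(10, 38, 24, 10, 38))
  xs <- matrix(rep(1:nr, nr), nr); ys <- t(xs)
  for (i in 1:5)
    img <- img + amp[i] * exp(-((xs - pos[i, 1])^2 + (ys - pos[i, 2])^2) / (2 * 1.2^2))
  sub <- subtract_background(img, "rolling_ball", ball_radius_px = 8)
  peaks <- sub[pos]
  expect_true(all(abs(peaks - amp) / amp < 0.05))
  # and the implementation agrees with the brute-force opening oracle
  # (same replicate-pad-and-crop border convention, computed by loops)
  ri <- c(rep(1, 8), 1:nr, rep(nr, 8))
  bg_oracle <- brute_opening(img[ri, ri], 8)[8 + 1:nr, 8 + 1:nr]
  oracle <- pmax(img - bg_oracle, 0)
  expect_equal(sub, oracle, tolerance = 1e-9)
})

test_that("contrast enhancement clips the stated percentiles and is monotone", {
  v <- matrix(rep(0:99, 2), 10)  # uniform 0..99
  out <- enhance_contrast(v, 1, 98)
  expect_true(all(out >= 0 & out <= 1))
  q99 <- quantile(v, 0.99); q2 <- quantile(v, 0.02)
  expect_true(all(out[v >= q99] == 1))
  expect_true(all(out[v <= q2] == 0))
  # monotone: no rank inversions
  o <- order(as.numeric(v))
  expect_true(all(diff(as.numeric(out)[o]) >= 0))
  expect_warning(ec <- enhance_contrast(matrix(5, 4, 4)), "degenerate")
  expect_equal(ec, matrix(0, 4, 4))
})

test_that("nucleus segmentation counts blobs and splits engineered overlaps", {
  blank <- matrix(0, 128, 128)
  expect_equal(nrow(segment_nuclei(blank)$table), 0)

  # 20 well-separated nuclei at SNR >= 10
  g <- generate_field(small_synth(13, n_cells = 20, ciliation_fraction = 0))
  bg <- subtract_background(g$field$channels$nuclei)
  nm <- segment_nuclei(bg)
  expect_equal(nrow(nm$table), 20)
  m <- match_centroids(nm$table,
                       as.matrix(g$truth$cells[, c("nucleus_row", "nucleus_col")]),
                       tol = 4)
  expect_equal(unname(m["tp"]), 20L)

  # 20 nuclei with one engineered >60% overlapping pair: 19..21 objects
  set.seed(5)
  img <- matrix(0, 256, 256)
  xs <- matrix(rep(1:256, 256), 256); ys <- t(xs)
  cent <- cbind(rep(seq(30, 230, length.out = 5), 4),
                rep(seq(30, 230, length.out = 4), each = 5))
  cent <- cent[-1, , drop = FALSE]              # 19 separated nuclei
  cent <- rbind(cent, c(30, 30), c(30, 36))     # plus a pair 6 px apart (r=8)
  for (i in seq_len(nrow(cent)))
    img <- img + 1200 * exp(-((sqrt((xs - cent[i, 1])^2 + (ys - cent[i, 2])^2)) / 8)^4)
  img <- img + matrix(rnorm(256^2, 0, 60), 256)
  img[img < 0] <- 0
  n <- nrow(segment_nuclei(subtract_background(img))$table)
  expect_true(n >= 19 && n <= 21)
})

test_that("basal-body segmentation removes aggregates and is scale covariant", {
  blank <- matrix(0, 128, 128)
  expect_equal(nrow(segment_basal_bodies(blank)$table), 0)

  set.seed(9)
  nr <- 256
  img <- matrix(0, nr, nr)
  xs <- matrix(rep(1:nr, nr), nr); ys <- t(xs)
  pts <- cbind(rep(seq(25, 230, length.out = 5), 3),
               rep(seq(40, 200, length.out = 3), each = 5))  # 15 puncta
  for (i in seq_len(nrow(pts)))
    img <- img + 1000 * exp(-((xs - pts[i, 1])^2 + (ys - pts[i, 2])^2) / (2 * 1.7^2))
  agg <- cbind(c(50, 100, 205), c(80, 160, 80))               # 3 aggregates
  for (i in 1:3)
    img <- img + 1000 * exp(-((sqrt((xs - agg[i, 1])^2 + (ys - agg[i, 2])^2)) / 12)^4)
  img <- img + matrix(rnorm(nr^2, 0, 100), nr)
  img[img < 0] <- 0
  bg <- subtract_background(img)
  bm <- segment_basal_bodies(bg)
  expect_equal(nrow(bm$table), 15)
  m <- match_centroids(bm$table, pts - 1, tol = 3)
  expect_equal(unname(m["tp"]), 15L)
  expect_true(all(bm$table$area <= segmentation_params()$bb_max_area_px))

  bm10 <- segment_basal_bodies(bg * 8)
  expect_identical(bm$labels, bm10$labels)
})

test_that("local background normalization applies the percentile cut per neighborhood", {
  # neighborhood = whole 11x10 image (radius clipped at the borders):
  # multiset {0.1 x 100, 0.9 x 10}; only the 0.9 pixels exceed the 80th pctl
  enh <- matrix(0.1, 11, 10)
  bright <- sample(seq_len(110), 10)
  enh[bright] <- 0.9
  labs <- matrix(0L, 11, 10); labs[6, 5] <- 1L
  bm <- manual_mask(labs, local_radius_px = 40)
  out <- local_background_normalize(enh, bm)
  expect_equal(sort(which(out > 0)), sort(bright))
  expect_equal(out[bright], rep(0.9, 10))
  # oracle: direct percentile over the listed multiset
  expect_equal(unname(quantile(enh, 0.8)), 0.1)

  # no basal bodies -> all zero
  out0 <- local_background_normalize(enh, manual_mask(matrix(0L, 11, 10),
                                                      local_radius_px = 40))
  expect_true(all(out0 == 0))

  # pixel far outside every neighborhood is removed even at intensity 1.0
  enh2 <- matrix(0, 64, 64); enh2[60, 60] <- 1
  enh2[30:34, 30:34] <- 0.5
  labs2 <- matrix(0L, 64, 64); labs2[32, 32] <- 1L
  out2 <- local_background_normalize(enh2, manual_mask(labs2, local_radius_px = 10))
  expect_equal(out2[60, 60], 0)
})

test_that("cluster segmentation keeps the high intensity class only", {
  # three well-separated levels; candidates are exactly the 0.95 pixels
  set.seed(2)
  img <- matrix(0, 64, 64)
  lev <- sample(c(0.2, 0.5, 0.95), 300, replace = TRUE)
  idx <- sample(64 * 64, 300)
  img[idx] <- lev
  cm <- cluster_segment_cilia(img)
  expect_setequal(which(cm$labels > 0), idx[lev == 0.95])

  # all-zero field: no candidates
  expect_equal(nrow(cluster_segment_cilia(matrix(0, 32, 32))$table), 0)

  # bimodal field degenerates: all nonzero pixels become candidates, warning
  img2 <- matrix(0, 32, 32); img2[1:20] <- 0.3; img2[101:110] <- 0.9
  expect_warning(cm2 <- cluster_segment_cilia(img2), "distinct")
  expect_setequal(which(cm2$labels > 0), which(img2 > 0))
})

test_that("candidate components are 8-connected", {
  m <- matrix(0, 8, 8)
  m[cbind(1:5, 1:5)] <- 1  # diagonal line
  lab <- ciliaHTS:::label8(m)
  expect_equal(max(lab), 1L)
  m[8, 8] <- 1             # isolated pixel
  expect_equal(max(ciliaHTS:::label8(m)), 2L)
})
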