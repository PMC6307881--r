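# Hand-built pixel configurations exercise each filter's arithmetic against
# direct computation from the raw pixel sets.

test_that("touching filter links candidates by Chebyshev gap with low-label ties", {
  nr <- 40
  labs_bb <- matrix(0L, nr, nr)
  labs_bb[10:11, 10:11] <- 1L
  labs_bb[10:11, 30:31] <- 2L
  labs_cand <- matrix(0L, nr, nr)
  labs_cand[12:14, 10] <- 1L   # shares an edge with bb 1 (distance 1)
  labs_cand[25:27, 10] <- 2L   # ~14 px from bb 1: fails at gap 1
  labs_cand[10, 20:21] <- 3L   # equidistant (9 px) between bb 1 and 2
  bm <- manual_mask(labs_bb, local_radius_px = 15)
  cand <- filter_touching(as_candidates(manual_mask(labs_cand)), bm,
                          touch_max_gap_px = 1)
  tab <- cand$table
  expect_true(tab$pass_touching[1])
  expect_equal(tab$linked_bb[1], 1L)
  expect_equal(tab$touch_dist_px[1], 1)
  expect_false(tab$pass_touching[2])
  expect_false(tab$pass_touching[3])

  # widen the gap so the equidistant candidate links: tie -> lower label
  cand9 <- filter_touching(as_candidates(manual_mask(labs_cand)), bm,
                           touch_max_gap_px = 8)
  expect_true(cand9$table$pass_touching[3])
  expect_equal(cand9$table$linked_bb[3], 1L)
  # oracle: brute-force nearest-pixel Chebyshev distance
  d1 <- cheb_dist_sets(which(labs_cand == 3L), which(labs_bb == 1L), nr)
  d2 <- cheb_dist_sets(which(labs_cand == 3L), which(labs_bb == 2L), nr)
  expect_equal(d1, d2)
  expect_equal(cand9$table$touch_dist_px[3], d1)
})

test_that("size filter uses a closed interval", {
  labs <- matrix(0L, 20, 20)
  labs[1, 1] <- 1L            # area 1
  labs[5, 1:5] <- 2L          # area 5 == min bound
  labs[10:12, 1:10] <- 3L     # area 30
  cand <- filter_size(as_candidates(manual_mask(labs)), 5, 200)
  expect_equal(cand$table$pass_size, c(FALSE, TRUE, TRUE))
})

test_that("mask-area ratio compares against the local-neighborhood area", {
  nr <- 60
  labs_bb <- matrix(0L, nr, nr); labs_bb[30, 30] <- 1L
  bm <- manual_mask(labs_bb, local_radius_px = 10)
  nb_area <- length(ciliaHTS:::neighborhood_indices(c(31, 31),
                                                    ciliaHTS:::disc_offsets(10),
                                                    c(nr, nr)))
  labs_cand <- matrix(0L, nr, nr)
  labs_cand[25:35, 25:35] <- 1L  # 121 px blob at the basal body
  labs_cand[30, 38:40] <- 2L     # thin 3 px object
  cand <- as_candidates(manual_mask(labs_cand))
  cand <- filter_touching(cand, bm, touch_max_gap_px = 10)
  cand <- filter_mask_ratio(cand, bm, max_mask_area_ratio = 0.1)
  expect_equal(cand$table$mask_area_ratio, c(121, 3) / nb_area)
  expect_equal(cand$table$pass_ratio, c(FALSE, TRUE))

  # boundary: ratio exactly at the threshold passes
  cand2 <- filter_mask_ratio(cand, bm, max_mask_area_ratio = 121 / nb_area)
  expect_true(cand2$table$pass_ratio[1])

  # cascade-order violation: unlinked candidates cannot be ratio-filtered
  expect_error(filter_mask_ratio(as_candidates(manual_mask(labs_cand)), bm),
               "filter_touching")
})

test_that("snr and sd-distance filters match direct computation from pixel sets", {
  nr <- 41
  labs_bb <- matrix(0L, nr, nr); labs_bb[21, 21] <- 1L
  bm <- manual_mask(labs_bb, local_radius_px = 12)
  labs_cand <- matrix(0L, nr, nr)
  labs_cand[21, 22:27] <- 1L
  raw <- matrix(10, nr, nr)           # flat local background, mean 10
  raw[labs_cand == 1L] <- 100         # candidate mean 100 -> snr 10
  cand <- as_candidates(manual_mask(labs_cand))
  cand <- filter_touching(cand, bm, touch_max_gap_px = 1)
  cand <- filter_snr(cand, raw, bm, min_snr = 2)
  expect_equal(cand$table$snr, 10)
  expect_true(cand$table$pass_snr)

  # candidate equal to background fails at min_snr 2
  raw_eq <- matrix(10, nr, nr)
  c2 <- filter_snr(filter_touching(as_candidates(manual_mask(labs_cand)), bm, 1),
                   raw_eq, bm, min_snr = 2)
  expect_equal(c2$table$snr, 1)
  expect_false(c2$table$pass_snr)

  # zero-mean background: snr = Inf, pass
  raw0 <- matrix(0, nr, nr); raw0[labs_cand == 1L] <- 50
  c3 <- filter_snr(filter_touching(as_candidates(manual_mask(labs_cand)), bm, 1),
                   raw0, bm, min_snr = 2)
  expect_equal(c3$table$snr, Inf)

  # sd-distance against the local centrosome mask (neighborhood minus the
  # candidate), verified by direct mean/sd computation
  set.seed(7)
  raw2 <- matrix(rnorm(nr * nr, 10, 5), nr, nr)
  raw2[labs_cand == 1L] <- 40
  c4 <- filter_centrosome_sd(
    filter_touching(as_candidates(manual_mask(labs_cand)), bm, 1),
    raw2, bm, min_sd_distance = 2)
  nb <- ciliaHTS:::neighborhood_indices(c(21, 21), ciliaHTS:::disc_offsets(12),
                                        c(nr, nr))
  mask_idx <- setdiff(nb, which(labs_cand == 1L))
  expected <- (40 - mean(raw2[mask_idx])) / sd(raw2[mask_idx])
  expect_equal(c4$table$sd_distance, expected, tolerance = 1e-12)
  expect_equal(c4$table$pass_sd, expected >= 2)

  # boundary: exactly min_sd_distance passes (inclusive)
  c5 <- filter_centrosome_sd(
    filter_touching(as_candidates(manual_mask(labs_cand)), bm, 1),
    raw2, bm, min_sd_distance = expected)
  expect_true(c5$table$pass_sd)
})

test_that("cascade is conjunctive, ordered, and ratio-invariant to scaling", {
  g <- generate_field(small_synth(31, n_cells = 40, ciliation_fraction = 0.5,
                                  streaks = 4, mtocs = 1, shape = c(384L, 384L)))
  bg <- lapply(g$field$channels, subtract_background)
  bm <- segment_basal_bodies(bg$basal_body)
  enh <- enhance_contrast(bg$cilium)
  norm <- local_background_normalize(enh, bm)
  cm <- cluster_segment_cilia(norm)
  cc <- run_filter_cascade(cm, bm, bg$cilium)
  tab <- cc$table
  # accepted rows pass all five stages; failed rows record the first failure
  acc <- tab[tab$accepted, ]
  expect_true(all(acc$pass_touching & acc$pass_size & acc$pass_ratio &
                    acc$pass_snr & acc$pass_sd))
  expect_true(all(is.na(acc$first_fail)))
  expect_true(all(!is.na(tab$first_fail[!tab$accepted])))

  # global intensity scaling leaves the accepted set unchanged
  # (power-of-2 factor: exact in floating point, isolating the algorithmic
  # scale covariance from representation rounding)
  cc2 <- run_filter_cascade(cm, bm, bg$cilium * 16)
  expect_equal(which(cc2$table$accepted), which(tab$accepted))

  # tightening any single threshold never increases the accepted count
  base <- sum(tab$accepted)
  tighter <- list(
    filter_params(touch_max_gap_px = 0),
    filter_params(cilium_min_area_px = 15),
    filter_params(cilium_max_area_px = 40),
    filter_params(max_mask_area_ratio = 0.01),
    filter_params(min_snr = 5),
    filter_params(min_sd_distance = 6))
  for (fp in tighter)
    expect_lte(sum(run_filter_cascade(cm, bm, bg$cilium, fp)$table$accepted),
               base)

  # empty candidate list flows through
  empty <- run_filter_cascade(manual_mask(matrix(0L, 384, 384)), bm, bg$cilium)
  expect_equal(nrow(accepted_cilia(empty)), 0)
})
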