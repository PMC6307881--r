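test_that("z_prime matches the control-separation formula", {
  expect_equal(z_prime(c(10, 10, 10), c(0, 0, 0)), 1)
  # sample moments mu_p=10 sd_p=1, mu_n=0 sd_n=1 -> 1 - 3*2/10 = 0.4
  expect_equal(z_prime(c(9, 10, 11), c(-1, 0, 1)), 0.4)
  expect_error(z_prime(c(5, 5), c(5, 5)), "undefined")
  expect_error(z_prime(10, c(0, 0)), "at least 2")
  # invariance: shift by a constant, joint positive rescale
  pos <- c(62, 71, 68); neg <- c(18, 22, 25)
  expect_equal(z_prime(pos + 13, neg + 13), z_prime(pos, neg))
  expect_equal(z_prime(pos * 3.5, neg * 3.5), z_prime(pos, neg))
  expect_lte(z_prime(pos, neg), 1)
})

test_that("toxicity filter is strict at the 80% boundary", {
  ctrl <- c(90, 100, 110)  # mean 100
  expect_equal(toxicity_filter(c(79, 80, 81, 100, 150), ctrl),
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_error(toxicity_filter(c(50), numeric(0)), "positive-control")
})

test_that("z-scores standardize against the negative-reference wells", {
  ref <- c(8, 10, 12)  # mean 10, sd 2
  expect_equal(z_scores(10, ref), 0)
  expect_equal(z_scores(20, ref), 5)
  expect_error(z_scores(10, c(7, 7, 7)), "zero SD")
  expect_error(z_scores(10, 7), "at least 2")
})

test_that("hit calling combines the 3-SD rule with toxicity exclusion", {
  z <- c(4.8, 2.9, 3.5, 3.0, NA)
  toxic <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(call_hits(z, toxic), c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(call_hits(c(-4, 4), c(FALSE, FALSE), two_sided = TRUE),
               c(TRUE, TRUE))
  # hit set shrinks monotonically with k_sd
  set.seed(3)
  zz <- rnorm(200, 0, 2); tox <- rep(FALSE, 200)
  counts <- vapply(c(1, 2, 3, 4), function(k) sum(call_hits(zz, tox, k)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a spiked well and only that well is called on simulated plates", {
  # negative references ~ Normal(mu, sigma); one compound spiked at mu + 5 sigma
  lay_wells <- data.frame(
    well = sprintf("%s%02d", rep(LETTERS[1:16], each = 24), rep(1:24, 16)),
    treatment = "x", role = "negative_reference",
    compound_id = NA, dose_uM = NA)
  lay_wells$role[1:16] <- "positive_control"
  lay_wells$role[17] <- "compound"
  lay_wells$compound_id[17] <- "spike"
  mu <- 20; sg <- 1
  ok <- 0L
  for (rep_i in 1:500) {
    set.seed(rep_i)
    pc <- rnorm(384, mu, sg)
    pc[1:16] <- rnorm(16, 70, 0.05 * 70)
    pc[17] <- mu + 5 * sg
    wells <- data.frame(well = lay_wells$well, treatment = "x",
                        role = lay_wells$role, cell_count = 450,
                        ciliated_count = 0, percent_ciliated = pc)
    res <- screen_stats(wells, k_sd = 3)
    hits <- res$wells$well[res$wells$hit]
    if (identical(hits, lay_wells$well[17])) ok <- ok + 1L
  }
  expect_gte(ok / 500, 0.95)
})

test_that("screen_stats flags toxic wells, zeroes their z-scores and reports controls", {
  lay <- test_layout(3, 3, 2)
  wells <- simulate_plate_values(lay, role_effects = c(positive_control = 0.7,
                                                       negative_reference = 0.2,
                                                       compound = 0.2,
                                                       cmp01 = 0.65),
                                 seed = 4)
  wells$cell_count[wells$treatment == "cmp02"] <- 100  # ~22% survival
  res <- screen_stats(wells, plate_id = "TOX")
  w <- res$wells
  expect_true(w$toxic[w$treatment == "cmp02"])
  expect_true(is.na(w$z_score[w$treatment == "cmp02"]))
  expect_false(w$hit[w$treatment == "cmp02"])
  expect_true(w$hit[w$treatment == "cmp01"])
  expect_false(any(w$hit & w$toxic))
  expect_equal(res$controls$n, c(3, 3))
  expect_error(screen_stats(wells[wells$role != "positive_control", ]),
               ">= 2 positive_control")
})
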