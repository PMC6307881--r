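# Shared fixtures: all test inputs are generated in code.

# Greedy centroid matching of detected objects to ground-truth positions.
match_centroids <- function(found, truth_rc, tol = 3) {
  used <- rep(FALSE, nrow(truth_rc)); tp <- 0L
  for (i in seq_len(nrow(found))) {
    d2 <- (truth_rc[, 1] - found$centroid_row[i])^2 +
          (truth_rc[, 2] - found$centroid_col[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= tol^2) { tp <- tp + 1L; used[j] <- TRUE }
  }
  c(tp = tp, fp = nrow(found) - tp, fn = nrow(truth_rc) - tp)
}

# A small control+compound layout.
test_layout <- function(n_pos = 3, n_neg = 3, n_cmp = 2) {
  rows <- LETTERS[2:15]; k <- n_pos + n_neg + n_cmp
  wells <- sprintf("%s%02d", rows[ceiling(seq_len(k) / 20)],
                   (seq_len(k) - 1L) %% 20 + 2L)
  plate_layout("TEST", data.frame(
    well = wells,
    treatment = c(rep("siC+DMSO", n_pos), rep("siVHL+DMSO", n_neg),
                  sprintf("cmp%02d", seq_len(n_cmp))),
    role = c(rep("positive_control", n_pos), rep("negative_reference", n_neg),
             rep("compound", n_cmp)),
    compound_id = c(rep(NA, n_pos + n_neg), sprintf("cmp%02d", seq_len(n_cmp))),
    dose_uM = c(rep(NA, n_pos + n_neg), rep(10, n_cmp))),
    channels = c(nuclei = 1, basal_body = 2, cilium = 3))
}

# Compact synthetic fields for fast unit tests.
small_synth <- function(seed, n_cells = 20, ciliation_fraction = 0.5,
                        streaks = 0, mtocs = 0, shape = c(256L, 256L), ...) {
  synth_params(field_shape_px = shape, n_cells = n_cells,
               ciliation_fraction = ciliation_fraction,
               n_cytoplasmic_streaks = streaks, n_mtoc_blobs = mtocs,
               seed = seed, ...)
}

# Build a label_mask around explicit label matrices (tests construct exact
# pixel configurations for the filter arithmetic).
manual_mask <- function(labels, intensity = NULL, local_radius_px = NULL) {
  m <- ciliaHTS:::new_label_mask(labels, intensity)
  if (!is.null(local_radius_px)) m$local_radius_px <- local_radius_px
  m
}

# Brute-force Chebyshev distance between two linear-index pixel sets.
cheb_dist_sets <- function(a, b, nr) {
  ra <- (a - 1L) %% nr; ca <- (a - 1L) %/% nr
  rb <- (b - 1L) %% nr; cb <- (b - 1L) %/% nr
  min(vapply(seq_along(ra), function(i)
    min(pmax(abs(rb - ra[i]), abs(cb - ca[i]))), numeric(1)))
}
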