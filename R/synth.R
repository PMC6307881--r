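#' Synthetic-field generator parameters
#'
#' Parameters of the seeded ground-truth simulator. Each synthetic cell is a
#' nucleus blob (nuclei channel), a basal-body punctum (basal-body channel)
#' and — with probability `ciliation_fraction` — an attached curvilinear
#' axoneme in the cilium channel. Confounders emulate the assay's stated
#' failure modes: detached cytoplasmic acetylated-tubulin streaks (false
#' positives removed by the touching filter) and bright mitotic-organizing-
#' center blobs (removed by the mask-area-ratio filter).
#'
#' @param field_shape_px Field dimensions `(rows, cols)` in pixels.
#' @param n_cells Number of cells per field.
#' @param ciliation_fraction Per-cell Bernoulli probability of carrying an
#'   axoneme.
#' @param nucleus_radius_px Nucleus radius (pixels).
#' @param bb_diameter_px Basal-body punctum FWHM diameter (pixels).
#' @param axoneme_length_px Length range `c(min, max)` of axonemes (pixels).
#' @param axoneme_width_px Stroke width (FWHM, pixels).
#' @param amplitudes Named per-channel peak amplitudes above background
#'   (`nuclei`, `basal_body`, `cilium`).
#' @param noise_sigma Named per-channel Gaussian noise SDs. The per-channel
#'   SNR is `amplitudes / noise_sigma` (default 10).
#' @param photon_noise Add a Poisson resampling stage before Gaussian noise.
#' @param n_cytoplasmic_streaks Number of detached acetylated-tubulin streaks
#'   (never within touching range of a basal body, by construction).
#' @param n_mtoc_blobs Number of mitotic-organizing-center blobs, each
#'   centered on a non-ciliated cell's basal body.
#' @param mtoc_radius_px MTOC blob radius (pixels).
#' @param background_offset Constant background level (all channels).
#' @param background_gradient Peak-to-peak amplitude of a smooth linear
#'   background gradient across the field.
#' @param pixel_size_um Pixel size recorded in metadata (default 0.33, the
#'   20x objective class).
#' @param seed Integer seed; fields are bit-reproducible for a fixed seed.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(field_shape_px = c(512L, 512L),
                         n_cells = 100L,
                         ciliation_fraction = 0.2,
                         nucleus_radius_px = 8,
                         bb_diameter_px = 4,
                         axoneme_length_px = c(12, 30),
                         axoneme_width_px = 2,
                         amplitudes = c(nuclei = 1200, basal_body = 1000, cilium = 1000),
                         noise_sigma = c(nuclei = 120, basal_body = 100, cilium = 100),
                         photon_noise = FALSE,
                         n_cytoplasmic_streaks = 0L,
                         n_mtoc_blobs = 0L,
                         mtoc_radius_px = 25,
                         background_offset = 80,
                         background_gradient = 60,
                         pixel_size_um = 0.33,
                         seed = 1L) {
  p <- as.list(environment())
  if (p$n_cells < 0 || p$n_cytoplasmic_streaks < 0 || p$n_mtoc_blobs < 0)
    stopf("object counts must be >= 0")
  if (p$ciliation_fraction < 0 || p$ciliation_fraction > 1)
    stopf("ciliation_fraction must lie in [0, 1]")
  if (any(p$amplitudes <= 0)) stopf("amplitudes must be positive")
  roles <- c("nuclei", "basal_body", "cilium")
  if (!all(roles %in% names(p$amplitudes)) || !all(roles %in% names(p$noise_sigma)))
    stopf("amplitudes and noise_sigma must be named for nuclei, basal_body, cilium")
  structure(p, class = "synth_params")
}

# Ciliation-fraction lookup: compound id wins over role; NULL when unmapped.
lookup_effect <- function(role_effects, compound_id, role) {
  if (!is.na(compound_id) && nzchar(compound_id) &&
      compound_id %in% names(role_effects))
    return(role_effects[[compound_id]])
  if (role %in% names(role_effects)) return(role_effects[[role]])
  NULL
}

# Stamp `values` additively at linear indices.
stamp <- function(img, idx, values) {
  img[idx] <- img[idx] + values
  img
}

# Super-Gaussian blob template around a (row, col) centre; returns linear
# indices and intensities for pixels inside `extent`.
blob_template <- function(center, radius, amplitude, dim, extent = radius + 3,
                          power = 4) {
  r0 <- max(1L, floor(center[1] - extent)); r1 <- min(dim[1], ceiling(center[1] + extent))
  c0 <- max(1L, floor(center[2] - extent)); c1 <- min(dim[2], ceiling(center[2] + extent))
  if (r0 > r1 || c0 > c1) return(list(idx = integer(0), val = numeric(0)))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, "+")
  val <- amplitude * exp(-(sqrt(d2) / radius)^power)
  idx <- as.vector(outer(rr, (cc - 1L) * dim[1], "+"))
  keep <- val > amplitude * 1e-3
  list(idx = idx[keep], val = as.numeric(val)[keep])
}

# Gaussian punctum template (sigma = fwhm / 2.355).
punctum_template <- function(center, fwhm, amplitude, dim) {
  sg <- fwhm / 2.355
  extent <- ceiling(3 * sg)
  r0 <- max(1L, floor(center[1] - extent)); r1 <- min(dim[1], ceiling(center[1] + extent))
  c0 <- max(1L, floor(center[2] - extent)); c1 <- min(dim[2], ceiling(center[2] + extent))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, "+")
  val <- amplitude * exp(-d2 / (2 * sg^2))
  idx <- as.vector(outer(rr, (cc - 1L) * dim[1], "+"))
  keep <- val > amplitude * 1e-3
  list(idx = idx[keep], val = as.numeric(val)[keep])
}

# Anti-aliased quadratic Bezier stroke: Gaussian cross-section of FWHM
# `width` along the curve p0 -> p2 with control point p1. Returns template
# indices/values plus the half-maximum truth pixel set.
stroke_template <- function(p0, p1, p2, width, amplitude, dim) {
  n_samp <- max(20L, ceiling(4 * sqrt(sum((p2 - p0)^2))))
  t <- seq(0, 1, length.out = n_samp)
  bez_r <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  bez_c <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  pad <- width + 2
  r0 <- max(1L, floor(min(bez_r) - pad)); r1 <- min(dim[1], ceiling(max(bez_r) + pad))
  c0 <- max(1L, floor(min(bez_c) - pad)); c1 <- min(dim[2], ceiling(max(bez_c) + pad))
  rr <- r0:r1; cc <- c0:c1
  px_r <- rep(rr, times = length(cc))
  px_c <- rep(cc, each = length(rr))
  # min distance to sampled curve
  d2 <- rep(Inf, length(px_r))
  for (j in seq_len(n_samp)) {
    dj <- (px_r - bez_r[j])^2 + (px_c - bez_c[j])^2
    d2 <- pmin(d2, dj)
  }
  sg <- width / 2
  val <- amplitude * exp(-d2 / (2 * sg^2))
  idx <- (px_c - 1L) * dim[1] + px_r
  keep <- val > amplitude * 1e-3
  list(idx = idx[keep], val = val[keep],
       truth = idx[val >= amplitude / 2],
       inbounds = min(bez_r) > pad && max(bez_r) < dim[1] - pad &&
                  min(bez_c) > pad && max(bez_c) < dim[2] - pad)
}

# Chebyshev dilation of a linear-index set by `d` pixels, clipped to bounds.
dilate_idx <- function(idx, d, dim) {
  if (length(idx) == 0L || d <= 0L) return(idx)
  nr <- dim[1]
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  out <- integer(0)
  for (dr in -d:d) for (dc in -d:d) {
    rr <- row + dr; cc <- col + dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= dim[2]
    out <- c(out, (cc[ok] - 1L) * nr + rr[ok])
  }
  unique(out)
}

#' Generate one synthetic field with ground truth
#'
#' Deterministic for a fixed seed. Cells are placed without same-channel
#' object overlap (bounded retries; an error suggests lowering `n_cells`),
#' axonemes originate at their basal body's centroid, cytoplasmic streaks are
#' kept clear of every basal body, and MTOC blobs sit on non-ciliated cells'
#' basal bodies. Background offset, a smooth gradient, optional Poisson
#' resampling and Gaussian noise are applied last; intensities are clipped at
#' zero.
#'
#' @param params A [synth_params()] object.
#' @param well_id,field_index Metadata recorded on the returned field.
#' @return List with `field` (a `field_image`: per-channel matrices,
#'   `pixel_size_um`, `z_projected = FALSE`) and `truth` (list with the
#'   per-cell table `cells` — 0-based centroids, `ciliated`, `mtoc` —,
#'   `axoneme_pixels`, `confounders`, and `percent_ciliated`).
#' @export
generate_field <- function(params = synth_params(), well_id = "A01",
                           field_index = 0L) {
  p <- params
  with_seed(p$seed, generate_field_impl(p, well_id, field_index))
}

generate_field_impl <- function(p, well_id, field_index) {
  dm <- as.integer(p$field_shape_px)
  nr <- dm[1]; nc <- dm[2]
  ch <- list(nuclei = matrix(0, nr, nc), basal_body = matrix(0, nr, nc),
             cilium = matrix(0, nr, nc))
  margin <- p$nucleus_radius_px + 4
  min_sep <- 2 * p$nucleus_radius_px + 3

  # --- place nuclei ---
  centers <- matrix(numeric(0), 0, 2)
  for (i in seq_len(p$n_cells)) {
    ok <- FALSE
    for (try in seq_len(300L)) {
      cand <- c(stats::runif(1, margin, nr - margin),
                stats::runif(1, margin, nc - margin))
      if (nrow(centers) == 0L ||
          min((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >= min_sep^2) {
        centers <- rbind(centers, cand); ok <- TRUE; break
      }
    }
    if (!ok) stopf("could not place %d non-overlapping cells; lower n_cells", p$n_cells)
  }

  # --- place basal bodies just outside the nucleus edge ---
  bb <- matrix(numeric(0), 0, 2)
  bb_off <- p$nucleus_radius_px + 2 + p$bb_diameter_px / 2
  for (i in seq_len(p$n_cells)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      th <- stats::runif(1, 0, 2 * pi)
      cand <- centers[i, ] + bb_off * c(cos(th), sin(th))
      inb <- cand[1] > 6 && cand[1] < nr - 6 && cand[2] > 6 && cand[2] < nc - 6
      far <- nrow(bb) == 0L ||
        min((bb[, 1] - cand[1])^2 + (bb[, 2] - cand[2])^2) >= 8^2
      if (inb && far) { bb <- rbind(bb, cand); ok <- TRUE; break }
    }
    if (!ok) stopf("could not place non-colliding basal bodies; lower n_cells")
  }

  ciliated <- if (p$n_cells > 0L)
    stats::rbinom(p$n_cells, 1L, p$ciliation_fraction) == 1L else logical(0)

  # --- choose MTOC hosts among non-ciliated cells ---
  mtoc_host <- integer(0)
  if (p$n_mtoc_blobs > 0L) {
    pool <- which(!ciliated)
    if (length(pool) < p$n_mtoc_blobs)
      stopf("not enough non-ciliated cells to host %d MTOC blobs", p$n_mtoc_blobs)
    mtoc_host <- if (length(pool) == 1L) pool else
      sample(pool, p$n_mtoc_blobs)
    # cells whose basal body falls under a blob cannot grow a clear axoneme;
    # they are forced non-ciliated (recorded as such in the truth table)
    blk <- 1.2 * p$mtoc_radius_px + 6
    for (h in mtoc_host) {
      d2 <- (bb[, 1] - bb[h, 1])^2 + (bb[, 2] - bb[h, 2])^2
      ciliated[d2 <= blk^2] <- FALSE
    }
  }

  # --- render nuclei (basal-body puncta are rendered after axoneme
  #     placement: a crowded cell may relocate its basal body) ---
  for (i in seq_len(p$n_cells)) {
    t1 <- blob_template(centers[i, ], p$nucleus_radius_px, p$amplitudes[["nuclei"]], dm)
    ch$nuclei <- stamp(ch$nuclei, t1$idx, t1$val)
  }

  # occupancy of the cilium channel (logical vectors over pixels)
  occ <- logical(nr * nc)        # placed cilium-channel objects, dilated
  occ_bb <- logical(nr * nc)     # basal-body footprints (per-cell lists kept)
  bb_foot <- vector("list", p$n_cells)
  for (i in seq_len(p$n_cells)) {
    f <- neighborhood_indices(bb[i, ], disc_offsets(3), dm)
    bb_foot[[i]] <- f
    occ_bb[f] <- TRUE
  }

  # --- MTOC blobs (on the basal body, in the cilium channel) ---
  mtoc_pixels <- list()
  for (h in mtoc_host) {
    t3 <- blob_template(bb[h, ], p$mtoc_radius_px, p$amplitudes[["cilium"]], dm,
                        extent = p$mtoc_radius_px + 3)
    ch$cilium <- stamp(ch$cilium, t3$idx, t3$val)
    truth <- t3$idx[t3$val >= p$amplitudes[["cilium"]] / 2]
    mtoc_pixels[[length(mtoc_pixels) + 1L]] <- truth
    occ[dilate_idx(truth, 2L, dm)] <- TRUE
  }

  # --- axonemes ---
  # Strokes avoid every placed cilium-channel object and every other cell's
  # basal-body footprint (so each base zone stays reachable). A crowded cell
  # may, as a last resort, relocate its own basal body around the nucleus.
  try_axoneme <- function(i, n_random = 150L) {
    for (try in seq_len(n_random)) {
      u0 <- (bb[i, ] - centers[i, ])
      u0 <- u0 / sqrt(sum(u0^2))
      spread <- if (try <= 40L) pi / 5 else pi
      ang <- atan2(u0[2], u0[1]) + stats::runif(1, -spread, spread)
      u <- c(cos(ang), sin(ang))
      lmax <- if (try <= 80L) p$axoneme_length_px[2] else mean(p$axoneme_length_px)
      L <- stats::runif(1, p$axoneme_length_px[1], lmax)
      perp <- c(-u[2], u[1])
      curv <- stats::runif(1, -0.2, 0.2) * L
      p0 <- bb[i, ]
      st <- stroke_template(p0, p0 + (L / 2) * u + curv * perp,
                            p0 + L * u + 0.3 * curv * perp,
                            p$axoneme_width_px, p$amplitudes[["cilium"]], dm)
      if (!st$inbounds) next
      foot <- dilate_idx(st$truth, 2L, dm)
      if (any(occ[foot])) next
      clash_bb <- occ_bb[foot]
      clash_bb[foot %in% bb_foot[[i]]] <- FALSE
      if (any(clash_bb)) next
      return(list(st = st, foot = foot))
    }
    # deterministic straight sweep at minimum length
    for (ang in seq(0, 2 * pi, length.out = 91L)[-91L]) {
      u <- c(cos(ang), sin(ang))
      L <- p$axoneme_length_px[1]
      p0 <- bb[i, ]
      st <- stroke_template(p0, p0 + (L / 2) * u, p0 + L * u,
                            p$axoneme_width_px, p$amplitudes[["cilium"]], dm)
      if (!st$inbounds) next
      foot <- dilate_idx(st$truth, 2L, dm)
      clash_bb <- occ_bb[foot]
      clash_bb[foot %in% bb_foot[[i]]] <- FALSE
      if (any(occ[foot]) || any(clash_bb)) next
      return(list(st = st, foot = foot))
    }
    NULL
  }
  axoneme_pixels <- vector("list", p$n_cells)
  for (i in seq_len(p$n_cells)) {
    if (!ciliated[i]) next
    hit <- try_axoneme(i)
    if (is.null(hit) && !(i %in% mtoc_host)) {
      # relocate this cell's basal body around its nucleus and retry
      for (reloc in seq_len(30L)) {
        th <- stats::runif(1, 0, 2 * pi)
        cand <- centers[i, ] + bb_off * c(cos(th), sin(th))
        inb <- cand[1] > 6 && cand[1] < nr - 6 && cand[2] > 6 && cand[2] < nc - 6
        if (!inb) next
        d2 <- (bb[, 1] - cand[1])^2 + (bb[, 2] - cand[2])^2
        d2[i] <- Inf
        if (min(d2) < 8^2) next
        foot_new <- neighborhood_indices(cand, disc_offsets(3), dm)
        if (any(occ[foot_new])) next
        other_bb <- occ_bb
        other_bb[bb_foot[[i]]] <- FALSE
        if (any(other_bb[foot_new])) next
        occ_bb[bb_foot[[i]]] <- FALSE
        bb[i, ] <- cand
        bb_foot[[i]] <- foot_new
        occ_bb[foot_new] <- TRUE
        hit <- try_axoneme(i, n_random = 60L)
        if (!is.null(hit)) break
      }
    }
    if (is.null(hit)) stopf("could not place a non-overlapping axoneme; lower n_cells")
    ch$cilium <- stamp(ch$cilium, hit$st$idx, hit$st$val)
    axoneme_pixels[[i]] <- hit$st$truth
    occ[hit$foot] <- TRUE
  }

  # --- render basal-body puncta at their final positions ---
  for (i in seq_len(p$n_cells)) {
    t2 <- punctum_template(bb[i, ], p$bb_diameter_px, p$amplitudes[["basal_body"]], dm)
    ch$basal_body <- stamp(ch$basal_body, t2$idx, t2$val)
  }

  # --- detached cytoplasmic streaks ---
  streak_pixels <- list()
  clearance <- disc_offsets(8)
  if (p$n_cytoplasmic_streaks > 0L) {
    bb_clear <- logical(nr * nc)
    for (i in seq_len(p$n_cells))
      bb_clear[neighborhood_indices(bb[i, ], clearance, dm)] <- TRUE
    for (s in seq_len(p$n_cytoplasmic_streaks)) {
      placed <- FALSE
      for (try in seq_len(300L)) {
        c0 <- c(stats::runif(1, margin, nr - margin), stats::runif(1, margin, nc - margin))
        ang <- stats::runif(1, 0, 2 * pi)
        u <- c(cos(ang), sin(ang))
        L <- stats::runif(1, p$axoneme_length_px[1], p$axoneme_length_px[2])
        perp <- c(-u[2], u[1])
        curv <- stats::runif(1, -0.2, 0.2) * L
        st <- stroke_template(c0, c0 + (L / 2) * u + curv * perp,
                              c0 + L * u + 0.3 * curv * perp,
                              p$axoneme_width_px, p$amplitudes[["cilium"]], dm)
        if (!st$inbounds) next
        foot <- dilate_idx(st$truth, 2L, dm)
        if (any(occ[foot]) || any(bb_clear[foot])) next
        ch$cilium <- stamp(ch$cilium, st$idx, st$val)
        streak_pixels[[length(streak_pixels) + 1L]] <- st$truth
        occ[foot] <- TRUE
        placed <- TRUE
        break
      }
      if (!placed) stopf("could not place a detached streak; lower object counts")
    }
  }

  # --- background, noise ---
  gdir <- stats::runif(2)
  grad <- p$background_gradient *
    (outer(seq(0, gdir[1], length.out = nr), seq(0, gdir[2], length.out = nc), "+")) /
    max(gdir[1] + gdir[2], .Machine$double.eps)
  for (nm in names(ch)) {
    v <- ch[[nm]] + p$background_offset + grad
    if (isTRUE(p$photon_noise)) v <- matrix(stats::rpois(nr * nc, pmax(v, 0)), nr, nc)
    v <- v + matrix(stats::rnorm(nr * nc, 0, p$noise_sigma[[nm]]), nr, nc)
    v[v < 0] <- 0
    ch[[nm]] <- v
  }

  cells <- data.frame(
    cell = seq_len(p$n_cells),
    nucleus_row = if (p$n_cells) centers[, 1] - 1 else numeric(0),
    nucleus_col = if (p$n_cells) centers[, 2] - 1 else numeric(0),
    bb_row = if (p$n_cells) bb[, 1] - 1 else numeric(0),
    bb_col = if (p$n_cells) bb[, 2] - 1 else numeric(0),
    ciliated = as.integer(ciliated),
    mtoc = seq_len(p$n_cells) %in% mtoc_host)

  field <- structure(list(well_id = well_id, field_index = as.integer(field_index),
                          channels = ch, pixel_size_um = p$pixel_size_um,
                          z_projected = FALSE),
                     class = "field_image")
  truth <- list(cells = cells, axoneme_pixels = axoneme_pixels,
                confounders = list(streaks = streak_pixels, mtocs = mtoc_pixels),
                percent_ciliated = if (p$n_cells) 100 * mean(ciliated) else NA_real_)
  list(field = field, truth = truth)
}

#' Generate a synthetic plate
#'
#' One seeded field set per non-empty well of the layout. Per-well ciliation
#' fractions come from `role_effects`, looked up by `compound_id` first and
#' by `role` otherwise. Wells are independently reproducible through a
#' counter-based seed scheme: `seed + 7919 * well_index + 131 * field_index`.
#'
#' @param layout A `plate_layout`.
#' @param role_effects Named list/vector mapping roles (and optionally
#'   compound ids) to ciliation fractions. Defaults mirror the assay's
#'   biology: scrambled-siRNA controls ciliate (0.70), VHL-knockdown
#'   reference wells largely do not (0.20).
#' @param params Base [synth_params()] (per-well seed and fraction are
#'   overridden).
#' @param seed Plate-level seed.
#' @param fields_per_well Fields imaged per well (default 4).
#' @param out_dir Optional directory: when given, fields are written as
#'   16-bit TIFFs (`<well>_f<field>.tif`) with a `truth.csv` table instead of
#'   being returned in memory.
#' @return List with `fields` (named list well -> list of
#'   [generate_field()] outputs; `NULL` when `out_dir` is used) and `truth`
#'   (per-well data frame: `well`, `role`, `fraction`, `n_cells`,
#'   `truth_percent_ciliated`).
#' @export
generate_plate <- function(layout, role_effects = c(positive_control = 0.70,
                                                    negative_reference = 0.20,
                                                    compound = 0.20),
                           params = synth_params(), seed = 1L,
                           fields_per_well = 4L, out_dir = NULL) {
  wells <- layout$wells[layout$wells$role != "empty", , drop = FALSE]
  fields <- if (is.null(out_dir)) stats::setNames(vector("list", nrow(wells)), wells$well)
            else NULL
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  truth <- data.frame(well = wells$well, role = wells$role,
                      fraction = NA_real_, n_cells = NA_integer_,
                      truth_percent_ciliated = NA_real_)
  for (i in seq_len(nrow(wells))) {
    fr <- lookup_effect(role_effects, wells$compound_id[i], wells$role[i])
    if (is.null(fr)) stopf("no ciliation fraction mapped for well %s (role %s)",
                           wells$well[i], wells$role[i])
    wf <- vector("list", fields_per_well)
    n_cil <- 0L; n_tot <- 0L
    for (f in seq_len(fields_per_well)) {
      p <- params
      p$ciliation_fraction <- fr
      p$seed <- (params$seed + seed + 7919L * i + 131L * (f - 1L)) %% 2147483647L
      g <- generate_field(p, well_id = wells$well[i], field_index = f - 1L)
      n_cil <- n_cil + sum(g$truth$cells$ciliated)
      n_tot <- n_tot + nrow(g$truth$cells)
      if (is.null(out_dir)) wf[[f]] <- g
      else {
        write_field_tiff(g$field, file.path(out_dir,
                                            sprintf("%s_f%d.tif", wells$well[i], f - 1L)))
      }
    }
    if (is.null(out_dir)) fields[[i]] <- wf
    truth$fraction[i] <- fr
    truth$n_cells[i] <- n_tot
    truth$truth_percent_ciliated[i] <- if (n_tot) 100 * n_cil / n_tot else NA_real_
  }
  if (!is.null(out_dir))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  list(fields = fields, truth = truth)
}

#' Simulate per-well screen readouts (no images)
#'
#' Fast value-level simulator for studying the plate statistics themselves:
#' per-well percent-ciliated values are drawn as Normal(100 f, cv * 100 f)
#' for each well's mapped ciliation fraction f, and cell counts as
#' Normal(n_cells, cv * n_cells), truncated at zero.
#'
#' @param layout A `plate_layout`.
#' @param role_effects Named map role/compound -> ciliation fraction (see
#'   [generate_plate()]).
#' @param cv Coefficient of variation of both readouts (default 0.05).
#' @param n_cells_per_well Mean cell count per well (default 450).
#' @param seed Integer seed.
#' @return A wells data frame suitable for [screen_stats()].
#' @export
simulate_plate_values <- function(layout, role_effects = c(positive_control = 0.70,
                                                           negative_reference = 0.20,
                                                           compound = 0.20),
                                  cv = 0.05, n_cells_per_well = 450, seed = 1L) {
  wells <- layout$wells[layout$wells$role != "empty", , drop = FALSE]
  with_seed(seed, {
    fr <- vapply(seq_len(nrow(wells)), function(i) {
      v <- lookup_effect(role_effects, wells$compound_id[i], wells$role[i])
      if (is.null(v)) stopf("no ciliation fraction mapped for well %s", wells$well[i])
      v
    }, numeric(1))
    pc <- pmin(100, pmax(0, stats::rnorm(nrow(wells), 100 * fr, cv * 100 * fr)))
    n <- pmax(0, round(stats::rnorm(nrow(wells), n_cells_per_well,
                                    cv * n_cells_per_well)))
    data.frame(well = wells$well, treatment = wells$treatment, role = wells$role,
               cell_count = n, ciliated_count = round(n * pc / 100),
               percent_ciliated = pc)
  })
}
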