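#' Filter-cascade parameters
#'
#' Thresholds for the five-stage candidate filter cascade that turns raw
#' cilia candidates into accepted primary cilia: touching (axoneme must abut
#' its basal body), size, mask-area ratio (removes mitotic-organizing
#' centers), signal-to-background ratio, and local centrosome SD distance.
#' All boundary comparisons are inclusive.
#'
#' @param touch_max_gap_px Maximum tolerated gap, in pixels, between a
#'   candidate and the nearest basal-body pixel (Chebyshev metric; adjacent
#'   pixels have gap 0). Default 1: segmentation may erode one pixel at the
#'   axoneme base.
#' @param cilium_min_area_px,cilium_max_area_px Closed area bounds (pixels^2)
#'   for the size-exclusion filter.
#' @param max_mask_area_ratio Maximum candidate area as a fraction of its
#'   linked basal body's local-neighborhood area. The local percentile cut
#'   retains at most the top (100 - `local_pctl_cut`)% of neighborhood pixels
#'   (20% at the default cut), so ratios are bounded by ~0.2; the default 0.1
#'   sits halfway to that bound and removes blob-like mitotic-organizing
#'   centers while thin axonemes score well below 0.05.
#' @param min_snr Minimum signal-to-background ratio: mean raw candidate
#'   intensity over mean raw intensity of the local background (the linked
#'   neighborhood minus all candidate and basal-body pixels).
#' @param min_sd_distance Minimum number of local-centrosome-mask standard
#'   deviations the candidate's mean raw intensity must lie above the local
#'   mean (default 2, the assay's fixed criterion).
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(touch_max_gap_px = 1,
                          cilium_min_area_px = 5,
                          cilium_max_area_px = 4000,
                          max_mask_area_ratio = 0.1,
                          min_snr = 2.0,
                          min_sd_distance = 2.0) {
  p <- list(touch_max_gap_px = touch_max_gap_px,
            cilium_min_area_px = cilium_min_area_px,
            cilium_max_area_px = cilium_max_area_px,
            max_mask_area_ratio = max_mask_area_ratio,
            min_snr = min_snr, min_sd_distance = min_sd_distance)
  if (p$touch_max_gap_px < 0) stopf("touch_max_gap_px must be >= 0")
  if (any(unlist(p[-1]) <= 0)) stopf("filter thresholds must be positive")
  if (p$cilium_min_area_px > p$cilium_max_area_px)
    stopf("cilium_min_area_px must not exceed cilium_max_area_px")
  structure(p, class = "filter_params")
}

#' Build cilia candidates from a raw candidate mask
#'
#' Converts a candidate `label_mask` into a `cilia_candidates` object: the
#' per-candidate pixel sets plus a flag table that the filter stages fill in.
#'
#' @param candidate_mask `label_mask` from [cluster_segment_cilia()].
#' @return A `cilia_candidates` object (list with `dim`, `pixels`, `table`).
#' @export
as_candidates <- function(candidate_mask) {
  labels <- candidate_mask$labels
  n <- max(labels, 0L)
  idx <- which(labels > 0L)
  pixels <- if (n > 0L) split(idx, factor(labels[idx], levels = seq_len(n)))
            else list()
  tab <- data.frame(label = seq_len(n),
                    area_px = if (n > 0L) unname(lengths(pixels)) else integer(0),
                    linked_bb = rep(NA_integer_, n),
                    touch_dist_px = rep(NA_real_, n),
                    mask_area_ratio = rep(NA_real_, n), snr = rep(NA_real_, n),
                    sd_distance = rep(NA_real_, n),
                    pass_touching = rep(NA, n), pass_size = rep(NA, n),
                    pass_ratio = rep(NA, n), pass_snr = rep(NA, n),
                    pass_sd = rep(NA, n),
                    first_fail = rep(NA_character_, n), accepted = rep(NA, n),
                    row.names = NULL)
  structure(list(dim = dim(labels), pixels = unname(pixels), table = tab),
            class = "cilia_candidates")
}

# Local-neighborhood linear-index sets for every basal body, clipped to the
# field. Cached on the candidates object by the cascade.
bb_neighborhoods <- function(bb_mask) {
  radius <- bb_mask$local_radius_px
  if (is.null(radius)) stopf("basal-body mask carries no local_radius_px")
  offs <- disc_offsets(radius)
  tab <- bb_mask$table
  lapply(seq_len(nrow(tab)), function(i)
    neighborhood_indices(c(tab$centroid_row[i] + 1, tab$centroid_col[i] + 1),
                         offs, dim(bb_mask$labels)))
}

#' Touching filter
#'
#' A candidate passes if any of its pixels lies within `touch_max_gap_px`
#' empty pixels of a basal-body pixel (Chebyshev distance <= gap + 1;
#' overlapping counts as gap 0). The candidate is linked to the nearest such
#' basal body; ties at equal distance resolve to the lower label.
#'
#' @param candidates A `cilia_candidates` object.
#' @param bb_mask Basal-body `label_mask`.
#' @param touch_max_gap_px Gap tolerance in pixels.
#' @param link_all If `TRUE` (used by the cascade's ablation switch), failing
#'   candidates are still linked to the basal body with the nearest centroid
#'   so that downstream local statistics remain defined.
#' @return The candidates with `linked_bb`, `touch_dist_px` and
#'   `pass_touching` filled in.
#' @export
filter_touching <- function(candidates, bb_mask, touch_max_gap_px = 1,
                            link_all = FALSE) {
  if (!identical(candidates$dim, dim(bb_mask$labels)))
    stopf("candidate and basal-body masks differ in shape")
  tab <- candidates$table
  max_d <- as.integer(touch_max_gap_px) + 1L
  nl <- nearest_label_map(bb_mask$labels, max_d)
  for (i in seq_len(nrow(tab))) {
    px <- candidates$pixels[[i]]
    d <- nl$dist[px]
    if (all(is.na(d))) {
      tab$pass_touching[i] <- FALSE
      if (link_all && nrow(bb_mask$table) > 0L) {
        # centroid-based fallback link for ablation runs
        nr <- candidates$dim[1]
        cr <- mean((px - 1L) %% nr); cc <- mean((px - 1L) %/% nr)
        dd <- (bb_mask$table$centroid_row - cr)^2 + (bb_mask$table$centroid_col - cc)^2
        tab$linked_bb[i] <- bb_mask$table$label[which.min(dd)]
      }
    } else {
      dmin <- min(d, na.rm = TRUE)
      at <- px[!is.na(d) & d == dmin]
      tab$linked_bb[i] <- min(nl$label[at])
      tab$touch_dist_px[i] <- dmin
      tab$pass_touching[i] <- TRUE  # dmin <= max_d by construction
    }
  }
  candidates$table <- tab
  candidates
}

#' Size-exclusion filter
#'
#' Pass iff the candidate area lies in the closed interval
#' `[cilium_min_area_px, cilium_max_area_px]`.
#'
#' @param candidates A `cilia_candidates` object.
#' @param cilium_min_area_px,cilium_max_area_px Area bounds (pixels^2).
#' @return Candidates with `pass_size` filled in.
#' @export
filter_size <- function(candidates, cilium_min_area_px = 5,
                        cilium_max_area_px = 4000) {
  a <- candidates$table$area_px
  candidates$table$pass_size <- a >= cilium_min_area_px & a <= cilium_max_area_px
  candidates
}

#' Mask-area-ratio filter
#'
#' Removes objects that take up the linked basal body's local neighborhood —
#' the signature of mitotic-organizing centers. Pass iff
#' `area / neighborhood_area <= max_mask_area_ratio` (inclusive).
#'
#' @param candidates Candidates with `linked_bb` set (cascade order).
#' @param bb_mask Basal-body `label_mask`.
#' @param max_mask_area_ratio Maximum allowed ratio.
#' @param neighborhoods Optional precomputed [bb_neighborhoods()] list.
#' @return Candidates with `mask_area_ratio` and `pass_ratio` filled in.
#' @export
filter_mask_ratio <- function(candidates, bb_mask, max_mask_area_ratio = 0.1,
                              neighborhoods = NULL) {
  tab <- candidates$table
  if (any(is.na(tab$linked_bb) & is.na(tab$pass_touching)))
    stopf("filter_mask_ratio requires linked candidates (run filter_touching first)")
  if (is.null(neighborhoods)) neighborhoods <- bb_neighborhoods(bb_mask)
  for (i in seq_len(nrow(tab))) {
    b <- tab$linked_bb[i]
    if (is.na(b)) next
    tab$mask_area_ratio[i] <- tab$area_px[i] / length(neighborhoods[[b]])
    tab$pass_ratio[i] <- tab$mask_area_ratio[i] <= max_mask_area_ratio
  }
  candidates$table <- tab
  candidates
}

#' Signal-to-background filter
#'
#' Uses the raw (background-subtracted, pre-enhancement) cilium channel:
#' snr = mean candidate intensity / mean intensity of the local background,
#' where the local background is the linked neighborhood minus all candidate
#' pixels and all basal-body pixels. A zero-mean background gives snr = Inf
#' (pass). Pass iff snr >= `min_snr`.
#'
#' @param candidates Candidates with `linked_bb` set.
#' @param raw_cilium Raw cilium channel matrix.
#' @param bb_mask Basal-body `label_mask`.
#' @param min_snr Minimum ratio.
#' @param neighborhoods Optional precomputed [bb_neighborhoods()] list.
#' @return Candidates with `snr` and `pass_snr` filled in.
#' @export
filter_snr <- function(candidates, raw_cilium, bb_mask, min_snr = 2,
                       neighborhoods = NULL) {
  tab <- candidates$table
  if (is.null(neighborhoods)) neighborhoods <- bb_neighborhoods(bb_mask)
  excl <- c(unlist(candidates$pixels), which(bb_mask$labels > 0L))
  for (i in seq_len(nrow(tab))) {
    b <- tab$linked_bb[i]
    if (is.na(b)) next
    bg_idx <- setdiff(neighborhoods[[b]], excl)
    cand_mean <- mean(raw_cilium[candidates$pixels[[i]]])
    bg_mean <- if (length(bg_idx)) mean(raw_cilium[bg_idx]) else 0
    tab$snr[i] <- if (bg_mean == 0) Inf else cand_mean / bg_mean
    tab$pass_snr[i] <- tab$snr[i] >= min_snr
  }
  candidates$table <- tab
  candidates
}

#' Local centrosome SD-distance filter
#'
#' The candidate's mean raw cilium-channel intensity must lie at least
#' `min_sd_distance` standard deviations above the mean intensity under the
#' linked basal body's local centrosome mask (the local neighborhood
#' excluding all candidate pixels, so that the candidate cannot inflate its
#' own reference). With a zero local SD the candidate passes iff its mean
#' exceeds the local mean. Pass is boundary-inclusive.
#'
#' @param candidates Candidates with `linked_bb` set.
#' @param raw_cilium Raw cilium channel matrix.
#' @param bb_mask Basal-body `label_mask`.
#' @param min_sd_distance Minimum SD distance (default 2).
#' @param neighborhoods Optional precomputed [bb_neighborhoods()] list.
#' @return Candidates with `sd_distance` and `pass_sd` filled in.
#' @export
filter_centrosome_sd <- function(candidates, raw_cilium, bb_mask,
                                 min_sd_distance = 2, neighborhoods = NULL) {
  tab <- candidates$table
  if (is.null(neighborhoods)) neighborhoods <- bb_neighborhoods(bb_mask)
  cand_px <- unlist(candidates$pixels)
  for (i in seq_len(nrow(tab))) {
    b <- tab$linked_bb[i]
    if (is.na(b)) next
    mask_idx <- setdiff(neighborhoods[[b]], cand_px)
    cand_mean <- mean(raw_cilium[candidates$pixels[[i]]])
    if (length(mask_idx) < 2L) { tab$sd_distance[i] <- Inf; tab$pass_sd[i] <- TRUE; next }
    mu <- mean(raw_cilium[mask_idx])
    sg <- stats::sd(raw_cilium[mask_idx])
    if (sg == 0) {
      tab$sd_distance[i] <- if (cand_mean > mu) Inf else 0
      tab$pass_sd[i] <- cand_mean > mu
    } else {
      tab$sd_distance[i] <- (cand_mean - mu) / sg
      tab$pass_sd[i] <- tab$sd_distance[i] >= min_sd_distance
    }
  }
  candidates$table <- tab
  candidates
}

#' Run the full candidate filter cascade
#'
#' Applies the five filters in assay order — touching, size, mask-area ratio,
#' signal-to-background, centrosome SD distance. Acceptance is conjunctive
#' (order affects only the `first_fail` bookkeeping). Candidates that fail a
#' stage remain in the flag table with their first failing stage recorded;
#' stages whose statistics cannot be computed for an unlinked candidate stay
#' `NA`. Individual stages can be ablated via `skip` to demonstrate their
#' necessity.
#'
#' @param candidate_mask `label_mask` of raw candidates (or a
#'   `cilia_candidates` object).
#' @param bb_mask Basal-body `label_mask` (with `local_radius_px`).
#' @param raw_cilium Raw background-subtracted cilium channel.
#' @param params A [filter_params()] object.
#' @param skip Character vector of stages to ablate, among
#'   `"touching"`, `"size"`, `"ratio"`, `"snr"`, `"sd"`.
#' @return A `cilia_candidates` object whose table has all flags,
#'   `first_fail` and `accepted` filled in.
#' @export
run_filter_cascade <- function(candidate_mask, bb_mask, raw_cilium,
                               params = filter_params(), skip = character(0)) {
  stages <- c("touching", "size", "ratio", "snr", "sd")
  bad <- setdiff(skip, stages)
  if (length(bad)) stopf("unknown filter stage(s): %s", paste(bad, collapse = ", "))
  cand <- if (inherits(candidate_mask, "cilia_candidates")) candidate_mask
          else as_candidates(candidate_mask)
  nb <- bb_neighborhoods(bb_mask)
  cand <- filter_touching(cand, bb_mask, params$touch_max_gap_px,
                          link_all = "touching" %in% skip)
  cand <- filter_size(cand, params$cilium_min_area_px, params$cilium_max_area_px)
  cand <- filter_mask_ratio(cand, bb_mask, params$max_mask_area_ratio, neighborhoods = nb)
  cand <- filter_snr(cand, raw_cilium, bb_mask, params$min_snr, neighborhoods = nb)
  cand <- filter_centrosome_sd(cand, raw_cilium, bb_mask, params$min_sd_distance,
                               neighborhoods = nb)
  tab <- cand$table
  flags <- cbind(touching = tab$pass_touching, size = tab$pass_size,
                 ratio = tab$pass_ratio, snr = tab$pass_snr, sd = tab$pass_sd)
  for (s in skip) flags[, s] <- TRUE
  pass_all <- apply(flags, 1L, function(f) all(f %in% TRUE))
  first_fail <- apply(flags, 1L, function(f) {
    bad <- which(!(f %in% TRUE)); if (length(bad)) stages[bad[1]] else NA_character_
  })
  tab$accepted <- pass_all
  tab$first_fail <- first_fail
  cand$table <- tab
  cand
}

#' Accepted-cilia table
#'
#' Convenience accessor: the rows of the cascade flag table that passed every
#' stage.
#'
#' @param candidates Output of [run_filter_cascade()].
#' @return Data frame of accepted candidates.
#' @export
accepted_cilia <- function(candidates) {
  candidates$table[candidates$table$accepted %in% TRUE, , drop = FALSE]
}
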