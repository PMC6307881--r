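#' Segmentation parameters
#'
#' Bundles the tunable parameters of the per-field segmentation stages:
#' background subtraction, nucleus and basal-body mask generation, the
#' aggressive contrast stretch of the cilium channel, the local
#' basal-body-neighborhood percentile cut, and the three-class intensity
#' clustering that yields raw cilia candidates.
#'
#' @param bg_method Background-subtraction method, `"rolling_ball"`
#'   (grayscale opening with a disc structuring element) or `"mode"`
#'   (subtract the modal pixel value of the field).
#' @param ball_radius_px Rolling-ball (disc) radius in pixels.
#' @param bb_local_radius_px Radius (pixels) of the circular local
#'   neighborhood attached to every basal body; this single region serves as
#'   the normalization mask, the local-background region for the
#'   signal-to-background filter, and the local centrosome mask for the
#'   SD-distance filter.
#' @param bb_min_area_px,bb_max_area_px Area bounds (pixels^2) for basal-body
#'   objects; objects outside the closed interval are removed (aggregates,
#'   specks).
#' @param bb_smooth_sigma Gaussian pre-smoothing sigma (pixels) applied to the
#'   basal-body channel before the Otsu auto-threshold. Puncta channels have a
#'   tiny foreground fraction; without smoothing the threshold collapses into
#'   the noise floor.
#' @param nucleus_min_area_px Minimum nucleus area (pixels^2).
#' @param nucleus_smooth_sigma Gaussian pre-smoothing sigma for the nuclei
#'   channel.
#' @param contrast_low_pct Percentage of top pixel intensities driven to
#'   saturation (1.0 by the stretch; default 1).
#' @param contrast_high_pct Percentage of the intensity distribution mapped
#'   into the usable range; the (100 - `contrast_high_pct`)-th percentile is
#'   the black point (default 98, i.e. the 2nd percentile maps to 0).
#' @param local_pctl_cut Percentile (default 80) below which pixels inside a
#'   basal body's local neighborhood are zeroed during local background
#'   normalization.
#' @param cluster_k Number of intensity classes for the cluster segmentation
#'   of the cilium channel (>= 3; the highest class is kept).
#' @return An object of class `segmentation_params` (a validated list).
#' @export
segmentation_params <- function(bg_method = c("rolling_ball", "mode"),
                                ball_radius_px = 25,
                                bb_local_radius_px = 50,
                                bb_min_area_px = 4,
                                bb_max_area_px = 200,
                                bb_smooth_sigma = 1,
                                nucleus_min_area_px = 60,
                                nucleus_smooth_sigma = 2,
                                contrast_low_pct = 1,
                                contrast_high_pct = 98,
                                local_pctl_cut = 80,
                                cluster_k = 3L) {
  bg_method <- match.arg(bg_method)
  p <- list(bg_method = bg_method, ball_radius_px = ball_radius_px,
            bb_local_radius_px = bb_local_radius_px,
            bb_min_area_px = bb_min_area_px, bb_max_area_px = bb_max_area_px,
            bb_smooth_sigma = bb_smooth_sigma,
            nucleus_min_area_px = nucleus_min_area_px,
            nucleus_smooth_sigma = nucleus_smooth_sigma,
            contrast_low_pct = contrast_low_pct,
            contrast_high_pct = contrast_high_pct,
            local_pctl_cut = local_pctl_cut, cluster_k = as.integer(cluster_k))
  if (!(p$contrast_low_pct >= 0 && p$contrast_low_pct < p$contrast_high_pct &&
        p$contrast_high_pct <= 100))
    stopf("require 0 <= contrast_low_pct < contrast_high_pct <= 100")
  for (f in c("ball_radius_px", "bb_local_radius_px", "bb_min_area_px",
              "bb_max_area_px", "nucleus_min_area_px"))
    if (p[[f]] <= 0) stopf("%s must be > 0", f)
  if (p$cluster_k < 3L) stopf("cluster_k must be >= 3")
  if (!(p$local_pctl_cut > 0 && p$local_pctl_cut < 100))
    stopf("local_pctl_cut must lie in (0, 100)")
  structure(p, class = "segmentation_params")
}

#' Subtract image background
#'
#' `rolling_ball` estimates the background as the grayscale opening of the
#' field with a disc structuring element of radius `ball_radius_px` and
#' subtracts it; `mode` subtracts the modal pixel value (the "black space"
#' level). Output is clipped at zero.
#'
#' @param channel 2D numeric matrix of finite, non-negative intensities.
#' @param method `"rolling_ball"` or `"mode"`.
#' @param ball_radius_px Disc radius in pixels (rolling_ball only).
#' @return Matrix of the same shape, non-negative.
#' @export
subtract_background <- function(channel, method = c("rolling_ball", "mode"),
                                ball_radius_px = 25) {
  method <- match.arg(method)
  if (!all(is.finite(channel))) stopf("channel contains non-finite pixels")
  if (method == "rolling_ball") {
    if (is.null(ball_radius_px) || ball_radius_px <= 0)
      stopf("ball_radius_px must be a positive number for rolling_ball")
    # Euclidean disc structuring element (dr^2 + dc^2 <= r^2). The field is
    # edge-replicated by r before the opening and cropped afterwards, so
    # border estimates use real edge values rather than implicit zeros.
    # EBImage grayscale morphology operates on [0, 1]; intensities are
    # rescaled by the field maximum around the call (exactly invertible).
    r <- ceiling(ball_radius_px)
    off <- disc_offsets(ball_radius_px)
    brush <- matrix(0L, 2L * r + 1L, 2L * r + 1L)
    brush[cbind(off[, 1] + r + 1L, off[, 2] + r + 1L)] <- 1L
    m <- max(channel)
    if (m <= 0) return(matrix(0, nrow(channel), ncol(channel)))
    ri <- c(rep(1L, r), seq_len(nrow(channel)), rep(nrow(channel), r))
    ci <- c(rep(1L, r), seq_len(ncol(channel)), rep(ncol(channel), r))
    bg <- EBImage::opening(channel[ri, ci] / m, brush)[r + seq_len(nrow(channel)),
                                                       r + seq_len(ncol(channel))] * m
  } else {
    bg <- pixel_mode(channel)
  }
  out <- channel - bg
  out[out < 0] <- 0
  matrix(as.numeric(out), nrow(channel))
}

# Modal pixel value: exact tabulation for quantized data, 256-bin histogram
# midpoint otherwise. Ties -> lowest value (black space wins).
pixel_mode <- function(channel) {
  v <- as.numeric(channel)
  if (all(v == round(v))) {
    tab <- table(v)
    as.numeric(names(tab)[which.max(tab)])
  } else {
    h <- graphics::hist(v, breaks = 256, plot = FALSE)
    h$mids[which.max(h$counts)]
  }
}

# Build a label-mask object: integer label matrix plus an object table with
# 0-based (row, col) centroids and mean raw intensity per object.
new_label_mask <- function(labels, intensity = NULL) {
  labels <- matrix(as.integer(labels), nrow(labels))
  n <- max(labels, 0L)
  if (n == 0L) {
    tab <- data.frame(label = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      mean_intensity = numeric(0))
  } else {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    nr <- nrow(labels)
    row0 <- (idx - 1L) %% nr       # 0-based
    col0 <- (idx - 1L) %/% nr
    area <- tabulate(lab, nbins = n)
    tab <- data.frame(
      label = seq_len(n),
      area = area,
      centroid_row = as.numeric(tapply(row0, lab, mean)),
      centroid_col = as.numeric(tapply(col0, lab, mean)),
      mean_intensity = if (is.null(intensity)) NA_real_ else
        as.numeric(tapply(intensity[idx], lab, mean)))
  }
  structure(list(labels = labels, table = tab), class = "label_mask")
}

# Drop objects whose area falls outside [min_area, max_area] and relabel 1..n
# in column-major first-pixel order.
filter_relabel <- function(labels, min_area = 1, max_area = Inf) {
  n <- max(labels, 0L)
  if (n == 0L) return(labels)
  area <- tabulate(labels[labels > 0L], nbins = n)
  keep <- which(area >= min_area & area <= max_area)
  out <- matrix(0L, nrow(labels), ncol(labels))
  if (length(keep)) {
    idx <- which(labels %in% keep)
    old <- labels[idx]
    first <- !duplicated(old)
    relab <- integer(n)
    relab[old[first]] <- seq_along(keep)
    out[idx] <- relab[old]
  }
  out
}

# Scale-covariant Otsu threshold: histogram over [0, max(x)] with 256 levels.
# Returns Inf for a blank image so that `x > th` is empty.
auto_threshold <- function(x) {
  m <- max(x)
  if (m <= 0) return(Inf)
  EBImage::otsu(x / m, range = c(0, 1), levels = 256L) * m
}

#' Segment nuclei
#'
#' Gaussian smoothing, Otsu auto-threshold, hole filling, and a seeded
#' watershed on the distance transform to split touching nuclei; objects
#' below `nucleus_min_area_px` are removed. The number of retained labels is
#' the field's cell count.
#'
#' @param channel Background-subtracted nuclei channel (matrix).
#' @param params A [segmentation_params()] object.
#' @return A `label_mask` (list with the integer `labels` matrix and an object
#'   `table` of label, area, 0-based centroid and mean intensity).
#' @export
segment_nuclei <- function(channel, params = segmentation_params()) {
  sm <- EBImage::gblur(channel, sigma = params$nucleus_smooth_sigma)
  sm[sm < 0] <- 0
  th <- auto_threshold(sm)
  mask <- sm > th
  if (!any(mask)) return(new_label_mask(matrix(0L, nrow(channel), ncol(channel)), channel))
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  dm <- EBImage::distmap(mask)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  labels <- filter_relabel(matrix(as.integer(EBImage::imageData(ws)), nrow(channel)),
                           min_area = params$nucleus_min_area_px)
  new_label_mask(labels, channel)
}

#' Segment basal bodies
#'
#' Gaussian smoothing, a scale-covariant Otsu auto-threshold, connected-
#' component labeling, and closed-interval area filtering to remove specks
#' and aggregates. The returned mask carries `local_radius_px`, defining each
#' basal body's circular local neighborhood used by the normalization and
#' filter stages.
#'
#' @param channel Background-subtracted basal-body channel (matrix).
#' @param params A [segmentation_params()] object.
#' @return A `label_mask` with attribute fields `local_radius_px`.
#' @export
segment_basal_bodies <- function(channel, params = segmentation_params()) {
  sm <- EBImage::gblur(channel, sigma = params$bb_smooth_sigma)
  sm[sm < 0] <- 0
  th <- auto_threshold(sm)
  mask <- sm > th
  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labels <- filter_relabel(matrix(as.integer(EBImage::imageData(labels)), nrow(channel)),
                           min_area = params$bb_min_area_px,
                           max_area = params$bb_max_area_px)
  m <- new_label_mask(labels, channel)
  m$local_radius_px <- params$bb_local_radius_px
  m
}

#' Aggressive linear contrast enhancement
#'
#' Linear stretch of the cilium channel: the top `contrast_low_pct` percent of
#' pixel intensities saturate at 1 and the (100 - `contrast_high_pct`)-th
#' percentile maps to 0; values in between are linear. The transform is
#' monotone non-decreasing.
#'
#' @param channel Background-subtracted cilium channel (matrix).
#' @param contrast_low_pct,contrast_high_pct See [segmentation_params()].
#' @return Matrix with values in `[0, 1]`. A constant input yields all zeros
#'   with a warning (degenerate percentiles).
#' @export
enhance_contrast <- function(channel, contrast_low_pct = 1,
                             contrast_high_pct = 98) {
  if (!all(is.finite(channel))) stopf("channel contains non-finite pixels")
  v <- as.numeric(channel)
  hi <- stats::quantile(v, 1 - contrast_low_pct / 100, names = FALSE)
  lo <- stats::quantile(v, (100 - contrast_high_pct) / 100, names = FALSE)
  if (hi <= lo) {
    warnf("degenerate contrast percentiles (constant image?); returning zeros")
    return(matrix(0, nrow(channel), ncol(channel)))
  }
  out <- (channel - lo) / (hi - lo)
  out[out < 0] <- 0
  out[out > 1] <- 1
  matrix(as.numeric(out), nrow(channel))
}

#' Local background normalization under basal-body neighborhoods
#'
#' Multiplies the enhanced cilium channel by the normalization mask (the
#' union of all basal-body local neighborhoods: pixels outside every
#' neighborhood become 0), then removes, within each neighborhood, pixels
#' that do not exceed that neighborhood's `local_pctl_cut` intensity
#' percentile. A pixel covered by several neighborhoods survives if it
#' exceeds the cutoff of at least one of them.
#'
#' @param enhanced Contrast-enhanced cilium channel in `[0, 1]`.
#' @param bb_mask Basal-body `label_mask` from [segment_basal_bodies()].
#' @param params A [segmentation_params()] object (uses `local_pctl_cut` and
#'   `bb_local_radius_px` when the mask does not carry a radius).
#' @return Matrix of the same shape; zero wherever removed. All-zero when the
#'   field has no basal bodies.
#' @export
local_background_normalize <- function(enhanced, bb_mask,
                                       params = segmentation_params()) {
  if (!identical(dim(enhanced), dim(bb_mask$labels)))
    stopf("enhanced image and basal-body mask differ in shape")
  out <- matrix(0, nrow(enhanced), ncol(enhanced))
  tab <- bb_mask$table
  if (nrow(tab) == 0L) return(out)
  radius <- if (!is.null(bb_mask$local_radius_px)) bb_mask$local_radius_px
            else params$bb_local_radius_px
  offs <- disc_offsets(radius)
  p <- params$local_pctl_cut / 100
  for (i in seq_len(nrow(tab))) {
    idx <- neighborhood_indices(c(tab$centroid_row[i] + 1, tab$centroid_col[i] + 1),
                                offs, dim(enhanced))
    v <- enhanced[idx]
    cut <- stats::quantile(v, p, names = FALSE)
    keep <- idx[v > cut]
    out[keep] <- enhanced[keep]
  }
  out
}

# Deterministic 1-D k-means: centers initialized at fixed percentiles of the
# nonzero intensities, assignment ties broken toward the lower class, empty
# classes keep their center. Returns per-value class (1..k, ascending center).
kmeans1d <- function(x, k = 3L, max_iter = 100L, tol = 1e-6) {
  qs <- seq(0.1, 0.9, length.out = k)
  centers <- stats::quantile(x, qs, names = FALSE)
  for (it in seq_len(max_iter)) {
    d <- abs(outer(x, centers, "-"))
    cls <- max.col(-d, ties.method = "first") # first = lowest class on ties
    new_centers <- centers
    for (j in seq_len(k)) {
      if (any(cls == j)) new_centers[j] <- mean(x[cls == j])
    }
    if (max(abs(new_centers - centers)) < tol) { centers <- new_centers; break }
    centers <- new_centers
  }
  ord <- order(centers)
  rank <- integer(k); rank[ord] <- seq_len(k)
  list(class = rank[cls], centers = sort(centers))
}

#' Cluster-based segmentation of cilia candidates
#'
#' One-dimensional k-means clustering of the nonzero normalized intensities
#' into `cluster_k` (default 3) classes — high, medium, background. Only the
#' highest-mean class is retained; its 8-connected components become the raw
#' cilia candidates. With fewer than three distinct nonzero values the field
#' degenerates and all nonzero pixels are taken as the high class (warning).
#'
#' @param normalized Output of [local_background_normalize()].
#' @param cluster_k Number of intensity classes (>= 3).
#' @return A `label_mask` of raw cilia candidates.
#' @export
cluster_segment_cilia <- function(normalized, cluster_k = 3L) {
  idx <- which(normalized > 0)
  lab <- matrix(0L, nrow(normalized), ncol(normalized))
  if (length(idx) == 0L) return(new_label_mask(lab, normalized))
  v <- normalized[idx]
  if (length(unique(v)) < cluster_k) {
    warnf("fewer than %d distinct nonzero intensities; treating all nonzero pixels as high class",
          cluster_k)
    high <- idx
  } else {
    km <- kmeans1d(v, k = as.integer(cluster_k))
    high <- idx[km$class == cluster_k]
  }
  sel <- matrix(FALSE, nrow(normalized), ncol(normalized))
  sel[high] <- TRUE
  new_label_mask(label8(sel), normalized)
}
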