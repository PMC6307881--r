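#' Analyze one imaging field
#'
#' Runs the complete per-field pipeline: background subtraction of all three
#' channels, nucleus segmentation (cell count), basal-body segmentation,
#' aggressive contrast enhancement of the cilium channel, local background
#' normalization under the basal-body neighborhoods, three-class cluster
#' segmentation into raw cilia candidates, the five-stage filter cascade, and
#' per-basal-body Boolean ciliation assignment.
#'
#' @param field A `field_image` (from [load_field()] or [generate_field()]).
#' @param seg_params A [segmentation_params()] object.
#' @param filt_params A [filter_params()] object.
#' @param skip Filter stages to ablate (see [run_filter_cascade()]).
#' @return An object of class `field_result`: list with `well_id`,
#'   `field_index`, `nuclei_mask`, `bb_mask`, `candidates` (full flag table),
#'   `records` (per-basal-body ciliation), `cell_count` (nuclei) and
#'   `bb_count`.
#' @export
analyze_field <- function(field, seg_params = segmentation_params(),
                          filt_params = filter_params(), skip = character(0)) {
  ch <- field$channels
  bg <- lapply(ch, subtract_background, method = seg_params$bg_method,
               ball_radius_px = seg_params$ball_radius_px)
  nuclei_mask <- segment_nuclei(bg$nuclei, seg_params)
  bb_mask <- segment_basal_bodies(bg$basal_body, seg_params)
  enhanced <- enhance_contrast(bg$cilium, seg_params$contrast_low_pct,
                               seg_params$contrast_high_pct)
  normalized <- local_background_normalize(enhanced, bb_mask, seg_params)
  cand_mask <- cluster_segment_cilia(normalized, seg_params$cluster_k)
  cand <- run_filter_cascade(cand_mask, bb_mask, bg$cilium, filt_params, skip = skip)
  records <- assign_ciliation(bb_mask, cand)
  records$field_index <- field$field_index
  structure(list(well_id = field$well_id, field_index = field$field_index,
                 nuclei_mask = nuclei_mask, bb_mask = bb_mask,
                 candidates = cand, records = records,
                 cell_count = nrow(nuclei_mask$table),
                 bb_count = nrow(bb_mask$table)),
            class = "field_result")
}

#' Analyze all fields of one well
#'
#' Pools the per-field ciliation records of a well: the percent-ciliated
#' value is the mean Boolean over all basal bodies across fields, and the
#' cell count is the summed nucleus count (used by the toxicity filter). A
#' nucleus/basal-body count discrepancy above 20% is reported with a message.
#'
#' @param fields List of `field_image`s belonging to one well.
#' @param seg_params,filt_params,skip Passed to [analyze_field()].
#' @return List with `well_id`, `cell_count`, `bb_count`, `ciliated_count`,
#'   `percent_ciliated`, `fields` (per-field summary data frame) and
#'   `field_results`.
#' @export
analyze_well <- function(fields, seg_params = segmentation_params(),
                         filt_params = filter_params(), skip = character(0)) {
  if (length(fields) == 0L) stopf("well has no fields")
  res <- lapply(fields, analyze_field, seg_params = seg_params,
                filt_params = filt_params, skip = skip)
  records <- lapply(res, `[[`, "records")
  cell_count <- sum(vapply(res, `[[`, integer(1), "cell_count"))
  bb_count <- sum(vapply(res, `[[`, integer(1), "bb_count"))
  ciliated <- sum(unlist(lapply(records, function(r) r$ciliated)))
  if (cell_count > 0 && abs(bb_count - cell_count) / cell_count > 0.2)
    message(sprintf("well %s: nucleus count (%d) and basal-body count (%d) disagree by >20%%",
                    res[[1]]$well_id, cell_count, bb_count))
  per_field <- data.frame(
    field_index = vapply(res, `[[`, integer(1), "field_index"),
    cell_count = vapply(res, `[[`, integer(1), "cell_count"),
    bb_count = vapply(res, `[[`, integer(1), "bb_count"),
    ciliated_count = vapply(res, function(r) sum(r$records$ciliated), numeric(1)),
    percent_ciliated = vapply(res, function(r) percent_ciliated(r$records), numeric(1)))
  list(well_id = res[[1]]$well_id, cell_count = cell_count, bb_count = bb_count,
       ciliated_count = ciliated, percent_ciliated = percent_ciliated(records),
       fields = per_field, field_results = res)
}

#' Analyze a whole plate
#'
#' Runs [analyze_well()] over every non-empty well, joins the layout's
#' treatment annotations, and computes the plate-level screening statistics
#' with [screen_stats()]. Wells with no usable basal bodies get an undefined
#' percent-ciliated value and are excluded from the statistics with a
#' warning.
#'
#' @param field_sets Named list (well address -> list of `field_image`s), or
#'   a list of [generate_field()] outputs per well as returned by
#'   [generate_plate()].
#' @param layout A `plate_layout`.
#' @param seg_params,filt_params Pipeline parameters.
#' @param k_sd,toxicity_fraction,two_sided Passed to [screen_stats()].
#' @return A `screen_result` whose `wells` table also carries `bb_count`.
#' @export
analyze_plate <- function(field_sets, layout,
                          seg_params = segmentation_params(),
                          filt_params = filter_params(),
                          k_sd = 3, toxicity_fraction = 0.80,
                          two_sided = FALSE) {
  wl <- layout$wells
  rows <- list()
  for (w in names(field_sets)) {
    fs <- field_sets[[w]]
    # accept generate_plate() output elements (field + truth pairs)
    fs <- lapply(fs, function(f) if (inherits(f, "field_image")) f else f$field)
    aw <- analyze_well(fs, seg_params, filt_params)
    i <- match(w, wl$well)
    if (is.na(i)) stopf("well %s not present in layout", w)
    rows[[w]] <- data.frame(
      well = w, treatment = wl$treatment[i], role = wl$role[i],
      cell_count = aw$cell_count, bb_count = aw$bb_count,
      ciliated_count = aw$ciliated_count, percent_ciliated = aw$percent_ciliated)
  }
  wells <- do.call(rbind, rows)
  rownames(wells) <- NULL
  screen_stats(wells, plate_id = layout$plate_id, k_sd = k_sd,
               toxicity_fraction = toxicity_fraction, two_sided = two_sided)
}
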