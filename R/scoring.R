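#' Assign per-basal-body Boolean ciliation
#'
#' Every basal-body object yields exactly one record: ciliated = 1 if at
#' least one accepted cilium links to it (multiple cilia on one basal body
#' still count once), 0 if the basal body stands alone. The basal body is the
#' countable cell proxy for ciliation scoring.
#'
#' @param bb_mask Basal-body `label_mask`.
#' @param accepted Data frame of accepted cilia (from [accepted_cilia()]) or a
#'   `cilia_candidates` object.
#' @return Data frame with columns `bb_label`, `ciliated` (integer 0/1).
#' @export
assign_ciliation <- function(bb_mask, accepted) {
  if (inherits(accepted, "cilia_candidates")) accepted <- accepted_cilia(accepted)
  labs <- bb_mask$table$label
  linked <- accepted$linked_bb
  if (length(linked) && any(!linked %in% labs))
    stopf("accepted cilium linked to nonexistent basal-body label %s",
          paste(setdiff(linked, labs), collapse = ", "))
  data.frame(bb_label = labs, ciliated = as.integer(labs %in% linked))
}

#' Percent ciliated cells
#'
#' 100 times the mean of the per-basal-body Boolean ciliation values, pooled
#' across all of a well's fields.
#'
#' @param records Data frame(s) of ciliation records from
#'   [assign_ciliation()]; a list of per-field data frames is pooled.
#' @return Percentage in `[0, 100]`, or `NA_real_` for an empty record set
#'   (undefined; propagates as a missing well value).
#' @export
percent_ciliated <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  cil <- unlist(lapply(records, function(r) r$ciliated))
  if (length(cil) == 0L) return(NA_real_)
  100 * mean(cil)
}
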