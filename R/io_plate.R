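VALID_ROLES <- c("positive_control", "negative_reference", "compound", "empty")
CHANNEL_ROLES <- c("nuclei", "basal_body", "cilium")

#' Construct and validate a plate layout
#'
#' @param plate_id Plate identifier.
#' @param wells Data frame with columns `well` (row letter + column number,
#'   e.g. `B02`), `treatment`, `role` (one of positive_control,
#'   negative_reference, compound, empty), `compound_id`, `dose_uM`.
#' @param channels Named integer map role -> 1-based channel index for
#'   `nuclei`, `basal_body`, `cilium`; indices must be distinct.
#' @param plate_dims Plate geometry `(rows, cols)`; default 384-well
#'   (16 x 24). Addresses outside the geometry are rejected.
#' @return A validated object of class `plate_layout`.
#' @export
plate_layout <- function(plate_id, wells, channels, plate_dims = c(16L, 24L)) {
  if (!is.data.frame(wells) || nrow(wells) == 0L)
    stopf("layout must contain at least one well")
  need <- c("well", "treatment", "role")
  miss <- setdiff(need, names(wells))
  if (length(miss)) stopf("wells table lacks column(s): %s", paste(miss, collapse = ", "))
  if (is.null(wells$compound_id)) wells$compound_id <- NA_character_
  if (is.null(wells$dose_uM)) wells$dose_uM <- NA_real_
  wells$compound_id <- as.character(wells$compound_id)
  wells$compound_id[!is.na(wells$compound_id) & !nzchar(wells$compound_id)] <- NA
  wells$dose_uM <- as.numeric(wells$dose_uM)
  wells$well <- normalize_well(wells$well, plate_dims)
  dup <- wells$well[duplicated(wells$well)]
  if (length(dup)) stopf("duplicate well address(es): %s", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(wells$role), VALID_ROLES)
  if (length(bad)) stopf("unknown role(s): %s (valid: %s)",
                         paste(bad, collapse = ", "), paste(VALID_ROLES, collapse = ", "))
  miss_ch <- setdiff(CHANNEL_ROLES, names(channels))
  if (length(miss_ch)) stopf("channel map missing role(s): %s", paste(miss_ch, collapse = ", "))
  channels <- vapply(channels[CHANNEL_ROLES], as.integer, integer(1))
  if (anyDuplicated(channels)) stopf("channel indices must be distinct")
  if (any(channels < 1L)) stopf("channel indices must be >= 1")
  structure(list(plate_id = as.character(plate_id),
                 wells = wells[, c("well", "treatment", "role", "compound_id", "dose_uM")],
                 channels = channels, plate_dims = as.integer(plate_dims)),
            class = "plate_layout")
}

# Validate and zero-pad well addresses like "B2" -> "B02".
normalize_well <- function(well, plate_dims = c(16L, 24L)) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-Z])([0-9]{1,2})$", well))
  out <- character(length(well))
  for (i in seq_along(well)) {
    if (length(m[[i]]) != 3L) stopf("malformed well address: '%s'", well[i])
    r <- match(m[[i]][2], LETTERS)
    cnum <- as.integer(m[[i]][3])
    if (r > plate_dims[1] || cnum < 1L || cnum > plate_dims[2])
      stopf("well address '%s' outside the %dx%d plate", well[i],
            plate_dims[1], plate_dims[2])
    out[i] <- sprintf("%s%02d", m[[i]][2], cnum)
  }
  out
}

#' Read a plate layout file
#'
#' Two dialects, chosen by extension. CSV: header comment lines
#' `# plate_id: <id>` and `# channels: nuclei=1; basal_body=2; cilium=3`
#' followed by RFC-4180 columns `well,treatment,role,compound_id,dose_uM`.
#' YAML: top-level keys `plate_id`, `channels` (role -> index map) and
#' `wells` (list of the same fields).
#'
#' @param path Path to a `.csv`, `.yaml` or `.yml` layout file.
#' @param plate_dims Plate geometry, see [plate_layout()].
#' @return A validated `plate_layout`.
#' @export
read_plate_layout <- function(path, plate_dims = c(16L, 24L)) {
  if (!file.exists(path)) stopf("layout file not found: %s", path)
  if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    if (is.null(y$wells) || length(y$wells) == 0L)
      stopf("layout must contain at least one well")
    wells <- do.call(rbind, lapply(y$wells, function(w)
      data.frame(well = w$well %||% NA_character_,
                 treatment = w$treatment %||% "",
                 role = w$role %||% NA_character_,
                 compound_id = w$compound_id %||% NA_character_,
                 dose_uM = w$dose_uM %||% NA_real_)))
    return(plate_layout(y$plate_id %||% "plate", wells,
                        unlist(y$channels), plate_dims))
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  plate_id <- sub("^#\\s*plate_id:\\s*", "", grep("plate_id:", hdr, value = TRUE)[1])
  ch_line <- grep("channels:", hdr, value = TRUE)[1]
  channels <- integer(0)
  if (!is.na(ch_line)) {
    body <- sub("^#\\s*channels:\\s*", "", ch_line)
    for (kv in strsplit(body, "[;,]")[[1]]) {
      kv <- strsplit(trimws(kv), "=")[[1]]
      if (length(kv) == 2L) channels[trimws(kv[1])] <- as.integer(kv[2])
    }
  }
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)],
                         stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stopf("layout must contain at least one well")
  plate_layout(if (is.na(plate_id)) "plate" else plate_id, tab, channels, plate_dims)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a plate layout file
#'
#' Inverse of [read_plate_layout()]; the written file re-reads to an
#' identical layout.
#'
#' @param layout A `plate_layout`.
#' @param path Destination `.csv`, `.yaml` or `.yml` path.
#' @return `path`, invisibly.
#' @export
write_plate_layout <- function(layout, path) {
  if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE)) {
    wells <- lapply(seq_len(nrow(layout$wells)), function(i) {
      w <- as.list(layout$wells[i, ])
      w[vapply(w, function(x) is.na(x), logical(1))] <- NULL
      w
    })
    yaml::write_yaml(list(plate_id = layout$plate_id,
                          channels = as.list(layout$channels),
                          wells = wells), path)
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c(sprintf("# plate_id: %s", layout$plate_id),
                 sprintf("# channels: %s",
                         paste(sprintf("%s=%d", names(layout$channels),
                                       layout$channels), collapse = "; "))),
               con)
    utils::write.csv(layout$wells, con, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Load one imaging field
#'
#' Reads a field as either one multi-page TIFF (pages ordered z-major:
#' page = (z - 1) * n_channels + channel index from the layout's channel map)
#' or one single/multi-page TIFF per channel (a character vector named by
#' channel role). Sample values are used as stored (no bit-depth rescaling):
#' every downstream threshold is relative. A z-dimension must be collapsed by
#' `projection` (`max` or `mean`); `none` is only valid for single-plane
#' input.
#'
#' @param path Single file path, or character vector named
#'   `nuclei`/`basal_body`/`cilium`.
#' @param layout A `plate_layout` (channel map).
#' @param projection `"max"`, `"mean"` or `"none"`.
#' @param well_id,field_index Metadata; parsed from a
#'   `<well>_f<field>.tif` filename when `NULL`.
#' @param pixel_size_um Pixel size metadata (default 0.33).
#' @return A `field_image`.
#' @export
load_field <- function(path, layout, projection = c("max", "mean", "none"),
                       well_id = NULL, field_index = NULL, pixel_size_um = 0.33) {
  projection <- match.arg(projection)
  ch_map <- layout$channels
  read_pages <- function(f) {
    if (!file.exists(f)) stopf("image file not found: %s", f)
    pg <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
    lapply(pg, function(m) {
      if (length(dim(m)) == 3L) m <- m[, , 1]
      matrix(as.numeric(m), nrow(m), ncol(m))
    })
  }
  if (length(path) > 1L || !is.null(names(path))) {
    miss <- setdiff(CHANNEL_ROLES, names(path))
    if (length(miss)) stopf("per-channel paths missing role(s): %s",
                            paste(miss, collapse = ", "))
    planes <- lapply(CHANNEL_ROLES, function(r) read_pages(path[[r]]))
    names(planes) <- CHANNEL_ROLES
    fname <- path[[1]]
  } else {
    pages <- read_pages(path)
    nch <- length(ch_map)
    if (length(pages) %% nch != 0L)
      stopf("page count (%d) is not a multiple of the channel count (%d)",
            length(pages), nch)
    nz <- length(pages) %/% nch
    planes <- lapply(CHANNEL_ROLES, function(r)
      pages[(seq_len(nz) - 1L) * nch + ch_map[[r]]])
    names(planes) <- CHANNEL_ROLES
    fname <- path
  }
  dims <- unique(lapply(unlist(planes, recursive = FALSE), dim))
  if (length(dims) != 1L) stopf("channel planes differ in shape")
  nz <- length(planes[[1]])
  if (nz > 1L && projection == "none")
    stopf("z-stack input (%d planes) requires projection 'max' or 'mean'", nz)
  collapse <- function(pl) {
    if (length(pl) == 1L) return(pl[[1]])
    a <- array(unlist(pl), dim = c(dim(pl[[1]]), length(pl)))
    apply(a, c(1, 2), if (projection == "max") max else mean)
  }
  channels <- lapply(planes, collapse)
  if (is.null(well_id) || is.null(field_index)) {
    m <- regmatches(basename(fname),
                    regexec("^([A-Za-z][0-9]+)_f([0-9]+)\\.", basename(fname)))[[1]]
    if (is.null(well_id)) well_id <- if (length(m) == 3L) toupper(m[2]) else "A01"
    if (is.null(field_index)) field_index <- if (length(m) == 3L) as.integer(m[3]) else 0L
  }
  structure(list(well_id = well_id, field_index = as.integer(field_index),
                 channels = channels, pixel_size_um = pixel_size_um,
                 z_projected = nz > 1L),
            class = "field_image")
}

#' Write a field as a 16-bit multi-page TIFF
#'
#' Pages are ordered by the channel map (default nuclei, basal body, cilium =
#' pages 1..3). Intensities are stored as `value / 65535`, clipped to
#' `[0, 1]`; [load_field()] restores the 0..65535 scale. Output is
#' byte-stable.
#'
#' @param field A `field_image`.
#' @param path Destination path.
#' @param channels Named role -> page index map.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path,
                             channels = c(nuclei = 1L, basal_body = 2L, cilium = 3L)) {
  pages <- vector("list", length(channels))
  for (r in names(channels)) {
    v <- round(field$channels[[r]])
    v[v < 0] <- 0; v[v > 65535] <- 65535
    pages[[channels[[r]]]] <- v / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write per-well and per-plate CSV reports
#'
#' Emits `wells.csv` (one row per analyzed well: treatment, cell count,
#' percent ciliated, toxicity flag, Z-score, hit flag) and
#' `plate_summary.csv` (Z', control summaries, hit list). Output is
#' deterministic and byte-stable: rows are sorted by well address and numbers
#' are written with full precision.
#'
#' @param result A `screen_result` from [screen_stats()] or [analyze_plate()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_reports <- function(result, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory: %s", out_dir)
  }
  w <- result$wells
  cols <- c("well", "treatment", "role", "cell_count", "ciliated_count",
            "percent_ciliated", "toxic", "z_score", "hit")
  for (cl in setdiff(cols, names(w))) w[[cl]] <- NA
  w <- w[order(w$well), cols, drop = FALSE]
  wells_path <- file.path(out_dir, "wells.csv")
  write_csv_stable(w, wells_path)
  ctrl <- result$controls
  pick <- function(col, role) {
    if (is.null(ctrl)) return(NA_real_)
    v <- ctrl[[col]][ctrl$role == role]
    if (length(v)) v[1] else NA_real_
  }
  summary <- data.frame(
    plate_id = result$plate_id %||% NA_character_,
    n_wells = nrow(w),
    z_prime = result$z_prime %||% NA_real_,
    k_sd = result$k_sd %||% NA_real_,
    toxicity_fraction = result$toxicity_fraction %||% NA_real_,
    pos_mean_percent = pick("mean_percent", "positive_control"),
    pos_sd_percent = pick("sd_percent", "positive_control"),
    neg_mean_percent = pick("mean_percent", "negative_reference"),
    neg_sd_percent = pick("sd_percent", "negative_reference"),
    n_toxic = sum(w$toxic %in% TRUE),
    n_hits = sum(w$hit %in% TRUE),
    hits = paste(sort(w$well[w$hit %in% TRUE]), collapse = ";"))
  summary_path <- file.path(out_dir, "plate_summary.csv")
  write_csv_stable(summary, summary_path)
  invisible(c(wells = wells_path, plate_summary = summary_path))
}

# write.csv with a binary connection: fixed "\n" line endings on every
# platform, full-precision numbers.
write_csv_stable <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, na = "")
}
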