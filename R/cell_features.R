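# Per-cell OMI feature extraction: mask ingestion, per-cell aggregation of
# pixel fit maps, optical redox ratio from summed intensities, and the four
# quality-control exclusion rules.

#' Load a cell label image
#'
#' Ingests an integer label image (0 = background) from a single-page TIFF or
#' an in-memory matrix and re-indexes the labels contiguously from 1.
#' Mask *generation* (segmentation) is out of scope; labels may come from any
#' segmentation tool.
#'
#' @param x Path to a single-page label TIFF, or an integer-valued matrix.
#' @return Integer label matrix with attribute `n_cells`.
#' @export
load_masks <- function(x) {
  m <- if (is.character(x)) read_label_tiff(x) else x
  if (!is.matrix(m)) stop("label image must be a single-page 2-D image", call. = FALSE)
  if (max(abs(m - round(m))) > 1e-6) {
    stop("label image is not integer-valued", call. = FALSE)
  }
  m <- round(m)
  labs <- sort(unique(m[m != 0]))
  if (length(labs) == 0) {
    warning("label image contains no cells")
  }
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_along(labs)) out[m == labs[i]] <- i
  attr(out, "n_cells") <- length(labs)
  out
}

#' Aggregate one cell's OMI features
#'
#' Lifetime variables are the unweighted mean over *valid* fitted pixels in
#' the mask; the optical redox ratio is computed at the cell level from raw
#' summed intensities, ORR = sum(I_NADPH) / (sum(I_NADPH) + sum(I_FAD)) over
#' all cell pixels (sum-then-ratio, which bounds it in \[0, 1\]);
#' `mean_nadph_intensity` is total NAD(P)H photons / area (in a.u. after
#' `intensity_scale`); `chi2_max` is the maximum per-pixel reduced chi-square
#' among valid pixels in the mask (both channels), with the pixel mean also
#' recorded as `chi2_mean` — on binned images edge pixels mix neighbouring
#' emitters, so the conservative maximum can flag cells whose interior fits
#' are good.
#'
#' @param fitmaps List with elements `nadph`, `fad` of `pixel_fit_map`.
#' @param label_image Integer label matrix on the same grid.
#' @param cell_id Label to aggregate.
#' @param intensity_scale Photons per arbitrary intensity unit (divisor).
#' @return One-row data.frame (a cell record).
#' @export
aggregate_cell <- function(fitmaps, label_image, cell_id, intensity_scale = 1) {
  stopifnot(all(c("nadph", "fad") %in% names(fitmaps)))
  fn <- fitmaps$nadph; ff <- fitmaps$fad
  if (!all(dim(fn$tau_m) == dim(label_image)) ||
      !all(dim(ff$tau_m) == dim(label_image))) {
    stop("fit maps and label image must share the same pixel grid", call. = FALSE)
  }
  in_mask <- label_image == cell_id
  if (!any(in_mask)) stop("cell_id ", cell_id, " not present in label image", call. = FALSE)
  area <- sum(in_mask)
  sum_n <- sum(fn$intensity[in_mask])
  sum_f <- sum(ff$intensity[in_mask])
  orr <- if (sum_n + sum_f > 0) sum_n / (sum_n + sum_f) else NA_real_

  vn <- in_mask & fn$valid_mask
  vf <- in_mask & ff$valid_mask
  avg <- function(m, v) if (any(v)) mean(m[v]) else NA_real_
  chi2_vals <- c(fn$chi2[vn], ff$chi2[vf])
  rec <- data.frame(
    cell_id = cell_id,
    area_px = area,
    nadph_tau_m = avg(fn$tau_m, vn), nadph_tau1 = avg(fn$tau1, vn),
    nadph_tau2 = avg(fn$tau2, vn), nadph_alpha1 = avg(fn$alpha1_pct, vn),
    fad_tau_m = avg(ff$tau_m, vf), fad_tau1 = avg(ff$tau1, vf),
    fad_tau2 = avg(ff$tau2, vf), fad_alpha1 = avg(ff$alpha1_pct, vf),
    orr = orr,
    mean_nadph_intensity = sum_n / area / intensity_scale,
    chi2_max = if (length(chi2_vals)) max(chi2_vals) else NA_real_,
    chi2_mean = if (length(chi2_vals)) mean(chi2_vals) else NA_real_,
    valid_pixel_frac = (sum(vn) + sum(vf)) / (2 * area),
    qc_pass = TRUE, qc_reasons = "",
    stringsAsFactors = FALSE)
  # a channel with no valid fitted pixels leaves its lifetime variables
  # undefined, so the record cannot enter the 10-variable analyses
  if (!any(vn) || !any(vf)) {
    rec$qc_pass <- FALSE
    rec$qc_reasons <- "no-valid-pixels"
  }
  rec
}

#' Extract the per-cell feature table from fitted channels
#'
#' Runs [aggregate_cell()] for every label in the image and attaches optional
#' metadata columns.
#'
#' @inheritParams aggregate_cell
#' @param meta Optional data.frame with one row per cell (matched by
#'   position) of metadata such as `donor`, `condition`, `cell_type`.
#' @return Cell feature table (data.frame), one row per cell.
#' @export
extract_features <- function(fitmaps, label_image, meta = NULL,
                             intensity_scale = 1) {
  ids <- sort(unique(label_image[label_image != 0]))
  if (length(ids) == 0) {
    warning("empty label image: returning empty feature table")
    return(data.frame())
  }
  tab <- do.call(rbind, lapply(ids, function(i) {
    aggregate_cell(fitmaps, label_image, i, intensity_scale)
  }))
  if (!is.null(meta)) {
    stopifnot(nrow(meta) == nrow(tab))
    extra <- setdiff(names(meta), names(tab))
    tab <- cbind(meta[, extra, drop = FALSE], tab)
  }
  tab
}

#' Apply the OMI quality-control exclusion rules
#'
#' Flags cells failing any of the four rules (strict inequalities, boundary
#' values retained): summed NAD(P)H average cell intensity < `min_intensity`
#' a.u. ("low-photons"); mask area < `min_area` pixels ("small-mask");
#' goodness of fit chi-square > `max_chi2` ("poor-fit"); NAD(P)H
#' tau1 < `min_nadph_tau1` ps ("short-tau1"). Rows failing any rule get
#' `qc_pass = FALSE` with all applicable reason codes (comma separated);
#' existing reason codes (e.g. "no-valid-pixels") are preserved. The
#' operation is idempotent.
#'
#' @param table Cell feature table.
#' @param min_intensity,min_area,max_chi2,min_nadph_tau1 Rule thresholds.
#' @param chi2_col Which chi-square aggregate to test (default `"chi2_max"`,
#'   the conservative per-cell maximum).
#' @return The table with refreshed `qc_pass` / `qc_reasons`, and an
#'   attribute `qc_counts` giving exclusion counts per reason.
#' @export
apply_qc <- function(table, min_intensity = 10, min_area = 70,
                     max_chi2 = 1.3, min_nadph_tau1 = 350,
                     chi2_col = "chi2_max") {
  stopifnot(all(c("mean_nadph_intensity", "area_px", chi2_col, "nadph_tau1")
                %in% names(table)))
  base <- if ("qc_reasons" %in% names(table)) {
    ifelse(is.na(table$qc_reasons), "", table$qc_reasons)
  } else rep("", nrow(table))
  # re-applying must not duplicate rule codes
  rule_codes <- c("low-photons", "small-mask", "poor-fit", "short-tau1")
  base <- vapply(strsplit(base, ","), function(r) {
    paste(setdiff(r, rule_codes), collapse = ",")
  }, character(1))

  fails <- list(
    "low-photons" = !is.na(table$mean_nadph_intensity) &
      table$mean_nadph_intensity < min_intensity,
    "small-mask" = table$area_px < min_area,
    "poor-fit" = !is.na(table[[chi2_col]]) & table[[chi2_col]] > max_chi2,
    "short-tau1" = !is.na(table$nadph_tau1) & table$nadph_tau1 < min_nadph_tau1
  )
  reasons <- base
  for (code in names(fails)) {
    hit <- fails[[code]]
    reasons[hit] <- ifelse(reasons[hit] == "", code,
                           paste(reasons[hit], code, sep = ","))
  }
  table$qc_reasons <- reasons
  table$qc_pass <- reasons == ""
  attr(table, "qc_counts") <- vapply(fails, sum, integer(1))
  table
}

#' Retain only QC-passing cells
#' @param table A table processed by [apply_qc()].
#' @return The filtered table.
#' @export
qc_filter <- function(table) {
  stopifnot("qc_pass" %in% names(table))
  table[table$qc_pass, , drop = FALSE]
}

#' Gate CD56 bright vs dim NK cells
#'
#' Bright if stain intensity strictly exceeds the threshold (default 100
#' a.u., calibrated to capture roughly the top 10% brightest NK cells).
#'
#' @param table Feature table with a stain intensity column.
#' @param threshold Gate, arbitrary units.
#' @param column Stain column name.
#' @return The table with a `cd56_bright` logical column; attribute
#'   `bright_fraction` reports the gated fraction.
#' @export
gate_cd56 <- function(table, threshold = 100, column = "stain_intensity") {
  if (!column %in% names(table)) {
    stop("stain intensity column '", column, "' missing", call. = FALSE)
  }
  table$cd56_bright <- !is.na(table[[column]]) & table[[column]] > threshold
  attr(table, "bright_fraction") <-
    mean(table$cd56_bright[!is.na(table[[column]])])
  table
}

#' Gate CD69-positive cells against a quiescent reference
#'
#' The positivity threshold is the quiescent mean plus 1.5 sample standard
#' deviations; a cell is positive if its intensity strictly exceeds it.
#'
#' @param intensities Stain intensities of the population to gate.
#' @param quiescent Reference (quiescent) intensities, length >= 2.
#' @return List: `threshold`, logical `positive`, `positive_fraction`.
#' @export
gate_cd69 <- function(intensities, quiescent) {
  if (length(quiescent) < 2) stop("need >= 2 quiescent cells to set the gate", call. = FALSE)
  s <- stats::sd(quiescent)
  if (s == 0) warning("zero-variance quiescent population: threshold equals its mean")
  thr <- mean(quiescent) + 1.5 * s
  pos <- intensities > thr
  list(threshold = thr, positive = pos, positive_fraction = mean(pos))
}
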