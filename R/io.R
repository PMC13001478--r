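# Plain-format I/O: multi-page TIFF decay cubes, 16-bit label TIFFs, CSV
# feature tables. TIFF pages are stored as 16-bit unsigned integers (counts
# and labels both fit comfortably).

.SCALE16 <- 65535

#' Write / read a decay cube as a multi-page TIFF
#'
#' One page per time bin, 16-bit; counts must not exceed 65535 per bin.
#'
#' @param cube A `decay_cube`.
#' @param path TIFF path.
#' @param bin_width_ps,channel Axis metadata supplied on read (TIFF carries
#'   none).
#' @return `read_decay_cube_tiff` returns a `decay_cube`;
#'   `write_decay_cube_tiff` returns `path` invisibly.
#' @export
write_decay_cube_tiff <- function(cube, path) {
  stopifnot(inherits(cube, "decay_cube"))
  if (max(cube$counts) > .SCALE16) stop("counts exceed 16-bit range", call. = FALSE)
  pages <- lapply(seq_len(dim(cube$counts)[3]),
                  function(b) cube$counts[, , b] / .SCALE16)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_decay_cube_tiff
#' @export
read_decay_cube_tiff <- function(path, bin_width_ps = 12500 / 256,
                                 channel = "NADPH") {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) arr[, , b] <- as.integer(round(pages[[b]] * .SCALE16))
  new_decay_cube(arr, bin_width_ps, channel)
}

#' Write / read a 16-bit label image TIFF
#' @param label Integer label matrix (0 = background).
#' @param path TIFF path.
#' @return `read_label_tiff` returns an integer matrix.
#' @export
write_label_tiff <- function(label, path) {
  stopifnot(is.matrix(label), max(label) <= .SCALE16)
  tiff::writeTIFF(label / .SCALE16, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * .SCALE16)), nrow(m), ncol(m))
}

#' Export a synthetic scene to a directory
#'
#' Writes `nadph.tif` / `fad.tif` multi-page decay cubes, `labels.tif`,
#' `truth.csv`, and per-channel IRF CSVs.
#'
#' @param scene A [build_scene()] result.
#' @param dir Output directory (created if absent).
#' @return `dir` invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_decay_cube_tiff(scene$cubes$nadph, file.path(dir, "nadph.tif"))
  write_decay_cube_tiff(scene$cubes$fad, file.path(dir, "fad.tif"))
  write_label_tiff(scene$label_image, file.path(dir, "labels.tif"))
  utils::write.csv(scene$truth_table, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  write_irf_csv(scene$irf$nadph, file.path(dir, "irf_nadph.csv"))
  write_irf_csv(scene$irf$fad, file.path(dir, "irf_fad.csv"))
  invisible(dir)
}

#' Write / read a cell feature table CSV
#'
#' Fixed documented column order: metadata first (`cell_id`, `donor`,
#' `condition`, `cell_type` where present), then the 10 OMI variables, then
#' QC columns, then anything else.
#'
#' @param table Feature table.
#' @param path CSV path.
#' @return `read_feature_csv` returns the data.frame.
#' @export
write_feature_csv <- function(table, path) {
  lead <- intersect(c("cell_id", "donor", "condition", "cell_type"), names(table))
  omi <- intersect(omi_variables(), names(table))
  qc <- intersect(c("mean_nadph_intensity", "chi2_max", "valid_pixel_frac",
                    "qc_pass", "qc_reasons"), names(table))
  rest <- setdiff(names(table), c(lead, omi, qc))
  utils::write.csv(table[, c(lead, omi, qc, rest), drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
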