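# Scene and ground-truth I/O. Channel rasters are stored as 32-bit TIFF in
# [0, 1] with the scale factor recorded in a JSON sidecar; label masks as
# 16-bit TIFF.

#' Write an image scene to disk
#'
#' Writes the channel rasters as one multi-page 32-bit TIFF (values scaled
#' to [0, 1]; the scale is recorded in the sidecar), the label mask as a
#' 16-bit TIFF, and a JSON sidecar with channel names, scale, pixel size and
#' seed.
#'
#' @param scene an `image_scene`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the vector of files written.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f_img <- file.path(dir, paste0(prefix, "_channels.tif"))
  f_lab <- file.path(dir, paste0(prefix, "_labels.tif"))
  f_meta <- file.path(dir, paste0(prefix, "_meta.json"))
  scale <- max(1, max(vapply(scene$channels, max, 0)))
  tiff::writeTIFF(lapply(scene$channels, function(ch) ch / scale),
                  f_img, bits.per.sample = 32L, compression = "none")
  tiff::writeTIFF(scene$labels / 65535, f_lab, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(
    list(channels = names(scene$channels), intensity_scale = scale,
         pixel_size_um = scene$pixel_size_um, seed = scene$seed),
    f_meta, auto_unbox = TRUE, digits = NA)
  invisible(c(f_img, f_lab, f_meta))
}

#' Read an image scene written by [write_scene()]
#' @param dir directory.
#' @param prefix file name prefix.
#' @return an `image_scene`.
#' @export
read_scene <- function(dir, prefix = "scene") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, paste0(prefix, "_channels.tif")), all = TRUE)
  channels <- stats::setNames(lapply(pages, function(m) m * meta$intensity_scale),
                              meta$channels)
  lab <- tiff::readTIFF(file.path(dir, paste0(prefix, "_labels.tif")))
  labels <- matrix(as.integer(round(lab * 65535)), nrow(lab), ncol(lab))
  structure(list(channels = channels, labels = labels,
                 pixel_size_um = meta$pixel_size_um, seed = meta$seed),
            class = "image_scene")
}

#' Write a hyperspectral scene to disk
#'
#' Stack as a multi-page 32-bit TIFF (one page per wavelength channel,
#' scaled to [0, 1]), labels as 16-bit TIFF, and a JSON sidecar carrying the
#' wavelength grid and the intensity scale.
#'
#' @param scene a `spectral_scene`.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return invisibly, the files written.
#' @export
write_spectral_scene <- function(scene, dir, prefix = "spectral") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f_img <- file.path(dir, paste0(prefix, "_stack.tif"))
  f_lab <- file.path(dir, paste0(prefix, "_labels.tif"))
  f_meta <- file.path(dir, paste0(prefix, "_meta.json"))
  K <- dim(scene$stack)[3]
  scale <- max(1, max(scene$stack))
  tiff::writeTIFF(lapply(seq_len(K), function(k) scene$stack[, , k] / scale),
                  f_img, bits.per.sample = 32L, compression = "none")
  tiff::writeTIFF(scene$labels / 65535, f_lab, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(
    list(wavelengths_nm = scene$wavelengths_nm, intensity_scale = scale,
         pixel_size_um = scene$pixel_size_um, seed = scene$seed),
    f_meta, auto_unbox = TRUE, digits = NA)
  invisible(c(f_img, f_lab, f_meta))
}

#' Read a hyperspectral scene written by [write_spectral_scene()]
#' @param dir directory.
#' @param prefix file name prefix.
#' @return a `spectral_scene`.
#' @export
read_spectral_scene <- function(dir, prefix = "spectral") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, paste0(prefix, "_stack.tif")), all = TRUE)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  stack <- array(0, dim = c(H, W, length(pages)))
  for (k in seq_along(pages)) stack[, , k] <- pages[[k]] * meta$intensity_scale
  lab <- tiff::readTIFF(file.path(dir, paste0(prefix, "_labels.tif")))
  labels <- matrix(as.integer(round(lab * 65535)), nrow(lab), ncol(lab))
  structure(list(stack = stack, wavelengths_nm = meta$wavelengths_nm,
                 labels = labels, pixel_size_um = meta$pixel_size_um,
                 seed = meta$seed),
            class = "spectral_scene")
}

#' Write generator ground truth as CSV + JSON sidecar
#'
#' One CSV row per cell, one per focus, one long-format CSV for the true
#' centrelines, and a JSON sidecar with the fully resolved parameter set.
#'
#' @param truth a `ground_truth`.
#' @param params resolved generator parameter list.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_ground_truth <- function(truth, params, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f_cells <- file.path(dir, "truth_cells.csv")
  f_foci <- file.path(dir, "truth_foci.csv")
  f_cl <- file.path(dir, "truth_centerlines.csv")
  f_par <- file.path(dir, "params.json")
  utils::write.csv(truth$cells, f_cells, row.names = FALSE)
  utils::write.csv(truth$foci, f_foci, row.names = FALSE)
  cl <- do.call(rbind, lapply(seq_along(truth$centerlines), function(i) {
    m <- truth$centerlines[[i]]
    data.frame(cell_id = i, point = seq_len(nrow(m)), row = m[, 1], col = m[, 2])
  }))
  utils::write.csv(cl, f_cl, row.names = FALSE)
  par <- params[!vapply(params, is.null, logical(1))]
  par$explicit_cells <- NULL
  jsonlite::write_json(par, f_par, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(f_cells, f_foci, f_cl, f_par))
}

#' Write per-cell profiles as long-format CSV
#' @param profiles list of `intensity_profile`.
#' @param file output CSV path.
#' @return invisibly, `file`.
#' @export
write_profiles_csv <- function(profiles, file) {
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(cell_id = p$cell_id, channel = p$channel,
               position = p$positions, value = p$values,
               length_um = p$length_um)
  }))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read long-format profile CSV back into `intensity_profile` objects
#' @param file CSV written by [write_profiles_csv()].
#' @return list of `intensity_profile`.
#' @export
read_profiles_csv <- function(file) {
  df <- utils::read.csv(file)
  out <- list()
  for (key in unique(paste(df$cell_id, df$channel))) {
    sub <- df[paste(df$cell_id, df$channel) == key, ]
    out[[length(out) + 1]] <- structure(
      list(cell_id = sub$cell_id[1], channel = sub$channel[1],
           positions = sub$position, values = sub$value,
           length_um = sub$length_um[1], native_step_um = NA_real_),
      class = "intensity_profile")
  }
  out
}
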