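# Fixtures built in code; no binary data.

# Binary capsule mask: segment from (row, c0) to (row, c1) dilated by
# `radius`, in an nr x nc label raster (label 1).
capsule_mask <- function(nr, nc, row, c0, c1, radius) {
  lab <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      px <- c(r - 1, cc - 1)
      t <- min(max((px[2] - c0) / (c1 - c0), 0), 1)
      d <- sqrt((px[1] - row)^2 + (px[2] - (c0 + t * (c1 - c0)))^2)
      if (d <= radius) lab[r, cc] <- 1L
    }
  }
  lab
}

# Horizontal medial axis object along a given 0-based row.
horizontal_axis <- function(row, c0, c1, pixel_size_um = 0.105, cell_id = 1L) {
  pts <- cbind(rep(row, c1 - c0 + 1), c0:c1)
  structure(list(cell_id = cell_id, points = pts,
                 arc_length_px = mycomorph:::arc_length(pts),
                 pixel_size_um = pixel_size_um),
            class = "medial_axis")
}

# An intensity_profile from a plain value vector on a uniform [0, 1] grid.
profile_from_values <- function(values, cell_id = 1L, channel = "hada",
                                length_um = 7) {
  structure(list(cell_id = cell_id, channel = channel,
                 positions = seq(0, 1, length.out = length(values)),
                 values = values, length_um = length_um,
                 native_step_um = 0.105),
            class = "intensity_profile")
}

# Sum-of-Gaussians profile on a P-point grid.
gaussian_profile <- function(centers, amps, sigmas, P = 101, ...) {
  x <- seq(0, 1, length.out = P)
  v <- numeric(P)
  for (i in seq_along(centers)) v <- v + amps[i] * exp(-(x - centers[i])^2 / (2 * sigmas[i]^2))
  profile_from_values(v, ...)
}

# Noiseless, PSF-free single-cell population from an explicit spec.
noiseless_cell <- function(length_um = 8, foci, seed = 1, theta = 0.3,
                           bow_frac = 0, septum_pos = NA, septate = FALSE,
                           ch2_w = NULL, psf = 0, extra = list()) {
  ex <- list(list(length_um = length_um, foci = foci, theta = theta,
                  bow_frac = bow_frac, septum_pos = septum_pos,
                  septate = septate, ch2_w = ch2_w))
  ov <- c(list(explicit_cells = ex, noise = FALSE, psf_sigma_px = psf,
               amp_scale = 1), extra)
  generate_population("custom", n = 1, seed = seed, overrides = ov)
}

# Named septation flags from generator truth.
truth_septate <- function(pop) {
  stats::setNames(pop$truth$cells$septate, as.character(pop$truth$cells$cell_id))
}

# Foci table for one cell id from generator truth.
truth_foci <- function(pop, id) pop$truth$foci[pop$truth$foci$cell_id == id, ]

# Directed Hausdorff distance between two polylines (px).
hausdorff <- function(a, b) {
  da <- max(mycomorph:::polyline_distance(a, b)$dist)
  db <- max(mycomorph:::polyline_distance(b, a)$dist)
  max(da, db)
}
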