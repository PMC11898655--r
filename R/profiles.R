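#' Extract the medial axis of one cell
#'
#' Skeletonizes the cell mask (Zhang-Suen thinning), takes the longest
#' geodesic path through the skeleton, smooths it with a smoothing spline,
#' and extends both ends along the local tangent until they reach the mask
#' boundary. The resulting polyline is resampled at 1-px arc steps. The axis
#' orientation is deterministic: the endpoint with the smaller (row, col)
#' lexicographic coordinate comes first; orientation carries no biological
#' meaning (pole identities are assigned later from landmarks).
#'
#' @param labels integer label raster (0 = background).
#' @param cell_id the label of the cell to process.
#' @param pixel_size_um pixel size in micrometres.
#' @param min_elongation cells whose mask is not elongated at least this
#'   much (PCA major/minor extent ratio) are rejected as degenerate.
#' @return object of class `medial_axis` with `points` (n x 2, 0-based
#'   row/col, sub-pixel), `arc_length_px`, `cell_id`, `pixel_size_um`.
#'   Branched or degenerate cells raise an error of class
#'   `mycomorph_cell_flagged` carrying the reason.
#' @export
extract_medial_axis <- function(labels, cell_id, pixel_size_um = 0.105,
                                min_elongation = 1.8) {
  mask <- labels == cell_id
  if (!any(mask)) stop_config("cell_id %s not present in labels", cell_id)
  px <- which(mask, arr.ind = TRUE)
  # elongation check on the raw mask (degenerate disk-like regions rejected)
  ctr <- colMeans(px)
  cv <- stats::cov(px)
  ev <- eigen(cv, symmetric = TRUE)$values
  elong <- sqrt(max(ev) / max(min(ev), 1e-9))
  if (!is.finite(elong) || elong < min_elongation) {
    cnd <- structure(class = c("mycomorph_cell_flagged", "error", "condition"),
                     list(message = sprintf("cell %s flagged: degenerate (elongation %.2f < %.2f)",
                                            cell_id, elong, min_elongation),
                          call = NULL, reason = "degenerate"))
    stop(cnd)
  }
  # crop to bounding box with 1-px pad for speed
  r0 <- max(1, min(px[, 1]) - 1); r1 <- min(nrow(mask), max(px[, 1]) + 1)
  c0 <- max(1, min(px[, 2]) - 1); c1 <- min(ncol(mask), max(px[, 2]) + 1)
  sub <- mask[r0:r1, c0:c1]
  skel <- thin_mask(sub)
  path <- longest_skeleton_path(skel)
  if (is.null(path) || nrow(path) < 2) {
    cnd <- structure(class = c("mycomorph_cell_flagged", "error", "condition"),
                     list(message = sprintf("cell %s flagged: skeleton too short", cell_id),
                          call = NULL, reason = "short_skeleton"))
    stop(cnd)
  }
  # back to full-raster 0-based coordinates
  pts <- cbind(path[, 1] + r0 - 2, path[, 2] + c0 - 2)

  # smooth row(t), col(t) with a modest-df spline
  n <- nrow(pts)
  s <- arc_length(pts)
  sm <- if (n >= 8) {
    df <- max(4, min(12, n / 8))
    t <- s
    list(r = stats::predict(stats::smooth.spline(t, pts[, 1], df = df), t)$y,
         c = stats::predict(stats::smooth.spline(t, pts[, 2], df = df), t)$y)
  } else {
    list(r = pts[, 1], c = pts[, 2])
  }
  sp <- cbind(sm$r, sm$c)
  sp <- resample_polyline(sp, step = 1)

  # extend both ends along the end tangents to the mask boundary
  mask01 <- matrix(0, nrow(mask), ncol(mask)); mask01[mask] <- 1
  extend_end <- function(pt, tangent) {
    tangent <- tangent / sqrt(sum(tangent^2))
    pos <- pt
    step <- 0.5
    for (i in 1:200) {
      cand <- pos + step * tangent
      v <- bilinear(mask01, cand[1], cand[2])
      if (is.na(v) || v < 0.5) break
      pos <- cand
    }
    # bisect the 0.5-crossing for sub-pixel end placement
    for (i in 1:5) {
      step <- step / 2
      cand <- pos + step * tangent
      v <- bilinear(mask01, cand[1], cand[2])
      if (!is.na(v) && v >= 0.5) pos <- cand
    }
    pos
  }
  m <- nrow(sp)
  head_pt <- extend_end(sp[1, ], sp[1, ] - sp[min(3, m), ])
  tail_pt <- extend_end(sp[m, ], sp[m, ] - sp[max(1, m - 2), ])
  sp <- rbind(head_pt, sp, tail_pt)
  sp <- resample_polyline(sp, step = 1)

  # coverage check on the extended axis: it must span most of the mask's
  # major extent, else the skeleton was branched or badly bent
  dirv <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  proj <- (px[, 1] - ctr[1]) * dirv[1] + (px[, 2] - ctr[2]) * dirv[2]
  expected <- diff(range(proj))
  axis_len <- arc_length(sp)
  if (axis_len[length(axis_len)] < 0.8 * expected) {
    cnd <- structure(class = c("mycomorph_cell_flagged", "error", "condition"),
                     list(message = sprintf("cell %s flagged: branched/bent skeleton (axis %.1f px < 80%% of extent %.1f px)",
                                            cell_id, axis_len[length(axis_len)], expected),
                          call = NULL, reason = "branched"))
    stop(cnd)
  }

  # deterministic orientation
  a <- sp[1, ]; b <- sp[nrow(sp), ]
  if (a[1] > b[1] || (a[1] == b[1] && a[2] > b[2])) sp <- sp[nrow(sp):1, , drop = FALSE]

  structure(list(cell_id = cell_id, points = sp, arc_length_px = arc_length(sp),
                 pixel_size_um = pixel_size_um),
            class = "medial_axis")
}

#' Cell length from a medial axis
#'
#' Arc length of the axis polyline times the pixel size.
#'
#' @param axis a `medial_axis`.
#' @return length in micrometres.
#' @export
measure_length <- function(axis) {
  stopifnot(inherits(axis, "medial_axis"))
  s <- axis$arc_length_px
  total <- s[length(s)]
  if (total <= 0) stop_config("zero-length axis")
  total * axis$pixel_size_um
}

#' Reverse the orientation of a medial axis
#' @param axis a `medial_axis`.
#' @return the axis with points in reverse order.
#' @export
reverse_axis <- function(axis) {
  axis$points <- axis$points[nrow(axis$points):1, , drop = FALSE]
  axis$arc_length_px <- arc_length(axis$points)
  axis
}

#' Extract the length-normalized axial intensity profile of one cell
#'
#' At each 1-px arc-length station along the axis the channel is sampled at
#' `width_px` points spaced 1 px apart along the perpendicular centred on the
#' axis (bilinear interpolation) and averaged across the band, emulating a
#' wide segmented-line profile. The averaged trace is background-subtracted,
#' clamped at zero, and resampled to `resample_points` uniform normalized
#' positions on [0, 1].
#'
#' @param channel 2D intensity raster.
#' @param axis a `medial_axis`.
#' @param width_px width of the transverse averaging band in pixels
#'   (default 10, about 1.06 um at 0.105 um/px).
#' @param resample_points number of uniform output positions (default 101,
#'   i.e. a step of 0.01 of the cell length).
#' @param background constant background level subtracted from the averaged
#'   trace (e.g. the median intensity outside all cells); default 0.
#' @param channel_name stored channel label.
#' @return object of class `intensity_profile` with `positions`, `values`,
#'   `length_um`, `native_step_um`.
#' @export
extract_profile <- function(channel, axis, width_px = 10L, resample_points = 101L,
                            background = 0, channel_name = "channel") {
  stopifnot(width_px >= 1, resample_points >= 2)
  pts <- axis$points
  s <- axis$arc_length_px
  total <- s[length(s)]
  n <- nrow(pts)
  # unit tangents by central differences, then unit normals
  tg <- rbind(pts[2, ] - pts[1, ],
              (pts[-(1:2), , drop = FALSE] - pts[1:(n - 2), , drop = FALSE]) / 2,
              pts[n, ] - pts[n - 1, ])
  tln <- sqrt(rowSums(tg^2)); tln[tln == 0] <- 1
  tg <- tg / tln
  nrm <- cbind(-tg[, 2], tg[, 1])
  offs <- seq_len(width_px) - (width_px + 1) / 2
  rr <- outer(pts[, 1], rep(1, width_px)) + outer(nrm[, 1], offs)
  cc <- outer(pts[, 2], rep(1, width_px)) + outer(nrm[, 2], offs)
  v <- bilinear(channel, as.vector(rr), as.vector(cc))
  v <- matrix(v, n, width_px)
  n_out <- sum(is.na(v))
  if (n_out > 0) warning(sprintf("profile band extends outside the raster for %d sample(s); truncated", n_out))
  vals <- rowMeans(v, na.rm = TRUE)
  vals[is.nan(vals)] <- 0
  vals <- pmax(vals - background, 0)
  posn <- s / total
  grid <- seq(0, 1, length.out = resample_points)
  out <- stats::approx(posn, vals, xout = grid, ties = "ordered", rule = 2)$y
  structure(list(cell_id = axis$cell_id, channel = channel_name,
                 positions = grid, values = out,
                 length_um = total * axis$pixel_size_um,
                 native_step_um = axis$pixel_size_um),
            class = "intensity_profile")
}

#' Reverse an intensity profile end-for-end
#' @param profile an `intensity_profile`.
#' @return the profile with its value vector reversed.
#' @export
reverse_profile <- function(profile) {
  profile$values <- rev(profile$values)
  profile
}

#' Average a set of intensity profiles into a population mean profile
#'
#' Elementwise mean and sample standard deviation (n - 1 denominator)
#' across cells sharing the same normalized position grid and channel.
#'
#' @param profiles list of `intensity_profile` objects on identical grids.
#' @return object of class `mean_profile` with `positions`, `mean`, `sd`,
#'   `n_cells`, `channel`.
#' @export
average_profiles <- function(profiles) {
  if (length(profiles) == 0) stop_config("no profiles to average")
  pos <- profiles[[1]]$positions
  chan <- profiles[[1]]$channel
  for (p in profiles) {
    if (length(p$positions) != length(pos) || max(abs(p$positions - pos)) > 1e-12)
      stop_config("profiles are on different position grids")
    if (!identical(p$channel, chan)) stop_config("profiles mix channels")
  }
  M <- do.call(rbind, lapply(profiles, `[[`, "values"))
  mu <- colMeans(M)
  sdv <- if (nrow(M) > 1) apply(M, 2, stats::sd) else rep(0, ncol(M))
  structure(list(positions = pos, mean = mu, sd = sdv,
                 n_cells = length(profiles), channel = chan),
            class = "mean_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("intensity_profile: cell %s, channel %s, %d points, length %.2f um, peak %.3g\n",
              x$cell_id, x$channel, length(x$values), x$length_um, max(x$values)))
  invisible(x)
}

#' @export
print.mean_profile <- function(x, ...) {
  cat(sprintf("mean_profile: channel %s, %d cells, %d points\n",
              x$channel, x$n_cells, length(x$positions)))
  invisible(x)
}

#' @export
print.medial_axis <- function(x, ...) {
  s <- x$arc_length_px
  cat(sprintf("medial_axis: cell %s, %d points, %.1f px (%.2f um)\n",
              x$cell_id, nrow(x$points), s[length(s)], s[length(s)] * x$pixel_size_um))
  invisible(x)
}

#' Median background level of a scene channel
#'
#' Median intensity over all pixels not belonging to any cell (label 0).
#'
#' @param channel 2D intensity raster.
#' @param labels integer label raster.
#' @return scalar background level.
#' @export
estimate_background <- function(channel, labels) {
  stats::median(channel[labels == 0])
}

#' Otsu segmentation helper for synthetic scenes
#'
#' Thresholds a (membrane) channel with Otsu's method and labels connected
#' components. Intended only for synthetic scenes where cells are well
#' separated; it is not a general segmentation tool.
#'
#' @param channel 2D intensity raster.
#' @param min_px discard components smaller than this many pixels.
#' @return integer label raster.
#' @export
segment_otsu <- function(channel, min_px = 20) {
  rng <- range(channel)
  norm <- (channel - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  th <- EBImage::otsu(norm, range = c(0, 1))
  lab <- EBImage::bwlabel(norm > th)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  tab <- table(lab[lab > 0])
  drop <- as.integer(names(tab)[tab < min_px])
  lab[lab %in% drop] <- 0L
  # relabel compactly
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(ids)) lab <- matrix(match(lab, ids, nomatch = 0L), nrow(lab), ncol(lab))
  lab
}
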