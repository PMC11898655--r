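#' Detect HADA foci on an axial intensity profile
#'
#' Finds all local maxima of the profile with topographic prominence at or
#' above the threshold and pairwise separation at least `min_separation`
#' (in normalized-length units). Profile endpoints are eligible maxima, so
#' pole-tip foci are detected.
#'
#' @param profile an `intensity_profile`.
#' @param prominence prominence floor, in the profile's intensity units
#'   (> 0); typically the value frozen by [calibrate_prominence()].
#' @param min_separation minimum separation between retained foci as a
#'   fraction of cell length (default 0.08, in [0, 0.5)).
#' @return object of class `foci_set`: `cell_id`, `foci` (data frame
#'   `rel_pos`, `value`, `prominence`, sorted by position), `count`.
#' @export
detect_foci <- function(profile, prominence, min_separation = 0.08) {
  stopifnot(prominence > 0, min_separation >= 0, min_separation < 0.5)
  pk <- find_peaks(profile$values, profile$positions,
                   prominence = prominence, min_separation = min_separation)
  foci <- data.frame(rel_pos = pk$position, value = pk$value,
                     prominence = pk$prominence)
  foci <- foci[order(foci$rel_pos), , drop = FALSE]
  rownames(foci) <- NULL
  structure(list(cell_id = profile$cell_id, foci = foci, count = nrow(foci)),
            class = "foci_set")
}

#' @export
print.foci_set <- function(x, ...) {
  cat(sprintf("foci_set: cell %s, %d focus/foci at [%s]\n", x$cell_id, x$count,
              paste(sprintf("%.2f", x$foci$rel_pos), collapse = ", ")))
  invisible(x)
}

#' Calibrate the foci-detection prominence on a control population
#'
#' In the control phenotype, cells carry two HADA foci (both poles) when
#' non-septate and three (poles plus septum) when septate. The prominence
#' floor is chosen, over a 30-point logarithmic grid spanning 1% to 100% of
#' the control population's median peak intensity, as the value that
#' maximizes the fraction of control cells whose detected focus count
#' matches that expectation; ties are broken to the candidate nearest the
#' log-midpoint of the optimal plateau (the maximum-margin choice, least
#' sensitive to noise on either side). The returned value is then frozen
#' and applied unchanged to comparison groups.
#'
#' @param control_profiles list of `intensity_profile` (control cells).
#' @param septate_flags logical vector, one per profile.
#' @param min_separation passed to [detect_foci()].
#' @param grid_size number of candidate prominences (default 30).
#' @return list of class `prominence_calibration`: `prominence` (frozen
#'   value), `agreement` (best fraction), `grid` (data frame of candidate
#'   values and agreement fractions).
#' @export
calibrate_prominence <- function(control_profiles, septate_flags,
                                 min_separation = 0.08, grid_size = 30) {
  if (length(control_profiles) < 20)
    stop_config("calibration needs >= 20 control cells (got %d)", length(control_profiles))
  if (length(septate_flags) != length(control_profiles))
    stop_config("septate_flags must match control_profiles")
  target <- ifelse(septate_flags, 3L, 2L)
  med_peak <- stats::median(vapply(control_profiles, function(p) max(p$values), 0))
  if (med_peak <= 0) stop_config("control profiles are flat; cannot calibrate")
  cand <- exp(seq(log(0.01), log(1), length.out = grid_size)) * med_peak
  agree <- vapply(cand, function(pr) {
    counts <- vapply(control_profiles, function(p)
      detect_foci(p, prominence = pr, min_separation = min_separation)$count,
      integer(1))
    mean(counts == target)
  }, numeric(1))
  best <- max(agree)
  if (best < 0.5)
    stop_config("no prominence achieves >= 50%% count agreement on the control population (best %.2f)", best)
  plateau <- which(agree == best)
  mid <- sqrt(cand[min(plateau)] * cand[max(plateau)])
  pick <- plateau[which.min(abs(log(cand[plateau]) - log(mid)))]
  structure(list(prominence = cand[pick], agreement = best,
                 grid = data.frame(prominence = cand, agreement = agree),
                 median_peak = med_peak),
            class = "prominence_calibration")
}

#' @export
print.prominence_calibration <- function(x, ...) {
  cat(sprintf("prominence_calibration: %.4g (%.0f%% count agreement; %.1f%% of median peak)\n",
              x$prominence, 100 * x$agreement, 100 * x$prominence / x$median_peak))
  invisible(x)
}

#' Consecutive distances between foci, as fractions of cell length
#'
#' @param foci a `foci_set`.
#' @return numeric vector of consecutive position differences (empty, with
#'   attribute `flagged = TRUE`, when fewer than two foci are present).
#' @export
interfoci_distances <- function(foci) {
  pos <- sort(foci$foci$rel_pos)
  if (length(pos) < 2) {
    out <- numeric(0)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  diff(pos)
}

#' Locate pole and septum landmarks on an axial profile
#'
#' Pole peaks are the highest local maxima within the terminal 15% window at
#' each end of the profile (falling back to the endpoint values when no
#' interior maximum exists there). The septum is the highest local maximum
#' within the central 70% whose prominence reaches `prominence`; its
#' relative position is reported as the distance to the nearest pole as a
#' fraction of length (in (0, 0.5]).
#'
#' @param profile an `intensity_profile`.
#' @param prominence septum prominence floor (the calibrated value).
#' @param septate_expected `TRUE`, `FALSE`, or `NA` (unknown). When `FALSE`
#'   no septum is searched for; otherwise a qualifying interior peak decides.
#' @param pole_window terminal window fraction per end (default 0.15).
#' @return object of class `cell_landmarks`: pole positions/intensities,
#'   septum position/intensity (or `NA`), `septum_rel_pos`, and `new_pole` /
#'   `old_pole` labels (filled by [classify_new_old()]).
#' @export
locate_landmarks <- function(profile, prominence, septate_expected = NA,
                             pole_window = 0.15) {
  pos <- profile$positions; val <- profile$values
  pk <- find_peaks(val, pos, prominence = 0, min_separation = 0)

  pole_pick <- function(window_lo, window_hi, endpoint_index) {
    cand <- pk[pk$position >= window_lo & pk$position <= window_hi, , drop = FALSE]
    if (nrow(cand) == 0)
      return(list(pos = pos[endpoint_index], value = val[endpoint_index]))
    top <- cand[which.max(cand$value), ]
    list(pos = top$position, value = top$value)
  }
  p1 <- pole_pick(0, pole_window, 1L)
  p2 <- pole_pick(1 - pole_window, 1, length(pos))

  septum_pos <- NA_real_; septum_val <- NA_real_
  if (!isFALSE(septate_expected)) {
    inner <- pk[pk$position >= 0.15 & pk$position <= 0.85 &
                  pk$prominence >= prominence, , drop = FALSE]
    if (nrow(inner) > 0) {
      top <- inner[which.max(inner$value), , drop = FALSE]
      near <- inner[abs(inner$position - top$position[1]) <= 0.05, , drop = FALSE]
      if (nrow(near) > 1) {
        top <- near[which.max(near$prominence), , drop = FALSE]
        message(sprintf("cell %s: %d septum candidates within 0.05; picked the most prominent",
                        profile$cell_id, nrow(near)))
      }
      septum_pos <- top$position[1]; septum_val <- top$value[1]
    } else if (isTRUE(septate_expected)) {
      # expected but not found above threshold: report absent
      septum_pos <- NA_real_
    }
  }
  structure(list(
    cell_id = profile$cell_id,
    pole1_pos = p1$pos, pole1_value = p1$value,
    pole2_pos = p2$pos, pole2_value = p2$value,
    septum_pos = septum_pos, septum_value = septum_val,
    septum_rel_pos = if (is.na(septum_pos)) NA_real_ else min(septum_pos, 1 - septum_pos),
    new_pole = NA_integer_, old_pole = NA_integer_,
    grid_step = pos[2] - pos[1]
  ), class = "cell_landmarks")
}

#' @export
print.cell_landmarks <- function(x, ...) {
  cat(sprintf("cell_landmarks: cell %s, poles at %.2f / %.2f%s%s\n",
              x$cell_id, x$pole1_pos, x$pole2_pos,
              if (is.na(x$septum_pos)) ", non-septate" else
                sprintf(", septum at %.2f (rel %.2f)", x$septum_pos, x$septum_rel_pos),
              if (is.na(x$new_pole)) "" else
                sprintf(", new pole = pole%d", x$new_pole)))
  invisible(x)
}

#' Label poles as new or old from septum proximity
#'
#' The pole nearer the septum is the new pole (formed at the last division);
#' the far pole is the old, faster-growing pole. Poles equidistant from the
#' septum within one grid step are labelled ambiguous and excluded from
#' pole-aligned statistics.
#'
#' @param landmarks a `cell_landmarks` with a septum present.
#' @return the landmarks with `new_pole` / `old_pole` set to 1 or 2, or to
#'   `NA` with attribute `ambiguous = TRUE` on a tie. Non-septate input is
#'   returned unchanged (labels absent).
#' @export
classify_new_old <- function(landmarks) {
  if (is.na(landmarks$septum_pos)) return(landmarks)
  d1 <- abs(landmarks$septum_pos - landmarks$pole1_pos)
  d2 <- abs(landmarks$septum_pos - landmarks$pole2_pos)
  if (abs(d1 - d2) <= landmarks$grid_step + 1e-12) {
    landmarks$new_pole <- NA_integer_
    landmarks$old_pole <- NA_integer_
    attr(landmarks, "ambiguous") <- TRUE
    return(landmarks)
  }
  landmarks$new_pole <- if (d1 < d2) 1L else 2L
  landmarks$old_pole <- 3L - landmarks$new_pole
  landmarks
}
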