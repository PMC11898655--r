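#' Fit the polar intensity decay slope
#'
#' Takes `k_points` consecutive resampled grid points starting at the pole
#' peak and moving inward (toward the septum when present, toward midcell
#' otherwise) and fits an ordinary least-squares line through the
#' (position, intensity) pairs. The decay is reported as the magnitude of
#' the fitted slope, in intensity units per normalized length; a gentler
#' slope means a broader polar incorporation zone (the faster-growing pole).
#'
#' @param profile an `intensity_profile`.
#' @param pole 1 or 2 (profile start / end).
#' @param landmarks a `cell_landmarks` for the same cell (pole positions).
#' @param k_points number of grid points in the fit (default 10).
#' @return list with `slope` (magnitude), `r2`, `intercept`, `pole`.
#' @export
fit_pole_decay <- function(profile, pole, landmarks, k_points = 10L) {
  stopifnot(pole %in% c(1L, 2L), k_points >= 2)
  pos <- profile$positions; val <- profile$values
  P <- length(pos)
  peak_pos <- if (pole == 1L) landmarks$pole1_pos else landmarks$pole2_pos
  i0 <- which.min(abs(pos - peak_pos))
  idx <- if (pole == 1L) i0:(i0 + k_points - 1L) else i0:(i0 - k_points + 1L)
  if (min(idx) < 1 || max(idx) > P)
    stop_config("pole %d: fewer than %d grid points available from the pole peak inward", pole, k_points)
  x <- pos[idx]; y <- val[idx]
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else ifelse(ssr == 0, 1, 0)
  list(slope = abs(slope), r2 = r2,
       intercept = unname(stats::coef(fit)[1]), pole = pole)
}

#' Pole-to-septum intensity ratio
#'
#' Mean of the two pole peak intensities divided by the septum peak
#' intensity. Values above 1 indicate pole-dominated wall synthesis (the
#' control phenotype); values below 1, septum-dominated synthesis.
#'
#' @param landmarks a `cell_landmarks` of a septate cell.
#' @return the ratio, or `NA` (with a message) when the septum is absent or
#'   has non-positive intensity.
#' @export
pole_septum_ratio <- function(landmarks) {
  if (is.na(landmarks$septum_pos) || is.na(landmarks$septum_value) ||
      landmarks$septum_value <= 0) {
    message(sprintf("cell %s: septum absent or zero intensity; ratio undefined, cell excluded",
                    landmarks$cell_id))
    return(NA_real_)
  }
  if (landmarks$pole1_value <= 0 || landmarks$pole2_value <= 0) {
    message(sprintf("cell %s: non-positive pole intensity; ratio undefined", landmarks$cell_id))
    return(NA_real_)
  }
  ((landmarks$pole1_value + landmarks$pole2_value) / 2) / landmarks$septum_value
}

#' Per-cell pole metrics
#'
#' Convenience wrapper fitting both pole decay slopes and the pole/septum
#' ratio for one cell.
#'
#' @param profile an `intensity_profile` (HADA channel).
#' @param landmarks a `cell_landmarks` (ideally after [classify_new_old()]).
#' @param k_points fit length, see [fit_pole_decay()].
#' @return object of class `pole_metrics`.
#' @export
pole_metrics <- function(profile, landmarks, k_points = 10L) {
  f1 <- fit_pole_decay(profile, 1L, landmarks, k_points)
  f2 <- fit_pole_decay(profile, 2L, landmarks, k_points)
  ratio <- if (is.na(landmarks$septum_pos)) NA_real_ else
    suppressMessages(pole_septum_ratio(landmarks))
  structure(list(
    cell_id = landmarks$cell_id,
    slope_pole1 = f1$slope, r2_pole1 = f1$r2, value_pole1 = landmarks$pole1_value,
    slope_pole2 = f2$slope, r2_pole2 = f2$r2, value_pole2 = landmarks$pole2_value,
    pole_septum_ratio = ratio,
    new_pole = landmarks$new_pole, old_pole = landmarks$old_pole
  ), class = "pole_metrics")
}

#' @export
print.pole_metrics <- function(x, ...) {
  cat(sprintf("pole_metrics: cell %s, slopes %.3g / %.3g, ratio %s\n",
              x$cell_id, x$slope_pole1, x$slope_pole2,
              if (is.na(x$pole_septum_ratio)) "NA" else sprintf("%.2f", x$pole_septum_ratio)))
  invisible(x)
}

#' Pole-aligned population mean profile
#'
#' Orients every septate, unambiguously classified cell so the new pole sits
#' at position 0 and the old pole at 1, then averages the profiles as in
#' [average_profiles()].
#'
#' @param profiles list of `intensity_profile`.
#' @param landmarks_list matching list of `cell_landmarks` (after
#'   [classify_new_old()]).
#' @return a `mean_profile` with attribute `alignment = "new_pole_at_0"`.
#' @export
aligned_mean_profile <- function(profiles, landmarks_list) {
  stopifnot(length(profiles) == length(landmarks_list))
  keep <- list()
  for (i in seq_along(profiles)) {
    lm_i <- landmarks_list[[i]]
    if (is.na(lm_i$septum_pos) || is.na(lm_i$new_pole)) next
    p <- profiles[[i]]
    if (lm_i$new_pole == 2L) p <- reverse_profile(p)
    keep[[length(keep) + 1]] <- p
  }
  if (length(keep) == 0) stop_config("no septate, unambiguous cells to align")
  out <- average_profiles(keep)
  attr(out, "alignment") <- "new_pole_at_0"
  out
}

#' Second-channel intensity at each pole, keyed by pole age
#'
#' Mean intensity of a second channel (e.g. mScarlet-tagged protein) within
#' a window around each pole position, reported for the old and new pole as
#' defined by the landmarks (HADA-based classification).
#'
#' @param profile_ch2 `intensity_profile` of the second channel, on the same
#'   grid as the HADA profile.
#' @param landmarks classified `cell_landmarks` (new/old labels set).
#' @param window half-width of the averaging window as a fraction of length
#'   (default 0.05; 0 means the single nearest grid point).
#' @return named numeric `c(old = , new = )`, or `NULL` (with a message)
#'   when pole labels are ambiguous.
#' @export
pole_channel_intensity <- function(profile_ch2, landmarks, window = 0.05) {
  if (is.na(landmarks$new_pole)) {
    message(sprintf("cell %s: ambiguous pole labels; excluded", landmarks$cell_id))
    return(NULL)
  }
  pos <- profile_ch2$positions; val <- profile_ch2$values
  grab <- function(center) {
    if (window <= 0) return(val[which.min(abs(pos - center))])
    sel <- abs(pos - center) <= window + 1e-12
    mean(val[sel])
  }
  pole_pos <- c(landmarks$pole1_pos, landmarks$pole2_pos)
  c(old = grab(pole_pos[landmarks$old_pole]),
    new = grab(pole_pos[landmarks$new_pole]))
}

#' Classify pole age from HADA decay slopes
#'
#' The faster-growing (old) pole shows HADA incorporation over a broader
#' zone from the tip and hence a smaller decay-slope magnitude; the pole
#' with the smaller slope is labelled old and the other new. Slopes within
#' 10% of each other (relative to the larger) are ambiguous.
#'
#' @param metrics a `pole_metrics`.
#' @param rel_tol relative ambiguity threshold (default 0.10).
#' @return list with `old_pole`, `new_pole` (1/2 or `NA`), `ambiguous`.
#' @export
slope_based_pole_age <- function(metrics, rel_tol = 0.10) {
  s <- c(metrics$slope_pole1, metrics$slope_pole2)
  hi <- max(s)
  if (hi <= 0 || abs(s[1] - s[2]) / hi <= rel_tol) {
    return(list(old_pole = NA_integer_, new_pole = NA_integer_, ambiguous = TRUE))
  }
  old <- which.min(s)
  list(old_pole = as.integer(old), new_pole = as.integer(3 - old), ambiguous = FALSE)
}
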