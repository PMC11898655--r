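#' Spectral phasor transform of a hyperspectral stack
#'
#' For each pixel with spectrum \eqn{I_k} (k = 0, ..., K-1, k = 0 at the
#' shortest wavelength) the first-harmonic Fourier coordinates are
#' \deqn{G = \sum_k I_k \cos(2\pi h k / K) / \sum_k I_k, \quad
#'       S = \sum_k I_k \sin(2\pi h k / K) / \sum_k I_k.}
#' The angular position \eqn{\Phi = atan2(S, G)} tracks the spectral centre
#' of mass (a red shift increases \eqn{\Phi} under this convention) and the
#' radial position \eqn{M = \sqrt{G^2 + S^2}} decreases with spectral
#' widening; for any nonnegative spectrum \eqn{M \le 1}.
#'
#' @param scene a `spectral_scene`, or a plain H x W x K array (then
#'   `wavelengths_nm` is taken as `1:K`).
#' @param harmonic harmonic number h (default 1).
#' @param intensity_threshold pixels with total intensity at or below this
#'   are marked invalid; `NULL` (default) uses Otsu's threshold on the
#'   total-intensity image, restricted to labelled pixels when the scene
#'   carries labels.
#' @return object of class `phasor_field`: rasters `G`, `S`, `Phi`, `M`,
#'   `total`, logical `valid`, plus `harmonic` and `wavelengths_nm`.
#' @export
spectral_phasor <- function(scene, harmonic = 1L, intensity_threshold = NULL) {
  if (inherits(scene, "spectral_scene")) {
    stack <- scene$stack; wl <- scene$wavelengths_nm; labels <- scene$labels
  } else {
    stack <- scene; wl <- seq_len(dim(stack)[3]); labels <- NULL
  }
  stopifnot(length(dim(stack)) == 3, harmonic >= 1)
  K <- dim(stack)[3]
  if (K < 2) stop_config("need at least 2 spectral channels")
  if (any(stack < 0)) stop_config("negative intensities in spectral stack")
  H <- dim(stack)[1]; W <- dim(stack)[2]
  flat <- matrix(stack, H * W, K)
  total <- rowSums(flat)
  k <- 0:(K - 1)
  cosv <- cos(2 * pi * harmonic * k / K)
  sinv <- sin(2 * pi * harmonic * k / K)
  if (is.null(intensity_threshold)) {
    tot_img <- matrix(total, H, W)
    sel <- if (!is.null(labels)) tot_img[labels > 0] else as.vector(tot_img)
    sel <- sel[sel > 0]
    intensity_threshold <- if (length(sel) > 1 && stats::sd(sel) > 0) {
      rng <- range(sel)
      EBImage::otsu(matrix((sel - rng[1]) / diff(rng), ncol = 1), range = c(0, 1)) *
        diff(rng) + rng[1]
    } else 0
  }
  valid <- total > intensity_threshold
  if (!any(valid)) stop_config("no pixel exceeds the intensity threshold")
  G <- S <- rep(NA_real_, H * W)
  G[valid] <- (flat[valid, , drop = FALSE] %*% cosv) / total[valid]
  S[valid] <- (flat[valid, , drop = FALSE] %*% sinv) / total[valid]
  Gm <- matrix(G, H, W); Sm <- matrix(S, H, W)
  structure(list(
    G = Gm, S = Sm,
    Phi = atan2(Sm, Gm), M = sqrt(Gm^2 + Sm^2),
    total = matrix(total, H, W),
    valid = matrix(valid, H, W),
    harmonic = as.integer(harmonic),
    wavelengths_nm = wl,
    intensity_threshold = intensity_threshold
  ), class = "phasor_field")
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf("phasor_field: %d x %d px, harmonic %d, %d valid pixel(s)\n",
              nrow(x$G), ncol(x$G), x$harmonic, sum(x$valid)))
  invisible(x)
}

#' Intensity-weighted phasor summary per group
#'
#' Intensity-weighted mean (G, S) over valid pixels, per label group or for
#' the whole field; the mean angle and modulus are derived from the mean
#' vector, and dispersion is the weighted RMS distance of pixel phasors
#' from the group mean.
#'
#' @param field a `phasor_field`.
#' @param labels optional integer raster; group 0 (background) is skipped.
#' @return data frame with one row per group: `group`, `n_pixels`,
#'   `mean_G`, `mean_S`, `mean_Phi`, `mean_M`, `dispersion`.
#' @export
phasor_summary <- function(field, labels = NULL) {
  groups <- if (is.null(labels)) list(all = field$valid) else {
    ids <- sort(setdiff(unique(as.vector(labels)), 0L))
    stats::setNames(lapply(ids, function(i) field$valid & labels == i), as.character(ids))
  }
  rows <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    if (!any(sel)) { message(sprintf("phasor_summary: empty group %s skipped", g)); next }
    w <- field$total[sel]
    G <- field$G[sel]; S <- field$S[sel]
    mg <- sum(w * G) / sum(w); ms <- sum(w * S) / sum(w)
    disp <- sqrt(sum(w * ((G - mg)^2 + (S - ms)^2)) / sum(w))
    rows[[g]] <- data.frame(group = g, n_pixels = sum(sel),
                            mean_G = mg, mean_S = ms,
                            mean_Phi = atan2(ms, mg),
                            mean_M = sqrt(mg^2 + ms^2),
                            dispersion = disp)
  }
  if (length(rows) == 0) stop_config("no non-empty group")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-reference linear-combination fraction per pixel
#'
#' Projects each valid pixel's (G, S) orthogonally onto the segment joining
#' two reference phasors and reports the position as the fraction of
#' reference A (1 at `ref_a`, 0 at `ref_b`), clipped to [0, 1]. Because the
#' phasor of a sum of spectra is the intensity-weighted mean of the
#' component phasors, this fraction recovers the mixing weight of two
#' equal-intensity components exactly.
#'
#' @param field a `phasor_field`.
#' @param ref_a,ref_b reference phasors, each a numeric `c(G, S)`.
#' @return raster of fractions (`NA` at invalid pixels).
#' @export
linear_fraction <- function(field, ref_a, ref_b) {
  a <- as.numeric(ref_a)[1:2]; b <- as.numeric(ref_b)[1:2]
  d <- b - a
  len2 <- sum(d^2)
  if (len2 < 1e-20) stop_config("degenerate references: ref_a == ref_b")
  t <- ((field$G - a[1]) * d[1] + (field$S - a[2]) * d[2]) / len2
  frac <- 1 - t
  frac[!field$valid] <- NA_real_
  pmin(pmax(frac, 0), 1)
}

#' Intensity-vs-fraction curve and its centre of mass
#'
#' Histograms pixel total intensities over bins of the linear-combination
#' fraction, normalizes the curve to unit maximum, and computes the centre
#' of mass of the (unnormalized) intensity mass.
#'
#' @param field a `phasor_field`.
#' @param fractions raster of per-pixel fractions from [linear_fraction()].
#' @param bins number of fraction bins (default 50).
#' @return object of class `fraction_curve`: `mid` (bin centres), `value`
#'   (unit-maximum normalized intensity), `mass` (raw per-bin intensity),
#'   `center_of_mass`, `degenerate` flag.
#' @export
fraction_curve <- function(field, fractions, bins = 50L) {
  stopifnot(bins >= 2)
  sel <- field$valid & !is.na(fractions)
  f <- fractions[sel]; w <- field$total[sel]
  edges <- seq(0, 1, length.out = bins + 1)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- pmin(pmax(findInterval(f, edges, rightmost.closed = TRUE), 1L), bins)
  mass <- vapply(seq_len(bins), function(b) sum(w[bin == b]), numeric(1))
  com <- sum(mid * mass) / sum(mass)
  degenerate <- all(f <= edges[2]) || all(f >= edges[bins])
  if (degenerate) message("fraction_curve: all fractions at one endpoint; curve degenerate")
  structure(list(mid = mid, value = mass / max(mass), mass = mass,
                 center_of_mass = com, degenerate = degenerate),
            class = "fraction_curve")
}

#' @export
print.fraction_curve <- function(x, ...) {
  cat(sprintf("fraction_curve: %d bins, centre of mass %.3f%s\n",
              length(x$mid), x$center_of_mass,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Phasor of a single spectrum
#'
#' @param intensities nonnegative spectrum.
#' @param harmonic harmonic number (default 1).
#' @return named numeric `c(G, S, Phi, M)`.
#' @export
phasor_point <- function(intensities, harmonic = 1L) {
  if (any(intensities < 0)) stop_config("negative intensities")
  K <- length(intensities)
  k <- 0:(K - 1)
  tot <- sum(intensities)
  if (tot <= 0) stop_config("zero total intensity")
  G <- sum(intensities * cos(2 * pi * harmonic * k / K)) / tot
  S <- sum(intensities * sin(2 * pi * harmonic * k / K)) / tot
  c(G = G, S = S, Phi = atan2(S, G), M = sqrt(G^2 + S^2))
}
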