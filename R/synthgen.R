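#' Preset parameters for the synthetic cell generator
#'
#' Resolves the full parameter set describing one of the emulated strain
#' phenotypes. `control` renders cells whose nascent peptidoglycan (HADA)
#' signal peaks at the poles with asymmetric polar decay (the old,
#' fast-growing pole has a broader incorporation zone, hence a gentler
#' axial decay) and an off-centre septum. `delta_fhaA` renders shorter,
#' more homogeneous cells whose HADA maximum sits at the septum, with
#' equal polar decays and a near-midcell septum. `overexpressor` renders
#' short cells that carry two extra HADA foci along the cell body in
#' addition to poles and septum. `custom` starts from the shared defaults
#' with all phenotype parameters unset; they must be supplied through
#' `overrides`.
#'
#' @param preset one of `"control"`, `"delta_fhaA"`, `"overexpressor"`,
#'   `"custom"`.
#' @param pixel_size_um pixel size in micrometres.
#' @param overrides named list overriding any parameter.
#' @return named list with the fully resolved parameter set.
#' @export
preset_params <- function(preset = c("control", "delta_fhaA", "overexpressor", "custom"),
                          pixel_size_um = 0.105, overrides = list()) {
  preset <- match.arg(preset)
  p <- list(
    preset = preset,
    pixel_size_um = pixel_size_um,
    width_um = 0.8,
    curv_frac = 0.04,          # max bow amplitude as fraction of length
    membrane_amp = 0.5,
    amp_scale = 100,           # photons per unit amplitude (SNR ~ 10 at unit peaks)
    read_sd = 2,               # Gaussian read noise, photons
    noise = TRUE,
    psf_sigma_px = 1.5,
    transverse_sigma_px = 1.0, # transverse falloff of centreline-rendered signal
    transverse_core_px = 1.0,  # flat-top core half-width: pixels on the axis carry full amplitude
    septum_sigma = 0.025,      # axial sigma of the septal focus, fraction of length
    channel2 = FALSE,
    ch2_amp = 1.0,
    ch2_sigma = 0.05,
    cells_per_scene = 25,
    placement_margin_px = 3,
    max_place_retries = 200,
    length_min_um = 2.8,
    length_max_um = 14,
    # phenotype block (NA for custom)
    length_mean_um = NA_real_, length_sd_um = NA_real_,
    septate_fraction = NA_real_,
    septum_frac_range = c(NA_real_, NA_real_),
    pole_amp_new = NA_real_, pole_amp_old = NA_real_,
    pole_extent_new = NA_real_, pole_extent_old = NA_real_,
    septum_amp = NA_real_,
    body_foci_n = 0L, body_amp = 1.0, body_sigma = 0.035,
    ch2_w_old = 1.0, ch2_w_new = 0.3,
    explicit_cells = NULL
  )
  pheno <- switch(preset,
    control = list(
      length_mean_um = 7.0, length_sd_um = 1.5,
      septate_fraction = 0.4,
      septum_frac_range = c(0.30, 0.45),
      pole_amp_new = 1.0, pole_amp_old = 1.0,
      pole_extent_new = 0.10, pole_extent_old = 0.22,
      septum_amp = 0.6,
      channel2 = TRUE
    ),
    delta_fhaA = list(
      length_mean_um = 5.5, length_sd_um = 0.8,
      septate_fraction = 0.4,
      septum_frac_range = c(0.42, 0.50),
      pole_amp_new = 0.5, pole_amp_old = 0.5,
      pole_extent_new = 0.25, pole_extent_old = 0.25,
      septum_amp = 1.0
    ),
    overexpressor = list(
      length_mean_um = 4.5, length_sd_um = 1.0,
      septate_fraction = 0.4,
      septum_frac_range = c(0.30, 0.45),
      pole_amp_new = 1.0, pole_amp_old = 1.0,
      pole_extent_new = 0.10, pole_extent_old = 0.14,
      septum_amp = 0.6,
      body_foci_n = 2L
    ),
    custom = list()
  )
  p[names(pheno)] <- pheno
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad)) stop_config("unknown generator parameter(s): %s", paste(bad, collapse = ", "))
    p[names(overrides)] <- overrides
  }
  if (is.null(p$explicit_cells)) {
    needed <- c("length_mean_um", "length_sd_um", "septate_fraction",
                "pole_amp_new", "pole_amp_old", "pole_extent_new",
                "pole_extent_old", "septum_amp")
    miss <- needed[vapply(needed, function(f) any(is.na(p[[f]])), logical(1))]
    if (any(is.na(p$septum_frac_range))) miss <- c(miss, "septum_frac_range")
    if (length(miss)) stop_config("unresolved generator parameter(s): %s", paste(miss, collapse = ", "))
    stopifnot(p$pole_extent_new > 0, p$pole_extent_new < 0.5,
              p$pole_extent_old > 0, p$pole_extent_old < 0.5)
  }
  p
}

# Sample intrinsic parameters of one cell (no placement yet).
sample_cell_spec <- function(p, i, seed) {
  with_seed(cell_seed(seed, i), {
    ex <- if (!is.null(p$explicit_cells)) p$explicit_cells[[((i - 1) %% length(p$explicit_cells)) + 1]] else NULL
    if (!is.null(ex)) {
      spec <- list(
        cell_id = i,
        length_um = ex$length_um,
        width_um = ex$width_um %||% p$width_um,
        septate = isTRUE(ex$septate),
        septum_pos = ex$septum_pos %||% NA_real_,
        bow_frac = ex$bow_frac %||% 0,
        theta = ex$theta %||% 0,
        foci = ex$foci,
        ch2_w = ex$ch2_w %||% c(0, 0),
        new_pole = ex$new_pole %||% NA_integer_,
        old_pole = ex$old_pole %||% NA_integer_
      )
      return(spec)
    }
    sdlog <- sqrt(log(1 + (p$length_sd_um / p$length_mean_um)^2))
    meanlog <- log(p$length_mean_um) - sdlog^2 / 2
    L <- min(max(stats::rlnorm(1, meanlog, sdlog), p$length_min_um), p$length_max_um)
    septate <- stats::runif(1) < p$septate_fraction
    if (septate) {
      f <- stats::runif(1, p$septum_frac_range[1], p$septum_frac_range[2])
      side <- sample(1:2, 1)
      septum_pos <- if (side == 1) f else 1 - f
      new_pole <- side                 # the pole nearest the septum is the new one
    } else {
      septum_pos <- NA_real_
      new_pole <- sample(1:2, 1)
    }
    old_pole <- 3L - new_pole
    amp <- c(NA_real_, NA_real_); ext <- c(NA_real_, NA_real_)
    amp[new_pole] <- p$pole_amp_new;  amp[old_pole] <- p$pole_amp_old
    ext[new_pole] <- p$pole_extent_new; ext[old_pole] <- p$pole_extent_old
    foci <- data.frame(
      kind = c("pole1", "pole2"),
      rel_pos = c(0, 1),
      amplitude = amp,
      axial_sigma = ext / 2,
      stringsAsFactors = FALSE
    )
    if (septate) {
      foci <- rbind(foci, data.frame(kind = "septum", rel_pos = septum_pos,
                                     amplitude = p$septum_amp,
                                     axial_sigma = p$septum_sigma))
    }
    if (p$body_foci_n > 0) {
      # discrete foci must stay optically resolvable: at least 0.8 um apart
      sep <- max(0.15, 0.8 / L)
      pos <- numeric(0)
      blocked <- c(if (septate) septum_pos)
      for (b in seq_len(p$body_foci_n)) {
        cand <- sample_in_intervals(0.2, 0.8, c(blocked, pos), sep)
        if (is.na(cand)) break
        pos <- c(pos, cand)
      }
      if (length(pos))
        foci <- rbind(foci, data.frame(kind = "body", rel_pos = pos,
                                       amplitude = p$body_amp,
                                       axial_sigma = p$body_sigma))
    }
    foci <- foci[order(foci$rel_pos), , drop = FALSE]
    ch2_w <- c(0, 0)
    if (isTRUE(p$channel2)) {
      ch2_w[old_pole] <- p$ch2_w_old
      ch2_w[new_pole] <- p$ch2_w_new
    }
    list(cell_id = i, length_um = L, width_um = p$width_um, septate = septate,
         septum_pos = septum_pos,
         bow_frac = stats::runif(1, 0, p$curv_frac),
         theta = stats::runif(1, 0, pi),
         foci = foci, ch2_w = ch2_w,
         new_pole = new_pole, old_pole = old_pole)
  })
}

#' Analytic axial intensity profile of a synthetic cell
#'
#' Sum of axial Gaussian components (poles, septum, body foci) evaluated on
#' normalized positions, before any optical blur or noise. This is the
#' generator's ground-truth profile against which extracted profiles are
#' validated.
#'
#' @param foci data frame with columns `rel_pos`, `amplitude`, `axial_sigma`
#'   (all as fractions of cell length / intensity units).
#' @param positions numeric vector of normalized axial positions in `[0, 1]`.
#' @return numeric vector of intensities.
#' @export
analytic_profile <- function(foci, positions) {
  v <- numeric(length(positions))
  for (j in seq_len(nrow(foci))) {
    v <- v + foci$amplitude[j] *
      exp(-(positions - foci$rel_pos[j])^2 / (2 * foci$axial_sigma[j]^2))
  }
  v
}

# Closed-form OLS slope magnitude over the first k grid points of the
# analytic profile from a given end (independent of the asymmetry module).
true_pole_slope <- function(foci, pole, k = 10, step = 0.01) {
  x <- seq(0, by = step, length.out = k)
  pos <- if (pole == 1) x else 1 - x
  y <- analytic_profile(foci, pos)
  xm <- x - mean(x); ym <- y - mean(y)
  abs(sum(xm * ym) / sum(xm * xm))
}

# Build the tip-to-tip centreline of one cell in pixel coordinates,
# given placement (centre, orientation, bow).
make_centerline <- function(len_px, theta, bow_px, center_rc, n = NULL) {
  if (is.null(n)) n <- max(9, ceiling(len_px / 4) + 1)
  t <- seq(-0.5, 0.5, length.out = n)
  x <- t * len_px
  y <- bow_px * cos(pi * t)           # perpendicular bow, zero slope at centre
  y <- y - mean(y)
  r <- center_rc[1] + x * sin(theta) + y * cos(theta)
  c <- center_rc[2] + x * cos(theta) - y * sin(theta)
  pts <- cbind(r, c)
  # rescale so the realized arc length equals len_px
  A <- arc_length(pts)
  sc <- len_px / A[length(A)]
  ctr <- colMeans(pts)
  pts <- sweep(sweep(pts, 2, ctr), 2, c(sc, sc), `*`)
  sweep(pts, 2, ctr, `+`)
}

# Sub-polyline of a centreline between arc-length s0 and s1.
trim_polyline <- function(pts, s0, s1) {
  s <- arc_length(pts)
  n <- 64
  si <- seq(s0, s1, length.out = n)
  cbind(stats::approx(s, pts[, 1], xout = si, ties = "ordered")$y,
        stats::approx(s, pts[, 2], xout = si, ties = "ordered")$y)
}

# Render one cell into the scene rasters (modified in place via environment).
render_cell <- function(env, spec, p, cline_px) {
  H <- nrow(env$labels); W <- ncol(env$labels)
  radius <- spec$width_um / 2 / p$pixel_size_um
  len_px <- spec$length_um / p$pixel_size_um
  pad <- ceiling(radius + 4 * p$transverse_sigma_px + 3)
  r0 <- max(0, floor(min(cline_px[, 1])) - pad)
  r1 <- min(H - 1, ceiling(max(cline_px[, 1])) + pad)
  c0 <- max(0, floor(min(cline_px[, 2])) - pad)
  c1 <- min(W - 1, ceiling(max(cline_px[, 2])) + pad)
  rr <- r0:r1; cc <- c0:c1
  grid <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
  pd <- polyline_distance(grid, cline_px)
  # distance to the tip-trimmed spine, reconstructed from (s, d) along the
  # full centreline (caps treated as locally straight)
  cap <- pmax(radius - pd$s, pd$s - (len_px - radius), 0)
  spine_dist <- sqrt(pd$dist^2 + cap^2)
  inside <- spine_dist <= radius
  srel <- pmin(pmax(pd$s / len_px, 0), 1)
  g <- analytic_profile(spec$foci, srel)
  dfall <- pmax(pd$dist - p$transverse_core_px, 0)
  kt <- exp(-dfall^2 / (2 * p$transverse_sigma_px^2))
  idx <- cbind(grid[, 1] + 1, grid[, 2] + 1)
  env$membrane[idx] <- env$membrane[idx] + p$membrane_amp * inside
  env$hada[idx] <- env$hada[idx] + g * kt
  if (isTRUE(p$channel2)) {
    g2 <- spec$ch2_w[1] * exp(-srel^2 / (2 * p$ch2_sigma^2)) +
      spec$ch2_w[2] * exp(-(1 - srel)^2 / (2 * p$ch2_sigma^2))
    env$ch2[idx] <- env$ch2[idx] + p$ch2_amp * g2 * kt
  }
  lab <- env$labels[idx]
  lab[inside & lab == 0] <- spec$cell_id
  env$labels[idx] <- lab
  invisible(NULL)
}

#' Generate a synthetic population of two-channel cell images
#'
#' Draws `n` rod-shaped cells from the chosen phenotype preset, places them
#' without overlap into one or more scenes, renders a membrane channel
#' (uniform envelope signal over the cell mask), an HADA-like channel (axial
#' Gaussian foci rendered along the centreline), and optionally an
#' mScarlet-like channel with pole-age-weighted polar signal. Each channel is
#' convolved with an isotropic Gaussian PSF and corrupted with Poisson shot
#' noise plus Gaussian read noise (both can be switched off). Returns the
#' scenes together with a complete ground-truth record.
#'
#' @param preset phenotype preset, see [preset_params()].
#' @param n number of cells (>= 1).
#' @param pixel_size_um pixel size in micrometres (default 0.105).
#' @param seed integer root seed; the same `(preset, n, seed)` always yields
#'   bit-identical output.
#' @param overrides named list of parameter overrides, see [preset_params()].
#' @return list with elements `scenes` (list of `image_scene`), `truth`
#'   (`ground_truth`: per-cell table, foci table, true centrelines), and
#'   `params` (the resolved parameter set).
#' @export
generate_population <- function(preset = "control", n, pixel_size_um = 0.105,
                                seed, overrides = list()) {
  if (missing(seed)) stop_config("a seed is required")
  if (n < 1) stop_config("n must be >= 1")
  p <- preset_params(preset, pixel_size_um, overrides)
  specs <- lapply(seq_len(n), function(i) sample_cell_spec(p, i, seed))

  max_len_px <- max(vapply(specs, function(s) s$length_um, 0)) / p$pixel_size_um
  per_scene <- min(p$cells_per_scene, n)
  n_scenes <- ceiling(n / per_scene)
  scenes <- vector("list", n_scenes)
  truth_cells <- vector("list", n)
  truth_foci <- vector("list", n)
  centerlines <- vector("list", n)

  for (sc in seq_len(n_scenes)) {
    ids <- ((sc - 1) * per_scene + 1):min(sc * per_scene, n)
    k <- length(ids)
    max_radius <- max(vapply(specs, function(s) s$width_um, 0)) / 2 / p$pixel_size_um
    spacing <- max_len_px + 2 * max_radius + 12
    side <- max(64L, as.integer(ceiling(ceiling(sqrt(k)) * spacing)))
    env <- new.env()
    env$membrane <- matrix(0, side, side)
    env$hada <- matrix(0, side, side)
    if (isTRUE(p$channel2)) env$ch2 <- matrix(0, side, side)
    env$labels <- matrix(0L, side, side)
    placed <- list()   # per placed cell: centreline + radius

    for (i in ids) {
      spec <- specs[[i]]
      len_px <- spec$length_um / p$pixel_size_um
      radius <- spec$width_um / 2 / p$pixel_size_um
      cl <- NULL
      with_seed(cell_seed(seed, 100000L + i), {
        margin <- len_px / 2 + radius + 4
        for (try in seq_len(p$max_place_retries)) {
          ctr <- stats::runif(2, margin, side - 1 - margin)
          bow_px <- spec$bow_frac * len_px
          cand <- make_centerline(len_px, spec$theta, bow_px, ctr)
          ok <- TRUE
          for (q in placed) {
            d <- min(polyline_distance(cand, q$cl)$dist)
            if (d < radius + q$radius + p$placement_margin_px) { ok <- FALSE; break }
          }
          if (ok) { cl <- cand; break }
        }
      })
      if (is.null(cl)) stop_config("could not place cell %d without overlap after %d retries",
                                   i, p$max_place_retries)
      placed[[length(placed) + 1]] <- list(cl = cl, radius = radius)
      render_cell(env, spec, p, cl)
      centerlines[[i]] <- cl
      truth_cells[[i]] <- data.frame(
        cell_id = spec$cell_id, scene = sc, preset = p$preset,
        length_um = spec$length_um, width_um = spec$width_um,
        septate = spec$septate,
        septum_pos = spec$septum_pos,
        septum_min_frac = if (is.na(spec$septum_pos)) NA_real_ else
          min(spec$septum_pos, 1 - spec$septum_pos),
        new_pole = spec$new_pole, old_pole = spec$old_pole,
        ch2_w1 = spec$ch2_w[1], ch2_w2 = spec$ch2_w[2],
        true_slope_pole1 = true_pole_slope(spec$foci, 1),
        true_slope_pole2 = true_pole_slope(spec$foci, 2),
        stringsAsFactors = FALSE
      )
      truth_foci[[i]] <- data.frame(cell_id = spec$cell_id, spec$foci,
                                    stringsAsFactors = FALSE)
    }

    channels <- list(membrane = env$membrane, hada = env$hada)
    if (isTRUE(p$channel2)) channels$mscarlet <- env$ch2
    # photon scaling, optics, noise
    channels <- lapply(channels, function(ch) ch * p$amp_scale)
    if (p$psf_sigma_px > 0)
      channels <- lapply(channels, function(ch) EBImage::gblur(ch, sigma = p$psf_sigma_px))
    if (isTRUE(p$noise)) {
      with_seed(cell_seed(seed, 200000L + sc), {
        channels <- lapply(channels, function(ch) {
          v <- stats::rpois(length(ch), pmax(ch, 0)) +
            stats::rnorm(length(ch), 0, p$read_sd)
          matrix(pmax(v, 0), nrow(ch), ncol(ch))
        })
      })
    }
    scenes[[sc]] <- structure(
      list(channels = channels, labels = env$labels,
           pixel_size_um = p$pixel_size_um, seed = seed),
      class = "image_scene")
  }

  truth <- structure(
    list(cells = do.call(rbind, truth_cells),
         foci = do.call(rbind, truth_foci),
         centerlines = centerlines),
    class = "ground_truth")
  list(scenes = scenes, truth = truth, params = p)
}

#' @export
print.image_scene <- function(x, ...) {
  cat(sprintf("image_scene: %d x %d px, %d channel(s) [%s], %d cell(s), %.3f um/px\n",
              nrow(x$labels), ncol(x$labels), length(x$channels),
              paste(names(x$channels), collapse = ", "),
              length(setdiff(unique(as.vector(x$labels)), 0L)),
              x$pixel_size_um))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d cell(s), %d foci\n", nrow(x$cells), nrow(x$foci)))
  invisible(x)
}

#' Generate a synthetic hyperspectral (LAURDAN-like) scene
#'
#' Renders small rod cells whose per-pixel emission spectrum is a discretized
#' Gaussian on a 30-channel wavelength grid (centres 423-713 nm, 10 nm bins),
#' with Poisson noise on photon counts. The `shifted` preset changes the
#' emission centre (default -30 nm, i.e. blue-shifted) and narrows the
#' spectrum relative to `control_like`, emulating a strain with an altered
#' membrane environment.
#'
#' @param preset `"control_like"` or `"shifted"`.
#' @param n_cells number of cells rendered in the scene.
#' @param seed integer root seed.
#' @param overrides named list; recognised entries include `lambda_c_nm`,
#'   `sigma_lambda_nm`, `delta_lambda_nm`, `amp_total`, `noise`,
#'   `pixel_size_um`, `wavelengths_nm`, `lambda_jitter_nm`.
#' @return list with `scene` (`spectral_scene`: stack H x W x K,
#'   `wavelengths_nm`, `labels`) and `truth` (per-pixel `lambda_c`,
#'   `sigma_l`, `amplitude` rasters).
#' @export
generate_spectral_population <- function(preset = c("control_like", "shifted"),
                                         n_cells, seed, overrides = list()) {
  preset <- match.arg(preset)
  if (missing(seed)) stop_config("a seed is required")
  p <- list(
    pixel_size_um = 0.05,
    wavelengths_nm = seq(423, 713, by = 10),
    lambda_c_nm = 490,
    sigma_lambda_nm = 25,
    delta_lambda_nm = -30,
    lambda_jitter_nm = 2,
    amp_total = 500,
    cell_length_um = 3, cell_width_um = 0.8,
    noise = TRUE
  )
  bad <- setdiff(names(overrides), names(p))
  if (length(bad)) stop_config("unknown spectral parameter(s): %s", paste(bad, collapse = ", "))
  p[names(overrides)] <- overrides
  if (preset == "shifted" && !("lambda_c_nm" %in% names(overrides))) {
    p$lambda_c_nm <- p$lambda_c_nm + p$delta_lambda_nm
    if (!("sigma_lambda_nm" %in% names(overrides))) p$sigma_lambda_nm <- 20
  }
  if (p$sigma_lambda_nm <= 0) stop_config("sigma_lambda_nm must be > 0")
  wl <- p$wavelengths_nm
  if (is.unsorted(wl, strictly = TRUE)) stop_config("wavelengths must be strictly increasing")
  K <- length(wl)

  len_px <- p$cell_length_um / p$pixel_size_um
  radius <- p$cell_width_um / 2 / p$pixel_size_um
  spacing <- len_px + 2 * radius + 16
  side <- max(128L, as.integer(ceiling(ceiling(sqrt(n_cells)) * spacing)))
  labels <- matrix(0L, side, side)
  lambda_c <- matrix(NA_real_, side, side)
  sigma_l <- matrix(NA_real_, side, side)
  amplitude <- matrix(0, side, side)
  placed <- list()
  for (i in seq_len(n_cells)) {
    with_seed(cell_seed(seed, 300000L + i), {
      theta <- stats::runif(1, 0, pi)
      lam_i <- p$lambda_c_nm + stats::rnorm(1, 0, p$lambda_jitter_nm)
      cl <- NULL
      margin <- len_px / 2 + radius + 3
      for (try in 1:200) {
        ctr <- stats::runif(2, margin, side - 1 - margin)
        cand <- make_centerline(len_px, theta, 0, ctr)
        ok <- TRUE
        for (q in placed) {
          if (min(polyline_distance(cand, q)$dist) < 2 * radius + 3) { ok <- FALSE; break }
        }
        if (ok) { cl <- cand; break }
      }
      if (is.null(cl)) stop_config("could not place spectral cell %d", i)
      placed[[length(placed) + 1]] <- cl
      pad <- ceiling(radius + 2)
      r0 <- max(0, floor(min(cl[, 1])) - pad); r1 <- min(side - 1, ceiling(max(cl[, 1])) + pad)
      c0 <- max(0, floor(min(cl[, 2])) - pad); c1 <- min(side - 1, ceiling(max(cl[, 2])) + pad)
      grid <- cbind(rep(r0:r1, times = c1 - c0 + 1), rep(c0:c1, each = r1 - r0 + 1))
      spine <- trim_polyline(cl, radius, len_px - radius)
      d <- polyline_distance(grid, spine)$dist
      inside <- d <= radius
      idx <- cbind(grid[inside, 1] + 1, grid[inside, 2] + 1)
      labels[idx] <- i
      lambda_c[idx] <- lam_i
      sigma_l[idx] <- p$sigma_lambda_nm
      amplitude[idx] <- p$amp_total
    })
  }
  stack <- array(0, dim = c(side, side, K))
  valid <- which(amplitude > 0)
  if (length(valid)) {
    w <- exp(-sweep(outer(rep(1, length(valid)), wl), 1, lambda_c[valid])^2 /
               (2 * sigma_l[valid]^2))
    w <- w / rowSums(w)
    spec <- w * amplitude[valid]
    if (isTRUE(p$noise)) {
      with_seed(cell_seed(seed, 400000L), {
        spec <- matrix(stats::rpois(length(spec), spec), nrow(spec), ncol(spec))
      })
    }
    for (k in seq_len(K)) {
      plane <- stack[, , k]
      plane[valid] <- spec[, k]
      stack[, , k] <- plane
    }
  }
  scene <- structure(
    list(stack = stack, wavelengths_nm = wl, labels = labels,
         pixel_size_um = p$pixel_size_um, seed = seed),
    class = "spectral_scene")
  truth <- list(lambda_c = lambda_c, sigma_l = sigma_l, amplitude = amplitude,
                params = p)
  list(scene = scene, truth = truth)
}

#' @export
print.spectral_scene <- function(x, ...) {
  cat(sprintf("spectral_scene: %d x %d px, %d channels (%g-%g nm), %d cell(s)\n",
              dim(x$stack)[1], dim(x$stack)[2], dim(x$stack)[3],
              min(x$wavelengths_nm), max(x$wavelengths_nm),
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}
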