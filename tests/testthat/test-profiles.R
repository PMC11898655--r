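test_that("medial axis of a straight capsule spans tip to tip", {
  lab <- capsule_mask(21, 120, row = 10, c0 = 13.5, c1 = 105.5, radius = 4)
  # mask columns span ~100 px end to end
  ax <- extract_medial_axis(lab, 1L, pixel_size_um = 0.105)
  len <- max(ax$arc_length_px)
  expect_lt(abs(len - (diff(range(which(lab > 0, arr.ind = TRUE)[, 2])))), 1.5)
  expect_equal(measure_length(ax), len * 0.105)
})

test_that("degenerate disk-shaped regions are flagged, not profiled", {
  lab <- capsule_mask(31, 31, row = 15, c0 = 14.5, c1 = 15.5, radius = 9)
  expect_error(extract_medial_axis(lab, 1L), class = "mycomorph_cell_flagged")
  expect_error(extract_medial_axis(lab, 2L), "not present")
})

test_that("recovered axis tracks the true centreline of a curved cell within 1 px", {
  foci <- data.frame(kind = "body", rel_pos = 0.5, amplitude = 1, axial_sigma = 0.1)
  g <- noiseless_cell(length_um = 8, foci = foci, theta = 0.5, bow_frac = 0.04, seed = 17)
  ax <- extract_medial_axis(g$scenes[[1]]$labels, 1L, 0.105)
  expect_lt(hausdorff(ax$points, g$truth$centerlines[[1]]), 1)
})

test_that("lengths of noiseless generated cells are recovered within 2%", {
  pop <- generate_population("control", n = 20, seed = 3,
                             overrides = list(noise = FALSE, psf_sigma_px = 0,
                                              channel2 = FALSE))
  ex <- extract_cell_profiles(pop$scenes, channels = "hada")
  m <- merge(ex$lengths, pop$truth$cells, by = "cell_id")
  expect_equal(nrow(m), 20)
  expect_lt(mean(abs(m$length_um.x - m$length_um.y) / m$length_um.y), 0.02)
})

test_that("a uniform channel yields a constant background-subtracted profile", {
  lab <- capsule_mask(21, 120, row = 10, c0 = 14, c1 = 105, radius = 4)
  ax <- extract_medial_axis(lab, 1L)
  chan <- matrix(3, 21, 120)
  pr <- extract_profile(chan, ax, width_px = 5, background = 0.5)
  expect_true(all(abs(pr$values - 2.5) < 1e-9))
  expect_identical(range(pr$positions), c(0, 1))
  # all-zero channel: flat zero profile is valid
  pr0 <- extract_profile(matrix(0, 21, 120), ax, width_px = 5)
  expect_true(all(pr0$values == 0))
})

test_that("noiseless profile matches the generator's analytic profile within 2% of peak", {
  foci <- data.frame(kind = c("body", "body"), rel_pos = c(0.35, 0.7),
                     amplitude = c(2, 1.2), axial_sigma = c(0.1, 0.08))
  g <- noiseless_cell(length_um = 10, foci = foci, theta = 0.3, seed = 9)
  ax <- extract_medial_axis(g$scenes[[1]]$labels, 1L, 0.105)
  pr <- extract_profile(g$scenes[[1]]$channels$hada, ax, width_px = 1)
  tru <- analytic_profile(truth_foci(g, 1), pr$positions)
  expect_lt(max(abs(pr$values - tru)), 0.02 * max(tru))
  # argmax of the extracted profile sits at the true focus position
  expect_lt(abs(pr$positions[which.max(pr$values)] - 0.35), 0.011)
})

test_that("band averaging equals a direct pixel-averaging oracle, and off-axis foci lose peak height", {
  nr <- 21; nc <- 120
  ax <- horizontal_axis(10, 10, 109)
  blob <- function(r0, c0) outer(0:(nr - 1), 0:(nc - 1), function(r, cc)
    5 * exp(-((r - r0)^2 + (cc - c0)^2) / (2 * 2.5^2)))
  on_axis <- blob(10, 60); off_axis <- blob(13, 60)
  # odd width: perpendicular samples land exactly on pixel centres
  w <- 9L
  pr_on <- extract_profile(on_axis, ax, width_px = w, resample_points = 100L)
  pr_off <- extract_profile(off_axis, ax, width_px = w, resample_points = 100L)
  oracle <- function(chan) {
    sapply(10:109, function(cc) mean(chan[(10 + (-4:4)) + 1, cc + 1]))
  }
  expect_lt(max(abs(pr_on$values - oracle(on_axis))), 1e-9)
  expect_lt(max(abs(pr_off$values - oracle(off_axis))), 1e-9)
  expect_gte(max(pr_on$values), max(pr_off$values))
})

test_that("flipping the axis orientation reverses the profile exactly", {
  foci <- data.frame(kind = c("pole1", "body"), rel_pos = c(0, 0.6),
                     amplitude = c(1, 2), axial_sigma = c(0.06, 0.08))
  g <- noiseless_cell(length_um = 7, foci = foci, theta = 1.1, seed = 23, psf = 1.5)
  ax <- extract_medial_axis(g$scenes[[1]]$labels, 1L, 0.105)
  ch <- g$scenes[[1]]$channels$hada
  pr <- extract_profile(ch, ax, width_px = 10)
  pr_rev <- extract_profile(ch, reverse_axis(ax), width_px = 10)
  expect_lt(max(abs(pr$values - rev(pr_rev$values))), 1e-9)
})

test_that("widening the band never increases the peak of a centred axial signal", {
  nr <- 21; nc <- 120
  ax <- horizontal_axis(10, 10, 109)
  chan <- outer(0:(nr - 1), 0:(nc - 1), function(r, cc)
    5 * exp(-((r - 10)^2 + (cc - 60)^2) / (2 * 2.5^2)))
  peaks <- sapply(c(1L, 3L, 5L, 9L, 15L), function(w)
    max(extract_profile(chan, ax, width_px = w)$values))
  expect_true(all(diff(peaks) <= 1e-12))
})

test_that("profile averaging: mean, sample SD and grid checks", {
  p1 <- profile_from_values(rep(0, 50))
  p2 <- profile_from_values(rep(2, 50))
  mp <- average_profiles(list(p1, p2))
  expect_true(all(mp$mean == 1))
  expect_true(all(abs(mp$sd - sqrt(2)) < 1e-12))  # sample SD of {0, 2}
  same <- average_profiles(list(p1, p1, p1))
  expect_true(all(same$sd == 0))
  expect_identical(same$mean, p1$values)
  expect_error(average_profiles(list()), "no profiles")
  expect_error(average_profiles(list(p1, profile_from_values(rep(1, 40)))),
               "different position grids")
})

test_that("pole-aligned mean profile of septate control cells has exactly three peaks", {
  pop <- generate_population("control", n = 60, seed = 41,
                             overrides = list(noise = FALSE, channel2 = FALSE))
  res <- analyze_population(pop$scenes, septate = truth_septate(pop),
                            prominence = 0.05)
  sept_ids <- as.character(pop$truth$cells$cell_id[pop$truth$cells$septate])
  amp <- aligned_mean_profile(res$profiles[sept_ids], res$landmarks[sept_ids])
  expect_gte(amp$n_cells, 10)
  pk <- detect_foci(profile_from_values(amp$mean),
                    prominence = 0.1 * max(amp$mean), min_separation = 0.08)
  expect_equal(pk$count, 3)
})

test_that("Otsu helper segments a synthetic membrane channel into the right cell count", {
  pop <- generate_population("control", n = 6, seed = 19,
                             overrides = list(channel2 = FALSE))
  sc <- pop$scenes[[1]]
  lab <- segment_otsu(sc$channels$membrane)
  expect_equal(length(setdiff(unique(as.vector(lab)), 0L)),
               length(setdiff(unique(as.vector(sc$labels)), 0L)))
})
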