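landmarks_stub <- function(pole1_pos = 0, pole2_pos = 1, pole1_value = 1,
                           pole2_value = 1, septum_pos = NA, septum_value = NA,
                           new_pole = NA_integer_, grid_step = 0.01) {
  structure(list(cell_id = 1L, pole1_pos = pole1_pos, pole1_value = pole1_value,
                 pole2_pos = pole2_pos, pole2_value = pole2_value,
                 septum_pos = septum_pos, septum_value = septum_value,
                 septum_rel_pos = if (is.na(septum_pos)) NA_real_ else
                   min(septum_pos, 1 - septum_pos),
                 new_pole = new_pole,
                 old_pole = if (is.na(new_pole)) NA_integer_ else 3L - new_pole,
                 grid_step = grid_step),
            class = "cell_landmarks")
}

test_that("pole decay slope is exact on linear and constant segments", {
  x <- seq(0, 1, length.out = 101)
  lin <- profile_from_values(pmax(1 - 2 * x, 0))
  f <- fit_pole_decay(lin, 1L, landmarks_stub())
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  const <- profile_from_values(rep(3, 101))
  expect_equal(fit_pole_decay(const, 1L, landmarks_stub())$slope, 0, tolerance = 1e-12)
  short <- profile_from_values(rep(1, 5))
  expect_error(fit_pole_decay(short, 2L, landmarks_stub(grid_step = 0.25), k_points = 10),
               "fewer than")
})

test_that("fitted slopes match the closed-form normal-equations solution", {
  set.seed(3)
  for (i in 1:50) {
    v <- rnorm(101, sd = 2) + 5
    p <- profile_from_values(abs(v))
    f <- fit_pole_decay(p, 2L, landmarks_stub())
    x <- p$positions[101:92]; y <- p$values[101:92]
    beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_lt(abs(f$slope - abs(beta)), 1e-10)
  }
})

test_that("pole/septum ratio follows its definition and excludes undefined cells", {
  expect_equal(pole_septum_ratio(landmarks_stub(pole1_value = 2, pole2_value = 2,
                                                septum_pos = 0.4, septum_value = 1)), 2)
  expect_equal(pole_septum_ratio(landmarks_stub(pole1_value = 1, pole2_value = 1,
                                                septum_pos = 0.4, septum_value = 1)), 1)
  expect_message(r <- pole_septum_ratio(landmarks_stub(septum_pos = 0.4, septum_value = 0)),
                 "excluded")
  expect_true(is.na(r))
})

test_that("pole/septum ratio is scale invariant", {
  p <- gaussian_profile(c(0, 0.4, 1), c(2, 1.2, 1.8), c(0.05, 0.03, 0.05))
  r1 <- pole_septum_ratio(locate_landmarks(p, prominence = 0.1))
  p2 <- p; p2$values <- p$values * 7.3
  r2 <- pole_septum_ratio(locate_landmarks(p2, prominence = 0.1))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("aligned mean profile puts the new pole at 0 regardless of orientation", {
  p <- gaussian_profile(c(0, 0.4, 1), c(2, 1.2, 1.8), c(0.05, 0.03, 0.05))
  lm1 <- classify_new_old(locate_landmarks(p, prominence = 0.1))
  expect_equal(lm1$new_pole, 1L)
  out1 <- aligned_mean_profile(list(p), list(lm1))
  expect_equal(out1$mean, p$values)
  # same cell seen in the flipped orientation
  q <- reverse_profile(p)
  lm2 <- classify_new_old(locate_landmarks(q, prominence = 0.1))
  expect_equal(lm2$new_pole, 2L)
  out2 <- aligned_mean_profile(list(q), list(lm2))
  expect_equal(out2$mean, out1$mean, tolerance = 1e-12)
  expect_error(aligned_mean_profile(list(p), list(landmarks_stub())), "no septate")
})

test_that("per-cell asymmetry metrics are invariant under profile reversal", {
  pop <- generate_population("control", n = 12, seed = 27,
                             overrides = list(channel2 = FALSE))
  res <- analyze_population(pop$scenes, septate = truth_septate(pop), prominence = 5)
  for (key in names(res$profiles)[1:6]) {
    p <- res$profiles[[key]]
    q <- reverse_profile(p)
    lmp <- classify_new_old(locate_landmarks(p, 5))
    lmq <- classify_new_old(locate_landmarks(q, 5))
    mp <- pole_metrics(p, lmp); mq <- pole_metrics(q, lmq)
    expect_equal(sort(c(mp$slope_pole1, mp$slope_pole2)),
                 sort(c(mq$slope_pole1, mq$slope_pole2)), tolerance = 1e-9)
    expect_equal(mp$pole_septum_ratio, mq$pole_septum_ratio, tolerance = 1e-9)
  }
})

test_that("second-channel pole intensity is keyed by pole age", {
  uni <- profile_from_values(rep(4, 101), channel = "mscarlet")
  lm <- landmarks_stub(septum_pos = 0.4, septum_value = 1, new_pole = 1L)
  ci <- pole_channel_intensity(uni, lm)
  expect_equal(ci[["old"]], ci[["new"]])
  # window 0: single nearest grid point
  v <- rep(0, 101); v[1] <- 3; v[101] <- 9
  spot <- profile_from_values(v, channel = "mscarlet")
  c0 <- pole_channel_intensity(spot, lm, window = 0)
  expect_equal(unname(c0), c(9, 3))  # old pole = pole2 here
  expect_message(expect_null(pole_channel_intensity(uni, landmarks_stub())),
                 "ambiguous")
})

test_that("generator pole weights are recovered from the second channel", {
  foci <- data.frame(kind = c("pole1", "pole2", "septum"), rel_pos = c(0, 1, 0.4),
                     amplitude = c(1, 1, 0.6), axial_sigma = c(0.05, 0.11, 0.025))
  g <- noiseless_cell(length_um = 8, foci = foci, septum_pos = 0.4, septate = TRUE,
                      ch2_w = c(0.25, 1), seed = 15, psf = 1.5,
                      extra = list(channel2 = TRUE))
  sc <- g$scenes[[1]]
  ax <- extract_medial_axis(sc$labels, 1L, 0.105)
  ph <- extract_profile(sc$channels$hada, ax, width_px = 10, channel_name = "hada")
  p2 <- extract_profile(sc$channels$mscarlet, ax, width_px = 10, channel_name = "mscarlet")
  lm <- classify_new_old(locate_landmarks(ph, prominence = 0.05))
  ci <- pole_channel_intensity(p2, lm)
  # generator put weight 1 on pole2 (old: septum at 0.4 is nearer pole1)
  expect_equal(lm$new_pole, 1L)
  expect_lt(abs(ci[["old"]] / ci[["new"]] - 4) / 4, 0.1)
})

test_that("slope-based pole age: smaller decay is the old pole, near-equal is ambiguous", {
  pm <- structure(list(slope_pole1 = 1, slope_pole2 = 3), class = "pole_metrics")
  age <- slope_based_pole_age(pm)
  expect_equal(age$old_pole, 1L)
  expect_equal(age$new_pole, 2L)
  tie <- structure(list(slope_pole1 = 2, slope_pole2 = 2.05), class = "pole_metrics")
  expect_true(slope_based_pole_age(tie)$ambiguous)
})

test_that("equal-decay populations show no systematic pole slope difference", {
  pop <- generate_population("delta_fhaA", n = 60, seed = 51,
                             overrides = list(noise = FALSE))
  res <- analyze_population(pop$scenes, septate = truth_septate(pop), prominence = 2)
  d <- res$metrics$slope_pole1 - res$metrics$slope_pole2
  d <- d[!is.na(d) & d != 0]
  bt <- binom.test(sum(d > 0), length(d))
  expect_gt(bt$p.value, 0.01)
})

test_that("control cells elongate asymmetrically: new-pole slope exceeds old-pole slope", {
  pop <- generate_population("control", n = 40, seed = 61,
                             overrides = list(noise = FALSE, channel2 = FALSE))
  res <- analyze_population(pop$scenes, septate = truth_septate(pop), prominence = 2)
  m <- merge(res$metrics, pop$truth$cells, by = "cell_id")
  sept <- m[!is.na(m$slope_new), ]
  expect_gte(mean(sept$slope_new > sept$slope_old), 0.95)
  # and the aligned mean profile decays more gently at the old pole (position 1)
  sept_ids <- as.character(m$cell_id[m$septate])
  amp <- aligned_mean_profile(res$profiles[sept_ids], res$landmarks[sept_ids])
  mp <- profile_from_values(amp$mean)
  s_new <- fit_pole_decay(mp, 1L, landmarks_stub())$slope
  s_old <- fit_pole_decay(mp, 2L, landmarks_stub())$slope
  expect_gt(s_new, s_old)
})
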