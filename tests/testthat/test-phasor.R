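K30 <- 30
wl30 <- seq(423, 713, by = 10)

# brute-force trig-summation oracle, written independently of the package
oracle_gs <- function(spec, h = 1) {
  K <- length(spec)
  G <- 0; S <- 0; tot <- 0
  for (k in 0:(K - 1)) {
    G <- G + spec[k + 1] * cos(2 * pi * h * k / K)
    S <- S + spec[k + 1] * sin(2 * pi * h * k / K)
    tot <- tot + spec[k + 1]
  }
  c(G / tot, S / tot)
}

test_that("uniform spectra map to the origin, delta spectra to the unit circle", {
  u <- phasor_point(rep(7, K30))
  expect_lt(abs(u[["G"]]), 1e-12)
  expect_lt(abs(u[["S"]]), 1e-12)
  d <- phasor_point(c(5, rep(0, K30 - 1)))
  expect_equal(unname(d[c("G", "S", "M", "Phi")]), c(1, 0, 1, 0), tolerance = 1e-12)
})

test_that("per-pixel G and S agree with the trig oracle and the generic DFT", {
  set.seed(19)
  for (i in 1:200) {
    spec <- runif(K30)^2 * 10
    gs <- phasor_point(spec)
    o <- oracle_gs(spec)
    expect_lt(max(abs(gs[c("G", "S")] - o)), 1e-12)
    f <- fft(spec)[2]
    expect_lt(abs(Re(f) / sum(spec) - gs[["G"]]), 1e-10)
    expect_lt(abs(-Im(f) / sum(spec) - gs[["S"]]), 1e-10)
    expect_lte(gs[["M"]], 1 + 1e-12)
  }
})

test_that("the phasor transform is scale invariant and errors on bad input", {
  spec <- exp(-(wl30 - 490)^2 / (2 * 25^2))
  a <- phasor_point(spec); b <- phasor_point(spec * 137.5)
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(phasor_point(rep(0, K30)), "zero total")
  expect_error(phasor_point(c(-1, rep(1, K30 - 1))), "negative")
  stack <- array(-1, dim = c(2, 2, K30))
  expect_error(spectral_phasor(stack, intensity_threshold = 0), "negative")
})

test_that("phasor of a mixture is the intensity-weighted mean of component phasors", {
  A <- exp(-(wl30 - 440)^2 / (2 * 15^2))
  B <- exp(-(wl30 - 520)^2 / (2 * 30^2)); B <- B * sum(A) / sum(B)
  pa <- phasor_point(A); pb <- phasor_point(B)
  for (w in c(0, 0.25, 0.5, 0.75, 1)) {
    pm <- phasor_point(w * A + (1 - w) * B)
    expect_lt(abs(pm[["G"]] - (w * pa[["G"]] + (1 - w) * pb[["G"]])), 1e-12)
    expect_lt(abs(pm[["S"]] - (w * pa[["S"]] + (1 - w) * pb[["S"]])), 1e-12)
  }
  # general linearity on random spectra
  set.seed(23)
  for (i in 1:20) {
    I <- runif(K30); J <- runif(K30) * 3
    pi_ <- phasor_point(I); pj <- phasor_point(J); ps <- phasor_point(I + J)
    wI <- sum(I) / sum(I + J)
    expect_lt(abs(ps[["G"]] - (wI * pi_[["G"]] + (1 - wI) * pj[["G"]])), 1e-12)
    expect_lt(abs(ps[["S"]] - (wI * pi_[["S"]] + (1 - wI) * pj[["S"]])), 1e-12)
  }
})

test_that("linear fraction recovers the mixing weight and honours endpoints", {
  A <- exp(-(wl30 - 440)^2 / (2 * 15^2))
  B <- exp(-(wl30 - 520)^2 / (2 * 30^2)); B <- B * sum(A) / sum(B)
  ws <- c(0, 0.25, 0.5, 0.75, 1)
  stack <- array(0, dim = c(1, length(ws), K30))
  for (j in seq_along(ws)) stack[1, j, ] <- ws[j] * A + (1 - ws[j]) * B
  field <- spectral_phasor(stack, intensity_threshold = 0)
  fr <- linear_fraction(field, phasor_point(A)[c("G", "S")],
                        phasor_point(B)[c("G", "S")])
  expect_lt(max(abs(as.vector(fr) - ws)), 1e-9)
  expect_error(linear_fraction(field, c(0.5, 0.5), c(0.5, 0.5)), "degenerate")
})

test_that("phasor summaries aggregate by intensity weight", {
  stack <- array(0, dim = c(1, 2, K30))
  stack[1, 1, ] <- c(10, rep(0, K30 - 1))             # phasor (1, 0)
  stack[1, 2, 1 + K30 / 2] <- 10                      # phasor (-1, 0)
  field <- spectral_phasor(stack, intensity_threshold = 0)
  sm <- phasor_summary(field)
  expect_equal(sm$mean_G, 0, tolerance = 1e-12)
  expect_equal(sm$mean_S, 0, tolerance = 1e-12)
  expect_equal(sm$dispersion, 1, tolerance = 1e-12)
  # identical pixels: summary equals the pixel, dispersion 0
  same <- array(rep(exp(-(wl30 - 490)^2 / 1250), each = 4), dim = c(2, 2, K30))
  f2 <- spectral_phasor(same, intensity_threshold = 0)
  s2 <- phasor_summary(f2)
  expect_equal(s2$dispersion, 0, tolerance = 1e-12)
  expect_equal(c(s2$mean_G, s2$mean_S),
               unname(phasor_point(exp(-(wl30 - 490)^2 / 1250))[c("G", "S")]),
               tolerance = 1e-12)
})

test_that("fraction curves: centre of mass matches the pixel fraction distribution", {
  mkfield <- function(fracs, weights) {
    structure(list(G = matrix(fracs, 1), S = matrix(0, 1, length(fracs)),
                   valid = matrix(TRUE, 1, length(fracs)),
                   total = matrix(weights, 1)), class = "phasor_field")
  }
  # references (1,0) and (0,0): fraction of ref_a equals G directly
  ra <- c(1, 0); rb <- c(0, 0)
  f1 <- mkfield(rep(0.5, 10), rep(2, 10))
  cv1 <- fraction_curve(f1, linear_fraction(f1, ra, rb), bins = 25)
  expect_equal(cv1$center_of_mass, 0.5, tolerance = 1e-12)
  f2 <- mkfield(c(rep(0.2, 5), rep(0.8, 5)), rep(1, 10))
  cv2 <- fraction_curve(f2, linear_fraction(f2, ra, rb), bins = 20)
  expect_equal(cv2$center_of_mass, 0.5, tolerance = 1e-9)
  expect_equal(max(cv2$value), 1)
  # known mixture distribution: COM = intensity-weighted mean within bin width
  set.seed(31)
  ws <- runif(400); wt <- runif(400, 1, 3)
  f3 <- mkfield(ws, wt)
  cv3 <- fraction_curve(f3, linear_fraction(f3, ra, rb), bins = 50)
  expect_lt(abs(cv3$center_of_mass - sum(ws * wt) / sum(wt)), 0.02)
  # degenerate: everything at one endpoint
  f4 <- mkfield(rep(0, 5), rep(1, 5))
  expect_message(cv4 <- fraction_curve(f4, linear_fraction(f4, ra, rb), bins = 10),
                 "degenerate")
  expect_true(cv4$degenerate)
})

test_that("thresholding marks dim pixels invalid and empty fields error", {
  stack <- array(0, dim = c(2, 2, K30))
  stack[1, 1, ] <- 100 * exp(-(wl30 - 490)^2 / 1250)
  stack[2, 2, ] <- 1e-3
  field <- spectral_phasor(stack, intensity_threshold = 1)
  expect_identical(sum(field$valid), 1L)
  expect_true(is.na(field$G[2, 2]))
  expect_error(spectral_phasor(stack, intensity_threshold = 1e9), "no pixel")
})
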