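# Internal helpers shared across modules.

# Derive a per-cell RNG seed from a root seed and a counter, so each cell's
# parameters are reproducible independently of how many cells precede it.
cell_seed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 65011 + 1) * 30011 + 7919 * as.numeric(i)) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# Bilinear interpolation on a matrix at continuous 0-based (row, col)
# coordinates with pixel centers at integers. Points outside the raster
# return NA.
bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(r))
  ok <- r >= 0 & r <= nr - 1 & c >= 0 & c <= nc - 1
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  r0 <- pmax(r0, 0); c0 <- pmax(c0, 0)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0 + 1, c0 + 1)
  v <- img[i00] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 2, c0 + 1)] * fr * (1 - fc) +
    img[cbind(r0 + 1, c0 + 2)] * (1 - fr) * fc +
    img[cbind(r0 + 2, c0 + 2)] * fr * fc
  out[ok] <- v
  out
}

# Cumulative arc length of a polyline given as an n x 2 matrix.
arc_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(d))
}

# Resample a polyline at (approximately) uniform arc-length steps.
resample_polyline <- function(pts, step = 1, n = NULL) {
  s <- arc_length(pts)
  total <- s[length(s)]
  if (is.null(n)) n <- max(2L, as.integer(round(total / step)) + 1L)
  si <- seq(0, total, length.out = n)
  cbind(
    stats::approx(s, pts[, 1], xout = si, ties = "ordered")$y,
    stats::approx(s, pts[, 2], xout = si, ties = "ordered")$y
  )
}

# Distance from points to a polyline, plus arc-length coordinate of the
# nearest point on the polyline. pts: m x 2 query points; line: n x 2.
polyline_distance <- function(pts, line) {
  m <- nrow(pts)
  best_d2 <- rep(Inf, m)
  best_s <- rep(0, m)
  s <- arc_length(line)
  for (i in seq_len(nrow(line) - 1)) {
    a <- line[i, ]; b <- line[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    d2 <- dx * dx + dy * dy
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- s[i] + t[upd] * sqrt(len2)
  }
  list(dist = sqrt(best_d2), s = best_s)
}

# Draw one uniform point in [lo, hi] at least `sep` away from every point
# in `avoid`; samples directly from the feasible sub-intervals (NA when the
# feasible set is empty).
sample_in_intervals <- function(lo, hi, avoid, sep) {
  starts <- lo; ends <- hi
  for (a in avoid) {
    new_s <- c(); new_e <- c()
    for (j in seq_along(starts)) {
      s <- starts[j]; e <- ends[j]
      if (a - sep > s) { new_s <- c(new_s, s); new_e <- c(new_e, min(e, a - sep)) }
      if (a + sep < e) { new_s <- c(new_s, max(s, a + sep)); new_e <- c(new_e, e) }
    }
    starts <- new_s; ends <- new_e
    if (!length(starts)) return(NA_real_)
  }
  len <- ends - starts
  u <- stats::runif(1, 0, sum(len))
  cum <- cumsum(len)
  j <- which(u <= cum)[1]
  starts[j] + u - c(0, cum)[j]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
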