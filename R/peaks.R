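# 1D local-maximum detection with topographic prominence.
#
# Prominence of a peak = peak height minus the higher of the two base
# minima, where each base is the minimum between the peak and the nearest
# strictly higher point on that side. A side whose walk reaches the signal
# end without meeting a higher point is "open": the axial profile is
# truncated at the cell boundary, so the outward flank of a pole-tip peak
# is unobservable and must not set the base. An open side is ignored when
# the other side is closed; when both sides are open (the global maximum)
# the base is the global minimum. Signal endpoints are eligible peaks
# (pole tips sit at profile ends). Plateaus collapse to their centre index.

find_local_maxima <- function(v) {
  n <- length(v)
  if (n < 2) return(integer(0))
  peaks <- integer(0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && v[j + 1] == v[i]) j <- j + 1
    left_ok <- i == 1 || v[i - 1] < v[i]
    right_ok <- j == n || v[j + 1] < v[i]
    if (left_ok && right_ok && !(i == 1 && j == n)) {
      peaks <- c(peaks, as.integer(floor((i + j) / 2)))
    }
    i <- j + 1
  }
  peaks
}

peak_prominence <- function(v, idx) {
  n <- length(v)
  vapply(idx, function(i) {
    h <- v[i]
    walk <- function(ks) {
      m <- h; closed <- FALSE
      for (k in ks) {
        if (v[k] > h) { closed <- TRUE; break }
        m <- min(m, v[k])
      }
      list(base = m, closed = closed)
    }
    left <- if (i > 1) walk((i - 1):1) else list(base = h, closed = FALSE)
    right <- if (i < n) walk((i + 1):n) else list(base = h, closed = FALSE)
    base <- if (left$closed && right$closed) {
      max(left$base, right$base)
    } else if (left$closed) {
      left$base
    } else if (right$closed) {
      right$base
    } else {
      min(left$base, right$base)
    }
    h - base
  }, numeric(1))
}

# Peak detection with a prominence floor and a minimum mutual separation
# (in position units). Peaks are kept greedily in decreasing height order.
find_peaks <- function(values, positions = seq_along(values),
                       prominence = 0, min_separation = 0) {
  idx <- find_local_maxima(values)
  if (length(idx) == 0)
    return(data.frame(index = integer(0), position = numeric(0),
                      value = numeric(0), prominence = numeric(0)))
  prom <- peak_prominence(values, idx)
  keep <- prom >= prominence
  idx <- idx[keep]; prom <- prom[keep]
  if (length(idx) && min_separation > 0) {
    ord <- order(values[idx], prom, decreasing = TRUE)
    chosen <- integer(0)
    for (k in ord) {
      if (all(abs(positions[idx[k]] - positions[idx[chosen]]) >= min_separation))
        chosen <- c(chosen, k)
    }
    chosen <- sort(chosen)
    idx <- idx[chosen]; prom <- prom[chosen]
  }
  data.frame(index = idx, position = positions[idx],
             value = values[idx], prominence = prom)
}
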