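# Morphological thinning and longest-path extraction for rod-shaped masks.
# Zhang-Suen thinning, vectorized over the whole mask; masks here are small
# (one cell bounding box), so a handful of passes suffices.

shift_mat <- function(M, dr, dc) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs - dr, cs - dc] <- M[rs, cs]
  out
}

thin_mask <- function(mask) {
  M <- mask > 0
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P2 <- shift_mat(M, -1, 0); P3 <- shift_mat(M, -1, 1)
      P4 <- shift_mat(M, 0, 1);  P5 <- shift_mat(M, 1, 1)
      P6 <- shift_mat(M, 1, 0);  P7 <- shift_mat(M, 1, -1)
      P8 <- shift_mat(M, 0, -1); P9 <- shift_mat(M, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
        (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      if (step == 1) {
        cond <- !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      del <- M & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) { M[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  M
}

# Longest geodesic path on an 8-connected skeleton, found with a double BFS
# (exact on trees; skeletons of simply connected rods are trees).
longest_skeleton_path <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(NULL)
  if (n == 1) return(idx)
  id_map <- matrix(0L, nrow(skel), ncol(skel))
  id_map[idx] <- seq_len(n)
  nbrs <- function(i) {
    r <- idx[i, 1]; c <- idx[i, 2]
    rr <- pmax(1, r - 1):pmin(nrow(skel), r + 1)
    cc <- pmax(1, c - 1):pmin(ncol(skel), c + 1)
    v <- id_map[rr, cc]
    v <- v[v > 0 & v != i]
    v
  }
  bfs <- function(start) {
    dist <- rep(NA_real_, n); parent <- rep(0L, n)
    dist[start] <- 0
    queue <- start; head <- 1
    while (head <= length(queue)) {
      u <- queue[head]; head <- head + 1
      for (v in nbrs(u)) {
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + sqrt(sum((idx[u, ] - idx[v, ])^2))
          parent[v] <- u
          queue <- c(queue, v)
        }
      }
    }
    list(dist = dist, parent = parent)
  }
  b1 <- bfs(1L)
  a <- which.max(b1$dist)
  b2 <- bfs(a)
  b <- which.max(b2$dist)
  path <- integer(0); u <- b
  while (u != 0) { path <- c(path, u); u <- b2$parent[u] }
  idx[rev(path), , drop = FALSE]
}
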