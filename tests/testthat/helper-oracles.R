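# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by naive enumeration so they share no code path with the
# package implementations they check.

# Phansalkar threshold evaluated pixel-by-pixel with an explicit window loop.
bf_phansalkar <- function(img, radius, k = 0.25, r = 0.5, p = 2, q = 10,
                          circular = TRUE) {
  rng <- range(img)
  x <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  ny <- nrow(x); nx <- ncol(x)
  out <- matrix(FALSE, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    vals <- c()
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (circular && di^2 + dj^2 > radius^2 + 1e-9) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= ny && jj >= 1 && jj <= nx) vals <- c(vals, x[ii, jj])
    }
    mu <- mean(vals)
    sdv <- sqrt(max(mean(vals^2) - mu^2, 0))
    thr <- mu * (1 + p * exp(-q * mu) + k * (sdv / r - 1))
    if (abs(thr) < 1e-9) thr <- 0
    out[i, j] <- x[i, j] > thr
  }
  out
}

# Otsu by exhaustive search over all histogram split points.
bf_otsu <- function(v, nbins = 256) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), nbins), nbins)
  centers <- (edges[-1] + edges[-(nbins + 1)]) / 2
  best <- -Inf; bk <- 1
  for (kk in 1:(nbins - 1)) {
    w0 <- sum(h[1:kk]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:kk] * centers[1:kk]) / w0
    m1 <- sum(h[(kk + 1):nbins] * centers[(kk + 1):nbins]) / w1
    sb <- w0 * w1 * (m0 - m1)^2
    if (sb > best) { best <- sb; bk <- kk }
  }
  edges[bk + 1]
}

# Queue-based flood fill, 8-connectivity, 2D.
flood_label <- function(mask) {
  d <- dim(mask); lab <- array(0L, d); cur <- 0; seen <- array(FALSE, d)
  idx <- which(mask, arr.ind = TRUE)
  for (s in seq_len(nrow(idx))) {
    if (seen[idx[s, 1], idx[s, 2]]) next
    cur <- cur + 1; q <- list(idx[s, ]); seen[idx[s, 1], idx[s, 2]] <- TRUE
    while (length(q)) {
      p <- q[[1]]; q <- q[-1]; lab[p[1], p[2]] <- cur
      for (di in -1:1) for (dj in -1:1) {
        a <- p[1] + di; b <- p[2] + dj
        if (a >= 1 && a <= d[1] && b >= 1 && b <= d[2] && mask[a, b] && !seen[a, b]) {
          seen[a, b] <- TRUE; q <- c(q, list(c(a, b)))
        }
      }
    }
  }
  lab
}

same_partition <- function(L1, L2, mask) {
  max(L1) == max(L2) && length(unique(paste(L1[mask], L2[mask]))) == max(L1)
}

# Exhaustive minimal-cost matching between point sets A (n x 2) and B (m x 2):
# each link costs squared distance (forbidden beyond max_link), every
# unmatched point on either side costs max_link^2. Returns the minimal total.
oracle_link_cost <- function(A, B, max_link) {
  b <- max_link^2
  n <- nrow(A); m <- nrow(B)
  best <- Inf
  rec <- function(i, usedB, cost) {
    if (cost >= best) return()
    if (i > n) {
      best <<- min(best, cost + b * sum(!usedB))
      return()
    }
    rec(i + 1, usedB, cost + b)            # A_i unmatched
    for (j in which(!usedB)) {
      d2 <- sum((A[i, ] - B[j, ])^2)
      if (d2 <= b) {
        usedB[j] <- TRUE
        rec(i + 1, usedB, cost + d2)
        usedB[j] <- FALSE
      }
    }
  }
  rec(1, rep(FALSE, m), 0)
  best
}

# Cost actually realized by link_trajectories on a two-frame problem.
realized_link_cost <- function(traj, A, B, max_link) {
  b <- max_link^2
  linked <- 0; cost <- 0
  for (id in unique(traj$track_id)) {
    tr <- traj[traj$track_id == id, ]
    if (nrow(tr) == 2) {
      cost <- cost + sum((tr$y_um[1] - tr$y_um[2])^2 + (tr$x_um[1] - tr$x_um[2])^2)
      linked <- linked + 1
    }
  }
  cost + b * (nrow(A) - linked) + b * (nrow(B) - linked)
}

# Match measured nuclei to ground-truth nuclei by center position.
match_nuclei <- function(ft, truth) {
  ft$match_id <- vapply(seq_len(nrow(ft)), function(i) {
    which.min((truth$center_y_px - ft$center_y_px[i])^2 +
                (truth$center_x_px - ft$center_x_px[i])^2)
  }, integer(1))
  dplyr::left_join(ft, truth, by = c(match_id = "nucleus_id"),
                   suffix = c("", ".true"))
}
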