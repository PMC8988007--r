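# Internal numerical primitives shared across modules: padded FFT convolution
# for local-window statistics, connected-component labeling (8/26-connectivity),
# a Hungarian assignment solver for particle linking, Otsu's threshold,
# histogram-mode background estimation, and subpixel peak refinement.

#' @importFrom stats fft rnorm rpois runif sd lm coef vcov cor setNames quantile median nls.control
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Circular or square binary window
#'
#' @param radius window radius in pixels.
#' @param circular logical; if `TRUE` (default) pixels farther than `radius`
#'   from the center are excluded.
#' @return a (2*radius+1) square 0/1 matrix.
#' @keywords internal
#' @noRd
window_kernel <- function(radius, circular = TRUE) {
  n <- 2L * as.integer(radius) + 1L
  if (!circular) return(matrix(1, n, n))
  d <- seq_len(n) - radius - 1L
  k <- outer(d, d, function(y, x) sqrt(y^2 + x^2) <= radius + 1e-9)
  storage.mode(k) <- "double"
  k
}

# Zero-padded linear convolution of a 2D image with a centered kernel
# (kernel dims odd). Returns an array the size of the image holding window
# sums with windows clipped at the image edge (zero padding).
conv2_clip <- function(x, kern) {
  nr <- nrow(x); nc <- ncol(x)
  kr <- nrow(kern); kc <- ncol(kern)
  pr <- nr + kr - 1L; pc <- nc + kc - 1L
  px <- matrix(0, pr, pc); px[seq_len(nr), seq_len(nc)] <- x
  pk <- matrix(0, pr, pc); pk[seq_len(kr), seq_len(kc)] <- kern
  conv <- Re(fft(fft(px) * fft(pk), inverse = TRUE)) / (pr * pc)
  r0 <- (kr - 1L) %/% 2L
  c0 <- (kc - 1L) %/% 2L
  conv[r0 + seq_len(nr), c0 + seq_len(nc)]
}

# Local mean and SD over a clipped window, via normalized convolution.
local_stats <- function(x, kern) {
  n  <- conv2_clip(matrix(1, nrow(x), ncol(x)), kern)
  m  <- conv2_clip(x, kern) / n
  m2 <- conv2_clip(x * x, kern) / n
  list(mean = m, sd = sqrt(pmax(m2 - m^2, 0)))
}

# Shift an array by an integer offset (one entry per dimension), filling
# vacated cells with `fill`.
shift_array <- function(a, offset, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", length(d))
  for (i in seq_along(d)) {
    o <- offset[i]
    if (abs(o) >= d[i]) return(out)
    if (o >= 0) { dst[[i]] <- (1 + o):d[i]; src[[i]] <- 1:(d[i] - o) }
    else        { dst[[i]] <- 1:(d[i] + o); src[[i]] <- (1 - o):d[i] }
  }
  if (length(d) == 2) {
    out[dst[[1]], dst[[2]]] <- a[src[[1]], src[[2]]]
  } else if (length(d) == 3) {
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  } else stop("shift_array supports 2D/3D only")
  out
}

neighbor_offsets <- function(ndim, connectivity) {
  if (ndim == 2) {
    off <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
    off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
    if (connectivity == 4) off <- off[abs(off[, 1]) + abs(off[, 2]) == 1, , drop = FALSE]
  } else {
    off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    off <- off[rowSums(off != 0) > 0, , drop = FALSE]
    if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  }
  off
}

#' Connected-component labeling
#'
#' Iterative minimum-label propagation: every foreground pixel starts with its
#' linear index and repeatedly takes the minimum over its foreground
#' neighbors until a fixed point. Components are then renumbered 1..k in
#' order of their smallest linear index (top-left first), which makes labels
#' deterministic.
#'
#' @param mask logical matrix (2D) or array (3D).
#' @param connectivity 8 or 4 for 2D; 26 or 6 for 3D. Defaults: 8 (2D), 26 (3D).
#' @return integer array of the same shape; 0 = background.
#' @export
label_components <- function(mask, connectivity = NULL) {
  d <- dim(mask)
  ndim <- length(d)
  stopifnot(ndim %in% c(2, 3))
  connectivity <- connectivity %||% if (ndim == 2) 8 else 26
  if (!any(mask)) return(array(0L, d))
  L <- array(Inf, d)
  L[mask] <- which(mask)
  off <- neighbor_offsets(ndim, connectivity)
  # run-minimum along dimension `dm`: contiguous foreground runs along an
  # axis are connected, so a whole run can adopt its minimum in one pass
  run_min <- function(L, mask, dm) {
    perm <- c(dm, setdiff(seq_along(d), dm))
    Lp <- aperm(L, perm); Mp <- aperm(mask, perm)
    n1 <- dim(Lp)[1]
    m <- as.vector(Mp); v <- as.vector(Lp)
    first_in_col <- (seq_along(m) - 1L) %% n1 == 0L
    prev <- c(FALSE, m[-length(m)])
    starts <- m & (first_in_col | !prev)
    g <- cumsum(starts)
    vm <- v[m]; gm <- g[m]
    o <- order(gm, vm)
    fu <- !duplicated(gm[o])
    mins <- vm[o][fu]
    v[m] <- mins[match(gm, gm[o][fu])]
    aperm(array(v, dim(Lp)), order(perm))
  }
  repeat {
    L_old <- L
    for (i in seq_len(nrow(off))) {
      Ls <- shift_array(L, off[i, ], fill = Inf)
      L <- pmin(L, Ls)
      L[!mask] <- Inf
    }
    for (dm in seq_along(d)) L <- run_min(L, mask, dm)
    if (identical(L, L_old)) break
  }
  out <- array(0L, d)
  vals <- sort(unique(L[mask]))
  out[mask] <- match(L[mask], vals)
  out
}

# Fill holes: background components (complement connectivity) not touching the
# array border become foreground.
fill_holes <- function(mask) {
  d <- dim(mask)
  comp <- label_components(!mask, connectivity = if (length(d) == 2) 4 else 6)
  if (max(comp) == 0) return(mask)
  border <- array(FALSE, d)
  if (length(d) == 2) {
    border[c(1, d[1]), ] <- TRUE; border[, c(1, d[2])] <- TRUE
  } else {
    border[c(1, d[1]), , ] <- TRUE; border[, c(1, d[2]), ] <- TRUE
    border[, , c(1, d[3])] <- TRUE
  }
  outside <- unique(comp[border & comp > 0])
  mask | (comp > 0 & !(comp %in% outside))
}

# Binary dilation by `iter` steps of the given connectivity.
dilate_mask <- function(mask, iter = 1, connectivity = NULL) {
  d <- dim(mask)
  connectivity <- connectivity %||% if (length(d) == 2) 8 else 26
  off <- neighbor_offsets(length(d), connectivity)
  m <- mask
  for (k in seq_len(iter)) {
    acc <- m
    for (i in seq_len(nrow(off))) acc <- acc | shift_array(m, off[i, ], fill = FALSE)
    m <- acc
  }
  m
}

#' Otsu's threshold
#'
#' Exhaustively maximizes the between-class variance of a 256-bin intensity
#' histogram (vectorized cumulative-sum form). Returns the threshold value on
#' the intensity scale; pixels strictly above it are foreground.
#'
#' @param x numeric vector/array of intensities.
#' @param nbins number of histogram bins (default 256).
#' @return threshold value, or `NA` when the image has no spread.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  v <- as.vector(x)
  rng <- range(v, finite = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), nbins), nbins)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-(nbins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb[-nbins])
  edges[k + 1]
}

# Histogram-mode estimate of a background/camera offset.
mode_estimate <- function(x, nbins = 256) {
  v <- as.vector(x)
  rng <- range(v, finite = TRUE)
  if (diff(rng) <= 0) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  bins <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), nbins)
  h <- tabulate(bins, nbins)
  stats::median(v[bins == which.max(h)])
}

# Hungarian algorithm (Kuhn-Munkres with potentials), O(n^3), square cost
# matrix. Returns for each row the assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  a <- rbind(0, cbind(0, cost))      # 1-based with dummy row/col 1
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0
      for (j in seq_len(n + 1)[-1]) {
        if (used[j]) next
        cur <- a[i0 + 1, j] - u[i0 + 1] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) { u[p[j] + 1] <- u[p[j] + 1] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n + 1)[-1]) if (p[j] > 0) ans[p[j]] <- j - 1L
  ans
}

# Local maxima of a 2D image: strictly greater than all 8 neighbors.
local_maxima_2d <- function(x) {
  off <- neighbor_offsets(2, 8)
  is_max <- matrix(TRUE, nrow(x), ncol(x))
  for (i in seq_len(nrow(off))) {
    is_max <- is_max & (x > shift_array(x, off[i, ], fill = -Inf))
  }
  is_max
}

# Quadratic (separable parabola) subpixel refinement around an interior pixel.
# Returns offsets in (-0.5, 0.5) for each axis.
quad_subpixel <- function(fm, f0, fp) {
  den <- fm - 2 * f0 + fp
  out <- ifelse(abs(den) < .Machine$double.eps, 0, 0.5 * (fm - fp) / den)
  pmin(pmax(out, -0.5), 0.5)
}

# Small-sample-corrected Akaike information criterion from a Gaussian RSS.
aicc_from_rss <- function(rss, n, n_par) {
  k <- n_par + 1 # + residual variance
  if (rss <= 0) return(-Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1e-9)
}

# Laplacian-of-Gaussian kernel, sign-flipped so bright blobs give positive
# response, scale-normalized (multiplied by sigma^2).
log_kernel <- function(sigma) {
  half <- max(2L, ceiling(3.5 * sigma))
  d <- (-half):half
  g <- exp(-d^2 / (2 * sigma^2))
  G <- outer(g, g)
  r2 <- outer(d^2, d^2, "+")
  k <- -(r2 - 2 * sigma^2) / sigma^4 * G
  k <- k * sigma^2
  k - mean(k)  # zero response to constant background
}
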