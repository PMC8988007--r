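#' Exact fractional Gaussian noise
#'
#' Samples `n` increments of fractional Brownian motion with Hurst exponent
#' `H` and per-increment variance `sigma2`, using Davies-Harte circulant
#' embedding (exact; O(n log n)). If the embedding is not nonnegative
#' definite for the requested `H`, falls back to Cholesky factorization of
#' the Toeplitz covariance (exact; O(n^3), used only for small `n`).
#'
#' The increment autocovariance is
#' `gamma(k) = sigma2/2 * (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H))`.
#'
#' Uses the current RNG state; seed control belongs to the caller.
#'
#' @param n number of increments.
#' @param H Hurst exponent in (0, 1].
#' @param sigma2 variance of a single increment.
#' @return numeric vector of length `n`.
#' @export
fgn_sample <- function(n, H, sigma2 = 1) {
  stopifnot(n >= 1, H > 0, H <= 1, sigma2 >= 0)
  if (sigma2 == 0) return(numeric(n))
  if (abs(H - 0.5) < 1e-12) return(rnorm(n, sd = sqrt(sigma2)))
  k <- 0:n
  gam <- sigma2 / 2 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  m <- 2L * n
  circ <- c(gam[1:(n + 1)], gam[n:2])           # gamma_0..gamma_n, gamma_{n-1}..gamma_1
  lam <- Re(fft(circ))
  if (min(lam) < -1e-8 * max(lam)) {
    # embedding failed: exact Cholesky fallback
    Sigma <- sigma2 / 2 * outer(seq_len(n), seq_len(n), function(i, j) {
      d <- abs(i - j)
      abs(d + 1)^(2 * H) - 2 * abs(d)^(2 * H) + abs(d - 1)^(2 * H)
    })
    return(as.vector(chol(Sigma + diag(1e-12, n)) %*% rnorm(n)))
  }
  lam <- pmax(lam, 0)
  w <- complex(length.out = m)
  z1 <- rnorm(m / 2 + 1)
  z2 <- rnorm(m / 2 + 1)
  w[1] <- sqrt(lam[1] / m) * z1[1]
  w[m / 2 + 1] <- sqrt(lam[m / 2 + 1] / m) * z1[m / 2 + 1]
  idx <- 2:(m / 2)
  w[idx] <- sqrt(lam[idx] / (2 * m)) * complex(real = z1[idx], imaginary = z2[idx])
  w[m + 2 - idx] <- Conj(w[idx])
  x <- Re(fft(w))
  x[1:n]
}

#' Simulate subdiffusive telomere trajectories (fractional Brownian motion)
#'
#' Generates 2D trajectories whose ensemble mean squared displacement follows
#' the anomalous-diffusion law `MSD(tau) = D * tau^alpha` (MSD summed over x
#' and y; each coordinate contributes `D * tau^alpha / 2`). Independent
#' Gaussian localization error is added per frame, parameterized by the SD of
#' the 2D error vector, so a frozen trajectory has `MSD(tau) = 2 * loc_noise^2`
#' at every lag.
#'
#' @param alpha anomalous exponent in (0, 2].
#' @param D_gen generalized diffusion coefficient, um^2 s^-alpha.
#' @param n_traj number of trajectories.
#' @param n_frames frames per trajectory.
#' @param dt frame interval, s.
#' @param loc_noise SD of the 2D localization error vector, um.
#' @param seed integer seed; the only source of randomness.
#' @return list with `trajectories` (tibble: track_id, frame, t_s, x_um, y_um,
#'   quality) and `truth` (list of generative parameters).
#' @export
sim_fbm_trajectories <- function(alpha, D_gen, n_traj = 200, n_frames = 300,
                                 dt = 1, loc_noise = 0, seed = 1) {
  stopifnot(alpha > 0, alpha <= 2, D_gen >= 0, n_traj >= 1, n_frames >= 2)
  H <- alpha / 2
  sigma2 <- (D_gen / 2) * dt^alpha          # per-coordinate increment variance
  n_inc <- n_frames - 1L
  sd_coord <- loc_noise / sqrt(2)
  traj <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_traj), function(id) {
      x <- cumsum(c(0, fgn_sample(n_inc, H, sigma2)))
      y <- cumsum(c(0, fgn_sample(n_inc, H, sigma2)))
      if (loc_noise > 0) {
        x <- x + rnorm(n_frames, sd = sd_coord)
        y <- y + rnorm(n_frames, sd = sd_coord)
      }
      tibble::tibble(
        track_id = id, frame = seq_len(n_frames), t_s = (seq_len(n_frames) - 1) * dt,
        x_um = x, y_um = y, quality = 1
      )
    })
  })
  list(
    trajectories = traj,
    truth = list(kind = "trajectories", alpha = alpha, D = D_gen, dt = dt,
                 n_traj = n_traj, n_frames = n_frames, loc_noise = loc_noise,
                 seed = seed)
  )
}
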