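#' Generate compact spatial components (Gaussian blobs)
#'
#' Places `n` isotropic Gaussian bumps at distinct, well-separated positions
#' of a 2D or 3D field. Each component has unit peak and is strictly
#' nonnegative, emulating the compact spatial footprints of neuronal sources.
#'
#' Centers are drawn on a jittered grid so that pairwise distances stay
#' larger than the blob width; this keeps components mostly non-overlapping.
#'
#' @param n Number of components (>= 1).
#' @param shape Integer vector of spatial dims, length 2 or 3.
#' @param sigma Blob standard deviation in voxels.
#' @param seed Integer RNG seed (center jitter only).
#' @return Matrix `W_true` with `prod(shape)` rows (voxels, column-major
#'   order) and `n` columns; attribute `centers` holds the n x d center
#'   coordinates and attribute `shape` the spatial dims.
#' @export
make_spatial_components <- function(n, shape, sigma = max(1, min(shape) / 10),
                                    seed = 0L) {
  stopifnot(n >= 1, length(shape) %in% c(2L, 3L), all(shape >= 2))
  d <- length(shape)
  # jittered-grid placement at the widest spacing the field affords:
  # prefer 3*sigma cells (blobs essentially non-overlapping), shrinking to
  # 2.5 or 2*sigma only when n would not fit otherwise
  for (spacing in c(3, 2.5, 2)) {
    per_axis <- pmax(1L, shape %/% ceiling(spacing * sigma))
    if (prod(per_axis) >= n) break
  }
  capacity <- prod(per_axis)
  if (n > capacity)
    stop(sprintf(
      "cannot place %d blobs of sigma %.2f in a %s field (capacity %d); reduce n or sigma",
      n, sigma, paste(shape, collapse = "x"), capacity))
  rng <- local_seed(seed)
  cell <- shape / per_axis
  grid <- as.matrix(expand.grid(lapply(seq_len(d), function(i)
    (seq_len(per_axis[i]) - 0.5) * cell[i])))
  pick <- sample.int(nrow(grid), n)
  jitter_amp <- pmin(cell / 6, sigma)
  centers <- grid[pick, , drop = FALSE] +
    matrix(stats::runif(n * d, -1, 1), n, d) %*% diag(jitter_amp, d)
  # snap to the voxel lattice so every blob peaks at exactly 1
  centers <- round(centers)
  for (i in seq_len(d)) centers[, i] <- pmin(pmax(centers[, i], 1), shape[i])
  # evaluate the Gaussian at every voxel
  coords <- as.matrix(expand.grid(lapply(shape, seq_len)))
  W <- matrix(0, nrow(coords), n)
  for (j in seq_len(n)) {
    d2 <- rowSums((coords - matrix(centers[j, ], nrow(coords), d,
                                   byrow = TRUE))^2)
    W[, j] <- exp(-d2 / (2 * sigma^2))
  }
  attr(W, "centers") <- centers
  attr(W, "shape") <- as.integer(shape)
  attr(W, "sigma") <- sigma
  W
}

#' Generate ground-truth component timecourses
#'
#' `transient` mode draws Poisson-timed calcium-transient-like events with a
#' double-exponential kernel (fast rise, slow decay), emulating GCaMP
#' fluorescence. `slow` mode additionally convolves each trace with a smooth
#' Gaussian kernel and delays it, emulating the sluggish hemodynamic response
#' that low-pass filters neural activity.
#'
#' @param n Number of components.
#' @param n_frames Number of frames (>= 2).
#' @param fps Frame rate (Hz).
#' @param mode `"transient"` or `"slow"`.
#' @param event_rate Mean event rate per component, events/minute.
#' @param amplitude Peak amplitude of a single event (arbitrary fluorescence
#'   units); individual events are scaled by a random factor in
#'   `[0.5, 1] * amplitude`.
#' @param tau_rise,tau_decay Kernel time constants, seconds.
#' @param slow_fwhm FWHM of the hemodynamic smoothing kernel, seconds.
#' @param slow_delay Hemodynamic delay, seconds.
#' @param seed Integer RNG seed.
#' @param event_times Optional list of length `n` forcing event onset times
#'   (seconds) per component; overrides Poisson draws.
#' @return Matrix `H_true` (`n` x `n_frames`), nonnegative; attribute
#'   `event_times` holds the per-component event onsets in seconds.
#' @export
make_timecourses <- function(n, n_frames, fps = 10, mode = c("transient", "slow"),
                             event_rate = 6, amplitude = 1,
                             tau_rise = 0.05, tau_decay = 0.5,
                             slow_fwhm = 2, slow_delay = 1,
                             seed = 0L, event_times = NULL) {
  stopifnot(n >= 1, n_frames >= 2, fps > 0, event_rate >= 0)
  mode <- match.arg(mode)
  rng <- local_seed(seed)
  duration <- n_frames / fps
  tt <- (seq_len(n_frames) - 1) / fps
  kern <- transient_kernel(tt, tau_rise, tau_decay)
  H <- matrix(0, n, n_frames)
  ev <- vector("list", n)
  for (j in seq_len(n)) {
    onsets <- if (!is.null(event_times)) {
      event_times[[j]]
    } else {
      o <- sort(stats::runif(stats::rpois(1, event_rate * duration / 60),
                             0, duration))
      # every component carries at least one event when a rate is requested,
      # so short fixtures never yield silent (degenerate) timecourses
      if (length(o) == 0L && event_rate > 0)
        o <- stats::runif(1, 0, duration * 0.9)
      o
    }
    ev[[j]] <- onsets
    h <- numeric(n_frames)
    for (t0 in onsets) {
      amp <- amplitude * stats::runif(1, 0.5, 1)
      sh <- tt - t0
      h <- h + amp * ifelse(sh >= 0, transient_kernel(sh, tau_rise, tau_decay), 0)
    }
    H[j, ] <- h
  }
  if (mode == "slow") {
    H <- t(apply(H, 1L, smooth_delay, fps = fps,
                 fwhm = slow_fwhm, delay = slow_delay))
    if (n == 1L) H <- matrix(H, 1L)
  }
  H[H < 0] <- 0
  attr(H, "event_times") <- ev
  attr(H, "fps") <- fps
  H
}

# unit-peak double-exponential: (1 - exp(-t/tr)) * exp(-t/td), normalized
transient_kernel <- function(t, tau_rise, tau_decay) {
  raw <- (1 - exp(-t / tau_rise)) * exp(-t / tau_decay)
  t_peak <- tau_rise * log1p(tau_decay / tau_rise)
  peak <- (1 - exp(-t_peak / tau_rise)) * exp(-t_peak / tau_decay)
  out <- raw / peak
  out[t < 0] <- 0
  out
}

# Gaussian smooth (given FWHM in s) followed by integer-frame delay
smooth_delay <- function(h, fps, fwhm, delay) {
  sd_frames <- fwhm / (2 * sqrt(2 * log(2))) * fps
  half <- max(1L, ceiling(3 * sd_frames))
  k <- stats::dnorm(seq(-half, half), sd = sd_frames)
  k <- k / sum(k)
  n <- length(h)
  padded <- c(rep(h[1L], half), h, rep(h[n], half))
  sm <- stats::filter(padded, k, sides = 2L)[(half + 1L):(half + n)]
  dly <- round(delay * fps)
  out <- c(rep(0, dly), sm)[seq_len(n)]
  as.numeric(out)
}

#' Assemble a synthetic movie from ground-truth components
#'
#' Forms the nonnegative linear mixture `V = W_true %*% H_true`, adds
#' Gaussian noise of standard deviation `noise_sigma`, and clips at zero
#' (all pipeline stages assume nonnegative signal above baseline).
#'
#' @param W_true Output of [make_spatial_components()] (voxels x n).
#' @param H_true Output of [make_timecourses()] (n x frames).
#' @param noise_sigma Additive Gaussian noise SD; 0 gives the exact product.
#' @param fps Frame rate to attach.
#' @param seed Integer RNG seed for the noise.
#' @return A [Movie()]; attribute `ground_truth` holds `W_true`, `H_true`,
#'   `noise_sigma` and `seed`.
#' @export
make_movie <- function(W_true, H_true, noise_sigma = 0.1, fps = 10, seed = 0L) {
  if (ncol(W_true) != nrow(H_true))
    stop(sprintf("component count mismatch: W has %d, H has %d",
                 ncol(W_true), nrow(H_true)))
  shape <- attr(W_true, "shape")
  if (is.null(shape)) stop("W_true must carry a `shape` attribute")
  V <- W_true %*% H_true
  if (noise_sigma > 0) {
    rng <- local_seed(seed)
    V <- V + matrix(stats::rnorm(length(V), 0, noise_sigma), nrow(V))
    V[V < 0] <- 0
  }
  m <- Movie(array(V, c(shape, ncol(H_true))), fps)
  attr(m, "ground_truth") <- list(W_true = W_true, H_true = H_true,
                                  noise_sigma = noise_sigma, seed = seed)
  m
}

#' One-call synthetic fixture
#'
#' Convenience wrapper generating spatial blobs, transient timecourses and a
#' noisy movie in one step, with the ground truth attached.
#'
#' @param n Components.
#' @param shape Spatial dims.
#' @param n_frames Frames.
#' @param fps Frame rate.
#' @param noise_sigma Noise SD.
#' @param event_rate Events per minute per component.
#' @param seed Integer seed controlling all randomness.
#' @param mode Timecourse mode, see [make_timecourses()].
#' @return A [Movie()] with `ground_truth` attribute.
#' @export
make_fixture <- function(n = 6, shape = c(64, 64), n_frames = 600, fps = 10,
                         noise_sigma = 0.1, event_rate = 6, seed = 0L,
                         mode = "transient") {
  W <- make_spatial_components(n, shape, seed = seed)
  H <- make_timecourses(n, n_frames, fps, mode = mode,
                        event_rate = event_rate, seed = seed + 1L)
  make_movie(W, H, noise_sigma = noise_sigma, fps = fps, seed = seed + 2L)
}

# Seed the RNG locally, restoring the caller's state on exit of the caller.
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  withr::defer({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }, envir = env)
  invisible(seed)
}
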