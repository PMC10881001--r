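#' Build a per-component color map assignment
#'
#' Samples `n` colors at evenly spaced positions across a named color map
#' and assigns them to components in the given ordering: the component
#' ranked first receives the first map color. Maps are computed by formula
#' (not read from a graphics device) so output is identical everywhere.
#'
#' Registry: `jet` (the classic blue-cyan-yellow-red ramp) and `hsv`
#' (hue circle, red to pink).
#'
#' @param n Number of components (>= 1).
#' @param map_name Name in the registry.
#' @param order Integer permutation (position i = component ranked i-th);
#'   default identity.
#' @return An n x 3 matrix `C` of RGB rows in `[0,1]`, row j = color of
#'   component j; attributes `map` and `order` record provenance.
#' @export
make_colormap <- function(n, map_name = "jet", order = seq_len(n)) {
  stopifnot(n >= 1)
  registry <- c("jet", "hsv")
  if (!map_name %in% registry)
    stop("unknown color map '", map_name, "'; available: ",
         paste(registry, collapse = ", "))
  if (!setequal(order, seq_len(n))) stop("order must be a permutation of 1..n")
  pos <- if (n == 1L) 0.5 else (seq_len(n) - 1) / (n - 1)
  cols <- switch(map_name, jet = jet_ramp(pos), hsv = hsv_ramp(pos))
  C <- matrix(0, n, 3L)
  C[order, ] <- cols            # rank i gets the i-th sampled color
  attr(C, "map") <- map_name
  attr(C, "order") <- as.integer(order)
  C
}

# MATLAB-style jet: piecewise-linear ramps, endpoints deep blue / deep red
jet_ramp <- function(pos) {
  ch <- function(x, c) pmax(pmin(1.5 - abs(4 * x - c), 1), 0)
  cbind(r = ch(pos, 3), g = ch(pos, 2), b = ch(pos, 1))
}

hsv_ramp <- function(pos) {
  # hues over [0, 0.9] so the first and last colors stay distinct
  t(grDevices::col2rgb(grDevices::hsv(pos * 0.9, 1, 1)) / 255)
}

#' Colorize one frame from the linear model
#'
#' The color-remix model: each pixel's color is the W-weighted mix of the
#' component colors scaled by the components' activity at that frame,
#' `image(s, 1:3) = sum_n W(s, n) * max(h_n, 0) * C(n, 1:3)`,
#' clipped to `[0,1]` after summation. Negative component activity
#' contributes nothing, i.e. renders black.
#'
#' @param W Spatial weights (voxels x n).
#' @param h_at_T Component activity at one frame (length n).
#' @param C Colors (n x 3, rows in `[0,1]`).
#' @param gain Scalar intensity gain applied pre-clip.
#' @param clip If `FALSE`, return the pre-clip image (used by oracles and
#'   normalization).
#' @return Voxels x 3 matrix of RGB values.
#' @export
colorize_frame <- function(W, h_at_T, C, gain = 1, clip = TRUE) {
  if (!is.matrix(W)) W <- matrix(W, ncol = 1L)
  if (ncol(W) != length(h_at_T) || ncol(W) != nrow(C) || ncol(C) != 3L)
    stop("shape mismatch between W, h_at_T and C")
  img <- gain * (W %*% (pmax(h_at_T, 0) * C))
  if (clip) img <- pmin(pmax(img, 0), 1)
  img
}

#' Construct an RGBVideo
#'
#' @param frames Numeric 4D array `(y, x, 3, t)` with values in `[0,1]`.
#' @param fps Frame rate.
#' @return Object of class `RGBVideo`.
#' @export
RGBVideo <- function(frames, fps) {
  stopifnot(is.array(frames), length(dim(frames)) == 4L, dim(frames)[3L] == 3L,
            fps > 0)
  if (min(frames) < 0 || max(frames) > 1)
    stop("frame values must lie in [0,1]")
  structure(list(frames = frames, fps = as.numeric(fps)), class = "RGBVideo")
}

#' @export
print.RGBVideo <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("RGBVideo: %d x %d, %d frames @ %g fps (%.2f s)\n",
              d[1L], d[2L], d[4L], x$fps, d[4L] / x$fps))
  invisible(x)
}

#' Number of frames in an RGBVideo
#' @param video An [RGBVideo()].
#' @return Integer frame count.
#' @export
n_frames_video <- function(video) dim(video$frames)[4L]

#' Render the color-remixed component video
#'
#' Applies [colorize_frame()] to every frame of the decomposition, with a
#' single global gain chosen so that the 99th percentile of the pre-clip
#' intensity distribution maps to 1.0 (deterministic display scaling).
#' Volumetric components are first flattened to a top-view maximum
#' intensity projection.
#'
#' @param decomp A [decomposition()].
#' @param C Color matrix (n x 3); default jet over `decomp$order`.
#' @param gain Override the automatic gain (a number), or `NULL` for the
#'   percentile rule.
#' @return An [RGBVideo()]; attribute `gain` records the gain used.
#' @export
render_component_video <- function(decomp, C = NULL, gain = NULL) {
  stopifnot(inherits(decomp, "decomposition"))
  if (is.null(C)) C <- make_colormap(decomp$n, "jet", decomp$order)
  W <- decomp$W
  shape <- decomp$shape
  if (length(shape) == 3L) {       # volumetric: render the top-view MIP
    W <- apply(array(W, c(shape, decomp$n)), c(1L, 2L, 4L), max)
    W <- matrix(W, ncol = decomp$n)
    shape <- shape[1:2]
  }
  Hp <- pmax(decomp$H, 0)
  if (is.null(gain)) {
    # pre-clip intensities of the whole dataset, channel-wise
    pre <- vapply(1:3, function(ch) W %*% (Hp * C[, ch]),
                  matrix(0, nrow(W), ncol(decomp$H)))
    q <- stats::quantile(pre[pre > 0], 0.99, names = FALSE)
    gain <- if (is.na(q) || q == 0) 1 else 1 / q
  }
  t_n <- ncol(decomp$H)
  frames <- array(0, c(shape, 3L, t_n))
  for (ti in seq_len(t_n)) {
    img <- colorize_frame(W, decomp$H[, ti], C, gain = gain)
    frames[, , , ti] <- array(img, c(shape, 3L))
  }
  v <- RGBVideo(frames, decomp$fps)
  attr(v, "gain") <- gain
  v
}

#' Three-view maximum intensity projections
#'
#' Projects a 3D volume along each spatial axis, giving the top
#' (max over z), front (max over y) and side (max over x) views.
#'
#' @param volume 3D numeric array `(y, x, z)`.
#' @return Named list of 2D matrices `top` (y,x), `front` (x,z),
#'   `side` (y,z).
#' @export
mip_views <- function(volume) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("mip_views requires a 3D array")
  list(
    top = apply(volume, c(1L, 2L), max),
    front = apply(volume, c(2L, 3L), max),
    side = apply(volume, c(1L, 3L), max)
  )
}

#' Compose several videos into one panel grid
#'
#' Places videos on an `nrow x ncol` grid. Each panel is letterboxed
#' (centered on a black canvas of the common cell size) so aspect ratio is
#' preserved; frame counts are aligned by truncating to the shortest video.
#' All inputs must share one fps.
#'
#' @param videos Nonempty list of [RGBVideo()] objects.
#' @param layout Integer vector `c(nrow, ncol)`; default one row.
#' @return An [RGBVideo()].
#' @export
compose_panels <- function(videos, layout = c(1L, length(videos))) {
  if (length(videos) == 0L) stop("empty video list")
  stopifnot(all(vapply(videos, inherits, logical(1), "RGBVideo")))
  fps <- vapply(videos, function(v) v$fps, numeric(1))
  if (length(unique(fps)) > 1L) stop("all videos must share one fps")
  if (prod(layout) < length(videos)) stop("layout too small for panel count")
  n_t <- min(vapply(videos, n_frames_video, integer(1)))
  cell_h <- max(vapply(videos, function(v) dim(v$frames)[1L], integer(1)))
  cell_w <- max(vapply(videos, function(v) dim(v$frames)[2L], integer(1)))
  out <- array(0, c(layout[1L] * cell_h, layout[2L] * cell_w, 3L, n_t))
  for (i in seq_along(videos)) {
    r <- (i - 1L) %/% layout[2L]
    cc <- (i - 1L) %% layout[2L]
    d <- dim(videos[[i]]$frames)
    oy <- r * cell_h + (cell_h - d[1L]) %/% 2L
    ox <- cc * cell_w + (cell_w - d[2L]) %/% 2L
    out[oy + seq_len(d[1L]), ox + seq_len(d[2L]), , seq_len(n_t)] <-
      videos[[i]]$frames[, , , seq_len(n_t), drop = FALSE]
  }
  RGBVideo(out, fps[1L])
}

#' Wrap a grayscale movie as an RGB video panel
#'
#' Scales the movie to `[0,1]` by its 99th percentile and replicates it
#' across the three channels, for side-by-side raw-data panels.
#'
#' @param movie A [Movie()] (planar).
#' @return An [RGBVideo()].
#' @export
movie_to_gray_video <- function(movie) {
  stopifnot(inherits(movie, "Movie"))
  if (movie$space_rank != 2L) stop("grayscale panel supports planar movies only")
  V <- movie$data
  q <- stats::quantile(V[V > 0], 0.99, names = FALSE)
  if (is.na(q) || q == 0) q <- 1
  V <- pmin(pmax(V / q, 0), 1)
  d <- dim(V)
  frames <- array(0, c(d[1L], d[2L], 3L, d[3L]))
  for (ch in 1:3) frames[, , ch, ] <- V
  RGBVideo(frames, movie$fps)
}
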