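#' Percent dF/F normalization
#'
#' Converts raw fluorescence to percent change over baseline,
#' `100 * (F - F0) / F0`, where `F0` is the per-voxel mean over the baseline
#' frames. Voxels with nonpositive baseline are undefined and returned as
#' `NA`, with their linear indices in attribute `invalid_voxels`.
#'
#' @param movie A [Movie()].
#' @param baseline_frames Integer vector of frame indices (1-based) defining
#'   the baseline window.
#' @return A [Movie()] of percent dF/F values (may contain NA and negatives).
#' @export
compute_dff <- function(movie, baseline_frames) {
  stopifnot(inherits(movie, "Movie"))
  t <- n_frames(movie)
  if (length(baseline_frames) == 0L)
    stop("baseline_frames must be nonempty")
  if (any(baseline_frames < 1L) || any(baseline_frames > t))
    stop("baseline_frames out of range")
  V <- movie_matrix(movie)
  F0 <- rowMeans(V[, baseline_frames, drop = FALSE])
  bad <- which(F0 <= 0)
  out <- 100 * (V - F0) / F0
  out[bad, ] <- NA_real_
  m <- Movie(array(out, dim(movie$data)), movie$fps)
  attr(m, "invalid_voxels") <- bad
  m
}

#' Select active voxels by z-score exceedance
#'
#' Z-scores every voxel's timecourse and keeps a voxel iff strictly more
#' than `min_frac` of its frames exceed `z_thresh`. Zero-variance voxels
#' cannot be z-scored and are always excluded.
#'
#' @param movie A [Movie()].
#' @param z_thresh Z-score threshold (default 4).
#' @param min_frac Minimum exceedance fraction (default 0.05, i.e. 5% of
#'   frames).
#' @return Logical vector over linear voxel indices (`TRUE` = keep).
#' @export
filter_active_voxels <- function(movie, z_thresh = 4, min_frac = 0.05) {
  stopifnot(inherits(movie, "Movie"))
  V <- movie_matrix(movie)
  mu <- rowMeans(V)
  sd <- apply(V, 1L, stats::sd)
  ok <- sd > 0 & is.finite(sd)
  frac <- rep(0, nrow(V))
  if (any(ok)) {
    z <- (V[ok, , drop = FALSE] - mu[ok]) / sd[ok]
    frac[ok] <- rowMeans(z > z_thresh)
  }
  frac > min_frac & ok
}

#' K-means clustering of voxel timecourses under correlation distance
#'
#' Clusters voxel timecourses with Lloyd iterations where distance is
#' `1 - Pearson r` between a voxel trace and the cluster centroid trace
#' (the mean of member traces). Initialization is k-means++ on the same
#' distance; `restarts` independent runs are performed and the solution with
#' the lowest total within-cluster distance (inertia) is kept. A cluster
#' emptied during iteration is re-seeded from the point farthest from its
#' centroid (logged via `message`). Deterministic given `seed`.
#'
#' Zero-variance voxels have undefined correlation and are excluded; they
#' receive the background label 0, as do voxels outside `mask`.
#'
#' @param movie A [Movie()].
#' @param k Number of clusters (>= 1).
#' @param seed Integer seed.
#' @param mask Optional logical vector over linear voxel indices restricting
#'   clustering (e.g. from [filter_active_voxels()]).
#' @param restarts Number of random restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart.
#' @return Integer vector of labels over linear voxel indices: 1..k within
#'   the mask, 0 for background/excluded voxels. Attribute `inertia` holds
#'   the winning total distance.
#' @export
kmeans_correlation <- function(movie, k, seed = 0L, mask = NULL,
                               restarts = 10L, max_iter = 100L) {
  stopifnot(inherits(movie, "Movie"), k >= 1)
  V <- movie_matrix(movie)
  n_vox <- nrow(V)
  if (is.null(mask)) mask <- rep(TRUE, n_vox)
  stopifnot(length(mask) == n_vox)
  sd <- apply(V, 1L, stats::sd)
  use <- which(mask & sd > 0)
  if (length(use) < k)
    stop(sprintf("k = %d exceeds the %d usable voxels", k, length(use)))
  # z-score traces once; correlation of raw traces = dot product of these
  X <- V[use, , drop = FALSE]
  X <- (X - rowMeans(X)) / (sd[use] * sqrt(ncol(X) - 1))  # unit-norm rows
  # seed pool: upper variance quartile (at least k voxels), so k-means++
  # seeds land on active voxels rather than background noise
  pool <- which(sd[use] >= stats::quantile(sd[use], 0.75))
  if (length(pool) < k) pool <- order(sd[use], decreasing = TRUE)[seq_len(k)]
  rng <- local_seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- lloyd_corr(X, k, max_iter, pool)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  labels <- integer(n_vox)
  labels[use] <- best$cluster
  attr(labels, "inertia") <- best$inertia
  attr(labels, "shape") <- spatial_dims(movie)
  labels
}

# One k-means run on row-normalized X; distance = 1 - X %*% centroid_z
lloyd_corr <- function(X, k, max_iter, pool = seq_len(nrow(X))) {
  n <- nrow(X)
  # k-means++ seeding under correlation distance, restricted to the pool
  centers <- integer(k)
  centers[1L] <- pool[sample.int(length(pool), 1L)]
  d2 <- corr_dist_to(X[pool, , drop = FALSE], X[centers[1L], ])
  if (k > 1L) for (j in 2:k) {
    p <- pmax(d2, 0)
    centers[j] <- if (sum(p) > 0) pool[sample.int(length(pool), 1L, prob = p)]
                  else pool[sample.int(length(pool), 1L)]
    d2 <- pmin(d2, corr_dist_to(X[pool, , drop = FALSE], X[centers[j], ]))
  }
  C <- X[centers, , drop = FALSE]
  cl <- integer(n)
  for (it in seq_len(max_iter)) {
    D <- 1 - X %*% t(normalize_rows(C))      # n x k correlation distances
    new_cl <- max.col(-D, ties.method = "first")
    for (j in seq_len(k)) {                  # re-seed empty clusters
      if (!any(new_cl == j)) {
        far <- which.max(D[cbind(seq_len(n), new_cl)])
        message("kmeans_correlation: cluster ", j,
                " emptied; re-seeded from farthest voxel")
        new_cl[far] <- j
      }
    }
    C <- rowsum(X, new_cl) / as.vector(table(new_cl))
    if (all(new_cl == cl)) { cl <- new_cl; break }
    cl <- new_cl
  }
  D <- 1 - X %*% t(normalize_rows(C))
  list(cluster = cl, inertia = sum(D[cbind(seq_len(n), cl)]))
}

normalize_rows <- function(M) {
  M <- M - rowMeans(M)
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  M / nrm
}

corr_dist_to <- function(X, v) {
  v <- v - mean(v)
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(rep(1, nrow(X)))
  as.numeric(1 - X %*% (v / nv))
}

#' Erode cluster label maps into ROI masks
#'
#' Each cluster's binary mask is morphologically eroded with a
#' face-connected (cross) structuring element, the given number of
#' iterations. A cluster eroded to empty falls back to its original mask and
#' a warning is emitted.
#'
#' @param labels Integer label vector (0 = background) with a `shape`
#'   attribute, as returned by [kmeans_correlation()], or an integer array.
#' @param iterations Erosion depth (default 1; 0 = identity).
#' @return List of logical arrays (one ROI mask per cluster id present),
#'   named by cluster id.
#' @export
erode_labels <- function(labels, iterations = 1L) {
  if (is.array(labels)) {
    shape <- dim(labels)
    lab <- as.integer(labels)
  } else {
    shape <- attr(labels, "shape")
    if (is.null(shape)) stop("labels must carry a `shape` attribute or be an array")
    lab <- as.integer(labels)
  }
  ids <- sort(unique(lab[lab > 0L]))
  out <- lapply(ids, function(id) {
    m0 <- array(lab == id, shape)
    m <- m0
    if (iterations > 0L) for (i in seq_len(iterations)) m <- erode_cross(m)
    if (!any(m)) {
      warning("erode_labels: cluster ", id,
              " eroded to empty; falling back to un-eroded mask")
      m <- m0
    }
    m
  })
  names(out) <- ids
  out
}

# binary erosion with the face-connected cross SE, any spatial rank
erode_cross <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (ax in seq_along(d)) {
    out <- out & shift_array(mask, ax, 1L) & shift_array(mask, ax, -1L)
  }
  out
}

# shift along axis, padding with FALSE/0 (erosion treats outside as background)
shift_array <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- idx
  n <- d[axis]
  if (by > 0) {          # value at i comes from i+by
    src[[axis]] <- c((1L + by):n, rep(NA_integer_, by))
  } else {
    src[[axis]] <- c(rep(NA_integer_, -by), 1L:(n + by))
  }
  out <- array(FALSE, d)
  keep <- !is.na(src[[axis]])
  dst <- idx; dst[[axis]] <- which(keep)
  src[[axis]] <- src[[axis]][keep]
  out[as.matrix(expand.grid(dst))] <- a[as.matrix(expand.grid(src))]
  out
}

#' Extract mean ROI timecourses
#'
#' `H[j, t]` is the mean over ROI `j`'s voxels at frame `t`.
#'
#' @param movie A [Movie()].
#' @param rois List of logical masks (arrays or vectors over linear voxel
#'   index), e.g. from [erode_labels()].
#' @return Matrix H (n x frames), with `fps` attribute.
#' @export
extract_timecourses <- function(movie, rois) {
  stopifnot(inherits(movie, "Movie"), length(rois) >= 1L)
  V <- movie_matrix(movie)
  H <- t(vapply(seq_along(rois), function(j) {
    idx <- which(as.logical(rois[[j]]))
    if (length(idx) == 0L) stop("ROI ", j, " is empty")
    colMeans(V[idx, , drop = FALSE])
  }, numeric(ncol(V))))
  attr(H, "fps") <- movie$fps
  H
}

#' Per-voxel non-negative least squares spatial fit
#'
#' For every voxel `s` solves `min_{w >= 0} || V(s,.) - w %*% H ||_2`,
#' yielding the nonnegative spatial weight map of each basis timecourse.
#' Voxels are solved independently (Lawson-Hanson via
#' [pracma::lsqnonneg()]), so the result does not depend on any chunking.
#'
#' @param movie A [Movie()].
#' @param H Basis timecourse matrix (n x frames).
#' @return Matrix W (voxels x n), all entries >= 0, with `shape` attribute.
#' @export
nnls_spatial_fit <- function(movie, H) {
  stopifnot(inherits(movie, "Movie"))
  if (!is.matrix(H)) H <- matrix(H, nrow = 1L)
  if (ncol(H) != n_frames(movie))
    stop("H frame count does not match the movie")
  zero_rows <- which(rowSums(abs(H)) == 0)
  if (length(zero_rows))
    stop("degenerate H: all-zero row(s) ", paste(zero_rows, collapse = ", "))
  V <- movie_matrix(movie)
  Ht <- t(H)                                   # frames x n design matrix
  W <- t(apply(V, 1L, function(v) pracma::lsqnonneg(Ht, v)$x))
  if (nrow(H) == 1L) W <- matrix(W, ncol = 1L)
  attr(W, "shape") <- spatial_dims(movie)
  W
}

#' Reconstruct the linear model and residual statistics
#'
#' Forms `V' = W %*% H` and compares it to the movie.
#'
#' @param movie A [Movie()] (the original data).
#' @param W Spatial weights (voxels x n).
#' @param H Basis timecourses (n x frames).
#' @return List with `model` (a [Movie()] of V'), `residual_mean_per_frame`
#'   (mean of V - V' per frame) and `residual_rms` (global root mean square
#'   of V - V').
#' @export
reconstruct <- function(movie, W, H) {
  stopifnot(inherits(movie, "Movie"))
  if (ncol(W) != nrow(H)) stop("component count mismatch between W and H")
  V <- movie_matrix(movie)
  if (nrow(W) != nrow(V) || ncol(H) != ncol(V))
    stop("W/H dimensions do not match the movie")
  Vp <- W %*% H
  R <- V - Vp
  list(
    model = Movie(array(Vp, dim(movie$data)), movie$fps),
    residual_mean_per_frame = colMeans(R),
    residual_rms = sqrt(mean(R^2))
  )
}

#' Order components by spatial centroid position
#'
#' The centroid of component `j` is its weight-weighted mean coordinate;
#' components are sorted by the centroid coordinate along `axis`
#' (e.g. front-to-back of the brain). Ties break by component index.
#'
#' @param W Spatial weights (voxels x n) with a `shape` attribute.
#' @param axis Spatial axis to sort along (1-based).
#' @param direction `"ascending"` or `"descending"`.
#' @return Integer permutation: position i holds the component ranked i-th.
#' @export
order_by_centroid <- function(W, axis = 1L, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  shape <- attr(W, "shape")
  if (is.null(shape)) stop("W must carry a `shape` attribute")
  if (any(colSums(W) == 0)) stop("all-zero component; centroid undefined")
  coords <- as.matrix(expand.grid(lapply(shape, seq_len)))
  cent <- colSums(W * coords[, axis]) / colSums(W)
  ord <- order(cent, seq_along(cent),
               decreasing = (direction == "descending"))
  as.integer(ord)
}

#' Order components by first supra-threshold event time
#'
#' Components are sorted by the first frame where their timecourse exceeds
#' `threshold`; components that never exceed it are placed last, in index
#' order.
#'
#' @param H Basis timecourses (n x frames).
#' @param threshold Event threshold (signal units).
#' @return Integer permutation (as in [order_by_centroid()]).
#' @export
order_by_first_event <- function(H, threshold) {
  if (!is.matrix(H)) H <- matrix(H, nrow = 1L)
  first <- apply(H, 1L, function(h) {
    i <- which(h > threshold)
    if (length(i)) i[1L] else Inf
  })
  as.integer(order(first, seq_len(nrow(H))))
}

#' 3x3x3 spatial median filter
#'
#' Median filters a volumetric component over its 27-voxel neighborhood,
#' with reflection at the edges. Used to clean background speckle from 3D
#' spatial maps.
#'
#' @param volume 3D numeric array.
#' @return Filtered array of the same dimensions.
#' @export
median_filter_3d <- function(volume) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("median_filter_3d requires a 3D array")
  d <- dim(volume)
  # reflection-pad by 1 on every face
  ix <- function(n) c(2L, seq_len(n), n - 1L)
  if (any(d < 2L)) stop("each dimension must have length >= 2 for reflection")
  P <- volume[ix(d[1L]), ix(d[2L]), ix(d[3L])]
  stack <- matrix(0, prod(d), 27L)
  s <- 0L
  for (dz in 0:2) for (dy in 0:2) for (dx in 0:2) {
    s <- s + 1L
    stack[, s] <- as.vector(P[dx + seq_len(d[1L]), dy + seq_len(d[2L]),
                              dz + seq_len(d[3L])])
  }
  med <- apply(stack, 1L, stats::median)
  array(med, d)
}

#' Subset a decomposition to selected components
#'
#' Keeps the listed components, consistently subsetting W, H, colors and the
#' ordering (re-ranked among survivors). Stands in for the manual pruning of
#' components lacking well-defined morphology.
#'
#' @param decomp A [decomposition()] object.
#' @param keep Integer vector of component indices to keep (unique, valid,
#'   nonempty).
#' @return A [decomposition()] with `n = length(keep)`.
#' @export
select_components <- function(decomp, keep) {
  stopifnot(inherits(decomp, "decomposition"))
  if (length(keep) == 0L) stop("keep must be nonempty")
  if (anyDuplicated(keep)) stop("duplicate indices in keep")
  if (any(keep < 1L) || any(keep > decomp$n)) stop("component index out of range")
  keep <- as.integer(keep)
  ranks <- match(decomp$order, keep)        # position in old order of kept comps
  new_order <- keep[order(match(keep, decomp$order))]
  new_order <- match(new_order, keep)       # re-index to 1..length(keep)
  labels <- decomp$labels
  if (!is.null(labels)) {
    relab <- integer(decomp$n)
    relab[keep] <- seq_along(keep)
    labels[!(labels %in% keep)] <- 0L
    labels[labels > 0L] <- relab[labels[labels > 0L]]
  }
  decomposition(
    W = decomp$W[, keep, drop = FALSE],
    H = decomp$H[keep, , drop = FALSE],
    labels = labels,
    order = as.integer(new_order),
    colors = if (!is.null(decomp$colors)) decomp$colors[keep, , drop = FALSE],
    fps = decomp$fps,
    shape = decomp$shape
  )
}

#' Construct a decomposition object
#'
#' Bundles the linear-model factors: nonnegative spatial weights `W`
#' (voxels x n), basis timecourses `H` (n x frames), optional voxel labels,
#' a component ordering and per-component display colors.
#'
#' @param W Spatial weights, nonnegative, voxels x n.
#' @param H Timecourses, n x frames.
#' @param labels Optional integer voxel labels (0 = background).
#' @param order Integer permutation of 1..n (display/pitch ordering);
#'   defaults to identity.
#' @param colors Optional n x 3 matrix of RGB rows in [0,1].
#' @param fps Frame rate of the source movie.
#' @param shape Spatial dims of the source movie.
#' @return Object of class `decomposition`.
#' @export
decomposition <- function(W, H, labels = NULL, order = NULL, colors = NULL,
                          fps = NULL, shape = attr(W, "shape")) {
  if (!is.matrix(W) || !is.matrix(H)) stop("W and H must be matrices")
  n <- ncol(W)
  if (nrow(H) != n) stop("W and H disagree on component count")
  if (any(W < 0)) stop("W must be nonnegative")
  if (is.null(order)) order <- seq_len(n)
  if (length(order) != n || !setequal(order, seq_len(n)))
    stop("order must be a permutation of 1..n")
  if (!is.null(colors) && (ncol(colors) != 3L || nrow(colors) != n))
    stop("colors must be an n x 3 matrix")
  structure(list(W = W, H = H, labels = labels, order = as.integer(order),
                 colors = colors, n = n, fps = fps, shape = shape),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("decomposition: %d components, %d voxels x %d frames\n",
              x$n, nrow(x$W), ncol(x$H)))
  invisible(x)
}

#' Run the full decomposition pipeline on a movie
#'
#' Chains the unmixing stages: optional active-voxel filtering, k-means
#' clustering under correlation distance, ROI erosion, timecourse
#' extraction, NNLS spatial fitting and component ordering.
#'
#' @param movie A [Movie()].
#' @param k Number of components.
#' @param seed Integer seed for clustering.
#' @param filter Logical: apply [filter_active_voxels()] before clustering.
#' @param z_thresh,min_frac Passed to [filter_active_voxels()].
#' @param erode_iter Erosion depth for ROI masks.
#' @param ordering `"centroid"` or `"first_event"`.
#' @param order_axis Spatial axis for centroid ordering.
#' @param event_threshold Threshold for first-event ordering; default is the
#'   per-matrix `baseline + 2 SD` rule of [default_threshold()] applied to H.
#' @return A [decomposition()].
#' @export
decompose_movie <- function(movie, k, seed = 0L, filter = TRUE,
                            z_thresh = 4, min_frac = 0.05, erode_iter = 1L,
                            ordering = c("centroid", "first_event"),
                            order_axis = 1L, event_threshold = NULL) {
  ordering <- match.arg(ordering)
  mask <- if (filter) {
    m <- filter_active_voxels(movie, z_thresh, min_frac)
    if (!any(m)) {
      warning("active-voxel filter kept nothing; proceeding unfiltered")
      NULL
    } else m
  } else NULL
  labels <- kmeans_correlation(movie, k, seed = seed, mask = mask)
  rois <- erode_labels(labels, iterations = erode_iter)
  H <- extract_timecourses(movie, rois)
  W <- nnls_spatial_fit(movie, H)
  ord <- if (ordering == "centroid") {
    order_by_centroid(W, axis = order_axis)
  } else {
    thr <- if (is.null(event_threshold)) default_threshold(H) else event_threshold
    order_by_first_event(H, thr)
  }
  decomposition(W = W, H = H, labels = as.integer(labels), order = ord,
                fps = movie$fps, shape = spatial_dims(movie))
}

#' Save / load a decomposition container
#'
#' Persists W, H, labels, order, colors and fps in one named-array RDS
#' container.
#'
#' @param decomp A [decomposition()].
#' @param path Destination `.rds` path.
#' @return `path` invisibly (write) or the [decomposition()] (read).
#' @export
write_decomposition <- function(decomp, path) {
  stopifnot(inherits(decomp, "decomposition"))
  saveRDS(unclass(decomp), path)
  invisible(path)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(path) {
  x <- readRDS(path)
  decomposition(W = x$W, H = x$H, labels = x$labels, order = x$order,
                colors = x$colors, fps = x$fps, shape = x$shape)
}
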