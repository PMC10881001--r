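test_that("percent dF/F matches the per-voxel definition", {
  m <- Movie(array(5, c(4, 4, 10)), fps = 2)
  out <- compute_dff(m, 1:3)
  expect_true(all(out$data == 0))

  dat <- array(10, c(2, 2, 5)); dat[1, 1, 4] <- 11
  m2 <- Movie(dat, fps = 1)
  out2 <- compute_dff(m2, 1:3)
  expect_equal(out2$data[1, 1, 4], 10.0)

  # elementwise oracle on a random movie
  m3 <- make_fixture(n = 2, shape = c(6, 6), n_frames = 30, seed = 8)
  m3 <- Movie(m3$data + 1, m3$fps)           # strictly positive baseline
  out3 <- compute_dff(m3, 1:5)
  V <- movie_matrix(m3)
  expected <- t(vapply(seq_len(nrow(V)), function(s) {
    f0 <- mean(V[s, 1:5]); 100 * (V[s, ] - f0) / f0
  }, numeric(ncol(V))))
  expect_equal(movie_matrix(out3), expected, ignore_attr = TRUE)

  expect_error(compute_dff(m, integer(0)), "nonempty")
  # nonpositive baseline voxels are flagged invalid
  dat4 <- array(1, c(2, 1, 4)); dat4[1, 1, ] <- 0
  out4 <- compute_dff(Movie(dat4, 1), 1:2)
  expect_equal(attr(out4, "invalid_voxels"), 1L)
  expect_true(all(is.na(out4$data[1, 1, ])))
})

test_that("active-voxel filter applies the z-score exceedance rule", {
  m <- Movie(array(3, c(3, 3, 20)), fps = 1)
  expect_true(!any(filter_active_voxels(m)))   # no variance anywhere

  # constructed trace: 4 spikes among 79 frames; z > 4 at the spikes,
  # exceedance fraction 4/79 = 5.06% -- kept at 5%, dropped at 10%
  h <- c(rep(0, 40), rep(10, 4), rep(0, 35))
  z <- (h - mean(h)) / sd(h)
  frac <- mean(z > 4)                          # brute-force oracle
  expect_true(all(z[h == 10] > 4))
  expect_equal(frac, 4 / 79)
  dat <- array(0, c(1, 2, 79))
  dat[1, 1, ] <- h
  dat[1, 2, ] <- 1                             # constant companion voxel
  mv <- Movie(dat, fps = 1)
  expect_equal(filter_active_voxels(mv, 4, 0.05), c(TRUE, FALSE))
  expect_equal(filter_active_voxels(mv, 4, 0.10), c(FALSE, FALSE))
})

test_that("correlation k-means recovers planted groups and is scale-invariant", {
  # 8 voxels, two groups with identical within-group timecourses
  set.seed(3)
  t1 <- as.numeric(arima.sim(list(ar = 0.5), 60))
  t2 <- as.numeric(arima.sim(list(ar = 0.5), 60))
  scales <- c(1, 2, 0.5, 3, 1, 5, 0.25, 2)    # positive rescaling per voxel
  dat <- array(0, c(2, 4, 60))
  truth <- integer(8)
  for (s in 1:8) {
    g <- if (s <= 4) 1L else 2L
    truth[s] <- g
    dat[((s - 1) %% 2) + 1, ((s - 1) %/% 2) + 1, ] <-
      scales[s] * (if (g == 1L) t1 else t2) + 10
  }
  mv <- Movie(dat, fps = 1)
  labels <- kmeans_correlation(mv, 2, seed = 1)
  # exact recovery up to label permutation
  expect_equal(length(unique(labels[truth == 1])), 1L)
  expect_equal(length(unique(labels[truth == 2])), 1L)
  expect_false(labels[1] == labels[8])

  # brute-force over all 2-partitions: the found partition is optimal
  X <- movie_matrix(mv)
  Xn <- t(scale(t(X))) / sqrt(ncol(X) - 1)
  part_inertia <- function(assign) {
    s <- 0
    for (g in unique(assign)) {
      idx <- which(assign == g)
      cm <- colMeans(Xn[idx, , drop = FALSE])
      cm <- cm - mean(cm); cm <- cm / sqrt(sum(cm^2))
      s <- s + sum(1 - Xn[idx, , drop = FALSE] %*% cm)
    }
    s
  }
  best <- Inf
  for (code in 1:(2^7 - 1)) {                  # nontrivial bipartitions
    assign <- c(1L, as.integer(intToBits(code)[1:7]) + 1L)
    best <- min(best, part_inertia(assign))
  }
  expect_equal(attr(labels, "inertia"), best, tolerance = 1e-8)

  expect_true(all(kmeans_correlation(mv, 1, seed = 1) == 1L))
  expect_error(kmeans_correlation(mv, 20, seed = 1), "exceeds")
})

test_that("label erosion follows the cross structuring element contract", {
  lab <- array(0L, c(5, 5))
  lab[2:4, 2:4] <- 1L                          # 3x3 solid square
  rois <- erode_labels(lab, iterations = 1)
  expect_equal(which(rois[["1"]]), which(array(seq_len(25), c(5, 5)) == 13))

  rois0 <- erode_labels(lab, iterations = 0)
  expect_equal(rois0[["1"]], array(lab == 1L, c(5, 5)))

  lab1 <- array(0L, c(4, 4)); lab1[2, 2] <- 1L
  expect_warning(r1 <- erode_labels(lab1, 1), "fallback|falling back")
  expect_equal(sum(r1[["1"]]), 1L)             # degenerate ROI preserved
})

test_that("ROI timecourse extraction averages member voxels", {
  m <- make_fixture(n = 2, shape = c(8, 8), n_frames = 30, noise_sigma = 0.2,
                    seed = 9)
  V <- movie_matrix(m)
  roi1 <- array(FALSE, c(8, 8)); roi1[3, 4] <- TRUE
  roi2 <- array(FALSE, c(8, 8)); roi2[c(1, 2), 1] <- TRUE
  H <- extract_timecourses(m, list(roi1, roi2))
  expect_equal(H[1, ], V[which(roi1), ], ignore_attr = TRUE)
  expect_equal(H[2, ], colMeans(V[which(roi2), ]), ignore_attr = TRUE)
  expect_error(extract_timecourses(m, list(array(FALSE, c(8, 8)))), "empty")

  # noiseless movie with disjoint-support components + true ROIs:
  # extracted H is exactly proportional to H_true (correlation 1)
  Wd <- make_spatial_components(3, c(20, 20), sigma = 1.5, seed = 10)
  support <- apply(Wd, 1, which.max)
  for (j in 1:3) Wd[support != j, j] <- 0      # hard-disjoint supports
  Ht <- make_timecourses(3, 80, fps = 10, seed = 10)
  m0 <- make_movie(Wd, Ht, noise_sigma = 0, fps = 10)
  rois <- lapply(1:3, function(j) array(Wd[, j] > 0.5, c(20, 20)))
  H0 <- extract_timecourses(m0, rois)
  mt <- match_components(H0, Ht)
  expect_true(all(mt$r > 1 - 1e-9))
})

test_that("NNLS spatial fit is nonnegative and recovers ground truth", {
  h <- matrix(abs(sin(1:40)) + 0.1, nrow = 1)
  dat <- array(2 * h, c(1, 1, 40))
  m <- Movie(dat, fps = 1)
  W <- nnls_spatial_fit(m, h)
  expect_equal(W[1, 1], 2.0, tolerance = 1e-10)

  # anti-correlated voxel gets weight 0 under the constraint
  m_neg <- Movie(array(pmax(-h, 0), c(1, 1, 40)), fps = 1)
  expect_equal(nnls_spatial_fit(m_neg, h)[1, 1], 0)

  m0 <- make_fixture(n = 3, shape = c(16, 16), n_frames = 100,
                     noise_sigma = 0, seed = 13)
  gt <- attr(m0, "ground_truth")
  W0 <- nnls_spatial_fit(m0, gt$H_true)
  expect_true(all(W0 >= 0))
  expect_lt(max(abs(W0 - gt$W_true)), 1e-6)

  bad <- rbind(gt$H_true, 0)
  expect_error(nnls_spatial_fit(m0, bad), "row")
})

test_that("NNLS dominates a per-voxel nonnegative grid search", {
  # 4-voxel instance, 2 components; grid at 0.01 resolution
  set.seed(21)
  H <- matrix(abs(rnorm(2 * 30)), 2, 30)
  Wt <- matrix(runif(8), 4, 2)
  V <- Wt %*% H + matrix(rnorm(4 * 30, sd = 0.05), 4)
  V[V < 0] <- 0
  m <- Movie(array(V, c(2, 2, 30)), fps = 1)
  W <- nnls_spatial_fit(m, H)
  grid <- seq(0, 2, by = 0.01)
  for (s in 1:4) {
    fit_rss <- sum((V[s, ] - W[s, ] %*% H)^2)
    g <- expand.grid(grid, grid)
    rss <- colSums((V[s, ] - H[1, ] %o% g[, 1] - H[2, ] %o% g[, 2])^2)
    expect_lte(fit_rss, min(rss) + 1e-9)
  }
})

test_that("reconstruction reports faithful residual statistics", {
  m0 <- make_fixture(n = 2, shape = c(10, 10), n_frames = 40,
                     noise_sigma = 0, seed = 14)
  gt <- attr(m0, "ground_truth")
  rec <- reconstruct(m0, gt$W_true, gt$H_true)
  expect_lt(rec$residual_rms, 1e-10)

  W0 <- matrix(0, 100, 2); attr(W0, "shape") <- c(10L, 10L)
  rec0 <- reconstruct(m0, W0, gt$H_true)
  expect_true(all(rec0$model$data == 0))
  expect_equal(rec0$residual_rms, sqrt(mean(m0$data^2)))

  # seeded noisy fixture: model residual cannot exceed the injected noise by
  # more than 10%
  mN <- make_fixture(n = 2, shape = c(10, 10), n_frames = 40,
                     noise_sigma = 0.1, seed = 14)
  gtN <- attr(mN, "ground_truth")
  recN <- reconstruct(mN, nnls_spatial_fit(mN, gtN$H_true), gtN$H_true)
  expect_lte(recN$residual_rms, 0.1 * 1.1)

  expect_error(reconstruct(m0, gt$W_true, gt$H_true[, 1:10]), "dimensions")
})

test_that("component orderings behave as sorts with stated tie/degenerate rules", {
  # blobs centered at rows 5, 1, 9 of a 10x4 field
  W <- matrix(0, 40, 3); attr(W, "shape") <- c(10L, 4L)
  W[5 + 10 * (0:3), 1] <- 1
  W[1 + 10 * (0:3), 2] <- 1
  W[9 + 10 * (0:3), 3] <- 1
  expect_equal(order_by_centroid(W, axis = 1), c(2L, 1L, 3L))
  expect_equal(order_by_centroid(W, axis = 1, direction = "descending"),
               c(3L, 1L, 2L))
  W1 <- W[, 1, drop = FALSE]; attr(W1, "shape") <- c(10L, 4L)
  expect_equal(order_by_centroid(W1, 1), 1L)

  # flipping the field along the axis reverses a two-blob ordering
  W2 <- make_spatial_components(2, c(12, 12), seed = 2)
  flip <- W2[as.vector(array(seq_len(144), c(12, 12))[12:1, ]), ]
  attr(flip, "shape") <- c(12L, 12L)
  expect_equal(order_by_centroid(flip, 1), rev(order_by_centroid(W2, 1)))

  Wz <- cbind(W[, 1], 0); attr(Wz, "shape") <- c(10L, 4L)
  expect_error(order_by_centroid(Wz, 1), "all-zero")

  H <- rbind(c(0, 0, 0, 0, 0, 1, 0), c(0, 1, 0, 0, 0, 0, 0),
             c(0, 0, 0, 0, 0, 0, 0, 0, 1)[1:7])
  H[3, ] <- 0; H[3, 7] <- 1
  expect_equal(order_by_first_event(H, 0.5), c(2L, 1L, 3L))
  Hs <- rbind(H[1, ], rep(0, 7))               # silent component placed last
  expect_equal(order_by_first_event(Hs, 0.5), c(1L, 2L))

  # fixture event log agrees with first-event ordering
  fps <- 10
  Hf <- make_timecourses(3, 120, fps = fps,
                         event_times = list(4, 1, 8), seed = 6)
  expect_equal(order_by_first_event(Hf, 0.3), c(2L, 1L, 3L))

  # orderings are bijections; applying a permutation then its inverse is id
  ord <- order_by_centroid(make_spatial_components(5, c(24, 24), seed = 4),
                           axis = 2)
  expect_setequal(ord, 1:5)
  inv <- order(ord)
  expect_equal(ord[inv], 1:5)
})

test_that("3x3x3 median filter matches the naive neighborhood oracle", {
  v <- array(0, c(5, 5, 5)); v[3, 3, 3] <- 10
  expect_true(all(median_filter_3d(v) == 0))   # lone voxel removed

  vc <- array(7, c(4, 4, 4))
  expect_equal(median_filter_3d(vc), vc)

  set.seed(15)
  vr <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  out <- median_filter_3d(vr)
  refl <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  d <- dim(vr)
  for (pick in list(c(1, 1, 1), c(3, 2, 2), c(6, 5, 4), c(2, 5, 1))) {
    nb <- numeric(0)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
      nb <- c(nb, vr[refl(pick[1] + dx, d[1]), refl(pick[2] + dy, d[2]),
                     refl(pick[3] + dz, d[3])])
    expect_equal(out[pick[1], pick[2], pick[3]], median(nb))
  }
  expect_error(median_filter_3d(matrix(0, 3, 3)), "3D")
})

test_that("component selection subsets every field consistently", {
  m <- make_fixture(n = 4, shape = c(16, 16), n_frames = 60, seed = 16)
  d <- suppressWarnings(decompose_movie(m, k = 4, seed = 1, filter = FALSE))
  d$colors <- make_colormap(4, "jet", d$order)

  all4 <- select_components(d, 1:4)
  expect_equal(all4$W, d$W, ignore_attr = TRUE)
  expect_equal(all4$H, d$H, ignore_attr = TRUE)
  expect_equal(all4$order, d$order)

  one <- select_components(d, 2)
  expect_equal(one$n, 1L)
  rec <- reconstruct(m, one$W, one$H)
  expect_equal(movie_matrix(rec$model),
               d$W[, 2, drop = FALSE] %*% d$H[2, , drop = FALSE],
               ignore_attr = TRUE)

  expect_error(select_components(d, integer(0)), "nonempty")
  expect_error(select_components(d, c(1, 1)), "duplicate")
  expect_error(select_components(d, 9), "range")
})
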