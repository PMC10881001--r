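#' Construct a Movie object
#'
#' A `Movie` wraps a nonnegative spatiotemporal array with spatial dimensions
#' first and time last -- `(y, x, t)` for planar data or `(y, x, z, t)` for
#' volumetric data -- together with its frame rate.
#'
#' @param data Numeric array, 3- or 4-dimensional, spatial dims first and
#'   time last. Values are fluorescence (arbitrary units) above a nonnegative
#'   baseline.
#' @param fps Frame rate in frames per second; must be positive.
#' @return An object of class `Movie` with elements `data`, `fps` and
#'   `space_rank` (2 for planar, 3 for volumetric data).
#' @examples
#' m <- Movie(array(runif(4 * 4 * 10), c(4, 4, 10)), fps = 5)
#' n_frames(m)
#' @export
Movie <- function(data, fps) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3D (y,x,t) or 4D (y,x,z,t) array")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("`fps` must be a single positive number")
  nd <- length(dim(data))
  if (dim(data)[nd] < 2L)
    stop("movie must have at least 2 frames")
  structure(
    list(data = data, fps = as.numeric(fps), space_rank = nd - 1L),
    class = "Movie"
  )
}

#' @export
print.Movie <- function(x, ...) {
  d <- dim(x$data)
  nd <- length(d)
  cat(sprintf(
    "Movie: %s spatial, %d frames @ %g fps (%.2f s)\n",
    paste(d[-nd], collapse = " x "), d[nd], x$fps, d[nd] / x$fps
  ))
  invisible(x)
}

#' Number of frames in a Movie
#' @param movie A [Movie()] object.
#' @return Integer frame count.
#' @export
n_frames <- function(movie) {
  stopifnot(inherits(movie, "Movie"))
  d <- dim(movie$data)
  d[length(d)]
}

#' Spatial dimensions of a Movie
#' @param movie A [Movie()] object.
#' @return Integer vector of spatial dims (length 2 or 3).
#' @export
spatial_dims <- function(movie) {
  stopifnot(inherits(movie, "Movie"))
  d <- dim(movie$data)
  d[-length(d)]
}

#' Flatten a Movie to a voxels-by-frames matrix
#'
#' Voxels are linearized in array (column-major) order, so row `s` of the
#' result is the timecourse of linear voxel index `s`.
#'
#' @param movie A [Movie()] object.
#' @return Matrix with one row per voxel and one column per frame.
#' @export
movie_matrix <- function(movie) {
  stopifnot(inherits(movie, "Movie"))
  t <- n_frames(movie)
  matrix(movie$data, ncol = t)
}

#' Read a movie from disk
#'
#' Supported containers: multipage TIFF (one page per frame, grayscale) and
#' RDS array files holding either a plain array (spatial dims first, time
#' last) or a `Movie` object.
#'
#' @param path Path to a `.tif`/`.tiff` or `.rds` file.
#' @param fps Frame rate to attach (ignored when the RDS already stores a
#'   `Movie` with its own fps).
#' @param format One of `"auto"`, `"tiff"`, `"rds"`.
#' @return A [Movie()] object.
#' @export
read_movie <- function(path, fps = 10, format = c("auto", "tiff", "rds")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      tif = , tiff = "tiff",
      rds = "rds",
      stop("cannot infer format from extension '", ext,
           "'; pass `format` explicitly")
    )
  }
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse to grayscale
      p
    })
    arr <- array(unlist(frames), c(dim(frames[[1L]]), length(frames)))
    Movie(arr, fps)
  } else {
    obj <- readRDS(path)
    if (inherits(obj, "Movie")) obj else Movie(obj, fps)
  }
}

#' Write a movie to disk
#'
#' TIFF output stores one 32-bit float page per frame. TIFF storage is
#' defined on `[0, 1]`, so data with a larger peak are divided by their
#' maximum before writing (the scale factor is returned in attribute
#' `scale`); use RDS when absolute units must round-trip. RDS output stores
#' the full `Movie` object losslessly.
#'
#' @param movie A [Movie()] object.
#' @param path Destination path (`.tif`/`.tiff` or `.rds`).
#' @param format One of `"auto"`, `"tiff"`, `"rds"`.
#' @return `path`, invisibly, with attribute `scale` (TIFF only).
#' @export
write_movie <- function(movie, path, format = c("auto", "tiff", "rds")) {
  stopifnot(inherits(movie, "Movie"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tif = , tiff = "tiff", rds = "rds",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format == "tiff") {
    if (movie$space_rank != 2L)
      stop("TIFF output supports planar (2D+time) movies only; use RDS for volumes")
    t <- n_frames(movie)
    peak <- max(movie$data)
    scale <- if (peak > 1) peak else 1
    pages <- lapply(seq_len(t), function(i) movie$data[, , i] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    return(invisible(structure(path, scale = scale)))
  } else {
    saveRDS(movie, path)
  }
  invisible(path)
}
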