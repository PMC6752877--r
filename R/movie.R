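#' Render a trace set as a synthetic 8-bit calcium movie
#'
#' Each neuron is drawn as a Gaussian blob (truncated at its ROI radius, so
#' ROIs never bleed into each other) whose brightness follows its
#' fluorescence trace; the whole movie is scaled to the 8-bit range and
#' quantised, matching the 8-bit TIFF-stack processing of real recordings.
#' The paired label mask maps pixels to neuron IDs, so
#' [extract_traces()] applied to the rendered movie recovers the input
#' traces up to quantisation.
#'
#' @param traces a [trace_set()] (raw or delta-F/F; values are used as
#'   brightness directly).
#' @param centroids 2-column (x, y) matrix of blob centres, one per neuron;
#'   defaults to a jittered grid layout.
#' @param radius ROI radius in pixels (default 4).
#' @param frame_shape `(height, width)` in pixels; defaults to a square just
#'   large enough for the grid layout.
#' @return object of class `calcium_movie`: list with `frames` (integer
#'   array height x width x frames, values 0..255), `mask` (integer label
#'   matrix), `centroids`, `radius`, `scale`.
#' @examples
#' ts <- trace_set(matrix(100 + 10 * sin(1:60 / 3), 2, 30, byrow = TRUE), 10)
#' mv <- render_movie(ts, radius = 3)
#' dim(mv$frames)
#' @export
render_movie <- function(traces, centroids = NULL, radius = 4,
                         frame_shape = NULL) {
  stopifnot(inherits(traces, "trace_set"))
  n <- nrow(traces$values)
  if (is.null(centroids)) {
    per_row <- ceiling(sqrt(n))
    step <- 4 * radius
    gx <- ((seq_len(n) - 1) %% per_row) * step + 2 * radius
    gy <- ((seq_len(n) - 1) %/% per_row) * step + 2 * radius
    centroids <- cbind(gx, gy)
  }
  centroids <- as.matrix(centroids)
  stopifnot(nrow(centroids) == n, ncol(centroids) == 2)
  frame_shape <- frame_shape %||%
    rep(ceiling(max(centroids) + 2 * radius), 2)
  h <- frame_shape[1]; w <- frame_shape[2]
  if (any(centroids[, 1] < radius) || any(centroids[, 1] > w - radius) ||
      any(centroids[, 2] < radius) || any(centroids[, 2] > h - radius)) {
    stop_midnet("centroids (with radius) must lie inside the frame")
  }
  if (n > 1) {
    d <- as.matrix(dist(centroids))
    diag(d) <- Inf
    if (min(d) <= 2 * radius) {
      stop_midnet("overlapping ROIs: minimum centroid distance must exceed ",
                  "2 * radius")
    }
  }

  ## per-neuron blob template restricted to its ROI disk
  mask <- matrix(0L, h, w)
  blob_px <- vector("list", n)
  blob_wt <- vector("list", n)
  sigma <- radius / 2
  for (i in seq_len(n)) {
    cx <- centroids[i, 1]; cy <- centroids[i, 2]
    xs <- max(1, floor(cx - radius)):min(w, ceiling(cx + radius))
    ys <- max(1, floor(cy - radius)):min(h, ceiling(cy + radius))
    grid <- expand.grid(y = ys, x = xs)
    dd2 <- (grid$x - cx)^2 + (grid$y - cy)^2
    inside <- dd2 <= radius^2
    px <- (grid$x[inside] - 1) * h + grid$y[inside]
    mask[px] <- i
    blob_px[[i]] <- px
    blob_wt[[i]] <- exp(-dd2[inside] / (2 * sigma^2))
  }

  n_frames <- ncol(traces$values)
  peak <- max(traces$values)
  if (peak <= 0) stop_midnet("traces must contain positive values to render")
  scale <- 255 / peak
  frames <- array(0L, dim = c(h, w, n_frames))
  for (t in seq_len(n_frames)) {
    fr <- matrix(0, h, w)
    for (i in seq_len(n)) {
      fr[blob_px[[i]]] <- blob_wt[[i]] * traces$values[i, t] * scale
    }
    frames[, , t] <- as.integer(pmin(pmax(round(fr), 0), 255))
  }

  structure(
    list(frames = frames, mask = mask, centroids = centroids,
         radius = radius, scale = scale,
         frame_rate_hz = traces$frame_rate_hz, condition = traces$condition),
    class = "calcium_movie"
  )
}

#' @export
print.calcium_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<calcium_movie> %dx%d px, %d frames, %d ROIs, 8-bit\n",
              d[1], d[2], d[3], max(x$mask)))
  invisible(x)
}

#' Write / read a calcium movie as multi-page grayscale TIFF
#'
#' `write_movie_tiff()` writes the frames as an 8-bit multi-page TIFF and
#' the label mask as a single-page 8- or 16-bit TIFF next to it.
#' `read_movie_tiff()` reads a multi-page grayscale TIFF back into a
#' height x width x frames integer array; `read_mask_tiff()` reads a label
#' mask.
#'
#' @param movie a `calcium_movie`.
#' @param path output TIFF path for the frames.
#' @param mask_path output path for the mask (default: `path` with
#'   `_mask.tiff` suffix).
#' @return `write_movie_tiff()`: the two paths, invisibly.
#' @export
write_movie_tiff <- function(movie, path,
                             mask_path = sub("\\.tiff?$", "_mask.tiff", path)) {
  stopifnot(inherits(movie, "calcium_movie"))
  pages <- lapply(seq_len(dim(movie$frames)[3]),
                  function(t) movie$frames[, , t] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  depth <- if (max(movie$mask) < 256) 8L else 16L
  tiff::writeTIFF(movie$mask / (2^depth - 1), mask_path,
                  bits.per.sample = depth)
  invisible(c(path, mask_path))
}

#' @rdname write_movie_tiff
#' @param bits bit depth of the file being read (8 or 16).
#' @export
read_movie_tiff <- function(path, bits = 8L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) {
    pg <- pages[[t]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    arr[, , t] <- as.integer(round(pg * (2^bits - 1)))
  }
  arr
}

#' @rdname write_movie_tiff
#' @export
read_mask_tiff <- function(path, bits = 8L) {
  pg <- tiff::readTIFF(path)
  if (length(dim(pg)) == 3) pg <- pg[, , 1]
  matrix(as.integer(round(pg * (2^bits - 1))), nrow = nrow(pg))
}
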