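#' Fluorescence trace set
#'
#' Container for a neurons-by-frames fluorescence matrix with its acquisition
#' metadata. `values` holds either raw fluorescence (strictly positive) or
#' delta-F/F, distinguished by the `dff` flag.
#'
#' @param values numeric matrix, one row per neuron, one column per frame.
#' @param frame_rate_hz acquisition rate in Hz.
#' @param condition condition label (one label per trace set).
#' @param div days in vitro (integer, `NA` if unknown).
#' @param neuron_ids character vector of stable neuron identifiers
#'   (default `n001`, `n002`, ...).
#' @param centroids optional 2-column matrix of (x, y) soma centroids.
#' @param dff logical: are `values` already delta-F/F?
#' @return object of class `trace_set`.
#' @examples
#' ts <- trace_set(matrix(100 + runif(20), 2, 10), frame_rate_hz = 10,
#'                 condition = "baseline")
#' ts
#' @export
trace_set <- function(values, frame_rate_hz, condition = "baseline",
                      div = NA_integer_, neuron_ids = NULL, centroids = NULL,
                      dff = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop_midnet("trace values must be finite numerics")
  }
  if (!dff && any(values <= 0)) {
    stop_midnet("raw fluorescence must be strictly positive; ",
                "set dff = TRUE for normalised traces")
  }
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0) {
    stop_midnet("frame_rate_hz must be positive")
  }
  neuron_ids <- neuron_ids %||% sprintf("n%03d", seq_len(nrow(values)))
  if (length(neuron_ids) != nrow(values)) {
    stop_midnet("neuron_ids length must match the number of rows")
  }
  if (anyDuplicated(neuron_ids)) stop_midnet("neuron_ids must be unique")
  rownames(values) <- neuron_ids
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)
    stopifnot(nrow(centroids) == nrow(values), ncol(centroids) == 2)
  }
  structure(
    list(values = values, frame_rate_hz = frame_rate_hz,
         condition = condition, div = as.integer(div),
         neuron_ids = as.character(neuron_ids), centroids = centroids,
         dff = isTRUE(dff)),
    class = "trace_set"
  )
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d neurons x %d frames at %g Hz (%s, %s)%s\n",
              nrow(x$values), ncol(x$values), x$frame_rate_hz,
              x$condition, if (x$dff) "dF/F" else "raw",
              if (is.na(x$div)) "" else sprintf(", DIV %d", x$div)))
  invisible(x)
}

#' Plot a trace set as stacked time series
#'
#' @param x a [trace_set()].
#' @param max_neurons cap on the number of traces drawn.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trace_set <- function(x, max_neurons = 20, ...) {
  n <- min(nrow(x$values), max_neurons)
  tt <- (seq_len(ncol(x$values)) - 1) / x$frame_rate_hz
  v <- x$values[seq_len(n), , drop = FALSE]
  spread <- max(apply(v, 1, function(r) diff(range(r))), 1e-12)
  plot(range(tt), c(0, n + 1), type = "n", xlab = "time (s)",
       ylab = "neuron", yaxt = "n", ...)
  axis(2, at = seq_len(n), labels = x$neuron_ids[seq_len(n)], las = 1,
       cex.axis = 0.6)
  for (i in seq_len(n)) {
    lines(tt, i + (v[i, ] - mean(v[i, ])) / spread * 0.9)
  }
  invisible(x)
}

#' Subset a trace set to a frame window
#'
#' @param ts a [trace_set()].
#' @param window 0-based half-open `(start, end)` frame range.
#' @param condition condition label of the result (default: unchanged).
#' @return a [trace_set()] covering only the window.
#' @export
window_traces <- function(ts, window, condition = ts$condition) {
  stopifnot(inherits(ts, "trace_set"))
  idx <- window_idx(window, ncol(ts$values))
  trace_set(ts$values[, idx, drop = FALSE], frame_rate_hz = ts$frame_rate_hz,
            condition = condition, div = ts$div, neuron_ids = ts$neuron_ids,
            centroids = ts$centroids, dff = ts$dff)
}

## Convert a 0-based half-open [start, end) frame window into column indices.
window_idx <- function(window, n_frames, what = "window") {
  if (length(window) != 2 || any(!is.finite(window))) {
    stop_midnet(what, " must be a (start, end) pair")
  }
  start <- as.integer(window[1]); end <- as.integer(window[2])
  if (start < 0 || end > n_frames || end <= start) {
    stop_midnet(what, sprintf(" [%d, %d) out of range for %d frames",
                              start, end, n_frames))
  }
  (start + 1L):end
}
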