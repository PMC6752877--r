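#' Extract per-neuron traces from an image stack and ROI label mask
#'
#' The trace of a neuron is the mean pixel intensity over its mask pixels in
#' each frame, the standard readout for manually segmented somata. Neurons
#' are returned in ascending label order.
#'
#' @param stack a numeric 3-D array (height x width x frames) or list of
#'   equally sized frame matrices.
#' @param masks integer label matrix of the same height/width; 0 is
#'   background, labels `1..max` are ROIs. Every label up to the maximum must
#'   own at least one pixel.
#' @param frame_rate_hz acquisition rate of the stack.
#' @param condition,div metadata forwarded to the [trace_set()].
#' @return a raw [trace_set()]; centroids are the ROI pixel centroids.
#' @examples
#' fr <- matrix(10, 4, 4); fr[1, 1] <- 20
#' mk <- matrix(0L, 4, 4); mk[1, 1:2] <- 1L
#' extract_traces(list(fr, fr), mk, frame_rate_hz = 10)
#' @export
extract_traces <- function(stack, masks, frame_rate_hz,
                           condition = "baseline", div = NA_integer_) {
  if (is.list(stack)) {
    stack <- array(unlist(stack),
                   dim = c(dim(stack[[1]]), length(stack)))
  }
  stopifnot(length(dim(stack)) == 3)
  masks <- as.matrix(masks)
  if (!all(dim(masks) == dim(stack)[1:2])) {
    stop_midnet("mask dimensions must equal frame dimensions")
  }
  if (any(masks < 0) || any(masks != round(masks))) {
    stop_midnet("mask labels must be nonnegative integers")
  }
  n_labels <- max(masks)
  if (n_labels < 1) stop_midnet("mask contains no ROI labels")
  n_frames <- dim(stack)[3]

  vals <- matrix(NA_real_, nrow = n_labels, ncol = n_frames)
  centroids <- matrix(NA_real_, nrow = n_labels, ncol = 2)
  flat <- matrix(stack, nrow = prod(dim(masks)), ncol = n_frames)
  for (lab in seq_len(n_labels)) {
    px <- which(masks == lab)
    if (length(px) == 0) {
      stop_midnet(sprintf("ROI label %d has zero pixels", lab))
    }
    vals[lab, ] <- colMeans(flat[px, , drop = FALSE])
    rc <- arrayInd(px, dim(masks))
    centroids[lab, ] <- c(mean(rc[, 2]), mean(rc[, 1]))  # (x, y)
  }
  trace_set(vals, frame_rate_hz = frame_rate_hz, condition = condition,
            div = div, centroids = centroids, dff = FALSE)
}

#' Normalise raw fluorescence to delta-F/F
#'
#' Computes `(F(t) - F0) / F0` per neuron, with `F0` the per-neuron mean of
#' the raw trace over the reference window (`method = "mean"`, the default:
#' the delta-F/F then averages exactly to zero over that window, a testable
#' invariant) or a lower percentile of it (`method = "percentile"`).
#' When baseline and treatment windows live in one continuous recording,
#' pass the baseline window here and both conditions are referenced to the
#' same `F0`, so activity suppression shows up as reduced integrals.
#'
#' @param raw a raw [trace_set()].
#' @param f0_window 0-based half-open `(start, end)` frame range for `F0`.
#' @param method `"mean"` or `"percentile"`.
#' @param prob percentile used when `method = "percentile"` (default 0.2).
#' @param eps positivity floor for `F0`; a neuron whose `F0` falls at or
#'   below it is a hard error (division blow-up).
#' @return a delta-F/F [trace_set()]; per-neuron `F0` in attribute `"f0"`.
#' @examples
#' ts <- trace_set(matrix(c(100, 150), 1, 2), 10)
#' normalize_dff(ts, c(0, 1))$values  # 0, 0.5
#' @export
normalize_dff <- function(raw, f0_window, method = c("mean", "percentile"),
                          prob = 0.2, eps = 1e-8) {
  stopifnot(inherits(raw, "trace_set"))
  if (raw$dff) stop_midnet("traces are already delta-F/F")
  method <- match.arg(method)
  idx <- window_idx(f0_window, ncol(raw$values), "f0_window")
  ref <- raw$values[, idx, drop = FALSE]
  f0 <- if (method == "mean") {
    rowMeans(ref)
  } else {
    apply(ref, 1, quantile, probs = prob, names = FALSE)
  }
  bad <- which(f0 <= eps)
  if (length(bad)) {
    stop_midnet("F0 at or below the positivity floor for neuron(s): ",
                paste(raw$neuron_ids[bad], collapse = ", "))
  }
  out <- sweep(sweep(raw$values, 1, f0, "-"), 1, f0, "/")
  res <- trace_set(out, frame_rate_hz = raw$frame_rate_hz,
                   condition = raw$condition, div = raw$div,
                   neuron_ids = raw$neuron_ids, centroids = raw$centroids,
                   dff = TRUE)
  attr(res, "f0") <- f0
  res
}

#' Integrated activity per neuron
#'
#' Trapezoidal integral of the (signed) delta-F/F trace over a frame window,
#' in units of delta-F/F times seconds — the "total intensity per neuron"
#' summary used to compare baseline and treatment activity. Negative
#' excursions subtract; set `rectify = TRUE` to integrate `|dF/F|` instead.
#'
#' @param dff a delta-F/F [trace_set()].
#' @param window 0-based half-open `(start, end)` frame range (default: all
#'   frames); must span at least 2 frames.
#' @param rectify integrate the absolute trace instead of the signed one.
#' @return object of class `activity_summary`: data.frame with `neuron_id`
#'   and `integral`, condition in attribute `"condition"`.
#' @examples
#' ts <- trace_set(matrix(c(0, 1, 0), 1, 3), 10, dff = TRUE)
#' integrate_activity(ts)$integral  # 0.1
#' @export
integrate_activity <- function(dff, window = NULL, rectify = FALSE) {
  stopifnot(inherits(dff, "trace_set"))
  if (!dff$dff) stop_midnet("integrate_activity expects delta-F/F traces")
  window <- window %||% c(0L, ncol(dff$values))
  idx <- window_idx(window, ncol(dff$values))
  if (length(idx) < 2) stop_midnet("window must span at least 2 frames")
  y <- dff$values[, idx, drop = FALSE]
  if (rectify) y <- abs(y)
  dt <- 1 / dff$frame_rate_hz
  integral <- dt * (rowSums(y) - 0.5 * (y[, 1] + y[, ncol(y)]))
  out <- data.frame(neuron_id = dff$neuron_ids, integral = unname(integral),
                    stringsAsFactors = FALSE)
  attr(out, "condition") <- dff$condition
  class(out) <- c("activity_summary", "data.frame")
  out
}

#' Fraction of neurons whose treatment activity falls below baseline
#'
#' In a baseline-vs-treatment scatter of integrated activity, neurons below
#' the unity line were more active at baseline. This returns the fraction of
#' such neurons (ties count as not-below) together with the per-neuron flags.
#'
#' @param base,treat `activity_summary` objects for the two conditions, with
#'   identical neuron sets.
#' @return list with `fraction`, and `flags` (named logical vector:
#'   `TRUE` when treatment < baseline).
#' @export
below_unity_fraction <- function(base, treat) {
  stopifnot(inherits(base, "activity_summary"),
            inherits(treat, "activity_summary"))
  if (!setequal(base$neuron_id, treat$neuron_id) ||
      nrow(base) != nrow(treat)) {
    stop_midnet("baseline and treatment summaries cover different neurons")
  }
  m <- match(base$neuron_id, treat$neuron_id)
  flags <- treat$integral[m] < base$integral
  names(flags) <- base$neuron_id
  list(fraction = mean(flags), flags = flags)
}
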