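#' Spearman functional-connectivity matrix
#'
#' Pairwise Spearman rank correlations of the neurons' traces over the whole
#' (single-condition) window: the rank statistic makes the measure invariant
#' to any strictly monotone transform of the fluorescence, so raw and
#' delta-F/F traces give identical matrices. The result is exactly
#' symmetric with a zero diagonal. A constant (zero-variance) trace leaves
#' its pairs undefined; those entries are set to 0 with a warning naming the
#' neurons, so downstream metrics stay computable.
#'
#' @param traces a [trace_set()] with at least 2 neurons and 3 frames.
#' @return object of class `connectivity_matrix`: list with `rho` (n x n
#'   matrix), `condition`, `div`, `neuron_ids`.
#' @examples
#' ts <- trace_set(rbind(1:5, c(5, 6, 7, 8, 7)), 10, dff = TRUE)
#' functional_connectivity(ts)$rho[1, 2]
#' @export
functional_connectivity <- function(traces) {
  stopifnot(inherits(traces, "trace_set"))
  v <- traces$values
  if (nrow(v) < 2) stop_midnet("need at least 2 neurons")
  if (ncol(v) < 3) stop_midnet("need at least 3 frames")

  const <- apply(v, 1, function(r) max(r) == min(r))
  rho <- suppressWarnings(cor(t(v), method = "spearman"))
  if (any(const)) {
    warning("constant trace(s), correlations set to 0 for neuron(s): ",
            paste(traces$neuron_ids[const], collapse = ", "), call. = FALSE)
  }
  rho[!is.finite(rho)] <- 0
  rho <- (rho + t(rho)) / 2       # exact symmetry
  diag(rho) <- 0
  dimnames(rho) <- list(traces$neuron_ids, traces$neuron_ids)

  structure(
    list(rho = rho, condition = traces$condition, div = traces$div,
         neuron_ids = traces$neuron_ids),
    class = "connectivity_matrix"
  )
}

#' Construct a connectivity matrix from an existing rho matrix
#'
#' For matrices read from file or planted synthetically.
#'
#' @param rho symmetric numeric matrix with entries in `[-1, 1]`.
#' @param condition,div,neuron_ids metadata.
#' @return a `connectivity_matrix`.
#' @export
connectivity_matrix <- function(rho, condition = "baseline",
                                div = NA_integer_, neuron_ids = NULL) {
  rho <- as.matrix(rho)
  stopifnot(nrow(rho) == ncol(rho))
  if (max(abs(rho - t(rho))) > 1e-8) stop_midnet("rho must be symmetric")
  if (any(abs(rho) > 1 + 1e-12)) stop_midnet("rho entries must lie in [-1, 1]")
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 0
  neuron_ids <- neuron_ids %||% rownames(rho) %||%
    sprintf("n%03d", seq_len(nrow(rho)))
  dimnames(rho) <- list(neuron_ids, neuron_ids)
  structure(
    list(rho = rho, condition = condition, div = as.integer(div),
         neuron_ids = neuron_ids),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  ut <- upper.tri(x$rho)
  cat(sprintf(
    "<connectivity_matrix> %d neurons (%s%s), mean rho %.3f, range [%.3f, %.3f]\n",
    nrow(x$rho), x$condition,
    if (is.na(x$div)) "" else sprintf(", DIV %d", x$div),
    mean(x$rho[ut]), min(x$rho[ut]), max(x$rho[ut])))
  invisible(x)
}

#' Heatmap of a connectivity matrix
#'
#' @param x a `connectivity_matrix`.
#' @param ... passed to [graphics::image()].
#' @export
plot.connectivity_matrix <- function(x, ...) {
  n <- nrow(x$rho)
  image(seq_len(n), seq_len(n), t(x$rho[n:1, , drop = FALSE]),
        zlim = c(-1, 1), col = hcl.colors(64, "Blue-Red 3"),
        xlab = "neuron", ylab = "neuron",
        main = sprintf("Spearman rho (%s)", x$condition), ...)
  invisible(x)
}

## Upper-triangle pair index (i < j) of an n x n matrix.
pair_index <- function(n) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
}

new_thresholded_network <- function(weights, threshold, cm) {
  diag(weights) <- 0
  dimnames(weights) <- list(cm$neuron_ids, cm$neuron_ids)
  structure(
    list(weights = weights, threshold = threshold,
         n_edges = sum(weights[upper.tri(weights)] != 0),
         condition = cm$condition, div = cm$div, neuron_ids = cm$neuron_ids),
    class = "thresholded_network"
  )
}

#' Proportional (top-fraction) threshold
#'
#' Retains the strongest `p` fraction of the `n(n-1)/2` unique connections
#' as weighted edges — the scheme used to compare networks of different
#' sizes (default in the pipeline: p = 0.15, the strongest 15\%).
#' "Strongest" defaults to largest signed rho; set `rank_by = "abs"` to rank
#' by magnitude. Exactly `floor(p * E)` edges are kept; ties at the cutoff
#' are broken deterministically by `(i, j)` lexicographic order.
#'
#' @param c a `connectivity_matrix`.
#' @param p fraction in `(0, 1]`.
#' @param rank_by `"signed"` (default) or `"abs"`.
#' @return object of class `thresholded_network` (retained edges keep their
#'   rho values; everything else is 0).
#' @examples
#' cm <- connectivity_matrix(matrix(0.5, 4, 4) - diag(0.5, 4))
#' proportional_threshold(cm, 0.5)$n_edges  # floor(0.5 * 6)
#' @export
proportional_threshold <- function(c, p, rank_by = c("signed", "abs")) {
  stopifnot(inherits(c, "connectivity_matrix"))
  rank_by <- match.arg(rank_by)
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1) {
    stop_midnet("p must lie in (0, 1]")
  }
  n <- nrow(c$rho)
  pi_ <- pair_index(n)
  w <- c$rho[pi_]
  key <- if (rank_by == "signed") -w else -abs(w)
  ord <- order(key, pi_[, 1], pi_[, 2])
  n_keep <- floor(p * nrow(pi_))
  keep <- ord[seq_len(n_keep)]

  weights <- matrix(0, n, n)
  weights[pi_[keep, , drop = FALSE]] <- w[keep]
  weights <- weights + t(weights)
  new_thresholded_network(
    weights, list(mode = "proportional", p = p, rank_by = rank_by), c)
}

#' Absolute correlation threshold
#'
#' Retains edges with signed `rho >= t`.
#'
#' @param c a `connectivity_matrix`.
#' @param t threshold in `(0, 1]`.
#' @return a `thresholded_network`.
#' @export
absolute_threshold <- function(c, t) {
  stopifnot(inherits(c, "connectivity_matrix"))
  if (!is.numeric(t) || length(t) != 1 || t <= 0 || t > 1) {
    stop_midnet("t must lie in (0, 1]")
  }
  weights <- ifelse(c$rho >= t, c$rho, 0)
  new_thresholded_network(weights, list(mode = "absolute", t = t), c)
}

#' Densiometric threshold sweep
#'
#' Network density as a function of an absolute correlation threshold swept
#' from 0.05 to 1 in steps of 0.05 (20 points); density is non-increasing in
#' the threshold by construction.
#'
#' @param c a `connectivity_matrix`.
#' @param thresholds threshold grid (default `seq(0.05, 1, by = 0.05)`).
#' @return data.frame with columns `t` and `density`.
#' @export
density_sweep <- function(c, thresholds = seq(0.05, 1, by = 0.05)) {
  stopifnot(inherits(c, "connectivity_matrix"))
  density <- vapply(thresholds, function(t) {
    network_density(absolute_threshold(c, t))
  }, numeric(1))
  data.frame(t = thresholds, density = density)
}

#' @export
print.thresholded_network <- function(x, ...) {
  n <- nrow(x$weights)
  desc <- if (x$threshold$mode == "proportional") {
    sprintf("top %.0f%%", 100 * x$threshold$p)
  } else {
    sprintf("rho >= %.2f", x$threshold$t)
  }
  cat(sprintf("<thresholded_network> %d nodes, %d edges (%s), density %.3f\n",
              n, x$n_edges, desc, network_density(x)))
  invisible(x)
}

#' Spatial graph plot of a thresholded network
#'
#' Draws retained connections as lines between soma centroids (or a circular
#' layout when no centroids are available).
#'
#' @param x a `thresholded_network`.
#' @param centroids optional 2-column coordinate matrix.
#' @param ... passed to [graphics::plot()].
#' @export
plot.thresholded_network <- function(x, centroids = NULL, ...) {
  n <- nrow(x$weights)
  if (is.null(centroids)) {
    th <- 2 * pi * seq_len(n) / n
    centroids <- cbind(cos(th), sin(th))
  }
  plot(centroids, pch = 16, cex = 0.8, xlab = "x", ylab = "y",
       asp = 1, ...)
  pi_ <- pair_index(n)
  w <- x$weights[pi_]
  for (k in which(w != 0)) {
    segments(centroids[pi_[k, 1], 1], centroids[pi_[k, 1], 2],
             centroids[pi_[k, 2], 1], centroids[pi_[k, 2], 2],
             lwd = 0.5 + 2 * abs(w[k]),
             col = if (w[k] >= 0) "#2166AC88" else "#B2182B88")
  }
  invisible(x)
}
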