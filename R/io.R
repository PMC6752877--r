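#' Read and write trace CSV files
#'
#' Dialect: first column `neuron_id`, remaining columns one frame each,
#' header `neuron_id,f0000,f0001,...`. Floats are written at 17 significant
#' digits so round-trips are exact.
#'
#' @param ts a [trace_set()].
#' @param path CSV path.
#' @return `write_traces_csv()` the path invisibly; `read_traces_csv()` a
#'   [trace_set()].
#' @export
write_traces_csv <- function(ts, path) {
  stopifnot(inherits(ts, "trace_set"))
  n_frames <- ncol(ts$values)
  df <- data.frame(neuron_id = ts$neuron_ids, stringsAsFactors = FALSE)
  vals <- as.data.frame(ts$values)
  names(vals) <- sprintf("f%04d", seq_len(n_frames) - 1)
  write_csv_precise(cbind(df, vals), path)
}

#' @rdname write_traces_csv
#' @param frame_rate_hz,condition,div,dff metadata for the trace set being
#'   read (the CSV stores only values).
#' @export
read_traces_csv <- function(path, frame_rate_hz, condition = "baseline",
                            div = NA_integer_, dff = FALSE) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "neuron_id") {
    stop_midnet("trace CSV must start with a neuron_id column")
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  dimnames(vals) <- NULL
  trace_set(vals, frame_rate_hz = frame_rate_hz, condition = condition,
            div = div, neuron_ids = as.character(df$neuron_id), dff = dff)
}

#' Read and write adjacency (connectivity) matrices as CSV
#'
#' Square matrix with a `neuron_id` header row and column.
#'
#' @param cm a `connectivity_matrix`.
#' @param path CSV path.
#' @export
write_adjacency_csv <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  df <- cbind(data.frame(neuron_id = cm$neuron_ids, stringsAsFactors = FALSE),
              as.data.frame(cm$rho))
  names(df)[-1] <- cm$neuron_ids
  write_csv_precise(df, path)
}

#' @rdname write_adjacency_csv
#' @param condition,div metadata for the matrix being read.
#' @export
read_adjacency_csv <- function(path, condition = "baseline",
                               div = NA_integer_) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df$neuron_id)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  connectivity_matrix(m, condition = condition, div = div, neuron_ids = ids)
}

#' Write a thresholded network as an edge-list CSV
#'
#' Columns `i`, `j`, `weight` (neuron identifiers), one row per retained
#' undirected edge, for interoperability with graph tools.
#'
#' @param net a `thresholded_network`.
#' @param path CSV path.
#' @export
write_edges_csv <- function(net, path) {
  stopifnot(inherits(net, "thresholded_network"))
  n <- nrow(net$weights)
  pi_ <- pair_index(n)
  w <- net$weights[pi_]
  on <- w != 0
  df <- data.frame(i = net$neuron_ids[pi_[on, 1]],
                   j = net$neuron_ids[pi_[on, 2]],
                   weight = w[on], stringsAsFactors = FALSE)
  write_csv_precise(df, path)
}

#' Write topology metrics and community partitions
#'
#' `write_metrics_csv()` takes a list of `topology_metrics` and writes one
#' row per (recording, condition); `write_partition_csv()` writes the
#' `neuron_id, community` table of a single report.
#'
#' @param metrics list of `topology_metrics` objects (or a single one).
#' @param path CSV path.
#' @export
write_metrics_csv <- function(metrics, path) {
  if (inherits(metrics, "topology_metrics")) metrics <- list(metrics)
  rows <- lapply(metrics, as.data.frame)
  write_csv_precise(do.call(rbind, rows), path)
}

#' @rdname write_metrics_csv
#' @export
write_partition_csv <- function(metrics, path) {
  stopifnot(inherits(metrics, "topology_metrics"))
  df <- data.frame(neuron_id = names(metrics$partition) %||%
                     seq_along(metrics$partition),
                   community = as.integer(metrics$partition),
                   stringsAsFactors = FALSE)
  write_csv_precise(df, path)
}

#' Write a pair-deviation table and its summary
#'
#' @param dset a `pair_deviation_set`.
#' @param path CSV path for the per-pair table.
#' @export
write_deviations_csv <- function(dset, path) {
  stopifnot(inherits(dset, "pair_deviation_set"))
  write_csv_precise(as.data.frame(dset), path)
}

#' @rdname write_deviations_csv
#' @param stats a `deviation_stats` object.
#' @export
write_deviation_summary_json <- function(stats, path) {
  stopifnot(inherits(stats, "deviation_stats"))
  jsonlite::write_json(
    list(n = stats$n, mean = stats$mean, skewness_g1 = stats$skewness_g1,
         kurtosis_g2 = stats$kurtosis_g2, ks_p = stats$ks_p,
         wilcoxon_p = stats$wilcoxon_p),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
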