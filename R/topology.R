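## Nonnegative weight matrix for the weighted metrics. Negative correlations
## that survive a permissive threshold are clipped to 0 (with a message) —
## the weighted clustering/modularity formulas require nonnegative weights.
nonneg_weights <- function(net, clip = TRUE) {
  W <- if (inherits(net, "thresholded_network")) net$weights else as.matrix(net)
  if (any(W < 0)) {
    if (!clip) stop_midnet("negative edge weights encountered")
    message(sprintf("clipping %d negative edge weight(s) to 0",
                    sum(W[upper.tri(W)] < 0)))
    W[W < 0] <- 0
  }
  diag(W) <- 0
  W
}

#' Network density
#'
#' Fraction of realised connections out of all `n(n-1)/2` possible unique
#' pairs (self-connections excluded).
#'
#' @param net a `thresholded_network` (or square weight matrix).
#' @return density in `[0, 1]`.
#' @export
network_density <- function(net) {
  W <- if (inherits(net, "thresholded_network")) net$weights else as.matrix(net)
  n <- nrow(W)
  if (n < 2) stop_midnet("need at least 2 nodes")
  sum(W[upper.tri(W)] != 0) / (n * (n - 1) / 2)
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per-node fraction of closed triangles, generalised to weighted graphs by
#' the Onnela geometric-mean form: weights are scaled by the global maximum,
#' and `C_i = sum_{j!=h} (w'_ij w'_ih w'_jh)^(1/3) / (k_i (k_i - 1))` with
#' `k_i` the binary degree. Nodes with fewer than two neighbours get 0. On
#' 0/1 weights this reduces to the binary triangle fraction. Negative
#' weights are clipped to 0 first.
#'
#' @param net a `thresholded_network` (or square weight matrix).
#' @return list with `per_node` (named vector in `[0, 1]`) and `mean`.
#' @export
clustering_coefficient <- function(net) {
  W <- nonneg_weights(net)
  n <- nrow(W)
  k <- rowSums(W > 0)
  mx <- max(W)
  per_node <- numeric(n)
  if (mx > 0) {
    Wh <- (W / mx)^(1 / 3)
    tri <- diag(Wh %*% Wh %*% Wh)   # = sum over ordered (j, h) of geometric means
    elig <- k >= 2
    per_node[elig] <- tri[elig] / (k[elig] * (k[elig] - 1))
  }
  names(per_node) <- rownames(W) %||% as.character(seq_len(n))
  list(per_node = per_node, mean = mean(per_node))
}

#' Weighted modularity Q of a given partition
#'
#' `Q = (1/2m) * sum_ij [w_ij - gamma * s_i s_j / (2m)] * delta(c_i, c_j)`
#' with `s` the node strengths and `2m` the total weight (both matrix
#' halves). This is the quantity community detection maximises; it is also
#' useful standalone to score a known partition.
#'
#' @param net a `thresholded_network` or square nonnegative weight matrix.
#' @param membership integer/character community label per node.
#' @param gamma resolution parameter (default 1).
#' @return scalar Q.
#' @export
modularity_q <- function(net, membership, gamma = 1) {
  W <- nonneg_weights(net)
  n <- nrow(W)
  stopifnot(length(membership) == n)
  m2 <- sum(W)
  if (m2 == 0) stop_midnet("modularity undefined on an edgeless network")
  s <- rowSums(W)
  same <- outer(membership, membership, "==")
  sum((W - gamma * outer(s, s) / m2) * same) / m2
}

#' Community detection by seeded Louvain with restarts
#'
#' Runs the Louvain algorithm (via igraph) `restarts` times under a derived
#' seed stream and keeps the partition with the highest [modularity_q()].
#' Deterministic given `seed`.
#'
#' @param net a `thresholded_network` or square nonnegative weight matrix.
#' @param gamma resolution parameter (default 1).
#' @param restarts number of independent runs (default 10).
#' @param seed RNG seed (default 1).
#' @return list with `partition` (integer labels, named) and `q`.
#' @export
community_louvain <- function(net, gamma = 1, restarts = 10, seed = 1) {
  W <- nonneg_weights(net)
  if (sum(W) == 0) stop_midnet("modularity undefined on an edgeless network")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best_q <- -Inf
  best <- NULL
  for (r in seq_len(restarts)) {
    cl <- with_seed(derive_seed(seed, 404, r),
                    igraph::cluster_louvain(g, resolution = gamma))
    mem <- igraph::membership(cl)
    q <- modularity_q(W, as.integer(mem), gamma = gamma)
    if (q > best_q) {
      best_q <- q
      best <- as.integer(mem)
    }
  }
  names(best) <- rownames(W)
  list(partition = best, q = best_q)
}

#' Modularity index of a thresholded network
#'
#' Finds a community partition with [community_louvain()] and reports its
#' modularity Q (the existence and strength of subnetworks within the larger
#' network). Errors on an edgeless network, where Q is undefined.
#'
#' @inheritParams community_louvain
#' @return list with `partition`, `q`, `n_communities`.
#' @examples
#' W <- matrix(0, 8, 8)
#' W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
#' modularity(W, seed = 1)$q  # 0.5
#' @export
modularity <- function(net, gamma = 1, restarts = 10, seed = 1) {
  res <- community_louvain(net, gamma = gamma, restarts = restarts, seed = seed)
  res$n_communities <- length(unique(res$partition))
  res
}

#' Strength assortativity of a weighted network
#'
#' Pearson correlation of endpoint node strengths over the edge list, each
#' undirected edge contributing both orientations (strength = sum of
#' incident weights). Positive values mean strongly connected neurons attach
#' to other strongly connected neurons (resilient topology); negative values
#' indicate hub-and-spoke mixing. When the endpoint strengths have zero
#' variance (e.g. regular graphs) the measure is undefined and `NA` is
#' returned with attribute `undefined = TRUE`. `variant = "degree"` uses
#' binary degrees instead of strengths.
#'
#' @param net a `thresholded_network` or square nonnegative weight matrix.
#' @param variant `"strength"` (default) or `"degree"`.
#' @return scalar in `[-1, 1]`, or flagged `NA` when undefined.
#' @examples
#' star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
#' assortativity_strength(star)  # -1
#' @export
assortativity_strength <- function(net, variant = c("strength", "degree")) {
  variant <- match.arg(variant)
  W <- nonneg_weights(net)
  n <- nrow(W)
  pi_ <- pair_index(n)
  edges <- pi_[W[pi_] != 0, , drop = FALSE]
  if (nrow(edges) < 2) stop_midnet("need at least 2 edges")
  s <- if (variant == "strength") rowSums(W) else rowSums(W > 0)
  x <- c(s[edges[, 1]], s[edges[, 2]])
  y <- c(s[edges[, 2]], s[edges[, 1]])
  if (var(x) == 0 || var(y) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  cor(x, y)
}

#' Full topology report for one thresholded network
#'
#' Computes density, Onnela clustering, Louvain modularity Q and strength
#' assortativity, recording the configuration for provenance. Degenerate
#' networks do not abort: an edgeless network reports density 0, clustering
#' 0, modularity as flagged-missing and assortativity as undefined.
#'
#' @param net a `thresholded_network`.
#' @param gamma,restarts,seed community-detection options, see
#'   [community_louvain()].
#' @param assortativity_variant `"strength"` or `"degree"`.
#' @return object of class `topology_metrics`.
#' @export
topology_report <- function(net, gamma = 1, restarts = 10, seed = 1,
                            assortativity_variant = "strength") {
  stopifnot(inherits(net, "thresholded_network"))
  flags <- character(0)
  if (any(net$weights < 0)) flags <- c(flags, "negative_weights_clipped")
  dens <- network_density(net)
  cc <- suppressMessages(clustering_coefficient(net))

  mod <- tryCatch(
    suppressMessages(modularity(net, gamma = gamma, restarts = restarts,
                                seed = seed)),
    error = function(e) {
      flags <<- c(flags, "modularity_undefined")
      list(partition = rep(NA_integer_, nrow(net$weights)), q = NA_real_,
           n_communities = NA_integer_)
    })

  assort <- tryCatch(
    suppressMessages(assortativity_strength(net, variant = assortativity_variant)),
    error = function(e) structure(NA_real_, undefined = TRUE))
  if (isTRUE(attr(assort, "undefined"))) {
    flags <- c(flags, "assortativity_undefined")
  }

  structure(
    list(density = dens,
         clustering_per_node = cc$per_node, clustering_mean = cc$mean,
         modularity_q = mod$q, partition = mod$partition,
         n_communities = mod$n_communities,
         assortativity_r = as.numeric(assort),
         condition = net$condition, div = net$div,
         flags = flags,
         config = list(threshold = net$threshold, gamma = gamma,
                       restarts = restarts, seed = seed,
                       assortativity_variant = assortativity_variant)),
    class = "topology_metrics"
  )
}

#' @export
print.topology_metrics <- function(x, ...) {
  cat("<topology_metrics>", x$condition,
      if (!is.na(x$div)) sprintf("DIV %d", x$div), "\n")
  cat(sprintf("  density %.4f | clustering %.4f | Q %.4f (%s communities) | assortativity %s\n",
              x$density, x$clustering_mean,
              if (is.na(x$modularity_q)) NA else x$modularity_q,
              x$n_communities,
              if (is.na(x$assortativity_r)) "undefined"
              else sprintf("%.4f", x$assortativity_r)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.topology_metrics <- function(x, ...) {
  data.frame(
    div = x$div, condition = x$condition,
    p = x$config$threshold$p %||% NA_real_,
    density = x$density, clustering_mean = x$clustering_mean,
    modularity_q = x$modularity_q, n_communities = x$n_communities,
    assortativity_r = x$assortativity_r,
    flags = paste(x$flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}
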