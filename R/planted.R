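#' Planted-structure weighted networks
#'
#' Ground-truth generators for recovery tests of the topology metrics.
#' Three presets:
#' \describe{
#'   \item{`"assortative"`}{disjoint cliques of increasing size with unit
#'     weights: every edge joins two equal-strength nodes, so endpoint
#'     strengths correlate positively across cliques of different sizes.}
#'   \item{`"disassortative"`}{hub-and-spoke mixing with unit weights
#'     (`hubs = 1` gives the pure star, whose strength assortativity is
#'     exactly -1).}
#'   \item{`"modular"`}{`k` dense blocks with within-block weights
#'     U(0.5, 1); each between-block pair carries a weak U(0, 0.3) edge with
#'     probability `p_between` (0 leaves the blocks as disconnected
#'     components).}
#' }
#'
#' @param n number of nodes, at least 8.
#' @param structure `"assortative"`, `"disassortative"`, or `"modular"`.
#' @param k number of planted blocks for `"modular"` (default 3).
#' @param p_between between-block edge probability for `"modular"`.
#' @param hubs number of hubs for `"disassortative"` (default 1).
#' @param seed RNG seed for the random weights (modular preset).
#' @return symmetric n x n weight matrix with zero diagonal, weights in
#'   `[0, 1]`, and attribute `"membership"` (planted block labels for the
#'   modular preset).
#' @examples
#' W <- generate_planted_network(12, "modular", k = 2, p_between = 0)
#' table(attr(W, "membership"))
#' @export
generate_planted_network <- function(n,
                                     structure = c("assortative",
                                                   "disassortative",
                                                   "modular"),
                                     k = 3, p_between = 0.1, hubs = 1,
                                     seed = 1) {
  structure <- match.arg(structure)
  n <- as.integer(n)
  if (n < 8) stop_midnet("n must be at least 8")
  W <- matrix(0, n, n)

  if (structure == "assortative") {
    ## cliques of strictly increasing size covering n nodes
    sizes <- clique_sizes(n)
    stop_at <- cumsum(sizes)
    start_at <- c(1L, head(stop_at, -1) + 1L)
    for (b in seq_along(sizes)) {
      idx <- start_at[b]:stop_at[b]
      W[idx, idx] <- 1
    }
    diag(W) <- 0
  } else if (structure == "disassortative") {
    hubs <- max(1L, as.integer(hubs))
    if (hubs >= n) stop_midnet("need more leaves than hubs")
    leaf <- (hubs + 1):n
    hub_of <- rep_len(seq_len(hubs), length(leaf))
    W[cbind(hub_of, leaf)] <- 1
    W <- W + t(W)
  } else {
    membership <- sort(rep_len(seq_len(k), n))
    same <- outer(membership, membership, "==")
    pi_ <- pair_index(n)
    w <- with_seed(derive_seed(seed, 505), {
      within <- same[pi_]
      out <- numeric(nrow(pi_))
      out[within] <- runif(sum(within), 0.5, 1)
      between_on <- !within & runif(nrow(pi_)) < p_between
      out[between_on] <- runif(sum(between_on), 0, 0.3)
      out
    })
    W[pi_] <- w
    W <- W + t(W)
    attr(W, "membership") <- membership
  }
  W
}

## Partition n into at least two strictly increasing clique sizes (>= 3).
clique_sizes <- function(n) {
  sizes <- integer(0)
  s <- 3L
  left <- n
  while (left >= s + (s + 1)) {   # keep room for one larger final clique
    sizes <- c(sizes, s)
    left <- left - s
    s <- s + 1L
  }
  c(sizes, left)
}
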