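# Shared fixtures, built in code at test time.

# Two 4-cliques with unit weights and no inter-clique edges.
two_cliques <- function() {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  diag(W) <- 0
  W
}

# Two 4-cliques joined by a single bridge edge.
bridged_cliques <- function() {
  W <- two_cliques()
  W[4, 5] <- W[5, 4] <- 1
  W
}

unit_star <- function(n) {
  W <- matrix(0, n, n)
  W[1, 2:n] <- 1
  W + t(W)
}

unit_ring <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    W[i, j] <- W[j, i] <- 1
  }
  W
}

# Random symmetric weight matrix with distinct positive weights.
random_weight_matrix <- function(n, seed) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  W[ut] <- sample(seq_len(sum(ut))) / (sum(ut) + 1)
  W + t(W)
}

# Random symmetric rho-like matrix with values in [-1, 1].
random_rho_matrix <- function(n, seed) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  W[ut] <- runif(sum(ut), -1, 1)
  W <- W + t(W)
  diag(W) <- 0
  W
}

# Simulate one paired recording and return both condition connectivity
# matrices plus the pieces the comparison tests need.
paired_recording <- function(spec, treatment = "meth") {
  ex <- simulate_experiment(spec, treatment)
  dff <- normalize_dff(ex$raw, ex$baseline_window)
  base <- window_traces(dff, ex$baseline_window, "baseline")
  treat <- window_traces(dff, ex$treatment_window, "treatment")
  list(
    labels = ex$labels,
    dff_base = base, dff_treat = treat,
    cm_base = suppressWarnings(functional_connectivity(base)),
    cm_treat = suppressWarnings(functional_connectivity(treat)),
    act_base = integrate_activity(base),
    act_treat = integrate_activity(treat)
  )
}
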