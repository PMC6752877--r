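# Independent brute-force oracles, deliberately written from the definitions
# (explicit ranking, explicit loops) rather than through the package's code
# paths or the library routines the package calls.

oracle_avg_rank <- function(v) {
  vapply(v, function(a) sum(v < a) + (sum(v == a) + 1) / 2, numeric(1))
}

oracle_pearson <- function(a, b) {
  da <- a - mean(a); db <- b - mean(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_avg_rank(x), oracle_avg_rank(y))
}

oracle_spearman_matrix <- function(values) {
  n <- nrow(values)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <- oracle_spearman(values[i, ], values[j, ])
    }
  }
  out
}

oracle_onnela <- function(W) {
  n <- nrow(W)
  C <- numeric(n)
  mx <- max(W)
  if (mx == 0) return(C)
  Wh <- W / mx
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          acc <- acc + (Wh[i, j] * Wh[i, h] * Wh[j, h])^(1 / 3)
        }
      }
    }
    C[i] <- acc / (k * (k - 1))
  }
  C
}

oracle_assortativity <- function(W, use_strength = TRUE) {
  n <- nrow(W)
  s <- if (use_strength) rowSums(W) else rowSums(W > 0)
  xs <- c(); ys <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (W[i, j] != 0) {
        xs <- c(xs, s[i], s[j])
        ys <- c(ys, s[j], s[i])
      }
    }
  }
  oracle_pearson(xs, ys)
}

oracle_modularity_q <- function(W, membership, gamma = 1) {
  n <- nrow(W)
  m2 <- sum(W)
  s <- rowSums(W)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + W[i, j] - gamma * s[i] * s[j] / m2
      }
    }
  }
  q / m2
}

# All set partitions of n elements as restricted-growth label vectors.
all_partitions <- function(n) {
  res <- list()
  rec <- function(labels, mx) {
    if (length(labels) == n) {
      res[[length(res) + 1]] <<- labels
      return(invisible(NULL))
    }
    for (l in seq_len(mx + 1)) rec(c(labels, l), max(mx, l))
  }
  rec(integer(0), 0L)
  res
}

oracle_best_partition <- function(W, gamma = 1) {
  best_q <- -Inf
  best <- NULL
  for (p in all_partitions(nrow(W))) {
    q <- oracle_modularity_q(W, p, gamma)
    if (q > best_q) {
      best_q <- q
      best <- p
    }
  }
  list(q = best_q, partition = best)
}
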