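test_that("Spearman connectivity matches rank arithmetic on known pairs", {
  # strictly increasing map of the same ranks -> rho = 1
  ts <- trace_set(rbind(1:6, 2 * (1:6) + 1), 10, dff = TRUE)
  expect_equal(functional_connectivity(ts)$rho[1, 2], 1)

  # rank reversal -> rho = -1
  ts <- trace_set(rbind(1:6, -(1:6)), 10, dff = TRUE)
  expect_equal(functional_connectivity(ts)$rho[1, 2], -1)

  # tied ranks, frozen value computed with the average-rank Pearson oracle
  x <- c(1, 2, 3, 4, 5)
  y <- c(5, 6, 7, 8, 7)
  expect_equal(oracle_spearman(x, y), 0.8207826816681233, tolerance = 1e-15)
  ts <- trace_set(rbind(x, y), 10, dff = TRUE)
  expect_equal(functional_connectivity(ts)$rho[1, 2], 0.8207826816681233,
               tolerance = 1e-12)
})

test_that("connectivity matrices are exactly symmetric with zero diagonal", {
  spec <- sim_spec(n_neurons = 12, seed = 21)
  ts <- spikes_to_fluorescence(simulate_spikes(spec, "baseline"), spec)
  cm <- functional_connectivity(ts)
  expect_identical(cm$rho, t(cm$rho))
  expect_true(all(diag(cm$rho) == 0))
  expect_true(all(abs(cm$rho) <= 1))
})

test_that("connectivity is invariant under strictly monotone transforms", {
  set.seed(31)
  v <- matrix(runif(8 * 50, 1, 2), 8, 50)
  cm <- functional_connectivity(trace_set(v, 10, dff = TRUE))
  warped <- v
  warped[1:4, ] <- exp(v[1:4, ])      # increasing maps preserve ranks
  warped[5:8, ] <- v[5:8, ]^3 + 10 * v[5:8, ]
  cm2 <- functional_connectivity(trace_set(warped, 10, dff = TRUE))
  expect_equal(cm2$rho, cm$rho, tolerance = 1e-12)
})

test_that("connectivity matches the brute-force oracle to 1e-12", {
  for (sd_ in 1:3) {
    set.seed(sd_)
    v <- matrix(sample(1:5, 6 * 10, replace = TRUE) + runif(60), 6, 10)
    cm <- functional_connectivity(trace_set(v, 10, dff = TRUE))
    expect_equal(unname(cm$rho), oracle_spearman_matrix(v), tolerance = 1e-12)
  }
})

test_that("constant traces produce zeroed correlations with a warning", {
  v <- rbind(rep(1, 10), 1:10, 10:1)
  expect_warning(
    cm <- functional_connectivity(trace_set(v, 10, neuron_ids = c("flat", "a", "b"),
                                            dff = TRUE)),
    "flat")
  expect_true(all(cm$rho["flat", ] == 0))
  expect_equal(cm$rho["a", "b"], -1)
})

test_that("proportional threshold keeps exactly floor(p*E) strongest edges", {
  # 5-node matrix with distinct weights, p = 0.2 -> the two largest of 10
  rho <- random_rho_matrix(5, seed = 5)
  cm <- connectivity_matrix(rho)
  net <- proportional_threshold(cm, 0.2)
  expect_equal(net$n_edges, 2)
  kept <- sort(net$weights[upper.tri(net$weights)][net$weights[upper.tri(net$weights)] != 0],
               decreasing = TRUE)
  expect_equal(kept, sort(rho[upper.tri(rho)], decreasing = TRUE)[1:2])

  # p = 1 retains everything
  expect_equal(network_density(proportional_threshold(cm, 1)), 1)

  # exact density floor(p*E)/E for distinct weights, n = 100
  cm100 <- connectivity_matrix(random_rho_matrix(100, seed = 6))
  net100 <- proportional_threshold(cm100, 0.15)
  expect_identical(network_density(net100), floor(0.15 * 4950) / 4950)

  expect_error(proportional_threshold(cm, 0), "p must")
  expect_error(proportional_threshold(cm, 1.2), "p must")
})

test_that("threshold ties break deterministically and abs ranking works", {
  rho <- matrix(0.5, 4, 4); diag(rho) <- 0
  rho[1, 4] <- rho[4, 1] <- -0.9
  cm <- connectivity_matrix(rho)
  # all remaining candidates tie at 0.5: lexicographic (i, j) order wins
  net <- proportional_threshold(cm, 1 / 3)  # floor(6/3) = 2 edges
  expect_equal(net$n_edges, 2)
  expect_equal(net$weights[1, 2], 0.5)
  expect_equal(net$weights[1, 3], 0.5)
  # magnitude ranking promotes the strong negative edge
  net_abs <- proportional_threshold(cm, 1 / 6, rank_by = "abs")
  expect_equal(net_abs$weights[1, 4], -0.9)
})

test_that("absolute threshold retains signed rho >= t", {
  rho <- matrix(0, 4, 4)
  rho[1, 2] <- rho[2, 1] <- 0.8
  rho[1, 3] <- rho[3, 1] <- 0.5
  rho[3, 4] <- rho[4, 3] <- -0.7
  cm <- connectivity_matrix(rho)
  net <- absolute_threshold(cm, 0.5)
  expect_equal(net$n_edges, 2)        # 0.8 and 0.5; -0.7 excluded (signed)
  expect_equal(network_density(absolute_threshold(cm, 0.95)), 0)

  all_half <- connectivity_matrix(matrix(0.5, 5, 5) - diag(0.5, 5))
  expect_equal(network_density(absolute_threshold(all_half, 0.05)), 1)
})

test_that("density sweep covers the 0.05..1 grid and is non-increasing", {
  zero <- connectivity_matrix(matrix(0, 5, 5))
  sw <- density_sweep(zero)
  expect_equal(nrow(sw), 20)
  expect_equal(sw$t, seq(0.05, 1, by = 0.05))
  expect_true(all(sw$density == 0))

  ones <- connectivity_matrix(matrix(1, 5, 5) - diag(1, 5))
  expect_true(all(density_sweep(ones)$density == 1))

  for (sd_ in 1:10) {
    cm <- connectivity_matrix(random_rho_matrix(15, seed = sd_))
    expect_true(all(diff(density_sweep(cm)$density) <= 0))
  }
})

test_that("adjacency and trace CSV round-trips are exact", {
  spec <- sim_spec(n_neurons = 6, seed = 13)
  ts <- spikes_to_fluorescence(simulate_spikes(spec, "baseline"), spec)
  tp <- tempfile(fileext = ".csv")
  write_traces_csv(ts, tp)
  ts2 <- read_traces_csv(tp, frame_rate_hz = 10)
  expect_equal(ts2$values, ts$values, tolerance = 0)

  cm <- functional_connectivity(ts)
  ap <- tempfile(fileext = ".csv")
  write_adjacency_csv(cm, ap)
  cm2 <- read_adjacency_csv(ap)
  expect_equal(cm2$rho, cm$rho, tolerance = 0)
  unlink(c(tp, ap))
})
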