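test_that("unity deviation is the signed perpendicular distance", {
  rho_b <- random_rho_matrix(6, seed = 1)
  cb <- connectivity_matrix(rho_b, condition = "baseline")
  ct <- connectivity_matrix(rho_b, condition = "treat")
  expect_true(all(unity_deviation(cb, ct)$d == 0))

  rho_t <- rho_b
  rho_t[1, 2] <- rho_t[2, 1] <- rho_b[1, 2] + 1
  ct <- connectivity_matrix(pmin(rho_t, 1), condition = "treat")
  rho_b[1, 2] <- rho_b[2, 1] <- 0
  rho_t[1, 2] <- rho_t[2, 1] <- 1
  dv <- unity_deviation(connectivity_matrix(rho_b), connectivity_matrix(rho_t))
  expect_equal(dv$d[dv$neuron_i == "n001" & dv$neuron_j == "n002"],
               1 / sqrt(2), tolerance = 1e-12)

  # raw-difference scale is sqrt(2) times the perpendicular one
  dv2 <- unity_deviation(connectivity_matrix(rho_b), connectivity_matrix(rho_t),
                         scale = "difference")
  expect_equal(dv2$d, dv$d * sqrt(2), tolerance = 1e-12)

  # mismatched neuron sets abort
  ct_bad <- connectivity_matrix(rho_t, neuron_ids = paste0("x", 1:6))
  expect_error(unity_deviation(connectivity_matrix(rho_b), ct_bad),
               "different neurons")
})

test_that("swapping baseline and treatment negates every deviation", {
  cb <- connectivity_matrix(random_rho_matrix(8, seed = 2))
  ct <- connectivity_matrix(random_rho_matrix(8, seed = 3))
  expect_equal(unity_deviation(ct, cb)$d, -unity_deviation(cb, ct)$d,
               tolerance = 1e-15)
})

test_that("deviation statistics follow the population-moment conventions", {
  # odd symmetry kills g1
  expect_equal(deviation_stats(rep(c(-1, 0, 1), 10))$skewness_g1, 0)

  # fixed 10-value fixture against direct moment computation
  d <- c(0.3, -0.2, 0.5, 1.1, -0.7, 0.05, -0.15, 0.8, -1.2, 0.4)
  st <- deviation_stats(d)
  m <- mean(d); m2 <- mean((d - m)^2)
  expect_equal(st$skewness_g1, mean((d - m)^3) / m2^1.5, tolerance = 1e-14)
  expect_equal(st$kurtosis_g2, mean((d - m)^4) / m2^2 - 3, tolerance = 1e-14)
  # cross-check against e1071's type-1 (population-moment) estimators
  expect_equal(st$skewness_g1, e1071::skewness(d, type = 1), tolerance = 1e-12)
  expect_equal(st$kurtosis_g2, e1071::kurtosis(d, type = 1), tolerance = 1e-12)

  # negation: g1 flips sign, g2 and the Wilcoxon p are invariant
  st_neg <- deviation_stats(-d)
  expect_equal(st_neg$skewness_g1, -st$skewness_g1, tolerance = 1e-14)
  expect_equal(st_neg$kurtosis_g2, st$kurtosis_g2, tolerance = 1e-14)
  expect_equal(st_neg$wilcoxon_p, st$wilcoxon_p, tolerance = 1e-12)

  # zero variance flags the statistics undefined
  st0 <- deviation_stats(rep(0.2, 20))
  expect_true(st0$undefined)
  expect_true(is.na(st0$skewness_g1))

  expect_error(deviation_stats(1:5), "at least 8")
})

test_that("shape statistics are invariant to the deviation-scale choice", {
  spec <- sim_spec(n_neurons = 15, seed = 17)
  rec <- paired_recording(spec, "meth")
  a <- deviation_stats(unity_deviation(rec$cm_base, rec$cm_treat))
  b <- deviation_stats(unity_deviation(rec$cm_base, rec$cm_treat,
                                       scale = "difference"))
  expect_equal(a$skewness_g1, b$skewness_g1, tolerance = 1e-12)
  expect_equal(a$kurtosis_g2, b$kurtosis_g2, tolerance = 1e-12)
  expect_equal(a$ks_p, b$ks_p, tolerance = 1e-9)
  expect_equal(a$wilcoxon_p, b$wilcoxon_p, tolerance = 1e-9)
})

test_that("a large normal sample scores near-zero excess kurtosis and flat KS", {
  set.seed(12)
  d <- rnorm(2e5)
  st <- deviation_stats(d)
  expect_lt(abs(st$kurtosis_g2), 0.05)
  expect_lt(abs(st$skewness_g1), 0.05)
  expect_gt(st$ks_p, 0.01)  # consistent with normality
})

test_that("drug suppression of a subpopulation skews deviations negative", {
  hits <- 0
  for (sd_ in 1:3) {
    spec <- sim_spec(n_neurons = 30, frac_d2 = 0, drug_factor = 0.1,
                     seed = sd_)
    meth <- paired_recording(spec, "meth")
    ctrl <- paired_recording(spec, "baseline")
    g1_meth <- deviation_stats(unity_deviation(meth$cm_base, meth$cm_treat))$skewness_g1
    g1_ctrl <- deviation_stats(unity_deviation(ctrl$cm_base, ctrl$cm_treat))$skewness_g1
    if (g1_meth < g1_ctrl) hits <- hits + 1
    # the dropout mass sits on pairs involving suppressed neurons
    dv <- unity_deviation(meth$cm_base, meth$cm_treat)
    da_ids <- meth$labels$neuron_id[meth$labels$d2]
    on_da <- dv$neuron_i %in% da_ids | dv$neuron_j %in% da_ids
    expect_lt(mean(dv$d[on_da]), mean(dv$d[!on_da]))
  }
  expect_gte(hits, 2)
})

test_that("DIV regression matches closed-form least squares", {
  tr <- div_regression(c(9, 12, 15, 18, 21), 2 * c(9, 12, 15, 18, 21) + 1)
  expect_equal(tr$slope, 2, tolerance = 1e-12)
  expect_equal(tr$r_squared, 1, tolerance = 1e-12)

  flat <- div_regression(c(9, 12, 15), rep(0.4, 3))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  set.seed(44)
  div <- rep(c(9, 12, 15, 21), each = 3)
  y <- 0.9 - 0.02 * div + rnorm(12, 0, 0.05)
  tr <- div_regression(div, y)
  # closed-form OLS oracle
  bx <- sum((div - mean(div)) * (y - mean(y))) / sum((div - mean(div))^2)
  ax <- mean(y) - bx * mean(div)
  yhat <- ax + bx * div
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_equal(tr$slope, bx, tolerance = 1e-10)
  expect_equal(tr$intercept, ax, tolerance = 1e-10)
  expect_equal(tr$r_squared, r2, tolerance = 1e-10)
  se <- sqrt(sum((y - yhat)^2) / 10 / sum((div - mean(div))^2))
  expect_equal(tr$p_value, 2 * pt(-abs(bx / se), df = 10), tolerance = 1e-10)

  expect_error(div_regression(c(9, 9, 9), 1:3), "3 distinct")
})

test_that("mean connectivity averages unique off-diagonal entries", {
  half <- connectivity_matrix(matrix(0.5, 5, 5) - diag(0.5, 5))
  expect_equal(mean_connectivity(half), 0.5)

  anti <- matrix(0, 4, 4)
  anti[1, 2] <- anti[2, 1] <- 0.3
  anti[3, 4] <- anti[4, 3] <- -0.3
  expect_equal(mean_connectivity(connectivity_matrix(anti)), 0)

  rho <- matrix(0, 4, 4)
  vals <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  rho[upper.tri(rho)] <- vals
  rho <- rho + t(rho)
  expect_equal(mean_connectivity(connectivity_matrix(rho)), mean(vals))
})
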