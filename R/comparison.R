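#' Per-pair deviation from the unity line
#'
#' In a scatter of treatment vs baseline correlation for every unique neuron
#' pair, points on the diagonal are unchanged by treatment. The signed
#' perpendicular distance to that unity line,
#' `d = (rho_treat - rho_base) / sqrt(2)`, quantifies which condition each
#' pair favours: positive favours treatment, negative favours baseline.
#' `scale = "difference"` returns the raw difference instead; since the two
#' differ by a constant factor, all shape statistics computed by
#' [deviation_stats()] (skewness, excess kurtosis, KS and Wilcoxon p) are
#' identical under either choice.
#'
#' @param base,treat `connectivity_matrix` objects over the same neurons in
#'   the same order.
#' @param scale `"perpendicular"` (default) or `"difference"`.
#' @return object of class `pair_deviation_set`: data.frame with columns
#'   `neuron_i`, `neuron_j`, `rho_base`, `rho_treat`, `d`.
#' @export
unity_deviation <- function(base, treat,
                            scale = c("perpendicular", "difference")) {
  stopifnot(inherits(base, "connectivity_matrix"),
            inherits(treat, "connectivity_matrix"))
  scale <- match.arg(scale)
  if (!identical(base$neuron_ids, treat$neuron_ids)) {
    stop_midnet("baseline and treatment matrices cover different neurons")
  }
  n <- nrow(base$rho)
  pi_ <- pair_index(n)
  rho_b <- base$rho[pi_]
  rho_t <- treat$rho[pi_]
  d <- (rho_t - rho_b) / if (scale == "perpendicular") sqrt(2) else 1
  out <- data.frame(
    neuron_i = base$neuron_ids[pi_[, 1]],
    neuron_j = base$neuron_ids[pi_[, 2]],
    rho_base = rho_b, rho_treat = rho_t, d = d,
    stringsAsFactors = FALSE
  )
  attr(out, "scale") <- scale
  class(out) <- c("pair_deviation_set", "data.frame")
  out
}

#' Histogram of unity deviations
#'
#' @param x a `pair_deviation_set`.
#' @param breaks passed to [graphics::hist()].
#' @param ... passed to [graphics::hist()].
#' @export
plot.pair_deviation_set <- function(x, breaks = 50, ...) {
  hist(x$d, breaks = breaks, xlab = "deviation from unity",
       main = "baseline vs treatment pair deviations", ...)
  abline(v = 0, col = "red", lwd = 2)
  invisible(x)
}

#' Distribution statistics of unity deviations
#'
#' Summarises the deviation distribution with the Fisher-Pearson moment
#' coefficient of skewness `g1 = m3 / m2^(3/2)`, the excess kurtosis
#' `g2 = m4 / m2^2 - 3` (a normal distribution scores 0), a
#' Kolmogorov-Smirnov test against a normal with the sample's mean and SD
#' (parameters are estimated, so the p-value is approximate in the
#' Lilliefors sense), and a Wilcoxon signed-rank test of median 0 (normal
#' approximation for large n).
#'
#' @param dset a `pair_deviation_set`, or a plain numeric vector of
#'   deviations (at least 8 values).
#' @return object of class `deviation_stats`: list with `n`, `mean`,
#'   `skewness_g1`, `kurtosis_g2`, `ks_p`, `wilcoxon_p`, and `undefined`
#'   (TRUE when the deviations have zero variance, in which case the shape
#'   statistics are `NA`).
#' @examples
#' deviation_stats(rnorm(1000))
#' @export
deviation_stats <- function(dset) {
  d <- if (inherits(dset, "pair_deviation_set")) dset$d else as.numeric(dset)
  if (any(!is.finite(d))) stop_midnet("deviations must be finite")
  n <- length(d)
  if (n < 8) stop_midnet("need at least 8 deviations")
  m <- mean(d)
  m2 <- mean((d - m)^2)
  if (m2 == 0) {
    res <- list(n = n, mean = m, skewness_g1 = NA_real_,
                kurtosis_g2 = NA_real_, ks_p = NA_real_,
                wilcoxon_p = NA_real_, undefined = TRUE)
    class(res) <- "deviation_stats"
    return(res)
  }
  g1 <- mean((d - m)^3) / m2^1.5
  g2 <- mean((d - m)^4) / m2^2 - 3
  ks_p <- suppressWarnings(ks.test(d, "pnorm", m, sqrt(m2 * n / (n - 1))))$p.value
  wilcoxon_p <- suppressWarnings(
    wilcox.test(d, mu = 0, exact = FALSE, correct = TRUE))$p.value
  res <- list(n = n, mean = m, skewness_g1 = g1, kurtosis_g2 = g2,
              ks_p = ks_p, wilcoxon_p = wilcoxon_p, undefined = FALSE)
  class(res) <- "deviation_stats"
  res
}

#' @export
print.deviation_stats <- function(x, ...) {
  cat("<deviation_stats>\n")
  cat(sprintf("  n = %d, mean = %.4g\n", x$n, x$mean))
  if (x$undefined) {
    cat("  zero variance: shape statistics undefined\n")
  } else {
    cat(sprintf("  skewness g1 = %.4f, excess kurtosis g2 = %.4f\n",
                x$skewness_g1, x$kurtosis_g2))
    cat(sprintf("  KS (vs fitted normal) p = %.3g, Wilcoxon signed-rank p = %.3g\n",
                x$ks_p, x$wilcoxon_p))
  }
  invisible(x)
}

#' Linear trend of a network metric across days in vitro
#'
#' Ordinary least-squares regression of a per-recording metric (e.g. mean
#' functional connectivity, assortativity) on culture age, the analysis used
#' to establish the age-dependent connectivity decay. Requires at least 3
#' distinct DIV values. A metric with zero variance yields slope 0 and
#' r-squared 0 with an `NA` p-value.
#'
#' @param div numeric vector of days in vitro.
#' @param value metric values, same length.
#' @param condition label stored with the result.
#' @return object of class `div_trend`: list with `slope` (per day),
#'   `intercept`, `r_squared`, `p_value`, `n`, `condition`.
#' @examples
#' div_regression(c(9, 12, 15, 18, 21), c(0.7, 0.66, 0.61, 0.58, 0.55))
#' @export
div_regression <- function(div, value, condition = NA_character_) {
  stopifnot(length(div) == length(value))
  ok <- is.finite(div) & is.finite(value)
  div <- div[ok]; value <- value[ok]
  if (length(unique(div)) < 3) {
    stop_midnet("need at least 3 distinct DIV values")
  }
  if (var(value) == 0) {
    res <- list(slope = 0, intercept = value[1], r_squared = 0,
                p_value = NA_real_, n = length(div), condition = condition)
  } else {
    fit <- lm(value ~ div)
    sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
    res <- list(slope = unname(coef(fit)[2]),
                intercept = unname(coef(fit)[1]),
                r_squared = sm$r.squared,
                p_value = sm$coefficients[2, 4],
                n = length(div), condition = condition)
  }
  class(res) <- "div_trend"
  res
}

#' @export
print.div_trend <- function(x, ...) {
  cat(sprintf(
    "<div_trend>%s slope %.4g per day, r^2 = %.4g, p = %.3g (n = %d)\n",
    if (is.na(x$condition)) "" else paste0(" ", x$condition),
    x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Mean pairwise functional connectivity
#'
#' Mean of the `n(n-1)/2` unique off-diagonal Spearman correlations — the
#' per-recording scalar regressed against culture age.
#'
#' @param c a `connectivity_matrix`.
#' @return scalar.
#' @export
mean_connectivity <- function(c) {
  stopifnot(inherits(c, "connectivity_matrix"))
  if (nrow(c$rho) < 2) stop_midnet("need at least 2 neurons")
  mean(c$rho[upper.tri(c$rho)])
}
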