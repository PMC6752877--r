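#' Simulate correlated spike trains for one condition window
#'
#' Draws per-neuron spike trains from the multiple-interaction process (MIP)
#' described in [sim_spec()]: each module has a Poisson mother train at rate
#' `base_rate / share_eff`, each member neuron keeps each mother spike with
#' probability `share_eff`, and an optional independent Poisson background
#' (`bg_rate`) is superposed. Under `"meth"` the spikes of D2-positive
#' neurons are thinned by `drug_factor` (suppression); under
#' `"meth+sulpiride"` the factor is `sulpiride_factor` and values above 1 add
#' extra background spikes at `(factor - 1) * base_rate` (activity above
#' baseline under D2 blockade).
#'
#' The draw is deterministic given the spec's `seed`: every module, neuron
#' and condition has its own derived RNG stream.
#'
#' @param spec a [sim_spec()].
#' @param condition one of `"baseline"`, `"meth"`, `"meth+sulpiride"`.
#' @return an object of class `spike_trains`: list with `times` (per-neuron
#'   sorted spike-time vectors, seconds), `labels` (data.frame with
#'   `neuron_id`, `cell_type`, `d2`, `module`), `condition`, `duration_s`.
#' @examples
#' tr <- simulate_spikes(sim_spec(n_neurons = 10, seed = 7), "baseline")
#' lengths(tr$times)
#' @export
simulate_spikes <- function(spec, condition = c("baseline", "meth", "meth+sulpiride")) {
  stopifnot(inherits(spec, "sim_spec"))
  condition <- match.arg(condition)
  ci <- condition_index(condition)
  n <- spec$n_neurons
  dur <- spec$duration_s
  share <- effective_share(spec)

  if (share == 0 && spec$n_modules > 0 && spec$base_rate == 0 && spec$bg_rate == 0) {
    warning("degenerate simulation: no mother process and zero rates; ",
            "no activity will be generated", call. = FALSE)
  }

  labels <- sim_labels(spec)

  ## mother trains, one per module
  mother_rate <- if (share > 0) spec$base_rate / share else 0
  mothers <- lapply(seq_len(spec$n_modules), function(m) {
    with_seed(derive_seed(spec$seed, 101, ci, m), {
      k <- rpois(1, mother_rate * dur)
      sort(runif(k, 0, dur))
    })
  })

  factor_for <- function(i) {
    if (condition == "baseline" || !labels$d2[i]) return(1)
    if (condition == "meth") spec$drug_factor else spec$sulpiride_factor
  }

  times <- vector("list", n)
  for (i in seq_len(n)) {
    times[[i]] <- with_seed(derive_seed(spec$seed, 202, ci, i), {
      mo <- mothers[[labels$module[i]]]
      sp <- if (share > 0 && length(mo)) mo[runif(length(mo)) < share] else numeric(0)
      if (spec$bg_rate > 0) {
        k <- rpois(1, spec$bg_rate * dur)
        sp <- c(sp, runif(k, 0, dur))
      }
      f <- factor_for(i)
      if (f < 1 && length(sp)) sp <- sp[runif(length(sp)) < f]
      if (f > 1) {
        k <- rpois(1, (f - 1) * spec$base_rate * dur)
        sp <- c(sp, runif(k, 0, dur))
      }
      sort(sp)
    })
  }
  names(times) <- labels$neuron_id

  structure(
    list(times = times, labels = labels, condition = condition,
         duration_s = dur),
    class = "spike_trains"
  )
}

## Deterministic cell-type / D2 / module assignment shared by all conditions.
sim_labels <- function(spec) {
  n <- spec$n_neurons
  n_da <- round(spec$frac_da * n)
  cell_type <- c(rep("DA", n_da), rep("GABA", n - n_da))
  d2 <- with_seed(derive_seed(spec$seed, 77), {
    cell_type == "DA" | runif(n) < spec$frac_d2
  })
  module <- rep_len(seq_len(spec$n_modules), n)
  data.frame(
    neuron_id = sprintf("n%03d", seq_len(n)),
    cell_type = cell_type, d2 = d2, module = module,
    stringsAsFactors = FALSE
  )
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("<spike_trains> %d neurons, %s, %g s, %.3g spikes/s mean\n",
              length(x$times), x$condition, x$duration_s,
              mean(lengths(x$times)) / x$duration_s))
  invisible(x)
}

## GCaMP6f response kernel: difference of exponentials normalised to unit
## peak, so one spike contributes amp_per_spike at its peak.
gcamp_kernel <- function(t, tau_rise, tau_decay) {
  t_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise)) / peak
  out
}

#' Forward model: spike trains to GCaMP6f fluorescence traces
#'
#' Each neuron's trace is
#' `F(t) = f0 * (1 + amp_per_spike * sum_s k(t - t_s)) + eps(t)` with `k` the
#' unit-peak difference-of-exponentials kernel and `eps` i.i.d. Gaussian
#' noise, sampled at `frame_rate_hz` (frame times `0, 1/rate, ...`).
#'
#' @param trains a `spike_trains` object from [simulate_spikes()].
#' @param spec the [sim_spec()] that produced it.
#' @return a raw-fluorescence [trace_set()] (neurons x frames).
#' @examples
#' spec <- sim_spec(n_neurons = 5, seed = 3)
#' ts <- spikes_to_fluorescence(simulate_spikes(spec, "baseline"), spec)
#' dim(ts$values)
#' @export
spikes_to_fluorescence <- function(trains, spec) {
  stopifnot(inherits(trains, "spike_trains"), inherits(spec, "sim_spec"))
  n <- length(trains$times)
  n_frames <- as.integer(round(trains$duration_s * spec$frame_rate_hz))
  tt <- (seq_len(n_frames) - 1) / spec$frame_rate_hz

  vals <- matrix(0, nrow = n, ncol = n_frames)
  for (i in seq_len(n)) {
    conv <- numeric(n_frames)
    for (s in trains$times[[i]]) {
      j0 <- floor(s * spec$frame_rate_hz) + 1
      if (j0 > n_frames) next
      idx <- j0:n_frames
      conv[idx] <- conv[idx] +
        gcamp_kernel(tt[idx] - s, spec$tau_rise_s, spec$tau_decay_s)
    }
    vals[i, ] <- spec$f0 * (1 + spec$amp_per_spike * conv)
  }
  if (spec$noise_sd > 0) {
    ci <- condition_index(trains$condition)
    noise <- with_seed(derive_seed(spec$seed, 303, ci),
                       rnorm(n * n_frames, 0, spec$noise_sd))
    vals <- vals + matrix(noise, nrow = n)
  }

  trace_set(vals,
            frame_rate_hz = spec$frame_rate_hz,
            condition = trains$condition,
            div = spec$div,
            neuron_ids = trains$labels$neuron_id,
            dff = FALSE)
}

#' Simulate a paired baseline + treatment recording
#'
#' Emulates one continuous acquisition: a spontaneous-activity baseline
#' window followed by a treatment window (drug added at the window boundary),
#' concatenated into a single raw trace set the way the real recordings are
#' processed (delta-F/F for both windows is referenced to the baseline
#' window).
#'
#' @param spec a [sim_spec()].
#' @param treatment condition of the second window: `"meth"`,
#'   `"meth+sulpiride"`, or `"baseline"` (drug-free control).
#' @return object of class `sim_experiment`: list with `raw` (combined
#'   [trace_set()]), `baseline_window`/`treatment_window` (0-based, half-open
#'   frame ranges), `labels`, `treatment`, `spec`.
#' @examples
#' ex <- simulate_experiment(sim_spec(n_neurons = 12, seed = 5), "meth")
#' ex$treatment_window
#' @export
simulate_experiment <- function(spec,
                                treatment = c("meth", "meth+sulpiride", "baseline")) {
  treatment <- match.arg(treatment)
  base_tr <- simulate_spikes(spec, "baseline")
  base_ts <- spikes_to_fluorescence(base_tr, spec)
  if (treatment == "baseline") {
    ## independent drug-free window: reuse the meth condition stream index
    ## but with factor 1 by temporarily disabling the drug
    spec2 <- spec
    spec2$drug_factor <- 1
    treat_tr <- simulate_spikes(spec2, "meth")
    treat_ts <- spikes_to_fluorescence(treat_tr, spec2)
    treat_ts$condition <- "baseline2"
  } else {
    treat_tr <- simulate_spikes(spec, treatment)
    treat_ts <- spikes_to_fluorescence(treat_tr, spec)
  }
  n_frames <- ncol(base_ts$values)
  raw <- trace_set(cbind(base_ts$values, treat_ts$values),
                   frame_rate_hz = spec$frame_rate_hz,
                   condition = "paired",
                   div = spec$div,
                   neuron_ids = base_tr$labels$neuron_id,
                   dff = FALSE)
  structure(
    list(raw = raw,
         baseline_window = c(0L, n_frames),
         treatment_window = c(n_frames, 2L * n_frames),
         labels = base_tr$labels,
         treatment = treatment,
         spec = spec),
    class = "sim_experiment"
  )
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("<sim_experiment> %d neurons, baseline + %s, DIV %d\n",
              nrow(x$raw$values), x$treatment, x$spec$div))
  invisible(x)
}

#' Mean functional connectivity across simulated culture ages
#'
#' Convenience sweep for the age-dependence analysis: simulates one
#' drug-free recording per DIV value, computes its baseline-window Spearman
#' connectivity, and returns the per-recording mean pairwise correlation.
#'
#' @param spec a [sim_spec()]; its `div` field is overridden per point.
#' @param divs integer vector of days in vitro.
#' @param seeds optional vector of seeds, one per DIV (defaults to
#'   `spec$seed + 0:(length(divs)-1)`).
#' @return data.frame with columns `div`, `seed`, `mean_rho`.
#' @export
simulate_div_series <- function(spec, divs = c(9, 12, 15, 18, 21), seeds = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  seeds <- seeds %||% (spec$seed + seq_along(divs) - 1)
  stopifnot(length(seeds) == length(divs))
  rows <- lapply(seq_along(divs), function(k) {
    sp <- spec
    sp$div <- as.integer(divs[k])
    sp$seed <- as.integer(seeds[k])
    ts <- spikes_to_fluorescence(simulate_spikes(sp, "baseline"), sp)
    dff <- normalize_dff(ts, f0_window = c(0L, ncol(ts$values)))
    cm <- suppressWarnings(functional_connectivity(dff))
    data.frame(div = divs[k], seed = seeds[k], mean_rho = mean_connectivity(cm))
  })
  do.call(rbind, rows)
}
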