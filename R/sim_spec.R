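#' Simulation specification for a synthetic midbrain culture
#'
#' Bundles every knob of the synthetic spiking/GCaMP6f model into one
#' validated object. The defaults emulate the study conditions of a cultured
#' ventral-midbrain network: ~12\% dopaminergic neurons with the remainder
#' GABAergic, 2-minute condition windows imaged at 10 Hz, D2-receptor-mediated
#' activity suppression under methamphetamine (reversed and overshot by
#' sulpiride), and a per-day decay of correlated firing that reproduces the
#' sign of the age-dependent connectivity loss.
#'
#' Spike correlations are planted with a multiple-interaction process (MIP):
#' each module owns a Poisson "mother" train at rate
#' `base_rate / within_module_share`, and each member neuron keeps each mother
#' spike independently with probability `within_module_share`, which makes the
#' pairwise spike-count correlation of two members equal to
#' `within_module_share` while keeping Poisson marginals at `base_rate`.
#' Culture age enters through
#' `share_eff = within_module_share * div_decay^(div - 9)` (day 9 is the first
#' recording day of the emulated study).
#'
#' @param n_neurons number of neurons per recording (default 35, a typical
#'   single-field-of-view count).
#' @param frac_da fraction of dopaminergic neurons (default 0.12).
#' @param frac_d2 probability that a GABAergic neuron expresses D2 receptors
#'   (default 1); dopaminergic neurons are always D2-positive (autoreceptors).
#' @param n_modules number of correlated modules (default 1: cultured
#'   networks at these ages burst near-globally, which is what the high mean
#'   pairwise correlations of real recordings reflect).
#' @param within_module_share copy probability of the MIP; equals the planted
#'   pairwise spike-count correlation within a module. In `[0, 1]`. The
#'   default 0.7 reproduces the observed regime of mean baseline Spearman
#'   correlations around 0.6-0.7 in young cultures.
#' @param base_rate mean firing rate per neuron, spikes/s.
#' @param bg_rate additional uncorrelated background rate, spikes/s
#'   (default 0: the per-neuron rate is then exactly `base_rate`).
#' @param duration_s length of one condition window, seconds (default 120).
#' @param dt_s nominal simulation resolution, seconds; must not exceed one
#'   frame interval. Spike times are drawn in continuous time; `dt_s` only
#'   bounds the temporal granularity guaranteed by the generator.
#' @param frame_rate_hz output sampling rate, Hz (default 10).
#' @param tau_rise_s,tau_decay_s GCaMP6f kernel time constants, seconds
#'   (defaults 0.1 and 0.6, literature-typical for GCaMP6f).
#' @param amp_per_spike peak delta-F/F contributed by one isolated spike
#'   (the kernel is normalised to unit peak).
#' @param f0 baseline fluorescence, arbitrary units, strictly positive.
#' @param noise_sd SD of additive Gaussian fluorescence noise (same units
#'   as `f0`).
#' @param drug_factor multiplicative rate factor applied to D2-positive
#'   neurons during a `"meth"` window (default 0.5, suppression).
#' @param sulpiride_factor rate factor for the `"meth+sulpiride"` preset
#'   (default 1.2: D2 blockade abolishes the suppression and pushes activity
#'   above baseline).
#' @param div days in vitro of the simulated culture (default 11).
#' @param div_decay per-day multiplicative decay of `within_module_share`
#'   (default 0.97), emulating the age-dependent loss of functional
#'   connectivity.
#' @param seed root RNG seed; all child streams are derived from it.
#'
#' @return an object of class `sim_spec` (a validated named list).
#' @seealso [simulate_spikes()], [spikes_to_fluorescence()],
#'   [simulate_experiment()]
#' @examples
#' spec <- sim_spec(n_neurons = 20, seed = 42)
#' spec
#' @export
sim_spec <- function(n_neurons = 35,
                     frac_da = 0.12,
                     frac_d2 = 1.0,
                     n_modules = 1,
                     within_module_share = 0.7,
                     base_rate = 0.5,
                     bg_rate = 0,
                     duration_s = 120,
                     dt_s = 0.01,
                     frame_rate_hz = 10,
                     tau_rise_s = 0.1,
                     tau_decay_s = 0.6,
                     amp_per_spike = 0.4,
                     f0 = 100,
                     noise_sd = 0.5,
                     drug_factor = 0.5,
                     sulpiride_factor = 1.2,
                     div = 11,
                     div_decay = 0.97,
                     seed = 1) {
  spec <- list(
    n_neurons = as.integer(n_neurons), frac_da = frac_da, frac_d2 = frac_d2,
    n_modules = as.integer(n_modules),
    within_module_share = within_module_share,
    base_rate = base_rate, bg_rate = bg_rate,
    duration_s = duration_s, dt_s = dt_s, frame_rate_hz = frame_rate_hz,
    tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
    amp_per_spike = amp_per_spike, f0 = f0, noise_sd = noise_sd,
    drug_factor = drug_factor, sulpiride_factor = sulpiride_factor,
    div = as.integer(div), div_decay = div_decay, seed = as.integer(seed)
  )
  class(spec) <- "sim_spec"
  validate_sim_spec(spec)
}

validate_sim_spec <- function(spec) {
  with(spec, {
    if (!is_count(n_neurons) || n_neurons < 1) {
      stop_midnet("n_neurons must be a positive integer")
    }
    for (nm in c("frac_da", "frac_d2", "within_module_share")) {
      if (!is_fraction(spec[[nm]])) {
        stop_midnet(nm, " must lie in [0, 1]")
      }
    }
    if (!is_count(n_modules) || n_modules < 1) {
      stop_midnet("n_modules must be a positive integer")
    }
    if (base_rate < 0 || bg_rate < 0) stop_midnet("rates must be nonnegative")
    if (duration_s <= 0) stop_midnet("duration_s must be positive")
    n_frames <- duration_s * frame_rate_hz
    if (abs(n_frames - round(n_frames)) > 1e-9) {
      stop_midnet("duration_s * frame_rate_hz must be an integer frame count")
    }
    if (frame_rate_hz <= 0) stop_midnet("frame_rate_hz must be positive")
    if (dt_s <= 0 || dt_s > 1 / frame_rate_hz + 1e-12) {
      stop_midnet("dt_s must be positive and at most one frame interval")
    }
    if (!(tau_decay_s > tau_rise_s && tau_rise_s > 0)) {
      stop_midnet("need tau_decay_s > tau_rise_s > 0")
    }
    if (f0 <= 0) stop_midnet("f0 must be strictly positive")
    if (noise_sd < 0) stop_midnet("noise_sd must be nonnegative")
    if (drug_factor < 0 || sulpiride_factor < 0) {
      stop_midnet("drug factors must be nonnegative")
    }
    if (div_decay < 0) stop_midnet("div_decay must be nonnegative")
  })
  spec
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("<sim_spec>\n")
  cat(sprintf("  %d neurons (%.0f%% DA, %d modules), DIV %d\n",
              x$n_neurons, 100 * x$frac_da, x$n_modules, x$div))
  cat(sprintf("  rate %.3g Hz, share %.3g (div_decay %.3g), %g s at %g Hz\n",
              x$base_rate, x$within_module_share, x$div_decay,
              x$duration_s, x$frame_rate_hz))
  cat(sprintf("  kernel rise/decay %.3g/%.3g s, amp %.3g, f0 %.3g, noise %.3g\n",
              x$tau_rise_s, x$tau_decay_s, x$amp_per_spike, x$f0, x$noise_sd))
  cat(sprintf("  drug_factor %.3g, sulpiride_factor %.3g, seed %d\n",
              x$drug_factor, x$sulpiride_factor, x$seed))
  invisible(x)
}

## Effective within-module copy probability after culture-age decay.
effective_share <- function(spec) {
  s <- spec$within_module_share * spec$div_decay^(spec$div - 9)
  min(max(s, 0), 1)
}

sim_conditions <- c("baseline", "meth", "meth+sulpiride")

condition_index <- function(condition) {
  match(match.arg(condition, sim_conditions), sim_conditions)
}
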