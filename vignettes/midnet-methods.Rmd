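---
title: "Functional connectivity and topology of cultured neuronal networks: methods"
author: "midnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional connectivity and topology of cultured neuronal networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midnet)
```

## The analysis

`midnet` implements a network analysis of single-neuron-resolution calcium
imaging in cultured neuronal networks, of the kind used to study how
dopaminergic drugs reshape activity in mixed ventral-midbrain cultures
(~12% dopaminergic neurons, the remainder predominantly GABAergic, imaged
over days in vitro, DIV). A recording consists of a spontaneous-activity
baseline window followed by a treatment window (e.g. methamphetamine, or
methamphetamine with the D~2~-receptor antagonist sulpiride), both sampled
at 10 Hz for 2 minutes in the default configuration.

The pipeline is:

1. **delta-F/F**: each neuron's raw fluorescence trace $F(t)$ is expressed
   as $(F(t) - F_0)/F_0$. $F_0$ is the per-neuron *mean* of the baseline
   window by default. The phrase "baseline condition" underdetermines
   $F_0$; the mean was chosen because the delta-F/F then averages exactly
   to zero over the reference window — an invariant the tests assert
   exactly — while a lower-percentile reference is exposed as
   `method = "percentile"` for users who prefer a floor-like baseline.
   Both condition windows are normalised to the *baseline-window* $F_0$,
   because a drug recording is one continuous acquisition: suppression is
   then visible as negative treatment-window integrals.
2. **Integrated activity**: the per-neuron trapezoidal integral of signed
   delta-F/F over a window (delta-F/F·s). Signed integration is the
   default because it is linear (tested); rectified integration is an
   option. The fraction of neurons whose treatment integral falls below
   their baseline integral summarises activity suppression (ties count as
   not-below).
3. **Functional connectivity**: pairwise Spearman rank correlation over
   the whole window, per condition. The rank statistic makes the matrix
   invariant to any strictly monotone transform of the traces, so it is
   indifferent to the raw/delta-F/F distinction. Matrices are exactly
   symmetric with a zero diagonal. A constant trace leaves its
   correlations undefined; those entries are set to 0 with a warning
   naming the neurons, rather than propagating `NaN` into every downstream
   metric.
4. **Thresholding**: either an absolute sweep (densities at thresholds
   0.05 to 1 in steps of 0.05) or the proportional scheme retaining the
   strongest fraction $p$ of the $n(n-1)/2$ unique connections
   (default $p = 0.15$), which makes networks of different sizes
   comparable. "Strongest" means largest *signed* correlation: these
   matrices are predominantly positive and anticorrelation is treated as
   connection loss, not strength; magnitude ranking is exposed via
   `rank_by = "abs"`. Exactly $\lfloor p E \rfloor$ edges are kept, with
   cutoff ties broken deterministically in lexicographic $(i, j)$ order.
5. **Topology** on the thresholded weighted graph:
   - *density* — realised unique pairs over possible pairs;
   - *clustering* — the Onnela geometric-mean weighted triangle fraction,
     $C_i = \frac{1}{k_i(k_i-1)} \sum_{j \ne h}
     (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$ with weights scaled by the
     global maximum and $k_i$ the binary degree ($C_i = 0$ for $k_i < 2$);
     it reduces to the binary triangle fraction on 0/1 weights (tested on
     random graphs);
   - *modularity* — $Q = \frac{1}{2m}\sum_{ij}
     \left[w_{ij} - \gamma \frac{s_i s_j}{2m}\right]\delta(c_i, c_j)$,
     maximised by seeded Louvain with 10 restarts (best $Q$ kept,
     deterministic given the seed). Louvain is the de facto standard for
     weighted $Q$; exhaustive search over all partitions of small fixtures
     confirms it attains the global optimum on the test graphs;
   - *assortativity* — the Pearson correlation of endpoint node
     *strengths* over the edge list, both orientations per undirected
     edge. Strengths rather than binary degrees match the weighted
     analysis; the degree variant is exposed for sensitivity checks. On
     regular graphs the endpoint variance is zero and the value is
     reported as a flagged missing value (not an error), so sweeps over
     DIV do not abort.

   Negative correlations that survive a permissive threshold are clipped
   to 0 before the weighted metrics (they require nonnegative weights);
   at the default $p = 0.15$ on predominantly positive matrices this is
   rarely triggered, and it is flagged when it happens.
6. **Comparison**: for every unique pair, the signed perpendicular
   distance of $(\rho_\text{base}, \rho_\text{treat})$ to the unity line,
   $d = (\rho_\text{treat} - \rho_\text{base})/\sqrt{2}$ (positive favours
   treatment). The raw difference is available via
   `scale = "difference"`; the two differ by a constant factor, so every
   shape statistic reported — skewness, excess kurtosis, KS, Wilcoxon — is
   identical under either choice (asserted by test). Summaries use the
   population-moment conventions $g_1 = m_3/m_2^{3/2}$ and
   $g_2 = m_4/m_2^2 - 3$, so a normal distribution scores excess kurtosis
   0; at the pair counts these experiments produce (tens of thousands),
   bias-corrected variants are numerically indistinguishable. The KS test
   is against a normal with estimated mean and SD; since the parameters
   are fitted, the p-value is approximate (the Lilliefors caveat) and is
   reported as such. Per-metric trends across DIV use ordinary least
   squares (slope per day, $r^2$, two-sided p).

## The synthetic culture

Real recordings of this kind are rarely published, so the package carries
a generative model rich enough to exercise every stage against known
ground truth. It is a mechanistic stand-in, not a biophysical model.

**Spikes.** Correlated trains come from a multiple-interaction process
(MIP): each module owns a Poisson mother train at rate
$\lambda/c$ (with $\lambda$ = `base_rate`, $c$ = `within_module_share`),
and each member neuron keeps each mother spike independently with
probability $c$. This yields Poisson marginals at rate $\lambda$ and a
pairwise spike-count correlation of exactly $c$ within a module — a
closed-form dial for the planted connectivity. An optional independent
background (`bg_rate`, default 0) dilutes the correlation; with the
default of zero, `within_module_share = 1` makes module members fire in
perfect lockstep, a useful degenerate test case.

**Defaults as study conditions.** `n_neurons = 35` matches a typical
single-field-of-view segmentation count (tens of thousands of pairs over
a few dozen recordings implies roughly 35 neurons each).
`n_modules = 1` and `within_module_share = 0.7`: young cultures burst
near-globally, and mean pairwise Spearman correlations around 0.6–0.7 in
young networks — the empirically observed regime — require network-wide
correlated firing, not small modules. `base_rate = 0.5` spikes/s is a
typical spontaneous rate for such cultures; no event statistics are
published for these particular cultures, so this is a field-typical
placeholder, stated as such. Culture age enters as
$c_\text{eff} = c \cdot \texttt{div\_decay}^{(\text{DIV} - 9)}$ with
`div_decay = 0.97` — day 9 is the first recording day, and a ~3%/day
relative decay reproduces mean-connectivity decay on the order of 0.02
per day from a 0.6–0.7 starting level across DIV 9–21.

**Calcium.** A spike adds a difference-of-exponentials GCaMP6f transient
($\tau_\text{rise} = 0.1$ s, $\tau_\text{decay} = 0.6$ s,
literature-typical values; the indicator's kinetics are not reported per
culture). The kernel is normalised to unit peak so `amp_per_spike` reads
directly as the peak delta-F/F of an isolated spike; traces are
$F(t) = F_0(1 + a \sum_s k(t - t_s)) + \varepsilon(t)$ with i.i.d.
Gaussian noise, evaluated analytically at the frame times (no convolution
grid, so the only discretisation is the 10 Hz sampling itself).

**Pharmacology.** Dopaminergic neurons are always D~2~-positive
(autoreceptors); GABAergic neurons are D~2~-positive with probability
`frac_d2` (default 1, since the GABAergic majority of the ventral
midbrain expresses D~2~). Methamphetamine is a rate multiplier on
D~2~-positive neurons only: `drug_factor = 0.5` thins their spikes
(suppression); the sulpiride preset uses `sulpiride_factor = 1.2`,
adding spikes above baseline, because D~2~ blockade both abolishes the
suppression and disinhibits the network. No receptor kinetics, dopamine
diffusion or spatial geometry are modelled.

Two distinct drug scenarios matter for validation. Network-wide
suppression (`frac_d2 = 1`) reproduces the *activity* direction: every
treatment integral drops below baseline. But it shifts all correlations
roughly uniformly, producing a left-shifted yet near-symmetric deviation
distribution. The *negative skew* of unity deviations — connection
dropout concentrated in a subset — requires suppressing a minority
subpopulation, e.g. `frac_d2 = 0` so that only the ~12% dopaminergic
cells are hit, consistent with the interpretation that the dropout pairs
in a predominantly GABAergic network are the non-GABAergic minority.
The direction tests use both configurations accordingly.

**Movies.** For end-to-end tests of trace extraction, a trace set can be
rendered as an 8-bit multi-page TIFF (Gaussian soma blobs truncated at
the ROI radius, so ROIs cannot overlap; a paired label mask defines the
ground-truth segmentation). Extraction recovers the input traces to
$r > 0.99$ per neuron; the residual is 8-bit quantisation.

**Planted topology.** `generate_planted_network()` provides ground truth
for metric recovery: disjoint unit-weight cliques of increasing size
(every edge joins equal-strength nodes — strength assortativity exactly
+1), unit-weight hub-and-spoke graphs (the pure star scores exactly −1),
and modular($k$) block matrices with dense U(0.5, 1) within-block weights
and sparse weak between-block edges (Louvain recovers the blocks with
adjusted Rand index 1 at the default between-block density).

## What passing tests do and do not show

The simulator emulates the *directions* of the studied effects —
D~2~-mediated activity suppression, its reversal by sulpiride,
age-dependent connectivity decay, dropout-driven negative skew — under
Poisson spiking with planted correlations. It does not emulate bursting
dynamics, photobleaching, motion artifacts, spatial correlation
structure, or the magnitudes of any published statistic; recovery of a
planted effect here demonstrates that the pipeline measures what it
claims to measure, not that real cultures behave like the model.

## Numerical choices and degenerate inputs

- Windows are 0-based and half-open $[\text{start}, \text{end})$; frames
  are sampled at $t = 0, 1/r, 2/r, \ldots$
- All randomness flows from one root seed through derived child streams
  (per module, neuron, condition, restart), so draws are reproducible and
  independent of evaluation order; re-running a pipeline config
  reproduces byte-identical output files (CSV floats are written at 17
  significant digits).
- Spearman ties use average ranks; threshold-cutoff ties use
  lexicographic order; Louvain ties across restarts keep the first best.
- $F_0$ below a positivity floor ($10^{-8}$) is a hard error naming the
  neuron; an edgeless network makes $Q$ an error standalone and a flagged
  missing value inside `topology_report()`; fewer than 2 edges make
  assortativity an error; zero-variance deviation sets flag all shape
  statistics as undefined.
- Problem sizes in the shipped tests (up to 100 neurons × 1200 frames per
  window, 3 seeds per stochastic property, exhaustive partition search up
  to 8 nodes) were chosen so the whole suite exercises every stage at
  full fidelity in well under a minute of compute per file; they are the
  smallest sizes at which the planted effects are unambiguous.

## Known limitations

- The MIP plants a single correlation level per module; no distance
  dependence, no heavy-tailed weight distribution, no negative planted
  correlations.
- The KS p-value with estimated parameters is anti-conservative; treat it
  as descriptive, as the corresponding analyses do.
- Group-level ANOVAs across coverslips/conditions are out of scope; the
  package reports per-recording metrics and simple DIV regressions, and
  users can feed `metrics.csv` to any standard statistics tool.
- Proportional thresholding with `rank_by = "signed"` can retain negative
  edges when $p$ is large; they are clipped (and flagged) before the
  weighted metrics, which slightly biases those metrics at extreme $p$.
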