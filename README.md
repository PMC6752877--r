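# midnet

Functional connectivity and network topology of cultured neuronal networks
from single-neuron calcium imaging.

## The problem

Calcium imaging of cultured networks (for example mixed
dopaminergic/GABAergic ventral-midbrain cultures expressing GCaMP6f)
records a fluorescence trace per segmented neuron at ~10 Hz, typically a
2-minute spontaneous baseline followed by a 2-minute drug window. The
questions such experiments ask are network-level: how strongly is each
pair of neurons functionally coupled, how is the resulting graph organised
(density, clustering, community structure, assortativity), how does that
organisation change with culture age (days in vitro, DIV), and what does a
drug such as methamphetamine — which suppresses activity through
D<sub>2</sub>-receptor activation — do to it?

`midnet` is a tested, reusable implementation of that analysis for R
users:

- **delta-F/F** normalisation (`normalize_dff`), per-neuron integrated
  activity (`integrate_activity`), and the below-unity suppression summary
  (`below_unity_fraction`);
- **functional connectivity** as pairwise Spearman rank correlation
  (`functional_connectivity`), with absolute-threshold density sweeps
  (`density_sweep`) and proportional thresholding keeping the strongest
  fraction *p* of connections (`proportional_threshold`, default
  *p* = 0.15);
- **weighted undirected topology**: density, Onnela clustering
  coefficient

  C_i = (1/(k_i(k_i−1))) Σ_{j≠h} (ŵ_ij ŵ_ih ŵ_jh)^(1/3),

  modularity Q = (1/2m) Σ_ij [w_ij − γ s_i s_j/(2m)] δ(c_i, c_j) maximised
  by seeded Louvain, and strength assortativity (endpoint-strength Pearson
  over the edge list);
- **baseline-vs-treatment statistics**: signed perpendicular deviations
  from the unity line d = (ρ_treat − ρ_base)/√2 with skewness g₁, excess
  kurtosis g₂ (normal = 0), Kolmogorov–Smirnov and Wilcoxon signed-rank
  summaries (`unity_deviation`, `deviation_stats`), and OLS trends across
  DIV (`div_regression`);
- a **synthetic culture generator** (`sim_spec`, `simulate_experiment`,
  `render_movie`, `generate_planted_network`): correlated Poisson spiking
  via a multiple-interaction process, a unit-peak GCaMP6f kernel,
  D<sub>2</sub>-dependent drug modulation with a sulpiride preset,
  culture-age connectivity decay, planted modular/assortative structure,
  and 8-bit TIFF movie rendering — so every stage is verifiable against
  ground truth;
- an **orchestrated pipeline** (`pipeline_config`, `run_pipeline`) writing
  CSV/JSON products with a run manifest, plus a thin CLI at
  `inst/scripts/midnet.R`.

## Worked example

Simulate one paired recording (35 neurons, baseline then methamphetamine),
run the analysis, and look at age dependence:

```r
library(midnet)

spec <- sim_spec(n_neurons = 35, seed = 42)
ex   <- simulate_experiment(spec, "meth")

dff   <- normalize_dff(ex$raw, ex$baseline_window)
base  <- window_traces(dff, ex$baseline_window, "baseline")
treat <- window_traces(dff, ex$treatment_window, "meth")

cm_base  <- functional_connectivity(base)
cm_treat <- functional_connectivity(treat)
cm_base
#> <connectivity_matrix> 35 neurons (baseline, DIV 11), mean rho 0.574, range [0.338, 0.769]

net <- proportional_threshold(cm_base, 0.15)
net
#> <thresholded_network> 35 nodes, 89 edges (top 15%), density 0.150

topology_report(net, seed = 42)
#> <topology_metrics> baseline DIV 11
#>   density 0.1496 | clustering 0.3075 | Q 0.2858 (7 communities) | assortativity -0.0821

below_unity_fraction(integrate_activity(base), integrate_activity(treat))$fraction
#> [1] 1

deviation_stats(unity_deviation(cm_base, cm_treat))
#> <deviation_stats>
#>   n = 595, mean = -0.1706
#>   skewness g1 = -0.0763, excess kurtosis g2 = -0.4175
#>   KS (vs fitted normal) p = 0.643, Wilcoxon signed-rank p = 6.63e-99

rows <- simulate_div_series(spec, divs = c(9, 12, 15, 18, 21))
div_regression(rows$div, rows$mean_rho, condition = "baseline")
#> <div_trend> baseline slope -0.01571 per day, r^2 = 0.9796, p = 0.00124 (n = 5)
```

Reading the output: mean baseline connectivity is high (0.574), as
expected for a young, globally bursting culture. The 15% proportional
threshold keeps exactly ⌊0.15·595⌋ = 89 of the 595 unique pairs. Under
simulated methamphetamine every neuron's integrated delta-F/F falls below
its baseline (fraction 1), the pairwise deviations from unity shift
significantly negative (Wilcoxon p ≪ 0.01 with mean −0.17: connectivity
favours the baseline condition), and mean connectivity decays across
DIV 9–21 at about −0.016 per day.

The same analysis runs end to end from a config:

```r
cfg <- pipeline_config(out_dir = "run1", seed = 42,
                       simulation = list(n_neurons = 35, treatment = "meth"))
run_pipeline(cfg)   # writes dff.csv, adjacency_*.csv, metrics.csv,
                    # deviations.csv, deviation_summary.json, manifest.json, ...
```

or from a shell: `Rscript inst/scripts/midnet.R all -c config.yml`.

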