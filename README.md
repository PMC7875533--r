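# bipsim

Bridging-induced phase separation (BIPS) of DNA-bridging proteins:
a coarse-grained polymer simulator plus the single-molecule analysis toolbox
that quantifies it.

DNA-bridging proteins such as SMC complexes (cohesin) condense DNA into
liquid-like clusters without any direct protein-protein attraction. The
mechanism is a positive feedback: a protein that bridges two DNA segments
raises the local DNA concentration, which recruits more proteins. Two
quantitative signatures identify BIPS:

* **A critical DNA length.** Clusters only nucleate on DNA longer than the
  looping length `l_C = 2 pi^2 l_P ~ 987 nm ~ 2903 bp` (persistence length
  `l_P = 50` nm): shorter DNA is too stiff to bend back onto itself.
* **Valence-dependent size scaling.** Above `l_C` the cluster radius of
  gyration grows as `R_G ~ l^alpha`, where multivalent bridges (~10 binding
  sites) collapse DNA into a globule (`alpha = 1/3`) while bridges with 2-3
  binding sites build porous clusters (`alpha ~ 0.45` and `0.40`) and induce
  only weak Hi-C compartments.

`bipsim` is aimed at single-molecule biophysicists and chromosome-organization
modellers. It provides:

* a Langevin-dynamics simulator (compiled core) of a Kremer-Grest semiflexible
  DNA chain with diffusing bridge particles of bounded valence, Metropolis
  binding kinetics, and cluster extraction
  (`chain_config()`, `bridge_config()`, `simulate_bips()`,
  `largest_cluster()`, `scaling_experiment()`);
* scaling analysis: `radius_of_gyration()`, `fit_power_law()`,
  `piecewise_scaling_fit()` (constant-below / power-law-above `l_C`),
  `critical_looping_length()`;
* in-silico Hi-C: `aggregate_map()`, `compartment_strength()`;
* fluorescence trace analysis: `build_kymograph()`, `cluster_size_kbp()`,
  `compaction_time()` (5-95% of a Savitzky-Golay smoothed trace),
  `fit_exponential()` (FRAP / dissociation), `find_steps()`
  (photobleaching step counting), `count_complexes()`;
* image geometry: `gaussian_diameter()` (full width at 20% of the fitted
  maximum), `circularity()` (`4*pi*A/P^2` with a sub-pixel perimeter),
  `grain_volumes()`, `afm_flatten()`, `single_molecule_threshold()`
  (mean + 7 SD), `cluster_stoichiometry()`, `classify_bridging()`;
* seeded synthetic-data generators with attached ground truth for every one
  of those estimators (`gen_*`), and a config-driven stage runner
  (`run_stage()`).

## Worked example

Simulate a 9.7-kbp DNA with trivalent bridges, then measure the largest
cluster:

```r
library(bipsim)

chain   <- chain_config(330)            # 330 beads x 29.4 bp = 9.7 kbp
bridges <- bridge_config(valence = 3)   # 66 bridges, eps = 4 kT
traj    <- simulate_bips(chain, bridges,
                         sim_params(n_steps = 6e5, snapshot_every = 3e4,
                                    seed = 1150))
cluster_rg(snapshot_state(traj, 20))[c("rg_nm", "n_members")]
#> $rg_nm
#> [1] 40.20949
#> $n_members
#> [1] 210
```

The cluster holds 210 particles (DNA beads plus bridges) with a radius of
gyration of about 40 nm. Sweeping chain length at fixed bridge concentration
and fitting the medians gives the BIPS scaling law:

```r
df  <- scaling_experiment(valence = 3, seed = 1)
fit <- fit_scaling_experiment(df)
fit
#> Scaling fit R_G ~ l^alpha: alpha = 0.403 +/- 0.072
```

i.e. trivalent bridges compact DNA into clusters intermediate between a
collapsed globule (`alpha = 1/3`, which `valence = 10` reproduces) and an
ideal polymer (`alpha = 0.5`, which the phantom bridge-free control
reproduces). The analytic critical looping length:

```r
critical_looping_length(50)
#> $nm
#> [1] 986.9604
#> $bp
#> [1] 2903
```

And a taste of the measurement toolbox:

```r
g <- gen_exponential_trace("recovery", tau = 126, noise_sd = 0.05, seed = 7)
fit_exponential(g$trace, "recovery")
#> Single-exponential recovery fit: tau = 119 +/- 5.4 s
#>   amplitude = 0.9858, baseline = 0.00767 a.u.

set.seed(3)
single_molecule_threshold(rnorm(50000, 300, 262), k = 7)  # nm^3
#> [1] 2145.339
count_complexes(2220, 3.0)                                # cluster / step
#> [1] 740
```

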