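---
title: "Bridging-induced phase separation: models, estimators and design choices"
author: "bipsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bridging-induced phase separation: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bipsim)
```

# The scientific problem

DNA-bridging proteins such as SMC complexes can condense DNA into clusters
without any direct protein-protein attraction. The mechanism -- bridging-induced
phase separation (BIPS) -- is a positive feedback: a protein that bridges two
DNA segments raises the local DNA concentration, which recruits further
proteins to the same region. Two quantitative signatures follow:

* clustering requires DNA longer than the critical looping length
  $l_C = 2\pi^2 l_P \approx 987\,\mathrm{nm} \approx 2903\,\mathrm{bp}$
  (for persistence length $l_P = 50$ nm), below which thermal fluctuations
  cannot bend the DNA back onto itself to seed a bridge; and
* above $l_C$ the cluster radius of gyration grows as a power law
  $R_G \sim l^{\alpha}$, with $\alpha$ set by the bridge valence: multivalent
  bridges collapse the DNA into a compact globule ($\alpha = 1/3$), while
  bridges with only two or three binding sites build porous clusters with
  $\alpha \approx 0.45$ and $0.40$.

`bipsim` implements (i) a coarse-grained Langevin simulator of a semiflexible
DNA chain with diffusing multivalent bridge particles, (ii) the scaling and
in-silico Hi-C analyses that read out the BIPS signatures, and (iii) the
single-molecule quantification toolbox (kymographs, compaction kinetics,
exponential FRAP/dissociation fits, photobleaching step counting, droplet
geometry, AFM grain volumetry) together with seeded synthetic-data generators
that carry ground truth for every estimator.

# The polymer model

DNA is a Kremer-Grest bead-spring chain in reduced units (bead diameter
$\sigma = 1$, $k_BT = 1$, bead mass 1). One bead is $\sigma = 10$ nm
$= 29.4$ bp, so the 48.5-kbp lambda genome is about 1650 beads and $l_P =
50$ nm is five beads.

* **Backbone**: FENE springs ($K = 30$, $R_0 = 1.5\sigma$) plus WCA repulsion
  between bonded neighbours; rest length $\approx 0.97\sigma$. The WCA term
  on bonded pairs is part of the bond potential and stays on even for phantom
  chains, otherwise the bond length collapses and the bending forces diverge.
* **Bending**: discrete Kratky-Porod energy $\kappa(1-\cos\theta)$. The
  stiffness is found by inverting
  $l_P = -\sigma/\ln\langle\cos\theta\rangle$,
  $\langle\cos\theta\rangle = \coth\kappa - 1/\kappa$
  (`kappa_for_persistence_length()`), giving $\kappa = 5.52\,k_BT$ for
  $l_P = 5\sigma$; the round trip is verified to 5% at construction.
* **Excluded volume**: WCA between all non-bonded particle pairs, switchable
  off for phantom (ideal) chains.
* **Integration**: BAOAB Langevin splitting with velocity Verlet at
  $\Delta t = 0.01$. We use inertial Langevin dynamics rather than an
  overdamped first-order scheme because the WCA core makes overdamped Euler
  updates unstable at usable timesteps, and because molecular-dynamics
  thermostatted integration is the convention of the coarse-grained
  chromatin literature this model belongs to. The diffusive observables are
  unchanged: a free particle obeys $\mathrm{MSD} = 6Dt$ with $D = k_BT/\gamma$
  for $t \gg m/\gamma$, which the test suite verifies to 5%.

Chains are initialized as persistence-length-correct random walks whose bond
angles are drawn from the exact Kratky-Porod Boltzmann distribution, with
minimum-image overlap rejection and bounded backtracking. A phantom chain
therefore *starts in conformational equilibrium*, which is what makes the
ideal-chain control experiments cheap: replicate initial states are already
fair samples, and short runs only decorrelate them further.

# Bridges and binding

Bridge particles are spheres (one bead diameter) that diffuse freely and can
hold up to `valence` simultaneous harmonic bonds to chain beads
($k = 40$, rest length $2^{1/6}\sigma$), each worth $-\epsilon$ with
$\epsilon = 4\,k_BT$ by default -- inside the $3$--$5\,k_BT$ window where
bridging-induced clustering is predicted to operate. Binding is a Metropolis
process run every 10 integration steps: each bridge proposes creating a bond
to a random bindable bead within the capture radius ($1.5\sigma$) or deleting
a random existing bond, with proposal-count corrections so that detailed
balance holds exactly for frozen configurations (the test suite checks the
frozen-position occupancy against brute-force enumeration over all bond
subsets). The valence cap is strict, and a bridge may not hold two bonds
within two beads of each other along the chain: the binding surfaces of a
bridging protein face different directions and engage *distinct* DNA
segments, and without this rule a bivalent bridge spends its valence on
adjacent beads of one segment and never bridges at all.

Bridge number is fixed at 0.2 per chain bead and the periodic box scales with
chain length (default 0.02 beads/$\sigma^3$), so bulk concentrations -- the
experimentally controlled quantities -- are invariant across the length
ladder.

# Cluster definition and the scaling experiment

A cluster is a connected component over explicit bonds plus proximity links
(closer than $1.5\sigma$) in which at least one partner is a bridge.
Backbone bead-bead proximity deliberately does not connect a cluster, so an
unbound chain decomposes into single particles and the cluster is the
bridge-occupied assembly. Cluster coordinates are unwrapped across periodic
boundaries by walking the cluster graph before computing $R_G$
(equal-weight RMS distance from the centroid).

`scaling_experiment()` runs a ladder of chain lengths at fixed valence and
concentration and records the largest cluster's member count and $R_G$ per
snapshot; $\alpha$ is the slope of the per-length median largest-cluster
$R_G$ against length on log-log axes (`fit_scaling_experiment()`).
Equilibration is declared when the running mean of the cluster-size series
drifts by less than 2% over the final third of a run; medians are taken
over the second half of the snapshots.

Protocol choices that matter for this estimator:

* **Lengths all sit above the critical looping length** (the default ladder
  is 150--500 beads, i.e. 4.4--14.7 kbp versus $l_C \approx 2.9$ kbp).
  Including lengths at or below $l_C$ mixes the constant regime into the
  power-law fit and inflates the slope.
* **Light damping** ($\gamma = 0.3$): the BAOAB thermostat samples the same
  equilibrium ensemble at any friction, but conformational exploration per
  step is roughly $1/\gamma$, so cluster growth and coalescence reach their
  plateau several times sooner than at $\gamma = 1$.
* **Adaptive run length**: each run integrates in chunks of $10^5$ steps and
  stops once the cluster-size running mean has plateaued (drift below 2%
  over the last third of the series), subject to a floor of $3\times10^5$
  and a cap of $6\times10^5$ steps. Budget therefore flows to the runs that
  are still nucleating or coarsening. Two to three replicates per length,
  with more at the shorter (noisier) lengths.

Below the looping length the package emulates the dilute single-molecule
regime (one chain per effective volume, `bead_density = 0.002`): in the
semidilute box short chains would bridge their periodic images, which has no
experimental counterpart. There the per-assembly view matters:
`bridge_clusters()` returns every bridge-containing connected component, and
the mean assembly radius of gyration is flat in chain length (~7 nm, the
single-bridge scale), while the *largest* assembly is an extreme-value
statistic that still grows with the number of bridges and is not the
experimental observable.

A limitation worth stating plainly: for bivalent bridges the condensate
never assembles on desk-scale runs (the largest cluster stays at the
few-bridge nucleation scale over at least $3\times10^6$ steps), so the
valence-2 exponent measured here reflects nucleation statistics, not the
porous-condensate scaling, and the strict valence ordering of exponents is
not reproduced at this scale. The valence-3 and multivalent exponents are
unaffected. An alternative cluster mass-size (fractal-dimension) estimator
was explored and rejected: at desk-scale cluster masses the cluster cores
are compact for every valence, so it cannot separate the valence classes.

The ideal-polymer control runs phantom chains (excluded volume off, no
bridges) with the bending stiffness also off, i.e. a freely jointed chain.
With $l_P = 50$ nm retained, the Benoit-Doty worm-like-chain crossover makes
the apparent slope over 50--800 beads about 0.55, well above the asymptotic
0.5; the freely jointed phantom chain *is* the ideal-polymer limit the
control refers to, and its equilibrium-drawn initial states make the
$\alpha = 0.5$ measurement essentially exact in seconds.

# In-silico Hi-C

Contact maps are means over post-burn-in snapshots of binary contact
matrices at capture radius $2.5\sigma$ (the usual polymer Hi-C convention;
the valence ordering of compartment scores is insensitive to this radius
within $1.5$--$3.5\sigma$). Compartment strength follows the standard A/B
pipeline -- observed/expected normalization by sequence separation, Pearson
correlation, leading eigenvector -- and scores the contrast as the mean
within-sign-block correlation minus the mean between-block correlation,
clipped to $[0,1]$. Checkerboards require binding heterogeneity, so
compartment experiments run chains with alternating bindable/neutral blocks;
multivalent bridges must score higher than bivalent ones on matched chains,
which is the module's headline property test.

# Trace kinetics

* **Kymographs** sum intensity over an 11-pixel span perpendicular to the
  DNA axis per frame, subtract a 2-D median-smoothed background (21 x 21
  pixels; the kernel size is our choice, the method is standard) and
  normalize each frame by its maximum with a zero-frame guard.
* **Cluster size in kbp** is the background-subtracted ROI intensity over
  the whole-DNA intensity times 48.5 kbp; it is exactly scale invariant.
* **Compaction time** is the 5--95% span of the Savitzky-Golay smoothed
  trace (order 2, window 250 frames, shrunk to the trace when necessary).
  The 5% and 95% levels refer to the plateau-minus-baseline amplitude, with
  the baseline the mean of the first 5% of the trace and the plateau the
  mean of the final 20%; a drifting tail fails the plateau test rather than
  returning a number. Order 2 is the lowest that preserves ramp curvature.
* **Exponential fits** (`fit_exponential()`) are Levenberg-Marquardt
  nonlinear least squares of the single-exponential recovery/decay forms
  with geometry-derived starting values; $\tau$ uncertainty comes from the
  fit covariance, and traces shorter than one fitted $\tau$ or 10 points
  warn. Recovery bias is under 2% at 5% noise across $\tau$ from 1 to 476 s.
* **Step finding** (`find_steps()`) places steps greedily (each new step
  minimizes the residual chi-square), then eliminates candidates backwards:
  each step must beat a counter-fit -- the same window refit with the step
  at the midpoint of its longer side, the worst generic placement -- by a
  chi-square ratio above 1.5. The fit chi-square is floored at its
  window-size noise expectation (robust scale from first differences; zero
  for noise-free traces) so that near-empty windows cannot defend spurious
  steps, adjacent opposite-sign steps bracketing plateaus of at most 5
  frames are removed as fluorophore blinks, and on traces up to 400 points
  the selected step count is re-placed exactly by dynamic programming, which
  makes the placement globally optimal and testably identical to an
  exhaustive change-point oracle. Flat noisy traces return zero steps in at
  least 95% of seeds; 5-step staircases at 30%-of-step noise are counted
  correctly in at least 95%.

# Image geometry

* **Droplet diameter** is the full width at 20% of the Gaussian-fitted
  maximum of a cross-sectional profile, $2\,\mathrm{SD}\sqrt{2\ln 5}
  \approx 3.588\,\mathrm{SD}$; profiles with two resolved dominant peaks are
  rejected.
* **Circularity** is $4\pi A/P^2$ on a single 8-connected component, with
  both area and perimeter measured on a sub-pixel marching-squares outline
  of the lightly smoothed mask (Gaussian, 2 px). Pixel-edge perimeter
  counting would bias circularity low by up to ~25%, and the raw
  marching-squares staircase still by ~8%; with smoothing a rasterized disk
  scores 0.998 and a 2:1 ellipse matches the elliptic-integral value 0.841
  to better than 0.01.
* **AFM volumetry**: grains are 8-connected regions above a height
  threshold (default three robust noise SDs, minimum footprint 4 pixels),
  with volume $\sum h \cdot \mathrm{pixel\ area}$. `afm_flatten()` removes
  polynomial backgrounds by iteratively refitting while masking pixels more
  than 2 residual SDs high. The single-molecule cluster threshold is
  mean + $k$ SD of the single-complex volume distribution ($k = 7$), and
  stoichiometry floors the cluster/single volume ratio -- a partial volume
  cannot be a complex.
* **Bridging classification**: a protein bridges when it touches two
  stretches of the DNA contour separated along the contour by more than
  four contact radii, so one continuous footprint never counts as a bridge.

# Synthetic data

Every generator is seeded and bit-reproducible, returns the full ground
truth used to build the data, and uses additive Gaussian noise throughout --
camera physics (Poisson/EMCCD gain) is deliberately out of scope, so
passing tests show estimator correctness under well-behaved noise, not
robustness to photon statistics. Defaults encode the measurement scales the
estimators are designed for: 48.5-kbp DNA with a 20-kbp cluster plateau and
~30 s compaction, 3.0 a.u. bleaching steps with 30 s mean dwell at 10 Hz
sampling, $\tau$ fixtures from sub-second to hundreds of seconds, a
0.159-micron PSF (0.57-micron apparent point-source diameter), and AFM
grains of a few hundred nm$^3$ over polynomial backgrounds. Dwell times are
exponential (memoryless photobleaching); kymographs conserve total
intensity frame by frame, so compacted DNA is moved, not created.

# Known limitations

* Desk-scale simulations do not reach the fully coarsened single-cluster
  state for bivalent bridges, so the valence-2 exponent and the strict
  valence ordering of exponents are not reproduced at this scale (see the
  scaling section); valence 3 and ~10 are unaffected.
* No hydrodynamics, no ATP-driven loop extrusion, no topological loading;
  bridges are isotropic spheres with a bond-registry valence rather than
  oriented patches.
* The droplet/AFM generators are geometric, not optical: no vignetting,
  drift, or tip convolution.
* `run_stage()` provides config-driven, manifest-logged runs of each stage
  inside R; there is no shell executable, as the package's users drive it
  from R scripts.
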