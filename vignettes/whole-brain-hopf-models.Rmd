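---
title: "Whole-brain Hopf models: simulation, fitting and in-silico perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain Hopf models: simulation, fitting and in-silico perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(hopfbrain)
```

## The model

`hopfbrain` models each brain region of a parcellation as a Stuart–Landau
oscillator — the normal form of a supercritical Hopf bifurcation — coupled
to the other regions through a structural connectome. For region $j$ with
state $z_j = x_j + i y_j$, bifurcation parameter $a_j$ and intrinsic
angular frequency $\omega_j$, the coupled stochastic equations are

$$
\dot x_j = (a_j - x_j^2 - y_j^2)\,x_j - \omega_j y_j
  + G\sum_i C_{ij}(x_i - x_j) + \beta\,\eta_j(t),
$$
$$
\dot y_j = (a_j - x_j^2 - y_j^2)\,y_j + \omega_j x_j
  + G\sum_i C_{ij}(y_i - y_j) + \beta\,\eta_j(t),
$$

with $C$ the coupling matrix, $G$ a global coupling gain, and
$\beta\,\eta_j$ additive Gaussian noise. For $a_j < 0$ the node has a
stable fixed point at the origin and shows noise-driven fluctuations; for
$a_j > 0$ it settles on a limit cycle of radius $\sqrt{a_j}$ and frequency
$\omega_j / 2\pi$; near $a_j \approx 0$ the noise induces continual
switching between the two regimes. The real part $x_j$ serves as the
BOLD proxy; no hemodynamic convolution is applied.

The working hypothesis behind the toolkit is that different global states
of consciousness (wakefulness, sleep stages, propofol sedation and
anesthesia, post-comatose disorders of consciousness) correspond to
different regional bifurcation-parameter configurations, and that the
stability of a state can be probed by simulating external periodic
stimulation and asking whether the perturbed model reproduces the
functional connectivity (FC) of another state.

## Parameters, units and defaults

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `a` | regional bifurcation parameters | fitted | dimensionless |
| `omega` | intrinsic angular frequencies (rad/s) | estimated | spectral peak in the analysis band |
| `G` | global coupling gain | 0.5 | fixed, not fitted |
| `beta` | noise amplitude | 0.04 | per equation, per node |
| `dt` | Euler–Maruyama step (s) | 0.1 | `tr` must be a multiple |
| `tr` | sampling interval (s) | 2.0 | matches typical fMRI repetition times |
| band | analysis band (Hz) | 0.04–0.07 | most reliable resting-state band |
| ceiling | max structural coupling | 0.2 | weak-coupling condition |

The connectome is always rescaled so its largest entry is 0.2; this keeps
the coupled system in the weakly coupled regime in which nodes with
$a_j > 0$ retain their oscillatory character. Tractography connectomes,
which can be asymmetric, are symmetrized by averaging with their transpose
on load, because the model uses a single weight per edge. No streamline
threshold is applied by the loader; whether thresholding should precede or
follow cross-subject averaging of tractography is left to the data
provider.

## The observation pipeline

Empirical and simulated signals go through the same pipeline: band-pass
filtering to 0.04–0.07 Hz, per-region z-scoring, Pearson correlation, and
Fisher r-to-z averaging across subjects (fixed-effect group FC). Regional
natural frequencies are the Welch-periodogram peaks of the band-passed
signals (segment length `min(T, 128)`, Hann window, 50% overlap), averaged
across subjects and constrained to the analysis band.

Numerical choices worth knowing:

* The band-pass is a 2nd-order Butterworth applied forward and backward
  (zero phase). Edge handling uses odd end-extension with steady-state
  matched initial conditions — the scheme of the widely used `filtfilt`
  implementations. At this very low band, zero-state filtering would leave
  large edge transients (a constant input would not come out near zero);
  the matched-state scheme removes DC exactly. The interior of the output
  agrees with `signal::filtfilt` to high precision.
* Correlations are clipped to $\pm(1 - 10^{-6})$ before `atanh`, the
  diagonal is excluded from averaging and reset to 1.
* Inside `simulated_group_fc()` the explicit z-scoring step is skipped:
  Pearson correlation is invariant to per-column affine rescaling, so the
  result is bit-identical to the explicit pipeline (this equality is
  pinned by a test).

## Goodness of fit

Similarity between two FC matrices is measured with the structural
similarity index (SSIM), treating the matrices as images: a Gaussian
weighted sliding window (11×11, $\sigma = 1.5$) computes local means,
variances and covariances, combined with the standard stabilizing
constants $K_1 = 0.01$, $K_2 = 0.03$ and data range 2 (correlations span
$[-1, 1]$). The score is the mean over all fully supported window
positions; windows shrink to the largest odd size that fits small
matrices. The fitting objective is $1 - \mathrm{GoF}$.

Because the window statistics are local and Gaussian-weighted, the score
is *not* invariant under relabeling the regions (only the degenerate
single-uniform-window case is); region order is part of the comparison, as
it is for any image-structural metric. Both inputs must therefore use the
same parcellation ordering.

## Fitting: RSN priors and the genetic algorithm

Rather than fitting one $a_j$ per region, regions are grouped by
resting-state-network (RSN) membership $M \in \{0,1\}^{N \times K}$ and
$a = M g$ with $g \in \mathbb{R}^K$; with the usual six networks this is a
six-dimensional search space. Overlapping memberships and regions outside
every network (which receive $a_j = 0$, with a warning) are allowed.

The optimizer is a real-coded genetic algorithm: tournament selection
(size 2), uniform crossover (per-gene rate 0.5), Gaussian mutation
(sd 0.02, per-gene rate 0.2), elitism of 1, genes clamped to
$[-0.3, 0.3]$ — a range bracketing the near-bifurcation regime the model
explores. Defaults are a population of 10, 200 generations and 100
independent runs, all scalable down; the best solution across runs (lowest
$1-\mathrm{GoF}$, i.e. highest SSIM) is returned. Each run evaluates every
candidate with one fixed simulation seed (common random numbers), so each
run optimizes a deterministic surface; runs differ in their seeds. The
best objective is non-increasing over generations by elitism, and the
reported GoF is reproducible from the stored seeds.

## The perturbation protocol

External periodic stimulation (a conceptual model of bilateral tACS) is an
additive forcing $F_j = F_0 \cos(\omega_j t)$ applied to both nodes of a
homotopic pair, each at its own intrinsic frequency. The forcing enters
the real-part equation only by default (`force_both` adds it to the
imaginary part as well). For an ordered pair of states, the initial
state's fitted model is simulated under forcing of every homotopic pair at
every amplitude of a grid (default 0 to 2 in steps of 0.1), averaging
`n_reps` independent FC realizations per cell by Fisher-z averaging — the
same averaging used for empirical group FC (the protocol could also
average GoF values across realizations; averaging FCs was chosen to mirror
the empirical pipeline). Each cell is scored by

$$
\Delta\mathrm{GoF} =
\frac{\mathrm{GoF}(\mathrm{sim}_{target}, \mathrm{emp}_{target}) -
      \mathrm{GoF}(\mathrm{sim}_{forced}, \mathrm{emp}_{target})}
     {\mathrm{GoF}(\mathrm{sim}_{target}, \mathrm{emp}_{target}) -
      \mathrm{GoF}(\mathrm{sim}_{initial}, \mathrm{emp}_{target})},
$$

which is 0 when the perturbed model fits the target state as well as the
target's own best fit, and 1 when the perturbation leaves the model at its
initial state. Scores below 0 (perturbed fit better than the target's own)
are reported, not clipped. The unforced baseline is simulated once per
sweep with the same realization seeds as every forced cell (common random
numbers) and reused, making the $F_0 = 0$ column exactly 1 and removing
Monte-Carlo asymmetry from the ratio; state pairs whose baseline already
fits the target as well as the target's own fit have an undefined score
and are rejected. The perturbational distance of an ordered state pair is
the global minimum of the grid over pairs and amplitudes (the grid itself
is retained for per-pair analyses).

Downstream analytics: a directed transition graph thresholded at
$\Delta\mathrm{GoF} \le 0.3$ (inclusive); the instability index of a state
(its out-degree); a two-dimensional state diagram of level (Euclidean
distance between a state's fitted parameters and its wakefulness
baseline's) versus instability; and regional rankings of homotopic pairs
by best score, averaged within groups of transitions that increase or
decrease the level of consciousness. A transition counts as increasing
when the target is a wakefulness state or is shallower on the same
acquisition route; cross-route transitions to non-wake states are excluded
because their relative depths are not comparable.

## Descriptive distances

Three data-driven distances complement the perturbational one:

* **Connectivity-correlation distance**: for each region, the profile of
  FC changes relative to wakefulness (row of the state-minus-wake
  difference matrix, diagonal excluded) is correlated between two states;
  the distance is one minus the fraction of regions with $|R| > 0.5$ and
  Bonferroni-corrected $p < 0.05$. The absolute value is used (anticorrelated
  profiles also indicate shared structure); the signed $R$ is returned so
  either convention can be audited.
* **Classification distance**: $1 - \langle\mathrm{AUC}\rangle$ of random
  forests (1000 trees, $\sqrt{p}$ features per split, Gini, fully grown)
  trained to separate a state from its matched wakefulness using the
  vectorized upper triangle of individual FC matrices, with no feature
  selection. Self-distance uses stratified 5-fold cross-validation;
  transfer distance trains on one state-versus-wake cohort and evaluates
  on another, with mean and sd over forest re-trainings (the source of
  variability for transfer is a package choice; fold-wise variability only
  exists for self-classification). Significance comes from label-shuffled
  retrainings.
* **Model-parameter distance**: the Euclidean distance between fitted
  regional bifurcation-parameter vectors.

Distance matrices are z-scored over their informative entries (unique
pairs for symmetric metrics, all off-diagonal entries for directed ones;
population standard deviation) for cross-metric comparison, and
"top fraction" edge lists keep the closest state pairs. Cross-metric
agreement is summarized by Spearman rank correlations over unique state
pairs (directed metrics are symmetrized by averaging the two directions
first).

Whether classifier inputs should use filtered or unfiltered FC is not
uniquely determined by common practice; the package applies the same
filtered pipeline everywhere and exposes `filter = FALSE` as a switch.

## The synthetic study

Because suitable clinical recordings cannot be redistributed, the package
ships a generator that builds a complete study with known ground truth,
using the forward model itself:

* a homotopically mirrored modular connectome (interleaved left/right
  ordering, identical intra-hemispheric blocks, attenuated
  cross-hemispheric weights, strong homotopic edges, scaled to 0.2),
* a hemisphere-symmetric RSN partition with optional overlap,
* multi-subject cohorts simulated per state from state-specific network
  contributions $g$, with optional forcing-derived states.

The default study (`toy_ground_truth()`) has 20 regions, 3 networks, 5
states and 20 subjects per state with 200 samples at TR = 2 s: a
wakefulness baseline on the oscillatory side of the bifurcation and four
graded states whose contributions move toward increasingly negative
values, mimicking the ordinal structure of states of reduced
consciousness. Intrinsic frequencies are uniform in 0.04–0.07 Hz and
shared within homotopic pairs. These sizes were chosen so that the full
pipeline, including a scaled-down genetic algorithm (population 10, 50
generations, a handful of runs, 10 simulated subjects per objective
evaluation), runs in minutes on a single CPU; they are study conditions,
fixed once, not tuning knobs.

What the synthetic study does *not* emulate: hemodynamics, head motion,
scanner differences, lesion heterogeneity, or any spatial embedding of
regions. Passing tests on it demonstrates internal consistency of the
machinery — recovery of generating parameters, closure of the
perturbation loop on forcing-constructed states, classifier calibration —
not clinical validity on real fMRI.

One empirical note from validating the generator: across-subject FC
variability is highest for deeply subcritical states (weak, noise-driven
correlations carry high estimator variance), so the noise-induced
switching signature of $a \approx 0$ shows up as *larger* variability
relative to the stable oscillatory regime ($a > 0$), not relative to
deeply negative $a$. The test suite asserts the former comparison.

## Degenerate inputs and tie-breaking

* All-zero connectomes cannot be scaled; zero-variance regions stop the
  pipeline with the offending region named (except in the
  connectivity-correlation distance, where a zero-variance profile sets
  that region's indicator to 0 with a warning).
* Candidates whose simulation diverges during fitting receive a penalty
  objective (default 10) with a warning, so the optimizer can continue.
* Edge lists and top-fraction selections break ties deterministically by
  region/state index; rank ties get average ranks.
* Amplitude grids must be strictly increasing and start at 0, so the
  cached-baseline column is always present.

## Reproducibility

Every stochastic routine takes a seed; child seeds are derived
deterministically, and the integrator uses its own seeded generator
(mt19937-64 with a hand-coded polar normal transform) so trajectories are
bit-reproducible for a given seed regardless of the platform's standard
library or R's global RNG state. `run_full_study()` writes every stage to
its output directory and skips stages whose output files already exist;
resumption is by file existence (not checksums), so delete stale outputs
when inputs change.

## A minimal session

```{r example, eval = FALSE}
gt <- toy_ground_truth(seed = 42)
cohorts <- make_multistate_cohort(gt)
fc_wake <- cohort_group_fc(cohorts$wake)

fit <- fit_state(fc_wake, gt$connectome, gt$membership, gt$omega,
                 ga_config = list(population = 10, generations = 50,
                                  n_runs = 5),
                 sim_config = list(n_subjects = 10, n_samples = 200),
                 master_seed = 1)
fit

res <- run_full_study(cohorts, gt$connectome, gt$parcellation,
                      gt$membership,
                      config = list(
                        ga = list(population = 10, generations = 50,
                                  n_runs = 3),
                        sim = list(n_subjects = 10, n_samples = 200),
                        sweep = list(n_reps = 10)),
                      master_seed = 1, out_dir = "study_out")
res$transition_graph
res$state_diagram
```

## Known limitations

* The BOLD proxy is the oscillator's real part; no hemodynamic forward
  model is applied, so absolute timescales should be read qualitatively.
* Only homotopic pair stimulation is implemented, matching experimentally
  plausible bilateral protocols; single-node or arbitrary-set stimulation
  is out of scope.
* The GA explores a six-or-so-dimensional box; it is not suited to
  fitting one parameter per region, and the global coupling `G` is fixed
  by design.
* SSIM-based GoF depends on region ordering (see above) and on the window
  configuration, which is exposed but rarely worth changing.
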