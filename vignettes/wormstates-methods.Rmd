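---
title: "Postural state analysis of eigenworm time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Postural state analysis of eigenworm time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormstates)
```

## The problem

*C. elegans* crawling postures can be summarized frame by frame as a
4-dimensional **eigenworm** vector: 48 tangent angles along the midline,
mean-centered to discard overall orientation, projected onto four
principal axes. A strain's behavior then becomes a time series in a
4-D posture space, and questions about behavioral phenotypes become
questions about (i) *which regions of posture space a strain occupies*
(state occurrence) and (ii) *how it moves between them* (state
transitions). The two are strongly coupled — using different postures
forces different transitions — so a strain is only interestingly
"atypical" when its transition pattern deviates from what its posture
usage already predicts. This package implements that whole chain of
reasoning as tested, reusable code, together with a synthetic data
generator so every claim can be verified without access to a behavioral
database.

## Postural states: a shrinkage-EM Gaussian mixture

Frames are binned into **postural states** by fitting a full-covariance
Gaussian mixture to a 1% subsample of all pooled frames
(`sample_frames()`, `fit_fab_gmm()`). Each mixture component is a state;
per-frame **responsibilities** (posterior state probabilities,
`responsibilities()`) represent every frame as a point on the K-simplex
rather than a hard label. A K-means/Lloyd baseline (`fit_kmeans()`)
provides the corresponding one-hot binning.

The number of states is selected automatically during fitting. After each
standard E-step, every responsibility column is multiplied by
`exp(-D_c / (2 N_k))`, where `D_c = 14` is the per-component parameter
count in 4-D (4 mean + 10 covariance entries) and `N_k` the component's
effective count; rows are renormalized and the shrinkage is iterated to
its fixpoint, so responsibilities and effective counts are
self-consistent. This factor is the component-wise gradient of the
factorized information criterion's `-(D_c/2) log N_k` penalty: components
with weak support shrink, which weakens them further, until their mixture
ratio falls below the threshold `eps` and they are pruned. Monitored
objective: expected complete-data log-likelihood + responsibility entropy
`- (D_c/2) sum_k log N_k - ((K-1)/2) log N`.

Numerical choices that matter:

* **Convergence tolerance 1e-10 with a 2000-iteration cap.** The
  objective flattens long before redundant-component competition
  finishes; with a looser tolerance the fit regularly stops one or two
  components above the correct count. The slowest resolving cases we
  observed needed roughly 1350 iterations.
* **Global-covariance initialization.** Components start at K-means++
  centers but all share the data's global covariance. Starting from tight
  per-cluster covariances lets a component lock onto a small pocket of
  tail points early and survive shrinkage indefinitely; broad initial
  overlap lets the shrinkage compete components while they can still
  exchange mass.
* **Covariance ridge 1e-6 after every M-step**, preventing collapse on
  near-duplicate frames.
* **Pruning from the first iteration**, with surviving weights always at
  least `eps`; states are reported ordered by descending weight.
* With shrinkage and pruning disabled the update is exactly EM (tested
  for monotone log-likelihood and against an independent mixture
  implementation).

## Occurrence, transitions, and divergences

For worm *i* with responsibilities `r[f, k]`:

* occurrence `r_i = mean_f r[f, ]` — a distribution over states;
* transitions `T_i[k, l] = mean_f r[f, k] r[f+1, l]` — a joint
  distribution over state pairs at adjacent frames (grand total exactly 1
  because each row of `r` is a distribution).

Distributions are compared with the **Jensen-Shannon divergence** in
natural-log units (`jsd()`, bounded by `log 2`); transition matrices are
compared as flattened distributions. Because the row marginal of `T_i`
is the occurrence over the first `F - 1` frames, the transition
divergence between two worms or strains dominates their occurrence
divergence up to an `O(1/F)` boundary term — a data-processing
inequality that the tests verify both exactly (on matrix pairs) and in
the per-worm form with tolerance `2 log(2) / F`.

**Binning evaluation.** If binning preserves postural information, worms
of one strain should use states more similarly than worms of different
strains. For each worm we compare its mean divergence to same-strain
worms (`delta_intra`) against an equally sized random sample of
other-strain worms (`delta_inter`); per strain, a one-sided
Wilcoxon-Mann-Whitney test (`wmw_one_sided()`, exact by enumeration for
combined samples up to 12 without ties, normal approximation with tie and
continuity corrections otherwise) asks whether `delta_intra` is
stochastically smaller, with Benjamini-Hochberg control across strains
(`bh_adjust()`, q < 0.05). Soft binning should — and in our tests does —
reach significance for at least as many strains as one-hot binning at the
matched state count.

## Screening for atypical transition patterns

Strain aggregates (`aggregate_strain()`) are unweighted means across
individuals; after quality control all worms have nearly equal frame
counts, so frame-weighting would change little. Against a reference
strain (wild type), each strain gets `delta_r = jsd(r_S, r_ref)` and
`delta_T = jsd(T_S, T_ref)`. Across strains these fall on a tight linear
trend; `regress_z()` fits `delta_T ~ delta_r` by OLS with intercept and
standardizes residuals, and `detect_atypical()` converts the upper tail
(`1 - Phi(z)`) to Benjamini-Hochberg q-values. Only the upper tail is
interesting: strains *below* the trend transition more predictably than
their postures suggest.

**Robust residual scale.** The screen's purpose is to find off-trend
strains, and those strains sit inside the naive residual SD: with `k`
equally off-trend strains among `n` records, `e / sqrt(RSS / (n - 2))`
can never exceed `sqrt((n - 2) / k)` — on a 20-strain panel with three
genuinely rewired strains that cap is 2.38, below any conventional
flagging threshold. The default estimator therefore discards residuals beyond 2 SDs and
rescales the remainder by the variance of a standard normal truncated to
[-2, 2] (0.7737), iterating the trim to a fixpoint — a single extreme
outlier otherwise inflates the first-pass SD enough to shelter moderate
ones — so the scale stays consistent when nothing is atypical. The
fitted line itself remains the plain OLS fit on all strains, as the
screen defines it; only the residual scale is robustified. `trim =
Inf` restores the naive estimator; `leverage = TRUE` switches to
internally studentized residuals. Residuals themselves are unchanged, so
`mean(z) = 0` always, and under the null the trimmed scale is consistent,
leaving false-discovery control intact (verified by simulation).

Flagged strains are characterized by per-state occurrence **fold
changes** against the reference with a pseudo-count
`1 / (10 K mean_F)` (`state_fold_change()`), and the corresponding
postures can be drawn by mapping state means back to 48 midline angles
through the orthonormal, column-centered basis
(`reconstruct_posture()`).

## Factor dissection: artificial reference strains

Two mundane factors can produce dramatic transition atypicality:
eliminating inactivity (quiescence) bouts and uniformly faster postural
change. `fit_artificial_params()` builds *artificial* reference strains:
every reference worm is transformed by

1. **inactivity removal** (`remove_inactivity()`): frame `f` is dropped
   iff its distance to the *previous original* frame is below `alpha`
   (single pass over original adjacency; frame 1 always kept);
2. **acceleration** (`accelerate()`): `beta = 2` keeps every other
   frame; `beta = 1.5` averages the second and third frame of every
   non-overlapping triple (trailing remainder kept); `beta = 1` is the
   identity —

in that order, for every pair on the grid `alpha = 0.3, 0.4, ..., 1.0`,
`beta = 1.5, 2.0`. The pair minimizing the L1 distance between pooled
empirical speed CDFs (`speed_cdf_distance()`, computed exactly on the
merged breakpoint grid; identical to the 1-D Wasserstein-1 distance) is
selected, ties to smaller `alpha` then smaller `beta`. Speeds are
Euclidean distances between adjacent eigenworm vectors, kept in per-frame
units at the working 5 fps. `evaluate_reproduction()` then re-bins the
transformed worms with the *fixed* state model — refitting the model on
transformed data would conflate binning changes with behavioral ones —
and standardizes the resulting divergences against the *previously
fitted* trend (`Z_a`). A strain whose `|Z_a|` is small is explained by
the two factors.

An extended grid with the identity cell (`alpha = 0`, `beta = 1`) is
available via `include_identity = TRUE` and returns the identity exactly
when the target is the reference itself.

## The synthetic generator: what it emulates, and what not

`simulate_strains()` generates collections with the statistical structure
the analysis assumes. Per worm, a latent attractor chain over `G = 6`
centers in 4-D (drawn once per collection with spread `5 sigma_act` so
states are resolvable) switches by a sticky row-stochastic matrix built
from symmetric edge weights `W = (1 - u) Q + u diag(pi)`; because `W`'s
row sums equal `pi`, the chain is reversible with stationary law `pi`
for any stickiness `u`. Active dynamics relax toward the current
attractor (`v <- v + lambda (m_g - v) + sigma_act xi`); at switch
boundaries a **rest bout** starts with probability 0.3, during which the
posture performs a tiny random walk (`sigma_rest = 0.02 << sigma_act =
0.2`) until a geometric exit (rate 0.05) — producing the contiguous
near-zero mode of postural change speed that real quiescent worms show.
A fraction of interior frames (default 5%) is masked as missing; the
first and last frames never are, because interpolation needs two flanks.

Defaults are the study conditions: 10 worms per strain (databases
typically record tens of individuals; 5 is just the QC survival
threshold), 4500 frames at 5 fps (900 s), `lambda = 0.5`. The relaxation
rate deserves a note: at 5 fps, `lambda = 0.5` means sub-second postural
relaxation. Much slower relaxation smears every attractor switch over
many intermediate frames, and the latent transition structure — the very
thing the retransition perturbation manipulates — becomes nearly
invisible to frame-pair statistics.

Perturbation kinds, mirroring what mutants do:

* **reweight** — different stationary usage `pi` (on-trend strains:
  occurrence and transitions shift together);
* **retransition** — switch targets rewired to a ring topology at
  *identical* diagonal (dwell times) and stationary vector: transition
  structure changes at matched state usage. Changing stickiness instead
  turned out to move occurrence and transitions proportionally (more
  boundaries mean more rest bouts, shifting occupancy), i.e. it is not a
  transition-specific perturbation;
* **no_rest** — rest-bout entry probability zero;
* **accelerate** — the dynamics are replaced by their `gamma`-step
  subsampled counterpart: `lambda' = 1 - (1 - lambda)^gamma`, noise
  compounded accordingly, switching matrix raised to the `gamma`-th
  power. Subsampling preserves the stationary posture distribution — and
  hence state usage — *exactly*, which is precisely the premise of the
  acceleration analysis (naively scaling `lambda` and `sigma` jointly
  inflates the stationary spread `sigma^2 / (2 lambda - lambda^2)` and
  changes state usage, which we verified breaks the artificial-strain
  reproduction). Kinds compose, e.g. `c("no_rest", "accelerate")` for a
  fast, never-resting mutant.

Reproducibility: one seed per collection draws the attractor geometry;
per-worm substreams are derived arithmetically from the collection seed
and worm index, so collections are bit-identical per seed and worms can
be generated independently.

What the generator does **not** emulate: measurement noise on the 48
angles, dorsal/ventral ambiguity, trajectory (x, y) information,
long-range non-stationarity (hunger, lethargus), or realistic
within-strain individuality beyond sampling noise. Green tests therefore
show that the *pipeline* is correct and discriminating under its own
assumptions, not that those assumptions exhaust real worm behavior.

## Problem sizes used by the tests

Unit tests run on deliberately tiny collections (hundreds of frames).
The end-to-end property tests use study-scale collections of 10-20
strains at 10 worms x 4500 frames, ten independent seeds each; the
mixture recovery benchmark uses n = 10,000 points with 50 initial
components; null-calibration simulations use 200 strains x 200
replicates (occurrence vectors simulated directly under the null, since
the tests under study operate on occurrence vectors, not raw frames).
These sizes were chosen as the smallest at which the studied effects are
stable across seeds.

## Known limitations

* The shrinkage construction (factor form, `(K - 1)/2` weight penalty)
  is one standard reading of FIC for mixtures; other readings differ in
  constants, which shifts the selected state count only at the margin.
* The mixture occasionally (about 1 seed in 10 at our benchmark sizes)
  retains one spurious low-weight component on hard cases; all
  state-count claims are therefore framed over seeds.
* Whether the 1% fitting subsample should be stratified by strain is
  open; we sample uniformly over pooled frames.
* The retransition perturbation's ring topology requires uniform
  stationary usage; non-uniform matched-usage rewiring needs a custom
  edge-perturbation matrix.
* Speed thresholds (`alpha`) act on per-frame displacements and are not
  rescaled if data are processed at a frame rate other than 5 fps.
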