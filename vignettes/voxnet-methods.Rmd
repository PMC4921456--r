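---
title: "voxnet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxnet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxnet)
```

## What the package computes

`voxnet` studies how voxel-level functional brain networks reorganize between
resting and task states, using the Iowa Gambling Task (IGT) as the task probe.
The analysis chain is: voxel time series → cleaning → Pearson correlation
matrix → density-controlled binary graph → efficiency and degree metrics →
regional (DMN/FPN) summaries, hub-topography comparison and group statistics.
Because no raw imaging data ship with the package, a synthetic-data module
generates the full multi-session study with known ground truth, and every
stage is tested against that ground truth or an independent oracle.

## The synthetic generator

Gray-matter voxels belong to labeled communities on a toy volumetric grid
(default: 4 mm voxels on a 48 × 56 × 44 grid whose affine covers standard
MNI-like coordinates, so the shipped DMN/FPN seed table is exercised
verbatim). Voxel $v$ in community $c$ follows a factor model

$$ y_v(t) = \sqrt{\rho_b}\,u_0(t) + \sqrt{\rho_c - \rho_b}\,u_c(t) +
\sqrt{1-\rho_c}\,e_v(t), $$

where $u_0$, $u_c$ and $e_v$ are independent unit-variance AR(1) processes.
This yields an exactly block compound-symmetric correlation structure —
within-community correlation $\rho_c$, between-community correlation
$\rho_b$ — and is positive semi-definite precisely when
$\rho_b \le \min_c \rho_c$, which `sim_params()` enforces with an informative
error. A shared global component (its own SD) is added to every voxel so that
global-signal regression removes something real, and motion-flagged volumes
receive additive displacement artifacts plus realignment-trace spikes so that
scrubbing has ground truth.

State presets encode the modular-to-integrated shift the analysis is designed
to detect:

| state | $\rho_w$ | DMN offset | FPN offset | $\rho_b$ |
|---|---|---|---|---|
| rest | 0.60 | +0.10 | 0 | 0.05 |
| task (IGT) | 0.45 | −0.10 | +0.10 | 0.25 |
| orienting | 0.50 | 0 | 0 | 0.15 |

These values were fixed once, on first principles: rest-like data are
strongly modular with a DMN advantage; task-like data are more integrated,
with fronto-parietal coupling up and default-mode coupling down; orienting is
intermediate (its blocks are generated and networked but excluded from
analysis, mirroring the session design of four repetitions of
rest → IGT → orienting per subject, 12 blocks and 108 networks for nine
subjects). Defaults elsewhere: 120 volumes at TR = 2 s, AR(1) coefficient
0.3, global-signal SD 0.5, two high-motion volumes of 1.5 mm per block.

What the generator does *not* emulate: hemodynamic convolution, scanner noise
spectra (1/f, physiological cycles), realistic continuous head-motion
trajectories, and spatial autocorrelation within communities. Passing tests
therefore demonstrate that the *pipeline* recovers planted structure — not
that real fMRI satisfies the block-covariance model.

## Cleaning chain

Fixed default order: discard the first 10 volumes, scrub volumes whose
framewise displacement exceeds 0.5 mm (FD is the sum of absolute translation
differences plus rotation differences converted on a 50 mm head radius; no
neighbor augmentation), band-pass 0.009–0.08 Hz, then regress white-matter
mean, CSF mean, the six realignment parameters and the gray-matter global
mean. The filter is a second-order Butterworth applied forward–backward
(zero phase); series are demeaned first since DC lies outside the pass band.
Filtering precedes regression so that the confound columns pass through the
same filter as the data, avoiding reintroduction of removed frequencies; the
reverse order is available via `order = "regress_first"` because the original
processing order in this literature is often unstated. The scrubbing
threshold is configurable; 0.5 mm is the common convention where none is
printed.

## Network construction

Edges come from the positive tail of the Pearson correlation matrix. The
density rule $N = K^S$ (default $S = 2.5$) fixes the target mean degree at
$K = N^{1/S}$, i.e. the edge count at $E = \mathrm{round}(NK/2)$ (half-up
rounding), so density — not a raw correlation cutoff — is matched across
blocks, subjects and conditions. The threshold $r^\*$ is the $E$-th largest
positive off-diagonal correlation; every pair at exactly $r^\*$ is kept
(deterministic, order-independent, may overshoot by the tie count; with
continuous data ties have measure zero and the granularity bound
$|K_{\mathrm{achieved}} - K| \le 2/N$ holds). Negative correlations are never
edges. `threshold_sweep()` takes either an $S$ list or an explicit target-$K$
list — some robustness analyses are reported on other thresholding scales —
and warns, recording the component count, when a sparse network fragments
(common for $S > 3$).

## Efficiency metrics

Global efficiency is the mean of $1/d(i,j)$ over ordered pairs, with
disconnected pairs contributing 0; this is the original mean-of-inverse-
distance definition, bounded in $[0,1]$ and finite on fragmented graphs,
which the inverse-of-mean-path-length reading is not — an important property
here because density-controlled voxel graphs at rest routinely split into
components. Local efficiency of a node is the global efficiency of its
neighbor-induced subgraph, 0 by convention for degree < 2. Whole-graph
distances come from breadth-first search (igraph); neighbor subgraphs use an
internal small-graph BFS. Both are verified against an independent
Floyd–Warshall oracle to 10⁻¹².

## Hub comparison

Hubs are the top 20% of the degree distribution (ceiling, extended across
ties at the cutoff; the realized fraction is recorded). Similarity between
two networks' hub sets is the Jaccard index, with two empty sets defined as
identical. The comparison statistic is mean within-condition similarity over
mean between-condition similarity; its null distribution is built from 512
label permutations. The default scheme permutes condition labels within
subject, respecting the repeated-measures exchangeability structure; a free
scheme is available. When the within-subject scheme admits no more distinct
rearrangements than requested, they are enumerated exhaustively (with a
warning). The p-value uses the add-one estimator
$(1+\#\{T^\pi \ge T\})/(1+n_\pi)$ with exceedance defined by ≥ (conservative,
never zero); its floor at 512 permutations is $1/513 \approx 0.00195$, which
is what a maximally separated topography attains — printed bounds smaller
than this floor cannot be produced by this test, and the result object
reports the floor explicitly.

## Regional masks

The shipped ROI table holds the 11 standard-space seeds (7 FPN, 4 DMN), each
a 10 mm sphere; masks include voxels whose center lies within the radius
(inclusive), with distances through the volume affine, and are intersected
with the gray-matter mask before averaging nodal metrics. The default study
atlas places a gray-matter community at each seed plus five generic
communities (~1000 nodes total), chosen to give desk-scale networks whose
target degree ($1004^{0.4} \approx 16$) is comfortably above fragmentation
while keeping a full 108-block study around a minute of compute. Node counts
of the original gray-matter networks are unknown, so network size is an
explicit synthetic parameter, not an emulation target.

## Group statistics

The 2 (condition) × 4 (session) repeated-measures ANOVA uses the classic
within-subject strata (each effect tested against its subject-by-effect
interaction); effect size is partial η² = SS_effect/(SS_effect + SS_error)
from the same decomposition — values like η² = 0.53 alongside F(1,8) are only
consistent with the partial form, so that is what is reported. Degrees of
freedom are uncorrected by default, matching common reporting practice;
Greenhouse–Geisser correction is available by flag (ε computed from
orthonormal-contrast covariances and clamped to ≤ 1). The
connectivity-performance model is a REML linear mixed model,
`score ~ K + E_loc + E_glob` with a subject random intercept and AR(1)
within-subject errors indexed by session order, fitted with nlme;
non-convergence is reported with the design size, never silently.

The behavioral simulator implements the four-deck payoff schedule as data:
decks 1/3 pay \$150 and net +\$250 per 10-card cycle, decks 2/4 pay \$200 and
net −\$250; decks 1/2 carry one large penalty per cycle, decks 3/4 five small
ones. Exact penalty positions are a design choice (fixed positions within the
cycle), since only the contingency structure is specified in this literature;
deck state resets between blocks. Performance is net-advantageous selections,
(decks 1+3) − (decks 2+4); missed responses count toward neither.

## Numerical and testing choices

Problem sizes in the test suite were chosen so the full run stays fast while
keeping statistical checks meaningful: oracle equivalence on 200 random
graphs of ≤ 40 nodes; permutation-test size calibration on 500 simulated
null datasets of 16 scaled-down networks (512 permutations each, binomial
95% tolerance around α = 0.05); mixed-model coverage over 100 simulations at
the 9-subject × 4-session design size; rest/task direction over 10 seeds with
a sign test. All simulator checks run under fixed seeds; generators are
bit-reproducible given a seed, and a full pipeline rerun with the same
configuration yields an identical manifest.

Known limitations: no hemodynamic model; compound-symmetric blocks cannot
express distance-dependent correlations; the permutation statistic compares
only hub-set overlap (no other network features); weighted and signed graphs
are out of scope; and the mixed model assumes a common AR(1) across subjects.
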