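---
title: "Simulating the molecular signature of clades in decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the molecular signature of clades in decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Molecular phylogenies contain only the species alive today. Methods that
read diversification history out of them almost universally assume that
diversity has been growing, yet the fossil record shows that many clades
spend long stretches of their history *losing* species. This package
simulates clades that rise and then fall in diversity and asks what their
extant-only ("reconstructed") phylogenies look like through the lens of the
most widely used slowdown detector, the gamma statistic — and whether that
look can be told apart from diversity-dependent diversification, the usual
interpretation of a slowdown.

## The model

Diversity follows a two-phase constant-rate birth–death process. During the
*waxing* phase each lineage speciates at rate $\lambda_{wax}$ and goes
extinct at rate $\mu_{wax}$ (net $r = \lambda - \mu > 0$); at the rate
shift the clade switches to a *waning* phase with
$\lambda_{wane} < \mu_{wane}$ and declines exponentially in expectation.
Simulations are conditioned on two outcomes: exactly `n_final` extant
lineages at the present (default 10) and a decline phase of exactly
`decline_duration` My (default 10). The conditioning makes scenarios with
different rise rates comparable: they all peak, on average, at about the
same standing diversity (about 76 lineages under the defaults), differing
only in how long they take to get there. The classic way to obtain such
trees is an off-the-shelf conditioned simulator (e.g. TreeSim); we use
transparent rejection sampling instead, described below.

The gamma statistic is computed from the internode intervals
$g_2, \dots, g_n$ of an ultrametric tree ($g_k$ = time during which exactly
$k$ reconstructed lineages exist, $T = \sum_j j g_j$):

$$\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1}\bigl(\sum_{k=2}^{i} k
g_k\bigr) - T/2}{T\sqrt{1/(12(n-2))}}$$

Under a constant-rate pure-birth process it is asymptotically standard
normal; the one-tailed 5% cutoff $\gamma < -1.645$ is the conventional test
for a diversification slowdown. The most negative value attainable with
$n$ tips is $-\sqrt{3(n-2)}$, reached by a star phylogeny (all splits at
the crown) — the limit of a clade aged for infinitely long. We expose this
bound (`gamma_star_min()`) and a normalization `normalized_gamma()`
(gamma divided by the magnitude of the bound, so every star phylogeny
scores $-1$); raw gamma is size-dependent, which matters when comparing
trees of different tip numbers.

## Parameters that matter

All rates are events/lineage/My, times in My.

* `lambda_wax` — rise-phase speciation. The study design varies it
  (0.25, 1.0, 2.0 by default in the analysis scripts) against a fixed
  decline, giving wax/wane speciation ratios of 2.5, 10 and 20 — it is the
  ratio, not the absolute rates, that controls the strength of the decline
  signature.
* `mu_wax = 0.1` — rise-phase extinction, held constant.
* `lambda_wane = 0.1`, `mu_wane = 0.3` — decline rates, identical across
  scenarios, net $-0.2$/My; matching the printed zero-speciation scenario's
  net rate.
* `decline_duration = 10`, `n_final = 10` — the conditioning targets.
* `t1_max = 60` — rejection proposals draw the rise duration uniformly on
  $[0, t1\_max]$; 60 My comfortably covers the slowest rise
  ($r = 0.15$ reaches the typical peak in $\approx 30$ My).
* `n_cap = 5000` — growth-phase proposals whose standing diversity exceeds
  the cap are rejected immediately. A clade at 5000 lineages has
  essentially zero probability of declining to exactly 10 tips in 10 My at
  net $-0.2$/My (binomial tail $< 10^{-200}$), so the cap only prunes
  doomed proposals early.

## The conditioned sampler

Rejection sampling: propose a rise duration uniformly,
simulate the rise from a single stem lineage, reject proposals extinct at
the shift (or capped), simulate the decline for exactly
`decline_duration`, and accept when exactly `n_final` lineages survive.
This is an approximation to the exactly conditioned rate-shift process
under a uniform origin-time prior; because that prior is a modelling
choice, distributions over the *time to peak* are not exactly comparable
with other conditioning schemes, and we verify instead the quantities the
design pins down — the conditioning itself (exact, on every accepted tree)
and the mean peak diversity (about 76). Each accepted tree records its
shift time, peak diversity and the number of proposals consumed; the
default budget is $10^6$ proposals, and exhausting it is an error rather
than a silent retry. Replicates draw independent substream seeds from the
master seed, so any single replicate can be reproduced alone.

Trees stopped at a fixed standing diversity (`simulate_fixed_n()`) stop,
by default, at the instant the target count is reached — the natural
reading of "grow to $n$ species", which leaves the last internode interval
zero. For null calibration of gamma that convention is biased: the proper
$n$-conditioned pure-birth sample includes the full exponential waiting
time while $n$ lineages exist. `complete_last_interval = TRUE` provides
it (the clock runs to the moment the next event *would* fire), and the
calibration and under-sampling experiments use that variant.

## What the experiments emulate — and what they do not

`run_decline_experiment()` "time travels": it slices each tree every 1 My
through the decline, prunes to the lineages that would have been sampled
then, and records diversity and gamma. `run_undersampling_experiment()`
isolates the effect of losing tips (extinction as "evolutionary
under-sampling") by pruning random tips from purely grown clades;
`run_stasis_experiment()` isolates the effect of elapsed time by aging
fixed clades; `run_no_speciation_decline()` removes the one ingredient —
decline-phase speciation — that adds young nodes during a decline.

The generator emulates the study conditions, not nature: rates are
constant within phases, there is no diversity dependence, no trait or age
dependence, no incomplete present-day sampling, and no phylogenetic
estimation error (trees are known exactly, with perfect branch lengths).
Passing tests therefore show that the *statistical signature* of decline
behaves as described under these idealized conditions; they say nothing
about whether a particular empirical gamma was produced by decline,
diversity dependence, or sampling artifacts — indeed the central point is
that these are confounded.

## Numerical choices

* Aliveness at a time point uses the half-open convention
  $[t_{birth}, t_{death})$: a lineage born exactly at a slice is counted
  (with a zero-length branch), one dying exactly there is not. Both events
  have probability zero in simulation; the convention only matters for
  hand-built trees.
* Ultrametricity is checked to an absolute $10^{-9}$ My; reconstructed
  trees are ultrametric by construction (tip times are all the present).
* Gamma requires $n \ge 3$ and a positive crown age; time-travel points
  with fewer than 3 lineages report `NA`, and summaries average only the
  defined values, reporting the excluded count rather than imputing.
* Significance uses the one-tailed normal cutoff with no multiple-testing
  correction across time points, matching the study design.
* The star bound is asserted with a $10^{-9}$ numerical cushion: interval
  vectors engineered to sit exactly on the bound can undershoot it by one
  ulp.
* Newick output carries 12 significant digits so event tables round trip
  to $10^{-9}$ My; extinct tips are flagged with a configurable `"X_"`
  label prefix, and node labels preserve lineage identity across pruning.

## Design choices where the design was open

* **Decline rates.** Since only the wax/wane speciation *ratio* matters
  qualitatively, we fix the decline at $\lambda = 0.1, \mu = 0.3$ (net
  $-0.2$/My, the same net rate as the zero-speciation scenario) and move
  the rise rate. Chosen once; all are overridable.
* **Normalization.** Several normalizations of gamma by tip number are
  conceivable; we divide by the magnitude of the star-phylogeny bound,
  $|\!-\!\sqrt{3(n-2)}|$, so that the normalized value is $-1$ exactly at
  the infinitely-aged limit for every $n$.
* **Under-sampling grid.** The default is 12 log-spaced retained-tip
  counts from the pool size down to 10, nested within a replicate (the
  $k-1$ set is a subset of the $k$ set) so trajectories are smooth in $k$.
* **Summary convention.** Trajectory means average only replicates whose
  gamma is defined ($\ge 3$ lineages at the time point) and report the
  excluded count, rather than imputing.
* **Envelope at the end of the zero-speciation decline.** Once the
  declining clade is down to exactly `n_final` tips its mean gamma
  converges onto the `n_final`-tip pure-aging curve (both trees then have
  the same tip count and comparable aging), so the between-the-curves
  property is asserted on the interior of the decline; at the endpoint
  only the lower (76-tip) envelope is meaningful.

## Problem sizes

The test suite and the acceptance script run the conditioning experiments
at 100 replicates (the study's own replicate count) and the scenario
contrasts at 50 replicates per scenario with Monte-Carlo-aware
assertions; null calibration uses 1000 pure-birth trees of 50 tips.
The analysis scripts under `analysis/` default to 50 replicates per
scenario.

## Known limitations

* The rejection sampler's uniform origin-time prior is a stated
  approximation; quantities that depend on the origin prior (e.g. the
  distribution of times to peak) are reported but not calibrated against
  any external reference.
* No exact (non-rejection) conditioned sampler, no diversity-dependent or
  protracted-speciation models, and no likelihood-based rate estimation:
  the package measures what gamma sees, it does not fit models.
* Polytomies are supported only as the degenerate star construction via
  interval vectors; simulated trees are strictly binary.
* Significance fractions at 50–100 replicates carry binomial noise of a
  few percentage points; the experiment summaries report standard
  deviations so users can scale replicates to their question.
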