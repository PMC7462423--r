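---
title: "Methods: transfer-entropy networks and partial information decomposition for spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transfer-entropy networks and partial information decomposition for spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikePID)
```

## Overview

spikePID analyzes multineuron spike-train recordings — the kind produced by
large multielectrode arrays over cortical cultures, with hundreds of
well-isolated neurons firing at lognormally distributed rates over an hour —
and asks how the correlation between pairs of *sender* neurons relates to
the information processing performed by a common *receiver*. The pipeline
has four stages:

1. **Discretization.** Spike times are binned into binary occupancy states
   at one of ten standard timescales (bin widths 0.05–750 ms, each with a
   set of source delays).
2. **Effective connectivity.** Directed connections are established by
   delay-maximized transfer entropy (TE), kept only when significant
   against a jitter-surrogate null.
3. **Triad decomposition.** For every pair of senders converging on a
   receiver, the senders' zero-lag normalized mutual information
   (pMI^max) is measured, and the multivariate TE into the receiver is
   decomposed into unique, redundant, and synergistic components
   (Williams–Beer partial information decomposition with I_min
   redundancy), each normalized by the receiver's entropy (pH^rec).
4. **Regime statistics.** Per network, triads are collapsed into deciles of
   sender MI; Spearman correlations and log10–log10 regression slopes of
   synergy, redundancy, and mvTE against MI are computed on the decile
   medians, compared across timescale groups with Wilcoxon tests, and
   summarized with percentile-bootstrap medians.

## The information measures

All information quantities use base-2 logarithms and plug-in
(maximum-likelihood) estimation of discrete joint distributions, with no
bias correction: the design relies on normalization — not debiasing — to
make values comparable across neuron pairs, and normalized quantities are
base-invariant.

**Normalized mutual information.** For simultaneous binned states of two
senders,

$$\mathrm{pMI^{max}}(J;K) = \frac{I(J;K)}{\min(H(J), H(K))} \in [0, 1],$$

the fraction of the maximum achievable mutual information given the two
entropies. When either marginal entropy is zero the quantity is undefined
and is returned as a flagged missing value, never a division by zero.

**Transfer entropy.** With order-1 receiver history (the single bin
preceding the future bin),

$$TE_d(J \to I) = \sum p(i_t, i_{t-1}, j_{t-d})
  \log_2 \frac{p(i_t \mid i_{t-1}, j_{t-d})}{p(i_t \mid i_{t-1})}.$$

A timescale evaluates TE at every delay in its set and keeps the maximum
(ties broken toward the smallest delay). Order-1 history is a deliberate
choice: higher orders explode the state space at submillisecond bins, and
the binary alphabet keeps every joint table small enough for exact plug-in
estimation. All delays of one timescale are scored on a common alignment
(the sample starting after the largest delay), so the delay comparison is
fair and the receiver-entropy bound `TE <= H(receiver)` holds exactly.

**Partial information decomposition.** For two senders at their own peak
delays, the multivariate TE $TE(\{J,K\} \to I)$ is decomposed as

$$Synergy = mvTE - TE_J - TE_K + Redundancy,$$

with redundancy the Williams–Beer I_min term: the expectation over the
receiver's (future, past) states of the smaller source-specific
information

$$I_{spec}(i_t; S \mid i_p) = \sum_s p(s \mid i_t, i_p)
  \left[\log_2 p(i_t \mid s, i_p) - \log_2 p(i_t \mid i_p)\right].$$

Because $I_{spec}$ is a Kullback–Leibler divergence it is nonnegative, so
redundancy is bounded by the smaller bivariate TE and both unique terms
are nonnegative by construction. All terms — including the bivariate TEs —
are evaluated on one shared joint table over (receiver future, receiver
past, J lagged, K lagged), which makes the accounting identity
`unique_j + unique_k + redundancy + synergy = mvte` hold to numerical
precision on every input. A second mode computes the *lower bound* of
redundancy, `max(0, TE_J + TE_K - mvTE)`: the smallest redundancy
consistent with nonnegative unique terms, giving the most conservative
synergy estimate `max(0, mvTE - TE_J - TE_K)`. Decompositions beyond two
senders are out of scope: triads subsample the input space of each
receiver while keeping the term structure tractable.

Normalization by the receiver's single-bin entropy (pH^rec) expresses each
term as the proportion of the receiver's capacity it accounts for; the
entropy is computed on the same delay-aligned sample as the decomposition,
and normalizing twice is an error.

## The ten timescales

The printed span of each timescale (0.05–3 ms up to 750–3,000 ms) fixes a
bin width and a delay set. All spans except the first have a max/min ratio
of 4, and the first has 3/0.05 = 60; the only delay sets consistent with
every span are therefore 1..4 bins (1..60 for the first timescale) at a
bin width equal to the span minimum. The nominal centers (3, 5, 11, 23,
48, 104, 225, 485, 1,044, 2,250 ms) are carried as labels only — they are
neither midpoints nor geometric means of the spans. Timescales 1–3 are the
*synaptic* group, 7–9 the *extrasynaptic* group.

Binarization uses occupancy (1 iff at least one spike in the bin) at every
bin width, including the widest. This is the standard choice for TE on
spike trains and keeps all alphabets binary; `binSpikes(..., binarize =
FALSE)` switches to spike counts, which the information code handles as a
larger discrete alphabet, for sensitivity analyses at wide bins.

## Surrogate significance testing

The null for one directed pair jitters each source spike independently by
uniform(−h, +h) and recomputes the delay-maximized TE; the target and its
history structure are untouched. The half-window defaults to 5× the
timescale's maximum lag — wide enough to destroy within-window spike
timing, narrow enough to preserve slow rate fluctuations. The p-value uses
the add-one rank estimator `(1 + #{null >= obs}) / (1 + n_jitter)`, which
is never zero; the defaults (5,000 jitters, alpha = 0.001) give a minimum
attainable p of about 2×10⁻⁴, and the code refuses configurations where
`n_jitter < 1/alpha - 1`. Edges are tested independently per timescale
with no multiple-comparison correction at the edge level. A TE of exactly
zero can never be significant, because every surrogate TE is nonnegative.

Note that significant TE marks *effective*, not anatomical, connectivity:
a chain A→B→C or a shared driver also induces genuine lagged dependence
between A and C at the analyzed timescale. The recovery tests therefore
score chance-level calibration only on pairs with no planted dependence
path.

## Regime statistics

Per network, usable triads (unflagged, with defined sender MI) are sorted
by pMI^max and split into ten contiguous deciles; when the count is not
divisible by ten the remainder goes to the lowest-MI deciles — any fixed
rule works, this one is deterministic and documented. Analyses run on the
decile medians (the triad-level mode is available as a switch, and the
whole pipeline can run non-normalized). Log-log fits exclude nonpositive
medians and report the exclusion count rather than flooring them, which
would bias slopes; fits with fewer than three usable points are flagged.

Both Wilcoxon tests use the normal approximation with average ranks and
tie-corrected variances, reporting signed Z statistics (this is what makes
the degenerate closed forms checkable: 75 uniformly signed distinct values
give Z ≈ 7.52, fully separated 75-vs-75 groups give Z ≈ 10.57).
Bootstrap CIs are percentile-based (2.5th/97.5th of the median over
resamples), deterministic given a seed. Holm correction wraps
`stats::p.adjust`.

The *saturation point* of one network is the decile-median MI at which the
decile-median synergy peaks; a peak at the first or last decile is a
boundary case (monotone curve) and is flagged. Across networks the median
and its bootstrap CI are reported.

## The synthetic generators

The generators define the study conditions for every validation in the
package; real recordings of this type are not redistributable, so all
tests run against synthetic data with known ground truth.

* **Triads** (`generateTriad`): senders are Poisson trains sharing a
  common Poisson source. The shared fraction c is the correlation dial:
  superposition preserves marginal rates exactly and gives analytic c = 0
  (independent) and c = 1 (identical) limits, which a copula-thinning
  construction would not. The receiver applies a boolean gate (`copy_j`,
  `or`, `and`, `xor`) to binarized sender states at an internal 1-ms bin
  width — decoupled from the analysis bin width — and fires at a fixed lag
  with given reliability over background Poisson noise.
* **Networks** (`generateNetwork`): lognormal rates (default median
  2 spikes/s, log-sd 0.5, matching the order of magnitude of culture
  recordings), independent directed edges, each implemented as lagged
  excitation (per source spike, a target spike at the connection's lag
  with the connection's reliability). Defaults use lags of 2–6 ms and
  reliability 0.8 — placeholder values in the physiological range, not
  claims about any real preparation.
* **Regime populations** (`plantedRegimePopulation`): triad tables with
  log-uniform MI and synergy following either a planted power law
  (`mi^0.46` by default) or a log-Gaussian bump peaking at a planted
  saturation point; redundancy and mvTE are constructed as fixed
  multiples of synergy so the accounting identity holds with nonnegative
  uniques. In bump mode each network's MI range is shifted by a uniform
  ±0.15 decades so the recovered per-network saturation points vary
  continuously around the planted value rather than snapping to a decile
  grid.

What the generators deliberately do not emulate: bursting and avalanche
dynamics, refractoriness, inhibition, nonstationarity, and electrode-array
geometry. Passing tests therefore demonstrate the correctness and
calibration of the estimators and statistics under Poisson-like
conditions, not robustness to every feature of real cortical data.

## Numerical choices and problem sizes

* `0 log 0 = 0` throughout; distributions are validated to sum to 1 within
  1e-8; PID terms are required to be ≥ −1e-10 and to satisfy the
  accounting identity within 1e-10, else an internal-consistency error is
  raised.
* Undefined quantities (zero-entropy marginals) are flagged missing
  values, and flagged triads are excluded from decile statistics.
* Delay ties in the TE maximization break toward the smallest delay.
* All randomness flows through explicit integer seeds
  (`withr::with_seed`); no function touches global RNG state, and the
  pipeline derives per-task subseeds from its master seed, making triad
  tables byte-identical across reruns.
* Validation problem sizes are scaled for a desk run: surrogate
  calibration uses 200–500 independent pairs at 200 jitters and
  alpha 0.05; edge recovery uses 30 neurons, 20 planted edges, 60-s
  recordings, and 199 jitters at alpha 0.01; regime recovery uses 75
  networks × 800 triads. The defaults (5,000 jitters, alpha 0.001,
  10,000 bootstrap iterations, hour-long recordings with hundreds of
  neurons) are the intended operating point for real data.

## Known limitations

* Plug-in TE is biased upward at short recordings; the jitter null
  absorbs the bias for significance testing, but raw TE values from short
  rasters should not be compared across very different sequence lengths.
* I_min is known to overestimate redundancy in some constructions; the
  `lower_bound` mode provides the conservative alternative, and both are
  exposed.
* The mvTE delay handling evaluates each sender at its own peak delay; a
  joint delay search is conceivable but quadratic in the delay set.
* Effective connectivity includes indirect (chain and common-drive)
  dependencies by design; downstream interpretation should not read edges
  as monosynaptic contacts.
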