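# spikePID

Transfer-entropy effective networks and partial information decomposition
for multineuron spike-train recordings.

## What it is for

Large multielectrode-array recordings yield hour-long spike trains from
hundreds of neurons. A recurring question about such data is whether
*correlated* activity between neurons helps or hinders the *computation*
performed downstream. spikePID implements an information-dynamics pipeline
that answers this at the level of **triads** — two sender neurons with
significant directed connections onto a common receiver:

1. **Effective connectivity.** Directed connections are established by
   delayed transfer entropy, maximized over a timescale-specific delay
   set,

   TE_d(J→I) = Σ p(i_t, i_{t−1}, j_{t−d}) log₂ [ p(i_t | i_{t−1}, j_{t−d}) / p(i_t | i_{t−1}) ],

   and kept only when significant against a spike-jitter surrogate null
   (default α = 0.001 with 5,000 jitters). Ten standard timescales span
   bins of 0.05–3 ms ("synaptic") up to 750–3,000 ms ("extrasynaptic").
2. **Sender correlation.** Per triad, the senders' zero-lag mutual
   information normalized by the smaller sender entropy,
   pMI^max = I(J;K) / min(H(J), H(K)) ∈ [0, 1].
3. **Decomposition of transmission.** The multivariate transfer entropy
   TE({J,K}→I) is split into unique, redundant, and synergistic parts by
   the Williams–Beer partial information decomposition with I_min
   redundancy:

   Synergy({J,K}→I) = TE({J,K}→I) − TE(J→I) − TE(K→I) + Redundancy({J,K}→I),

   each term normalized by the receiver's entropy (pH^rec). A
   conservative `lower_bound` redundancy mode is also provided.
4. **Regime statistics.** Triads are collapsed into deciles of pMI^max
   per network; Spearman correlations, log₁₀–log₁₀ regression slopes,
   percentile-bootstrap medians, Wilcoxon signed-rank / rank-sum Z
   statistics, Holm correction, and saturation-point detection operate on
   the decile medians.

Because recordings of this type are rarely redistributable, the package
ships a spike-train simulator (correlated Poisson senders via a shared
source, boolean-gate receivers, lognormal-rate networks with planted
lagged connections, and planted regime populations) so that every stage
is testable against known ground truth.

## Worked example

Simulate a triad whose senders share half their drive (an OR-gate
receiver at a 4-ms lag), build the effective network at a 4-ms timescale,
and decompose the transmission:

```r
library(spikePID)

rec <- generateTriad(rateJ = 30, rateK = 30, commonDrive = 0.5, gate = "or",
                     lagMs = 4, reliability = 0.9, backgroundRate = 2,
                     duration = 120, seed = 42)
rec
#> SpikeRecording: 3 neurons, 12350 spikes, 120 s
#>   label: synthetic triad (or gate, c = 0.5)
#>   firing rates (Hz): median 30.6, range [30.2, 42.1]

spec <- list(id = NA, bin_width_ms = 4, delays = 1:4)
net <- buildEffectiveNetwork(rec, spec, nJitter = 199, alpha = 0.01, seed = 7)
edges(net)
#>    source target        te   te_norm peak_delay p_value
#> 3       1      3 0.2935543 0.4671859          1   0.005
#> 31      2      3 0.2851895 0.4538735          1   0.005

evaluateTriads(rec, net)[, c("mi_norm", "mvte", "redundancy", "synergy",
                             "unique_j", "unique_k")]
#>   mi_norm  mvte redundancy synergy unique_j unique_k
#> 1    0.23 0.797      0.454   0.329   0.0133 8.84e-17
```

Both planted connections are recovered (p = 0.005 is the smallest
attainable p with 199 jitters) at the true 1-bin delay. The senders share
23% of their maximum possible mutual information; the two together
account for 80% of the receiver's entropy, of which more than half is
redundant (the senders share an OR-driven receiver and half their drive),
a third is synergistic, and almost nothing is unique — the symmetric
construction leaves no information that only one sender carries.

For a full multi-timescale run over recordings on disk, see
`runPipeline()`, or the thin command-line wrapper in
`inst/exec/spikepid.R` (subcommands `simulate-triad`, `simulate-network`,
`build-network`, `run`).

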