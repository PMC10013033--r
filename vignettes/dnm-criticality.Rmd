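---
title: "Detecting brain criticality with dynamical network markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting brain criticality with dynamical network markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnmcrit)
```

## The model and its assumptions

The critical-brain hypothesis holds that healthy cortical dynamics sit near
a phase-transition-like critical state, while psychotic disorders push the
system into more stable, less flexible regimes. `dnmcrit` operationalises
this with the dynamical-network-marker (DNM) framework applied to
multichannel event-related EEG.

The observable is the **corrected epoch**: a deviant-stimulus epoch minus
the subject's mean standard-stimulus response, sample by sample. Near a
codimension-one bifurcation this difference process is well approximated by
a linear stochastic recursion

\[ z(t+1) = A(\lambda)\, z(t) + \xi(t), \]

where \(A(\lambda)\) is the Jacobian of the underlying dynamics and \(\xi\)
small additive noise. DNM theory predicts that as the leading eigenvalue
modulus of \(A\) approaches 1, a specific subnetwork — the DNM group —
shows sharply increased signal variance and inter-member correlation, while
other channels stay bounded. All downstream statistics are built on this
prediction:

* **DNMnet selection.** Channels whose corrected-epoch SD is significantly
  larger in the near-critical group than in the stable group become nodes
  (one-sided test, Benjamini–Hochberg FDR, adjusted p < 10⁻³); channel
  pairs with significantly stronger absolute pooled correlation become
  edges (one-sided rank-sum, adjusted p < 0.005). A reverse screen reports
  pairs whose correlation significantly *decreases* (α = 0.05).
* **DNM index.** The geometric mean of the node SDs times the geometric
  mean of the absolute edge correlations. It is dimensionally a voltage
  (µV) and scales linearly with the signal; it rises near criticality.
* **Distribution entropy (DE)** and **network entropy (NE)**. Lagged
  Gaussian mutual information \(I_{x\to y} = -\tfrac12\log(1-\rho^2)\),
  with \(\rho\) the Pearson correlation of \((x_t, y_{t+\Delta t})\), is
  computed for every ordered node pair. DE is the Shannon entropy of the
  normalised MI distribution over all \(n(n-1)\) directed pairs, divided by
  \(\log n(n-1)\) (so DE ∈ [0,1] and is base-independent); NE is the mean
  per-node entropy of normalised *outgoing* MI (nats, at most
  \(\log(n-1)\)). Isotropic information flow — the critical regime where
  all intra-DNM couplings grow together — gives high entropy.
* **Conditional transfer entropy (CTE).** For every ordered channel pair,
  \(-\tfrac12\log(1-r^2)\) with \(r\) the partial correlation of
  \((x_t, y_{t+\Delta t})\) given all channels at time \(t\) except \(x\)
  (the target's present value included). Conditioning on the full present
  state excludes influences routed through third channels, so CTE reads
  out *direct* causality. Stable dynamics show regular, strong direct
  causality; near-critical dynamics are dominated by the collective
  critical mode and show weak direct pairwise transfer.
* **Risk.** Per-epoch covariance features restricted to DNMnet channels
  feed a bagged classification-tree ensemble trained on the stable
  (label 1) versus near-critical (label 0) epochs; a subject's risk is the
  mean hard label over their epochs, and cohort-level risk-accuracy
  indices summarise how well the sorted risks recover the group blocks.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `delta_t` | 20 | ms | MI/CTE lag; must be a multiple of the sample interval |
| `node_alpha` | 1e-3 | — | FDR-adjusted node-selection level |
| `edge_alpha` | 0.005 | — | FDR-adjusted edge-selection level |
| `screen_alpha` | 0.05 | — | decreasing-correlation screen level |
| `epoch_window` | −100..400 | ms | epoch extent (inclusive start, exclusive end) |
| `baseline_window` | −100..0 | ms | per-epoch baseline subtraction |
| `reject_amplitude` | 100 | µV | absolute-peak artifact rejection |
| `n_trees` | 100 | — | bagged trees in the risk ensemble |
| `cv_folds` | 5 | — | subject-grouped cross-validation folds |

MMN is measured per channel as the most negative sample between 100 and
250 ms (peak latency, ties to the earliest sample) and the mean signal over
a fixed window — 135–205 ms for duration deviants, 100–200 ms for frequency
deviants. We read the conventional "mean around the peak" definition as the
fixed stated windows rather than a peak-centred window: the windows are
given as fixed intervals, and a fixed window keeps the statistic linear in
the waveform.

## What the simulator emulates — and what it does not

No public corrected-epoch dataset accompanies this analysis, so the package
ships a generative model of the study conditions: 64-channel recordings at
500 Hz, 2000-stimulus two-tone oddball sequences (90% standard / 10%
deviant, 500 ms SOA, no two consecutive deviants), and three groups
mirroring a 49 HC / 24 UHR / 29 PD cohort.

Each group is a linear network:

* a planted DNM block (8 fronto-central channels) with uniform all-to-all
  coupling rescaled so the block spectral radius equals the group's
  `gamma` — 0.97 for HC (near-critical), 0.8 for UHR, 0.6 for PD (stable);
* remaining channels with weak self-coupling (0.25) plus a directed
  nearest-neighbour coupling ring whose strength is *inversely* related to
  criticality (0.10 HC, 0.15 UHR, 0.65 PD) and which acts through a 10 ms
  conduction delay. This is the generative mechanism for the
  stable-brain-stronger direct causality: a system far from criticality
  expresses its couplings as regular pairwise transfer, and the
  physiological conduction delay keeps that transfer visible at lags of
  10–40 ms. The delayed system is stationarity-checked in companion
  (stacked-state) form, which restores the first-order recursion exactly.
  A plain lag-1 ring was rejected during design because multi-step path
  attenuation extinguishes its transfer by a 40 ms lag, inverting the
  causality ordering there;
* standard stimuli evoke a fixed biphasic ERP template on the DNM channels
  (it cancels exactly in corrected epochs); deviants additionally evoke a
  negative Gaussian MMN deflection (−3/−2/−1 µV at 170/175/180 ms for
  HC/UHR/PD, width 25 ms) and carry one stationary segment of the
  difference-process dynamics, so corrected epochs realise \(z(t)\);
* i.i.d. Gaussian sensor noise (5 µV) everywhere; dynamical noise
  \(\xi\) also 5 µV.

The magnitude of \(\xi\) relative to the ERP is not identified by any
published quantity; the defaults were chosen once so that group separation
is detectable at cohort sizes of roughly 30 per group, and they are
deliberately not tuned beyond that. Omissions that matter when porting
conclusions to real data: no 1/f spectral structure or line noise, no
volume conduction or electrode geometry, no per-subject heterogeneity in
`gamma`, no artifacts beyond amplitude outliers, and groups that differ
*only* through the planted mechanisms. Passing tests therefore demonstrate
that the estimators recover known structure under the stated model, not
that real EEG satisfies that model.

## Numerical choices

* Natural logarithms throughout (nats); DE is base-independent by
  normalisation.
* Lagged pairs never cross epoch boundaries; epochs are demeaned per
  channel within each epoch before pooling, removing stimulus-locked
  covariance from correlation estimates (switchable via
  `demean_epochs = FALSE`).
* \(| \rho |\) is clipped so \(\rho^2 \le 1 - 10^{-12}\): degenerate
  perfectly-dependent inputs give large finite MI/CTE instead of Inf.
  Zero-variance channels yield MI/correlation 0 with a warning.
* All-zero MI networks: DE returns 1 (maximal uniformity), NE counts
  silent nodes as zero-entropy contributors; both warn.
* The CTE conditioning set is all channels at time \(t\) except the
  source — including the target's present value — read literally from the
  definition of the conditional mutual information; this makes CTE a
  transfer-entropy-like quantity that accounts for the target's own past.
* The 65-variable partial correlations are computed through the precision
  matrix of the pooled lagged covariance (mathematically identical to
  residualising both variables on the conditioning block); if that matrix
  is ill-conditioned (reciprocal condition number < 1e-12), a ridge of
  1e-6 × mean diagonal is added. A pooled-sample floor of 5× the
  conditioning dimension is enforced with an informative error.
* Rank-sum tests are exact for untied samples (both sizes < 50), otherwise
  the continuity-corrected normal approximation with tie correction is
  used; degenerate all-tied inputs return p = 1 with a warning.
* Risk ties are broken by a stable sort on subject order, documented in
  `risk_accuracy()`.

## Open design points and how they were resolved

* **Node test.** The source analyses describe the node criterion once as a
  one-sided paired t-test and once as a one-sided rank-sum test. The
  default here is the rank-sum contrast of per-subject corrected-epoch SDs
  between the near-critical and stable groups (robust, and matching the
  edge criterion); `node_test = "paired_t"` implements the other reading —
  each near-critical subject's corrected-epoch SD paired against the same
  subject's standard-epoch SD, the only within-subject pairing available.
* **Edge universe.** Whether edges were tested among all channels or only
  among selected nodes is not documented; the default tests all pairs
  (`edge_universe = "nodes"` restricts).
* **Pooling.** MI/CTE correlations are pooled across epochs after
  per-epoch demeaning rather than averaged per epoch; per-epoch estimates
  of a 65-variable partial correlation would be badly rank-deficient at
  250 samples per epoch.
* **Per-epoch covariance features.** "Covariance features per sample" is
  read as per-epoch covariance matrices: the epoch-level classifier
  outputs are what the subject-level risk averages over.
* **UHR placement.** UHR subjects are never used in training; they are
  scored by the HC/PD-trained ensemble only.

## Problem sizes used in the shipped checks

The bundled tests and the acceptance script run the full pipeline on
cohorts of 30 HC / 20 UHR / 30 PD subjects, 32 channels with an 8-channel
planted DNM block, and 150 stimuli per subject (≈15 corrected epochs), with
10 independent seeds for the recovery and ordering statistics; estimator
oracles use 10⁴–10⁵ samples. These sizes were chosen as the smallest at
which the group-level effects are comfortably powered; the simulator scales
to the full 64-channel, 2000-stimulus design through `sim_config()`.

## Known limitations

* The Gaussian MI/CTE forms are exact only for jointly Gaussian processes;
  on strongly non-Gaussian data they measure linear dependence only.
* The CTE null is biased upward by finite-sample partial-correlation noise
  (order \(1/2(n-p)\) nats); group comparisons are unaffected because the
  bias is common, but absolute CTE values should not be read as
  information rates.
* With very few corrected epochs per subject the per-epoch covariance
  features become noisy and the risk CV accuracy degrades before the
  group-median ordering does.
* The archive format is a plain-text CSV set; it is exact but not compact,
  and is intended for moderate epoch counts.

## A worked example

```{r example, eval = FALSE}
library(dnmcrit)

gs <- default_group_specs()
gs$n <- c(12L, 8L, 10L)           # scaled-down cohort for illustration
cfg <- sim_config(n_channels = 32, n_stimuli = 300, dnm_members = 1:8,
                  groups = gs, seed = 1)

fit <- dnm_analysis(generate_study(cfg), seed = 1)
summary(fit)
plot(fit)
```

The printed summary reports the selected DNMnet, the median DNM index, DE
and NE per group (expected ordering HC > UHR > PD), the rank-sum contrasts,
and the risk analysis with its subject-grouped cross-validation accuracy
and risk-accuracy indices.
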