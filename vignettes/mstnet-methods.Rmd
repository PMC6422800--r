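---
title: "Phase-lag-index spanning-tree analysis of resting-state EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-lag-index spanning-tree analysis of resting-state EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(mstnet)
```

## The problem

Comparing functional brain networks between groups with conventional
thresholded graphs is fragile: every choice of threshold changes edge density,
and most graph measures covary with density. The minimum-spanning-tree (MST)
approach sidesteps this by reducing every subject's connectivity matrix to its
unique strongest-connection backbone — an acyclic subgraph with exactly
`n - 1` edges for `n` electrodes — so that any two subjects' networks are
compared at identical size and purely on topology. `mstnet` implements that
pipeline end to end for multichannel resting-state EEG: band-limited phase lag
index (PLI) connectivity, descending-weight Kruskal tree extraction, nodal and
global tree measures with hub localisation, and covariate-adjusted group and
severity statistics. A synthetic cohort generator with controllable phase
coupling and group-dependent topology makes every stage testable without
access to recordings.

## Connectivity: the phase lag index

For two channels with instantaneous phases $\phi_i(t_k)$ and $\phi_j(t_k)$,

$$\mathrm{PLI}_{ij} \;=\; \bigl|\,\langle \operatorname{sign}\,
\sin(\phi_i(t_k) - \phi_j(t_k)) \rangle_k \,\bigr| \in [0, 1].$$

The PLI measures the *asymmetry* of the phase-difference distribution around
zero (mod $\pi$). A consistent nonzero lag gives values near 1; zero-lag
synchrony — the signature of volume conduction, where one source projects
instantaneously to several electrodes — gives exactly 0 because
$\operatorname{sign}\sin(0) = 0$. Exact zeros of the sine contribute 0 with no
epsilon thresholding, following the estimator's definition literally.

Implementation choices:

* Phases come from the analytic signal (frequency-domain Hilbert transform),
  computed per epoch on data that were **band-filtered as a continuous
  recording** — filtering before segmentation keeps filter edge transients out
  of the epochs.
* The first and last 5% of samples of each epoch are excluded from the signum
  average (`edge_trim = 0.05`, configurable) because the analytic signal is
  least reliable at epoch edges.
* Inside `pli_matrix()` the signum is evaluated directly on the analytic
  signal via $\operatorname{sign}\sin(\phi_i-\phi_j) =
  \operatorname{sign}\,\mathrm{Im}(z_i \bar z_j)$, which is exactly equivalent
  to the phase-difference route (the tests assert bitwise agreement with
  `pli_pair()` on explicit phases).
* PLI is estimated per epoch and then averaged across epochs, which matches
  the convention of averaging network characteristics over epochs per subject;
  a pooled mode (concatenating epochs into one estimate) is available behind
  `pooled = TRUE`.

## Preprocessing

* **Filtering**: zero-phase (forward–backward) Butterworth of design order 4
  per band via `bandpass()`; the default bands are delta 0.5–4, theta 4–8,
  alpha1 8–10, alpha2 10–13, beta 13–25 and gamma 25–49 Hz. A broadband
  0.5–50 Hz pre-filter (`prefilter()`) stands in for the usual
  drift/line-noise cleanup stage. The C++ filtering kernel replicates
  `signal::filtfilt` exactly (tested to equality); note that high-Q
  narrowband IIR recursions are conditioned such that independent orderings
  of the same arithmetic can differ at the $10^{-7}$ relative level, which is
  why the linearity test uses that tolerance.
* **Segmentation**: consecutive non-overlapping 2000 ms epochs, trailing
  partial epoch discarded.
* **Rejection**: any epoch exceeding ±150 µV at any channel/sample is
  rejected automatically (the amplitude criterion replaces interactive
  artifact screening; independent-component cleanup is out of scope).
  Subjects with fewer than 80 surviving epochs are flagged in the QC table
  and by a warning, not dropped — small synthetic fixtures run with a lower
  `min_epochs`.
* **Band power**: the ANCOVA covariate is the kept-epoch mean of the
  per-epoch periodogram integrated over the band (epochs act as Welch
  segments with a rectangular window); a unit-amplitude in-band sinusoid has
  power 0.5 and power scales quadratically with amplitude.
* Optional mastoid-style re-referencing is provided as a linear hook
  (`rereference()`), off by default for synthetic data.

## Tree extraction and measures

The "minimum spanning tree" of this literature is the **maximum-weight**
spanning tree of the PLI matrix (equivalently the minimum tree of
1 − PLI): weights are sorted in descending order and added unless they close
a loop (Kruskal), with exact ties broken deterministically by the
lexicographically smallest channel-index pair so results are identical across
platforms.

Nodal measures: raw degree (normalized by `n - 1`), betweenness centrality
(fraction of the $(n-1)(n-2)/2$ unordered pairs of other nodes whose unique
tree path crosses the node), eccentricity in hops (normalized by `n - 1`).
Global measures: `max_degree`, `max_bc`, mean normalized eccentricity `ecc`,
`diameter`, leaf fraction `leaf`, tree hierarchy
$Th = L / (2 (n-1) \, \mathrm{BC}_{max})$, degree divergence
$\kappa = \sum k^2 / \sum k$, and the degree correlation `r` (Pearson
correlation of endpoint degrees over the symmetrized edge list). Anchors: a
path has $Th \to 0$ and diameter 1; a perfect star has $Th = 0.5$,
leaf fraction $(n-1)/n$, diameter $2/(n-1)$, $\kappa = n/2$ and $r = -1$.
The normalizations (degree/ecc/diameter by `n - 1`, BC by the pair count,
leaf by `n`, kappa unnormalized) reproduce the magnitudes conventionally
reported for 64-channel MSTs. Where the endpoint degrees have zero variance
(a two-node tree) `r` is reported missing, never coerced to 0; epoch averages
of `r` use only the epochs where it is defined and report the count.
Kappa is implemented as the degree divergence $\sum k^2/\sum k$, the standard
reading of the "synchronization-related" kappa measure in this literature.

The hub is the channel maximizing the group mean of nodal degree or
betweenness; ties break by montage order. Whether nodal analyses should use
epoch-averaged nodal values is not fixed by convention; epoch-averaged is
implemented.

## Statistics

* **Group comparison**: one-way ANCOVA per measure and band —
  `measure ~ group + age + sex + log(band power)` — testing the group term
  with a partial F (type-III equivalent, group being the only factor),
  $p$ from $F(1, n-k-1)$, effect size partial $\eta^2 =
  SS_g / (SS_g + SS_{res})$. Sex is coded 0/1; band power is that band's own
  power, log-transformed by default for variance stabilization (toggleable).
  Covariates with zero variance (e.g. an all-female small cohort) are dropped
  with a message instead of producing a rank-deficient design.
* **Multiple comparisons**: Bonferroni over the nine global measures per
  band, threshold $0.05/9 \approx 0.006$.
* **Regional tests**: per-channel two-sample t-tests (pooled variance by
  default, Welch behind a flag) on nodal degree and betweenness, uncorrected
  (with an optional FDR column), matching the exploratory convention.
* **Severity**: Pearson correlation between measures and the IAT score with
  the exact $t$-transform $p$-value.
* **Demographics**: age/IAT two-sample t-tests and a Pearson chi-square
  without continuity correction for sex (Yates correction behind a flag),
  with validity warnings for small expected counts.

## The synthetic cohort generator

Each channel carries a narrowband oscillator — a sinusoid at the band centre
whose instantaneous frequency wanders inside the band (smoothed white-noise
jitter, SD = bandwidth/6) — plus 1/f noise. A coupling edge makes the
receiving channel mix in a lagged copy of the source channel's oscillator.
Mixing is **power-preserving**: with variance share $s$, the channel is
$\sqrt{1-s}\,\times$ own oscillator $+ \sqrt{s}\,\times$ lagged copy, so
per-channel signal power is independent of the coupling structure. This
matters statistically: if coupling changed signal power, the band-power
ANCOVA covariate would be mechanically confounded with the group effect and
would absorb genuine topology differences.

A cohort's coupling structure per band is a mixture of a **star** (one hub
coupled to every other channel) and a **path** (channels chained in montage
order); the mixing proportion ("star bias", 0.5 by default with
between-subject SD 0.08) is the single dial that moves tree topology between
line-like and star-like. Group-dependent topology (`star_bias` added for the
IA group) and severity-dependent topology (`iat_coupling`, centred at the
IAT normal/excessive boundary of 50 where the topology response is steepest)
are injected through it; specific edges can additionally be boosted per group
(`edge_boost`). Metadata emulate the study population the pipeline is aimed
at: IAT 59.0 ± 7.88 resampled into 50–79 (IA) vs 34.4 ± 8.53 into 20–49
(HC), ages ~21.0 ± 2.13 vs ~20.5 ± 1.59, sex ratios ~7/30 vs ~6/30 male,
integer scores clipped to the 20–100 scale. Amplitude artifacts (a
configurable per-epoch spike probability) exercise the rejection stage, with
the injected epochs recorded for bookkeeping tests.

What the generator does **not** emulate: volume conduction and field spread
(beyond the zero-lag case PLI suppresses by construction), realistic scalp
topographies from forward models, ocular/muscle artifact morphology, and
non-stationarities such as drowsiness. Passing tests therefore demonstrate
the correctness and calibration of the estimators and statistics, not that
real recordings would show any particular effect.

### Calibrated effect sizes

Two generator settings are frozen calibration results rather than arbitrary
defaults, obtained on pilot cohorts (8 channels, 125 Hz, 30 two-second
epochs, 30 subjects/group) with seeds disjoint from every test seed:

* `star_bias = 0.145` produces a standardized MaxDeg group difference of
  ~0.7 SD (measured d = 0.68 ± 0.06 over 16 pilot cohorts) — the canonical
  moderate effect used in the direction-recovery check;
* `iat_coupling = 0.3` yields severity correlations of magnitude ~0.3 with
  the sign pattern MaxDeg +, kappa +, eccentricity −, diameter −.

## Numerical choices and degenerate inputs

* Kruskal ties: stable sort, deterministic lexicographic tie-break.
* `sign(0) = 0` exactly in the PLI; no tolerance.
* Constant channels have undefined phase: flagged with a warning, `NA`.
* Two-node trees: betweenness 0 by convention (no interior pairs), `th`
  undefined (max BC = 0), `r` undefined.
* ANCOVA on a zero-variance measure returns `NaN`/`NA` statistics and an
  "n.s." direction instead of failing; the severity table likewise degrades
  to `NA` rows.
* All randomness flows through explicit seeds; fixed seed gives bit-identical
  recordings, metadata and report tables (the pipeline stamps every output
  table with the seed and a hash of the scientific configuration).

## Problem sizes used in the checks

The test suite exercises the pipeline at deliberately modest scales chosen as
representative rather than exhaustive: null calibration uses 500 replicate
cohorts of 10 subjects/group, 8 channels and 30 epochs at 125 Hz (pooled
over the nine global measures, the ANCOVA rejection rate at α = 0.05 must
stay inside [0.03, 0.07]); direction recovery uses 40 replicate cohorts of
30 subjects/group at the calibrated ~0.7 SD star bias; oracle equivalence
enumerates every labelled tree up to n = 7 (18,248 trees) and samples 2,000
labelled trees at n = 8 plus 1,000 at n = 64 against a naive
BFS/path-enumeration implementation, and verifies Kruskal's total weight
against exhaustive spanning-tree enumeration up to n = 7. The full 64-channel
six-band configuration runs identically, only slower.

## Known limitations

* The per-epoch PLI of narrowband signals is biased upward at short epochs
  (few independent phase samples in 2 s of a 3 Hz-wide band); group
  comparisons are unaffected because the bias is common to both groups, but
  absolute PLI levels should not be over-interpreted.
* The amplitude-rejection criterion is the only artifact handling;
  component-based cleanup of real recordings must happen upstream.
* The 2×2 chi-square is unreliable for very small cohorts (it warns).
* `filtfilt`-style zero-phase filtering assumes the recording is long
  relative to the filter's transient; very short recordings in very narrow
  bands will show edge leakage (mitigated, not removed, by the per-epoch
  trim).
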