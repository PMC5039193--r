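---
title: "Multi-modal EEG-fMRI brain graphs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal EEG-fMRI brain graphs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegfmrigraph)
```

This vignette documents the model behind the package, the tunable
parameters and their defaults, the numerical conventions adopted where
the method leaves room, what the synthetic generator does and does not
emulate, and the known limitations.

## From two recordings to one graph

The framework treats EEG electrodes and fMRI independent components
(ICs) as nodes of one undirected weighted graph per frequency band.

**EEG side.** The recording (channels x samples, assumed already cleaned
of gradient, pulse and ocular artifacts — artifact removal is out of
scope) is variance normalized per channel over the full recording using
the n-1 divisor, segmented into consecutive non-overlapping epochs of
`epoch_seconds` (default 2 s, one per TR; epoch *k* covers samples
`[k*fs*epoch, (k+1)*fs*epoch)`, half-open, surplus samples discarded),
and Fourier transformed with no taper (rectangular window). Squared
magnitudes of the one-sided FFT are averaged over the bins of each band.
Interior band edges are half-open `[low, high)` so adjacent bands never
share a bin; the top band is closed at its upper edge. The shared edges
printed in the usual band table (4, 8, 13, 30 Hz) make some convention
unavoidable; half-open intervals are the least surprising one.

**Hemodynamic convolution.** Band-power time courses are convolved with
a canonical double-gamma HRF — gamma(6, 1) minus gamma(16, 1)/6, unit
dispersions, 32-s support — sampled on the TR grid and normalized by the
*continuous-time* peak, so kernels sampled at different TRs are samples
of one function and convolution rescales rather than amplifies.
Convolution is causal and truncated to the input length. The convolution
is applied once to all EEG columns before any correlation, so EEG-EEG
edges also use convolved power; whether those edges should instead use
raw power is genuinely open, and
`run_subject_pipeline(hrf_on_eeg_edges = FALSE)` recomputes the EEG-EEG
block from unconvolved power for sensitivity analysis. EEG power is not
band-pass filtered to the fMRI band: the HRF already acts as a strong
low-pass, and filtering is not part of the described procedure.

**fMRI side.** IC time courses (time x components, one row per TR)
undergo four steps in a fixed order: (1) least-squares removal of
polynomial trends up to cubic; (2) regression of the 6 realignment
parameters plus their temporal derivatives (first differences with a
leading zero) and an intercept — 13 regressors, rank-deficient designs
drop dependent columns with a warning; (3) despiking; (4) zero-phase
band-pass to 0.01–0.10 Hz. The despiking algorithm and the filter family
are not pinned down by the method description, so both are package
decisions, exposed as arguments: a robust z-score (median/MAD, threshold
4) with linear interpolation across flagged points stands in for
AFNI-style despiking deterministically, and the band-pass is a 5th-order
Butterworth run forward-backward (`signal::filtfilt`). Columns are
demeaned before filtering and the residual post-filter mean is removed:
`filtfilt` zero-pads, so a nonzero-mean input would otherwise leak edge
transients.

**Graphs.** The joint matrix `EF` concatenates EEG columns first (30)
then ICs (54), N = 84. Pearson correlations give `R`; the diagonal is
forced to zero. Self-loops must be excluded for the clustering and
efficiency formulas to be well-defined, and strength sums should not
include self-correlation. `R` is split into `W+` (positive entries) and
`W-` (absolute negative entries); the two never overlap and
`W+ - W- = R` off the diagonal. No thresholding is applied anywhere —
graphs stay fully weighted. Dynamic graphs use rectangular
(untapered) windows of `window_length_tr = 20` TRs stepping by 1;
columns are not re-standardized per window because Pearson correlation
already normalizes within the window. A T-row matrix yields
`floor((T - L)/step) + 1` windows — 237 at T = 256.

## Graph metrics

For a non-negative symmetric `W` with zero diagonal:

* **Strength** `CS_i = sum_j w_ij`; global = nodal mean.
* **Clustering** `CC_i = (1/D_i) sum_{j,k} (w_ij w_ik w_jk)^(1/3)`. The
  denominator is `k_i(k_i - 1)` with `k_i` the count of nonzero
  neighbours (the weighted-clustering convention of the standard brain
  connectivity toolbox, and the default here) or `CS_i(CS_i - 1)` (the
  formula as often printed). Both are implemented
  (`denominator = "degree"` / `"strength"`); they disagree whenever
  weights are not 0/1, and with weights in [0, 1] the strength
  denominator can even be non-positive, which is why degree is the
  default. Nodes with fewer than two neighbours get CC = 0. Weights must
  lie in [0, 1]: the geometric mean normalization assumes it.
* **Efficiency** `GE_i = mean_{j != i} 1/d_ij` where `d_ij` is the
  shortest path length under the inverse map `length = 1/weight`
  (Dijkstra, via `igraph::distances`). Unreachable pairs contribute 0
  rather than poisoning the mean with infinity, so disconnected nodes
  lower efficiency.

All three metrics are verified in the test suite against independent
brute-force oracles (explicit summation, exhaustive triple loops,
Floyd-Warshall) to 1e-12 on seeded random graphs.

## Dynamic summaries

A window series (one metric value per window) is sampled at
`1/(step x TR)` Hz — 0.5 Hz at the defaults. Its summaries are the n-1
sample variance; the low-frequency fluctuation amplitude (LFA), defined
as the mean one-sided DFT amplitude over bins in `(0, 0.025]` Hz after
mean removal — the printed band "0–0.025 Hz" literally includes DC, but
a constant offset is not a fluctuation, so DC is excluded; the one-sided
amplitude spectrum; and a KPSS level-stationarity test. The KPSS
statistic uses partial sums of the demeaned series over a Bartlett
long-run variance with the automatic lag `floor(4 (n/100)^(1/4))`, and
p-values are reported as interval bounds against the standard critical
value table (0.347/0.463/0.574/0.739 at 10/5/2.5/1%), matching how such
results are conventionally stated ("P < 0.01"). No packaged KPSS
implementation is among the dependencies, so the statistic is computed
directly; it was cross-checked against an independent reference
implementation during development.

## Connectivity states

Each window is reduced to its nodal-strength profile (windows x N);
Pearson correlations between profiles give the window-similarity matrix
CCS. Negative entries are clipped to zero before community detection —
the modularity algorithm used is defined for non-negative weights, and
signed-modularity variants are out of scope — and the diagonal is
removed. Newman's leading-eigenvector method then bisects recursively:
the leading eigenvector of the generalized modularity matrix
`B(g) = B[g,g] - diag(rowsums)` proposes a split, a Kernighan-Lin-style
pass of single-vertex moves refines it, and the split is accepted only
if its modularity contribution exceeds 1e-10. The algorithm is fully
deterministic: a dense symmetric eigendecomposition replaces iterative
eigensolvers, and the eigenvector sign is fixed so its
largest-magnitude entry is positive. States are relabelled by
descending occupancy. State graphs average the member windows'
correlation matrices and re-split the mean by sign; averaging `R` first
commutes with splitting only when edge signs agree across member
windows, which is the recorded choice.

## Group statistics

One measure per subject per band per condition forms a complete 5 x 2
within-subject design. "Compound symmetry" is implemented as the
classical univariate repeated-measures ANOVA with sphericity assumed
(compound symmetry implies sphericity; no Greenhouse-Geisser
correction), fit by `stats::aov` with Error strata; F ratios use
`(4, 4(n-1))`, `(1, n-1)` and `(4, 4(n-1))` degrees of freedom. Nodal
tests run per node, with Benjamini-Hochberg correction applied across
nodes within each metric (per-metric families; the 54 IC nodes are the
default family), and post-hoc paired t-tests per band only for nodes
whose omnibus condition effect survives.

## The synthetic generator

`simulation_spec()` describes a cohort: EEG channels are sums of
band-centred sinusoids whose amplitudes follow slow latent envelopes
(low-pass filtered Gaussian noise, 0.05 Hz cutoff, so the fMRI band-pass
preserves them), plus white noise; a coupled IC carries the same
envelope convolved with the canonical HRF plus filtered noise scaled so
the realized power/IC correlation approaches the target (`noise_sd = 1`
makes the latent/IC correlation equal the target; targets above
`1/sqrt(1 + noise_sd^2)` are rejected as unattainable). Uncoupled ICs
are band-passed noise. Coupling patterns switch on a TR schedule
(planted states) and coupling strengths into chosen ICs can be boosted
in the eyes-closed condition (planted effects). Amplitudes within one
TR are constant, so band power is exactly linear in the envelope.

Defaults are the reference study scale: 25 subjects, 256 TRs of 2 s, 30
channels, 54 ICs. The EEG rate defaults to 250 Hz — enough to cover the
low-gamma band with margin — and is configurable. The canonical
two-state experiment (`two_state_spec()`) alternates two patterns every
60 TRs, each coupling channels 1–10 (alpha) to a disjoint set of 10 ICs
at target 0.7 with `noise_sd = 0.5`: each regime plants one strongly
intercorrelated 20-node cluster, which is what makes the regimes
distinguishable in strength profiles; weak sparse couplings would sit
below the sampling noise floor of 20-TR window correlations
(SD ~ 1/sqrt(L)) and no detector could recover them.

The generator emulates the *statistical* structure the pipeline
consumes — band-limited power modulation, hemodynamic lag, slow IC
dynamics, switching coupling, condition shifts — not neurophysiology:
there are no volume conduction, no 1/f background, no artifacts, no
spatial maps. Passing tests therefore demonstrate that the computations
recover planted structure at realistic noise levels, not that real
eyes-closed data will show any particular effect.

Group-level validation runs at the measure-table scale:
`simulate_measure_tables()` draws per-node subjects x bands x conditions
arrays with subject and band effects, compound-symmetric unit noise and
a planted 1-SD condition shift, which is the level at which the ANOVA
and FDR machinery operate; repeating the full signal-level cohort
hundreds of times would add nothing to that check. The problem sizes
used throughout the suite (20 seeds for state recovery, 100 cohort
repetitions for effect recovery, 500/1000 null draws for calibration)
were chosen as the smallest that estimate the relevant rates with
useful precision.

## Numerical conventions and degenerate inputs

* Correlation matrices are computed once and mirrored, so symmetry is
  exact; diagonals are exactly 0 (graphs) or 1 (CCS).
* Constant columns inside a correlation window, zero-variance channels,
  and constant strength profiles raise errors naming the offender.
* Columns with MAD = 0 are skipped by the despiker (no division by
  zero); flagged fractions above 20% warn and proceed.
* The empty graph has CS = CC = GE = 0; a single-node graph has GE = 0.
* An all-zero CCS (after clipping) yields a single state with a warning.
* TSVs carry 17 significant digits, so write/read round trips are
  bit-exact for doubles; all time indices are 0-based and windows are
  named by the 0-based index of their first TR.

## Limitations

* Metrics are classical single-modality graph formulas applied to a
  mixed graph; how EEG-EEG, EEG-IC and IC-IC edge distributions shape
  the global values is an open interpretive question.
* Clustering requires weights in [0, 1] and is undefined (set to 0) for
  degree < 2; the strength-denominator variant can be unstable for
  weakly connected nodes.
* The KPSS p-value is a table bound, not a continuous value.
* State detection inherits modularity's resolution behaviour: very
  long runs or weak state contrast can merge or oversplit states.
* The statistics module assumes complete balanced designs; unbalanced
  or missing-cell data need mixed models, which are out of scope.
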