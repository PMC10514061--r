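---
title: "Latent-space dynamics of functional connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-space dynamics of functional connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`latentdyn` studies what happens to the *dynamics* of resting-state
functional connectivity when regional BOLD signals are compressed into a
low-dimensional latent space. The workflow has three stages:

1. **Embedding.** Concatenated, z-scored frames from all subjects are fed
   to a dense autoencoder whose bottleneck has `d` dimensions; a PCA of the
   same frames is the linear baseline. The question at this stage is how
   small `d` can be while the reconstruction still correlates highly with
   the input.
2. **Dynamical features.** A battery of signatures is computed *with the
   same code path* in the original ("source") region space and in the
   latent space: edge co-fluctuation events, the functional connectivity
   dynamics (FCD) matrix, edge metastability, signed constant-Potts
   modularity, functional complexity, and pairwise temporal
   irreversibility.
3. **Prediction.** Random forests classify subjects (control vs patient,
   lesion-severity split, recovery splits) from the upper triangle of
   either the FC matrix or the irreversibility matrix, in either space,
   with AUC as the accuracy measure.

Because suitable clinical recordings are not publicly distributable, the
package ships a synthetic cohort generator whose planted structure gives
every downstream stage a known ground truth. All statements below about
"patients" and "controls" refer to this generative model.

# The synthetic cohort

## Signal model

Each subject's series follows a first-order vector autoregression
`x(t+1) = W x(t) + eps`, `eps ~ N(0, noise_sd^2 I)`, sampled at TR = 2 s.
A VAR(1) was chosen over a continuous Ornstein-Uhlenbeck process because
the frames of an fMRI acquisition are discretely sampled at the TR and a
discrete model makes the lag-1 irreversibility analytically controllable
(the stationary and lag-1 covariances solve a discrete Lyapunov equation,
which `var1_stationary_cov()` exposes and the tests use as an oracle).

The coupling `W` is block structured: regions `1..n/2` form the left
hemisphere, region `i` is homotopic to `i + n/2`, and module labels are
mirrored across hemispheres. Within-module weight is `within_w = 1`,
between-module weight `between_w = -0.1`, homotopic weight
`homotopic_w = 0.5`, and an antisymmetric perturbation with entry SD
`asymmetry = 0.05` makes even control dynamics weakly irreversible, as
resting brains are. The whole matrix is rescaled to spectral radius
`target_radius = 0.85`, keeping the process stationary while strongly
correlated.

The *negative* default between-module weight deserves a note: it produces
anticorrelated module blocks in FC, which is the realistic regime for
global-signal-regressed BOLD and the regime in which a signed
(constant-Potts) community analysis is meaningful. With all-positive FC
the two-community structure that the modularity sweep looks for simply
does not exist at any nonnegative resolution.

One consequence of the mirrored-hemisphere design is worth stating
explicitly: because region `i` and its twin `i + n/2` receive symmetric
inputs, homotopic pairs remain substantially correlated through indirect
paths even when their direct weight is severed. Lesions therefore lower
interhemispheric FC relative to controls — the planted contrast — but do
not push cross-hemisphere FC below within-hemisphere FC.

## Lesions and severity

Patients carry a latent severity `s ~ Beta(2, 2)` and a recovery rate
`r ~ Gamma(shape 2, scale 0.5)` per year; severity at `tau` years
post-stroke is `s exp(-r tau)` (timepoints 2 weeks, 3 months, 1 year).
The lesion acts on the coupling in three severity-scaled ways
(`lesion_coupling()`):

* homotopic weights shrink by `1 - k_homotopic * s`, with
  `k_homotopic = 0.3`;
* an antisymmetric perturbation with entry SD `k_asym * s`
  (`k_asym = 0.05`) raises temporal irreversibility;
* the rows and columns of `round(s * n_roi * 0.15)` randomly chosen
  regions are multiplied by 0.1 — structural damage that keeps matrix
  shapes constant across subjects. The damaged set is fixed per subject
  across timepoints: anatomy does not heal, while the severity-scaled
  coupling effects do recover.

The lesion's antisymmetric perturbation is **low-rank**: it is assembled
from random directed imbalances between the module-by-hemisphere blocks
(`A = U C U'` with block-indicator patterns `U` and a random antisymmetric
`C`, rescaled to the requested entry SD). This is a deliberate design
choice. Directional disruption after a large-vessel stroke operates at the
scale of networks and hemispheres, not as independent noise on every
region pair; and only asymmetry that lives on the large-scale modes can
survive a low-dimensional embedding at all. With an isotropic full-rank
perturbation most of the asymmetry is orthogonal to the leading modes, the
latent space cannot see it, and the premise of analysing irreversibility
in a compressed representation collapses.

Clinical covariates derive from the same severity: lesion volume as above,
`NIHSS = round(20 s + N(0,1))` clipped at zero, and nine behavioral domain
scores per timepoint, `score_d = -beta_d * s(tau) + N(0, 0.5)` with
`beta_d ~ Uniform(1, 3)` drawn once per cohort. Controls have severity
zero throughout, so their scores are pure noise around zero, the z-scored
convention of clinical batteries.

Calibration of the free coefficients (`k_homotopic`, `k_asym`, block
weights) was done once, at design time, to place the cohort in the regime
the method targets: FC alterations present but not trivially separable,
temporal-asymmetry alterations strong and latent-visible, and all planted
group contrasts detectable at n = 30 + 60. The full-scale geometry
(235 regions, 896 frames) is available as a configuration profile; the
defaults use 50 regions and 400 frames so a full cohort simulates in
seconds on one CPU.

## What the generator does not emulate

No hemodynamic response convolution, no scanner noise spectrum, no spatial
lesion geometry, no tractography. Passing tests on this cohort demonstrate
that the pipeline recovers planted statistical structure of the kinds the
analyses assume — not that real stroke data behave this way.

# The autoencoder

The embedding network is a mirrored dense stack
(`n_roi -> 128 -> 64 -> d -> 64 -> 128 -> n_roi` by default; hidden layers
wider than the input or narrower than the bottleneck are dropped
automatically at small `n_roi`), rectified-linear hidden units, linear
bottleneck and output. Training minimises mean-squared reconstruction
error with Adam (learning rate 1e-3, batches of 256 frames), an 80/20
frame-wise train/validation split, at most 100 epochs, and early stopping
after 10 epochs without validation improvement, restoring the best
weights. All randomness — split, initialisation, batch order — flows from
one seed, so a fit is exactly reproducible; the split indices are stored
in the model for audit.

The frame-wise split means every subject contributes frames to both sides
of the split; downstream group statistics therefore use all subjects.
Classification is protected separately: those splits are at the subject
level, so no subject's frames inform a forest that is evaluated on them.

The "source-latent correlation" reported by `reconstruction_curve()` is
the Pearson correlation between validation input frames and their
reconstructions, flattened. An alternative reading — correlating FC
matrices rather than frames — exists; the frame reading is implemented
because it is the quantity the reconstruction loss controls. The selected
dimension is the smallest whose mean correlation over seeds reaches 0.9.
On the synthetic cohort the correlation at `d = 6` sits far below the
values reported for real BOLD: a VAR driven by isotropic innovations has
substantial variance outside any low-dimensional subspace, whereas real
BOLD is dominated by a few global modes. The curve's *shape* (steep rise,
then flattening at the planted dimension) is the meaningful object here,
and the planted-manifold tests exercise exactly that.

# Dynamical features

**Edge time series.** After population-SD z-scoring (dividing by n, not
n-1 — this is what makes the algebra exact), the edge series of regions i
and j is `e_ij(t) = z_i(t) z_j(t)`, whose time average is *exactly* the
Pearson correlation. The root-sum-square of all edges per frame (RSS) is
the collective co-fluctuation amplitude; its transient peaks are candidate
events.

**Event detection.** The null model circularly rotates each region's
series by an independent uniform offset (1000 iterations by default),
preserving autocorrelation and each row's value multiset while destroying
cross-region alignment. Frames whose RSS exceeds the pooled-null
`1 - p` quantile (`p = 0.001`) are events; a pooled quantile is used
rather than per-frame thresholds because circular shifts make frames
exchangeable. Flagged frames whose z-score against the trace's own mean
and SD exceeds 4.5 are excluded as artefact-like extremes; the trace's own
moments are the reference because the exclusion targets outliers of the
empirical recording, not of the null. Peak agreement between two spaces
counts exactly coinciding frame indices (no +/-1 tolerance):
`hits / (hits + miss)`, defined as 1 when both sets are empty. Frame
indices are 1-based throughout, as is idiomatic in this language.

**FCD.** FC in sliding windows (default 30 frames = 60 s, step 3),
correlating upper triangles of window pairs. The default window follows
common FCD practice at TR = 2 s and is robust at the desk-scale 400-frame
series; group comparisons pool upper-triangle FCD values across subjects,
with subject-mean comparison available.

**Edge metastability.** The population SD over time of the RSS trace —
the variability of global synchrony. The per-edge reading (mean of each
edge's temporal SD) is available via `type = "per_edge"`; the RSS reading
is the default because it is the one tied to the event analysis.

**Signed modularity.** Constant-Potts quality
`Q = sum_{i!=j} (w_ij - gamma) delta(c_i, c_j) / sum |w_ij|` on the full
signed FC, optimised by a Louvain algorithm (compiled; 20 seeded restarts
per resolution, best quality kept, ties broken by first-found). The
normalisation by total absolute weight makes Q comparable across subjects.
A coarse resolution sweep (default `-0.3` to `1` in steps of 0.05) locates
where a two-community structure lives, with a finer sweep inside the
exact two-community interval and inside the transition gap between the
single-community regime and the first split, where thin bands hide. At
resolutions where the unconstrained optimum has more than two communities
the agglomeration is continued: communities are greedily merged down to
two and polished by single-node moves, alongside refined random
bipartition restarts, and the best-quality bipartition over the whole
sweep is returned. The grid extends below zero because on matrices with
weakly attached nodes (e.g. a patient's lesioned regions) the
two-community regime sits at or below resolution zero, where the constant
null rewards merging. The tests verify the returned quality against an
exhaustive search over every bipartition on small matrices.

**Functional complexity.** The histogram of upper-triangle FC values over
`m = 20` equal bins on `[-1, 1]` is compared with the uniform distribution:
`C = 1 - (1/c_m) sum_mu |p_mu - 1/m|`, `c_m = 2(m-1)/m`. C is 0 for a
delta distribution, 1 for a uniform one; the bin count is a free parameter
and 20 gives stable values at the desk-scale edge counts.

**Irreversibility.** For each pair, the forward lagged correlation
`cor(x_i(t), x_j(t+1))` is compared with the same quantity on the
time-reversed pair of series; `I_ij` is the absolute difference. Reversing
both series turns the lag around, so the reversed correlation equals the
forward correlation with the roles swapped — the matrix is symmetric with
an exactly zero diagonal, which the tests assert to machine precision. The
shift is fixed at one frame (the minimal step, avoiding any window-length
choice) but exposed as a parameter. The matrix implementation is one call
to `cor()` on lagged frame blocks and is verified against the literal
pairwise definition to 1e-10.

# Outcomes and prediction

FC distance is the Frobenius norm of the difference to the control-average
FC; SC-FC coupling is the Pearson correlation between functional and
structural strengths over pairs with nonzero structural weight (structural
zeros are masked because correlating against them mostly measures
sparsity). Behavioral recovery of a domain is the relative change
`(score_1yr - score_2wk) / score_2wk`; with z-scored deficit scores the
baseline is typically negative, so improving deficits give negative
ratios, and a zero baseline yields a flagged missing value rather than an
error.

"Domains recovered" supports two explicit rules. The default counts a
domain whose 1-year score is inside the normal range (|score| < 1, i.e.
twice the nominal control noise SD) — recovery as a *state*. The
alternative counts any decrease in deficit magnitude — recovery as a
*change*. The state rule is the default because the three recovery
criteria (domain count, 1-year FC distance, 1-year SC-FC coupling) are
used as interchangeable labels for "how recovered is this patient", and
only under the state reading do all three measure the same construct, the
residual deficit: improvement *counts* grow with baseline severity, which
makes the change reading anti-correlate with the other two criteria.

Median splits label values above the median "high" and below "low";
values equal to the median fill the low group in stable input order until
it reaches `ceiling(n/2)`, then the high group, so counts never differ by
more than one.

Random forests use 1000 trees and otherwise common defaults (unlimited
depth, sqrt(p) features per split), 10 stratified subject-level 80/20
splits, AUC on the held-out subjects, reported mean and SD. Both the
splits and the forests are seeded, and a repeat re-randomises both.

# Problem sizes and numerical choices

The shipped defaults are sized for a single CPU: desk-profile cohorts
(50 x 400, 90 subjects) simulate in ~2 s; an autoencoder fit at `d = 6`
with hidden widths 32/16 and up to 40 epochs takes ~15 s; the modularity
sweep over 90 subjects ~4 s; a 1000-tree forest over 10 splits a few
seconds. The test suite's planted-structure experiments (manifold
embedding, 10-cohort contrast recovery) run minutes, not hours. Degenerate
inputs fail loudly and early: ragged or non-numeric text files report the
offending row and column, zero-variance regions are named, unstable
couplings (spectral radius >= 1) are rejected, and the modularity sweep
errors with advice when no resolution yields a bipartition.
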