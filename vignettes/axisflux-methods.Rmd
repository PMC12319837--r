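---
title: "Methods: session-wise S-A axes, variability, and spatial nulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: session-wise S-A axes, variability, and spatial nulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`axisflux` implements a dense-sampling analysis of day-to-day variability in
functional cortical organization.  A subject is scanned on many consecutive
days; each session yields parcellated BOLD time series; each session's
functional connectome is summarized by its principal connectivity gradient —
the sensorimotor-association (S-A) axis, which orders parcels from unimodal
sensory/motor cortex to transmodal association cortex — and the session-wise
axes become the raw material for variability, covariate-effect, and network
topology statistics.  This vignette documents the model at each stage, the
parameters that matter, the numerical decisions, and what the synthetic-data
module does and does not emulate.

## From time series to connectomes

Each parcel's series (a voxel block can first be reduced to its first
eigenvariate, `first_eigenvariate()`, the rank-1 temporal factor with a
majority-positive sign convention) is band-limited to the low-frequency
window used for resting-state coupling.  Band-limiting uses the maximal
overlap discrete wavelet transform with the least-asymmetric length-8 filter:
each series is replaced by the sum of its multiresolution detail components
over scales 3–6.  At a repetition time of 0.72 s those dyadic bands union to
`passband_edges(0.72, 3:6)` = 0.0109–0.1736 Hz, i.e. the familiar
~0.01–0.17 Hz window.  Boundary handling is by reflection, which minimizes
leakage on series of a few hundred samples; details carry no DC component, so
band-limited series are zero-mean up to boundary effects.  The transform is
implemented in the package (additivity of the multiresolution components is
exact to ~1e-12, and an FFT oracle confirms >90% variance retention in band
and <10% out of band).

Connectivity is Welch magnitude-squared coherence
$C_{xy}(f) = |S_{xy}(f)|^2 / (S_{xx}(f)\,S_{yy}(f))$, averaged over the
frequency bins inside the passband: Hann-windowed, demeaned segments of 128
samples at 50% overlap.  Coherence is used rather than correlation because it
is insensitive to regional differences in hemodynamic response shape.  The
segment length fixes the frequency resolution at `1/(128·TR)` Hz (about one
bin per 0.011 Hz at TR = 0.72 s, ~16 bins in band) and, with ~900 timepoints,
gives 13 segments and an effective number of independent averages
`d = 1 + 0.5·(n_seg − 1)` (each 50%-overlapped segment counts one half).
Edge p-values use the standard Welch-coherence null `p = (1 − C)^(d−1)`;
the upper-triangle edges are Benjamini–Hochberg corrected at `q = 0.05` and
non-surviving edges are zeroed.  The p-value is approximate for the
band-averaged statistic (averaging across correlated bins narrows the null),
which makes the edge screen conservative; simulations with white-noise
parcels leave essentially no surviving edges.  The diagonal is set to zero:
self-coherence is uninformative and would otherwise dominate the row-wise
density thresholding below.

## From connectomes to session-wise S-A axes

Each connectome is sparsified row-wise to its top 10% entries (`density =
0.10`; ties break stably to the lower column index), converted to a
normalized-angle affinity `a_ij = 1 − acos(cosine(row_i, row_j))/π`, and
embedded by diffusion maps: the affinity is density-normalized with
`alpha = 0.5` (`A_ij / (d_i d_j)^α`), made row-stochastic, and
eigendecomposed via its symmetric conjugate.  The trivial constant
eigenvector is dropped; with diffusion time `t = 0` the components are scaled
by `λ/(1−λ)` (the multi-scale convention of the common gradient toolboxes),
otherwise by `λ^t`.  Ten components are retained.  Variance explained is
reported as `λ_k / Σλ` over the retained components; this quantity is
convention-dependent (it changes with the kernel and the number of retained
components), so printed variance-explained figures from other toolchains are
not comparable across conventions and are not used as tests here.

The subject's mean connectome is embedded to give the reference; each
session's embedding is aligned to it by orthogonal Procrustes — centering
and rotation/reflection only, **no scaling**, because downstream dispersion
statistics live in loading units and scaling would corrupt them.  The
session S-A axis is the first aligned component.  Orientation uses a
template-free anchor: if default-mode parcels do not sit above somatomotor
parcels on the axis, the sign of the reference and of every session is
flipped together (association-positive convention).  A network-label anchor
was chosen over an external template so that synthetic parcellations work
unchanged.

Session quality control (`session_qc()`) makes "markedly dissimilar"
sessions reproducible to detect instead of excluded by hand: a session is
flagged when its Spearman correlation with the mean axis falls below 0.5 or
its own first-component variance explained sits more than 3 robust SDs
(MAD) below the median.  Exclusion itself stays config-driven
(`filter_sessions()`), so an analysis records exactly which days entered.

## Variability, effects, and dispersion

*Variability.* Intra-individual variability is the sample SD (denominator
S−1) of each parcel's loading across sessions; the sample form was chosen as
the unbiased estimator under the implicit i.i.d. model.  Between-subject
variance differences are tested parcel-wise with the classic mean-centered
Levene test (median-centering, the Brown–Forsythe variant, is a config
switch), FDR-corrected across parcels; the SD difference supplies the
direction.  All multiple-testing correction in the package is
Benjamini–Hochberg step-up.

*Local effects.* Parcel-wise models regress session loadings on z-scored
covariates (jointly per covariate set), with a per-session random intercept
for the longitudinal design.  With one observation per session — the
canonical dense-sampling case — the random-intercept variance is not
identifiable, and the fallback ladder goes deterministically to OLS, flagged
`ols_fallback`; replicated sessions are fit by REML (`lmerTest`), flagging
boundary fits.  Covariates are z-scored within subject so that t-statistics
are comparable across hormones with different units; rescaling a covariate
leaves t and p unchanged.  Perceived stress is modelled separately from
hormones by default (stress and hormone levels can share variance to
different degrees per subject; separate models keep the two effect families
comparable across subjects), and a joint model remains available by passing
both to the same call.

*Dispersion.* Network topology along the axis uses the seven canonical
networks.  Within-network dispersion is the sum of squared distances of a
network's loadings to the network median — the axis is one-dimensional, so
Euclidean distance is absolute difference; larger means more segregated.
Between-network dispersion is the absolute distance between two network
medians, for the 21 unordered pairs in the fixed canonical order (visual,
somatomotor, dorsal attention, ventral attention, limbic, frontoparietal,
default mode).  Medians with even counts are the midpoint of the central
pair.  The same covariate models are fit per measure; significance uses
Bonferroni families of 0.025/7 (within) and 0.025/21 (between), i.e. the
conventional 0.004 and 0.001 after rounding.  Positive t means segregation
increases with the covariate, negative means integration.

*Spatial nulls.* Spin permutations operate at parcel level: a uniform random
rotation (QR of a Gaussian matrix, determinant corrected to +1) is applied to
left-hemisphere centroids and its x-mirrored counterpart to the right, and
each original parcel location takes the value of the nearest rotated
centroid within its hemisphere (many-to-one allowed, as is standard for
centroid-based spins).  Permutation p-values use the +1-corrected count, so
the smallest attainable p is `1/(n_perm + 1)` and p is never zero.  Map
decoding spins the subject map, not the feature maps, so one null serves all
features.  Dispersion-effect specificity re-derives the *network labels*
through the spin while loadings stay fixed — the label topography is the
object whose specificity is tested.  Permutations that empty a network
involved in the measure are dropped from the null.

## The synthetic-data module

The generator produces every input the pipeline consumes, with known ground
truth, emulating the study conditions of a dense-sampling design:
~30 daily sessions, menstrual-cycle-like estradiol (dominant ovulatory peak
near mid-series, smaller luteal peak; mean ≈ 84 pg/mL) and progesterone
(near zero follicular, elevated luteal; mean ≈ 5 ng/mL) for the cycle
design; positive AR(1) morning testosterone (≈ 102 pg/mL) and cortisol
(≈ 0.50 µg/dL) for the diurnal design; integer PSS scores 0–40 with
subject-typical means (≈ 8 cycle, ≈ 10 diurnal).  The cycle length equals
the session count, and the diurnal design represents morning-only sampling.
One global seed is split into per-component substreams by stable hashing of
component names, so adding a generator never perturbs the others; all
generators are bit-reproducible given a seed.

Planted loadings follow
`g_s = g0 + Σ_h β_h z_h(s)`, then a per-network scaling about the network
median by `1 + Σ_h γ_{h,n} z_h(s)` (matching the median-based dispersion
definition), then i.i.d. Gaussian noise.  Effect sizes for β and γ have no
empirical anchor; the defaults used in the recovery tests are chosen for
test power, not realism, and are documented as such.

Session time series use a factor model built to guarantee that coherence
connectivity recovers the loading geometry: latent band-limited sources tile
the axis at equal *quantiles* of the loading distribution, and parcels mix
sources with Gaussian weights (bandwidth 1/8 of the rank range) centered at
their own rank position, plus white noise.  Rank positioning means every
stretch of the axis is equally represented regardless of how loadings
cluster, so the embedding's first component recovers the axis up to a
monotone transform — which is exactly what the rank-correlation recovery
tests measure.  The generator does *not* emulate hemodynamic response
functions, realistic fMRI noise spectra (1/f, motion, physiology), voxel
structure, or spatially correlated session noise.  Passing tests therefore
demonstrate correctness of the pipeline's statistics under its own model
assumptions, not robustness to fMRI artifacts.

Smooth feature maps (`simulate_smooth_map()`) are random mixtures of 25
spherical Gaussian bumps of width 0.3 rad, bilaterally mirror-symmetric by
default.  Two properties of this ensemble matter for the spin-null
calibration simulations: bilateral symmetry (the mirrored-rotation null
assumes it, as real cortical maps approximately satisfy it), and a
correlation length of a few parcel spacings.  Calibration degrades at the
extremes — maps much smoother than a few parcel widths have so few spatial
degrees of freedom that any parcel-level rotation null becomes
anticonservative, and structure finer than the parcellation aliases through
the nearest-centroid assignment.  This is a known limitation of
centroid-based spin tests, not specific to this implementation.

## Problem sizes and numerical choices

The shipped tests and the acceptance script size their simulations for a
single CPU: parcellations of 100–400 parcels, 20–29 sessions of 900
timepoints, 200 spin permutations and 200 replicates for calibration runs,
and 20–100 seeds for the null-rate simulations; each stage completes in
seconds to a couple of minutes.  Analyses of real data would typically use
1,000 permutations (the `analysis_config()` default).

Other numerical decisions, collected: coherence values are clipped to
[0, 1] and symmetrized after floating-point roundoff; the affinity graph
must be connected on the symmetrized support of the thresholded connectome
(checked by BFS) or the embedding errors; eigenvector signs inside the
embedding are fixed by making the largest-magnitude entry positive
(alignment and orientation absorb any residual sign ambiguity); perfect-fit
regressions floor the residual variance at 1e-300 so t-statistics stay
finite; the Mann–Whitney comparison enumerates all assignments exactly up to
a combined n of 20 (ties included) and uses the tie-corrected normal
approximation with continuity correction above that; parcel order is the
metadata file order everywhere, with 1-based parcel ids.

Persistence is deliberately plain text: sessions and matrices as TSV,
metadata and covariates as CSV, written at 17 significant digits so
round-trips are exact to ~1e-12.
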