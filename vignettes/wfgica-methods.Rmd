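---
title: "Group ICA of wide-field calcium imaging across brain states: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group ICA of wide-field calcium imaging across brain states: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Wide-field calcium imaging records bulk neuronal activity over the dorsal
cortex of a mouse as a fluorescence movie: one intensity per pixel per frame.
When the brain state is manipulated — here, graded isoflurane anesthesia from
a deep, burst-suppressed regime through oscillatory intermediate levels to
wakefulness — the spatial organization of cortical activity changes
qualitatively. The questions this package addresses are (i) which cortical
components generate the fluorescence signal consistently across subjects and
sessions, and (ii) how each component's contribution and the co-activation
structure between components depend on the brain state.

`wfgica` implements the full analysis chain as a tested, reusable pipeline:
image pre-processing, group spatial ICA with ICASSO stabilization and
R-index order selection, GICA back-reconstruction, atlas annotation with
artifact flagging, threshold-based activation-occurrence statistics with a
bootstrap expected-occurrence null, binarized co-occurrence (phi)
correlation analysis, and repeated-measures state tests. Because no public
dataset accompanies this design, the package ships a first-class synthetic
data generator (`simulate_study()`) that emulates the study conditions with
known ground truth, so every stage has a recovery-based test.

# Pre-processing

Raw movies (`raw_movie`) are processed by `preprocess_session()`:

1. **Block-mean downsampling** (`downsample()`), factor 4 for real
   512-pixel data; the synthetic movies are generated at the target
   resolution, so the factor defaults to 1. Non-divisible dimensions crop
   the bottom/right remainder.
2. **Two-landmark registration** (`register()`): a similarity transform
   (translation, rotation, isotropic scale — 4 degrees of freedom,
   determined exactly by the bregma and lambda pairs) with bilinear
   interpolation. A movie whose landmarks already equal the reference is
   returned untouched.
3. **Percent dF/F0** (`compute_dff()`): per pixel, against the session-mean
   baseline F0. We normalize post-registration; states recorded in one
   session share one F0.
4. **Zero-phase high-pass at 0.1 Hz** (`highpass()`): a 4th-order
   Butterworth squared-magnitude response applied in the frequency domain
   with reflection padding, which is what forward–backward (`filtfilt`)
   filtering computes, vectorized over pixels. The residual per-pixel mean
   left by the finite window is subtracted, so filtered traces are exactly
   DC-free. No explicit low-pass is applied: the upper band edge is the
   Nyquist frequency. The filter family and order are our declared choice;
   the tests verify DC gain < 1e-3 and 1 Hz gain within [0.95, 1.05], and
   cross-check the implementation against `signal::filtfilt` on vectors.
5. **State concatenation** (`concatenate_states()`) with a segment table of
   1-based inclusive frame ranges, ordered deepest state to awake. The six
   canonical states are `iso2.0, iso1.75, iso1.5, iso1.0, iso0.5, awake`.

Pixels are linearized in column-major mask order (`pixel_idx`), fixed for
all sessions by the common mask (`common_mask()`, the AND of per-session
valid regions).

# Group spatial ICA

`wfica()` is the estimator at the package's core. Data are oriented the
fMRI way: observations are pixels, so independence is over space and each
component is a spatial map with an associated time course.

* **Stage-1 reduction** (`reduce_session()`): temporal-domain PCA of each
  session's `T x P` matrix to `L1` dimensions (default `ceiling(1.5 k)`,
  capped by rank), computed from the pixel Gram matrix. Outputs are whitened
  (`X X'/(P-1) = I`) with stored dewhitening `G`.
* **Stage-2 reduction** (`reduce_group()`): the per-session whitened
  matrices are stacked and reduced to `k` dimensions with the same contract.
* **FastICA** (`fastica()`): logcosh contrast, symmetric decorrelation,
  seeded random orthonormal initialization. The reference study used
  Infomax through a MATLAB toolbox; FastICA is our declared substitute,
  validated by the recovery tests (matched spatial |r| > 0.99 at the study
  scale).
* **ICASSO** (`icasso()`): `n_runs` re-estimations under random
  re-initialization and/or pixel bootstrap (bootstrap runs are re-whitened
  and their unmixing applied to the original data). Estimates are clustered
  by average-linkage agglomeration on `1 - |r|`; each cluster's centrotype
  (the member with maximal within-cluster similarity) becomes a component;
  the per-cluster stability index is the mean within-cluster similarity.
* **Sign and scale conventions**: maps are z-scored over masked pixels and
  oriented so the pixel of maximum |weight| is positive; time courses carry
  the complementary arbitrary ICA scale. All downstream thresholds are
  sigma-based, so these conventions do not affect the statistics.
* **Back-reconstruction** (`back_reconstruct()`): per-session time courses
  `G_s Ghat_s A` and maps `pinv(Ghat_s A) X_s`, the standard GICA
  matrix-multiplication chain through the stored reduction models.

## Order selection and the R-index

`select_order()` runs ICASSO for every candidate order and picks the
minimizer of `r_index()`. The index is a compactness/separation ratio over
the estimate clusters, computed in similarity space:

`R = mean_q [ max_{q' != q} s_ex(q, q') / s_in(q) ]`,

with `s` the mean |correlation| within (`s_in`) or between (`s_ex`)
clusters. Over-ordering splits clusters into near-duplicates (`s_ex -> 1`),
under-ordering leaves mixture estimates that remain mutually correlated
across clusters; both inflate the ratio, giving an interior minimum at the
true order. We deliberately avoided a dissimilarity-only ratio
(`mean d_in / mean d_ex`): on clean, well-separated sources under-order ICA
solutions are perfectly stable, their within-cluster dissimilarity is ~0 at
every order at or below the truth, and such a ratio degenerates to picking
the smallest candidate. The selection experiment (candidates {4, 8, 12, 16}
against 8 planted sources) validates the implemented form.

# Annotation and artifact flagging

Each component is tagged by the atlas label of its peak pixel — the maximum
|weight|, independent of sign, ties broken row-major (`locate_peak()`,
`assign_group()`). `flag_artifacts()` excludes components that are
`midline` (more than `midline_frac = 0.5` of the top-decile-|weight| pixels
inside the midline column band) or `vessel` (half-max support with a
second-moment axis ratio above `elongation = 4`; vessels are ridges,
cortical parcels are compact). The elongation rule uses the half-max rather
than the top-decile support because with ~10^3 masked pixels the top decile
is an order of magnitude larger than a vessel ridge and dilutes it with
scattered noise pixels. The reference workflow applied these criteria
visually; the automated rules are declared, tunable and manually
overridable. `match_components()` matches two component sets by maximum
total |r| injective (rectangular) assignment, solved with an in-package
Munkres implementation tested against brute-force enumeration.

# Activation and co-occurrence statistics

Per session and component, `compute_thresholds()` sets
`th = mean ± 3 sd` of the deepest-state (iso 2%) segment of the
back-reconstructed time course — the global-inactivation reference.
`binarize()` marks frames strictly beyond either threshold (both polarities
counted; values exactly at a threshold are 0). The number of activations
`N[IC, state]` is the suprathreshold *frame* count, and relative occurrence
is `N / sum_IC N` over retained components; a state with no crossings at
all is reported missing, not zero (`count_and_proportion()`).

`expected_null()` draws 5,000 crossings with replacement from the pooled
crossing identities of the deepest state and 5,000 from the awake state
(10,000 total), giving each component's expected proportion free of
between-state crossing-rate bias; a component is *prominent* in a state
when the lower bound of its across-subject t-based 95% CI exceeds that
expectation (`prominent_components()`). Occurrence is aggregated IC → group
→ session → subject (`occurrence_by_group()`).

Co-occurrence between components is the Pearson correlation of their binary
vectors within each state (the phi coefficient, `binary_corr()`,
`state_matrices()`); within-group values are Fisher-z transformed (|r|
clipped at `1 - 1e-6` so exactly coincident vectors stay finite), averaged
over pairs and sessions (`fisher_group_mean()`, `cooccurrence_by_group()`).

State dependence is tested with a one-way repeated-measures ANOVA over the
six states (`rm_anova()`, `F` with df `(s-1, (s-1)(n-1))`, no sphericity
correction, subjects with missing states dropped listwise) and Holm-corrected
paired t post hocs over all state pairs (`posthoc_holm()`). Degenerate
tables (zero residual variance) are reported as such rather than yielding a
spurious F.

# The synthetic study generator

`simulate_study()` emulates the study conditions: 3 subjects x 2 sessions,
64 x 64 px, 40 Hz, six states of 5 min each, concatenated deepest-to-awake.
Eight Gaussian sources (sigma 3.5 px, peak 5% dF/F0) sit in the five macro
groups of a bilaterally symmetric synthetic atlas (`make_atlas()`): a
retrosplenial pair plus somatomotor, somatosensory, visual and posterior
parietal blobs. Subjects differ by a global ±10% amplitude factor.

Temporal regimes follow the brain-state phenomenology:

* `iso2.0`, `iso1.75` — *bistable*: a global Poisson up-state train at
  0.15–0.18 events/s that every source joins probabilistically
  (near-global synchrony), per-event amplitude jitter ±20%.
* `iso1.5`–`iso0.5` — *oscillatory*: jittered-periodic master events at
  0.30–0.60 events/s, with a per-state `sync` fraction (0.65 → 0.30) of
  each source's events locked to the master train and the rest private.
* `awake` — *asynchronous*: independent Poisson transients per source.

Events are rendered as single-exponential calcium transients (tau = 0.5 s,
a slow red-indicator-like decay — a deliberate simplification over a
biophysical model). Event rates rise monotonically for every source toward
wakefulness (crossing counts increase as anesthesia lightens) while the
retrosplenial pair's *share* of total activity falls monotonically
(0.154 → 0.031), which is what the occurrence statistics must recover.

The retrosplenial pair's event-level co-activation is calibrated
(`calibrate_coupling()`) so that the *measured* phi between their binarized
time courses hits designed targets 0.80, 0.70, 0.60, 0.50, 0.42, 0.35
deepest-to-awake. The calibration inverts the sparse-activation relation
`phi = (p11 - p_i p_j)/sqrt(p_i(1-p_i) p_j(1-p_j))` using the forward
model: deepest-state variance from the discrete Campbell theorem
(threshold = 3 sigma), the exact frame count a jittered transient spends
above threshold, and the expected overlap of jointly triggered transients.
Ground-truth checks recover the targets within ±0.05.

Nuisance terms exercise the pre-processing and flagging stages: i.i.d.
Gaussian sensor noise (sd 1 count against a 5-count signal peak, i.e.
peak SNR 5 at the default baseline f0 = 100), a global multiplicative
drift (0.02 Hz sinusoid + linear term, removed by the 0.1 Hz high-pass),
and one static vessel-like ridge with white temporal noise (sd 0.5%
dF/F0 — deliberately weaker than the neural sources, consistent with the
minimal hemodynamic contribution of red-shifted indicators, so that the
sources occupy the top of the variance spectrum).

## What the generator does not emulate

Real optics (skull scattering, vignetting), hemodynamic absorption
spectra, behavioral covariates (whisking, movement), spatially correlated
noise, and non-exponential indicator kinetics. Passing recovery tests
therefore demonstrates that the pipeline's inference chain is correct under
its own forward model, not that real data meet that model's assumptions.

# Problem sizes used by the tests and the acceptance script

Chosen as the package's own balance of fidelity and desk-scale runtime:

* Full-scale recovery and session-consistency checks: the emulated study
  layout at 64 x 64 px and 5 min/state, sampled at 10 Hz (the dynamics of
  interest live well below 5 Hz, so 10 Hz preserves them while keeping the
  run to a few minutes).
* Repeated-seed occurrence/coupling checks: 20 seeds at 48 x 48 px, 10 Hz
  (2 min/state in the test suite, 90 s/state in the acceptance script).
  48 px, not smaller: at coarser grids the source blobs overlap enough that
  residual ICA mixing visibly biases the awake-state phi upward.
* Order selection: 10 seeds at 32 x 32 px and 1 min/state.

# Numerical choices and degenerate inputs

* Whitening tolerance 1e-6 on the identity-covariance contract; FastICA
  tolerance 1e-6, 200 iterations, warning (not silence) on
  non-convergence.
* Correlation of a constant binary vector is reported missing with a
  warning; Fisher z clips |r| at 1 - 1e-6; assignment ties and peak ties
  break deterministically (first index / row-major).
* RM ANOVA with zero residual variance reports a degenerate fit (F = NA);
  states with zero crossings propagate as missing and drop the affected
  subject listwise from the test, with a message.
* All randomness flows through explicit integer seeds (`with_seed()`
  restores the caller's RNG state); repeated runs are bit-identical.

# Known limitations

* The ICA algorithm (FastICA/logcosh) and the ICASSO similarity measure
  (|Pearson r|) are fixed; Infomax and mutual-information similarities are
  out of scope.
* The atlas is a synthetic macro-area parcellation behind the same label
  -image interface a real atlas registration would use; no true CCF
  registration is performed.
* Sessions must share a pixel grid after registration; freely-moving
  preparations with large motion are not handled.
* The bootstrap null treats crossings as exchangeable frame events within
  the two reference states; temporally clustered crossings are not
  resampled as runs.
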