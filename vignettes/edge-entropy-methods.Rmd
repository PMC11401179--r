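---
title: "Edge sample entropy and brain-behavior variance components: methods"
author: "edgentropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge sample entropy and brain-behavior variance components: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Resting-state functional connectivity is usually summarized by one
correlation per region pair. Time-varying functional connectivity (TVFC)
instead tracks the correlation of two parcels through a sliding window,
yielding one *edge timeseries* per parcel pair. The regularity of that
edge timeseries carries information of its own: edges whose windowed
correlation drifts smoothly ("long timescales") behave differently from
edges that fluctuate roughly. `edgentropy` quantifies this regularity
with sample entropy (edge sample entropy, ESE), builds group templates
of the highest- and lowest-entropy edges (HEN and LEN), and asks how
much behavioral variance across a cognitive battery is explained by
inter-subject similarity of ESE inside each template, using a
multivariate variance-component model.

## Pipeline and parameters

1. **Preprocessing** (`preprocess_timeseries`): 4th-order zero-phase
   Butterworth bandpass (default 0.017-0.1 Hz), OLS regression of the
   cross-parcel mean signal (a form of global-signal regression), then
   removal of 10 frames per end. The filter is zero-phase so window
   boundaries are not shifted in time; the band default is the standard
   slow-fluctuation range for TR = 0.8 s acquisitions.
2. **Sliding windows** (`sliding_window_correlation`): rectangular
   window of 60 s (75 frames at TR 0.8 s) slid by one TR; Pearson
   correlation per window and parcel pair; Fisher z-transform with r
   clipped to +-(1 - 1e-12) so degenerate synthetic inputs stay finite.
   With 410 input frames, 10+10 trimmed and a 75-frame window this
   yields 316 windows; the frame count is treated as data-driven
   throughout (a published run length of 5 min 47 s at this TR is
   nominally ~434 frames, which gives 340 windows with the same
   settings; the package never hard-codes the window count).
3. **Edge sample entropy** (`sample_entropy`, `edge_entropy`): SampEn
   with embedding dimension m = 2 and tolerance eps = 0.20 (defaults),
   tolerance r = eps * sigma with the *population* standard deviation,
   Chebyshev distance, boundary inclusive (a distance exactly equal to r
   counts as a match). Template vectors run over i = 1..N-m for both
   lengths, so the m+1 matches are a subset of the m matches and the
   estimate is the ratio of pooled counts. Undefined values (no matching
   pair at either length) are flagged `NA` rather than infinite and are
   excluded from template construction.
4. **Templates and similarity** (`proportional_threshold`,
   `build_similarity`, `sweep_templates`): HEN keeps the
   `floor(density * E)` edges with the highest control-group mean ESE,
   LEN the lowest; ties at the cutoff break by canonical edge order.
   Subjects' masked ESE vectors are correlated pairwise (Pearson) to
   give the similarity kernel R with unit diagonal. Sixteen candidate
   densities per tail (1%..16% in 1% steps by default) are each scored
   by the model below, and ranked on mean variance explained, p-Wald,
   p-Perm and |p-Perm - p-Wald| (concordance); the best average rank
   wins, ties toward the sparser template.
5. **Variance-component model** (`fit_varcomp` and friends):
   Y = XB + C + E with Vec(C) ~ N(0, Sigma_c (x) R) and
   Vec(E) ~ N(0, Sigma_e (x) I). An orthonormal basis of the orthogonal
   complement of span([1 X]) removes the fixed effects exactly;
   moment matching on the transformed model gives
   Sigma_c = Y'(R - tau I)Y / nu and Sigma_e = Y'(kappa I - tau R)Y / nu
   with tau = Tr(R)/N, kappa = Tr(R^2)/N, nu = N(kappa - tau^2).
   Variance explained is M = Tr(Sigma_c)/(Tr(Sigma_c) + Tr(Sigma_e)),
   clipped to [0, 1] for reporting; per-measure fractions use the
   diagonals. Behavioral scores are rank-based inverse-normal
   transformed first (`quantile_normalize`); missing scores take the
   column median and a missing medication dose is zero
   (`impute_behavior`).

## Inference choices

*Wald test.* No closed-form SE is canonical for the trace ratio, so the
package derives both from the exact covariance of Gaussian quadratic
forms (all matrices involved are polynomials in R, so every trace is a
spectral sum). The reported `SE` plugs the fitted (Sigma_c, Sigma_e)
into that covariance and is validated against a parametric bootstrap in
the test suite. The *test* statistic, however, uses the variance
evaluated at the null (Sigma_c = 0, fitted total covariance): the
plug-in variance contains Tr(Sigma_c^2), whose estimate is positively
biased near the null, which would make p-Wald conservative and
non-uniform. With the score-type SE the null distribution of p-Wald is
approximately uniform and concordant with the permutation p, which is
exactly the property the density-selection rule relies on.

*Permutation test.* Rows and columns of the projected kernel are
permuted jointly; tau, kappa and nu are permutation invariant, so each
permutation reduces to one weighted sum over the Gram matrix of the
projected outcomes. p-values use the add-one estimator and never reach
zero.

*Contrasts.* HEN vs LEN differences (overall and per measure) are
resampled over patients. Bootstrap resamples rebuild both similarity
matrices (duplicated subjects yield off-diagonal 1s; accepted, the
intervals are rank-based), refit both models, and form bias-corrected
percentile intervals at level alpha / (P + 1) (Bonferroni over the
overall test plus P measures). A confirmatory jackknife uses
leave-one-out estimates with normal-theory intervals. Degenerate
resamples (kernel numerically proportional to the identity,
rank-deficient resampled design) are redrawn up to 10 times.

*Edgewise model.* The per-edge variant uses a rank-one kernel
z z' from patientwise standardized ESE with the diagonal reset to 1.
This construction is a documented reconstruction: it follows the kernel
algebra of the multivariate model, and its null behavior is verified by
simulation in the test suite. Edge values are the mean of the
per-measure clipped fractions.

## Network statistics

Edgewise values are averaged within and between the 8 systems (7
cortical networks + subcortex). Two null models assess block enrichment:
uniform relocation of the template's edges (size- and density-matched;
an equivalent value-permutation variant is provided and tested for
agreement) and degree-preserving double-edge swaps with greedy weight
re-sorting by original nodal strength rank (the degree sequence is a
hard constraint; strength matching is approximate and its Spearman
fidelity is reported per permutation). Tests are one-sided "greater"
(the scientific question is excess explained variance), with add-one
p-values and BH-FDR over the full 36-block family — the widest, hence
most conservative, grouping. Normalized degree-centrality divides each
node's binary degree by its mean under the relocation null;
node-entropy is the cortical HEN - LEN difference of normalized
degrees min-max rescaled to [0, 1] (degenerate constant differences are
an error, not a silent rescale).

## Spatial surrogate tests

Correlations between parcel maps inherit the spatial autocorrelation of
both maps, so naive parametric p-values overreject. Annotation-map
tests therefore compare the empirical correlation against surrogates of
the annotation map that preserve its value distribution exactly (rank
remapping) and approximately match its variogram: each surrogate is a
random permutation smoothed by exponential kernels over a bandwidth
grid, blended with its white permutation by nonnegative least squares
against the source variogram (variograms of independent fields add),
and rank-remapped. Variogram matching (not spin rotation) is the right
family here because parcellations mixing cortical and subcortical
structures have no spherical geometry. Maps with |r| below 0.2 are
dropped before testing; retained maps get two-sided surrogate p-values
(the direction of a map correlation is not prespecified) and BH-FDR.
The test suite demonstrates the core trade-off: surrogates decorrelate
from the source while matching its variogram within 20% per distance
bin, and on smooth independent map pairs the surrogate test removes the
overrejection that the parametric test shows.

## The synthetic-data generator

The source imaging data are access-restricted, so the package ships a
generator whose defaults mirror the study design: 53 controls and 97
patients, 116 parcels, 410 frames at TR 0.8 s, 7 behavioral measures, 5
covariates (age, sex, medication dose, mean framewise displacement,
phenotype, matched in distributional shape). Ground truth is planted at
three levels:

* **Edge dynamics.** Background parcels carry independent band-limited
  noise in 0.03-0.08 Hz. "Regular" edges are vertex-disjoint pairs
  whose coupling weight is a slow sinusoid (period 700 frames, peak
  0.95): their windowed correlation tracks a smooth, large-amplitude
  trajectory, giving the lowest ESE. "Irregular" edges are all edges of
  a few *fast hub* parcels carrying narrow-band noise at the top of the
  passband (carrier period 12.5 frames): the spectral mismatch between
  a fast hub and any mid-band partner concentrates the
  correlation-product energy at high frequencies, so these edges
  fluctuate roughly at the window scale and have the highest ESE. The
  mechanism was chosen because the windowed-correlation entropy of a
  planted edge is governed by the *spectral separation* of its
  endpoints: amplitude-modulated couplings, whatever their speed, add
  smooth low-frequency variance to the edge timeseries and thus lower
  its entropy — they cannot place a planted edge above the background.
  Fast hubs also reproduce a qualitative feature of empirical
  high-entropy templates, which concentrate on subcortical hubs. For
  short test runs the slow period should be scaled to the run length
  (the pair must traverse a good part of one modulation cycle).
* **Behavior.** Y = XB + sum_k C_k + E with Vec(C_k) ~
  N(0, Sigma_k (x) R_k). Kernels default to the empirical similarity
  matrices computed from the synthetic patients' masked ESE vectors,
  closing the loop with the real pipeline; isotropic Sigma choices
  plant exact overall variance fractions. Planting 0.2 on the HEN
  kernel and 0.5 on the LEN kernel yields a recoverable negative
  HEN - LEN contrast.
* **Maps.** Annotation maps are Gaussian fields with exponential
  covariance exp(-d / range) on parcel centroid distances. Centroids
  place one cluster center per system on a ring with isotropic jitter
  (sd 20 units): systems overlap spatially and parcels cover the volume
  semi-uniformly, like real centroids; tightly clumped systems would
  produce a step-shaped variogram that no smoothing family matches. The
  default map range of 15 units gives moderate parcel-level
  autocorrelation; longer ranges (40+) are used in tests to demonstrate
  parametric p-inflation.

What the generator does *not* emulate: hemodynamic response shapes,
scanner noise spectra and drifts, motion artifacts, spatially
heterogeneous temporal SNR, or volumetric geometry. Passing tests
therefore show that the pipeline recovers structure *of the planted
kind* at realistic dimensions — not that the empirical findings of any
particular dataset are correct.

## Problem sizes used in tests and the acceptance script

Monte-Carlo checks run at the sizes a careful desk validation would
use: variance-component recovery and calibration at N = 100, P = 7 with
500 (tests) or 200-300 (script) replicates; the end-to-end planted
study at 40 parcels with the full subject count (53 + 97) in the test
suite and a 20 + 60 subset in the acceptance script; surrogate checks
at 80 parcels with 500-1000 surrogates; network nulls at 10,000
permutations where enrichment detection is asserted and 100-200 where
only hard invariants are checked. Structural counts (116 parcels, 6670
edges; 16 densities per tail, 32 templates) are computed at the study's
exact geometry.

## Known limitations

* The moment estimator is unbiased but unconstrained; clipping to
  [0, 1] introduces boundary bias visible as a small positive mean at a
  planted fraction of zero.
* The bias-corrected bootstrap can produce very short intervals when
  the resampling distribution is strongly shifted relative to the
  estimate (heavy duplicate-induced kernel distortion at small N); the
  jackknife contrast is the cross-check.
* The edgewise rank-one kernel is a reconstruction (see above), not a
  transcription of a published formula.
* Surrogate variogram matching is approximate by construction; fidelity
  degrades for maps whose correlation range approaches the map extent.
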