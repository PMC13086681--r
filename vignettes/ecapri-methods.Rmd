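---
title: "Methods: imaging biomarkers and Cox risk scoring for post-TAVI mortality"
author: "ecapri package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imaging biomarkers and Cox risk scoring for post-TAVI mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Patients undergoing transcatheter aortic valve implantation (TAVI) are old
and heavily comorbid; up to a quarter of high-risk patients do poorly within
a year. The CAPRI score predicts one-year all-cause mortality from 13
clinical variables plus the thoracic aortic calcium (TAC) volume measured on
the pre-procedural CT; its extension, eCAPRI, adds three automatically
extracted imaging biomarkers: BSA-indexed right-ventricle volume, BSA-indexed
pulmonary-artery maximal radius, and the abdominal-muscle cross-sectional
area at the L3 vertebral level (a sarcopenia surrogate).

This package implements the full methodology as reusable, testable
components: the segmentation scaffolding used to automate TAC measurement,
the biomarker extractors, the score itself (with the published coefficients
packaged as defaults), the three-step biomarker selection pipeline, and the
evaluation machinery. Because the underlying patient cohorts are private,
the package also ships generators for CT phantoms and survival cohorts so
that every stage can be verified against known ground truth.

## The score

For a patient with covariate vector $X$, the score is the mean-centered Cox
linear predictor

$$\mathrm{score}(pat) = \sum_i \beta_i \,\bigl(X_i(pat) - \bar X_i\bigr),$$

where $\beta_i$ are multivariate Cox proportional-hazards coefficients and
$\bar X_i$ the training-cohort means. `capri_model()` and `ecapri_model()`
return the frozen published fits (14 and 17 variables). Two properties are
exact by construction and asserted in the tests: the score vanishes at the
training means, and score *differences* between patients do not depend on
the centering.

**Ordinal grade coding.** NYHA, mitral-regurgitation and renal-clearance
grades are encoded 0-based (grade I $\to$ 0). This is the only coding under
which the packaged training means (clearance 1.67, NYHA 1.41, mitral 0.83)
are consistent with the published category frequencies of the training
cohort, so `encode_clinical()` maps Roman grades accordingly and numeric
inputs are taken as already 0-based. The PAPs convention is enforced as
published: when the systolic pulmonary artery pressure is unavailable
(`paps_available = 0`) the pressure term is zero.

Some packaged coefficient signs run against clinical intuition (e.g. the
negative coefficient on aortic calcium volume, or on coronary disease).
They are transcribed as published, not "corrected": the score is a
multivariate fit and individual signs absorb correlations with the other
variables.

## Segmentation scaffolding and the baseline calcium segmenter

The automated TAC measurement in the source methodology trains a 3D U-Net
with a *masked* binary cross-entropy so that the network only needs to learn
the appearance of calcium, not its anatomical position. Training the network
is out of scope here (GPU-scale, private data); everything around it is
implemented and testable:

* **Inclusion mask** `build_aorta_mask()`: the aorta segmentation dilated by
  a ball of per-axis voxel radius $\mathrm{round}(2/sp)$ — a ~2 mm physical
  margin however anisotropic the voxels — admitting wall calcium that
  protrudes beyond the segmented lumen.
* **Spine exclusion** `build_spine_exclusion()`: the vertebral bodies
  dilated by $\mathrm{round}(1/sp)$ and inverted, so cortical bone and its
  rim never contribute.
* **Valve exclusion** `build_valve_exclusion()`: Euclidean distance maps
  from LV, LA and aorta; the aortic-valve zone is within `tau_mm` of both LV
  and aorta, the mitral zone within `tau_mm` of both LV and LA. The distance
  threshold is not stated in the source; the default is 5 mm and
  configurable — an open choice, documented as such.
* **Masked loss** `masked_bce()`: the mean over all voxels of the per-voxel
  binary cross-entropy multiplied by the product of the three masks. The
  printed form of the loss is ambiguous about whether the mask product
  applies to the whole per-voxel term or only the background term; the
  package multiplies the whole term, because the stated intent is that
  candidates outside the aorta are excluded entirely. The alternative
  reading is available via `mask_whole = FALSE`. The conventional leading
  minus sign is restored (the returned loss is positive and minimized), and
  predictions are clipped at `eps = 1e-7` before the logarithms — a pure
  numerical safeguard, immaterial at test tolerances.
* **Preprocessing** `preprocess_ct()`: crop to the aorta bounding box padded
  by the dilation margin, clip HU to $[-200, 1000]$ (soft tissue to dense
  calcium), map affinely to $[-1, 1]$. `sample_patches()` draws the
  100-voxel training patches uniformly and reproducibly.
* **Baseline segmenter** `threshold_calcium()`: the adaptive-threshold
  procedure used to produce reference annotations — seeds at $\ge$ 130 HU
  (the conventional calcium cut-off) inside the inclusion mask and outside
  the exclusions, each seed's connected component of $\ge$ 130 HU voxels
  grown to cover the whole calcification. Growth uses 26-connectivity and
  the *same* 130 HU floor: "extended to cover the entire calcification" is
  read as connected-component completion, the most conservative
  interpretation; threshold and connectivity are arguments.

## Biomarker extraction

Volumes are voxel counts times voxel volume; the L3 muscle area is the
in-plane count at the L3 centroid slice times the in-plane pixel area; the
emphysema ratio is the percentage of lung voxels strictly below $-950$ HU
(the threshold is configurable because its ideal value under contrast
injection is debated). Maximal vessel radii are computed from the exact
anisotropic Euclidean distance transform of the vessel mask: the skeleton is
taken as the 26-neighborhood local maxima of the boundary distance (a
distance-ridge medial-axis approximation rather than iterative topological
thinning — the maximal inscribed radius is identical and the approximation
is rotation-stable), and the largest boundary distance on the skeleton is
returned in cm. Body surface area uses Boyd's 1935 formula
$0.0003207\, h^{0.3}\, w_g^{0.7285 - 0.0188 \log_{10} w_g}$ (weight in
grams); Du Bois and Mosteller variants are available for sensitivity
checks. All biomarkers except the (dimensionless) emphysema ratio get a
BSA-indexed twin. Implausibly small results — muscle area below 10 cm²,
radii below 0.2 cm — trigger segmentation-failure warnings, mirroring the
failure modes observed with automated segmentation in practice.

The radius-versus-diameter ambiguity in the source material (tables list
"max radius (cm)", prose says "max diameter") is resolved by computing and
storing the **radius**; a diameter is simply twice it.

## Three-step biomarker selection

1. **Univariate screen** (`univariate_screen`): one-variable Cox fits; the
   likelihood-ratio statistic $2(\ell_1 - \ell_0)$ against $\chi^2_1$;
   candidates with $p > 0.2$ eliminated (the boundary is retained). The
   permissive threshold deliberately tolerates confounded effects.
2. **Correlation pruning** (`prune_correlated`): mixed-type correlations —
   tetrachoric for binary pairs, polychoric for ordinal pairs, Spearman
   whenever a continuous variable is involved. Any candidate correlated
   above 0.85 in absolute value with a core score variable, or with another
   candidate achieving a strictly better univariate p-value, is dropped;
   core variables are never dropped (PAPs and its availability flag stay
   together by design). Ties in p-value break lexically. The rule is
   applied unconditionally (a candidate falls to a better-p competitor even
   if that competitor itself falls to a third variable), which reduces any
   mutually correlated clique to its single best-p member.
3. **Exhaustive subset search** (`combination_search`): every subset of the
   surviving candidates (capped at 20 candidates, $2^k$ subsets including
   the empty one) is added to the core variables, fitted on each fold's 75%
   and scored by the one-year-event AUC on the held-out 25% of a 4-fold
   partition stratified by event status; the best mean AUC wins, ties
   breaking toward the smaller subset, then lexically. Patients censored
   before the horizon (impossible with administrative one-year censoring,
   possible in user data) are excluded from fold AUCs with a warning.

`select_biomarkers()` chains the three steps and refits the chosen augmented
score on the whole training set; the final coefficients and training means
are the deployable score.

The tetrachoric/polychoric estimator is the standard two-step
latent-bivariate-normal maximum likelihood: thresholds from the marginal
frequencies, then a one-dimensional likelihood maximization over the latent
correlation. The bivariate normal CDF is evaluated by 64-point
Gauss–Legendre quadrature of the conditional probit integrand (accurate to
~1e-15 against adaptive quadrature). Estimates at the boundary with an
empty contingency cell are clamped to $\pm 0.999$ with a warning. Cox fits
use `survival::coxph` with the Efron tie correction (Breslow by flag).

## Evaluation

`auc()` is the Mann–Whitney concordance with midrank tie handling;
`auc_ci()` adds a percentile bootstrap stratified by event status. The
published comparison of two scores describes a "permutation test
(bootstrap)", which conflates two procedures; the package implements the
paired sign-flip permutation as primary — the (A, B) score pair is swapped
within each patient with probability one half, the statistic is the AUC
difference, and the two-sided p-value uses add-one smoothing
$(r+1)/(B+1)$ so it is never exactly zero. `risk_probability()` maps the
linear score to an absolute risk via the Breslow baseline cumulative hazard
of the fitting cohort, $P = 1 - \exp(-H_0(t)\,e^{\mathrm{score}})$,
referenced to a patient at the training means; the source never states how
its calibration plots mapped scores to probabilities, so this is a
documented choice. `calibration()` uses equal-count (quantile) decile bins
with tied break points merged; a constant forecast (the climatology
reference) collapses to a single bin with a warning rather than an error,
because its Brier skill score — exactly 0 — is still well defined.

## Synthetic data: what it emulates and what it does not

**Phantoms** (`phantom_spec`/`generate_phantom`) rasterize geometric
primitives — a tubular aorta with spherical wall calcium (300–1000 HU),
ellipsoidal chambers, an ellipsoidal lung field with sub-$-950$ HU pockets,
ellipsoidal vertebral bodies, an annular L3 muscle belt — onto a voxel grid
in a documented order (background, lungs, spine, muscle, chambers, aorta,
calcium; later stamps overwrite earlier HU), then add Gaussian HU noise.
Masks and ground truth are computed *before* noise; volumes and areas in the
truth are mask-derived (voxel count times voxel volume) so extraction tests
are independent of rasterization error, while vessel-radius truth is the
analytic descriptor radius (a mask cannot yield an inscribed radius without
the very algorithm under test — the tests therefore allow one voxel
diagonal). The default phantom uses a 96³ grid at 1 mm spacing with a 40 HU
(non-contrast) aortic lumen; geometry is deterministically jittered per seed
when requested so repeated phantoms exercise different configurations.
Phantoms are deliberately *not* anatomically realistic: no contrast
dynamics, no scanner model, no partial-volume blur. Passing phantom tests
demonstrates correctness of the measurement operators, not robustness to
real-world segmentation quality.

**Cohorts** (`cohort_sim_spec`/`simulate_cohort`) draw covariates from the
published training-cohort marginals — truncated normals within the printed
ranges for continuous variables, category frequencies for ordinal grades,
prevalences for binaries — independently by default (the source reports only
marginals), with an optional Gaussian copula for tests that need correlated
inputs. Event times are exponential with rate
$\lambda_0 \exp\{\beta^\top(x - \mu)\}$ and administrative censoring at 365
days. The default baseline $\lambda_0 = -\log(1-0.093)/365$ calibrates the
expected one-year event fraction to the 9.3% one-year mortality observed in
the emulated cohort. Truncation pulls continuous means slightly below their
nominal values (about 0.35 years for age); the simulator centers its linear
predictor on the exact truncated means, so planted effects are unbiased.

## Problem sizes and test design

The test suite exercises: phantoms at 96³ (extraction, segmentation) and
32–64³ (voxel-wise oracles against brute-force dilation/counting loops);
Cox recovery at n = 2000 over 20 seeds with a brute-force one-dimensional
partial-likelihood grid as the small-sample oracle; the null behavior of
the 0.2-level LRT screen over 500 replicates; latent-correlation recovery
at n = 5000 for $\rho \in \{0, 0.3, 0.6, 0.9\}$; the full selection
pipeline at n = 2000 with three planted effects (hazard ratios 2.0, 1.7 and
1.4 per standard deviation, the last protective) among seven noise
candidates, over 20 seeds with a 20-seed no-signal control; and permutation
p-value uniformity over 200 replicates. These sizes were chosen to make the
statistical assertions sharp at conventional three-standard-error
tolerances while keeping the default suite fast.

## Known limitations

* The packaged coefficients are a transcription of a fit on one European
  TAVI cohort; no claim of transportability is made, and the published
  cohort-level discrimination figures cannot be reproduced without the
  private evaluation data.
* The baseline thresholding segmenter is the reference annotation
  procedure, not a replacement for a trained network; on contrast-enhanced
  scans (lumen ≥ 130 HU) it will flood the lumen by design, exactly as the
  un-curated annotation procedure would before manual validation.
* `vessel_max_radius` measures half-widths of the provided mask; on masks
  with severe segmentation failure it warns rather than repairs.
* Phantom geometry is axis-aligned and piecewise-constant; it cannot probe
  partial-volume or motion effects.
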