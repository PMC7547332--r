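---
title: "Texture-morphology score fusion for breast ultrasound classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-morphology score fusion for breast ultrasound classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(busfusion)
```

## The problem and the model

Benign and malignant breast lesions differ on ultrasound in two largely
complementary ways. Their *internal and marginal echo texture* differs:
malignant lesions tend to have heterogeneous internal echoes and blurred,
poorly defined margins. And their *shape* differs: benign lesions are
typically round or oval with smooth contours, while malignant lesions are
lobulated and irregular. A single classifier fed the concatenation of both
feature families tends to be dominated by the high-dimensional texture
block, drowning out the handful of shape features that carry much of the
diagnostic signal.

busfusion therefore keeps the two families in separate channels and
combines them only at the score level:

* **Texture channel.** Local binary patterns (256-bin code histogram),
  histograms of oriented gradients on a fixed canvas, and Haralick
  statistics (energy, contrast, correlation, homogeneity) of gray-level
  co-occurrence matrices feed an RBF-kernel support vector machine whose
  Platt-calibrated output $S_{\mathrm{SVM}} \in [0,1]$ is the texture
  malignancy score.
* **Morphology channel.** Four contour descriptors — compactness
  $C = 4\pi A / L^2$, elliptic compactness
  $EC = \pi(a+b)/L$ from a direct least-squares ellipse fit, and the mean
  and variance of the log-amplitude Fourier spectrum of the radial-distance
  signature — feed a Gaussian naive Bayes classifier whose malignant
  posterior $S_{\mathrm{NB}}$ is the shape score.
* **Fusion.** The final score is the convex combination
  $S_c(\lambda) = \lambda\, S_{\mathrm{SVM}} + (1-\lambda)\, S_{\mathrm{NB}}$,
  and a lesion is called malignant when $S_c \ge 0.5$ (a tie scores
  malignant). The default weight is $\lambda = 0.8$; `lambda_sweep()`
  evaluates the whole grid $\lambda \in \{0, 0.1, \dots, 1\}$, whose
  endpoints reproduce the single channels exactly.

The naive Bayes channel is deliberately low-dimensional and
non-parametric in spirit: pairing it with the already heavily
parameterized SVM keeps the complexity of the combined system close to
that of the SVM alone while letting the shape features speak with full
weight.

## Preprocessing

The conditioning chain is fixed in order: border crop, speckle-reducing
anisotropic diffusion (SRAD), global histogram equalization.

SRAD evolves the image under
$I_{t+1} = I_t + \tfrac{dt}{4}\,\mathrm{div}\!\left(c(q)\,\nabla I_t\right)$
where $q$ is the local instantaneous coefficient of variation and
$c(q) = 1/\bigl(1 + (q^2 - q_0^2)/(q_0^2(1+q_0^2))\bigr)$. In fully
developed speckle $q \approx q_0$ and diffusion proceeds; at edges
$q \gg q_0$ and diffusion stops, which is why the filter smooths
multiplicative speckle without washing out lesion boundaries. Parameter
defaults are the common practice for this filter, exposed in
`fusion_config()`:

* `n_iter = 100` iterations with time step `dt = 0.05` (stability requires
  $dt \le 0.25$);
* $q_0$ starts at the coefficient of variation of a homogeneous reference
  patch — auto-estimated from the darkest $32\times32$ block, which in a
  hypoechoic-lesion image is a reasonable homogeneous candidate — and
  decays as $q_0(t) = q_0(0)\,e^{-t/6}$ with diffusion time;
* replicate (mirror) boundary conditions; output clipped to the input
  intensity range.

Histogram equalization uses the 8-bit CDF mapping
$T(v) = \max(0, \lfloor 256\,\mathrm{cdf}(v)\rfloor - 1)$, which is exactly
the identity on an already-uniform histogram, monotone (it never reorders
pixel intensities), and idempotent up to rounding. Global (not adaptive)
equalization is used. Internally images are real-valued in $[0,1]$;
quantization to the 8-bit grid happens only at module boundaries, rounding
half up.

## Feature extraction choices

Several details are open in principle; the package fixes them as follows
(all config-exposed where tunable):

* **LBP neighbor order.** The eight 3×3 neighbors are read clockwise from
  the top-left corner, $p = 1..8$, weighted $2^{p-1}$, with the sign
  function taking $s(0) = 1$. The basic 256-code operator is used, not the
  uniform or rotation-invariant variants. Codes are computed only for
  pixels whose full 3×3 window lies inside the region of interest.
* **Region of interest.** LBP and GLCM statistics are computed over the
  lesion contour filled and dilated by 8 px — the marginal rim carries the
  boundary-echo texture that distinguishes well-defined from blurred
  margins. Pixel pairs whose GLCM partner falls outside the ROI are
  skipped, never padded.
* **HOG canvas.** Lesions vary in size but HOG needs a fixed grid, so the
  lesion bounding box is resized (bilinear) to a 128×128 canvas: 32-px
  cells, 2×2-cell blocks at stride one cell, 9 unsigned orientation bins
  over $[0^\circ, 180^\circ)$, square-root gamma compression, L2 block
  normalization with $\varepsilon = 10^{-12}$. Descriptor length is
  $3 \times 3 \times 4 \times 9 = 324$, a function of the configuration
  only.
* **GLCM.** 64 gray levels (equal-width bins of the full intensity
  range), distances 1–10, directions 0/45/90/135 — 40 matrices per image,
  each symmetrized and normalized; the four Haralick statistics are kept
  per matrix (160 texture values), not averaged, preserving the
  distance-direction structure.
* **Radial-distance spectrum.** The contour is resampled to $N = 128$
  points equally spaced in arc length so spectra are comparable across
  contours of different vertex counts; the center is the polygon area
  centroid. One-sided harmonic amplitudes $2|F_k|/N$, $k = 1..N/2$, enter
  as $\log(\text{amp} + 10^{-8})$; the DC term is excluded because it
  encodes lesion size, not margin roughness. Natural log and the one-sided
  spectrum are package decisions. Under uniform scaling
  the spectrum statistics behave predictably: the log-amplitude mean
  shifts by the log of the scale factor while the variance, compactness
  and elliptic compactness are scale-invariant (tested properties).
* **Compactness convention.** $C = 4\pi A / L^2$, the isoperimetric
  ratio: exactly 1 for a continuous circle and below 1 otherwise, which is
  the only reading consistent with "closer to 1, more likely benign". For
  a polygonal contour of a circle, $C$ approaches 1 from below as the
  vertex count grows.
* **Ellipse fitting.** The direct least-squares conic fit with the
  ellipse constraint $4AC - B^2 = 1$ (Fitzgibbon–Pilu–Fisher), in the
  numerically stabilized partitioned formulation of Halir and Flusser,
  after centering and scaling the points. The solution is guaranteed to be
  an ellipse; collinear or under-determined inputs (fewer than 6 points)
  raise a fit error. Noiseless sampled ellipses are recovered to $10^{-6}$
  relative error.

## Normalization, dimension reduction, and leakage control

Each feature is min-max scaled to $[0,1]$ with training-set statistics;
constant features map to 0 and out-of-range test values are clipped. The
texture block is then reduced by mean-centered PCA, retaining the smallest
number of components reaching 95% cumulative explained variance (the
retained dimension is data-dependent; the threshold is the tunable). The
4-feature morphology block bypasses PCA — it is already low-dimensional,
and reduction there would only blur interpretable descriptors.

Normalizer and PCA states are fit once on the training split and frozen;
the public pipeline API offers no way to refit them on test data. Min-max
scaling (rather than z-scoring) is the default because it pairs well with
the RBF kernel's distance geometry; z-scoring can be substituted by
normalizing externally.

## Classifier settings

* **SVM.** Grid search over $(c, g) \in 2^{\{-5,-3,\dots,15\}} \times
  2^{\{-15,-13,\dots,3\}}$ (the libsvm-conventional lattice) by seeded,
  stratified 5-fold cross-validation on the training split; ties resolve
  to the smallest $c$, then the smallest $g$. The selected model is refit
  on the full training set. Probability calibration is a Platt sigmoid fit
  by logistic regression on *cross-validated* decision values — computed
  out-of-fold with the same fold assignment — which avoids the optimism of
  calibrating on resubstitution values and gives a deterministic, correctly
  oriented mapping (libsvm's built-in estimates can invert on separable
  data).
* **Naive Bayes.** Gaussian class conditionals per feature with a
  variance floor of $10^{-9}$ (degenerate features never raise an error),
  priors from training frequencies. Continuous features make the Gaussian
  variant the natural choice.
* **Split.** 80/20 train/test, stratified by class so both splits keep
  the benign:malignant prior; with 448 samples this yields 358 training
  and 90 test cases.
* **Baselines.** KNN ($k = 5$, score = malignant fraction among
  neighbors), a CART classification tree, and LDA, all emitting the same
  $[0,1]$ malignancy-score contract for comparison experiments.

## The phantom generator

The clinical images behind this method are not redistributable, so the
package ships a seeded lesion-phantom generator that reproduces the
*statistical structure* the classifier relies on, with class priors
defaulting to the 184 benign : 264 malignant composition of the original
collection. The lesion boundary is the polar curve

$$r(\theta) = r_0 \left(1 + \sum_k \alpha_k \cos(k\theta + \varphi_k)\right)$$

with seeded random phases. Fixed parameter bands keep the acceptance
properties stable:

| parameter | benign | malignant |
|---|---|---|
| harmonic orders $k$ | $\le 2$ | 3 from $\{3..8\}$ |
| relative amplitudes $\alpha_k$ | $\le 0.03$ | $[0.08, 0.25]$ |
| margin blur $\sigma$ (px) | 1.5 | 4.0 |
| internal heterogeneity | 0.05 | 0.25 |

plus, for both classes: base radius 34–50 px in a 256-px frame,
hypoechoic lesion (gray 60) on brighter background (gray 150), and
unit-mean multiplicative Gamma speckle with shape 4 — the standard
fully-developed-speckle approximation. The "internal heterogeneity" is a
smoothed multiplicative random field inside the lesion; together with the
margin blur it gives the texture channel a class signal with the textbook
clinical direction (heterogeneous echoes and blurred margins suggest
malignancy). Stored contours carry sub-pixel radial annotation jitter
(SD 0.05 px), emulating manual radiologist tracing; this also sets a
genuine spectral floor for the radial-distance signature, without which
the log-amplitude statistics of analytically smooth curves are dominated
by the $10^{-8}$ numerical guard.

What the phantoms do *not* emulate: acoustic shadowing and enhancement,
beam/point-spread-function physics, depth-dependent attenuation, BI-RADS
subcategory structure, and annotation disagreement between readers.
Passing tests on phantoms therefore demonstrate that the pipeline's
machinery is correct and that it recovers class structure of the asserted
kind — not that the published clinical operating points transfer to any
particular scanner or population.

Because the phantom classes are strongly separated by construction,
classifiers saturate near 100% accuracy at moderate sample sizes; the
interesting guarantees on phantoms are therefore directional (benign
compactness higher, malignant radial variance higher) and structural
(fusion at least as good as each channel within 2 points, byte-exact
reruns), not the clinical percentages.

## Numerical and reproducibility choices

* All randomness flows from a single run seed through deterministic
  per-stage derived seeds; the RNG kind is pinned, so a rerun with the
  same configuration and seed reproduces the serialized report
  byte-for-byte on one platform.
* SRAD is implemented as a compiled kernel (a pure-R reference
  implementation is kept and the two are asserted equal in tests).
* Degenerate inputs fail loudly and early with classed conditions:
  zero-area contours, under-determined ellipse fits, ROIs smaller than an
  LBP window, margins exceeding the frame, empty classes.
* Ties: fused score exactly 0.5 is called malignant; SVM grid ties pick
  the smallest cost then gamma; ROC ties are handled by the
  threshold-sweep construction, whose trapezoid AUC equals the
  Mann–Whitney pairwise-concordance statistic with ties counted half.
* Default problem sizes used by the shipped experiments: the test suite's
  end-to-end simulation uses 400 phantoms (164/236, preserving the 41/59
  prior) at 256×256 px with the full 100-iteration SRAD; smaller examples
  in the documentation use 24–98 phantoms at 128 px.

## Known limitations

* The phantom bands are invented: no quantitative shape statistics of the
  original clinical lesions are published, so the generator encodes the
  qualitative radiological description only.
* The published clinical accuracy/sensitivity/specificity and AUC values
  cannot be reproduced without the private dataset; the package verifies
  the *arithmetic* of those operating points (confusion-matrix
  reconstruction) and all method-level contracts instead.
* SRAD iteration count, time step and $q_0$ schedule for the original
  experiments are unknown; the defaults here are standard practice and are
  exposed for tuning on real data.
* HOG bin count and whether HOG ran on the lesion box or the whole frame
  are likewise unstated in the source method; both are config-exposed
  decisions here (9 bins, lesion box).
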