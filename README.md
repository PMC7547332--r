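# busfusion

Computer-aided benign/malignant classification of breast ultrasound
lesions by **late fusion of a texture channel and a morphology channel**.

Breast lesions separate on ultrasound along two complementary axes:
internal/marginal echo **texture** (malignant lesions have heterogeneous
echoes and blurred margins) and contour **shape** (malignant lesions are
lobulated and irregular rather than round or oval). Concatenating both
feature families into one classifier lets the high-dimensional texture
block drown out the few shape features, so busfusion keeps them apart:

* **Texture → RBF SVM.** Local binary patterns (256-bin histogram),
  histograms of oriented gradients on a fixed 128×128 canvas, and
  energy/contrast/correlation/homogeneity of 40 gray-level co-occurrence
  matrices (64 levels, distances 1–10, directions 0°/45°/90°/135°); the
  block is min-max normalized, PCA-reduced (95% variance), and classified
  by a grid-searched RBF SVM with Platt-calibrated malignancy score
  *S*<sub>SVM</sub> ∈ [0, 1].
* **Morphology → Gaussian naive Bayes.** Compactness *C* = 4πA/L²,
  elliptic compactness *EC* = π(a+b)/L from a direct least-squares
  (Fitzgibbon) ellipse fit, and the mean/variance of the log-amplitude
  Fourier spectrum of the radial-distance signature; the malignant
  posterior is *S*<sub>NB</sub>.
* **Fusion.** *S*<sub>c</sub>(λ) = λ·*S*<sub>SVM</sub> + (1−λ)·*S*<sub>NB</sub>,
  malignant iff *S*<sub>c</sub> ≥ 0.5, default λ = 0.8;
  `lambda_sweep()` evaluates the whole weight grid, whose endpoints are
  exactly the single channels.

Inputs are 8-bit grayscale images plus a closed lesion contour per image
(ordered point list). Preprocessing is border crop → speckle-reducing
anisotropic diffusion (SRAD, a compiled PDE filter) → global histogram
equalization. Because the clinical dataset behind the method is private,
the package ships a seeded **lesion-phantom generator** that reproduces
the statistical structure the classifier assumes (smooth elliptical
benign vs lobulated blurred malignant lesions, multiplicative Gamma
speckle, 184:264 class prior), so the entire pipeline is buildable and
testable from nothing. KNN (k = 5), decision-tree and LDA baselines share
the same score contract for comparison experiments.

## Worked example

```r
library(busfusion)

cfg <- fusion_config(n_benign = 10L, n_malignant = 14L,
                     image_size = 128L, srad_iters = 30L)
run <- run_fusion_pipeline(cfg, seed = 7)
print(run)
#> <fusion_run>
#>   samples: 19 train / 5 test, lambda = 0.80
#>   fused: accuracy 100.00%, sensitivity 100.00%, specificity 100.00%, AUC 1.0000
#>   channels: SVM(texture) 100.00%, NB(morphology) 100.00%

tidy(run)
#> # A tibble: 5 × 7
#>   id     label     s_svm     s_nb   s_c lambda predicted
#>   <chr>  <fct>     <dbl>    <dbl> <dbl>  <dbl> <fct>
#> 1 b_0007 benign    0.377 8.20e-24 0.302    0.8 benign
#> 2 b_0010 benign    0.380 2.20e-22 0.304    0.8 benign
#> 3 m_0012 malignant 0.910 1   e+ 0 0.928    0.8 malignant
#> 4 m_0020 malignant 0.998 1   e+ 0 0.998    0.8 malignant
#> 5 m_0024 malignant 0.985 1   e+ 0 0.988    0.8 malignant
```

The run simulates 24 seeded phantoms, preprocesses them, extracts both
feature blocks, fits the frozen normalizer/PCA and both channels on the
stratified 80% training split, and evaluates the held-out 20%. Each test
row shows the two channel scores, the fused score
`s_c = 0.8 * s_svm + 0.2 * s_nb`, and the ≥ 0.5 malignancy call. Phantom
classes are strongly separated by construction, so accuracy saturates at
modest sample sizes — the informative outputs on phantoms are the scores,
the channel comparison (`run$metrics`), the ROC (`autoplot(run, "roc")`)
and the weight sweep (`autoplot(run, "sweep")`); `glance(run)` gives the
one-row summary. `report_json(run)` serializes the whole report
deterministically: rerunning with the same config and seed reproduces it
byte for byte.

On real data: write images as PNG and contours as
`{"points": [[x, y], ...]}` JSON next to a `file,label,seed` manifest
(exactly what `generate_dataset()` emits), read them with
`read_dataset()`, and pass the result as `data =` to
`run_fusion_pipeline()`. A thin command-line front end is installed at
`inst/cli/busfusion.R` (`simulate` and `run` subcommands).

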