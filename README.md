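# nslt — neutrosophic–Slantlet texture features for brain tumor classification

`nslt` implements a texture-based pipeline for classifying grayscale
(brain MRI) slices as benign or malignant. It is aimed at researchers in
radiomics-style image analysis who want a fully reproducible, dependency-
light implementation of the composite **neutrosophic–Slantlet (NS-SLT)**
representation, from raw image to cross-validated classifier metrics.

## The method

1. **Preprocess** — crop to the foreground bounding box, resize to a
   square working size (default 512 × 512, bilinear).
2. **Neutrosophic transform** — map each pixel *g(i,j)* to three
   membership degrees in [0, 1]:

   - *T(i,j)* = (ḡ − ḡ_min) / (ḡ_max − ḡ_min), the min–max normalised
     local mean ḡ over an *a* × *a* window (default *a* = 5);
   - *I(i,j)* = (δ − δ_min) / (δ_max − δ_min) with δ = |g − ḡ|;
   - *F(i,j)* = 1 − *T(i,j)*.

3. **Slantlet transform** — each membership map is decomposed with the
   orthonormal Slantlet filter bank: `2l` parallel channels of
   piecewise-linear filters with two vanishing moments (supports
   2^(i+1)), applied separably in 2D (default *l* = 2).
4. **Texture descriptors** — on the quantized coefficient array (default
   8 gray levels): 10 co-occurrence (GLCM), 7 run-length (GLRLM), and 4
   difference-statistics (GLDS) descriptors, averaged over the four
   distance-1 directions; each descriptor is summed over the T, I, F
   channels (e.g. NS-HOM = HOM_T + HOM_I + HOM_F).
5. **Selection and evaluation** — z-score standardization, one-way ANOVA
   ranking (top-*k* by p-value), then stratified 10-fold cross-validation
   of four classifiers (RBF SVM, decision tree, 5-NN, Gaussian naive
   Bayes) with accuracy, precision, sensitivity, specificity, and
   ROC/AUC (threshold sweep ≡ Mann–Whitney statistic; positive class =
   malignant).

A seeded two-class texture phantom generator (smooth vs. rough Gaussian
random fields, with lesion-like blobs) makes the whole pipeline runnable
and testable without any imaging data.

## Worked example

```r
library(nslt)

ph  <- generate_phantoms(n_per_class = 20, side = 128, seed = 7)
cfg <- scenario_config("ns-slt", technique = "glrlm",
                       preprocess = TRUE, side = 128)
tab <- extract_dataset(ph$images, ph$labels, cfg)
dim(tab)
#> [1] 40  8          # 40 images, 7 run-length descriptors + label

sel <- select_features(normalize_features(tab), k = 3)
attr(sel, "anova")[1:2, 1:4]
#>           feature statistic      p.value rank
#> 1 nsslt_glrlm_sre 204.59938 7.033531e-17    1
#> 2 nsslt_glrlm_lre  71.33482 2.990782e-10    3

cross_validate(tab, "svm", folds = 10, seed = 7, select_k = 3)
#> SVM | 10-fold CV on 40 samples (positive = malignant)
#>   accuracy     0.9750 +/- 0.0791
#>   precision    1.0000 +/- 0.0000
#>   sensitivity  0.9500 +/- 0.1581
#>   specificity  1.0000 +/- 0.0000
#>   auc          1.0000 +/- 0.0000
#>   pooled AUC   0.9850
```

Short-run emphasis (`glrlm_sre`) ranks first: the rough malignant-like
phantoms break into many short gray-level runs, exactly the contrast the
composite representation is designed to expose. The per-fold mean ± SD
accuracy of 0.975 ± 0.079 says the two texture classes are recovered
almost perfectly from three selected descriptors.

Real images enter the same way via `read_gray_image()` (PNG, TIFF, or
NIfTI with `slice`/`axis` selectors) and a `path,label` manifest; see the
command-line front end in `inst/cli/nslt.R`
(`synth | extract | select | evaluate | run`).

## Package layout

- `R/preprocess.R`, `R/neutrosophic.R`, `R/slantlet.R` — image stages
- `R/texture.R` — GLCM / GLRLM / GLDS descriptors and NS aggregation
- `R/pipeline.R` — scenario configuration, per-image and batch extraction
- `R/selection.R`, `R/evaluation.R` — ANOVA selection, CV, ROC/AUC
- `R/synthetic.R` — seeded phantom generator
- `R/io.R` — image readers, CSV feature tables, phantom directories
- `vignettes/nslt-methods.Rmd` — the model, assumptions, and design
  choices in full
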