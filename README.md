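# qtimcd

Tensor-valued diffusion MRI analysis for differentiating cortex and white
matter in malformations of cortical development (MCD).

## The problem

MCD — periventricular and subcortical heterotopia (PH, SH), focal cortical
dysplasia (FCD), polymicrogyria (PMG) — are misplaced or malformed cortical
tissue and a major cause of drug-resistant epilepsy.  Their surgical
delineation relies on MRI, but T1- and T2-weighted contrasts separate
cortex from white matter through **myelin**, which is unreliable in these
lesions.  The diffusion-tensor FA is axon-sensitive but confounded by
orientation coherence: dispersed axons have low FA however anisotropic
their microenvironments are.

Tensor-valued diffusion encoding (linear + spherical b-tensors) resolves
this.  Fitting the q-space trajectory imaging (QTI) cumulant model

    log s(B) = log S0 − B : ⟨D⟩ + ½ (B⊗B) :: C

per voxel yields the mean diffusion tensor ⟨D⟩ and the covariance C of the
voxel's diffusion-tensor distribution, from which the package derives MD,
FA, and the kurtosis decomposition — in particular the **anisotropic
(microscopic) kurtosis**

    MK_A = (6/5) · ⟨V_λ⟩ / MD²,

where ⟨V_λ⟩ is the mean eigenvalue variance of the microscopic tensors.
MK_A is exactly invariant to orientation dispersion (a coherent stick, a
90° crossing and a uniformly dispersed stick mixture all have MK_A = 2.4
while their FA is 1, √½ and ≈0), so it tracks axonal content rather than
myelin or coherence.  The package is aimed at diffusion-MRI methodologists
and anyone wanting a fully tested, reproducible reference implementation
of the QTI fit, its metrics and the downstream lesion statistics.

Since no patient data are distributable, a first-class **digital MCD
phantom** generates aligned multi-contrast volumes with known ground
truth: lesions that are cortex-like in pseudo-T1w/FLAIR intensity while a
designed fraction of their voxels carries white-matter-like
microstructure, plus Rician noise at configurable SNR.  An ROC back end
derives per-contrast thresholds from normal cortex/white-matter ROIs and
reports each lesion's white-matter-like percentage (WM%).

## Worked example

The analysis is organised as numbered scripts over the package API:

```sh
Rscript analysis/01_simulate.R   # phantom + b-tensor sidecar -> results/phantom
Rscript analysis/02_fit.R        # smooth + QTI fit           -> results/maps
Rscript analysis/03_classify.R   # ROC thresholds + classification
Rscript analysis/04_report.R     # per-lesion WM% table
```

Output of the final two steps (seed 1):

```
ROC thresholds for normal cortex vs white matter:
 contrast threshold polarity       auc youden
      T1w 0.6736317     high 1.0000000 1.0000
    FLAIR 1.2305196      low 1.0000000 1.0000
       FA 0.4124270     high 0.9999992 0.9995
      MKA 0.6118822     high 1.0000000 1.0000

Percentages of lesion voxels classified as white matter-like
  lesion_id type n_voxels T1w FLAIR FA MKA
  lesion_PH   PH       42   0     0 17  12
  lesion_SH   SH      148   0     0 42  40
 lesion_FCD  FCD      220   0     0 30  30
 lesion_PMG  PMG      108   0     0 44  44

SH dissociation: MK_A WM% = 39.9 vs pseudo-T1w WM% = 0.0
(designed WM-like fraction 0.40)
```

Reading the numbers: every lesion is uniformly cortex-like in the
structural contrasts (WM% = 0 in pseudo-T1w/FLAIR, by construction of the
phantom's myelin surrogate), yet MK_A recovers the designed
white-matter-like voxel fractions (13/40/29/44%) to within a few points —
the dissociation that makes microscopic anisotropy useful for MCD
delineation.  The same chain is available in one call:

```r
library(qtimcd)
res <- run_pipeline(default_run_config(seed = 1))
res$report
```

Lower-level entry points: `build_protocol()` / `qti_design()` for
encodings, `qti_fit()` / `qti_metrics()` for single voxels,
`qti_fit_volume()` for maps, `build_phantom()` for synthetic data,
`gaussian_smooth()` / `exclude_csf_voxels()` for preprocessing, and
`average_distributions()` / `roc_threshold()` / `classify_wm_percent()`
for the statistics.  The methods vignette
(`vignettes/qtimcd-methods.Rmd`) documents the model, the identifiability
of the 28 cumulant parameters under linear + spherical encoding, and every
numerical choice.

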