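# dtpradiomics

Radiomic features promise to quantify intratumoral heterogeneity on
<sup>18</sup>F-FDG PET, but their values drift with the tracer uptake time
(the delay between injection and scanning) and fluctuate between
repeat scans. Before a feature can be trusted in a cross-sectional study —
or deliberately exploited in a dual-time-point protocol — one has to know
whether its uptake-time change exceeds its own test–retest variability.

`dtpradiomics` implements that full analysis as a reusable R pipeline, for
imaging scientists working on PET radiomics harmonization:

* a **synthetic study generator** emulating a double-baseline,
  dual-time-point FDG-PET design (10 patients, 1–10 lesions each, scans on
  2 days at 60 and 90 min post-injection, 4 mm voxels, configurable
  Gaussian PSF as the reconstruction surrogate) with known ground truth;
* three **lesion delineations**: isocontour at 40 % of SUVmax, fixed
  SUV 4.0, and a contrast-based isocontour at
  `0.5 × SUVpeak + background`, the background being the mean SUV in a
  shell 2 cm from the 70 %-of-SUVmax volume (voxels with SUV > 4
  excluded), with the ≥ 64-voxel qualification filter;
* two **intensity discretizations**: fixed bin width (0.25 g/mL over
  0–60 g/mL) and fixed bin number (64 bins over the lesion's own range);
* a **49-feature panel** in 7 classes — 6 conventional SUV metrics,
  5 shape, 6 histogram, 7 GLCM, 11 GLRLM, 11 GLZLM and 3 NGLDM features —
  computed from first principles following IBSI conventions, with 3-D
  texture matrices pooled over all 13 directions;
* the **statistical layer**: paired Wilcoxon signed-rank tests (60 vs
  90 min) with Benjamini–Hochberg correction, agreement ICC
  (two-way mixed, single rating) against a 0.9 repeatability gate, and the
  uptake-time z score

  $$z = \frac{(RF_{90} - RF_{60}) - \overline{TRT_{60}}}{\mathrm{SD}(TRT_{60})}$$

  which measures each lesion's 60→90 min feature change in units of
  test–retest variability ($TRT_{60}$ is the day-2 minus day-1 value at
  60 min);
* the **use-case classifier**: a feature is *discarded* unless both ICCs
  exceed 0.9; a repeatable feature that is significantly affected by
  uptake time (q < 0.05) *and* changes by more than test–retest
  variability (|mean z| ≥ 1) is suited to **dual-time-point** imaging
  (DTP); clearly unaffected features are **cross-sectional level 2**
  (CS2, robust); the rest are **cross-sectional level 1** (CS1, unclear
  time dependence).

## Worked example

```r
library(dtpradiomics)

design <- study_design(n_patients = 10, lesions_per_patient = c(3, 3),
                       grid_shape = c(48, 48, 48), rng_seed = 7)
specs  <- sample_lesion_specs(design, uptake_slope_mean = 0.25,
                              uptake_slope_sd = 0.05, trt_noise_cv = 0.03)
study  <- generate_study(design, specs)

tab    <- extract_study_features(study, method = "pct40",
                                 config = binning_config("FBW"))
report <- classify_all(tab)
table(report$use_case)
#>       CS1       CS2 DISCARDED       DTP
#>         2         2         1        44

subset(report, feature == "CONV_SUVmean",
       select = c(feature, icc60, icc90, q_fdr, mean_z, use_case))
#>        feature     icc60     icc90        q_fdr   mean_z use_case
#> 2 CONV_SUVmean 0.9966717 0.9924905 3.301401e-06 8.249409      DTP
```

With a strong injected uptake drift (+25 % per 30 min) and low test–retest
noise (CV 3 %), nearly all intensity-coupled features are recovered as
dual-time-point: SUVmean is highly repeatable on both days
(ICC ≈ 0.99), its 60→90 min increase is significant after FDR correction,
and its mean z ≈ 8 means the uptake-time change dwarfs day-to-day
variability.

`run_pipeline()` drives the same steps over every requested
(reconstruction, delineation, discretization) combination and writes
feature tables, classification CSVs and JSON summaries; configurations
can be read from YAML with `read_run_config()`.

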