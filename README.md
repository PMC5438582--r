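# ctcomp

Whole-body CT body composition: per-subject Hounsfield-unit calibration,
adipose/lean tissue segmentation and volumetry, and prediction of total
body adipose-tissue (AT) and lean-tissue (LT) volumes and masses from
single axial slices.

## Who this is for

Researchers and clinical scientists who have CT volumes (whole-body or a
few axial levels) and want body-composition estimates that are comparable
across scanners. Fixed AT windows such as -190..-30 HU drift with scanner
offset and reconstruction kernel; on whole-body stacks that drift turns
into substantial volume discrepancies. `ctcomp` instead calibrates the
AT/LT density cutoff per subject and provides the published single-slice
equations so that a single L4-L5 or mid-thigh slice can stand in for a
whole-body measurement.

## The method in brief

1. **Denoise** the stack with a 3x3x3 median filter.
2. **Calibrate**: eight operator-drawn line segments on three slices
   (L4-L5; 85% and 15% of femoral length) yield eight upper density
   limits — the 98th percentile for pure-adipose lines, the
   kernel-density antimode for lines crossing an AT/LT transition. Their
   mean (integer HU) is the subject's cutoff.
3. **Classify**: AT = HU in `[-205, cutoff]`, LT = `[cutoff + 1, scan max]`;
   volumes are voxel counts in liters, slice areas in cm^2 at L3-L4,
   L4-L5 and mid-thigh.
4. **Predict** whole-body quantities from single-slice areas with affine
   equations `V = slope * area + intercept` (e.g.
   `AT volume [L] = 0.074 * AT_L4-L5 [cm^2] + 2.737`), AT mass via the
   0.92 kg/L density of fat, LT mass as weight minus AT mass, and a
   multislice linear epsilon-SVR predictor cross-validated by
   leave-one-out. Serial-slice (trapezoidal) volumes
   `V = sum a_i (b_i + c_i)/2` support the older 22-slice protocol.

Everything is testable offline: `make_phantom()` builds CT phantoms with
exact ground-truth masks, canonical calibration lines and landmarks;
`make_cohort()` builds cohort tables whose generating truth is the
published equations. Minimal NIfTI-1 and DICOM (explicit VR little
endian) readers/writers are included, along with ICC and Bland-Altman
agreement statistics for repeatability studies.

## Worked example

```r
library(ctcomp)

# a seeded phantom: volume + ground truth + landmarks + calibration lines
ph <- make_phantom(phantom_spec(shape = c(40, 128, 128), seed = 1))
report <- run_pipeline(ph$volume, ph$lines, ph$landmarks)

report$calibration$cutoff
#> [1] -48
report$volumes_L
#> measured AT 2.32 L (truth 2.33), LT 4.18 L (truth 4.26)
report$areas_cm2$at_l4l5
#> [1] 297.0
report$predictions[["current_study:AT:volume_L:l4l5"]]$prediction
#> [1] 24.71    # 0.074 * 297.0 + 2.737 -- a whole-body extrapolation of
#>              # the phantom slice, not the phantom's (partial) volume

# a synthetic cohort at the published noise level, and the model fits
co <- make_cohort(cohort_spec(seed = 1))
fit_ols(co$at_area_l4l5, co$at_volume_L)
#> <ols_fit n=41> y = 0.0728 * x +3.288
#>   |PE| 1.74, %PE 7.28; DW 2.19, BP p 0.421, ANOVA p 1.43e-20

m <- fit_svmr(co, "at_volume")
abs_pred_error(co$at_volume_L, predict(m, co))   # 1.48 L training MAE
loocv_mae(co, svmr_model_spec("at_volume"))      # 1.57 L cross-validated
```

The phantom cutoff (-48 HU) sits below the -16..26 HU corridor reported
for human raters: deterministic percentile read-offs are conservative
relative to visual histogram reads. The cutoff lies in the empty density
valley between adipose and muscle, so segmentation accuracy is unaffected
(measured AT 2.32 L vs 2.33 L truth); the vignette discusses this in
detail. The cohort fit recovers the generating slope 0.074 within
sampling error, with |PE| near the published 1.86 L, and the multislice
SVR improves on the single slice (1.48 L training, 1.57 L
cross-validated).

## Command line

```sh
Rscript -e 'ctcomp::ctcomp_main()' phantom --out demo --seed 1 --shape 40,128,128
Rscript -e 'ctcomp::ctcomp_main()' run --volume demo/phantom.nii.gz \
    --lines demo/lines.csv --landmarks demo/landmarks.txt --out demo/report.json
Rscript -e 'ctcomp::ctcomp_main()' cohort --out cohort.csv --seed 1
Rscript -e 'ctcomp::ctcomp_main()' fit --cohort cohort.csv --model svmr:at --loocv
```

Subcommands: `phantom`, `cohort`, `calibrate`, `segment`, `predict`,
`fit`, `agreement`, `run`. (The installed `exec/ctcomp` script is the
same entry point.)

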