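# clusteridif

Fully automated image-derived input functions for dynamic brain PET by
supervised clustering, with partial-volume and metabolite correction and
Logan graphical analysis — plus a synthetic phantom generator that makes
every stage testable without scanner data.

## The problem

Quantifying a reversible radioligand with no reference region (total
distribution volume V_T, or V_T/f_P after normalizing by the plasma free
fraction) normally requires continuous arterial blood sampling — invasive
and labor-intensive. The carotid arteries are visible in the PET frames
themselves, but manually segmenting them is slow and operator-dependent,
and the thin vessels (diameter comparable to the scanner point-spread
function) suffer severe partial-volume loss and spill-in from surrounding
tissue.

This package automates the whole chain:

1. **Supervised clustering (SVCA).** Every frame is standardized to zero
   mean / unit variance; each voxel's standardized time-activity curve
   (TAC) y is decomposed against three kinetic class templates
   (gray matter, white matter, blood) by exact non-negative least squares:
   `w(v) = argmin_{w >= 0} || y_v - T w ||^2`. The blood-weight volume
   localizes the vessels with no operator input.
2. **Template masks.** Blood-weight images from a template cohort are
   averaged; voxels above 0.2 form the carotid template mask, and the
   (0.001, 0.1) band of its 7 mm Gaussian blur forms the surrounding-tissue
   mask.
3. **Extraction and correction.** The carotid TAC (blood-weighted mean of
   voxels whose relative blood weight exceeds 50%) and surround TAC
   (unweighted mean of voxels with < 0.1% relative blood weight) enter the
   Chen partial-volume model
   `C_carotid(t) = RC * C_wb(t) + SP * C_surround(t)`,
   fitted by least squares at a handful of arterial sample times (6, 20,
   60, 90 min). Inverting it and multiplying by a monoexponential
   parent-fraction fit yields the metabolite-corrected plasma input, whose
   post-peak tail is smoothed by a tri-exponential fit.
4. **Quantification.** Logan graphical analysis: the slope of
   `int_0^t C_T / C_T(t)` against `int_0^t C_p / C_T(t)` for t >= t*
   (default 30 min) estimates V_T; dividing by f_P gives V_T/f_P.

The phantom module simulates the whole acquisition with known ground truth:
an arterial curve with a sharp early peak and tri-exponential washout,
two-tissue-compartment gray/white kinetics (`V_T = (K1/k2)(1 + k3/k4)`),
thin carotid cylinders, 7 mm PSF blur, frame-duration integration over a
33-frame / 90-min ladder, and duration-scaled Gaussian reconstruction
noise.

## Worked example

Derive an input function and gray-matter V_T/f_P on a noiseless blurred
phantom (the code below is exactly what the package prints):

```r
library(clusteridif)
ph <- build_phantom(phantom_spec(noise = 0))   # noiseless, 7 mm PSF
std <- standardize_frames(ph$image)
tmpl <- build_template_tacs(list(list(
  std = std,
  gray = gray_matter_mask(ph$truth$gm_prob),
  white = white_matter_mask(ph$truth$gm_prob, ph$truth$wm_prob,
                            ph$image$voxel_size_mm),
  blood = ph$truth$masks$carotid)))
w <- solve_weights(std, tmpl)
vt <- average_blood_weights(list(w))
carotid <- carotid_template_mask(vt)
surround <- surround_template_mask(carotid, ph$image$voxel_size_mm)
deriv <- derive_input_function(ph$image, carotid, surround, w,
                               sample_blood(ph$truth))
sprintf("RC = %.3f, SP = %.3f", deriv$pvc$RC, deriv$pvc$SP)
#> "RC = 0.246, SP = 0.932"
deriv$input_fn
#> <input_function> peak 56.3 kBq/mL at 0.75 min; A = (31.8, 17, 7.48),
#>   lambda = (2.87, 0.24, 0.0243)/min, fit RMSE 0.0945
gm <- gray_matter_mask(ph$truth$gm_prob)
labels <- region_labels(array(as.integer(gm$indicator),
                              dim = dim(gm$indicator)),
                        names = c("1" = "gray_matter"))
logan_vt(regional_tacs(ph$image, labels)$gray_matter, deriv$input_fn,
         t_star = 30, f_P = 0.04)
#> <logan_result> VT = 4.247 (t* = 30 min, 12 points, R^2 = 1.0000), VT/fP = 106.2
```

Reading the numbers: only ~25% of the true blood signal survives in the
5-mm vessels after 7-mm blur (RC = 0.246) and the carotid curve is
dominated by tissue spill-in (SP = 0.93) — which is exactly what the Chen
correction removes. The fitted input peaks at 0.75 min and decays
tri-exponentially. The measured gray-matter V_T/f_P of 106 sits below the
compartmental truth (118.5) because the *measured tissue curve* mixes
blurred white matter and blood volume into the gray mask — an effect
shared by any input function; comparing Logan with the estimated input
against Logan with the true arterial input on the same tissue curves gives
ratios of 1.01-1.05 (see `scripts/acceptance.R`).

The full multi-subject workflow (template cohort, per-subject blood
samples, results table) is driven by [run_pipeline()] or the CLI:

```sh
Rscript inst/cli/clusteridif simulate --out cohort/ --subjects 8 --seed 1
Rscript inst/cli/clusteridif run --config config.json
```

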