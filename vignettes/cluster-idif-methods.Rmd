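---
title: "Supervised-clustering image-derived input functions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised-clustering image-derived input functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models and their assumptions, every tunable parameter with its default
and rationale, what the synthetic phantom does and does not emulate, the
numerical choices, and the places where the design was genuinely open and
we had to decide.

## 1. The measurement model

A dynamic brain PET scan of a reversible radioligand with no reference
region is quantified by the total distribution volume $V_T$ (or
$V_T/f_P$, normalized by the plasma free fraction $f_P$), which requires
the arterial plasma concentration of unmetabolized parent ligand,
$C_p(t)$, as the model input. The package estimates $C_p(t)$ from the
images themselves in four stages.

**Supervised clustering.** Each frame $f$ of the dynamic image is
standardized, $z = (x - \mu_f)/\sigma_f$, with $\mu_f, \sigma_f$ computed
over a field-of-view mask (voxels whose time-averaged activity exceeds 5%
of the maximum; air would otherwise dominate the statistics — the
literature does not state a mask, so this is a declared choice). Each
voxel's standardized TAC $y_v$ is then decomposed against three
standardized kinetic class templates — gray matter, white matter, blood —
stacked as the columns of a frame $\times$ 3 matrix $T$:
$$ w(v) = \arg\min_{w \ge 0} \lVert y_v - T w \rVert^2 . $$
The nonnegative weights measure similarity to each class; they are *not*
normalized to sum to one, because their amplitude is reused later both for
selecting and for weighting carotid voxels. The templates come from a
small template cohort: per subject and tissue, the mean standardized TAC
over a tissue mask (gray: probability $> 0.9$; white: probability $> 0.5$
*and* gray-matter spill-over under a 7 mm blur below 0.5% of a uniform
unit gray activity; blood: a supplied carotid mask standing for manual
early-frame drawing), averaged across subjects.

The NNLS problem is solved exactly by support enumeration: all $2^3$
candidate supports are solved by unconstrained least squares and the
feasible minimum-residual candidate is returned. For a 3-column design
this *is* the exact minimizer (the optimal active set's unconstrained
solution is feasible and optimal), has no iteration tolerance, and
vectorizes over $10^5$ voxels as dense matrix algebra. Frames are
unweighted in the fit (duration weighting is not described in the source
method; declared choice).

**Template masks.** Blood-weight volumes of the template cohort are
averaged into a vascular template. The carotid template mask keeps voxels
strictly above 0.2; an optional user-supplied exclusion mask reproduces
the manual removal of venous sinuses. The surrounding-tissue mask is the
strict $(0.001, 0.1)$ band of the 7 mm Gaussian blur of the binary carotid
mask, *minus the carotid mask itself*: for thin vessels the vessel's own
edge voxels can fall inside the band, and the two masks must be disjoint
for the correction model to make sense, so the exclusion is explicit.
All literature thresholds ("greater than 0.9", "higher than 0.2",
"between 0.1 and 0.001") are implemented as strict inequalities, matching
their wording; boundary values are excluded and tested. Template masks are
mapped to a subject grid by nearest-neighbour resampling through a
pluggable affine transform (identity by default; nonlinear warps are out
of scope).

**Extraction and correction.** Within the subject-space carotid mask,
voxels whose *relative* blood weight $w_b/(w_g + w_w + w_b)$ strictly
exceeds 0.5 are averaged, weighted by $w_b$. The phrase "more than 50% of
weighting parameter values" is ambiguous (it could denote the median); we
read it as blood outweighing the other two classes combined, and expose
the threshold. The surround TAC is the unweighted mean of surround-mask
voxels with relative blood weight strictly below 0.001, the same scale as
the carotid rule. The Chen partial-volume model
$$ C_\mathrm{carotid}(t) = RC \cdot C_\mathrm{wb}(t) +
   SP \cdot C_\mathrm{surround}(t) $$
is fitted by unweighted ordinary least squares at the arterial sampling
times (typically 6, 20, 60, 90 min; three samples suffice), with TAC
values at sample times obtained by linear interpolation of the mid-frame
curves, held constant beyond the last mid-frame time (a 90-min sample
falls 2.5 min after the last mid-frame of the default ladder). $RC$ is
the recovery coefficient (partial-volume loss), $SP$ the spill-in
coefficient; a negative fitted $SP$ is flagged, not fatal. The whole-blood
IDIF is the inverted model, multiplied by a monoexponential parent
fraction $f(t) = a e^{-\lambda t}$ fitted to the sampled parent fractions
(evaluation clamped to $[0,1]$; extrapolation to $t=0$ uses the fitted
curve). Finally the plasma curve's post-peak samples are fitted by
$\sum_{j=1}^3 A_j e^{-\lambda_j (t - t_\mathrm{peak})}$ and the input
function used downstream is piecewise: the measured rise up to the peak,
the fitted tail after it. Most of the area under an input curve of this
kind sits under the peak, so the raw rise is kept rather than replaced by
a parametric form.

**Logan analysis.** For mid-frame times $t \ge t^*$,
$$ \frac{\int_0^t C_T}{C_T(t)} = V_T \frac{\int_0^t C_p}{C_T(t)} + b, $$
with the slope estimated by OLS. The input integral evaluates the
piecewise input function on a 1 s grid; the tissue integral uses the
trapezoid rule over mid-frame samples with an initial triangle from
$(0,0)$. $t^* = 30$ min by default — standard for a 90-min acquisition —
and validated by the monotone convergence of the estimate toward the
analytic value over $t^* \in \{20, 30, 40\}$ min on noiseless
simulations. Note the slope's exact scaling laws (tested as properties):
scaling the tissue curve by $c$ scales the slope by $c$, and scaling the
input by $c$ scales it by $1/c$.

## 2. The phantom: a stated world

The generator emulates the acquisition the method was designed for, at
desk scale:

| parameter | default | why |
|---|---|---|
| grid | 64 x 64 x 24 voxels of 2 x 2 x 4.25 mm | the scanner's voxel size and slice count ballpark with a reduced in-plane matrix, to keep the full pipeline in CPU-minutes |
| frame ladder | 8x30 s, 6x60 s, 5x120 s, 14x300 s (33 frames, 90 min) | frames of increasing length from 30 s to 5 min; the exact ladder between the endpoints is not printed anywhere, so this is a declared config default |
| PSF | 7 mm FWHM isotropic Gaussian | the reconstructed image resolution of the target scanner |
| arterial curve | linear rise to 80 kBq/mL at 0.75 min, then 3-exponential decay (fractions 0.65/0.25/0.10, rates 4/0.25/0.012 per min) | a sharp early peak holding a large share of the AUC, with fast, intermediate and slow washout phases; amplitudes renormalized so the curve is continuous at the peak |
| gray kinetics | K1 0.35, k2 0.12, k3 0.05, k4 0.08, vb 0.05 | two-tissue-compartment, $V_T \approx 4.7$; moderate specific binding |
| white kinetics | K1 0.15, k2 0.09, k3 0.03, k4 0.07, vb 0.03 | lower delivery and binding than gray |
| carotids | two vertical cylinders, radius 2.5 mm, embedded in gray matter | the internal carotid's ~5 mm diameter, below the scanner resolution — the partial-volume problem the method exists for |
| parent fraction | $0.95\,e^{-0.012 t}$ | monoexponential truth so the pipeline's monoexponential correction is exactly specified; a biexponential mismatch mode exists for robustness tests |
| f_P | 0.04 | a few-percent plasma free fraction, typical of lipophilic ligands |
| noise | 0.05 (fractional), frame sd $= 0.05\, A_f / \sqrt{\mathrm{dur}_f\,[\mathrm{min}]}$ with $A_f$ the mean head activity of the frame | additive Gaussian in concentration space, so voxels can go negative like filtered back projection; variance inversely proportional to frame duration as count statistics dictate |

The three kinetic classes are exactly the three clustering templates.
That is deliberate: the method models voxels as nonnegative combinations
of gray, white and blood kinetics, and the validation substrate should
satisfy the model's own premise. An earlier draft added a fourth
"neck soft tissue" class; a class that none of the templates can
represent is systematically misclassified as blood (the only template
with its sign pattern), which says something true about supervised
clustering — it needs templates spanning the tissues in the field of view
— but tests the wrong claim here.

What the phantom does **not** emulate, and hence what a green test does
not establish: head motion, scatter/attenuation residuals, spatially
correlated reconstruction noise (noise here is white), anatomical
variability beyond small geometric jitter, venous sinuses (the manual
exclusion step is idle on the phantom), arterial dispersion/delay, and
any model error in the blood samples themselves (sampled values are
exact). Cohort jitter (integer-voxel vessel shifts, ~10% lognormal
kinetic scatter, 15% input amplitude scatter) is a stand-in for
between-subject variability, not a calibrated population model.

Simulation numerics: tissue curves solve the 2TCM ODEs analytically — the
bi-exponential impulse response (roots of
$s^2 + (k_2+k_3+k_4)s + k_2 k_4$) convolved with the plasma input by FFT
with trapezoid end-correction on a 0.25 s grid; an independent RK4
integrator serves as the oracle in tests. Frame values are
duration-weighted means via an exactly interpolated cumulative trapezoid
(exact for piecewise-linear curves). The Gaussian blur is separable with
row-normalized dense kernels, so constants are preserved exactly and
interior mass is conserved; near the grid boundary renormalization acts
like mild reflection.

## 3. Numerical choices and degenerate inputs

* All internal times are minutes, activities kBq/mL; conversions only at
  I/O boundaries. Input images are assumed decay-corrected (standard for
  reconstructed PET; the source protocol does not state it, noted as an
  assumption).
* Standardization uses the sample standard deviation (ddof = 1; not
  stated in the literature, declared so the hand examples are forced).
  Zero within-mask variance in any frame is an error naming the frame.
* NNLS support enumeration breaks ties toward the sparser support only
  through a strict improvement threshold ($10^{-12}$ relative); exact
  zero-residual mixtures are recovered to $10^{-9}$.
* The tri-exponential fit uses variable projection (amplitudes by exact
  NNLS given rates, rates by bounded quasi-Newton from five multi-start
  seeds); coincident rates are collapsed before solving, so
  single-exponential data degrade gracefully to a one-term fit. The
  fitted tail is nonnegative by construction (nonnegative amplitudes and
  rates). A curve whose maximum is its last sample has no tail to fit and
  errors.
* The parent-fraction fit seeds a bounded quasi-Newton refinement with
  the log-linear solution; exactly monoexponential data are recovered to
  $10^{-6}$.
* Logan requires at least 3 usable frames after $t^*$ and errors on zero
  tissue activity at a used frame.
* Masks and images must share grids exactly; there is no implicit
  resampling anywhere.

## 4. Open design points, decided

* **Template-mask geometry check.** The package asserts (as a test) that
  the carotid template mask from a 10-subject template cohort — the
  clinical protocol's template cohort size — overlaps the cohort's pooled
  true vessel geometry with Jaccard $\ge 0.3$ and that the peak-weight
  voxel lies on a true vessel. With only 3 template subjects the overlap
  sits at the 0.3 boundary: averaging more subjects is precisely what
  suppresses the blur fringe above threshold.
* **Which curves enter the tri-exponential fit.** Fitted to the
  metabolite-corrected plasma curve, from its peak onward; whether the
  original implementation fitted whole-blood or plasma curves, from the
  peak or a fixed time, is not stated. Declared, not guessed further.
* **Reference for end-to-end validation.** The clinical study's headline
  ratio compares Logan with the image-derived input against Logan with
  the arterial input *on the same measured tissue curves*. The phantom
  analogue does the same (estimated vs true-arterial input on identical
  regional TACs). Comparing instead against the compartmental $V_T$ truth
  conflates input-function fidelity with tissue partial-volume mixing,
  which no input function can repair; the vb-admixture alone shifts
  apparent $V_T$ by ~3% at vb = 0.05.
* **Dropped samples.** The criterion by which a late blood sample might
  be rejected ("shape inconsistent with an input function") is undefined
  in the literature; sample selection is left to the caller rather than
  automated.

## 5. Known limitations

Registration is affine-only and identity by default, so real-data use
requires externally estimated transforms. The NIfTI reader/writer is
minimal (NIfTI-1, 3D/4D, five datatypes, no orientation handling beyond
voxel sizes). The noise model is white Gaussian; correlated
reconstruction noise will make the NNLS weights noisier than the phantom
suggests. The method inherits supervised clustering's premise that the
three templates span the field of view's kinetics; tissues far outside
that span (large necrotic lesions, strong extracerebral uptake) would
need additional templates. Scaled-down tests: the noise-variance property
uses 400 draws on a miniature phantom (not 1000 on the full grid), and
the end-to-end cohort uses 5 + 3 subjects on a reduced matrix — both
declared here rather than silently widened.
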