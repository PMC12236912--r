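---
title: "Brain-age prediction and PAD variance analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-age prediction and PAD variance analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Brain-age modeling predicts a person's chronological age from structural MRI
and interprets the *predicted age difference* (PAD = predicted − chronological
age) as a marker of atypical maturation or aging: a positive PAD reads as an
"older-looking" brain. In clinical groups, the interesting signal is not only
a shift of mean PAD but also its *dispersion* — a heterogeneous disorder can
leave mean brain age untouched while broadening the distribution of
individual deviations. `brainpad` implements the complete analysis chain for
this question: a 4-channel voxelwise 3D CNN age regressor, deep-ensemble
averaging with ICC(2,k) reliability, PAD descriptive statistics, Levene
variance-heterogeneity tests across diagnosis and an age-25 partition, and
permutation GLM inference with variance groups, sign-flipping, and
max-statistic FWER correction.

The clinical data this design targets (multi-site consortium MRI of
generalized anxiety disorder and healthy controls) are access-restricted, so
the package ships a synthetic phantom generator that reproduces the
*statistical structure* the analysis must detect — a clinical group with
inflated morphological variance but no mean shift — and the whole pipeline is
exercised end-to-end on phantoms at desk scale.

## The CNN

The architecture is a scalable family (`arch_config()`). A block is
`[3D conv (kernel 3, padding 1) → batch norm → ReLU] × 2` followed by a
stride-2, window-2 max pool that floor-halves each spatial dimension.
Blocks repeat with doubling filter counts; the head is
`flatten → dropout → FC → dropout → FC → … → FC(1) → ReLU`, the terminal
ReLU clamping predictions at zero (negative ages are impossible by
construction). The full-size default — 4 input channels (gray matter, white
matter, T1, warp Jacobian) at 75×88×78 voxels, filters 8/16/32/64/128, FC
head 128/32/1 — has exactly **1,020,721** trainable parameters and a flatten
length of **1,024** (128 filters × 2×2×2 after five floor-halvings).

Two readings of the motivating architecture were possible, since it is
described with plural convolutional layers per block but no count. With one
convolution per block the closed-form count gives 430,729; with two
convolutions per block, each with its own batch-norm, it gives 1,020,721 —
exactly the published total. Likewise the 1,024-unit layer after the last
block is read as *the flatten itself* (length 1,024, forced by 2×2×2×128),
feeding FC(128) directly: inserting a separate 1,024-wide dense layer would
add over a million parameters and contradict the published count. Both
readings are enforced by tests
(`count_parameters()` vs brute-force enumeration of the realized model, and
`forward_shapes()` vs probe activations).

Training (`train_config()`, `train_model()`) optimizes batch-mean absolute
error with Adam (default learning rate 1e-4), clips the global gradient norm
at 1 each step, and tracks MAE and MSE on a held-out validation split; the
weights of the best-validation-MAE epoch are returned. MSE is monitored but
never optimized. The layers are implemented natively (RcppArmadillo im2col
convolutions with exact analytic gradients, verified against finite
differences in the test suite); batch norm follows the standard exponential
moving-average convention (momentum 0.1, eps 1e-5, biased variance for
normalization, unbiased for the running estimate), and inference uses running
statistics with dropout disabled, making predictions independent of batch
partitioning.

Choices the published regime leaves open, fixed here:

* **Initialization** — fan-in-scaled uniform weights, fully seeded. In
  addition, the output bias starts at the median training age
  (`init_output_bias = TRUE`). With a terminal ReLU and MAE loss, a
  near-zero output initialization either kills the output unit (pre-activation
  below zero) or spends most of the step budget learning the age *scale*;
  warm-starting the bias at the target median removes that plateau without
  touching what the network must actually learn.
* **Dropout placement** — before every fully-connected layer (after the
  flatten and after each hidden FC); parameter-count neutral.
* **Max-pool window** — 2, the only window that halves each dimension at
  stride 2; odd trailing voxels are dropped by the floor.
* **Epoch budget, batch size, early stopping** — configuration-driven; the
  desk-scale replica uses learning rate 2e-3, batch 24, up to 10 epochs with
  patience 4, chosen in pilot runs as the smallest budget at which held-out
  MAE clearly separates from the no-information baseline.

## The homogeneous ensemble

`ensemble_spec()` / `train_ensemble()` implement the published strategy: k
(default 8; 3 in the replica) instantiations of the identical architecture,
each initialized with its own random weights and trained on its own random
90/10 train/validation split, with test predictions averaged across members
(`ensemble_predict()`). Member seeds derive from the base seed through a
documented mixing function (`mix_seed()`), so any member is reproducible in
isolation.

Reliability of the member predictions uses the Shrout–Fleiss two-way
random-effects, average-of-k-raters, absolute-agreement ICC:

$$\mathrm{ICC}(2,k) = \frac{MSR - MSE}{MSR + (MSC - MSE)/n}$$

with MSR/MSC/MSE the between-subject, between-model and residual mean
squares. The cited form [2,k] does not distinguish
agreement/consistency; absolute agreement is the default and the consistency
variant is available via a flag. The ICC is computed over the whole test set
(a per-site breakdown was considered and left out: the source analysis
reports one value).

## PAD and the variance analyses

`compute_pad()` uses PAD = predicted − chronological, the convention under
which positive PAD means an older-looking brain. (The source text is
internally inconsistent about the subtraction order between its summary and
its methods; the summary/introduction convention is adopted.) The age
partition places subjects strictly younger than 25 in `under25` and 25 or
older in `over25`; the boundary is configurable.

`group_metrics()` reports MAE, MSE, mean/median/SD/variance of PAD per group
with the unbiased (n−1) SD. `levene_test()` implements the classic ANOVA on
absolute deviations from group centers (mean-centered by default;
median-centering — Brown–Forsythe — behind a flag), referred to
F(g−1, N−g). `pairwise_variance_tests()` runs the six pairs among
{GAD<25, HC<25, GAD>25, HC>25} plus the overall GAD-vs-HC test.
`site_age_matching()` runs per-site Welch t-tests of mean age between
diagnostic groups, flagging sites with an empty group as N/A rather than
failing.

## Permutation GLMs with variance groups

Three designs (`build_design()`), all with per-site intercepts: (1)
diagnosis only; (2) diagnosis plus site-wise slopes for age, sex, medication
and comorbidity (continuous covariates mean-centered within site); (3) the
design of (2) with the diagnosis × centered-age interaction as the tested
term. Rank-deficient columns (e.g., a covariate constant within every site)
are dropped with a warning, never the tested column.

The test statistic (`glm_statistic()`) must respect unequal error variances
between diagnostic groups (the *variance groups*). The exact statistic used
by the referenced permutation software is not printed, so the package uses a
weighted-least-squares t-like statistic: an OLS start yields per-group
residual variances (group RSS over group residual degrees of freedom,
n_g − Σ leverages), one WLS step with weights 1/σ̂²_g then gives
c'β̂ / √(c'(X'WX)⁻¹c). Two exact reductions pin the construction down and
are enforced by tests: with a single variance group it equals the classical
pooled t, and for a two-group design with per-group variances it equals
Welch's t.

Inference is by sign-flipping (`sign_flip_test()`), matching the published
scheme, with Freedman–Lane handling of nuisance covariates: the response is
residualized against the nuisance part of the reparametrized design, signs
are flipped on the residuals, the nuisance fit is added back, and the full
statistic (including re-estimated group variances) is recomputed per flip.
Validity rests on symmetric errors, which the phantom generator satisfies.
When 2ⁿ ≤ n_perm the 2ⁿ sign patterns are enumerated (exact test; the test
suite checks exact agreement with an independent brute-force oracle);
otherwise p = (1 + #{|T*| ≥ |T|}) / (n_perm + 1), with ≥ comparisons so ties
count conservatively. FWER correction (`fwer_adjust()`) is by the
max-statistic method across the contrasts of one run — here the three model
contrasts, all evaluated on a shared permutation schedule; the corrected
family is configurable because the source does not state what family it
corrected over. Two-sided tails are assumed throughout.

## The phantom generator

`phantom_params()` / `render_phantom()` produce four spatially coherent
channels on a common grid from a simple geometric brain: an ellipsoidal
gray-matter shell whose thickness falls linearly with age around a
white-matter core containing a central spherical ventricle whose radius
grows linearly with age. GM and WM are smoothed indicator fields (Gaussian
FWHM 2 voxels by default — the original VBM smoothing kernel is unstated, so
this is a free config value); T1 is a fixed linear combination of the two
plus a per-site intensity offset and voxelwise noise; the Jacobian channel
is 1 plus the smoothed deviation of the subject's geometry from the
age-midpoint template, so a noise-free midpoint-age subject renders a
constant-1 Jacobian.

The critical design decision is **where noise enters**. Subject-level noise
perturbs the *geometry* (shell thickness and ventricle radius, SD in
voxels), and the clinical group's geometry-noise SD is the control SD times
`variance_inflation` (default 1.7, mirroring the printed clinical/control
PAD SD ratio 8.53/4.97). Because the CNN reads age out of exactly this
geometry, geometry noise propagates into *prediction* noise — the clinical
group becomes harder to predict, inflating PAD variance without any mean
shift. Inflating mere intensity noise would largely average out over voxels
and miss the mechanism of interest. With `variance_inflation = 1` the groups
are exchangeable by construction, which is what the calibration tests
exploit.

Cohort structure (`cohort_spec()` / `sample_cohort()`): ages are uniform or
(default) youth-heavy bimodal — 55% in a narrow child mode (N(10, 2²)) and
45% in a broad adult mode (N(35, 15²)), truncated to the configured range —
mimicking a test sample dominated by a large pediatric study; sites are
assigned round-robin over a shuffled order (balanced to ±1); sex is
Bernoulli(0.5); medication and comorbidity flags exist only in the clinical
group (marginals 0.3 / 0.25). Every subject's renderer seed derives from the
cohort seed and the subject index, so cohorts are bit-reproducible and any
subject can be re-rendered in isolation.

What the phantom deliberately does **not** emulate: anatomical realism,
scanner artifacts, the actual VBM segmentation/modulation pipeline,
nonlinear age trajectories, or site differences beyond an intensity offset.
Tests passing on phantoms therefore certify the *pipeline* — that the
implemented estimator, ensemble, and inference machinery recover a known
age signal and a known variance-heterogeneity structure — not performance on
real MRI.

## The desk-scale replica

`replica_config()` fixes the package's study replica: 600 subjects total —
360 healthy controls over 3 sites for training, 120 controls + 120 clinical
subjects over 4 sites for testing — phantoms rendered at 28×32×28 voxels and
center-cropped to the 24×28×24 input grid (mirroring the full-size
91×109×91 → 75×88×78 centered crop, low-side margin floor((src−tgt)/2));
a 2-block CNN (filters 4/8, FC 16) trained as above; k = 3; 500 sign-flips
for the GLMs. These sizes keep the full study under ~10 minutes on one CPU
while preserving the qualitative pattern the analysis exists to detect:
the ensemble beats the predict-the-median baseline by a wide margin, member
predictions are highly reliable (ICC(2,3) > 0.8), and in the majority of
replicated test cohorts the GAD-vs-HC Levene test rejects while the GLM
diagnosis contrasts do not. Sampling stability is assessed by drawing fresh
test cohorts through the *fixed* trained ensemble
(`replicate_test_analysis()`): the model is trained once, as in the source
study, and the replicated unit is the cohort-level inference.

One genuine subtlety surfaces here. The diagnosis × age interaction (model
3) is not exactly null under the generator: because the CNN's
geometry-to-age readout is mildly nonlinear, inflating the clinical group's
geometry noise shifts its *expected* prediction by a Jensen-type term that
varies with age, inducing a small real interaction even with zero injected
mean effect. Its p-value therefore hovers near the threshold in some
replicates — a property of running a nonlinear estimator on a
variance-inflated group, not an inference error (the calibration tests show
the machinery is exact under the true null), and a caveat that applies
equally to interaction tests on real brain-age data.

## Numerical notes and limitations

* Convolution is exact im2col + GEMM (full-volume gather for small grids,
  bounded z-slice gather at full size); gradients are analytic and checked
  against finite differences.
* Seeds: every random draw descends from one integer seed through
  `mix_seed()` (a fixed congruential mix evaluated exactly in doubles);
  reruns are bit-identical, which the pipeline test asserts.
* Levene's test is asymptotic; its small-sample type-I error is part of the
  method, and the calibration test checks it at n = 100 per group against an
  exact binomial band.
* Permutation p-values are never smaller than 1/(n_perm+1); enumerated
  schedules include the identity flip.
* The centered crop assumes the head is centered in the field of view (true
  for template-space data and for the phantom); a content-bounding crop
  would need orientation metadata the pipeline does not consume.
* Degenerate inputs are defined, not crashed: zero total variance gives
  ICC = 1 with a flag; identical groups give W = 0, p = 1; sites with an
  empty diagnostic group are flagged N/A; all-zero or non-finite channels
  fail QC flags rather than erroring.
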