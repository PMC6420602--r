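---
title: "Detecting visual-field progression from changes in spatial correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting visual-field progression from changes in spatial correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Open-angle glaucoma is monitored with standard automated perimetry: at each
clinic visit an eye yields differential light sensitivities (dB) at the 52
non-blind-spot points of the 24-2 test pattern. Deciding whether a series of
such tests shows true progression — as opposed to test–retest variability —
is hard, and most statistical tools attack it through *trends in the mean*:
regression of a global index on time (GI), pointwise linear regression of
each location on time with order-statistic p-values (P1–P4), the mean slope
of significantly deteriorating locations (MS), and the permutation-of-PLR
test (PoPLR).

`vfprog` implements those trend metrics alongside a predictor built on a
different physiological signal: *changes over time in the spatial
correlation structure* of the field. Glaucomatous damage follows the
retinal nerve fibre bundles, so correlation between neighbouring test
points is anatomically structured; if the estimated spatial correlation
varies strongly from visit to visit, that variability itself predicts
progression even when the mean field is flat. The package estimates it with
a Bayesian spatiotemporal boundary-detection model and summarises it as the
STBound predictor triple.

## The boundary-detection model

Each test point is assigned the angle at which its nerve-fibre bundle
enters the optic disc; adjacent points `i, j` get a dissimilarity

$$z_{ij} = \mathrm{circ}(|\theta_i - \theta_j|)\, /\, \max_{(k,l)}
\mathrm{circ}(|\theta_k - \theta_l|) \in [0, 1],$$

small along a bundle, large across anatomical boundaries (the temporal
raphe above all). The field at visit $t$ is a proper conditional
autoregression with boundary-detection weights
$w_{ij}(\alpha) = e^{-\alpha z_{ij}}$:

$$y_t \sim N\!\big(\mu_t 1,\ \tau^2_t\, Q(\alpha_t)^{-1}\big), \qquad
Q(\alpha) = \rho\,\big(D(\alpha) - W(\alpha)\big) + (1 - \rho) I,$$

with $D$ the diagonal of row sums and $\rho = 0.99$ fixed for propriety
(smallest eigenvalue of $Q$ at least $1 - \rho$). Large $\alpha$ shrinks
weights across dissimilar pairs — boundaries appear — so $\alpha_t$ is the
per-visit spatial-smoothness parameter.

Across visits the blocks $\theta_t = (\mu_t, \ln \tau^2_t, \ln \alpha_t)$
carry a matrix-normal prior
$\Theta \sim MN(\delta 1', \Sigma, \Psi(\phi))$ with exponential temporal
correlation $\Psi(\phi)_{ts} = e^{-\phi |v_t - v_s|}$; $\delta$ is Gaussian
(variance 1000 per component), $\Sigma$ inverse-Wishart (df 5, identity
scale), and $\phi$ uniform on bounds chosen so the temporal correlation
spans 0.999 at the largest visit gap down to 0.01 at the smallest. Fitting
is Metropolis-within-Gibbs: conjugate draws for $\delta$ and $\Sigma$,
random-walk proposals for each $\theta_t$ and for $\phi$ (on a logit
scale), with proposal scales adapted during burn-in toward acceptance 0.35.
The sampler is written in C++ (RcppArmadillo) and is bit-reproducible given
a seed. A Tobit variant (left-censoring of observed 0 dB values, imputed by
Gibbs) is available behind `likelihood = "tobit"`; the default is Gaussian
because the synthetic cohorts rarely touch the floor.

Per kept draw $s$ the coefficient of variation
$\mathrm{CV}^{(s)} = \mathrm{sd}(\{\alpha_t^{(s)}\}_t) /
\mathrm{mean}(\{\alpha_t^{(s)}\}_t)$ (sample sd, $T-1$ denominator) is
computed *within the draw*; its posterior mean, posterior sd and their
product are the STBound predictors. Computing the CV per draw — rather
than the CV of posterior means — is what makes a posterior sd of the CV
well defined.

Several elements of this hierarchy are reconstructions: the published
account of the method defers the weight form, the transform of
$\alpha$ and the hyperpriors to its companion methods work and its
reference implementation, neither of which is redistributable here. The
exponential weight on the dissimilarity scale is the standard continuous
boundary-detection choice; it is isolated behind `precisionMatrix()` so a
reader with the original specification in hand can swap it. The unbounded
log transform of $\alpha$ replaces a bounded transform; the uniform
$\phi$ bounds compensate. Validation is therefore *parameter recovery on
this model's own generative law*, not agreement with the original fits.

## The packaged entry-angle table is synthetic

The published structure–function map assigning each 24-2 point an
optic-disc entry angle could not be redistributed with this package. The
packaged table is an anatomically motivated synthetic stand-in: bundles are
modelled as arcs around the optic nerve head at $(15, 2)$ degrees, with a
temporal raphe splitting fibres just above and below the horizontal into
arcades that enter the disc at least 20 degrees from the temporal pole.
This reproduces the map's qualitative structure — smooth within arcades, a
sharp discontinuity across the raphe, continuity around the nasal
periphery. The raphe offset of 20 degrees was chosen so that the resulting
dissimilarities are well spread: a larger offset concentrates almost all
$z$ near zero (after normalisation by the raphe maximum) and leaves the
near-raphe points with uniformly moderate dissimilarities on *every* edge,
which makes them effectively disconnected — and their field variance
explode — at the smoothness scales where $\alpha$ is statistically
identifiable. `buildGrid(gh_angle = ...)` accepts a replacement table for
analyses that have the published angles.

## What the synthetic cohorts emulate

`simulateCohort()` reproduces the descriptive statistics of the clinical
cohort the method was validated against: 26% progressing eyes, visit
counts with mean 7.4 clipped to [2, 21] (shifted Poisson), follow-up with
mean 2.6 years clipped to [0.2, 9.4] (gamma, shape 2), and dB
sensitivities centred near mean 23 with dispersion from three sources —
the spatial CAR field ($\tau^2 = 9$, giving ~5 dB of marginal spread at
the default smoothness), heteroscedastic test noise, and per-eye baseline
defects (27 dB minus a gamma(0.5, scale 8) loss, floored at 10 dB). Visit
times put the baseline at 0 and the closing test at the follow-up span, so
the realised follow-up matches the configured one; interior visits are
uniform.

Four generating mechanisms are provided. `stable` and the two trend
mechanisms (`global_trend`, default −1.5 dB/year; `sector_trend`,
restricted to a superior arcuate sector) move the mean field only.
`correlation_shift` holds the mean flat and drifts the smoothness
log-linearly, $\ln \alpha_t = \ln \alpha_0 + \gamma v_t$ with
$\gamma = \ln 3 / 2.6$ (a 3-fold change over the mean follow-up) — the
mechanism separation that makes STBound predictive while leaving the trend
metrics at chance, and the generative analogue of the observed
near-zero correlation between STBound and the trend metrics.

Numerical defaults that matter, and why:

* $\alpha_0 = 6$: per-visit Fisher information for $\ln \alpha$ on the
  packaged grid gives a standard error of about 0.21 there; at
  $\alpha_0 = 1$ the likelihood in $\alpha$ is nearly flat (se ≈ 1.5) and
  no method could recover a 3-fold drift from 52 points per visit.
* $\tau^2 = 9$ dB²: about 5 dB of marginal spatially structured spread,
  which together with the defect distribution matches the clinical dB
  dispersion while keeping values clamped at the [0, 50] bounds below 1%.
* noise link $(\sigma_0, \sigma_1) = (1, 0.1)$, a hinge at 30 dB:
  measurement noise is constant for healthy sensitivities and grows as
  sensitivity falls, the qualitative inverse sensitivity–variability
  relationship; no quantitative form is established, so the link is kept
  simple and monotone.

What passing tests on these cohorts do **not** show: the generator has no
learning or fatigue effects, no floor-censoring psychophysics, no
normative-database deviations, and its progressing eyes mix the three
mechanisms in equal thirds, which is unknowable for real cohorts. Results
on synthetic data demonstrate internal consistency and recovery of the
model's own signal, not clinical performance.

## The evaluation framework

Every metric is turned into a progression probability by logistic
regression of its predictors on the clinical (here: simulated) label;
models are compared by AIC ($2k - 2\log L$), full AUC (Mann–Whitney, ties
one half), and partial AUC over the clinically relevant specificity band
85–100%, normalised by the band width (chance 0.075, perfect 1) —
printed partial AUCs in this literature exceed the raw band maximum of
0.15, implying exactly this normalisation. Added value over GI is tested
by likelihood-ratio tests of nested fits; AUC differences by the paired
DeLong test and pAUC differences by a paired bootstrap over eyes (the
original comparison test is not stated; these are this package's declared
choices). Thresholds maximise sensitivity subject to specificity ≥ 85%,
with ties broken toward higher specificity then lower threshold. All fits
and ROC summaries are in-sample, matching the evaluated procedure; this is
a deliberate evaluation caveat, not an oversight — no cross-validation is
attempted.

The longitudinal analysis truncates each series at half-year cutoffs and
recomputes everything. Two protocols are mixed deliberately: AUC and pAUC
at a cutoff come from models *refit* at that cutoff (discrimination with
the data in hand), while sensitivity and specificity apply the
*final-study* coefficients and thresholds to the cutoff predictors (the
clinical rule is fixed at study end). Eyes enter a metric's summary once
they meet its minimum visit count — 3 for the trend metrics, 2 for
STBound, which is the boundary-detection model's practical advantage at
early cutoffs. Time to first diagnosis walks each progressing eye's visits
in order, recomputes predictors on the history available at each visit,
and flags the first visit whose predicted probability reaches the
threshold; undetected eyes carry the last visit's day (365.25 days/year).

## Sampler presets and problem sizes

The full preset (10,000 burn-in, 10,000 sampling iterations thinned by 10)
mirrors the defaults documented for the reference implementation of the
boundary-detection model. The package's own studies use two reduced
presets chosen as deliberate simulation sizes: `reduced` (2,000/2,000/4,
500 kept draws) for recovery experiments on 40 eyes with 10 visits, and
`mini` (400/400/4, 100 kept draws) for pipeline runs that refit hundreds
of truncated series. Chains are initialised from a per-visit profile
maximum likelihood (a grid scan over $\ln \alpha$ with the conditional
MLE of $\tau^2$ at each candidate), which removes burn-in failures when
the likelihood is locally flat. Kept-draw counts below 100 are rejected by
`stboundConfig()` so the posterior CV summaries are never computed from a
handful of draws.

Degenerate inputs follow fixed conventions: regressions with fewer than 3
points report slope 0 and p 1; zero-residual fits report p 0 (declining)
or 1 (otherwise); PoPLR enumerates all $T!$ permutations exactly when
$T! \le n_{perm}$, with a relative tie tolerance so the identity
permutation always counts; the mean slope over an empty qualifying set is
0; and an intercept-only logistic fit reproduces the logit of prevalence
to machine precision.

## Known limitations

* The boundary-detection hierarchy is a declared reconstruction (above);
  its agreement with the original implementation is unverified.
* The entry-angle table is synthetic; substitute the published map for
  clinical use.
* In-sample evaluation overstates absolute performance; the framework
  reports it because that is the procedure being reproduced.
* With measurement noise well above the spatial signal the smoothness
  parameter saturates and STBound loses power; the model has no nugget
  term to absorb unmodelled white noise.
* Detection-time comparisons depend on the selected thresholds; with
  high-specificity thresholds a better-calibrated model can flag *later*
  than a noisier one on particular synthetic mixes.
* Because the generated fields are spatially correlated, the per-test
  mean sensitivity fluctuates by several dB between visits, so the trend
  metrics have modest power against the default −1.5 dB/year decline at
  cohort scale. This mirrors the clinical difficulty the methods face,
  but absolute AUC values on synthetic cohorts should not be read as
  estimates of clinical performance.
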