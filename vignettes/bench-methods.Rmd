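---
title: "Inferring changes in degenerate diffusion-model parameters without inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring changes in degenerate diffusion-model parameters without inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(benchmri)
```

## The problem

Biophysical models of the diffusion MRI signal, such as the
three-compartment "standard model" of white matter, are *degenerate* with
conventional multi-shell acquisitions: many parameter settings produce
identical data, so the inverse problem has no unique solution. The usual
escape is to constrain the model (NODDI-style: fix the diffusivities, tie
the tortuosity to the signal fractions) until it becomes invertible — at
the cost that a wrong constraint biases every remaining estimate.

In many studies, however, the quantity of interest is not the parameters
themselves but their *change* between conditions (patient vs control,
lesion vs normal tissue, time points). `benchmri` implements an
inversion-free Bayesian treatment of exactly that question: given a
baseline measurement $y$ and an observed change $\Delta y$, which sparse
*pattern of change* $\hat{\Delta v}$ (a unit vector in parameter space;
by default one parameter at a time) best explains $\Delta y$?

## The inference model

For a small change of amount $t = |\Delta v|$ along pattern
$\hat{\Delta v}$, a first-order expansion of the forward model $M$ gives
$\Delta y \approx t\,\nabla_{\hat{\Delta v}} M(v) + \epsilon$. The
baseline parameters $v$ are unknowable (the model is degenerate), so the
directional derivative is treated as a random variable conditioned on
the *measurements*:

$$\nabla_{\hat{\Delta v}} M \mid y \;\sim\;
  \mathcal N\!\left(\mu_{\hat{\Delta v}}(y),\, \Sigma_{\hat{\Delta v}}(y)\right),$$

which transfers the parameter-space uncertainty into measurement space.
The likelihood of an observed change at amount $t$ is then

$$P(\Delta y \mid y, \hat{\Delta v}, t) =
  \mathcal N\!\left(\Delta y;\; t\,\mu_{\hat{\Delta v}}(y),\;
  t^2 \Sigma_{\hat{\Delta v}}(y) + \Sigma_n\right),$$

with $\Sigma_n$ the measurement-noise covariance. The amount carries a
log-normal prior (changes plausibly span orders of magnitude) and is
marginalised numerically; a uniform prior over the hypothesis set
$\{\text{no change}\} \cup \{\hat{\Delta v}_k\}$ yields posterior model
probabilities, and the posterior over $t$ within a pattern gives MAP and
expected amounts. The no-change likelihood is
$\mathcal N(\Delta y; 0, \Sigma_n)$.

The functions $\mu(y), \Sigma(y)$ are *change models*: regressions
trained once per pattern on simulated $(y, \nabla M)$ pairs drawn from a
wide parameter prior, and reusable for any data acquired with the same
protocol. The mean uses a full quadratic polynomial design (with cross
terms) in the feature vector, the covariance a linear design mapped
through a log-Cholesky parameterisation so that any weight vector
yields a valid SPD matrix; both are fitted jointly by maximum
likelihood (analytic gradients, BFGS from an ordinary-least-squares
warm start, Nelder-Mead polish, best stage kept).

The feature vector is $y$ itself plus, for each log-power coordinate
$l_2$, the winsorised inverse root power $\min(e^{-l_2/2}, 60)$. The
reason is structural: because the degree-2 shell power is quadratic in
the compartment signal fractions, the derivative of $\log y_2$ with
respect to a fraction scales exactly with $e^{-l_2/2}$ — a function no
low-order polynomial in $l_2$ can track over its range (roughly $-27$
to $-3$). With plain polynomial features the surrogate mean for the
$s_{in}$ and $s_{ex}$ patterns regresses towards their common
signature and the two become confusable; the augmented features remove
most of that misfit. Plain features remain available
(`augment = FALSE`). The BFGS stage caps at 400 iterations by default:
running to full convergence (~2000 iterations, roughly ten times the
cost) improves the training likelihood substantially but was measured
to change held-out classification accuracy by only a few points, so
the cap is a deliberate runtime choice.

## The forward model

The diffusion signal is $S = s_{iso} A_{iso} + s_{in} A_{in} + s_{ex}
A_{ex}$, with free parameters (fractions $s_{iso}, s_{in}, s_{ex}$;
diffusivities $d_{iso}, d_{in,a}, d_{ex,a}$ in um^2/ms; tortuosity ratio
$\tau \in [0,1]$; orientation dispersion ODI $\in (0,1)$) — 8 in total,
plus a nuisance fibre orientation. The free-water compartment decays as
$e^{-b d_{iso}}$; the intra-axonal compartment is a stick (zero radial
diffusivity) and the extra-axonal compartment a zeppelin (radial
diffusivity $\tau\, d_{ex,a}$), both dispersed by a shared Watson
orientation distribution with concentration
$\kappa = \cot(\pi\,\mathrm{ODI}/2)$.

The Watson-convolved attenuations are integrals of
$\exp(n^\top(\kappa\mu\mu^\top - k\,gg^\top)n)$ over the sphere. We
evaluate them through the eigenvalues of that rank-2 matrix and a 1-D
integral representation involving the modified Bessel function $I_0$
(equivalent to the confluent hypergeometric function of matrix
argument), with 24 Gauss-Legendre nodes (converged to ~1e-6 relative;
a 256-node log-space route takes over for concentrations above 600).
The test suite validates both convolutions against an independent dense
2-D spherical product quadrature to 1e-4 absolute, and against the
closed-form limits ($\tau = 1$, ODI $\to$ 0, uniform ODF).

## Summary measures

Each shell of the (by default UK-Biobank-like) protocol — b = 1 and 2
ms/um^2, 50 quasi-uniform directions each, plus 5 b = 0 volumes — is
decomposed into even-degree real spherical harmonics by least squares.
Per shell we keep the degree-0 invariant (the spherical mean) and the
log of the degree-2 power $y_2 = \tfrac{1}{5}\sum_m C_{2m}^2$, giving
the 5-vector `(b0_mean, b1_mean, b1_l2, b2_mean, b2_l2)`. These are
rotation invariant (verified to 1e-5 under 100 random joint rotations of
the gradient table and the fibre orientation), so the nuisance fibre
direction can be fixed to +z during training.

Numerical choices:

* The degree-2 fit uses `l_max = 2`; with 50 directions per shell a
  higher-order fit is possible (the basis supports `l_max = 4`) but
  aliases more noise into the retained invariants and is not part of the
  default 5-vector.
* The log transform gets an additive floor, `log(y_2 + 1e-12)`, so that
  perfectly isotropic noise-free signals stay finite; noisy data never
  reaches the floor.
* Baseline summaries and changes from real data are normalised by the
  baseline b0 mean; log-power coordinates are shifted by
  $-2\log(\text{b0 mean})$ (the log-domain image of the same scaling)
  and a *change* in a log coordinate is scale-invariant and passed
  through untouched. This keeps real data commensurate with training
  data, whose fractions are normalised to sum to one (so the training
  b0 mean is exactly 1).
* Because the training b0 mean is constant, it carries no regression
  information; constant summary coordinates are automatically excluded
  from the design features (they remain part of the derivative
  targets). Without this the weights along the constant direction are
  unidentified and explode at noisy test inputs.

## Priors and the synthetic-data generator

Training samples and simulated test data share one prior, chosen to
cover brain-like tissue: $s_{iso}$ is a 50/50 mixture of a point mass
at 0 (pure tissue) and Uniform(0,1) (partial volume); $s_{in}, s_{ex}$
are Uniform(0,1); the three fractions are then normalised to sum to 1;
$d_{iso} \sim \mathcal N(3, 0.1)$ and $d_{in,a}, d_{ex,a} \sim
\mathcal N(1.7, 0.3)$ um^2/ms truncated at zero; $\tau \sim$
Uniform(0,1); ODI $\sim$ Beta(2,5), clipped to [1e-3, 1-1e-3] so the
Watson concentration stays finite. The two axial diffusivities share
one prior (the natural reading of a single axial-diffusivity prior for
both compartments); the delta-mixture weight is configurable because
only the presence of the point mass, not its exact weight, is
documented for the original design.

Measurement noise is additive i.i.d. Gaussian with sigma = 0.01
(SNR 100 at unit b0) — the regime of group-averaged data rather than a
single subject. What the generator deliberately does *not* emulate:
Rician noise floors, multiple fibre populations, exchange,
between-subject biological variability, or spatial correlation. Passing
simulation tests therefore demonstrates correctness of the method under
its own assumptions, not robustness to everything real data can do.

## Derivatives and training sizes

Directional derivatives of the noise-free summaries use central finite
differences with a relative step of 1e-4 of the pattern-weighted
parameter scale, falling back to one-sided differences when a baseline
sits on a parameter boundary — important because the prior places half
its $s_{iso}$ mass exactly at 0, and the derivative definition is
itself a one-sided limit. Steps shrink geometrically if no admissible
perturbation exists and the sample is dropped only when the step falls
below 1e-8 of scale.

Change models in this package's own experiments are trained on 14,000
prior samples for the constrained model and 8,000 for the full
standard model, rather than the 100,000 of a full-scale run;
`n = 100000` remains the documented default of
`build_training_set()`/`train_change_models()`. At these sizes every
weight is still constrained by far more than 10 samples and the
simulation experiments below are reproduced in scaled-down form; the
residual surrogate error contributes (honestly) to the reported
confusion rates. Single-parameter patterns use a component-reuse fast
path for the derivative evaluation (only the compartment a
perturbation touches is recomputed; fraction perturbations are exact
and free), verified against the general finite-difference path in the
test suite.

## Validation harness

`generate_test_pairs()` reproduces the simulation design: balanced
classes over {each parameter, no change}, one parameter increased by
0.1 (baselines resampled when the perturbation would leave its range),
noise added to both members. The per-pair noise covariance is the
sample covariance of summary differences over 100 noisy instances. Two
pipelines classify each pair:

* **Inversion baseline** (constrained 4-parameter model only): MAP fit
  by bounded quasi-Newton, Laplace covariance (inverse Hessian at the
  mode — the estimate-variance source of such z-tests is a free
  choice; the Laplace route is the default and a repeated-fit
  bootstrap would be a drop-in alternative), per-parameter z-tests with
  Bonferroni correction over the 4 free parameters, minimum-p labelling
  with a p > 0.05 no-change rule.
* **Change-model pipeline**: posterior over patterns, argmax winner
  (deterministic tie order: no-change first, then registration order).

`confusion_matrix()` tabulates column-normalised percentages;
`sensitivity_curves()` sweeps effect sizes 0 to 0.1 and tabulates the
true pattern's posterior and the MAP amount against the truth.

## Design decisions taken where the design was open

* **Amount prior hyperparameters** (not specified anywhere): log-normal
  with median 0.1 and log-sd 1, spanning roughly 0.005-2 in parameter
  units — wide enough for several orders of magnitude while centred on
  the effect sizes of interest. Exposed via `amount_prior()`.
* **Amount quadrature**: 128-point trapezoid in log-amount across the
  prior's 0.01%-99.99% quantiles. A narrower 0.1%-99.9% span was
  rejected because its 0.2% truncated mass shows up as a measurable
  bias against Monte-Carlo integration; grid doubling changes results
  by <0.1% (asserted in tests).
* **Quadratic design with cross terms**: "second-degree polynomial" is
  read as the full quadratic; a pure-powers mode exists
  (`cross = FALSE`).
* **Direction sets**: deterministic spherical-Fibonacci points per
  shell, rotated by a seed-controlled random rotation, persisted with
  the protocol (any quasi-uniform scheme works; determinism matters for
  reproducibility and protocol hashing).
* **Decreases**: the default hypothesis set uses positive single-
  parameter patterns (amounts are positive under the log-normal prior);
  negated patterns can be added explicitly via `change_pattern()`.
* **Group statistics**: the noise covariance of a two-group comparison
  is the baseline-group within-group covariance divided by the
  baseline-group size, as specified for the intended
  normal-tissue-vs-lesion design; a pooled two-group variant is
  available (`pool = TRUE`).

## Known limitations

* The surrogate is a single Gaussian conditional on $y$. Where the
  prior's point mass at $s_{iso} = 0$ places a lower-dimensional
  population next to the partial-volume population, the true
  conditional derivative distribution is multimodal and the Gaussian
  averages the modes. The visible consequence at the scaled-down
  training sizes used here is a residual $s_{in}/s_{ex}$ confusion of
  roughly 20-30% in the constrained-model experiment (all other
  classes resolve at 97-100%), which persists under larger training
  sets, full optimiser convergence and richer polynomial designs — an
  oracle with exact derivatives resolves ~95%+, so this is a surrogate
  limitation, not a limit of the inference rule.
* Diffusivity changes are intrinsically hard at b = 1, 2 ms/um^2: the
  posterior confuses the three diffusivity parameters with each other
  (and $d_{iso}$ with no-change, since at these b-values free water is
  almost fully attenuated). This is a property of the acquisition, not
  a bug; the confusion-matrix experiment asserts exactly this block
  structure.
* One parameter changing at a time is an assumption of the hypothesis
  set, not of the mathematics; multi-parameter patterns are expressible
  as `change_pattern()` vectors but hyperplane (2-D+) changes are out
  of scope.
* The first-order expansion underlying the likelihood degrades for
  large changes, visibly so for parameters entering the model strongly
  non-linearly (tortuosity coupling near $s_{in}+s_{ex} \to 0$,
  ODI near its bounds).
* Inference treats voxels independently; no spatial model.
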