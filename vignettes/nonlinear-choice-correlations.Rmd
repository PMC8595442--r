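---
title: "Testing optimal decoding of nonlinear population codes with choice correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing optimal decoding of nonlinear population codes with choice correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlcc)
```

## The problem

In a *linear* population code, everything a downstream area needs to know
about a task variable $s$ sits in the mean firing rates: the tuning curve
$f(s) = \langle r \mid s\rangle$ carries the signal, and a weighted sum of
spike counts decodes it. Many natural tasks are not like this. When a
*nuisance* variable $\nu$ — spatial phase, contrast polarity, an object's
pose — varies from trial to trial, it can wash the mean tuning out entirely
while leaving the task information intact in *higher-order statistics* of
the response: stimulus-dependent variances, covariances, or third moments.
The classic example is a linear filter viewing an edge of unknown polarity:
its mean response to any orientation is zero, but its response *variance* is
orientation tuned, which is why energy-model complex cells square their
inputs.

`nlcc` implements a complete workflow for studying such *nonlinear
population codes* and, crucially, for asking whether a subject's brain
*decodes* them efficiently:

* simulators of codes whose information lives in nonlinear statistics
  (XOR pairs, Gabor populations under phase/polarity nuisance, Gaussian
  codes with stimulus-dependent covariance, cubic exponential-family codes,
  information-limiting noise);
* polynomial statistics $R(r) = \{r_i,\; r_i r_j,\; r_i r_j r_k\}$ with the
  residualization used in data analysis, and their signal/noise summaries;
* optimal and deliberately suboptimal linear-in-statistics decoders, plus a
  generic trained ReLU network decoder;
* choice correlations, their optimal-decoding predictions, efficiency
  slopes with bootstrap intervals, shuffle controls and null-distribution
  p-values;
* an ideal-observer model and synthetic-session generator for a coarse
  two-alternative orientation-variance discrimination task.

## Choice correlations and the optimality test

Write the processing chain as $(s, \nu) \to r \to R(r) \to \hat s$: stimulus
and nuisance drive responses $r$, downstream circuits compute statistics
$R(r)$, and a linear readout $\hat s = w^\top R(r) + c$ produces the
behavioral estimate. The *nonlinear choice correlation* of statistic $R_k$
is its correlation with the estimate at fixed stimulus,

$$C_{R_k} = \mathrm{Corr}(R_k(r), \hat s \mid s)
          = \frac{(\Gamma w)_k}{\sqrt{\Gamma_{kk}\, w^\top \Gamma w}},$$

where $\Gamma = \mathrm{Cov}(R \mid s)$ is the stimulus-conditioned
covariance of the statistics (including nuisance-induced correlations) and
$w^\top \Gamma w = \sigma^2_{\hat s}$ is the estimator variance. The
minimum-variance unbiased readout has $w_{\mathrm{opt}} \propto
\Gamma^{-1} F'$ with $F' = \partial\langle R \mid s\rangle/\partial s$, and
substituting it gives the central prediction of the framework:

$$C^{\mathrm{opt}}_{R_k} = \frac{d'_{R_k}}{d'},$$

the ratio of the statistic's discriminability $d'_{R_k} = F'_k \Delta s /
\sqrt{\Gamma_{kk}}$ to the behavioral discriminability. Statistics that
carry more information must correlate more strongly with the choice — *if*
decoding is optimal. The prediction can equivalently be written as a ratio
of thresholds, estimator variances or Fisher informations
(`equivalent_ratios()`), and for binary discrimination both sides are
estimable from the total correlations $D = \mathrm{Corr}(x, s)$ through
$d' = 2D/\sqrt{1 - D^2}$ (`dprime_from_total_correlation()`).

For *coarse* tasks — where the noise statistics themselves change across
the stimulus range — the conditional covariances are averaged over
categories first, giving the normalized average conditional choice
correlation (NACCC, `naccc()`):

$$B_{R_k} = \frac{\langle\mathrm{Cov}(R_k, \hat s \mid s)\rangle_s}
  {\sqrt{\langle\mathrm{Var}(R_k \mid s)\rangle_s\,
         \langle\mathrm{Var}(\hat s \mid s)\rangle_s}},$$

which is bounded by 1 and converges to the fine correlation as the stimulus
range shrinks.

### Efficiency and information limits

When a code inherits its information from a smaller input population,
correlated fluctuations equivalent to stimulus jitter — *information-limiting
correlations*, $\Gamma = \Gamma_0 + \epsilon F'F'^\top$ — bound every
decoder's estimator variance below by $\epsilon$ and the Fisher information
by $J = (1/J_\infty + 1/J_0)^{-1}$ with $J_\infty = 1/\epsilon$
(`inject_information_limit()`, `fisher_information()`). Under such limits
even decoders with imperfect weights can approach the optimal pattern of
choice correlations; the slope $\alpha$ of measured against predicted
choice correlations equals $\epsilon/\sigma^2_{\hat s}$, the fraction of
behavioral variance explained by information-limiting noise. `nlcc`
estimates $\alpha$ as the angle of the first principal axis of the
bivariate scatter (total least squares — both axes are correlations with
sampling error), with a bootstrap interval (`efficiency_slope()`).

## The variance-discrimination task

The flagship application is a coarse 2AFC task: on each trial an
orientation $\phi = \sqrt{s}\,\nu$ is drawn with $\nu \sim N(0,1)$ and the
category $s$ is the orientation *variance* — wide
($\sigma_+ = 15^\circ$) or narrow ($\sigma_- = 3^\circ$). The ideal
observer thresholds $\phi^2$ at
$\theta^2_{\mathrm{opt}} = (\log s_+ - \log s_-)/(s_-^{-1} - s_+^{-1})$
($\theta_{\mathrm{opt}} \approx 5.49^\circ$), achieving a fraction correct
of $0.82$ (`optimal_threshold()`, `ideal_fraction_correct()`). Orientation
is the nuisance here: it moves category information into the second-order
statistics of orientation-tuned neurons, so the analysis tests linear terms
$r_i$ together with *residualized* squares $\delta r_i^2$ and cross
products $\delta r_i \delta r_j$, where $\delta r_i = r_i - \langle r_i
\mid \hat s_1\rangle$ removes the linearly decodable component
(`residualize()`).

```{r v1-example, eval = FALSE}
spec <- variance_task(alpha = 0.75, seed = 1)   # subject wastes 25% of its variance budget
session <- generate_session(spec, seed = 2)
fit <- cc_test(session, seed = 3)
summary(fit)
plot(fit)
```

### What the generator emulates — and what it does not

`generate_session()` draws Poisson (or Gaussian) spike counts from von
Mises orientation tuning curves (period $180^\circ$) whose preferred
orientations, widths, gains and baselines are randomized per neuron within
plausible ranges; oriented stimuli, equiprobable categories and a
configurable synthetic subject complete the session. Defaults are 12
neurons and 4000 trials — a scale at which the full analysis (90
statistics) runs in about two seconds, chosen as an idealized stand-in for
a cortical array session. The generator emulates the *statistical
structure* of such data (nuisance-driven nonlinear information, optional
shared internal noise via `shared_noise_sd`), not any particular recording:
real multiunits have unknown tuning statistics, slow drifts, and behavioral
nonstationarities that are absent here, so green tests certify the
machinery and its calibration, not properties of any specific dataset.

### The synthetic subject, and why the default is a regression readout

Three subject models are available in `variance_task()`:

* `"direct"` thresholds the true orientation — the textbook ideal observer,
  used to verify the analytic fraction correct;
* `"ideal-rule"` squares the locally optimal linear orientation estimate
  $\hat\phi$ from its own neurons and thresholds at $\theta_{\mathrm{opt}}$
  — the accuracy-maximizing likelihood rule;
* `"regression"` (default) thresholds the optimal *linear-in-statistics*
  readout $w^\top R + c$, $w \propto \bar\Gamma^{-1}\Delta F$, fit on the
  session itself.

The distinction matters for parameter recovery. The efficiency slope
measures optimality in the estimator-variance sense, and the likelihood
rule is *not* the variance-optimal readout here: the decision variable
$\hat\phi^2$ is dominated by the wide category's heavy tail, so a noiseless
ideal-rule subject scores far below 1 on a continuous-estimate slope even
though its binary accuracy is maximal. The regression subject is precisely
the decoder for which the optimality identity is exact, which makes the
planted-efficiency experiment well-posed: a degraded subject adds decision
noise of variance $\sigma^2_u(1/\alpha - 1)$ to the readout, and `cc_test()`
recovers $\alpha$.

### Binary choices: calibrated corrections

Binarizing a continuous decision variable attenuates choice correlations
and distorts the total-correlation route to $d'$ by order-1 factors
(conventionally $\zeta$ and $\delta$; $\delta$ comes out near 1.2 for an
ideal subject in this task). Because their exact values depend on the
response distributions, `cc_test()` calibrates the whole prediction by
Monte Carlo under an explicit subject model: choices are
$\mathrm{sign}(\hat u + \eta - \theta)$, where $\hat u$ is the analyst's
plug-in optimal readout and the threshold $\theta$ and noise SD of $\eta$
are estimated by probit regression of the observed choices on $\hat u$
(`cc_corrections()`, `estimate_threshold()`). Choices are then regenerated
from the session's own readout values, so every distribution-shape effect
is handled by trial resampling rather than by Gaussian formulas. Constant
corrections (`corrections = "constant"`, e.g. $\delta = 1.2$) remain
available.

Uncertainty for the slope in this calibrated path comes from a
nonparametric trial bootstrap of the entire analysis (resample trials,
refit the probit, regenerate model choices). A bootstrap over statistic
*terms* alone — the default in `efficiency_slope()`, and appropriate for
the fine-task analyses — under-covers here because term-level errors are
strongly correlated through shared neurons, shared choices and the shared
threshold fit.

## Encoding models

**Quadratic codes.** `quadratic_code()` draws Gaussian responses with a
constant mean and a smoothly stimulus-dependent covariance
(`rotating_cov()` is the canonical two-neuron family): all information is
in second-order statistics.

**Cubic codes.** The pure-cubic density
$p(z \mid s) \propto \exp(-\lVert z\rVert^4 + \gamma s\, z_1 z_2 z_3)$ is
sampled via a four-component Gaussian mixture at the vertices
$(1,1,1), (1,-1,-1), (-1,1,-1), (-1,-1,1)$ of a regular tetrahedron (all
with coordinate product $+1$), scaled by
$c(s) = \mathrm{sign}(\gamma s)\,\lvert\gamma s\rvert^{1/3}$ and given
compensating isotropic component covariance so that the mean is exactly
zero and the covariance exactly the identity for every $s$: first- and
second-order statistics carry no information at this stage, while the
third moment $\langle z_1 z_2 z_3 \mid s\rangle = a^3 \gamma s$ is exactly
linear in the stimulus (a pure sign-flip construction would make it a step
function with zero slope at the reference, killing fine decoding). A
stimulus-dependent affine map $r = f(s) + \Sigma^{1/2}(s)\, z$ then adds
linear and quadratic information; for $N > 3$ only disjoint triplets are
coupled ($N$ must be divisible by 3). The construction requires
$a^2\lvert\gamma s\rvert^{2/3} < 1$, bounding the usable stimulus range.

**Default cubic regime.** The defaults ($\gamma = 4.5$, vertex scale
$a = 0.8$, mean slope 0.5, log-variance slope 0.3, stimuli within
$\pm 0.26$ of the reference) put roughly 80% of the local Fisher
information into the third-order statistics while giving the optimal
decoder useful single-trial precision. This is the regime in which a
generic trained decoder can, in principle, extract most of the available
information; in low-information regimes (weak $\gamma$, wide stimulus
range) stochastic gradient descent on a small network provably settles on
the quadratic-only solution and never learns the three-way interaction,
which says more about noisy-label optimization than about the code.

**The network decoder.** `fit_network_decoder()` trains a fully connected
ReLU regression network (default two hidden layers of 30 units) by
minibatch backpropagation (Adam, learning rate $10^{-2}$ in the reference
experiment, batch 256, 400 epochs — a training-loss plateau; all settings
are logged in the run manifest). `network_information_experiment()` runs
the reference experiment: train on 20,000 pairs from the cubic code,
measure the fraction of optimal information extracted as the ratio of
inverse estimator variances on held-out trials at $s_0 \pm 0.1$, against
the closed-form optimal variance $(F'^\top\Gamma^{-1}F')^{-1}$ over the
degree-3 polynomial statistics; repeated over seeds (five by default, mean
about 0.93 with seed SD about 0.06). Training is the only stochastic
optimization in the package and is flagged — never silently accepted — if
its loss ends well above its running minimum.

## Shuffle controls

Two stratified permutation controls localize the origin of nonlinear choice
correlations, each resampling every neuron *independently* within strata so
that single-neuron conditional marginals are preserved exactly:

* `shuffle_internal_noise()` matches stimulus category, nuisance
  (orientation within $\pm 1.5^\circ$ by default, implemented as fixed bins
  of width $3^\circ$) and choice: internal noise correlations are
  destroyed, nuisance correlations survive;
* `shuffle_nuisance()` matches category and choice only: nuisance-induced
  correlations between neurons are destroyed too.

On a nuisance-driven code the first control leaves the measured-versus-
predicted relationship intact while the second collapses the cross-term
relationship toward zero. Reproducing the collapse requires a session
whose choice does not itself retain too much orientation information (an
imperfect subject, and a population large enough that no single neuron
dominates the readout): the packaged demonstration uses 30 neurons, 2000
trials, subject efficiency 0.5 and shared internal noise, where the
cross-term correlation falls from about 0.95 to below 0.3 under the
nuisance shuffle and stays above 0.9 under the internal-noise shuffle.
Single-trial strata cannot be permuted and are counted and reported.

Significance of individual terms comes from shuffle nulls
(`shuffle_null_pvalues()`): 100 shuffled choices (within stimulus, for the
measured correlations) or 100 shuffled stimulus labels (for the stimulus
information), a zero-mean Gaussian fit to the null, and the two-sided tail
$p = \mathrm{erfc}(\lvert x\rvert/\sqrt{2}\sigma_x)$ — uniform under the
null by construction. A one-sided variant (`tail = "upper"`), which gives
$p = 0.5$ at a vanishing statistic, is provided for comparability with
reports that use that convention.

## Numerical choices and degenerate inputs

* Covariance inversions use a relative ridge
  $\lambda = 10^{-6}\,\mathrm{tr}(\Gamma)/K$; a genuinely singular
  covariance without ridge is an error, not a silent pseudo-inverse.
* Zero-variance statistics are flagged degenerate, get $d' = 0$, and raise
  a warning rather than produce NaN correlations.
* Conditional means for residualization are estimated by per-category
  linear regression on $\hat s_1$ (the minimal model consistent with a
  linear readout and stable at session sizes); a binned-mean option exists.
* Fine-mode signal slopes use a central difference over the two stimulus
  values nearest the middle of the tested range.
* Ties at a decision threshold go to the narrow category — a
  probability-zero event for continuous estimates.
* The efficiency slope of an exactly self-consistent session (a noiseless
  in-sample subject) is exactly 1 with a zero-width interval; a numerical
  floor of $10^{-6}$ on the standard error keeps the interval well-defined.
* All simulators take integer seeds; the same seed reproduces the same
  table bit-for-bit, and the caller's RNG state is restored afterwards.

## Problem sizes

The shipped tests and the acceptance script run the analyses at the
following scales, chosen so each estimate's Monte-Carlo error is small
relative to the effect it checks: optimality identities on 20 random codes
of up to 10 statistics with 50,000 trials each; efficiency recovery on
sessions of 4000 trials and 12 neurons (90 statistics), 20 sessions per
planted efficiency; the network experiment at its reference size (20,000
training pairs, five seeds); shuffle controls on a 30-neuron, 2000-trial
session.

## Known limitations

* The choice-correlation machinery is feedforward and spatial: recurrent
  dynamics, temporal codes and feedback-induced correlations are out of
  scope.
* Only polynomial statistic bases are implemented (the architecture admits
  others); complex natural tasks whose nonlinearities are not compactly
  spanned by low-order polynomials are beyond the method's reach.
* The binary-choice calibration assumes the subject's decision variable is
  (affinely related to) a linear readout of the tested statistics plus
  independent Gaussian noise; a subject using a qualitatively different
  rule is only approximately captured, and readout-estimation noise in
  small sessions makes the estimated efficiency conservative.
* Absolute information levels of the synthetic V1 generator are not
  calibrated to any particular recording; only the statistical structure is
  emulated.
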