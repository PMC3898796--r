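---
title: "Cognitive tomography: models, priors, and validation on synthetic observers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive tomography: models, priors, and validation on synthetic observers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogtomo)
```

## The problem

People carry rich prior expectations — here called *subjective
distributions* — over complex stimuli such as faces. These priors are not
directly observable: all we get in an experiment is a sequence of discrete
choices. Cognitive tomography reconstructs the prior from those choices by
inverting a task-specific Bayesian ideal observer model. Because the prior is
modeled separately from the task-specific decision machinery, priors
recovered from *different* tasks can be compared on equal footing, and a
prior recovered from one task can be used to predict behavior in another.

The stimulus space is a bounded two-dimensional feature box: each face is a
point whose coordinates (in SD units) are scores on the first two principal
components of facial structure, and the box spans ±4 SD per dimension. The
package takes these coordinates as given; constructing the feature space from
face scans is out of scope.

## The forward model

A subject's prior $P$ is represented as a finite Gaussian mixture with $K$
components (weights $w_k$, means $\mu_k$, covariances $\Sigma_k$, in
SD/SD² units). A mixture was chosen because it can express the multimodal,
nonconvex shapes that recovered human priors show, while keeping every
observer likelihood analytic through Gaussian convolution identities.
Components are *not* truncated to the box; grid discretizations renormalize
over the box instead, because truncation would break the analytic marginals
and the mass outside ±4 SD is negligible for realistic fits.

Perception is noisy: a presented stimulus $s^*$ is perceived as
$s \sim \mathcal N(s^*, \sigma_p^2 I)$. The perceived stimulus is never
represented explicitly — it is integrated out analytically in every
likelihood below. The noise is isotropic and shared across tasks; a single
scalar $\sigma_p$ keeps the model identifiable from choice data alone.

**Familiarity task (2AFC).** Hypothesis $k$ states that stimulus $k$ is the
familiar one — a noise-corrupted sample from $P$ — while the other stimulus
is uniform on the box (density $u = (2 \cdot 4)^{-2}$). Integrating out the
latent face gives the marginal likelihood

$$ v_k = u \sum_m w_m \, \mathcal N(s^*_k;\, \mu_m,\, \Sigma_m + \sigma_p^2 I). $$

The unfamiliar face's uniform marginal is used without convolving it with
perceptual noise; the edge effect of that convolution is of order
$\sigma_p / 4$ and only matters within $\sigma_p$ of the box boundary.

**Odd-one-out task (3AFC).** Hypothesis $k$ states that the other two
stimuli $\{i, j\}$ are noisy realizations of one face drawn from $P$ and
stimulus $k$ is a noisy realization of an independent second draw:

$$ v_k = \mathcal N(s^*_i;\, s^*_j,\, 2\sigma_p^2 I)
   \Big[\textstyle\sum_m w_m \mathcal N\big(\tfrac{s^*_i+s^*_j}{2};\, \mu_m,\, \Sigma_m + \tfrac{\sigma_p^2}{2} I\big)\Big]
   \Big[\textstyle\sum_m w_m \mathcal N(s^*_k;\, \mu_m,\, \Sigma_m + \sigma_p^2 I)\Big]. $$

On equidistant triads the pairwise geometry term is common to all three
hypotheses, so choices are driven purely by the prior: stimuli lying in
high-probability regions are easier to tell apart, because apparent
differences there are more plausibly explained by two distinct samples than
by perceptual noise alone.

**Decision rule.** Hypothesis likelihoods map to choice probabilities by a
softmax with temperature $\beta$ on log likelihoods, mixed with a uniform
lapse:

$$ p = (1 - \lambda)\,\mathrm{softmax}(\beta \log v) + \lambda / n. $$

Temperature and lapse are both inferred, so the model can fit either
sharp-but-lapsing or soft responders. No stimulus-position or order biases
are modeled. Log likelihoods are floored at $-745$ (the smallest double's
log) so far-outlying stimuli cannot produce `-Inf`.

## The inversion

Given responses $R$ and presented stimuli $S^*$, the posterior over the
prior and observer parameters is

$$ P(P, \Omega \mid R, S^*) \propto P(P)\, P(\Omega) \prod_t
   P_{\mathrm{obs}}(R_t \mid S^*_t, P, \Omega), $$

sampled by random-walk Metropolis-within-Gibbs over blocks: softmax
coordinates of the weights, each component's mean, each component's
covariance (log eigen-scales plus a rotation angle, wrapped modulo $\pi$),
$\log \sigma_p$, $\log \beta$, and logit lapse. Proposal scales adapt toward
0.25 acceptance during burn-in only and are frozen afterwards, preserving
detailed balance; every fit is bit-reproducible from its seed. A bespoke
sampler (rather than a probabilistic-programming backend) was chosen because
the analytic choice likelihoods make posterior evaluation cheap, and full
control of proposals and seeding makes the test suite exactly reproducible.
The per-draw likelihood kernel is compiled (RcppArmadillo) and is checked
against the exported analytic R implementation, which in turn is checked
against tensor-product Gauss–Legendre quadrature oracles.

### Priors and defaults

| parameter | prior | default | why |
|---|---|---|---|
| weights | symmetric Dirichlet | $\alpha = 2$ | mild shrinkage toward balanced components |
| means | $\mathcal N(0, 2^2 I)$ | sd 2 | keeps components inside the ±4 box |
| covariance eigen-scales (SD) | log-normal | $(\log 0.6,\, 0.5)$ | realistic mode widths 0.2–1.5 SD |
| orientation | uniform on $[0, \pi)$ | — | no preferred axis |
| $\sigma_p$ (SD) | log-normal | $(\log 0.5,\, 0.5)$ | perceptual noise below stimulus spacing |
| $\beta$ | log-normal | $(\log 2,\, 0.7)$ | spans soft to near-argmax responders |
| lapse $\lambda$ | Beta | $(1, 1)$ | uniform: a fully random responder must remain *a priori* plausible, so that uninformative data leave the posterior over $P$ at its prior rather than pushing $P$ toward flatness |

$K$ is fixed per fit (default 3); selecting $K$ by cross-validated
prediction is left to the user, and no reversible-jump moves over $K$ are
attempted. Label switching between components is irrelevant because only
grid-level summaries (below) are ever reported. Default sampler settings:
25% burn-in, thinning to at most 2000 retained draws, initialization at
uniform weights, prior-median scales and prior-drawn means with up to 100
re-draws if the starting log posterior is not finite.

### Summaries

The recovered prior is reported as the posterior-mean *grid density*: each
retained draw's mixture is evaluated on a 100×100 grid of cell centers over
the box, renormalized, and averaged. Grids are the common currency for
plotting, for Jensen-Shannon (JS) divergences, and for moment matching. JS
divergence is computed in bits (base-2 logs) so its maximum is exactly 1;
$\sqrt{\mathrm{JS}}$ is a true metric and is what feeds classical
(Torgerson) multidimensional scaling. The default 100×100 resolution keeps
the discretization error (JS between a 100- and 200-cell discretization of
the same mixture is below $10^{-3}$ bits for mode widths ≥ 0.3 SD) far
below the between-task differences the analyses compare.

## Comparing and predicting

*Task invariance* is tested by comparing the $n$ same-subject,
different-task JS distances against the different-subject, same-task
distances per task with a one-sided Wilcoxon rank-sum test; the test behind
the original analysis is not specified, and a rank-sum on the two distance
populations is the natural nonparametric choice. MDS uses the classical
Torgerson dialect for determinism, with per-axis signs fixed by convention.

*Prediction* averages ideal-observer response probabilities over posterior
draws. Across-task prediction reuses the fitted $\Omega$ from the source
task: the transfer claim under test concerns $P$, and refitting $\Omega$ on
target-task data would leak target-task information. Performance is
reported as the mean probability assigned to the subject's actual choice (a
threshold-free score); a hard-accuracy variant (argmax agreement) is also
available and is what the consistency bound naturally constrains.

*Consistency* is the fraction of identically answered pairs among repeated
presentations. Under a symmetric response model (majority option
probability $p$, remainder split equally), consistency is
$c = p^2 + (1-p)^2$ for two alternatives and $c = p^2 + (1-p)^2/2$ for
three; inverting gives the best expected accuracy of any predictor,
$p = (1 + \sqrt{2c-1})/2$ and $p = (1 + \sqrt{6c-2})/3$ respectively. The
equal split of the non-majority probability is an assumption; it is the
least-favorable symmetric completion given only $c$.

*Baselines.* The moment-matched predictor replaces each draw's mixture with
the single Gaussian of the same mean and covariance — if the recovered
multimodal detail were idiosyncratic, it would predict as well as the full
model. The discriminative baseline is a Gaussian-process classifier
(squared-exponential kernel via kernlab, kernel width by a seeded
cross-validated grid) on concatenated stimulus coordinates with symmetry
augmentation (stimulus swap for 2AFC, cyclic rotations for 3AFC, with
matching label changes); its predictions are averaged over the same
augmentation group, so it respects the task's permutation structure
exactly. It fits a stimulus-to-response mapping for one task and therefore
cannot produce across-task predictions at all; requesting them is an error
by design. No claim is made that this matches any particular published GP
implementation in detail.

## The synthetic-observer world

Because no human data ship with the package, every empirical claim is
validated on synthetic observers whose ground truth is known:

* ground-truth priors: $K$ components with means rejection-sampled in the
  box at pairwise separation ≥ 2.5 SD (kept 1 SD inside the edge), flat
  Dirichlet weights, eigen-scales uniform in 0.3–1.0 SD;
* stimulus designs: uniform pairs for familiarity; for odd-one-out, 90% of
  triads are equilateral with uniform center and orientation and side
  lengths 1–4 SD (small triads probe noise, large triads probe prior
  shape), the remaining 10% are independent uniform triples — the geometry
  of non-equidistant trials is otherwise unconstrained, so uniform triples
  are the declared stand-in;
* responses sampled from the ideal observer at $\sigma_p = 0.5$,
  $\beta = 3$, $\lambda = 0.05$, with repeated trials re-answered
  independently (which is what makes consistency < 1).

Trial counts are configuration, not facts about any experiment: the
recovery experiment uses 1,000 familiarity trials with the full 20,000-step
sampler; the ten-subject task-invariance world uses 500 trials per task
with a reduced 4,000-step sampler; the bound and baseline experiments use
20 seeds each (600 trials with 30% repeats, and 500 training / 300 held-out
trials with 3,000-step fits, respectively). These sizes were chosen once so
that each experiment's conclusion is stable across seeds while the whole
suite runs on a laptop.

What passing these tests shows — and what it does not: the pipeline
recovers multimodal priors from choices generated *by its own model class*,
transfers them across tasks, and respects the information-theoretic limits
of noisy responders. It cannot show that human priors are Gaussian
mixtures, that human perceptual noise is isotropic, or that the softmax
plus lapse decision rule is the right account of human decision noise; the
mixture family itself is a stand-in for whatever flexible family underlies
the original analyses, which is not recoverable from the main text.

## Numerical choices and degenerate inputs

* Likelihoods are computed in log space throughout; log hypothesis values
  are floored at −745.
* Grid masses renormalize to 1 within $10^{-9}$; `0 log 0` is treated as 0
  in JS sums.
* Weights must sum to 1 within $10^{-8}$ on construction (then exactly
  renormalized); covariances must be symmetric positive definite.
* The all-identical-distances case in the invariance test returns p = 1 by
  contract rather than attempting a rank-sum on ties.
* MDS pads missing dimensions with zeros for rank-deficient (e.g. all-zero)
  distance matrices and warns when more than 10% of the eigenvalue mass is
  negative.
* `consistency_upper_bound` clips consistency at the chance level from
  above and errors below it.

## A worked example

```{r example, eval = FALSE}
world <- simulate_subject(seed = 1, n_trials = 500)
fit <- fit_cogtomo(world$familiarity, prior_config(K = 3),
  n_steps = 4000, seed = 2
)
autoplot(fit) # the recovered prior as a gray-level map

# across-task prediction
test <- make_stimuli("odd_one_out", 300, seed = 3)
resp <- simulate_responses(test, world$truth, world$params, seed = 4)
evaluate_predictions(predict(fit, test), resp)
```

## Known limitations

* Only the 2-D feature space is exercised; the math is written generically
  but higher dimensions are untested and the odd-one-out pair term assumes
  isotropic noise.
* No joint hierarchical fitting across subjects, no variational or SMC
  alternatives, and no model averaging over $K$.
* The split-half "lower bound" diagnostic of the original distance analysis
  is not reproduced; only the within/between comparison is.
* Reaction times, confidence, and stimulus-order biases are outside the
  model.
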