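---
title: "Inference for stochastic single-cell dynamics: models, algorithms and design choices"
author: "ssmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inference for stochastic single-cell dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmem)
```

## The model class

`ssmem` fits *state-space mixed-effects models* (SSMEMs) to time-lapse
measurements from many single cells. Each cell $i$ carries a latent Markov
process $X^{(i)}(t)$ — a chemical reaction network with $d$ species and $R$
reactions whose propensities $h(x, c, \kappa, t)$ may depend on time — and
is observed at discrete times $t^{(i)}_1 < \dots < t^{(i)}_{n_i}$ through

$$ y^{(i)}_l = g\!\left(x^{(i)}_l\right) + \epsilon^{(i)}_l, \qquad
   \epsilon^{(i)}_l \sim N(0, \mathrm{diag}(\xi^2)). $$

Three parameter blocks drive the dynamics:

* **cell-individual rates** $c^{(i)}$, modelling extrinsic noise through a
  log-normal population law $c^{(i)} \sim LN(\mu, \Omega)$ with population
  parameters $\eta = (\mu, \Omega)$;
* **cell-constant rates** $\kappa$, shared by all cells (known constants,
  such as a rate fixed by the experimental design, are declared separately
  and never sampled);
* **error scales** $\xi$, the measurement noise SDs.

Cell-varying initial conditions are expressed as extra coordinates of
$c^{(i)}$ (slot `x0FromC`), so the same inference machinery covers them.
Intrinsic noise — the stochasticity of the reactions themselves — enters
through the latent process; extrinsic noise through the population law.

The target of inference is the joint posterior

$$ \pi(c^{(1:M)}, \kappa, \eta, \xi \mid y) \propto
   \pi(c^{(1:M)}, \kappa, \eta, \xi)\,
   \prod_{i=1}^{M} \pi\!\left(y^{(i)} \mid c^{(i)}, \kappa, \xi\right). $$

## Simulators and when each applies

Four integrators simulate the latent process:

* **SSA (Gillespie direct)** — exact for time-invariant propensities.
* **Extrande** — exact thinning for time-varying propensities: candidate
  events arrive at a bound rate $B$ over a lookahead window and are either
  accepted as reaction $j$ (probability $h_j/B$) or discarded as virtual.
  Because the state is constant inside a window, $B$ only needs to dominate
  $h_{\text{tot}}(x, t)$ in $t$ at fixed $x$; the built-in time-varying
  network carries an analytic bound and the bound is runtime-checked, so an
  insufficient user bound is an error rather than a silent bias.
* **tau-leap** — fixed-step Poisson leaping, appropriate when propensities
  change little over a step. Species pushed negative have their propensity
  inputs clamped at zero and, inside a particle filter, the offending
  particle's weight is set to zero at the next observation; this keeps the
  likelihood estimator non-negative and unbiased for the leaping model
  without rejection loops.
* **chemical Langevin** — Euler–Maruyama on
  $dx = S h\,dt + S\,\mathrm{diag}(h)^{1/2} dW$, for large copy numbers.
  States are real-valued and may dip below zero; propensity evaluations
  clamp at zero (reflecting drift).

The engine never switches integrator automatically: exact simulators are
always allowed, the approximate ones only where the user asserts the leap
conditions hold. Benchmark datasets are always *generated* with an exact
simulator (SSA, Extrande, or the exact Ornstein–Uhlenbeck transition), even
when inference then runs on an approximate integrator — mirroring how real
data never come from the inference approximation.

For the Ornstein–Uhlenbeck (OU) benchmark the linear SDE integrates in
closed form, so the particle filters propagate OU particles with the exact
discrete Gaussian transition rather than an Euler step. This removes
discretisation bias from the likelihood estimate, which is what makes the
unbiasedness comparison against the Kalman oracle exact at any step size.
The generic Euler path remains available in `simulateLangevin()` and is
tested for convergence to the exact transition as $dt \to 0$.

## Particle-filter likelihood estimation

The per-cell likelihood $\pi(y^{(i)} \mid c^{(i)}, \kappa, \xi)$ is
intractable; `pfLogLik()` estimates it unbiasedly with sequential Monte
Carlo. The bootstrap filter propagates $N$ particles with the model
dynamics and weights them by the observation density; systematic resampling
triggers when the effective sample size falls below half of $N$ (never
after the last observation). All weight arithmetic is in log space.
A zero estimate (all particles dead) is returned as `-Inf` and treated by
the samplers as an automatic rejection, never as an exception.

**Correlated auxiliary numbers.** Successive pseudo-marginal iterations can
reuse randomness: the auxiliary variables $u$ are standard normals in a
fixed layout (particle × interval × substep × noise channel, one
resampling variate per interval), refreshed by Crank–Nicolson,
$u' = \rho u + \sqrt{1-\rho^2}\,\zeta$. Only tau-leap and Langevin
integrators have a fixed randomness layout (tau-leap converts normals to
Poisson counts via $\mathrm{qpois}(\Phi(u))$), so $\rho > 0$ is restricted
to them; the exact jump simulators always draw fresh randomness. When
$\rho > 0$ the filter resamples at *every* observation with particles
sorted by state before the systematic draw: the adaptive ESS trigger flips
between iterations and was measured to break the estimator correlation
(0.88 versus 0.97 with sorted always-resampling at $N = 50$,
$\rho = 0.999$), and a correlated filter only helps if successive
estimates actually co-move.

**Guided proposals.** For scalar-state Langevin dynamics with a scalar
linear-Gaussian observation, the modified-diffusion-bridge filter
propagates particles from a one-step Gaussian proposal conditioned on the
next observation: with drift $a(x)$, diffusion variance $b(x)$, time-to-go
$\Delta$ and observation variance $\sigma^2$,

$$ m = x + a\,dt + \frac{b p\,(y - p(x + a \Delta))}{p^2 b \Delta + \sigma^2}\,dt,
 \qquad v = b\,dt\left(1 - \frac{p^2 b\,dt}{p^2 b \Delta + \sigma^2}\right), $$

with importance weights equal to latent-transition over proposal density,
accumulated across substeps, plus the observation density at each
observation. For the OU benchmark both factors are exactly Gaussian and
the proposal is the exact conditional. On the bistable benchmark the
guided filter reduces the estimator variance by roughly an order of
magnitude at equal $N$ — this is what allows ten particles per cell there.
Guided support is deliberately restricted to this linear-Gaussian scalar
case; most guided filters share that restriction, and both systems that
benefit here are scalar.

## The Gibbs samplers

The **unperturbed** sampler loops three steps: (1) per-cell pseudo-marginal
Metropolis–Hastings updates of $c^{(i)}$ (each cell touches only its own
likelihood estimate and auxiliary numbers — the pseudo-marginal bookkeeping
invariant); (2) a joint update of $(\kappa, \xi)$ accepted against the
*summed* likelihood estimate over all cells; (3) an exact draw of $\eta$
from its Normal-Inverse-Wishart (NIW) full conditional given
$\log c^{(i)}$, or a Hamiltonian Monte Carlo update for non-conjugate
priors.

Step 2 is the scalability bottleneck: the variance of a sum of $M$
independently estimated log-likelihoods grows linearly in $M$, so keeping
the sampler mobile requires ever more particles as cells are added. The
**perturbed** sampler removes step 2 by letting the cell-constant
parameters vary weakly between cells on the log scale,
$\log \kappa^{(i)} \sim N(\log \kappa_{pop}, \delta^2 I)$ (and likewise
$\xi^{(i)}$), with $\delta$ fixed by the user (default 0.1, roughly a 10%
coefficient of variation — small against typical posterior scales).
$(\kappa^{(i)}, \xi^{(i)})$ then join the cell's step-1 block, and the
population locations get closed-form Gaussian draws in step 3. The cost is
a slightly diffuser posterior for the error-scale location; the benefit is
per-cell particle counts that stay flat as $M$ grows.

**Parameter scales.** All positive parameters are stored and proposed on
the log scale; the population law and the perturbation law are densities
*on that scale*, so no Jacobian corrections appear in the acceptance
ratios.

**Adaptive proposals.** Three schemes are available per block: adaptive
Metropolis (AM, empirical covariance scaled by $2.38^2/p$), AM with global
scaling, and robust AM (RAM, rank-one Cholesky updates driving acceptance
to a target). RAM with target 0.234 is the default everywhere; adaptation
decays as $n^{-0.66}$ and continues for the whole run (diminishing
adaptation), with an option to freeze. Defaults
($\beta = 0.66$, $\epsilon = 10^{-8}$, $\sigma_0 = 0.1$ log units) are
config-exposed.

**The translation move.** Centred hierarchies mix the population mean only
through the individual blocks: with weakly identified per-cell parameters
the per-cell autocorrelation time reached several hundred iterations on
the OU benchmark, and $\mu$ drifted accordingly. After each individual
sweep the sampler therefore proposes a common shift $\delta$ added to
$\mu$ *and* to every $\log c^{(i)}$. The population-law term is invariant
under this translation, so the acceptance ratio involves only the NIW
prior on $\mu$ and one fresh (correlated) likelihood estimate per cell.
On the OU benchmark this tripled the effective sample size of the slowest
population mean. The move is a valid Metropolis update of the joint
target, is on by default, and can be disabled or applied every $k$-th
iteration (`shiftMove`); it pays when the summed estimate has low variance
(exact or guided/correlated likelihoods) and is wasted effort when the sum
is noisy — the circadian study below disables it for exactly that reason.

**Priors.** The default NIW hyperprior is weakly informative: $\nu_0 =
p + 2$ (the vaguest proper inverse-Wishart), $\Psi_0$ set so the prior
mean of $\Omega$ equals the model's nominal between-cell variances, and
$\lambda_0 = 0.1$ pseudo-observations for $\mu$. Cell-constant rates and
error scales get independent Gaussian priors on the log scale with SD 1 —
one decade at one sigma.

## The Kalman oracle

The OU model $dX = \theta_1(\theta_2 - X)dt + \theta_3 dW$ with direct
Gaussian observation is linear-Gaussian: `kalmanLogLik()` computes the
exact likelihood by the scalar prediction/update recursion using the exact
discrete transition, and `exactGibbsOU()` runs the identical Gibbs loops
with every particle-filter estimate replaced by the exact likelihood. This
oracle validates, in order: propensity-free SDE simulation, both particle
filters (unbiasedness: $E[\exp(\hat\ell - \ell_{exact})] = 1$), the
correlated refresh, and finally posterior exactness of both full samplers
by per-parameter Wasserstein distances between chains.

## Tuning and diagnostics

* `tuneParticles()` walks a geometric ladder of particle counts and
  returns the smallest $N$ whose log-likelihood variance at a pilot
  parameter value is below 2.0 — the usual pseudo-marginal working rule.
  Perturbed mode tunes each cell against its own estimate; unperturbed
  mode tunes the summed estimate, which is why its tuned $N$ grows with
  $M$ while the perturbed sampler's per-cell $N$ stays flat. That
  contrast, not wall-clock time, is the package's scalability claim.
* `multiESS()` implements the multivariate effective sample size
  $n (\det \hat\Lambda / \det \hat\Sigma)^{1/p}$ with a batch-means
  long-run covariance, batch size $\lfloor\sqrt n\rfloor$.
* `wasserstein1()` computes the exact 1-d first-order Wasserstein distance
  from empirical quantile functions; a brute-force exact assignment solver
  (`wassersteinExactSmall()`, $n \le 8$) cross-checks the multivariate
  intuition. Posterior comparisons report per-parameter 1-d distances.
* `posteriorVisualCheck()` draws posterior samples, simulates full
  synthetic populations with the exact simulator, and returns 95%
  envelopes of the per-time 0.05/0.5/0.95 quantiles — the
  posterior-predictive check used for model comparison. The default 500
  repeats (config-exposed) keeps the check inside interactive runtimes.

## Benchmark systems and their default regimes

The defaults below were fixed once, to land each system in the regime the
method is meant for; they are design choices of this package, not values
quoted from elsewhere.

**Circadian gene expression** (`makeCircadianModel`): mRNA/Protein, four
reactions, transcription modulated by $1 + 0.6\sin(2\pi t/24)$ (24 h
rhythm). Population log-means $\log(0.4, 1.0, 2.0, 0.15)$ with scales
$(0.2, 0.15, 0.2, 0.15)$ and a 0.3 correlation between translation and
protein decay; $\sigma = 1.5$ on protein counts. This keeps mean mRNA
below one and protein near five — strong intrinsic noise, a few hundred
reaction events per cell over the 72 h / 25-point grid, and a clearly
detectable 24 h protein rhythm. Only Protein is observed, which makes the
per-cell rates individually weak and the population law do real work.

**Schlögl** (`makeSchloglModel`): the classic bistable system
$2X \rightleftharpoons 3X$, $\emptyset \rightleftharpoons X$ with
combinatorial mass-action propensities (the $x^2/x^3$ convention is
selectable). Defaults put the deterministic fixed points near 100 and 400
(unstable point 220): $c_1 = 0.024$ cell-varying with
$\log c_1 \sim N(\log 0.024, 0.15^2)$, $\kappa = (c_2, c_3) =
(10^{-4}, 146.7)$, $c_4 = 2.5$ known, $\sigma = 10$, 40 observations over
8 time units. About a quarter of simulated cells cross between states at
least once over the horizon, and low-$c_1$ cells commit to the low state —
the qualitative behaviour that makes this a stress test for
pseudo-marginal methods. Inference uses Langevin dynamics with the guided
filter and $\rho = 0.999$.

**Ornstein–Uhlenbeck** (`makeOUModel`): $\theta$ cell-varying with
log-means $\log(0.5, 5, 0.5)$, scales $(0.2, 0.1, 0.2)$, $\sigma = 0.2$,
20 unit-spaced observations, stationary initial law. Chosen so the
reversion time (2 time units) is resolved by the grid and the
stationary SD (0.5) is a few times the observation noise.

## Numerical choices and edge cases

* Log-sum-exp throughout the filters; ESS computed from normalized
  weights; `-Inf` likelihoods propagate to rejections.
* Non-positive-definite adapted covariances are jittered
  ($\epsilon I$), never fatal.
* The tau-leap substep count is $\lceil \text{gap}/dt \rceil$ with the
  last substep shortened, so output times are hit exactly.
* Degenerate population laws (zero variance) are supported for tests; the
  NIW draw uses the Bartlett decomposition.
* Event caps (default $10^7$) guard exact simulators against runaway
  networks; Extrande verifies its bound at every accepted candidate.
* Checkpointed runs restore the RNG state and are bit-identical to
  uninterrupted runs.

## Problem sizes used by the validation suite

The test suite and the acceptance script run the full studies at desk
scale, chosen as the smallest sizes at which each property is a meaningful
check rather than noise: unbiasedness ratios over a few hundred replicate
filters; posterior exactness on $M = 5$ OU cells with $2\times10^4$
iterations per chain; circadian recovery on $M = 10$ cells with
$5\times10^3$ iterations and ten seeded replicates (40 cells and
$5\times10^4$ iterations being the full-scale analogue); Schlögl recovery
on $M = 30$ cells with $10^4$ iterations; and the particle-count
scalability contrast on $M \in \{20, 40, 80\}$. The replicated circadian
study observes two days (17 points at the standard 2.88 h spacing) rather
than the default three-day grid, runs without the translation move (its
summed estimate is too noisy under the uncorrelated Extrande filter to
ever accept), and uses per-cell particle counts tuned on the ladder
32–108 against the variance-2 rule: cells whose trajectories make the
likelihood estimate noisy get more particles, which is exactly the
stickiness the tuner exists to prevent.

## What the synthetic studies do and do not show

The generator reproduces the structure the method assumes: exact latent
dynamics, Gaussian additive error, log-normal extrinsic noise, shared
observation grids. Real single-cell microscopy adds segmentation and
tracking artefacts, photobleaching trends, non-Gaussian and
state-dependent measurement error, cell division and death, and model
misspecification — none of which the synthetic studies probe. Passing
tests therefore demonstrate the correctness and internal calibration of
the inference machinery, not that any particular biological model fits
any particular dataset. The posterior visual check is the tool intended to
carry that second burden on real data.

## Known limitations

* Guided proposals only for scalar-state Langevin models with scalar
  linear-Gaussian observation.
* No adaptive tau-leap step selection and no hybrid jump/diffusion
  simulators.
* Correlated auxiliary numbers are unavailable for SSA/Extrande (their
  randomness has no fixed layout), so time-varying-propensity models pay
  the full uncorrelated pseudo-marginal penalty.
* With few cells and weakly identified per-cell rates, the between-cell
  scales $\tau$ are systematically pulled low (shrinkage), and population
  mean intervals inherit some of that optimism; the effect fades as $M$
  grows.
* HMC for the population step uses numerical gradients; it is meant for
  low-dimensional population blocks.
```
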