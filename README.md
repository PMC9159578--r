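# ssmem

Bayesian inference for **state-space mixed-effects models (SSMEMs)** of
stochastic reaction dynamics observed in many single cells — the situation
created by fluorescent time-lapse microscopy, where every cell runs its own
noisy copy of a reaction network and cells differ from each other in their
kinetic rates.

Each cell `i` has latent dynamics `X⁽ⁱ⁾(t)` (a chemical reaction network or
SDE) observed as `y⁽ⁱ⁾ₗ = g(x⁽ⁱ⁾ₗ) + εₗ`, `εₗ ~ N(0, diag(ξ²))`. Cell-individual
rates follow a log-normal population law `c⁽ⁱ⁾ ~ LN(μ, Ω)` (extrinsic noise);
the reactions themselves supply intrinsic noise; cell-constant rates `κ` and
the error scales `ξ` complete the parameter set. The package targets the
joint posterior

```
π(c⁽¹⁾…c⁽ᴹ⁾, κ, η, ξ | y) ∝ π(c, κ, η, ξ) ∏ᵢ π(y⁽ⁱ⁾ | c⁽ⁱ⁾, κ, ξ),   η = (μ, Ω)
```

with a pseudo-marginal particle Gibbs sampler: per-cell likelihoods are
estimated unbiasedly by particle filters (bootstrap or guided
modified-diffusion-bridge, optionally with correlated auxiliary numbers),
so the Markov chain targets the exact posterior despite the approximation.
A scalable "perturbed" variant lets `(κ, ξ)` vary weakly between cells
(`log κ⁽ⁱ⁾ ~ N(log κ_pop, δ²I)`), eliminating the expensive joint update
whose summed likelihood estimate otherwise forces particle counts to grow
with the number of cells.

What is inside:

* **Simulators** — exact SSA (Gillespie direct) and Extrande (thinning, for
  time-varying propensities), fixed-step tau-leap and chemical Langevin.
* **Particle filters** — bootstrap for any integrator; guided
  (modified-diffusion-bridge) for scalar Langevin dynamics with
  linear-Gaussian observation; Crank–Nicolson correlated auxiliary numbers
  for the fixed-layout integrators.
* **Samplers** — unperturbed 3-step and perturbed 2-step Gibbs, conjugate
  Normal-Inverse-Wishart or HMC population updates, adaptive proposals
  (AM, globally-scaled AM, robust AM), and a translation move for the
  population mean.
* **Oracle** — exact Kalman likelihood and gold-standard Gibbs sampler for
  the Ornstein–Uhlenbeck benchmark, validating every stochastic component.
* **Toolbox** — particle-count tuning, multivariate ESS, 1-d Wasserstein
  distances, posterior-predictive quantile-band checks, benchmark model
  factory (circadian gene expression, Schlögl bistable switch, OU), YAML
  configs, chain serialization with manifests, and a small CLI
  (`inst/scripts/ssmem-cli.R`) with `generate`, `simulate`, `tune`,
  `infer`, `diagnose` and `check` subcommands.

## Worked example

Generate a 40-cell dataset from the bistable Schlögl benchmark and re-infer
its parameters with the guided correlated filter:

```r
library(ssmem)
set.seed(1)

m  <- makeSchloglModel()          # c1 cell-varying, (c2, c3) shared, c4 known
ds <- generateDataset(m, M = 40, times = benchmarkTimes("schlogl"))

pf  <- pfConfig(nParticles = 10, kind = "guided_mdb",
                integrator = "langevin", dt = 0.1, rho = 0.999)
fit <- runInference(m, ds$data,
                    inferenceConfig(nIterations = 10000, mode = "perturbed",
                                    pf = pf, shiftMove = FALSE))
posteriorSummary(fit)
```

```
  parameter          mean           sd          q2.5         q97.5
1     mu_c1 -3.746085e+00 3.794696e-02 -3.823654e+00 -3.674674e+00
2    tau_c1  1.080636e-01 2.464049e-02  6.614372e-02  1.608105e-01
3        c2  9.585008e-05 5.084707e-06  8.730726e-05  1.067714e-04
4        c3  1.537432e+02 4.791166e+00  1.446153e+02  1.633185e+02
5     sigma  9.992620e+00 3.961781e-01  9.212342e+00  1.077919e+01
```

The generating values were `mu_c1 = log(0.024) = -3.73`, `tau_c1 = 0.15`,
`c2 = 1e-4`, `c3 = 146.7`, `sigma = 10`: every population-level parameter
lands inside its 95% credible interval. The cell-to-cell spread `tau_c1` of
the autocatalytic rate — the quantity that decides which cells commit to
the low-expression state and which keep switching — is covered but shrunk
towards the low end, the usual behaviour of hierarchical scale estimates at
moderate cell numbers.

The same engine exposes the exact-likelihood oracle for the OU benchmark:

```r
ou  <- makeOUModel()
dso <- generateDataset(ou, M = 5, times = benchmarkTimes("ou"))
gold <- exactGibbsOU(ou, dso$data, inferenceConfig(nIterations = 20000,
                                                   mode = "unperturbed"))
```

against which `runInference()` chains can be compared with
`wasserstein1()` / `tauSamples()`.

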