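# Worked example configuration: circadian gene-expression benchmark.
# Every key shown here is optional; omitted keys take the documented
# defaults (see ?loadConfig). Schema:
#   model:     name (circadian | schlogl | ou)
#   dataset:   M (cells), t0
#   inference: nIterations, mode (perturbed | unperturbed), delta, burnin,
#              thinning, etaKind (conjugate_niw | hmc), likelihood (pf | kalman),
#              saveIndividuals
#   pf:        nParticles, kind (bootstrap | guided_mdb),
#              integrator (ssa | extrande | tauleap | langevin), dt, rho,
#              essThreshold, lookahead, maxEvents
#   proposal:  kind (RAM | AM | AM_global), targetAcceptance, beta, sigma0
#   seed:      integer
model:
  name: circadian
dataset:
  M: 40
  t0: 0
inference:
  nIterations: 5000
  mode: perturbed
  delta: 0.1
pf:
  nParticles: 40
  kind: bootstrap
  integrator: extrande
proposal:
  kind: RAM
seed: 1
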