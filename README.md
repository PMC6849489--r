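# mlphotodyn

Machine-learned potentials for nonadiabatic surface-hopping photodynamics,
end to end in R: feed-forward neural networks that predict several coupled
electronic states at once (energies, forces as analytic derivatives,
phase-corrected nonadiabatic couplings, dipoles, optional spin–orbit
couplings), a fewest-switches surface-hopping (FSSH) driver running on an
ensemble of such networks, ensemble-disagreement adaptive sampling that
grows the training set where the networks disagree, and optimization and
statistics of conical intersections on the learned surfaces.

The package is for method development and teaching: instead of an external
quantum-chemistry backend it bundles analytic multi-state diabatic model
Hamiltonians whose diagonalization provides exact energies,
Hellmann–Feynman gradients and NAC vectors — and which can randomize the
sign of every eigenvector per call, reproducing the wavefunction-phase
problem that makes raw coupling data unlearnable. Everything is therefore
testable against a known ground truth.

## The core machinery

* **FSSH**: classical nuclei on the active adiabatic surface (velocity
  Verlet, default 0.5 fs), electronic coefficients propagated with the
  exact unitary substep propagator of
  `H_eff = diag(E) − i (v·d)`, hops drawn from the fewest-switches
  probability `g(a→j) = max(0, 2 Δt Re[c_j c_a*] (v·d_aj)/|c_a|²)` with
  kinetic-energy gating and velocity rescaling.
* **NN potential**: inverse-distance descriptor (exactly
  translation/rotation invariant, analytic Jacobian), shared
  shifted-softplus trunk, one head per property block. Forces are the
  exact analytic gradient of the energy head; the force loss is trained
  through that derivative (Hessian-vector products, hand-derived and
  finite-difference-verified), so the learned force field is conservative
  and dynamics conserves energy.
* **Phase correction**: overlap tracking `S = U_a' U_b` between
  eigenvector sets along geometry paths with recursive bisection, per-state
  sign vectors composed by elementwise product, applied as `p_i p_j` to all
  off-diagonal properties relative to one reference record.
* **Adaptive sampling**: per-property disagreement thresholds, ×0.95 decay
  per trigger until the cumulative-simulation-time freeze horizon, then
  frozen while points keep being added; order is always provider →
  phase-correction → append → retrain.
* **Conical intersections**: gradient-only penalty MECI optimization
  `(E_i+E_j)/2 + σ Δ²/(Δ+α)` (needs no NACs), plus near-seam gap
  statistics with bootstrap confidence intervals.

## Worked example

Train a two-member ensemble on a phase-corrected scan of the bundled
three-state cascade model, then compare NN-driven against exact-model
surface hopping:

```r
library(mlphotodyn)

det <- model_three_state()                        # exact reference
rnd <- model_three_state(randomize_phase = TRUE)  # what "QC output" looks like

ds  <- evaluate_dataset(rnd, as.list(seq(-1.5, 4.8, length.out = 240)))
ds  <- phase_correct_dataset(ds, det)             # one global sign convention
ts  <- training_set(ds, validation_fraction = 0.1, seed = 5)
ens <- train_ensemble(ts, list(hidden = c(40, 40), epochs = 2500), seed = 1)
ens$members[[1]]$val_rmse
#>       energy        force          nac       dipole
#> 0.0001209398 0.0012177885 0.2105034259 0.0361311939

hess <- numerical_hessian(det, 0, 1)              # ground-state curvature
samp <- list(type = "wigner", x_eq = 0, hessian = hess)
p_exact <- run_ensemble_of_trajectories(det, 100, samp, initial_state = 3,
                                        t_max_fs = 100, seed = 42)$populations
p_nn    <- run_ensemble_of_trajectories(ens, 100, samp, initial_state = 3,
                                        t_max_fs = 100, seed = 42)$populations
population_mae(p_exact, p_nn)
#> [1] 0.04480929
```

The validation RMSEs are in atomic units (0.12 mHa on energies, 1.2 mHa/Bohr
on forces); the population mean absolute error of 0.045 says the NN-driven
ensemble reproduces the exact-model S2 → S1 → S0 population curves to within
a few percent per (time, state) cell — the same comparison, at the same
ensemble size, that validates the surrogate against its reference.

A command-line wrapper covering the pipeline stages
(`generate`, `phase-correct`, `train`, `sample`, `dynamics`, `optimize`,
`analyze`) is installed under `inst/scripts/mlphotodyn`; see
`mlphotodyn --help`.

## Vignette

`vignettes/ml-photodynamics.Rmd` documents the models, the phase-correction
algorithm and its Berry-phase limits, the NN architecture and the
second-order force-loss training pass, the adaptive-sampling schedule, the
FSSH conventions, and what the synthetic study conditions do and do not
demonstrate.
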