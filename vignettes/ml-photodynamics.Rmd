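---
title: "Machine-learned potentials for nonadiabatic surface-hopping dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Machine-learned potentials for nonadiabatic surface-hopping dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlphotodyn)
```

## The problem

Photodynamics simulations couple classical nuclear motion to quantum
electronic transitions: after a molecule absorbs light, its excited-state
population relaxes through conical intersections back to the ground state on
femtosecond-to-picosecond time scales. Fewest-switches surface hopping
(FSSH) treats the nuclei classically on one *active* adiabatic potential
energy surface and the electrons through complex coefficients $c_i$
propagated with

$$ i\,\dot c_i = E_i(R)\,c_i - i \sum_j \big(v \cdot d_{ij}(R)\big)\, c_j, $$

with stochastic hops between surfaces drawn from the fewest-switches
probability
$g_{a\to j} = \max\!\big(0,\; 2\,\Delta t\,\mathrm{Re}[c_j c_a^*]\,
(v\cdot d_{aj}) / |c_a|^2\big)$.
Every step needs the adiabatic energies $E_i$, their gradients $G_i$, and
the nonadiabatic coupling (NAC) vectors $d_{ij}$ — normally from an
electronic-structure calculation, which dominates the cost. This package
replaces that calculation with multi-output feed-forward neural networks and
implements the full surrounding workflow: initial training sets from
normal-mode scans, sign-consistent (phase-corrected) training data,
ensemble-disagreement adaptive sampling, the FSSH driver itself, and
optimization and analysis of conical intersections on the learned surfaces.

Because a real quantum-chemistry backend is out of scope, the reference
("quantum chemistry") role is played by bundled analytic diabatic model
Hamiltonians. Their eigendecomposition supplies exact energies,
Hellmann–Feynman gradients $G_i = U_i^\top (\partial H/\partial R)\, U_i$ and
NACs $d_{ij} = U_i^\top (\partial H/\partial R)\, U_j / (E_j - E_i)$, and —
crucially — they can *randomize the sign of every eigenvector on every
call*, reproducing the arbitrary-phase behavior of real electronic-structure
codes that makes raw coupling data unlearnable.

## Bundled reference models

* `model_avoided_crossing()` — a one-dimensional two-state single avoided
  crossing ($V_{11} = -V_{22} = A\tanh BR$, Gaussian coupling), with smooth
  dipole and scalar spin–orbit operators so every NN output head can be
  exercised. Mass 2000 $m_e$.
* `model_three_state()` — three displaced harmonic diabats
  ($k = 0.032$ Ha/Bohr$^2$, minima at $R = 0, 1, 2$ Bohr, offsets
  0, 0.02, 0.04 Ha) with Gaussian couplings at all three diabatic crossings.
  A wavepacket excited vertically from the ground-state minimum to the
  highest adiabat cascades S2 → S1 → S0 through two coupling regions; with
  $\omega \approx 0.004$ a.u. (period ≈ 38 fs) a 0.5 fs velocity-Verlet
  step integrates it tightly. Because the model is bound and
  one-dimensional, trajectories recross the coupling regions and the
  populations partially recur — unlike a many-atom molecule, where
  vibrational energy redistribution makes the decay quasi-irreversible.
  This matters for what the oracle-equivalence test shows: agreement
  between NN-driven and exact-model-driven ensembles, not
  monotone-exponential curves.
* `model_conical_triatomic()` — a Cartesian (3-atom, 9-dof) two-state model
  built from the three interatomic distances, with diabatic coupling
  $\gamma\,(r_{12} - r_{13})$ that vanishes on the symmetric plane. The
  degeneracy seam ($r_{12} = r_{13}$, $r_{23} = r_{23}^*$) and its
  minimum-energy point have closed forms, so optimizers can be checked
  against brute-force grids and analytic fixtures. The cone is genuinely
  conical: the gap opens linearly along both branching-plane directions.

## Phase correction

Adiabatic eigenvectors are defined only up to a sign; two calculations at
neighboring geometries may return opposite conventions. Diagonal
observables (energies, gradients, permanent dipoles) square the phase away;
off-diagonal ones (NACs, transition dipoles, SOCs) flip with $p_i p_j$ and
become discontinuous, which destroys NN training. The correction tracks
overlaps $S = U_a^\top U_b$ between eigenvector sets along geometry
sequences: a state is *decided* when its diagonal overlap exceeds a
threshold (default 0.5 — a "close to ±1" criterion that separates
cleanly from rotated/mixed states); undecided segments are bisected
recursively (default up to 10 levels), evaluating the provider at midpoints,
and per-segment sign vectors compose by elementwise product. Random signs
at midpoints cancel in that product, so tracking works even through a
phase-randomizing provider. A dataset is corrected relative to one
reference record, establishing a single virtual phase convention.

Two deliberate limitations, both accepted as approximations: (i) the Berry
geometric phase makes a truly global convention impossible — a closed loop
around a conical intersection flips the sign once, so paths that wind
differently around the seam can disagree. Tracking therefore fails (with a
named error) for straight paths passing arbitrarily close to the seam; the
affected volume is small, and the triatomic training sets used for the
conical-intersection experiments are built with the deterministic sign
convention instead. (ii) Learning $|d_{ij}|$ instead of the signed coupling
is rejected: the relative signs of the per-atom components matter for the
dynamics.

## The NN potential

The descriptor is the vector of pairwise inverse distances $1/r_{ab}$ in
fixed lexicographic order — exactly translation- and rotation-invariant,
with an analytic Jacobian (1-D models use the coordinate itself). One
shared trunk (default two hidden layers × 50 units) with shifted-softplus
activations $\ln(1+e^x) - \ln 2$ feeds linear heads for energies (one
output per state), NAC vectors, dipoles and optionally SOCs. Shifted
softplus is chosen because analytic forces require a twice-differentiable
network.

Forces are **never** a separate head: $G_i = (\partial E_i^{NN}/\partial D)
(\partial D/\partial R)$ by the chain rule, so the force field is the exact
gradient of the predicted energy — a conservative field, which is what makes
microcanonical surface hopping conserve total energy. The force loss is
trained *through* this derivative: its weight-gradient is a Hessian-vector
product, implemented as a forward-tangent pass (tangent = the adjoint force
residual mapped into descriptor space) followed by a reverse pass through
that extended graph, which needs the second derivative of the activation.
The whole loss gradient is verified against central finite differences in
the test suite at $10^{-7}$ absolute tolerance.

Numerical choices, all persisted inside the model object for
reproducibility: descriptors are z-scored with training-split statistics;
energies share a single global mean/scale across states so that gaps are
preserved; NACs, dipoles and SOCs are scaled per property block (per-column
z-scoring would inflate physically tiny components). Default loss weights
are 1.0 (energy), 1.0 (force), 0.1 (NAC), 0.1 (dipole), 0.1 (SOC);
optimization is full-batch Adam (lr $5\times10^{-3}$, up to a few thousand
epochs) with early stopping on the validation loss, keeping the best
weights. Training is bit-reproducible for a fixed seed. Hyperparameters
can be chosen by `random_grid_search()`, ranked by validation energy RMSE
with force RMSE as tie-break.

A documented property of the surrogate is smoothing at conical
intersections: the network is differentiable everywhere, so the cone tip is
rounded into a small positive minimum gap. On the triatomic model this
floor is a few milli-Hartree (of the order of 0.1 eV) with the training
sets used here, and near-seam gaps are overestimated on average — the same
signature the reference method's comparison reports.

## Adaptive sampling

Two (or more) networks are trained on the same set with different seeds;
their disagreement (RMS deviation from the member mean, pooled per
property) is compared at every dynamics step against per-property
thresholds. Initial thresholds are the worst member validation RMSE times
a safety factor (default 3). Any single exceeded property triggers: the
geometry is recomputed with the reference provider, phase-corrected against
the training set's reference record, appended, and the ensemble retrained;
the trajectory restarts (the continue-from-checkpoint alternative is left as
configuration). On each trigger *before* the freeze horizon, thresholds
are multiplied by 0.95 — the sequence is exactly $\theta_0\, 0.95^k$ after
$k$ pre-freeze triggers. The freeze clock is the *cumulative simulated
time across the run* (default 10 ps): past it, points are still added and
the networks retrained, but thresholds are kept at their previous value.
This freeze is what lets the loop converge — with a per-trigger decay that
never stops, thresholds tighten geometrically while coverage improves only
point by point, and no ensemble can ever satisfy them.

Two desk-scale demonstrations are used (problem sizes chosen as the
package's own study conditions): on the 1-D three-state model, a sparse
normal-mode-scan set (7 points, amplitudes −3…3) is expanded during
50 fs S2 trajectories (8-trajectory budget, extended until three in a row
complete without a trigger) with a 60 fs cumulative freeze horizon; the
loop typically converges within a handful to a few dozen added points and
fresh-trajectory replays then exceed the final thresholds at under 1% of
steps. On the triatomic model,
an initial set confined to $r_{23} \le 2.45$ Bohr (far from the seam at
2.77) is expanded during excited-state dynamics heading into the seam; the
added points lie stochastically closer to the seam than the initial set
(compared by median seam distance). NAC disagreement near the seam is
dominated by the $1/(E_2-E_1)$ divergence, which no smooth surrogate can
resolve; the NAC loss weight is reduced to 0.02 for the triatomic
experiments so that the energy/gradient trust signal, which actually drives
the nuclear dynamics, governs the loop.

## Surface hopping

Velocity Verlet on the active surface (default $\Delta t = 0.5$ fs);
electronic coefficients advanced with the exact unitary substep propagator
$\exp(-i\,\Delta\tau\, H_\mathrm{eff})$, $H_\mathrm{eff} = \mathrm{diag}(E)
- i\,(v\cdot d)$, with energies and couplings linearly interpolated across
the nuclear step (default 20 substeps — electronic phases rotate on the
$E\,\Delta t$ scale, which a 0.5 fs step cannot resolve directly). Hop
probabilities accumulate per substep and one uniform draw per nuclear step
selects the target; hops are accepted only if kinetic energy can absorb the
potential jump, with the velocity rescaled along the full velocity vector
(NAC-projected rescaling available); frustrated hops leave velocities
unchanged and are logged. An energy-based decoherence damping is available
but off by default — plain fewest switches is the reference behavior.
Model providers get on-the-fly sign alignment of their eigenvectors
between steps (overlap with the previous step), so exact-model dynamics is
well-defined even with phase randomization on; NN surfaces are smooth by
construction and skip this. Trajectories are bit-reproducible given the
seed, the time step and a single thread.

Populations are reported classically (fraction of trajectories in each
active state); mean $|c_i|^2$ is tabulated alongside for diagnostics but
the classical count is the headline quantity, matching surface-hopping
convention.

## Conical intersections

Minima are optimized by BFGS on the state energy with analytic gradients.
MECIs use a gradient-only penalty objective
$(E_i+E_j)/2 + \sigma\,\Delta^2/(\Delta+\alpha)$ with
$\sigma_0 = 3.5$, $\alpha = 0.02$ Ha, $\sigma \leftarrow 1.5\sigma$ per
outer cycle until the gap falls below `gap_tol`; this needs only energies
and gradients — precisely the NN interface — and never the NAC direction.
Optimization is done in Cartesians; the descriptor's invariance makes the
NN surface exactly flat along translations/rotations, so those directions
simply stay put. Convergence is judged on the gap and on the mean-energy
gradient projected orthogonal to the gap-gradient direction. On the exact
triatomic model the optimizer reproduces the closed-form/grid-search MECI
to well under $10^{-2}$ Bohr in the internal coordinates with a gap below
$10^{-4}$ Ha; on the NN surrogate the converged gap is positive (the
rounded cone) but below the configured tolerance. `gap_statistics()`
quantifies the smoothing: among geometries whose reference gap is below
0.8 eV, the mean signed surrogate−reference gap difference is reported with
a bootstrap confidence interval.

## Kinetics analysis

`fit_time_constants()` fits the closed-form sequential first-order scheme
A → B → C,
$P_A = e^{-t/\tau_1}$,
$P_B = \tfrac{\tau_2}{\tau_2-\tau_1}(e^{-t/\tau_2}-e^{-t/\tau_1})$,
$P_C = 1 - P_A - P_B$, jointly to all three curves with binomial weights
$p(1-p)/n$ (floored), over $\log\tau$ with a small multi-start; the
degenerate $\tau_1 = \tau_2$ limit $P_B = (t/\tau)e^{-t/\tau}$ is handled
analytically, and non-decaying input is flagged rather than fitted.
Standard errors come from the Gauss–Newton approximation. On noiseless
synthetic curves with $\tau_1 = 25$ fs, $\tau_2 = 52$ fs the estimates are
exact to well under 1%; with binomial noise at 200 trajectories they stay
within a few standard errors.

## What the synthetic conditions do and do not show

The bundled models give the pipeline the right *topology* — avoided
crossings, a true conical intersection seam, sequential multi-state decay,
randomized wavefunction phases — with exact derivatives, so every claim the
tests make (force consistency, energy conservation, phase-correction
fidelity, NN-vs-reference population agreement, seam-directed sampling,
MECI accuracy and smoothing bias) is checked against a known ground truth.
They do not emulate: high-dimensional vibrational energy redistribution
(hence population recurrences), electronic-structure noise or convergence
failures, intruder states, spin–orbit-driven intersystem crossing (SOCs are
trained and predicted but not consumed by the shipped dynamics), or
Berry-phase-consistent coupling data around the seam. Passing here means
the machinery is correct, not that a given real molecule is learnable with
a given data budget.

## Problem sizes used by the shipped experiments

Chosen once as the package's study conditions: 200-point scans for phase
correction; 240-record training sets and 2×(40×40) ensembles for the
three-state model; ~390-record sets and 50×50 networks for the triatomic;
200 trajectories per population ensemble over 100 fs at 0.5 fs; 300
near-seam geometries for gap statistics; $10^4$ draws for stochastic-hop
consistency.

## Known limitations

* The adaptive loop has no recovery mechanism for an unluckily tight initial
  threshold: thresholds derive from the validation RMSE of networks trained
  on the sparse initial set, and a small validation split can underestimate
  the error, putting the (monotonically decaying) threshold below the level
  at which two independently trained members can ever agree. The loop then
  keeps adding points until its budget runs out. This is a property of the
  validation-calibrated decaying-threshold scheme itself; in practice it
  shows up as occasional random-split realizations where the post-run replay
  exceedance stays at a few percent instead of dropping below 1%.
* NAC magnitudes diverge at degeneracies; the provider floors the gap at
  $10^{-8}$ Ha, which keeps values finite but enormous, and such points
  poison NAC training if added to a set — the adaptive experiments
  therefore down-weight the NAC loss near seams.
* The FSSH variant implemented is the plain NAC-vector fewest-switches
  scheme; no locally diabatic propagation, no claim of equivalence with any
  specific production code's three-step propagator.
* The sequential-kinetics fit assumes first-order A → B → C; it is not a
  general kinetic-model fitter.
* The CLI's dataset and model archives are R serializations with md5
  checksums; they are containers for this package, not an exchange format.
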