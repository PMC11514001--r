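---
title: "Per-atom Gaussian process potentials for the water dimer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-atom Gaussian process potentials for the water dimer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimergpr)
```

## The modeling problem

`dimergpr` builds a machine-learned potential for the gas-phase water
dimer from *atomic* energy contributions. Instead of learning one
regression for the total energy, each of the six atoms (fixed ordering
O1 H2 H3 O4 H5 H6; atoms 1–3 are molecule A, 4–6 molecule B) gets its
own exact Gaussian-process regressor trained on that atom's share of the
total energy. The dimer potential is then

$$E(\mathbf{R}) = \sum_{a=1}^{6} \mu_a\!\left(\mathbf{f}_a(\mathbf{R})\right),$$

where $\mathbf{f}_a$ are the atom's Atomic Local Frame (ALF) descriptors
and $\mu_a$ the GP posterior mean. Cartesian forces follow analytically
from the chain rule,

$$\mathbf{F} = -\sum_a J_a^{\top}\,\nabla_{\!f}\,\mu_a,
\qquad J_a = \partial \mathbf{f}_a / \partial \mathbf{R},$$

so geometry optimization, coordinate scans and NVT molecular dynamics
can be driven entirely by the learned models. Summing trained atomic
contributions is what lets the same machinery scale to larger clusters,
which is why the dimer — the smallest system with an intermolecular
interaction — is the proving ground.

## The surrogate labelling oracle

Reference per-atom energies in the original setting come from a quantum
topological energy partition of density-functional calculations. Those
labels are far outside a desk-scale budget, so the package ships an
analytic flexible-water surrogate (`oracle_spec()`) that plays the same
role: harmonic O–H bonds ($k_b (r - r_0)^2$, $k_b = 2215.76$ kJ/mol/Å²,
$r_0 = 0.9572$ Å), harmonic H–O–H angles ($k_\theta (\theta-\theta_0)^2$,
$k_\theta = 158.78$ kJ/mol/rad², $\theta_0 = 104.52^\circ$), fixed point
charges (O $-0.834\,e$, H $+0.417\,e$) on all nine intermolecular pairs,
and one O–O 12-6 term (well depth 0.6364 kJ/mol, contact distance
3.1507 Å). The charge and 12-6 values are widely used rigid-water
parameters; the spring constants are typical flexible-water values
halved to match the $k\delta^2$ convention. The surrogate is smooth,
has a hydrogen-bonded bound minimum (−28.5 kJ/mol at
$r_{\mathrm{OO}} \approx 2.73$ Å), and supports an *exact* atomic
partition: bond terms split half–half between their atoms, angle terms
assigned to the vertex oxygen, every intermolecular pair term split
half–half. The partition sums to the total by construction (verified to
1e-10 across the test suite), which is exactly the property the
learning target needs. It is explicitly **not** an attempt to reproduce
density-functional energetics: it is a stand-in PES on which every
pipeline stage can be validated against analytic energies, atomic
energies and forces.

Because the surrogate is much smoother than a quantum-mechanical PES
(no charge transfer, no polarization, no short-range exchange
repulsion structure), accuracy numbers obtained on it are expected to
be *better* than the published quantum-labeled figures at equal
training-set size. Passing the analog suites therefore demonstrates
the pipeline's correctness and calibration machinery, not chemical
accuracy of a production water potential.

## Synthetic dataset design

`generate_dataset()` emulates the published dataset's design goal —
sample the dimer configuration space *uniformly*, so either molecule
can donate or accept the hydrogen bond:

* O–H bond lengths uniform on [0.85, 1.10] Å and H–O–H angles uniform
  on [95°, 115°] per monomer, independently. The published distortion
  ranges are not printed; these generously bracket thermal distortion
  at 298 K and are config-exposed.
* each monomer receives an independent orientation drawn uniformly from
  the rotation group (normalized 4-normal quaternion);
* the O1–O4 separation is uniform on [2.0, 5.5] Å along a uniformly
  random direction;
* geometries with any intermolecular contact below 1.4 Å, or a bond
  outside the distortion range inflated by 10%, are rejected.

On rejection, only the monomers, orientations and direction are
redrawn; the sampled separation is kept. This makes the separation
marginal of the *filtered* dataset exactly uniform — plain rejection
would deplete the short-separation bins, because close contacts are
more likely there (at 35 bins the max/min bin ratio would exceed 2).
The contact floor of 1.4 Å keeps surrogate labels finite and bounded;
the learned models are expected to degrade below ~2.2 Å separation
where the 12-6 wall dominates, which the scan diagnostics show.

One seeded generator stream drives the whole run; a fixed
configuration + seed reproduces a dataset bitwise. The full-scale
preset (`wd24_config()`: 100,000 geometries, 65,000/15,000 split)
generates in well under a minute.

## ALF descriptors and their Jacobians

Each atom's descriptor frame is defined by two reference atoms chosen
by a fixed priority rule — bonded neighbour of highest mass first, ties
broken by lowest index, extended breadth-first through
neighbours-of-neighbours when an atom has fewer than two bonded
neighbours. For the water dimer this gives, e.g., O1 → (x-axis H2,
plane H3) and H2 → (x-axis O1, plane H3). The 12 features (3N−6 for
N=6) are the two frame distances, the frame angle, and spherical
coordinates $(r, \theta, \phi)$ of the three non-frame atoms in the
local frame, in ascending global index order. They are exactly
rotation- and translation-invariant, and minimal: no redundancy, so no
constraint surface to respect during optimization.

Forces need $\partial \mathbf{f}/\partial \mathbf{R}$. The package
computes these analytically (unit-vector projectors for distances, the
standard three-point angle gradient, cross-product differentials for
the frame axes, quotient rules for $\theta$ and $\phi$). The tests pin
the Jacobians against a five-point finite-difference oracle to 1e-6
and verify that every row annihilates all six rigid-motion generators.
Degenerate (collinear) frames raise an error instead of being
perturbed: silent perturbation would corrupt the Jacobian and hence
the forces.

$\phi$ is an azimuth with a branch cut at $\pm\pi$. The cut is handled
in the kernel, not the descriptor (below).

## The per-atom GP regressors

The kernel is a product of a squared-exponential ARD factor over the
non-azimuthal dimensions and a periodic squared-exponential factor over
each azimuthal dimension:

$$k(\mathbf{f}, \mathbf{g}) = \sigma_f^2
  \exp\!\Big(-\sum_{d \in \mathrm{SE}} \frac{(\Delta_d)^2}{2\ell_d^2}\Big)
  \prod_{d \in \phi} \exp\!\Big(-\frac{2\sin^2(\Delta_d/2)}{\ell_d^2}\Big).$$

One lengthscale per input dimension (automatic relevance
determination). The periodic factor makes predictions and their
gradients continuous across the $\phi = \pm\pi$ cut, which a plain
squared exponential would violate; the tests evaluate both sides of
the cut. Non-azimuthal features are standardized per dimension;
azimuths stay in radians so the periodic factor sees true angle
differences. The prior mean is fixed at the training-label mean rather
than optimized: it reduces the search dimensionality and produces the
expected far-field behaviour — predictions revert to the prior mean
away from all data, so the dimer's far-field total tends to the sum of
the six prior means.

Hyperparameters (12 lengthscales, signal variance, noise variance) are
optimized over their logarithms by restarted L-BFGS-B on the exact log
marginal likelihood with analytic gradients; the first restart starts
from unit lengthscales and the label variance, further restarts
perturb the start (sd 0.5 in log space, seeded). Numerical choices
that matter:

* **Jitter.** 1e-8 of the signal variance is added to the kernel
  diagonal for factorization, escalated tenfold up to 1e-4 on Cholesky
  failure; failure beyond that raises an error naming the conditioning
  problem.
* **Bounded signal variance** ($\sigma_f^2 \le 4\,\mathrm{var}(y)$) and
  **lengthscales** ($\ell \in [10^{-2}, 10^{2}]$ standardized units).
  The unbounded likelihood has a ridge at jointly large
  $\sigma_f, \ell$ that models near-linear trends with huge cancelling
  kernel terms. On that ridge the predictor is numerically
  ill-conditioned (meaningful digits are lost to cancellation) and
  never reverts to the prior mean at any practical distance.
* **Noise floor** at 1e-6 of the label variance (σ ≈ 0.01 kJ/mol on
  these labels). With exactly noiseless analytic labels the likelihood
  drives the noise to zero, the dual-coefficient norm explodes, and
  the predictor "rings" outside the data instead of decaying. The
  floor is far below the model's achievable accuracy, so it costs
  nothing in-range.
* **Subsampled hyperparameter search.** The exact marginal likelihood
  costs $O(n^3)$ per evaluation, so hyperparameters are optimized on a
  fixed-seed subsample (default 400 points); the dual coefficients are
  then solved on the full training set at those hyperparameters. 400
  points estimate 14 smooth hyperparameters comfortably; the
  parameter-recovery test reconstructs known lengthscales from 300
  GP-sampled points to well within 30%.

Prediction uses blocked matrix-free reductions (`blocked_kernel_matvec`
and the blocked paths inside `predict_energy`): kernel rows are
streamed in blocks so peak working storage is proportional to
block_size × n, never n². Blocked and dense results agree to 1e-10 for
every block size — the portable analog of on-the-fly GPU kernel
reductions, and the property that removes the n² memory ceiling.

## The simulation engine

`forces()` applies the chain rule through all six models — every atomic
model depends on all 18 coordinates, so each contributes force on every
atom. Net force and net torque vanish identically because the
descriptors are rigid-motion invariant.

* **Optimization** (`optimize_geometry`) is damped dynamics:
  velocity-Verlet steps whose velocity is projected onto the force
  direction and zeroed when it opposes it, with a per-step displacement
  cap (0.1 Å) and convergence at max |force component| < 1.0 kJ/mol/Å.
  The threshold and the dynamics-based method are conventional for ML
  potentials; a quasi-Newton mode (`method = "lbfgs"`) is provided as
  an alternative. For optimizations started far out on the attractive
  tail the threshold must be chosen below the local force scale — at a
  shortest O···H contact of 4.3 Å the physical intermolecular forces
  are themselves under 1 kJ/mol/Å, so the far-start experiments use
  `fmax = 0.5`.
* **Dynamics** (`run_nvt`) is velocity Verlet with a single
  Nosé–Hoover thermostat (chain length 1, coupling constant
  $\tau$ = 100 fs, $Q = N_f k_B T \tau^2$) applied in half-steps around
  the Verlet update; kinetic temperature uses $3N-3 = 15$ degrees of
  freedom (centre-of-mass drift removed at initialization, no
  constraints). Initial velocities are Maxwell–Boltzmann at the target
  temperature. With the thermostat off the integrator is plain NVE and
  conserves the surrogate's energy to a secular drift (slope of a
  linear fit × duration — the standard measure, insensitive to the
  bounded within-period oscillation of a symplectic integrator) far
  below 0.1 kJ/mol over 10,000 half-femtosecond steps.
* **Scans** (`scan_coordinate`) hold both monomers internally rigid and
  translate molecule B along the O1→O4 unit vector across a grid,
  recording predicted (and optionally surrogate-reference) energies.
* Non-finite energies or forces abort a run with the step index rather
  than propagating NaNs — the typical failure mode is extrapolation
  into the short-range repulsive wall.

## Problem sizes and what the checks do (and do not) show

The analog experiment suite trains all six atomic models on 2,000
surrogate-labeled geometries sampled under the full-scale design and
evaluates 1,000 held-out geometries; at these sizes the whole suite
(generation, training, evaluation, optimization, a 10 ps NVT run) is a
few minutes on one CPU core. Under these study conditions the package
reproduces the qualitative headline behaviours end to end: well over
90% of held-out geometries within chemical accuracy (4.184 kJ/mol);
damped-dynamics optimization from a start with a ~4.3 Å shortest
O···H contact converging in a few thousand steps to within 0.02 Å RMSD
and a fraction of a kJ/mol of the independently located surrogate
minimum; far-field reversion toward the prior-mean sum by 10 Å
separation; and a 10 ps NVT mean temperature within a few percent of
the 298 K target.

The generator emulates uniform-coverage dataset design, not the
physics of real water sampling: it contains no Boltzmann weighting, no
correlated monomer distortions, and its labels come from the smooth
surrogate above. Consequently the passing suites certify the
*machinery* — descriptors, derivatives, training, reductions,
integrators — and its calibration protocol; they say nothing about the
accuracy of any specific quantum-labeled water model, which requires
the corresponding reference data.

## Known limitations

* Fixed atom ordering and per-atom models: chemically identical atoms
  get different models, and molecular permutation symmetry is not
  exploited.
* Exact GPR only — no inducing-point or gradient-enhanced training;
  the practical ceiling is a few thousand training points per atom on
  one CPU.
* Gas-phase dimer only: no periodic boundary conditions, no Ewald
  summation, at most two molecules.
* The short-range wall (separations below ~2.2 Å) is outside the
  filtered training support and is extrapolated poorly, by design of
  the dataset.
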