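---
title: "Methods: locality of quantum force corrections and machine-learned centroid MD"
author: "mlcmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locality of quantum force corrections and machine-learned centroid MD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mlcmd)
```

## The model

A quantum nucleus at inverse temperature $\beta$ is isomorphic to a
classical cyclic "ring polymer" of $P$ beads: positions $x_1 \dots
x_P$ (cyclic, $x_{P+1} = x_1$) sampled from

$$ \exp\Big\{ -\beta \sum_k \Big[ \tfrac12 m\,\omega_P^2 (x_{k+1} -
x_k)^2 + U(x_k)/P \Big] \Big\}, \qquad \omega_P =
\frac{\sqrt{P}}{\beta\hbar}. $$

As $P \to \infty$ the bead marginal converges to the exact quantum
Boltzmann distribution.  Centroid molecular dynamics coarse-grains
the ring into its centroid $x_c = \frac1P \sum_k x_k$, which moves on
the centroid potential of mean force $U_c$; the quantum centroid
force is the conditional bead-force average

$$ F_c(x_0) = -\frac{dU_c}{dx_0} = \big\langle \tfrac1P \textstyle
\sum_k F(x_k) \big\rangle_{x_c = x_0}. $$

The package's deliverable is the *correction* $\Delta F_c = F_c -
F_\mathrm{classical}$, which is learned by a localized regression
model and added to classical forces at run time ("ML-CMD"), giving
quantum centroid statistics at classical cost.

Internal units are Angstrom, femtosecond, amu, kJ/mol and Kelvin
throughout; `phys_constants()` lists the derived constants.

## Why the correction is local

Expanding $U$ to second order around the centroid, the imaginary-time
path fluctuates in independent Gaussian Matsubara modes
($\omega_n = 2\pi n/\beta\hbar$), giving the bead-distribution second
moment per Cartesian degree of freedom

$$ \langle x^2 \rangle = \frac{\beta\hbar^2}{2\pi^2 m}\left[
-\frac{1}{2t^2} + \frac{\pi}{2t}\coth(\pi t) \right], \qquad t =
\frac{\beta\hbar\omega}{2\pi}, \quad \omega = \sqrt{U''/m}. $$

Its high-$T$ limit $\hbar^2\beta/12m$ is the Gaussian kernel width of
the Feynman–Hibbs effective potential; its $T \to 0$ limit
$\hbar/2m\omega$ is the harmonic ground-state variance.  Both are
rigorous upper bounds (`matsubara_width()`, `fhc_width()`,
`qho_width()`; the direct Matsubara summation with an arctangent tail
is kept as an independent cross-check, `method = "sum"`).

For two atoms interacting through the slowest-decaying (Coulombic)
force at separation $R$, second-order smearing gives the relative
force correction bound

$$ \frac{\Delta F}{F} \le \frac{3}{R^2}\big[\langle x_i^2\rangle +
\langle x_j^2\rangle - 2\langle x_i x_j\rangle\big] \le
\frac{12\,\langle x^2\rangle_{\max}}{R^2}, $$

the last step by Cauchy–Schwarz (`force_correction_bound()`; the
cross-correlation is exposed through `drop_correlation` rather than
modeled, since it only tightens the bound).  With the hydrogen
librational frequency 670 cm⁻¹ — the lowest-frequency, most
delocalized hydrogen mode in liquid water — the worst case at the 4 Å
model cutoff stays below 2% at every temperature between 1 and
1000 K, and dropping the (positive) correlation at 300 K gives
≈0.43%.  That is the quantitative license for a 4 Å learning cutoff.

The closed form assumes positive curvature; tunneling/transition-state
regions (negative $U''$) are outside its domain and outside this
package's scope.

## Samplers and their verification

`pimd_run()` integrates the ring polymer in normal-mode coordinates:
exact free-ring-polymer rotation, velocity-Verlet force splitting
(BAOAB ordering), and per-mode Langevin friction — the centroid mode
at a configurable friction (default 1 ps⁻¹), internal modes
critically damped at twice their frequency.  Fictitious mode masses
equal the physical mass on every mode: only the sampled distribution
matters here, not mode dynamics.  Fixed-centroid sampling zeroes the
centroid-mode momentum at every stage, which is the exact holonomic
constraint in mode space; the centroid is then constant to machine
precision.  One-dimensional systems use a compiled sampler with the
identical scheme.

Defaults follow common practice for room-temperature water-like
systems: 0.5 fs timestep, 1 ps⁻¹ centroid friction, 32 beads at
T ≥ 200 K and 64 below, 10% burn-in, block-averaged standard errors
with 20 blocks, and a per-record convergence tolerance of
0.2 kJ/(mol Å) on the force SEM (records failing it are flagged, not
dropped).  All are arguments.

Two independent routes verify the sampler:

* **Transfer-matrix oracle** (`exact_centroid_force_1d()`): the
  fixed-centroid constraint is Fourier-resolved,
  $\rho_c(c) \propto \int d\lambda\, e^{-i\lambda P c}\,
  \mathrm{Tr}[B(\lambda)^P]$, with $B$ the per-bead transfer operator
  on a dense spatial grid carrying a phase $e^{i\lambda x}$.  The
  density and its derivative come from the same quadrature, so
  $F_c = kT\,\rho_c'/\rho_c$ needs no numerical differentiation.  The
  $\lambda$ range is set from the classical centroid spread with a
  16-fold safety factor (the quantum spread can be narrower than the
  classical estimate); the spatial grid covers the thermally
  accessible region (30 kT) padded by the free-particle bead width.
  $P$ can climb a 16→32→64→128 ladder until $F_c$ moves less than
  10⁻³ kJ/(mol Å).  The oracle is itself cross-checked in the test
  suite against brute-force quadrature of the constrained integral at
  $P = 4$, against the exactly-known harmonic case ($\Delta F_c
  \equiv 0$ at any $P$), and against the classical limit at 3000 K.

* **Closed forms**: free-particle width $\frac{\beta\hbar^2}{12m}(1 -
  P^{-2})$ at finite $P$, the discrete Matsubara sum for harmonic
  wells, and the centroid-virial kinetic-energy estimator against
  $(\hbar\omega/4)\coth(\beta\hbar\omega/2)$.

A note on integrator bias: BAOAB sampling carries an $O(dt^2)$
configurational bias; at 0.5 fs it is ≈2% of the harmonic bead width
(visible only because block SEMs resolve 0.3%), so width-sensitive
tests run at 0.25 fs.

## The correction model

**Descriptors.**  For each atom, squared embedded densities built
from Cartesian-moment-weighted Gaussian-type orbitals over neighbours
within $r_c$:

$$ f_{a,(l,j)} = \sum_{|\alpha|=l} \binom{l}{\alpha}
\Big[\sum_{b\neq a} c_{e(b)}\, \Delta_x^{\alpha_x}\Delta_y^{\alpha_y}
\Delta_z^{\alpha_z}\, e^{-\eta (r_b - r_j)^2} f_c(r_b)\Big]^2 $$

with a cosine cutoff $f_c$ (C¹ at $r_c$), 11 radial centres spread on
$[0, r_c]$, $\eta = 1/2\Delta r^2$, angular momentum $l \le 2$, and
fixed distinct per-element embedding coefficients.  Defaults: 4 Å
cutoff, 33 features.  The features are exactly invariant under
rotation, translation and same-element permutation, and identically
zero for an isolated atom.  Exact hyperparameters (centres, widths,
cutoff function) are this package's documented choices; the locality
analysis above is what fixes the only physically critical one, $r_c$.

One-dimensional model systems sit in an *external* potential, so no
translation-invariant environment exists; they instead use a Gaussian
coordinate basis along the active coordinate
(`descriptor_params_1d()`), which makes the 1D learner a radial-basis
network in $x$ — same training machinery, same conservative-force
structure.

**Networks and training.**  Per-element feed-forward networks (two
tanh hidden layers, default 20+20) map features to atomic scalars;
the predicted correction force is the exact analytic negative
gradient of their sum, so the correction is conservative and sums to
zero over atoms by construction.  Because fixed-centroid sampling
yields forces only, training is pure force matching and the scalar is
defined up to a constant (the output bias is pinned at zero).
Features are standardized by their training-set rms — the raw
embedded densities span orders of magnitude.

Training is ELM-LM: with hidden weights frozen at seeded random
values, predicted forces are *linear* in the output weights, so stage
one is a ridge-regularised linear least-squares solve; stage two
refines all weights by Levenberg–Marquardt with analytic Jacobians of
the force residuals (hand-derived, finite-difference-verified in the
suite) plus Tikhonov weight-decay rows, which both regularise and
keep the least-squares problem overdetermined when records are few.
The convergence criterion is on the loss defined as the RMS force
residual in kJ/(mol Å), default threshold 0.1, exposed as
`loss_tol`.  Training is bitwise reproducible for a given seed.

**Closure evidence** (all recomputed by the test suite): a model
trained on 20 oracle centroid forces of the quartic well predicts 20
held-out points within 2% of the maximum correction; a student
network recovers a synthetic random teacher's forces on 200 toy-water
octamers to under 5% of the label RMS on held-out clusters; and
models trained only on octamer clusters transfer to configurations
the training never saw (the fluid experiment below).

## ML-CMD and observables

`run_md()` adds the predicted correction to classical forces inside a
velocity-Verlet/Langevin loop; prediction uses a pair-vectorized
evaluation whose cost is linear in atom count at fixed neighbour
density.  On the quartic well at 100 K, ML-CMD's stationary centroid
histogram matches $e^{-\beta U_c}$ from the oracle to a
Kolmogorov–Smirnov distance below 0.02 at 10⁵ samples, while
classical sampling of the same well fails that bound — the package's
core end-to-end claim at desk scale.

Structural observables are computed on centroid variables: `rdf()`
(shell-volume-normalized pair histogram, minimum image),
`virial_pressure()` (pair-virial form), `msd_diffusion()` (multiple
time origins, Einstein relation, block-averaged uncertainty over five
origin blocks, and a log-log slope diagnostic that flags
non-diffusive windows).

## The synthetic systems

The generator (`make_fixtures()`) produces:

* **toy water** — flexible 3-site molecules (harmonic bonds
  r₀ = 0.9572 Å, k = 2200 kJ/mol/Ų; harmonic angle 104.52°,
  320 kJ/mol/rad²; O-site LJ ε = 0.65 kJ/mol, σ = 3.15 Å; charges
  ∓0.84/+0.42 e), 30 molecules at 0.997 g/ml in a periodic box,
  briefly equilibrated classically at 300 K.  Clusters of a central
  molecule plus its 7 nearest neighbours (complete first solvation
  shell by construction) are the training geometries.  Periodic runs
  use shifted-force LJ and Coulomb within a cutoff; clusters use bare
  1/r.  The stiff O–H stretch makes hydrogens strongly quantum at
  300 K ($\beta\hbar\omega \approx 7$), a demanding learning target.
* **cold LJ fluid** — 32 atoms, ε = 1 kJ/mol, σ = 2.8 Å, mass
  2.016 amu at 30 K, where the free-particle bead spread (rms
  ≈ 0.26 Å) visibly softens the first RDF peak.  The end-to-end fluid
  test trains on 12 fixed-centroid records at 16 beads and shows the
  ML-CMD centroid RDF at least halving classical MD's L¹ error
  against the PIMD reference.
* **1D suites** — quartic/Morse/harmonic wells on centroid grids.

What these systems do *not* emulate: long-range electrostatics under
periodic boundary conditions (no Ewald — clusters use bare Coulomb,
periodic runs shifted-force truncation), polarization and multipoles,
bond dissociation, and real production force fields.  Passing tests
therefore demonstrate the method's internal consistency and its
locality-based transferability mechanism, not quantitative accuracy
for real water.

## Numerical choices and problem sizes

* Sampling checks run 10⁵–10⁶ steps of the compiled 1D sampler;
  molecular fixed-centroid records use 2500–4000 steps at 16 beads in
  the suite (SEM tolerances widened accordingly and recorded on each
  record) — production-quality labels simply need longer runs of the
  same code.
* The oracle uses a 241-point spatial grid and 128 Fourier nodes by
  default; the harmonic case is exact to ≈10⁻¹², and rung-doubling
  changes quartic forces by < 10⁻³ kJ/(mol Å).
* Ties and degenerate inputs: empty neighbourhoods give zero features
  and zero correction; P = 1 reduces every sampler to classical MD
  with identical trajectories for identical seeds; free particles
  reduce the oracle to a flat PMF up to grid-truncation edge effects
  (bounded by 0.1 kJ/(mol Å) on the default grids).
* Wall-clock: the correction evaluation is within a small factor of a
  classical force call at these system sizes (both are
  neighbour-list-bounded); this is observed, not asserted in CI,
  since timing is hardware-dependent.

## Known limitations

Centroid statistics only (no bead-level structure is reported; a
one-bead PMF could be trained the same way but is not implemented).
No negative-curvature (tunneling) regimes.  No Ewald electrostatics,
so periodic toy systems are short-ranged by construction.  The
multi-dimensional sampler is verified against closed forms and the 1D
oracle rather than an exact multi-atom reference — exactness in many
dimensions is delegated to fixed-centroid PIMD with tight statistical
control.
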