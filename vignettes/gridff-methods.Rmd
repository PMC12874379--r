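---
title: "Grid-projected force fields for rigid substrates: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-projected force fields for rigid substrates: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridff)
```

# The model

`gridff` simulates a flexible molecule adsorbed on a **rigid** crystalline
substrate.  Because the substrate never moves, everything the molecule can
feel from it is a fixed function of space, and can therefore be precomputed
once on 3D grids and interpolated at run time.  The package implements this
idea end to end: grid construction, smooth interpolation with exact
analytic forces, structural relaxation, manipulation scans and
configuration sampling — together with a direct pairwise-sum + Ewald
reference backend used to validate every grid result.

## Pair interactions and factorization

Molecule–substrate dispersion and repulsion use the Morse potential with
Lorentz–Berthelot mixing.  For a molecule atom $i$ and substrate atoms $j$,

$$E_i(\mathbf r_i) \;=\; \sum_j \sqrt{\epsilon_i\epsilon_j}\,
  \Big[ e^{-2\alpha(r_{ij}-R_i-R_j)} - 2\,e^{-\alpha(r_{ij}-R_i-R_j)} \Big],$$

with well depths $\epsilon$ (eV), per-atom radii $R$ (Å, the mixed
equilibrium distance is $R_i+R_j$), and one global stiffness
$\alpha$ (default **1.5 Å⁻¹** for all pairs, with a **17 Å** cutoff).
Because $\sqrt{\epsilon_i\epsilon_j} = \sqrt{\epsilon_i}\sqrt{\epsilon_j}$
and the exponentials factor through $e^{\alpha R_i}$, the sums over
substrate atoms are independent of the probe atom:

$$E_i = \sqrt{\epsilon_i}\,e^{2\alpha R_i}\, G_P(\mathbf r_i)
      \;-\; 2\sqrt{\epsilon_i}\,e^{\alpha R_i}\, G_L(\mathbf r_i),
\qquad
G_{P/L}(\mathbf r) = \sum_j \sqrt{\epsilon_j}\,
   e^{-\{2\alpha,\alpha\}(|\mathbf r-\mathbf r_j|-R_j)} .$$

Only two scalar fields (*Pauli* $G_P$ and *London* $G_L$) are therefore
stored, regardless of how many atom types the molecule or substrate
contains.  The identity between the factorized and the direct form is an
exact algebraic statement and is enforced in the test suite to $10^{-12}$
relative.  Note the square roots: a formulation storing $\epsilon_j$
un-rooted would only be consistent with geometric-mean mixing of
$\epsilon$ if the probe weight also used the full $\epsilon_i$, and would
then not reproduce $\sqrt{\epsilon_i\epsilon_j}$; the rooted convention is
the one compatible with Lorentz–Berthelot mixing.

## Electrostatics

The substrate's electrostatic potential $V(\mathbf r)$ is computed once by
a reciprocal-space Poisson solve and stored as the third grid.  Charges are
spread onto a fully periodic grid (vacuum-padded along $z$) as normalized
Gaussians of width $\sigma$ (default **0.3 Å**, truncated at $6.5\sigma$
and renormalized so every atom deposits exactly its charge), then
$\hat V(\mathbf k) = 4\pi k_e \hat\rho(\mathbf k)/|\mathbf k|^2$ with the
$\mathbf k=0$ mode set to zero (tin-foil convention; the cell must be
neutral).

The Gaussian width plays the role of the Ewald splitting parameter,
$\beta = 1/(\sigma\sqrt2) \approx 2.36$ Å⁻¹: the grid holds exactly the
reciprocal-space part of an Ewald sum, and the omitted real-space residual
is $\mathrm{erfc}(\beta r)/r$, which at every physically reachable
molecule–ion separation ($r \gtrsim 1.8$ Å, enforced by Pauli repulsion)
is below $10^{-8}$ eV.  This is why a reciprocal-only solver reaches
$\sim 10^{-5}$ meV accuracy here: the smearing is fine enough to be
resolved by the 0.1 Å grid (aliasing factor $e^{-(\pi\sigma/h)^2 \cdot 2}
\sim e^{-44}$) yet sharp enough that its near-field correction never
matters.  The accuracy is gated in the acceptance suite against a
fully converged real+reciprocal Ewald oracle, not assumed.

Two practical consequences of the periodic formulation deserve note:

* **Vacuum padding.**  For a laterally periodic slab the potential above
  the surface decays like $e^{-2\pi z/L}$ per lateral harmonic.  The
  default padding (≥ 16 Å above the window) makes spurious $z$-image
  contributions negligible for the 4 Å rocksalt cell; for larger lateral
  cells the padding must grow accordingly (the test suite uses 40 Å for a
  12 Å cell).
* **Plane neutrality.**  Slabs whose atomic planes are individually
  neutral (true for the rocksalt fixtures) contribute no
  $k_\parallel = 0$ modes, so the result is independent of the cell
  height; this is checked by varying the Ewald splitting and padding.

## Interpolation: tricubic B-splines with exact gradients

Each component is represented as a tensor product of 1D cubic B-splines.
Interpolation reads a $4\times4\times4$ coefficient stencil; evaluation
runs innermost along $z$ (the contiguous storage axis), then $y$, then
$x$.  Forces are the *analytic* derivatives of the piecewise-cubic
interpolant — there is no separately stored force grid, so forces and
energy can never disagree.  This is the property that makes NVE dynamics
on the interpolated field conserve energy (tested: drift $< 10^{-4}$ eV/ps
for a bound dimer) and lets FIRE converge below $10^{-4}$ eV/Å thresholds.

B-spline coefficients are not the node values; they solve $B c = f$ where
$B$ is the separable node-interpolation operator (1D stencil
$[1,4,1]/6$, cyclic on periodic axes, repeated-edge on the clamped $z$
axis).  Two solvers ship:

* `fit_coeffs(..., method = "descent")` (default): fixed-step gradient
  descent on the SPD quadratic $\tfrac12 c^TBc - f^Tc$, initialized at
  $c = f$.  The spectrum of $B$ lies in $[1/27, 1]$, so the optimal step
  $2/(\lambda_{\min}+\lambda_{\max}) = 27/14$ gives a contraction factor
  $13/14$ per iteration — node RMS residuals reach $10^{-10}$ (the default
  tolerance) in roughly 200 iterations, far inside the 3000-iteration
  default cap.
* `method = "prefilter"`: the exact separable solve (Thomas algorithm per
  line; Sherman–Morrison cyclic variant on periodic axes).  It is the
  independent reference path; both must agree, and the suite checks
  interpolated values from the two paths to $10^{-8}$ on a toy grid.

Boundary handling: lateral axes are periodic (evaluation folds
coordinates, so any lateral position is valid); $z$ is clamped with
repeated edge coefficients.  Repeated-edge clamping reproduces node values
everywhere but bends the interpolant within $\sim3$ nodes of the edges
(the contamination decays by $\approx(2{-}\sqrt3)$ per node); the grid
window is therefore chosen so that nothing of interest happens near its
edges — the default window spans 0.5–12 Å above the top atomic layer.
Above the window top the surface terms are defined as zero (all fields are
below $10^{-5}$ eV there by construction); below the bottom, evaluation
raises an explicit domain error rather than extrapolating.

## Default grid and why 0.1 Å

The default spacing is **0.1 Å**.  Cubic-spline interpolation error scales
as $(kh)^4/384$ per spatial harmonic $k$; with the rocksalt surface's
dominant harmonic $k = 2\pi/4$ Å⁻¹ and $h = 0.1$ Å this is $\sim10^{-6}$
relative, which is what makes the $10^{-6}$ eV (Morse) and $10^{-5}$ eV
(Coulomb) rigid-scan error budgets attainable.  Coarser grids degrade as
$h^4$; a 0.2 Å grid is used in some tests where only qualitative structure
matters.

# The simulation engine

The molecule is a flexible body with a minimal valence force field:
harmonic bonds ($E=\tfrac k2(r-r_0)^2$), harmonic angles, 3-term cosine
torsions $\sum_m k_m(1+\cos(m\phi-\gamma_m))$, and intramolecular
nonbonded Morse + Coulomb over all pairs except 1-2 and 1-3 (1-4
interactions are at full strength).  The molecular subsystem is never
periodically imaged.  Substrate interactions come either from the fitted
grid (`grid_backend`) or from direct sums (`direct_backend`: Morse over
explicit lateral images within the cutoff, Coulomb via precomputed-
structure-factor Ewald) — every scan driver runs unchanged on either.

**FIRE relaxation** uses the standard published parameters
($\alpha_{\rm start}=0.1$, $f_{\rm inc}=1.1$, $f_{\rm dec}=0.5$,
$N_{\min}=5$, $f_\alpha=0.99$), semi-implicit Euler integration with real
masses, $dt_{\rm init}=0.5$ fs, $dt_{\max}=10\,dt_{\rm init}$, and a
0.2 Å per-step displacement cap.  One deliberate refinement: after the
requested force threshold `f_max` is first met, the optimizer keeps
relaxing down to `settle * f_max` (default 0.1).  Stopping at the first
threshold crossing leaves soft modes (low-barrier torsions) at
trajectory-dependent phases; for warm-started scans that noise — much
larger than the force differences between backends — can flip which
conformer basin the next point falls into, turning backend comparisons
into coin flips at bifurcation points.  Settling makes the endpoint a
well-defined basin minimizer; the `converged` flag still refers to
`f_max`.  With this, the grid and reference backends track identical
branches through an entire 188-point relaxed pull, and their energy
difference measures grid fidelity rather than optimizer chaos (the
acceptance suite verifies the sub-0.9 meV agreement; the measured value is
unchanged when the whole scan is instead run at 10× or 100× tighter
thresholds).

**Langevin dynamics** uses a BAOAB-split leapfrog with the exact
Ornstein–Uhlenbeck update for the friction/noise step; with $\gamma=0$,
$T=0$ it reduces to velocity Verlet.  Defaults $\gamma = 0.01$ fs⁻¹ and
$dt = 0.5$ fs are engine knobs, not physical claims; equipartition of the
sampled kinetic energy to $k_BT/2$ per degree of freedom is verified to
5 %.  Noise comes from a counter-based RNG (hash of seed, replica stream
and step counter), so every replica's trajectory is bitwise reproducible
and independent of how many replicas run alongside it.

**Replica batches** share one read-only field and evolve independently —
the observable semantics of a many-replica GPU layout, kept as the
contract here without the kernel machinery.

# Experiment drivers

* `rigid_z_scan` / `rigid_lateral_scan`: rigid-body translations recording
  the (bonded, intramolecular-nonbonded, surface-Morse, surface-Coulomb)
  decomposition; the lateral map covers one surface cell with periodic
  folding.
* `relaxed_pull`: one anchor atom is restrained and stepped along $z$
  (default 0.1 Å), all other atoms FIRE-relaxed at every point,
  warm-started from the previous geometry (cold start available).
  Non-converged points are flagged and kept, never dropped.
* `drag_scan`: the anchor is stepped along a lateral direction; besides
  the profile it records the anchor's straight path and the trajectory of
  a free reference atom, whose lateral deviation is the stick–slip
  signature.
* `minima_hop`: replicas alternate `n_md` Langevin steps at temperature
  `T` (defaults 1000 steps, 300 K) with FIRE relaxation to 0.1 meV/Å;
  converged minima enter a catalogue deduplicated by RMSD.

**RMSD uniqueness** is computed in the absolute surface frame with *no*
rotational or translational superposition, threshold 0.1 Å: two copies of
the same conformer on different adsorption sites, or differently oriented,
count as distinct minima.  This is deliberate — the catalogue enumerates
adsorption configurations, not conformers.  Folding by a lattice vector
before comparison is available as an opt-in flag (`fold_cell`) and is what
the exhaustive-start oracle test uses to compare site catalogues.  After
each relaxation a replica is re-thermalized from its relaxed geometry
(rather than re-seeded elsewhere); this keeps the walk local and is the
documented default.

# Synthetic fixtures — what they emulate and what they do not

`build_rocksalt_slab(nx, ny, nlayers)` builds the rigid ionic substrate:
an $a\times a$ surface cell ($a = 4$ Å) with one Na⁺ and one Cl⁻ per
layer (charges $\pm0.9e$), layers stacked at $a/2$ with alternating
registry, top layer at $z=0$.  An 8×8×3 slab has 384 atoms and a 20×20×3
slab 2400.  `introduce_vacancy_pair` removes the nearest-neighbour
cation–anion pair closest to the centre of the top layer, leaving a
neutral point defect.  Because the substrate is rigid, substrate–substrate
energetics never enter any computed quantity; the fixture's role is to
generate realistic *fields* (alternating-charge electrostatics with
$e^{-2\pi z/L}$ decay, Morse corrugation), not bulk NaCl physics.

`make_probe_molecule` generates neutral probes deterministically from a
seed: `rigid-planar` (a carbon ring with alternating ±0.05 e partial
charges, used rigidly), `flexible-chain` (a zig-zag carbon chain, bond
1.53 Å, angle 111°, alternating ±0.1 e charges, low torsion barriers —
deliberately floppy so that relaxed scans exercise conformational
response), and `polyol-chain` (oxygen side groups carrying ±0.3 e pairs,
an H-bond-like charge pattern).  These stand in for real adsorbates whose
geometries and fitted charges are external data; they reproduce the
*structure* of the problem (many soft degrees of freedom over a corrugated
ionic surface) but none of the chemistry of any specific molecule.
Passing tests therefore demonstrate method fidelity — grid vs direct-sum
agreement, energy conservation, catalogue completeness — on molecules of
this class, not predictions for a particular experimental system.

The per-element nonbonded table shipped in
`inst/extdata/uff_elements.dat` carries standard UFF-derived constants
(well depths converted from kcal/mol; radii are half the UFF vdW
distance); they are editable external constants, and all accuracy gates
compare like against like, so they are insensitive to the exact values.

# Numerical choices and degenerate inputs

* Units: eV, Å, e, fs everywhere; $k_e = 14.399645$ eV·Å/e²;
  masses in eV·fs²/Å² (1 amu = 103.6427).
* Morse cutoff: plain truncation at 17 Å; the discontinuity is
  $\sim\epsilon\,e^{-\alpha r_c} < 10^{-10}$ eV and both backends truncate
  identically.
* Ewald truncations are chosen from the requested tolerance (per-mode
  bounds with a 100–1000× safety margin) and validated by
  splitting-parameter invariance ($<10^{-4}$ meV under $\beta$ changes).
* Overlapping atoms ($r<10^{-6}$ Å), zero bond lengths, non-neutral cells,
  nodes coinciding with atoms, out-of-range topology indices and
  mismatched RMSD shapes are rejected with explicit errors.
* Collinear torsion quadruples are skipped (their dihedral is undefined
  and their force is zero by symmetry).
* Grid containers are a single file: one JSON header line (spec, α,
  cutoff, substrate hash, dtype, endianness) followed by raw little-endian
  float64 arrays in z-fastest order; loaders validate representation flags
  and payload lengths.

# Problem sizes used by the tests

The suite and the acceptance script run on the NaCl unit cell
(1×1×3 = 6 atoms) at the production 0.1 Å spacing — grid construction and
fitting take seconds, yet every accuracy gate (fit residuals ≤ 10⁻⁵,
0.01 meV electrostatics, 10⁻⁶/10⁻⁵ eV rigid-scan budgets, 0.9 meV relaxed
pulls over 188 points) is evaluated at full production settings.  Larger
supercells (up to 20×20×3 = 2400 atoms) are exercised for fixture
counts and defect scans at 0.2 Å spacing, where only geometric structure
matters.  These sizes are the package's reference configurations; the
methods scale to larger substrates with memory as the only practical
limit.

# Known limitations

* The substrate is perfectly rigid: no polarization, no deflection, no
  three-body terms.  This is the method's core assumption, not an
  implementation shortcut.
* Memory grows with the supercell for non-periodic (defective) surfaces,
  since the grid must span the full supercell laterally.
* The valence force field is minimal (harmonic + cosine); it is a carrier
  for flexibility, not a calibrated chemistry model.
* Warm-started relaxed scans can still bifurcate for molecules with
  near-degenerate conformers when the energy gap between branches exceeds
  the optimizer's settled noise floor; the profiles then genuinely differ
  and the convergence flags plus stored geometries make this visible.
* The electrostatic solve requires a neutral substrate cell; charged
  defects would need a compensating background, which is not implemented.
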