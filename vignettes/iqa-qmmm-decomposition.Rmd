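---
title: "IQA energy decomposition for QM/MM systems: models, numerics, conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IQA energy decomposition for QM/MM systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters, the numerical
design choices, and the limits of what passing tests demonstrate.

## The decomposition model

QTAIM partitions space into atomic basins $\Omega_I$, the attraction
basins of $\nabla\rho$.  The package decomposes a closed-shell QM energy
as

$$E^{QM} = \sum_I E^I_{net} + \sum_{I<J} E^{IJ}_{int},
  \qquad E^{IJ}_{int} = E^{IJ}_{ele} + E^{IJ}_{xc},$$

with $E^I_{net} = T_I + V^{II}_{ne} + V^{II}_{ee}$ integrated over
$\Omega_I$ and the pair terms collecting the nucleus–nucleus,
nucleus–electron and electron–electron interactions between two basins.
The electron pair density is split as
$\rho_2(r_1,r_2) = \rho(r_1)\rho(r_2) + \rho_{xc}(r_1,r_2)$; for a
closed-shell single determinant
$\rho_{xc} = -\tfrac12\rho_1(r_1,r_2)^2$, which is also the working
definition applied to Kohn–Sham orbitals.  Because the HF-like exchange
of a DFT determinant does not integrate to the functional's
exchange-correlation energy, `scale_dft_xc()` applies one global factor
$\kappa$ to all intra- and inter-basin xc terms so the reconstructed
total matches the SCF energy exactly; $\kappa$ is recorded on the term
object and in every report.  This global rescaling is a deliberately
simple, fully documented choice — per-term scaling schemes exist in the
literature and could be plugged in, but no claim of equivalence to them
is made.

Kinetic energies use the positive-definite (gradient) form
$\tfrac12\sum_i n_i|\nabla\phi_i|^2$.  For exact basins it agrees with
the Hamiltonian form; on numerical basins the difference lands in the
reported reconstruction residual rather than being absorbed silently.

Additive energies take half of every pair interaction
(`half_share`); for QM/MM energies the alternative `qm_full_qmmm`
convention ascribes each QM–MM pair term wholly to the QM atom, which is
the convention under which relative (binding) energies of rigid
geometries close exactly over the QM atoms alone.  Both conventions are
labelled in reports; the consistency checker uses the one in which the
closure identity is exact.

## Basins and quadrature

The numerical design differs from classic atomic-quadrature codes in
three places, each forced by measured accuracy on the packaged fixtures:

* **Angular rules.** Product Gauss–Legendre ($\cos\theta$) × uniform
  ($\varphi$) rules, exact to the polynomial degree of the familiar
  Lebedev rule sizes in which presets are declared.  A product rule of
  equal degree uses about 1.5× the points of the corresponding Lebedev
  rule; it is used here because its node sets are generated in closed
  form rather than from coefficient tables.
* **Radial rules.** Gauss–Legendre inside the β-sphere (always interior
  to the basin, never crossed by the interatomic surface) and a
  composite midpoint (Euler–Maclaurin-style) cell rule outside, under
  the map $r = r_\beta + (r_{max}-r_\beta)t^2$.  Cells — not abstract
  nodes — matter at the basin boundary: the crossing radius of the
  interatomic surface along each ray is located by bisecting the
  gradient-ascent assignment, the straddling cell's weight is split
  fractionally between the two basins, and the fraction is refined by
  four sub-rays spread over the angular cell.  This removes the
  leading-order masking bias of pointwise node assignment (measured at
  several 10⁻³ e per basin on H₂ at working resolution before the fix).
* **A Becke partition of unity across the overlapping atom-centred
  grids.** Every node carries the smooth partition weight of its owning
  grid, so node-sum integrals route each region of space to the grid
  centred there — sharp features near a nucleus are always sampled by
  that nucleus's own $r^2$-weighted radial rule.  The partition is an
  exact regrouping (weights sum to one), so it introduces no model
  error, and whole-space sums over basins reproduce the molecular
  quadrature identically.

Two-electron terms use single-center Laplace (real spherical-harmonic)
expansions rather than six-dimensional double-grid sums: every
basin-masked density and occupied orbital-pair product is projected
shell by shell onto $Y_{lm}$ on each grid of the Becke partition, the
radial Poisson problem is solved per $(l,m)$ by cubic-spline cumulative
integrals (the $r_<^l/r_>^{l+1}$ kernel kink falls on interval
boundaries, so each piece is smooth — partial sums of a plain quadrature
rule here cost about 2×10⁻⁴ relative accuracy, which the oxygen core
amplifies to 10⁻² hartree), and the superposed potentials are evaluated
at all nodes and nuclei.  Because the basin masks sum to one, the
mask-induced high-harmonic content cancels between basins in every
total: reconstruction residuals are protected by construction, and
truncation at $\lambda_{max}$ affects only the intra/inter split.  A
direct double-grid summation path (`ee_method = "doublesum"`) is kept
for cross-checks; it converges only first-order in grid spacing at the
interatomic surface, which is the documented reason the production path
is the expansion one.

Electron–nucleus attractions are integrated as direct node sums (the
nuclei sit close to basin boundaries, where the truncated harmonic
series of a masked density Gibbs-oscillates, while the node
representation stays robust).

**Basin assignment** is adaptive backtracking gradient ascent from each
outside node, captured on entry into any β-sphere.  Exact separatrix
points (vanishing gradient) resolve deterministically to the lowest
attractor index; nodes below the density floor of 10⁻¹² au are assigned
to the nearest attractor and flagged.  Non-nuclear attractors found by
the critical-point search would enter as pseudo-atoms; none occur on the
packaged systems.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| preset | `"desk"` | 194/110-point angular rules outside β-spheres (heavy/H), 110/50 inside; 96/64 radial cells outside/inside for heavy atoms (80/56 for H); $r_{max}$ 12/9 bohr |
| `lmax` | 10 (6 inside) | Laplace/bipolar expansion order of $1/r_{12}$ |
| `screen_threshold` | 10⁻⁶ au | per-basin orbital selection by diagonal atomic overlap |
| `beta_fraction` | 0.6 | β-sphere radius as a fraction of the nucleus–BCP distance |
| `xc_rcut` (multipolar mode) | 17 au | beyond this separation $E_{xc}$ is neglected |
| PB `spacing` | 0.33 Å | finite-difference lattice |
| PB dielectrics | 1 / 80 | solute / solvent |
| probe | 1.4 Å | SAS/SAV constructions |
| `p` (cavity) | 0.069 kcal/(mol Å³) | solvent pressure parameter |
| `rho_w` | 0.03343 Å⁻³ | water number density in the surface-dispersion kernel |

The `"paper"` preset stores production-grade settings (5810/974-point
angular declarations, 512/384 radial, $r_{max}$ 15/10 bohr) for large
systems; the packaged fixtures do not need it.  The `"desk"` problem
sizes used throughout the tests — three-atom molecules, ~7×10⁴
quadrature nodes, ~30 s per water decomposition — were chosen as the
smallest grids whose reconstruction residuals sit comfortably below
10⁻³ hartree on the packaged wavefunctions.

## QM/MM coupling

Electrostatics is basin-integrated against MM point charges with the
same machinery as the electron–nucleus terms; the summed pair matrix
reproduces the unpartitioned Coulomb integral of the full QM density to
quadrature accuracy (an identity test on every fixture).  Covalent
boundaries follow the hydrogen link-atom convention: the link hydrogen
participates in QM electrostatics as a source basin, while MM sites
bonded directly to a QM host are excluded (their role is taken by the
link atom).  vdW terms use the Amber Lennard-Jones convention
($r_{min}$, geometric ε, arithmetic combination) with the topology's
exclusion list and 1–4 divisors (1.2/2.0 by default); whether 1–4
scaling applies across a QM–MM boundary follows the topology's own
records, since force-field exports differ on this point.  No cutoffs are
applied to nonbonded sums.  MM bond/angle/torsion records split
atomically as exact ½/⅓/¼ shares; relative-energy workflows drop the
purely-MM blocks, which cancel for fixed geometries.

## Dispersion

The D3 model with Becke–Johnson damping is implemented in full:
smooth coordination numbers, Gaussian-weighted interpolation of pair C6
coefficients over tabulated reference points, $C_8 = 3C_6\sqrt{Q_iQ_j}$,
and $-s_6C_6/(R^6+f^6) - s_8C_8/(R^8+f^8)$ with
$f = a_1\sqrt{C_8/C_6}+a_2$.  The three-body term is omitted (only
pairwise terms merge into the diatomic matrix).  Dispersion defaults to
QM-region pairs only — the MM side already carries LJ dispersion — with
the merge left to the caller for other choices.  **Data provenance:**
the covalent radii and the B3LYP/PBE0 damping sets are published values;
the per-element C6 reference tables and multipole factors shipped in
`inst/extdata/d3/*_synthetic.csv` are synthetic stand-ins with
representative magnitudes, generated by `data-raw/make_d3_data.R`.  They
exercise the complete machinery and can be replaced file-for-file by the
published tables (same CSV schema); numerical agreement with reference
dispersion programs is *not* claimed with the synthetic tables, and the
dispersion tests therefore check invariants and an independent
direct-summation oracle over the same data.

## Solvation

The polar term solves the Poisson equation twice on one finite-difference
lattice (solvent dielectric outside the cavity vs the solute dielectric
everywhere); the reaction field is the difference at the atom positions,
which cancels the lattice self-energy.  Charges spread trilinearly; edge
dielectrics use the harmonic mean over a 9-point sampling of each edge
(the exact series composition of a piecewise-uniform edge), which brings
the Born-ion error to ~0.2% at 0.33 Å spacing.  The dielectric boundary
follows the site PB radii as given (Bondi values by default) — callers
wanting a probe-inflated boundary simply pass inflated radii.  Only the
pure Poisson limit (zero ionic strength) is supported.  The atomic polar
term adopts the linear-response convention $\tfrac12 q_I\Phi_{RF}(R_I)$,
recorded in output metadata.

Nonpolar terms: per-atom solvent-accessible volumes (voxel integration,
nearest-inflated-surface assignment, exact sum) scale the cavity term
$pV_I$; the attractive solute–solvent $r^{-6}$ interaction over the
solvent region is evaluated by its divergence-theorem surface form on a
deterministic Fibonacci-lattice SAS, with the water-oxygen LJ site
defining the per-solute-atom attraction coefficient.  The raw pair terms
$G^{IJ}$ are not symmetric; the symmetrized
$G'^{IJ} = (G^{IJ}+G^{JI})/2$ conserve the total exactly and are what
enters $G^I_{solv} = G^I_{pol} + pV_I + \sum_J G'^{IJ}$.

ESP-fitted charges for the QM region use a cubic-lattice shell between
per-element exclusion radii and a 2.8 Å cutoff, a least-squares fit with
the total charge enforced exactly by a Lagrange multiplier, and the
package's own density quadrature for the electronic potential.

## Scoring

`qmmm_pbsa_score()` differences per-species component vectors,
$\Delta G = G(\mathrm{cmplx}) - G(\mathrm{enz}^*) - G(\mathrm{inh}^*)$,
with the starred species at their in-complex geometries.  The optional
$-3RT$ term (six translational/rotational degrees of freedom lost on
binding, −1.789 kcal/mol at 300 K) defaults to off, so printed component
sums reproduce scoring tables exactly; absolute free energies turn it
on.  Fragment regrouping (`iqf_regroup`) conserves the atomic totals to
machine precision for any atom-to-fragment map, and
`fragment_additive_energy` composes the standard
$\Delta E_{net} + \Delta G_{solv} + \tfrac12\Delta E_{int}$ fragment
summary.

## What the synthetic systems do and do not show

The analytic spherical-Gaussian systems give closed-form populations,
cloud–cloud Coulomb energies (error functions) and dipoles — they
validate quadrature, assignment and bookkeeping, but their densities
have no core structure, no shell structure and featureless separatrices.
The packaged HF/B3LYP wavefunctions (H₂, He, HeH⁺, H₂O up to
cc-pVTZ) add real cores and polar bonds; they are still three-atom
molecules, so passing tests bound quadrature errors only at that scale.
The metal-ion/water cluster generator reproduces the geometric
conditions of hydrated-cation studies (octahedral first shell, rigid
three-site waters, TIP3P charges, shell series 6/12/24/48/96) but the
packaged wavefunctions do not cover those cluster sizes — cluster runs
exercise geometry, tagging, masks and MM terms, not converged QM
energetics.  The toy host–guest complex exercises the full scoring
pipeline end to end with exact bookkeeping, not chemistry.

## Known limitations

* Closed-shell, single-determinant wavefunctions only; open-shell input
  is rejected loudly.  No correlated pair densities.
* Cartesian Gaussian basis functions up to f; spherical-harmonic Molden
  exports are rejected with a pointer to re-export in Cartesian form.
* The intra/inter split of two-electron terms carries the
  $\lambda_{max}$ truncation error of masked densities (totals are
  protected); bonded-pair terms are reliable to ~10⁻³ hartree at the
  `desk` preset, not to the 10⁻⁴ level of the totals.
* The global DFT xc scaling recovers the total exactly but distributes
  the correction proportionally to the HF-like terms.
* No periodic systems, no Ewald electrostatics, no polarizable MM, no
  salt (nonlinear Boltzmann) term, no interatomic-surface triangulation.
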