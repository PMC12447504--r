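---
title: "Methods: a hybrid semilocal + physics-based long-range force field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hybrid semilocal + physics-based long-range force field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridff)
```

## The model

`hybridff` decomposes the potential energy of a molecular system into four
terms,

$$E_\mathrm{pot} = E_\mathrm{ZBL} + E_\mathrm{semilocal} + E_\mathrm{elec} + E_\mathrm{disp},$$

combining a learned semilocal many-body term with universal, physically
motivated pairwise interactions. The semilocal model predicts three atomic
quantities from positions $R$, atomic numbers $Z$, total charge $Q$ and total
spin $S$: atomic energies $E_i$, raw partial charges $q_i$ and Hirshfeld
ratios $h_i$ (atom-in-molecule effective volume over free-atom volume). The
charges and Hirshfeld ratios parametrize the two long-range terms, so all
four terms are coupled: displacing an atom changes its predicted $q_i$ and
$h_i$ and thereby the long-range energies. Forces are the exact negative
gradient of the composed scalar including these couplings; since R has no
automatic differentiation, the package implements a hand-written reverse-mode
(vector-Jacobian) pass through the message-passing network, verified against
central finite differences to better than $10^{-5}$ relative error.

Supported elements are the eight predominant in biosystems: H, C, N, O, F,
P, S, Cl.

### Nuclear repulsion (ZBL)

At very short range the energy follows the universal screened-Coulomb
Ziegler--Biersack--Littmark form
$E_{ij} = \frac{Z_i Z_j e^2}{4\pi\varepsilon_0 r}\,\varphi(r/a_{ij})$ with the
standard 4-exponential screening function and screening length
$a_{ij} = 0.46850/(Z_i^{0.23}+Z_j^{0.23})$ Å. A cosine switch takes the term
smoothly ($C^1$) to zero between 1.5 and 2.0 Å. All constants live in
`zbl_config()` and can be overridden, so a refit parametrization can be
dropped in without code changes.

### Electrostatics

Point charges interact through an erf-damped Coulomb potential,
$E_\mathrm{elec} = k_e \sum_{i<j} q_i q_j\, \mathrm{erf}(r_{ij}/\sigma)/r_{ij}$,
which is finite at $r=0$ (the limit is $2/(\sigma\sqrt\pi)$ per unit charge
product) and exactly Coulombic for $r \gg \sigma$. Raw model charges are
projected onto the total-charge constraint by a uniform shift
(`project_charges()`), the simplest projection whose Jacobian
($I - \mathbf{1}\mathbf{1}^\top/N$) is applied analytically in the force
chain rule. Dipoles for training are taken about the center of nuclear
charge, which is well defined for ions; for neutral systems the dipole is
origin-independent. The default damping width is $\sigma = 1$ Å,
config-exposed, with `calibrate_damping()` available to tune it against
dimer-scan references. Real-space truncation uses a per-pair energy shift to
zero at the long-range cutoff (12 Å by default); particle-mesh Ewald is out
of scope.

### Dispersion

Dispersion uses a damped interatomic multipole series,
$E_\mathrm{disp} = -\sum_{i<j}\sum_{n=3}^{5} C_{2n}^{ij}/(r_{ij}^{2n} + R_{d,ij}^{2n})$,
finite at $r = 0$ and asymptotically $-C_6/r^6$. Per-atom parameters come
from Tkatchenko--Scheffler volume scaling of free-atom references
($\alpha_i = h_i\,\alpha^\mathrm{free}$, $C_6^{ii} = h_i^2\,C_6^\mathrm{free}$;
Chu--Dalgarno values stored in `free_atom_reference()`), combined across
atoms with the TS combination rule. The damping radii derive from
polarizabilities,
$R_{d,ij} = 2\gamma\,(\alpha_\mathrm{fsc}^{-4/3}\,\bar\alpha_{ij})^{1/7}$ in
atomic units, with $\gamma$ the single tunable damping strength (default 1).
Higher orders follow quantum-Drude-oscillator scaling:
$C_8 = c_8\, C_6 R_\mathrm{vdW}^2$ with $c_8 = 0.48$ chosen once to
reproduce the hydrogen $C_8/C_6$ ratio (about 19 a.u.) with the pair radius
above, and $C_{10} = \tfrac{49}{40}\,C_8^2/C_6$, which enforces the exact
Drude-model universality $C_{10}C_6/C_8^2 = 49/40$. Both constants are
config-exposed. A useful identity: for TS-scaled inputs the combination rule
collapses to $C_6^{ij} = h_i h_j\, C_6^{ij,\mathrm{free}}$, which the
implementation exploits for clean analytic $\partial E/\partial h$.

One subtlety about asymptotics: at $r = 5R_d$ the damped series matches the
*undamped* multipole sum to about $6\times10^{-5}$ relative (that is the
damping correction $R_d^6/r^6$), but it still differs from the bare
$-C_6/r^6$ term by a couple of percent because $C_8$ and $C_{10}$ are
physically sizable there. The package's tests therefore check the damping
asymptote at $5R_d$ and the pure $-C_6/r^6$ limit at much larger separation
($40R_d$), where it genuinely holds.

### The semilocal reference model

The full production-scale equivariant architecture is out of scope; the
package ships an interface-compatible reference model: an invariant
message-passing network over radial-basis edge features (Gaussians times a
$C^1$ cosine envelope that vanishes at the local cutoff). Atom embeddings are
initialized per element; the total charge and spin enter as normalized global
features ($Q/N$, $S/N$) added to every embedding, the minimal conditioning
contract. After $T$ interaction layers the readout heads produce $E_i$,
$q_i$, and $h_i$, the last through a softplus so $h_i > 0$ always. The
receptive field is bounded by `r_local * layers` (`effective_cutoff()`):
with the default 4.5 Å and 3 layers, 13.5 Å. Outputs are invariant under
rigid motions, equivariant under atom permutation, and bit-reproducible from
the spec seed. Tests exercise a reduced 16-feature, 2-layer model; the
defaults mirror the production configuration (128 features, 3 layers).

## Training

The combined loss is a per-structure-normalized sum of force, dipole and
Hirshfeld terms with trade-off weights $\lambda_F, \lambda_\mu, \lambda_h$
(defaults 1, 0.01, 0.01; the force term is per-atom averaged, the dipole
term is not). The partial charges are trained only indirectly through
dipoles. Training is force-only by design for the energy head: forces never
constrain the per-element energy offsets, so only relative energies are
identifiable — the package asserts exactly that (relative conformer energies
recovered, absolute offsets unconstrained).

A deliberate design choice keeps training CPU-friendly: the trainable
parameters are the readout heads over the seeded message-passing trunk held
fixed (a random-features design). With a fixed trunk the force and dipole
losses are exactly quadratic in their head weights, so gradients are analytic
and cheap: the per-structure feature-to-force maps are precomputed once with
$F$ reverse-mode passes and every optimizer step is pure linear algebra.
Optimization uses Adam with exponential learning-rate decay, full batch, and
is fully deterministic. Training the trunk itself would require second
derivatives of the network for the force loss, which is out of proportion
for a desk-scale reference implementation; the recovery experiments in the
test suite (teacher--student with shared trunk) are designed to be well-posed
under this restriction.

`calibrate_damping()` recovers $(\gamma, \sigma)$ by grid search on
interaction-energy errors over rigid dimer scans, with a deterministic
tie-break toward the smallest $\gamma$, then $\sigma$.

## Molecular dynamics

`run_md()` drives velocity-Verlet NVE, Langevin NVT (kick--drift--OU--drift--kick
splitting; with zero friction it reduces exactly to velocity Verlet), and an
isotropic NPT that combines the Langevin thermostat with Berendsen-style cell
rescaling from the instantaneous pressure (kinetic part plus pair virial, or
a volume finite difference for calculators without one). These integrators
are simple, stable and testable; they are not claimed to be equivalent to any
particular production thermostat/barostat. The default time step is 1 fs;
temperature is defined over $3N$ degrees of freedom.

An untrained (randomly initialized) semilocal term plus ZBL is net repulsive
at bonded distances, so chemically drawn structures are far from equilibrium
of the *composed* potential. Conservation experiments therefore first relax
to a local minimum (`relax_structure()`, backtracking steepest descent) and
then integrate; the shipped check holds energy drift below 1 meV/atom over
2000 steps at dt = 0.5 fs on a water trimer.

## Observables

The trajectory toolkit implements volume-normalized radial distribution
functions; self-diffusion from time-origin-averaged mean-squared
displacements (coordinates unwrapped by per-step minimum-image increments,
$D$ = slope/6, with an $R^2$ diagnostic that flags non-diffusive input);
Ramachandran free-energy surfaces by Boltzmann inversion
($F = -k_BT\ln p$, minimum shifted to zero, empty bins $+\infty$, kcal/mol);
lag-resolved optimal-superposition (Kabsch) RMSD excluding hydrogens by
default; vibrational power spectra from the Hann-windowed mass-weighted
velocity autocorrelation, reported in cm$^{-1}$ up to the Nyquist limit (at
a 2.5 fs frame interval, about 6671 cm$^{-1}$); C--H order parameters
$S_{CD} = \langle (3\cos^2\theta - 1)/2\rangle$; and bilayer metrics — the
head-to-head thickness $D_{HH}$ from the two maxima of the headgroup density
profile along $z$ (0.5 Å bins, quadratic sub-bin peak interpolation) and the
time-averaged area per lipid $\langle L_xL_y\rangle/(N_\mathrm{lip}/2)$.
Observables referencing the bilayer normal are, by construction, not
rotation-invariant; all others are.

## Chemical-space coverage: atom-environment orbits

The diversity a training set must cover can be summarized by *orbits*:
equivalence classes of atoms whose labeled environments up to a graph-distance
cutoff are isomorphic, pooled across molecules. `orbit_count()` compares
rooted induced subgraphs of radius `depth` via iterative label refinement to
a fixpoint, with exact VF2 isomorphism resolving rare signature collisions;
a brute-force pairwise-isomorphism oracle in the test suite confirms the
partition on all shipped fixtures.

The convention was chosen deliberately and is pinned by a fixture. By
default the comparison runs on the heavy-atom skeleton — hydrogens implicit,
exactly as in molecular graphs derived from line notations (the natural
graph for SMILES-sourced libraries), with `include_hydrogens = TRUE`
available for explicit-hydrogen analyses (methane then has two orbits: one
C, one H). Under the heavy-atom convention the uncapped alanine tetrapeptide
(Ala)$_4$ has exactly **10** orbits at depth 2, robustly across protonation
states (neutral, cationic, anionic, zwitterionic all give 10), and the
classes are chemically transparent: one orbit for all four side-chain
methyls, one for the three backbone carbonyl carbons, one for the three
amide nitrogens, distinct classes for the termini and for the C$_\alpha$
positions 1, 2--3, and 4. We verified exhaustively (ball radii 1--3, label
refinement depths 1--4, element and element+H labels, capped and uncapped
variants) that no explicit-hydrogen convention yields 10 on a realistic
tetrapeptide topology, so the heavy-atom reading is the one that reproduces
the printed figure — and it is consistent with treating a tetrapeptide as a
length-4 sequence, as the companion coverage arithmetic does
(`sequence_space_size(20, 4) * 1000` conformations = 160 million;
10 orbits × 100 conformations per orbit = 1000).

The shipped `alanine_tetrapeptide` fixture is therefore uncapped
H--(Ala)$_4$--OH (43 atoms); the capped Ac--Ala$_3$--NMe variant (42 atoms),
conventionally also called an alanine tetrapeptide in the simulation
literature, is available as the `acala3nme` fixture and is used for
dihedral-metadata and dynamics tests.

## Synthetic generators and what they do (not) show

All test inputs are generated in code, bit-reproducibly from seeds:
jittered-lattice periodic water boxes at a target density (rigid gas-phase
geometry, 0.9572 Å / 104.52°, 0.1 Å jitter, O--O clash guard at 2.2 Å),
compact water clusters, rigid dimer scans, idealized-internal-coordinate
peptides (standard bond lengths and angles, extended backbone), a toy lipid
slab, and composer-labeled training sets whose forces are the exact analytic
gradients of the generating potential. These emulate the *inputs* of
production datasets, not their quantum-mechanical labels: passing tests
demonstrates the machinery (energies, exact forces, training, integrators,
estimators) is correct, not that the shipped random-initialization model is
chemically accurate. Reproducing published accuracy metrics would require
the pretrained production model and reference quantum data, both outside
this package's scope.

## Numerical choices and problem sizes

- Units: Å, eV, e, fs, amu, K externally; dispersion internals in Hartree
  atomic units; every conversion constant lives in `ff_constants`.
- Neighbor lists are vectorized all-pairs half lists (i < j); the
  minimum-image bound (cutoff at most half the smallest perpendicular cell
  width) is enforced with an explicit error. At the package's desk scale
  (up to a few thousand atoms) cell lists are unnecessary.
- Long-range cutoff 12 Å with per-pair energy shift (forces are $C^0$ at the
  cutoff; the residual force step there is negligible at 12 Å).
- Finite-difference verifications use central differences with step
  $10^{-4}$ Å ($10^{-6}$ Å where the ZBL core makes curvature extreme).
- Test problem sizes: 10-atom random systems for force consistency (20
  replicates), a water trimer for 2000-step conservation runs, 10--12
  peptide conformers for training recovery, and trajectories of a few
  hundred frames for the estimator checks. These sizes keep the entire
  suite around half a minute while leaving every scientific property
  observable.

## Known limitations

- The semilocal reference model is invariant (distance-based), not
  equivariant, and its trunk is not trained; it preserves the interface and
  coupling structure, not the accuracy, of a production model.
- Electrostatics are leading-order point charges with real-space truncation;
  no Ewald/PME, no multipoles.
- The barostat is isotropic only; no constraint algorithms (rigid water is a
  fixture geometry, not a dynamical constraint).
- `coverage_estimate()` uses double-precision integers (exact below
  $2^{53}$) and warns beyond.
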